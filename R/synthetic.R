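# Synthetic EEG with known microstate structure, band-limited rhythms and
# subject-level questionnaire scores. Everything is seed-reproducible and the
# ground truth (run table, templates, signs) travels with each recording.

#' Generator configuration
#'
#' Describes one synthetic recording: the number of quasi-stable states and
#' their mean dwell times, the global-field-power envelope scale, the sensor
#' noise level, and optional band-limited oscillations.
#'
#' Oscillations are given as a list of entries
#' `list(low_hz=, high_hz=, amplitude_uv=, channels=)`; each is rendered as a
#' sinusoid at a frequency drawn uniformly inside the band, with a fixed
#' sum-to-zero spatial weight pattern (unit mean-square over the carrying
#' channels) so that average referencing leaves it untouched. `channels = NULL`
#' means all channels.
#'
#' @param n_states number of microstate classes (default 4).
#' @param mean_durations_ms mean dwell time per state in ms (all > 0).
#' @param gfp_scale_uv scale of the GFP envelope in microvolts.
#' @param noise_sd_uv standard deviation of white sensor noise in microvolts.
#' @param oscillations list of oscillation specs (see Details).
#' @param fs_hz sampling rate; must exceed twice the highest oscillation edge.
#' @param length_s recording duration in seconds.
#' @param envelope_freq_hz frequency of the rectified-sinusoid GFP envelope.
#' @param envelope_floor relative floor added to the rectified envelope so
#'   that GFP never vanishes (keeps peak picking well defined).
#' @param min_duration_ms minimum dwell time of the truncated-geometric run
#'   law (runs are `min + geometric tail`, with the tail tuned so the mean
#'   equals `mean_durations_ms`); capped at half the state's mean.
#' @param seed integer seed.
#' @return A validated list of class `ms_gen_config`.
#' @export
gen_config <- function(n_states = 4,
                       mean_durations_ms = c(60, 80, 100, 120),
                       gfp_scale_uv = 9,
                       noise_sd_uv = 2,
                       oscillations = list(),
                       fs_hz = 512,
                       length_s = 60,
                       envelope_freq_hz = 5,
                       envelope_floor = 0.2,
                       min_duration_ms = 30,
                       seed = 1L) {
  if (length(mean_durations_ms) == 1L) {
    mean_durations_ms <- rep(mean_durations_ms, n_states)
  }
  if (length(mean_durations_ms) != n_states) {
    stop_invalid("need one mean duration per state")
  }
  if (any(mean_durations_ms <= 0)) stop_invalid("mean durations must be > 0")
  if (fs_hz <= 0 || length_s <= 0) stop_invalid("fs_hz and length_s must be > 0")
  if (noise_sd_uv < 0 || gfp_scale_uv <= 0) {
    stop_invalid("gfp_scale_uv must be > 0 and noise_sd_uv >= 0")
  }
  for (o in oscillations) {
    if (o$low_hz >= o$high_hz) stop_invalid("oscillation band low < high required")
    if (fs_hz <= 2 * o$high_hz) {
      stop_invalid("fs_hz must exceed twice the highest oscillation frequency")
    }
  }
  structure(
    list(n_states = as.integer(n_states),
         mean_durations_ms = as.numeric(mean_durations_ms),
         gfp_scale_uv = gfp_scale_uv, noise_sd_uv = noise_sd_uv,
         oscillations = oscillations, fs_hz = fs_hz, length_s = length_s,
         envelope_freq_hz = envelope_freq_hz, envelope_floor = envelope_floor,
         min_duration_ms = min_duration_ms,
         seed = as.integer(seed)),
    class = "ms_gen_config"
  )
}

#' Generate spatially smooth, mutually orthogonal template topographies
#'
#' Draws `k` smooth random scalp maps (a Gaussian process over electrode
#' positions with squared-exponential covariance), removes the channel mean
#' from each, orthogonalizes them within the zero-mean subspace, and scales
#' each to unit global field power. Orthogonality makes the pairwise spatial
#' correlation exactly zero, satisfying the near-orthogonality contract
#' (|r| <= 0.3); real microstate templates are merely weakly correlated, a
#' deliberate idealization documented in the methods vignette.
#'
#' @param montage an `ms_montage`.
#' @param k number of templates (2 <= k < n_channels; the zero-mean
#'   constraint removes one degree of freedom).
#' @param smoothness length scale (chordal distance on the unit sphere) of
#'   the spatial covariance; larger is smoother.
#' @param seed integer seed.
#' @return An `ms_templates` object (maps are channels x k).
#' @export
generate_templates <- function(montage, k = 4, smoothness = 0.8, seed = 1L) {
  if (k < 2) stop_invalid("k must be >= 2")
  if (k > montage$n_channels - 1L) {
    stop_invalid("k must be < n_channels: zero-mean maps span only ",
                 montage$n_channels - 1L, " dimensions")
  }
  n <- montage$n_channels
  d2 <- as.matrix(stats::dist(montage$positions))^2
  K <- exp(-d2 / (2 * smoothness^2)) + diag(1e-8, n)
  L <- t(chol(K))
  maps <- with_seed(seed, L %*% matrix(stats::rnorm(n * k), n, k))
  maps <- maps - rep(colMeans(maps), each = n)
  # Gram-Schmidt inside the zero-mean subspace
  for (j in seq_len(k)) {
    if (j > 1L) {
      prev <- maps[, seq_len(j - 1L), drop = FALSE]
      maps[, j] <- maps[, j] - prev %*% crossprod(prev, maps[, j])
    }
    nrm <- sqrt(sum(maps[, j]^2))
    if (nrm < 1e-8) stop("degenerate template draw; change seed or smoothness")
    maps[, j] <- maps[, j] / nrm
  }
  maps <- maps * sqrt(n)  # unit GFP: sqrt(mean(v^2)) == 1
  new_templates(maps, class_labels = LETTERS[seq_len(k)], level = "generative")
}

#' Sample a semi-Markov microstate label sequence
#'
#' Dwell times follow a truncated-geometric law: a minimum dwell of
#' `min_duration_ms` (capped at half the state's mean) plus a geometric tail
#' whose constant per-sample hazard is tuned so the mean dwell equals the
#' state's `mean_durations_ms` - the memoryless analogue of the 60-120 ms
#' quasi-stability of scalp topographies. The successor state is uniform
#' over the other states, so consecutive runs never share a label. A per-run
#' polarity sign is drawn here and carried in the ground-truth run table.
#'
#' @param config an `ms_gen_config`.
#' @return An `ms_labels` object with `source = "ground_truth"` and a `runs`
#'   data.frame (start, end, state, sign; sample indices are 1-based and
#'   inclusive).
#' @export
sample_state_sequence <- function(config) {
  stopifnot(inherits(config, "ms_gen_config"))
  n <- as.integer(round(config$length_s * config$fs_hz))
  k <- config$n_states
  mean_len <- pmax(config$mean_durations_ms * config$fs_hz / 1000, 1)
  min_len <- as.integer(round(pmin(config$min_duration_ms * config$fs_hz / 1000,
                                   mean_len / 2)))
  tail_mean <- pmax(mean_len - min_len, 1)  # tail includes the final +1
  with_seed(config$seed, {
    states <- integer(0); lens <- integer(0)
    total <- 0
    cur <- sample.int(k, 1L)
    while (total < n) {
      m <- ceiling((n - total) / min(mean_len) * 1.3) + 20L
      sts <- integer(m); lns <- integer(m)
      for (i in seq_len(m)) {
        sts[i] <- cur
        lns[i] <- min_len[cur] + stats::rgeom(1L, 1 / tail_mean[cur]) + 1L
        cur <- if (k == 1L) cur else {
          cand <- sample.int(k - 1L, 1L)
          if (cand >= cur) cand + 1L else cand
        }
      }
      states <- c(states, sts); lens <- c(lens, lns)
      total <- total + sum(lns)
    }
    cum <- cumsum(lens)
    last <- which(cum >= n)[1L]
    states <- states[seq_len(last)]; lens <- lens[seq_len(last)]
    lens[last] <- lens[last] - (cum[last] - n)
    signs <- sample(c(-1L, 1L), last, replace = TRUE)
    ends <- cumsum(lens)
    runs <- data.frame(start = ends - lens + 1L, end = ends,
                       state = states, sign = signs)
    labels <- rep.int(states, lens)
    new_labels(labels, config$fs_hz, k = k, source = "ground_truth",
               runs = runs)
  })
}

# rectified-sinusoid GFP envelope with a constant floor, unit "shape" scale
gfp_envelope <- function(config, n = round(config$length_s * config$fs_hz)) {
  t <- (seq_len(n) - 1L) / config$fs_hz
  config$gfp_scale_uv *
    (config$envelope_floor + abs(sin(2 * pi * config$envelope_freq_hz * t)))
}

#' Render a multichannel EEG recording from a label sequence
#'
#' Each sample is the active template times a nonnegative GFP envelope and the
#' run's polarity sign, plus white sensor noise and the configured band-limited
#' oscillations; the result is average-referenced. Ground truth (labels, runs,
#' templates) is attached as attribute `ground_truth`.
#'
#' @param labels an `ms_labels` sequence with a run table (see
#'   [sample_state_sequence()]).
#' @param templates an `ms_templates` whose count matches the label alphabet.
#' @param config the `ms_gen_config` used for the envelope, noise and
#'   oscillations. Noise and oscillation draws use `config$seed` offset by one
#'   so they are independent of the sequence draw.
#' @return An `ms_recording` with attribute `ground_truth`.
#' @export
render_eeg <- function(labels, templates, config) {
  stopifnot(inherits(labels, "ms_labels"), inherits(templates, "ms_templates"))
  k <- ncol(templates$maps)
  if (labels$k != k) {
    stop_invalid("label alphabet (", labels$k, ") does not match template count (",
                 k, ")")
  }
  n_ch <- nrow(templates$maps)
  n <- length(labels$labels)
  env <- gfp_envelope(config, n)
  sign_per_sample <- rep.int(labels$runs$sign,
                             labels$runs$end - labels$runs$start + 1L)
  X <- templates$maps[, labels$labels, drop = FALSE] *
    rep(env * sign_per_sample, each = n_ch)
  with_seed(derive_seed(config$seed, "render"), {
    if (config$noise_sd_uv > 0) {
      X <- X + matrix(stats::rnorm(n_ch * n, sd = config$noise_sd_uv), n_ch, n)
    }
    t <- (seq_len(n) - 1L) / config$fs_hz
    for (o in config$oscillations) {
      ch <- o$channels %||% seq_len(n_ch)
      f <- stats::runif(1L, o$low_hz, o$high_hz)
      phase <- stats::runif(1L, 0, 2 * pi)
      w <- stats::rnorm(length(ch))
      w <- w - mean(w)                      # sum-to-zero: survives avg ref
      w <- w / sqrt(mean(w^2))              # unit mean-square on the subset
      X[ch, ] <- X[ch, ] + o$amplitude_uv *
        (w %o% sin(2 * pi * f * t + phase))
    }
    X
  }) -> X
  X <- X - rep(colMeans(X), each = n_ch)    # average reference
  mont <- attr(templates, "montage") %||% NULL
  if (is.null(mont) || mont$n_channels != n_ch) {
    mont <- if (n_ch %in% c(19L, 60L) || n_ch <= 60L) montage_1020(n_ch) else
      stop_invalid("no montage available for ", n_ch, " channels")
  }
  rec <- new_recording(X, config$fs_hz, mont,
                       annotations = sprintf("synthetic render (seed %d)",
                                             config$seed))
  attr(rec, "ground_truth") <- list(labels = labels, templates = templates,
                                    config = config)
  rec
}

# ---- study-level generation --------------------------------------------

.score_defaults <- list(
  TMNMT = list(THI = c(38.50, 19.15), TFI = c(94.76, 61.60),
               VAS = c(4.85, 2.10), RI_intensity = c(-3.6, 1.3),
               RI_duration_s = c(403, 215), age = c(39.18, 20.99)),
  Placebo = list(THI = c(38.7, 15.96), TFI = c(94.45, 52.08),
                 VAS = c(4.77, 1.91), RI_intensity = c(-1.1, 1.6),
                 RI_duration_s = c(96, 123), age = c(37.73, 16.67))
)

.score_ranges <- list(THI = c(0, 100), TFI = c(0, Inf), VAS = c(0, 10),
                      RI_intensity = c(-5, 5), RI_duration_s = c(0, Inf),
                      age = c(18, 90))

#' Build a study manifest
#'
#' Defines the two-group (TMNMT vs Placebo), three-condition (pre, during,
#' post) design: subject ids, group assignment, per-subject questionnaire
#' scores drawn from group-level Gaussian summaries clamped to instrument
#' ranges, and the effect specification that the generator injects.
#'
#' `effect_spec` is a nested list keyed by group then condition, each entry a
#' list with `band_db` (named dB offsets applied to the matching oscillation
#' amplitudes) and `duration_mult` (named per-state mean-duration
#' multipliers), e.g.
#' `list(TMNMT = list(post = list(band_db = c(alpha2 = -3),
#'                                duration_mult = c(B = 0.8))))`.
#'
#' @param n_per_group subjects per group.
#' @param effect_spec see Details; default no injected effects.
#' @param subject_sigma list with `duration` (SD of a log-normal per-subject
#'   duration multiplier) and `band_db` (SD of a per-subject oscillation gain
#'   in dB); these are the subject-level random effects.
#' @param seed integer seed for the score draws.
#' @return A list of class `ms_manifest` with a `subjects` data.frame,
#'   `conditions`, `effect_spec` and `subject_sigma`.
#' @export
study_manifest <- function(n_per_group = 22, effect_spec = list(),
                           subject_sigma = list(duration = 0.08, band_db = 1),
                           seed = 1L) {
  groups <- c("TMNMT", "Placebo")
  for (g in names(effect_spec)) {
    if (!g %in% groups) stop_invalid("unknown group in effect_spec: ", g)
  }
  subj <- with_seed(derive_seed(seed, "scores"), {
    rows <- lapply(groups, function(g) {
      ids <- sprintf("%s%02d", ifelse(g == "TMNMT", "nm", "pb"),
                     seq_len(n_per_group))
      sc <- lapply(names(.score_defaults[[g]]), function(s) {
        ms <- .score_defaults[[g]][[s]]
        rg <- .score_ranges[[s]]
        pmin(pmax(stats::rnorm(n_per_group, ms[1], ms[2]), rg[1]), rg[2])
      })
      names(sc) <- names(.score_defaults[[g]])
      cbind(data.frame(subject_id = ids, group = g,
                       stringsAsFactors = FALSE),
            as.data.frame(sc))
    })
    do.call(rbind, rows)
  })
  if (anyDuplicated(subj$subject_id)) stop_invalid("duplicate subject_id")
  structure(
    list(subjects = subj, conditions = c("pre", "during", "post"),
         effect_spec = effect_spec, subject_sigma = subject_sigma,
         seed = as.integer(seed)),
    class = "ms_manifest"
  )
}

effect_for <- function(manifest, group, condition) {
  e <- manifest$effect_spec[[group]][[condition]]
  list(band_db = e$band_db %||% numeric(), duration_mult = e$duration_mult %||% numeric())
}

#' Generate a full synthetic study
#'
#' Renders one recording per subject and condition from a shared template set,
#' applying the manifest's effect specification (band-power offsets in dB on
#' the matching oscillations, and per-state mean-duration multipliers) and
#' per-subject log-normal random effects. Recordings carry their ground truth.
#'
#' @param manifest an `ms_manifest`.
#' @param base an `ms_gen_config` giving the per-recording defaults. Name the
#'   `oscillations` entries (e.g. `alpha2 = list(...)`) so `band_db` offsets
#'   can address them.
#' @param montage montage used for all recordings.
#' @return An `ms_study`: list with `manifest`, `templates`, `recordings`
#'   (named `subject|condition`), and `base` config.
#' @export
generate_study <- function(manifest, base = gen_config(),
                           montage = montage_1020(60)) {
  stopifnot(inherits(manifest, "ms_manifest"), inherits(base, "ms_gen_config"))
  if (anyDuplicated(manifest$subjects$subject_id)) {
    stop_invalid("duplicate subject_id in manifest")
  }
  templates <- generate_templates(montage, k = base$n_states,
                                  seed = derive_seed(base$seed, "templates"))
  attr(templates, "montage") <- montage
  subj <- manifest$subjects
  state_names <- LETTERS[seq_len(base$n_states)]
  recs <- list()
  for (i in seq_len(nrow(subj))) {
    sid <- subj$subject_id[i]; grp <- subj$group[i]
    sfx <- with_seed(derive_seed(base$seed, "subj", sid), {
      list(dur = exp(stats::rnorm(base$n_states, 0,
                                  manifest$subject_sigma$duration %||% 0)),
           gain_db = stats::rnorm(1, 0, manifest$subject_sigma$band_db %||% 0))
    })
    for (cond in manifest$conditions) {
      eff <- effect_for(manifest, grp, cond)
      cfg <- base
      dm <- rep(1, base$n_states)
      if (length(eff$duration_mult)) {
        idx <- match(names(eff$duration_mult), state_names)
        if (anyNA(idx)) stop_invalid("unknown state in duration_mult")
        dm[idx] <- eff$duration_mult
      }
      cfg$mean_durations_ms <- base$mean_durations_ms * dm * sfx$dur
      if (length(cfg$oscillations)) {
        for (ob in names(cfg$oscillations)) {
          db <- sfx$gain_db +
            (if (ob %in% names(eff$band_db)) eff$band_db[[ob]] else 0)
          cfg$oscillations[[ob]]$amplitude_uv <-
            cfg$oscillations[[ob]]$amplitude_uv * 10^(db / 20)
        }
      }
      cfg$seed <- derive_seed(base$seed, "rec", sid, cond)
      lab <- sample_state_sequence(cfg)
      recs[[paste(sid, cond, sep = "|")]] <- render_eeg(lab, templates, cfg)
    }
  }
  structure(list(manifest = manifest, templates = templates,
                 recordings = recs, base = base, montage = montage),
            class = "ms_study")
}

#' @export
print.ms_study <- function(x, ...) {
  cat(sprintf("<ms_study> %d subjects x %d conditions = %d recordings\n",
              nrow(x$manifest$subjects), length(x$manifest$conditions),
              length(x$recordings)))
  invisible(x)
}

#' Write a study to disk (EDF + manifest + ground truth)
#'
#' Writes `manifest.tsv` (subject, group, condition, path, scores), one EDF
#' per recording, and a `truth/<recording>.tsv` run table (start and end
#' sample, state, sign) per recording.
#'
#' @param study an `ms_study`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(file.path(dir, "truth"), recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (nm in names(study$recordings)) {
    parts <- strsplit(nm, "|", fixed = TRUE)[[1]]
    fn <- paste0(gsub("[^A-Za-z0-9]", "_", nm), ".edf")
    rec <- study$recordings[[nm]]
    write_recording_edf(rec, file.path(dir, fn))
    gt <- attr(rec, "ground_truth")
    data.table::fwrite(gt$labels$runs,
                       file.path(dir, "truth", sub("edf$", "tsv", fn)),
                       sep = "\t")
    srow <- study$manifest$subjects[
      study$manifest$subjects$subject_id == parts[1], , drop = FALSE]
    srow$condition <- parts[2]; srow$path <- fn
    rows[[nm]] <- srow
  }
  man <- do.call(rbind, rows)
  data.table::fwrite(man, file.path(dir, "manifest.tsv"), sep = "\t")
  invisible(dir)
}
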