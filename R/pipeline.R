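# Config-driven orchestration: simulate -> preprocess -> spectral +
# microstate -> stats -> report.

#' Default pipeline configuration
#'
#' Returns the full parameter set of the pipeline with the study's canonical
#' preprocessing values (band-pass 0.5-100 Hz, notches at 50 and 100 Hz,
#' average reference, 2-s epochs with a +/-100 uV rejection threshold, a
#' 2-20 Hz band for the microstate branch, Welch spectra in 2-s segments
#' with 50 percent overlap, k = 4 microstate classes). The simulation block
#' defaults to a desk-scale demo study (6 subjects per group, 12-s
#' recordings, 19 channels at 256 Hz) rather than the full-scale design; any
#' entry can be overridden via `overrides` or a YAML/JSON config file.
#'
#' @param overrides named list merged over the defaults (nested lists merge
#'   recursively).
#' @return A list of class `ms_pipeline_config`.
#' @export
pipeline_config <- function(overrides = list()) {
  cfg <- list(
    seed = 1L,
    simulate = list(
      n_per_group = 6,
      n_channels = 19,
      fs_hz = 256,
      length_s = 12,
      n_states = 4,
      mean_durations_ms = c(60, 80, 100, 120),
      gfp_scale_uv = 9,
      noise_sd_uv = 2,
      # modest rhythm amplitudes: the 2-20 Hz microstate branch shares this
      # band, so rhythms must not drown the quasi-stable topographies
      oscillations = list(
        alpha2 = list(low_hz = 10, high_hz = 13, amplitude_uv = 3),
        theta = list(low_hz = 4.5, high_hz = 7.5, amplitude_uv = 2)
      ),
      effect_spec = list(),
      subject_sigma = list(duration = 0.08, band_db = 1)
    ),
    preprocess = list(
      target_fs_hz = NULL,       # NULL: keep the simulated rate
      band = c(0.5, 100),
      notch_hz = c(50, 100),
      epoch_length_s = 2,
      threshold_uv = 100,
      microstate_band = c(2, 20)
    ),
    welch = list(segment_s = 2, overlap = 0.5, window = "hamming"),
    microstate = list(k = 4, min_separation_ms = 10,
                      max_maps_per_recording = 120,
                      backfit_level = "group"),
    stats = list(alpha = 0.05)
  )
  merge_rec <- function(a, b) {
    for (nm in names(b)) {
      a[[nm]] <- if (is.list(a[[nm]]) && is.list(b[[nm]]) &&
                     !is.null(names(b[[nm]]))) {
        merge_rec(a[[nm]], b[[nm]])
      } else {
        b[[nm]]
      }
    }
    a
  }
  structure(merge_rec(cfg, overrides), class = "ms_pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path `.yaml`/`.yml` or `.json` file with (a subset of) the
#'   [pipeline_config()] schema; missing entries keep their defaults.
#' @return An `ms_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ov <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  pipeline_config(ov)
}

# Preprocess every recording of a study. Returns, per recording, the
# broadband epochs (for spectra) and the 2-20 Hz concatenated retained
# epochs (for microstates), plus rejection bookkeeping.
preprocess_study <- function(study, pp) {
  out <- list(spectral = list(), microstate = list(), rejected = integer(0))
  for (nm in names(study$recordings)) {
    rec <- study$recordings[[nm]]
    if (!is.null(pp$target_fs_hz) && pp$target_fs_hz != rec$fs_hz) {
      rec <- resample_recording(rec, pp$target_fs_hz)
    }
    nyq <- rec$fs_hz / 2
    rec <- filter_band(rec, pp$band[1], min(pp$band[2], nyq * 0.96),
                       notch_hz = pp$notch_hz[pp$notch_hz < nyq])
    rec <- rereference_average(rec)
    ep <- epoch_and_reject(rec, pp$epoch_length_s, pp$threshold_uv)
    ms_rec <- filter_band(rec, pp$microstate_band[1], pp$microstate_band[2])
    ms_ep <- epoch_and_reject(ms_rec, pp$epoch_length_s, Inf)
    ms_ep$rejected <- ep$rejected       # share the broadband rejection mask
    if (all(ep$rejected)) {
      warning("all epochs rejected for ", nm, "; recording excluded")
      next
    }
    out$spectral[[nm]] <- ep
    out$microstate[[nm]] <- epochs_to_recording(ms_ep)
    out$rejected[nm] <- sum(ep$rejected)
  }
  out
}

study_info <- function(study, names_kept) {
  parts <- strsplit(names_kept, "|", fixed = TRUE)
  data.frame(
    subject_id = vapply(parts, `[`, "", 1L),
    group = study$manifest$subjects$group[
      match(vapply(parts, `[`, "", 1L), study$manifest$subjects$subject_id)],
    condition = vapply(parts, `[`, "", 2L),
    stringsAsFactors = FALSE)
}

# paired t-tests across condition pairs, one family per group x measure,
# FDR-adjusted within the family
condition_contrasts <- function(tab, value_col, unit_cols, group,
                                conditions = c("pre", "during", "post")) {
  pairs <- utils::combn(conditions, 2, simplify = FALSE)
  rows <- list()
  for (u in split(tab, tab[unit_cols], drop = TRUE)) {
    for (pr in pairs) {
      x <- u[u$condition == pr[1], ]
      y <- u[u$condition == pr[2], ]
      shared <- intersect(x$subject, y$subject)
      if (length(shared) < 2) next
      x <- x[match(shared, x$subject), value_col]
      y <- y[match(shared, y$subject), value_col]
      r <- tryCatch(ttest_paired(x, y), error = function(e) NULL)
      if (is.null(r)) next
      rows[[length(rows) + 1L]] <- data.frame(
        group = group,
        measure = paste(vapply(unit_cols, function(cn) as.character(u[[cn]][1]),
                               ""), collapse = "."),
        comparison = paste(pr, collapse = "-"),
        t = r$statistic, df = r$df, p_raw = r$p_raw)
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(out)) out$p_fdr <- fdr_adjust(out$p_raw)
  out
}

#' Run the full analysis pipeline
#'
#' Simulates the study, preprocesses every recording, computes the per-band
#' spectral table, derives two-level microstate templates and back-fits them,
#' computes temporal metrics and transition syntax, runs the statistical
#' comparison layer, and (when `out_dir` is given) writes all tabular
#' artifacts plus `report.json`. Identical config + seed give identical
#' outputs.
#'
#' @param cfg an `ms_pipeline_config`.
#' @param out_dir optional output directory.
#' @param until last stage to execute ("simulate", "preprocess", "spectral",
#'   "microstate", or "stats"); later tables are absent from the report.
#' @return An `ms_run_report` list: `tables` (band, metrics, transitions,
#'   stats, correlations, anova), `templates`, `config`, and per-stage
#'   bookkeeping (`counts`).
#' @export
run_pipeline <- function(cfg = pipeline_config(), out_dir = NULL,
                         until = "stats") {
  until <- match.arg(until, c("simulate", "preprocess", "spectral",
                              "microstate", "stats"))
  ord <- c(simulate = 1, preprocess = 2, spectral = 3, microstate = 4,
           stats = 5)
  want <- function(s) ord[[s]] <= ord[[until]]
  band_tab <- metrics_tab <- trans_tab <- stats_tab <- cor_tab <-
    anova_tab <- NULL
  tpls <- NULL
  pre <- NULL
  label_seqs <- list()
  stage <- "simulate"
  report <- tryCatch({
    sim <- cfg$simulate
    manifest <- study_manifest(n_per_group = sim$n_per_group,
                               effect_spec = sim$effect_spec,
                               subject_sigma = sim$subject_sigma,
                               seed = derive_seed(cfg$seed, "manifest"))
    base <- gen_config(n_states = sim$n_states,
                       mean_durations_ms = sim$mean_durations_ms,
                       gfp_scale_uv = sim$gfp_scale_uv,
                       noise_sd_uv = sim$noise_sd_uv,
                       oscillations = sim$oscillations,
                       fs_hz = sim$fs_hz, length_s = sim$length_s,
                       seed = derive_seed(cfg$seed, "study"))
    study <- generate_study(manifest, base,
                            montage = montage_1020(sim$n_channels))

    if (want("preprocess")) {
    stage <- "preprocess"
    pre <- preprocess_study(study, cfg$preprocess)
    info <- study_info(study, names(pre$spectral))
    }

    if (want("spectral")) {
    stage <- "spectral"
    M <- round(cfg$welch$segment_s * pre$spectral[[1]]$fs_hz)
    wc <- welch_config(M, round(M * cfg$welch$overlap),
                       window = cfg$welch$window,
                       fs_hz = pre$spectral[[1]]$fs_hz)
    band_tab <- band_table(pre$spectral, info, wc)
    }

    if (want("microstate")) {
    stage <- "microstate"
    msc <- cfg$microstate
    tpls <- two_level_templates(pre$microstate, info, k = msc$k,
                                min_separation_ms = msc$min_separation_ms,
                                max_maps_per_recording =
                                  msc$max_maps_per_recording)
    metrics_rows <- list(); trans_rows <- list(); label_seqs <- list()
    for (i in seq_along(pre$microstate)) {
      nm <- names(pre$microstate)[i]
      sg <- paste(info$group[i], info$condition[i], sep = ".")
      tpl <- if (msc$backfit_level == "grand") tpls$grand else
        tpls$group[[sg]]
      lab <- backfit(pre$microstate[[nm]], tpl,
                     min_separation_ms = msc$min_separation_ms)
      label_seqs[[nm]] <- data.frame(
        epoch = lab$epoch_id, sample = seq_along(lab$labels),
        class = tpl$class_labels[lab$labels])
      met <- microstate_metrics(lab)
      met$class <- tpl$class_labels[met$state]
      metrics_rows[[nm]] <- cbind(info[i, ], met, row.names = NULL)
      tp <- transition_probabilities(lab)
      dimnames(tp) <- list(tpl$class_labels, tpl$class_labels)
      tr <- as.data.frame(as.table(unclass(tp)), stringsAsFactors = FALSE)
      names(tr) <- c("from", "to", "p")
      tr <- tr[tr$from != tr$to, ]
      trans_rows[[nm]] <- cbind(info[i, ], tr, row.names = NULL)
    }
    metrics_tab <- do.call(rbind, c(metrics_rows, make.row.names = FALSE))
    trans_tab <- do.call(rbind, c(trans_rows, make.row.names = FALSE))
    names(metrics_tab)[1] <- names(trans_tab)[1] <- "subject"
    }

    if (want("stats")) {
    stage <- "stats"
    stats_rows <- list(); anova_rows <- list()
    for (g in unique(info$group)) {
      bt <- band_tab[band_tab$group == g, ]
      stats_rows[[paste0(g, ".band")]] <-
        condition_contrasts(bt, "db", "band", g)
      mt <- metrics_tab[metrics_tab$group == g, ]
      for (meas in c("duration_ms", "occurrence_per_s", "coverage")) {
        m2 <- mt[, c("subject", "condition", "class", meas)]
        names(m2)[4] <- "value"
        m2$measure <- meas
        stats_rows[[paste0(g, ".", meas)]] <-
          condition_contrasts(m2, "value", c("measure", "class"), g)
        # paper-style RM-ANOVA: class within, subgroup (condition) between,
        # subject x condition treated as the observational unit
        m2$unit <- paste(m2$subject, m2$condition, sep = ".")
        av <- mixed_anova(m2, dv = "value", within = "class",
                          between = "condition", subject = "unit")
        anova_rows[[paste(g, meas, sep = ".")]] <-
          cbind(group = g, measure = meas, av)
      }
      tt <- trans_tab[trans_tab$group == g &
                        trans_tab$condition %in% c("pre", "post"), ]
      tt$measure <- paste0(tt$from, ">", tt$to)
      stats_rows[[paste0(g, ".transition")]] <-
        condition_contrasts(tt, "p", "measure", g,
                            conditions = c("pre", "post"))
    }
    stats_tab <- do.call(rbind, c(stats_rows, make.row.names = FALSE))

    # duration-vs-TFI correlations per subgroup x class, one FDR family
    scores <- study$manifest$subjects
    cor_rows <- list()
    for (sg in split(metrics_tab, list(metrics_tab$group,
                                       metrics_tab$condition))) {
      for (cl in unique(sg$class)) {
        d <- sg[sg$class == cl, ]
        tfi <- scores$TFI[match(d$subject, scores$subject_id)]
        r <- tryCatch(correlate_metric_score(d$duration_ms, tfi),
                      error = function(e) NULL)
        if (is.null(r)) next
        cor_rows[[length(cor_rows) + 1L]] <- data.frame(
          group = d$group[1], condition = d$condition[1], class = cl,
          metric = "duration_ms", r = r$r, p_raw = r$p_raw)
      }
    }
    cor_tab <- do.call(rbind, cor_rows)
    if (!is.null(cor_tab)) cor_tab$p_fdr <- fdr_adjust(cor_tab$p_raw)

    anova_tab <- do.call(rbind, c(anova_rows, make.row.names = FALSE))
    }
    list(
      tables = list(bands = band_tab, metrics = metrics_tab,
                    transitions = trans_tab, stats = stats_tab,
                    correlations = cor_tab, anova = anova_tab),
      templates = tpls,
      labels = label_seqs,
      counts = list(recordings = length(study$recordings),
                    kept = length(pre$microstate),
                    rejected_epochs = pre$rejected,
                    grand_ev = tpls$grand$explained_variance %||% NA_real_),
      config = cfg,
      version = as.character(utils::packageVersion("mstateri"))
    )
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  class(report) <- "ms_run_report"
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.ms_run_report <- function(x, ...) {
  cat(sprintf("<ms_run_report> %d recordings (%d kept), grand EV %.3f\n",
              x$counts$recordings, x$counts$kept, x$counts$grand_ev))
  invisible(x)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fw <- function(d, f) {
    if (!is.null(d)) data.table::fwrite(d, file.path(out_dir, f), sep = "\t")
  }
  fw(report$tables$bands, "psd_bands.tsv")
  fw(report$tables$metrics, "metrics.tsv")
  fw(report$tables$transitions, "transitions.tsv")
  fw(report$tables$stats, "stats_report.tsv")
  fw(report$tables$correlations, "correlations.tsv")
  fw(report$tables$anova, "anova.tsv")
  if (!is.null(report$templates)) {
    tpl <- report$templates$grand
    fw(data.frame(channel = rownames(tpl$maps) %||%
                    seq_len(nrow(tpl$maps)), tpl$maps),
       "templates_grand.tsv")
    grp <- do.call(rbind, lapply(names(report$templates$group), function(sg) {
      g <- report$templates$group[[sg]]
      cbind(subgroup = sg,
            data.frame(channel = rownames(g$maps) %||% seq_len(nrow(g$maps)),
                       g$maps))
    }))
    fw(grp, "templates_group.tsv")
  }
  if (length(report$labels)) {
    dir.create(file.path(out_dir, "labels"), showWarnings = FALSE)
    for (nm in names(report$labels)) {
      fw(report$labels[[nm]],
         file.path("labels", paste0(gsub("[^A-Za-z0-9]", "_", nm), ".tsv")))
    }
  }
  inventory <- intersect(c("psd_bands.tsv", "metrics.tsv", "transitions.tsv",
                           "stats_report.tsv", "correlations.tsv",
                           "anova.tsv", "templates_grand.tsv",
                           "templates_group.tsv"),
                         list.files(out_dir))
  jsonlite::write_json(
    list(version = report$version, counts = report$counts,
         config = report$config, files = inventory),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
    force = TRUE)
  invisible(out_dir)
}

#' Render human-readable summary tables
#'
#' Formats the pipeline outputs in the conventional layout of microstate
#' study reports: one row per measure level (band or microstate class), one
#' `mean (SD)` column per subgroup, plus t/p columns for the within-group
#' condition contrasts.
#'
#' @param report an `ms_run_report` (or a directory containing pipeline
#'   outputs).
#' @param what "metrics" (duration/occurrence/coverage) or "bands".
#' @return Named list of data.frames (one per group x measure).
#' @export
render_tables <- function(report, what = c("metrics", "bands")) {
  what <- match.arg(what)
  if (is.character(report)) {
    rd <- function(f) {
      p <- file.path(report, f)
      if (!file.exists(p)) stop("missing pipeline output: ", p)
      as.data.frame(data.table::fread(p))
    }
    tables <- list(metrics = rd("metrics.tsv"), bands = rd("psd_bands.tsv"),
                   stats = rd("stats_report.tsv"))
  } else {
    tables <- report$tables
  }
  fmt <- function(v) sprintf("%.2f (%.2f)", mean(v), stats::sd(v))
  out <- list()
  if (what == "metrics") {
    tab <- tables$metrics
    if (is.null(tab) || !nrow(tab)) stop("empty metrics table")
    for (g in unique(tab$group)) {
      for (meas in c("duration_ms", "occurrence_per_s", "coverage")) {
        sub <- tab[tab$group == g, ]
        wide <- do.call(rbind, lapply(sort(unique(sub$class)), function(cl) {
          row <- list(class = cl)
          for (cond in c("pre", "during", "post")) {
            row[[cond]] <- fmt(sub[[meas]][sub$class == cl &
                                             sub$condition == cond])
          }
          st <- tables$stats
          st <- st[st$group == g & st$measure == paste(meas, cl, sep = "."), ]
          for (i in seq_len(nrow(st))) {
            row[[st$comparison[i]]] <- sprintf("%.3f/%.4f", st$t[i],
                                               st$p_fdr[i])
          }
          as.data.frame(row, check.names = FALSE)
        }))
        out[[paste(g, meas, sep = ".")]] <- wide
      }
    }
  } else {
    tab <- tables$bands
    if (is.null(tab) || !nrow(tab)) stop("empty band table")
    for (g in unique(tab$group)) {
      sub <- tab[tab$group == g, ]
      wide <- do.call(rbind, lapply(unique(sub$band), function(b) {
        row <- list(band = b)
        for (cond in c("pre", "during", "post")) {
          row[[cond]] <- fmt(sub$db[sub$band == b & sub$condition == cond])
        }
        as.data.frame(row, check.names = FALSE)
      }))
      out[[g]] <- wide
    }
  }
  out
}
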