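# Shared fixtures and independent brute-force oracles. Oracles are written
# from the definitions, independent of the package implementation.

quick_montage <- function(n = 19) montage_1020(n)

# brute-force run-length metrics from a plain label vector (one epoch)
oracle_runs <- function(lab) {
  runs <- list()
  start <- 1L
  for (i in seq_along(lab)[-1]) {
    if (lab[i] != lab[i - 1L]) {
      runs[[length(runs) + 1L]] <- c(state = lab[start], len = i - start)
      start <- i
    }
  }
  runs[[length(runs) + 1L]] <- c(state = lab[start],
                                 len = length(lab) - start + 1L)
  do.call(rbind, runs)
}

oracle_metrics <- function(lab, fs, k) {
  r <- oracle_runs(lab)
  t_total <- length(lab) / fs
  data.frame(
    state = seq_len(k),
    duration_ms = vapply(seq_len(k), function(s) {
      ln <- r[r[, "state"] == s, "len"]
      if (length(ln)) mean(ln) * 1000 / fs else NA_real_
    }, 0),
    occurrence_per_s = vapply(seq_len(k), function(s) {
      sum(r[, "state"] == s) / t_total
    }, 0),
    coverage = vapply(seq_len(k), function(s) {
      sum(r[r[, "state"] == s, "len"]) / length(lab)
    }, 0))
}

oracle_transitions <- function(lab, k) {
  r <- oracle_runs(lab)
  counts <- matrix(0, k, k)
  if (nrow(r) >= 2) {
    for (i in seq_len(nrow(r) - 1L)) {
      counts[r[i, "state"], r[i + 1L, "state"]] <-
        counts[r[i, "state"], r[i + 1L, "state"]] + 1
    }
  }
  rs <- rowSums(counts)
  counts / ifelse(rs > 0, rs, 1)
}

# definitional BH step-up via the threshold formulation
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) adj[o[i]] <- min(1, min(p[o[i:m]] * m / (i:m)))
  # classical implementation: adj_(i) = min_{j>=i} p_(j) m / j
  adj
}

# random label sequence without constraints on self-succession (exercises
# the run-length encoders on arbitrary inputs)
oracle_free_sequence <- function(n, k) sample.int(k, n, replace = TRUE)

# small synthetic recording with known labels (no oscillations)
quick_render <- function(seed = 1, n_ch = 19, fs = 256, length_s = 10,
                         noise = 2, scale = 9, durations = c(60, 80, 100, 120)) {
  mont <- montage_1020(n_ch)
  tpl <- generate_templates(mont, length(durations), seed = seed + 1000L)
  cfg <- gen_config(n_states = length(durations),
                    mean_durations_ms = durations, gfp_scale_uv = scale,
                    noise_sd_uv = noise, fs_hz = fs, length_s = length_s,
                    seed = seed)
  lab <- sample_state_sequence(cfg)
  list(rec = render_eeg(lab, tpl, cfg), labels = lab, templates = tpl,
       config = cfg, montage = mont)
}
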