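# Welch power spectral density and nine-band dB summarization.

#' Welch configuration
#'
#' @param segment_length_samples segment length M.
#' @param overlap_samples overlap D between consecutive segments
#'   (`0 <= D < M`); `M/2` gives the conventional 50 percent overlap.
#' @param window taper name: "hamming", "hann" or "rect".
#' @param fs_hz sampling rate.
#' @return A list of class `ms_welch_config`.
#' @export
welch_config <- function(segment_length_samples = 1024,
                         overlap_samples = segment_length_samples / 2,
                         window = c("hamming", "hann", "rect"),
                         fs_hz = 512) {
  window <- match.arg(window)
  M <- as.integer(segment_length_samples); D <- as.integer(overlap_samples)
  if (D < 0L || D >= M) stop_invalid("need 0 <= overlap < segment length")
  structure(list(segment_length_samples = M, overlap_samples = D,
                 window = window, fs_hz = fs_hz),
            class = "ms_welch_config")
}

taper_window <- function(name, M) {
  t <- seq_len(M) - 1L
  switch(name,
         hamming = 0.54 - 0.46 * cos(2 * pi * t / (M - 1)),
         hann = 0.5 - 0.5 * cos(2 * pi * t / (M - 1)),
         rect = rep(1, M))
}

# Welch per-channel PSD over one continuous matrix (channels x samples).
welch_matrix <- function(x, cfg) {
  M <- cfg$segment_length_samples; D <- cfg$overlap_samples
  n <- ncol(x)
  if (M > n) stop_invalid("segment length exceeds data length")
  step <- M - D
  starts <- seq(1L, n - M + 1L, by = step)
  w <- taper_window(cfg$window, M)
  U <- sum(w^2)
  nch <- nrow(x)
  acc <- matrix(0, nch, M %/% 2L + 1L)
  for (s in starts) {
    seg <- x[, s:(s + M - 1L), drop = FALSE] * rep(w, each = nch)
    spec <- Mod(t(stats::mvfft(t(seg))))^2
    acc <- acc + spec[, seq_len(M %/% 2L + 1L), drop = FALSE]
  }
  psd <- acc / (length(starts) * cfg$fs_hz * U)
  # one-sided: double everything except DC and (for even M) Nyquist
  dbl <- rep(2, ncol(psd)); dbl[1] <- 1
  if (M %% 2L == 0L) dbl[length(dbl)] <- 1
  psd <- psd * rep(dbl, each = nch)
  list(psd = psd, K = length(starts))
}

#' Welch power spectral density
#'
#' Segments the signal (never across epoch boundaries when given epochs),
#' applies the taper, averages the windowed periodograms, and normalizes by
#' the window power so that white noise of variance `s^2` has flat density
#' `s^2 / (fs/2)` (one-sided).
#'
#' @param x an `ms_recording` or `ms_epochs` (rejected epochs are skipped).
#' @param cfg an `ms_welch_config`; its `fs_hz` is overridden by the data's.
#' @return An `ms_psd`: list with `freqs_hz`, `power` (channel x frequency
#'   one-sided density, in squared-amplitude units per Hz), and
#'   `n_segments`.
#' @export
welch_psd <- function(x, cfg = welch_config(fs_hz = x$fs_hz)) {
  cfg$fs_hz <- x$fs_hz
  if (inherits(x, "ms_recording")) {
    res <- welch_matrix(x$data, cfg)
    psd <- res$psd; K <- res$K
  } else if (inherits(x, "ms_epochs")) {
    idx <- which(!x$rejected)
    if (!length(idx)) stop("all epochs rejected")
    psd <- NULL; K <- 0L
    for (e in idx) {
      res <- welch_matrix(x$data[, , e], cfg)
      psd <- if (is.null(psd)) res$psd * res$K else psd + res$psd * res$K
      K <- K + res$K
    }
    psd <- psd / K
  } else {
    stop_invalid("x must be an ms_recording or ms_epochs")
  }
  M <- cfg$segment_length_samples
  structure(
    list(freqs_hz = (0:(M %/% 2L)) * x$fs_hz / M, power = psd,
         n_segments = K, fs_hz = x$fs_hz),
    class = "ms_psd"
  )
}

#' The nine-band decomposition
#'
#' delta 0.5-4, theta 4-8, alpha1 8-10, alpha2 10-13, beta1 13-18,
#' beta2 18-21, beta3 21-30, gamma1 30-45, gamma2 55-100 Hz. The 45-55 Hz
#' gap is intentional (line-noise region). Bands are half-open `[low, high)`.
#'
#' @return A data.frame of class `ms_bands` with band, low_hz, high_hz.
#' @export
band_scheme_default <- function() {
  out <- data.frame(
    band = c("delta", "theta", "alpha1", "alpha2", "beta1", "beta2", "beta3",
             "gamma1", "gamma2"),
    low_hz = c(0.5, 4, 8, 10, 13, 18, 21, 30, 55),
    high_hz = c(4, 8, 10, 13, 18, 21, 30, 45, 100)
  )
  class(out) <- c("ms_bands", "data.frame")
  out
}

#' Band power table
#'
#' Per channel and band, the mean spectral density over the in-band bins
#' (`low <= f < high`) converted to dB (`10*log10`); the whole-brain summary
#' is the mean of the per-channel dB values.
#'
#' @param psd an `ms_psd`.
#' @param scheme band scheme data.frame (band, low_hz, high_hz).
#' @return An `ms_bandpower`: list with `db` (channel x band matrix),
#'   `whole_brain` (named vector of channel-mean dB per band), and `scheme`.
#'   Bands with zero power give `-Inf` dB.
#' @export
band_power <- function(psd, scheme = band_scheme_default()) {
  if (any(scheme$low_hz >= scheme$high_hz)) stop_invalid("band low < high required")
  fmax <- max(psd$freqs_hz)
  if (any(scheme$low_hz > fmax)) {
    stop_invalid("band outside the frequency grid (max ", fmax, " Hz)")
  }
  db <- sapply(seq_len(nrow(scheme)), function(i) {
    sel <- psd$freqs_hz >= scheme$low_hz[i] & psd$freqs_hz < scheme$high_hz[i]
    if (!any(sel)) return(rep(NA_real_, nrow(psd$power)))
    10 * log10(rowMeans(psd$power[, sel, drop = FALSE]))
  })
  colnames(db) <- scheme$band
  structure(list(db = db, whole_brain = colMeans(db), scheme = scheme),
            class = "ms_bandpower")
}

#' Long-form per-subject band-power table
#'
#' Runs Welch + band summarization on every recording of a study and returns
#' one row per subject x condition x band with the whole-brain dB value.
#' Recordings with non-finite dB (e.g. all-zero data) are excluded with a
#' warning.
#'
#' @param recordings named list of `ms_recording` or `ms_epochs`
#'   (names `subject|condition`).
#' @param info data.frame (`subject_id`, `group`, `condition`) matching
#'   `recordings`.
#' @param cfg an `ms_welch_config`.
#' @param scheme band scheme.
#' @return data.frame: subject, group, condition, band, db (deterministic
#'   row order).
#' @export
band_table <- function(recordings, info, cfg = NULL,
                       scheme = band_scheme_default()) {
  rows <- vector("list", length(recordings))
  for (i in seq_along(recordings)) {
    x <- recordings[[i]]
    c_i <- cfg %||% welch_config(
      segment_length_samples = min(1024L,
        if (inherits(x, "ms_epochs")) dim(x$data)[2] else ncol(x$data)),
      fs_hz = x$fs_hz)
    bp <- band_power(welch_psd(x, c_i), scheme)
    if (any(!is.finite(bp$whole_brain))) {
      warning("non-finite band power for ", names(recordings)[i],
              "; excluded")
      next
    }
    rows[[i]] <- data.frame(
      subject = info$subject_id[i], group = info$group[i],
      condition = info$condition[i], band = scheme$band,
      db = unname(bp$whole_brain), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
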