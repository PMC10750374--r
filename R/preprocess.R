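# Deterministic preprocessing: resampling, zero-phase FIR band-pass and
# notch filtering, average referencing, fixed-length epoching with
# amplitude-threshold rejection. No randomness anywhere in this file.

# ---- FFT helpers --------------------------------------------------------

# linear convolution via FFT, returning the "same" central part with the
# kernel's group delay removed (kernel must be odd-length, symmetric)
conv_same <- function(x, h) {
  n <- length(x); m <- length(h)
  L <- stats::nextn(n + m - 1L, 2L)
  y <- Re(stats::fft(stats::fft(c(x, numeric(L - n))) *
                       stats::fft(c(h, numeric(L - m))), inverse = TRUE)) / L
  d <- (m - 1L) %/% 2L
  y[(d + 1L):(d + n)]
}

# even-reflection padding: mirrors the signal at both edges. For zero-mean
# oscillatory signals this continues each sinusoid with at most a phase
# error, so the forward-backward edge transient stays small (odd reflection
# injects a step whose passband ringing is visible with long kernels).
reflect_pad <- function(x, p) {
  n <- length(x)
  p <- min(p, n - 1L)
  c(x[(p + 1L):2L], x, x[(n - 1L):(n - p)])
}

# windowed-sinc low-pass FIR, Hamming window, odd length
fir_lowpass <- function(fc_norm, taps) {
  taps <- as.integer(taps)
  if (taps %% 2L == 0L) taps <- taps + 1L
  m <- (taps - 1L) / 2L
  t <- seq(-m, m)
  h <- 2 * fc_norm * sinc(2 * fc_norm * t)
  w <- 0.54 + 0.46 * cos(pi * t / m)
  h <- h * w
  h / sum(h)
}

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

# ---- operations ---------------------------------------------------------

#' Resample a recording
#'
#' Fourier-domain resampling: the spectrum is truncated (down-sampling, which
#' is also the anti-alias step) or zero-padded (up-sampling) and inverse
#' transformed at the new rate. The output length is
#' `round(n * target_fs / fs)`.
#'
#' @param rec an `ms_recording`.
#' @param target_fs_hz new sampling rate (> 0).
#' @return The resampled `ms_recording`.
#' @export
resample_recording <- function(rec, target_fs_hz) {
  if (!is.numeric(target_fs_hz) || target_fs_hz <= 0) {
    stop_invalid("target_fs_hz must be positive")
  }
  if (target_fs_hz == rec$fs_hz) return(rec)
  n <- ncol(rec$data)
  m <- round(n * target_fs_hz / rec$fs_hz)
  X <- t(stats::mvfft(t(rec$data)))           # channel-wise FFT (rows)
  Y <- matrix(0 + 0i, nrow(X), m)
  keep <- min(n, m)
  h <- keep %/% 2L
  pos <- seq_len(h + 1L)                      # DC .. +Nyquist of smaller grid
  Y[, pos] <- X[, pos]
  if (h > 1L) {
    neg <- seq_len(h - 1L)
    Y[, m - neg + 1L] <- X[, n - neg + 1L]
  }
  if (keep %% 2L == 0L) {
    # split the shared Nyquist bin to keep the signal real and unbiased
    Y[, h + 1L] <- Y[, h + 1L] / 2
    Y[, m - h + 1L] <- Y[, m - h + 1L] + Conj(X[, h + 1L]) / 2
  }
  y <- Re(t(stats::mvfft(t(Y), inverse = TRUE))) / n
  out <- new_recording(y, target_fs_hz, rec$montage, rec$annotations)
  annotate(out, sprintf("resampled %g -> %g Hz (%d -> %d samples)",
                        rec$fs_hz, target_fs_hz, n, m))
}

#' Zero-phase FIR band-pass and notch filtering
#'
#' Windowed-sinc FIR (Hamming window, order about `3.3 * fs / transition
#' width`) band-pass between `low_hz` and `high_hz`, optionally combined with
#' band-stop notches of +/- 2 Hz around each entry of `notch_hz`. The
#' combined kernel is applied forward and backward (zero phase) with
#' odd-reflection edge padding.
#'
#' @param rec an `ms_recording`.
#' @param low_hz,high_hz pass-band edges, `0 < low < high < Nyquist`.
#' @param notch_hz numeric vector of notch center frequencies (each below
#'   Nyquist), or NULL.
#' @param transition_hz transition width; default `min(2, low_hz)`.
#' @param notch_halfwidth_hz half width of each band-stop notch.
#' @return The filtered `ms_recording`.
#' @export
filter_band <- function(rec, low_hz, high_hz, notch_hz = NULL,
                        transition_hz = NULL, notch_halfwidth_hz = 2) {
  nyq <- rec$fs_hz / 2
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq)) {
    stop_invalid("need 0 < low_hz < high_hz < Nyquist (", nyq, " Hz)")
  }
  if (any(notch_hz >= nyq)) stop_invalid("notch frequencies must be < Nyquist")
  fs <- rec$fs_hz
  tw <- transition_hz %||% min(2, low_hz)
  taps <- ceiling(3.3 * fs / tw)
  h <- fir_lowpass(high_hz / fs, taps) # cumulative kernel; start as low-pass
  lp_low <- fir_lowpass(low_hz / fs, taps)
  # band-pass = lp(high) - lp(low), aligned at center
  h <- h - lp_low
  for (f0 in notch_hz) {
    ntaps <- ceiling(3.3 * fs / 1)     # 1 Hz transition for the notches
    lo <- max(f0 - notch_halfwidth_hz, 0.1)
    hi <- min(f0 + notch_halfwidth_hz, nyq * 0.999)
    bs <- -(fir_lowpass(hi / fs, ntaps) - fir_lowpass(lo / fs, ntaps))
    mid <- (length(bs) + 1L) / 2L
    bs[mid] <- bs[mid] + 1            # spectral inversion: band-stop
    h <- conv_full(h, bs)
  }
  n <- ncol(rec$data)
  p <- min(length(h), n - 1L)
  d <- (length(h) - 1L) %/% 2L
  np <- n + 2L * p
  L <- stats::nextn(np + length(h) - 1L, 2L)
  Hf <- stats::fft(c(h, numeric(L - length(h))))
  apply_kernel <- function(M) {   # samples x channels, padded length np
    M <- rbind(M, matrix(0, L - np, ncol(M)))
    Y <- stats::mvfft(M) * Hf
    Re(stats::mvfft(Y, inverse = TRUE))[(d + 1L):(d + np), , drop = FALSE] / L
  }
  X <- t(rec$data)[c((p + 1L):2L, seq_len(n), (n - 1L):(n - p)), ,
                   drop = FALSE]                       # even reflection
  Y <- apply_kernel(X)
  Y <- apply_kernel(Y[np:1L, , drop = FALSE])[np:1L, , drop = FALSE]
  out <- rec
  out$data <- t(Y[(p + 1L):(p + n), , drop = FALSE])
  dimnames(out$data) <- dimnames(rec$data)
  annotate(out, sprintf("FIR band-pass %g-%g Hz%s, zero-phase (%d taps)",
                        low_hz, high_hz,
                        if (length(notch_hz)) paste0(", notch ",
                          paste(notch_hz, collapse = "/"), " Hz") else "",
                        length(h)))
}

conv_full <- function(a, b) {
  L <- stats::nextn(length(a) + length(b) - 1L, 2L)
  out <- Re(stats::fft(stats::fft(c(a, numeric(L - length(a)))) *
                         stats::fft(c(b, numeric(L - length(b)))),
                       inverse = TRUE)) / L
  out[seq_len(length(a) + length(b) - 1L)]
}

#' Re-reference to the common average
#'
#' Subtracts the across-channel mean at every sample, so every column of the
#' result sums to zero.
#'
#' @param rec an `ms_recording` with at least 2 channels.
#' @return The re-referenced `ms_recording`.
#' @export
rereference_average <- function(rec) {
  if (nrow(rec$data) < 2L) stop_invalid("need >= 2 channels")
  out <- rec
  out$data <- rec$data - rep(colMeans(rec$data), each = nrow(rec$data))
  annotate(out, "average reference")
}

#' Cut into fixed epochs and reject by amplitude
#'
#' Divides the recording into consecutive non-overlapping epochs of
#' `epoch_length_s` (a trailing partial epoch is discarded) and rejects any
#' epoch in which any sample of any channel exceeds `threshold_uv` in
#' absolute value.
#'
#' @param rec an `ms_recording`.
#' @param epoch_length_s epoch length in seconds (default 2).
#' @param threshold_uv rejection threshold in microvolts (default 100).
#' @return An `ms_epochs`: list with `data` (channel x sample x epoch array),
#'   `fs_hz`, `epoch_length_s`, `rejected` (logical per epoch), `reasons`
#'   (character per epoch) and `montage`.
#' @export
epoch_and_reject <- function(rec, epoch_length_s = 2, threshold_uv = 100) {
  if (threshold_uv <= 0) stop_invalid("threshold_uv must be positive")
  spe <- round(epoch_length_s * rec$fs_hz)
  n_ep <- ncol(rec$data) %/% spe
  if (n_ep < 1L) stop("recording shorter than one epoch")
  nch <- nrow(rec$data)
  arr <- array(rec$data[, seq_len(n_ep * spe)], dim = c(nch, spe, n_ep))
  peak <- apply(abs(arr), 3L, max)
  rejected <- peak > threshold_uv
  reasons <- ifelse(rejected,
                    sprintf("amplitude %.1f uV > %.0f uV", peak, threshold_uv),
                    "")
  structure(
    list(data = arr, fs_hz = rec$fs_hz, epoch_length_s = epoch_length_s,
         rejected = rejected, reasons = reasons, montage = rec$montage,
         annotations = c(rec$annotations,
                         sprintf("epoched: %d x %gs, %d rejected (+/-%g uV)",
                                 n_ep, epoch_length_s, sum(rejected),
                                 threshold_uv))),
    class = "ms_epochs"
  )
}

#' Serialize epochs to disk
#'
#' Writes one `epoch_<i>.tsv` per epoch (samples x channels, with the
#' `# fs_hz=` header used by [read_recording()]) plus `rejection.tsv`
#' (epoch, rejected, reason).
#'
#' @param ep an `ms_epochs`.
#' @param dir output directory (created if missing).
#' @param keep_rejected also write the rejected epochs (default TRUE; they
#'   are flagged in `rejection.tsv` either way).
#' @return `dir`, invisibly.
#' @export
write_epochs <- function(ep, dir, keep_rejected = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n_ep <- dim(ep$data)[3]
  for (i in seq_len(n_ep)) {
    if (!keep_rejected && ep$rejected[i]) next
    rec <- new_recording(ep$data[, , i], ep$fs_hz, ep$montage)
    write_recording_tsv(rec, file.path(dir, sprintf("epoch_%03d.tsv", i)))
  }
  data.table::fwrite(
    data.frame(epoch = seq_len(n_ep), rejected = ep$rejected,
               reason = ep$reasons),
    file.path(dir, "rejection.tsv"), sep = "\t")
  invisible(dir)
}

#' @export
print.ms_epochs <- function(x, ...) {
  cat(sprintf("<ms_epochs> %d epochs x %g s, %d channels @ %g Hz, %d rejected\n",
              dim(x$data)[3], x$epoch_length_s, dim(x$data)[1], x$fs_hz,
              sum(x$rejected)))
  invisible(x)
}

#' Concatenate retained epochs back into a recording
#'
#' Joins the non-rejected epochs into one `ms_recording` and returns it with
#' an `epoch_id` attribute so downstream label-sequence analyses can avoid
#' crossing epoch boundaries.
#'
#' @param ep an `ms_epochs`.
#' @param keep logical vector of epochs to keep (default: the non-rejected).
#' @return An `ms_recording` with attribute `epoch_id` (per-sample index).
#' @export
epochs_to_recording <- function(ep, keep = !ep$rejected) {
  idx <- which(keep)
  if (!length(idx)) stop("no retained epochs")
  nch <- dim(ep$data)[1]; spe <- dim(ep$data)[2]
  mat <- matrix(ep$data[, , idx], nrow = nch)
  rec <- new_recording(mat, ep$fs_hz, ep$montage, ep$annotations)
  attr(rec, "epoch_id") <- rep(seq_along(idx), each = spe)
  rec
}
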