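# Recording container and file I/O (delimited text and EDF).

#' Construct a Recording
#'
#' A recording is a channel-by-sample matrix of scalp potentials in microvolts
#' with a sampling rate and montage. An `annotations` character vector carries
#' a provenance log that processing steps append to.
#'
#' @param data numeric matrix, channels in rows, samples in columns.
#' @param fs_hz sampling rate in Hz (> 0).
#' @param montage an `ms_montage` whose size matches `nrow(data)`.
#' @param annotations character vector of provenance messages.
#' @return An `ms_recording` object.
#' @export
new_recording <- function(data, fs_hz, montage, annotations = character()) {
  data <- as.matrix(data)
  if (!is.numeric(data) || !all(is.finite(data))) {
    stop_invalid("recording data must be finite numeric")
  }
  if (!is.numeric(fs_hz) || length(fs_hz) != 1L || fs_hz <= 0) {
    stop_invalid("fs_hz must be a positive scalar")
  }
  if (!inherits(montage, "ms_montage")) stop_invalid("montage must be an ms_montage")
  if (nrow(data) != montage$n_channels) {
    stop_invalid("channel count (", nrow(data), ") does not match montage (",
                 montage$n_channels, ")")
  }
  rownames(data) <- montage$channel_names
  structure(
    list(data = data, fs_hz = as.numeric(fs_hz), montage = montage,
         annotations = as.character(annotations)),
    class = "ms_recording"
  )
}

annotate <- function(rec, msg) {
  rec$annotations <- c(rec$annotations, msg)
  rec
}

n_samples <- function(rec) ncol(rec$data)

#' @export
print.ms_recording <- function(x, ...) {
  cat(sprintf("<ms_recording> %d channels x %d samples @ %g Hz (%.2f s)\n",
              nrow(x$data), ncol(x$data), x$fs_hz, ncol(x$data) / x$fs_hz))
  if (length(x$annotations)) {
    cat("  log: ", paste(utils::tail(x$annotations, 3), collapse = " | "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Write a recording to a tab-delimited matrix file
#'
#' Format: a first comment line `# fs_hz=<rate>`, then a header row of channel
#' names and one row per sample (samples in rows, channels in columns).
#'
#' @param rec an `ms_recording`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_recording_tsv <- function(rec, path) {
  writeLines(sprintf("# fs_hz=%.10g", rec$fs_hz), path)
  dt <- data.table::as.data.table(t(rec$data))
  data.table::setnames(dt, rec$montage$channel_names)
  data.table::fwrite(dt, path, sep = "\t", append = TRUE, col.names = TRUE)
  invisible(path)
}

read_recording_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  if (!length(first)) stop("empty recording file: ", path)
  m <- regmatches(first, regexec("^#\\s*fs_hz=([0-9.eE+-]+)", first))[[1]]
  if (length(m) < 2L) stop("missing '# fs_hz=' header in ", path)
  fs <- as.numeric(m[2])
  dt <- data.table::fread(path, skip = 1L, sep = "\t", header = TRUE)
  list(data = t(as.matrix(dt)), fs_hz = fs, labels = colnames(dt))
}

# ---- EDF (European Data Format) ----------------------------------------
# Minimal self-contained EDF codec: a single data record spanning the whole
# recording, 16-bit samples, physical units uV. Sufficient for round-tripping
# the synthetic recordings of this package; no annotations/EDF+ support.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write a recording as EDF
#'
#' Writes a minimal single-record EDF file with 16-bit samples and physical
#' units of microvolts. The quantization step per channel is
#' `(physmax - physmin) / 65535`.
#'
#' @param rec an `ms_recording`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_recording_edf <- function(rec, path) {
  ns <- nrow(rec$data)
  nsamp <- ncol(rec$data)
  pmin <- apply(rec$data, 1L, min)
  pmax <- apply(rec$data, 1L, max)
  flat <- pmax - pmin < 1e-12
  pmin[flat] <- pmin[flat] - 1
  pmax[flat] <- pmax[flat] + 1
  dmin <- -32768L; dmax <- 32767L
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8),                                     # version
    edf_pad("X X X X", 80),                              # patient id
    edf_pad("Startdate X X X X", 80),                    # recording id
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),      # date, time
    edf_pad(256 + 256 * ns, 8),                          # header bytes
    edf_pad("", 44),                                     # reserved
    edf_pad(1, 8),                                       # n data records
    edf_pad(format(nsamp / rec$fs_hz, digits = 7), 8),   # record duration (s)
    edf_pad(ns, 4)
  )
  writeChar(hdr, con, eos = NULL)
  fields <- list(
    vapply(rec$montage$channel_names, edf_pad, "", width = 16),
    rep(edf_pad("EEG", 80), ns),
    rep(edf_pad("uV", 8), ns),
    vapply(pmin, function(v) edf_pad(format(v, digits = 8), 8), ""),
    vapply(pmax, function(v) edf_pad(format(v, digits = 8), 8), ""),
    rep(edf_pad(dmin, 8), ns),
    rep(edf_pad(dmax, 8), ns),
    rep(edf_pad("", 80), ns),
    rep(edf_pad(nsamp, 8), ns),
    rep(edf_pad("", 32), ns)
  )
  for (f in fields) writeChar(paste(f, collapse = ""), con, eos = NULL)
  for (i in seq_len(ns)) {
    dig <- round((rec$data[i, ] - pmin[i]) / (pmax[i] - pmin[i]) *
                   (dmax - dmin) + dmin)
    writeBin(as.integer(dig), con, size = 2L, endian = "little")
  }
  invisible(path)
}

read_recording_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  rd(8)                       # version
  rd(160)                     # patient + recording id
  rd(16)                      # date + time
  rd(8)                       # header bytes
  rd(44)                      # reserved
  nrec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (!is.finite(ns) || ns < 1) stop("corrupt EDF header in ", path)
  labels <- trimws(vapply(seq_len(ns), function(i) rd(16), ""))
  rd(80 * ns); rd(8 * ns)     # transducer, units
  pmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  rd(80 * ns)                 # prefiltering
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  rd(32 * ns)                 # reserved
  data <- matrix(0, nrow = ns, ncol = spr[1] * nrec)
  for (r in seq_len(nrec)) {
    for (i in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[i], size = 2L, signed = TRUE,
                     endian = "little")
      phys <- (dig - dmin[i]) / (dmax[i] - dmin[i]) * (pmax[i] - pmin[i]) +
        pmin[i]
      data[i, (r - 1) * spr[i] + seq_len(spr[i])] <- phys
    }
  }
  list(data = data, fs_hz = spr[1] * nrec / (dur * nrec), labels = labels)
}

#' Read a recording from EDF or delimited text
#'
#' Reads an EDF file or a tab-delimited matrix (see [write_recording_tsv()]),
#' resolves channel labels against `montage` (case-insensitively), drops
#' channels absent from the montage with a logged warning, and returns the
#' channels in montage order.
#'
#' @param path path to an `.edf` or delimited-text recording.
#' @param montage target `ms_montage`.
#' @return An `ms_recording`.
#' @export
read_recording <- function(path, montage) {
  if (!file.exists(path)) stop("cannot read recording: ", path)
  if (file.size(path) == 0) stop("empty recording file: ", path)
  is_edf <- grepl("\\.edf$", path, ignore.case = TRUE)
  raw <- if (is_edf) read_recording_edf(path) else read_recording_tsv(path)
  idx <- match(toupper(montage$channel_names), toupper(raw$labels))
  if (all(is.na(idx))) {
    stop("no overlap between file channels and montage in ", path)
  }
  keep <- montage$channel_names[!is.na(idx)]
  dropped <- setdiff(raw$labels, raw$labels[idx[!is.na(idx)]])
  sub_mont <- if (length(keep) == montage$n_channels) montage else {
    new_montage(keep, montage$positions[!is.na(idx), , drop = FALSE])
  }
  rec <- new_recording(raw$data[idx[!is.na(idx)], , drop = FALSE],
                       raw$fs_hz, sub_mont)
  msg <- sprintf("read %s: kept %d channels, dropped %d [%s]",
                 basename(path), length(keep), length(dropped),
                 paste(utils::head(dropped, 8), collapse = ","))
  if (length(dropped)) warning(msg, call. = FALSE)
  annotate(rec, msg)
}
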