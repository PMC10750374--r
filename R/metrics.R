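# Temporal microstate metrics and transition syntax.

# run-length encode the labels of one epoch; NA samples act as boundaries
# and are excluded
epoch_runs <- function(lab) {
  ok <- !is.na(lab)
  if (!any(ok)) return(data.frame(state = integer(0), length = integer(0)))
  r <- rle(ifelse(ok, lab, -1L))
  keep <- r$values != -1L
  data.frame(state = r$values[keep], length = r$lengths[keep])
}

#' Temporal microstate metrics
#'
#' For each state: mean duration (ms) of its uninterrupted runs, occurrence
#' rate (appearances per second) and time coverage (fraction of labelled
#' samples). Metrics are computed per epoch and averaged across epochs with
#' equal weights; runs truncated by epoch boundaries are included. Duration
#' is averaged over the epochs in which the state appears; occurrence and
#' coverage count absent epochs as zero.
#'
#' @param labels an `ms_labels` (its `epoch_id` defines the epochs).
#' @return An `ms_metrics` data.frame: state, class (letter), duration_ms,
#'   occurrence_per_s, coverage.
#' @export
microstate_metrics <- function(labels) {
  stopifnot(inherits(labels, "ms_labels"))
  if (!length(labels$labels)) stop_invalid("empty label sequence")
  k <- labels$k
  fs <- labels$fs_hz
  eps <- split(seq_along(labels$labels), labels$epoch_id)
  dur <- occ <- cov <- matrix(NA_real_, length(eps), k)
  for (e in seq_along(eps)) {
    lab <- labels$labels[eps[[e]]]
    runs <- epoch_runs(lab)
    n_lab <- sum(runs$length)
    t_epoch <- length(lab) / fs
    for (s in seq_len(k)) {
      rs <- runs$length[runs$state == s]
      occ[e, s] <- length(rs) / t_epoch
      cov[e, s] <- if (n_lab > 0) sum(rs) / n_lab else NA_real_
      dur[e, s] <- if (length(rs)) mean(rs) * 1000 / fs else NA_real_
    }
  }
  out <- data.frame(
    state = seq_len(k),
    class = LETTERS[seq_len(k)],
    duration_ms = colMeans(dur, na.rm = TRUE),
    occurrence_per_s = colMeans(occ),
    coverage = colMeans(cov, na.rm = TRUE)
  )
  out$duration_ms[is.nan(out$duration_ms)] <- NA_real_
  class(out) <- c("ms_metrics", "data.frame")
  out
}

#' Transition probability matrix
#'
#' Counts run-to-run transitions (self-transitions are impossible by
#' construction; transitions across epoch boundaries are not counted) and
#' row-normalizes the outgoing counts. Rows with no outgoing transition stay
#' zero and are flagged in the `no_outgoing` attribute.
#'
#' @param labels an `ms_labels`.
#' @return A k x k matrix of class `ms_transitions` with zero diagonal; rows
#'   with at least one transition sum to 1. Attribute `counts` holds the raw
#'   counts.
#' @export
transition_probabilities <- function(labels) {
  stopifnot(inherits(labels, "ms_labels"))
  k <- labels$k
  counts <- matrix(0, k, k, dimnames = list(LETTERS[seq_len(k)],
                                            LETTERS[seq_len(k)]))
  total_runs <- 0L
  for (idx in split(seq_along(labels$labels), labels$epoch_id)) {
    runs <- epoch_runs(labels$labels[idx])
    total_runs <- total_runs + nrow(runs)
    if (nrow(runs) >= 2L) {
      from <- runs$state[-nrow(runs)]
      to <- runs$state[-1L]
      counts <- counts + matrix(tabulate(from + (to - 1L) * k, nbins = k * k),
                                k, k)
    }
  }
  if (sum(counts) == 0) {
    warning("fewer than two runs: transition matrix is all zero")
  }
  rs <- rowSums(counts)
  p <- counts / ifelse(rs > 0, rs, 1)
  structure(p, class = c("ms_transitions", class(p)),
            counts = counts, no_outgoing = which(rs == 0))
}

#' @export
print.ms_transitions <- function(x, ...) {
  cat("<ms_transitions>\n")
  print(round(unclass(x), 3))
  invisible(x)
}
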