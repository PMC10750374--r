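# Core microstate machinery: global field power, GFP-peak extraction,
# polarity-invariant clustering (AAHC and modified k-means), and model
# selection by cross-validation and Krzanowski-Lai criteria.

#' Construct a template set
#'
#' @param maps channels x K matrix; each column is centered (zero channel
#'   mean). Columns are stored as given; clustering functions produce
#'   unit-norm maps, the generator unit-GFP maps.
#' @param class_labels one label per map (subset of LETTERS).
#' @param level one of "generative", "subject", "group", "grand".
#' @param explained_variance global explained variance in `[0, 1]` (NA when
#'   not applicable).
#' @return An `ms_templates` object.
#' @export
new_templates <- function(maps, class_labels = LETTERS[seq_len(ncol(maps))],
                          level = "subject", explained_variance = NA_real_) {
  maps <- as.matrix(maps)
  if (ncol(maps) < 1L) stop_invalid("need at least one map")
  if (length(class_labels) != ncol(maps)) stop_invalid("one label per map")
  if (!is.na(explained_variance) &&
      (explained_variance < 0 || explained_variance > 1)) {
    stop_invalid("explained_variance must be in [0, 1]")
  }
  colnames(maps) <- class_labels
  structure(list(maps = maps, class_labels = class_labels, level = level,
                 explained_variance = explained_variance),
            class = "ms_templates")
}

#' @export
print.ms_templates <- function(x, ...) {
  cat(sprintf("<ms_templates> %d maps (%s), level %s, EV %.3f\n",
              ncol(x$maps), paste(x$class_labels, collapse = ""),
              x$level, x$explained_variance))
  invisible(x)
}

#' Construct a label sequence
#'
#' @param labels per-sample state index (1..k) or NA for unassigned.
#' @param fs_hz sampling rate.
#' @param k alphabet size.
#' @param source "ground_truth" or "backfit".
#' @param runs optional ground-truth run table.
#' @param epoch_id optional per-sample epoch index; metrics and transitions
#'   are computed per epoch and never cross epoch boundaries.
#' @return An `ms_labels` object.
#' @export
new_labels <- function(labels, fs_hz, k = max(labels, na.rm = TRUE),
                       source = "backfit", runs = NULL, epoch_id = NULL) {
  labels <- as.integer(labels)
  if (any(labels > k, na.rm = TRUE) || any(labels < 1L, na.rm = TRUE)) {
    stop_invalid("labels must lie in 1..k")
  }
  structure(list(labels = labels, fs_hz = fs_hz, k = as.integer(k),
                 source = source, runs = runs,
                 epoch_id = epoch_id %||% rep(1L, length(labels))),
            class = "ms_labels")
}

#' Global field power
#'
#' GFP(t) is the spatial standard deviation of the scalp potential at time t:
#' `sqrt(sum_i (V_i(t) - Vmean(t))^2 / N)`. The input is re-referenced to the
#' average internally, so the result is reference-independent.
#'
#' @param rec an `ms_recording`, or a bare channels x samples matrix.
#' @return An `ms_gfp`: list with `values` (per-sample, microvolts) and
#'   `fs_hz`.
#' @export
gfp <- function(rec) {
  x <- if (inherits(rec, "ms_recording")) rec$data else as.matrix(rec)
  fs <- if (inherits(rec, "ms_recording")) rec$fs_hz else NA_real_
  mu <- colMeans(x)
  v <- sqrt(colMeans(x^2) - mu^2)
  v[v < 0] <- 0
  structure(list(values = as.numeric(v), fs_hz = fs), class = "ms_gfp")
}

#' Find GFP peaks
#'
#' Strictly interior local maxima of the GFP series; when two maxima fall
#' within `min_separation_ms` of each other, the larger one is kept (ties go
#' to the earlier peak). Deterministic.
#'
#' @param g an `ms_gfp` (or numeric vector plus `fs_hz`).
#' @param min_separation_ms minimum separation between retained peaks, ms.
#' @param fs_hz sampling rate, required when `g` is a bare vector.
#' @return Integer vector of peak sample indices (possibly empty).
#' @export
find_gfp_peaks <- function(g, min_separation_ms = 10, fs_hz = NULL) {
  v <- if (inherits(g, "ms_gfp")) g$values else as.numeric(g)
  fs <- if (inherits(g, "ms_gfp")) g$fs_hz else fs_hz
  n <- length(v)
  if (n < 3L) return(integer(0))
  i <- 2:(n - 1L)
  cand <- i[v[i] > v[i - 1L] & v[i] > v[i + 1L]]
  if (!length(cand) || min_separation_ms <= 0) return(cand)
  if (is.null(fs) || is.na(fs)) stop_invalid("fs_hz required for separation")
  min_gap <- min_separation_ms * fs / 1000
  # greedy: accept by decreasing amplitude (earlier index wins ties)
  ord <- cand[order(-v[cand], cand)]
  accepted <- integer(0)
  for (p in ord) {
    if (!length(accepted) || all(abs(accepted - p) >= min_gap)) {
      accepted <- c(accepted, p)
    }
  }
  sort(accepted)
}

#' Spatial correlation between two topographies
#'
#' Pearson correlation across channels after removing each map's channel
#' mean; with `ignore_polarity = TRUE` (the default, as microstate clustering
#' ignores polarity) the absolute value is returned.
#'
#' @param a,b numeric channel vectors of equal length.
#' @param ignore_polarity return `|r|` instead of signed r.
#' @return Correlation in `[0, 1]` (or `[-1, 1]` with polarity).
#' @export
spatial_correlation <- function(a, b, ignore_polarity = TRUE) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop_invalid("maps must have equal length")
  a <- a - mean(a); b <- b - mean(b)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("undefined correlation: zero-variance map")
  r <- sum(a * b) / (na * nb)
  if (ignore_polarity) abs(r) else r
}

# center columns (maps) of a channels x n matrix
center_maps <- function(m) m - rep(colMeans(m), each = nrow(m))

# leading eigenvector of S (symmetric psd), deterministic sign: the channel
# with the largest absolute loading is positive
principal_orientation <- function(S) {
  u <- eigen(S, symmetric = TRUE)$vectors[, 1L]
  j <- which.max(abs(u))
  if (u[j] < 0) u <- -u
  u
}

# ---- AAHC ---------------------------------------------------------------

#' Atomize-and-agglomerate hierarchical clustering of topographies
#'
#' Bottom-up, deterministic, polarity-invariant clustering. Every map starts
#' as its own cluster; at each step the cluster contributing least to the
#' global explained variance is atomized and each of its members is
#' reassigned to the cluster whose map it correlates with best (in absolute
#' value). A cluster's map is the first principal orientation of its member
#' maps (sign-free), and its contribution is the GFP-weighted sum of squared
#' correlations of members with that map.
#'
#' @param peak_maps channels x n matrix of topographies (GFP-peak maps).
#' @param k_target number of clusters to stop at.
#' @param collect_range optional integer vector of intermediate cluster
#'   counts at which to snapshot template sets (used by [choose_k()]).
#' @return An `ms_templates` with unit-norm maps, `explained_variance`, and
#'   attributes `assignment` (per-map cluster index) and, when requested,
#'   `snapshots` (named list of template sets per collected k).
#' @export
aahc_cluster <- function(peak_maps, k_target, collect_range = integer(0)) {
  V <- center_maps(as.matrix(peak_maps))
  n <- ncol(V); nch <- nrow(V)
  if (k_target > n) stop_invalid("k_target exceeds number of maps")
  if (k_target < 1L) stop_invalid("k_target must be >= 1")
  w_total <- sum(V^2)
  if (w_total == 0) stop_invalid("all maps are flat")
  # Per-cluster state: member indices, unit-norm map (column of Umat),
  # quality u'Su (GFP-weighted sum of squared member correlations), and a
  # lazily built scatter matrix S = sum vv' for clusters with > 1 member.
  members <- as.list(seq_len(n))
  norms <- sqrt(colSums(V^2))
  Umat <- V / rep(pmax(norms, 1e-300), each = nch)
  S <- vector("list", n)
  qual <- norms^2
  alive <- rep(TRUE, n)
  n_alive <- n
  snapshots <- list()
  snap <- function() {
    idx <- which(alive)
    maps <- Umat[, idx, drop = FALSE]
    asg <- integer(n)
    for (j in seq_along(idx)) asg[members[[idx[j]]]] <- j
    tpl <- new_templates(maps, class_labels = LETTERS[seq_along(idx)],
                         level = "subject",
                         explained_variance =
                           min(1, max(0, sum(qual[idx]) / w_total)))
    attr(tpl, "assignment") <- asg
    tpl
  }
  while (n_alive > k_target) {
    idx <- which(alive)
    worst <- idx[which.min(qual[idx])]
    alive[worst] <- FALSE; n_alive <- n_alive - 1L
    S[worst] <- list(NULL)
    rest <- which(alive)
    orphans <- members[[worst]]
    proj <- abs(crossprod(Umat[, rest, drop = FALSE],
                          V[, orphans, drop = FALSE]))   # n_alive x m
    dest <- rest[max.col(t(proj), ties.method = "first")]
    for (d in unique(dest)) {
      mem <- orphans[dest == d]
      if (is.null(S[[d]])) {
        S[[d]] <- tcrossprod(V[, c(members[[d]], mem), drop = FALSE])
      } else {
        S[[d]] <- S[[d]] + tcrossprod(V[, mem, drop = FALSE])
      }
      members[[d]] <- c(members[[d]], mem)
      Umat[, d] <- principal_orientation(S[[d]])
      qual[d] <- drop(crossprod(Umat[, d], S[[d]] %*% Umat[, d]))
    }
    members[[worst]] <- integer(0)
    if (n_alive %in% collect_range) {
      snapshots[[as.character(n_alive)]] <- snap()
    }
  }
  out <- snap()
  out$level <- "subject"
  if (length(collect_range)) attr(out, "snapshots") <- snapshots
  out
}

#' Polarity-invariant modified k-means clustering of topographies
#'
#' The classical microstate k-means: assignment by maximal squared spatial
#' correlation (polarity ignored), cluster maps re-estimated as the first
#' principal orientation of assigned maps; best of `n_restarts` random
#' initializations by explained variance. Seed-reproducible.
#'
#' @param peak_maps channels x n matrix.
#' @param k number of clusters.
#' @param n_restarts random restarts.
#' @param seed integer seed.
#' @param max_iter iteration cap per restart.
#' @return An `ms_templates` with attribute `assignment`.
#' @export
modified_kmeans <- function(peak_maps, k, n_restarts = 10, seed = 1L,
                            max_iter = 100) {
  V <- center_maps(as.matrix(peak_maps))
  n <- ncol(V)
  if (k > n) stop_invalid("k exceeds number of maps")
  w_total <- sum(V^2)
  norms <- sqrt(colSums(V^2))
  norms[norms == 0] <- 1
  Vn <- V / rep(norms, each = nrow(V))
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      centers <- Vn[, sample.int(n, k), drop = FALSE]
      asg_old <- integer(n)
      for (it in seq_len(max_iter)) {
        proj <- abs(crossprod(centers, V))           # k x n
        asg <- max.col(t(proj), ties.method = "first")
        if (identical(asg, asg_old)) break
        asg_old <- asg
        for (j in seq_len(k)) {
          mem <- which(asg == j)
          if (!length(mem)) {  # re-seed empty cluster at worst-fit map
            fit <- proj[cbind(asg, seq_len(n))] / norms
            mem <- which.min(fit)
            asg[mem] <- j
          }
          centers[, j] <- principal_orientation(
            tcrossprod(V[, mem, drop = FALSE]))
        }
      }
      ev <- sum((abs(crossprod(centers, V))[cbind(asg, seq_len(n))])^2) /
        w_total
      if (is.null(best) || ev > best$ev) {
        best <- list(centers = centers, asg = asg, ev = ev)
      }
    }
  })
  out <- new_templates(best$centers, class_labels = LETTERS[seq_len(k)],
                       level = "subject", explained_variance = best$ev)
  attr(out, "assignment") <- best$asg
  out
}

# ---- model selection ----------------------------------------------------

#' Choose the number of microstate classes
#'
#' Runs a single deterministic AAHC pass and scores each candidate k by the
#' cross-validation (CV) criterion, `sigma2_hat * ((C-1)/(C-1-k))^2` with
#' `sigma2_hat` the mean residual variance of the polarity-invariant fit
#' (C = number of channels), and by the Krzanowski-Lai (KL) criterion, the
#' relative change of the dimension-adjusted within-cluster dispersion curve
#' `|DIFF(k)| / |DIFF(k+1)|` with
#' `DIFF(k) = (k-1)^(2/C) W(k-1) - k^(2/C) W(k)`. The selected k is the KL
#' argmax inside `k_range` (CV is reported alongside). The selection is
#' flagged low-confidence when no KL value dominates (max < 1.5 x the second
#' largest) or the argmax sits on the range boundary.
#'
#' @param peak_maps channels x n matrix of GFP-peak maps.
#' @param k_range integer range of candidate k (width >= 2, within
#'   `[2, n_maps - 1]`).
#' @return List with `k` (selected), `scores` (data.frame k, cv, kl, W),
#'   `low_confidence`, and `templates` (the AAHC set at the selected k).
#' @export
choose_k <- function(peak_maps, k_range = 2:8) {
  k_range <- sort(unique(as.integer(k_range)))
  V <- center_maps(as.matrix(peak_maps))
  n <- ncol(V); C <- nrow(V)
  if (length(k_range) < 2L) stop_invalid("k_range must contain at least 2 values")
  if (min(k_range) < 2L || max(k_range) > n - 1L) {
    stop_invalid("k_range must lie within [2, n_maps - 1]")
  }
  need <- (min(k_range) - 1L):(max(k_range) + 1L)
  res <- aahc_cluster(V, k_target = min(need), collect_range = need)
  snaps <- attr(res, "snapshots")
  snaps[[as.character(min(need))]] <- res
  W <- cv <- stats::setNames(rep(NA_real_, length(need)), as.character(need))
  for (k in need) {
    tpl <- snaps[[as.character(k)]]
    proj <- abs(crossprod(tpl$maps, V))           # k x n, unit-norm maps
    bestfit <- proj[cbind(max.col(t(proj), ties.method = "first"),
                          seq_len(n))]
    resid <- colSums(V^2) - bestfit^2
    W[as.character(k)] <- sum(resid)
    sigma2 <- sum(resid) / (n * (C - 1))
    cv[as.character(k)] <- sigma2 * ((C - 1) / (C - 1 - k))^2
  }
  diffk <- function(k) {
    (k - 1)^(2 / C) * W[as.character(k - 1)] - k^(2 / C) * W[as.character(k)]
  }
  kl <- vapply(k_range, function(k) {
    d1 <- diffk(k); d2 <- diffk(k + 1)
    if (!is.finite(d2) || abs(d2) < .Machine$double.eps) return(NA_real_)
    abs(d1) / abs(d2)
  }, 0)
  k_sel <- k_range[which.max(kl)]
  kl_sorted <- sort(kl[is.finite(kl)], decreasing = TRUE)
  low_conf <- length(kl_sorted) < 2L ||
    kl_sorted[1] < 1.5 * kl_sorted[2] ||
    k_sel %in% range(k_range)
  scores <- data.frame(k = k_range,
                       cv = cv[as.character(k_range)],
                       kl = kl,
                       W = W[as.character(k_range)], row.names = NULL)
  list(k = k_sel, scores = scores, low_confidence = low_conf,
       templates = snaps[[as.character(k_sel)]])
}
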