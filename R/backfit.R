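# Back-fitting and the two-level (subject -> group -> grand) template
# derivation with class-label alignment.

# peak maps of a recording: channels x n_peaks matrix (+ peak indices)
peak_maps_of <- function(rec, min_separation_ms = 10, max_maps = Inf) {
  g <- gfp(rec)
  pk <- find_gfp_peaks(g, min_separation_ms = min_separation_ms)
  if (length(pk) > max_maps) {
    # deterministic thinning: keep an even stride across the recording
    pk <- pk[unique(round(seq(1L, length(pk), length.out = max_maps)))]
  }
  list(maps = rec$data[, pk, drop = FALSE], peaks = pk)
}

#' Back-fit template maps to a recording
#'
#' Labels every GFP peak with the template of maximal polarity-invariant
#' spatial correlation (ties broken toward the lowest class index), then
#' assigns every other sample the label of its nearest peak (ties toward the
#' earlier peak); samples before the first or after the last peak take that
#' peak's label.
#'
#' @param rec an `ms_recording` (average-referenced internally).
#' @param templates an `ms_templates` with matching channel count.
#' @param min_separation_ms GFP peak separation (ms), see
#'   [find_gfp_peaks()].
#' @return An `ms_labels` with `source = "backfit"` and attribute `peaks`
#'   (peak indices) and `peak_labels`.
#' @export
backfit <- function(rec, templates, min_separation_ms = 10) {
  if (nrow(templates$maps) != nrow(rec$data)) {
    stop_invalid("template channel count does not match recording")
  }
  pm <- peak_maps_of(rec, min_separation_ms)
  if (!length(pm$peaks)) stop("no GFP peaks found; cannot back-fit")
  k <- ncol(templates$maps)
  Tm <- center_maps(templates$maps)
  Tm <- Tm / rep(sqrt(colSums(Tm^2)), each = nrow(Tm))
  Vm <- center_maps(pm$maps)
  proj <- abs(crossprod(Tm, Vm))                # k x n_peaks
  peak_lab <- max.col(t(proj), ties.method = "first")
  # nearest-neighbor interpolation between peaks (ties -> earlier peak)
  n <- ncol(rec$data)
  mids <- floor((pm$peaks[-length(pm$peaks)] + pm$peaks[-1L]) / 2)
  owner <- findInterval(seq_len(n) - 0.5, mids) + 1L
  labels <- peak_lab[owner]
  out <- new_labels(labels, rec$fs_hz, k = k, source = "backfit",
                    epoch_id = attr(rec, "epoch_id"))
  attr(out, "peaks") <- pm$peaks
  attr(out, "peak_labels") <- peak_lab
  out
}

# greedy one-to-one label alignment: returns for each column of `maps` the
# class label of the reference map it matches best, highest correlation first
align_classes <- function(maps, ref_maps, ref_labels) {
  k <- ncol(maps)
  r <- matrix(0, k, ncol(ref_maps))
  for (i in seq_len(k)) {
    for (j in seq_len(ncol(ref_maps))) {
      r[i, j] <- spatial_correlation(maps[, i], ref_maps[, j])
    }
  }
  lab <- character(k)
  for (step in seq_len(min(k, ncol(ref_maps)))) {
    ij <- arrayInd(which.max(r), dim(r))
    lab[ij[1]] <- ref_labels[ij[2]]
    r[ij[1], ] <- -Inf; r[, ij[2]] <- -Inf
  }
  lab[lab == ""] <- setdiff(LETTERS, lab)[seq_len(sum(lab == ""))]
  lab
}

reorder_templates <- function(tpl, labels) {
  ord <- order(labels)
  out <- new_templates(tpl$maps[, ord, drop = FALSE],
                       class_labels = labels[ord], level = tpl$level,
                       explained_variance = tpl$explained_variance)
  out
}

#' Two-level microstate template derivation
#'
#' Implements the hierarchical template scheme: each recording's GFP-peak
#' maps are clustered (AAHC) at the subject level; the pooled subject maps of
#' each subgroup (group x condition) are clustered at the group level; all
#' subject maps together yield the grand level. Grand clusters are labelled
#' A.. in order of decreasing explained-variance contribution; group and
#' subject sets inherit class labels from the grand set by greedy best
#' polarity-invariant correlation matching.
#'
#' @param recordings named list of `ms_recording` (names `subject|condition`).
#' @param info data.frame with columns `subject_id`, `group`, `condition`,
#'   one row per recording, rows matching `names(recordings)`.
#' @param k number of classes (default 4).
#' @param min_separation_ms GFP-peak separation.
#' @param max_maps_per_recording cap on peak maps used per recording
#'   (deterministic thinning; `Inf` to disable).
#' @return List with `grand` (`ms_templates`), `group` (named list by
#'   subgroup `group.condition`), and `subject` (named list by
#'   `subject|condition`).
#' @export
two_level_templates <- function(recordings, info, k = 4,
                                min_separation_ms = 10,
                                max_maps_per_recording = 200) {
  stopifnot(length(recordings) == nrow(info))
  subject_sets <- list()
  for (i in seq_along(recordings)) {
    nm <- names(recordings)[i]
    pm <- peak_maps_of(recordings[[i]], min_separation_ms,
                       max_maps = max_maps_per_recording)
    if (ncol(pm$maps) < k) {
      warning("recording ", nm, " has fewer peak maps than k; excluded")
      next
    }
    tpl <- aahc_cluster(pm$maps, k)
    tpl$level <- "subject"
    subject_sets[[nm]] <- tpl
  }
  if (!length(subject_sets)) stop("no usable recordings")
  kept <- names(subject_sets)
  info <- info[match(kept, paste(info$subject_id, info$condition, sep = "|")), ]
  pool <- function(sets) do.call(cbind, lapply(sets, function(s) s$maps))
  grand <- aahc_cluster(pool(subject_sets), k)
  grand$level <- "grand"
  # label grand classes A.. by decreasing contribution (stable, deterministic)
  contrib <- tabulate(attr(grand, "assignment"), nbins = k)
  ord <- order(-contrib)
  grand <- new_templates(grand$maps[, ord, drop = FALSE],
                         class_labels = LETTERS[seq_len(k)], level = "grand",
                         explained_variance = grand$explained_variance)
  subgroup <- paste(info$group, info$condition, sep = ".")
  group_sets <- list()
  for (sg in unique(subgroup)) {
    sets <- subject_sets[kept[subgroup == sg]]
    tpl <- aahc_cluster(pool(sets), k)
    tpl <- reorder_templates(
      tpl, align_classes(tpl$maps, grand$maps, grand$class_labels))
    tpl$level <- "group"
    group_sets[[sg]] <- tpl
  }
  subject_sets <- lapply(subject_sets, function(s) {
    reorder_templates(s, align_classes(s$maps, grand$maps, grand$class_labels))
  })
  list(grand = grand, group = group_sets, subject = subject_sets)
}
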