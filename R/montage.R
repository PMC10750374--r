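# Montage: electrode names plus nominal unit-sphere positions.

# Schematic 10-10 layout for the 60 scalp channels of a 64-channel cap
# (mastoid/cheek channels excluded). Coordinates are nominal: each electrode
# is placed on a planar schematic disk (x: left-negative/right-positive,
# y: nose-positive) and projected onto the unit sphere by mapping planar
# radius to inclination from the vertex. Positions are used only for
# distance-based spatial smoothing of synthetic topographies; they are not
# digitized head coordinates.
.montage_rows <- list(
  FP  = list(y = 0.95, chans = c(FP1 = -0.31, FPZ = 0, FP2 = 0.31)),
  AF  = list(y = 0.75, chans = c(AF3 = -0.30, AF4 = 0.30)),
  F   = list(y = 0.55, chans = c(F7 = -0.80, F5 = -0.62, F3 = -0.44,
                                 F1 = -0.22, FZ = 0, F2 = 0.22, F4 = 0.44,
                                 F6 = 0.62, F8 = 0.80)),
  FC  = list(y = 0.28, chans = c(FT7 = -0.92, FC5 = -0.70, FC3 = -0.47,
                                 FC1 = -0.23, FCZ = 0, FC2 = 0.23,
                                 FC4 = 0.47, FC6 = 0.70, FT8 = 0.92)),
  C   = list(y = 0.00, chans = c(T7 = -1.00, C5 = -0.75, C3 = -0.50,
                                 C1 = -0.25, CZ = 0, C2 = 0.25, C4 = 0.50,
                                 C6 = 0.75, T8 = 1.00)),
  CP  = list(y = -0.28, chans = c(TP7 = -0.92, CP5 = -0.70, CP3 = -0.47,
                                  CP1 = -0.23, CPZ = 0, CP2 = 0.23,
                                  CP4 = 0.47, CP6 = 0.70, TP8 = 0.92)),
  P   = list(y = -0.55, chans = c(P7 = -0.80, P5 = -0.62, P3 = -0.44,
                                  P1 = -0.22, PZ = 0, P2 = 0.22, P4 = 0.44,
                                  P6 = 0.62, P8 = 0.80)),
  PO  = list(y = -0.75, chans = c(PO7 = -0.58, PO5 = -0.44, PO3 = -0.29,
                                  POZ = 0, PO4 = 0.29, PO6 = 0.44,
                                  PO8 = 0.58)),
  O   = list(y = -0.95, chans = c(O1 = -0.31, OZ = 0, O2 = 0.31))
)

# classic 19-channel 10-20 subset, in conventional order
.montage_1020_19 <- c("FP1", "FP2", "F7", "F3", "FZ", "F4", "F8",
                      "T7", "C3", "CZ", "C4", "T8",
                      "P7", "P3", "PZ", "P4", "P8", "O1", "O2")

.montage_table <- function() {
  rows <- lapply(.montage_rows, function(r) {
    data.frame(name = names(r$chans), x = unname(r$chans), y = r$y,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  # planar radius -> inclination from vertex (outer ring ~ 97 degrees, i.e.
  # slightly below the equator, as on a real cap)
  r2d <- sqrt(tab$x^2 + tab$y^2)
  inc <- r2d / max(r2d) * (97 * pi / 180)
  az <- atan2(tab$x, tab$y)     # 0 at nose, positive to the right
  tab$px <- sin(inc) * sin(az)  # right
  tab$py <- sin(inc) * cos(az)  # nose
  tab$pz <- cos(inc)            # vertex
  tab
}

#' Standard 10-20/10-10 montage
#'
#' Builds a montage of scalp electrodes with nominal unit-sphere positions.
#' `n_channels = 60` gives the 60 scalp channels of a 64-channel cap laid out
#' on the extended 10-10 grid; `n_channels = 19` gives the classic 10-20 set.
#' Other values take the first `n_channels` electrodes of the 60-channel
#' ordering (frontal to occipital).
#'
#' @param n_channels number of electrodes (2..60).
#' @return An object of class `ms_montage`: a list with `channel_names`,
#'   `positions` (n x 3 matrix of unit vectors) and `n_channels`.
#' @export
#' @examples
#' m <- montage_1020(60)
#' m$n_channels
montage_1020 <- function(n_channels = 60) {
  if (!is.numeric(n_channels) || length(n_channels) != 1L ||
      n_channels < 2 || n_channels > 60) {
    stop_invalid("n_channels must be between 2 and 60")
  }
  n_channels <- as.integer(n_channels)
  tab <- .montage_table()
  if (n_channels == 19L) {
    tab <- tab[match(.montage_1020_19, tab$name), ]
  } else {
    tab <- tab[seq_len(n_channels), ]
  }
  new_montage(tab$name, as.matrix(tab[, c("px", "py", "pz")]))
}

#' Construct a montage from names and positions
#'
#' @param channel_names unique electrode labels.
#' @param positions numeric matrix, one row per channel, 3 columns; each row
#'   is normalized to unit length (must be within 1e-9 of unit norm or is
#'   rescaled from a nonzero vector).
#' @return An `ms_montage` object.
#' @export
new_montage <- function(channel_names, positions) {
  channel_names <- as.character(channel_names)
  positions <- as.matrix(positions)
  if (anyDuplicated(channel_names)) stop_invalid("channel names must be unique")
  if (length(channel_names) < 2L) stop_invalid("need at least 2 channels")
  if (nrow(positions) != length(channel_names) || ncol(positions) != 3L) {
    stop_invalid("positions must be an n_channels x 3 matrix")
  }
  nrm <- sqrt(rowSums(positions^2))
  if (any(nrm == 0)) stop_invalid("positions must be nonzero")
  positions <- positions / nrm
  dimnames(positions) <- list(channel_names, c("x", "y", "z"))
  structure(
    list(channel_names = channel_names, positions = positions,
         n_channels = length(channel_names)),
    class = "ms_montage"
  )
}

#' @export
print.ms_montage <- function(x, ...) {
  cat("<ms_montage> ", x$n_channels, " channels: ",
      paste(utils::head(x$channel_names, 6), collapse = ", "),
      if (x$n_channels > 6) ", ..." else "", "\n", sep = "")
  invisible(x)
}
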