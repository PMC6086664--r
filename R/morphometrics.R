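#' @include AllClasses.R livewire-tracing.R
NULL

#' Euclidean path length
#'
#' Sum of Euclidean step lengths between consecutive path pixels, using
#' the per-axis physical spacing. Invariant under path reversal and
#' additive under concatenation.
#'
#' @param path a \linkS4class{PixelPath}, a \linkS4class{FilopodiumTrace},
#'   or a numeric matrix with one pixel per row.
#' @param spacing micrometres per pixel per axis (taken from the object
#'   when a path class is supplied).
#' @return length in micrometres.
#' @examples
#' p <- cbind(row = 1:11, col = rep(1, 11))
#' pathLengthEuclidean(p, spacing = c(0.5, 0.5))   # 5 um
#' @export
pathLengthEuclidean <- function(path, spacing = NULL) {
  if (is(path, "PixelPath") || is(path, "FilopodiumTrace")) {
    spacing <- path@spacing
    path <- path@path
  }
  if (!is.matrix(path)) path <- matrix(path, nrow = 1L)
  if (nrow(path) < 1L) stop("path must contain at least one pixel")
  if (is.null(spacing)) spacing <- rep(1, ncol(path))
  if (length(spacing) != ncol(path))
    stop("'spacing' must have one entry per path axis")
  if (nrow(path) == 1L) return(0)
  steps <- diff(path) * rep(spacing, each = nrow(path) - 1L)
  sum(sqrt(rowSums(steps^2)))
}

#' Per-cell filopodia metrics
#'
#' Count, arithmetic mean length and cumulative length of a cell's traced
#' filopodia. A cell with no filopodia gets zero metrics flagged absent
#' via \code{hasFilopodia = FALSE}.
#'
#' @param traces list of \linkS4class{FilopodiumTrace}.
#' @return one-row data.frame with columns \code{count},
#'   \code{meanLengthUm}, \code{cumLengthUm}, \code{hasFilopodia}.
#' @export
cellMetrics <- function(traces) {
  lens <- vapply(traces, traceLength, numeric(1))
  n <- length(lens)
  data.frame(count = n,
             meanLengthUm = if (n) mean(lens) else 0,
             cumLengthUm = if (n) sum(lens) else 0,
             hasFilopodia = n > 0L)
}

#' Cell roundness (width/length ratio)
#'
#' Ratio of the minor to the major principal-axis extent of a mask,
#' computed from the second moments of its pixel coordinates (plus the
#' 1/12-pixel-area term, so a discrete rectangle scores its exact side
#' ratio). Ranges from 0 (infinitely elongated) to 1 (perfect circle);
#' invariant under rotation and uniform scaling.
#'
#' @param mask a non-empty 2D \linkS4class{BinaryMask}.
#' @return roundness in [0, 1].
#' @export
roundness <- function(mask) {
  stopifnot(is(mask, "BinaryMask"))
  v <- mask@values
  if (length(dim(v)) != 2L) stop("roundness is defined for 2D masks")
  if (!any(v)) stop("empty mask")
  xy <- which(v, arr.ind = TRUE)
  xy <- xy * rep(mask@spacing, each = nrow(xy))
  n <- nrow(xy)
  ctr <- colMeans(xy)
  dxy <- sweep(xy, 2L, ctr)
  cov <- crossprod(dxy) / n +
    diag(mask@spacing^2) / 12           # pixels as little squares
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  sqrt(max(ev[2L], 0) / ev[1L])
}

#' Percentile-based screen hit calling
#'
#' Given a screen table of per-gene relative filopodia number and length,
#' computes per-column thresholds at the requested percentile (linear
#' interpolation between order statistics) and calls a gene a hit iff both
#' its relative number and relative length are greater than or equal to
#' their thresholds (inclusive rule). Explicit thresholds may be supplied
#' instead of a percentile.
#'
#' @param records data.frame with columns \code{gene}, \code{rel_number},
#'   \code{rel_length}, all values > 0, at least two rows.
#' @param percentile percentile in (0, 100) used for both columns
#'   (ignored when \code{thresholds} is given).
#' @param thresholds optional explicit \code{c(number, length)} thresholds.
#' @return list with \code{thresholds} (named numeric: percentile, number,
#'   length) and \code{hits} (the hit rows of \code{records}).
#' @examples
#' rec <- data.frame(gene = c("a", "b"), rel_number = c(1.2, 0.9),
#'                   rel_length = c(1.5, 1.0))
#' screenHits(rec, thresholds = c(1.20, 1.25))
#' @export
screenHits <- function(records, percentile = 85, thresholds = NULL) {
  need <- c("gene", "rel_number", "rel_length")
  if (!is.data.frame(records) || !all(need %in% names(records)))
    stop("'records' needs columns gene, rel_number, rel_length")
  if (nrow(records) == 0L) stop("empty screen table")
  if (is.null(thresholds)) {
    if (nrow(records) < 2L)
      stop("need at least two records to compute percentile thresholds")
    if (!is.numeric(percentile) || percentile < 0 || percentile > 100)
      stop("'percentile' must lie in [0, 100]")
    thrN <- unname(stats::quantile(records$rel_number, percentile / 100,
                                   type = 7))
    thrL <- unname(stats::quantile(records$rel_length, percentile / 100,
                                   type = 7))
  } else {
    if (length(thresholds) != 2L)
      stop("'thresholds' must be c(number, length)")
    thrN <- thresholds[1L]
    thrL <- thresholds[2L]
    percentile <- NA_real_
  }
  isHit <- records$rel_number >= thrN & records$rel_length >= thrL
  list(thresholds = c(percentile = percentile, number = thrN,
                      length = thrL),
       hits = records[isHit, , drop = FALSE])
}
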