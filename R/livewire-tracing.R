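#' @include AllClasses.R imaging-core.R
NULL

#' PixelPath: an ordered pixel path with physical spacing
#'
#' Consecutive pixels are 8-neighbours (2D) or lateral 8-neighbour steps
#' with a bounded plane change (3D); no pixel repeats.
#'
#' @slot path integer matrix, one pixel per row, columns (row, col) or
#'   (plane, row, col), 1-based.
#' @slot spacing micrometres per pixel per axis.
#' @slot cost total livewire cost of the path (NA when not applicable).
#' @export
setClass("PixelPath",
  representation(path = "matrix", spacing = "numeric", cost = "numeric"),
  validity = function(object) {
    if (nrow(object@path) < 1L) return("path must contain a pixel")
    if (length(object@spacing) != ncol(object@path))
      return("'spacing' must match path dimensionality")
    if (anyDuplicated(object@path)) return("path must not repeat a pixel")
    TRUE
  }
)

setMethod("show", "PixelPath", function(object) {
  cat(sprintf("PixelPath: %d px, %d axes, length %.3f um, cost %.4g\n",
              nrow(object@path), ncol(object@path),
              pathLengthEuclidean(object), object@cost))
})

#' Convert an edge-strength map into a minimizable cost map
#'
#' \code{cost(p) = (max(edge) - edge(p)) + epsilon}, so the maximally
#' scoring pixel of the edge map has minimal cost and cost + edge is
#' constant everywhere.
#'
#' @param edgeMap a finite \linkS4class{SpacedImage} (typically the
#'   objectness response).
#' @param epsilon small positive offset keeping all costs > 0.
#' @return a non-negative cost \linkS4class{SpacedImage}.
#' @export
buildCostMap <- function(edgeMap, epsilon = 1e-6) {
  stopifnot(is(edgeMap, "SpacedImage"))
  v <- max(edgeMap@values) - edgeMap@values + epsilon
  SpacedImage(v, spacing = edgeMap@spacing, channel = edgeMap@channel)
}

## start/stop conversion helpers -------------------------------------------

.asStopMask <- function(stop, d) {
  if (is(stop, "BinaryMask")) {
    m <- stop@values
    if (!identical(dim(m), d)) stop("stop mask shape mismatch")
    return(m)
  }
  stopPix <- if (is.matrix(stop)) stop else matrix(stop, nrow = 1L)
  if (ncol(stopPix) != 2L) stop("stop pixels must be (row, col)")
  m <- array(FALSE, d)
  m[stopPix] <- TRUE
  m
}

#' Livewire shortest-path trace on a cost map
#'
#' Finds the minimum-total-cost 8-connected path from \code{start} to the
#' first pixel of the stop region reached. A step between pixels p and q
#' adds the mean of their two node costs times the geometric step length
#' (1 for axial, sqrt(2) for diagonal moves); the symmetric form makes
#' the total cost invariant under start/stop reversal. Ties are resolved
#' deterministically (lexicographic pixel order).
#'
#' @param cost a non-negative 2D cost \linkS4class{SpacedImage} (see
#'   \code{\link{buildCostMap}}).
#' @param start starting pixel, \code{c(row, col)}.
#' @param stop stop region: a \linkS4class{BinaryMask}, a pixel
#'   \code{c(row, col)}, or a matrix of stop pixels.
#' @return a \linkS4class{PixelPath} whose first pixel is \code{start} and
#'   whose last pixel is the first stop pixel reached.
#' @export
livewireTrace <- function(cost, start, stop) {
  stopifnot(is(cost, "SpacedImage"))
  v <- cost@values
  if (length(dim(v)) != 2L) stop("livewireTrace runs on 2D cost maps")
  if (any(v < 0)) stop("cost map must be non-negative")
  d <- dim(v)
  start <- as.integer(start)
  if (length(start) != 2L || any(start < 1L) || start[1] > d[1] ||
      start[2] > d[2])
    stop("'start' must be a pixel inside the grid")
  stopMask <- .asStopMask(stop, d)
  if (!any(stopMask)) stop("stop region is empty")
  res <- .cq_livewire(as.numeric(v), d[1], d[2],
                      (start[2] - 1L) * d[1] + start[1] - 1L,
                      as.logical(stopMask))
  if (!isTRUE(res$found))
    stop("no path: stop region unreachable from start")
  idx <- res$path
  path <- cbind(row = idx %% d[1] + 1L, col = idx %/% d[1] + 1L)
  storage.mode(path) <- "integer"
  new("PixelPath", path = path, spacing = cost@spacing, cost = res$cost)
}

#' Trace all filopodia of a segmented cell (2D)
#'
#' Runs a livewire search from every candidate tip towards the cell body
#' on the cost map derived from the edge-enhanced (objectness) image; each
#' trace terminates at the first body pixel reached. Traces shorter than
#' \code{minLengthPx} (geometric length in pixels) are discarded, and tips
#' already inside the body yield no trace. Tips whose search fails are
#' skipped with a warning. Because skeleton spurs can spawn several tips
#' on one filopodium, traces sharing at least \code{overlapFrac} of their
#' pixels with a longer trace are dropped (set \code{overlapFrac = 1} to
#' keep one trace per tip unconditionally).
#'
#' @param seg a \linkS4class{CellSegmentation}.
#' @param edgeMap the objectness response \linkS4class{SpacedImage} used as
#'   the edge map.
#' @param minLengthPx minimum geometric trace length, pixels.
#' @param cellId identifier attached to the traces.
#' @param overlapFrac pixel-overlap fraction above which the shorter of
#'   two traces is discarded.
#' @param intensity optional \linkS4class{SpacedImage} (typically the
#'   smoothed input image); when given, leading trace pixels whose
#'   intensity falls below \code{tipTrimFrac} of the on-path median are
#'   trimmed, correcting the slight overshoot of skeleton tips beyond
#'   the intensity terminus.
#' @param tipTrimFrac intensity fraction used for tip trimming.
#' @return list of \linkS4class{FilopodiumTrace}.
#' @export
traceFilopodia2d <- function(seg, edgeMap, minLengthPx = 5, cellId = "",
                             overlapFrac = 0.5, intensity = NULL,
                             tipTrimFrac = 0.5) {
  stopifnot(is(seg, "CellSegmentation"), is(edgeMap, "SpacedImage"))
  body <- seg@body@values
  if (!any(body)) stop("segmentation has an empty body")
  cost <- buildCostMap(edgeMap)
  out <- list()
  tips <- seg@tips
  for (i in seq_len(nrow(tips))) {
    tip <- tips[i, ]
    if (body[tip[1], tip[2]]) next                    # tip inside body
    p <- tryCatch(livewireTrace(cost, tip, seg@body),
                  error = function(e) NULL)
    if (is.null(p)) {
      warning(sprintf("tip (%d, %d) unreachable; skipped",
                      tip[1], tip[2]))
      next
    }
    path <- p@path
    if (!is.null(intensity) && nrow(path) > 2L)
      path <- .refineTip(path, intensity@values, tipTrimFrac)
    ## half-pixel end correction: endpoints sit at pixel centres inside
    ## the structure, so centre-to-centre measurement loses ~0.5 px at
    ## the tip and at the body entry
    endCorr <- mean(p@spacing)
    lenUm <- .polylineLength(path, p@spacing) + endCorr
    lenPx <- .polylineLength(path, c(1, 1)) + 1
    if (lenPx < minLengthPx) next
    out[[length(out) + 1L]] <- new("FilopodiumTrace", path = path,
      spacing = p@spacing, lengthUm = lenUm,
      tip = path[1L, ], cellId = as.character(cellId))
  }
  if (length(out) > 1L && overlapFrac < 1) {
    d <- dim(seg@body@values)
    ord <- order(vapply(out, traceLength, numeric(1)),
                 decreasing = TRUE)
    covered <- array(FALSE, d)
    kept <- list()
    for (i in ord) {
      p <- out[[i]]@path
      frac <- mean(covered[p])
      if (frac < overlapFrac) {
        kept[[length(kept) + 1L]] <- out[[i]]
        covered[p] <- TRUE
      }
    }
    ord2 <- order(vapply(kept, function(t) t@tip[1L] * (d[2L] + 1L) +
                           t@tip[2L], numeric(1)))
    out <- kept[ord2]
  }
  out
}

## Tip refinement against the (smoothed) intensity image: the skeleton
## endpoint can overshoot the intensity terminus by a few pixels (mask
## dilation) or fall short of it when noise truncates the faint tip.
## Both are corrected against the same criterion, a fraction of the
## median on-path intensity: leading low-intensity pixels are trimmed,
## and the trace is extended outward along the brightest forward
## neighbour while the intensity stays above the criterion.
.refineTip <- function(path, img, frac = 0.5, maxExtend = 8L) {
  vals <- img[path[, , drop = FALSE]]
  thr <- frac * stats::median(vals)
  ## trim overshoot (bounded: the skeleton error is a few px)
  k <- which(vals >= thr)[1L]
  if (is.na(k)) k <- 1L
  k <- min(k, 5L)
  path <- path[k:nrow(path), , drop = FALSE]
  ## extend a truncated tip outward
  n <- nrow(path)
  if (n >= 3L) {
    d <- dim(img)
    back <- min(4L, n - 1L)
    dir <- path[1L, ] - path[1L + back, ]
    nv <- sqrt(sum(dir^2))
    if (nv > 0) {
      dir <- dir / nv
      cur <- path[1L, ]
      for (step in seq_len(maxExtend)) {
        best <- NULL; bestVal <- -Inf
        for (dr in -1:1) for (dc in -1:1) {
          if (dr == 0 && dc == 0) next
          nb <- cur + c(dr, dc)
          if (nb[1] < 1 || nb[1] > d[1] || nb[2] < 1 || nb[2] > d[2])
            next
          stepv <- c(dr, dc) / sqrt(dr^2 + dc^2)
          if (sum(stepv * dir) < 0.5) next        # forward cone only
          if (any(path[, 1] == nb[1] & path[, 2] == nb[2])) next
          v <- img[nb[1], nb[2]]
          if (v > bestVal) { bestVal <- v; best <- nb }
        }
        if (is.null(best) || bestVal < thr) break
        path <- rbind(best, path)
        dir <- 0.5 * dir + 0.5 * (best - cur) / sqrt(sum((best - cur)^2))
        dir <- dir / sqrt(sum(dir^2))
        cur <- best
      }
    }
  }
  path
}

## Length of a pixel chain measured on a smoothed polyline: a centred
## moving average (window 5, shrinking at the ends so the endpoints stay
## put) removes the systematic over-measurement of 8-connected chains
## along oblique straight structures before the Euclidean sum.
.polylineLength <- function(path, spacing, window = 5L) {
  n <- nrow(path)
  if (n < 2L) return(0)
  h <- window %/% 2L
  sm <- path
  if (n > 2L) {
    for (j in seq_len(ncol(path))) {
      cs <- cumsum(c(0, path[, j]))
      i <- seq_len(n)
      lo <- pmax(i - h, 1L)
      hi <- pmin(i + h, n)
      ## symmetric shrinking window
      half <- pmin(i - lo, hi - i)
      lo <- i - half; hi <- i + half
      sm[, j] <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
    }
  }
  steps <- diff(sm) * rep(spacing, each = n - 1L)
  sum(sqrt(rowSums(steps^2)))
}

## Dynamic programme assigning a plane to every lateral path position:
## maximize the summed voxel intensity subject to |delta z| <= zStep per
## lateral step, with both end planes pinned. profile is an
## nPositions x nPlanes matrix of intensities. Ties prefer the smaller
## plane index. Returns the 1-based plane per position.
.zAssignDP <- function(profile, zStart, zEnd, zStep = 1L) {
  M <- nrow(profile); nz <- ncol(profile)
  if (abs(zEnd - zStart) > (M - 1L) * zStep)
    stop("end plane unreachable under the plane-step constraint")
  if (M == 1L) {
    if (zStart != zEnd) stop("single-position path with differing planes")
    return(zStart)
  }
  NEG <- -Inf
  dp <- matrix(NEG, M, nz)
  dp[1L, zStart] <- profile[1L, zStart]
  pred <- matrix(0L, M, nz)
  for (i in 2:M) {
    for (z in seq_len(nz)) {
      zs <- max(1L, z - zStep):min(nz, z + zStep)
      vals <- dp[i - 1L, zs]
      j <- which.max(vals)                 # first max: smallest plane wins
      if (is.finite(vals[j])) {
        dp[i, z] <- vals[j] + profile[i, z]
        pred[i, z] <- zs[j]
      }
    }
  }
  if (!is.finite(dp[M, zEnd]))
    stop("no admissible plane assignment")
  z <- integer(M)
  z[M] <- zEnd
  for (i in M:2) z[i - 1L] <- pred[i, z[i]]
  z
}

#' Semi-automatic 3D filopodium tracing
#'
#' Two-stage search, given user-provided start and end voxels: the lateral
#' (row, col) path is found by livewire on the objectness-filtered axial
#' maximum-intensity projection; the plane per path position is then
#' assigned by dynamic programming maximizing the summed voxel intensity
#' along the path, with at most \code{zStep} plane change per lateral step
#' and the end planes pinned at the provided voxels.
#'
#' @param img3d a 3D \linkS4class{SpacedImage}, indexed (plane, row, col).
#' @param start,end voxels \code{c(plane, row, col)}.
#' @param zStep maximum plane change per lateral step.
#' @param params \linkS4class{ObjectnessParams} for the projected edge map.
#' @return a 3D \linkS4class{PixelPath} (plane, row, col).
#' @export
traceFilopodium3d <- function(img3d, start, end, zStep = 1L,
                              params = objectnessParams()) {
  stopifnot(is(img3d, "SpacedImage"))
  A <- img3d@values
  if (length(dim(A)) != 3L) stop("'img3d' must be a 3D image")
  d <- dim(A)
  start <- as.integer(start); end <- as.integer(end)
  for (p in list(start, end))
    if (length(p) != 3L || any(p < 1L) || any(p > d))
      stop("start and end must be voxels inside the volume")
  mip <- apply(A, c(2L, 3L), max)
  edge <- objectnessFilter(SpacedImage(mip, spacing = img3d@spacing[2:3]),
                           params)
  lat <- livewireTrace(buildCostMap(edge), start[2:3], end[2:3])
  lp <- lat@path
  profile <- matrix(A[cbind(rep(seq_len(d[1]), each = nrow(lp)),
                            rep(lp[, 1L], d[1]),
                            rep(lp[, 2L], d[1]))],
                    nrow = nrow(lp))
  z <- .zAssignDP(profile, start[1], end[1], zStep = as.integer(zStep))
  path <- cbind(plane = as.integer(z), row = lp[, 1L], col = lp[, 2L])
  new("PixelPath", path = path, spacing = img3d@spacing, cost = lat@cost)
}
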