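#' @include AllClasses.R imaging-core.R livewire-tracing.R morphometrics.R
NULL

#' Configuration of the filopodia detection pipeline
#'
#' Defaults are the reference pipeline parameters: Gaussian smoothing with
#' variance 1 px^2 (sigma = 1), objectness (sigma = 1, alpha = 1, beta = 1,
#' gamma = 0.003, line-like order 2), local adaptive threshold (window
#' radius 200 px, multiplier 1, sized for ~1024 px fields) and opening
#' radius 2 px. The remaining knobs are the package's own cleanup
#' defaults: a 5 px minimum trace length, 10 px minimum ridge-component
#' area and 50% trace-overlap deduplication (see the methods vignette).
#'
#' @param smoothSigma Gaussian smoothing sigma, px.
#' @param objectness an \linkS4class{ObjectnessParams}.
#' @param threshold a \linkS4class{ThresholdParams}.
#' @param openRadius opening disc radius, px.
#' @param minLengthPx minimum filopodium trace length, px (geometric;
#'   protrusions shorter than this are treated as segmentation noise).
#' @param minFiloAreaPx connected components of the ridge (filopodia) mask
#'   smaller than this many pixels are discarded as speckle before the
#'   masks are combined.
#' @param overlapFrac traces sharing at least this fraction of their
#'   pixels with a longer trace are dropped (skeleton-spur
#'   deduplication).
#' @param minBodyAreaPx a segmentation whose largest body component is
#'   smaller than this is rejected (guards against pure-noise fields
#'   masquerading as a cell).
#' @return a named list understood by \code{\link{segmentCell}} and
#'   friends.
#' @export
filopodiaConfig <- function(smoothSigma = 1,
                            objectness = objectnessParams(),
                            threshold = thresholdParams(),
                            openRadius = 2L, minLengthPx = 5,
                            minFiloAreaPx = 10L, overlapFrac = 0.5,
                            minBodyAreaPx = 50L) {
  stopifnot(is(objectness, "ObjectnessParams"),
            is(threshold, "ThresholdParams"),
            smoothSigma > 0, openRadius >= 1, minLengthPx >= 0,
            minFiloAreaPx >= 0, overlapFrac > 0, overlapFrac <= 1,
            minBodyAreaPx >= 1)
  list(smoothSigma = smoothSigma, objectness = objectness,
       threshold = threshold, openRadius = as.integer(openRadius),
       minLengthPx = minLengthPx,
       minFiloAreaPx = as.integer(minFiloAreaPx),
       overlapFrac = overlapFrac,
       minBodyAreaPx = as.integer(minBodyAreaPx))
}

## full pipeline, returning the intermediate edge map for reuse
.segmentCellFull <- function(img, cfg = filopodiaConfig()) {
  stopifnot(is(img, "SpacedImage"))
  smoothed <- gaussianSmooth(img, cfg$smoothSigma)
  edge <- objectnessFilter(smoothed, cfg$objectness)
  filoMask <- localAdaptiveThreshold(edge, cfg$threshold)
  if (cfg$minFiloAreaPx > 0 && any(filoMask@values)) {
    lab <- .cq_label(as.logical(filoMask@values),
                     as.integer(dim(filoMask@values)))
    keep <- which(tabulate(lab) >= cfg$minFiloAreaPx)
    v <- array(lab %in% keep, dim(filoMask@values))
    filoMask <- BinaryMask(v, spacing = filoMask@spacing)
  }
  bodyThresh <- localAdaptiveThreshold(smoothed, cfg$threshold)
  bodyOpen <- morphologicalOpen(bodyThresh, cfg$openRadius)
  if (!any(bodyOpen@values))
    stop("segmentation failed: no cell body left after opening")
  body <- largestComponent(bodyOpen)
  if (sum(body@values) < cfg$minBodyAreaPx)
    stop("segmentation failed: largest component below the minimum ",
         "body area (no dominant cell in the field)")
  combined <- combineMasks(body, filoMask)
  ## single-cell field of view: keep the component containing the body
  lab <- .cq_label(as.logical(combined@values),
                   as.integer(dim(combined@values)))
  bodyLab <- lab[which(body@values)[1L]]
  combined <- BinaryMask(array(lab == bodyLab, dim(combined@values)),
                         spacing = combined@spacing)
  ep <- skeletonEndpoints(combined)
  if (nrow(ep)) {
    outside <- !body@values[ep]
    ep <- ep[outside, , drop = FALSE]
  }
  seg <- new("CellSegmentation", body = body, combined = combined,
             tips = ep)
  list(seg = seg, edge = edge, smoothed = smoothed)
}

#' Segment a single cell and its filopodia
#'
#' End-to-end segmentation of a single-cell field of view: Gaussian
#' smoothing; in one branch, objectness ridge enhancement followed by the
#' local adaptive threshold (filopodia mask); in the other, the local
#' adaptive threshold on the smoothed image, a morphological opening and
#' the largest connected component (cell body). The combined mask is their
#' union and candidate tips are the skeleton endpoints of the combined
#' mask lying outside the body.
#'
#' @param img a 2D \linkS4class{SpacedImage} (membrane-marker channel).
#' @param cfg a \code{\link{filopodiaConfig}} list.
#' @return a \linkS4class{CellSegmentation}.
#' @export
segmentCell <- function(img, cfg = filopodiaConfig()) {
  .segmentCellFull(img, cfg)$seg
}

#' Segment and trace a single cell
#'
#' Runs \code{\link{segmentCell}} and then traces every candidate tip back
#' to the cell body with the livewire on the objectness edge map.
#'
#' @inheritParams segmentCell
#' @param cellId identifier attached to the traces.
#' @return list with elements \code{seg} (a
#'   \linkS4class{CellSegmentation}) and \code{traces} (list of
#'   \linkS4class{FilopodiumTrace} with micron lengths).
#' @export
analyzeCell <- function(img, cfg = filopodiaConfig(), cellId = "") {
  full <- .segmentCellFull(img, cfg)
  traces <- traceFilopodia2d(full$seg, full$edge,
                             minLengthPx = cfg$minLengthPx,
                             cellId = cellId,
                             overlapFrac = cfg$overlapFrac,
                             intensity = full$smoothed)
  list(seg = full$seg, traces = traces)
}

#' Batch per-cell filopodia quantification
#'
#' Analyzes a set of single-cell images and tabulates per-cell filopodia
#' count, mean length and cumulative length. Per-image failures are logged
#' as warnings and omitted from the table, not fatal.
#'
#' @param images list of 2D \linkS4class{SpacedImage}s (or a single
#'   image).
#' @param cfg a \code{\link{filopodiaConfig}} list.
#' @param ids image identifiers (defaults to list names or indices).
#' @return data.frame with columns \code{image}, \code{cell},
#'   \code{count}, \code{meanLengthUm}, \code{cumLengthUm}.
#' @export
batchAnalyze <- function(images, cfg = filopodiaConfig(), ids = NULL) {
  if (is(images, "SpacedImage")) images <- list(images)
  if (is.null(ids)) {
    ids <- names(images)
    if (is.null(ids)) ids <- as.character(seq_along(images))
  }
  rows <- vector("list", length(images))
  for (i in seq_along(images)) {
    res <- tryCatch(analyzeCell(images[[i]], cfg, cellId = ids[i]),
                    error = function(e) e)
    if (inherits(res, "error")) {
      warning(sprintf("image '%s' failed: %s", ids[i],
                      conditionMessage(res)))
      next
    }
    m <- cellMetrics(res$traces)
    rows[[i]] <- data.frame(image = ids[i], cell = ids[i],
                            count = m$count,
                            meanLengthUm = m$meanLengthUm,
                            cumLengthUm = m$cumLengthUm)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(image = character(), cell = character(),
                      count = integer(), meanLengthUm = numeric(),
                      cumLengthUm = numeric()))
  do.call(rbind, rows)
}
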