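#' @include AllClasses.R
NULL

#' Read a grayscale TIFF image or stack
#'
#' Multi-page TIFFs become 3D images indexed (plane, row, col). Pixel
#' spacing is taken from the TIFF resolution tags when present; an
#' explicit \code{spacing} argument always wins.
#'
#' @param path TIFF file.
#' @param spacing micrometres per pixel (scalar or per axis); overrides
#'   file metadata.
#' @param channel channel label to attach.
#' @return a \linkS4class{SpacedImage}.
#' @export
readImageTiff <- function(path, spacing = NULL, channel = "") {
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  toGray <- function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1L]      # first channel
    p
  }
  fileSpacing <- NULL
  xres <- attr(pages[[1L]], "x.resolution")
  if (!is.null(xres) && is.finite(xres) && xres > 0) {
    unit <- attr(pages[[1L]], "resolution.unit")
    perUm <- switch(as.character(unit %||% "none"),
                    "inch" = xres / 25400, "cm" = xres / 1e4, xres)
    if (perUm > 0) fileSpacing <- 1 / perUm
  }
  vals <- if (length(pages) == 1L) {
    v <- toGray(pages[[1L]])
    attributes(v) <- list(dim = dim(v))    # drop TIFF info attributes
    v
  } else {
    arr <- array(0, c(length(pages), dim(toGray(pages[[1L]]))))
    for (i in seq_along(pages)) arr[i, , ] <- toGray(pages[[i]])
    arr
  }
  nd <- length(dim(vals))
  sp <- if (!is.null(spacing)) spacing
        else if (!is.null(fileSpacing)) rep(fileSpacing, nd)
        else rep(1, nd)
  SpacedImage(vals, spacing = sp, channel = channel)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an image as a 16-bit grayscale TIFF
#'
#' Intensities are expected in [0, 1] (out-of-range values are clipped);
#' 3D images are written as multi-page stacks. Pixel spacing is not
#' embedded in the file; supply it on read (or via config, which always
#' wins over file metadata).
#'
#' @param img a \linkS4class{SpacedImage}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeImageTiff <- function(img, path) {
  stopifnot(is(img, "SpacedImage"))
  v <- pmin(pmax(img@values, 0), 1)
  if (length(dim(v)) == 2L) {
    tiff::writeTIFF(v, path, bits.per.sample = 16L)
  } else {
    pages <- lapply(seq_len(dim(v)[1L]), function(p) v[p, , ])
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  }
  invisible(path)
}

#' Write a binary mask as an 8-bit TIFF (0 / 255)
#'
#' @param mask a 2D \linkS4class{BinaryMask}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeMaskTiff <- function(mask, path) {
  stopifnot(is(mask, "BinaryMask"))
  tiff::writeTIFF(mask@values * 1, path, bits.per.sample = 8L)
  invisible(path)
}

#' Read / write line-scan FCS pseudo images
#'
#' Photon-count x-t records are stored as 32-bit float TIFF scaled by
#' 1/65535 (the tiff container stores [0, 1]); reading restores the count
#' scale.
#'
#' @param rec a \linkS4class{LineScanRecord}.
#' @param path TIFF file.
#' @param pixelStepNm,linePeriodS,channel metadata attached on read.
#' @return \code{writeLineScanTiff}: the path; \code{readLineScanTiff}: a
#'   \linkS4class{LineScanRecord}.
#' @export
writeLineScanTiff <- function(rec, path) {
  stopifnot(is(rec, "LineScanRecord"))
  tiff::writeTIFF(rec@image / 65535, path, bits.per.sample = 32L)
  invisible(path)
}

#' @rdname writeLineScanTiff
#' @export
readLineScanTiff <- function(path, pixelStepNm = 100, linePeriodS = 0.002,
                             channel = "") {
  m <- tiff::readTIFF(path)
  lineScanRecord(m * 65535, pixelStepNm = pixelStepNm,
                 linePeriodS = linePeriodS, channel = channel)
}

#' Read a simulation config from YAML
#'
#' Keys map 1:1 to \linkS4class{SimConfig} fields; missing keys fall back
#' to the defaults and unknown keys raise an error naming the offending
#' key. Arguments in \code{...} override file values.
#'
#' @param path YAML file.
#' @param ... overriding \linkS4class{SimConfig} fields.
#' @return a \linkS4class{SimConfig}.
#' @export
readSimConfig <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  over <- list(...)
  vals[names(over)] <- over
  do.call(simConfig, vals)
}

#' Read a screen table from CSV
#'
#' @param path CSV with header \code{gene,rel_number,rel_length}.
#' @return data.frame.
#' @export
readScreenTable <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("gene", "rel_number", "rel_length")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("screen table is missing column(s): ",
         paste(miss, collapse = ", "))
  tab
}

#' Write screen hits plus threshold metadata
#'
#' Hits go to CSV; the thresholds (and percentile) to a JSON sidecar
#' \code{<path>.thresholds.json}.
#'
#' @param result output of \code{\link{screenHits}}.
#' @param path CSV output file.
#' @return the path, invisibly.
#' @export
writeScreenHits <- function(result, path) {
  utils::write.csv(result$hits, path, row.names = FALSE)
  jsonlite::write_json(as.list(result$thresholds),
                       paste0(path, ".thresholds.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export traces as CSV
#'
#' One row per path pixel: trace id, point index, pixel coordinates and
#' physical coordinates in micrometres (x = col, y = row[, z = plane]).
#'
#' @param traces list of \linkS4class{FilopodiumTrace} (or
#'   \linkS4class{PixelPath}).
#' @param path CSV output file.
#' @return the path, invisibly.
#' @export
writeTracesCsv <- function(traces, path) {
  rows <- list()
  for (i in seq_along(traces)) {
    tr <- traces[[i]]
    p <- tr@path
    sp <- tr@spacing
    if (ncol(p) == 2L) {
      df <- data.frame(trace = i, point = seq_len(nrow(p)),
                       row_px = p[, 1L], col_px = p[, 2L],
                       x_um = p[, 2L] * sp[2L], y_um = p[, 1L] * sp[1L])
    } else {
      df <- data.frame(trace = i, point = seq_len(nrow(p)),
                       plane_px = p[, 1L], row_px = p[, 2L],
                       col_px = p[, 3L],
                       x_um = p[, 3L] * sp[3L], y_um = p[, 2L] * sp[2L],
                       z_um = p[, 1L] * sp[1L])
    }
    df$length_um <- if (is(tr, "FilopodiumTrace")) tr@lengthUm
                    else pathLengthEuclidean(tr)
    rows[[i]] <- df
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(trace = integer(), point = integer())
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write a detection overlay PNG
#'
#' Grayscale image with the body outline and traces in colour (body rim
#' blue, traces red, tips green).
#'
#' @param img the analyzed \linkS4class{SpacedImage}.
#' @param seg the \linkS4class{CellSegmentation}.
#' @param traces list of \linkS4class{FilopodiumTrace}.
#' @param path PNG output file.
#' @return the path, invisibly.
#' @export
writeOverlayPng <- function(img, seg, traces, path) {
  v <- img@values
  v <- (v - min(v)) / max(max(v) - min(v), .Machine$double.eps)
  r <- g <- b <- v
  body <- seg@body@values
  rim <- body & !(shiftMat(body, 1, 0) & shiftMat(body, -1, 0) &
                    shiftMat(body, 0, 1) & shiftMat(body, 0, -1))
  b[rim] <- 1; r[rim] <- 0; g[rim] <- 0
  for (tr in traces) {
    p <- tr@path
    idx <- cbind(p[, 1L], p[, 2L])
    r[idx] <- 1; g[idx] <- 0; b[idx] <- 0
  }
  tips <- seg@tips
  if (nrow(tips)) {
    g[tips] <- 1; r[tips] <- 0; b[tips] <- 0
  }
  arr <- array(c(r, g, b), c(dim(v), 3L))
  grDevices::png(path, width = ncol(v), height = nrow(v))
  op <- graphics::par(mar = c(0, 0, 0, 0))
  graphics::plot.new()
  graphics::rasterImage(arr, 0, 0, 1, 1, interpolate = FALSE)
  graphics::par(op)
  grDevices::dev.off()
  invisible(path)
}
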