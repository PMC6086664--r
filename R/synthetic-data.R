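#' @include AllClasses.R
NULL

## quantize intensities to a 16-bit grid in [0, 1]; this emulates a 16-bit
## camera and makes TIFF round trips bit-exact
.quantize16 <- function(x) {
  x <- pmin(pmax(x, 0), 1)
  round(x * 65535) / 65535
}

## anti-aliased distance-based rendering of a thick segment into a canvas
.renderSegment <- function(canvas, p0, p1, width, intensity) {
  nr <- nrow(canvas); nc <- ncol(canvas)
  pad <- width / 2 + 2
  r0 <- max(1L, floor(min(p0[1], p1[1]) - pad))
  r1 <- min(nr, ceiling(max(p0[1], p1[1]) + pad))
  c0 <- max(1L, floor(min(p0[2], p1[2]) - pad))
  c1 <- min(nc, ceiling(max(p0[2], p1[2]) + pad))
  rs <- r0:r1; cs <- c0:c1
  R <- matrix(rs, length(rs), length(cs))
  C <- matrix(cs, length(rs), length(cs), byrow = TRUE)
  v <- p1 - p0
  vv <- sum(v^2)
  t <- if (vv > 0) ((R - p0[1]) * v[1] + (C - p0[2]) * v[2]) / vv else 0
  t <- pmin(pmax(t, 0), 1)
  d <- sqrt((R - (p0[1] + t * v[1]))^2 + (C - (p0[2] + t * v[2]))^2)
  val <- pmin(pmax(width / 2 + 0.5 - d, 0), 1) * intensity
  canvas[rs, cs] <- pmax(canvas[rs, cs], val)
  canvas
}

#' Render a synthetic membrane-marker cell with known filopodia
#'
#' Draws a filled disc (the cell body, anti-aliased rim) plus thin
#' anti-aliased line filopodia radiating from the rim, adds optional
#' Gaussian noise, and quantizes to a 16-bit intensity grid. The returned
#' ground truth lists each filopodium's true tip pixel and true Euclidean
#' length (rim to tip) in micrometres. Deterministic given the spec seed.
#'
#' @param spec a \linkS4class{SyntheticCellSpec}.
#' @return list with \code{image} (a \linkS4class{SpacedImage}) and
#'   \code{truth} (data.frame: id, angle, lengthPx, lengthUm, tipRow,
#'   tipCol; plus body centre/radius as attributes).
#' @export
makeCellImage <- function(spec) {
  stopifnot(is(spec, "SyntheticCellSpec"))
  set.seed(spec@seed)
  nr <- spec@imageSize[1L]; nc <- spec@imageSize[2L]
  ctr <- (c(nr, nc) + 1) / 2
  R <- matrix(seq_len(nr), nr, nc)
  C <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  d <- sqrt((R - ctr[1])^2 + (C - ctr[2])^2)
  canvas <- pmin(pmax(spec@bodyRadiusPx + 0.5 - d, 0), 1) *
    spec@bodyIntensity
  fl <- spec@filopodia
  truth <- data.frame(id = integer(), angle = numeric(),
                      lengthPx = numeric(), lengthUm = numeric(),
                      tipRow = numeric(), tipCol = numeric())
  for (i in seq_len(nrow(fl))) {
    a <- fl$angle[i]
    dir <- c(-sin(a), cos(a))          # +angle turns counter-clockwise
    p0 <- ctr + spec@bodyRadiusPx * dir
    p1 <- ctr + (spec@bodyRadiusPx + fl$lengthPx[i]) * dir
    if (p1[1] < 2 || p1[1] > nr - 1 || p1[2] < 2 || p1[2] > nc - 1)
      stop(sprintf("filopodium %d exits the image bounds", i))
    canvas <- .renderSegment(canvas, p0, p1, fl$widthPx[i],
                             fl$intensity[i])
    truth <- rbind(truth, data.frame(id = i, angle = a,
      lengthPx = fl$lengthPx[i],
      lengthUm = fl$lengthPx[i] * spec@spacingUm,
      tipRow = round(p1[1]), tipCol = round(p1[2])))
  }
  if (spec@noiseSd > 0)
    canvas <- canvas + stats::rnorm(length(canvas), 0, spec@noiseSd)
  canvas <- .quantize16(canvas)
  dim(canvas) <- c(nr, nc)
  attr(truth, "bodyCenter") <- ctr
  attr(truth, "bodyRadiusPx") <- spec@bodyRadiusPx
  list(image = SpacedImage(canvas, spacing = spec@spacingUm,
                           channel = "memCherry"),
       truth = truth)
}

## 8-connected digital line between two pixels (Bresenham-like via
## rounded linear interpolation at unit parameter steps)
.digitalLine <- function(p0, p1) {
  nsteps <- max(abs(round(p1) - round(p0)))
  if (nsteps == 0) return(matrix(round(p0), 1L))
  t <- seq(0, 1, length.out = nsteps + 1L)
  pts <- round(cbind(p0[1] + t * (p1[1] - p0[1]),
                     p0[2] + t * (p1[2] - p0[2])))
  pts[!duplicated(pts), , drop = FALSE]
}

#' Render a synthetic 3D cell stack with known filopodium paths
#'
#' Voxelizes the 2D synthetic cell into a stack: the body sits in the
#' central plane and each filopodium follows a linear plane trajectory
#' (at most \code{maxZSlope} planes per lateral pixel, so the true path
#' obeys the one-plane-per-step rule used by the 3D tracer); everything
#' is blurred along the plane axis with a Gaussian. Ground truth is the
#' true voxel path (plane, row, col) of every filopodium.
#'
#' @param spec a \linkS4class{SyntheticCellSpec}.
#' @param nPlanes number of planes.
#' @param zBlurSd plane-axis Gaussian blur, planes.
#' @param zSlopes optional per-filopodium plane change per lateral pixel
#'   (|slope| <= \code{maxZSlope}); random in [-maxZSlope, maxZSlope]
#'   when missing.
#' @param maxZSlope bound on the plane slope.
#' @return list with \code{image} (3D \linkS4class{SpacedImage}, (plane,
#'   row, col)) and \code{truth} (list of voxel-path matrices plus the
#'   spec-level 2D truth).
#' @export
makeCellStack <- function(spec, nPlanes = 16L, zBlurSd = 0.8,
                          zSlopes = NULL, maxZSlope = 0.5) {
  stopifnot(is(spec, "SyntheticCellSpec"))
  set.seed(spec@seed)
  nr <- spec@imageSize[1L]; nc <- spec@imageSize[2L]
  zc <- ceiling(nPlanes / 2)
  ctr <- (c(nr, nc) + 1) / 2
  fl <- spec@filopodia
  if (is.null(zSlopes)) {
    zSlopes <- stats::runif(nrow(fl), -maxZSlope, maxZSlope)
  } else if (length(zSlopes) != nrow(fl)) {
    stop("need one z slope per filopodium")
  }
  ## clamp slopes so trajectories stay inside the stack
  for (i in seq_len(nrow(fl))) {
    lim <- (min(zc - 2, nPlanes - 1 - zc)) / max(fl$lengthPx[i], 1)
    zSlopes[i] <- sign(zSlopes[i]) * min(abs(zSlopes[i]), lim, maxZSlope)
  }
  vol <- array(0, c(nPlanes, nr, nc))
  zw <- function(z0) exp(-((seq_len(nPlanes) - z0)^2) / (2 * zBlurSd^2))
  ## body disc in the central plane
  plane <- matrix(0, nr, nc)
  R <- matrix(seq_len(nr), nr, nc)
  C <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  d <- sqrt((R - ctr[1])^2 + (C - ctr[2])^2)
  plane <- pmin(pmax(spec@bodyRadiusPx + 0.5 - d, 0), 1) *
    spec@bodyIntensity
  wz <- zw(zc)
  for (p in seq_len(nPlanes))
    vol[p, , ] <- pmax(vol[p, , ], plane * wz[p])
  truthPaths <- list()
  for (i in seq_len(nrow(fl))) {
    a <- fl$angle[i]
    dir <- c(-sin(a), cos(a))
    p0 <- ctr + spec@bodyRadiusPx * dir
    p1 <- ctr + (spec@bodyRadiusPx + fl$lengthPx[i]) * dir
    if (p1[1] < 2 || p1[1] > nr - 1 || p1[2] < 2 || p1[2] > nc - 1)
      stop(sprintf("filopodium %d exits the image bounds", i))
    ## splat anti-aliased samples along the segment with a z-Gaussian
    nsamp <- max(2L, ceiling(2 * fl$lengthPx[i]))
    ts <- seq(0, 1, length.out = nsamp)
    for (t in ts) {
      pt <- p0 + t * (p1 - p0)
      zt <- zc + zSlopes[i] * t * fl$lengthPx[i]
      wz <- zw(zt)
      rs <- max(1L, floor(pt[1] - 1)):min(nr, ceiling(pt[1] + 1))
      cs <- max(1L, floor(pt[2] - 1)):min(nc, ceiling(pt[2] + 1))
      lat <- outer(rs, cs, function(r, c)
        pmin(pmax(fl$widthPx[i] / 2 + 0.5 -
                    sqrt((r - pt[1])^2 + (c - pt[2])^2), 0), 1))
      for (p in seq_len(nPlanes))
        vol[p, rs, cs] <- pmax(vol[p, rs, cs],
                               fl$intensity[i] * lat * wz[p])
    }
    lp <- .digitalLine(p0, p1)
    tt <- seq(0, 1, length.out = nrow(lp))
    zpath <- round(zc + zSlopes[i] * tt * fl$lengthPx[i])
    truthPaths[[i]] <- cbind(plane = as.integer(zpath),
                             row = as.integer(lp[, 1L]),
                             col = as.integer(lp[, 2L]))
  }
  if (spec@noiseSd > 0)
    vol <- vol + stats::rnorm(length(vol), 0, spec@noiseSd)
  vol <- .quantize16(vol)
  dim(vol) <- c(nPlanes, nr, nc)
  list(image = SpacedImage(vol,
         spacing = c(spec@spacingUm * 2, spec@spacingUm, spec@spacingUm),
         channel = "memCherry"),
       truth = list(paths = truthPaths, zSlopes = zSlopes,
                    bodyPlane = zc))
}

#' Simulate a two-colour line-scan FCS record
#'
#' Point emitters perform 2D Brownian motion on a periodic membrane strip
#' and are detected through an elliptical Gaussian focus (lateral waist
#' \code{w0}, axial waist \code{S w0}); per scan line, the detected rate
#' is spread as a Gaussian membrane profile across the scan pixels,
#' background is added and Poisson shot noise applied. The number of
#' molecules per species is drawn from a Poisson law at the requested
#' density, so correlation amplitudes carry the full occupation-number
#' statistics. Deterministic given the spec seed.
#'
#' @param spec an \linkS4class{FcsSimSpec}.
#' @param shotNoise apply Poisson noise (disable for noise-free
#'   fixtures).
#' @return list with \code{green}, \code{red}
#'   (\linkS4class{LineScanRecord}s) and \code{truth} (species table,
#'   drawn molecule numbers, expected amplitudes).
#' @export
simulateLsfcs <- function(spec, shotNoise = TRUE) {
  stopifnot(is(spec, "FcsSimSpec"))
  set.seed(spec@seed)
  nLines <- as.integer(round(spec@durationS / spec@linePeriodS))
  if (nLines < 10L) stop("record too short")
  sp <- spec@species
  area <- spec@boxLengthUm * spec@boxDepthUm
  N <- stats::rpois(nrow(sp), sp$density * area)
  base <- spec@membraneCenterPx +
    spec@membraneDriftPx * (seq_len(nLines) - 1L) / max(nLines - 1L, 1L)
  if (spec@membraneJitterPx > 0)
    base <- base + stats::rnorm(nLines, 0, spec@membraneJitterPx)
  profileSdPx <- (spec@w0 / 2) / (spec@pixelStepNm / 1000)
  res <- .cq_fcs_sim(nLines, spec@pixelsPerLine, sp$D, as.integer(N),
                     sp$brightGreen, sp$brightRed, spec@w0, spec@S,
                     spec@boxLengthUm, spec@boxDepthUm, spec@linePeriodS,
                     base, profileSdPx, spec@backgroundPerPixel,
                     isTRUE(shotNoise))
  Aeff <- pi * spec@w0^2 * spec@S
  truth <- list(species = sp, nMolecules = N,
                tauD = ifelse(sp$D > 0, spec@w0^2 / (4 * sp$D), Inf),
                G0SingleSpecies = ifelse(sp$density > 0,
                                         1 / (sp$density * Aeff), NA),
                Aeff = Aeff)
  list(green = lineScanRecord(res$green, pixelStepNm = spec@pixelStepNm,
         linePeriodS = spec@linePeriodS, channel = "green"),
       red = lineScanRecord(res$red, pixelStepNm = spec@pixelStepNm,
         linePeriodS = spec@linePeriodS, channel = "red"),
       truth = truth)
}

#' Species tables for the two measured membrane spots
#'
#' Convenience ground-truth species tables: \code{"spot1"} is a single
#' red-labelled receptor species (D = 0.28 um^2/s, 37 um^-2, no green
#' signal); \code{"spot2-bound"} is the dual-labelled ligand-receptor
#' complex diffusing slowly as large clusters (D = 0.02 um^2/s; density
#' is a documented calibration choice, not a printed value).
#'
#' @param kind \code{"spot1"} or \code{"spot2-bound"}.
#' @param brightness expected photons per molecule per line at focus.
#' @return species data.frame for \code{\link{fcsSimSpec}}.
#' @export
fcsSpeciesTable <- function(kind = c("spot1", "spot2-bound"),
                            brightness = 20) {
  kind <- match.arg(kind)
  switch(kind,
    "spot1" = data.frame(D = 0.28, density = 37,
                         brightGreen = 0, brightRed = brightness),
    "spot2-bound" = data.frame(D = 0.02, density = 20,
                               brightGreen = brightness,
                               brightRed = brightness))
}

#' Generate a synthetic kinase-screen table with planted hits
#'
#' Background genes draw relative filopodia number and length from a
#' lognormal law around 1; planted hits sit a fixed margin above the
#' background percentile thresholds in both columns. Deterministic given
#' the seed.
#'
#' @param nGenes number of genes, >= 10.
#' @param nHits number of planted hits.
#' @param hitMargin relative margin above the background thresholds.
#' @param sdlog lognormal sigma of the background.
#' @param percentile percentile used to place the planted hits.
#' @param seed integer RNG seed.
#' @return list with \code{records} (data.frame gene, rel_number,
#'   rel_length) and \code{truth} (logical planted-hit labels).
#' @export
makeScreenTable <- function(nGenes = 100L, nHits = 5L, hitMargin = 0.2,
                            sdlog = 0.15, percentile = 85, seed = 1L) {
  if (nGenes < 10L) stop("need at least 10 genes")
  if (nHits >= nGenes / 2) stop("too many planted hits")
  set.seed(seed)
  relN <- stats::rlnorm(nGenes, 0, sdlog)
  relL <- stats::rlnorm(nGenes, 0, sdlog)
  truth <- rep(FALSE, nGenes)
  if (nHits > 0) {
    qN <- stats::quantile(relN, percentile / 100, type = 7)
    qL <- stats::quantile(relL, percentile / 100, type = 7)
    idx <- sample.int(nGenes, nHits)
    bump <- 1 + hitMargin + stats::runif(nHits, 0, hitMargin / 2)
    relN[idx] <- qN * bump
    bump2 <- 1 + hitMargin + stats::runif(nHits, 0, hitMargin / 2)
    relL[idx] <- qL * bump2
    truth[idx] <- TRUE
  }
  list(records = data.frame(gene = sprintf("gene%03d", seq_len(nGenes)),
                            rel_number = relN, rel_length = relL),
       truth = truth)
}
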