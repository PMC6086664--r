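#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib CytoQuant, .registration = TRUE
NULL

# ---------------------------------------------------------------------------
# Imaging carriers
# ---------------------------------------------------------------------------

#' SpacedImage: an intensity grid with physical pixel spacing
#'
#' Carrier for all image operators. Holds a 2D (row, col) or 3D
#' (plane, row, col) numeric array together with the physical size of one
#' pixel per axis (micrometres) and a free-text channel label. Row 1 is the
#' image top; all in-R coordinates are 1-based \code{(row, col)} or
#' \code{(plane, row, col)}.
#'
#' @slot values numeric array, 2 or 3 dimensions, all finite.
#' @slot spacing numeric, one positive entry per axis, micrometres per pixel.
#' @slot channel single character string.
#'
#' @examples
#' img <- SpacedImage(matrix(0, 8, 8), spacing = c(0.2, 0.2))
#' pixelSpacing(img)
#' @export
setClass("SpacedImage",
  representation(values = "array", spacing = "numeric", channel = "character"),
  validity = function(object) {
    nd <- length(dim(object@values))
    if (!nd %in% c(2L, 3L))
      return("'values' must be a 2D or 3D array")
    if (!all(is.finite(object@values)))
      return("'values' must be finite")
    if (length(object@spacing) != nd)
      return("'spacing' must have one entry per image axis")
    if (!all(is.finite(object@spacing)) || any(object@spacing <= 0))
      return("all 'spacing' entries must be positive and finite")
    if (length(object@channel) != 1L)
      return("'channel' must be a single string")
    TRUE
  }
)

#' @param values numeric matrix or 3D array.
#' @param spacing micrometres per pixel, one value per axis (recycled from a
#'   scalar).
#' @param channel channel label.
#' @rdname SpacedImage-class
#' @export
SpacedImage <- function(values, spacing = 1, channel = "") {
  values <- as.array(values)
  if (is.null(dim(values)))
    stop("'values' must be a matrix or array")
  nd <- length(dim(values))
  if (length(spacing) == 1L)
    spacing <- rep(as.numeric(spacing), nd)
  new("SpacedImage", values = values, spacing = as.numeric(spacing),
      channel = as.character(channel))
}

#' BinaryMask: a boolean grid sharing the geometry of its source image
#'
#' @slot values logical array, same dimensionality as the source image.
#' @slot spacing micrometres per pixel, inherited from the source image.
#' @export
setClass("BinaryMask",
  representation(values = "array", spacing = "numeric"),
  validity = function(object) {
    nd <- length(dim(object@values))
    if (!nd %in% c(2L, 3L))
      return("'values' must be a 2D or 3D array")
    if (!is.logical(object@values))
      return("'values' must be logical")
    if (any(is.na(object@values)))
      return("'values' must not contain NA")
    if (length(object@spacing) != nd || any(object@spacing <= 0))
      return("'spacing' must have one positive entry per axis")
    TRUE
  }
)

#' @param values logical matrix or array (numeric input is coerced by
#'   \code{> 0}).
#' @param spacing micrometres per pixel per axis.
#' @rdname BinaryMask-class
#' @export
BinaryMask <- function(values, spacing = 1) {
  values <- as.array(values)
  if (!is.logical(values)) {
    v <- values > 0
    dim(v) <- dim(values)
    values <- v
  }
  nd <- length(dim(values))
  if (length(spacing) == 1L)
    spacing <- rep(as.numeric(spacing), nd)
  new("BinaryMask", values = values, spacing = as.numeric(spacing))
}

#' ObjectnessParams: parameters of the Hessian ridge (objectness) filter
#'
#' \code{sigma} is the Gaussian-derivative scale in pixels; \code{alpha},
#' \code{beta} and \code{gamma} shape the response (\code{gamma} weights the
#' Frobenius-norm "structureness" term and assumes intensities normalized to
#' [0, 1]); \code{order} selects the enhanced structure dimensionality
#' (1 = blob-like, 2 = line-like in a 2D image).
#'
#' @slot sigma,alpha,beta,gamma positive numerics.
#' @slot order integer, 1 or 2.
#' @export
setClass("ObjectnessParams",
  representation(sigma = "numeric", alpha = "numeric", beta = "numeric",
                 gamma = "numeric", order = "integer"),
  validity = function(object) {
    for (s in c("sigma", "alpha", "beta", "gamma")) {
      v <- slot(object, s)
      if (length(v) != 1L || !is.finite(v) || v <= 0)
        return(sprintf("'%s' must be a single positive number", s))
    }
    if (!object@order %in% c(1L, 2L))
      return("'order' must be 1 or 2")
    TRUE
  }
)

#' @param sigma,alpha,beta,gamma,order see the class description. Defaults
#'   are the filopodia-pipeline settings.
#' @rdname ObjectnessParams-class
#' @export
objectnessParams <- function(sigma = 1, alpha = 1, beta = 1, gamma = 0.003,
                             order = 2L) {
  new("ObjectnessParams", sigma = sigma, alpha = alpha, beta = beta,
      gamma = gamma, order = as.integer(order))
}

#' ThresholdParams: parameters of the local adaptive threshold
#'
#' A pixel is foreground iff its value exceeds the regional mean plus
#' \code{stdMultiplier} times the regional standard deviation, computed over
#' a square window of radius \code{windowRadius} with reflected borders.
#'
#' @slot windowRadius integer window radius in pixels, >= 1.
#' @slot stdMultiplier non-negative numeric.
#' @export
setClass("ThresholdParams",
  representation(windowRadius = "integer", stdMultiplier = "numeric"),
  validity = function(object) {
    if (length(object@windowRadius) != 1L || object@windowRadius < 1L)
      return("'windowRadius' must be a single integer >= 1")
    if (length(object@stdMultiplier) != 1L ||
        !is.finite(object@stdMultiplier) || object@stdMultiplier < 0)
      return("'stdMultiplier' must be a single non-negative number")
    TRUE
  }
)

#' @param windowRadius,stdMultiplier see the class description.
#' @rdname ThresholdParams-class
#' @export
thresholdParams <- function(windowRadius = 200L, stdMultiplier = 1) {
  new("ThresholdParams", windowRadius = as.integer(windowRadius),
      stdMultiplier = as.numeric(stdMultiplier))
}

# ---------------------------------------------------------------------------
# Segmentation / tracing results
# ---------------------------------------------------------------------------

#' CellSegmentation: per-cell body, combined mask and candidate tips
#'
#' @slot body \linkS4class{BinaryMask}, the cell body.
#' @slot combined \linkS4class{BinaryMask}, body plus filopodia; the body is
#'   a subset of the combined mask.
#' @slot tips integer matrix, one candidate filopodium tip per row
#'   (row, col), 1-based; every tip lies inside the combined mask.
#' @export
setClass("CellSegmentation",
  representation(body = "BinaryMask", combined = "BinaryMask",
                 tips = "matrix"),
  validity = function(object) {
    if (!identical(dim(object@body@values), dim(object@combined@values)))
      return("body and combined masks must share a shape")
    if (any(object@body@values & !object@combined@values))
      return("body must be a subset of the combined mask")
    if (nrow(object@tips) > 0) {
      if (ncol(object@tips) != 2L)
        return("'tips' must have two columns (row, col)")
      idx <- object@tips
      inside <- object@combined@values[idx]
      if (!all(inside))
        return("every tip must lie inside the combined mask")
    }
    TRUE
  }
)

#' FilopodiumTrace: one traced filopodium
#'
#' Ordered pixel path from the tip to the cell body, with the Euclidean
#' path length in micrometres. Consecutive pixels are 8-neighbours (2D) or
#' z-constrained lattice steps (3D); no pixel repeats.
#'
#' @slot path integer matrix, one pixel per row; columns (row, col) or
#'   (plane, row, col), 1-based; first row is the tip.
#' @slot spacing micrometres per pixel per axis.
#' @slot lengthUm Euclidean length along the path, micrometres.
#' @slot tip integer vector, coordinates of the tip pixel.
#' @slot cellId character cell identifier.
#' @export
setClass("FilopodiumTrace",
  representation(path = "matrix", spacing = "numeric", lengthUm = "numeric",
                 tip = "integer", cellId = "character"),
  validity = function(object) {
    if (nrow(object@path) < 1L) return("path must contain at least one pixel")
    if (length(object@spacing) != ncol(object@path))
      return("'spacing' must match path dimensionality")
    if (object@lengthUm < 0) return("'lengthUm' must be >= 0")
    if (anyDuplicated(object@path)) return("path must not repeat a pixel")
    TRUE
  }
)

# ---------------------------------------------------------------------------
# Transport simulator
# ---------------------------------------------------------------------------

#' SimConfig: parameters of the cytoneme transport Monte-Carlo model
#'
#' Defaults are the reference study conditions (1000 x 1000
#' micrometre domain, 8 micrometre cell radius, 1 s step, 180 simulated
#' minutes, wild-type signaling probability 1/30 per producer per step) and
#' documented calibration choices elsewhere (see the methods vignette).
#'
#' @slot domainWidth,domainHeight domain size, micrometres.
#' @slot cellRadius cell radius, micrometres.
#' @slot dt simulation step, seconds.
#' @slot durationMin simulated duration, minutes.
#' @slot pFilo per-producer per-step probability of forming a cytoneme.
#' @slot pInsert,pMigrate,pDecay per-receiver per-step probabilities of cell
#'   insertion, neighbour swapping and morphogen decay.
#' @slot lFiloMean,lFiloSd cytoneme length distribution (Gaussian, truncated
#'   at zero), micrometres.
#' @slot angleDist "uniform-halfplane" or "von-mises" (mean direction into
#'   the receiving tissue).
#' @slot angleKappa von Mises concentration (used only for "von-mises").
#' @slot tipTol deposition tolerance around the receiving cell surface,
#'   micrometres.
#' @slot reseedTol margin-distance tolerance when choosing the duplicated
#'   cell after an insertion, micrometres.
#' @slot depositAmount,decayAmount morphogen units added per deposition and
#'   removed per decay event.
#' @slot initialBandUm initial depth of the receiving tissue band,
#'   micrometres.
#' @slot seed integer RNG seed (NA = leave the RNG state alone).
#' @export
setClass("SimConfig",
  representation(domainWidth = "numeric", domainHeight = "numeric",
    cellRadius = "numeric", dt = "numeric", durationMin = "numeric",
    pFilo = "numeric", pInsert = "numeric", pMigrate = "numeric",
    pDecay = "numeric", lFiloMean = "numeric", lFiloSd = "numeric",
    angleDist = "character", angleKappa = "numeric", tipTol = "numeric",
    reseedTol = "numeric", depositAmount = "numeric", decayAmount = "numeric",
    initialBandUm = "numeric", seed = "integer"),
  validity = function(object) {
    ps <- c(object@pFilo, object@pInsert, object@pMigrate, object@pDecay)
    if (any(ps < 0 | ps > 1)) return("probabilities must lie in [0, 1]")
    if (object@dt <= 0) return("'dt' must be > 0")
    if (object@cellRadius <= 0) return("'cellRadius' must be > 0")
    if (object@domainWidth <= 0 || object@domainHeight <= 0)
      return("domain size must be positive")
    if (object@durationMin < 0) return("'durationMin' must be >= 0")
    if (object@tipTol < 0 || object@reseedTol < 0)
      return("tolerances must be >= 0")
    if (object@lFiloMean <= 0 || object@lFiloSd < 0)
      return("filopodium length distribution must have positive mean")
    if (!object@angleDist %in% c("uniform-halfplane", "von-mises"))
      return("'angleDist' must be 'uniform-halfplane' or 'von-mises'")
    TRUE
  }
)

#' @param ... slot values overriding the defaults (see the class
#'   description).
#' @rdname SimConfig-class
#' @export
simConfig <- function(...) {
  args <- list(...)
  defaults <- list(domainWidth = 1000, domainHeight = 1000, cellRadius = 8,
    dt = 1, durationMin = 180, pFilo = 1 / 30, pInsert = 1 / 600,
    pMigrate = 1 / 60, pDecay = 1 / 7200, lFiloMean = 20, lFiloSd = 5,
    angleDist = "uniform-halfplane", angleKappa = 4, tipTol = 2,
    reseedTol = 6, depositAmount = 1, decayAmount = 1, initialBandUm = 200,
    seed = NA_integer_)
  unknown <- setdiff(names(args), names(defaults))
  if (length(unknown))
    stop("unknown SimConfig field(s): ", paste(unknown, collapse = ", "))
  defaults[names(args)] <- args
  defaults$seed <- as.integer(defaults$seed)
  do.call(new, c(list("SimConfig"), defaults))
}

#' Tissue: state of the simulated cell lattice
#'
#' Cells live on precomputed, fixed hexagonal lattice positions. Roles:
#' 0 = empty position, 1 = producer (marginal morphogen source, unlimited),
#' 2 = receiver. The morphogen ledger (cumulative deposits and effective
#' decays) is carried with the state so conservation can be checked at any
#' step.
#'
#' @slot pos numeric matrix of lattice positions (x, y), micrometres.
#' @slot marginDist distance of each position from the producer margin,
#'   micrometres.
#' @slot role integer vector per position (0 empty, 1 producer, 2 receiver).
#' @slot wnt morphogen content per position, >= 0 (0 at empty positions).
#' @slot neighbors integer matrix, up to 6 lattice neighbour indices per
#'   position, 0-padded.
#' @slot stepCount steps executed so far.
#' @slot deposits,insertGain,decays cumulative morphogen ledger: deposited
#'   units, units gained by duplication at insertions, effectively decayed
#'   units. At all times deposits + insertGain - decays equals the total
#'   receiver content.
#' @slot config the \linkS4class{SimConfig} used to build the lattice.
#' @export
setClass("Tissue",
  representation(pos = "matrix", marginDist = "numeric", role = "integer",
    wnt = "numeric", neighbors = "matrix", stepCount = "integer",
    deposits = "numeric", insertGain = "numeric", decays = "numeric",
    config = "SimConfig"),
  validity = function(object) {
    n <- nrow(object@pos)
    if (length(object@role) != n || length(object@wnt) != n ||
        length(object@marginDist) != n)
      return("per-position vectors must match the number of positions")
    if (!all(object@role %in% 0:2)) return("roles must be 0, 1 or 2")
    if (any(object@wnt < 0)) return("morphogen content must be >= 0")
    if (any(object@wnt[object@role == 0L] != 0))
      return("empty positions must hold no morphogen")
    ## cells sit on fixed lattice positions with centre spacing >= one
    ## diameter; checked exhaustively on small lattices, via the
    ## precomputed neighbour structure on large ones
    occ <- object@role != 0L
    if (sum(occ) >= 2 && sum(occ) <= 2000) {
      p <- object@pos[occ, , drop = FALSE]
      mind <- min(stats::dist(p))
      if (mind < 2 * object@config@cellRadius - 1e-9)
        return("occupied positions closer than one cell diameter")
    } else if (n >= 2) {
      i <- rep(seq_len(n), ncol(object@neighbors))
      j <- as.vector(object@neighbors)
      keep <- j != 0L
      if (any(keep)) {
        dd <- sqrt(rowSums((object@pos[i[keep], , drop = FALSE] -
                              object@pos[j[keep], , drop = FALSE])^2))
        if (min(dd) < 2 * object@config@cellRadius - 1e-9)
          return("lattice spacing below one cell diameter")
      }
    }
    TRUE
  }
)

# ---------------------------------------------------------------------------
# lsFCS
# ---------------------------------------------------------------------------

#' LineScanRecord: an x-t pseudo image from line-scanning FCS
#'
#' Rows are successive scan lines (time), columns are pixels along the scan
#' line crossing the membrane.
#'
#' @slot image numeric matrix, lines x pixels, non-negative.
#' @slot pixelStepNm pixel step along the line, nanometres.
#' @slot linePeriodS time between successive lines, seconds.
#' @slot channel channel label.
#' @export
setClass("LineScanRecord",
  representation(image = "matrix", pixelStepNm = "numeric",
                 linePeriodS = "numeric", channel = "character"),
  validity = function(object) {
    if (ncol(object@image) < 3L)
      return("a scan line needs at least 3 pixels")
    if (object@pixelStepNm <= 0 || object@linePeriodS <= 0)
      return("pixel step and line period must be positive")
    if (any(!is.finite(object@image)) || any(object@image < 0))
      return("intensities must be finite and non-negative")
    TRUE
  }
)

#' @param image lines x pixels numeric matrix.
#' @param pixelStepNm,linePeriodS,channel see the class description.
#' @rdname LineScanRecord-class
#' @export
lineScanRecord <- function(image, pixelStepNm = 100, linePeriodS = 0.002,
                           channel = "") {
  new("LineScanRecord", image = as.matrix(image),
      pixelStepNm = pixelStepNm, linePeriodS = linePeriodS,
      channel = as.character(channel))
}

#' IntensityTrace: integrated membrane intensity per scan line
#'
#' @slot values non-negative intensities, one per scan line.
#' @slot dt sampling interval (the line period), seconds.
#' @export
setClass("IntensityTrace",
  representation(values = "numeric", dt = "numeric"),
  validity = function(object) {
    if (object@dt <= 0) return("'dt' must be positive")
    if (any(!is.finite(object@values)) || any(object@values < 0))
      return("trace values must be finite and non-negative")
    TRUE
  }
)

#' @param values intensity values per line.
#' @param dt line period, seconds.
#' @rdname IntensityTrace-class
#' @export
intensityTrace <- function(values, dt) {
  new("IntensityTrace", values = as.numeric(values), dt = dt)
}

#' CorrelationCurve: a correlation function on a quasi-logarithmic lag grid
#'
#' @slot lag lag times, seconds, strictly increasing, all > 0.
#' @slot G correlation values per lag.
#' @slot se per-lag standard errors (NA when not estimable).
#' @slot pair label such as "GG", "RR" or "GR".
#' @export
setClass("CorrelationCurve",
  representation(lag = "numeric", G = "numeric", se = "numeric",
                 pair = "character"),
  validity = function(object) {
    if (length(object@lag) != length(object@G))
      return("'lag' and 'G' must have equal length")
    if (any(object@lag <= 0)) return("all lags must be > 0")
    if (is.unsorted(object@lag, strictly = TRUE))
      return("lags must be strictly increasing")
    if (length(object@se) != length(object@G))
      return("'se' must match 'G' in length")
    TRUE
  }
)

#' DiffusionFit: fitted one-component 2D membrane diffusion model
#'
#' Model: G(tau) = G0 (1 + tau/tauD)^(-1/2) (1 + tau/(S^2 tauD))^(-1/2),
#' with D = w0^2 / (4 tauD) and concentration C = 1 / (G0 * pi * w0^2 * S)
#' (effective detection area A_eff = pi * w0 * (S w0) for a membrane crossed
#' perpendicularly by an elliptical Gaussian focus).
#'
#' @slot G0 fitted amplitude.
#' @slot tauD fitted diffusion time, seconds.
#' @slot D derived diffusion coefficient, square micrometres per second.
#' @slot C derived area density, per square micrometre.
#' @slot w0 focal waist, micrometres.
#' @slot S axial-to-lateral focus ratio.
#' @slot offset fitted baseline (finite-record correlation offset; 0 when
#'   fitted without a baseline).
#' @slot se named standard errors (G0, tauD, D, C).
#' @slot converged logical.
#' @export
setClass("DiffusionFit",
  representation(G0 = "numeric", tauD = "numeric", D = "numeric",
    C = "numeric", w0 = "numeric", S = "numeric", offset = "numeric",
    se = "numeric", converged = "logical"),
  prototype(G0 = NA_real_, tauD = NA_real_, D = NA_real_, C = NA_real_,
    w0 = NA_real_, S = NA_real_, offset = 0, se = numeric(),
    converged = FALSE),
  validity = function(object) {
    if (object@converged) {
      if (object@tauD <= 0 || object@D <= 0 || object@C <= 0)
        return("tauD, D and C must be positive in a converged fit")
    }
    TRUE
  }
)

# ---------------------------------------------------------------------------
# Synthetic-data specifications
# ---------------------------------------------------------------------------

#' SyntheticCellSpec: ground-truth description of a rendered cell image
#'
#' @slot imageSize image size, pixels (rows, cols).
#' @slot spacingUm micrometres per pixel (isotropic).
#' @slot bodyRadiusPx body disc radius, pixels.
#' @slot bodyIntensity body intensity in [0, 1].
#' @slot filopodia data.frame with columns angle (radians), lengthPx,
#'   widthPx, intensity; filopodia attach to the body rim.
#' @slot noiseSd Gaussian noise standard deviation (0 = noise-free).
#' @slot seed integer RNG seed.
#' @export
setClass("SyntheticCellSpec",
  representation(imageSize = "integer", spacingUm = "numeric",
    bodyRadiusPx = "numeric", bodyIntensity = "numeric",
    filopodia = "data.frame", noiseSd = "numeric", seed = "integer"),
  validity = function(object) {
    if (length(object@imageSize) != 2L || any(object@imageSize < 8L))
      return("'imageSize' must be two integers >= 8")
    if (object@spacingUm <= 0) return("'spacingUm' must be positive")
    if (object@bodyRadiusPx <= 0) return("'bodyRadiusPx' must be positive")
    fl <- object@filopodia
    need <- c("angle", "lengthPx", "widthPx", "intensity")
    if (nrow(fl) > 0) {
      if (!all(need %in% names(fl)))
        return("filopodia table needs angle, lengthPx, widthPx, intensity")
      if (any(fl$lengthPx <= 0)) return("filopodium lengths must be > 0")
      if (any(fl$widthPx < 1)) return("filopodium widths must be >= 1 px")
    }
    if (object@noiseSd < 0) return("'noiseSd' must be >= 0")
    TRUE
  }
)

#' @param imageSize,spacingUm,bodyRadiusPx,bodyIntensity,filopodia,noiseSd,seed
#'   see the class description.
#' @rdname SyntheticCellSpec-class
#' @export
syntheticCellSpec <- function(imageSize = c(256L, 256L), spacingUm = 0.2,
    bodyRadiusPx = 40, bodyIntensity = 0.8,
    filopodia = data.frame(angle = numeric(), lengthPx = numeric(),
                           widthPx = numeric(), intensity = numeric()),
    noiseSd = 0, seed = 1L) {
  new("SyntheticCellSpec", imageSize = as.integer(imageSize),
      spacingUm = spacingUm, bodyRadiusPx = bodyRadiusPx,
      bodyIntensity = bodyIntensity, filopodia = filopodia,
      noiseSd = noiseSd, seed = as.integer(seed))
}

#' FcsSimSpec: ground-truth description of a simulated lsFCS record
#'
#' Membrane modelled as a 2D strip; species diffuse freely (Brownian) and
#' are detected through an elliptical Gaussian focus of lateral waist
#' \code{w0} and axial waist \code{S * w0}. Bound (dual-labelled) species
#' have non-zero brightness in both channels.
#'
#' @slot species data.frame with columns D (um^2/s), density (um^-2),
#'   brightGreen, brightRed (expected photons per line per molecule at the
#'   focus centre).
#' @slot pixelStepNm,pixelsPerLine,linePeriodS,durationS scan geometry and
#'   timing.
#' @slot w0,S focus waist (um) and axial ratio.
#' @slot backgroundPerPixel expected background photons per pixel per line.
#' @slot membraneCenterPx,membraneDriftPx,membraneJitterPx membrane position
#'   (pixels): static centre, total linear drift over the record, and
#'   per-line Gaussian jitter.
#' @slot boxLengthUm,boxDepthUm periodic simulation box on the membrane
#'   (lateral x axial extent). The lateral extent must be much larger
#'   than the focal waist: the slowest relaxation mode of the periodic
#'   box, (L / 2 pi)^2 / D, truncates the correlation tail and biases
#'   fitted diffusion coefficients upward when the box is small.
#' @slot seed integer RNG seed.
#' @export
setClass("FcsSimSpec",
  representation(species = "data.frame", pixelStepNm = "numeric",
    pixelsPerLine = "integer", linePeriodS = "numeric", durationS = "numeric",
    w0 = "numeric", S = "numeric", backgroundPerPixel = "numeric",
    membraneCenterPx = "numeric", membraneDriftPx = "numeric",
    membraneJitterPx = "numeric", boxLengthUm = "numeric",
    boxDepthUm = "numeric", seed = "integer"),
  validity = function(object) {
    sp <- object@species
    need <- c("D", "density", "brightGreen", "brightRed")
    if (!all(need %in% names(sp)))
      return("species table needs D, density, brightGreen, brightRed")
    if (nrow(sp) == 0 || all(sp$density <= 0))
      return("at least one species must have positive density")
    if (any(sp$D < 0) || any(sp$density < 0))
      return("species D and density must be >= 0")
    if (object@pixelsPerLine < 3L) return("need at least 3 pixels per line")
    if (object@durationS <= 0 || object@linePeriodS <= 0)
      return("duration and line period must be positive")
    if (object@w0 <= 0 || object@S <= 0) return("w0 and S must be positive")
    if (object@boxLengthUm <= 0 || object@boxDepthUm <= 0)
      return("simulation box must be positive")
    TRUE
  }
)

#' @param species,pixelStepNm,pixelsPerLine,linePeriodS,durationS,w0,S
#'   see the class description.
#' @param backgroundPerPixel,membraneCenterPx,membraneDriftPx,membraneJitterPx
#'   see the class description.
#' @param boxLengthUm,boxDepthUm,seed see the class description.
#' @rdname FcsSimSpec-class
#' @export
fcsSimSpec <- function(species, pixelStepNm = 100, pixelsPerLine = 100L,
    linePeriodS = 0.004, durationS = 390, w0 = 0.25, S = 5,
    backgroundPerPixel = 0.2, membraneCenterPx = 50,
    membraneDriftPx = 0, membraneJitterPx = 0,
    boxLengthUm = 10, boxDepthUm = 8, seed = 1L) {
  new("FcsSimSpec", species = species, pixelStepNm = pixelStepNm,
      pixelsPerLine = as.integer(pixelsPerLine), linePeriodS = linePeriodS,
      durationS = durationS, w0 = w0, S = S,
      backgroundPerPixel = backgroundPerPixel,
      membraneCenterPx = membraneCenterPx, membraneDriftPx = membraneDriftPx,
      membraneJitterPx = membraneJitterPx, boxLengthUm = boxLengthUm,
      boxDepthUm = boxDepthUm, seed = as.integer(seed))
}
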