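#' @include AllClasses.R AllGenerics.R
NULL

#' @rdname accessors
#' @export
setMethod("imgValues", "SpacedImage", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("imgValues", "BinaryMask", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("imgValues", "IntensityTrace", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("pixelSpacing", "SpacedImage", function(x) x@spacing)

#' @rdname accessors
#' @export
setMethod("pixelSpacing", "BinaryMask", function(x) x@spacing)

#' @rdname accessors
#' @export
setMethod("channelLabel", "SpacedImage", function(x) x@channel)

#' @rdname accessors
#' @export
setMethod("tracePath", "FilopodiumTrace", function(x) x@path)

#' @rdname accessors
#' @export
setMethod("traceLength", "FilopodiumTrace", function(x) x@lengthUm)

#' @rdname accessors
#' @export
setMethod("bodyMask", "CellSegmentation", function(x) x@body)

#' @rdname accessors
#' @export
setMethod("combinedMask", "CellSegmentation", function(x) x@combined)

#' @rdname accessors
#' @export
setMethod("tipPixels", "CellSegmentation", function(x) x@tips)

#' @rdname accessors
#' @export
setMethod("lagTimes", "CorrelationCurve", function(x) x@lag)

#' @rdname accessors
#' @export
setMethod("corrValues", "CorrelationCurve", function(x) x@G)

#' @describeIn SpacedImage-class dimensions of the pixel grid.
#' @export
setMethod("dim", "SpacedImage", function(x) dim(x@values))

#' @describeIn BinaryMask-class dimensions of the mask.
#' @export
setMethod("dim", "BinaryMask", function(x) dim(x@values))

setMethod("show", "SpacedImage", function(object) {
  d <- dim(object@values)
  cat(sprintf("SpacedImage: %s px, spacing %s um/px%s\n",
              paste(d, collapse = " x "),
              paste(signif(object@spacing, 4), collapse = " x "),
              if (nzchar(object@channel))
                paste0(", channel '", object@channel, "'") else ""))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(object@values), max(object@values)))
})

setMethod("show", "BinaryMask", function(object) {
  d <- dim(object@values)
  cat(sprintf("BinaryMask: %s px, %d foreground px (%.2f%%)\n",
              paste(d, collapse = " x "), sum(object@values),
              100 * mean(object@values)))
})

setMethod("show", "CellSegmentation", function(object) {
  cat(sprintf(
    "CellSegmentation: body %d px, combined %d px, %d candidate tip(s)\n",
    sum(object@body@values), sum(object@combined@values),
    nrow(object@tips)))
})

setMethod("show", "FilopodiumTrace", function(object) {
  cat(sprintf(
    "FilopodiumTrace%s: %d px from tip (%s), length %.3f um\n",
    if (nzchar(object@cellId)) paste0(" [", object@cellId, "]") else "",
    nrow(object@path), paste(object@tip, collapse = ", "),
    object@lengthUm))
})

setMethod("show", "Tissue", function(object) {
  cat(sprintf(
    paste0("Tissue: %d lattice positions, %d producer(s), %d receiver(s), ",
           "step %d\n  morphogen: total %.0f (deposited %.0f, duplicated %.0f, ",
           "decayed %.0f)\n"),
    nrow(object@pos), sum(object@role == 1L), sum(object@role == 2L),
    object@stepCount, sum(object@wnt[object@role == 2L]),
    object@deposits, object@insertGain, object@decays))
})

setMethod("show", "CorrelationCurve", function(object) {
  cat(sprintf(
    "CorrelationCurve [%s]: %d lags, %.4g s .. %.4g s, G(first) = %.4g\n",
    object@pair, length(object@lag), min(object@lag), max(object@lag),
    object@G[1]))
})

setMethod("show", "DiffusionFit", function(object) {
  if (!object@converged) {
    cat("DiffusionFit: not converged\n")
    return(invisible(NULL))
  }
  cat(sprintf(
    paste0("DiffusionFit: G0 = %.4g, tauD = %.4g s\n",
           "  D = %.4g um^2/s, C = %.4g um^-2 (w0 = %g um, S = %g)\n"),
    object@G0, object@tauD, object@D, object@C, object@w0, object@S))
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(
    paste0("SimConfig: %g x %g um domain, cell radius %g um, dt %g s, ",
           "%g min\n  pFilo %.4g, pInsert %.4g, pMigrate %.4g, pDecay %.4g\n"),
    object@domainWidth, object@domainHeight, object@cellRadius, object@dt,
    object@durationMin, object@pFilo, object@pInsert, object@pMigrate,
    object@pDecay))
})

setMethod("show", "LineScanRecord", function(object) {
  cat(sprintf(
    "LineScanRecord%s: %d lines x %d px, %g nm/px, %g ms/line (%.1f s)\n",
    if (nzchar(object@channel)) paste0(" [", object@channel, "]") else "",
    nrow(object@image), ncol(object@image), object@pixelStepNm,
    1e3 * object@linePeriodS, nrow(object@image) * object@linePeriodS))
})
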