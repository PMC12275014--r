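#' @rdname accessors
#' @export
setGeneric("deviationMatrix", function(x, ...) standardGeneric("deviationMatrix"))

#' @rdname accessors
#' @export
setGeneric("thresholdValue", function(x) standardGeneric("thresholdValue"))

#' @rdname accessors
#' @export
setGeneric("scaleEstimate", function(x) standardGeneric("scaleEstimate"))

#' @rdname accessors
#' @export
setGeneric("shapeEstimate", function(x) standardGeneric("shapeEstimate"))

#' @rdname accessors
#' @export
setGeneric("locationEstimate", function(x) standardGeneric("locationEstimate"))

#' @rdname accessors
#' @export
setGeneric("standardErrors", function(x) standardGeneric("standardErrors"))

#' @rdname accessors
#' @export
setGeneric("nExceedances", function(x) standardGeneric("nExceedances"))

#' @rdname accessors
#' @export
setGeneric("exceedanceRate", function(x) standardGeneric("exceedanceRate"))

#' @rdname accessors
#' @export
setGeneric("radialThreshold", function(x) standardGeneric("radialThreshold"))

#' @rdname accessors
#' @export
setGeneric("radii", function(x) standardGeneric("radii"))

#' @rdname accessors
#' @export
setGeneric("angles", function(x) standardGeneric("angles"))

#' @rdname accessors
#' @export
setGeneric("tpdmMatrix", function(x) standardGeneric("tpdmMatrix"))

#' @rdname accessors
#' @export
setGeneric("eigenValues", function(x) standardGeneric("eigenValues"))

#' @rdname accessors
#' @export
setGeneric("eigenVectors", function(x) standardGeneric("eigenVectors"))

#' @rdname accessors
#' @export
setGeneric("scaleProportions", function(x) standardGeneric("scaleProportions"))

#' @rdname accessors
#' @export
setGeneric("pseudoFrechetValues", function(x) standardGeneric("pseudoFrechetValues"))

#' Accessors for extremeNorm objects
#'
#' Slot access for the S4 result classes: thresholds, parameter estimates and
#' standard errors of tail fits, radial quantities of polar decompositions,
#' the TPDM matrix, and the eigenstructure of an extreme PCA.
#'
#' @param x an extremeNorm S4 object
#' @param ... further arguments (unused)
#' @return the requested component
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("deviationMatrix", "DeviationExperiment", function(x, ...) {
  t(SummarizedExperiment::assay(x, "values"))
})

#' @rdname accessors
#' @export
setMethod("thresholdValue", "GPDFit", function(x) x@threshold)

#' @rdname accessors
#' @export
setMethod("scaleEstimate", "GPDFit", function(x) x@scale)

#' @rdname accessors
#' @export
setMethod("shapeEstimate", "GPDFit", function(x) x@shape)

#' @rdname accessors
#' @export
setMethod("standardErrors", "GPDFit", function(x) x@se)

#' @rdname accessors
#' @export
setMethod("nExceedances", "GPDFit", function(x) x@nExceedances)

#' @rdname accessors
#' @export
setMethod("exceedanceRate", "GPDFit", function(x) x@exceedRate)

#' @rdname accessors
#' @export
setMethod("scaleEstimate", "GEVDFit", function(x) x@scale)

#' @rdname accessors
#' @export
setMethod("shapeEstimate", "GEVDFit", function(x) x@shape)

#' @rdname accessors
#' @export
setMethod("locationEstimate", "GEVDFit", function(x) x@location)

#' @rdname accessors
#' @export
setMethod("standardErrors", "GEVDFit", function(x) x@se)

#' @rdname accessors
#' @export
setMethod("radialThreshold", "PolarDecomposition", function(x) x@radialThreshold)

#' @rdname accessors
#' @export
setMethod("radii", "PolarDecomposition", function(x) x@radius)

#' @rdname accessors
#' @export
setMethod("angles", "PolarDecomposition", function(x) x@angles)

#' @rdname accessors
#' @export
setMethod("nExceedances", "PolarDecomposition", function(x) x@nExceedances)

#' @rdname accessors
#' @export
setMethod("tpdmMatrix", "TPDM", function(x) x@matrix)

#' @rdname accessors
#' @export
setMethod("nExceedances", "TPDM", function(x) x@nExceedances)

#' @rdname accessors
#' @export
setMethod("radialThreshold", "TPDM", function(x) x@radialThreshold)

#' @rdname accessors
#' @export
setMethod("eigenValues", "ExtremeEigenBasis", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("eigenVectors", "ExtremeEigenBasis", function(x) x@vectors)

#' @rdname accessors
#' @export
setMethod("scaleProportions", "ExtremeEigenBasis", function(x) x@proportions)

#' @rdname accessors
#' @export
setMethod("pseudoFrechetValues", "PseudoFrechet", function(x) x@values)

setMethod("show", "NormativeModel", function(object) {
  cat("NormativeModel:", length(object@weights), "basis coefficients;",
      if (length(object@warp)) "sinh-arcsinh warp on" else "warp off", "\n")
  cat("  noise variance:", format(object@noiseVariance, digits = 4),
      " log evidence:", format(object@logEvidence, digits = 6), "\n")
})

setMethod("show", "GPDFit", function(object) {
  cat("Generalized Pareto peaks-over-threshold fit\n")
  cat(sprintf("  threshold: %.4g   exceedances: %d / %d (rate %.4g)\n",
              object@threshold, object@nExceedances, object@nTotal,
              object@exceedRate))
  cat(sprintf("  scale: %.4g +/- %.3g   shape: %.4g +/- %.3g\n",
              object@scale, object@se[["scale"]],
              object@shape, object@se[["shape"]]))
  cat(sprintf("  log-likelihood: %.4f\n", object@logLik))
})

setMethod("show", "GEVDFit", function(object) {
  cat("Generalized extreme value block-maxima fit\n")
  cat(sprintf("  blocks: %d\n", object@nBlocks))
  cat(sprintf("  location: %.4g +/- %.3g  scale: %.4g +/- %.3g  shape: %.4g +/- %.3g\n",
              object@location, object@se[["location"]],
              object@scale, object@se[["scale"]],
              object@shape, object@se[["shape"]]))
})

setMethod("show", "PseudoFrechet", function(object) {
  cat(sprintf("PseudoFrechet: %d subjects x %d variables, tail index alpha = %g\n",
              nrow(object@values), ncol(object@values), object@alpha))
})

setMethod("show", "PolarDecomposition", function(object) {
  cat(sprintf("PolarDecomposition (L2): %d subjects x %d variables\n",
              length(object@radius), ncol(object@angles)))
  cat(sprintf("  radial threshold r0 = %.4g (quantile %.3g), %d exceedances\n",
              object@radialThreshold, object@quantile, object@nExceedances))
})

setMethod("show", "TPDM", function(object) {
  cat(sprintf("TPDM: %d x %d, normalization '%s' (trace %.6g)\n",
              nrow(object@matrix), ncol(object@matrix), object@mode,
              sum(diag(object@matrix))))
  cat(sprintf("  r0 = %.4g, %d radial exceedances (quantile %.3g)\n",
              object@radialThreshold, object@nExceedances, object@quantile))
})

setMethod("show", "ExtremeEigenBasis", function(object) {
  cat("ExtremeEigenBasis:", length(object@values), "components\n")
  k <- min(5L, length(object@values))
  cat("  leading scale proportions:",
      paste(sprintf("%.2f%%", 100 * object@proportions[seq_len(k)]),
            collapse = ", "), "\n")
})
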