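#' @import methods
#' @importFrom stats median optim optimHess qnorm pnorm rnorm runif rbinom
#'   quantile sd var cor cor.test complete.cases setNames predict
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#' @importFrom S4Vectors DataFrame
NULL

#' DeviationExperiment: deviation scores with subject covariates
#'
#' A thin subclass of \linkS4class{SummarizedExperiment} holding a
#' variables-by-subjects matrix of continuous values (raw phenotypes or
#' normative deviation z-scores) in the assay \code{"values"}, with the
#' subject covariates (age, sex, site, ...) in \code{colData}. Following the
#' usual container convention, variables are rows and subjects are columns;
#' use \code{\link{deviationMatrix}} to obtain the subjects-by-variables
#' orientation that the extreme-value functions consume.
#'
#' @slot .Data inherited SummarizedExperiment structure
#' @seealso \code{\link{DeviationExperiment}} constructor
#' @export
setClass("DeviationExperiment", contains = "SummarizedExperiment")

setValidity("DeviationExperiment", function(object) {
  if (!("values" %in% SummarizedExperiment::assayNames(object)))
    return("assay 'values' is required")
  a <- SummarizedExperiment::assay(object, "values")
  if (!is.numeric(a)) return("assay 'values' must be numeric")
  TRUE
})

#' Construct a DeviationExperiment
#'
#' @param values numeric matrix, subjects in rows and variables in columns
#'   (the orientation written by the CSV interfaces); it is stored transposed.
#' @param covariates data.frame of per-subject covariates, one row per
#'   subject, aligned with \code{values}.
#' @return a \linkS4class{DeviationExperiment}
#' @examples
#' z <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("v1", "v2")))
#' cov <- data.frame(age = runif(10, 40, 80), sex = rbinom(10, 1, 0.53))
#' de <- DeviationExperiment(z, cov)
#' dim(deviationMatrix(de))
#' @export
DeviationExperiment <- function(values, covariates = NULL) {
  values <- as.matrix(values)
  if (is.null(colnames(values)))
    colnames(values) <- paste0("v", seq_len(ncol(values)))
  if (is.null(covariates))
    covariates <- data.frame(row.names = seq_len(nrow(values)))
  stopifnot(nrow(covariates) == nrow(values))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(values = t(values)),
    colData = S4Vectors::DataFrame(covariates))
  new("DeviationExperiment", se)
}

#' Normative model fit for a single variable
#'
#' Bayesian linear regression on a covariate basis (cubic age spline, sex,
#' site), with prior and noise precision set by marginal-likelihood
#' (evidence) maximization, and an optional monotone sinh-arcsinh warp of the
#' response estimated by maximum likelihood. The warp variant implemented
#' here is a documented simplification of warped BLR normative models.
#'
#' @slot basisSpec list; frozen basis description (knots, site levels, ...)
#' @slot weights numeric; posterior mean of the regression weights
#' @slot weightCov matrix; posterior covariance of the weights
#' @slot noiseVariance numeric(1); 1 / evidence-optimized noise precision
#' @slot priorPrecision numeric(1); evidence-optimized prior precision
#' @slot warp list; warp parameters, or empty list when warping is off
#' @slot trainSummary list; mean, variance and n of the (warped) training
#'   response, the baseline for MSLL
#' @slot logEvidence numeric(1); maximized log marginal likelihood
#' @export
setClass("NormativeModel",
  representation(basisSpec = "list", weights = "numeric",
                 weightCov = "matrix", noiseVariance = "numeric",
                 priorPrecision = "numeric", warp = "list",
                 trainSummary = "list", logEvidence = "numeric"))

setValidity("NormativeModel", function(object) {
  if (length(object@noiseVariance) != 1L || object@noiseVariance <= 0)
    return("noiseVariance must be a single positive number")
  if (nrow(object@weightCov) != length(object@weights))
    return("weightCov dimension does not match weights")
  TRUE
})

#' Generalized Pareto peaks-over-threshold fit
#'
#' Maximum-likelihood fit of the generalized Pareto distribution to the
#' excesses above a threshold on the deviation-score scale, with standard
#' errors from the inverse observed information.
#'
#' @slot threshold numeric(1); threshold k on the z-score scale
#' @slot scale numeric(1); GPD scale (sigma-tilde, defined at the threshold)
#' @slot shape numeric(1); GPD shape xi
#' @slot se named numeric(2); standard errors of scale and shape
#' @slot vcov 2x2 matrix; asymptotic covariance of (scale, shape)
#' @slot nExceedances integer(1); number of observations above the threshold
#' @slot nTotal integer(1); sample size the exceedance rate refers to
#' @slot exceedRate numeric(1); zeta = nExceedances / nTotal
#' @slot logLik numeric(1); maximized log-likelihood of the excesses
#' @slot excesses numeric; the excess values used for the fit (diagnostics)
#' @export
setClass("GPDFit",
  representation(threshold = "numeric", scale = "numeric", shape = "numeric",
                 se = "numeric", vcov = "matrix", nExceedances = "integer",
                 nTotal = "integer", exceedRate = "numeric",
                 logLik = "numeric", excesses = "numeric"))

setValidity("GPDFit", function(object) {
  if (object@scale <= 0) return("scale must be positive")
  if (object@nExceedances < 1L) return("at least one exceedance is required")
  if (object@shape < 0) {
    upper <- -object@scale / object@shape
    if (any(object@excesses > upper + 1e-8))
      return("excesses beyond the upper endpoint for shape < 0")
  }
  TRUE
})

#' Generalized extreme value block-maxima fit
#'
#' @slot location,scale,shape numeric(1); GEVD parameters (mu, sigma, xi)
#' @slot se named numeric(3); standard errors
#' @slot nBlocks integer(1); number of block maxima used
#' @slot logLik numeric(1)
#' @export
setClass("GEVDFit",
  representation(location = "numeric", scale = "numeric", shape = "numeric",
                 se = "numeric", nBlocks = "integer", logLik = "numeric"))

setValidity("GEVDFit", function(object) {
  if (object@scale <= 0) return("scale must be positive")
  TRUE
})

#' Marginally transformed (pseudo-Frechet) data
#'
#' Values obtained from a deviation matrix by the per-column rank transform
#' F-hat = rank/(n+1) followed by the Frechet(alpha = 2) quantile map
#' x = (-log F-hat)^(-1/2), so that every column is (up to rank
#' discretization) Frechet with common tail index 2 — the marginal
#' standardization multivariate regular variation requires.
#'
#' @slot values positive matrix, subjects by variables
#' @slot alpha numeric(1); the common tail index, fixed at 2
#' @slot sourceColumns character; names of the originating columns
#' @export
setClass("PseudoFrechet",
  representation(values = "matrix", alpha = "numeric",
                 sourceColumns = "character"))

setValidity("PseudoFrechet", function(object) {
  if (any(object@values <= 0)) return("all values must be positive")
  if (!identical(object@alpha, 2)) return("tail index alpha is fixed at 2")
  TRUE
})

#' Polar decomposition with radial threshold
#'
#' Each subject's pseudo-Frechet row x is written as r * omega with r the L2
#' norm and omega on the unit sphere; the radial threshold r0 is an empirical
#' quantile of r, and exceedances r > r0 are the multivariate extremes.
#'
#' @slot radius numeric; per-subject L2 radius
#' @slot angles matrix; per-subject unit-norm angular components (L2)
#' @slot radialThreshold numeric(1); r0
#' @slot quantile numeric(1); the radial quantile used (default 0.95)
#' @slot exceedanceMask logical; r > r0 per subject
#' @slot nExceedances integer(1)
#' @export
setClass("PolarDecomposition",
  representation(radius = "numeric", angles = "matrix",
                 radialThreshold = "numeric", quantile = "numeric",
                 exceedanceMask = "logical", nExceedances = "integer"))

setValidity("PolarDecomposition", function(object) {
  norms <- sqrt(rowSums(object@angles^2))
  if (any(abs(norms - 1) > 1e-8)) return("angle rows must have unit L2 norm")
  if (object@nExceedances != sum(object@exceedanceMask))
    return("nExceedances does not match the mask")
  TRUE
})

#' Tail pairwise dependence matrix (TPDM)
#'
#' Second-moment summary of the angular measure of a regularly varying
#' vector with common tail index 2: the extremal analogue of a covariance
#' matrix. Estimated from angular components of radial exceedances. Two
#' normalizations are carried: \code{"printed"} uses the constant 2 (trace
#' is exactly 2), \code{"unit"} uses the dimension D (trace exactly D, so
#' that unit-scale Frechet margins give unit diagonal). The two differ by
#' the scalar D/2 only, so all eigenstructure is shared.
#'
#' @slot matrix symmetric D x D matrix
#' @slot mode character(1); "unit" or "printed"
#' @slot radialThreshold numeric(1); the r0 used
#' @slot nExceedances integer(1)
#' @slot quantile numeric(1); radial quantile behind r0
#' @export
setClass("TPDM",
  representation(matrix = "matrix", mode = "character",
                 radialThreshold = "numeric", nExceedances = "integer",
                 quantile = "numeric"))

setValidity("TPDM", function(object) {
  m <- object@matrix
  if (nrow(m) != ncol(m)) return("TPDM must be square")
  if (max(abs(m - t(m))) > 1e-10) return("TPDM must be symmetric")
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(abs(ev), 1))
    return("TPDM must be positive semidefinite")
  if (!object@mode %in% c("unit", "printed"))
    return("mode must be 'unit' or 'printed'")
  TRUE
})

#' Extreme principal component basis
#'
#' Eigendecomposition of a TPDM. Eigenvalues ("scales", the extremal
#' analogue of variances) are in descending order; eigenvectors are
#' orthonormal with the sign convention that each vector's largest-magnitude
#' entry is positive.
#'
#' @slot values numeric; descending nonnegative eigenvalues
#' @slot vectors matrix; orthonormal eigenvectors in columns
#' @slot proportions numeric; scale proportions lambda_l / sum(lambda)
#' @export
setClass("ExtremeEigenBasis",
  representation(values = "numeric", vectors = "matrix",
                 proportions = "numeric"))

setValidity("ExtremeEigenBasis", function(object) {
  if (is.unsorted(rev(object@values))) return("eigenvalues must be descending")
  g <- crossprod(object@vectors)
  if (max(abs(g - diag(ncol(object@vectors)))) > 1e-10)
    return("eigenvectors must be orthonormal")
  if (abs(sum(object@proportions) - 1) > 1e-8)
    return("scale proportions must sum to 1")
  TRUE
})
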