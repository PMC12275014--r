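# Graphical threshold-selection diagnostics for peaks over threshold:
# the mean residual life (mean excess) plot and the parameter (threshold)
# stability plot. Both return tidy data frames ready for plotting; the
# selection itself is a visual judgement, so no automatic choice is made
# beyond the documented candidate grid.

#' Default candidate-threshold grid
#'
#' Empirical quantiles of \code{z} from 0.50 to 0.995 in steps of 0.005,
#' bracketing the 90th/95th/99th percentiles commonly examined.
#'
#' @param z numeric vector of deviation scores
#' @return ascending numeric vector of candidate thresholds
#' @export
thresholdGrid <- function(z) {
  unname(quantile(z[is.finite(z)], probs = seq(0.50, 0.995, by = 0.005)))
}

#' Mean residual life (mean excess) diagnostic
#'
#' For each candidate threshold k, the mean of the excesses z - k over
#' observations z > k, with a normal-approximation confidence band. Where
#' the generalized Pareto model holds with shape xi, the mean excess is
#' linear in k with slope xi / (1 - xi) — flat for exponential tails.
#' Thresholds at or above the sample maximum are flagged undefined rather
#' than dropped.
#'
#' @param z numeric vector of deviation scores
#' @param thresholds ascending candidate thresholds; defaults to
#'   \code{\link{thresholdGrid}}
#' @param conf confidence level of the band (default 0.95)
#' @return data.frame with columns \code{threshold}, \code{meanExcess},
#'   \code{lower}, \code{upper}, \code{nExceedances}, \code{defined}
#' @export
meanResidualLife <- function(z, thresholds = thresholdGrid(z), conf = 0.95) {
  z <- z[is.finite(z)]
  if (is.unsorted(thresholds, strictly = TRUE))
    stop("thresholds must be strictly ascending")
  zcrit <- qnorm(1 - (1 - conf) / 2)
  rows <- lapply(thresholds, function(k) {
    exc <- z[z > k] - k
    n <- length(exc)
    if (n == 0L)
      return(data.frame(threshold = k, meanExcess = NA_real_,
                        lower = NA_real_, upper = NA_real_,
                        nExceedances = 0L, defined = FALSE))
    m <- mean(exc)
    half <- if (n > 1L) zcrit * sd(exc) / sqrt(n) else NA_real_
    data.frame(threshold = k, meanExcess = m, lower = m - half,
               upper = m + half, nExceedances = n, defined = TRUE)
  })
  do.call(rbind, rows)
}

#' Parameter (threshold) stability diagnostic
#'
#' Refits the generalized Pareto distribution at each candidate threshold and
#' reports the shape estimate and the modified scale
#' \code{sigma* = scale - shape * threshold} with delta-method confidence
#' intervals. Under a GPD tail both are threshold-invariant in expectation,
#' so the curves flatten where the tail model becomes adequate. Fit failures
#' are recorded per threshold, not propagated.
#'
#' @inheritParams meanResidualLife
#' @param minExceedances skip thresholds with fewer exceedances (default 30)
#' @return data.frame with columns \code{threshold}, \code{shape},
#'   \code{shapeLower}, \code{shapeUpper}, \code{modifiedScale},
#'   \code{modifiedScaleLower}, \code{modifiedScaleUpper},
#'   \code{nExceedances}, \code{ok}
#' @export
parameterStability <- function(z, thresholds = thresholdGrid(z), conf = 0.95,
                               minExceedances = 30L) {
  z <- z[is.finite(z)]
  if (is.unsorted(thresholds, strictly = TRUE))
    stop("thresholds must be strictly ascending")
  zcrit <- qnorm(1 - (1 - conf) / 2)
  rows <- lapply(thresholds, function(k) {
    na <- data.frame(threshold = k, shape = NA_real_, shapeLower = NA_real_,
                     shapeUpper = NA_real_, modifiedScale = NA_real_,
                     modifiedScaleLower = NA_real_,
                     modifiedScaleUpper = NA_real_,
                     nExceedances = sum(z > k), ok = FALSE)
    if (sum(z > k) < minExceedances) return(na)
    fit <- try(suppressWarnings(fitGPD(z, k, minExceedances = 1L)),
               silent = TRUE)
    if (inherits(fit, "try-error")) return(na)
    modScale <- fit@scale - fit@shape * k
    # delta method: var(sigma*) = g' V g with g = (1, -k)
    g <- c(1, -k)
    vs <- drop(t(g) %*% fit@vcov %*% g)
    seMod <- if (is.finite(vs) && vs > 0) sqrt(vs) else NA_real_
    data.frame(threshold = k, shape = fit@shape,
               shapeLower = fit@shape - zcrit * fit@se[["shape"]],
               shapeUpper = fit@shape + zcrit * fit@se[["shape"]],
               modifiedScale = modScale,
               modifiedScaleLower = modScale - zcrit * seMod,
               modifiedScaleUpper = modScale + zcrit * seMod,
               nExceedances = fit@nExceedances, ok = TRUE)
  })
  do.call(rbind, rows)
}
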