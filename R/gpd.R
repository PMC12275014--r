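# Generalized Pareto distribution for threshold excesses, and the
# peaks-over-threshold maximum-likelihood machinery built on it.
#
# Parameterization: excesses y = z - k >= 0 given z > k follow
#   H(y) = 1 - (1 + xi * y / sigma)^(-1/xi),    sigma > 0,
# with the exponential limit 1 - exp(-y/sigma) as xi -> 0. Below
# .XI_EPS in |xi| the limit formulas are used for numerical stability.

.XI_EPS <- 1e-6

#' Generalized Pareto distribution functions for excesses
#'
#' CDF, quantile function, density and random generation for the generalized
#' Pareto distribution of threshold excesses \code{y >= 0}, parameterized by
#' \code{scale} (sigma-tilde) and \code{shape} (xi). The exponential limit is
#' used for \code{|shape| < 1e-6}. For \code{shape < 0}, values beyond the
#' upper endpoint \code{-scale/shape} have probability 1.
#'
#' @param y nonnegative excesses
#' @param p probabilities in (0, 1)
#' @param n number of draws
#' @param scale positive scale parameter
#' @param shape shape parameter
#' @param log return the log density (\code{dgpd} only)
#' @return \code{pgpd}: probabilities; \code{qgpd}: excesses; \code{dgpd}:
#'   densities; \code{rgpd}: random excesses.
#' @examples
#' pgpd(1, scale = 1, shape = 0)     # 1 - exp(-1)
#' qgpd(pgpd(1.3, 2, 0.2), 2, 0.2)   # round-trip
#' @export
pgpd <- function(y, scale, shape) {
  stopifnot(scale > 0)
  if (any(y < 0)) stop("excesses must be nonnegative")
  if (abs(shape) < .XI_EPS) return(-expm1(-y / scale))
  arg <- 1 + shape * y / scale
  if (shape < 0) {
    p <- ifelse(arg <= 0, 1, -expm1((-1 / shape) * log(pmax(arg, 1e-300))))
  } else {
    p <- -expm1((-1 / shape) * log(arg))
  }
  p
}

#' @rdname pgpd
#' @export
qgpd <- function(p, scale, shape) {
  stopifnot(scale > 0)
  if (any(p <= 0 | p >= 1)) stop("probabilities must be in (0, 1)")
  if (abs(shape) < .XI_EPS) return(-scale * log1p(-p))
  scale * expm1(-shape * log1p(-p)) / shape
}

#' @rdname pgpd
#' @export
dgpd <- function(y, scale, shape, log = FALSE) {
  stopifnot(scale > 0)
  if (abs(shape) < .XI_EPS) {
    ld <- -log(scale) - y / scale
    ld[y < 0] <- -Inf
  } else {
    arg <- 1 + shape * y / scale
    ld <- ifelse(y >= 0 & arg > 0,
                 -log(scale) - (1 / shape + 1) * log(pmax(arg, 1e-300)),
                 -Inf)
  }
  if (log) ld else exp(ld)
}

#' @rdname pgpd
#' @export
rgpd <- function(n, scale, shape) {
  qgpd(runif(n), scale, shape)
}

# negative log-likelihood of GPD excesses at (scale, shape)
gpdNegLogLik <- function(par, y) {
  sigma <- par[1]; xi <- par[2]
  if (!is.finite(sigma) || sigma <= 0) return(Inf)
  if (abs(xi) < .XI_EPS) return(length(y) * log(sigma) + sum(y) / sigma)
  arg <- 1 + xi * y / sigma
  if (any(arg <= 0)) return(Inf)
  length(y) * log(sigma) + (1 / xi + 1) * sum(log(arg))
}

# probability-weighted-moment starting values (Hosking & Wallis)
gpdPWMStart <- function(y) {
  y <- sort(y)
  n <- length(y)
  b0 <- mean(y)
  b1 <- sum((seq_len(n) - 1) / (n - 1) * y) / n
  denom <- b0 - 2 * b1
  if (denom <= 0) return(c(scale = b0, shape = 0.01))
  xi <- 2 - b0 / denom
  sigma <- 2 * b0 * b1 / denom
  if (!is.finite(sigma) || sigma <= 0) sigma <- b0
  xi <- min(max(xi, -0.45), 0.95)
  c(scale = sigma, shape = xi)
}

#' Fit a generalized Pareto distribution by peaks over threshold
#'
#' Maximum-likelihood fit of the GPD to the excesses of \code{z} above the
#' threshold \code{k}. The optimizer works on (log scale, shape) with the
#' shape restricted to (-0.5, 1] for estimator regularity, started from
#' probability-weighted-moment estimates. Standard errors come from the
#' inverse observed information at the optimum.
#'
#' @param z numeric vector of deviation scores (full sample, not excesses)
#' @param threshold threshold k on the scale of \code{z}
#' @param minExceedances warn when fewer exceedances than this are available
#'   (default 30)
#' @return a \linkS4class{GPDFit}
#' @examples
#' set.seed(1)
#' z <- rnorm(5000)
#' fitGPD(z, threshold = quantile(z, 0.95))
#' @seealso \code{\link{returnLevel}}, \code{\link{parameterStability}},
#'   \code{\link{gpdProfile}}
#' @export
fitGPD <- function(z, threshold, minExceedances = 30L) {
  z <- z[is.finite(z)]
  y <- z[z > threshold] - threshold
  nexc <- length(y)
  if (nexc == 0L) stop("no exceedances above the threshold")
  if (nexc < minExceedances)
    warning(sprintf("only %d exceedances above threshold %.4g", nexc,
                    threshold))
  start <- gpdPWMStart(y)
  nll <- function(par) {  # par = (log sigma, xi)
    xi <- par[2]
    if (xi <= -0.5 || xi > 1) return(1e10)
    v <- gpdNegLogLik(c(exp(par[1]), xi), y)
    if (!is.finite(v)) 1e10 else v
  }
  fit <- optim(c(log(start[1]), start[2]), nll, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
  # polish from a second start if the first appears stuck
  fit2 <- optim(c(log(mean(y)), 0.01), nll, method = "Nelder-Mead",
                control = list(maxit = 2000, reltol = 1e-12))
  if (fit2$value < fit$value) fit <- fit2
  if (fit$convergence != 0)
    stop("GPD maximum-likelihood optimization did not converge: code ",
         fit$convergence, " (", fit$counts[1], " evaluations)")
  sigma <- unname(exp(fit$par[1])); xi <- unname(fit$par[2])
  hess <- try(optimHess(c(sigma, xi), gpdNegLogLik, y = y), silent = TRUE)
  vcov <- matrix(NA_real_, 2, 2)
  if (!inherits(hess, "try-error")) {
    vc <- try(solve(hess), silent = TRUE)
    if (!inherits(vc, "try-error") && all(diag(vc) > 0)) vcov <- vc
  }
  dimnames(vcov) <- list(c("scale", "shape"), c("scale", "shape"))
  se <- sqrt(diag(vcov))
  new("GPDFit", threshold = as.numeric(threshold), scale = sigma, shape = xi,
      se = c(scale = unname(se[1]), shape = unname(se[2])), vcov = vcov,
      nExceedances = nexc, nTotal = length(z),
      exceedRate = nexc / length(z), logLik = -fit$value, excesses = y)
}

#' Return level of a peaks-over-threshold fit
#'
#' The level exceeded on average once every \code{m} observations under the
#' fitted tail model:
#' \code{x_m = k + (scale/shape) * ((m * zeta)^shape - 1)}, with the limit
#' \code{k + scale * log(m * zeta)} as the shape tends to 0, where zeta is
#' the exceedance rate. Requires \code{m * zeta >= 1}: levels below the
#' threshold are not defined by the tail model.
#'
#' @param fit a \linkS4class{GPDFit}
#' @param m observations-per-event count (may be a vector)
#' @return return level(s) on the original z-score scale
#' @export
returnLevel <- function(fit, m) {
  stopifnot(is(fit, "GPDFit"))
  mz <- m * fit@exceedRate
  if (any(mz < 1))
    stop("m * exceedance rate must be >= 1: the tail model does not define ",
         "levels below the threshold")
  if (abs(fit@shape) < .XI_EPS)
    fit@threshold + fit@scale * log(mz)
  else
    fit@threshold + fit@scale * expm1(fit@shape * log(mz)) / fit@shape
}

#' Profile log-likelihood of a GPD fit
#'
#' One-dimensional profile of the excess log-likelihood over a grid of one
#' parameter, maximizing over the other. Useful for judging how peaked the
#' likelihood is around the estimates.
#'
#' @param fit a \linkS4class{GPDFit}
#' @param which \code{"shape"} or \code{"scale"}
#' @param grid parameter values to profile over; a default grid of +/- 4 SE
#'   around the estimate is used when missing
#' @return data.frame with columns \code{value} and \code{profileLogLik}
#' @export
gpdProfile <- function(fit, which = c("shape", "scale"), grid = NULL) {
  which <- match.arg(which)
  y <- fit@excesses
  est <- if (which == "shape") fit@shape else fit@scale
  se <- fit@se[[which]]
  if (is.null(grid)) {
    if (!is.finite(se)) se <- abs(est) * 0.25 + 0.05
    grid <- seq(est - 4 * se, est + 4 * se, length.out = 41)
    if (which == "scale") grid <- grid[grid > 0]
  }
  prof <- vapply(grid, function(g) {
    if (which == "shape") {
      o <- optim(log(fit@scale),
                 function(ls) gpdNegLogLik(c(exp(ls), g), y),
                 method = "Brent", lower = log(fit@scale) - 8,
                 upper = log(fit@scale) + 8)
    } else {
      o <- optim(fit@shape, function(xi) gpdNegLogLik(c(g, xi), y),
                 method = "Brent", lower = -0.49, upper = 1)
    }
    -o$value
  }, numeric(1))
  data.frame(value = grid, profileLogLik = prof)
}
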