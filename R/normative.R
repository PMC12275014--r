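# Normative modeling: per-variable Bayesian linear regression on a covariate
# basis, hyperparameters by marginal-likelihood (evidence) maximization, and
# an optional monotone sinh-arcsinh response warp fitted by maximum
# likelihood. Held-out deviation (z) scores standardize each subject's
# (possibly warped) response against the posterior predictive distribution.
#
# The warp family is sinh-arcsinh over an affine standardization layer:
#   w(y) = sinh(delta * asinh((y - a) / b) - epsilon),
# strictly monotone for delta > 0, b > 0, identity-like at
# (epsilon, delta) = (0, 1). This is a deliberately simplified warped-BLR
# variant; see the methods vignette for what is and is not reproduced.

warpForward <- function(y, wp) {
  u <- (y - wp$a) / wp$b
  sinh(wp$delta * asinh(u) - wp$epsilon)
}

warpInverse <- function(w, wp) {
  wp$a + wp$b * sinh((asinh(w) + wp$epsilon) / wp$delta)
}

# log |dw/dy|, needed for the warped likelihood
warpLogJacobian <- function(y, wp) {
  u <- (y - wp$a) / wp$b
  t <- wp$delta * asinh(u) - wp$epsilon
  log(wp$delta) + log(cosh(t)) - 0.5 * log1p(u^2) - log(wp$b)
}

#' Build (or apply) the normative covariate basis
#'
#' Design matrix of an intercept, a cubic B-spline in age with interior
#' knots at training quantiles, a sex indicator, and one-hot site columns
#' (reference level dropped). \code{buildBasisSpec} freezes the knots,
#' boundary and site levels from training data; \code{basisMatrix} applies a
#' frozen spec to (new) covariates and refuses unseen site labels by name
#' rather than extrapolating silently.
#'
#' @param covariates data.frame with columns age, sex, site (site optional)
#' @param nKnots number of interior age knots (default 3)
#' @return \code{buildBasisSpec}: a list spec; \code{basisMatrix}: a design
#'   matrix
#' @export
buildBasisSpec <- function(covariates, nKnots = 3L) {
  stopifnot(all(c("age", "sex") %in% names(covariates)))
  age <- covariates$age
  knots <- unname(quantile(age, probs = seq_len(nKnots) / (nKnots + 1)))
  list(knots = knots,
       boundary = range(age) + c(-1, 1) * 0.05 * diff(range(age)),
       degree = 3L,
       siteLevels = if ("site" %in% names(covariates))
         sort(unique(as.character(covariates$site))) else character(0))
}

#' @rdname buildBasisSpec
#' @param spec frozen basis spec from \code{buildBasisSpec}
#' @export
basisMatrix <- function(spec, covariates) {
  ageBasis <- splines::bs(covariates$age, knots = spec$knots,
                          degree = spec$degree,
                          Boundary.knots = spec$boundary)
  X <- cbind(intercept = 1, ageBasis, sex = as.numeric(covariates$sex))
  colnames(X) <- c("intercept", paste0("age_bs", seq_len(ncol(ageBasis))),
                   "sex")
  if (length(spec$siteLevels)) {
    site <- as.character(covariates$site)
    unseen <- setdiff(unique(site), spec$siteLevels)
    if (length(unseen))
      stop("unseen site label(s): ", paste(unseen, collapse = ", "))
    for (lev in spec$siteLevels[-1])
      X <- cbind(X, as.numeric(site == lev))
    colnames(X)[(ncol(X) - length(spec$siteLevels) + 2):ncol(X)] <-
      paste0("site_", spec$siteLevels[-1])
  }
  X
}

# Evidence-maximized Bayesian linear regression.
# Returns hyperparameters, posterior and the maximized log marginal
# likelihood for responses t on design X.
evidenceBLR <- function(X, t, nStarts = 3L) {
  n <- nrow(X); p <- ncol(X)
  XtX <- crossprod(X)
  Xt <- crossprod(X, t)
  tt <- sum(t^2)
  logML <- function(la, lb) {
    alpha <- exp(la); beta <- exp(lb)
    A <- alpha * diag(p) + beta * XtX
    ch <- tryCatch(chol(A), error = function(e) NULL)
    if (is.null(ch)) return(-Inf)
    m <- beta * backsolve(ch, forwardsolve(t(ch), Xt))
    # E(m) = beta/2 ||t - Xm||^2 + alpha/2 m'm, via expanded quadratic
    rss <- tt - 2 * sum(m * Xt) + drop(t(m) %*% XtX %*% m)
    e <- beta / 2 * rss + alpha / 2 * sum(m^2)
    p / 2 * la + n / 2 * lb - e - sum(log(diag(ch))) - n / 2 * log(2 * pi)
  }
  obj <- function(par) {
    v <- logML(par[1], par[2])
    if (!is.finite(v)) 1e10 else -v
  }
  varT <- var(t)
  starts <- list(c(log(1e-2), log(1 / max(varT, 1e-12))),
                 c(log(1), log(1)),
                 c(log(1e-4), log(10 / max(varT, 1e-12))))
  best <- NULL
  for (s in starts[seq_len(min(nStarts, 3L))]) {
    o <- optim(s, obj, method = "Nelder-Mead",
               control = list(maxit = 500, reltol = 1e-10))
    if (is.null(best) || o$value < best$value) best <- o
  }
  alpha <- exp(best$par[1]); beta <- exp(best$par[2])
  A <- alpha * diag(p) + beta * XtX
  S <- solve(A)
  m <- beta * drop(S %*% Xt)
  list(alpha = alpha, beta = beta, weights = m, weightCov = S,
       logEvidence = -best$value)
}

#' Fit a normative model for one variable
#'
#' Bayesian linear regression of a response on the covariate basis (age
#' spline + sex + site), with prior and noise precisions chosen by
#' maximizing the marginal likelihood. With \code{warp = TRUE} a monotone
#' sinh-arcsinh transform of the response is estimated jointly by maximum
#' likelihood (evidence of the warped regression plus the warp Jacobian) and
#' the regression is fitted in warped space — the device that lets strongly
#' non-Gaussian responses yield calibrated Gaussian deviation scores.
#'
#' @param y numeric response vector (one variable)
#' @param covariates data.frame with columns age, sex and optionally site
#' @param warp estimate the sinh-arcsinh response warp (default FALSE)
#' @param nKnots interior age-spline knots (default 3)
#' @param nStarts multi-start count for the evidence optimization
#' @return a \linkS4class{NormativeModel}
#' @examples
#' sim <- simulateCovariateIDP(300, 1, seed = 1)
#' fit <- fitNormative(sim$values[, 1], sim$covariates)
#' fit
#' @export
fitNormative <- function(y, covariates, warp = FALSE, nKnots = 3L,
                         nStarts = 3L) {
  if (any(!is.finite(y))) stop("response must be finite")
  if (sd(y) == 0) stop("degenerate input: response is constant")
  if (anyNA(covariates)) stop("covariates must be complete")
  spec <- buildBasisSpec(covariates, nKnots = nKnots)
  X <- basisMatrix(spec, covariates)
  if (nrow(X) < 10 * ncol(X))
    warning("fewer than 10 training rows per basis column; the fit may be ",
            "poorly determined")
  condX <- kappa(X, exact = FALSE)
  if (condX > 1e8)
    warning(sprintf("basis is near rank-deficient (condition number %.3g)",
                    condX))
  wp <- list()
  if (warp) {
    a0 <- mean(y); b0 <- sd(y)
    # par = (epsilon, log delta); affine layer pinned to training moments,
    # which keeps the optimization 2-dimensional and well-scaled
    warpObj <- function(par) {
      w <- list(a = a0, b = b0, epsilon = par[1], delta = exp(par[2]))
      t <- warpForward(y, w)
      if (any(!is.finite(t)) || sd(t) == 0) return(1e10)
      ev <- evidenceBLR(X, t, nStarts = 1L)
      -(ev$logEvidence + sum(warpLogJacobian(y, w)))
    }
    o <- optim(c(0, 0), warpObj, method = "Nelder-Mead",
               control = list(maxit = 200, reltol = 1e-8))
    wp <- list(a = a0, b = b0, epsilon = o$par[1], delta = exp(o$par[2]))
  }
  t <- if (length(wp)) warpForward(y, wp) else y
  ev <- evidenceBLR(X, t, nStarts = nStarts)
  new("NormativeModel", basisSpec = spec, weights = ev$weights,
      weightCov = ev$weightCov, noiseVariance = 1 / ev$beta,
      priorPrecision = ev$alpha, warp = wp,
      trainSummary = list(mean = mean(t), var = var(t), n = length(t)),
      logEvidence = ev$logEvidence)
}

# posterior predictive mean and variance on the (warped) response scale
predictiveMoments <- function(fit, covariates) {
  X <- basisMatrix(fit@basisSpec, covariates)
  mu <- drop(X %*% fit@weights)
  v <- fit@noiseVariance + rowSums((X %*% fit@weightCov) * X)
  list(mean = mu, var = v)
}

#' Deviation (z) scores under a normative model
#'
#' Standardizes each subject's (warped) response against the posterior
#' predictive distribution: z = (w(y) - predictive mean) / predictive SD,
#' where the predictive variance is the noise variance plus the
#' basis-dependent posterior weight uncertainty.
#'
#' @param fit a \linkS4class{NormativeModel}
#' @param y response vector
#' @param covariates data.frame matching the fit's basis (unseen site labels
#'   raise an error naming the label)
#' @return numeric vector of deviation scores, one per subject
#' @export
computeZscores <- function(fit, y, covariates) {
  stopifnot(is(fit, "NormativeModel"))
  pm <- predictiveMoments(fit, covariates)
  t <- if (length(fit@warp)) warpForward(y, fit@warp) else y
  (t - pm$mean) / sqrt(pm$var)
}

#' Held-out fit metrics for a normative model
#'
#' Explained variance of the predictive mean, mean standardized log loss
#' (mean predictive Gaussian negative log-likelihood minus that of a trivial
#' Gaussian fitted to the training response; negative is better than
#' trivial), and the skewness and excess kurtosis of the held-out deviation
#' scores — all computed on the (warped) response scale.
#'
#' @inheritParams computeZscores
#' @return one-row data.frame with columns \code{explainedVariance},
#'   \code{msll}, \code{skewness}, \code{kurtosis} (excess) and \code{n}
#' @export
evaluateNormative <- function(fit, y, covariates) {
  stopifnot(is(fit, "NormativeModel"))
  if (length(y) < 3L) stop("at least 3 test rows are required")
  pm <- predictiveMoments(fit, covariates)
  t <- if (length(fit@warp)) warpForward(y, fit@warp) else y
  ev <- 1 - mean((t - pm$mean)^2) / var(t)
  nllPred <- 0.5 * log(2 * pi * pm$var) + (t - pm$mean)^2 / (2 * pm$var)
  ts <- fit@trainSummary
  nllTriv <- 0.5 * log(2 * pi * ts$var) + (t - ts$mean)^2 / (2 * ts$var)
  z <- (t - pm$mean) / sqrt(pm$var)
  data.frame(explainedVariance = ev, msll = mean(nllPred) - mean(nllTriv),
             skewness = sampleSkewness(z), kurtosis = sampleKurtosis(z),
             n = length(y))
}

#' Fit normative models for every variable of a matrix
#'
#' Convenience wrapper that fits one normative model per column on a
#' training split, computes held-out deviation scores and fit metrics, and
#' applies a quality-control filter: variables with negative held-out
#' explained variance or |skewness| / |excess kurtosis| of the deviation
#' scores beyond configured bounds are flagged for exclusion.
#'
#' @param values subjects-by-variables response matrix
#' @param covariates covariate data.frame aligned with \code{values}
#' @param trainFraction fraction of subjects used for training (default 0.1,
#'   appropriate only for large cohorts; use a more conservative split, e.g.
#'   one half, for smaller datasets)
#' @param warp estimate the response warp per variable
#' @param maxAbsSkewness,maxAbsKurtosis QC bounds on the held-out deviation
#'   scores (defaults 2 and 10)
#' @param seed integer seed for the train/test partition
#' @return list with \code{models} (per variable), \code{z} (held-out
#'   deviation matrix), \code{metrics} (per-variable data.frame with a
#'   \code{qcPass} column), \code{trainIndex} and \code{testIndex}
#' @export
fitNormativeAll <- function(values, covariates, trainFraction = 0.1,
                            warp = FALSE, maxAbsSkewness = 2,
                            maxAbsKurtosis = 10, seed = NULL) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == nrow(covariates),
            trainFraction > 0, trainFraction < 1)
  n <- nrow(values)
  idx <- withSeed(seed, sample.int(n, max(2L, round(trainFraction * n))))
  trainIndex <- sort(idx)
  testIndex <- setdiff(seq_len(n), trainIndex)
  covTrain <- covariates[trainIndex, , drop = FALSE]
  covTest <- covariates[testIndex, , drop = FALSE]
  models <- list()
  z <- matrix(NA_real_, length(testIndex), ncol(values),
              dimnames = list(NULL, colnames(values)))
  metrics <- NULL
  for (j in seq_len(ncol(values))) {
    fit <- fitNormative(values[trainIndex, j], covTrain, warp = warp)
    models[[j]] <- fit
    z[, j] <- computeZscores(fit, values[testIndex, j], covTest)
    m <- evaluateNormative(fit, values[testIndex, j], covTest)
    metrics <- rbind(metrics, m)
  }
  metrics$variable <- colnames(values)
  metrics$qcPass <- metrics$explainedVariance >= 0 &
    abs(metrics$skewness) <= maxAbsSkewness &
    abs(metrics$kurtosis) <= maxAbsKurtosis
  names(models) <- colnames(values)
  list(models = models, z = z, metrics = metrics,
       trainIndex = trainIndex, testIndex = testIndex)
}
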