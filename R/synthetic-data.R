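# Synthetic-data generators. Everything the pipeline consumes — covariates,
# raw phenotype responses, deviation matrices with known tail dependence,
# and behavioral phenotypes — can be generated here with analytically known
# ground truth, so the whole framework is testable without restricted data.
#
# The tail-dependence ground truth is a max-linear construction:
#   X_i = max_k B[i, k] * Z_k,   Z_k i.i.d. Frechet(alpha = 2),
# whose angular measure places mass ||B[, k]||^2 at the atom
# B[, k] / ||B[, k]||, so the true TPDM is exactly B %*% t(B). That closed
# form is the oracle against which the estimator is validated.

#' Simulate a covariate table
#'
#' Subject identifiers, ages uniform on a range (default 40-80 years), a
#' binary sex code (default 53% female, coded 1), and a categorical site
#' label.
#'
#' @param nSubjects number of subjects
#' @param ageRange length-2 numeric, in years (default c(40, 80))
#' @param femaleProportion probability of sex code 1 (default 0.53)
#' @param sites character vector of site labels (default 3 sites)
#' @param seed integer seed; generation is reproducible given the seed
#' @return data.frame with columns subject_id, age, sex, site
#' @export
simulateCovariates <- function(nSubjects, ageRange = c(40, 80),
                               femaleProportion = 0.53,
                               sites = paste0("site", 1:3), seed = NULL) {
  n <- checkCount(nSubjects, "nSubjects", min = 2L)
  stopifnot(length(ageRange) == 2L, all(is.finite(ageRange)),
            ageRange[1] < ageRange[2],
            femaleProportion > 0, femaleProportion < 1)
  withSeed(seed, {
    data.frame(
      subject_id = sprintf("sub-%06d", seq_len(n)),
      age = runif(n, ageRange[1], ageRange[2]),
      sex = rbinom(n, 1L, femaleProportion),
      site = sample(sites, n, replace = TRUE),
      stringsAsFactors = FALSE)
  })
}

#' Default per-variable trend specification
#'
#' A simple smooth mean model per variable: intercept + linear and quadratic
#' age terms + sex effect, plus additive per-site intercepts. Coefficients
#' are drawn once from fixed ranges so that each variable has its own trend.
#'
#' @param dVariables number of variables
#' @param nSites number of sites
#' @param seed integer seed
#' @return list with matrix \code{coef} (columns intercept, age, age2, sex)
#'   and matrix \code{siteEffects} (dVariables x nSites)
#' @export
defaultTrendSpec <- function(dVariables, nSites = 3L, seed = NULL) {
  d <- checkCount(dVariables, "dVariables")
  withSeed(seed, {
    coef <- cbind(intercept = runif(d, -1, 1),
                  age = runif(d, -0.05, 0.05),
                  age2 = runif(d, -5e-4, 5e-4),
                  sex = runif(d, -0.5, 0.5))
    siteEffects <- matrix(runif(d * nSites, -0.3, 0.3), d, nSites)
    list(coef = coef, siteEffects = siteEffects)
  })
}

evalTrend <- function(trendSpec, covariates) {
  coef <- trendSpec$coef
  siteLevels <- sort(unique(covariates$site))
  if (ncol(trendSpec$siteEffects) < length(siteLevels))
    stop("trendSpec has fewer site-effect columns than sites present")
  siteIdx <- match(covariates$site, siteLevels)
  ageC <- covariates$age - 60  # centre age so the quadratic stays tame
  mu <- outer(rep(1, nrow(covariates)), coef[, "intercept"]) +
    outer(ageC, coef[, "age"]) +
    outer(ageC^2, coef[, "age2"]) +
    outer(covariates$sex, coef[, "sex"]) +
    t(trendSpec$siteEffects[, siteIdx, drop = FALSE])
  mu
}

#' Simulate covariates and phenotype responses
#'
#' Generates a covariate table and a subjects-by-variables response matrix
#' equal to a per-variable mean trend in the covariates plus independent
#' Gaussian noise: the well-specified setting under which normative-model
#' calibration can be checked exactly.
#'
#' @inheritParams simulateCovariates
#' @param dVariables number of response variables (IDPs)
#' @param trendSpec per-variable trend parameters as returned by
#'   \code{\link{defaultTrendSpec}}; generated from the seed when NULL
#' @param noiseSD per-variable noise standard deviation, recycled to
#'   \code{dVariables}; zero gives the noiseless case
#' @param seed integer seed
#' @return list with \code{covariates} (data.frame), \code{values}
#'   (matrix), \code{trueMean} (matrix) and \code{trendSpec}
#' @export
simulateCovariateIDP <- function(nSubjects, dVariables, trendSpec = NULL,
                                 noiseSD = 1, ageRange = c(40, 80),
                                 femaleProportion = 0.53,
                                 sites = paste0("site", 1:3), seed = NULL) {
  n <- checkCount(nSubjects, "nSubjects", min = 2L)
  d <- checkCount(dVariables, "dVariables")
  noiseSD <- rep_len(noiseSD, d)
  if (any(!is.finite(noiseSD)) || any(noiseSD < 0))
    stop("noiseSD must be finite and nonnegative")
  withSeed(seed, {
    covariates <- simulateCovariates(n, ageRange, femaleProportion, sites)
    if (is.null(trendSpec)) trendSpec <- defaultTrendSpec(d, length(sites))
    if (any(!is.finite(trendSpec$coef)) ||
        any(!is.finite(trendSpec$siteEffects)))
      stop("trend parameters must be finite")
    mu <- evalTrend(trendSpec, covariates)
    noise <- matrix(rnorm(n * d), n, d) %*% diag(noiseSD, d)
    values <- mu + noise
    colnames(values) <- colnames(mu) <- paste0("idp", seq_len(d))
    list(covariates = covariates, values = values, trueMean = mu,
         trendSpec = trendSpec)
  })
}

checkMaxLinearB <- function(B) {
  B <- as.matrix(B)
  if (any(!is.finite(B)) || any(B < 0))
    stop("coefficient matrix B must be nonnegative and finite")
  if (any(rowSums(B) == 0))
    stop("coefficient matrix B must have no all-zero row")
  B
}

#' Simulate a max-linear regularly varying vector
#'
#' Draws X with rows X_i = max_k B[i,k] * Z_k from i.i.d. Frechet factors
#' Z_k with tail index \code{alpha} (inverse-CDF sampling,
#' Z = (-log U)^(-1/alpha)). For \code{alpha = 2} the margins are
#' Frechet(2) with scale \code{sqrt(rowSums(B^2))} and the TPDM of X is
#' exactly \code{B \%*\% t(B)} — the closed-form oracle used throughout the
#' tests.
#'
#' @param nSubjects number of rows to draw
#' @param B nonnegative D x K coefficient matrix with no all-zero row
#' @param alpha positive tail index; 2 is required for the TPDM oracle
#' @param seed integer seed
#' @return nSubjects x D matrix of positive values
#' @export
simulateMaxLinear <- function(nSubjects, B, alpha = 2, seed = NULL) {
  n <- checkCount(nSubjects, "nSubjects")
  B <- checkMaxLinearB(B)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0)
    stop("tail index alpha must be a positive number")
  withSeed(seed, {
    K <- ncol(B)
    Z <- matrix((-log(runif(n * K)))^(-1 / alpha), n, K)
    X <- matrix(-Inf, n, nrow(B))
    for (k in seq_len(K))
      X <- pmax(X, tcrossprod(Z[, k], B[, k]))
    colnames(X) <- paste0("v", seq_len(nrow(B)))
    X
  })
}

#' Simulate deviation scores with known tail dependence
#'
#' Draws a max-linear vector with tail index 2 and pushes every column
#' through its exact Frechet CDF (scale \code{sqrt(rowSums(B^2))}) and the
#' standard normal quantile function. The margins are exactly standard
#' normal; the copula — and hence the tail dependence, with true TPDM
#' \code{B \%*\% t(B)} after unit-scale normalization of the rows of B — is
#' preserved because both maps are strictly monotone.
#'
#' @inheritParams simulateMaxLinear
#' @return nSubjects x D matrix of z-scores with standard normal margins
#' @export
simulateTailZ <- function(nSubjects, B, seed = NULL) {
  B <- checkMaxLinearB(B)
  X <- simulateMaxLinear(nSubjects, B, alpha = 2, seed = seed)
  scales <- sqrt(rowSums(B^2))
  Z <- X
  for (j in seq_len(ncol(X))) {
    # log F(x) = -(scale/x)^2 ; qnorm on the log scale avoids rounding at 1
    Z[, j] <- qnorm(-(scales[j] / X[, j])^2, log.p = TRUE)
  }
  colnames(Z) <- colnames(X)
  Z
}

#' Simulate behavioral phenotypes with planted associations
#'
#' Builds a phenotype table from subject-level component scores: planted
#' continuous phenotypes are effect * standardized score + unit Gaussian
#' noise; planted binary phenotypes are the median split of that latent
#' construct; null phenotypes are independent standard normal (continuous)
#' or fair binary draws.
#'
#' @param scores subjects-by-components numeric matrix
#' @param nNull number of pure-noise phenotypes
#' @param planted list of plantings, each a list with elements
#'   \code{component} (column index into \code{scores}), \code{effect}
#'   (finite real) and \code{binary} (logical, default FALSE)
#' @param nullBinary make the null phenotypes fair binary instead of normal
#' @param seed integer seed
#' @return data.frame of phenotypes; planted columns are named
#'   \code{planted1, ...} and null columns \code{null1, ...}; an attribute
#'   \code{"planted"} records the spec
#' @export
simulatePhenotypes <- function(scores, nNull = 0L, planted = list(),
                               nullBinary = FALSE, seed = NULL) {
  scores <- as.matrix(scores)
  if (nrow(scores) == 0L || ncol(scores) == 0L)
    stop("scores must be a non-empty matrix")
  nNull <- checkCount(nNull, "nNull", min = 0L)
  n <- nrow(scores)
  withSeed(seed, {
    out <- list()
    for (i in seq_along(planted)) {
      p <- planted[[i]]
      comp <- checkCount(p$component, "component")
      if (comp > ncol(scores))
        stop("planted component index ", comp, " exceeds the number of ",
             "score columns")
      if (!is.finite(p$effect)) stop("planted effect sizes must be finite")
      s <- as.numeric(scale(scores[, comp]))
      latent <- p$effect * s + rnorm(n)
      out[[paste0("planted", i)]] <-
        if (isTRUE(p$binary)) as.integer(latent > median(latent)) else latent
    }
    for (i in seq_len(nNull)) {
      out[[paste0("null", i)]] <-
        if (nullBinary) rbinom(n, 1L, 0.5) else rnorm(n)
    }
    res <- as.data.frame(out)
    attr(res, "planted") <- planted
    res
  })
}

#' Planted bulk-versus-tail contrast
#'
#' A four-variable construction in which ordinary (bulk) correlation and
#' tail dependence live on orthogonal directions: a (1 - tailFraction)
#' share of subjects is Gaussian with correlation \code{bulkCor} between
#' variables 1 and 2 (variables 3 and 4 independent), while the remaining
#' share lies on extreme rays along the (3, 4) diagonal with radius uniform
#' on \code{radiusRange}. Standard correlation PCA is dominated by the bulk
#' pair; the angular measure — and with it the TPDM — by the tail pair, so
#' the two leading eigenvectors are nearly orthogonal.
#'
#' @param nSubjects number of subjects
#' @param bulkCor Gaussian correlation of the bulk pair (default 0.9)
#' @param tailFraction share of subjects on the extreme rays (default 0.05)
#' @param radiusRange range of the tail radius (default c(6, 10))
#' @param seed integer seed
#' @return nSubjects x 4 matrix; attribute \code{"tailDirection"} holds the
#'   planted extreme direction and \code{"bulkDirection"} the bulk one
#' @export
simulateBulkTailContrast <- function(nSubjects, bulkCor = 0.9,
                                     tailFraction = 0.05,
                                     radiusRange = c(6, 10), seed = NULL) {
  n <- checkCount(nSubjects, "nSubjects", min = 10L)
  stopifnot(abs(bulkCor) < 1, tailFraction > 0, tailFraction < 0.5)
  withSeed(seed, {
    nTail <- max(1L, round(tailFraction * n))
    z <- matrix(rnorm(n * 4), n, 4)
    # correlate the bulk pair
    z[, 2] <- bulkCor * z[, 1] + sqrt(1 - bulkCor^2) * z[, 2]
    tailIdx <- sample.int(n, nTail)
    r <- runif(nTail, radiusRange[1], radiusRange[2])
    z[tailIdx, 3] <- r / sqrt(2) + rnorm(nTail, sd = 0.01)
    z[tailIdx, 4] <- r / sqrt(2) + rnorm(nTail, sd = 0.01)
    colnames(z) <- paste0("v", 1:4)
    attr(z, "tailDirection") <- c(0, 0, 1, 1) / sqrt(2)
    attr(z, "bulkDirection") <- c(1, 1, 0, 0) / sqrt(2)
    z
  })
}
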