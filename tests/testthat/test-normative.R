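test_that("a noiseless linear response is recovered exactly", {
  set.seed(71)
  cov <- simulateCovariates(400, seed = 71)
  mu <- 0.5 + 0.03 * cov$age - 0.2 * cov$sex
  tr <- 1:200; te <- 201:400
  fit <- fitNormative(mu[tr], cov[tr, ], warp = FALSE)
  pm <- extremeNorm:::predictiveMoments(fit, cov[te, ])
  # the spline basis spans linear-in-age functions: exact interpolation
  expect_lt(max(abs(pm$mean - mu[te])), 1e-4)
  metrics <- evaluateNormative(fit, mu[te], cov[te, ])
  expect_equal(metrics$explainedVariance, 1, tolerance = 1e-6)
  expect_lt(metrics$msll, 0)
})

test_that("posterior weight intervals have close to nominal coverage", {
  sexCover <- 0L
  nRep <- 200L
  for (r in seq_len(nRep)) {
    cov <- simulateCovariates(300, seed = 700 + r)
    sexEffect <- -0.4
    mu <- 1 + 0.02 * cov$age + sexEffect * cov$sex
    y <- mu + withr::with_seed(900 + r, rnorm(300))
    fit <- fitNormative(y, cov, warp = FALSE)
    X <- basisMatrix(fit@basisSpec, cov)
    sexIdx <- which(colnames(X) == "sex")
    est <- fit@weights[sexIdx]
    se <- sqrt(fit@weightCov[sexIdx, sexIdx])
    if (abs(est - sexEffect) <= 1.96 * se) sexCover <- sexCover + 1L
  }
  expect_gte(sexCover / nRep, 0.89)
  expect_lte(sexCover / nRep, 0.99)
})

test_that("the sinh-arcsinh warp reduces skew of held-out deviations", {
  sim <- simulateCovariateIDP(3000, 1, noiseSD = 0.5, seed = 72)
  y <- exp(sim$values[, 1])  # strongly right-skewed response
  tr <- 1:1000; te <- 1001:3000
  fitOff <- fitNormative(y[tr], sim$covariates[tr, ], warp = FALSE)
  fitOn <- fitNormative(y[tr], sim$covariates[tr, ], warp = TRUE)
  zOff <- computeZscores(fitOff, y[te], sim$covariates[te, ])
  zOn <- computeZscores(fitOn, y[te], sim$covariates[te, ])
  expect_lt(abs(extremeNorm:::sampleSkewness(zOn)),
            abs(extremeNorm:::sampleSkewness(zOff)))
})

test_that("warp forward/inverse round-trips over the response range", {
  wp <- list(a = 2, b = 1.5, epsilon = 0.3, delta = 1.7)
  y <- seq(-5, 10, length.out = 200)
  w <- extremeNorm:::warpForward(y, wp)
  expect_equal(extremeNorm:::warpInverse(w, wp), y, tolerance = 1e-10)
  expect_true(all(diff(w) > 0))  # strict monotonicity
})

test_that("deviation scores behave as standardized residuals", {
  sim <- simulateCovariateIDP(1000, 1, noiseSD = 1, seed = 73)
  fit <- fitNormative(sim$values[, 1], sim$covariates, warp = FALSE)
  pm <- extremeNorm:::predictiveMoments(fit, sim$covariates)
  # y at the predictive mean gives z = 0
  expect_equal(computeZscores(fit, pm$mean, sim$covariates),
               rep(0, 1000), tolerance = 1e-12)
  # for fixed covariates, z is strictly increasing in y
  covRow <- sim$covariates[rep(1, 50), ]
  yGrid <- seq(-3, 3, length.out = 50)
  expect_true(all(diff(computeZscores(fit, yGrid, covRow)) > 0))
})

test_that("held-out deviations are calibrated under the true model", {
  sim <- simulateCovariateIDP(12000, 1, noiseSD = 1, seed = 74)
  tr <- 1:2000; te <- 2001:12000
  fit <- fitNormative(sim$values[tr, 1], sim$covariates[tr, ])
  z <- computeZscores(fit, sim$values[te, 1], sim$covariates[te, ])
  # Monte-Carlo SEs combine test sampling and training estimation noise
  nTe <- length(te); nTr <- length(tr)
  expect_lt(abs(mean(z)), 3 * sqrt(1 / nTe + 1 / nTr))
  expect_lt(abs(var(z) - 1), 3 * sqrt(2 / nTe + 2 / nTr))
})

test_that("MSLL is near zero when the model carries no signal", {
  set.seed(75)
  cov <- simulateCovariates(4000, seed = 75)
  y <- rnorm(4000)  # independent of all covariates
  tr <- 1:2000; te <- 2001:4000
  fit <- fitNormative(y[tr], cov[tr, ])
  m <- evaluateNormative(fit, y[te], cov[te, ])
  expect_lt(abs(m$msll), 0.02)
})

test_that("degenerate inputs and unseen sites are rejected by name", {
  cov <- simulateCovariates(100, seed = 76)
  expect_error(fitNormative(rep(1, 100), cov), "constant")
  expect_error(fitNormative(c(NA, rnorm(99)), cov), "finite")
  fit <- fitNormative(rnorm(100), cov)
  covNew <- cov[1:5, ]
  covNew$site <- "siteX"
  expect_error(computeZscores(fit, rnorm(5), covNew), "siteX")
  expect_error(evaluateNormative(fit, rnorm(2), cov[1:2, ]), "3 test rows")
})

test_that("fitNormativeAll keeps splits disjoint, seeded, and applies QC", {
  sim <- simulateCovariateIDP(600, 3, noiseSD = 1, seed = 77)
  res <- fitNormativeAll(sim$values, sim$covariates, trainFraction = 0.5,
                         seed = 77)
  expect_length(intersect(res$trainIndex, res$testIndex), 0)
  expect_equal(sort(c(res$trainIndex, res$testIndex)), 1:600)
  expect_equal(nrow(res$z), length(res$testIndex))
  expect_true(all(res$metrics$qcPass))
  res2 <- fitNormativeAll(sim$values, sim$covariates, trainFraction = 0.5,
                          seed = 77)
  expect_identical(res$trainIndex, res2$trainIndex)
  expect_equal(res$z, res2$z)
})
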