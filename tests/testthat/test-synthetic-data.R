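test_that("covariate generation matches the configured population", {
  cov <- simulateCovariates(5000, seed = 1)
  expect_true(all(cov$age >= 40 & cov$age <= 80))
  expect_false(anyNA(cov))
  # female fraction within 3 binomial SEs of 0.53
  se <- sqrt(0.53 * 0.47 / 5000)
  expect_lt(abs(mean(cov$sex) - 0.53), 3 * se)
  expect_true(all(cov$site %in% paste0("site", 1:3)))
})

test_that("IDP responses are trend plus independent Gaussian noise", {
  # noiseless case: values equal the trend exactly
  sim0 <- simulateCovariateIDP(200, 3, noiseSD = 0, seed = 2)
  expect_identical(sim0$values, sim0$trueMean)
  # residual SD about the true trend recovers the configured noise
  sim1 <- simulateCovariateIDP(5000, 3, noiseSD = 1, seed = 3)
  resid <- sim1$values - sim1$trueMean
  for (j in 1:3) expect_lt(abs(sd(resid[, j]) - 1), 0.05)
  # non-finite trend parameters are rejected
  badSpec <- defaultTrendSpec(2, seed = 4)
  badSpec$coef[1, "age"] <- NaN
  expect_error(simulateCovariateIDP(100, 2, trendSpec = badSpec, seed = 4),
               "finite")
})

test_that("generators are reproducible under a fixed seed", {
  a <- simulateCovariateIDP(50, 2, seed = 10)
  b <- simulateCovariateIDP(50, 2, seed = 10)
  expect_identical(a, b)
  expect_identical(simulateTailZ(100, B_ORACLE, seed = 5),
                   simulateTailZ(100, B_ORACLE, seed = 5))
  expect_false(identical(simulateTailZ(100, B_ORACLE, seed = 5),
                         simulateTailZ(100, B_ORACLE, seed = 6)))
})

test_that("max-linear draws have the stated Frechet margins and geometry", {
  # identity B: unit Frechet(2) margin, P(X <= 1) = exp(-1)
  x <- simulateMaxLinear(20000, diag(2), seed = 6)
  p <- mean(x[, 1] <= 1)
  expect_lt(abs(p - exp(-1)), 3 * sqrt(exp(-1) * (1 - exp(-1)) / 20000))
  # single shared factor: complete dependence, all angles on the diagonal
  x2 <- simulateMaxLinear(500, rbind(1, 1), seed = 7)
  expect_equal(x2[, 1], x2[, 2], ignore_attr = TRUE)
  pol <- polarDecompose(x2)
  expect_equal(unname(angles(pol)[1, ]), rep(1 / sqrt(2), 2),
               tolerance = 1e-12)
  # parameter validation
  expect_error(simulateMaxLinear(10, diag(2), alpha = 0), "positive")
  expect_error(simulateMaxLinear(10, rbind(c(1, 0), c(0, 0))), "all-zero")
  expect_error(simulateMaxLinear(10, rbind(c(1, -1), c(0, 1))),
               "nonnegative")
})

test_that("tail z-scores preserve the copula and have normal margins", {
  n <- 20000
  x <- simulateMaxLinear(n, B_ORACLE, alpha = 2, seed = 8)
  z <- simulateTailZ(n, B_ORACLE, seed = 8)
  # strictly monotone marginal map: ranks are untouched
  for (j in 1:2)
    expect_identical(rank(z[, j]), rank(x[, j]))
  # margins exactly standard normal up to Monte-Carlo error
  se <- momentSE(n)
  for (j in 1:2) {
    expect_lt(abs(mean(z[, j])), 3 * se["mean"])
    expect_lt(abs(var(z[, j]) - 1), 3 * se["var"])
  }
})

test_that("TPDM estimation error shrinks as the sample grows", {
  oracle <- B_ORACLE %*% t(B_ORACLE)
  worse <- 0L
  for (s in 1:5) {
    errSmall <- max(abs(tpdmMatrix(tpdmFromZ(
      simulateMaxLinear(5000, B_ORACLE, seed = 100 + s))) - oracle))
    errLarge <- max(abs(tpdmMatrix(tpdmFromZ(
      simulateMaxLinear(80000, B_ORACLE, seed = 200 + s))) - oracle))
    if (errLarge >= errSmall) worse <- worse + 1L
  }
  expect_lte(worse, 1L)
})

test_that("phenotype planting produces the promised constructs", {
  set.seed(9)
  scores <- matrix(rnorm(4000), 2000, 2)
  phen <- simulatePhenotypes(
    scores, nNull = 3,
    planted = list(list(component = 1, effect = 1, binary = FALSE),
                   list(component = 2, effect = 1, binary = TRUE)),
    seed = 9)
  expect_named(phen, c("planted1", "planted2", paste0("null", 1:3)))
  expect_setequal(unique(phen$planted2), c(0L, 1L))
  # continuous planting correlates with its component, nulls do not
  expect_gt(cor(phen$planted1, scores[, 1], method = "spearman"), 0.5)
  expect_lt(abs(cor(phen$null1, scores[, 1], method = "spearman")), 0.1)
  # validation
  expect_error(simulatePhenotypes(matrix(nrow = 0, ncol = 0)), "non-empty")
  expect_error(simulatePhenotypes(
    scores, planted = list(list(component = 5, effect = 1))), "exceeds")
  expect_error(simulatePhenotypes(
    scores, planted = list(list(component = 1, effect = Inf))), "finite")
})

test_that("synthetic datasets round-trip through CSV with a sidecar", {
  dir <- withr::local_tempdir()
  sim <- simulateCovariateIDP(30, 2, seed = 11)
  paths <- writeSyntheticData(dir, covariates = sim$covariates,
                              values = sim$values,
                              spec = list(d = 2), seed = 11)
  expect_true(all(file.exists(paths)))
  back <- readSubjectMatrix(paths[["values"]])
  expect_equal(unname(back), unname(sim$values), tolerance = 1e-12)
  meta <- jsonlite::read_json(paths[["sidecar"]], simplifyVector = TRUE)
  expect_equal(meta$seed, 11)
})
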