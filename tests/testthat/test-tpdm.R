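test_that("the rank/Frechet transform has the stated closed forms", {
  # n = 3 sorted values: F-hat = 1/4, 2/4, 3/4
  x <- pseudoFrechetValues(
    suppressWarnings(toPseudoFrechet(cbind(v = c(5, 1, 3)))))
  expect_equal(unname(x[, 1]),
               (-log(c(3, 1, 2) / 4))^(-1 / 2), tolerance = 1e-14)
  # closed-form inverse of the Frechet(2) CDF: F = e^-1 -> x = 1,
  # F = e^(-1/4) -> x = 2
  expect_equal((-log(exp(-1)))^(-1 / 2), 1)
  expect_equal((-log(exp(-1 / 4)))^(-1 / 2), 2)
  # marginal law on a large normal column: P(X <= 1) ~ e^-1
  set.seed(51)
  xf <- pseudoFrechetValues(toPseudoFrechet(cbind(v = rnorm(50000))))
  expect_lt(abs(mean(xf <= 1) - exp(-1)),
            3 * sqrt(exp(-1) * (1 - exp(-1)) / 50000))
})

test_that("the transform validates its input", {
  expect_error(toPseudoFrechet(cbind(bad = rep(1, 30), ok = rnorm(30))),
               "bad")
  expect_warning(toPseudoFrechet(cbind(v = rep(1:5, 10))), "distinct")
  z <- cbind(a = rnorm(50), b = rnorm(50))
  z[3, 1] <- NA
  expect_message(out <- toPseudoFrechet(z), "1 rows")
  expect_equal(nrow(pseudoFrechetValues(out)), 49L)
})

test_that("polar decomposition is exact and counts exceedances correctly", {
  x <- rbind(c(3, 4), c(1, 1))
  pol <- suppressWarnings(polarDecompose(x, quantile = 0.5))
  expect_equal(radii(pol)[1], 5)
  expect_equal(unname(angles(pol)[1, ]), c(0.6, 0.8))
  # r * omega reconstructs x exactly
  expect_equal(angles(pol) * radii(pol), x, ignore_attr = TRUE)
  # counting above the empirical quantile
  set.seed(52)
  pol2 <- polarDecompose(matrix(rexp(2000), 1000, 2), quantile = 0.95)
  expect_equal(nExceedances(pol2), 50L)
  expect_equal(radialThreshold(pol2), unname(quantile(radii(pol2), 0.95)))
  expect_error(polarDecompose(x, quantile = 1.2), "quantile")
})

test_that("the TPDM estimator matches the printed formula exactly", {
  # a single exceedance with omega = (0.6, 0.8): printed mode gives
  # 2 * omega %*% t(omega)
  pol <- new("PolarDecomposition",
             radius = c(5, 1), angles = rbind(c(0.6, 0.8), c(1, 0)),
             radialThreshold = 2, quantile = 0.5,
             exceedanceMask = c(TRUE, FALSE), nExceedances = 1L)
  tp <- estimateTPDM(pol, mode = "printed")
  expect_equal(tpdmMatrix(tp),
               rbind(c(0.72, 0.96), c(0.96, 1.28)), tolerance = 1e-14)
  expect_equal(sum(diag(tpdmMatrix(tp))), 2, tolerance = 1e-14)
})

test_that("trace identities hold on arbitrary input", {
  set.seed(53)
  for (d in c(2, 5, 11)) {
    z <- matrix(rnorm(3000 * d), 3000, d)
    pol <- polarDecompose(toPseudoFrechet(z))
    expect_equal(sum(diag(tpdmMatrix(estimateTPDM(pol, "printed")))), 2,
                 tolerance = 1e-12)
    expect_equal(sum(diag(tpdmMatrix(estimateTPDM(pol, "unit")))), d,
                 tolerance = 1e-12)
  }
})

test_that("independence and complete-dependence limits are respected", {
  # Independent tail factors: off-diagonals vanish only in the receding-
  # threshold regime. At a fixed radial quantile the estimator has an O(1/r0)
  # positive bias under exact independence (the non-extreme coordinate still
  # contributes an angle of order 1/r0), so the limit is checked with a high
  # radial quantile where r0 ~ 100.
  zInd <- simulateMaxLinear(1e6, diag(2), seed = 54)
  expect_lt(abs(tpdmMatrix(tpdmFromZ(zInd, quantile = 0.9998))[1, 2]), 0.05)
  # one shared factor: identical columns, off-diagonal equals diagonal
  zDep <- simulateTailZ(5000, rbind(1, 1), seed = 55)
  m <- tpdmMatrix(tpdmFromZ(zDep))
  expect_equal(m[1, 2], m[1, 1], tolerance = 1e-12)
})

test_that("the TPDM is invariant to monotone marginal transforms", {
  z <- simulateTailZ(5000, B_ORACLE, seed = 56)
  zWarped <- cbind(exp(z[, 1]), z[, 2]^3)
  expect_equal(tpdmMatrix(tpdmFromZ(z)), tpdmMatrix(tpdmFromZ(zWarped)),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("extreme PCA has the documented eigenstructure conventions", {
  basis <- extremePCA(diag(c(2, 1, 1)))
  expect_equal(scaleProportions(basis), c(0.5, 0.25, 0.25))
  expect_error(extremePCA(matrix(c(1, 2, 0, 1), 2, 2)), "symmetric")
  # sign convention: largest-magnitude entry positive
  z <- simulateTailZ(5000, B_ORACLE, seed = 57)
  b <- extremePCA(tpdmFromZ(z))
  u <- eigenVectors(b)
  for (j in 1:2) expect_gt(u[which.max(abs(u[, j])), j], 0)
})

test_that("eigenstructure is identical across normalization modes", {
  z <- simulateTailZ(8000, B_ORACLE, seed = 58)
  pol <- polarDecompose(toPseudoFrechet(z))
  bUnit <- extremePCA(estimateTPDM(pol, "unit"))
  bPrinted <- extremePCA(estimateTPDM(pol, "printed"))
  expect_equal(eigenVectors(bUnit), eigenVectors(bPrinted),
               tolerance = 1e-10)
  expect_equal(scaleProportions(bUnit), scaleProportions(bPrinted),
               tolerance = 1e-10)
  # contribution rankings are also shared
  lcU <- loadingsContributions(bUnit, 2)
  lcP <- loadingsContributions(bPrinted, 2)
  expect_equal(order(lcU$contributions[, 1]), order(lcP$contributions[, 1]))
})

test_that("loadings and contributions follow both conventions", {
  basis <- new("ExtremeEigenBasis", values = c(2, 1),
               vectors = diag(2), proportions = c(2, 1) / 3)
  lcPrinted <- loadingsContributions(basis, 2, mode = "printed")
  expect_equal(lcPrinted$loadings[, 1], c(2, 0), ignore_attr = TRUE)
  expect_equal(lcPrinted$contributions[, 1], c(2, 0), ignore_attr = TRUE)
  lcConv <- loadingsContributions(basis, 2, mode = "conventional")
  expect_equal(lcConv$loadings[, 1], c(sqrt(2), 0), ignore_attr = TRUE)
  expect_equal(lcConv$contributions[, 1], c(1, 0), ignore_attr = TRUE)
  expect_equal(colSums(lcConv$contributions), c(EPC1 = 1, EPC2 = 1))
  expect_equal(lcConv$averageContribution, 0.5)
})

test_that("planted two-factor supports are recovered by contributions", {
  # unequal factor weights so the component order is identified
  B <- cbind(c(rep(0.9, 3), rep(0, 3)), c(rep(0, 3), rep(0.8, 3)),
             diag(sqrt(c(rep(1 - 0.81, 3), rep(1 - 0.64, 3))), 6))
  z <- simulateTailZ(20000, B, seed = 59)
  lc <- loadingsContributions(extremePCA(tpdmFromZ(z)), 2)
  top1 <- order(lc$contributions[, 1], decreasing = TRUE)[1:3]
  top2 <- order(lc$contributions[, 2], decreasing = TRUE)[1:3]
  expect_setequal(top1, 1:3)
  expect_setequal(top2, 4:6)
})

test_that("score projection is an orthonormal projection with a pre-map", {
  z <- simulateTailZ(3000, B_ORACLE, seed = 60)
  basis <- extremePCA(tpdmFromZ(z))
  u <- eigenVectors(basis)
  # a row equal to an eigenvector after the log pre-map loads only on it
  x1 <- new("PseudoFrechet", values = rbind(exp(u[, 1]), exp(u[, 2])),
            alpha = 2, sourceColumns = paste0("v", 1:2))
  s <- projectScores(x1, basis, nComponents = 2, map = "log")
  expect_equal(unname(s), rbind(c(1, 0), c(0, 1)), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_identical(attr(s, "map"), "log")
  # round-trip: U then U^T reconstructs the pre-mapped rows
  expect_equal(s %*% t(u), rbind(u[, 1], u[, 2]),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_error(projectScores(x1, basis, nComponents = 5), "exceeds")
})

test_that("single-factor scores separate extreme from central subjects", {
  w <- 0.95
  B <- cbind(rep(w, 3), diag(sqrt(1 - w^2), 3))
  z <- simulateTailZ(10000, B, seed = 61)
  xs <- toPseudoFrechet(z)
  pol <- polarDecompose(xs)
  basis <- extremePCA(estimateTPDM(pol))
  s <- projectScores(xs, basis, nComponents = 1)
  r <- radii(pol)
  top <- r >= quantile(r, 0.9)
  mid <- r >= quantile(r, 0.45) & r <= quantile(r, 0.55)
  w <- wilcox.test(abs(s[top, 1]), abs(s[mid, 1]), alternative = "greater")
  expect_lt(w$p.value, 1e-10)
})
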