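test_that("a median-split phenotype attains the theoretical point-biserial", {
  set.seed(81)
  n <- 5000
  scores <- cbind(EPC1 = rnorm(n), EPC2 = rnorm(n))
  phen <- data.frame(split = as.integer(scores[, 1] > median(scores[, 1])))
  tab <- associateComponents(scores, phen, nComponents = 2)
  r <- tab$correlation[tab$component == 1]
  # maximal point-biserial of a median-split normal: sqrt(2/pi) ~ 0.798
  expect_equal(r, sqrt(2 / pi), tolerance = 0.02)
  expect_identical(tab$testType[1], "point_biserial")
  expect_true(tab$bonferroniSignificant[tab$component == 1])
  expect_lt(tab$pValue[tab$component == 1], 1e-100)
})

test_that("the Bonferroni flag matches an independent recomputation", {
  set.seed(82)
  scores <- matrix(rnorm(600), 300, 2)
  phen <- as.data.frame(matrix(rnorm(300 * 20), 300))
  phen$effect <- scores[, 1] + rnorm(300, sd = 0.5)
  tab <- associateComponents(scores, phen, alpha = 0.05, nComponents = 2)
  m <- 21 * 2
  expect_equal(attr(tab, "m"), m)
  expect_equal(tab$bonferroniSignificant, tab$pValue <= 0.05 / m)
  expect_equal(tab$negLog10P, -log10(tab$pValue))
  expect_true(any(tab$bonferroniSignificant[tab$phenotype == "effect"]))
})

test_that("Spearman screening is invariant to monotone transforms", {
  set.seed(83)
  scores <- cbind(rnorm(200))
  phen <- data.frame(p = scores[, 1] + rnorm(200))
  phenWarped <- data.frame(p = exp(phen$p))
  scoresWarped <- cbind(scores[, 1]^3)
  t1 <- associateComponents(scores, phen, nComponents = 1)
  t2 <- associateComponents(scoresWarped, phenWarped, nComponents = 1)
  expect_equal(t1$correlation, t2$correlation, tolerance = 1e-12)
  expect_equal(t1$pValue, t2$pValue, tolerance = 1e-12)
})

test_that("a planted effect sized for correlation 0.3 is detected", {
  # population Spearman-scale effect 0.3 at n = 5000 has essentially
  # unit power at the Bonferroni threshold
  scores <- withr::with_seed(84, matrix(rnorm(10000), 5000, 2))
  effect <- 0.3145  # corr = e / sqrt(e^2 + 1) = 0.3
  phen <- simulatePhenotypes(
    scores, nNull = 100,
    planted = list(list(component = 1, effect = effect)), seed = 4184)
  tab <- associateComponents(scores, phen, nComponents = 2)
  hit <- tab[tab$phenotype == "planted1" & tab$component == 1, ]
  expect_true(hit$bonferroniSignificant)
  expect_equal(hit$correlation, 0.3, tolerance = 0.05)
})

test_that("unusable phenotypes are skipped with a record", {
  set.seed(85)
  scores <- cbind(rnorm(100))
  phen <- data.frame(ok = rnorm(100),
                     constant = rep(2, 100),
                     sparse = c(1.2, 0.8, rep(NA, 98)))
  tab <- associateComponents(scores, phen, nComponents = 1)
  expect_setequal(attr(tab, "skipped"), c("constant", "sparse"))
  expect_equal(attr(tab, "m"), 1L)
  # pairwise-complete n is recorded
  phen2 <- data.frame(p = c(rnorm(90), rep(NA, 10)))
  tab2 <- associateComponents(scores, phen2, nComponents = 1)
  expect_equal(tab2$nUsed, 90L)
})

test_that("category labels flow through and aggregation keeps the best", {
  set.seed(86)
  scores <- matrix(rnorm(400), 200, 2)
  phen <- data.frame(a = scores[, 1] + rnorm(200), b = rnorm(200))
  tab <- associateComponents(scores, phen, nComponents = 2,
                             categories = c(a = "cognition", b = "mental"))
  expect_setequal(unique(tab$category[tab$phenotype == "a"]), "cognition")
  agg <- aggregateAssociations(tab)
  expect_equal(nrow(agg), 2L)
  for (ph in c("a", "b"))
    expect_equal(agg$negLog10P[agg$phenotype == ph],
                 max(tab$negLog10P[tab$phenotype == ph]))
  mh <- manhattanTable(tab, 1)
  expect_equal(nrow(mh), 2L)
  expect_equal(unique(mh$thresholdLine), -log10(attr(tab, "bonferroniP")))
})

test_that("standard correlation PCA has the textbook structure", {
  set.seed(87)
  z <- matrix(rnorm(5000 * 4), 5000, 4)
  res <- standardPCA(z, nComponents = 2)
  expect_equal(sum(res$values), 4, tolerance = 1e-12)
  expect_equal(res$proportions, rep(0.25, 4), tolerance = 0.05)
  expect_equal(dim(res$scores), c(5000L, 2L))
  zBad <- cbind(z, fixed = rep(1, 5000))
  expect_error(standardPCA(zBad), "fixed")
})

test_that("deviation count scores count tail crossings", {
  z0 <- matrix(0, 10, 5)
  expect_equal(deviationCounts(z0)$nTotal, rep(0, 10))
  set.seed(88)
  d <- 50
  z <- matrix(rnorm(2000 * d), 2000, d)
  counts <- deviationCounts(z)  # default cutoff 1.96
  expected <- 2 * pnorm(-1.96) * d
  expect_equal(mean(counts$nTotal), expected, tolerance = 0.1)
  expect_equal(counts$nTotal, counts$nPositive + counts$nNegative)
  expect_error(deviationCounts(z, cutoff = -1), "positive")
})
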