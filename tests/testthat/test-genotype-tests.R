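test_that("a genotype block with no variation gives statistic 0 and df 0", {
  y <- rnorm(10)
  x <- matrix(1, 10, 1)
  r <- genotypeGroupTest(y, x, matrix(0L, 10, 3), glmFamily("gaussian"))
  expect_equal(statistic(r), 0, tolerance = 1e-10)
  expect_equal(pValue(r), 1)
  expect_identical(effectiveRank(r), 0L)
})

test_that("gaussian group LRT equals -N log(1 - R^2) from the OLS oracle", {
  y <- 1:8
  x <- matrix(1, 8, 1)
  g <- matrix(c(0, 0, 0, 0, 1, 1, 1, 1), ncol = 1)
  r <- genotypeGroupTest(y, x, g, glmFamily("gaussian"))
  rss0 <- sum((y - mean(y))^2)
  rss1 <- sum(stats::lm.fit(cbind(x, g), y)$residuals^2)
  R2 <- 1 - rss1 / rss0
  expect_equal(statistic(r), -8 * log(1 - R2), tolerance = 1e-10)
  expect_equal(testDf(r), 1)

  # F variant equals the textbook one-way F
  rF <- genotypeGroupTest(y, x, g, glmFamily("gaussian"), useF = TRUE)
  expect_equal(statistic(rF), ((rss0 - rss1) / 1) / (rss1 / 6),
               tolerance = 1e-10)
})

test_that("logistic group LRT matches the hand-computed grouped likelihood", {
  # one marker, no covariates beyond the intercept: saturated-by-genotype
  # fit has fitted probability = the group mean of y
  y <- c(0, 0, 1, 1, 0, 1, 1, 1)
  g <- matrix(c(0, 0, 0, 0, 1, 1, 2, 2), ncol = 1)
  r <- genotypeGroupTest(y, cbind(rep(1, 8)), g, glmFamily("logistic"))
  # oracle: explicit logistic log-likelihoods via glm on the dosage
  fit1 <- stats::glm(y ~ g, family = binomial())
  fit0 <- stats::glm(y ~ 1, family = binomial())
  expect_equal(statistic(r), fit0$deviance - fit1$deviance,
               tolerance = 1e-8)
})

test_that("group test is invariant to marker order", {
  set.seed(41)
  N <- 100
  calls <- cbind(rbinom(N, 2, 0.2), rbinom(N, 2, 0.4), rbinom(N, 2, 0.1))
  xc <- simulateCovariates(N)
  x <- cbind(1, xc)
  y <- simulatePhenotype(calls, xc, numeric(3), glmFamily("logistic"))
  r1 <- genotypeGroupTest(y, x, calls, glmFamily("logistic"))
  r2 <- genotypeGroupTest(y, x, calls[, c(3, 1, 2)], glmFamily("logistic"))
  expect_equal(statistic(r1), statistic(r2), tolerance = 1e-8)
})

test_that("burden test handles constant scores, single markers and weight
          rescaling", {
  x <- matrix(1, 2, 1)
  expect_warning(
    r <- burdenTest(c(0, 1), x, rbind(c(1L, 0L), c(0L, 1L)),
                    glmFamily("logistic")),
    "constant")
  expect_equal(pValue(r), 1)

  set.seed(43)
  N <- 120
  calls <- matrix(rbinom(N, 2, 0.3), ncol = 1)
  xc <- simulateCovariates(N)
  xm <- cbind(1, xc)
  y <- simulatePhenotype(calls, xc, 0.3, glmFamily("poisson"))
  b <- burdenTest(y, xm, calls, glmFamily("poisson"))
  g <- genotypeGroupTest(y, xm, calls, glmFamily("poisson"))
  expect_equal(statistic(b), statistic(g), tolerance = 1e-10)

  calls3 <- cbind(rbinom(N, 2, 0.05), rbinom(N, 2, 0.03),
                  rbinom(N, 2, 0.08))
  y3 <- simulatePhenotype(calls3, xc, numeric(3), glmFamily("logistic"))
  b1 <- burdenTest(y3, xm, calls3, glmFamily("logistic"),
                   weights = c(1, 2, 3))
  b2 <- burdenTest(y3, xm, calls3, glmFamily("logistic"),
                   weights = c(10, 20, 30))
  expect_equal(statistic(b1), statistic(b2), tolerance = 1e-10)
})

test_that("deep-sequencing burden pipeline matches the collapse test on
          degenerate posteriors", {
  set.seed(47)
  N <- 300; dg <- 6
  maf <- runif(dg, 0.02, 0.05)
  G <- sapply(maf, function(f) rbinom(N, 2, f))
  xc <- simulateCovariates(N)
  x <- cbind(1, xc)
  y <- simulatePhenotype(G, xc, numeric(dg), glmFamily("logistic"),
                         includeEtaNoise = TRUE)
  reads <- simulateReads(G, depth = 100)
  gl <- siteLikelihood(reads$nRef, reads$nAlt)
  calls <- callGenotypes(gl, afTwoStep(gl))
  expect_gt(mean(calls == G), 0.999)
  vc <- vcTest(y, x, posteriorMoments(gl, maf), glmFamily("logistic"))
  bd <- burdenTest(y, x, calls, glmFamily("logistic"))
  # LRT and score statistics agree asymptotically; both are 1-df tests of
  # the same collapsed effect
  expect_equal(statistic(vc), statistic(bd), tolerance = 0.05)
})
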