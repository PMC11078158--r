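# Small fixed instances for the score-test machinery.
makeInstance <- function(familyName, N = 6, dg = 2, seed = 3) {
  set.seed(seed)
  x <- cbind(1, rbinom(N, 1, 0.5), rnorm(N))
  y <- switch(familyName,
              gaussian = rnorm(N, drop(x %*% c(0.2, 0.5, -0.3))),
              logistic = rbinom(N, 1, plogis(drop(x %*% c(0, 0.5, -0.5)))),
              poisson = rpois(N, exp(drop(x %*% c(0.2, 0.5, -0.3)))))
  gl <- randomGL(N, dg, seed = seed + 100)
  f <- seq(0.15, 0.4, length.out = dg)
  list(y = y, x = x, gl = gl, f = f,
       post = posteriorMoments(gl, f), family = glmFamily(familyName))
}

test_that("beta score vanishes when posterior dosages are constant", {
  post <- new("SitePosterior", eg = matrix(0.8, 2, 3),
              eggDiag = matrix(1.0, 2, 3))
  nf <- fitNull(c(0, 1), matrix(1, 2, 1), glmFamily("logistic"))
  s <- scoreAtNull(c(0, 1), matrix(1, 2, 1), post, nf)
  expect_equal(s$sBeta, rep(0, 3), tolerance = 1e-12)
  expect_lt(s$alphaPhiScoreMax, 1e-8)
})

test_that("with known genotypes the score equals the classical GLM score", {
  set.seed(8)
  N <- 40
  x <- cbind(1, rnorm(N))
  G <- cbind(rbinom(N, 2, 0.3), rbinom(N, 2, 0.45))
  y <- rnorm(N, drop(x %*% c(1, 0.5)))
  fam <- glmFamily("gaussian")
  nf <- fitNull(y, x, fam)
  s <- scoreAtNull(y, x, degeneratePosterior(G), nf)
  expect_equal(s$sBeta,
               drop(crossprod(G, y - nf@mu)) / nullDispersion(nf),
               tolerance = 1e-10)
})

test_that("score and observed information match numerical differentiation
          of the latent-genotype log-likelihood", {
  skip_if_not_installed("pracma")
  for (familyName in c("gaussian", "logistic", "poisson")) {
    inst <- makeInstance(familyName)
    # N = 6 logistic fits can pin fitted probabilities; the diagnostic
    # warning is expected on this tiny oracle instance
    nf <- suppressWarnings(fitNull(inst$y, inst$x, inst$family))
    ll <- bruteForceLogLik(inst$y, inst$x, inst$gl@l0, inst$gl@l1,
                           inst$gl@l2, inst$f, familyName)
    theta <- c(nullCoef(nf), 0, 0,
               if (familyName == "gaussian") nullDispersion(nf))
    sc <- pracma::grad(ll, theta)
    H <- pracma::hessian(ll, theta)
    s <- scoreAtNull(inst$y, inst$x, inst$post, nf)
    expect_equal(s$sBeta, sc[4:5], tolerance = 1e-6, ignore_attr = TRUE)
    expect_lt(max(abs(sc[-(4:5)])), 1e-4)   # alpha/phi score ~ 0 at the MLE
    oi <- observedInformationAtNull(inst$y, inst$x, inst$post, nf)
    expect_equal(oi, -H, tolerance = 1e-4, ignore_attr = TRUE)
  }
})

test_that("the alpha-phi information block is exactly zero at the null fit", {
  inst <- makeInstance("gaussian", N = 25)
  nf <- fitNull(inst$y, inst$x, inst$family)
  oi <- observedInformationAtNull(inst$y, inst$x, inst$post, nf)
  p <- ncol(inst$x); dg <- 2
  expect_identical(oi[seq_len(p), p + dg + 1L], rep(0, p))
})

test_that("constant posteriors give a zero statistic through the
          rank-deficient path", {
  post <- new("SitePosterior", eg = matrix(0.8, 2, 3),
              eggDiag = matrix(0.64, 2, 3))
  expect_warning(
    r <- jsTest(c(0, 1), matrix(1, 2, 1), post, glmFamily("logistic")),
    "monomorphic")
  expect_equal(statistic(r), 0)
  expect_equal(pValue(r), 1)
  expect_identical(effectiveRank(r), 0L)
})

test_that("at depth 100 the JS test reduces to the classical group score
          test on true genotypes", {
  set.seed(23)
  N <- 400; dg <- 4
  maf <- c(0.15, 0.3, 0.42, 0.2)
  G <- sapply(maf, function(f) rbinom(N, 2, f))
  xc <- simulateCovariates(N)
  x <- cbind(1, xc)
  reads <- simulateReads(G, depth = 100)
  gl <- siteLikelihood(reads$nRef, reads$nAlt)
  for (familyName in c("logistic", "poisson")) {
    fam <- glmFamily(familyName)
    y <- simulatePhenotype(G, xc, numeric(dg), fam)
    r <- jsTest(y, x, posteriorMoments(gl, maf), fam)
    oracle <- classicalScoreStat(y, x, G, familyName)
    expect_equal(statistic(r), oracle, tolerance = 1e-3)
    expect_equal(testDf(r), dg)
  }
})

test_that("gaussian JS on known genotypes matches the classical score
          statistic asymptotically", {
  set.seed(29)
  N <- 1000; dg <- 3
  G <- cbind(rbinom(N, 2, 0.2), rbinom(N, 2, 0.35), rbinom(N, 2, 0.45))
  xc <- simulateCovariates(N)
  x <- cbind(1, xc)
  y <- simulatePhenotype(G, xc, numeric(dg), glmFamily("gaussian"))
  r <- jsTest(y, x, degeneratePosterior(G), glmFamily("gaussian"))
  oracle <- classicalScoreStat(y, x, G, "gaussian")
  expect_equal(statistic(r), oracle, tolerance = 0.02)
})

test_that("the collapse test with one site reproduces the joint test and is
          weight-scale invariant", {
  inst <- makeInstance("logistic", N = 60, dg = 1, seed = 13)
  js <- jsTest(inst$y, inst$x, inst$post, inst$family)
  vc <- vcTest(inst$y, inst$x, inst$post, inst$family, weights = 1)
  expect_equal(statistic(vc), statistic(js), tolerance = 1e-12)

  inst3 <- makeInstance("poisson", N = 60, dg = 3, seed = 14)
  v1 <- vcTest(inst3$y, inst3$x, inst3$post, inst3$family,
               weights = c(1, 1, 1))
  v2 <- vcTest(inst3$y, inst3$x, inst3$post, inst3$family,
               weights = c(2, 2, 2))
  expect_equal(statistic(v1), statistic(v2), tolerance = 1e-12)
  expect_equal(testDf(v1), 1)
})

test_that("with known genotypes the equal-weight collapse test equals the
          burden score test on the allele sum", {
  set.seed(37)
  N <- 300; dg <- 5
  G <- sapply(rep(0.03, dg), function(f) rbinom(N, 2, f))
  xc <- simulateCovariates(N)
  x <- cbind(1, xc)
  y <- simulatePhenotype(G, xc, numeric(dg), glmFamily("logistic"),
                         includeEtaNoise = TRUE)
  vc <- vcTest(y, x, degeneratePosterior(G), glmFamily("logistic"))
  oracle <- classicalScoreStat(y, x, rowSums(G), "logistic")
  expect_equal(statistic(vc), oracle, tolerance = 1e-8)
})

test_that("statistics are invariant to per-individual rescaling of the
          genotype likelihoods", {
  inst <- makeInstance("logistic", N = 80, dg = 3, seed = 19)
  scale <- rexp(80) + 0.1
  gl2 <- genotypeLikelihoods(inst$gl@l0 * scale, inst$gl@l1 * scale,
                             inst$gl@l2 * scale)
  f <- seq(0.15, 0.4, length.out = 3)
  r1 <- jsTest(inst$y, inst$x, posteriorMoments(inst$gl, f), inst$family)
  r2 <- jsTest(inst$y, inst$x, posteriorMoments(gl2, f), inst$family)
  expect_equal(statistic(r1), statistic(r2), tolerance = 1e-10)
})

test_that("stale null fits and bad weights are rejected", {
  inst <- makeInstance("logistic", N = 30, dg = 2, seed = 31)
  nfWrong <- fitNull(rbinom(30, 1, 0.5), inst$x, inst$family)
  expect_error(jsTest(inst$y, inst$x, inst$post, inst$family,
                      nullFit = nfWrong), "stale")
  expect_error(vcTest(inst$y, inst$x, inst$post, inst$family,
                      weights = c(1, -1)), "positive")
  expect_error(vcTest(inst$y, inst$x, inst$post, inst$family,
                      weights = 1), "length")
})

test_that("Beta(1,25) weights follow the closed-form density and the
          sum-to-dg constraint", {
  expect_equal(betaWeights(c(0.2, 0.2, 0.2)), rep(1, 3))
  expect_equal(betaWeights(0.37), 1)       # dg = 1: normalization forces 1
  w <- betaWeights(c(0.01, 0.04))
  expect_equal(sum(w), 2)
  expect_equal(w[1] / w[2], (0.99 / 0.96)^24)  # 25(1-x)^24 density ratio
  expect_error(betaWeights(c(0, 0.01)), "MAF")
})
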