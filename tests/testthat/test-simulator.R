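test_that("genotype simulation follows the MAF spectrum", {
  cfgFixed <- simulationConfig(10000, "common", mafRange = c(0.5, 0.5),
                               nMarkers = 2L)
  g <- simulateGenotypes(cfgFixed, seed = 1)
  expect_equal(g$maf, c(0.5, 0.5))
  expect_lt(max(abs(colMeans(g$genotypes) / 2 - 0.5)), 0.02)

  cfgZero <- simulationConfig(50, "common", mafRange = c(0, 0),
                              nMarkers = 3L)
  g0 <- simulateGenotypes(cfgZero, seed = 2)
  expect_true(all(g0$genotypes == 0L))

  cfg <- simulationConfig(300, "rare")
  expect_identical(simulateGenotypes(cfg, seed = 9),
                   simulateGenotypes(cfg, seed = 9))
})

test_that("empirical MAFs track the drawn frequencies at large N", {
  cfg <- simulationConfig(5000, "common", nMarkers = 20L)
  g <- simulateGenotypes(cfg, seed = 4)
  expect_lt(max(abs(colMeans(g$genotypes) / 2 - g$maf)), 0.025)
})

test_that("the optional LD mode preserves marginal frequencies and couples
          neighbours", {
  cfg <- simulationConfig(4000, "common", mafRange = c(0.3, 0.3),
                          nMarkers = 6L)
  g <- simulateGenotypes(cfg, seed = 6, ld = 0.9)
  expect_lt(max(abs(colMeans(g$genotypes) / 2 - 0.3)), 0.03)
  cors <- diag(cor(g$genotypes[, -6])[, -1])
  expect_gt(min(cors), 0.5)  # strong copying induces adjacent correlation
})

test_that("read simulation has the right depth and error profile", {
  set.seed(10)
  G <- matrix(0L, 500, 200)
  r <- simulateReads(G, depth = 4, errorRate = 0.005)
  tot <- r$nRef + r$nAlt
  expect_lt(abs(mean(tot) - 4), 0.05)
  expect_lt(abs(sum(r$nAlt) / sum(tot) - 0.005), 0.002)

  G1 <- matrix(1L, 500, 200)
  r1 <- simulateReads(G1, depth = 4, errorRate = 0.05)
  expect_lt(abs(sum(r1$nAlt) / sum(r1$nRef + r1$nAlt) - 0.5), 0.005)
})

test_that("phenotype generation matches the generative GLMs", {
  G <- matrix(0L, 10000, 2)
  xc <- matrix(0, 10000, 2)
  yB <- simulatePhenotype(G, xc, c(0, 0), "logistic",
                          includeEtaNoise = FALSE, betaCov = c(0, 0),
                          seed = 11)
  expect_lt(abs(mean(yB) - 0.5), 3 * sqrt(0.25 / 10000) + 0.005)
  yP <- simulatePhenotype(G, xc, c(0, 0), "poisson", betaCov = c(0, 0),
                          seed = 12)
  expect_lt(abs(mean(yP) - 1), 3 * sqrt(1 / 10000) + 0.005)
  expect_identical(yP, simulatePhenotype(G, xc, c(0, 0), "poisson",
                                         betaCov = c(0, 0), seed = 12))
  expect_error(simulatePhenotype(matrix(2L, 5, 1), matrix(0, 5, 2), 20,
                                 "poisson"), "overflow")
})

test_that("causal architectures split the total effect over the drawn
          causal set", {
  cfg0 <- simulationConfig(300, "common", totalEffect = 0)
  expect_equal(drawCausalArchitecture(cfg0, seed = 1)$effects, numeric(5))

  cfg <- simulationConfig(300, "common", totalEffect = 1)  # magnitude 5
  for (seed in 1:10) {
    a <- drawCausalArchitecture(cfg, seed = seed)
    nc <- length(a$causalIndex)
    expect_true(nc >= 2 && nc <= 5)
    expect_equal(sum(a$effects), 1, tolerance = 1e-12)
    expect_equal(unique(a$effects[a$causalIndex]), 1 / nc)
  }
  expect_identical(drawCausalArchitecture(cfg, seed = 3),
                   drawCausalArchitecture(cfg, seed = 3))

  cfgR <- simulationConfig(300, "rare", totalEffect = 0.6,
                           direction = "mixed")
  signs <- drawCausalArchitecture(cfgR, seed = 8)
  expect_true(all(abs(signs$effects[signs$causalIndex]) ==
                    0.6 / length(signs$causalIndex)))
})

test_that("the end-to-end pipeline is seed-deterministic and calls are
          concordant at depth 10", {
  cfg <- simulationConfig(500, "common", depth = 10)
  d1 <- simulateDataset(cfg, seed = 15)
  d2 <- simulateDataset(cfg, seed = 15)
  expect_identical(trueGenotypes(d1), trueGenotypes(d2))
  expect_identical(phenotype(d1), phenotype(d2))
  expect_identical(readCounts(d1), readCounts(d2))

  gl <- siteLikelihood(readCounts(d1)$nRef, readCounts(d1)$nAlt)
  calls <- callGenotypes(gl, afTwoStep(gl))
  # at mean depth 10 the residual miscall mass sits in heterozygotes whose
  # Binomial(n, 1/2) read split happens to look homozygous (~1-2% of cells
  # for a uniform common-MAF spectrum)
  expect_gt(mean(calls == trueGenotypes(d1)), 0.98)
})
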