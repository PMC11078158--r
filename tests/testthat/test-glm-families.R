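test_that("family terms match their closed forms at reference points", {
  lt <- familyTerms(glmFamily("logistic"), eta = 0)
  expect_equal(lt$b, log(2))
  expect_equal(lt$b1, 0.5)
  expect_equal(lt$b2, 0.25)

  pt <- familyTerms(glmFamily("poisson"), eta = 0)
  expect_equal(unlist(pt[c("b", "b1", "b2")]), c(b = 1, b1 = 1, b2 = 1))

  gt <- familyTerms(glmFamily("gaussian"), eta = 2, y = 0, phi = 1)
  expect_equal(gt$b, 2)          # eta^2 / 2
  expect_equal(gt$a, 1)
  expect_equal(gt$a1, 1)
  expect_equal(gt$a2, 0)

  # d/dphi of c(y, phi) = -y^2/(2 phi) - log(2 pi phi)/2 at y = 3, phi = 2
  g2 <- familyTerms(glmFamily("gaussian"), eta = 0, y = 3, phi = 2)
  expect_equal(g2$dc_dphi, 9 / 8 - 1 / 4)
  # confirm both phi-derivatives by central finite differences
  cfun <- function(phi) -9 / (2 * phi) - log(2 * pi * phi) / 2
  h <- 1e-5
  expect_equal(g2$dc_dphi, (cfun(2 + h) - cfun(2 - h)) / (2 * h),
               tolerance = 1e-8)
  expect_equal(g2$d2c_dphi2,
               (cfun(2 + h) - 2 * cfun(2) + cfun(2 - h)) / h^2,
               tolerance = 1e-4)   # second central difference at h = 1e-5
})

test_that("b' and b'' agree with finite differences over a wide eta grid", {
  h <- 1e-5
  for (fam in c("gaussian", "logistic", "poisson")) {
    f <- glmFamily(fam)
    phi <- if (fam == "gaussian") 1.7 else NULL
    eta <- seq(-10, 10, by = 0.5)
    tm <- familyTerms(f, eta, y = 0, phi = phi)
    bp <- familyTerms(f, eta + h, y = 0, phi = phi)$b
    bm <- familyTerms(f, eta - h, y = 0, phi = phi)$b
    expect_equal(tm$b1, (bp - bm) / (2 * h),
                 tolerance = 1e-6, ignore_attr = TRUE)
    b1p <- familyTerms(f, eta + h, y = 0, phi = phi)$b1
    b1m <- familyTerms(f, eta - h, y = 0, phi = phi)$b1
    expect_equal(tm$b2, (b1p - b1m) / (2 * h),
                 tolerance = 1e-6, ignore_attr = TRUE)
    expect_true(all(tm$b2 >= 0))   # convexity of b
  }
})

test_that("stable log1p form of the logistic b() holds at extreme eta", {
  tm <- familyTerms(glmFamily("logistic"), eta = c(-800, 800))
  expect_equal(tm$b, c(0, 800))
  expect_false(any(!is.finite(unlist(tm))))
})

test_that("family construction and dispersion rules are enforced", {
  expect_error(glmFamily("negbin"))
  expect_error(familyTerms(glmFamily("gaussian"), 0, 0), "phi")
  expect_error(familyTerms(glmFamily("gaussian"), 0, 0, phi = -1), "positive")
  expect_error(familyTerms(glmFamily("logistic"), 0, phi = 1),
               "dispersion-free")
  expect_false(glmFamily("poisson")@hasDispersion)
  expect_true(glmFamily("gaussian")@hasDispersion)
})

test_that("null fits reproduce closed-form intercept-only MLEs", {
  g <- fitNull(c(1, 2, 3), matrix(1, 3, 1), glmFamily("gaussian"))
  expect_equal(nullCoef(g), 2)
  expect_equal(nullDispersion(g), 2 / 3)   # divide by N, not N - p

  l <- fitNull(c(0, 0, 1, 1), matrix(1, 4, 1), glmFamily("logistic"))
  expect_equal(nullCoef(l), 0, tolerance = 1e-9)

  p <- fitNull(c(1, 2, 3, 4), matrix(1, 4, 1), glmFamily("poisson"))
  expect_equal(nullCoef(p), log(2.5), tolerance = 1e-9)
})

test_that("gaussian null fit equals the least-squares solution exactly", {
  set.seed(11)
  N <- 50
  x <- cbind(1, rbinom(N, 1, 0.5), rnorm(N))
  y <- rnorm(N, drop(x %*% c(0.5, 1, -0.3)))
  f <- fitNull(y, x, glmFamily("gaussian"))
  beta <- drop(solve(crossprod(x), crossprod(x, y)))
  expect_equal(nullCoef(f), beta, tolerance = 1e-10)
  expect_equal(nullDispersion(f),
               sum((y - drop(x %*% beta))^2) / N, tolerance = 1e-10)
})

test_that("null fit satisfies the score condition and ignores column order", {
  set.seed(12)
  N <- 120
  x <- cbind(1, rbinom(N, 1, 0.5), rnorm(N))
  for (fam in c("logistic", "poisson")) {
    f <- glmFamily(fam)
    y <- if (fam == "logistic") rbinom(N, 1, plogis(x[, 2] - x[, 3])) else
      rpois(N, exp(0.2 + 0.4 * x[, 2]))
    nf <- fitNull(y, x, f)
    tm <- familyTerms(f, nf@eta)
    expect_lt(max(abs(drop(crossprod(x, y - tm$b1)))), 1e-8)
    nf2 <- fitNull(y, x[, c(3, 1, 2)], f)
    expect_equal(nf2@mu, nf@mu, tolerance = 1e-8)
  }
})

test_that("degenerate designs are rejected", {
  x <- cbind(1, c(1, 2, 3, 4), c(2, 4, 6, 8))  # collinear
  expect_error(fitNull(rnorm(4), x, glmFamily("gaussian")), "rank")
  expect_error(fitNull(c(0, 1, 2), matrix(1, 3, 1), glmFamily("logistic")),
               "0/1")
  expect_error(fitNull(c(0.5, 1), matrix(1, 2, 1), glmFamily("poisson")))
})
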