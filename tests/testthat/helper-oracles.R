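# Independent oracles used across tests. These re-derive quantities by brute
# force (explicit enumeration over the genotype space, numerical
# differentiation, textbook closed forms) and never call the code paths they
# check.

# Posterior moments for ONE individual by explicit enumeration of all 3^dg
# genotype vectors with h(g, D) = prod_j L_j(g_j) * HWEprior_j(g_j).
bruteForceMoments <- function(l0, l1, l2, f) {
  dg <- length(f)
  gSpace <- as.matrix(expand.grid(rep(list(0:2), dg)))
  pri <- cbind((1 - f)^2, 2 * f * (1 - f), f^2)
  h <- apply(gSpace, 1L, function(g) {
    prod(vapply(seq_len(dg), function(j) {
      c(l0[j], l1[j], l2[j])[g[j] + 1L] * pri[j, g[j] + 1L]
    }, numeric(1)))
  })
  h <- h / sum(h)
  list(eg = colSums(gSpace * h), egg = t(gSpace) %*% (gSpace * h))
}

# Latent-genotype log-likelihood of one dataset as an explicit sum over
# {0,1,2}^dg, as a function of theta = (alpha, beta[, phi]). Used with
# numerical differentiation as the score/information oracle.
bruteForceLogLik <- function(y, x, l0, l1, l2, f, familyName) {
  N <- length(y); dg <- length(f)
  gSpace <- as.matrix(expand.grid(rep(list(0:2), dg)))
  pri <- cbind((1 - f)^2, 2 * f * (1 - f), f^2)
  hMat <- sapply(seq_len(nrow(gSpace)), function(k) {
    g <- gSpace[k, ]
    apply(vapply(seq_len(dg), function(j) {
      c1 <- cbind(l0[, j], l1[, j], l2[, j])[, g[j] + 1L]
      c1 * pri[j, g[j] + 1L]
    }, numeric(N)), 1L, prod)
  })                                      # N x 3^dg
  p <- ncol(x)
  function(theta) {
    alpha <- theta[seq_len(p)]
    beta <- theta[p + seq_len(dg)]
    phi <- if (familyName == "gaussian") theta[p + dg + 1L] else NULL
    tot <- 0
    for (i in seq_len(N)) {
      eta <- drop(x[i, ] %*% alpha) + drop(gSpace %*% beta)
      fy <- switch(familyName,
                   gaussian = stats::dnorm(y[i], eta, sqrt(phi)),
                   logistic = stats::dbinom(y[i], 1, stats::plogis(eta)),
                   poisson = stats::dpois(y[i], exp(eta)))
      tot <- tot + log(sum(fy * hMat[i, ]))
    }
    tot
  }
}

# Classical GLM group score test on a FIXED genotype design: textbook score
# statistic s^T V^{-1} s with s = Z^T (y - mu) / a and V the Schur complement
# of the genotype block of the Fisher information on [x | Z].
classicalScoreStat <- function(y, x, Z, familyName) {
  x <- as.matrix(x); Z <- as.matrix(Z)
  if (familyName == "gaussian") {
    cf <- stats::lm.fit(x, y)$coefficients
    eta <- drop(x %*% cf)
    a <- sum((y - eta)^2) / length(y)
    w <- rep(1, length(y))
    mu <- eta
  } else {
    fam <- if (familyName == "logistic") stats::binomial() else
      stats::poisson()
    ft <- stats::glm.fit(x, y, family = fam,
                         control = stats::glm.control(epsilon = 1e-13))
    mu <- ft$fitted.values
    w <- if (familyName == "logistic") mu * (1 - mu) else mu
    a <- 1
  }
  s <- drop(crossprod(Z, y - mu)) / a
  iZZ <- crossprod(Z * w, Z) / a
  iXZ <- crossprod(x * w, Z) / a
  iXX <- crossprod(x * w, x) / a
  V <- iZZ - crossprod(iXZ, solve(iXX, iXZ))
  drop(t(s) %*% solve(V, s))
}

# Tiny deterministic GL fixture: N individuals x dg sites of random positive
# likelihood triples under a fixed seed.
randomGL <- function(N, dg, seed) {
  set.seed(seed)
  genotypeLikelihoods(matrix(runif(N * dg), N),
                      matrix(runif(N * dg), N),
                      matrix(runif(N * dg), N))
}
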