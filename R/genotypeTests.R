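# Genotype-based comparators: the classical tests run on hard genotype
# calls, against which the sequencing-data tests are benchmarked.

.glmLogLik <- function(y, X, family) {
  if (family@name == "gaussian") {
    fit <- stats::lm.fit(X, y)
    rss <- sum(fit$residuals^2)
    n <- length(y)
    list(ll = -n / 2 * (log(2 * pi * rss / n) + 1), rank = fit$rank,
         rss = rss)
  } else {
    glmfam <- if (family@name == "logistic") stats::binomial() else
      stats::poisson()
    fit <- suppressWarnings(
      stats::glm.fit(X, y, family = glmfam,
                     control = stats::glm.control(epsilon = 1e-12,
                                                  maxit = 200)))
    if (!fit$converged)
      stop("comparator GLM did not converge (possible separation)")
    mu <- fit$fitted.values
    ll <- if (family@name == "logistic")
      sum(stats::dbinom(y, 1, mu, log = TRUE)) else
        sum(stats::dpois(y, mu, log = TRUE))
    list(ll = ll, rank = fit$rank)
  }
}

#' Genotype-based group test (chi-square / F) on called genotypes
#'
#' The classical comparator: fit the GLM of y on [x | calls] and on x alone,
#' and test the joint significance of the genotype block by the likelihood
#' ratio, with degrees of freedom equal to the rank the calls add beyond the
#' covariates (aliased or constant columns reduce it). For the gaussian
#' family the exact F statistic is available via \code{useF = TRUE}; the
#' default chi-square form is \eqn{N \log(RSS_0 / RSS_1)}.
#'
#' @param y,x response and covariate matrix (with intercept).
#' @param calls integer matrix N x dg of genotype calls in \{0, 1, 2\},
#'   e.g. from [callGenotypes()] with two-step frequencies.
#' @param family a [GLMFamily-class].
#' @param useF gaussian only: report the F statistic and F-tail p-value
#'   instead of the likelihood-ratio chi-square.
#' @return a [ScoreTestResult-class] with \code{method = "genotype_chisq"}.
#' @export
genotypeGroupTest <- function(y, x, calls, family, useF = FALSE) {
  x <- as.matrix(x); calls <- as.matrix(calls)
  y <- as.numeric(y)
  stopifnot(all(calls %in% 0:2))
  if (nrow(calls) != length(y) || nrow(x) != length(y))
    stop("dimension mismatch between y, x and calls")
  if (useF && family@name != "gaussian")
    stop("the F variant is defined for the gaussian family only")
  full <- .glmLogLik(y, cbind(x, calls), family)
  nullF <- .glmLogLik(y, x, family)
  q <- full$rank - nullF$rank
  n <- length(y)
  notes <- character(0)
  if (q == 0L) {
    return(new("ScoreTestResult", statistic = 0, df = 0, p.value = 1,
               score = numeric(0), info = matrix(0, 0, 0),
               method = "genotype_chisq", rank = 0L,
               nSites = ncol(calls),
               notes = "no genotype variation beyond covariates"))
  }
  if (useF) {
    stat <- ((nullF$rss - full$rss) / q) / (full$rss / (n - full$rank))
    p <- stats::pf(stat, q, n - full$rank, lower.tail = FALSE)
    notes <- sprintf("F on %d and %d df", q, n - full$rank)
  } else {
    stat <- max(2 * (full$ll - nullF$ll), 0)
    p <- stats::pchisq(stat, df = q, lower.tail = FALSE)
  }
  new("ScoreTestResult", statistic = stat, df = as.numeric(q), p.value = p,
      score = numeric(0), info = matrix(0, 0, 0),
      method = "genotype_chisq", rank = as.integer(q),
      nSites = ncol(calls), notes = notes)
}

#' Genotype-based weighted burden test
#'
#' Collapses the called genotypes into the weighted rare-allele sum
#' AG_i = sum_j w_j g_ij (weights normalized to sum to dg), fits the GLM of
#' y on [x | AG], and reports the 1-df likelihood-ratio chi-square.
#'
#' @inheritParams genotypeGroupTest
#' @param weights positive weights of length dg; defaults to equal weights.
#' @return a [ScoreTestResult-class] with \code{method = "burden"}.
#' @export
burdenTest <- function(y, x, calls, family, weights = NULL) {
  x <- as.matrix(x); calls <- as.matrix(calls)
  y <- as.numeric(y)
  stopifnot(all(calls %in% 0:2))
  dg <- ncol(calls)
  if (is.null(weights)) weights <- rep(1, dg)
  if (length(weights) != dg || any(weights <= 0))
    stop("weights must be positive and of length dg")
  w <- weights * dg / sum(weights)
  ag <- drop(calls %*% w)
  if (max(ag) - min(ag) < 1e-12) {
    warning("burden score is constant across individuals")
    return(new("ScoreTestResult", statistic = 0, df = 1, p.value = 1,
               score = numeric(0), info = matrix(0, 0, 0),
               method = "burden", rank = 0L, nSites = ncol(calls),
               notes = "constant burden score"))
  }
  full <- .glmLogLik(y, cbind(x, ag), family)
  nullF <- .glmLogLik(y, x, family)
  stat <- max(2 * (full$ll - nullF$ll), 0)
  new("ScoreTestResult", statistic = stat, df = 1,
      p.value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
      score = numeric(0), info = matrix(0, 0, 0), method = "burden",
      rank = 1L, nSites = ncol(calls), notes = character(0))
}
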