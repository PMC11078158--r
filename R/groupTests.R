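# Core of the package: score tests of H0: beta = 0 in the latent-genotype
# GLM, evaluated at the constrained null MLE. All formulas are the
# closed-form evaluations at theta-tilde; the alpha (and phi) components of
# the score vanish there by the first-order condition, so only the beta
# block of the score survives while the full observed information is kept.

# Shared block computations. Returns the beta score and all observed
# information blocks at the null fit, ordered (alpha, beta[, phi]).
.nullBlocks <- function(y, x, post, nf) {
  fam <- nf@family
  eta <- nf@eta
  phi <- if (fam@hasDispersion) nf@phi else NULL
  tm <- familyTerms(fam, eta, y = y, phi = phi)
  a <- if (fam@hasDispersion) phi else 1
  r <- y - tm$b1
  w <- tm$b2
  eg <- post@eg
  v <- pmax(post@eggDiag - eg^2, 0)         # per-individual posterior variance

  sBeta <- drop(crossprod(eg, r)) / a
  oAA <- crossprod(x, x * w) / a
  oAB <- crossprod(x, eg * w) / a
  # info_bb = sum_i (w_i/a)(eg eg^T + diag v) - (r_i^2/a^2) diag v
  oBB <- crossprod(eg * w, eg) / a
  diag(oBB) <- diag(oBB) + colSums(v * w) / a - colSums(v * r^2) / a^2
  out <- list(sBeta = sBeta, oAA = oAA, oAB = oAB, oBB = oBB)
  if (fam@hasDispersion) {
    # beta-phi block: -Hess = (a'/a^2) sum_i r_i eg_i; alpha-phi block is 0
    out$oBPhi <- tm$a1 / a^2 * drop(crossprod(eg, r))
    hPhi <- sum((y * eta - tm$b) *
                  (2 * tm$a1^2 / a^3 - tm$a2 / a^2) + tm$d2c_dphi2)
    out$oPhiPhi <- -hPhi
  }
  out
}

.checkNullFit <- function(y, x, nf) {
  if (length(nf@mu) != length(y))
    stop("null fit does not match the data dimensions")
  if (max(abs(drop(crossprod(x, y - nf@mu)))) > 1e-6)
    stop("stale null fit: alpha-score is not zero for these data")
}

# Symmetric (pseudo-)inverse quadratic form s^T M^{-1} s with eigenvalue
# truncation at 1e-10 * max; returns statistic and effective rank.
.quadInv <- function(M, s) {
  M <- (M + t(M)) / 2
  ev <- eigen(M, symmetric = TRUE)
  tol <- 1e-10 * max(abs(ev$values), 0)
  keep <- ev$values > tol
  if (!any(keep)) return(list(stat = 0, rank = 0L))
  proj <- drop(crossprod(ev$vectors[, keep, drop = FALSE], s))
  list(stat = sum(proj^2 / ev$values[keep]), rank = sum(keep))
}

# Identify monomorphic sites: constant dosage across individuals with no
# per-individual posterior uncertainty. Such sites carry no information and
# are removed from the group.
.monomorphicSites <- function(post) {
  v <- post@eggDiag - post@eg^2
  noUncert <- apply(v, 2L, max) < 1e-12
  constant <- apply(post@eg, 2L, function(z) max(z) - min(z)) < 1e-12
  noUncert & constant
}

.dropSites <- function(post, drop) {
  new("SitePosterior", eg = post@eg[, !drop, drop = FALSE],
      eggDiag = post@eggDiag[, !drop, drop = FALSE])
}

#' Score vector at the constrained null MLE
#'
#' Evaluates the full score at theta-tilde. The alpha component (and the phi
#' component in the gaussian family) vanish by the first-order condition of
#' the null fit and are asserted rather than recomputed; the beta component
#' is \eqn{\sum_i (y_i - b'(\tilde\alpha x_i^T)) / a(\tilde\phi)\,
#' E[g^T | D_i]}.
#'
#' @param y,x response and covariate matrix used for \code{nullFit}.
#' @param posterior a [SitePosterior-class].
#' @param nullFit a [NullFit-class] for the same (y, x, family).
#' @return list with \code{sBeta} (length dg) and \code{alphaPhiScoreMax},
#'   the largest absolute alpha/phi score component (certified < 1e-6).
#' @export
scoreAtNull <- function(y, x, posterior, nullFit) {
  x <- as.matrix(x)
  .checkNullFit(y, x, nullFit)
  if (nrow(posterior@eg) != length(y))
    stop("posterior does not match the data dimensions")
  fam <- nullFit@family
  a <- if (fam@hasDispersion) nullFit@phi else 1
  r <- y - nullFit@mu
  sAlpha <- drop(crossprod(x, r)) / a
  sPhi <- if (fam@hasDispersion) {
    tm <- familyTerms(fam, nullFit@eta, y = y, phi = nullFit@phi)
    sum(-(y * nullFit@eta - tm$b) / a^2 * tm$a1 + tm$dc_dphi)
  } else numeric(0)
  list(sBeta = drop(crossprod(posterior@eg, r)) / a,
       alphaPhiScoreMax = max(abs(c(sAlpha, sPhi))))
}

#' Observed information matrix at the constrained null MLE
#'
#' Assembles the negative Hessian of the latent-genotype log-likelihood at
#' theta-tilde from its closed-form blocks, ordered (alpha, beta) or
#' (alpha, beta, phi) for the gaussian family. The alpha-phi block is exactly
#' zero at the null fit.
#'
#' @inheritParams scoreAtNull
#' @return a symmetric matrix of size (dx+1) + dg (+ 1 with dispersion).
#' @export
observedInformationAtNull <- function(y, x, posterior, nullFit) {
  x <- as.matrix(x)
  .checkNullFit(y, x, nullFit)
  bl <- .nullBlocks(y, x, posterior, nullFit)
  if (!all(is.finite(unlist(bl))))
    stop("non-finite entries in the observed information")
  p <- ncol(x); dg <- ncol(posterior@eg)
  if (nullFit@family@hasDispersion) {
    o <- matrix(0, p + dg + 1L, p + dg + 1L)
    ia <- seq_len(p); ib <- p + seq_len(dg); ip <- p + dg + 1L
    o[ia, ia] <- bl$oAA; o[ia, ib] <- bl$oAB; o[ib, ia] <- t(bl$oAB)
    o[ib, ib] <- bl$oBB
    o[ib, ip] <- bl$oBPhi; o[ip, ib] <- bl$oBPhi
    o[ip, ip] <- bl$oPhiPhi                 # alpha-phi block stays zero
  } else {
    o <- matrix(0, p + dg, p + dg)
    ia <- seq_len(p); ib <- p + seq_len(dg)
    o[ia, ia] <- bl$oAA; o[ia, ib] <- bl$oAB; o[ib, ia] <- t(bl$oAB)
    o[ib, ib] <- bl$oBB
  }
  o
}

# Shared driver for jsTest / vcTest. weights = NULL selects the joint
# significance path; otherwise the score and information are projected
# through the weight vector (chain rule) onto the 1-df collapsed effect.
.groupScoreTest <- function(y, x, posterior, family, weights = NULL,
                            nullFit = NULL, dropMonomorphic = TRUE) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  stopifnot(is(posterior, "SitePosterior"))
  if (nrow(posterior@eg) != length(y) || nrow(x) != length(y))
    stop("dimension mismatch between y, x and posterior")
  if (is.null(nullFit)) nullFit <- fitNull(y, x, family)
  else .checkNullFit(y, x, nullFit)
  fam <- nullFit@family
  notes <- character(0)

  dgIn <- ncol(posterior@eg)
  collapse <- !is.null(weights)
  if (collapse) {
    if (length(weights) != dgIn) stop("weights length must equal dg")
    if (any(weights <= 0)) stop("weights must be positive")
  }
  if (dropMonomorphic) {
    mono <- .monomorphicSites(posterior)
    if (any(mono)) {
      notes <- c(notes, paste0(sum(mono), " monomorphic site(s) dropped"))
      warning(sum(mono), " monomorphic site(s) dropped from the group")
      posterior <- .dropSites(posterior, mono)
      if (collapse) weights <- weights[!mono]
    }
  }
  dg <- ncol(posterior@eg)
  method <- if (collapse) "vc" else "js"
  df <- if (collapse) 1 else dg
  if (dg == 0L)
    return(new("ScoreTestResult", statistic = 0, df = as.numeric(df),
               p.value = 1, score = numeric(0),
               info = matrix(0, 0, 0), method = method, rank = 0L,
               nSites = 0L, notes = c(notes, "no polymorphic sites")))
  if (!collapse && length(y) <= ncol(x) + dg)
    warning("sample size is small relative to dx + dg; ",
            "the chi-square approximation may be poor")

  bl <- .nullBlocks(y, x, posterior, nullFit)
  if (collapse) {
    w <- weights * dg / sum(weights)        # identification: sum(w) = dg
    s <- sum(w * bl$sBeta)
    oBB <- drop(w %*% bl$oBB %*% w)
    oAB <- bl$oAB %*% w
    if (fam@hasDispersion) oBPhi <- sum(w * bl$oBPhi)
  } else {
    s <- bl$sBeta
    oBB <- bl$oBB
    oAB <- bl$oAB
    if (fam@hasDispersion) oBPhi <- bl$oBPhi
  }

  # Schur complement of the beta block: algebraically s^T o^{-1} s with the
  # zero-padded score, but numerically safer.
  schur <- oBB - crossprod(oAB, solve(bl$oAA, oAB))
  if (fam@hasDispersion)
    schur <- schur - tcrossprod(oBPhi) / bl$oPhiPhi
  q <- .quadInv(as.matrix(schur), s)
  if (q$rank < (if (collapse) 1L else dg))
    notes <- c(notes, sprintf(
      "information rank %d < %d; pseudo-inverse used", q$rank,
      if (collapse) 1L else dg))
  stat <- max(q$stat, 0)
  new("ScoreTestResult", statistic = stat, df = as.numeric(df),
      p.value = if (q$rank == 0L) 1 else
        stats::pchisq(stat, df = df, lower.tail = FALSE),
      score = as.numeric(s), info = as.matrix(schur), method = method,
      rank = as.integer(q$rank), nSites = as.integer(dg), notes = notes)
}

#' Joint significance score test for a group of common variants
#'
#' Tests H0: beta = 0 for all dg markers jointly, from genotype likelihoods
#' rather than called genotypes. The statistic is
#' \eqn{R = s^T o^{-1} s} with s the full score and o the full observed
#' information at the constrained null MLE, computed via the Schur
#' complement of the beta block; under H0 it is approximately chi-square
#' with dg degrees of freedom. Monomorphic sites (no dosage variation and no
#' posterior uncertainty) are dropped with a warning; if the observed
#' information is numerically singular a truncated pseudo-inverse is used
#' and the effective rank reported, but the reference degrees of freedom
#' stay at dg.
#'
#' @param y numeric response vector.
#' @param x covariate matrix including an intercept column.
#' @param posterior a [SitePosterior-class] from [posteriorMoments()].
#' @param family a [GLMFamily-class].
#' @param nullFit optional precomputed [NullFit-class] (reused across tests
#'   on the same phenotype).
#' @param dropMonomorphic drop uninformative monomorphic sites (default).
#' @return a [ScoreTestResult-class] with \code{method = "js"}.
#' @seealso [vcTest()], [genotypeGroupTest()]
#' @export
jsTest <- function(y, x, posterior, family, nullFit = NULL,
                   dropMonomorphic = TRUE) {
  .groupScoreTest(y, x, posterior, family, weights = NULL,
                  nullFit = nullFit, dropMonomorphic = dropMonomorphic)
}

#' Variable collapse score test for a group of rare variants
#'
#' Constrains the marker effects to a single direction, beta = beta0 * W for
#' a positive weight vector W (normalized so its entries sum to dg), and
#' tests H0: beta0 = 0 with one degree of freedom. The score and observed
#' information of the joint parameterization are projected through W by the
#' chain rule; the statistic is the 1-df analogue of [jsTest()] and the
#' likelihood-uncertainty counterpart of the genotype-based weighted burden
#' test. The statistic is invariant to rescaling the weights.
#'
#' @inheritParams jsTest
#' @param weights positive weight vector of length dg; defaults to equal
#'   weights. See [betaWeights()] for the Beta(1, 25) MAF weighting.
#' @return a [ScoreTestResult-class] with \code{method = "vc"}, df = 1.
#' @export
vcTest <- function(y, x, posterior, family, weights = NULL, nullFit = NULL,
                   dropMonomorphic = TRUE) {
  if (is.null(weights)) weights <- rep(1, ncol(posterior@eg))
  .groupScoreTest(y, x, posterior, family, weights = weights,
                  nullFit = nullFit, dropMonomorphic = dropMonomorphic)
}

#' Beta(1, 25) weights from minor allele frequencies
#'
#' The customary rare-variant weighting: w_j proportional to the Beta(1, 25)
#' density at MAF_j, renormalized so the weights sum to dg (the
#' identification constraint of the collapsed model). Rarer variants receive
#' larger weight.
#'
#' @param mafs minor allele frequencies, each in (0, 1).
#' @return numeric weight vector summing to \code{length(mafs)}.
#' @examples
#' betaWeights(c(0.01, 0.01))  # equal MAFs give equal weights of 1
#' @export
betaWeights <- function(mafs) {
  if (any(mafs <= 0) || any(mafs >= 1))
    stop("MAFs must lie strictly in (0, 1); weight undefined at MAF = 0")
  w <- stats::dbeta(mafs, 1, 25)
  w * length(w) / sum(w)
}
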