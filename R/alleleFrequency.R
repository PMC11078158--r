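#' One-step EM maximum-likelihood allele frequencies from read data
#'
#' Maximizes, independently per site, the marginal read log-likelihood
#' \deqn{\ell(f) = \sum_i \log \sum_{g=0}^{2} p(D_i | g)\,
#'   \mathrm{HWE}(g | f)}
#' by EM: the E-step computes the posterior dosage of each individual under
#' the current f, the M-step sets f to the mean dosage over 2N chromosomes.
#' The per-site likelihood in f is unimodal for this model, so the
#' initialization f = 0.5 is not critical. The log-likelihood is checked to
#' be non-decreasing at every iteration.
#'
#' Sites where every individual has a flat likelihood (no coverage anywhere)
#' carry no information about f; they are returned at the initialization
#' value with a degenerate flag.
#'
#' @param gl a [GenotypeLikelihoods-class].
#' @param tol convergence tolerance on max |change in f|.
#' @param maxIter iteration cap; exceeding it is an error.
#' @param fInit initial frequency.
#' @return an [AlleleFrequencies-class] with method \code{"em_mle"}.
#' @examples
#' # a single certainly-heterozygous individual: argmax of log(2f(1-f))
#' gl <- genotypeLikelihoods(matrix(0), matrix(1), matrix(0))
#' alleleFreq(afEM(gl))  # 0.5
#' @export
afEM <- function(gl, tol = 1e-6, maxIter = 200L, fInit = 0.5) {
  stopifnot(is(gl, "GenotypeLikelihoods"))
  N <- nSamples(gl); dg <- nSites(gl)
  flat <- gl@l0 == gl@l1 & gl@l1 == gl@l2
  degen <- colSums(flat) == N
  f <- rep(fInit, dg)
  llPrev <- rep(-Inf, dg)
  for (it in seq_len(maxIter)) {
    p0 <- (1 - f)^2; p1 <- 2 * f * (1 - f); p2 <- f^2
    u0 <- sweep(gl@l0, 2L, p0, `*`)
    u1 <- sweep(gl@l1, 2L, p1, `*`)
    u2 <- sweep(gl@l2, 2L, p2, `*`)
    tot <- u0 + u1 + u2
    ll <- colSums(log(tot))
    if (any(ll < llPrev - 1e-8 * pmax(1, abs(ll))))
      stop("EM log-likelihood decreased; numerical failure")
    llPrev <- ll
    fNew <- pmin(1, pmax(0, colSums((u1 + 2 * u2) / tot) / (2 * N)))
    fNew[degen] <- fInit
    delta <- max(abs(fNew - f))
    f <- fNew
    if (delta < tol) {
      return(new("AlleleFrequencies", f = f, method = "em_mle",
                 degenerate = degen))
    }
  }
  stop("EM did not converge within ", maxIter,
       " iterations; last estimate: ", paste(format(f), collapse = ", "))
}

#' MAP genotype calls under a Hardy-Weinberg prior
#'
#' Per individual per site, returns the genotype maximizing
#' p(D | g) x HWE(g | f). Ties are broken toward the smaller genotype so the
#' call is deterministic.
#'
#' @param gl a [GenotypeLikelihoods-class].
#' @param f allele frequencies: numeric vector (length 1 or dg) or an
#'   [AlleleFrequencies-class].
#' @return an integer matrix N x dg with entries in \{0, 1, 2\}.
#' @export
callGenotypes <- function(gl, f) {
  stopifnot(is(gl, "GenotypeLikelihoods"))
  if (is(f, "AlleleFrequencies")) f <- alleleFreq(f)
  dg <- nSites(gl)
  if (length(f) == 1L) f <- rep(f, dg)
  if (length(f) != dg) stop("length(f) must equal the number of sites")
  u0 <- sweep(gl@l0, 2L, (1 - f)^2, `*`)
  u1 <- sweep(gl@l1, 2L, 2 * f * (1 - f), `*`)
  u2 <- sweep(gl@l2, 2L, f^2, `*`)
  # strict comparisons break ties toward the smaller genotype
  calls <- ifelse(u2 > pmax(u0, u1), 2L, ifelse(u1 > u0, 1L, 0L))
  dim(calls) <- dim(u0)
  storage.mode(calls) <- "integer"
  calls
}

#' Allele frequencies from hard genotype calls
#'
#' @param calls integer matrix N x dg with entries in \{0, 1, 2\}.
#' @return an [AlleleFrequencies-class] with method \code{"two_step"}:
#'   per site, mean(g) / 2.
#' @export
afFromCalls <- function(calls) {
  calls <- as.matrix(calls)
  if (!all(calls %in% 0:2)) stop("calls must be 0, 1 or 2")
  new("AlleleFrequencies", f = colMeans(calls) / 2, method = "two_step",
      degenerate = rep(FALSE, ncol(calls)))
}

#' Two-step genotype-based allele-frequency estimator
#'
#' The comparator estimator: first call genotypes, then count alleles. The
#' preliminary call uses a Hardy-Weinberg prior at f = 0.5; the resulting
#' frequencies drive one MAP re-call, after which frequencies are frozen
#' (one refinement round).
#'
#' @param gl a [GenotypeLikelihoods-class].
#' @return an [AlleleFrequencies-class] with method \code{"two_step"}.
#' @export
afTwoStep <- function(gl) {
  calls0 <- callGenotypes(gl, 0.5)
  f1 <- afFromCalls(calls0)
  calls1 <- callGenotypes(gl, f1)
  afFromCalls(calls1)
}
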