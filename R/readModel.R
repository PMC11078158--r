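#' Genotype likelihoods from read counts at a biallelic site
#'
#' Under the symmetric read-error model, a read from an individual with
#' genotype g (alternate-allele count, 0/1/2) reports the alternate allele
#' with probability \eqn{p(g) = (g/2)(1-e) + (1-g/2)e}, independently across
#' reads. The likelihood of observing \code{nAlt} alternate and \code{nRef}
#' reference reads is then \eqn{p(g)^{nAlt} (1-p(g))^{nRef}} up to a constant
#' binomial coefficient, which is omitted: the tests are invariant to a
#' positive rescaling of the triple. Zero reads yield the flat triple
#' (1, 1, 1). At extreme depth (more than 300 reads at a cell) the triple is
#' computed in log space and rescaled by its maximum to avoid underflow.
#'
#' @param nRef,nAlt non-negative integer matrices (or vectors/scalars) of
#'   reference and alternate read counts, individuals x sites.
#' @param errorRate per-base allele-flip probability, in (0, 0.5).
#' @return a [GenotypeLikelihoods-class] with the same dimensions.
#' @examples
#' gl <- siteLikelihood(nRef = 0, nAlt = 1, errorRate = 0.005)
#' likelihoodMatrix(gl, 0)  # 0.005
#' @export
siteLikelihood <- function(nRef, nAlt, errorRate = 0.005) {
  if (errorRate <= 0 || errorRate >= 0.5)
    stop("errorRate must lie in (0, 0.5)")
  nRef <- as.matrix(nRef); nAlt <- as.matrix(nAlt)
  if (!identical(dim(nRef), dim(nAlt)))
    stop("nRef and nAlt must share dimensions")
  if (min(nRef, nAlt) < 0 || any(nRef != round(nRef)) ||
      any(nAlt != round(nAlt)))
    stop("read counts must be non-negative integers")
  e <- errorRate
  if (max(nRef + nAlt) <= 300) {
    # p(alt-read | g) = e, 1/2, 1-e for g = 0, 1, 2
    l0 <- e^nAlt * (1 - e)^nRef
    l1 <- 0.5^(nAlt + nRef)
    l2 <- (1 - e)^nAlt * e^nRef
  } else {
    z0 <- nAlt * log(e) + nRef * log1p(-e)
    z1 <- (nAlt + nRef) * log(0.5)
    z2 <- nAlt * log1p(-e) + nRef * log(e)
    m <- pmax(z0, z1, z2)
    l0 <- exp(z0 - m); l1 <- exp(z1 - m); l2 <- exp(z2 - m)
  }
  genotypeLikelihoods(l0, l1, l2,
                      siteIDs = colnames(nRef), sampleIDs = rownames(nRef))
}

#' Hardy-Weinberg genotype prior
#'
#' @param f alternate-allele frequency (vector allowed), in [0, 1].
#' @return a length(f) x 3 matrix with columns p(g = 0), p(g = 1), p(g = 2) =
#'   ((1-f)^2, 2f(1-f), f^2); rows sum to 1.
#' @examples
#' hwePrior(0.2)  # 0.64 0.32 0.04
#' @export
hwePrior <- function(f) {
  if (any(f < 0 | f > 1)) stop("allele frequency must lie in [0, 1]")
  cbind(p0 = (1 - f)^2, p1 = 2 * f * (1 - f), p2 = f^2)
}

#' Posterior genotype moments given reads and an allele-frequency prior
#'
#' Combines per-site genotype likelihoods with the Hardy-Weinberg prior at
#' the supplied frequencies into the posterior over \{0,1,2\} at each site,
#' and returns the moments the score tests consume: the mean dosage
#' E[g | D_i] and the second moments E[g_j^2 | D_i]. The group-level
#' posterior over the full genotype space \{0,1,2\}^dg factorizes across
#' sites (both the read likelihood and the prior do), so these per-site
#' quantities determine the full E[g^T g | D_i]: off-diagonals are products
#' of means. This is an exact reformulation of the sum over all 3^dg
#' genotype vectors, not an approximation.
#'
#' Sites with no reads contribute the prior (mean dosage 2f), never dropped.
#'
#' @param gl a [GenotypeLikelihoods-class] (N individuals x dg sites).
#' @param f allele frequencies: a numeric vector of length dg or an
#'   [AlleleFrequencies-class].
#' @return a [SitePosterior-class].
#' @examples
#' gl <- siteLikelihood(matrix(0, 1, 1), matrix(0, 1, 1))
#' dosage(posteriorMoments(gl, 0.3))  # 0.6: prior mean 2f
#' @export
posteriorMoments <- function(gl, f) {
  stopifnot(is(gl, "GenotypeLikelihoods"))
  if (is(f, "AlleleFrequencies")) f <- alleleFreq(f)
  dg <- nSites(gl)
  if (length(f) == 1L) f <- rep(f, dg)
  if (length(f) != dg) stop("length(f) must equal the number of sites")
  pri <- hwePrior(f)
  # posterior columns per site, recycled prior by row
  u0 <- sweep(gl@l0, 2L, pri[, 1L], `*`)
  u1 <- sweep(gl@l1, 2L, pri[, 2L], `*`)
  u2 <- sweep(gl@l2, 2L, pri[, 3L], `*`)
  tot <- u0 + u1 + u2
  if (any(tot <= 0)) {
    bad <- which(tot <= 0, arr.ind = TRUE)[1L, ]
    stop("posterior mass is zero for individual ", bad[1L], " at site ",
         bad[2L], ": likelihood and prior are disjointly zero")
  }
  eg <- (u1 + 2 * u2) / tot
  eggDiag <- (u1 + 4 * u2) / tot
  new("SitePosterior", eg = eg, eggDiag = pmin(eggDiag, 2 * eg))
}

#' Degenerate posterior at known genotypes
#'
#' Builds the [SitePosterior-class] that places all mass on a hard genotype
#' matrix. With this input the sequencing-data tests reduce exactly to their
#' classical genotype-based counterparts.
#'
#' @param genotypes integer matrix N x dg with entries in \{0, 1, 2\}.
#' @return a [SitePosterior-class] with zero posterior variance.
#' @export
degeneratePosterior <- function(genotypes) {
  genotypes <- as.matrix(genotypes)
  stopifnot(all(genotypes %in% 0:2))
  new("SitePosterior", eg = genotypes + 0, eggDiag = genotypes^2 + 0)
}
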