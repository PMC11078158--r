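#' @import methods
NULL

#' Exponential-family descriptor for the phenotype model
#'
#' A \code{GLMFamily} identifies which member of the generalized linear model
#' family the phenotype follows: \code{"gaussian"} (continuous, linear
#' regression), \code{"logistic"} (binary) or \code{"poisson"} (count). The
#' gaussian family carries a free dispersion parameter \eqn{\phi = \sigma^2}
#' with \eqn{a(\phi)=\phi}; the logistic and Poisson families have
#' \eqn{a \equiv 1} and no dispersion, which selects the reduced
#' \eqn{(\alpha,\beta)} parameterization throughout the score machinery.
#'
#' @slot name one of \code{"gaussian"}, \code{"logistic"}, \code{"poisson"}.
#' @slot hasDispersion \code{TRUE} only for the gaussian family.
#' @seealso [glmFamily()], [familyTerms()], [fitNull()]
#' @exportClass GLMFamily
setClass("GLMFamily",
         representation(name = "character", hasDispersion = "logical"),
         validity = function(object) {
           if (length(object@name) != 1L ||
               !object@name %in% c("gaussian", "logistic", "poisson"))
             return("name must be one of 'gaussian', 'logistic', 'poisson'")
           if (!identical(object@hasDispersion, object@name == "gaussian"))
             return("hasDispersion must be TRUE exactly for the gaussian family")
           TRUE
         })

#' Construct a GLMFamily
#'
#' @param name family name: \code{"gaussian"}, \code{"logistic"} or
#'   \code{"poisson"}.
#' @return a [GLMFamily-class] object.
#' @examples
#' glmFamily("logistic")
#' @export
glmFamily <- function(name = c("gaussian", "logistic", "poisson")) {
  name <- match.arg(name)
  new("GLMFamily", name = name, hasDispersion = name == "gaussian")
}

setMethod("show", "GLMFamily", function(object) {
  cat("GLMFamily:", object@name,
      if (object@hasDispersion) "(with dispersion phi)" else "(a == 1)", "\n")
})

#' Per-site genotype likelihoods for a cohort
#'
#' Holds p(reads | g) for g = 0, 1, 2 at each biallelic site for each
#' individual, as three N x dg matrices. Likelihoods are unnormalized: every
#' downstream computation is invariant to rescaling the triple
#' (l0[i,j], l1[i,j], l2[i,j]) by a positive constant. A site with no reads
#' carries the flat triple (1, 1, 1).
#'
#' @slot l0,l1,l2 N x dg matrices of p(reads | g = 0), p(reads | g = 1),
#'   p(reads | g = 2).
#' @slot siteIDs character vector of site identifiers (length dg).
#' @slot sampleIDs character vector of sample identifiers (length N).
#' @seealso [genotypeLikelihoods()], [siteLikelihood()], [posteriorMoments()]
#' @exportClass GenotypeLikelihoods
setClass("GenotypeLikelihoods",
         representation(l0 = "matrix", l1 = "matrix", l2 = "matrix",
                        siteIDs = "character", sampleIDs = "character"),
         validity = function(object) {
           d <- dim(object@l0)
           if (!identical(d, dim(object@l1)) || !identical(d, dim(object@l2)))
             return("l0, l1, l2 must share dimensions")
           if (length(object@siteIDs) != d[2L])
             return("siteIDs length must equal the number of sites")
           if (length(object@sampleIDs) != d[1L])
             return("sampleIDs length must equal the number of individuals")
           if (anyNA(object@l0) || anyNA(object@l1) || anyNA(object@l2))
             return("likelihoods must be non-missing")
           if (min(object@l0, object@l1, object@l2) < 0)
             return("likelihoods must be non-negative")
           if (any(pmax(object@l0, object@l1, object@l2) <= 0))
             return("each likelihood triple needs at least one positive entry")
           TRUE
         })

#' Construct a GenotypeLikelihoods object
#'
#' @param l0,l1,l2 N x dg matrices of likelihoods for genotypes 0, 1, 2.
#' @param siteIDs,sampleIDs optional identifiers; defaults are generated.
#' @return a [GenotypeLikelihoods-class] object.
#' @export
genotypeLikelihoods <- function(l0, l1, l2,
                                siteIDs = NULL, sampleIDs = NULL) {
  l0 <- as.matrix(l0); l1 <- as.matrix(l1); l2 <- as.matrix(l2)
  if (is.null(siteIDs))
    siteIDs <- if (!is.null(colnames(l0))) colnames(l0) else
      paste0("site", seq_len(ncol(l0)))
  if (is.null(sampleIDs))
    sampleIDs <- if (!is.null(rownames(l0))) rownames(l0) else
      paste0("ind", seq_len(nrow(l0)))
  new("GenotypeLikelihoods", l0 = l0, l1 = l1, l2 = l2,
      siteIDs = as.character(siteIDs), sampleIDs = as.character(sampleIDs))
}

setMethod("show", "GenotypeLikelihoods", function(object) {
  cat("GenotypeLikelihoods:", nrow(object@l0), "individuals x",
      ncol(object@l0), "sites\n")
})

#' Posterior genotype moments given sequencing reads
#'
#' For each individual i the tests need the posterior mean dosage vector
#' E[g | D_i] and the second-moment matrix E[g^T g | D_i], where the posterior
#' combines the read likelihood with a Hardy-Weinberg prior at the supplied
#' allele frequencies. Because both the likelihood and the prior factorize
#' across sites, the posterior factorizes too: the full second-moment matrix
#' is E[g|D] E[g|D]^T off the diagonal with diagonal E[g_j^2 | D]. Only the
#' mean and the diagonal are stored; [egg()] materializes the dg x dg matrix
#' for one individual.
#'
#' @slot eg N x dg matrix of posterior mean dosages, entries in [0, 2].
#' @slot eggDiag N x dg matrix of posterior second moments E[g_j^2 | D_i].
#' @seealso [posteriorMoments()], [egg()], [jsTest()]
#' @exportClass SitePosterior
setClass("SitePosterior",
         representation(eg = "matrix", eggDiag = "matrix"),
         validity = function(object) {
           if (!identical(dim(object@eg), dim(object@eggDiag)))
             return("eg and eggDiag must share dimensions")
           if (length(object@eg) == 0L) return(TRUE)  # empty group
           tol <- 1e-8
           if (min(object@eg) < -tol || max(object@eg) > 2 + tol)
             return("posterior mean dosages must lie in [0, 2]")
           if (any(object@eggDiag < object@eg^2 - tol) ||
               any(object@eggDiag > 2 * object@eg + tol))
             return("second moments must satisfy eg^2 <= E[g^2] <= 2*eg")
           TRUE
         })

setMethod("show", "SitePosterior", function(object) {
  cat("SitePosterior:", nrow(object@eg), "individuals x",
      ncol(object@eg), "sites; mean dosage",
      format(mean(object@eg), digits = 4), "\n")
})

#' Constrained maximum-likelihood fit of the null model
#'
#' The score tests are evaluated at the constrained MLE under H0: beta = 0,
#' i.e. the GLM of phenotype on covariates only. For the gaussian family the
#' dispersion estimate is the MLE residual variance (residual sum of squares
#' divided by N, not N - p), because the score-test derivation evaluates at
#' the exact constrained maximum.
#'
#' @slot alpha covariate coefficients (including intercept).
#' @slot phi dispersion MLE for gaussian, \code{numeric(0)} otherwise.
#' @slot logLik null log-likelihood at the fit.
#' @slot family the [GLMFamily-class].
#' @slot eta,mu linear predictor and fitted mean per individual.
#' @seealso [fitNull()], [scoreAtNull()]
#' @exportClass NullFit
setClass("NullFit",
         representation(alpha = "numeric", phi = "numeric", logLik = "numeric",
                        family = "GLMFamily", eta = "numeric", mu = "numeric"),
         validity = function(object) {
           if (object@family@hasDispersion) {
             if (length(object@phi) != 1L || object@phi <= 0)
               return("gaussian null fit requires a positive phi")
           } else if (length(object@phi) != 0L)
             return("phi must be absent for dispersion-free families")
           TRUE
         })

setMethod("show", "NullFit", function(object) {
  cat("NullFit (", object@family@name, "): alpha = (",
      paste(format(object@alpha, digits = 5), collapse = ", "), ")",
      if (object@family@hasDispersion)
        paste0(", phi = ", format(object@phi, digits = 5)) else "",
      "\n  logLik = ", format(object@logLik, digits = 8), "\n", sep = "")
})

#' Result of a group score test
#'
#' @slot statistic the chi-square score statistic R >= 0.
#' @slot df degrees of freedom (dg for the joint significance test, 1 for the
#'   variable collapse and burden tests).
#' @slot p.value upper chi-square tail probability at \code{statistic}.
#' @slot score the score vector in beta (length dg, or 1 after collapsing).
#' @slot info the observed information used for the statistic (the Schur
#'   complement of the beta block after eliminating alpha and phi).
#' @slot method one of \code{"js"}, \code{"vc"}, \code{"genotype_chisq"},
#'   \code{"burden"}.
#' @slot rank effective rank used when inverting the information (may be less
#'   than df when the observed information is numerically singular; df is not
#'   reduced).
#' @slot nSites number of sites retained in the group.
#' @slot notes diagnostics (dropped monomorphic sites, pseudo-inverse use, ...).
#' @exportClass ScoreTestResult
setClass("ScoreTestResult",
         representation(statistic = "numeric", df = "numeric",
                        p.value = "numeric", score = "numeric",
                        info = "matrix", method = "character",
                        rank = "integer", nSites = "integer",
                        notes = "character"),
         validity = function(object) {
           if (object@statistic < -1e-8) return("statistic must be >= 0")
           if (object@p.value < 0 || object@p.value > 1)
             return("p.value must be a probability")
           TRUE
         })

setMethod("show", "ScoreTestResult", function(object) {
  cat("ScoreTestResult [", object@method, "]\n",
      "  statistic = ", format(object@statistic, digits = 6),
      ", df = ", object@df,
      ", p = ", format.pval(object@p.value, digits = 4), "\n",
      "  sites used = ", object@nSites,
      ", effective rank = ", object@rank, "\n", sep = "")
  if (length(object@notes)) cat("  notes:", paste(object@notes, collapse = "; "), "\n")
})

#' Allele-frequency estimates for a group of sites
#'
#' @slot f estimated alternate-allele frequencies, one per site, in [0, 1].
#' @slot method \code{"true"}, \code{"two_step"} (call genotypes, then count
#'   alleles) or \code{"em_mle"} (one-step EM maximizer of the read
#'   likelihood).
#' @slot degenerate logical per site: TRUE where every individual had a flat
#'   likelihood (no coverage anywhere), in which case f is the EM
#'   initialization value and carries no information.
#' @seealso [afEM()], [afTwoStep()], [afFromCalls()]
#' @exportClass AlleleFrequencies
setClass("AlleleFrequencies",
         representation(f = "numeric", method = "character",
                        degenerate = "logical"),
         validity = function(object) {
           if (any(object@f < 0 | object@f > 1))
             return("frequencies must lie in [0, 1]")
           if (length(object@degenerate) != length(object@f))
             return("degenerate flag must match f in length")
           TRUE
         })

setMethod("show", "AlleleFrequencies", function(object) {
  cat("AlleleFrequencies [", object@method, "]: ",
      length(object@f), " sites", sep = "")
  if (any(object@degenerate))
    cat(" (", sum(object@degenerate), " degenerate)", sep = "")
  cat("\n  f = ", paste(format(object@f, digits = 4), collapse = ", "), "\n",
      sep = "")
})

#' Configuration of a simulated sequencing study
#'
#' Encodes the generative design of the benchmark: biallelic markers with a
#' uniform MAF spectrum split at 0.05 into common (Uniform(0.05, 0.5), 5
#' markers per group) and rare (Uniform(0.005, 0.05), 10 markers per group)
#' variants; read counts Poisson with the given mean depth and a symmetric
#' per-base error (default 0.5%); covariates X1 ~ Bernoulli(0.5) and
#' X2 ~ N(0, 1) with coefficients (0, 1, 1) for (intercept, X1, X2); and a
#' causal architecture drawing the causal-variant count uniformly on a range
#' (2-5 common, 2-10 rare) with each effect equal to the total effect divided
#' by the causal count. The binary phenotype model includes an extra N(0, 1)
#' noise term inside the linear predictor; the Poisson model does not.
#'
#' @slot nIndividuals,nMarkers cohort and group sizes.
#' @slot mafRange MAF spectrum lower/upper bound.
#' @slot depth mean sequencing coverage per site per individual.
#' @slot errorRate per-base allele-flip probability, in (0, 0.5).
#' @slot family the phenotype [GLMFamily-class].
#' @slot nCausalRange integer range for the causal-variant count.
#' @slot totalEffect total genetic effect (0.2 x magnitude on the 0-5 grid).
#' @slot direction \code{"positive"} (all effects positive) or \code{"mixed"}.
#' @slot includeEtaNoise include N(0,1) noise inside the linear predictor.
#' @seealso [simulationConfig()], [simulateDataset()]
#' @exportClass SimulationConfig
setClass("SimulationConfig",
         representation(nIndividuals = "integer", nMarkers = "integer",
                        mafRange = "numeric", depth = "numeric",
                        errorRate = "numeric", family = "GLMFamily",
                        nCausalRange = "integer", totalEffect = "numeric",
                        direction = "character", includeEtaNoise = "logical"),
         validity = function(object) {
           if (object@depth <= 0) return("depth must be positive")
           if (object@errorRate <= 0 || object@errorRate >= 0.5)
             return("errorRate must lie in (0, 0.5)")
           if (object@totalEffect < 0) return("totalEffect must be >= 0")
           if (length(object@mafRange) != 2L ||
               any(object@mafRange < 0) || any(object@mafRange > 0.5) ||
               diff(object@mafRange) < 0)
             return("mafRange must be a non-decreasing pair in [0, 0.5]")
           if (any(object@nCausalRange < 1L) ||
               diff(object@nCausalRange) < 0 ||
               max(object@nCausalRange) > object@nMarkers)
             return("nCausalRange must fit within nMarkers")
           if (!object@direction %in% c("positive", "mixed"))
             return("direction must be 'positive' or 'mixed'")
           TRUE
         })

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig: N =", object@nIndividuals,
      ", markers =", object@nMarkers,
      ", MAF in [", object@mafRange[1L], ",", object@mafRange[2L], "]\n",
      "  depth =", object@depth, "X, error =", object@errorRate,
      ", family =", object@family@name, "\n",
      "  causal count in [", object@nCausalRange[1L], ",",
      object@nCausalRange[2L], "], total effect =", object@totalEffect, "\n")
})
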