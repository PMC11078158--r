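#' Construct a simulation configuration
#'
#' Presets encode the benchmark design: \code{variantClass = "common"} uses
#' groups of 5 markers with MAF ~ Uniform(0.05, 0.5) and 2-5 causal variants
#' under the alternative; \code{variantClass = "rare"} uses groups of 10
#' markers with MAF ~ Uniform(0.005, 0.05) and 2-10 causal variants. The
#' total genetic effect is 0.2 x magnitude with magnitude on a 0-5 grid, so
#' total effects span 0 to 1; each causal variant receives the total divided
#' by the causal count. Binary phenotypes include an N(0, 1) noise term
#' inside the linear predictor; Poisson and gaussian phenotypes do not (the
#' gaussian model has its own unit residual).
#'
#' @param nIndividuals sample size N.
#' @param variantClass \code{"common"} or \code{"rare"}; sets defaults for
#'   \code{nMarkers}, \code{mafRange}, \code{nCausalRange}.
#' @param family phenotype family name or [GLMFamily-class].
#' @param depth mean sequencing coverage (e.g. 1, 2, 4, 10).
#' @param errorRate per-base error, default 0.005.
#' @param nMarkers,mafRange,nCausalRange overrides of the class presets.
#' @param totalEffect total genetic effect size (0 under the null).
#' @param direction \code{"positive"} (all causal effects positive, the
#'   power-study design) or \code{"mixed"} (random signs).
#' @param includeEtaNoise override the family default for the latent N(0,1)
#'   noise inside the linear predictor.
#' @return a [SimulationConfig-class].
#' @export
simulationConfig <- function(nIndividuals = 300L,
                             variantClass = c("common", "rare"),
                             family = "logistic",
                             depth = 1, errorRate = 0.005,
                             nMarkers = NULL, mafRange = NULL,
                             nCausalRange = NULL, totalEffect = 0,
                             direction = c("positive", "mixed"),
                             includeEtaNoise = NULL) {
  variantClass <- match.arg(variantClass)
  direction <- match.arg(direction)
  if (is.character(family)) family <- glmFamily(family)
  if (is.null(nMarkers))
    nMarkers <- if (variantClass == "common") 5L else 10L
  if (is.null(mafRange))
    mafRange <- if (variantClass == "common") c(0.05, 0.5) else
      c(0.005, 0.05)
  if (is.null(nCausalRange))
    nCausalRange <- if (variantClass == "common") c(2L, 5L) else c(2L, 10L)
  nCausalRange <- pmin(as.integer(nCausalRange), as.integer(nMarkers))
  if (is.null(includeEtaNoise))
    includeEtaNoise <- family@name == "logistic"
  new("SimulationConfig", nIndividuals = as.integer(nIndividuals),
      nMarkers = as.integer(nMarkers), mafRange = as.numeric(mafRange),
      depth = depth, errorRate = errorRate, family = family,
      nCausalRange = as.integer(nCausalRange), totalEffect = totalEffect,
      direction = direction, includeEtaNoise = includeEtaNoise)
}

#' Simulate true genotypes from a MAF spectrum
#'
#' Draws a per-site MAF uniformly from the configured spectrum, then
#' genotypes as Binomial(2, MAF) independently per individual. An optional
#' LD mode couples adjacent sites by haplotype copying: each of the two
#' haplotypes repeats its allele state from the previous site with
#' probability \code{ld}, drawing fresh otherwise (off by default; the
#' operating characteristics under study depend on depth, error, MAF and
#' effect size rather than fine-scale LD).
#'
#' @param config a [SimulationConfig-class].
#' @param seed optional integer seed.
#' @param ld haplotype copying probability in [0, 1); 0 disables LD.
#' @return list with \code{genotypes} (integer matrix N x dg) and \code{maf}
#'   (the drawn per-site frequencies).
#' @export
simulateGenotypes <- function(config, seed = NULL, ld = 0) {
  if (!is.null(seed)) set.seed(seed)
  N <- config@nIndividuals; dg <- config@nMarkers
  maf <- stats::runif(dg, config@mafRange[1L], config@mafRange[2L])
  if (ld <= 0) {
    g <- matrix(stats::rbinom(N * dg, 2L, rep(maf, each = N)), N, dg)
  } else {
    h1 <- matrix(0L, N, dg); h2 <- matrix(0L, N, dg)
    h1[, 1L] <- stats::rbinom(N, 1L, maf[1L])
    h2[, 1L] <- stats::rbinom(N, 1L, maf[1L])
    for (j in seq_len(dg)[-1L]) {
      copy1 <- stats::rbinom(N, 1L, ld); copy2 <- stats::rbinom(N, 1L, ld)
      fresh1 <- stats::rbinom(N, 1L, maf[j])
      fresh2 <- stats::rbinom(N, 1L, maf[j])
      h1[, j] <- ifelse(copy1 == 1L, h1[, j - 1L], fresh1)
      h2[, j] <- ifelse(copy2 == 1L, h2[, j - 1L], fresh2)
    }
    g <- h1 + h2
  }
  storage.mode(g) <- "integer"
  list(genotypes = g, maf = maf)
}

#' Simulate read pileups over true genotypes
#'
#' Per individual per site, the total read count is Poisson with the mean
#' depth; each read reports the alternate allele with probability
#' (g/2)(1 - e) + (1 - g/2) e under the symmetric base-error model.
#'
#' @param genotypes integer matrix N x dg.
#' @param depth mean coverage.
#' @param errorRate per-base error in (0, 0.5).
#' @param seed optional integer seed.
#' @return list with integer matrices \code{nRef} and \code{nAlt}.
#' @export
simulateReads <- function(genotypes, depth, errorRate = 0.005, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (depth <= 0) stop("depth must be positive")
  n <- length(genotypes)
  tot <- stats::rpois(n, depth)
  pAlt <- genotypes / 2 * (1 - errorRate) +
    (1 - genotypes / 2) * errorRate
  nAlt <- stats::rbinom(n, tot, pAlt)
  d <- dim(genotypes)
  list(nRef = matrix(as.integer(tot - nAlt), d[1L], d[2L]),
       nAlt = matrix(as.integer(nAlt), d[1L], d[2L]))
}

#' Draw a causal-effect architecture
#'
#' Draws the number of causal variants uniformly on the configured integer
#' range, picks the causal sites uniformly without replacement, and assigns
#' each causal variant the effect totalEffect / nCausal (signs randomized
#' when \code{direction = "mixed"}).
#'
#' @param config a [SimulationConfig-class].
#' @param seed optional integer seed.
#' @return list with \code{effects} (length dg, zeros at non-causal sites)
#'   and \code{causalIndex}.
#' @export
drawCausalArchitecture <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dg <- config@nMarkers
  effects <- numeric(dg)
  if (config@totalEffect == 0)
    return(list(effects = effects, causalIndex = integer(0)))
  nc <- if (config@nCausalRange[1L] == config@nCausalRange[2L])
    config@nCausalRange[1L] else
      sample(config@nCausalRange[1L]:config@nCausalRange[2L], 1L)
  idx <- sort(sample.int(dg, nc))
  eff <- rep(config@totalEffect / nc, nc)
  if (config@direction == "mixed")
    eff <- eff * sample(c(-1, 1), nc, replace = TRUE)
  effects[idx] <- eff
  list(effects = effects, causalIndex = idx)
}

#' Simulate covariates X1 ~ Bernoulli(0.5), X2 ~ N(0, 1)
#'
#' @param n sample size.
#' @param seed optional integer seed.
#' @return an n x 2 matrix with columns X1, X2.
#' @export
simulateCovariates <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cbind(X1 = stats::rbinom(n, 1L, 0.5), X2 = stats::rnorm(n))
}

#' Simulate phenotypes from the generative GLM
#'
#' The linear predictor is
#' \eqn{\eta = \beta_0 + \beta_1 X_1 + \beta_2 X_2 + \sum_j \beta_{gj} G_j}
#' with defaults (0, 1, 1), plus an N(0, 1) noise term inside eta when
#' \code{includeEtaNoise} (the binary-phenotype design). Binary phenotypes
#' are Bernoulli(logistic(eta)); counts are Poisson(exp(eta)); continuous
#' phenotypes are N(eta, 1).
#'
#' @param genotypes integer matrix N x dg.
#' @param covariates N x 2 matrix (X1, X2).
#' @param effects per-marker effect vector (length dg).
#' @param family a [GLMFamily-class] or family name.
#' @param includeEtaNoise add N(0, 1) noise inside the linear predictor.
#' @param beta0,betaCov intercept and covariate coefficients.
#' @param seed optional integer seed.
#' @return numeric phenotype vector of length N.
#' @export
simulatePhenotype <- function(genotypes, covariates, effects, family,
                              includeEtaNoise = FALSE, beta0 = 0,
                              betaCov = c(1, 1), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.character(family)) family <- glmFamily(family)
  eta <- beta0 + drop(covariates %*% betaCov) +
    drop(genotypes %*% effects)
  if (includeEtaNoise) eta <- eta + stats::rnorm(length(eta))
  if (family@name == "poisson" && max(eta) > 30)
    stop("Poisson mean overflow (eta > 30); reduce effect sizes")
  switch(family@name,
         gaussian = eta + stats::rnorm(length(eta)),
         logistic = stats::rbinom(length(eta), 1L, stats::plogis(eta)) + 0,
         poisson = stats::rpois(length(eta), exp(eta)) + 0)
}

#' A fully simulated sequencing association study
#'
#' Bundle of true genotypes, read pileups, covariates, phenotype and the
#' causal architecture that generated them.
#'
#' @slot genotypes integer matrix N x dg of true genotypes.
#' @slot nRef,nAlt read-count matrices.
#' @slot covariates N x 2 matrix (X1, X2).
#' @slot phenotype numeric vector of length N.
#' @slot trueAF the drawn per-site allele frequencies.
#' @slot causalIndex,effects the causal architecture.
#' @slot config the generating [SimulationConfig-class].
#' @seealso [simulateDataset()]
#' @exportClass SimulatedDataset
setClass("SimulatedDataset",
         representation(genotypes = "matrix", nRef = "matrix",
                        nAlt = "matrix", covariates = "matrix",
                        phenotype = "numeric", trueAF = "numeric",
                        causalIndex = "integer", effects = "numeric",
                        config = "SimulationConfig"),
         validity = function(object) {
           N <- object@config@nIndividuals
           if (length(object@phenotype) != N)
             return("phenotype length must equal nIndividuals")
           if (!all(object@genotypes %in% 0:2))
             return("genotypes must be 0, 1 or 2")
           TRUE
         })

setMethod("show", "SimulatedDataset", function(object) {
  cat("SimulatedDataset:", nrow(object@genotypes), "individuals x",
      ncol(object@genotypes), "markers;",
      length(object@causalIndex), "causal\n")
  show(object@config)
})

#' @rdname SimulatedDataset-class
#' @param object an object.
#' @export
setGeneric("trueGenotypes", function(object) standardGeneric("trueGenotypes"))
#' @rdname SimulatedDataset-class
#' @export
setMethod("trueGenotypes", "SimulatedDataset",
          function(object) object@genotypes)
#' @rdname SimulatedDataset-class
#' @export
setGeneric("readCounts", function(object) standardGeneric("readCounts"))
#' @rdname SimulatedDataset-class
#' @export
setMethod("readCounts", "SimulatedDataset",
          function(object) list(nRef = object@nRef, nAlt = object@nAlt))
#' @rdname SimulatedDataset-class
#' @export
setGeneric("covariates", function(object) standardGeneric("covariates"))
#' @rdname SimulatedDataset-class
#' @export
setMethod("covariates", "SimulatedDataset",
          function(object) object@covariates)
#' @rdname SimulatedDataset-class
#' @export
setGeneric("phenotype", function(object) standardGeneric("phenotype"))
#' @rdname SimulatedDataset-class
#' @export
setMethod("phenotype", "SimulatedDataset", function(object) object@phenotype)
#' @rdname SimulatedDataset-class
#' @export
setGeneric("trueAF", function(object) standardGeneric("trueAF"))
#' @rdname SimulatedDataset-class
#' @export
setMethod("trueAF", "SimulatedDataset", function(object) object@trueAF)
#' @rdname SimulatedDataset-class
#' @export
setGeneric("causalEffects", function(object) standardGeneric("causalEffects"))
#' @rdname SimulatedDataset-class
#' @export
setMethod("causalEffects", "SimulatedDataset",
          function(object)
            list(causalIndex = object@causalIndex, effects = object@effects))

#' Simulate a complete study from a configuration
#'
#' Runs the full generative pipeline under one seed: MAF spectrum and true
#' genotypes, Poisson-depth reads with base errors, covariates, causal
#' architecture, and the phenotype. The same config and seed reproduce the
#' identical dataset.
#'
#' @param config a [SimulationConfig-class].
#' @param seed optional integer seed for the whole pipeline.
#' @return a [SimulatedDataset-class].
#' @export
simulateDataset <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  gsim <- simulateGenotypes(config)
  reads <- simulateReads(gsim$genotypes, config@depth, config@errorRate)
  covar <- simulateCovariates(config@nIndividuals)
  arch <- drawCausalArchitecture(config)
  y <- simulatePhenotype(gsim$genotypes, covar, arch$effects, config@family,
                         includeEtaNoise = config@includeEtaNoise)
  new("SimulatedDataset", genotypes = gsim$genotypes, nRef = reads$nRef,
      nAlt = reads$nAlt, covariates = covar, phenotype = y,
      trueAF = gsim$maf, causalIndex = as.integer(arch$causalIndex),
      effects = arch$effects, config = config)
}
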