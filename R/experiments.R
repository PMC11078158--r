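# Type I error / power benchmarking over the (sample size x depth x method)
# grid. Each replicate derives its random stream from (seed, cell index,
# replicate index), so results are reproducible and independent of execution
# order.

.replicateSeed <- function(seed, cell, rep) {
  as.integer((as.double(seed) %% 2147483647 * 48271 +
                cell * 99991 + rep * 7919) %% 2147483629 + 1)
}

.ngsMethods <- c("js1", "js2", "js3", "vc1", "vc2", "vc3")
.allMethods <- c(.ngsMethods, "genotype", "burden")

# One grid cell: a matrix of p-values, replicates x methods. NA marks a
# replicate where a method errored.
.cellPvalues <- function(config, methods, nReplicates, seed, cellIndex) {
  stopifnot(all(methods %in% .allMethods))
  fam <- config@family
  P <- matrix(NA_real_, nReplicates, length(methods),
              dimnames = list(NULL, methods))
  needNGS <- any(methods %in% .ngsMethods)
  needCalls <- any(methods %in% c("genotype", "burden"))
  need2 <- any(methods %in% c("js2", "vc2")) || needCalls
  need3 <- any(methods %in% c("js3", "vc3"))
  for (r in seq_len(nReplicates)) {
    sr <- .replicateSeed(seed, cellIndex, r)
    withCallingHandlers({
      ds <- simulateDataset(config, seed = sr)
      gl <- siteLikelihood(ds@nRef, ds@nAlt, config@errorRate)
      x <- cbind(1, ds@covariates)
      y <- ds@phenotype
      nf <- if (needNGS) tryCatch(fitNull(y, x, fam),
                                  error = function(e) NULL) else NULL
      f2 <- if (need2) tryCatch(afTwoStep(gl),
                                error = function(e) NULL) else NULL
      f3 <- if (need3) tryCatch(afEM(gl),
                                error = function(e) NULL) else NULL
      calls <- if (needCalls && !is.null(f2))
        callGenotypes(gl, f2) else NULL
      pOne <- function(m) {
        post <- function(f) {
          if (is.null(f)) stop("allele-frequency estimation failed")
          posteriorMoments(gl, f)
        }
        needFit <- function() if (is.null(nf))
          stop("null fit failed") else nf
        switch(m,
          js1 = pValue(jsTest(y, x, post(ds@trueAF), fam,
                              nullFit = needFit())),
          js2 = pValue(jsTest(y, x, post(f2), fam, nullFit = needFit())),
          js3 = pValue(jsTest(y, x, post(f3), fam, nullFit = needFit())),
          vc1 = pValue(vcTest(y, x, post(ds@trueAF), fam,
                              nullFit = needFit())),
          vc2 = pValue(vcTest(y, x, post(f2), fam, nullFit = needFit())),
          vc3 = pValue(vcTest(y, x, post(f3), fam, nullFit = needFit())),
          genotype = {
            if (is.null(calls)) stop("genotype calling failed")
            pValue(genotypeGroupTest(y, x, calls, fam))
          },
          burden = {
            if (is.null(calls)) stop("genotype calling failed")
            pValue(burdenTest(y, x, calls, fam))
          })
      }
      for (m in methods)
        P[r, m] <- tryCatch(pOne(m), error = function(e) NA_real_)
    }, warning = function(w) invokeRestart("muffleWarning"))
  }
  P
}

.summarizeCell <- function(P, alpha, maxErrorFrac = 0.01) {
  vapply(colnames(P), function(m) {
    p <- P[, m]
    nErr <- sum(is.na(p))
    if (nErr > maxErrorFrac * length(p))
      stop("method '", m, "' errored on ", nErr, " of ", length(p),
           " replicates; cell aborted (silently skipping would bias the ",
           "estimate)")
    est <- mean(p[!is.na(p)] <= alpha)
    c(estimate = est, n = sum(!is.na(p)))
  }, numeric(2))
}

#' Empirical Type I error over a simulation grid
#'
#' For every (sample size, depth) cell, simulates null datasets (no genetic
#' effects) from the configured design, applies each requested testing
#' method, and reports the fraction of p-values at or below \code{alpha}.
#' Methods: \code{"js1"}/\code{"js2"}/\code{"js3"} are the sequencing-based
#' joint significance test using true, two-step and EM allele frequencies;
#' \code{"vc1"}/\code{"vc2"}/\code{"vc3"} the variable collapse test
#' likewise; \code{"genotype"} the genotype-based chi-square group test and
#' \code{"burden"} the genotype-based weighted burden test (both on MAP
#' calls under two-step frequencies).
#'
#' @param family phenotype family name or [GLMFamily-class].
#' @param variantClass \code{"common"} or \code{"rare"}.
#' @param sampleSizes,depths grid of cohort sizes and mean coverages.
#' @param methods subset of the method names above.
#' @param nReplicates null replicates per cell (at least 100).
#' @param alpha nominal level.
#' @param seed master seed; each replicate derives its own stream.
#' @param ... further arguments to [simulationConfig()].
#' @return a data.frame with one row per (cell, method):
#'   \code{sampleSize}, \code{depth}, \code{family}, \code{variantClass},
#'   \code{method}, \code{metric}, \code{estimate},
#'   \code{mcStderr} = sqrt(est(1-est)/n), \code{nReplicates}.
#' @seealso [runPower()]
#' @export
runType1 <- function(family = "logistic", variantClass = "common",
                     sampleSizes = c(300L, 500L, 1000L),
                     depths = c(1, 2, 4, 10),
                     methods = NULL, nReplicates = 2000L, alpha = 0.05,
                     seed = 1L, ...) {
  if (nReplicates < 100L) stop("use at least 100 replicates")
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]")
  if (is.null(methods))
    methods <- if (variantClass == "common")
      c("genotype", "js1", "js2", "js3") else
        c("burden", "vc1", "vc2", "vc3")
  grid <- expand.grid(sampleSize = sampleSizes, depth = depths,
                      KEEP.OUT.ATTRS = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    cfg <- simulationConfig(nIndividuals = grid$sampleSize[i],
                            variantClass = variantClass, family = family,
                            depth = grid$depth[i], totalEffect = 0, ...)
    P <- .cellPvalues(cfg, methods, nReplicates, seed, cellIndex = i)
    sm <- .summarizeCell(P, alpha)
    data.frame(sampleSize = grid$sampleSize[i], depth = grid$depth[i],
               family = cfg@family@name, variantClass = variantClass,
               method = colnames(sm), metric = "type1",
               estimate = sm["estimate", ],
               mcStderr = sqrt(sm["estimate", ] * (1 - sm["estimate", ]) /
                                 sm["n", ]),
               nReplicates = as.integer(sm["n", ]), row.names = NULL)
  }))
  out
}

#' Empirical power over an effect-size grid
#'
#' Like [runType1()] but under the alternative: for each magnitude on the
#' grid the total genetic effect is 0.2 x magnitude, split equally over a
#' causal-variant count drawn per replicate (2-5 common, 2-10 rare), and the
#' rejection fraction per method is recorded. One row per (cell, magnitude,
#' method); magnitude 0 reproduces the Type I error within Monte Carlo
#' error.
#'
#' @inheritParams runType1
#' @param magnitudes effect magnitudes on the 0-5 grid.
#' @return a data.frame as in [runType1()] with additional columns
#'   \code{magnitude} and \code{totalEffect}, metric \code{"power"}.
#' @export
runPower <- function(family = "logistic", variantClass = "common",
                     sampleSizes = 300L, depths = 1,
                     magnitudes = 0:5, methods = NULL,
                     nReplicates = 500L, alpha = 0.05, seed = 1L, ...) {
  if (nReplicates < 100L) stop("use at least 100 replicates")
  if (is.null(methods))
    methods <- if (variantClass == "common")
      c("genotype", "js1", "js2", "js3") else
        c("burden", "vc1", "vc2", "vc3")
  grid <- expand.grid(sampleSize = sampleSizes, depth = depths,
                      magnitude = magnitudes, KEEP.OUT.ATTRS = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    cfg <- simulationConfig(nIndividuals = grid$sampleSize[i],
                            variantClass = variantClass, family = family,
                            depth = grid$depth[i],
                            totalEffect = 0.2 * grid$magnitude[i], ...)
    P <- .cellPvalues(cfg, methods, nReplicates, seed,
                      cellIndex = 1000L + i)
    sm <- .summarizeCell(P, alpha)
    data.frame(sampleSize = grid$sampleSize[i], depth = grid$depth[i],
               magnitude = grid$magnitude[i],
               totalEffect = 0.2 * grid$magnitude[i],
               family = cfg@family@name, variantClass = variantClass,
               method = colnames(sm), metric = "power",
               estimate = sm["estimate", ],
               mcStderr = sqrt(sm["estimate", ] * (1 - sm["estimate", ]) /
                                 sm["n", ]),
               nReplicates = as.integer(sm["n", ]), row.names = NULL)
  }))
  out
}

#' Null p-values for one grid cell
#'
#' Lower-level access to the simulation loop: returns the matrix of
#' per-replicate p-values (replicates x methods) for a single design cell,
#' for calibration diagnostics such as uniformity tests.
#'
#' @inheritParams runType1
#' @param nIndividuals sample size.
#' @param depth mean coverage.
#' @param totalEffect total genetic effect (0 for the null).
#' @return numeric matrix of p-values with one column per method.
#' @export
nullPvalueMatrix <- function(family = "logistic", variantClass = "common",
                             nIndividuals = 300L, depth = 1,
                             methods = "js1", nReplicates = 2000L,
                             seed = 1L, totalEffect = 0, ...) {
  cfg <- simulationConfig(nIndividuals = nIndividuals,
                          variantClass = variantClass, family = family,
                          depth = depth, totalEffect = totalEffect, ...)
  .cellPvalues(cfg, methods, nReplicates, seed, cellIndex = 0L)
}
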