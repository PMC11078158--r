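# Accessor generics: slots are never read directly by user code.

#' @rdname ScoreTestResult-class
#' @param object an object.
#' @export
setGeneric("statistic", function(object) standardGeneric("statistic"))
#' @rdname ScoreTestResult-class
#' @export
setGeneric("pValue", function(object) standardGeneric("pValue"))
#' @rdname ScoreTestResult-class
#' @export
setGeneric("testDf", function(object) standardGeneric("testDf"))
#' @rdname ScoreTestResult-class
#' @export
setGeneric("scoreVector", function(object) standardGeneric("scoreVector"))
#' @rdname ScoreTestResult-class
#' @export
setGeneric("informationMatrix",
           function(object) standardGeneric("informationMatrix"))
#' @rdname ScoreTestResult-class
#' @export
setGeneric("effectiveRank", function(object) standardGeneric("effectiveRank"))
#' @rdname ScoreTestResult-class
#' @export
setGeneric("testNotes", function(object) standardGeneric("testNotes"))

#' @rdname ScoreTestResult-class
#' @export
setMethod("statistic", "ScoreTestResult", function(object) object@statistic)
#' @rdname ScoreTestResult-class
#' @export
setMethod("pValue", "ScoreTestResult", function(object) object@p.value)
#' @rdname ScoreTestResult-class
#' @export
setMethod("testDf", "ScoreTestResult", function(object) object@df)
#' @rdname ScoreTestResult-class
#' @export
setMethod("scoreVector", "ScoreTestResult", function(object) object@score)
#' @rdname ScoreTestResult-class
#' @export
setMethod("informationMatrix", "ScoreTestResult",
          function(object) object@info)
#' @rdname ScoreTestResult-class
#' @export
setMethod("effectiveRank", "ScoreTestResult", function(object) object@rank)
#' @rdname ScoreTestResult-class
#' @export
setMethod("testNotes", "ScoreTestResult", function(object) object@notes)

#' @rdname GenotypeLikelihoods-class
#' @param object an object.
#' @export
setGeneric("nSamples", function(object) standardGeneric("nSamples"))
#' @rdname GenotypeLikelihoods-class
#' @export
setGeneric("nSites", function(object) standardGeneric("nSites"))
#' @rdname GenotypeLikelihoods-class
#' @param g genotype value 0, 1 or 2.
#' @export
setGeneric("likelihoodMatrix",
           function(object, g) standardGeneric("likelihoodMatrix"))

#' @rdname GenotypeLikelihoods-class
#' @export
setMethod("nSamples", "GenotypeLikelihoods",
          function(object) nrow(object@l0))
#' @rdname GenotypeLikelihoods-class
#' @export
setMethod("nSites", "GenotypeLikelihoods", function(object) ncol(object@l0))
#' @rdname GenotypeLikelihoods-class
#' @export
setMethod("likelihoodMatrix", "GenotypeLikelihoods", function(object, g) {
  stopifnot(g %in% 0:2)
  switch(as.character(g), "0" = object@l0, "1" = object@l1, "2" = object@l2)
})
#' @rdname GenotypeLikelihoods-class
#' @export
setGeneric("siteIDs", function(object) standardGeneric("siteIDs"))
#' @rdname GenotypeLikelihoods-class
#' @export
setMethod("siteIDs", "GenotypeLikelihoods", function(object) object@siteIDs)
#' @rdname GenotypeLikelihoods-class
#' @export
setGeneric("sampleIDs", function(object) standardGeneric("sampleIDs"))
#' @rdname GenotypeLikelihoods-class
#' @export
setMethod("sampleIDs", "GenotypeLikelihoods", function(object) object@sampleIDs)

#' @rdname SitePosterior-class
#' @param object an object.
#' @export
setGeneric("dosage", function(object) standardGeneric("dosage"))
#' @rdname SitePosterior-class
#' @export
setMethod("dosage", "SitePosterior", function(object) object@eg)

#' @rdname SitePosterior-class
#' @export
setGeneric("dosageSecondMoment",
           function(object) standardGeneric("dosageSecondMoment"))
#' @rdname SitePosterior-class
#' @export
setMethod("dosageSecondMoment", "SitePosterior",
          function(object) object@eggDiag)

#' Materialize E[g^T g | D_i] for one individual
#'
#' Under the cross-site factorization the dg x dg posterior second-moment
#' matrix has off-diagonal entries eg[j] * eg[k] and diagonal E[g_j^2 | D_i].
#'
#' @param object a [SitePosterior-class].
#' @param i individual index.
#' @return a symmetric dg x dg matrix.
#' @export
setGeneric("egg", function(object, i) standardGeneric("egg"))
#' @rdname egg
#' @export
setMethod("egg", "SitePosterior", function(object, i) {
  e <- object@eg[i, ]
  m <- tcrossprod(e)
  diag(m) <- object@eggDiag[i, ]
  m
})

#' @rdname AlleleFrequencies-class
#' @param object an object.
#' @export
setGeneric("alleleFreq", function(object) standardGeneric("alleleFreq"))
#' @rdname AlleleFrequencies-class
#' @export
setMethod("alleleFreq", "AlleleFrequencies", function(object) object@f)
#' @rdname AlleleFrequencies-class
#' @export
setGeneric("afMethod", function(object) standardGeneric("afMethod"))
#' @rdname AlleleFrequencies-class
#' @export
setMethod("afMethod", "AlleleFrequencies", function(object) object@method)
#' @rdname AlleleFrequencies-class
#' @export
setGeneric("degenerateSites",
           function(object) standardGeneric("degenerateSites"))
#' @rdname AlleleFrequencies-class
#' @export
setMethod("degenerateSites", "AlleleFrequencies",
          function(object) object@degenerate)

#' @rdname NullFit-class
#' @param object an object.
#' @export
setGeneric("nullCoef", function(object) standardGeneric("nullCoef"))
#' @rdname NullFit-class
#' @export
setMethod("nullCoef", "NullFit", function(object) object@alpha)
#' @rdname NullFit-class
#' @export
setGeneric("nullDispersion",
           function(object) standardGeneric("nullDispersion"))
#' @rdname NullFit-class
#' @export
setMethod("nullDispersion", "NullFit", function(object) object@phi)
#' @rdname NullFit-class
#' @export
setGeneric("nullLogLik", function(object) standardGeneric("nullLogLik"))
#' @rdname NullFit-class
#' @export
setMethod("nullLogLik", "NullFit", function(object) object@logLik)
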