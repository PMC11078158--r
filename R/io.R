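#' Read a BEAGLE genotype-likelihood text file
#'
#' The BEAGLE GL format is a whitespace-separated table with one row per
#' marker: columns \code{marker}, \code{allele1}, \code{allele2}, then three
#' likelihood columns per individual, ordered p(D | g = 0), p(D | g = 1),
#' p(D | g = 2) with g counting copies of \code{allele2}. The header row
#' repeats each sample identifier three times.
#'
#' @param path file path.
#' @return a [GenotypeLikelihoods-class] (individuals x markers).
#' @seealso [writeBeagleGL()]
#' @export
readBeagleGL <- function(path) {
  tab <- utils::read.table(path, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 6L || (ncol(tab) - 3L) %% 3L != 0L)
    stop("not a BEAGLE GL table: need 3 marker columns + 3 per individual")
  nInd <- (ncol(tab) - 3L) %/% 3L
  markers <- as.character(tab[[1L]])
  samples <- unique(names(tab)[-(1:3)])
  if (length(samples) != nInd)
    samples <- paste0("ind", seq_len(nInd))
  gmat <- as.matrix(tab[, -(1:3), drop = FALSE])
  storage.mode(gmat) <- "double"
  idx0 <- seq(1L, by = 3L, length.out = nInd)
  # rows = markers in file; transpose to individuals x markers
  genotypeLikelihoods(t(gmat[, idx0, drop = FALSE]),
                      t(gmat[, idx0 + 1L, drop = FALSE]),
                      t(gmat[, idx0 + 2L, drop = FALSE]),
                      siteIDs = markers, sampleIDs = samples)
}

#' Write genotype likelihoods in BEAGLE GL format
#'
#' Likelihood triples are normalized to sum to one per marker per individual
#' before writing, the convention of BEAGLE GL producers; the tests are
#' invariant to this rescaling.
#'
#' @param gl a [GenotypeLikelihoods-class].
#' @param path output file path.
#' @param alleles length-2 character vector written as allele1/allele2 for
#'   every marker (allele coding, e.g. \code{c("0", "1")}).
#' @return \code{path}, invisibly.
#' @export
writeBeagleGL <- function(gl, path, alleles = c("0", "1")) {
  stopifnot(is(gl, "GenotypeLikelihoods"))
  tot <- gl@l0 + gl@l1 + gl@l2
  n0 <- gl@l0 / tot; n1 <- gl@l1 / tot; n2 <- gl@l2 / tot
  nInd <- nSamples(gl); dg <- nSites(gl)
  out <- matrix(0, nrow = dg, ncol = 3L * nInd)
  idx0 <- seq(1L, by = 3L, length.out = nInd)
  out[, idx0] <- t(n0); out[, idx0 + 1L] <- t(n1); out[, idx0 + 2L] <- t(n2)
  header <- c("marker", "allele1", "allele2", rep(sampleIDs(gl), each = 3L))
  body <- cbind(siteIDs(gl), alleles[1L], alleles[2L],
                format(out, digits = 6, trim = TRUE, scientific = FALSE))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(header, collapse = "\t"), con)
  writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read genotype likelihoods from a VCF with GL or PL FORMAT fields
#'
#' Biallelic records only; multiallelic records abort with an error rather
#' than being silently split. GL fields (log10-scaled likelihoods) are
#' converted via 10^GL and PL fields (phred-scaled) via 10^(-PL/10). Sites
#' are identified as CHROM:POS for matching against group definitions.
#' Requires the VariantAnnotation package.
#'
#' @param path path to a VCF file (plain text or bgzipped).
#' @param genome genome label passed to the VCF reader (metadata only).
#' @return a [GenotypeLikelihoods-class] with siteIDs "CHROM:POS".
#' @export
readVcfGL <- function(path, genome = "unknown") {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("readVcfGL requires the VariantAnnotation package")
  vcf <- VariantAnnotation::readVcf(path, genome = genome)
  alt <- VariantAnnotation::alt(vcf)
  if (any(lengths(alt) != 1L))
    stop("multiallelic VCF records are not supported; ",
         "normalize to biallelic sites first")
  gen <- VariantAnnotation::geno(vcf)
  if ("GL" %in% names(gen)) {
    arr <- gen$GL
    conv <- function(v) 10^v
  } else if ("PL" %in% names(gen)) {
    arr <- gen$PL
    conv <- function(v) 10^(-v / 10)
  } else {
    stop("VCF has neither GL nor PL FORMAT fields")
  }
  rr <- SummarizedExperiment::rowRanges(vcf)
  sites <- paste0(as.character(GenomicRanges::seqnames(rr)), ":",
                  GenomicRanges::start(rr))
  samples <- colnames(vcf)
  nSite <- length(sites); nInd <- length(samples)
  l <- array(NA_real_, dim = c(nSite, nInd, 3L))
  if (is.list(arr) || is(arr, "List")) {
    # site x sample matrix of numeric triples
    for (j in seq_len(nSite)) for (i in seq_len(nInd)) {
      v <- arr[[j, i]]
      if (length(v) != 3L)
        stop("expected 3 likelihood values per genotype at ", sites[j])
      l[j, i, ] <- conv(v)
    }
  } else {
    if (dim(arr)[3L] != 3L)
      stop("expected 3 likelihood values per genotype")
    l[] <- conv(arr)
  }
  # missing triples are flat (no information)
  miss <- is.na(l[, , 1L]) | is.na(l[, , 2L]) | is.na(l[, , 3L])
  for (k in 1:3) { lk <- l[, , k]; lk[miss] <- 1; l[, , k] <- lk }
  sliceT <- function(k) t(matrix(l[, , k], nSite, nInd))
  genotypeLikelihoods(sliceT(1L), sliceT(2L), sliceT(3L),
                      siteIDs = sites, sampleIDs = samples)
}

#' Read marker-group definitions
#'
#' A two-column TSV (with header) mapping \code{group_id} to \code{site_id};
#' site identifiers must match the site IDs of the likelihood source
#' (marker names for BEAGLE input, CHROM:POS for VCF input).
#'
#' @param path file path.
#' @return a named list of character vectors of site IDs, one per group.
#' @export
readGroupFile <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("group file needs columns group_id, site_id")
  split(as.character(tab[[2L]]), as.character(tab[[1L]]))
}

#' Subset genotype likelihoods to a set of sites
#'
#' @param gl a [GenotypeLikelihoods-class].
#' @param sites character vector of site IDs (order preserved).
#' @return a [GenotypeLikelihoods-class] restricted to \code{sites}.
#' @export
subsetSites <- function(gl, sites) {
  idx <- match(sites, siteIDs(gl))
  if (anyNA(idx))
    stop("sites not present in likelihood data: ",
         paste(sites[is.na(idx)], collapse = ", "))
  genotypeLikelihoods(gl@l0[, idx, drop = FALSE],
                      gl@l1[, idx, drop = FALSE],
                      gl@l2[, idx, drop = FALSE],
                      siteIDs = siteIDs(gl)[idx], sampleIDs = sampleIDs(gl))
}
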