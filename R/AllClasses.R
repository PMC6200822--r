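#' Class "ValidationMatrix": PCR validation results for markers x taxa
#'
#' Cells hold `1L` (success, a single target band), `0L` (failure) or `NA`
#' (reaction not attempted). Row names are marker ids; column names are
#' species; each species carries an order label used for per-order success
#' summaries.
#'
#' @slot cells integer matrix, markers x taxa, values in {1, 0, NA}.
#' @slot orders character vector, one taxonomic order per column of `cells`.
#' @exportClass ValidationMatrix
setClass("ValidationMatrix",
  representation(cells = "matrix", orders = "character"),
  validity = function(object) {
    msg <- character()
    if (!is.integer(object@cells)) msg <- c(msg, "cells must be integer")
    if (length(object@orders) != ncol(object@cells))
      msg <- c(msg, "one order label per taxon column required")
    bad <- stats::na.omit(unique(as.vector(object@cells)))
    if (length(setdiff(bad, c(0L, 1L))))
      msg <- c(msg, "cells must be 1 (success), 0 (failure) or NA")
    if (is.null(rownames(object@cells)) || is.null(colnames(object@cells)))
      msg <- c(msg, "cells needs marker rownames and species colnames")
    if (length(msg)) msg else TRUE
  })

#' Class "MarkerPanel": PCR success-rate summary and universal marker set
#'
#' Produced by [summarizeValidation()]. PSR (PCR success rate) is the
#' fraction of attempted reactions that produced a single target band.
#'
#' @slot perMarker data.frame with marker, n_success, n_failure,
#'   n_not_attempted, psr.
#' @slot perOrder data.frame with order, n_success, n_attempted, psr.
#' @slot overallPSR numeric, successes / attempted over all cells.
#' @slot panel character, markers whose PSR meets the threshold.
#' @slot threshold numeric, PSR cutoff defining the universal panel.
#' @exportClass MarkerPanel
setClass("MarkerPanel",
  representation(perMarker = "data.frame", perOrder = "data.frame",
                 overallPSR = "numeric", panel = "character",
                 threshold = "numeric"))

#' Class "DistanceSummary": overall mean pairwise distance for one locus
#'
#' @slot locusId character scalar.
#' @slot model one of "p", "JC69", "K2P".
#' @slot dMean overall mean pairwise distance (substitutions/site).
#' @slot bootstrapSE standard error from site (column) bootstrap.
#' @slot nTaxa number of sequences.
#' @slot nSitesUsed mean number of comparable sites per pair after
#'   pairwise deletion of columns containing N or '-'.
#' @slot nBootstrap number of bootstrap replicates used.
#' @exportClass DistanceSummary
setClass("DistanceSummary",
  representation(locusId = "character", model = "character",
                 dMean = "numeric", bootstrapSE = "numeric",
                 nTaxa = "integer", nSitesUsed = "numeric",
                 nBootstrap = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@dMean < 0) msg <- c(msg, "dMean must be >= 0")
    if (object@bootstrapSE < 0) msg <- c(msg, "bootstrapSE must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' Class "RateEstimate": cyt-b-calibrated substitution rate for one locus
#'
#' The locus rate is the ratio of its overall mean distance to that of
#' cytochrome b on the same taxa, multiplied by the reference cyt-b rate
#' (default 0.01035 substitutions/site/million years).
#'
#' @slot locusId character scalar.
#' @slot ratio dimensionless distance ratio d_locus / d_cytb.
#' @slot mu calibrated rate, substitutions/site/My.
#' @slot referenceRate the cyt-b rate used, substitutions/site/My.
#' @exportClass RateEstimate
setClass("RateEstimate",
  representation(locusId = "character", ratio = "numeric", mu = "numeric",
                 referenceRate = "numeric"),
  validity = function(object) {
    if (object@mu < 0) "mu must be >= 0" else TRUE
  })

#' Class "HaplotypeAlignment": phased haplotypes for one locus/population
#'
#' The input contract for polymorphism statistics: phased haplotypes of
#' equal length (two per diploid individual for nuclear loci, one for
#' mtDNA).
#'
#' @slot seqs DNAStringSet of equal-width haplotypes.
#' @slot locusId character scalar.
#' @slot populationId character scalar.
#' @slot ploidy integer, haplotypes per individual (2 nuclear, 1 mtDNA).
#' @exportClass HaplotypeAlignment
setClass("HaplotypeAlignment",
  representation(seqs = "DNAStringSet", locusId = "character",
                 populationId = "character", ploidy = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@seqs) < 2L) msg <- c(msg, "need n >= 2 haplotypes")
    if (length(unique(Biostrings::width(object@seqs))) > 1L)
      msg <- c(msg, "haplotypes must have equal length")
    if (length(msg)) msg else TRUE
  })

#' Class "PopGenStats": polymorphism summary for one haplotype alignment
#'
#' @slot locusId,populationId identifiers copied from the input.
#' @slot n number of haplotypes.
#' @slot L alignment length (columns).
#' @slot S segregating sites (columns with >= 2 distinct A/C/G/T bases).
#' @slot H number of distinct haplotypes.
#' @slot Hd haplotype diversity with the n/(n-1) correction.
#' @slot kHat mean pairwise differences (sites), pairwise deletion.
#' @slot piPerSite nucleotide diversity per site, kHat / mean comparable
#'   sites.
#' @slot tajimaD Tajima's D, or NA when S = 0 or n < 4.
#' @exportClass PopGenStats
setClass("PopGenStats",
  representation(locusId = "character", populationId = "character",
                 n = "integer", L = "integer", S = "integer", H = "integer",
                 Hd = "numeric", kHat = "numeric", piPerSite = "numeric",
                 tajimaD = "numeric"))

#' Class "HKAResult": multilocus Hudson-Kreitman-Aguade test
#'
#' @slot table data.frame with per-locus observed and expected polymorphism
#'   (S) and divergence (D) and their model variances.
#' @slot thetaSite fitted per-site population mutation parameters.
#' @slot thetaLocus fitted per-locus theta (thetaSite x polymorphism
#'   length).
#' @slot T fitted scaled divergence time (units of 2N generations).
#' @slot X2 goodness-of-fit statistic at the fitted parameters.
#' @slot df degrees of freedom, 2L - (L + 1) = L - 1.
#' @slot pValue chi-square upper-tail probability.
#' @slot convergence optimizer convergence code (0 = converged).
#' @exportClass HKAResult
setClass("HKAResult",
  representation(table = "data.frame", thetaSite = "numeric",
                 thetaLocus = "numeric", T = "numeric", X2 = "numeric",
                 df = "integer", pValue = "numeric",
                 convergence = "integer"),
  validity = function(object) {
    if (object@X2 < -1e-9) "X2 must be >= 0" else TRUE
  })

#' Class "SuperMatrix": partitioned concatenation of locus alignments
#'
#' Rows are taxa, columns are alignment sites; the partition table maps
#' each locus to its column span. Taxa missing a locus are padded with
#' '-'.
#'
#' @slot matrix character matrix (taxa x sites) of single characters.
#' @slot partitions data.frame with locus, start, end (1-based inclusive).
#' @exportClass SuperMatrix
setClass("SuperMatrix",
  representation(matrix = "matrix", partitions = "data.frame"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@partitions) &&
        ncol(object@matrix) != max(object@partitions$end))
      msg <- c(msg, "column count must equal total partition span")
    if (is.null(rownames(object@matrix)))
      msg <- c(msg, "matrix needs taxon rownames")
    if (length(msg)) msg else TRUE
  })

setMethod("show", "ValidationMatrix", function(object) {
  att <- sum(!is.na(object@cells))
  cat("ValidationMatrix:", nrow(object@cells), "markers x",
      ncol(object@cells), "taxa (", length(unique(object@orders)),
      "orders )\n  attempted:", att, " successes:",
      sum(object@cells == 1L, na.rm = TRUE), "\n")
})

setMethod("show", "MarkerPanel", function(object) {
  cat("MarkerPanel: overall PSR", sprintf("%.1f%%", 100 * object@overallPSR),
      "|", length(object@panel), "markers with PSR >=",
      sprintf("%.0f%%", 100 * object@threshold), "\n")
})

setMethod("show", "DistanceSummary", function(object) {
  cat(sprintf("DistanceSummary [%s] model=%s d=%.5f se=%.5f (n=%d taxa, %.0f sites, %d bootstraps)\n",
              object@locusId, object@model, object@dMean,
              object@bootstrapSE, object@nTaxa, object@nSitesUsed,
              object@nBootstrap))
})

setMethod("show", "RateEstimate", function(object) {
  cat(sprintf("RateEstimate [%s] ratio=%.4f mu=%.6f subst/site/My (ref %.5f)\n",
              object@locusId, object@ratio, object@mu,
              object@referenceRate))
})

setMethod("show", "HaplotypeAlignment", function(object) {
  cat(sprintf("HaplotypeAlignment [%s/%s] %d haplotypes x %d bp (ploidy %d)\n",
              object@locusId, object@populationId, length(object@seqs),
              Biostrings::width(object@seqs)[1], object@ploidy))
})

setMethod("show", "PopGenStats", function(object) {
  cat(sprintf("PopGenStats [%s/%s] n=%d L=%d S=%d H=%d Hd=%.3f pi=%.5f D=%s\n",
              object@locusId, object@populationId, object@n, object@L,
              object@S, object@H, object@Hd, object@piPerSite,
              ifelse(is.na(object@tajimaD), "NA",
                     sprintf("%.3f", object@tajimaD))))
})

setMethod("show", "HKAResult", function(object) {
  cat(sprintf("HKAResult: %d loci, X2=%.4f df=%d p=%.4f T=%.3f\n",
              nrow(object@table), object@X2, object@df, object@pValue,
              object@T))
})

setMethod("show", "SuperMatrix", function(object) {
  cat("SuperMatrix:", nrow(object@matrix), "taxa x", ncol(object@matrix),
      "columns in", nrow(object@partitions), "partitions\n")
})
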