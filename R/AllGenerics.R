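# Accessor generics: slot access stays behind these in user code.

#' Accessors for pipeline result objects
#'
#' Small accessor family for the S4 result containers: `locusId()` returns
#' the locus identifier; `dMean()` and `bootstrapSE()` the overall mean
#' distance and its site-bootstrap standard error; `muRate()` and
#' `distanceRatio()` the calibrated rate (substitutions/site/My) and the
#' locus/cyt-b distance ratio; `overallPSR()`, `perMarkerPSR()` and
#' `panelMarkers()` the validation-matrix summaries; `lociPartitions()`
#' the partition table of a supermatrix; `haplotypes()` the sequences of a
#' haplotype alignment; `tajimaD()` Tajima's D; `hkaTable()` the per-locus
#' HKA table.
#'
#' @param x a result object from this package.
#' @return The corresponding component (scalar, vector or data.frame).
#' @name accessors
#' @aliases locusId dMean bootstrapSE muRate distanceRatio overallPSR
#'   perMarkerPSR panelMarkers lociPartitions haplotypes tajimaD hkaTable
#' @examples
#' a <- Biostrings::DNAStringSet(c(s1 = "ACGTACGT", s2 = "ACGAACGT"))
#' ds <- overallMeanDistance(a, locusId = "toy", bootstrapReps = 10, seed = 1)
#' dMean(ds)
NULL

#' @rdname accessors
#' @export
setGeneric("locusId", function(x) standardGeneric("locusId"))
#' @rdname accessors
#' @export
setGeneric("dMean", function(x) standardGeneric("dMean"))
#' @rdname accessors
#' @export
setGeneric("bootstrapSE", function(x) standardGeneric("bootstrapSE"))
#' @rdname accessors
#' @export
setGeneric("muRate", function(x) standardGeneric("muRate"))
#' @rdname accessors
#' @export
setGeneric("distanceRatio", function(x) standardGeneric("distanceRatio"))
#' @rdname accessors
#' @export
setGeneric("overallPSR", function(x) standardGeneric("overallPSR"))
#' @rdname accessors
#' @export
setGeneric("perMarkerPSR", function(x) standardGeneric("perMarkerPSR"))
#' @rdname accessors
#' @export
setGeneric("panelMarkers", function(x) standardGeneric("panelMarkers"))
#' @rdname accessors
#' @export
setGeneric("lociPartitions", function(x) standardGeneric("lociPartitions"))
#' @rdname accessors
#' @export
setGeneric("haplotypes", function(x) standardGeneric("haplotypes"))
#' @rdname accessors
#' @export
setGeneric("tajimaD", function(x) standardGeneric("tajimaD"))
#' @rdname accessors
#' @export
setGeneric("hkaTable", function(x) standardGeneric("hkaTable"))

#' @rdname accessors
setMethod("locusId", "DistanceSummary", function(x) x@locusId)
#' @rdname accessors
setMethod("locusId", "RateEstimate", function(x) x@locusId)
#' @rdname accessors
setMethod("locusId", "PopGenStats", function(x) x@locusId)
#' @rdname accessors
setMethod("locusId", "HaplotypeAlignment", function(x) x@locusId)
#' @rdname accessors
setMethod("dMean", "DistanceSummary", function(x) x@dMean)
#' @rdname accessors
setMethod("bootstrapSE", "DistanceSummary", function(x) x@bootstrapSE)
#' @rdname accessors
setMethod("muRate", "RateEstimate", function(x) x@mu)
#' @rdname accessors
setMethod("distanceRatio", "RateEstimate", function(x) x@ratio)
#' @rdname accessors
setMethod("overallPSR", "MarkerPanel", function(x) x@overallPSR)
#' @rdname accessors
setMethod("perMarkerPSR", "MarkerPanel", function(x) x@perMarker)
#' @rdname accessors
setMethod("panelMarkers", "MarkerPanel", function(x) x@panel)
#' @rdname accessors
setMethod("lociPartitions", "SuperMatrix", function(x) x@partitions)
#' @rdname accessors
setMethod("haplotypes", "HaplotypeAlignment", function(x) x@seqs)
#' @rdname accessors
setMethod("tajimaD", "PopGenStats", function(x) x@tajimaD)
#' @rdname accessors
setMethod("hkaTable", "HKAResult", function(x) x@table)

#' @describeIn accessors character matrix (taxa x sites) of a SuperMatrix.
#' @export
setMethod("as.matrix", "SuperMatrix", function(x, ...) x@matrix)
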