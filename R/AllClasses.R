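#' @import methods
#' @importFrom GenomicRanges GRanges seqnames start end
#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet
#' @importFrom S4Vectors DataFrame metadata
NULL

#' HervReference: a catalogue of autonomous HERV loci with sequences
#'
#' Holds the locus coordinate model used throughout the package: one
#' genomic range per autonomous HERV locus (1-based, inclusive; BED input
#' is converted on import) together with its nucleotide sequence. Locus
#' identifiers have the display form \code{"Chr3:46046256-46054342"}.
#'
#' @slot ranges a \link[GenomicRanges]{GRanges} of locus coordinates, named
#'   by locus identifier.
#' @slot sequences a \link[Biostrings]{DNAStringSet} of locus sequences,
#'   parallel to \code{ranges} and carrying the same names.
#'
#' @seealso [readLocusReference()], [makeReference()], [tileWindows()]
#' @export
setClass("HervReference",
    representation(ranges = "GRanges", sequences = "DNAStringSet"))

setValidity("HervReference", function(object) {
    msg <- NULL
    if (length(object@ranges) != length(object@sequences))
        msg <- c(msg, "ranges and sequences must have equal length")
    else {
        if (!identical(names(object@ranges), names(object@sequences)))
            msg <- c(msg, "ranges and sequences must carry identical names")
        if (anyDuplicated(names(object@ranges)))
            msg <- c(msg, "duplicate locus identifiers")
        bad <- GenomicRanges::width(object@ranges) !=
            Biostrings::width(object@sequences)
        if (any(bad))
            msg <- c(msg, paste0("sequence length does not match interval ",
                "length for: ",
                paste(head(names(object@ranges)[bad], 3), collapse = ", ")))
    }
    if (is.null(msg)) TRUE else msg
})

#' WindowCoverage: per-window read depths for one locus in one library
#'
#' The per-locus vector of mean per-base read depths across the sequential
#' non-overlapping windows of the locus, for one (sample, cell type, run)
#' combination. Produced by [computeWindowCoverage()] and consumed by
#' [callLocus()].
#'
#' @slot locusId,sampleId,cellType,runId character scalars identifying the
#'   locus and library (may be \code{NA} for ad hoc vectors).
#' @slot depths numeric vector, one mean per-base depth per full window.
#' @slot windowSize integer, window width in bp.
#' @slot nReads integer, number of identity-filtered alignments that
#'   contributed.
#'
#' @export
setClass("WindowCoverage",
    representation(locusId = "character", sampleId = "character",
        cellType = "character", runId = "character", depths = "numeric",
        windowSize = "integer", nReads = "integer"))

setValidity("WindowCoverage", function(object) {
    if (any(object@depths < 0)) "window depths must be non-negative"
    else if (object@windowSize < 1L) "windowSize must be >= 1"
    else TRUE
})

#' CohortMatrix: loci-by-samples presence/absence for one cell type
#'
#' Positive/negative status of HERV loci across the samples of a cohort,
#' for a single cell type, after control-exclusion filtering. Rows are
#' ordered by detection count (number of positive samples) descending,
#' ties broken by genomic position.
#'
#' @slot cellType character scalar.
#' @slot status logical matrix, loci in rows (names are locus identifiers),
#'   samples in columns; \code{TRUE} means a positive call.
#' @slot detectionCount integer vector parallel to the rows.
#'
#' @seealso [filterPatientLoci()], [rankAndSelectTop()],
#'   [writePresenceMatrix()]
#' @export
setClass("CohortMatrix",
    representation(cellType = "character", status = "matrix",
        detectionCount = "integer"))

setValidity("CohortMatrix", function(object) {
    msg <- NULL
    if (!is.logical(object@status))
        msg <- c(msg, "status must be a logical matrix")
    if (length(object@detectionCount) != nrow(object@status))
        msg <- c(msg, "detectionCount must have one entry per locus row")
    else if (nrow(object@status) &&
             !identical(unname(object@detectionCount),
                        unname(as.integer(rowSums(object@status)))))
        msg <- c(msg, "detectionCount must equal the row sums of status")
    if (is.null(msg)) TRUE else msg
})
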