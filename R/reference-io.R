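#' Load a HERV locus reference from FASTA and BED
#'
#' Reads locus coordinates from a BED file (0-based half-open, per the BED
#' standard) and locus sequences from a FASTA file, and assembles them into
#' a [HervReference-class]. Coordinates are converted to the 1-based
#' inclusive display convention used by locus identifiers. FASTA entries
#' are matched to BED records either by the BED name column or by the
#' derived locus identifier.
#'
#' @param fastaPath path to the locus FASTA file.
#' @param bedPath path to the BED3+ file of locus coordinates.
#' @return a [HervReference-class] with one locus per BED record.
#' @details A BED record with no matching FASTA entry, or whose FASTA
#'   sequence length differs from the interval length, is a hard error
#'   naming the offending record.
#' @examples
#' ref <- makeReference(simConfig(seed = 1, nLoci = 3))
#' fa <- tempfile(fileext = ".fa"); bed <- tempfile(fileext = ".bed")
#' writeReference(ref, fa, bed)
#' readLocusReference(fa, bed)
#' @export
readLocusReference <- function(fastaPath, bedPath) {
    gr <- rtracklayer::import(bedPath, format = "BED")
    seqs <- Biostrings::readDNAStringSet(fastaPath)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    if (length(gr) == 0L)
        return(newHervReference(gr, seqs[0]))
    ids <- formatLocusId(as.character(GenomicRanges::seqnames(gr)),
                         GenomicRanges::start(gr), GenomicRanges::end(gr))
    key <- if (!is.null(gr$name) && all(!is.na(gr$name)) &&
               all(gr$name %in% names(seqs))) gr$name else ids
    missing <- !(key %in% names(seqs))
    if (any(missing))
        stop("no FASTA sequence for BED record ",
             paste(head(ids[missing], 3), collapse = ", "))
    seqs <- seqs[key]
    names(seqs) <- ids
    names(gr) <- ids
    bad <- Biostrings::width(seqs) != GenomicRanges::width(gr)
    if (any(bad))
        stop("sequence length does not match interval length for ",
             paste(head(ids[bad], 3), collapse = ", "))
    newHervReference(gr, seqs)
}

newHervReference <- function(gr, seqs) {
    if (is.null(names(gr))) names(gr) <- character(length(gr))
    if (is.null(names(seqs))) names(seqs) <- character(length(seqs))
    new("HervReference", ranges = gr, sequences = seqs)
}

#' Write a HervReference back to FASTA and BED
#'
#' The inverse of [readLocusReference()]: BED output is 0-based half-open
#' and carries the locus identifier in the name column; FASTA entries are
#' keyed by locus identifier. A written reference re-read through
#' [readLocusReference()] is identical.
#'
#' @param ref a [HervReference-class].
#' @param fastaPath,bedPath output paths.
#' @return invisibly, the input `ref`.
#' @export
writeReference <- function(ref, fastaPath, bedPath) {
    gr <- ref@ranges
    bed <- data.frame(
        chrom = as.character(GenomicRanges::seqnames(gr)),
        start = GenomicRanges::start(gr) - 1L,
        end = GenomicRanges::end(gr),
        name = names(gr))
    utils::write.table(bed, bedPath, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    Biostrings::writeXStringSet(ref@sequences, fastaPath)
    invisible(ref)
}

#' @rdname HervReference-accessors
#' @name HervReference-accessors
#' @title Accessors for HervReference objects
#' @param x a [HervReference-class].
#' @aliases locusIds,HervReference-method
#' @export
setMethod("locusIds", "HervReference", function(x) names(x@ranges))

#' @rdname HervReference-accessors
#' @export
setMethod("locusRanges", "HervReference", function(x) x@ranges)

#' @rdname HervReference-accessors
#' @export
setMethod("locusSequences", "HervReference", function(x) x@sequences)

#' @rdname HervReference-accessors
#' @export
setMethod("locusLengths", "HervReference", function(x) {
    stats::setNames(GenomicRanges::width(x@ranges), names(x@ranges))
})

#' @rdname HervReference-accessors
#' @export
setMethod("length", "HervReference", function(x) length(x@ranges))

#' @rdname HervReference-accessors
#' @param i index or locus identifier
#' @param j,drop,... ignored
#' @export
setMethod("[", "HervReference", function(x, i, j, ..., drop = TRUE) {
    newHervReference(x@ranges[i], x@sequences[i])
})

setMethod("show", "HervReference", function(object) {
    cat("HervReference with", length(object), "loci\n")
    if (length(object)) {
        n <- min(length(object), 5L)
        cat(paste0("  ", locusIds(object)[seq_len(n)],
                   " (", locusLengths(object)[seq_len(n)], " bp)"),
            sep = "\n")
        if (length(object) > n) cat("  ...\n")
    }
})

#' Read per-cell annotations from a TSV
#'
#' Reads a barcode-to-cell-type annotation table of the kind produced by
#' reference-guided annotation workflows (one row per cell barcode with a
#' cell-type label and a mapping confidence score in [0, 1]).
#'
#' @param tsvPath path to a TSV with columns `barcode`, `cell_type` and
#'   optionally `mapping_score`. A missing `mapping_score` column is
#'   imputed as 1.0 with a warning.
#' @param minMappingScore rows with `mapping_score` below this value are
#'   dropped; the default 0 keeps everything, since the score is consumed
#'   for annotation-consistency assessment rather than filtering.
#' @param cellTypeVocabulary declared cell-type labels; labels outside it
#'   are kept with a warning.
#' @return data.frame with columns `barcode`, `cell_type`,
#'   `mapping_score`. Duplicate barcodes are a hard error.
#' @export
readCellAnnotations <- function(tsvPath, minMappingScore = 0,
                                cellTypeVocabulary = pbmcCellTypes()) {
    ann <- utils::read.delim(tsvPath, stringsAsFactors = FALSE)
    need <- c("barcode", "cell_type")
    if (!all(need %in% names(ann)))
        stop("annotation TSV must have columns barcode and cell_type")
    if (!"mapping_score" %in% names(ann)) {
        warning("no mapping_score column; imputing 1.0")
        ann$mapping_score <- 1.0
    }
    if (anyDuplicated(ann$barcode))
        stop("duplicate barcode(s) in annotation table: ",
             ann$barcode[which(duplicated(ann$barcode))[1L]])
    unknown <- setdiff(unique(ann$cell_type), cellTypeVocabulary)
    if (length(unknown))
        warning("cell type label(s) outside declared vocabulary: ",
                paste(unknown, collapse = ", "))
    ann[ann$mapping_score >= minMappingScore,
        c("barcode", "cell_type", "mapping_score"), drop = FALSE]
}

#' @rdname CohortMatrix-accessors
#' @name CohortMatrix-accessors
#' @title Accessors for CohortMatrix objects
#' @param x a [CohortMatrix-class].
#' @export
setMethod("cellType", "CohortMatrix", function(x) x@cellType)

#' @rdname CohortMatrix-accessors
#' @export
setMethod("detectionCount", "CohortMatrix", function(x) {
    stats::setNames(x@detectionCount, rownames(x@status))
})

#' @rdname CohortMatrix-accessors
#' @export
setMethod("presenceStatus", "CohortMatrix", function(x) x@status)

#' @rdname CohortMatrix-accessors
#' @export
setMethod("dim", "CohortMatrix", function(x) dim(x@status))

setMethod("show", "CohortMatrix", function(object) {
    cat("CohortMatrix [", object@cellType, "]: ", nrow(object@status),
        " loci x ", ncol(object@status), " samples\n", sep = "")
})

newCohortMatrix <- function(status, cellType = NA_character_) {
    new("CohortMatrix", cellType = cellType, status = status,
        detectionCount = as.integer(rowSums(status)))
}

#' Write and read a presence/absence matrix
#'
#' Serialises a [CohortMatrix-class] as a TSV of \code{"+"} (positive) and
#' \code{"-"} (negative) cells, loci in rows sorted by detection count
#' descending then genomic position, samples in columns — the layout of
#' published per-cell-type HERV presence tables. `readPresenceMatrix` is
#' the exact inverse (it also tolerates the typographic minus).
#'
#' @param mat a [CohortMatrix-class].
#' @param path output (input) TSV path.
#' @param cellType cell-type label to attach on reading.
#' @return `writePresenceMatrix` invisibly returns `path`;
#'   `readPresenceMatrix` returns a [CohortMatrix-class].
#' @export
writePresenceMatrix <- function(mat, path) {
    mat <- sortCohortMatrix(mat)
    st <- presenceStatus(mat)
    out <- matrix("-", nrow(st), ncol(st), dimnames = dimnames(st))
    out[st] <- "+"
    df <- data.frame(locus_id = if (is.null(rownames(st))) character(0)
                                else rownames(st),
                     out, check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname writePresenceMatrix
#' @export
readPresenceMatrix <- function(path, cellType = NA_character_) {
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    st <- as.matrix(df[, -1, drop = FALSE])
    st <- st == "+"
    rownames(st) <- df$locus_id
    newCohortMatrix(st, cellType)
}

sortCohortMatrix <- function(mat) {
    st <- presenceStatus(mat)
    if (nrow(st) == 0L) return(mat)
    cnt <- as.integer(rowSums(st))
    pos <- locusOrderKey(rownames(st))
    rank <- integer(nrow(st))
    rank[pos] <- seq_len(nrow(st))
    o <- order(-cnt, rank)
    newCohortMatrix(st[o, , drop = FALSE], cellType(mat))
}

#' Read and write the cohort sample sheet
#'
#' The sample sheet assigns each sample to a group (`patient` or
#' `control`) and tissue, and records the per-run read files and the
#' annotation TSV path. One row per sample; run paths are in columns
#' `run1`, `run2`, ... (duplicate technical runs; two by default
#' throughout the package).
#'
#' @param path TSV path.
#' @return data.frame with columns `sample_id`, `group`, `tissue`,
#'   `run1..runK`, `annotation`.
#' @export
readSampleSheet <- function(path) {
    sheet <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("sample_id", "group", "annotation")
    if (!all(need %in% names(sheet)))
        stop("sample sheet must have columns sample_id, group, annotation")
    if (!any(grepl("^run[0-9]+$", names(sheet))))
        stop("sample sheet must have at least one runN column")
    sheet
}

#' @rdname readSampleSheet
#' @param sheet data.frame as returned by [readSampleSheet()].
#' @export
writeSampleSheet <- function(sheet, path) {
    utils::write.table(sheet, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

runColumns <- function(sheet) {
    sort(grep("^run[0-9]+$", names(sheet), value = TRUE))
}
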