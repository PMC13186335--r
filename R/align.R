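#' Align reads to HERV loci and apply the strict identity filter
#'
#' Locus attribution for WHA: each read is aligned against the locus
#' reference with the package's built-in exact-k-mer-seeded,
#' ungapped seed-and-extend aligner, and only alignments with percent
#' identity strictly greater than `identityThreshold` are retained — a
#' read at exactly the threshold is discarded. A read matching multiple
#' loci is assigned to its single best-identity locus; a read whose best
#' identity is tied across distinct loci is discarded as ambiguous,
#' because locus-specific attribution is the point of the method.
#'
#' Percent identity is `matches / aligned_length * 100`, where
#' `aligned_length` is the ungapped aligned span clipped to the locus.
#'
#' @param reads a named \link[Biostrings]{DNAStringSet} or named character
#'   vector of read sequences, or a FASTQ path. Read names may carry the
#'   cell barcode after a `"|"` separator.
#' @param reference a [HervReference-class]; duplicate locus identifiers
#'   are an error.
#' @param identityThreshold retain only alignments with identity strictly
#'   above this value (default 99, the published rule).
#' @param seedLength exact-match seed k-mer length; reads shorter than
#'   this are skipped with a warning.
#' @return data.frame of retained alignments with columns `read_id`,
#'   `barcode`, `locus_id`, `start_offset` (0-based), `aligned_length`,
#'   `matches`, `percent_identity`. Filter accounting is attached as
#'   `attr(, "stats")`: input, retained, below-identity, ambiguous,
#'   unaligned and too-short read counts.
#' @seealso [readSamAlignments()] for ingesting externally produced SAM
#'   alignments through the same filter.
#' @export
alignAndFilter <- function(reads, reference, identityThreshold = 99,
                           seedLength = 21L) {
    if (is.character(reads) && length(reads) == 1L && file.exists(reads))
        reads <- readFastqReads(reads)
    if (is(reads, "XStringSet")) reads <- as.character(reads)
    if (anyDuplicated(locusIds(reference)))
        stop("reference contains duplicate locus identifiers")
    ids <- names(reads)
    if (is.null(ids)) ids <- as.character(seq_along(reads))
    hits <- cpp_align_reads(unname(reads),
                            as.character(locusSequences(reference)),
                            as.integer(seedLength))
    if (any(hits$status == 1L))
        warning(sum(hits$status == 1L), " read(s) shorter than the ",
                seedLength, " bp seed were skipped")
    aligned <- hits$status == 0L
    pid <- ifelse(aligned, 100 * hits$matches / hits$aligned_length, NA)
    keep <- aligned & pid > identityThreshold
    out <- data.frame(
        read_id = ids[keep],
        barcode = extractBarcodes(ids[keep]),
        locus_id = locusIds(reference)[hits$locus[keep]],
        start_offset = hits$start[keep],
        aligned_length = hits$aligned_length[keep],
        matches = hits$matches[keep],
        percent_identity = pid[keep],
        stringsAsFactors = FALSE)
    attr(out, "stats") <- c(
        input = length(reads), retained = sum(keep),
        below_identity = sum(aligned & !keep),
        ambiguous = sum(hits$status == 3L),
        unaligned = sum(hits$status == 2L),
        too_short = sum(hits$status == 1L))
    out
}

#' Read a FASTQ file as a named DNAStringSet
#' @param path FASTQ path.
#' @return \link[Biostrings]{DNAStringSet} named by the read identifier
#'   (header up to the first whitespace).
#' @export
readFastqReads <- function(path) {
    x <- Biostrings::readDNAStringSet(path, format = "fastq")
    names(x) <- sub("\\s.*$", "", names(x))
    x
}

#' Extract cell barcodes from read names
#'
#' Reads carry their cell barcode in the read name after a `"|"`
#' separator (`"<id>|<barcode>"`); reads without a separator yield `NA`.
#'
#' @param readNames character vector of read names.
#' @return character vector of barcodes (or `NA`).
#' @export
extractBarcodes <- function(readNames) {
    has <- grepl("|", readNames, fixed = TRUE)
    ifelse(has, sub("^.*\\|", "", readNames), NA_character_)
}

#' Partition reads by annotated cell type
#'
#' Emulates barcode-based extraction of reads for each annotated cell
#' population: every read is assigned, via the barcode in its name, to
#' exactly one cell-type bin, or to the `"unannotated"` bin when its
#' barcode is absent from the annotation table. Read counts are conserved.
#'
#' @param reads named \link[Biostrings]{DNAStringSet} or named character
#'   vector.
#' @param annotations data.frame from [readCellAnnotations()].
#' @return named list of read subsets, one per observed cell type plus
#'   `"unannotated"` (present even if empty).
#' @export
partitionReadsByCellType <- function(reads, annotations) {
    bc <- extractBarcodes(names(reads))
    ct <- annotations$cell_type[match(bc, annotations$barcode)]
    ct[is.na(ct)] <- "unannotated"
    bins <- split(seq_along(reads), ct)
    out <- lapply(bins, function(i) reads[i])
    if (!"unannotated" %in% names(out))
        out$unannotated <- reads[integer(0)]
    out
}

#' Ingest externally produced SAM alignments through the identity filter
#'
#' Alternative front end to [alignAndFilter()]: consumes SAM records made
#' by an external aligner against the locus reference, recomputes percent
#' identity from the alignment fields, and applies the same strict
#' threshold. Identity uses the aligned (non-soft-clipped) length as
#' denominator, with every inserted or deleted base counted as a
#' mismatch; mismatch counts come from the `NM` tag when present and are
#' otherwise recomputed by comparison against the reference sequence.
#'
#' @param samPath path to a SAM file with `@SQ` headers naming the loci.
#' @param reference a [HervReference-class] whose locus identifiers match
#'   the SAM reference names.
#' @inheritParams alignAndFilter
#' @return data.frame in the format of [alignAndFilter()].
#' @export
readSamAlignments <- function(samPath, reference, identityThreshold = 99) {
    bam <- Rsamtools::asBam(samPath,
        destination = tempfile(fileext = ""), overwrite = TRUE,
        indexDestination = FALSE)
    on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
    p <- Rsamtools::ScanBamParam(
        what = c("qname", "rname", "pos", "cigar", "seq"),
        tag = "NM",
        flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
    rec <- Rsamtools::scanBam(bam, param = p)[[1L]]
    n <- length(rec$qname)
    if (n == 0L)
        return(data.frame(read_id = character(), barcode = character(),
                          locus_id = character(), start_offset = integer(),
                          aligned_length = integer(), matches = integer(),
                          percent_identity = numeric()))
    ops <- GenomicAlignments::explodeCigarOpLengths(rec$cigar)
    opc <- GenomicAlignments::explodeCigarOps(rec$cigar)
    lens <- mapply(function(o, l) {
        c(M = sum(l[o %in% c("M", "=", "X")]), I = sum(l[o == "I"]),
          D = sum(l[o == "D"]))
    }, opc, ops)
    mlen <- lens["M", ]; ilen <- lens["I", ]; dlen <- lens["D", ]
    alen <- mlen + ilen + dlen
    nm <- rec$tag$NM
    if (is.null(nm)) nm <- rep(NA_integer_, n)
    miss <- which(is.na(nm))
    if (length(miss)) {
        refseqs <- as.character(locusSequences(reference))
        nm[miss] <- vapply(miss, function(i) {
            countSamEdits(as.character(rec$rname[i]), rec$pos[i],
                          opc[[i]], ops[[i]],
                          as.character(rec$seq[i]), refseqs)
        }, 0L)
    }
    subst <- pmax(nm - ilen - dlen, 0L)
    matches <- mlen - subst
    pid <- 100 * matches / alen
    keep <- !is.na(pid) & pid > identityThreshold
    out <- data.frame(
        read_id = rec$qname[keep],
        barcode = extractBarcodes(rec$qname[keep]),
        locus_id = as.character(rec$rname[keep]),
        start_offset = rec$pos[keep] - 1L,
        aligned_length = as.integer(alen[keep]),
        matches = as.integer(matches[keep]),
        percent_identity = pid[keep],
        stringsAsFactors = FALSE)
    attr(out, "stats") <- c(input = n, retained = sum(keep),
                            below_identity = sum(!keep))
    out
}

## Mismatch+indel edit count for one SAM record by walking the CIGAR
## against the reference sequence (used when the NM tag is absent).
countSamEdits <- function(rname, pos, opc, ops, qseq, refseqs) {
    refseq <- refseqs[[rname]]
    qpos <- 1L; rpos <- pos; edits <- 0L
    for (j in seq_along(opc)) {
        len <- ops[j]
        op <- opc[j]
        if (op %in% c("M", "=", "X")) {
            qs <- substring(qseq, qpos, qpos + len - 1L)
            rs <- substring(refseq, rpos, rpos + len - 1L)
            edits <- edits + sum(charToRaw(qs) != charToRaw(rs))
            qpos <- qpos + len; rpos <- rpos + len
        } else if (op == "I") {
            edits <- edits + len; qpos <- qpos + len
        } else if (op == "D" || op == "N") {
            if (op == "D") edits <- edits + len
            rpos <- rpos + len
        } else if (op %in% c("S", "H")) {
            if (op == "S") qpos <- qpos + len
        }
    }
    as.integer(edits)
}
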