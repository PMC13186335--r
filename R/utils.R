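#' Format and parse HERV locus identifiers
#'
#' Locus identifiers use the display form \code{"Chr{c}:{start}-{end}"}
#' with 1-based inclusive coordinates and no thousands separators. The
#' parser additionally tolerates comma separators and en-dash or Unicode
#' minus range separators, as found in printed locus names such as
#' \code{"Chr3:46,046,256-46,054,342"}.
#'
#' @param chrom chromosome name (a leading \code{"chr"} is normalised to
#'   \code{"Chr"}).
#' @param start,end 1-based inclusive coordinates.
#' @return `formatLocusId` returns a character vector of identifiers;
#'   `parseLocusId` returns a data.frame with columns `chrom`, `start`,
#'   `end` (1-based inclusive).
#' @examples
#' formatLocusId("chr3", 46046256, 46054342)
#' parseLocusId("Chr3:46,046,256-46,054,342")
#' @export
formatLocusId <- function(chrom, start, end) {
    chrom <- sub("^chr", "Chr", as.character(chrom))
    chrom <- ifelse(grepl("^Chr", chrom), chrom, paste0("Chr", chrom))
    sprintf("%s:%d-%d", chrom, as.integer(start), as.integer(end))
}

#' @rdname formatLocusId
#' @param locus_id character vector of locus identifiers.
#' @export
parseLocusId <- function(locus_id) {
    x <- gsub(",", "", locus_id, fixed = TRUE)
    x <- gsub("–|−|—", "-", x)
    m <- regmatches(x, regexec("^(Chr[^:]+):([0-9]+)-([0-9]+)$", x,
                               ignore.case = TRUE))
    bad <- vapply(m, length, 0L) != 4L
    if (any(bad))
        stop("malformed locus identifier: ",
             paste(head(locus_id[bad], 3), collapse = ", "))
    data.frame(
        locus_id = locus_id,
        chrom = vapply(m, `[`, "", 2L),
        start = as.integer(vapply(m, `[`, "", 3L)),
        end = as.integer(vapply(m, `[`, "", 4L)),
        stringsAsFactors = FALSE)
}

#' The default PBMC cell-type vocabulary
#'
#' The seven peripheral-blood mononuclear cell labels used by default for
#' annotation validation: classical (CD14+) and non-classical (CD16+)
#' monocytes, B cells, CD4+ and CD8+ T cells, NK cells and dendritic
#' cells. Annotations with labels outside the declared vocabulary are kept
#' with a warning, so that other tissues (e.g. lung monocyte-derived
#' macrophages) work unchanged.
#'
#' @return character vector of cell-type labels.
#' @export
pbmcCellTypes <- function() {
    c("CD14_Mono", "CD16_Mono", "B", "CD4_T", "CD8_T", "NK", "DC")
}

## Natural (chromosome, start) ordering of locus identifiers; used for all
## deterministic tie-breaks.
locusOrderKey <- function(locus_id) {
    p <- parseLocusId(locus_id)
    chrnum <- suppressWarnings(as.integer(sub("^Chr", "", p$chrom)))
    chrnum[is.na(chrnum)] <- 1000L + as.integer(factor(p$chrom[is.na(chrnum)]))
    order(chrnum, p$start, p$end)
}

## Run code under a temporary RNG state seeded from `seed`, restoring the
## caller's stream afterwards.
withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(),
                        inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
    force(expr)
}

## Deterministic sub-seed derivation, kept within 32-bit integer range.
deriveSeed <- function(seed, ...) {
    parts <- c(seed, ...)
    h <- 0
    for (p in parts) h <- (h * 1000003 + as.numeric(p) + 7) %% 2147483629
    as.integer(h)
}

.msg <- function(...) message("[WHAseq] ", ...)
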