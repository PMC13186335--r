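#' Index detectable HERV signal in control samples
#'
#' Control exclusion is the cohort filter of the method: any locus with
#' any detectable signal in any healthy-control sample is removed before
#' patient-cohort analysis. "Detectable signal" is operationalised as at
#' least one identity-filtered retained alignment in at least one control
#' sample — any cell type, any run — which is deliberately weaker than a
#' positive locus call; set `level = "call"` to require a positive call
#' instead.
#'
#' @param alignments data.frame of retained alignments (the
#'   [alignAndFilter()] format) from control samples pooled over cell
#'   types and runs, with a `sample_id` column.
#' @param controlSamples character vector of control sample identifiers;
#'   an empty cohort of controls is an error (the filter is undefined).
#' @param locusIds all locus identifiers of the reference.
#' @param level `"signal"` (any retained read, default) or `"call"`
#'   (requires `calls`, a consensus-call data.frame for the controls).
#' @param calls consensus calls for control samples when
#'   `level = "call"`.
#' @return data.frame with columns `locus_id`, `control_signal`
#'   (logical), `control_read_count`.
#' @export
buildControlIndex <- function(alignments, controlSamples, locusIds,
                              level = c("signal", "call"),
                              calls = NULL) {
    level <- match.arg(level)
    if (length(controlSamples) == 0L)
        stop("no control samples in cohort: control exclusion undefined")
    ctrl <- alignments[alignments$sample_id %in% controlSamples, ,
                       drop = FALSE]
    cnt <- table(factor(ctrl$locus_id, levels = locusIds))
    signal <- as.integer(cnt) > 0L
    if (level == "call") {
        if (is.null(calls))
            stop("level = 'call' requires control consensus calls")
        pos <- calls$locus_id[calls$sample_id %in% controlSamples &
                              calls$status == "positive"]
        signal <- locusIds %in% pos
    }
    data.frame(locus_id = locusIds, control_signal = signal,
               control_read_count = as.integer(cnt),
               stringsAsFactors = FALSE)
}

#' Build a control-excluded presence/absence matrix for one cell type
#'
#' Retains loci that are positive in at least one patient sample and show
#' no control signal, and assembles them into a [CohortMatrix-class]
#' (loci x patient samples), sorted by detection count.
#'
#' @param patientCalls consensus calls (data.frame) for one cell type,
#'   patient samples only.
#' @param controlIndex data.frame from [buildControlIndex()].
#' @param cellTypeLabel label recorded on the matrix.
#' @param samples optional character vector fixing the sample (column)
#'   order; defaults to the samples present in `patientCalls`.
#' @return a [CohortMatrix-class].
#' @export
filterPatientLoci <- function(patientCalls, controlIndex,
                              cellTypeLabel = NA_character_,
                              samples = NULL) {
    if (is.null(samples))
        samples <- sort(unique(patientCalls$sample_id))
    excluded <- controlIndex$locus_id[controlIndex$control_signal]
    pos <- patientCalls[patientCalls$status == "positive" &
                        !(patientCalls$locus_id %in% excluded), ,
                        drop = FALSE]
    loci <- unique(pos$locus_id)
    st <- matrix(FALSE, nrow = length(loci), ncol = length(samples),
                 dimnames = list(loci, samples))
    if (nrow(pos))
        st[cbind(match(pos$locus_id, loci),
                 match(pos$sample_id, samples))] <- TRUE
    sortCohortMatrix(newCohortMatrix(st, cellTypeLabel))
}

#' Select the most frequently detected loci
#'
#' Ranks loci by the number of patient samples in which they were
#' detected (descending; ties broken by ascending genomic position) and
#' keeps the first `n` — the prioritization used to pick the top loci for
#' visualization. Deterministic and permutation-stable.
#'
#' @param mat a [CohortMatrix-class].
#' @param n number of loci to keep (default 10); fewer are returned if
#'   the matrix is smaller.
#' @return a [CohortMatrix-class] with at most `n` rows, in rank order.
#' @export
rankAndSelectTop <- function(mat, n = 10) {
    stopifnot(n >= 1)
    mat <- sortCohortMatrix(mat)
    keep <- seq_len(min(as.integer(n), nrow(presenceStatus(mat))))
    newCohortMatrix(presenceStatus(mat)[keep, , drop = FALSE],
                    cellType(mat))
}

#' Intersection of detected loci across subsets
#'
#' Computes, for presence/absence matrices of two or more subsets (e.g.
#' CD14+ and CD16+ monocytes), the membership pattern of every detected
#' locus — the quantity behind an UpSet plot. A locus is "in" a subset
#' when it is positive in at least one sample of that subset's matrix;
#' every detected locus belongs to exactly one membership pattern, so
#' pattern counts sum to the number of distinct detected loci.
#'
#' @param matrices named list of [CohortMatrix-class] objects, one per
#'   subset label; at least two.
#' @return list with `membership` (data.frame `locus_id`, `pattern`, one
#'   logical column per subset) and `counts` (data.frame `pattern`,
#'   `count`, sorted by count descending).
#' @export
intersectSubsets <- function(matrices) {
    if (length(matrices) < 2L || is.null(names(matrices)))
        stop("need a named list of at least two subset matrices")
    inSubset <- lapply(matrices, function(m) {
        st <- presenceStatus(m)
        rownames(st)[rowSums(st) > 0L]
    })
    loci <- sort(unique(unlist(inSubset)))
    memb <- vapply(inSubset, function(ids) loci %in% ids,
                   logical(length(loci)))
    if (length(loci) == 1L) memb <- matrix(memb, nrow = 1L,
                                           dimnames = list(NULL,
                                               names(inSubset)))
    pattern <- apply(memb, 1L, function(r)
        paste(names(inSubset)[r], collapse = "&"))
    membership <- data.frame(locus_id = loci, pattern = pattern,
                             memb, stringsAsFactors = FALSE,
                             check.names = FALSE)
    tab <- table(pattern)
    counts <- data.frame(pattern = names(tab),
                         count = as.integer(tab),
                         stringsAsFactors = FALSE)
    counts <- counts[order(-counts$count, counts$pattern), , drop = FALSE]
    rownames(counts) <- NULL
    list(membership = membership, counts = counts)
}

#' Patient-detection counts per locus across cell types
#'
#' Tabulates, for each locus detected anywhere, the number of patient
#' samples with a positive call in each cell type, and flags loci
#' detected in exactly one cell type (e.g. the CD14-exclusive set).
#'
#' @param matrices named list of [CohortMatrix-class] objects from the
#'   same cohort, one per cell type.
#' @return data.frame with `locus_id`, one integer count column per cell
#'   type, and `exclusive_cell_type` (the cell type when the locus is
#'   detected in exactly one, otherwise `NA`). Loci absent everywhere are
#'   excluded.
#' @export
crossCellTypeSummary <- function(matrices) {
    stopifnot(length(matrices) >= 1L, !is.null(names(matrices)))
    loci <- sort(unique(unlist(lapply(matrices, function(m)
        rownames(presenceStatus(m))))))
    cnt <- vapply(matrices, function(m) {
        st <- presenceStatus(m)
        out <- integer(length(loci))
        i <- match(rownames(st), loci)
        out[i] <- as.integer(rowSums(st))
        out
    }, integer(length(loci)))
    if (length(loci) == 1L)
        cnt <- matrix(cnt, nrow = 1L, dimnames = list(NULL,
                                                      names(matrices)))
    keep <- rowSums(cnt) > 0L
    loci <- loci[keep]
    cnt <- cnt[keep, , drop = FALSE]
    ndet <- rowSums(cnt > 0L)
    exclusive <- ifelse(ndet == 1L,
        colnames(cnt)[apply(cnt > 0L, 1L, which.max)], NA_character_)
    out <- data.frame(locus_id = loci, cnt,
                      exclusive_cell_type = exclusive,
                      stringsAsFactors = FALSE, check.names = FALSE)
    out[order(-rowSums(cnt), loci), , drop = FALSE]
}
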