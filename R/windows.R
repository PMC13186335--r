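#' Tile a locus into sequential non-overlapping windows
#'
#' The windowing at the heart of the WHA statistic: a locus of length L is
#' tiled into \code{floor(L / windowSize)} contiguous windows of exactly
#' `windowSize` bp starting at offset 0; the trailing partial remainder is
#' discarded so that every window has the same length and the per-window
#' depth threshold is comparable across windows.
#'
#' @param x a [HervReference-class] (all loci tiled), or a numeric vector
#'   of locus lengths.
#' @param windowSize window width in bp (default 500).
#' @return data.frame with columns `locus_id`, `index` (0-based window
#'   index), `start_offset`, `end_offset` (0-based half-open offsets
#'   within the locus).
#' @examples
#' tileWindows(8087, windowSize = 500)  # 16 windows, last is [7500, 8000)
#' @export
tileWindows <- function(x, windowSize = 500) {
    windowSize <- as.integer(windowSize)
    if (is.na(windowSize) || windowSize < 1L)
        stop("windowSize must be a positive integer")
    if (is(x, "HervReference")) {
        lens <- locusLengths(x)
    } else {
        lens <- as.integer(x)
        if (is.null(names(lens)))
            names(lens) <- rep(NA_character_, length(lens))
    }
    res <- lapply(seq_along(lens), function(i) {
        n <- lens[i] %/% windowSize
        if (n == 0L)
            return(data.frame(locus_id = character(), index = integer(),
                              start_offset = integer(),
                              end_offset = integer()))
        idx <- seq_len(n) - 1L
        data.frame(locus_id = names(lens)[i], index = idx,
                   start_offset = idx * windowSize,
                   end_offset = (idx + 1L) * windowSize)
    })
    do.call(rbind, res)
}

#' Number of full windows of a locus
#' @param locusLength locus length(s) in bp.
#' @inheritParams tileWindows
#' @return integer vector.
#' @export
nWindows <- function(locusLength, windowSize = 500) {
    as.integer(locusLength) %/% as.integer(windowSize)
}

#' Compute per-window read depth for one locus
#'
#' Converts identity-filtered alignments on a single locus into the
#' per-window mean per-base depth vector used for locus calling. The depth
#' of window w is the total number of aligned bases falling inside w
#' divided by the window size. Alignments extending past the locus end are
#' clipped and counted only within the locus.
#'
#' @param alignments data.frame of filtered alignments on one locus, with
#'   columns `start_offset` (0-based within locus) and `aligned_length`
#'   (bp); typically a subset of [alignAndFilter()] output.
#' @param locusLength length of the locus in bp.
#' @param windowSize window width in bp.
#' @param locusId,sampleId,cellType,runId identifiers recorded on the
#'   result.
#' @return a [WindowCoverage-class] whose `depths` has one entry per full
#'   window.
#' @export
computeWindowCoverage <- function(alignments, locusLength,
                                  windowSize = 500,
                                  locusId = NA_character_,
                                  sampleId = NA_character_,
                                  cellType = NA_character_,
                                  runId = NA_character_) {
    locusLength <- as.integer(locusLength)
    windowSize <- as.integer(windowSize)
    nw <- locusLength %/% windowSize
    if (nrow(alignments) == 0L) {
        depths <- numeric(nw)
    } else {
        start1 <- pmax(as.integer(alignments$start_offset) + 1L, 1L)
        end1 <- pmin(as.integer(alignments$start_offset) +
                     as.integer(alignments$aligned_length), locusLength)
        keep <- end1 >= start1
        ir <- IRanges::IRanges(start = start1[keep], end = end1[keep])
        cov <- IRanges::coverage(ir, width = locusLength)
        if (nw > 0L) {
            v <- IRanges::Views(cov,
                start = (seq_len(nw) - 1L) * windowSize + 1L,
                width = windowSize)
            depths <- as.numeric(IRanges::viewMeans(v))
        } else depths <- numeric(0)
    }
    new("WindowCoverage", locusId = locusId, sampleId = sampleId,
        cellType = cellType, runId = runId, depths = depths,
        windowSize = windowSize, nReads = nrow(alignments))
}

#' @rdname WindowCoverage-accessors
#' @name WindowCoverage-accessors
#' @title Accessors for WindowCoverage objects
#' @param x a [WindowCoverage-class].
#' @export
setMethod("windowDepths", "WindowCoverage", function(x) x@depths)

#' @rdname WindowCoverage-accessors
#' @export
setMethod("length", "WindowCoverage", function(x) length(x@depths))

setMethod("show", "WindowCoverage", function(object) {
    cat("WindowCoverage ", object@locusId, " [", object@sampleId, "/",
        object@cellType, "/", object@runId, "]: ", length(object@depths),
        " windows of ", object@windowSize, " bp, ", object@nReads,
        " reads\n", sep = "")
})

#' Classify a locus as positive or negative from window coverage
#'
#' The WHA positive/negative rule: a window is usable when its depth is at
#' least `minDepth` (default 3); the locus is positive when at least
#' `minUsableWindows` (default 9) windows are usable, negative otherwise
#' (8 or fewer usable windows under the defaults).
#'
#' @param coverage a [WindowCoverage-class] or a bare numeric vector of
#'   per-window depths.
#' @param minDepth minimum per-window depth for a usable window.
#' @param minUsableWindows minimum number of usable windows for a positive
#'   call.
#' @param depthStatistic how window depth was summarised; `"mean"`
#'   (default) uses the mean per-base depth recorded in `coverage`.
#' @return one-row data.frame with columns `locus_id`, `sample_id`,
#'   `cell_type`, `run_id`, `usable_windows`, `status`
#'   (`"positive"`/`"negative"`), `raw_read_count`.
#' @examples
#' callLocus(c(rep(3, 9), rep(0, 7)))$status   # "positive"
#' callLocus(c(rep(50, 8), rep(0, 8)))$status  # "negative"
#' @export
callLocus <- function(coverage, minDepth = 3, minUsableWindows = 9) {
    if (minUsableWindows < 1L || minDepth < 0)
        stop("thresholds must be >= 1 window and >= 0 depth")
    if (is(coverage, "WindowCoverage")) {
        depths <- coverage@depths
        ids <- c(coverage@locusId, coverage@sampleId, coverage@cellType,
                 coverage@runId)
        nReads <- coverage@nReads
    } else {
        depths <- as.numeric(coverage)
        ids <- rep(NA_character_, 4L)
        nReads <- NA_integer_
    }
    usable <- sum(depths >= minDepth)
    data.frame(locus_id = ids[1L], sample_id = ids[2L], cell_type = ids[3L],
               run_id = ids[4L], usable_windows = as.integer(usable),
               status = if (usable >= minUsableWindows) "positive"
                        else "negative",
               raw_read_count = nReads, stringsAsFactors = FALSE)
}

#' Combine duplicate-run calls into a consensus call
#'
#' Each sample is processed as duplicate technical runs; `consensusCall`
#' collapses run-level calls to one call per (locus, sample, cell type).
#' Under the default `"intersection"` rule a locus is positive only when
#' positive in every run — the conservative reading of duplicate-run
#' robustness; `"union"` requires any run, `"single"` expects exactly one
#' run. The consensus `usable_windows` is the minimum across runs
#' (maximum under `"union"`); `raw_read_count` is summed.
#'
#' @param calls data.frame of run-level calls (rows as produced by
#'   [callLocus()], with `run_id` set).
#' @param mode consensus rule.
#' @param expectedRuns number of duplicate runs expected per group; a
#'   group with fewer triggers a warning and passes its calls through.
#' @return data.frame of consensus calls, one row per
#'   (locus, sample, cell type), without a `run_id` column.
#' @export
consensusCall <- function(calls,
                          mode = c("intersection", "union", "single"),
                          expectedRuns = 2L) {
    mode <- match.arg(mode)
    if (nrow(calls) == 0L)
        return(calls[, setdiff(names(calls), "run_id"), drop = FALSE])
    key <- paste(calls$locus_id, calls$sample_id, calls$cell_type,
                 sep = "\r")
    groups <- split(seq_len(nrow(calls)), key)
    short <- sum(vapply(groups, length, 0L) < expectedRuns)
    if (mode != "single" && short > 0L)
        warning(short, " call group(s) with fewer than ", expectedRuns,
                " runs; using available runs")
    rows <- lapply(groups, function(i) {
        g <- calls[i, , drop = FALSE]
        pos <- g$status == "positive"
        status <- switch(mode,
            intersection = all(pos),
            union = any(pos),
            single = pos[1L])
        uw <- switch(mode,
            intersection = min(g$usable_windows),
            union = max(g$usable_windows),
            single = g$usable_windows[1L])
        data.frame(locus_id = g$locus_id[1L], sample_id = g$sample_id[1L],
                   cell_type = g$cell_type[1L],
                   usable_windows = as.integer(uw),
                   status = if (status) "positive" else "negative",
                   raw_read_count = sum(g$raw_read_count),
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out[order(out$locus_id, out$sample_id, out$cell_type), , drop = FALSE]
}
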