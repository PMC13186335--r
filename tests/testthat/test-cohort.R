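mkAln <- function(locus_id, sample_id) {
    data.frame(read_id = paste0("r", seq_along(locus_id)),
               barcode = "AAAA", locus_id = locus_id,
               start_offset = 0L, aligned_length = 90L, matches = 90L,
               percent_identity = 100, sample_id = sample_id,
               stringsAsFactors = FALSE)
}

test_that("control signal is any retained read in any control sample", {
    loci <- formatLocusId("chr1", c(1001, 2001, 3001),
                          c(1900, 2900, 3900))
    aln <- mkAln(c(loci[1], loci[2]), c("control01", "patient01"))
    idx <- buildControlIndex(aln, "control01", loci)
    expect_identical(idx$control_signal, c(TRUE, FALSE, FALSE))
    expect_identical(idx$control_read_count, c(1L, 0L, 0L))
    expect_error(buildControlIndex(aln, character(0), loci),
                 "control")
})

test_that("control reads failing the identity filter leave no signal", {
    locus <- randomSeq(2000, seed = 91)
    ref <- refFromSeqs(locus)
    bad <- mutateAt(substring(locus, 1, 100), c(10, 60))  # 98% identity
    aln <- alignAndFilter(c(r1 = bad), ref)
    aln$sample_id <- rep("control01", nrow(aln))
    idx <- buildControlIndex(aln, "control01", locusIds(ref))
    expect_false(any(idx$control_signal))
})

test_that("call-level exclusion is available as a config switch", {
    loci <- formatLocusId("chr1", c(1001, 2001), c(1900, 2900))
    aln <- mkAln(loci[1], "control01")
    calls <- makeCalls(loci[2], "control01", "CD14_Mono", "positive")
    idx <- buildControlIndex(aln, "control01", loci, level = "call",
                             calls = calls)
    # read-level signal on locus 1 is ignored; the positive call on
    # locus 2 triggers exclusion instead
    expect_identical(idx$control_signal, c(FALSE, TRUE))
})

test_that("patient matrices keep control-silent patient-positive loci", {
    loci <- formatLocusId("chr1", c(1001, 2001, 3001),
                          c(1900, 2900, 3900))
    samples <- sprintf("patient%02d", 1:12)
    calls <- rbind(
        makeCalls(loci[1], samples[1:11], "B", "positive"),
        makeCalls(loci[1], samples[12], "B", "negative"),
        makeCalls(loci[2], samples, "B", "positive"),
        makeCalls(loci[3], samples[1:3], "B", "negative"))
    idx <- data.frame(locus_id = loci,
                      control_signal = c(FALSE, TRUE, FALSE),
                      control_read_count = c(0L, 1L, 0L))
    m <- filterPatientLoci(calls, idx, "B", samples = samples)
    # locus 2 positive in 12/12 but a single control read excludes it;
    # locus 3 has no patient positive; locus 1 detected in 11/12
    expect_identical(rownames(presenceStatus(m)), loci[1])
    expect_identical(unname(detectionCount(m)), 11L)
    expect_identical(ncol(presenceStatus(m)), 12L)
    # no patient positives -> empty matrix
    empty <- filterPatientLoci(makeCalls(loci[1], samples, "B",
                                         "negative"), idx, "B")
    expect_identical(nrow(presenceStatus(empty)), 0L)
    # soundness: no emitted locus has control signal
    expect_false(any(rownames(presenceStatus(m)) %in%
                     idx$locus_id[idx$control_signal]))
})

test_that("top-locus selection ranks by frequency with positional ties", {
    set.seed(101)
    loci <- formatLocusId(paste0("chr", rep(1:5, 5)),
                          seq(1001, by = 10000, length.out = 25),
                          seq(9000, by = 10000, length.out = 25))
    samples <- sprintf("p%02d", 1:12)
    counts <- sample(1:12, 25, replace = TRUE)
    st <- t(vapply(counts, function(k) seq_along(samples) <= k,
                   logical(12)))
    dimnames(st) <- list(loci, samples)
    m <- WHAseq:::newCohortMatrix(st, "CD14_Mono")
    top <- rankAndSelectTop(m, 10)
    expect_identical(nrow(presenceStatus(top)), 10L)
    expect_true(all(diff(unname(detectionCount(top))) <= 0))
    expect_identical(sort(unname(detectionCount(top)), decreasing = TRUE),
                     sort(counts, decreasing = TRUE)[1:10])
    # fewer candidates than n: all returned
    small <- rankAndSelectTop(m, 100)
    expect_identical(nrow(presenceStatus(small)), 25L)
    # deterministic tie-break: equal counts ordered by (chrom, start)
    st2 <- matrix(c(TRUE, TRUE), nrow = 2, dimnames = list(
        c("Chr2:5001-6000", "Chr1:9001-9900"), "p01"))
    m2 <- rankAndSelectTop(WHAseq:::newCohortMatrix(st2, "x"), 1)
    expect_identical(rownames(presenceStatus(m2)), "Chr1:9001-9900")
    # permutation stability: shuffled rows give the same ranking
    per <- sample(nrow(st))
    topPer <- rankAndSelectTop(
        WHAseq:::newCohortMatrix(st[per, , drop = FALSE], "CD14_Mono"),
        10)
    expect_identical(presenceStatus(topPer), presenceStatus(top))
})

test_that("subset intersection partitions loci and matches brute force", {
    loci <- formatLocusId("chr1", seq(1001, by = 10000, length.out = 6),
                          seq(9000, by = 10000, length.out = 6))
    mk <- function(ids, samples = c("p1", "p2")) {
        st <- matrix(TRUE, nrow = length(ids), ncol = length(samples),
                     dimnames = list(ids, samples))
        WHAseq:::newCohortMatrix(st, "x")
    }
    inter <- intersectSubsets(list(CD14_Mono = mk(loci[1:4]),
                                   CD16_Mono = mk(loci[3:5])))
    memb <- inter$membership
    expect_identical(memb$pattern[memb$locus_id == loci[1]], "CD14_Mono")
    expect_identical(memb$pattern[memb$locus_id == loci[3]],
                     "CD14_Mono&CD16_Mono")
    expect_identical(memb$pattern[memb$locus_id == loci[5]], "CD16_Mono")
    # pattern counts partition the detected loci
    expect_identical(sum(inter$counts$count), 5L)
    expect_error(intersectSubsets(list(a = mk(loci[1]))), "two")

    # brute-force double loop over loci x subsets on random instances
    set.seed(111)
    for (i in 1:10) {
        sets <- lapply(1:3, function(j)
            loci[sample(6, sample(0:6, 1))])
        names(sets) <- c("A", "B", "C")
        mats <- lapply(sets, function(ids)
            if (length(ids)) mk(ids) else
                WHAseq:::newCohortMatrix(matrix(logical(0), 0, 1,
                    dimnames = list(NULL, "p1")), "x"))
        inter <- intersectSubsets(mats)
        all_loci <- sort(unique(unlist(sets)))
        brute <- vapply(all_loci, function(l) paste(
            names(sets)[vapply(sets, function(s) l %in% s, TRUE)],
            collapse = "&"), "")
        expect_identical(inter$membership$pattern, unname(brute))
        bruteCounts <- sort(table(brute))
        expect_identical(sum(inter$counts$count), length(all_loci))
        expect_identical(sort(inter$counts$count),
                         unname(as.integer(bruteCounts)))
    }
})

test_that("cross-cell-type summary counts patients and flags exclusivity", {
    loci <- formatLocusId("chr1", c(1001, 20001), c(9000, 29000))
    samples <- sprintf("p%02d", 1:12)
    mk <- function(ids, k) {
        st <- t(vapply(k, function(x) seq_along(samples) <= x,
                       logical(12)))
        dimnames(st) <- list(ids, samples)
        WHAseq:::newCohortMatrix(st, "x")
    }
    mats <- list(CD14_Mono = mk(loci, c(11L, 4L)),
                 CD16_Mono = mk(loci[2], 2L),
                 B = mk(character(0), integer(0)))
    xct <- crossCellTypeSummary(mats)
    r1 <- xct[xct$locus_id == loci[1], ]
    expect_identical(r1$CD14_Mono, 11L)
    expect_identical(r1$CD16_Mono, 0L)
    expect_identical(r1$exclusive_cell_type, "CD14_Mono")
    r2 <- xct[xct$locus_id == loci[2], ]
    expect_true(is.na(r2$exclusive_cell_type))
    # counts bounded by cohort size
    expect_true(all(xct$CD14_Mono <= 12L))
})
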