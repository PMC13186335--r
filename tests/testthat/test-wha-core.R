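test_that("window tiling discards the trailing partial window", {
    w <- tileWindows(8087, windowSize = 500)
    expect_identical(nrow(w), 16L)
    expect_identical(w$start_offset[16], 7500L)
    expect_identical(w$end_offset[16], 8000L)
    expect_identical(nrow(tileWindows(499, 500)), 0L)
    w2 <- tileWindows(1000, 500)
    expect_identical(nrow(w2), 2L)
    expect_identical(w2$end_offset[2], 1000L)
    expect_error(tileWindows(1000, 0), "positive")
    # windows are sequential, non-overlapping, equal length, from offset 0
    w3 <- tileWindows(9731, 347)
    expect_identical(w3$start_offset, c(0L, head(w3$end_offset, -1)))
    expect_true(all(w3$end_offset - w3$start_offset == 347L))
})

test_that("the identity filter is strictly greater than the threshold", {
    locus <- randomSeq(2000, seed = 21)
    ref <- refFromSeqs(locus)
    clean <- substring(locus, 301, 400)
    reads <- c(r0 = clean,
               r1 = mutateAt(clean, 50),
               r2 = mutateAt(clean, c(30, 70)))
    aln <- alignAndFilter(reads, ref)
    # 100% identity retained; exactly 99.0% and 98.0% discarded
    expect_identical(aln$read_id, "r0")
    expect_identical(aln$percent_identity, 100)
    expect_identical(aln$start_offset, 300L)
    st <- attr(aln, "stats")
    expect_identical(unname(st["below_identity"]), 2L)
    # at a lower threshold the 1-mismatch read comes back
    aln98 <- alignAndFilter(reads, ref, identityThreshold = 98)
    expect_setequal(aln98$read_id, c("r0", "r1"))
    expect_identical(aln98$percent_identity[aln98$read_id == "r1"], 99)
})

test_that("reads tied across duplicate loci are discarded as ambiguous", {
    shared <- randomSeq(1500, seed = 31)
    ref <- refFromSeqs(c(shared, shared, randomSeq(1500, seed = 32)))
    reads <- c(amb = substring(shared, 101, 200),
               uniq = substring(as.character(locusSequences(ref)[[3]]),
                                101, 200))
    aln <- alignAndFilter(reads, ref)
    expect_identical(aln$read_id, "uniq")
    expect_identical(unname(attr(aln, "stats")["ambiguous"]), 1L)
})

test_that("reads shorter than the seed are skipped with a warning", {
    ref <- refFromSeqs(randomSeq(1000, seed = 41))
    reads <- c(short = "ACGTACGT")
    expect_warning(aln <- alignAndFilter(reads, ref), "seed")
    expect_identical(nrow(aln), 0L)
})

test_that("duplicate locus identifiers in a reference are rejected", {
    s <- randomSeq(600, seed = 51)
    expect_error(refFromSeqs(c(s, s), chrom = c("chr1", "chr1"),
                             start = c(101L, 101L)), "duplicate")
})

test_that("window coverage equals the per-base pileup oracle", {
    # no alignments -> all-zero vector
    none <- computeWindowCoverage(
        data.frame(start_offset = integer(), aligned_length = integer()),
        2000, 500)
    expect_identical(windowDepths(none), c(0, 0, 0, 0))
    # one 500 bp alignment exactly spanning a window
    one <- computeWindowCoverage(
        data.frame(start_offset = 500L, aligned_length = 500L), 2000, 500)
    expect_identical(windowDepths(one), c(0, 1, 0, 0))
    # 30 x 100 bp uniformly tiling a 1000 bp locus: depth 3 everywhere
    tiling <- data.frame(start_offset = rep(seq(0, 900, by = 100), 3),
                         aligned_length = 100L)
    expect_identical(windowDepths(
        computeWindowCoverage(tiling, 1000, 500)), c(3, 3))
    expect_equal(windowDepths(computeWindowCoverage(tiling, 1000, 500)),
                 pileupOracle(tiling, 1000, 500), tolerance = 1e-12)
    # random instances agree with the oracle to floating tolerance
    set.seed(61)
    for (i in 1:20) {
        L <- sample(600:3000, 1)
        ws <- sample(c(100L, 250L, 500L), 1)
        n <- sample(0:150, 1)
        aln <- data.frame(
            start_offset = sample(0:(L - 10), n, replace = TRUE),
            aligned_length = sample(30:120, max(n, 1),
                                    replace = TRUE)[seq_len(n)])
        expect_equal(windowDepths(computeWindowCoverage(aln, L, ws)),
                     pileupOracle(aln, L, ws), tolerance = 1e-9)
    }
})

test_that("alignments extending past the locus end are clipped", {
    over <- data.frame(start_offset = 900L, aligned_length = 300L)
    d <- windowDepths(computeWindowCoverage(over, 1000, 500))
    expect_identical(d, c(0, 100 / 500))  # only 100 bases inside
})

test_that("locus calling applies the depth-3 / 9-window rule", {
    expect_identical(callLocus(c(rep(3, 9), rep(0, 7)))$status, "positive")
    expect_identical(callLocus(c(rep(3, 9), rep(0, 7)))$usable_windows, 9L)
    # eight saturated windows are still negative
    expect_identical(callLocus(c(rep(50, 8), rep(0, 8)))$status, "negative")
    # sixteen windows just under the depth threshold: zero usable
    c16 <- callLocus(rep(2.9, 16))
    expect_identical(c16$usable_windows, 0L)
    expect_identical(c16$status, "negative")
    expect_error(callLocus(rep(3, 16), minUsableWindows = 0), "threshold")
})

test_that("adding reads is monotone: depths and calls never decrease", {
    set.seed(71)
    L <- 4000L; ws <- 500L
    base <- data.frame(start_offset = sample(0:(L - 90), 60, TRUE),
                       aligned_length = 90L)
    extra <- data.frame(start_offset = sample(0:(L - 90), 40, TRUE),
                        aligned_length = 90L)
    d1 <- windowDepths(computeWindowCoverage(base, L, ws))
    d2 <- windowDepths(computeWindowCoverage(rbind(base, extra), L, ws))
    expect_true(all(d2 >= d1))
    c1 <- callLocus(d1); c2 <- callLocus(d2)
    expect_true(c2$usable_windows >= c1$usable_windows)
    expect_false(c1$status == "positive" && c2$status == "negative")
})

test_that("duplicate-run consensus follows the intersection rule", {
    runs <- rbind(
        data.frame(locus_id = "Chr1:1-100", sample_id = "s1",
                   cell_type = "CD14_Mono", run_id = c("run1", "run2"),
                   usable_windows = c(12L, 10L),
                   status = c("positive", "positive"),
                   raw_read_count = c(100L, 110L)),
        data.frame(locus_id = "Chr2:1-100", sample_id = "s1",
                   cell_type = "CD14_Mono", run_id = c("run1", "run2"),
                   usable_windows = c(12L, 5L),
                   status = c("positive", "negative"),
                   raw_read_count = c(100L, 20L)))
    cons <- consensusCall(runs)
    expect_identical(cons$status[cons$locus_id == "Chr1:1-100"],
                     "positive")
    expect_identical(cons$usable_windows[cons$locus_id == "Chr1:1-100"],
                     10L)  # minimum across runs
    expect_identical(cons$status[cons$locus_id == "Chr2:1-100"],
                     "negative")
    # union mode flips the mixed pair
    expect_identical(
        consensusCall(runs, mode = "union")$status,
        c("positive", "positive"))
    # a single run passes through with a warning
    expect_warning(single <- consensusCall(runs[1, ]), "fewer than")
    expect_identical(single$status, "positive")
})

test_that("cell-type partitioning conserves reads", {
    ann <- data.frame(barcode = c("AAAA", "CCCC"),
                      cell_type = c("CD14_Mono", "B"),
                      mapping_score = 1)
    reads <- setNames(rep("ACGT", 10),
        paste0("r", 1:10, "|",
               c(rep("AAAA", 5), rep("CCCC", 3), rep("GGGG", 2))))
    bins <- partitionReadsByCellType(reads, ann)
    expect_identical(length(bins$CD14_Mono), 5L)
    expect_identical(length(bins$B), 3L)
    expect_identical(length(bins$unannotated), 2L)
    expect_identical(sum(lengths(bins)), length(reads))
    # all annotated: unannotated bin exists but is empty
    allann <- partitionReadsByCellType(reads[1:5], ann)
    expect_identical(length(allann$unannotated), 0L)
})

test_that("SAM ingestion recomputes identity and matches the built-in route", {
    locus <- randomSeq(1200, seed = 81)
    ref <- refFromSeqs(locus)
    id <- locusIds(ref)
    clean <- substring(locus, 101, 200)
    one <- mutateAt(clean, 40)
    sam <- tempfile(fileext = ".sam")
    writeLines(c(
        "@HD\tVN:1.6\tSO:unsorted",
        paste0("@SQ\tSN:", id, "\tLN:1200"),
        # perfect 100M with NM tag
        paste("q1|AAAA", 0, id, 101, 60, "100M", "*", 0, 0, clean,
              strrep("I", 100), "NM:i:0", sep = "\t"),
        # one mismatch, NM present: identity 99.0, discarded (strict)
        paste("q2|AAAA", 0, id, 101, 60, "100M", "*", 0, 0, one,
              strrep("I", 100), "NM:i:1", sep = "\t"),
        # no NM tag: mismatches recomputed against the reference
        paste("q3|CCCC", 0, id, 101, 60, "100M", "*", 0, 0, clean,
              strrep("I", 100), sep = "\t"),
        # soft clips excluded from the denominator: 90M at 99%+ retained
        paste("q4|CCCC", 0, id, 111, 60, "10S90M", "*", 0, 0,
              paste0(strrep("A", 10), substring(locus, 111, 200)),
              strrep("I", 100), "NM:i:0", sep = "\t"),
        # a 2 bp deletion counts 2 edits over 102 aligned: 98.04%
        paste("q5|GGGG", 0, id, 101, 60, "50M2D50M", "*", 0, 0, paste0(
              substring(locus, 101, 150), substring(locus, 153, 202)),
              strrep("I", 100), "NM:i:2", sep = "\t")),
        sam)
    aln <- readSamAlignments(sam, ref)
    expect_setequal(aln$read_id, c("q1|AAAA", "q3|CCCC", "q4|CCCC"))
    expect_identical(aln$start_offset[aln$read_id == "q1|AAAA"], 100L)
    expect_identical(aln$barcode[aln$read_id == "q4|CCCC"], "CCCC")
    # the built-in aligner agrees on the clean full-length read
    direct <- alignAndFilter(c("q1|AAAA" = clean), ref)
    expect_identical(direct$start_offset,
                     aln$start_offset[aln$read_id == "q1|AAAA"])
    expect_identical(direct$matches,
                     aln$matches[aln$read_id == "q1|AAAA"])
})

test_that("noise-free synthetic calls recover the truth table exactly", {
    cfg <- simConfig(seed = 19, nPatients = 3L, nControls = 2L,
                     nLoci = 6L, substitutionErrorRate = 0,
                     cellTypes = c(CD14_Mono = 10L, B = 8L))
    ref <- makeReference(cfg)
    plan <- expressionPlan(
        group = c("patient", "patient", "control"),
        cell_type = c("CD14_Mono", "B", "CD14_Mono"),
        locus_id = locusIds(ref)[c(1, 2, 3)],
        depth = c(8, 8, 6))
    dir <- withr::local_tempdir()
    sim <- simulateCohort(cfg, plan, ref, dir)
    res <- whaCallCohort(sim$sampleSheet, ref,
                         windowSize = cfg$windowSize)
    pos <- res$calls[res$calls$status == "positive",
                     c("sample_id", "cell_type", "locus_id")]
    rownames(pos) <- NULL
    ord <- function(d) {
        d <- d[order(d$sample_id, d$cell_type, d$locus_id), ]
        rownames(d) <- NULL
        d
    }
    expect_identical(ord(pos), ord(sim$truth))
})
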