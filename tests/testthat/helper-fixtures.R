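## Shared fixtures, built in code.

## A small deterministic reference with known locus ids.
testReference <- function(nLoci = 3L, seed = 42L,
                          lengthRange = c(8000L, 10000L)) {
    makeReference(simConfig(seed = seed, nLoci = nLoci,
                            locusLengthRange = lengthRange))
}

## Build a HervReference directly from named sequences placed at given
## coordinates (chrN cycling, 1-based starts).
refFromSeqs <- function(seqs, chrom = NULL, start = NULL) {
    n <- length(seqs)
    if (is.null(chrom)) chrom <- paste0("chr", seq_len(n))
    if (is.null(start)) start <- rep(1001L, n)
    end <- start + nchar(seqs) - 1L
    ids <- formatLocusId(chrom, start, end)
    dss <- Biostrings::DNAStringSet(seqs)
    names(dss) <- ids
    gr <- GenomicRanges::GRanges(chrom,
        IRanges::IRanges(start = start, end = end))
    names(gr) <- ids
    WHAseq:::newHervReference(gr, dss)
}

randomSeq <- function(len, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
          collapse = "")
}

## Substitute bases at given 1-based positions with a different base.
mutateAt <- function(seq, pos) {
    for (p in pos) {
        orig <- substring(seq, p, p)
        substring(seq, p, p) <- setdiff(c("A", "C", "G", "T"), orig)[1L]
    }
    seq
}

## Independent per-base pileup oracle for window depths: a plain loop
## incrementing an integer per-base counter, then averaging per window.
pileupOracle <- function(alignments, locusLength, windowSize) {
    depth <- integer(locusLength)
    for (i in seq_len(nrow(alignments))) {
        s <- alignments$start_offset[i] + 1L
        e <- min(alignments$start_offset[i] + alignments$aligned_length[i],
                 locusLength)
        if (e >= s) for (p in s:e) depth[p] <- depth[p] + 1L
    }
    nw <- locusLength %/% windowSize
    vapply(seq_len(nw), function(w) {
        mean(depth[((w - 1L) * windowSize + 1L):(w * windowSize)])
    }, 0)
}

## Build a consensus-call data.frame row block quickly.
makeCalls <- function(locus_id, sample_id, cell_type, status,
                      usable = ifelse(status == "positive", 12L, 0L)) {
    data.frame(locus_id = locus_id, sample_id = sample_id,
               cell_type = cell_type, usable_windows = usable,
               status = status, raw_read_count = 0L,
               stringsAsFactors = FALSE)
}

## One-way ANOVA + Tukey HSD oracle from first principles: F from sums
## of squares, Tukey adjusted p from the studentized range distribution.
anovaTukeyOracle <- function(y, g) {
    g <- factor(g)
    k <- nlevels(g)
    n <- length(y)
    means <- tapply(y, g, mean)
    ni <- tapply(y, g, length)
    grand <- mean(y)
    ssb <- sum(ni * (means - grand)^2)
    ssw <- sum((y - means[g])^2)
    dfb <- k - 1L
    dfw <- n - k
    mse <- ssw / dfw
    Fstat <- (ssb / dfb) / mse
    p <- stats::pf(Fstat, dfb, dfw, lower.tail = FALSE)
    cmb <- utils::combn(levels(g), 2L)
    pair <- paste(cmb[2L, ], cmb[1L, ], sep = "-")
    padj <- numeric(ncol(cmb))
    diffs <- numeric(ncol(cmb))
    for (j in seq_len(ncol(cmb))) {
        a <- cmb[2L, j]; b <- cmb[1L, j]
        diffs[j] <- means[a] - means[b]
        se <- sqrt(mse / 2 * (1 / ni[a] + 1 / ni[b]))
        q <- abs(diffs[j]) / se
        padj[j] <- stats::ptukey(q, k, dfw, lower.tail = FALSE)
    }
    list(F = Fstat, p = p,
         pairwise = data.frame(pair = pair, diff = diffs, p_adj = padj,
                               stringsAsFactors = FALSE))
}

## md5 digest of a set of files, named by relative path.
dirDigest <- function(dir) {
    files <- sort(list.files(dir, recursive = TRUE, full.names = TRUE))
    md5 <- tools::md5sum(files)
    names(md5) <- sub(paste0("^", dir, "/?"), "", files)
    md5
}
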