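#' Window/depth profile of a host gene for one sample
#'
#' Realigns a sample's reads to a host-gene reference sequence and
#' summarises the gene with the same machinery as the HERV loci: the same
#' strict identity filter, the same window tiling, and the same usable
#' window rule. Reported per sample are the number of usable windows
#' (depth >= `minDepth`) and the mean per-base depth over the gene.
#'
#' @param reads named \link[Biostrings]{DNAStringSet}, named character
#'   vector, or FASTQ path.
#' @param geneRef a [HervReference-class] holding the single gene
#'   sequence (build one with [readLocusReference()] or
#'   [geneReference()]). A gene shorter than one window is an error.
#' @param windowSize,minDepth,identityThreshold as in [callLocus()] and
#'   [alignAndFilter()].
#' @param sampleId,group identifiers recorded on the result row.
#' @return one-row data.frame: `gene_id`, `sample_id`, `group`,
#'   `usable_windows`, `total_windows`, `mean_depth`, `n_reads`.
#' @export
geneWindowProfile <- function(reads, geneRef, windowSize = 500,
                              minDepth = 3, identityThreshold = 99,
                              sampleId = NA_character_,
                              group = NA_character_) {
    stopifnot(length(geneRef) == 1L)
    glen <- unname(locusLengths(geneRef))
    if (glen < windowSize)
        stop("gene is shorter than one window")
    aln <- alignAndFilter(reads, geneRef,
                          identityThreshold = identityThreshold)
    cov <- computeWindowCoverage(aln, glen, windowSize,
                                 locusId = locusIds(geneRef))
    depths <- windowDepths(cov)
    data.frame(gene_id = locusIds(geneRef), sample_id = sampleId,
               group = group,
               usable_windows = sum(depths >= minDepth),
               total_windows = length(depths),
               mean_depth = if (length(depths)) mean(depths) else 0,
               n_reads = nrow(aln), stringsAsFactors = FALSE)
}

#' Build a single-gene reference
#'
#' Convenience wrapper turning one named sequence into a
#' [HervReference-class] usable by [geneWindowProfile()]; the gene is
#' placed at position 1 of a pseudo-chromosome named after it.
#'
#' @param geneId gene name.
#' @param sequence nucleotide sequence (character or
#'   \link[Biostrings]{DNAString}).
#' @return a [HervReference-class] of length 1.
#' @export
geneReference <- function(geneId, sequence) {
    sequence <- Biostrings::DNAStringSet(as.character(sequence))
    names(sequence) <- geneId
    gr <- GenomicRanges::GRanges(geneId,
        IRanges::IRanges(1L, Biostrings::width(sequence)))
    names(gr) <- geneId
    newHervReference(gr, sequence)
}

#' Compare a gene metric across sample groups (ANOVA + Tukey HSD)
#'
#' One-way ANOVA across sample groups followed by Tukey's honestly
#' significant difference test over all unordered group pairs, applied to
#' a per-sample gene metric (`usable_windows` or `mean_depth`). This is
#' the group comparison used for host genes hosting a HERV locus, e.g.
#' PASC vs control PBMCs, or BAL samples stratified into HERV-positive
#' and HERV-negative subsets vs lung controls.
#'
#' @param stats data.frame with one row per sample, containing `group`
#'   and the metric column.
#' @param metric name of the metric column (default `"mean_depth"`).
#' @param alpha significance level for flagging pairs (default 0.05).
#' @return list of class `"GroupComparison"`: `metric`, `anova_F`,
#'   `anova_p`, `alpha`, and `pairwise`, a data.frame with one row per
#'   group pair (`pair`, `diff`, `lwr`, `upr`, `p_adj`, `significant`).
#'   With no between- or within-group variation the F statistic is
#'   undefined; the comparison is then reported non-significant with a
#'   warning.
#' @export
compareGroups <- function(stats, metric = "mean_depth", alpha = 0.05) {
    stopifnot(metric %in% names(stats), "group" %in% names(stats))
    g <- factor(stats$group)
    if (nlevels(g) < 2L)
        stop("need at least two groups")
    if (any(table(g) < 2L))
        stop("need at least two samples per group")
    y <- stats[[metric]]
    pairsOf <- function(levels) {
        cmb <- utils::combn(levels, 2L)
        paste(cmb[2L, ], cmb[1L, ], sep = "-")
    }
    if (stats::var(y) == 0) {
        warning("no variation in '", metric,
                "': F undefined, reporting non-significant")
        pw <- data.frame(pair = pairsOf(levels(g)), diff = 0, lwr = 0,
                         upr = 0, p_adj = 1, significant = FALSE,
                         stringsAsFactors = FALSE)
        out <- list(metric = metric, anova_F = NA_real_,
                    anova_p = NA_real_, alpha = alpha, pairwise = pw)
        class(out) <- "GroupComparison"
        return(out)
    }
    fit <- stats::aov(y ~ g)
    s <- summary(fit)[[1L]]
    tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$g
    pw <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                     lwr = tk[, "lwr"], upr = tk[, "upr"],
                     p_adj = tk[, "p adj"],
                     significant = tk[, "p adj"] < alpha,
                     stringsAsFactors = FALSE)
    rownames(pw) <- NULL
    out <- list(metric = metric,
                anova_F = s[["F value"]][1L],
                anova_p = s[["Pr(>F)"]][1L],
                alpha = alpha, pairwise = pw)
    class(out) <- "GroupComparison"
    out
}

#' @export
print.GroupComparison <- function(x, ...) {
    cat("Group comparison of", x$metric, "\n")
    cat(sprintf("  one-way ANOVA: F = %.4g, p = %.3g\n",
                x$anova_F, x$anova_p))
    cat("  Tukey HSD pairs (alpha =", x$alpha, "):\n")
    print(x$pairwise, row.names = FALSE)
    invisible(x)
}
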