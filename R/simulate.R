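#' Configuration for the synthetic cohort generator
#'
#' Bundles and validates every knob of the synthetic-data generator. The
#' defaults emulate the study conditions the package is built around: a
#' 12-patient / 30-control PBMC cohort, seven annotated cell types per
#' sample, duplicate technical runs per sample, near-full-length
#' (8-10 kb) autonomous HERV loci tiled into 500 bp windows (at least 16
#' full windows per locus), 90 bp reads and a low substitution error rate
#' (0.001) under which the large majority of reads survive the strict
#' >99 percent identity filter.
#'
#' @param seed integer master seed; every downstream draw derives a
#'   sub-seed from it, so outputs are byte-identical across runs.
#' @param nPatients,nControls cohort sizes.
#' @param cellTypes named integer vector: cells per annotated cell type.
#' @param readLength read length in bp.
#' @param substitutionErrorRate i.i.d. per-base substitution probability;
#'   must be below 0.01 so planted signal survives the identity filter in
#'   expectation.
#' @param windowSize WHA window width in bp.
#' @param nLoci number of synthetic HERV loci.
#' @param locusLengthRange two integers, uniform locus length range in bp.
#' @param duplicateRuns technical runs per sample.
#' @param tissue tissue label written to the sample sheet.
#' @return validated list of class `"SimConfig"`.
#' @export
simConfig <- function(seed = 1L, nPatients = 12L, nControls = 30L,
                      cellTypes = c(CD14_Mono = 50L, CD16_Mono = 25L,
                                    B = 40L, CD4_T = 60L, CD8_T = 40L,
                                    NK = 25L, DC = 10L),
                      readLength = 90L, substitutionErrorRate = 0.001,
                      windowSize = 500L, nLoci = 30L,
                      locusLengthRange = c(8000L, 10000L),
                      duplicateRuns = 2L, tissue = "PBMC") {
    cfg <- list(seed = as.integer(seed), nPatients = as.integer(nPatients),
                nControls = as.integer(nControls),
                cellTypes = cellTypes, readLength = as.integer(readLength),
                substitutionErrorRate = substitutionErrorRate,
                windowSize = as.integer(windowSize),
                nLoci = as.integer(nLoci),
                locusLengthRange = as.integer(locusLengthRange),
                duplicateRuns = as.integer(duplicateRuns), tissue = tissue)
    stopifnot(cfg$nPatients >= 1L, cfg$nControls >= 0L,
              all(cfg$cellTypes >= 1L), !is.null(names(cfg$cellTypes)),
              cfg$readLength >= 1L, cfg$windowSize >= 1L, cfg$nLoci >= 1L,
              cfg$duplicateRuns >= 1L,
              cfg$substitutionErrorRate >= 0,
              cfg$substitutionErrorRate < 1,
              length(cfg$locusLengthRange) == 2L,
              cfg$locusLengthRange[1L] <= cfg$locusLengthRange[2L])
    if (cfg$locusLengthRange[1L] < cfg$windowSize)
        stop("locusLengthRange must allow at least one full window")
    class(cfg) <- "SimConfig"
    cfg
}

#' Generate a synthetic HERV locus reference
#'
#' Draws `nLoci` random-sequence loci with lengths uniform in
#' `locusLengthRange`, places them at non-overlapping positions on
#' cycling chromosomes, and returns them as a [HervReference-class].
#' Deterministic given the config seed.
#'
#' @param config a [simConfig()] object.
#' @return a [HervReference-class].
#' @export
makeReference <- function(config) {
    withSeed(deriveSeed(config$seed, 104729), {
        lens <- sample(seq(config$locusLengthRange[1L],
                           config$locusLengthRange[2L]),
                       config$nLoci, replace = TRUE)
        chrom <- paste0("chr", ((seq_len(config$nLoci) - 1L) %% 22L) + 1L)
        start <- integer(config$nLoci)
        for (ch in unique(chrom)) {
            i <- which(chrom == ch)
            gaps <- sample(10000:500000, length(i), replace = TRUE)
            start[i] <- cumsum(gaps) +
                cumsum(c(0L, head(lens[i], -1L)))
        }
        end <- start + lens - 1L
        seqs <- Biostrings::DNAStringSet(vapply(lens, function(L) {
            paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                  collapse = "")
        }, ""))
        ids <- formatLocusId(chrom, start, end)
        names(seqs) <- ids
        gr <- GenomicRanges::GRanges(chrom,
            IRanges::IRanges(start = start, end = end))
        names(gr) <- ids
        newHervReference(gr, seqs)
    })
}

#' Build an expression plan for the synthetic cohort
#'
#' An expression plan states, per (group, cell type, locus), the expected
#' per-window read depth and the expressed fraction of the locus. A locus
#' absent from every `control` row is control-silent: no read is ever
#' simulated from it in a control sample. Fractions below 1 restrict
#' simulated reads to a prefix of the locus covering
#' `round(fraction * nWindows)` full windows, so tests can plant loci
#' with exactly k covered windows.
#'
#' @param group,cell_type,locus_id,depth,fraction vectors, recycled to a
#'   common length. `depth` is the expected mean per-window read depth;
#'   `fraction` is in (0, 1].
#' @param target `"herv"` rows enter the truth table of planted positives;
#'   `"gene"` rows simulate host-gene reads and stay out of it.
#' @return data.frame of class `"ExpressionPlan"`.
#' @export
expressionPlan <- function(group, cell_type, locus_id, depth,
                           fraction = 1, target = "herv") {
    plan <- data.frame(group = group, cell_type = cell_type,
                       locus_id = locus_id, depth = depth,
                       fraction = fraction, target = target,
                       stringsAsFactors = FALSE)
    stopifnot(all(plan$depth >= 0), all(plan$fraction > 0),
              all(plan$fraction <= 1),
              all(plan$group %in% c("patient", "control")),
              all(plan$target %in% c("herv", "gene")))
    class(plan) <- c("ExpressionPlan", "data.frame")
    plan
}

#' Simulate reads from a single sequence
#'
#' Low-level read generator shared by the cohort simulator: draws read
#' start positions uniformly over a covered prefix of the sequence, so
#' that the expected mean per-base depth over the covered region equals
#' `depth`, and injects i.i.d. substitution errors.
#'
#' @param sequence character scalar nucleotide sequence.
#' @param depth expected mean per-base depth over the covered region.
#' @param coveredLength length in bp of the covered prefix (defaults to
#'   the full sequence).
#' @param readLength read length in bp.
#' @param errorRate per-base substitution probability.
#' @param n exact number of reads to draw; by default Poisson with mean
#'   `depth * coveredLength / readLength`.
#' @return character vector of read sequences.
#' @export
simulateReads <- function(sequence, depth, coveredLength = nchar(sequence),
                          readLength = 90L, errorRate = 0,
                          n = NULL) {
    coveredLength <- min(as.integer(coveredLength), nchar(sequence))
    if (coveredLength < readLength)
        stop("covered region (", coveredLength,
             " bp) is shorter than the read length")
    if (is.null(n))
        n <- stats::rpois(1L, depth * coveredLength / readLength)
    if (n == 0L) return(character(0))
    starts <- sample.int(coveredLength - readLength + 1L, n,
                         replace = TRUE)
    reads <- substring(sequence, starts, starts + readLength - 1L)
    injectSubstitutions(reads, errorRate)
}

## i.i.d. per-base substitutions: per read, a Binomial(readLength, rate)
## error count at uniform positions without replacement, substituting a
## uniformly chosen different base.
injectSubstitutions <- function(reads, rate) {
    if (rate <= 0 || length(reads) == 0L) return(reads)
    rl <- nchar(reads)
    nerr <- stats::rbinom(length(reads), rl, rate)
    for (i in which(nerr > 0L)) {
        pos <- sample.int(rl[i], nerr[i])
        for (p in pos) {
            orig <- substring(reads[i], p, p)
            repl <- sample(setdiff(c("A", "C", "G", "T"), orig), 1L)
            substring(reads[i], p, p) <- repl
        }
    }
    reads
}

#' Simulate a patient/control cohort with planted HERV activity
#'
#' Generates, for every sample of the configured cohort, per-run FASTQ
#' files (reads carry their cell barcode in the read name), a per-sample
#' barcode-to-cell-type annotation TSV with mapping scores, a cohort
#' sample sheet, and a ground-truth table listing every planted positive
#' (sample, cell type, locus) triple — every plan row whose planted depth
#' and covered-window count meet the positive-call thresholds, expanded
#' over the samples of its group. Duplicate runs are independent draws
#' under distinct derived sub-seeds; the whole output is byte-identical
#' across repeated calls with the same config.
#'
#' @param config a [simConfig()] object.
#' @param plan an [expressionPlan()]; rows referencing loci absent from
#'   `reference` are an error.
#' @param reference the [HervReference-class] to draw reads from (HERV
#'   loci, plus any host-gene sequences referenced by `target = "gene"`
#'   plan rows).
#' @param outDir output directory, created if needed.
#' @param truthMinDepth,truthMinUsableWindows thresholds defining which
#'   planted (group, cell type, locus) rows count as planted positives.
#' @return invisibly, a list with `sampleSheet` (data.frame), `truth`
#'   (data.frame sample_id/cell_type/locus_id) and the output paths.
#' @export
simulateCohort <- function(config, plan, reference, outDir,
                           truthMinDepth = 3,
                           truthMinUsableWindows = 9) {
    stopifnot(inherits(config, "SimConfig"))
    bad <- setdiff(plan$locus_id, locusIds(reference))
    if (length(bad))
        stop("expression plan references unknown locus: ",
             paste(head(bad, 3), collapse = ", "))
    bad <- setdiff(plan$cell_type, names(config$cellTypes))
    if (length(bad))
        stop("expression plan references unknown cell type: ",
             paste(head(bad, 3), collapse = ", "))
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)

    samples <- data.frame(
        sample_id = c(sprintf("patient%02d", seq_len(config$nPatients)),
                      sprintf("control%02d", seq_len(config$nControls))),
        group = rep(c("patient", "control"),
                    c(config$nPatients, config$nControls)),
        tissue = config$tissue, stringsAsFactors = FALSE)

    seqs <- as.character(locusSequences(reference))
    lens <- locusLengths(reference)
    truth <- list()
    annPaths <- character(nrow(samples))
    runPaths <- matrix("", nrow(samples), config$duplicateRuns)

    for (s in seq_len(nrow(samples))) {
        sid <- samples$sample_id[s]
        ann <- withSeed(deriveSeed(config$seed, s, 0L),
                        makeAnnotations(config))
        annPaths[s] <- file.path(outDir, paste0(sid, "_annotations.tsv"))
        utils::write.table(ann, annPaths[s], sep = "\t", quote = FALSE,
                           row.names = FALSE)
        rows <- plan[plan$group == samples$group[s], , drop = FALSE]
        for (r in seq_len(config$duplicateRuns)) {
            reads <- withSeed(deriveSeed(config$seed, s, r),
                sampleRunReads(rows, config, ann, seqs, lens, sid, r))
            runPaths[s, r] <- file.path(outDir,
                sprintf("%s_run%d.fastq", sid, r))
            writeFastq(reads, runPaths[s, r])
        }
        planted <- rows$target == "herv" &
            rows$depth >= truthMinDepth &
            round(rows$fraction *
                  nWindows(lens[rows$locus_id], config$windowSize)) >=
                truthMinUsableWindows
        if (any(planted))
            truth[[sid]] <- data.frame(sample_id = sid,
                cell_type = rows$cell_type[planted],
                locus_id = rows$locus_id[planted],
                stringsAsFactors = FALSE)
    }

    truth <- if (length(truth)) do.call(rbind, truth)
             else data.frame(sample_id = character(),
                             cell_type = character(),
                             locus_id = character())
    rownames(truth) <- NULL
    truthPath <- file.path(outDir, "truth.tsv")
    utils::write.table(truth, truthPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)

    sheet <- cbind(samples,
                   as.data.frame(stats::setNames(
                       as.data.frame(runPaths, stringsAsFactors = FALSE),
                       paste0("run", seq_len(config$duplicateRuns)))),
                   annotation = annPaths, stringsAsFactors = FALSE)
    sheetPath <- file.path(outDir, "samples.tsv")
    writeSampleSheet(sheet, sheetPath)
    invisible(list(sampleSheet = sheet, truth = truth,
                   sampleSheetPath = sheetPath, truthPath = truthPath,
                   dir = outDir))
}

makeAnnotations <- function(config) {
    nb <- sum(config$cellTypes)
    repeat {
        bcs <- vapply(seq_len(nb), function(i)
            paste(sample(c("A", "C", "G", "T"), 16L, replace = TRUE),
                  collapse = ""), "")
        if (!anyDuplicated(bcs)) break
    }
    data.frame(barcode = bcs,
               cell_type = rep(names(config$cellTypes), config$cellTypes),
               mapping_score = round(stats::runif(nb, 0.8, 1), 3),
               stringsAsFactors = FALSE)
}

sampleRunReads <- function(rows, config, ann, seqs, lens, sid, run) {
    out <- list()
    for (i in seq_len(nrow(rows))) {
        if (rows$depth[i] <= 0) next
        lid <- rows$locus_id[i]
        nw <- nWindows(lens[[lid]], config$windowSize)
        covw <- max(1L, as.integer(round(rows$fraction[i] * nw)))
        covlen <- min(covw * config$windowSize, lens[[lid]])
        reads <- simulateReads(seqs[[lid]], rows$depth[i], covlen,
                               config$readLength,
                               config$substitutionErrorRate)
        if (!length(reads)) next
        pool <- ann$barcode[ann$cell_type == rows$cell_type[i]]
        bc <- sample(pool, length(reads), replace = TRUE)
        names(reads) <- sprintf("%s.r%d.%s.%05d|%s", sid, run,
                                gsub("[^A-Za-z0-9]", "", lid),
                                seq_along(reads), bc)
        out[[length(out) + 1L]] <- reads
    }
    if (!length(out)) return(character(0))
    unlist(out)
}

writeFastq <- function(reads, path) {
    if (length(reads) == 0L) {
        file.create(path)
        return(invisible(path))
    }
    x <- Biostrings::DNAStringSet(reads)
    qual <- Biostrings::BStringSet(strrep("I", nchar(reads)))
    Biostrings::writeXStringSet(x, path, format = "fastq",
                                qualities = qual)
    invisible(path)
}
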