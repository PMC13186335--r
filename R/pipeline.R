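#' Run WHA calling over a cohort sample sheet
#'
#' For every sample and duplicate run in the sheet: reads the run's
#' FASTQ, aligns all reads to the locus reference through the strict
#' identity filter, attributes each retained alignment to a cell type via
#' the sample's barcode annotations, computes per-locus window coverage
#' and run-level positive/negative calls per (cell type, locus), and
#' finally collapses duplicate runs by [consensusCall()].
#'
#' @param sheet sample sheet data.frame ([readSampleSheet()] format).
#' @param reference a [HervReference-class].
#' @param windowSize,minDepth,minUsableWindows,identityThreshold WHA
#'   thresholds (defaults 500, 3, 9, 99).
#' @param consensus duplicate-run consensus mode for [consensusCall()].
#' @param minMappingScore annotation filter passed to
#'   [readCellAnnotations()].
#' @param logFun optional function(character) receiving stage log lines.
#' @return list: `runCalls` (run-level call data.frame), `calls`
#'   (consensus calls), `alignments` (retained alignments with
#'   `sample_id`, `cell_type`, `run_id` columns), `filterStats`
#'   (per sample/run retained/discarded accounting).
#' @export
whaCallCohort <- function(sheet, reference, windowSize = 500,
                          minDepth = 3, minUsableWindows = 9,
                          identityThreshold = 99,
                          consensus = "intersection",
                          minMappingScore = 0, logFun = NULL) {
    lens <- locusLengths(reference)
    runCols <- runColumns(sheet)
    allRun <- list(); allAln <- list(); statRows <- list()
    for (s in seq_len(nrow(sheet))) {
        sid <- sheet$sample_id[s]
        ann <- readCellAnnotations(sheet$annotation[s],
                                   minMappingScore = minMappingScore)
        sampleRuns <- list()
        for (rc in runCols) {
            path <- sheet[[rc]][s]
            if (is.na(path) || !nzchar(path)) next
            reads <- readFastqReads(path)
            aln <- alignAndFilter(reads, reference,
                                  identityThreshold = identityThreshold)
            st <- attr(aln, "stats")
            ct <- ann$cell_type[match(aln$barcode, ann$barcode)]
            ct[is.na(ct)] <- "unannotated"
            aln$sample_id <- rep(sid, nrow(aln))
            aln$cell_type <- ct
            aln$run_id <- rep(rc, nrow(aln))
            if (!is.null(logFun))
                logFun(sprintf(paste0("call %s/%s: %d reads, %d retained,",
                    " %d below identity, %d ambiguous, %d unaligned,",
                    " %d unannotated"),
                    sid, rc, st[["input"]], st[["retained"]],
                    st[["below_identity"]], st[["ambiguous"]],
                    st[["unaligned"]], sum(ct == "unannotated")))
            statRows[[paste(sid, rc)]] <- data.frame(sample_id = sid,
                run_id = rc, t(st), unannotated = sum(ct == "unannotated"))
            allAln[[paste(sid, rc)]] <- aln
            keep <- aln$cell_type != "unannotated"
            groups <- split(which(keep),
                paste(aln$cell_type[keep], aln$locus_id[keep],
                      sep = "\r"))
            calls <- lapply(names(groups), function(k) {
                parts <- strsplit(k, "\r", fixed = TRUE)[[1L]]
                cov <- computeWindowCoverage(
                    aln[groups[[k]], , drop = FALSE],
                    lens[[parts[2L]]], windowSize,
                    locusId = parts[2L], sampleId = sid,
                    cellType = parts[1L], runId = rc)
                callLocus(cov, minDepth, minUsableWindows)
            })
            sampleRuns[[rc]] <- if (length(calls)) do.call(rbind, calls)
                else emptyCalls()
        }
        allRun[[sid]] <- completeRunCalls(sampleRuns, sid)
    }
    runCalls <- do.call(rbind, c(allRun, list(emptyCalls())))
    rownames(runCalls) <- NULL
    cons <- suppressWarnings(
        consensusCall(runCalls, mode = consensus,
                      expectedRuns = length(runCols)))
    list(runCalls = runCalls, calls = cons,
         alignments = do.call(rbind, c(allAln,
             list(emptyAlignments()))),
         filterStats = do.call(rbind, statRows))
}

emptyCalls <- function() {
    data.frame(locus_id = character(), sample_id = character(),
               cell_type = character(), run_id = character(),
               usable_windows = integer(), status = character(),
               raw_read_count = integer(), stringsAsFactors = FALSE)
}

emptyAlignments <- function() {
    data.frame(read_id = character(), barcode = character(),
               locus_id = character(), start_offset = integer(),
               aligned_length = integer(), matches = integer(),
               percent_identity = numeric(), sample_id = character(),
               cell_type = character(), run_id = character(),
               stringsAsFactors = FALSE)
}

## A (cell type, locus) pair covered in one run but not another must be
## an explicit zero-coverage negative in the other, so that duplicate-run
## consensus sees every run.
completeRunCalls <- function(sampleRuns, sid) {
    if (!length(sampleRuns)) return(emptyCalls())
    pairs <- unique(do.call(rbind, lapply(sampleRuns, function(x)
        x[, c("locus_id", "cell_type"), drop = FALSE])))
    out <- lapply(names(sampleRuns), function(rc) {
        x <- sampleRuns[[rc]]
        have <- paste(x$locus_id, x$cell_type)
        need <- pairs[!(paste(pairs$locus_id, pairs$cell_type) %in% have),
                      , drop = FALSE]
        if (nrow(need)) {
            fill <- data.frame(locus_id = need$locus_id, sample_id = sid,
                cell_type = need$cell_type, run_id = rc,
                usable_windows = 0L, status = "negative",
                raw_read_count = 0L, stringsAsFactors = FALSE)
            x <- rbind(x, fill)
        }
        x
    })
    do.call(rbind, out)
}

#' Run the full synthetic WHA pipeline
#'
#' Orchestrates simulate, call, cohort and (optionally) host-gene stages
#' end to end, writing every stage output, a plain-text log, and a JSON
#' run manifest under `outDir`. Re-running with the same configuration
#' and seed reproduces byte-identical TSV outputs; any stage failure
#' aborts with the failing stage named.
#'
#' @param config a [simConfig()]; its seed drives all randomness.
#' @param plan an [expressionPlan()] of planted activity.
#' @param outDir output directory.
#' @param minDepth,minUsableWindows,identityThreshold,topN,alpha,consensus
#'   analysis thresholds; the defaults (3, 9, 99, 10, 0.05,
#'   intersection) are the method's published operating point.
#' @param subsets cell types for the subset-intersection stage.
#' @param geneRef optional [HervReference-class] of a host gene; when
#'   given (together with `target = "gene"` plan rows) the gene stage
#'   profiles it per sample and compares groups by ANOVA + Tukey.
#' @param stratifyLocus,stratifyCellType optional: stratify patient
#'   samples into HERV-positive / HERV-negative groups for the gene
#'   comparison, by the consensus call of this locus in this cell type.
#' @return invisibly, a list of all stage results (`truth`, `calls`,
#'   `matrices`, `top`, `intersection`, `crossCellType`, `geneStats`,
#'   `geneComparisons`, `manifestPath`, `dir`).
#' @export
runPipeline <- function(config, plan, outDir,
                        minDepth = 3, minUsableWindows = 9,
                        identityThreshold = 99, topN = 10, alpha = 0.05,
                        consensus = "intersection",
                        subsets = c("CD14_Mono", "CD16_Mono"),
                        geneRef = NULL, stratifyLocus = NULL,
                        stratifyCellType = "CD14_Mono") {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    logPath <- file.path(outDir, "log.txt")
    logCon <- file(logPath, open = "wt")
    on.exit(close(logCon), add = TRUE)
    logFun <- function(line) writeLines(line, logCon)
    stage <- function(name, expr) {
        logFun(paste0("stage ", name, ": start"))
        res <- tryCatch(expr, error = function(e)
            stop("pipeline stage '", name, "' failed: ",
                 conditionMessage(e), call. = FALSE))
        logFun(paste0("stage ", name, ": done"))
        res
    }

    reference <- stage("reference", makeReference(config))
    simDir <- file.path(outDir, "sim")
    sim <- stage("simulate", {
        simRef <- if (is.null(geneRef)) reference else
            newHervReference(
                suppressWarnings(c(locusRanges(reference),
                                   locusRanges(geneRef))),
                c(locusSequences(reference), locusSequences(geneRef)))
        simulateCohort(config, plan, simRef, simDir,
                       truthMinDepth = minDepth,
                       truthMinUsableWindows = minUsableWindows)
    })

    refDir <- file.path(outDir, "reference")
    dir.create(refDir, showWarnings = FALSE)
    writeReference(reference, file.path(refDir, "herv_loci.fa"),
                   file.path(refDir, "herv_loci.bed"))

    res <- stage("call", whaCallCohort(sim$sampleSheet, reference,
        windowSize = config$windowSize, minDepth = minDepth,
        minUsableWindows = minUsableWindows,
        identityThreshold = identityThreshold,
        consensus = consensus, logFun = logFun))
    callDir <- file.path(outDir, "calls")
    dir.create(callDir, showWarnings = FALSE)
    writeTsv(res$runCalls, file.path(callDir, "run_level_calls.tsv"))
    writeTsv(res$calls, file.path(callDir, "consensus_calls.tsv"))
    writeTsv(res$filterStats, file.path(callDir, "filter_stats.tsv"))

    cohort <- stage("cohort", {
        sheet <- sim$sampleSheet
        ctrlIds <- sheet$sample_id[sheet$group == "control"]
        patIds <- sheet$sample_id[sheet$group == "patient"]
        idx <- buildControlIndex(res$alignments, ctrlIds,
                                 locusIds(reference))
        cellTypes <- sort(unique(res$calls$cell_type))
        matrices <- lapply(cellTypes, function(ct) {
            pc <- res$calls[res$calls$cell_type == ct &
                            res$calls$sample_id %in% patIds, ,
                            drop = FALSE]
            filterPatientLoci(pc, idx, cellTypeLabel = ct,
                              samples = patIds)
        })
        names(matrices) <- cellTypes
        top <- lapply(matrices, rankAndSelectTop, n = topN)
        inter <- if (all(subsets %in% names(matrices)))
            intersectSubsets(matrices[subsets]) else NULL
        xct <- crossCellTypeSummary(matrices)
        list(controlIndex = idx, matrices = matrices, top = top,
             intersection = inter, crossCellType = xct)
    })
    cohDir <- file.path(outDir, "cohort")
    dir.create(cohDir, showWarnings = FALSE)
    writeTsv(cohort$controlIndex, file.path(cohDir, "control_index.tsv"))
    for (ct in names(cohort$matrices)) {
        writePresenceMatrix(cohort$matrices[[ct]],
            file.path(cohDir, paste0("matrix_", ct, ".tsv")))
        writePresenceMatrix(cohort$top[[ct]],
            file.path(cohDir, paste0("top_", ct, ".tsv")))
    }
    if (!is.null(cohort$intersection)) {
        writeTsv(cohort$intersection$counts,
                 file.path(cohDir, "intersection_counts.tsv"))
        writeTsv(cohort$intersection$membership,
                 file.path(cohDir, "intersection_membership.tsv"))
    }
    writeTsv(cohort$crossCellType,
             file.path(cohDir, "cross_celltype.tsv"))

    geneStats <- NULL; geneComparisons <- NULL
    if (!is.null(geneRef)) {
        gene <- stage("gene", {
            sheet <- sim$sampleSheet
            rows <- lapply(seq_len(nrow(sheet)), function(s) {
                sid <- sheet$sample_id[s]
                prof <- lapply(runColumns(sheet), function(rc)
                    geneWindowProfile(sheet[[rc]][s], geneRef,
                        windowSize = config$windowSize,
                        minDepth = minDepth,
                        identityThreshold = identityThreshold,
                        sampleId = sid, group = sheet$group[s]))
                prof <- do.call(rbind, prof)
                out <- prof[1L, , drop = FALSE]
                out$usable_windows <- mean(prof$usable_windows)
                out$mean_depth <- mean(prof$mean_depth)
                out$n_reads <- sum(prof$n_reads)
                out
            })
            st <- do.call(rbind, rows)
            if (!is.null(stratifyLocus)) {
                key <- res$calls[res$calls$locus_id == stratifyLocus &
                                 res$calls$cell_type == stratifyCellType &
                                 res$calls$status == "positive",
                                 "sample_id"]
                pat <- st$group == "patient"
                st$group[pat] <- ifelse(st$sample_id[pat] %in% key,
                                        "HERV_positive", "HERV_negative")
            }
            cmp <- lapply(c("usable_windows", "mean_depth"),
                          function(m) compareGroups(st, m, alpha))
            names(cmp) <- c("usable_windows", "mean_depth")
            list(stats = st, comparisons = cmp)
        })
        geneStats <- gene$stats
        geneComparisons <- gene$comparisons
        geneDir <- file.path(outDir, "gene")
        dir.create(geneDir, showWarnings = FALSE)
        writeTsv(geneStats, file.path(geneDir, "gene_stats.tsv"))
        cmpTab <- do.call(rbind, lapply(names(geneComparisons),
            function(m) {
                x <- geneComparisons[[m]]
                data.frame(metric = m, pair = x$pairwise$pair,
                           diff = x$pairwise$diff,
                           p_adj = x$pairwise$p_adj,
                           significant = x$pairwise$significant,
                           anova_F = x$anova_F, anova_p = x$anova_p,
                           stringsAsFactors = FALSE)
            }))
        writeTsv(cmpTab, file.path(geneDir, "group_comparisons.tsv"))
    }

    manifest <- list(
        package = "WHAseq",
        version = as.character(utils::packageVersion("WHAseq")),
        seed = config$seed,
        config = unclass(config),
        thresholds = list(windowSize = config$windowSize,
            minDepth = minDepth, minUsableWindows = minUsableWindows,
            identityThreshold = identityThreshold, topN = topN,
            alpha = alpha, consensus = consensus))
    manifest$config_md5 <- digestList(manifest)
    manifestPath <- file.path(outDir, "manifest.json")
    jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    logFun("pipeline: done")

    invisible(list(reference = reference, truth = sim$truth,
                   sampleSheet = sim$sampleSheet,
                   runCalls = res$runCalls, calls = res$calls,
                   alignments = res$alignments,
                   controlIndex = cohort$controlIndex,
                   matrices = cohort$matrices, top = cohort$top,
                   intersection = cohort$intersection,
                   crossCellType = cohort$crossCellType,
                   geneStats = geneStats,
                   geneComparisons = geneComparisons,
                   manifestPath = manifestPath, dir = outDir))
}

writeTsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

digestList <- function(x) {
    tmp <- tempfile()
    on.exit(unlink(tmp))
    writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA), tmp)
    unname(tools::md5sum(tmp))
}
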