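#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end run in one flat list. Defaults
#' follow the published analysis settings where the method states them
#' (minimum total count 100, coverage fraction 2/3, robust-CV threshold 1,
#' 10 latent variables, 5 CV folds, alpha 0.05); every interpretation that
#' was genuinely open is an explicit switch (`coverageMode`,
#' `logTransform`, `inertia`, `lambdaRule`, `sdFilter`).
#'
#' @param synthetic a `SyntheticConfig` ([syntheticConfig()]) to simulate a
#'   cohort, or `NULL` to read one from `inputDir`.
#' @param inputDir directory with `block_*.tsv` and `metadata.tsv` (see
#'   [writeCohort()]); ignored when `synthetic` is given.
#' @param outputDir where to write the report and intermediates (`NULL`:
#'   in-memory only).
#' @param minTotal,coverageFraction,coverageMode,rcvThreshold,mTrim,aTrim,logTransform
#'   preprocessing settings, see [preprocessBlock()].
#' @param inertia block scaling convention, see [standardizeBlock()].
#' @param nComponents latent variables to extract and evaluate.
#' @param solver,tol,maxIter see [fitMCIA()].
#' @param folds,lambdaRule,sdFilter,seedCV Lasso settings, see
#'   [lassoSelect()].
#' @param positiveGroups diagnosis labels forming the positive class.
#' @param heldOutGroups labels excluded from fitting and projected
#'   afterwards.
#' @param alpha significance threshold for the group rank-sum tests.
#' @return list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(synthetic = NULL, inputDir = NULL,
    outputDir = NULL, minTotal = 100, coverageFraction = 2 / 3,
    coverageMode = "both", rcvThreshold = 1, mTrim = 0.30, aTrim = 0.05,
    logTransform = TRUE, inertia = "root", nComponents = 10,
    solver = "svd", tol = 1e-9, maxIter = 1000, folds = 5,
    lambdaRule = "min", sdFilter = FALSE, seedCV = 1L,
    positiveGroups = c("RRMS", "CIS", "RIS"), heldOutGroups = "SPMS",
    alpha = 0.05) {
    if (is.null(synthetic) && is.null(inputDir))
        stop("either 'synthetic' or 'inputDir' must be given")
    if (!is.null(inputDir) && is.null(synthetic) && !dir.exists(inputDir))
        stop("input directory does not exist: ", inputDir)
    if (!length(positiveGroups)) stop("'positiveGroups' must be non-empty")
    structure(as.list(environment()), class = "PipelineConfig")
}

.configHash <- function(config) {
    tmp <- tempfile(fileext = ".json")
    on.exit(unlink(tmp))
    cfg <- config
    cfg$outputDir <- NULL
    jsonlite::write_json(cfg[order(names(cfg))], tmp, auto_unbox = TRUE,
        digits = NA, force = TRUE)
    unname(tools::md5sum(tmp))
}

.splitBlock <- function(block, idx) {
    OmicsBlock(block@values[idx, , drop = FALSE], block@assay, block@source)
}

#' Run the full integration pipeline
#'
#' Orchestrates simulate/read, per-assay preprocessing, standardization,
#' co-inertia fitting, per-component AUROC/split-join evaluation, Lasso
#' feature reduction with reduced-model refit and rank comparison,
#' projection of the held-out group onto the latent space, and group
#' rank-sum tests. Held-out samples never enter the filters, the TMM
#' reference choice, the fit, or the cross-validation; they are projected
#' with the training standardization parameters only.
#'
#' @param config a `PipelineConfig` from [pipelineConfig()].
#' @return A list of class `RunReport` with elements `filterCounts`,
#'   `componentTable`, `contributions`, `selection`, `selectionSummary`,
#'   `reducedEval`, `rankComparison`, `projection`, `groupTests`,
#'   `models` (full, reduced), `manifest`.
#' @examples
#' cfg <- pipelineConfig(synthetic = syntheticConfig(
#'     nPerGroup = c(positive = 8L, control = 8L, progressive = 3L),
#'     featuresPerBlock = c(plasma_smallseq = 60, csf_free_mintmap = 40),
#'     seed = 11), nComponents = 3)
#' rep <- runPipeline(cfg)
#' rep$componentTable
#' @export
runPipeline <- function(config) {
    stopifnot(inherits(config, "PipelineConfig"))
    stage <- "input"
    tryCatch({
        cohort <- if (!is.null(config$synthetic))
            generateCohort(config$synthetic)
        else readCohort(config$inputDir)
        md <- cohort$metadata
        fitIdx <- !md$group %in% config$heldOutGroups
        if (sum(fitIdx) < 3L) stop("too few fitting samples")
        fitLabels <- md$group[fitIdx]
        binLabels <- ifelse(fitLabels %in% config$positiveGroups,
            "positive", "control")

        stage <- "preprocess"
        prep <- list()
        filterCounts <- list()
        for (bn in names(cohort$blocks)) {
            blk <- cohort$blocks[[bn]]
            fitBlk <- .splitBlock(blk, which(fitIdx))
            heldBlk <- if (any(!fitIdx)) .splitBlock(blk, which(!fitIdx))
                else NULL
            pp <- preprocessBlock(fitBlk, groupLabels = binLabels,
                minTotal = config$minTotal,
                coverageFraction = config$coverageFraction,
                coverageMode = config$coverageMode,
                rcvThreshold = config$rcvThreshold, mTrim = config$mTrim,
                aTrim = config$aTrim, logTransform = config$logTransform,
                heldOut = heldBlk)
            for (rn in names(pp$reports))
                filterCounts[[paste(bn, rn)]] <- data.frame(block = bn,
                    rule = rn, n_before = pp$reports[[rn]]@nBefore,
                    n_after = pp$reports[[rn]]@nAfter,
                    stringsAsFactors = FALSE)
            if (ncol(blockValues(pp$block)) == 0L) {
                warning("block ", bn, " lost all features during filtering")
                next
            }
            prep[[bn]] <- pp
        }
        if (!length(prep)) stop("no block survived preprocessing")
        filterCounts <- do.call(rbind, c(filterCounts,
            make.row.names = FALSE))

        stage <- "fit"
        fitBlocks <- lapply(prep, `[[`, "block")
        std <- lapply(fitBlocks, standardizeBlock, inertia = config$inertia)
        K <- min(config$nComponents, sum(fitIdx) - 1L,
            sum(vapply(std, function(b) ncol(b@values), integer(1))))
        full <- fitMCIA(std, nComponents = K, sampleLabels = fitLabels,
            solver = config$solver, tol = config$tol,
            maxIter = config$maxIter)

        stage <- "evaluate"
        compTab <- evaluateComponents(full,
            positive = config$positiveGroups)
        contrib <- blockContributions(full, fractions = TRUE)

        stage <- "select"
        sel <- lassoSelect(full, component = 1, folds = config$folds,
            seed = config$seedCV, lambdaRule = config$lambdaRule,
            sdFilter = config$sdFilter)
        reduced <- NULL
        reducedEval <- NULL
        rankCmp <- NULL
        if (nrow(sel@selected)) {
            stage <- "refit"
            reduced <- reduceAndRefit(fitBlocks, sel,
                nComponents = min(K, nrow(sel@selected), sum(fitIdx) - 1L),
                sampleLabels = fitLabels)
            reducedEval <- evaluateComponents(reduced, components = 1,
                positive = config$positiveGroups)
            rankCmp <- compareRanks(full, reduced)
        }

        stage <- "project"
        projection <- NULL
        if (any(!fitIdx)) {
            heldBlocks <- lapply(prep, `[[`, "heldOut")
            if (!any(vapply(heldBlocks, is.null, logical(1)))) {
                ps <- projectSamples(full, heldBlocks)
                projection <- data.frame(sample_id = sampleIds(ps),
                    group = md$group[!fitIdx][match(sampleIds(ps),
                        md$sample_id[!fitIdx])],
                    globalScores(ps), check.names = FALSE,
                    stringsAsFactors = FALSE)
            }
        }

        stage <- "test"
        groupTests <- .groupTests(full, projection, md, fitIdx, config)

        stage <- "report"
        report <- list(
            filterCounts = filterCounts,
            componentTable = compTab,
            contributions = contrib,
            selection = list(n_selected = nrow(sel@selected),
                lambda = sel@lambda,
                per_block = as.list(table(sel@selected$block)),
                dropped_blocks = sel@droppedBlocks,
                fold_seed = sel@foldSeed,
                selected = sel@selected),
            selectionSummary = summarizeSelection(sel,
                blockInfo = .blockInfoFrom(prep)),
            reducedEval = reducedEval,
            rankComparison = if (is.null(rankCmp)) NULL else
                list(rho = rankCmp$rho, table = rankCmp$table),
            projection = projection,
            groupTests = groupTests,
            nFeaturesFull = nrow(full@loadings),
            models = list(full = full, reduced = reduced),
            truth = cohort$truth,
            manifest = list(config_hash = .configHash(config),
                seed_generator = if (!is.null(config$synthetic))
                    config$synthetic$seed else NA_integer_,
                seed_cv = config$seedCV,
                n_fit = sum(fitIdx), n_held_out = sum(!fitIdx)))
        class(report) <- "RunReport"
        if (!is.null(config$outputDir)) .writeReport(report, config)
        report
    }, error = function(e) {
        stop("pipeline failed at stage '", stage, "': ",
            conditionMessage(e), call. = FALSE)
    })
}

.blockInfoFrom <- function(prep) {
    data.frame(block = names(prep),
        source = vapply(prep, function(p) p$block@source, character(1)),
        assay = vapply(prep, function(p) p$block@assay, character(1)),
        stringsAsFactors = FALSE)
}

.groupTests <- function(full, projection, md, fitIdx, config) {
    L1 <- full@globalScores[, 1]
    fitMd <- md[fitIdx, , drop = FALSE]
    pos <- fitMd$group %in% config$positiveGroups
    tests <- list()
    addTest <- function(name, x, y) {
        if (length(x) < 2L || length(y) < 2L) return()
        rs <- rankSumTest(x, y)
        tests[[length(tests) + 1L]] <<- data.frame(comparison = name,
            n1 = length(x), n2 = length(y), statistic = rs$statistic,
            p_value = rs$p.value,
            significant = rs$p.value < config$alpha,
            stringsAsFactors = FALSE)
    }
    addTest("positive_vs_control", L1[pos], L1[!pos])
    ph <- fitMd$phase[pos]
    if (all(c("relapse", "remission") %in% ph))
        addTest("relapse_vs_remission", L1[pos][ph == "relapse"],
            L1[pos][ph == "remission"])
    ctl <- fitMd$group[!pos]
    if (all(c("INDC", "NINDC") %in% ctl))
        addTest("indc_vs_nindc", L1[!pos][ctl == "INDC"],
            L1[!pos][ctl == "NINDC"])
    if (!is.null(projection)) {
        pL1 <- projection[["L1"]]
        addTest("heldout_vs_positive", pL1, L1[pos])
        addTest("heldout_vs_control", pL1, L1[!pos])
    }
    do.call(rbind, tests)
}

.writeReport <- function(report, config) {
    dir <- config$outputDir
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    wtsv <- function(df, name) utils::write.table(df,
        file.path(dir, name), sep = "\t", quote = FALSE,
        row.names = FALSE)
    wtsv(report$filterCounts, "filter_counts.tsv")
    wtsv(report$componentTable, "component_table.tsv")
    full <- report$models$full
    wtsv(data.frame(sample_id = sampleIds(full),
        group = full@sampleLabels, globalScores(full),
        check.names = FALSE), "global_scores.tsv")
    if (!is.null(report$projection))
        wtsv(report$projection, "projected_scores.tsv")
    if (!is.null(report$groupTests))
        wtsv(report$groupTests, "group_tests.tsv")
    contrib <- as.data.frame(report$contributions)
    contrib <- cbind(block = rownames(report$contributions), contrib)
    wtsv(contrib, "contributions.tsv")
    roc <- aurocByRelocation(globalScores(full)[, 1], full@sampleLabels,
        config$positiveGroups)
    wtsv(rocPoints(roc), "roc_points_L1.tsv")
    json <- report[c("selection", "selectionSummary", "rankComparison",
        "nFeaturesFull", "manifest")]
    json$reducedEval <- report$reducedEval
    json$filterCounts <- report$filterCounts
    jsonlite::write_json(json, file.path(dir, "report.json"),
        auto_unbox = TRUE, digits = NA, force = TRUE, pretty = TRUE)
    invisible(dir)
}

#' @export
print.RunReport <- function(x, ...) {
    cat("RunReport\n")
    cat(sprintf("  features in full model: %d\n", x$nFeaturesFull))
    best <- x$componentTable[x$componentTable$best, ]
    cat(sprintf("  best component: L%d (AUC %.3f, split-join %d)\n",
        best$component, best$auc, best$split_join))
    if (!is.null(x$reducedEval))
        cat(sprintf("  reduced model: %d features, AUC %.3f, split-join %d\n",
            x$selection$n_selected, x$reducedEval$auc,
            x$reducedEval$split_join))
    if (!is.null(x$rankComparison))
        cat(sprintf("  full-vs-reduced rank correlation: %.3f\n",
            x$rankComparison$rho))
    invisible(x)
}

#' Percentage with half-up rounding to one decimal
#'
#' Report percentages are always the plain count ratio times 100, rounded
#' half-up to one decimal (so 19/32 prints as 59.4 and 2/32 as 6.3).
#'
#' @param count,total non-negative counts, `total > 0`.
#' @return numeric percentage(s) rounded to one decimal.
#' @examples
#' percentShare(19, 32)
#' @export
percentShare <- function(count, total) {
    stopifnot(all(total > 0))
    floor(count / total * 1000 + 0.5) / 10
}

#' Summarize a feature selection by compartment and assay
#'
#' Cross-tabulates the selected features per (assay, source) with
#' percentages computed within each assay (half-up, one decimal). With a
#' feature annotation table an additional biotype breakdown per source is
#' returned.
#'
#' @param selection a [SelectionResult-class].
#' @param blockInfo data.frame with columns `block`, `source`, `assay`
#'   mapping block names to their identity; defaults to parsing the
#'   built-in synthetic block registry.
#' @param annotations optional data.frame with columns `feature` and
#'   `biotype`.
#' @return list with `bySource` (data.frame `assay`, `source`, `count`,
#'   `total`, `percent`) and, when annotations are given, `byBiotype`.
#' @export
summarizeSelection <- function(selection, blockInfo = NULL,
    annotations = NULL) {
    stopifnot(is(selection, "SelectionResult"))
    sel <- selection@selected
    if (is.null(blockInfo)) {
        reg <- .blockRegistry()
        blockInfo <- data.frame(block = names(reg),
            source = vapply(reg, `[[`, character(1), "source"),
            assay = vapply(reg, `[[`, character(1), "assay"),
            stringsAsFactors = FALSE)
    }
    i <- match(sel$block, blockInfo$block)
    if (anyNA(i)) stop("unknown block(s): ",
        paste(unique(sel$block[is.na(i)]), collapse = ", "))
    sel$source <- blockInfo$source[i]
    sel$assay <- blockInfo$assay[i]
    rows <- list()
    for (a in unique(sel$assay)) {
        sub <- sel[sel$assay == a, ]
        tab <- table(sub$source)
        rows[[a]] <- data.frame(assay = a, source = names(tab),
            count = as.integer(tab), total = nrow(sub),
            percent = percentShare(as.integer(tab), nrow(sub)),
            stringsAsFactors = FALSE)
    }
    out <- list(bySource = do.call(rbind, c(rows, make.row.names = FALSE)))
    if (!is.null(annotations)) {
        j <- match(sel$feature, annotations$feature)
        sel$biotype <- annotations$biotype[j]
        tab <- as.data.frame(table(source = sel$source,
            biotype = sel$biotype), stringsAsFactors = FALSE)
        tab <- tab[tab$Freq > 0, , drop = FALSE]
        names(tab)[3] <- "count"
        tab$percent <- percentShare(tab$count, nrow(sel))
        rownames(tab) <- NULL
        out$byBiotype <- tab
    }
    out
}
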