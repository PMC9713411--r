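#' Configuration for a synthetic multi-omics cohort
#'
#' Builds the parameter set for [generateCohort()]. The defaults emulate the
#' kind of cohort the pipeline was designed around: a relapsing-remitting MS
#' (RRMS) group, a mixed neurological-disease control group, and a held-out
#' progressive (SPMS) group, each sample measured in five blocks of very
#' different size — Small-seq small-RNA counts from plasma, PBMCs and CSF
#' cells, MINTmap tRF counts from cell-free CSF, and a smoothed CSF-cell
#' methylome. A single latent factor separates cases from controls; its
#' loading strength is block-specific and deliberately weak in the PBMC and
#' methylome blocks, so that those blocks contribute little to the shared
#' structure.
#'
#' @param nPerGroup samples per diagnosis group. Either a single integer
#'   (used for all three groups) or a named integer vector with entries
#'   `positive`, `control`, `progressive`. The default (20/14/6) mirrors a
#'   realistic single-centre MS cohort.
#' @param featuresPerBlock named integer vector, features per block. Block
#'   names encode source and assay as `<source>_<assay>`.
#' @param blockLoadingStrength named numeric vector in `[0, 1]`; how
#'   strongly the planted factor loads on each block's informative features.
#' @param effectSize standardized mean shift of the latent factor between
#'   positives and controls (within-group factor SD is 1).
#' @param progressiveShift position of the held-out progressive group's
#'   factor mean, as a fraction of `effectSize` (default 0.5: intermediate
#'   between cases and controls).
#' @param informativeFraction fraction of each block's features loaded on
#'   the factor.
#' @param countDispersion negative-binomial size parameter for count blocks
#'   (variance = mu + mu^2/size); smaller = more overdispersed. The default
#'   2 reflects typical small-RNA UMI count overdispersion.
#' @param librarySizeCV coefficient of variation of the log-normally
#'   distributed library-size factors.
#' @param methylationPrecision range (length-2) of the per-feature beta
#'   precision for the variable (low-methylation) mode of the methylome
#'   block; smoothed low-input methylomes are noisy, so the default range
#'   is low.
#' @param seed integer seed; identical seeds give bit-identical cohorts.
#' @return A list of class `SyntheticConfig`.
#' @examples
#' cfg <- syntheticConfig(nPerGroup = 5, seed = 7,
#'     featuresPerBlock = c(plasma_smallseq = 40, csf_free_mintmap = 30))
#' cohort <- generateCohort(cfg)
#' names(cohort$blocks)
#' @export
syntheticConfig <- function(
    nPerGroup = c(positive = 20L, control = 14L, progressive = 6L),
    featuresPerBlock = c(pbmc_smallseq = 500L, plasma_smallseq = 300L,
        csf_cells_smallseq = 250L, csf_free_mintmap = 250L,
        csf_cells_methylome = 700L),
    blockLoadingStrength = c(pbmc_smallseq = 0.2, plasma_smallseq = 0.8,
        csf_cells_smallseq = 0.8, csf_free_mintmap = 0.8,
        csf_cells_methylome = 0.2),
    effectSize = 2,
    progressiveShift = 0.5,
    informativeFraction = 0.1,
    countDispersion = 2,
    librarySizeCV = 0.5,
    methylationPrecision = c(1, 5),
    seed = 1L) {

    if (length(nPerGroup) == 1L)
        nPerGroup <- c(positive = nPerGroup, control = nPerGroup,
            progressive = nPerGroup)
    nPerGroup <- as.integer(nPerGroup)
    names(nPerGroup) <- c("positive", "control", "progressive")
    if (any(nPerGroup[c("positive", "control")] <= 0L))
        stop("group sizes for positives and controls must be positive")
    if (nPerGroup["progressive"] < 0L)
        stop("held-out group size must be non-negative")
    unknown <- setdiff(names(featuresPerBlock), names(.blockRegistry()))
    if (length(unknown))
        stop("unknown block name(s): ", paste(unknown, collapse = ", "))
    if (effectSize < 0) stop("'effectSize' must be non-negative")
    if (any(blockLoadingStrength < 0 | blockLoadingStrength > 1))
        stop("loading strengths must lie in [0, 1]")
    if (countDispersion <= 0) stop("'countDispersion' must be positive")
    if (librarySizeCV < 0) stop("'librarySizeCV' must be non-negative")

    loading <- blockLoadingStrength[names(featuresPerBlock)]
    loading[is.na(loading)] <- 0.5
    names(loading) <- names(featuresPerBlock)

    structure(list(nPerGroup = nPerGroup,
        featuresPerBlock = featuresPerBlock,
        blockLoadingStrength = loading, effectSize = effectSize,
        progressiveShift = progressiveShift,
        informativeFraction = informativeFraction,
        countDispersion = countDispersion, librarySizeCV = librarySizeCV,
        methylationPrecision = methylationPrecision,
        seed = as.integer(seed)), class = "SyntheticConfig")
}

# source/assay identity of the named synthetic blocks
.blockRegistry <- function() {
    list(
        pbmc_smallseq = c(source = "pbmc", assay = "smallseq"),
        plasma_smallseq = c(source = "plasma", assay = "smallseq"),
        csf_cells_smallseq = c(source = "csf_cells", assay = "smallseq"),
        csf_free_smallseq = c(source = "csf_free", assay = "smallseq"),
        plasma_mintmap = c(source = "plasma", assay = "mintmap"),
        pbmc_mintmap = c(source = "pbmc", assay = "mintmap"),
        csf_cells_mintmap = c(source = "csf_cells", assay = "mintmap"),
        csf_free_mintmap = c(source = "csf_free", assay = "mintmap"),
        csf_cells_methylome = c(source = "csf_cells", assay = "methylome"))
}

#' Generate one synthetic multi-omics cohort
#'
#' Draws a per-sample latent factor (standard normal within group; the
#' positive group's mean exceeds the controls' by `effectSize`, the
#' progressive group sits at `progressiveShift * effectSize`), then
#' simulates every block conditional on that shared factor:
#' negative-binomial counts on a log-linear mean model for the count
#' assays, beta-distributed values whose mean is a logistic function of the
#' factor for the methylome. The progressive group is generated for
#' projection only and must be excluded from fitting by the caller (the
#' pipeline does this automatically).
#'
#' @param config a `SyntheticConfig` from [syntheticConfig()].
#' @return A list with elements
#'   \describe{
#'     \item{blocks}{named list of [OmicsBlock-class] objects covering all
#'       samples (fitting and held-out) in identical order.}
#'     \item{metadata}{data.frame with columns `sample_id`, `group`
#'       (`RRMS`, `NINDC`, `INDC`, `SPMS`), `phase` (`relapse`,
#'       `remission`, `progressive`, `none`).}
#'     \item{truth}{ground truth: `factorValues`, `groupLabels`,
#'       `informativeFeatureIds` (per block) and `informativeWeights`.}
#'   }
#' @examples
#' cohort <- generateCohort(syntheticConfig(nPerGroup = 4, seed = 1))
#' table(cohort$metadata$group)
#' @export
generateCohort <- function(config) {
    stopifnot(inherits(config, "SyntheticConfig"))
    set.seed(config$seed)

    n <- config$nPerGroup
    nTot <- sum(n)
    sid <- sprintf("S%03d", seq_len(nTot))
    group <- c(rep("RRMS", n["positive"]),
        rep(c("NINDC", "INDC"), length.out = n["control"]),
        rep("SPMS", n["progressive"]))
    phase <- rep("none", nTot)
    phase[group == "RRMS"] <- rep(c("relapse", "remission"),
        length.out = n["positive"])
    phase[group == "SPMS"] <- "progressive"

    mu <- numeric(nTot)
    mu[seq_len(n["positive"])] <- config$effectSize
    mu[group == "SPMS"] <- config$progressiveShift * config$effectSize
    factorValues <- stats::rnorm(nTot, mean = mu, sd = 1)
    names(factorValues) <- sid

    registry <- .blockRegistry()
    blocks <- list()
    informative <- list()
    weights <- list()
    for (bn in names(config$featuresPerBlock)) {
        p <- config$featuresPerBlock[[bn]]
        info <- registry[[bn]]
        nInfo <- max(1L, round(config$informativeFraction * p))
        idx <- sort(sample.int(p, nInfo))
        prefix <- paste0(bn, "_f")
        if (info["assay"] == "methylome") {
            blk <- generateMethylationBlock(nFeatures = p,
                informativeIdx = idx, factorValues = factorValues,
                loadingStrength = config$blockLoadingStrength[[bn]],
                precisionRange = config$methylationPrecision,
                source = info["source"], featurePrefix = prefix)
        } else {
            blk <- generateCountBlock(nFeatures = p, informativeIdx = idx,
                factorValues = factorValues,
                loadingStrength = config$blockLoadingStrength[[bn]],
                dispersion = config$countDispersion,
                librarySizeCV = config$librarySizeCV,
                assay = info["assay"], source = info["source"],
                featurePrefix = prefix)
        }
        blocks[[bn]] <- blk$block
        informative[[bn]] <- featureIds(blk$block)[idx]
        weights[[bn]] <- blk$weights
    }

    list(blocks = blocks,
        metadata = data.frame(sample_id = sid, group = group, phase = phase,
            stringsAsFactors = FALSE),
        truth = list(factorValues = factorValues, groupLabels = group,
            informativeFeatureIds = informative,
            informativeWeights = weights))
}

#' Simulate one overdispersed count block
#'
#' Counts are negative binomial on a log-linear mean model:
#' `mu_ij = exp(base_j + logLib_i + loadingStrength * w_j * f_i)` where
#' `f_i` is the latent factor, `w_j` a signed per-feature weight (nonzero
#' only for informative features) and `logLib_i` a log-normal library-size
#' offset with the requested coefficient of variation. Uses the current RNG
#' state; seed upstream for reproducibility.
#'
#' @param nFeatures number of features (columns).
#' @param informativeIdx integer indices of the features loaded on the
#'   factor.
#' @param factorValues named numeric vector of latent factor values (names
#'   become sample ids).
#' @param loadingStrength scalar in `[0, 1]` scaling the factor effect.
#' @param dispersion negative-binomial size; large values approach Poisson.
#' @param librarySizeCV CV of the library-size factors; 0 gives equal
#'   expected totals.
#' @param assay,source block identity (see [OmicsBlock()]).
#' @param featurePrefix prefix for generated feature ids.
#' @param baseLogMean,baseLogSd normal parameters for per-feature baseline
#'   log abundance.
#' @return list with `block` (an [OmicsBlock-class]) and `weights` (signed
#'   per-feature factor weights).
#' @export
generateCountBlock <- function(nFeatures, informativeIdx, factorValues,
    loadingStrength, dispersion = 2, librarySizeCV = 0.5,
    assay = "smallseq", source = "plasma", featurePrefix = "f",
    baseLogMean = 2, baseLogSd = 1.5) {

    if (nFeatures < 1L) stop("'nFeatures' must be at least 1")
    if (dispersion <= 0) stop("'dispersion' must be positive")
    if (length(informativeIdx) &&
        (min(informativeIdx) < 1L || max(informativeIdx) > nFeatures))
        stop("'informativeIdx' out of range")

    n <- length(factorValues)
    sid <- names(factorValues)
    if (is.null(sid)) sid <- sprintf("S%03d", seq_len(n))

    # log-normal library factor, mean 1, requested CV
    if (librarySizeCV > 0) {
        s2 <- log(1 + librarySizeCV^2)
        logLib <- stats::rnorm(n, mean = -s2 / 2, sd = sqrt(s2))
    } else {
        logLib <- rep(0, n)
    }
    base <- stats::rnorm(nFeatures, mean = baseLogMean, sd = baseLogSd)
    w <- rep(0, nFeatures)
    if (length(informativeIdx))
        w[informativeIdx] <- sample(c(-1, 1), length(informativeIdx),
            replace = TRUE) * stats::runif(length(informativeIdx), 0.5, 1.5)

    logMu <- outer(logLib, base, `+`) +
        loadingStrength * outer(factorValues, w)
    counts <- matrix(stats::rnbinom(n * nFeatures, mu = exp(logMu),
        size = dispersion), nrow = n)
    dimnames(counts) <- list(sid, paste0(featurePrefix, seq_len(nFeatures)))
    list(block = OmicsBlock(counts, assay = assay, source = source),
        weights = stats::setNames(w, colnames(counts)))
}

#' Simulate one smoothed methylation block
#'
#' Beta-distributed values whose mean follows a logistic model:
#' `m_ij = plogis(qlogis(b_j) + loadingStrength * w_j * f_i)` with
#' per-feature baseline `b_j` drawn from a bimodal mixture, as in smoothed
#' whole-genome methylomes: a stable high-methylation background (high
#' beta precision; removed wholesale by a robust-CV filter) and a
#' low-methylation, highly variable mode (low precision; partly retained).
#' Informative features are placed in the variable mode, where
#' between-group differential methylation is detectable. Values are
#' guaranteed to lie in `[0, 1]`.
#'
#' @inheritParams generateCountBlock
#' @param precisionRange length-2 range of the beta precision parameter
#'   (shape1 + shape2) for the variable mode; low precision = noisy
#'   smoothed estimates.
#' @param highPrecisionRange precision range for the stable
#'   high-methylation background.
#' @param lowModeFraction fraction of features in the low-methylation,
#'   high-variability mode (the mode that survives a robust-CV filter).
#' @param baseLogitMeans,baseLogitSds length-2 numeric: mean and SD of the
#'   per-feature baseline on the logit scale for the (low, high) modes.
#' @return list with `block` (an [OmicsBlock-class]) and `weights`.
#' @export
generateMethylationBlock <- function(nFeatures, informativeIdx, factorValues,
    loadingStrength, precisionRange = c(1, 5),
    highPrecisionRange = c(10, 30), lowModeFraction = 0.5,
    baseLogitMeans = c(stats::qlogis(0.03), stats::qlogis(0.85)),
    baseLogitSds = c(1.2, 0.5),
    source = "csf_cells", featurePrefix = "cpg") {

    if (nFeatures < 1L) stop("'nFeatures' must be at least 1")
    if (length(informativeIdx) &&
        (min(informativeIdx) < 1L || max(informativeIdx) > nFeatures))
        stop("'informativeIdx' out of range")

    n <- length(factorValues)
    sid <- names(factorValues)
    if (is.null(sid)) sid <- sprintf("S%03d", seq_len(n))

    low <- stats::runif(nFeatures) < lowModeFraction
    low[informativeIdx] <- TRUE
    baseLogit <- ifelse(low,
        stats::rnorm(nFeatures, mean = baseLogitMeans[1],
            sd = baseLogitSds[1]),
        stats::rnorm(nFeatures, mean = baseLogitMeans[2],
            sd = baseLogitSds[2]))
    phi <- ifelse(low,
        stats::runif(nFeatures, precisionRange[1], precisionRange[2]),
        stats::runif(nFeatures, highPrecisionRange[1],
            highPrecisionRange[2]))
    w <- rep(0, nFeatures)
    if (length(informativeIdx))
        w[informativeIdx] <- sample(c(-1, 1), length(informativeIdx),
            replace = TRUE) * stats::runif(length(informativeIdx), 1, 2)

    m <- stats::plogis(outer(rep(1, n), baseLogit) +
        loadingStrength * outer(factorValues, w))
    vals <- matrix(stats::rbeta(n * nFeatures,
        shape1 = m * rep(phi, each = n),
        shape2 = (1 - m) * rep(phi, each = n)), nrow = n)
    vals[vals < 0] <- 0
    vals[vals > 1] <- 1
    dimnames(vals) <- list(sid, paste0(featurePrefix, seq_len(nFeatures)))
    list(block = OmicsBlock(vals, assay = "methylome", source = source),
        weights = stats::setNames(w, colnames(vals)))
}

#' Write or read a cohort as delimited text
#'
#' `writeCohort` writes every block as a TSV matrix (first column
#' `sample_id`, header = feature ids) plus a `metadata.tsv`; `readCohort`
#' reads the same layout back. Block files are named
#' `block_<name>.tsv`; source and assay are recovered from the block name
#' via the built-in registry.
#'
#' @param cohort list with `blocks` and `metadata` as produced by
#'   [generateCohort()].
#' @param dir directory to write to / read from (created if missing).
#' @return `writeCohort` returns the directory invisibly; `readCohort`
#'   returns a list with `blocks` and `metadata`.
#' @export
writeCohort <- function(cohort, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (bn in names(cohort$blocks))
        writeBlockTSV(cohort$blocks[[bn]],
            file.path(dir, paste0("block_", bn, ".tsv")))
    utils::write.table(cohort$metadata, file.path(dir, "metadata.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(dir)
}

#' @rdname writeCohort
#' @export
readCohort <- function(dir) {
    files <- list.files(dir, pattern = "^block_.*\\.tsv$", full.names = TRUE)
    if (!length(files)) stop("no block_*.tsv files found in ", dir)
    registry <- .blockRegistry()
    blocks <- list()
    for (f in files) {
        bn <- sub("^block_(.*)\\.tsv$", "\\1", basename(f))
        info <- registry[[bn]]
        if (is.null(info))
            stop("unknown block name: ", bn)
        blocks[[bn]] <- readBlockTSV(f, assay = info[["assay"]],
            source = info[["source"]])
    }
    metadata <- utils::read.delim(file.path(dir, "metadata.tsv"),
        stringsAsFactors = FALSE)
    list(blocks = blocks, metadata = metadata)
}
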