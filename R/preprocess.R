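#' Per-assay feature filters
#'
#' Feature filters applied before integration, each returning the filtered
#' block together with a [FilterReport-class]:
#' \describe{
#'   \item{`filterMinTotalCount`}{drops count features whose total across
#'     all samples is below `minTotal` (default 100 UMI counts); a feature
#'     summing to exactly `minTotal` is kept.}
#'   \item{`filterGroupCoverage`}{drops features detected (count > 0) in
#'     less than a `fraction` of samples in either diagnosis group
#'     (`mode = "both"`: a feature must reach the coverage fraction in
#'     *both* groups to be kept; `mode = "either"`: one group suffices).}
#'   \item{`filterZeroSD`}{drops features with zero sample standard
#'     deviation (n-1 denominator).}
#'   \item{`filterRCV`}{methylome filter on the robust coefficient of
#'     variation, `RCV(x) = median(|x - median(x)|) / median(x)`; features
#'     with RCV below `threshold` or zero SD are dropped, and features with
#'     median 0 (undefined RCV) are excluded with a note in the report.}
#' }
#'
#' @param block an [OmicsBlock-class].
#' @param minTotal minimum summed count across samples.
#' @param groupLabels vector with one diagnosis label per sample; exactly
#'   two distinct labels must be present.
#' @param fraction required covered-sample fraction per group.
#' @param mode `"both"` (default) or `"either"`; see above.
#' @param threshold minimum robust coefficient of variation.
#' @return list with elements `block` (filtered [OmicsBlock-class]) and
#'   `report` (a [FilterReport-class]).
#' @examples
#' m <- matrix(c(0, 0, 0, 5, 6, 7, 40, 50, 60), 3, 3,
#'     dimnames = list(paste0("S", 1:3), paste0("f", 1:3)))
#' b <- OmicsBlock(m, "smallseq", "plasma")
#' filterMinTotalCount(b, minTotal = 10)$report
#' @name filters
NULL

.subsetFeatures <- function(block, keep) {
    OmicsBlock(block@values[, keep, drop = FALSE], assay = block@assay,
        source = block@source)
}

.colSds <- function(m) apply(m, 2, stats::sd)

#' @rdname filters
#' @export
filterMinTotalCount <- function(block, minTotal = 100) {
    stopifnot(is(block, "OmicsBlock"))
    if (!block@assay %in% .COUNT_ASSAYS)
        stop("min-total-count filter applies to count assays only, not ",
            sQuote(block@assay))
    totals <- colSums(block@values)
    keep <- stats::setNames(totals >= minTotal, colnames(block@values))
    if (length(keep) && !any(keep))
        warning("min-total-count filter removed every feature")
    list(block = .subsetFeatures(block, keep),
        report = .filterReport("min_total_count", keep))
}

#' @rdname filters
#' @export
filterGroupCoverage <- function(block, groupLabels, fraction = 2 / 3,
    mode = c("both", "either")) {
    stopifnot(is(block, "OmicsBlock"))
    mode <- match.arg(mode)
    groupLabels <- as.character(groupLabels)
    if (length(groupLabels) != nrow(block@values))
        stop("one group label per sample required")
    groups <- unique(groupLabels)
    if (length(groups) != 2L)
        stop("exactly two groups required, got ", length(groups))
    if (any(table(groupLabels) == 0L)) stop("empty group")
    covered <- block@values > 0
    frac <- vapply(groups, function(g)
        colMeans(covered[groupLabels == g, , drop = FALSE]),
        numeric(ncol(block@values)))
    if (ncol(block@values) <= 1L)
        frac <- matrix(frac, ncol = 2)
    ok <- frac >= fraction
    keep <- if (mode == "both") ok[, 1] & ok[, 2] else ok[, 1] | ok[, 2]
    keep <- stats::setNames(as.logical(keep), colnames(block@values))
    list(block = .subsetFeatures(block, keep),
        report = .filterReport("group_coverage", keep))
}

#' @rdname filters
#' @export
filterZeroSD <- function(block) {
    stopifnot(is(block, "OmicsBlock"))
    sds <- .colSds(block@values)
    keep <- stats::setNames(!is.na(sds) & sds > 0, colnames(block@values))
    list(block = .subsetFeatures(block, keep),
        report = .filterReport("zero_sd", keep))
}

#' @rdname filters
#' @export
filterRCV <- function(block, threshold = 1) {
    stopifnot(is(block, "OmicsBlock"))
    if (block@assay != "methylome")
        stop("the robust-CV filter applies to the methylome assay only")
    v <- block@values
    med <- apply(v, 2, stats::median)
    mad0 <- vapply(seq_len(ncol(v)), function(j)
        stats::median(abs(v[, j] - med[j])), numeric(1))
    sds <- .colSds(v)
    undef <- med == 0
    rcv <- rep(NA_real_, ncol(v))
    rcv[!undef] <- mad0[!undef] / med[!undef]
    keep <- !undef & !is.na(sds) & sds > 0 & rcv >= threshold
    keep <- stats::setNames(keep, colnames(v))
    notes <- if (any(undef))
        sprintf("%d feature(s) excluded: median 0, RCV undefined", sum(undef))
    else character()
    list(block = .subsetFeatures(block, keep),
        report = .filterReport("rcv", keep, notes))
}

# edgeR-style selection of the TMM reference sample: the sample whose
# 75th-percentile count (relative to library size) is closest to the mean
# 75th percentile.
.tmmRefSample <- function(counts) {
    lib <- rowSums(counts)
    q <- vapply(seq_len(nrow(counts)), function(i)
        stats::quantile(counts[i, ], probs = 0.75, names = FALSE) / lib[i],
        numeric(1))
    which.min(abs(q - mean(q)))
}

#' TMM normalization of a count block
#'
#' Trimmed-mean-of-M-values scaling factors (computed with
#' \pkg{edgeR}'s `calcNormFactors`) followed by conversion to counts per
#' million: `cpm_ij = count_ij / (libsize_i * factor_i) * 1e6`. Factors
#' have geometric mean 1 across the samples of `block`. M/A values are
#' computed on features nonzero in both the sample and the reference; the
#' reference sample is the one whose 75th-percentile count is closest to
#' the mean 75th percentile (pass `refSample` to fix it explicitly).
#'
#' If `heldOut` is supplied, its samples are normalized *against the
#' training reference* without influencing the training factors: their
#' pairwise factors are computed relative to the same reference sample and
#' rescaled by the training samples' geometric mean, so training output is
#' identical whether or not held-out samples are present.
#'
#' @param block an [OmicsBlock-class] with a count assay, at least 2
#'   samples.
#' @param mTrim,aTrim trim fractions for log-ratios (M) and absolute
#'   intensities (A); defaults are the published TMM defaults (30% / 5%).
#' @param refSample optional index of the reference sample within `block`.
#' @param heldOut optional [OmicsBlock-class] of additional samples with
#'   the same features, normalized on the training scale.
#' @return list with `block` (CPM-scaled [OmicsBlock-class]), `factors`
#'   (named per-sample scaling factors, geometric mean 1), `refSample`, and
#'   `heldOut` (CPM block, only if supplied).
#' @examples
#' m <- matrix(rpois(60, 20), 3, 20,
#'     dimnames = list(paste0("S", 1:3), paste0("g", 1:20)))
#' tmmNormalize(OmicsBlock(m, "smallseq", "plasma"))$factors
#' @export
tmmNormalize <- function(block, mTrim = 0.30, aTrim = 0.05,
    refSample = NULL, heldOut = NULL) {
    stopifnot(is(block, "OmicsBlock"))
    if (!block@assay %in% .COUNT_ASSAYS)
        stop("TMM normalization applies to count assays only")
    counts <- block@values
    if (nrow(counts) < 2L) stop("TMM requires at least 2 samples")
    if (any(rowSums(counts) == 0))
        stop("sample(s) with all-zero counts: ",
            paste(rownames(counts)[rowSums(counts) == 0], collapse = ", "))
    if (is.null(refSample)) refSample <- .tmmRefSample(counts)

    f <- edgeR::calcNormFactors(t(counts), method = "TMM",
        refColumn = refSample, logratioTrim = mTrim, sumTrim = aTrim)
    lib <- rowSums(counts)
    cpm <- counts / (lib * f) * 1e6
    out <- list(
        block = OmicsBlock(cpm, assay = block@assay,
            source = block@source),
        factors = stats::setNames(f, rownames(counts)),
        refSample = refSample)
    if (!is.null(heldOut)) {
        # held-out samples: pairwise TMM factors against the same training
        # reference, rescaled to the training factors' scale, computed in
        # a separate pass so the training output is untouched bitwise
        stopifnot(identical(colnames(heldOut@values), colnames(counts)))
        nTrain <- nrow(counts)
        fAll <- edgeR::calcNormFactors(t(rbind(counts, heldOut@values)),
            method = "TMM", refColumn = refSample,
            logratioTrim = mTrim, sumTrim = aTrim)
        fHeld <- fAll[-seq_len(nTrain)] /
            exp(mean(log(fAll[seq_len(nTrain)])))
        libH <- rowSums(heldOut@values)
        out$heldOut <- OmicsBlock(
            heldOut@values / (libH * fHeld) * 1e6,
            assay = block@assay, source = block@source)
        out$heldOutFactors <- stats::setNames(fHeld,
            rownames(heldOut@values))
    }
    out
}

#' Preprocess one block: per-assay filters plus normalization
#'
#' Dispatches the assay-specific filter chain, in this fixed order:
#' \describe{
#'   \item{smallseq}{min-total-count (>= `minTotal`), zero-SD, TMM/CPM.}
#'   \item{mintmap}{group coverage (>= `coverageFraction` in both groups by
#'     default), zero-SD, TMM/CPM.}
#'   \item{methylome}{robust-CV filter (which subsumes the zero-SD rule).}
#' }
#' Count blocks are `log2(x + 1)`-transformed after CPM scaling when
#' `logTransform = TRUE` (the default), stabilizing variance before the
#' linear latent model; a final zero-SD guard removes features that became
#' constant after normalization. Held-out samples, if supplied, are run
#' through the same feature subset and normalized on the training scale
#' (see [tmmNormalize()]); they never influence filter decisions or the
#' TMM reference.
#'
#' @param block an [OmicsBlock-class] (fitting samples only).
#' @param groupLabels per-sample diagnosis labels for the coverage filter
#'   (two groups); required for `mintmap` blocks.
#' @param minTotal,coverageFraction,coverageMode,rcvThreshold filter
#'   settings, see [filters].
#' @param mTrim,aTrim TMM trim fractions.
#' @param logTransform log2(x+1)-transform normalized counts.
#' @param heldOut optional [OmicsBlock-class] of held-out samples.
#' @return list with `block`, `reports` (named list of
#'   [FilterReport-class]), `factors` (TMM factors, count assays only) and
#'   `heldOut` (if supplied).
#' @export
preprocessBlock <- function(block, groupLabels = NULL, minTotal = 100,
    coverageFraction = 2 / 3, coverageMode = "both", rcvThreshold = 1,
    mTrim = 0.30, aTrim = 0.05, logTransform = TRUE, heldOut = NULL) {
    stopifnot(is(block, "OmicsBlock"))
    reports <- list()
    sub <- function(ho, keep) {
        if (is.null(ho)) NULL
        else OmicsBlock(ho@values[, keep, drop = FALSE], ho@assay, ho@source)
    }
    factors <- NULL
    if (block@assay == "smallseq") {
        st <- filterMinTotalCount(block, minTotal = minTotal)
        reports$min_total_count <- st$report
        heldOut <- sub(heldOut, st$report@keep)
        st <- filterZeroSD(st$block)
        reports$zero_sd <- st$report
        heldOut <- sub(heldOut, st$report@keep)
        block <- st$block
    } else if (block@assay == "mintmap") {
        if (is.null(groupLabels))
            stop("'groupLabels' required for the mintmap coverage filter")
        st <- filterGroupCoverage(block, groupLabels,
            fraction = coverageFraction, mode = coverageMode)
        reports$group_coverage <- st$report
        heldOut <- sub(heldOut, st$report@keep)
        st <- filterZeroSD(st$block)
        reports$zero_sd <- st$report
        heldOut <- sub(heldOut, st$report@keep)
        block <- st$block
    } else if (block@assay == "methylome") {
        st <- filterRCV(block, threshold = rcvThreshold)
        reports$rcv <- st$report
        heldOut <- sub(heldOut, st$report@keep)
        return(list(block = st$block, reports = reports, factors = NULL,
            heldOut = heldOut))
    } else {
        stop("unknown assay: ", sQuote(block@assay))
    }

    nm <- tmmNormalize(block, mTrim = mTrim, aTrim = aTrim,
        heldOut = heldOut)
    block <- nm$block
    heldOut <- nm$heldOut
    factors <- nm$factors
    if (logTransform) {
        block <- OmicsBlock(log2(block@values + 1), block@assay,
            block@source)
        if (!is.null(heldOut))
            heldOut <- OmicsBlock(log2(heldOut@values + 1), heldOut@assay,
                heldOut@source)
    }
    st <- filterZeroSD(block)
    reports$zero_sd_post_norm <- st$report
    heldOut <- sub(heldOut, st$report@keep)
    list(block = st$block, reports = reports, factors = factors,
        heldOut = heldOut)
}
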