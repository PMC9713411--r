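#' @import methods
NULL

.COUNT_ASSAYS <- c("smallseq", "mintmap")
.KNOWN_ASSAYS <- c("smallseq", "mintmap", "methylome")
.KNOWN_SOURCES <- c("plasma", "pbmc", "csf_cells", "csf_free")

#' OmicsBlock: one assay/compartment feature matrix
#'
#' An `OmicsBlock` holds a single samples-by-features matrix from one
#' molecular assay measured in one body compartment, e.g. Small-seq UMI
#' counts from plasma, MINTmap tRF counts from CSF cells, or a smoothed
#' methylation (beta value) matrix. Rows are samples, columns are features.
#'
#' @slot values numeric matrix, samples in rows (rownames = sample ids),
#'   features in columns (colnames = feature ids).
#' @slot assay character(1); one of `"smallseq"`, `"mintmap"`,
#'   `"methylome"`. The first two are count assays.
#' @slot source character(1); compartment label, one of `"plasma"`,
#'   `"pbmc"`, `"csf_cells"`, `"csf_free"`.
#'
#' @seealso [OmicsBlock()] for the constructor, [preprocessBlock()] for the
#'   per-assay filter/normalization dispatcher.
#' @exportClass OmicsBlock
setClass("OmicsBlock",
    representation(values = "matrix", assay = "character", source = "character"))

setValidity("OmicsBlock", function(object) {
    v <- object@values
    msg <- character()
    if (!is.numeric(v))
        msg <- c(msg, "'values' must be a numeric matrix")
    if (anyNA(v))
        msg <- c(msg, "'values' must not contain missing values")
    if (length(object@assay) != 1L || !object@assay %in% .KNOWN_ASSAYS)
        msg <- c(msg, sprintf("'assay' must be one of %s",
            paste(sQuote(.KNOWN_ASSAYS), collapse = ", ")))
    if (length(object@source) != 1L)
        msg <- c(msg, "'source' must be a single compartment label")
    if (is.null(rownames(v)) || anyDuplicated(rownames(v)))
        msg <- c(msg, "sample ids (rownames) must be present and unique")
    if (ncol(v) > 0 && (is.null(colnames(v)) || anyDuplicated(colnames(v))))
        msg <- c(msg, "feature ids (colnames) must be present and unique")
    if (length(msg) == 0L && length(object@assay) == 1L &&
        object@assay %in% .COUNT_ASSAYS && nrow(v) * ncol(v) > 0 && min(v) < 0)
        msg <- c(msg, "count assays must be non-negative")
    if (length(msg) == 0L && length(object@assay) == 1L &&
        object@assay == "methylome" && nrow(v) * ncol(v) > 0 &&
        (min(v) < 0 || max(v) > 1))
        msg <- c(msg, "methylome beta values must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' Construct an OmicsBlock
#'
#' @param values numeric matrix, samples x features, with rownames (sample
#'   ids) and colnames (feature ids).
#' @param assay assay kind: `"smallseq"`, `"mintmap"` or `"methylome"`.
#' @param source compartment label (e.g. `"plasma"`, `"pbmc"`,
#'   `"csf_cells"`, `"csf_free"`).
#' @return An [OmicsBlock-class] object.
#' @examples
#' m <- matrix(rpois(20, 5), 4, 5,
#'     dimnames = list(paste0("S", 1:4), paste0("f", 1:5)))
#' OmicsBlock(m, assay = "smallseq", source = "plasma")
#' @export
OmicsBlock <- function(values, assay, source) {
    values <- as.matrix(values)
    new("OmicsBlock", values = values, assay = assay, source = source)
}

setMethod("show", "OmicsBlock", function(object) {
    cat(sprintf("OmicsBlock: %d samples x %d features [assay=%s, source=%s]\n",
        nrow(object@values), ncol(object@values), object@assay, object@source))
})

#' FilterReport: bookkeeping for one feature filter
#'
#' Records, for one filtering rule applied to one block, how many features
#' went in, how many survived, and the per-feature pass flags. Reports chain
#' across a preprocessing run so that the final feature inventory can be
#' reconstructed rule by rule.
#'
#' @slot rule character(1), name of the filter rule.
#' @slot nBefore,nAfter integer(1), feature counts before/after.
#' @slot keep named logical, one flag per input feature.
#' @slot notes character, free-text reasons for special-cased exclusions
#'   (e.g. features with undefined robust CV).
#' @exportClass FilterReport
setClass("FilterReport",
    representation(rule = "character", nBefore = "integer", nAfter = "integer",
        keep = "logical", notes = "character"))

setValidity("FilterReport", function(object) {
    msg <- character()
    if (object@nAfter > object@nBefore)
        msg <- c(msg, "'nAfter' must not exceed 'nBefore'")
    if (length(object@keep) != object@nBefore)
        msg <- c(msg, "'keep' must have one flag per input feature")
    if (sum(object@keep) != object@nAfter)
        msg <- c(msg, "'nAfter' must equal the number of TRUE flags")
    if (length(msg)) msg else TRUE
})

.filterReport <- function(rule, keep, notes = character()) {
    new("FilterReport", rule = rule, nBefore = length(keep),
        nAfter = sum(keep), keep = keep, notes = notes)
}

setMethod("show", "FilterReport", function(object) {
    cat(sprintf("FilterReport [%s]: %d -> %d features\n",
        object@rule, object@nBefore, object@nAfter))
    if (length(object@notes))
        cat("  notes:", paste(object@notes, collapse = "; "), "\n")
})

#' StandardizedBlock: a block scaled for co-inertia analysis
#'
#' A preprocessed block after column centering, column scaling by the
#' sample standard deviation, and division of the whole block by the square
#' root of its total sum of squares (so the block has unit inertia). The
#' three parameter sets are stored so that unseen samples can be placed on
#' exactly the same scale before projection.
#'
#' @slot values numeric matrix, samples x features, unit total inertia.
#' @slot colMeans,colSds per-feature centering/scaling parameters.
#' @slot inertiaNorm positive scalar divisor applied blockwise.
#' @slot assay,source identity of the source block.
#' @seealso [standardizeBlock()], [fitMCIA()], [projectSamples()]
#' @exportClass StandardizedBlock
setClass("StandardizedBlock",
    representation(values = "matrix", colMeans = "numeric", colSds = "numeric",
        inertiaNorm = "numeric", assay = "character", source = "character"))

setValidity("StandardizedBlock", function(object) {
    msg <- character()
    p <- ncol(object@values)
    if (length(object@colMeans) != p || length(object@colSds) != p)
        msg <- c(msg, "'colMeans'/'colSds' must have one entry per feature")
    if (length(object@inertiaNorm) != 1L || object@inertiaNorm <= 0)
        msg <- c(msg, "'inertiaNorm' must be a single positive number")
    if (length(msg)) msg else TRUE
})

setMethod("show", "StandardizedBlock", function(object) {
    cat(sprintf(
        "StandardizedBlock: %d samples x %d features [assay=%s, source=%s], inertia norm %.4g\n",
        nrow(object@values), ncol(object@values), object@assay,
        object@source, object@inertiaNorm))
})

#' MCIAModel: fitted multiple co-inertia decomposition
#'
#' Holds the result of [fitMCIA()]: per-component global latent scores
#' (`U %*% Sigma` of the concatenated standardized blocks), the raw
#' concatenated singular vectors used for projection, per-block unit-norm
#' loadings and partial scores, singular-value-squared "eigenvalues" of the
#' progressively deflated matrix, block contribution table, and the
#' standardization parameters required to project unseen samples.
#'
#' @slot globalScores n x K matrix of global latent scores (L1..LK).
#' @slot loadings p x K matrix of raw concatenated right singular vectors
#'   (each column has unit norm over all features); used for projection and
#'   feature ranking.
#' @slot blockLoadings named list of p_k x K matrices; each column
#'   renormalized to unit norm within its block ("blockLoading" deflation
#'   vectors).
#' @slot partialScores named list of n x K matrices, block score
#'   `X_k %*% v_k`.
#' @slot eigenvalues numeric(K), squared leading singular value of the
#'   deflated concatenated matrix at each step.
#' @slot contributions blocks x K matrix of raw block contributions (see
#'   [blockContributions()]).
#' @slot blocks named list of the standardized training matrices (kept for
#'   downstream regression on the concatenated feature space).
#' @slot standardization named list per block: `colMeans`, `colSds`,
#'   `inertiaNorm`, `assay`, `source`, `featureIds`.
#' @slot featureBlock character vector mapping each row of `loadings` to
#'   its block.
#' @slot featureIds character vector of feature ids aligned with `loadings`.
#' @slot sampleIds fitted sample identifiers.
#' @slot sampleLabels diagnosis labels for fitted samples (may be empty).
#' @exportClass MCIAModel
setClass("MCIAModel",
    representation(globalScores = "matrix", loadings = "matrix",
        blockLoadings = "list", partialScores = "list",
        eigenvalues = "numeric", contributions = "matrix", blocks = "list",
        standardization = "list", featureBlock = "character",
        featureIds = "character", sampleIds = "character",
        sampleLabels = "character"))

setValidity("MCIAModel", function(object) {
    msg <- character()
    K <- ncol(object@globalScores)
    if (length(object@eigenvalues) != K)
        msg <- c(msg, "one eigenvalue per component required")
    if (ncol(object@loadings) != K)
        msg <- c(msg, "'loadings' must have one column per component")
    if (length(object@featureBlock) != nrow(object@loadings) ||
        length(object@featureIds) != nrow(object@loadings))
        msg <- c(msg, "feature bookkeeping out of step with 'loadings'")
    if (nrow(object@globalScores) != length(object@sampleIds))
        msg <- c(msg, "one global score row per fitted sample required")
    if (length(msg)) msg else TRUE
})

setMethod("show", "MCIAModel", function(object) {
    cat(sprintf("MCIAModel: %d samples, %d blocks, %d features, %d components\n",
        nrow(object@globalScores), length(object@blockLoadings),
        nrow(object@loadings), ncol(object@globalScores)))
    cat("  blocks:", paste(names(object@blockLoadings), collapse = ", "), "\n")
    ev <- object@eigenvalues
    cat("  eigenvalues:", paste(sprintf("%.4g", utils::head(ev, 5)),
        collapse = ", "), if (length(ev) > 5) "...\n" else "\n")
})

#' ProjectedScores: latent coordinates of unseen samples
#'
#' @slot scores n_new x K matrix of projected latent scores.
#' @slot sampleIds identifiers of the projected samples.
#' @slot projected logical(1) flag; always `TRUE` for objects returned by
#'   [projectSamples()], distinguishing them from fitted scores.
#' @exportClass ProjectedScores
setClass("ProjectedScores",
    representation(scores = "matrix", sampleIds = "character",
        projected = "logical"))

setValidity("ProjectedScores", function(object) {
    if (nrow(object@scores) != length(object@sampleIds))
        "one score row per sample required" else TRUE
})

setMethod("show", "ProjectedScores", function(object) {
    cat(sprintf("ProjectedScores: %d samples x %d components\n",
        nrow(object@scores), ncol(object@scores)))
})

#' ROCResult: an ROC curve with its area
#'
#' The ROC curves produced here are built from a two-cluster partition of a
#' single latent variable deformed by minimal-cost sample relocations (see
#' [aurocByRelocation()]), not from thresholding a classifier score.
#'
#' @slot points data.frame with columns `fpr`, `tpr`, sorted by (fpr, tpr),
#'   starting at (0,0) and ending at (1,1).
#' @slot auc area under the curve by the trapezoid rule.
#' @slot positiveClass labels treated as the positive class.
#' @exportClass ROCResult
setClass("ROCResult",
    representation(points = "data.frame", auc = "numeric",
        positiveClass = "character"))

setValidity("ROCResult", function(object) {
    pts <- object@points
    msg <- character()
    if (!all(c("fpr", "tpr") %in% names(pts)))
        msg <- c(msg, "'points' needs columns 'fpr' and 'tpr'")
    else {
        if (any(pts$fpr < 0 | pts$fpr > 1 | pts$tpr < 0 | pts$tpr > 1))
            msg <- c(msg, "ROC points must lie in the unit square")
        if (nrow(pts) < 2L || pts$fpr[1] != 0 || pts$tpr[1] != 0 ||
            pts$fpr[nrow(pts)] != 1 || pts$tpr[nrow(pts)] != 1)
            msg <- c(msg, "curve must start at (0,0) and end at (1,1)")
        if (is.unsorted(pts$fpr))
            msg <- c(msg, "points must be sorted non-decreasing in fpr")
    }
    if (object@auc < 0 || object@auc > 1)
        msg <- c(msg, "'auc' must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

setMethod("show", "ROCResult", function(object) {
    cat(sprintf("ROCResult: AUC = %.4f (%d points; positive = %s)\n",
        object@auc, nrow(object@points),
        paste(object@positiveClass, collapse = "/")))
})

#' SelectionResult: Lasso feature reduction outcome
#'
#' @slot selected data.frame with columns `block`, `feature`, `beta`
#'   (nonzero coefficients at the chosen penalty).
#' @slot lambda chosen penalty value.
#' @slot cvCurve data.frame with columns `lambda`, `cvm`, `cvsd` (mean
#'   cross-validated error and its standard error along the path).
#' @slot droppedBlocks blocks from which no feature was selected.
#' @slot foldSeed seed used for the cross-validation fold assignment.
#' @exportClass SelectionResult
setClass("SelectionResult",
    representation(selected = "data.frame", lambda = "numeric",
        cvCurve = "data.frame", droppedBlocks = "character",
        foldSeed = "integer"))

setValidity("SelectionResult", function(object) {
    msg <- character()
    if (!all(c("block", "feature", "beta") %in% names(object@selected)))
        msg <- c(msg, "'selected' needs columns block, feature, beta")
    else {
        if (nrow(object@selected) && any(object@selected$beta == 0))
            msg <- c(msg, "selected features must have nonzero coefficients")
        if (any(object@droppedBlocks %in% object@selected$block))
            msg <- c(msg, "a dropped block cannot also carry selections")
    }
    if (length(msg)) msg else TRUE
})

setMethod("show", "SelectionResult", function(object) {
    cat(sprintf("SelectionResult: %d features at lambda = %.4g\n",
        nrow(object@selected), object@lambda))
    if (nrow(object@selected)) {
        tab <- table(object@selected$block)
        cat("  per block:", paste(sprintf("%s=%d", names(tab), tab),
            collapse = ", "), "\n")
    }
    if (length(object@droppedBlocks))
        cat("  dropped blocks:", paste(object@droppedBlocks, collapse = ", "),
            "\n")
})
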