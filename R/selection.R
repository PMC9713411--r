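#' Lasso feature reduction against a latent score
#'
#' Regresses the component-1 global latent score on the concatenated
#' standardized feature matrix with an L1 penalty (coordinate descent via
#' \pkg{glmnet}), choosing the penalty by k-fold cross-validation and
#' keeping the features with nonzero coefficients. Folds are stratified by
#' class label when labels are available, and the fold seed is recorded in
#' the result. By default the CV-error-minimizing penalty (`lambda.min`) is
#' used; `lambdaRule = "1se"` selects the sparser one-standard-error rule.
#'
#' An optional post-selection magnitude filter (`sdFilter = TRUE`) keeps
#' only features whose `|beta|` exceeds one standard deviation of the
#' nonzero-`|beta|` distribution; it is off by default.
#'
#' @param x a fitted [MCIAModel-class] (the stored standardized blocks are
#'   concatenated) or a numeric samples x features matrix.
#' @param y response; defaults to the model's component-`component` global
#'   scores when `x` is a model.
#' @param component which global score to use as response (model method).
#' @param folds number of cross-validation folds (>= 2, <= sample count).
#' @param seed integer seed for the fold assignment.
#' @param lambdaRule `"min"` (default) or `"1se"`.
#' @param lambdaFixed optional fixed penalty value; skips cross-validation
#'   and evaluates the Lasso path at exactly this penalty.
#' @param sdFilter apply the optional 1-SD magnitude filter.
#' @param featureBlocks character vector assigning each column of a matrix
#'   `x` to a block (matrix method only; defaults to one block).
#' @param labels optional class labels for stratified folds (matrix
#'   method; the model method uses the stored labels).
#' @param ... passed on between methods.
#' @return A [SelectionResult-class].
#' @export
setGeneric("lassoSelect", function(x, ...) standardGeneric("lassoSelect"))

.stratifiedFolds <- function(labels, n, folds, seed) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
        globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    foldid <- integer(n)
    if (is.null(labels) || !length(labels)) labels <- rep("all", n)
    for (g in unique(labels)) {
        idx <- which(labels == g)
        foldid[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
    foldid
}

.lassoCore <- function(X, y, featureBlocks, labels, folds, seed,
    lambdaRule, sdFilter, lambdaFixed = NULL) {
    n <- nrow(X)
    if (length(y) != n) stop("response length must equal the sample count")
    if (folds < 2L) stop("at least 2 folds required")
    if (n < folds) stop("fewer samples than folds")
    if (is.null(lambdaFixed)) {
        foldid <- .stratifiedFolds(labels, n, folds, seed)
        cv <- glmnet::cv.glmnet(X, y, alpha = 1, foldid = foldid,
            standardize = TRUE, thresh = 1e-10)
        lambda <- if (lambdaRule == "min") cv$lambda.min else cv$lambda.1se
        cvCurve <- data.frame(lambda = cv$lambda, cvm = cv$cvm,
            cvsd = cv$cvsd)
        fit <- cv
    } else {
        lambda <- lambdaFixed
        cvCurve <- data.frame(lambda = numeric(0), cvm = numeric(0),
            cvsd = numeric(0))
        fit <- glmnet::glmnet(X, y, alpha = 1, standardize = TRUE,
            thresh = 1e-12)
    }
    beta <- if (is.null(lambdaFixed))
        as.numeric(stats::coef(fit, s = lambda))[-1]
    else  # exact solution at the requested penalty, not path interpolation
        as.numeric(stats::coef(fit, s = lambda, exact = TRUE, x = X,
            y = y))[-1]
    names(beta) <- colnames(X)
    nz <- beta != 0
    if (sdFilter && sum(nz) > 1L) {
        thr <- stats::sd(abs(beta[nz]))
        nz <- nz & abs(beta) > thr
    }
    selected <- data.frame(block = featureBlocks[nz],
        feature = colnames(X)[nz], beta = beta[nz],
        stringsAsFactors = FALSE)
    rownames(selected) <- NULL
    new("SelectionResult", selected = selected, lambda = lambda,
        cvCurve = cvCurve,
        droppedBlocks = setdiff(unique(featureBlocks), selected$block),
        foldSeed = as.integer(seed))
}

#' @rdname lassoSelect
#' @export
setMethod("lassoSelect", "MCIAModel", function(x, component = 1, folds = 5,
    seed = 1L, lambdaRule = c("min", "1se"), sdFilter = FALSE,
    lambdaFixed = NULL, ...) {
    lambdaRule <- match.arg(lambdaRule)
    X <- do.call(cbind, x@blocks)
    colnames(X) <- x@featureIds
    y <- x@globalScores[, component]
    labels <- if (length(x@sampleLabels)) x@sampleLabels else NULL
    .lassoCore(X, y, x@featureBlock, labels, folds, seed, lambdaRule,
        sdFilter, lambdaFixed)
})

#' @rdname lassoSelect
#' @export
setMethod("lassoSelect", "matrix", function(x, y, featureBlocks = NULL,
    labels = NULL, folds = 5, seed = 1L, lambdaRule = c("min", "1se"),
    sdFilter = FALSE, lambdaFixed = NULL, ...) {
    lambdaRule <- match.arg(lambdaRule)
    if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
    if (is.null(featureBlocks)) featureBlocks <- rep("block1", ncol(x))
    .lassoCore(x, y, featureBlocks, labels, folds, seed, lambdaRule,
        sdFilter, lambdaFixed)
})

#' Refit the latent model on the selected features
#'
#' Restricts every block to its Lasso-selected features, drops blocks from
#' which nothing was selected (a whole assay/compartment can leave the
#' model), restandardizes the reduced blocks and refits the co-inertia
#' decomposition. Blocks arrive already preprocessed; only
#' restandardization is redone on the reduced feature set.
#'
#' @param blocks named list of preprocessed (not yet standardized)
#'   [OmicsBlock-class] objects, as used for the full model.
#' @param selection a [SelectionResult-class].
#' @param nComponents components for the reduced model.
#' @param sampleLabels optional labels stored in the reduced model.
#' @return An [MCIAModel-class] fitted on the reduced feature set.
#' @export
reduceAndRefit <- function(blocks, selection, nComponents = 10,
    sampleLabels = NULL) {
    stopifnot(is(selection, "SelectionResult"))
    if (!nrow(selection@selected)) stop("zero features selected overall")
    reduced <- list()
    for (bn in names(blocks)) {
        feats <- selection@selected$feature[selection@selected$block == bn]
        if (!length(feats)) next
        b <- blocks[[bn]]
        reduced[[bn]] <- OmicsBlock(
            b@values[, intersect(featureIds(b), feats), drop = FALSE],
            b@assay, b@source)
    }
    if (!length(reduced)) stop("zero features selected overall")
    fitMCIA(reduced, nComponents = nComponents, sampleLabels = sampleLabels)
}

#' Compare feature ranks between the full and the reduced model
#'
#' Features are ranked by descending absolute component-1 loading in each
#' model; the comparison runs over the features the two models share (the
#' reduced feature set) and reports both rank columns plus Spearman's rank
#' correlation of the loading magnitudes over that shared set.
#'
#' @param fullModel,reducedModel fitted [MCIAModel-class] objects; the
#'   reduced model's features must be a subset of the full model's.
#' @param component component index (default 1).
#' @return list with `table` (data.frame: `block`, `feature`, `rank_full`,
#'   `rank_reduced`) and `rho` (Spearman correlation; `NA` with a warning
#'   when fewer than 3 features are shared).
#' @export
compareRanks <- function(fullModel, reducedModel, component = 1) {
    rf <- rankFeatures(fullModel, component)
    rr <- rankFeatures(reducedModel, component)
    keyF <- paste(rf$block, rf$feature, sep = "\r")
    keyR <- paste(rr$block, rr$feature, sep = "\r")
    if (!all(keyR %in% keyF))
        stop("reduced model features must be a subset of the full model's")
    i <- match(keyR, keyF)
    tab <- data.frame(block = rr$block, feature = rr$feature,
        rank_full = rf$rank[i], rank_reduced = rr$rank,
        stringsAsFactors = FALSE)
    if (nrow(tab) < 3L) {
        warning("fewer than 3 shared features; rank correlation undefined")
        rho <- NA_real_
    } else {
        rho <- stats::cor(abs(rf$loading[i]), abs(rr$loading),
            method = "spearman")
    }
    list(table = tab, rho = rho)
}
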