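#' Standardize a block for co-inertia analysis
#'
#' Column-centers the block, divides each column by its sample standard
#' deviation (n-1 denominator), then divides the whole block by the square
#' root of its total sum of squares, so the block has unit inertia. With
#' unit inertia every block enters the multi-block decomposition on equal
#' footing regardless of its feature count. All three parameter sets are
#' stored for projecting unseen samples later.
#'
#' @param block an [OmicsBlock-class], or a plain numeric samples x
#'   features matrix; every feature must have positive standard deviation
#'   (run [filterZeroSD()] or the full [preprocessBlock()] chain first).
#' @param inertia `"root"` (default) divides by the square root of the
#'   total sum of squares, giving unit block inertia; `"raw"` divides by
#'   the raw sum of squares. The two differ only by a per-block scale.
#' @return A [StandardizedBlock-class].
#' @examples
#' m <- matrix(c(0, 2, 2, 0), 2, 2,
#'     dimnames = list(c("a", "b"), c("f1", "f2")))
#' blockValues(standardizeBlock(OmicsBlock(m, "smallseq", "plasma")))
#' @export
standardizeBlock <- function(block, inertia = c("root", "raw")) {
    inertia <- match.arg(inertia)
    if (is(block, "OmicsBlock")) {
        v <- block@values
        assay <- block@assay
        source <- block@source
    } else if (is.matrix(block) && is.numeric(block)) {
        v <- block
        assay <- "smallseq"
        source <- "plasma"
    } else {
        stop("'block' must be an OmicsBlock or a numeric matrix")
    }
    mu <- colMeans(v)
    sds <- .colSds(v)
    if (any(bad <- is.na(sds) | sds == 0))
        stop("zero-standard-deviation feature(s) reached standardization ",
            "(missed filter): ",
            paste(utils::head(colnames(v)[bad], 5), collapse = ", "))
    z <- sweep(sweep(v, 2, mu, `-`), 2, sds, `/`)
    ss <- sum(z^2)
    norm <- if (inertia == "root") sqrt(ss) else ss
    if (norm == 0) norm <- 1
    new("StandardizedBlock", values = z / norm, colMeans = mu,
        colSds = sds, inertiaNorm = norm, assay = assay, source = source)
}

# leading singular triplet of X, by dense SVD or power iteration on v
.leadingTriplet <- function(X, solver = "svd", tol = 1e-9, maxIter = 1000) {
    if (solver == "svd") {
        sv <- svd(X, nu = 1, nv = 1)
        return(list(d = sv$d[1], u = sv$u[, 1], v = sv$v[, 1]))
    }
    # power iteration on t(X) %*% X applied to v
    v <- X[1, ] + colSums(X) / nrow(X)
    nv <- sqrt(sum(v^2))
    if (nv == 0) v[1] <- 1 else v <- v / nv
    for (it in seq_len(maxIter)) {
        w <- as.numeric(crossprod(X, X %*% v))
        nw <- sqrt(sum(w^2))
        if (nw == 0) break
        w <- w / nw
        if (sum(abs(w - v)) < tol) { v <- w; break }
        v <- w
    }
    t <- as.numeric(X %*% v)
    d <- sqrt(sum(t^2))
    list(d = d, u = if (d > 0) t / d else t, v = v)
}

#' Fit a multiple co-inertia (multi-block PCA) model
#'
#' Extracts `nComponents` shared latent variables from a set of
#' standardized blocks measured on the same samples. Per component:
#' \enumerate{
#'   \item concatenate the current (deflated) blocks column-wise;
#'   \item take the leading singular triplet (u, d, v) of the concatenated
#'     matrix;
#'   \item the global latent score is `u * d`;
#'   \item split v into block segments and renormalize each segment to unit
#'     length, giving the block loadings;
#'   \item the partial (block) score is the block matrix times its loading;
#'   \item deflate each block by the rank-1 projection onto its own loading,
#'     `X_k <- X_k (I - v_k v_k^T)` ("blockLoading" deflation, which makes
#'     loadings of different components orthogonal within every block).
#' }
#' Components are sign-fixed so that the largest-magnitude entry of the
#' concatenated loading vector is positive. A block whose rank is
#' exhausted by deflation (after `p_k` components) gets exactly zero
#' loadings and partial scores on the remaining components.
#'
#' @param blocks named list of [StandardizedBlock-class] (or
#'   [OmicsBlock-class], which are standardized on the fly) sharing sample
#'   order.
#' @param nComponents number of components K (capped at `n - 1` and the
#'   total feature count).
#' @param sampleLabels optional per-sample diagnosis labels, stored for
#'   evaluation.
#' @param solver `"svd"` (dense, default) or `"power"` (NIPALS-style power
#'   iteration with tolerance `tol`, at most `maxIter` iterations).
#' @param tol,maxIter power-iteration settings.
#' @return An [MCIAModel-class].
#' @examples
#' set.seed(1)
#' mk <- function(p, nm) OmicsBlock(
#'     matrix(rpois(8 * p, 20), 8, p,
#'         dimnames = list(paste0("S", 1:8), paste0(nm, 1:p))),
#'     "smallseq", "plasma")
#' fit <- fitMCIA(list(a = mk(5, "a"), b = mk(4, "b")), nComponents = 3)
#' eigenvalues(fit)
#' @export
fitMCIA <- function(blocks, nComponents = 10, sampleLabels = NULL,
    solver = c("svd", "power"), tol = 1e-9, maxIter = 1000) {
    solver <- match.arg(solver)
    if (is.null(names(blocks)) || anyDuplicated(names(blocks)))
        stop("'blocks' must be a uniquely named list")
    blocks <- lapply(blocks, function(b)
        if (is(b, "OmicsBlock")) standardizeBlock(b) else b)
    stopifnot(all(vapply(blocks, is, logical(1), "StandardizedBlock")))

    sids <- rownames(blocks[[1]]@values)
    for (b in blocks)
        if (!identical(rownames(b@values), sids))
            stop("all blocks must share the same sample ordering")
    n <- length(sids)
    pk <- vapply(blocks, function(b) ncol(b@values), integer(1))
    p <- sum(pk)
    K <- min(nComponents, n - 1L, p)
    if (K < 1L) stop("'nComponents' must allow at least one component")
    if (nComponents > min(n - 1L, p))
        warning("nComponents reduced to ", K)

    cur <- lapply(blocks, function(b) b@values)
    seg <- rep(names(blocks), pk)

    globalScores <- matrix(NA_real_, n, K,
        dimnames = list(sids, paste0("L", seq_len(K))))
    loadings <- matrix(NA_real_, p, K,
        dimnames = list(NULL, paste0("L", seq_len(K))))
    blockLoad <- lapply(blocks, function(b)
        matrix(NA_real_, ncol(b@values), K,
            dimnames = list(colnames(b@values), paste0("L", seq_len(K)))))
    partial <- lapply(blocks, function(b)
        matrix(NA_real_, n, K, dimnames = list(sids, paste0("L", seq_len(K)))))
    eig <- numeric(K)

    for (j in seq_len(K)) {
        X <- do.call(cbind, cur)
        tr <- .leadingTriplet(X, solver, tol, maxIter)
        d <- tr$d; u <- tr$u; v <- tr$v
        imax <- which.max(abs(v))
        if (v[imax] < 0) { v <- -v; u <- -u }
        globalScores[, j] <- u * d
        eig[j] <- d^2
        loadings[, j] <- v
        off <- 0L
        for (k in seq_along(cur)) {
            vk <- v[off + seq_len(pk[k])]
            nk <- sqrt(sum(vk^2))
            if (nk > 1e-8) {
                vk <- vk / nk
                tk <- as.numeric(cur[[k]] %*% vk)
                cur[[k]] <- cur[[k]] - tcrossprod(tk, vk)
            } else {
                # block rank exhausted by deflation: it carries nothing
                # on this and later components
                vk <- rep(0, pk[k])
                tk <- rep(0, n)
            }
            blockLoad[[k]][, j] <- vk
            partial[[k]][, j] <- tk
            off <- off + pk[k]
        }
    }

    std <- lapply(blocks, function(b) list(colMeans = b@colMeans,
        colSds = b@colSds, inertiaNorm = b@inertiaNorm, assay = b@assay,
        source = b@source, featureIds = colnames(b@values)))
    model <- new("MCIAModel", globalScores = globalScores,
        loadings = loadings, blockLoadings = blockLoad,
        partialScores = partial, eigenvalues = eig,
        contributions = matrix(numeric(0), 0, 0),
        blocks = lapply(blocks, function(b) b@values),
        standardization = std, featureBlock = seg,
        featureIds = unlist(lapply(blocks,
            function(b) colnames(b@values)), use.names = FALSE),
        sampleIds = sids,
        sampleLabels = if (is.null(sampleLabels)) character()
            else as.character(sampleLabels))
    model@contributions <- blockContributions(model, fractions = FALSE)
    model
}

#' Block contributions to each latent variable
#'
#' For block k and component j, with partial score `t_kj` and global score
#' `t_j`, the contribution is
#' `c_kj = ((t_kj' t_j) / (t_j' t_j))^2 * (t_j' t_j)`; fractions divide
#' each component's contributions by their sum, quantifying how much of a
#' latent variable each assay/compartment carries.
#'
#' @param model a fitted [MCIAModel-class].
#' @param fractions return per-component fractions (summing to 1) instead
#'   of raw contributions.
#' @return blocks x components numeric matrix.
#' @export
blockContributions <- function(model, fractions = TRUE) {
    stopifnot(is(model, "MCIAModel"))
    K <- ncol(model@globalScores)
    out <- matrix(NA_real_, length(model@blockLoadings), K,
        dimnames = list(names(model@blockLoadings),
            colnames(model@globalScores)))
    for (j in seq_len(K)) {
        tj <- model@globalScores[, j]
        denom <- sum(tj^2)
        if (denom == 0) stop("degenerate global score (norm 0) in component ", j)
        for (k in seq_along(model@partialScores)) {
            tkj <- model@partialScores[[k]][, j]
            out[k, j] <- (sum(tkj * tj) / denom)^2 * denom
        }
    }
    if (fractions) out <- sweep(out, 2, colSums(out), `/`)
    out
}

#' Project unseen samples onto a fitted latent space
#'
#' Each new block is standardized with the *training* column means, column
#' SDs and inertia divisor, concatenated in model block order, and
#' multiplied by the model's concatenated raw loading matrix. Projecting
#' the training samples themselves reproduces the stored global scores.
#'
#' @param model a fitted [MCIAModel-class].
#' @param newBlocks named list of [OmicsBlock-class] covering the model's
#'   blocks with identical feature sets (same order).
#' @return A [ProjectedScores-class].
#' @export
projectSamples <- function(model, newBlocks) {
    stopifnot(is(model, "MCIAModel"))
    missing <- setdiff(names(model@blocks), names(newBlocks))
    if (length(missing))
        stop("missing block(s): ", paste(missing, collapse = ", "))
    zs <- list()
    for (bn in names(model@blocks)) {
        pars <- model@standardization[[bn]]
        nb <- newBlocks[[bn]]
        nv <- if (is(nb, "OmicsBlock")) nb@values else as.matrix(nb)
        extra <- setdiff(colnames(nv), pars$featureIds)
        lost <- setdiff(pars$featureIds, colnames(nv))
        if (length(extra) || length(lost))
            stop("feature mismatch in block ", sQuote(bn),
                if (length(lost)) paste0("; absent from new data: ",
                    paste(utils::head(lost, 5), collapse = ", ")),
                if (length(extra)) paste0("; unknown to model: ",
                    paste(utils::head(extra, 5), collapse = ", ")))
        nv <- nv[, pars$featureIds, drop = FALSE]
        z <- sweep(sweep(nv, 2, pars$colMeans, `-`), 2, pars$colSds, `/`)
        zs[[bn]] <- z / pars$inertiaNorm
    }
    sids <- rownames(zs[[1]])
    Z <- do.call(cbind, zs)
    scores <- Z %*% model@loadings
    rownames(scores) <- sids
    new("ProjectedScores", scores = scores,
        sampleIds = as.character(sids), projected = TRUE)
}

#' Rank all features by loading magnitude
#'
#' Orders every feature across all blocks by descending absolute loading
#' on one component; ties are broken lexicographically by (block name,
#' feature id).
#'
#' @param model a fitted [MCIAModel-class].
#' @param component component index.
#' @return data.frame with columns `rank`, `block`, `feature`, `loading`.
#' @export
rankFeatures <- function(model, component = 1) {
    stopifnot(is(model, "MCIAModel"))
    K <- ncol(model@globalScores)
    if (component < 1 || component > K)
        stop("'component' must lie in 1..", K)
    df <- data.frame(block = model@featureBlock,
        feature = model@featureIds,
        loading = model@loadings[, component], stringsAsFactors = FALSE)
    ord <- order(-abs(df$loading), df$block, df$feature)
    df <- df[ord, , drop = FALSE]
    df <- cbind(rank = seq_len(nrow(df)), df)
    rownames(df) <- NULL
    df
}
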