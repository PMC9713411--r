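#' Exact two-cluster k-means on one dimension
#'
#' For one-dimensional data the optimal k = 2 partition is contiguous in
#' sorted order, so the global optimum is found exactly by enumerating the
#' n - 1 sorted split points — no random initialization, no seed
#' sensitivity. Cluster ids are ordered by cluster mean (cluster 1 = lower
#' mean). Objective ties are broken by the smallest split point.
#'
#' @param values numeric vector with at least two distinct values.
#' @return list with `cluster` (integer 1/2 per input element, input
#'   order), `objective` (total within-cluster sum of squared deviations
#'   from cluster means) and `centers` (the two cluster means, ascending).
#' @examples
#' kmeans1d(c(0, 1, 10, 11))
#' @export
kmeans1d <- function(values) {
    n <- length(values)
    if (n < 2L) stop("at least 2 values required")
    if (length(unique(values)) < 2L) stop("all values identical")
    ord <- order(values)
    x <- values[ord]
    cs <- cumsum(x)
    cs2 <- cumsum(x^2)
    tot <- cs[n]
    tot2 <- cs2[n]
    s <- seq_len(n - 1L)
    obj <- (cs2[s] - cs[s]^2 / s) +
        ((tot2 - cs2[s]) - (tot - cs[s])^2 / (n - s))
    best <- which.min(obj)  # ties: first (smallest split)
    cl <- integer(n)
    cl[ord] <- rep(1:2, c(best, n - best))
    list(cluster = cl, objective = obj[best],
        centers = c(cs[best] / best, (tot - cs[best]) / (n - best)))
}

#' Split-join distance between two partitions
#'
#' Counts, in both directions, the elements that must be moved to turn one
#' partition into the other:
#' `d = (n - sum_i max_j |A_i ∩ B_j|) + (n - sum_j max_i |B_j ∩ A_i|)`.
#' Lower is better; identical partitions give 0.
#'
#' @param a,b cluster assignments over the same elements (equal length;
#'   if both are named, elements are matched by name).
#' @return non-negative integer.
#' @examples
#' splitJoinDistance(c(1, 1, 2, 2), c(1, 2, 1, 2))
#' @export
splitJoinDistance <- function(a, b) {
    if (!is.null(names(a)) && !is.null(names(b))) {
        if (!setequal(names(a), names(b)))
            stop("partitions cover different sample universes")
        b <- b[names(a)]
    }
    if (length(a) != length(b))
        stop("partitions cover different sample universes")
    n <- length(a)
    tab <- table(a, b)
    as.integer((n - sum(apply(tab, 1, max))) +
        (n - sum(apply(tab, 2, max))))
}

# within-cluster sum of squares for a 1/2 assignment
.kmObjective <- function(x, cl) {
    obj <- 0
    for (c in 1:2) {
        xi <- x[cl == c]
        if (length(xi)) obj <- obj + sum((xi - mean(xi))^2)
    }
    obj
}

# one relocation sweep: repeatedly move the sample from cluster `from` to
# the other cluster whose move minimally changes the k-means objective
# (cluster means recomputed after every move), recording (fpr, tpr) after
# each move. Incremental O(1) objective deltas; ties -> smallest index.
.relocationSweep <- function(x, cl, from, pos, tpCluster) {
    to <- 3L - from
    nPos <- sum(pos)
    nCtl <- sum(!pos)
    s <- c(sum(x[cl == 1L]), sum(x[cl == 2L]))
    m <- c(sum(cl == 1L), sum(cl == 2L))
    pts <- matrix(NA_real_, sum(cl == from), 2L)
    r <- 0L
    while (m[from] > 0L) {
        idx <- which(cl == from)
        dec <- if (m[from] == 1L) rep(0, length(idx)) else
            (x[idx] - s[from] / m[from])^2 * m[from] / (m[from] - 1)
        inc <- if (m[to] == 0L) rep(0, length(idx)) else
            (x[idx] - s[to] / m[to])^2 * m[to] / (m[to] + 1)
        delta <- inc - dec
        i <- idx[which.min(delta)]
        cl[i] <- to
        s[from] <- s[from] - x[i]; m[from] <- m[from] - 1L
        s[to] <- s[to] + x[i]; m[to] <- m[to] + 1L
        r <- r + 1L
        predPos <- cl == tpCluster
        pts[r, ] <- c(sum(predPos & !pos) / nCtl, sum(predPos & pos) / nPos)
    }
    pts
}

#' AUROC of a latent variable via k-means relocation
#'
#' Builds an ROC curve from a single latent variable without a
#' probabilistic classifier: (1) exact two-cluster k-means; (2) the
#' true-positive cluster is the one holding the larger fraction of the
#' positive class; (3) record (FPR, TPR); (4) sweep A relocates, one at a
#' time, the cluster-1 sample whose move to cluster 2 minimally changes
#' the k-means objective (means recomputed after every move), recording
#' (FPR, TPR) after each move until cluster 1 empties; (5) the initial
#' clustering is reinstated and sweep B does the symmetric cluster-2 to
#' cluster-1 relocation; (6) the curve is the union of all recorded points
#' plus (0,0) and (1,1), sorted by (FPR, TPR), with the area computed by
#' the trapezoid rule. Relocation ties are broken by the smaller sample
#' index, making the result deterministic. When the initial cluster table
#' is exactly tied (positive and control fractions equal), cluster 2 is
#' designated true-positive; in that one configuration the designation,
#' and hence the AUC, is not invariant to flipping the sign of `values`.
#'
#' @param values numeric vector (one latent variable).
#' @param labels per-sample class labels.
#' @param positive labels forming the positive class.
#' @return An [ROCResult-class].
#' @examples
#' aurocByRelocation(c(0, 0, 1, 1), c("ctl", "ctl", "pos", "pos"), "pos")
#' @export
aurocByRelocation <- function(values, labels,
    positive = c("RRMS", "CIS", "RIS")) {
    pos <- as.character(labels) %in% positive
    if (!any(pos) || all(pos))
        stop("both classes must be present")
    if (length(values) != length(pos))
        stop("'values' and 'labels' must have equal length")

    km <- kmeans1d(values)
    cl0 <- km$cluster
    rPos <- sum(pos & cl0 == 1L) / sum(pos)
    rCtl <- sum(!pos & cl0 == 1L) / sum(!pos)
    tpCluster <- if (rPos > rCtl) 1L else 2L

    predPos <- cl0 == tpCluster
    p0 <- c(sum(predPos & !pos) / sum(!pos), sum(predPos & pos) / sum(pos))
    ptsA <- .relocationSweep(values, cl0, 1L, pos, tpCluster)
    ptsB <- .relocationSweep(values, cl0, 2L, pos, tpCluster)

    pts <- rbind(c(0, 0), c(1, 1), p0, ptsA, ptsB)
    pts <- unique(pts)
    pts <- pts[order(pts[, 1], pts[, 2]), , drop = FALSE]
    auc <- sum(diff(pts[, 1]) * (utils::head(pts[, 2], -1) +
        utils::tail(pts[, 2], -1)) / 2)
    new("ROCResult",
        points = data.frame(fpr = pts[, 1], tpr = pts[, 2]),
        auc = auc, positiveClass = as.character(positive))
}

#' Two-sample rank-sum (Mann-Whitney) test
#'
#' Thin, policy-setting wrapper around [stats::wilcox.test()]: the exact
#' null distribution is enumerated when the pooled sample size is at most
#' 12 and there are no ties; otherwise the normal approximation with tie
#' and continuity correction is used. Two-sided.
#'
#' @param x,y numeric vectors (independent groups, both non-empty).
#' @return list with `statistic` (the Mann-Whitney U for `x`) and
#'   `p.value`.
#' @examples
#' rankSumTest(1:3, 4:6)
#' @export
rankSumTest <- function(x, y) {
    if (!length(x) || !length(y)) stop("both groups must be non-empty")
    exact <- (length(x) + length(y) <= 12L) &&
        !anyDuplicated(c(x, y))
    res <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
        correct = TRUE, alternative = "two.sided"))
    list(statistic = unname(res$statistic), p.value = res$p.value)
}

#' Score every latent variable against the diagnosis labels
#'
#' For each requested component, computes the relocation AUROC of the
#' global score and the split-join distance between the exact two-cluster
#' k-means partition of the score and the label partition
#' (positive vs rest). The best component (maximum AUC; ties go to the
#' lower index) is flagged.
#'
#' @param model a fitted [MCIAModel-class].
#' @param labels per-sample labels; defaults to the labels stored at fit
#'   time.
#' @param components component indices to evaluate.
#' @param positive labels forming the positive class (default: the
#'   relapsing-remitting / isolated-syndrome phenotypes).
#' @return data.frame with columns `component`, `auc`, `split_join`,
#'   `best`.
#' @export
evaluateComponents <- function(model, labels = NULL,
    components = seq_len(nComponents(model)),
    positive = c("RRMS", "CIS", "RIS")) {
    stopifnot(is(model, "MCIAModel"))
    if (is.null(labels)) labels <- model@sampleLabels
    if (!length(labels)) stop("no labels available")
    pos <- as.character(labels) %in% positive
    labPart <- ifelse(pos, 1L, 2L)
    rows <- lapply(components, function(j) {
        v <- model@globalScores[, j]
        roc <- aurocByRelocation(v, labels, positive)
        km <- kmeans1d(v)
        data.frame(component = j, auc = roc@auc,
            split_join = splitJoinDistance(km$cluster, labPart))
    })
    out <- do.call(rbind, rows)
    out$best <- seq_len(nrow(out)) == which.max(out$auc)
    out
}
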