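# Independent reference implementations used to pin down expected values.
# Each oracle is written directly from the method definition, favouring
# plain loops and from-scratch recomputation over the optimized code paths
# used by the package.

# --- TMM scaling factors, step by step -------------------------------------
# counts: samples x features. Reference = sample whose 75th-percentile
# count/libsize is closest to the mean; per sample, doubly trimmed (30% on
# M, 5% on A) precision-weighted mean of M gives the log2 factor; factors
# rescaled to geometric mean 1.
oracleTMM <- function(counts, mTrim = 0.30, aTrim = 0.05) {
    lib <- rowSums(counts)
    n <- nrow(counts)
    q75 <- numeric(n)
    for (i in seq_len(n))
        q75[i] <- stats::quantile(counts[i, ], 0.75, names = FALSE) / lib[i]
    ref <- which.min(abs(q75 - mean(q75)))
    f <- numeric(n)
    for (i in seq_len(n)) {
        obs <- counts[i, ]; rf <- counts[ref, ]
        ok <- obs > 0 & rf > 0
        o <- obs[ok] / lib[i]; r <- rf[ok] / lib[ref]
        M <- log2(o / r)
        A <- (log2(o) + log2(r)) / 2
        w <- (lib[i] - obs[ok]) / (lib[i] * obs[ok]) +
            (lib[ref] - rf[ok]) / (lib[ref] * rf[ok])
        if (max(abs(M)) < 1e-6) { f[i] <- 1; next }
        m <- length(M)
        loL <- floor(m * mTrim) + 1; hiL <- m + 1 - loL
        loS <- floor(m * aTrim) + 1; hiS <- m + 1 - loS
        keep <- rank(M) >= loL & rank(M) <= hiL &
            rank(A) >= loS & rank(A) <= hiS
        f[i] <- 2^(sum(M[keep] / w[keep]) / sum(1 / w[keep]))
    }
    f / exp(mean(log(f)))
}

# --- multi-block co-inertia, literal five-step recursion -------------------
# mats: list of standardized matrices (samples x features). Leading triplet
# via the eigen-decomposition of X X^T (not svd()), segments renormalized
# with explicit loops, rank-1 deflation per block.
oracleMCIA <- function(mats, K) {
    cur <- mats
    n <- nrow(mats[[1]])
    res <- list(global = matrix(0, n, K), eig = numeric(K),
        loadings = vector("list", K),
        blockLoadings = lapply(mats, function(m)
            matrix(0, ncol(m), K)),
        partial = lapply(mats, function(m) matrix(0, n, K)))
    for (j in seq_len(K)) {
        X <- do.call(cbind, cur)
        e <- eigen(X %*% t(X), symmetric = TRUE)
        d <- sqrt(max(e$values[1], 0))
        u <- e$vectors[, 1]
        v <- as.numeric(t(X) %*% u) / d
        if (v[which.max(abs(v))] < 0) { v <- -v; u <- -u }
        res$global[, j] <- u * d
        res$eig[j] <- d^2
        res$loadings[[j]] <- v
        off <- 0
        for (k in seq_along(cur)) {
            p <- ncol(cur[[k]])
            vk <- v[(off + 1):(off + p)]
            nk <- sqrt(sum(vk^2))
            if (nk > 1e-8) {
                vk <- vk / nk
                tk <- numeric(n)
                for (i in seq_len(n)) tk[i] <- sum(cur[[k]][i, ] * vk)
                cur[[k]] <- cur[[k]] - outer(tk, vk)
            } else {
                vk <- rep(0, p)
                tk <- numeric(n)
            }
            res$blockLoadings[[k]][, j] <- vk
            res$partial[[k]][, j] <- tk
            off <- off + p
        }
    }
    res
}

# --- 1-D 2-means via Lloyd iterations from every split initialization ------
oracleLloyd <- function(values) {
    n <- length(values)
    xs <- sort(values)
    best <- NULL
    for (s in seq_len(n - 1)) {
        c1 <- mean(xs[1:s]); c2 <- mean(xs[(s + 1):n])
        if (c1 == c2) next
        km <- suppressWarnings(stats::kmeans(values,
            centers = matrix(c(c1, c2)), algorithm = "Lloyd",
            iter.max = 100))
        if (is.null(best) || km$tot.withinss < best$tot.withinss - 1e-12)
            best <- km
    }
    ord <- order(best$centers)
    cl <- match(best$cluster, ord)
    list(cluster = cl, objective = best$tot.withinss)
}

# --- relocation ROC, brute force -------------------------------------------
# Every candidate move is scored by recomputing the full k-means objective
# on the modified partition; points merged from both sweeps + (0,0),(1,1).
oracleRelocation <- function(values, labels, positive) {
    pos <- labels %in% positive
    obj <- function(cl) {
        o <- 0
        for (c in 1:2) {
            xi <- values[cl == c]
            if (length(xi)) o <- o + sum((xi - mean(xi))^2)
        }
        o
    }
    km <- oracleLloyd(values)
    cl0 <- km$cluster
    rP <- sum(pos & cl0 == 1) / sum(pos)
    rC <- sum(!pos & cl0 == 1) / sum(!pos)
    tp <- if (rP > rC) 1 else 2
    rates <- function(cl) {
        pred <- cl == tp
        c(sum(pred & !pos) / sum(!pos), sum(pred & pos) / sum(pos))
    }
    sweep1 <- function(cl, from) {
        to <- 3 - from
        pts <- NULL
        while (any(cl == from)) {
            idx <- which(cl == from)
            deltas <- sapply(idx, function(i) {
                cl2 <- cl; cl2[i] <- to; obj(cl2) - obj(cl)
            })
            i <- idx[which.min(deltas)]
            cl[i] <- to
            pts <- rbind(pts, rates(cl))
        }
        pts
    }
    pts <- rbind(c(0, 0), c(1, 1), rates(cl0), sweep1(cl0, 1),
        sweep1(cl0, 2))
    pts <- unique(pts)
    pts <- pts[order(pts[, 1], pts[, 2]), , drop = FALSE]
    auc <- 0
    for (i in seq_len(nrow(pts) - 1))
        auc <- auc + (pts[i + 1, 1] - pts[i, 1]) *
            (pts[i, 2] + pts[i + 1, 2]) / 2
    list(points = pts, auc = auc)
}

# --- split-join distance via explicit overlap loops ------------------------
oracleSplitJoin <- function(a, b) {
    n <- length(a)
    s1 <- 0
    for (i in unique(a)) {
        best <- 0
        for (j in unique(b)) best <- max(best, sum(a == i & b == j))
        s1 <- s1 + best
    }
    s2 <- 0
    for (j in unique(b)) {
        best <- 0
        for (i in unique(a)) best <- max(best, sum(a == i & b == j))
        s2 <- s2 + best
    }
    (n - s1) + (n - s2)
}

# --- exact Mann-Whitney two-sided p by enumeration -------------------------
oracleRankSumExact <- function(x, y) {
    m <- length(x); n <- length(y)
    pooled <- c(x, y)
    U <- sum(rank(pooled)[seq_len(m)]) - m * (m + 1) / 2
    combos <- utils::combn(m + n, m)
    Us <- apply(combos, 2, function(idx)
        sum(rank(pooled)[idx]) - m * (m + 1) / 2)
    pLe <- mean(Us <= U)
    pGe <- mean(Us >= U)
    list(U = U, p = min(1, 2 * min(pLe, pGe)))
}

# --- Spearman rho via rank-then-Pearson ------------------------------------
oracleSpearman <- function(x, y) {
    r <- rank(x); s <- rank(y)
    sum((r - mean(r)) * (s - mean(s))) /
        sqrt(sum((r - mean(r))^2) * sum((s - mean(s))^2))
}

# --- soft threshold (orthonormal-design Lasso closed form) -----------------
oracleSoftThreshold <- function(bhat, lambda) {
    sign(bhat) * pmax(abs(bhat) - lambda, 0)
}
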