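# mean-zero orthonormal design (population scaling): Helmert contrasts
helmertDesign <- function(n) {
    H <- stats::contr.helmert(n)
    sweep(H, 2, sqrt(colSums(H^2) / n), `/`)
}

test_that("Lasso matches the soft-threshold closed form on orthonormal designs", {
    set.seed(61)
    n <- 24
    X <- helmertDesign(n)[, 1:10]
    colnames(X) <- paste0("f", 1:10)
    beta <- c(3, -2, 1.5, 0.8, -0.4, rep(0, 5))
    y <- as.numeric(X %*% beta) + rnorm(n, sd = 0.1)
    bhat <- as.numeric(crossprod(X, y)) / n
    for (lam in c(0.05, 0.3, 1)) {
        sel <- lassoSelect(X, y = y, lambdaFixed = lam)
        expected <- oracleSoftThreshold(bhat, lam)
        got <- setNames(rep(0, 10), colnames(X))
        got[sel@selected$feature] <- sel@selected$beta
        expect_equal(unname(got), expected, tolerance = 1e-6)
    }
    # a penalty above max |X'y|/n selects nothing
    sel0 <- lassoSelect(X, y = y, lambdaFixed = max(abs(bhat)) * 1.01)
    expect_identical(nrow(sel0@selected), 0L)
    expect_identical(sel0@droppedBlocks, "block1")
    # coefficient path is monotone soft-thresholding in lambda
    lams <- c(0.05, 0.15, 0.3, 0.6, 1)
    paths <- sapply(lams, function(l) {
        s <- lassoSelect(X, y = y, lambdaFixed = l)
        b <- setNames(rep(0, 10), colnames(X))
        b[s@selected$feature] <- s@selected$beta
        b
    })
    for (j in 1:10)
        expect_true(all(diff(abs(paths[j, ])) <= 1e-6))
})

test_that("Lasso with CV recovers a planted predictor and is order-invariant", {
    set.seed(62)
    n <- 40
    X <- cbind(scale(rnorm(n)), matrix(rnorm(n * 50), n, 50))
    colnames(X) <- c("planted", paste0("noise", 1:50))
    y <- X[, "planted"] + rnorm(n, sd = 0.3)
    sel <- lassoSelect(X, y = y, seed = 7)
    expect_true("planted" %in% sel@selected$feature)
    expect_identical(sel@foldSeed, 7L)
    expect_true(nrow(sel@cvCurve) > 10)
    # permuting the feature columns leaves the selected set unchanged
    perm <- sample(ncol(X))
    selP <- lassoSelect(X[, perm], y = y, seed = 7)
    expect_setequal(selP@selected$feature, sel@selected$feature)
    expect_error(lassoSelect(X[1:3, ], y = y[1:3], folds = 5),
        "fewer samples than folds")
})

test_that("reduceAndRefit restricts blocks, drops empty ones, and preserves identity selections", {
    set.seed(63)
    raw <- list(
        a = mkBlock(matrix(10 * runif(80), 10, 8),
            fid = sprintf("af%d", 1:8)),
        b = mkBlock(matrix(10 * runif(60), 10, 6),
            fid = sprintf("bf%d", 1:6)),
        c = mkBlock(matrix(10 * runif(40), 10, 4),
            fid = sprintf("cf%d", 1:4)))
    full <- fitMCIA(lapply(raw, standardizeBlock), nComponents = 3)
    mkSel <- function(df) new("SelectionResult", selected = df,
        lambda = 0.1, cvCurve = data.frame(), foldSeed = 1L,
        droppedBlocks = setdiff(names(raw), df$block))
    # selection touching 2 of 3 blocks: reduced model has exactly those
    sel2 <- mkSel(data.frame(block = c("a", "a", "c"),
        feature = c("af1", "af3", "cf2"), beta = c(1, -1, 2)))
    red <- reduceAndRefit(raw, sel2, nComponents = 2)
    expect_identical(names(blockLoadings(red)), c("a", "c"))
    expect_identical(featureIds(red), c("af1", "af3", "cf2"))
    # selecting every feature reproduces the full model up to sign
    selAll <- mkSel(data.frame(block = rep(names(raw), c(8, 6, 4)),
        feature = unlist(lapply(raw, featureIds), use.names = FALSE),
        beta = 1))
    redAll <- reduceAndRefit(raw, selAll, nComponents = 3)
    expect_equal(abs(globalScores(redAll)), abs(globalScores(full)),
        tolerance = 1e-8)
    expect_error(reduceAndRefit(raw, mkSel(data.frame(block = character(),
        feature = character(), beta = numeric()))), "zero features")
})

test_that("rank comparison reproduces Spearman's rho from first principles", {
    set.seed(64)
    raw <- list(
        a = mkBlock(matrix(10 * runif(120), 12, 10),
            fid = sprintf("af%d", 1:10)),
        b = mkBlock(matrix(10 * runif(96), 12, 8),
            fid = sprintf("bf%d", 1:8)))
    full <- fitMCIA(lapply(raw, standardizeBlock), nComponents = 2)
    # identical models: rho exactly 1
    expect_equal(compareRanks(full, full)$rho, 1)
    # reduced refit: rho equals the rank-then-Pearson oracle
    sel <- new("SelectionResult", selected = data.frame(
        block = c(rep("a", 5), rep("b", 3)),
        feature = c(sprintf("af%d", 1:5), sprintf("bf%d", 1:3)),
        beta = 1), lambda = 0.1, cvCurve = data.frame(),
        droppedBlocks = character(), foldSeed = 1L)
    red <- reduceAndRefit(raw, sel, nComponents = 2)
    cmp <- compareRanks(full, red)
    expect_identical(nrow(cmp$table), 8L)
    key <- paste(cmp$table$block, cmp$table$feature)
    lf <- abs(featureLoadings(full)[, 1])
    names(lf) <- paste(full@featureBlock, featureIds(full))
    lr <- abs(featureLoadings(red)[, 1])
    names(lr) <- paste(red@featureBlock, featureIds(red))
    expect_equal(cmp$rho, oracleSpearman(lf[key], lr[key]),
        tolerance = 1e-12)
    # antitone loadings give rho -1
    fake <- function(lo) new("MCIAModel",
        globalScores = matrix(0, 2, 1, dimnames = list(c("s1", "s2"), "L1")),
        loadings = matrix(lo, length(lo), 1),
        blockLoadings = list(), partialScores = list(),
        eigenvalues = 1, contributions = matrix(numeric(0), 0, 0),
        blocks = list(), standardization = list(),
        featureBlock = rep("x", length(lo)),
        featureIds = paste0("f", seq_along(lo)),
        sampleIds = c("s1", "s2"), sampleLabels = character())
    expect_equal(compareRanks(fake(c(0.9, 0.5, 0.3, 0.1)),
        fake(c(0.1, 0.3, 0.5, 0.9)))$rho, -1)
    # fewer than 3 shared features: rho undefined with a warning
    expect_warning(
        out <- compareRanks(fake(c(0.9, 0.5)), fake(c(0.5, 0.9))),
        "fewer than 3")
    expect_true(is.na(out$rho))
})

test_that("planted features are enriched among Lasso selections", {
    co <- generateCohort(syntheticConfig(
        nPerGroup = c(positive = 15L, control = 15L, progressive = 0L),
        effectSize = 2, seed = 88))
    lab <- co$metadata$group
    bin <- ifelse(lab == "RRMS", "positive", "control")
    pp <- lapply(co$blocks, function(b) preprocessBlock(b, bin)$block)
    pp <- pp[vapply(pp, function(b) ncol(blockValues(b)) > 1, logical(1))]
    m <- fitMCIA(pp, nComponents = 2, sampleLabels = lab)
    sel <- lassoSelect(m, seed = 88)
    info <- unlist(co$truth$informativeFeatureIds, use.names = FALSE)
    univ <- featureIds(m)
    q <- sum(sel@selected$feature %in% info)
    mw <- sum(univ %in% info)
    p <- phyper(q - 1, mw, length(univ) - mw, nrow(sel@selected),
        lower.tail = FALSE)
    expect_lt(p, 0.01)
})
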