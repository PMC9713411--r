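test_that("standardization centers, scales and yields unit block inertia", {
    b <- mkBlock(rbind(c(0, 2), c(2, 0)))
    s <- standardizeBlock(b)
    expect_equal(unname(blockValues(s)),
        rbind(c(-0.5, 0.5), c(0.5, -0.5)))
    expect_equal(sum(blockValues(s)^2), 1)
    # generic blocks: column means ~0, total inertia 1, params stored
    set.seed(2)
    b2 <- mkBlock(matrix(10 * runif(50), 5, 10))
    s2 <- standardizeBlock(b2)
    expect_true(all(abs(colMeans(blockValues(s2))) < 1e-10))
    expect_equal(sum(blockValues(s2)^2), 1, tolerance = 1e-10)
    expect_equal(s2@colMeans, colMeans(blockValues(b2)))
    # standardizing an already-standardized block changes nothing
    s3 <- standardizeBlock(blockValues(s2))
    expect_equal(blockValues(s3), blockValues(s2), tolerance = 1e-12)
    # zero-SD column is an error naming the feature
    bad <- mkBlock(cbind(c(1, 1, 1), c(1, 2, 3)), fid = c("const", "ok"))
    expect_error(standardizeBlock(bad), "const")
    # raw-inertia variant differs only by a per-block scale
    sr <- standardizeBlock(b2, inertia = "raw")
    ratio <- blockValues(sr) / blockValues(s2)
    expect_equal(max(ratio) - min(ratio), 0, tolerance = 1e-12)
})

test_that("a single-block fit reduces to plain SVD of the block", {
    set.seed(7)
    s <- rStdBlocks(8, 6, seed = 7)
    m <- fitMCIA(s, nComponents = 5)
    sv <- svd(blockValues(s[[1]]))
    for (j in 1:5) {
        gs <- globalScores(m)[, j]
        ref <- sv$u[, j] * sv$d[j]
        expect_equal(abs(sum(gs * ref)) / sqrt(sum(gs^2) * sum(ref^2)), 1,
            tolerance = 1e-8)
        expect_equal(sort(abs(unname(gs))), sort(abs(ref)),
            tolerance = 1e-8)
        expect_equal(abs(featureLoadings(m)[, j]), abs(sv$v[, j]),
            tolerance = 1e-8)
    }
    expect_equal(eigenvalues(m), sv$d[1:5]^2, tolerance = 1e-8)
    # sole block contributes fraction 1 to every component
    expect_equal(unname(blockContributions(m)), matrix(1, 1, 5))
})

test_that("two identical blocks share the first component equally", {
    set.seed(9)
    raw <- matrix(10 * runif(35), 7, 5)
    s <- list(
        b1 = standardizeBlock(mkBlock(raw, fid = sprintf("b1_f%d", 1:5))),
        b2 = standardizeBlock(mkBlock(raw, fid = sprintf("b2_f%d", 1:5))))
    m <- fitMCIA(s, nComponents = 3)
    fr <- blockContributions(m)
    expect_equal(unname(fr[, 1]), c(0.5, 0.5), tolerance = 1e-10)
})

test_that("the fit agrees with an independent five-step oracle", {
    for (seed in c(1, 2, 3)) {
        s <- rStdBlocks(6, c(4, 3), seed = seed)
        mats <- lapply(s, blockValues)
        K <- 4
        m <- fitMCIA(s, nComponents = K)
        o <- oracleMCIA(mats, K)
        expect_equal(unname(globalScores(m)), o$global, tolerance = 1e-8)
        expect_equal(eigenvalues(m), o$eig, tolerance = 1e-8)
        for (j in seq_len(K))
            expect_equal(unname(featureLoadings(m)[, j]),
                o$loadings[[j]], tolerance = 1e-8)
        for (k in 1:2) {
            expect_equal(unname(blockLoadings(m)[[k]]),
                o$blockLoadings[[k]], tolerance = 1e-8)
            expect_equal(unname(partialScores(m)[[k]]),
                o$partial[[k]], tolerance = 1e-8)
        }
        # power-iteration solver agrees with the dense solver
        mp <- fitMCIA(s, nComponents = K, solver = "power", tol = 1e-12)
        expect_equal(globalScores(mp), globalScores(m), tolerance = 1e-6)
    }
})

test_that("structural invariants: eigenvalue order, orthogonality, fractions, block order", {
    s <- rStdBlocks(9, c(6, 4, 5), seed = 13)
    m <- fitMCIA(s, nComponents = 6)
    ev <- eigenvalues(m)
    expect_true(all(diff(ev) <= 1e-10))
    # block loadings of different components are orthogonal within a
    # block; each column has unit norm until the block's rank is exhausted
    # by deflation, after which it is exactly zero
    for (bl in blockLoadings(m)) {
        g <- crossprod(bl)
        expect_lt(max(abs(g[upper.tri(g)])), 1e-8)
        expect_true(all(abs(diag(g) - 1) < 1e-10 | diag(g) == 0))
    }
    fr <- blockContributions(m)
    expect_true(all(fr >= -1e-12 & fr <= 1 + 1e-12))
    expect_equal(unname(colSums(fr)), rep(1, 6), tolerance = 1e-10)
    # fitting is invariant to block input order up to component sign
    m2 <- fitMCIA(s[c(3, 1, 2)], nComponents = 6)
    expect_equal(abs(globalScores(m2)), abs(globalScores(m)),
        tolerance = 1e-8)
})

test_that("projection is consistent with the fitted scores", {
    set.seed(40)
    raw <- list(
        a = mkBlock(matrix(10 * runif(60), 10, 6),
            fid = sprintf("a_f%d", 1:6)),
        b = mkBlock(matrix(10 * runif(50), 10, 5),
            fid = sprintf("b_f%d", 1:5)))
    m <- fitMCIA(lapply(raw, standardizeBlock), nComponents = 4)
    # self-projection reproduces every stored global score
    ps <- projectSamples(m, raw)
    expect_equal(unname(globalScores(ps)), unname(globalScores(m)),
        tolerance = 1e-8)
    # a sample at the training feature means scores zero everywhere
    atMean <- lapply(raw, function(b) {
        v <- matrix(colMeans(blockValues(b)), 1,
            dimnames = list("new1", featureIds(b)))
        OmicsBlock(v, assayType(b), sourceLabel(b))
    })
    expect_equal(unname(globalScores(projectSamples(m, atMean))[1, ]),
        rep(0, 4), tolerance = 1e-10)
    # a duplicate of training sample 3 gets sample 3's scores
    dup <- lapply(raw, function(b) {
        v <- blockValues(b)[3, , drop = FALSE]
        rownames(v) <- "copy"
        OmicsBlock(v, assayType(b), sourceLabel(b))
    })
    expect_equal(unname(globalScores(projectSamples(m, dup))[1, 1]),
        unname(globalScores(m)[3, 1]), tolerance = 1e-8)
    # feature mismatch errors list the differences
    broken <- raw
    v <- blockValues(broken$a)
    colnames(v)[2] <- "alien"
    broken$a <- OmicsBlock(v, "smallseq", "plasma")
    expect_error(projectSamples(m, broken), "alien")
    expect_error(projectSamples(m, raw["a"]), "missing block")
})

test_that("feature ranking orders by |loading| with lexicographic ties", {
    s <- rStdBlocks(6, c(3, 2), seed = 21)
    m <- fitMCIA(s, nComponents = 2)
    rk <- rankFeatures(m, 1)
    expect_identical(nrow(rk), nrow(featureLoadings(m)))
    expect_true(all(diff(abs(rk$loading)) <= 1e-15))
    expect_identical(rk$rank, seq_len(nrow(rk)))
    expect_error(rankFeatures(m, 5), "must lie in")
    # explicit ordering and tie rule on a hand-built model
    fake <- new("MCIAModel",
        globalScores = matrix(0, 2, 1, dimnames = list(c("s1", "s2"), "L1")),
        loadings = matrix(c(0.9, -0.95, 0.1, 0.5, -0.5), 5, 1),
        blockLoadings = list(), partialScores = list(),
        eigenvalues = 1, contributions = matrix(numeric(0), 0, 0),
        blocks = list(), standardization = list(),
        featureBlock = c("blk1", "blk1", "blk1", "blk2", "blk1"),
        featureIds = c("a", "b", "c", "tie2", "tie1"),
        sampleIds = c("s1", "s2"), sampleLabels = character())
    rf <- rankFeatures(fake, 1)
    expect_identical(rf$feature, c("b", "a", "tie1", "tie2", "c"))
})

test_that("component 1 recovers a planted factor on a synthetic cohort", {
    co <- generateCohort(syntheticConfig(
        nPerGroup = c(positive = 15L, control = 15L, progressive = 0L),
        effectSize = 2, seed = 77))
    lab <- co$metadata$group
    bin <- ifelse(lab == "RRMS", "positive", "control")
    pp <- lapply(co$blocks, function(b) preprocessBlock(b, bin)$block)
    pp <- pp[vapply(pp, function(b) ncol(blockValues(b)) > 1, logical(1))]
    m <- fitMCIA(pp, nComponents = 2, sampleLabels = lab)
    rho <- cor(globalScores(m)[, 1], co$truth$factorValues,
        method = "spearman")
    expect_gte(abs(rho), 0.8)
})
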