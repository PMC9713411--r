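test_that("min-total-count filter keeps features at or above the threshold", {
    b <- mkBlock(rbind(c(33, 25, 40), c(33, 35, 30), c(33, 40, 31)))
    # feature totals 99, 100, 101
    res <- filterMinTotalCount(b, minTotal = 100)
    expect_identical(featureIds(res$block), c("f002", "f003"))
    expect_identical(res$report@nBefore, 3L)
    expect_identical(res$report@nAfter, 2L)
    # all-zero feature removed
    bz <- mkBlock(cbind(c(0, 0, 0), c(5, 50, 50)))
    expect_identical(featureIds(filterMinTotalCount(bz)$block), "f002")
    # zero threshold is the identity
    expect_identical(blockValues(filterMinTotalCount(b, 0)$block),
        blockValues(b))
    expect_error(filterMinTotalCount(mkBlock(matrix(runif(4), 2, 2),
        assay = "methylome")), "count assays")
    expect_warning(filterMinTotalCount(bz, minTotal = 1e6), "every feature")
})

test_that("group coverage uses a >= fraction rule in both groups by default", {
    g <- rep(c("a", "b"), c(9, 12))
    mk <- function(coverA, coverB) {
        col <- c(rep(1, coverA), rep(0, 9 - coverA),
            rep(1, coverB), rep(0, 12 - coverB))
        mkBlock(cbind(col, rep(1, 21)), assay = "mintmap")
    }
    # 6/9 and 8/12 are both exactly 2/3: kept
    expect_identical(unname(filterGroupCoverage(mk(6, 8), g)$report@keep),
        c(TRUE, TRUE))
    # full coverage kept
    expect_true(all(filterGroupCoverage(mk(9, 12), g)$report@keep))
    # 9/9 but 7/12 < 2/3: removed under "both", kept under "either"
    expect_identical(unname(filterGroupCoverage(mk(9, 7), g)$report@keep),
        c(FALSE, TRUE))
    expect_identical(unname(filterGroupCoverage(mk(9, 7), g,
        mode = "either")$report@keep), c(TRUE, TRUE))
    expect_error(filterGroupCoverage(mk(6, 8), rep("a", 21)),
        "exactly two groups")
})

test_that("zero-SD filter removes exactly the constant features", {
    b <- mkBlock(cbind(c(7, 7, 7), c(7, 7, 8)))
    res <- filterZeroSD(b)
    expect_identical(featureIds(res$block), "f002")
    # empty block is vacuously fine
    e <- filterZeroSD(mkBlock(matrix(numeric(0), 3, 0)))
    expect_identical(e$report@nBefore, 0L)
    expect_identical(ncol(blockValues(e$block)), 0L)
})

test_that("robust-CV filter matches hand-computed values", {
    mkMeth <- function(...) {
        cols <- list(...)
        mkBlock(do.call(cbind, cols), assay = "methylome")
    }
    # median 0.2, median |x - med| = 0.1, RCV = 0.5: removed at threshold 1
    b <- mkMeth(c(0.1, 0.2, 0.9))
    expect_false(any(filterRCV(b)$report@keep))
    # brute-force checks of listed vectors, all below 1
    for (x in list(c(0.01, 0.5, 0.99), c(0.01, 0.4, 0.99),
        c(0.01, 0.2, 0.99))) {
        med <- median(x)
        rcv <- median(abs(x - med)) / med
        expect_lt(rcv, 1)
        expect_false(any(filterRCV(mkMeth(x))$report@keep))
    }
    # constant feature removed (zero SD) even though RCV is 0/positive
    expect_false(any(filterRCV(mkMeth(c(0.4, 0.4, 0.4)))$report@keep))
    # high-variability low-median feature retained; this one sits exactly
    # at RCV = 1 (median 0.2, median |x - med| = 0.2), so it also pins the
    # >= threshold convention
    expect_true(all(filterRCV(mkMeth(c(0, 0, 0.2, 0.9, 0.95)))$report@keep))
    # median 0 is excluded with a note, not an error
    res <- filterRCV(mkMeth(c(0, 0, 0.9)))
    expect_false(any(res$report@keep))
    expect_match(res$report@notes, "median 0")
    expect_error(filterRCV(mkBlock(matrix(1:4, 2, 2))), "methylome")
})

test_that("TMM factors match a step-by-step trimmed-mean oracle", {
    # symmetry: identical samples get unit factors
    m <- matrix(rpois(40, 50), 2, 20, byrow = TRUE)
    m[2, ] <- m[1, ]
    bi <- mkBlock(m)
    expect_equal(unname(tmmNormalize(bi)$factors), c(1, 1))
    # scale equivariance: doubling a sample leaves CPM values equal
    m2 <- rbind(m[1, ], 2 * m[1, ])
    b2 <- mkBlock(m2)
    n2 <- tmmNormalize(b2)
    expect_equal(blockValues(n2$block)[1, ], blockValues(n2$block)[2, ])
    # worked random matrices against the independent oracle
    for (seed in 1:4) {
        set.seed(seed)
        counts <- matrix(rnbinom(5 * 300, mu = exp(rnorm(300, 3, 1)),
            size = 3), nrow = 5, byrow = TRUE)
        counts <- counts + matrix(rpois(5 * 300, 2), 5)
        b <- mkBlock(counts)
        got <- tmmNormalize(b)$factors
        expect_equal(unname(got), oracleTMM(counts), tolerance = 1e-6)
        # geometric mean exactly one
        expect_equal(exp(mean(log(got))), 1, tolerance = 1e-12)
        # invariant to a global rescaling of all samples
        expect_equal(unname(tmmNormalize(mkBlock(counts * 4))$factors),
            unname(got), tolerance = 1e-10)
    }
    expect_error(tmmNormalize(mkBlock(rbind(c(0, 0), c(1, 2)))),
        "all-zero")
})

test_that("filters are idempotent and never add features or touch samples", {
    set.seed(20)
    b <- rCountBlock(8, 60, seed = 20, lambda = 4)
    g <- rep(c("x", "y"), each = 4)
    ops <- list(
        function(z) filterMinTotalCount(z, 25),
        function(z) filterGroupCoverage(z, g),
        filterZeroSD)
    for (op in ops) {
        once <- op(b)
        twice <- op(once$block)
        expect_identical(blockValues(twice$block), blockValues(once$block))
        expect_lte(once$report@nAfter, once$report@nBefore)
        expect_identical(sampleIds(once$block), sampleIds(b))
        expect_true(all(twice$report@keep))
    }
    meth <- mkBlock(matrix(runif(8 * 40)^3, 8, 40), assay = "methylome")
    once <- filterRCV(meth)
    expect_identical(blockValues(filterRCV(once$block)$block),
        blockValues(once$block))
})

test_that("preprocessBlock dispatches the per-assay chain and keeps books", {
    co <- generateCohort(smallCohortConfig(seed = 31,
        nPerGroup = c(positive = 8L, control = 8L, progressive = 0L)))
    bin <- ifelse(co$metadata$group == "RRMS", "positive", "control")
    # methylome never passes through TMM: values are a subset of the input
    meth <- co$blocks$csf_cells_methylome
    ppm <- preprocessBlock(meth, bin)
    expect_named(ppm$reports, "rcv")
    expect_null(ppm$factors)
    expect_identical(blockValues(ppm$block),
        blockValues(meth)[, ppm$reports$rcv@keep, drop = FALSE])
    # smallseq chain: min-total then zero-SD then TMM; report chain
    # consistent with the final feature count and generator bookkeeping
    ss <- co$blocks$plasma_smallseq
    pps <- preprocessBlock(ss, bin)
    expect_identical(names(pps$reports),
        c("min_total_count", "zero_sd", "zero_sd_post_norm"))
    expect_identical(pps$reports$min_total_count@nAfter,
        as.integer(sum(colSums(blockValues(ss)) >= 100)))
    expect_identical(ncol(blockValues(pps$block)),
        pps$reports$zero_sd_post_norm@nAfter)
    expect_identical(pps$reports$min_total_count@nBefore,
        ncol(blockValues(ss)))
    # mintmap chain starts with group coverage
    pm <- preprocessBlock(co$blocks$csf_free_mintmap, bin)
    expect_identical(names(pm$reports)[1], "group_coverage")
    expect_error(preprocessBlock(co$blocks$csf_free_mintmap),
        "groupLabels")
})
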