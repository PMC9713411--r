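# Small in-code fixtures shared across test files.

mkBlock <- function(m, assay = "smallseq", source = "plasma",
    sid = NULL, fid = NULL) {
    m <- as.matrix(m)
    rownames(m) <- if (is.null(sid)) sprintf("S%02d", seq_len(nrow(m)))
        else sid
    colnames(m) <- if (is.null(fid)) sprintf("f%03d", seq_len(ncol(m)))
        else fid
    OmicsBlock(m, assay = assay, source = source)
}

rCountBlock <- function(n, p, seed = 1, assay = "smallseq",
    source = "plasma", lambda = 30) {
    set.seed(seed)
    mkBlock(matrix(rpois(n * p, lambda), n, p), assay, source)
}

# a cohort small enough for fast end-to-end runs
smallCohortConfig <- function(seed = 1, effectSize = 2,
    nPerGroup = c(positive = 10L, control = 10L, progressive = 4L), ...) {
    syntheticConfig(nPerGroup = nPerGroup,
        featuresPerBlock = c(pbmc_smallseq = 80L, plasma_smallseq = 60L,
            csf_cells_smallseq = 50L, csf_free_mintmap = 50L,
            csf_cells_methylome = 150L),
        effectSize = effectSize, seed = seed, ...)
}

# standardized random blocks for decomposition tests (positive values so
# they are valid count-assay blocks; the decomposition is scale-free)
rStdBlocks <- function(n, ps, seed = 1) {
    set.seed(seed)
    blocks <- list()
    for (k in seq_along(ps)) {
        nm <- paste0("b", k)
        blocks[[nm]] <- standardizeBlock(mkBlock(
            matrix(10 * runif(n * ps[k]), n, ps[k]),
            fid = sprintf("%s_f%02d", nm, seq_len(ps[k]))))
    }
    blocks
}
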