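#' Read / write a block as tab-separated text
#'
#' Matrix layout: header row with `sample_id` followed by the feature ids;
#' one row per sample, first column the sample id, numeric body. Values
#' are written with 17 significant digits so a write/read round trip
#' reproduces them exactly.
#'
#' @param path file path.
#' @param assay,source block identity attached on read (see
#'   [OmicsBlock()]).
#' @param block an [OmicsBlock-class] to write.
#' @return `readBlockTSV` returns an [OmicsBlock-class]; `writeBlockTSV`
#'   returns `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' m <- matrix(rpois(6, 9), 2, 3,
#'     dimnames = list(c("a", "b"), c("f1", "f2", "f3")))
#' writeBlockTSV(OmicsBlock(m, "smallseq", "plasma"), f)
#' readBlockTSV(f, "smallseq", "plasma")
#' @export
readBlockTSV <- function(path, assay, source) {
    df <- utils::read.delim(path, check.names = FALSE,
        stringsAsFactors = FALSE, colClasses = "character")
    if (!ncol(df)) stop("empty file: ", path)
    sid <- df[[1]]
    if (anyDuplicated(sid))
        stop("duplicate sample id(s): ",
            paste(unique(sid[duplicated(sid)]), collapse = ", "))
    fid <- colnames(df)[-1]
    if (anyDuplicated(fid))
        stop("duplicate feature id(s): ",
            paste(unique(fid[duplicated(fid)]), collapse = ", "))
    if (length(fid)) {
        body <- as.matrix(df[, -1, drop = FALSE])
        suppressWarnings(num <- matrix(as.numeric(body), nrow(body)))
        if (anyNA(num) && !anyNA(body))
            stop("non-numeric cell(s) in ", path)
        m <- num
    } else {
        m <- matrix(numeric(0), nrow = length(sid), ncol = 0)
    }
    dimnames(m) <- list(sid, fid)
    OmicsBlock(m, assay = assay, source = source)
}

#' @rdname readBlockTSV
#' @export
writeBlockTSV <- function(block, path) {
    stopifnot(is(block, "OmicsBlock"))
    v <- block@values
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste(c("sample_id", colnames(v)), collapse = "\t"), con)
    for (i in seq_len(nrow(v)))
        writeLines(paste(c(rownames(v)[i], sprintf("%.17g", v[i, ])),
            collapse = "\t"), con)
    invisible(path)
}
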