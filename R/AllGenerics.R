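#' Accessors for mbcoin classes
#'
#' Small accessor generics so downstream code never touches slots directly.
#'
#' @param x an [OmicsBlock-class], [StandardizedBlock-class],
#'   [MCIAModel-class], [ProjectedScores-class] or [ROCResult-class] object,
#'   as applicable.
#' @return `blockValues` the numeric matrix; `sampleIds`/`featureIds`
#'   character vectors; `assayType`/`sourceLabel` character(1);
#'   `globalScores` the n x K score matrix; `featureLoadings` the p x K raw
#'   loading matrix; `blockLoadings` / `partialScores` named lists;
#'   `eigenvalues` numeric(K); `nComponents` integer(1); `aucValue`
#'   numeric(1); `rocPoints` a data.frame.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("blockValues", function(x) standardGeneric("blockValues"))
#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @rdname accessors
#' @export
setGeneric("featureIds", function(x) standardGeneric("featureIds"))
#' @rdname accessors
#' @export
setGeneric("assayType", function(x) standardGeneric("assayType"))
#' @rdname accessors
#' @export
setGeneric("sourceLabel", function(x) standardGeneric("sourceLabel"))
#' @rdname accessors
#' @export
setGeneric("globalScores", function(x) standardGeneric("globalScores"))
#' @rdname accessors
#' @export
setGeneric("featureLoadings", function(x) standardGeneric("featureLoadings"))
#' @rdname accessors
#' @export
setGeneric("blockLoadings", function(x) standardGeneric("blockLoadings"))
#' @rdname accessors
#' @export
setGeneric("partialScores", function(x) standardGeneric("partialScores"))
#' @rdname accessors
#' @export
setGeneric("eigenvalues", function(x) standardGeneric("eigenvalues"))
#' @rdname accessors
#' @export
setGeneric("nComponents", function(x) standardGeneric("nComponents"))
#' @rdname accessors
#' @export
setGeneric("aucValue", function(x) standardGeneric("aucValue"))
#' @rdname accessors
#' @export
setGeneric("rocPoints", function(x) standardGeneric("rocPoints"))

#' @rdname accessors
setMethod("blockValues", "OmicsBlock", function(x) x@values)
#' @rdname accessors
setMethod("blockValues", "StandardizedBlock", function(x) x@values)
#' @rdname accessors
setMethod("sampleIds", "OmicsBlock", function(x) rownames(x@values))
#' @rdname accessors
setMethod("sampleIds", "StandardizedBlock", function(x) rownames(x@values))
#' @rdname accessors
setMethod("sampleIds", "MCIAModel", function(x) x@sampleIds)
#' @rdname accessors
setMethod("sampleIds", "ProjectedScores", function(x) x@sampleIds)
#' @rdname accessors
setMethod("featureIds", "OmicsBlock", function(x) colnames(x@values))
#' @rdname accessors
setMethod("featureIds", "StandardizedBlock", function(x) colnames(x@values))
#' @rdname accessors
setMethod("featureIds", "MCIAModel", function(x) x@featureIds)
#' @rdname accessors
setMethod("assayType", "OmicsBlock", function(x) x@assay)
#' @rdname accessors
setMethod("assayType", "StandardizedBlock", function(x) x@assay)
#' @rdname accessors
setMethod("sourceLabel", "OmicsBlock", function(x) x@source)
#' @rdname accessors
setMethod("sourceLabel", "StandardizedBlock", function(x) x@source)
#' @rdname accessors
setMethod("globalScores", "MCIAModel", function(x) x@globalScores)
#' @rdname accessors
setMethod("globalScores", "ProjectedScores", function(x) x@scores)
#' @rdname accessors
setMethod("featureLoadings", "MCIAModel", function(x) x@loadings)
#' @rdname accessors
setMethod("blockLoadings", "MCIAModel", function(x) x@blockLoadings)
#' @rdname accessors
setMethod("partialScores", "MCIAModel", function(x) x@partialScores)
#' @rdname accessors
setMethod("eigenvalues", "MCIAModel", function(x) x@eigenvalues)
#' @rdname accessors
setMethod("nComponents", "MCIAModel", function(x) ncol(x@globalScores))
#' @rdname accessors
setMethod("aucValue", "ROCResult", function(x) x@auc)
#' @rdname accessors
setMethod("rocPoints", "ROCResult", function(x) x@points)

#' @rdname accessors
#' @export
setMethod("dim", "OmicsBlock", function(x) dim(x@values))
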