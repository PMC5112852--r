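#' @include AllClasses.R
NULL

#' Accessors for GSReduce classes
#'
#' Small accessor generics so user code never touches slots directly.
#'
#' @param x an object of the documented class
#' @param ... further arguments for methods
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))
#' @rdname accessors
#' @export
setGeneric("sampleLabels", function(x) standardGeneric("sampleLabels"))
#' @rdname accessors
#' @export
setGeneric("labelSigns", function(x) standardGeneric("labelSigns"))
#' @rdname accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))
#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @rdname accessors
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))
#' @rdname accessors
#' @export
setGeneric("setIds", function(x) standardGeneric("setIds"))
#' @rdname accessors
#' @export
setGeneric("setSizes", function(x) standardGeneric("setSizes"))
#' @rdname accessors
#' @export
setGeneric("setDescriptions", function(x) standardGeneric("setDescriptions"))
#' @rdname accessors
#' @export
setGeneric("geneStatistics", function(x) standardGeneric("geneStatistics"))
#' @rdname accessors
#' @export
setGeneric("setStatistics", function(x) standardGeneric("setStatistics"))
#' @rdname accessors
#' @export
setGeneric("fudgeFactor", function(x) standardGeneric("fudgeFactor"))
#' @rdname accessors
#' @export
setGeneric("coreSubset", function(x) standardGeneric("coreSubset"))
#' @rdname accessors
#' @export
setGeneric("residualGenes", function(x) standardGeneric("residualGenes"))
#' @rdname accessors
#' @export
setGeneric("selectedGenes", function(x, ...) standardGeneric("selectedGenes"))
#' @rdname accessors
#' @export
setGeneric("beliefs", function(x) standardGeneric("beliefs"))
#' @rdname accessors
#' @export
setGeneric("truthIndices", function(x) standardGeneric("truthIndices"))
#' @rdname accessors
#' @export
setGeneric("runManifest", function(x) standardGeneric("runManifest"))

#' Predict class beliefs for new samples
#'
#' @param model a fitted classifier (\linkS4class{ScadSvmModel} or
#'   \linkS4class{PlattSvmModel})
#' @param ds an \linkS4class{ExpressionDataset} carrying every gene the model
#'   uses (missing genes are an error; there is no silent imputation)
#' @return a \linkS4class{PredictionSet} with classes
#'   \code{c("control", "diseased")}
#' @export
setGeneric("predictBeliefs", function(model, ds) standardGeneric("predictBeliefs"))

#' Decision values of a linear model on a dataset
#'
#' @param model a fitted classifier
#' @param ds an \linkS4class{ExpressionDataset}
#' @return named numeric vector of per-sample decision values f(x)
#' @export
setGeneric("decisionValues", function(model, ds) standardGeneric("decisionValues"))
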