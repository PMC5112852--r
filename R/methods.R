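#' @include AllGenerics.R
NULL

## ---- ExpressionDataset ----

#' @rdname accessors
#' @aliases exprValues,ExpressionDataset-method
setMethod("exprValues", "ExpressionDataset", function(x)
    SummarizedExperiment::assay(x, "exprs"))

#' @rdname accessors
#' @aliases sampleLabels,ExpressionDataset-method
setMethod("sampleLabels", "ExpressionDataset", function(x)
    colData(x)$label)

#' @rdname accessors
#' @aliases labelSigns,ExpressionDataset-method
setMethod("labelSigns", "ExpressionDataset", function(x) {
    lab <- colData(x)$label
    setNames(ifelse(lab == "diseased", 1, -1), colnames(x))
})

#' @rdname accessors
#' @aliases geneIds,ExpressionDataset-method
setMethod("geneIds", "ExpressionDataset", function(x) rownames(x))

#' @rdname accessors
#' @aliases sampleIds,ExpressionDataset-method
setMethod("sampleIds", "ExpressionDataset", function(x) colnames(x))

setMethod("show", "ExpressionDataset", function(object) {
    lab <- table(colData(object)$label)
    cat("ExpressionDataset with", nrow(object), "genes x",
        ncol(object), "samples\n")
    cat("  labels:", lab[["diseased"]], "diseased,",
        lab[["control"]], "control\n")
})

## ---- GeneSetCollection ----

#' @rdname accessors
#' @aliases geneSets,GeneSetCollection-method
setMethod("geneSets", "GeneSetCollection", function(x) x@sets)

#' @rdname accessors
#' @aliases setIds,GeneSetCollection-method
setMethod("setIds", "GeneSetCollection", function(x) names(x@sets))

#' @rdname accessors
#' @aliases setSizes,GeneSetCollection-method
setMethod("setSizes", "GeneSetCollection", function(x)
    vapply(x@sets, length, 0L))

#' @rdname accessors
#' @aliases setDescriptions,GeneSetCollection-method
setMethod("setDescriptions", "GeneSetCollection", function(x) x@descriptions)

#' @describeIn GeneSetCollection-class number of gene sets
#' @param x a GeneSetCollection
#' @export
setMethod("length", "GeneSetCollection", function(x) length(x@sets))

#' @describeIn GeneSetCollection-class extract one set's member genes by id
#' @param i set id or index
#' @export
setMethod("[[", "GeneSetCollection", function(x, i) x@sets[[i]])

setMethod("show", "GeneSetCollection", function(object) {
    sz <- setSizes(object)
    cat("GeneSetCollection with", length(object), "sets")
    if (length(object))
        cat(" (sizes ", min(sz), "-", max(sz), ")", sep = "")
    cat("\n")
    if (nzchar(object@source)) cat("  source:", object@source, "\n")
})

## ---- SamGsResult ----

#' @rdname accessors
#' @aliases geneStatistics,SamGsResult-method
setMethod("geneStatistics", "SamGsResult", function(x) x@geneStats)

#' @rdname accessors
#' @aliases setStatistics,SamGsResult-method
setMethod("setStatistics", "SamGsResult", function(x) x@setStats)

#' @rdname accessors
#' @aliases fudgeFactor,SamGsResult-method
setMethod("fudgeFactor", "SamGsResult", function(x) x@s0)

setMethod("show", "SamGsResult", function(object) {
    cat("SamGsResult:", nrow(object@setStats), "gene sets,",
        nrow(object@geneStats), "genes\n")
    cat("  permutations:", object@B,
        if (object@exhaustive) "(exhaustive)" else "(random)", "\n")
    cat(sprintf("  s0 = %.4g\n", object@s0))
})

## ---- ReductionTrace ----

#' @rdname accessors
#' @aliases coreSubset,ReductionTrace-method
setMethod("coreSubset", "ReductionTrace", function(x)
    x@orderedGenes[seq_len(x@chosenK)])

#' @rdname accessors
#' @aliases residualGenes,ReductionTrace-method
setMethod("residualGenes", "ReductionTrace", function(x)
    if (x@chosenK >= length(x@orderedGenes)) character(0)
    else x@orderedGenes[(x@chosenK + 1L):length(x@orderedGenes)])

setMethod("show", "ReductionTrace", function(object) {
    cat("ReductionTrace for set '", object@setId, "': core ",
        object@chosenK, "/", length(object@orderedGenes),
        " genes at cutoff ", object@cutoff, "\n", sep = "")
})

## ---- ScadSvmModel ----

#' @rdname accessors
#' @aliases selectedGenes,ScadSvmModel-method
#' @param tol weights with |w| at or below \code{tol} count as zero
setMethod("selectedGenes", "ScadSvmModel", function(x, tol = 0) {
    names(x@w)[abs(x@w) > tol]
})

#' @describeIn ScadSvmModel-class standardized-scale weights and intercept
#' @param object a ScadSvmModel
#' @export
setMethod("coef", "ScadSvmModel", function(object)
    c(`(Intercept)` = object@b, object@w))

setMethod("show", "ScadSvmModel", function(object) {
    cat("ScadSvmModel: ", sum(object@w != 0), "/", length(object@w),
        " genes with nonzero weight\n", sep = "")
    cat(sprintf("  lambda = %.4g, alpha = %.2f, %s after %d iterations\n",
        object@lambda, object@alpha,
        if (object@converged) "converged" else "NOT converged",
        object@iterations))
})

## ---- PredictionSet ----

#' @rdname accessors
#' @aliases beliefs,PredictionSet-method
setMethod("beliefs", "PredictionSet", function(x) x@beliefs)

#' @rdname accessors
#' @aliases truthIndices,PredictionSet-method
setMethod("truthIndices", "PredictionSet", function(x) x@truth)

setMethod("show", "PredictionSet", function(object) {
    cat("PredictionSet:", nrow(object@beliefs), "samples,",
        ncol(object@beliefs), "classes (",
        paste(object@classNames, collapse = ", "), ")\n")
})

## ---- PipelineResult ----

#' @rdname accessors
#' @aliases selectedGenes,PipelineResult-method
setMethod("selectedGenes", "PipelineResult", function(x) x@selectedGenes)

#' @rdname accessors
#' @aliases runManifest,PipelineResult-method
setMethod("runManifest", "PipelineResult", function(x) x@manifest)

setMethod("show", "PipelineResult", function(object) {
    cat("PipelineResult (", object@method, "): ",
        length(object@selectedGenes), " genes selected from ",
        length(object@candidateGenes), " candidates in ",
        length(object@significantSets), " significant sets\n", sep = "")
})
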