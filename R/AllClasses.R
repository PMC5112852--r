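#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame metadata
NULL

#' ExpressionDataset: a labelled two-class expression matrix
#'
#' Thin extension of \linkS4class{SummarizedExperiment} holding a genes x
#' samples matrix of log2-scale expression values together with a binary
#' phenotype label per sample (\code{"diseased"} vs \code{"control"}).
#' The single assay is named \code{"exprs"}; labels live in
#' \code{colData(x)$label}.
#'
#' @slot .. see \linkS4class{SummarizedExperiment}
#' @export
setClass("ExpressionDataset", contains = "SummarizedExperiment")

.validExpressionDataset <- function(object) {
    msg <- NULL
    if (!"exprs" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'exprs' is required")
    else {
        m <- SummarizedExperiment::assay(object, "exprs")
        if (!is.numeric(m))
            msg <- c(msg, "expression values must be numeric")
        if (anyNA(m))
            msg <- c(msg, "expression values contain missing values; imputation is not supported")
    }
    if (!"label" %in% colnames(colData(object)))
        msg <- c(msg, "colData column 'label' is required")
    else {
        lab <- colData(object)$label
        if (!is.factor(lab) || !identical(levels(lab), c("control", "diseased")))
            msg <- c(msg, "labels must be a factor with levels 'control', 'diseased'")
        if (anyNA(lab))
            msg <- c(msg, "every sample must carry exactly one label")
    }
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "gene ids must be present and unique")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "sample ids must be present and unique")
    if (is.null(msg)) TRUE else msg
}
setValidity("ExpressionDataset", .validExpressionDataset)

#' Construct an ExpressionDataset
#'
#' @param values numeric matrix, genes in rows, samples in columns, with
#'   unique row and column names; log2-scale expression, no missing values.
#' @param labels per-sample class labels, parallel to the columns of
#'   \code{values}. Accepted encodings: a factor/character with values
#'   \code{"control"}/\code{"diseased"}, or a numeric vector in \{-1, +1\}
#'   with +1 meaning diseased.
#' @return an \linkS4class{ExpressionDataset}
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' ds <- ExpressionDataset(m, c(1, 1, -1, -1))
#' @export
ExpressionDataset <- function(values, labels) {
    values <- as.matrix(values)
    if (length(labels) != ncol(values))
        stop("'labels' must have one entry per sample (column)")
    lab <- .coerceLabels(labels)
    se <- SummarizedExperiment(
        assays = list(exprs = values),
        colData = DataFrame(label = lab, row.names = colnames(values)))
    new("ExpressionDataset", se)
}

.coerceLabels <- function(labels) {
    if (is.numeric(labels)) {
        if (!all(labels %in% c(-1, 1)))
            stop("numeric labels must be coded -1 (control) / +1 (diseased)")
        labels <- ifelse(labels > 0, "diseased", "control")
    }
    labels <- as.character(labels)
    bad <- setdiff(unique(labels), c("control", "diseased"))
    if (length(bad))
        stop("unrecognized class label(s): ", paste(bad, collapse = ", "))
    factor(labels, levels = c("control", "diseased"))
}

#' GeneSetCollection: named gene sets
#'
#' A named collection of gene sets (pathways): each set is an ordered,
#' duplicate-free character vector of gene ids. A gene may belong to any
#' number of sets (overlap is allowed and is scientifically meaningful).
#'
#' @slot sets named list of character vectors of gene ids
#' @slot descriptions named character vector, parallel to \code{sets}
#' @slot source free-text provenance of the collection
#' @export
setClass("GeneSetCollection",
    representation(sets = "list", descriptions = "character",
                   source = "character"))

.validGeneSetCollection <- function(object) {
    msg <- NULL
    nm <- names(object@sets)
    if (length(object@sets) && (is.null(nm) || any(nm == "")))
        msg <- c(msg, "every gene set must be named")
    if (anyDuplicated(nm))
        msg <- c(msg, "duplicate gene-set names are not allowed")
    dup <- vapply(object@sets, anyDuplicated, 0L) > 0L
    if (any(dup))
        msg <- c(msg, paste0("duplicate member genes within set(s): ",
                             paste(nm[dup], collapse = ", ")))
    if (length(object@descriptions) != length(object@sets))
        msg <- c(msg, "one description per set is required")
    if (is.null(msg)) TRUE else msg
}
setValidity("GeneSetCollection", .validGeneSetCollection)

#' Construct a GeneSetCollection
#'
#' @param sets named list of character vectors of member gene ids
#' @param descriptions optional named character vector of set descriptions
#' @param source free-text provenance string
#' @return a \linkS4class{GeneSetCollection}
#' @examples
#' GeneSetCollection(list(S1 = c("A", "B"), S2 = c("B", "C")))
#' @export
GeneSetCollection <- function(sets, descriptions = NULL, source = "") {
    sets <- lapply(sets, as.character)
    if (is.null(descriptions))
        descriptions <- setNames(rep("", length(sets)), names(sets))
    new("GeneSetCollection", sets = sets,
        descriptions = descriptions[names(sets)], source = source)
}

#' SamGsResult: per-gene SAM statistics and per-set SAM-GS statistics
#'
#' Holds the observed per-gene moderated statistics, the per-set sum-of-squares
#' statistics, permutation p-values for both, and the retained permutation
#' draws (a permutations x genes matrix of per-gene statistics) so that the
#' reduction step can re-score arbitrary residual subsets on the very same
#' null draws.
#'
#' @slot geneStats data.frame with columns gene, d, meanDiseased, meanControl,
#'   s, geneP
#' @slot s0 the fudge constant added to every pooled SD
#' @slot setStats data.frame with columns setId, size, samgs, setP
#' @slot permD numeric matrix (permutations x genes) of per-gene statistics
#'   under label permutation
#' @slot B integer, number of permutations (for exhaustive mode, the number of
#'   distinct label assignments)
#' @slot seed integer seed used to draw permutations (NA in exhaustive mode)
#' @slot exhaustive logical, TRUE when all label assignments were enumerated
#' @slot s0Recomputed logical, TRUE when s0 was re-estimated inside each
#'   permutation
#' @slot s0Method list recording how s0 was chosen
#' @export
setClass("SamGsResult",
    representation(geneStats = "data.frame", s0 = "numeric",
                   setStats = "data.frame", permD = "matrix",
                   B = "integer", seed = "integer", exhaustive = "logical",
                   s0Recomputed = "logical", s0Method = "list"))

#' ReductionTrace: the peeling history of one gene set
#'
#' Records the significance-ordered member genes of one set, the sequence of
#' residual-subset permutation p-values c_k obtained as the top k genes are
#' peeled off, and the chosen core-subset size.
#'
#' @slot setId the gene set
#' @slot orderedGenes members sorted by ascending gene-level permutation
#'   p-value (ties: descending |d|, then gene id)
#' @slot ck residual p-values c_k for k = 1 .. (set size - 1)
#' @slot chosenK the smallest k with c_k > cutoff, or the set size when no
#'   c_k exceeds the cutoff (exhaustion: the whole set is the core)
#' @slot cutoff the threshold applied to c_k
#' @export
setClass("ReductionTrace",
    representation(setId = "character", orderedGenes = "character",
                   ck = "numeric", chosenK = "integer", cutoff = "numeric"))

#' ScadSvmModel: a SCAD-penalized linear support vector machine
#'
#' A sparse linear decision rule f(x) = sum_i w_i x_i + b fitted by
#' minimizing hinge-type loss plus a smoothly clipped absolute deviation
#' (SCAD) penalty on each coefficient. Features are standardized internally;
#' the standardization constants are stored so predictions are consistent.
#'
#' @slot w named numeric weight vector (on the standardized scale)
#' @slot b intercept
#' @slot lambda SCAD penalty scale
#' @slot alpha SCAD shape parameter (> 2; default 3.7)
#' @slot center,scale per-gene standardization constants
#' @slot platt length-2 numeric (A, B) of the sigmoid
#'   P(class = diseased | f) = 1 / (1 + exp(A f + B)) fitted on training
#'   decision values
#' @slot converged logical; FALSE when the outer loop hit its iteration cap
#' @slot iterations outer iterations used
#' @slot objective per-iteration objective values (non-increasing)
#' @slot cvTable per-lambda cross-validation table (possibly empty)
#' @slot huberDelta smoothing scale of the huberized hinge loss
#' @export
setClass("ScadSvmModel",
    representation(w = "numeric", b = "numeric", lambda = "numeric",
                   alpha = "numeric", center = "numeric", scale = "numeric",
                   platt = "numeric", converged = "logical",
                   iterations = "integer", objective = "numeric",
                   cvTable = "data.frame", huberDelta = "numeric"))

#' PlattSvmModel: a plain linear SVM with a Platt belief layer
#'
#' Wraps an \code{e1071} linear support vector machine restricted to a fixed
#' gene panel, plus a Platt sigmoid fitted on the training decision values so
#' the model emits class beliefs.
#'
#' @slot svmFit the underlying \code{e1071::svm} fit
#' @slot genes the gene panel (feature order)
#' @slot platt length-2 numeric (A, B), as in \linkS4class{ScadSvmModel}
#' @export
setClass("PlattSvmModel",
    representation(svmFit = "ANY", genes = "character", platt = "numeric"))

#' PredictionSet: per-sample class beliefs plus truth
#'
#' An n x K matrix of class beliefs (rows sum to 1) together with the true
#' class index of each sample; the common currency of the evaluation metrics.
#'
#' @slot beliefs numeric matrix, samples x classes, entries in [0, 1]
#' @slot truth integer vector of true class indices (1-based columns of
#'   \code{beliefs})
#' @slot classNames character vector of class labels (column order)
#' @export
setClass("PredictionSet",
    representation(beliefs = "matrix", truth = "integer",
                   classNames = "character"))

.validPredictionSet <- function(object) {
    msg <- NULL
    b <- object@beliefs
    if (nrow(b) == 0L)
        msg <- c(msg, "at least one sample is required")
    if (any(b < 0) || any(b > 1))
        msg <- c(msg, "beliefs must lie in [0, 1]")
    if (nrow(b) && any(abs(rowSums(b) - 1) > 1e-9))
        msg <- c(msg, "belief rows must sum to 1 (tolerance 1e-9)")
    if (length(object@truth) != nrow(b))
        msg <- c(msg, "one true class per sample is required")
    if (length(object@truth) &&
        (any(object@truth < 1L) || any(object@truth > ncol(b))))
        msg <- c(msg, "truth indices must address belief columns")
    if (length(object@classNames) != ncol(b))
        msg <- c(msg, "one class name per belief column is required")
    if (is.null(msg)) TRUE else msg
}
setValidity("PredictionSet", .validPredictionSet)

#' Construct a PredictionSet
#'
#' @param beliefs samples x classes matrix of class beliefs; rows must sum
#'   to 1
#' @param truth true classes: integer column indices, or a character/factor
#'   vector matched against \code{classNames}
#' @param classNames class labels; defaults to the column names of
#'   \code{beliefs}
#' @return a \linkS4class{PredictionSet}
#' @examples
#' PredictionSet(rbind(c(.8, .2), c(.4, .6)), c(1L, 2L), c("control", "diseased"))
#' @export
PredictionSet <- function(beliefs, truth, classNames = colnames(beliefs)) {
    beliefs <- as.matrix(beliefs)
    if (is.null(classNames))
        classNames <- paste0("class", seq_len(ncol(beliefs)))
    if (is.character(truth) || is.factor(truth)) {
        idx <- match(as.character(truth), classNames)
        if (anyNA(idx))
            stop("truth labels not found among class names")
        truth <- idx
    }
    new("PredictionSet", beliefs = beliefs, truth = as.integer(truth),
        classNames = as.character(classNames))
}

#' PipelineResult: outcome of a pathway-guided selection pipeline
#'
#' Shared container for the end-to-end gene-set-reduction pipeline and the
#' modified (SCAD-SVM) pipeline: the significant sets, the candidate gene
#' pool, the final selection, the fitted model and a reproducibility
#' manifest.
#'
#' @slot method "samgsr" or "msamgsr"
#' @slot significantSets set ids with permutation p at or below the threshold
#' @slot candidateGenes deduplicated union of the significant sets' members
#' @slot selectedGenes the final gene panel
#' @slot model the fitted classifier (\linkS4class{PlattSvmModel} or
#'   \linkS4class{ScadSvmModel}); NULL when the selection is empty
#' @slot traces list of \linkS4class{ReductionTrace} (empty for msamgsr)
#' @slot cutoffTable the per-cutoff tuning table (empty for msamgsr)
#' @slot manifest list of all resolved parameters, seeds and version info
#' @export
setClass("PipelineResult",
    representation(method = "character", significantSets = "character",
                   candidateGenes = "character", selectedGenes = "character",
                   model = "ANY", traces = "list", cutoffTable = "data.frame",
                   manifest = "list"))
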