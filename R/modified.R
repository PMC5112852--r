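#' @include scadsvm.R reduction.R
NULL

#' Modified gene-set-reduction pipeline: SCAD-SVM inside significant sets
#'
#' Scores all gene sets by permutation, pools the deduplicated union of the
#' members of the significant sets, and hands that candidate pool to the
#' SCAD-penalized linear SVM, which selects genes and fits the classifier
#' in one step (lambda tuned by stratified cross-validation). Whether a
#' gene survives therefore hinges solely on its contribution to the optimal
#' hyperplane, not on the magnitude of its individual gene statistic or on
#' how many sets contain it: the candidate pool keeps one feature per gene
#' however many significant sets it belongs to. A consequence worth
#' stating: a true marker contained in no gene set can never be selected.
#'
#' @inheritParams samgsrSelect
#' @param alpha SCAD shape parameter (default 3.7)
#' @param lambdaGrid penalty grid for \code{\link{tuneLambda}} (default
#'   \code{2^(-8:14)})
#' @param folds cross-validation folds (default 5)
#' @param ... further arguments for \code{\link{scadSvmFit}}
#' @return a \linkS4class{PipelineResult} with \code{method = "msamgsr"};
#'   with zero significant sets the selection is empty and there is no
#'   model
#' @export
msamgsrSelect <- function(ds, coll, B = 500L, seed = 1L,
                          setPThreshold = 0.05, pAdjust = c("raw", "BH"),
                          minSetSize = 2L, alpha = 3.7,
                          lambdaGrid = 2^(-8:14), folds = 5L,
                          s0Method = c("quantile", "fixed"),
                          s0Quantile = 0.05, s0Fixed = NULL,
                          recomputeS0 = TRUE, ...) {
    pAdjust <- match.arg(pAdjust)
    s0Method <- match.arg(s0Method)
    coll <- restrictCollection(coll, ds, minSetSize)
    res <- samGsPermutation(ds, coll, B = B, seed = seed,
                            s0Method = s0Method, s0Quantile = s0Quantile,
                            s0Fixed = s0Fixed, recomputeS0 = recomputeS0)
    sig <- significantSets(res, threshold = setPThreshold, method = pAdjust)
    manifest <- list(method = "msamgsr", B = res@B, seed = seed,
                     s0 = res@s0, s0Method = s0Method,
                     setPThreshold = setPThreshold, pAdjust = pAdjust,
                     minSetSize = minSetSize, alpha = alpha,
                     lambdaGrid = lambdaGrid, folds = folds,
                     recomputeS0 = recomputeS0,
                     version = as.character(utils::packageVersion("GSReduce")))
    if (!length(sig)) {
        return(new("PipelineResult", method = "msamgsr",
                   significantSets = character(0),
                   candidateGenes = character(0),
                   selectedGenes = character(0), model = NULL,
                   traces = list(), cutoffTable = data.frame(),
                   manifest = manifest))
    }
    candidates <- unique(unlist(geneSets(coll)[sig], use.names = FALSE))
    ## fold shuffles and lambda tuning get their own child seed so that the
    ## permutation stream and the CV stream never interleave
    cvSeed <- deriveSeed(seed, "cv")
    tuned <- tuneLambda(ds, genes = candidates, alpha = alpha,
                        lambdaGrid = lambdaGrid, folds = folds,
                        seed = cvSeed, ...)
    model <- scadSvmFit(ds, genes = candidates, lambda = tuned$lambda,
                        alpha = alpha, ...)
    model@cvTable <- tuned$table
    manifest$lambda <- tuned$lambda
    new("PipelineResult", method = "msamgsr", significantSets = sig,
        candidateGenes = candidates,
        selectedGenes = selectedGenes(model), model = model,
        traces = list(), cutoffTable = data.frame(), manifest = manifest)
}

#' Train both pipelines and evaluate them on train and test data
#'
#' Runs the reduction pipeline (\code{\link{samgsrSelect}}) and the
#' modified pipeline (\code{\link{msamgsrSelect}}) on the training set,
#' then scores each fitted model on the training and the test set with all
#' four metrics. Test data play no role in selection or tuning.
#'
#' @param dsTrain,dsTest \linkS4class{ExpressionDataset}s sharing a gene
#'   universe
#' @param coll a \linkS4class{GeneSetCollection}
#' @param ... arguments forwarded to both pipelines (B, seed, thresholds,
#'   grids, ...); arguments unknown to one pipeline are dropped for it
#' @return list with \code{samgsr}, \code{msamgsr} (the two
#'   \linkS4class{PipelineResult}s) and \code{table}, a data.frame with one
#'   row per (method, split): method, split, nSelected, errorPct, gbs, bcm,
#'   aupr
#' @export
compareMethods <- function(dsTrain, dsTest, coll, ...) {
    miss <- setdiff(geneIds(dsTrain), geneIds(dsTest))
    if (length(miss))
        stop("train and test must share the gene universe; missing in ",
             "test: ", paste(utils::head(miss, 5), collapse = ", "),
             if (length(miss) > 5) " ...")
    args <- list(...)
    keepArgs <- function(fun) args[names(args) %in% names(formals(fun))]
    fitS <- do.call(samgsrSelect,
                    c(list(ds = dsTrain, coll = coll), keepArgs(samgsrSelect)))
    fitM <- do.call(msamgsrSelect,
                    c(list(ds = dsTrain, coll = coll), keepArgs(msamgsrSelect)))
    rows <- list()
    for (fit in list(fitS, fitM)) {
        for (split in c("train", "test")) {
            ds <- if (split == "train") dsTrain else dsTest
            if (is.null(fit@model)) {
                rows[[length(rows) + 1L]] <- data.frame(
                    method = fit@method, split = split, nSelected = 0L,
                    errorPct = NA_real_, gbs = NA_real_, bcm = NA_real_,
                    aupr = NA_real_)
                next
            }
            m <- evaluatePredictions(predictBeliefs(fit@model, ds))
            rows[[length(rows) + 1L]] <- data.frame(
                method = fit@method, split = split,
                nSelected = length(fit@selectedGenes),
                errorPct = 100 * m$error, gbs = m$gbs, bcm = m$bcm,
                aupr = m$aupr)
        }
    }
    list(samgsr = fitS, msamgsr = fitM, table = do.call(rbind, rows))
}
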