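#' @include samgs.R
NULL

## Significance ordering of a set's members: ascending gene-level
## permutation p, ties by descending |d|, then gene id.
.orderSetGenes <- function(res, members) {
    gs <- res@geneStats[members, ]
    members[order(gs$geneP, -abs(gs$d), gs$gene)]
}

## Permutation p-value of the set statistic of an arbitrary gene subset,
## evaluated on the retained permutation draws of `res`.
.subsetP <- function(res, members) {
    obs <- sum(res@geneStats[members, "d"]^2)
    perm <- rowSums(res@permD[, members, drop = FALSE]^2)
    cnt <- sum(perm >= obs)
    if (res@exhaustive) cnt / res@B else (1 + cnt) / (res@B + 1)
}

#' Reduce one gene set to its core subset
#'
#' Orders the set's members by ascending gene-level permutation p-value
#' (ties: descending |d|, then gene id) and peels them off one at a time.
#' After removing the top k genes, \code{c_k} is the permutation p-value of
#' the residual subset's set statistic, evaluated on the same stored
#' permutation draws used for the set itself. The core subset is the first
#' k genes at the smallest k where \code{c_k} exceeds \code{cutoff}; if no
#' \code{c_k} does, the whole set is the core (exhaustion rule). The
#' \code{c_k} sequence need not be monotone and the implementation does not
#' assume it is.
#'
#' @param res a \linkS4class{SamGsResult} (its retained permutations are
#'   reused, making the reduction deterministic)
#' @param coll the \linkS4class{GeneSetCollection} that was scored
#' @param setId the set to reduce (>= 2 genes)
#' @param cutoff residual-significance threshold in (0, 1)
#' @return a \linkS4class{ReductionTrace}
#' @export
reduceSet <- function(res, coll, setId, cutoff) {
    if (cutoff <= 0 || cutoff >= 1)
        stop("cutoff must lie strictly inside (0, 1)")
    members <- coll[[setId]]
    m <- length(members)
    if (m < 2L)
        stop("set '", setId, "' has fewer than 2 genes")
    ordered <- .orderSetGenes(res, members)
    ck <- vapply(seq_len(m - 1L), function(k)
        .subsetP(res, ordered[(k + 1L):m]), 0)
    above <- which(ck > cutoff)
    chosenK <- if (length(above)) above[1L] else m
    new("ReductionTrace", setId = setId, orderedGenes = ordered,
        ck = ck, chosenK = as.integer(chosenK), cutoff = cutoff)
}

## Fit the plain linear SVM used throughout: linear kernel, unit cost,
## features standardized on the training data, plus a Platt belief layer.
.fitPlattSvm <- function(ds, genes) {
    X <- t(exprValues(ds)[genes, , drop = FALSE])
    y <- factor(sampleLabels(ds), levels = c("control", "diseased"))
    scale <- apply(X, 2L, stats::sd) > 0  # constant features cannot be scaled
    fit <- e1071::svm(X, y, kernel = "linear", cost = 1, scale = scale,
                      type = "C-classification")
    model <- new("PlattSvmModel", svmFit = fit, genes = genes,
                 platt = c(A = 0, B = 0))
    f <- decisionValues(model, ds)
    model@platt <- .plattFit(f, labelSigns(ds))
    model
}

#' @rdname decisionValues
#' @aliases decisionValues,PlattSvmModel-method
setMethod("decisionValues", c("PlattSvmModel", "ExpressionDataset"),
    function(model, ds) {
        miss <- setdiff(model@genes, geneIds(ds))
        if (length(miss))
            stop("model gene(s) absent from data: ",
                 paste(miss, collapse = ", "))
        X <- t(exprValues(ds)[model@genes, , drop = FALSE])
        pred <- stats::predict(model@svmFit, X, decision.values = TRUE)
        dv <- attr(pred, "decision.values")
        ## e1071 orients the decision value toward the class named first in
        ## the column label; normalize so f > 0 means diseased
        first <- sub("/.*$", "", colnames(dv)[1L])
        f <- as.numeric(dv[, 1L]) * if (first == "diseased") 1 else -1
        setNames(f, sampleIds(ds))
    })

#' @rdname predictBeliefs
#' @aliases predictBeliefs,PlattSvmModel-method
setMethod("predictBeliefs", c("PlattSvmModel", "ExpressionDataset"),
    function(model, ds) {
        f <- decisionValues(model, ds)
        p <- .plattProb(f, model@platt)
        PredictionSet(cbind(control = 1 - p, diseased = p),
                      truth = as.character(sampleLabels(ds)),
                      classNames = c("control", "diseased"))
    })

## Platt scaling: fit P(diseased | f) = 1 / (1 + exp(A f + B)) on training
## decision values, with Platt's smoothed targets so separable data do not
## send the slope to infinity.
.plattFit <- function(f, ySigns) {
    pos <- ySigns > 0
    np <- sum(pos); nn <- sum(!pos)
    t <- ifelse(pos, (np + 1) / (np + 2), 1 / (nn + 2))
    ## stable negative log-likelihood; p = 1 / (1 + exp(z))
    nll <- function(par) {
        z <- par[1L] * f + par[2L]
        ## log(1 + e^z) computed stably
        lse <- pmax(z, 0) + log1p(exp(-abs(z)))
        sum(t * lse + (1 - t) * (lse - z))
    }
    init <- c(A = 0, B = log((nn + 1) / (np + 1)))
    fit <- stats::optim(init, nll, method = "BFGS",
                        control = list(maxit = 200, reltol = 1e-12))
    setNames(fit$par, c("A", "B"))
}

.plattProb <- function(f, platt) {
    z <- platt[["A"]] * f + platt[["B"]]
    1 / (1 + exp(z))
}

#' Tune the residual-significance cutoff by SVM training error
#'
#' For every cutoff on the grid, reduces each significant set, pools the
#' union of core-subset genes, fits the plain linear SVM on the training
#' data restricted to that union, and records the training
#' misclassification error and the panel size. The winning cutoff has the
#' minimal error; ties go to the smaller panel, then to the smaller cutoff.
#'
#' @param ds the training \linkS4class{ExpressionDataset}
#' @param res a \linkS4class{SamGsResult} on \code{ds}
#' @param coll the scored \linkS4class{GeneSetCollection}
#' @param sigSets character vector of significant set ids (non-empty)
#' @param grid cutoff grid in (0, 1); default 0.05 to 0.50 by 0.05
#' @return list with \code{cutoff} (the winner) and \code{table}
#'   (data.frame: cutoff, error, nGenes)
#' @export
tuneCutoff <- function(ds, res, coll, sigSets,
                       grid = seq(0.05, 0.50, by = 0.05)) {
    if (!length(sigSets))
        stop("no significant gene sets: nothing to reduce or tune")
    if (!length(grid) || any(grid <= 0) || any(grid >= 1))
        stop("cutoff grid values must lie strictly inside (0, 1)")
    rows <- lapply(grid, function(ct) {
        genes <- unique(unlist(lapply(sigSets, function(s)
            coreSubset(reduceSet(res, coll, s, ct))), use.names = FALSE))
        fit <- .fitPlattSvm(ds, genes)
        pr <- predictBeliefs(fit, ds)
        data.frame(cutoff = ct, error = errorRate(pr),
                   nGenes = length(genes))
    })
    tab <- do.call(rbind, rows)
    best <- tab[order(tab$error, tab$nGenes, tab$cutoff), ][1L, ]
    list(cutoff = best$cutoff, table = tab)
}

#' Gene-set reduction feature selection (end to end)
#'
#' The full reduction pipeline: score all sets by permutation, keep the
#' significant ones, tune the residual-significance cutoff on the training
#' error of a plain linear SVM, reduce every significant set at the winning
#' cutoff, pool the deduplicated union of the core subsets, and fit the
#' final linear SVM (with a Platt belief layer) on that panel. With zero
#' significant sets the result carries an empty selection and no model.
#'
#' @param ds training \linkS4class{ExpressionDataset}
#' @param coll a \linkS4class{GeneSetCollection} (restricted internally to
#'   the dataset's gene universe)
#' @param B,seed,s0Method,s0Quantile,s0Fixed,recomputeS0 passed to
#'   \code{\link{samGsPermutation}}
#' @param setPThreshold set-level significance threshold (raw permutation p)
#' @param pAdjust \code{"raw"} or \code{"BH"}; see
#'   \code{\link{significantSets}}
#' @param ckGrid cutoff grid for \code{\link{tuneCutoff}}
#' @param minSetSize smallest post-restriction set size kept
#' @return a \linkS4class{PipelineResult} with \code{method = "samgsr"}
#' @export
samgsrSelect <- function(ds, coll, B = 500L, seed = 1L,
                         setPThreshold = 0.05, pAdjust = c("raw", "BH"),
                         ckGrid = seq(0.05, 0.50, by = 0.05),
                         minSetSize = 2L,
                         s0Method = c("quantile", "fixed"),
                         s0Quantile = 0.05, s0Fixed = NULL,
                         recomputeS0 = TRUE) {
    pAdjust <- match.arg(pAdjust)
    s0Method <- match.arg(s0Method)
    coll <- restrictCollection(coll, ds, minSetSize)
    res <- samGsPermutation(ds, coll, B = B, seed = seed,
                            s0Method = s0Method, s0Quantile = s0Quantile,
                            s0Fixed = s0Fixed, recomputeS0 = recomputeS0)
    sig <- significantSets(res, threshold = setPThreshold, method = pAdjust)
    manifest <- list(method = "samgsr", B = res@B, seed = seed,
                     s0 = res@s0, s0Method = s0Method,
                     setPThreshold = setPThreshold, pAdjust = pAdjust,
                     ckGrid = ckGrid, minSetSize = minSetSize,
                     recomputeS0 = recomputeS0,
                     version = as.character(utils::packageVersion("GSReduce")))
    if (!length(sig)) {
        return(new("PipelineResult", method = "samgsr",
                   significantSets = character(0),
                   candidateGenes = character(0),
                   selectedGenes = character(0), model = NULL,
                   traces = list(), cutoffTable = data.frame(),
                   manifest = manifest))
    }
    tuned <- tuneCutoff(ds, res, coll, sig, grid = ckGrid)
    traces <- lapply(sig, function(s) reduceSet(res, coll, s, tuned$cutoff))
    names(traces) <- sig
    genes <- unique(unlist(lapply(traces, coreSubset), use.names = FALSE))
    model <- .fitPlattSvm(ds, genes)
    manifest$cutoff <- tuned$cutoff
    candidates <- unique(unlist(geneSets(coll)[sig], use.names = FALSE))
    new("PipelineResult", method = "samgsr", significantSets = sig,
        candidateGenes = candidates, selectedGenes = genes, model = model,
        traces = traces, cutoffTable = tuned$table, manifest = manifest)
}
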