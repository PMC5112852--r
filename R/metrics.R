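#' @include AllClasses.R
NULL

#' Misclassification error rate
#'
#' Fraction of samples whose argmax-belief class differs from the truth.
#' Ties in beliefs go to the first (lowest-index) class; with sigmoid
#' beliefs ties are essentially impossible, but the rule keeps the call
#' deterministic.
#'
#' @param pred a \linkS4class{PredictionSet}
#' @return a number in [0, 1]
#' @export
errorRate <- function(pred) {
    b <- beliefs(pred)
    call <- max.col(b, ties.method = "first")
    mean(call != truthIndices(pred))
}

#' Generalized Brier Score
#'
#' \code{GBS = 1/(2n) * sum_i sum_k (Y_ik - p_ik)^2} where \code{Y_ik}
#' indicates the true class and \code{p_ik} is the belief. 0 is perfect,
#' 1 is anti-perfect; uniform beliefs over two classes give 0.25.
#'
#' @param pred a \linkS4class{PredictionSet}
#' @return a number in [0, 1]
#' @export
gbs <- function(pred) {
    b <- beliefs(pred)
    n <- nrow(b)
    Y <- matrix(0, n, ncol(b))
    Y[cbind(seq_len(n), truthIndices(pred))] <- 1
    sum((Y - b)^2) / (2 * n)
}

#' Belief Confusion Metric
#'
#' Average belief assigned to the true class: for each class k represented
#' in the truth, \code{B_k} is the mean belief in k over the samples truly
#' in k; BCM is the unweighted (macro) average of the \code{B_k} over the
#' represented classes. 1 is perfect, 0.5 equals uniform guessing at K = 2.
#' Classes absent from the truth are omitted from the average with a
#' warning. This is the mean diagonal of the belief confusion matrix; the
#' per-class weighting is documented here because the metric's original
#' challenge definition is prose, not a formula.
#'
#' @param pred a \linkS4class{PredictionSet}
#' @return a number in [0, 1]
#' @export
bcm <- function(pred) {
    b <- beliefs(pred)
    truth <- truthIndices(pred)
    present <- sort(unique(truth))
    if (length(present) < ncol(b))
        warning("class(es) absent from truth omitted from the BCM average: ",
                paste(pred@classNames[setdiff(seq_len(ncol(b)), present)],
                      collapse = ", "))
    bk <- vapply(present, function(k) mean(b[truth == k, k]), 0)
    mean(bk)
}

## Average precision for one binary ranking: precision-weighted sum of
## recall increments over the belief-descending step curve.
.averagePrecision <- function(score, positive) {
    ord <- order(score, decreasing = TRUE)  # ties: original sample order
    pos <- positive[ord]
    tp <- cumsum(pos)
    prec <- tp / seq_along(pos)
    sum(prec[pos]) / sum(pos)
}

#' Area under the precision-recall curve (average precision)
#'
#' Per class, samples are ranked by their belief in that class,
#' decreasingly, and the area is the average-precision (step-curve) sum --
#' not trapezoidal interpolation, which is known to overestimate PR area.
#' The returned value is the macro-average over classes having at least one
#' positive; classes without positives are skipped with a warning. Tied
#' beliefs are broken by original sample order (a warning is emitted when
#' ties are present, since the area then depends on that order).
#'
#' @param pred a \linkS4class{PredictionSet}
#' @return a number in [0, 1]
#' @export
aupr <- function(pred) {
    b <- beliefs(pred)
    truth <- truthIndices(pred)
    ap <- numeric(0)
    for (k in seq_len(ncol(b))) {
        positive <- truth == k
        if (!any(positive)) {
            warning("class '", pred@classNames[k],
                    "' has no positives; skipped in AUPR")
            next
        }
        if (anyDuplicated(b[, k]))
            warning("tied beliefs in class '", pred@classNames[k],
                    "'; ties broken by sample order")
        ap <- c(ap, .averagePrecision(b[, k], positive))
    }
    if (!length(ap))
        stop("no class has positive samples; AUPR undefined")
    mean(ap)
}

#' All four evaluation metrics at once
#'
#' @param pred a \linkS4class{PredictionSet}
#' @return named list: \code{error} (misclassification fraction),
#'   \code{gbs}, \code{bcm}, \code{aupr}
#' @export
evaluatePredictions <- function(pred) {
    list(error = errorRate(pred), gbs = gbs(pred), bcm = bcm(pred),
         aupr = aupr(pred))
}
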