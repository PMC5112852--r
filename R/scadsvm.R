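#' @include AllClasses.R
NULL

#' The SCAD penalty
#'
#' Smoothly clipped absolute deviation penalty for a coefficient w:
#' \itemize{
#'   \item \code{lambda * |w|} for \code{|w| <= lambda} (LASSO-like near 0),
#'   \item \code{-(|w|^2 - 2*alpha*lambda*|w| + lambda^2) / (2*(alpha - 1))}
#'     for \code{lambda < |w| <= alpha*lambda},
#'   \item \code{(alpha + 1) * lambda^2 / 2} for \code{|w| > alpha*lambda}
#'     (constant: large coefficients are not biased further).
#' }
#' Continuous and even in w, nondecreasing in |w|.
#'
#' @param w coefficient value(s); vectorized
#' @param lambda penalty scale, > 0
#' @param alpha shape parameter, > 2 (default 3.7)
#' @return nonnegative penalty value(s)
#' @examples
#' scadPenalty(2, lambda = 1)   # middle branch: ~1.814815
#' scadPenalty(10, lambda = 1)  # flat branch: 2.35
#' @export
scadPenalty <- function(w, lambda, alpha = 3.7) {
    .checkScadPars(lambda, alpha)
    a <- abs(w)
    ifelse(a <= lambda, lambda * a,
    ifelse(a <= alpha * lambda,
           -(a^2 - 2 * alpha * lambda * a + lambda^2) / (2 * (alpha - 1)),
           (alpha + 1) * lambda^2 / 2))
}

#' Derivative of the SCAD penalty in |w|
#'
#' \code{lambda} on \code{[0, lambda]}, linearly decaying
#' \code{(alpha*lambda - |w|) / (alpha - 1)} on \code{(lambda, alpha*lambda]},
#' and 0 beyond: large coefficients sit on an unpenalized plateau. These are
#' the weights of the local linear approximation.
#'
#' @param wAbs nonnegative coefficient magnitude(s); vectorized
#' @inheritParams scadPenalty
#' @return nonnegative derivative value(s)
#' @export
scadDerivative <- function(wAbs, lambda, alpha = 3.7) {
    .checkScadPars(lambda, alpha)
    if (any(wAbs < 0)) stop("wAbs must be nonnegative")
    ifelse(wAbs <= lambda, lambda,
    ifelse(wAbs <= alpha * lambda,
           (alpha * lambda - wAbs) / (alpha - 1), 0))
}

.checkScadPars <- function(lambda, alpha) {
    if (!is.numeric(lambda) || length(lambda) != 1L || lambda <= 0)
        stop("lambda must be a single positive number")
    if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 2)
        stop("alpha must be a single number > 2")
}

## Huberized (smoothed) hinge loss of the margin z = y * f(x):
## 0 for z >= 1; (1 - z)^2 / (2 delta) on (1 - delta, 1);
## 1 - z - delta/2 for z <= 1 - delta. Converges to the hinge as delta -> 0
## and has a 1/delta-Lipschitz derivative, which the coordinate-descent
## majorization needs.
.huberHinge <- function(z, delta) {
    ifelse(z >= 1, 0,
    ifelse(z > 1 - delta, (1 - z)^2 / (2 * delta), 1 - z - delta / 2))
}

.huberHingeGrad <- function(z, delta) {
    ifelse(z >= 1, 0,
    ifelse(z > 1 - delta, (z - 1) / delta, -1))
}

.softThreshold <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

## Weighted-L1 + huberized-hinge subproblem, solved by cyclic coordinate
## descent with per-coordinate quadratic majorization. Monotone descent in
## the subproblem objective; exact zeros via soft-thresholding. This is the
## reference implementation in plain R, retained for cross-checking; the
## fitter calls the identical compiled kernel.
.wl1HingeCDr <- function(X, y, u, w, b, delta, maxCycles = 2000L,
                         tol = 1e-7) {
    n <- nrow(X); p <- ncol(X)
    Mj <- colSums(X^2) / delta
    Mb <- n / delta
    f <- drop(X %*% w) + b
    z <- y * f
    for (cycle in seq_len(maxCycles)) {
        maxDelta <- 0
        for (j in seq_len(p)) {
            if (Mj[j] == 0) next
            g <- sum(.huberHingeGrad(z, delta) * y * X[, j])
            wNew <- .softThreshold(Mj[j] * w[j] - g, u[j]) / Mj[j]
            if (wNew != w[j]) {
                f <- f + X[, j] * (wNew - w[j])
                z <- y * f
                maxDelta <- max(maxDelta, abs(wNew - w[j]))
                w[j] <- wNew
            }
        }
        gb <- sum(.huberHingeGrad(z, delta) * y)
        bNew <- b - gb / Mb
        if (bNew != b) {
            f <- f + (bNew - b)
            z <- y * f
            maxDelta <- max(maxDelta, abs(bNew - b))
            b <- bNew
        }
        if (maxDelta < tol) break
    }
    list(w = w, b = b)
}

#' Fit a SCAD-penalized linear SVM
#'
#' Minimizes \code{sum_i loss(y_i f(x_i)) + sum_j scadPenalty(w_j)} with
#' \code{f(x) = sum_j w_j x_j + b}, the loss being the hinge smoothed at
#' scale \code{huberDelta} (the smoothing makes the margin loss
#' differentiable so the weighted-L1 subproblems admit a fast monotone
#' coordinate-descent solver). The nonconvex SCAD penalty is handled by
#' local linear approximation (LLA): starting from w = 0, each outer
#' iteration solves a weighted-L1 problem whose per-coefficient weights are
#' \code{scadDerivative(|w|)} at the current iterate -- the first iteration
#' is therefore exactly the L1-penalized fit at the same lambda. The full
#' objective is guaranteed non-increasing across outer iterations and is
#' recorded in the model. Features are standardized internally (the penalty
#' is scale-sensitive); constants are stored in the model. Weights below
#' \code{zeroTol} in magnitude are set exactly to zero.
#'
#' @param ds training \linkS4class{ExpressionDataset} (classes coded
#'   internally as +1 diseased / -1 control; >= 2 samples per class)
#' @param genes optional gene panel to restrict to (default: all genes)
#' @param lambda SCAD penalty scale, > 0
#' @param alpha SCAD shape, > 2 (default 3.7)
#' @param huberDelta hinge smoothing scale (default 0.5)
#' @param maxOuter,outerTol LLA outer-loop cap and max-|delta w| tolerance
#' @param maxInner,innerTol coordinate-descent cycle cap and tolerance
#' @param zeroTol hard-zero threshold on |w|
#' @param warmW,warmB optional warm start (standardized scale) for the
#'   solver of the first -- convex -- subproblem, e.g. the solution at a
#'   neighbouring lambda; this accelerates path-wise tuning without
#'   changing the algorithm (the first subproblem is still the L1 problem
#'   anchored at w = 0, and a safeguard re-solves from the anchor if the
#'   warm start ever fails to improve the objective)
#' @return a \linkS4class{ScadSvmModel}; if the outer loop hits
#'   \code{maxOuter} without meeting \code{outerTol} the best iterate is
#'   returned with a warning and \code{converged = FALSE}
#' @export
scadSvmFit <- function(ds, genes = NULL, lambda, alpha = 3.7,
                       huberDelta = 0.5, maxOuter = 50L, outerTol = 1e-4,
                       maxInner = 2000L, innerTol = 1e-7, zeroTol = 1e-6,
                       warmW = NULL, warmB = 0) {
    .checkScadPars(lambda, alpha)
    X0 <- exprValues(ds)
    if (!is.null(genes)) {
        miss <- setdiff(genes, rownames(X0))
        if (length(miss))
            stop("gene(s) absent from data: ", paste(miss, collapse = ", "))
        X0 <- X0[genes, , drop = FALSE]
    }
    y <- unname(labelSigns(ds))
    if (sum(y > 0) < 2L || sum(y < 0) < 2L)
        stop("each class needs at least 2 samples")
    X <- t(X0)
    center <- colMeans(X)
    scl <- apply(X, 2L, stats::sd)
    scl[scl == 0] <- 1  # constant genes stay centered, unscaled
    Xs <- sweep(sweep(X, 2L, center), 2L, scl, "/")

    p <- ncol(Xs)
    w <- rep(0, p); b <- 0
    objective <- numeric(0)
    obj <- function(w, b) {
        f <- drop(Xs %*% w) + b
        sum(.huberHinge(y * f, huberDelta)) +
            sum(scadPenalty(w, lambda, alpha))
    }
    objective <- obj(w, b)
    converged <- FALSE
    iter <- 0L
    startW <- if (is.null(warmW)) w else unname(warmW)
    startB <- warmB
    for (t in seq_len(maxOuter)) {
        iter <- t
        u <- scadDerivative(abs(w), lambda, alpha)
        sol <- .wl1HingeCDcpp(Xs, y, u, startW, startB, huberDelta,
                              as.integer(maxInner), innerTol)
        if (t == 1L && !is.null(warmW) && obj(sol$w, sol$b) > objective[1L])
            sol <- .wl1HingeCDcpp(Xs, y, u, w, b, huberDelta,
                                  as.integer(maxInner), innerTol)
        delta <- max(abs(c(sol$w - w, sol$b - b)))
        w <- sol$w; b <- sol$b
        objective <- c(objective, obj(w, b))
        ## the objective is monotone by construction, so a vanishing
        ## decrease is as good a stopping signal as a vanishing step (LLA
        ## can hop between near-equivalent sign patterns without either
        ## being an improvement)
        objDrop <- objective[length(objective) - 1L] -
            objective[length(objective)]
        if (delta < outerTol ||
            objDrop < 1e-8 * (1 + abs(objective[length(objective)]))) {
            converged <- TRUE
            break
        }
        startW <- w
        startB <- b
    }
    if (!converged)
        warning("SCAD-SVM outer loop did not converge in ", maxOuter,
                " iterations; returning the final iterate")
    w[abs(w) < zeroTol] <- 0
    names(w) <- colnames(Xs)
    model <- new("ScadSvmModel", w = w, b = b, lambda = lambda,
                 alpha = alpha, center = center, scale = scl,
                 platt = c(A = 0, B = 0), converged = converged,
                 iterations = iter, objective = objective,
                 cvTable = data.frame(), huberDelta = huberDelta)
    f <- drop(Xs %*% w) + b
    model@platt <- .plattFit(f, y)
    model
}

#' @rdname decisionValues
#' @aliases decisionValues,ScadSvmModel-method
setMethod("decisionValues", c("ScadSvmModel", "ExpressionDataset"),
    function(model, ds) {
        genes <- names(model@w)
        miss <- setdiff(genes, geneIds(ds))
        if (length(miss))
            stop("model gene(s) absent from data: ",
                 paste(miss, collapse = ", "))
        X <- t(exprValues(ds)[genes, , drop = FALSE])
        Xs <- sweep(sweep(X, 2L, model@center), 2L, model@scale, "/")
        setNames(drop(Xs %*% model@w) + model@b, sampleIds(ds))
    })

#' @rdname predictBeliefs
#' @aliases predictBeliefs,ScadSvmModel-method
setMethod("predictBeliefs", c("ScadSvmModel", "ExpressionDataset"),
    function(model, ds) {
        f <- decisionValues(model, ds)
        p <- .plattProb(f, model@platt)
        PredictionSet(cbind(control = 1 - p, diseased = p),
                      truth = as.character(sampleLabels(ds)),
                      classNames = c("control", "diseased"))
    })

#' Tune lambda by stratified k-fold cross-validation
#'
#' Grid search over \code{lambdaGrid} (default \code{2^(-8:14)}, 23 values)
#' with stratified fold assignment driven by \code{seed}. The criterion is
#' pooled CV misclassification error (class call = sign of the decision
#' value); ties are broken toward the LARGER lambda, i.e. the sparser
#' model.
#'
#' @inheritParams scadSvmFit
#' @param lambdaGrid positive penalty grid
#' @param folds number of folds (default 5)
#' @param seed integer seed for the fold shuffle
#' @param ... further arguments for \code{\link{scadSvmFit}}
#' @return list with \code{lambda} (winner) and \code{table} (data.frame:
#'   lambda, cvError, meanNonzero)
#' @export
tuneLambda <- function(ds, genes = NULL, alpha = 3.7,
                       lambdaGrid = 2^(-8:14), folds = 5L, seed = 1L, ...) {
    if (!length(lambdaGrid) || any(lambdaGrid <= 0))
        stop("lambdaGrid must contain positive values")
    y <- labelSigns(ds)
    fold <- .stratifiedFolds(y, folds, seed)
    n <- length(y)
    lambdaGrid <- sort(lambdaGrid)
    errs <- matrix(NA_real_, nrow = length(lambdaGrid), ncol = folds)
    nz <- matrix(NA_real_, nrow = length(lambdaGrid), ncol = folds)
    for (k in seq_len(folds)) {
        tr <- fold != k
        if (length(unique(y[tr])) < 2L || sum(y[tr] > 0) < 2L ||
            sum(y[tr] < 0) < 2L)
            stop("fold ", k, " leaves fewer than 2 training samples in a ",
                 "class; use fewer folds")
        dsTr <- ds[, tr]
        dsTe <- ds[, !tr]
        warmW <- NULL; warmB <- 0  # path-wise warm starts, large -> small
        for (i in rev(seq_along(lambdaGrid))) {
            fit <- scadSvmFit(dsTr, genes = genes, lambda = lambdaGrid[i],
                              alpha = alpha, warmW = warmW, warmB = warmB,
                              ...)
            warmW <- fit@w; warmB <- fit@b
            f <- decisionValues(fit, dsTe)
            call <- ifelse(f > 0, 1, -1)
            errs[i, k] <- sum(call != y[!tr])
            nz[i, k] <- sum(fit@w != 0)
        }
    }
    cvError <- rowSums(errs) / n
    tab <- data.frame(lambda = lambdaGrid, cvError = cvError,
                      meanNonzero = rowMeans(nz))
    best <- max(lambdaGrid[cvError == min(cvError)])  # tie -> sparser
    list(lambda = best, table = tab)
}

.stratifiedFolds <- function(y, folds, seed) {
    if (folds < 2L) stop("folds must be >= 2")
    set.seed(seed)
    fold <- integer(length(y))
    for (cls in unique(y)) {
        idx <- which(y == cls)
        idx <- idx[sample.int(length(idx))]
        fold[idx] <- rep_len(seq_len(folds), length(idx))
    }
    fold
}

#' Serialize a ScadSvmModel to JSON
#'
#' @param model a \linkS4class{ScadSvmModel}
#' @param path output path
#' @return \code{path}, invisibly
#' @export
writeScadSvmModel <- function(model, path) {
    jsonlite::write_json(list(
        genes = names(model@w), w = unname(model@w), b = model@b,
        lambda = model@lambda, alpha = model@alpha,
        center = unname(model@center), scale = unname(model@scale),
        platt = as.list(model@platt), huberDelta = model@huberDelta,
        converged = model@converged), path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}
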