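#' @include AllClasses.R
NULL

#' Pooled standard deviation of two groups (SAM convention)
#'
#' The gene-specific scatter used by the moderated SAM statistic:
#' \code{sqrt((1/n_d + 1/n_c) * (SS_d + SS_c) / (n_d + n_c - 2))}, where
#' \code{SS_g} is the within-group sum of squared deviations.
#'
#' @param xd,xc numeric vectors of values for the diseased and the control
#'   group; each must have at least 2 values
#' @return a nonnegative scalar
#' @examples
#' pooledSd(c(0, 2), c(0, 0))  # 1
#' @export
pooledSd <- function(xd, xc) {
    nd <- length(xd); nc <- length(xc)
    if (nd < 2L || nc < 2L)
        stop("each group needs at least 2 values")
    ss <- sum((xd - mean(xd))^2) + sum((xc - mean(xc))^2)
    sqrt((1 / nd + 1 / nc) * ss / (nd + nc - 2))
}

#' Moderated SAM statistic for one gene
#'
#' \code{d = (mean(xd) - mean(xc)) / (pooledSd(xd, xc) + s0)}. The fudge
#' constant \code{s0} stabilizes genes with tiny scatter.
#'
#' @inheritParams pooledSd
#' @param s0 fudge constant, >= 0; \code{pooledSd + s0} must be positive
#' @return a scalar; its sign matches the sign of the group-mean difference
#' @examples
#' samStatistic(c(2, 2), c(0, 0), s0 = 1)  # 2
#' @export
samStatistic <- function(xd, xc, s0 = 0) {
    if (s0 < 0) stop("s0 must be nonnegative")
    s <- pooledSd(xd, xc)
    if (s + s0 <= 0)
        stop("degenerate gene: pooled SD + s0 is zero")
    (mean(xd) - mean(xc)) / (s + s0)
}

#' Choose the fudge constant s0
#'
#' Either a fixed value, or an empirical quantile of the per-gene pooled
#' standard deviations (default: the 5th percentile, a simple deterministic
#' stand-in for SAM's coefficient-of-variation tuning, which is out of
#' scope). Quantiles use the default continuous convention of
#' \code{\link[stats]{quantile}} (type 7).
#'
#' @param sds per-gene pooled standard deviations (non-empty)
#' @param method \code{"quantile"} or \code{"fixed"}
#' @param q quantile in [0, 1] for \code{method = "quantile"}
#' @param fixedValue the value to return for \code{method = "fixed"}
#' @return a nonnegative scalar
#' @export
chooseS0 <- function(sds, method = c("quantile", "fixed"), q = 0.05,
                     fixedValue = NULL) {
    method <- match.arg(method)
    if (method == "fixed") {
        if (is.null(fixedValue) || fixedValue < 0)
            stop("method = 'fixed' needs a nonnegative fixedValue")
        return(fixedValue)
    }
    if (!length(sds)) stop("empty SD vector")
    if (q < 0 || q > 1) stop("q must lie in [0, 1]")
    unname(stats::quantile(sds, probs = q, type = 7, names = FALSE))
}

#' Gene-set statistic: sum of squared gene statistics
#'
#' The set-level statistic is the squared L2 norm of the member genes'
#' moderated statistics; it is nonnegative, invariant to gene order, and
#' additive over disjoint subsets.
#'
#' @param d named numeric vector of per-gene statistics
#' @param members character vector of member gene ids (all must be present
#'   in \code{d})
#' @return a nonnegative scalar
#' @examples
#' samgsStatistic(c(a = 1, b = 2, c = 2), c("a", "b", "c"))  # 9
#' @export
samgsStatistic <- function(d, members) {
    idx <- match(members, names(d))
    if (anyNA(idx))
        stop("unknown gene id(s): ",
             paste(members[is.na(idx)], collapse = ", "))
    sum(d[idx]^2)
}

## Per-gene stats for one label assignment. X is genes x samples,
## signs is +1 (diseased) / -1 (control).
.samStatsOnce <- function(X, signs, s0Method, s0Quantile, s0Fixed, s0 = NULL) {
    d <- signs > 0
    nd <- sum(d); nc <- sum(!d)
    if (nd < 2L || nc < 2L)
        stop("each class needs at least 2 samples")
    Xd <- X[, d, drop = FALSE]
    Xc <- X[, !d, drop = FALSE]
    meanD <- rowMeans(Xd)
    meanC <- rowMeans(Xc)
    ss <- rowSums((Xd - meanD)^2) + rowSums((Xc - meanC)^2)
    s <- sqrt((1 / nd + 1 / nc) * ss / (nd + nc - 2))
    if (is.null(s0))
        s0 <- chooseS0(s, method = s0Method, q = s0Quantile,
                       fixedValue = s0Fixed)
    denom <- s + s0
    if (any(denom <= 0))
        stop("degenerate gene(s): pooled SD + s0 is zero")
    list(d = (meanD - meanC) / denom, meanD = meanD, meanC = meanC,
         s = s, s0 = s0)
}

## All distinct assignments of nd '+1' labels to n samples, as a
## (count x n) sign matrix. Includes the observed assignment.
.enumerateSigns <- function(n, nd) {
    sets <- utils::combn(n, nd)
    t(apply(sets, 2L, function(ix) {
        v <- rep(-1, n); v[ix] <- 1; v
    }))
}

#' SAM-GS with phenotype-label permutation significance
#'
#' Computes the observed per-gene moderated statistics and per-set
#' sum-of-squares statistics, then draws \code{B} uniformly random shuffles
#' of the phenotype labels (or, with \code{exhaustive = TRUE}, enumerates
#' every distinct label assignment) and recomputes everything per draw.
#' Set and gene p-values use the add-one convention
#' \code{(1 + count) / (B + 1)} in random mode, so no p-value is ever 0; in
#' exhaustive mode the p-value is the exact proportion of assignments (the
#' observed one included) reaching the observed statistic. The per-draw
#' gene statistics are retained in the result so the reduction step can
#' score residual subsets on the identical null draws.
#'
#' By default the fudge constant \code{s0} is re-estimated inside every
#' permutation (shuffled labels change the pooled SDs); set
#' \code{recomputeS0 = FALSE} to freeze the observed \code{s0}.
#'
#' @param ds an \linkS4class{ExpressionDataset} with >= 2 samples per class
#' @param coll a \linkS4class{GeneSetCollection}; sets are used as-is (apply
#'   \code{\link{restrictCollection}} first)
#' @param B number of random permutations (>= 1); the field default of a few
#'   hundred is 500 here
#' @param seed integer seed driving the permutation draws
#' @param s0Method,s0Quantile,s0Fixed how to choose \code{s0}; see
#'   \code{\link{chooseS0}}
#' @param recomputeS0 logical; re-estimate \code{s0} per permutation
#'   (default TRUE)
#' @param exhaustive enumerate all label assignments instead of sampling;
#'   only allowed when their count is at most \code{maxExhaustive}
#' @param maxExhaustive cap on the enumeration size
#' @return a \linkS4class{SamGsResult}
#' @export
samGsPermutation <- function(ds, coll, B = 500L, seed = 1L,
                             s0Method = c("quantile", "fixed"),
                             s0Quantile = 0.05, s0Fixed = NULL,
                             recomputeS0 = TRUE,
                             exhaustive = FALSE, maxExhaustive = 10000L) {
    s0Method <- match.arg(s0Method)
    X <- exprValues(ds)
    y <- labelSigns(ds)
    genes <- rownames(X)
    for (nm in setIds(coll)) {
        unknown <- setdiff(coll@sets[[nm]], genes)
        if (length(unknown))
            stop("set '", nm, "' contains gene(s) absent from the dataset: ",
                 paste(unknown, collapse = ", "),
                 " (apply restrictCollection first)")
    }
    obs <- .samStatsOnce(X, y, s0Method, s0Quantile, s0Fixed)

    if (exhaustive) {
        nd <- sum(y > 0)
        total <- choose(ncol(X), nd)
        if (total > maxExhaustive)
            stop("exhaustive enumeration would need ", total,
                 " assignments (cap ", maxExhaustive, ")")
        signs <- .enumerateSigns(ncol(X), nd)
        B <- nrow(signs)
        seedUsed <- NA_integer_
    } else {
        if (B < 1L) stop("B must be >= 1")
        B <- as.integer(B)
        set.seed(seed)
        signs <- t(vapply(seq_len(B), function(b) sample(y), numeric(ncol(X))))
        seedUsed <- as.integer(seed)
    }

    permD <- matrix(0, nrow = B, ncol = length(genes),
                    dimnames = list(NULL, genes))
    frozenS0 <- if (recomputeS0) NULL else obs$s0
    for (b in seq_len(B))
        permD[b, ] <- .samStatsOnce(X, signs[b, ], s0Method, s0Quantile,
                                    s0Fixed, s0 = frozenS0)$d

    geneP <- .permPvalue(abs(permD), abs(obs$d), exhaustive)
    geneStats <- data.frame(gene = genes, d = unname(obs$d),
                            meanDiseased = unname(obs$meanD),
                            meanControl = unname(obs$meanC),
                            s = unname(obs$s), geneP = unname(geneP),
                            stringsAsFactors = FALSE, row.names = genes)

    setStats <- .scoreSets(coll, obs$d, permD, exhaustive)

    new("SamGsResult", geneStats = geneStats, s0 = obs$s0,
        setStats = setStats, permD = permD, B = B,
        seed = seedUsed, exhaustive = exhaustive,
        s0Recomputed = recomputeS0,
        s0Method = list(method = s0Method, q = s0Quantile, fixed = s0Fixed))
}

## p-values comparing observed statistics against a perm x stat matrix.
## Random mode: add-one convention; exhaustive: exact proportion.
.permPvalue <- function(permStat, obsStat, exhaustive) {
    counts <- colSums(permStat >= rep(obsStat, each = nrow(permStat)))
    if (exhaustive) counts / nrow(permStat)
    else (1 + counts) / (nrow(permStat) + 1)
}

.scoreSets <- function(coll, dObs, permD, exhaustive) {
    ids <- setIds(coll)
    samgs <- numeric(length(ids))
    pval <- numeric(length(ids))
    B <- nrow(permD)
    for (i in seq_along(ids)) {
        members <- coll@sets[[i]]
        obs <- sum(dObs[members]^2)
        perm <- rowSums(permD[, members, drop = FALSE]^2)
        cnt <- sum(perm >= obs)
        samgs[i] <- obs
        pval[i] <- if (exhaustive) cnt / B else (1 + cnt) / (B + 1)
    }
    data.frame(setId = ids, size = unname(setSizes(coll)), samgs = samgs,
               setP = pval, stringsAsFactors = FALSE, row.names = ids)
}

#' Significant gene sets of a SAM-GS run
#'
#' Sets whose permutation p-value is at or below \code{threshold}. The
#' default is raw permutation p <= 0.05; \code{method = "BH"} applies
#' Benjamini-Hochberg adjustment across sets before thresholding.
#'
#' @param res a \linkS4class{SamGsResult}
#' @param threshold significance threshold in (0, 1)
#' @param method \code{"raw"} or \code{"BH"}
#' @return character vector of set ids (possibly empty)
#' @export
significantSets <- function(res, threshold = 0.05, method = c("raw", "BH")) {
    method <- match.arg(method)
    p <- res@setStats$setP
    if (method == "BH") p <- stats::p.adjust(p, method = "BH")
    res@setStats$setId[p <= threshold]
}

#' Write per-set statistics to TSV
#'
#' @param res a \linkS4class{SamGsResult}
#' @param path output TSV path
#' @return \code{path}, invisibly
#' @export
writeSetStatistics <- function(res, path) {
    utils::write.table(res@setStats, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
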