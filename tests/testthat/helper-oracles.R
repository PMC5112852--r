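# Independent brute-force oracles, written as literal transcriptions of the
# printed formulas (explicit loops, no shared code with the package paths
# they check).

# Per-gene moderated statistics for one label assignment.
oracleSamStats <- function(X, ySigns, s0 = NULL, q = 0.05) {
    G <- nrow(X)
    d <- numeric(G); s <- numeric(G)
    meanD <- numeric(G); meanC <- numeric(G)
    for (i in seq_len(G)) {
        xd <- X[i, ySigns > 0]
        xc <- X[i, ySigns < 0]
        meanD[i] <- sum(xd) / length(xd)
        meanC[i] <- sum(xc) / length(xc)
        ssd <- 0
        for (v in xd) ssd <- ssd + (v - meanD[i])^2
        ssc <- 0
        for (v in xc) ssc <- ssc + (v - meanC[i])^2
        s[i] <- sqrt((1 / length(xd) + 1 / length(xc)) *
                     (ssd + ssc) / (length(xd) + length(xc) - 2))
    }
    if (is.null(s0))
        s0 <- unname(quantile(s, probs = q, type = 7))
    for (i in seq_len(G))
        d[i] <- (meanD[i] - meanC[i]) / (s[i] + s0)
    names(d) <- names(s) <- names(meanD) <- names(meanC) <- rownames(X)
    list(d = d, s = s, meanD = meanD, meanC = meanC, s0 = s0)
}

# Sum of squared gene statistics over a member list.
oracleSamgs <- function(d, members) {
    total <- 0
    for (g in members) total <- total + d[[g]]^2
    total
}

# Exhaustive enumeration of all distinct label assignments (nd diseased out
# of n); returns exact p-values for genes (|d|) and one gene set.
oracleExhaustiveP <- function(X, ySigns, members, q = 0.05) {
    n <- ncol(X)
    nd <- sum(ySigns > 0)
    obs <- oracleSamStats(X, ySigns, q = q)
    obsSet <- oracleSamgs(obs$d, members)
    splits <- combn(n, nd)
    total <- ncol(splits)
    geneCount <- numeric(nrow(X))
    setCount <- 0
    for (b in seq_len(total)) {
        y <- rep(-1, n)
        y[splits[, b]] <- 1
        st <- oracleSamStats(X, y, q = q)
        geneCount <- geneCount + (abs(st$d) >= abs(obs$d))
        if (oracleSamgs(st$d, members) >= obsSet)
            setCount <- setCount + 1
    }
    list(geneP = setNames(geneCount / total, rownames(X)),
         setP = setCount / total)
}

# A small random labelled dataset.
makeToyDataset <- function(G = 10, n = 8, seed = 1, shift = 0,
                           shiftGenes = character(0)) {
    set.seed(seed)
    m <- matrix(rnorm(G * n), G, n,
                dimnames = list(sprintf("g%02d", seq_len(G)),
                                sprintf("s%02d", seq_len(n))))
    labels <- rep(c("diseased", "control"), each = n / 2)
    if (length(shiftGenes))
        m[shiftGenes, labels == "diseased"] <-
            m[shiftGenes, labels == "diseased"] + shift
    ExpressionDataset(m, labels)
}
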