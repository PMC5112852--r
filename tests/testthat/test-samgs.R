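test_that("pooled SD follows the two-group formula and its symmetries", {
    expect_identical(pooledSd(c(1, 1), c(0, 0)), 0)
    # sqrt((1/2 + 1/2) * (2 + 0) / 2) = 1
    expect_equal(pooledSd(c(0, 2), c(0, 0)), 1)
    set.seed(5)
    xd <- rnorm(7); xc <- rnorm(5)
    expect_equal(pooledSd(3 * xd, 3 * xc), 3 * pooledSd(xd, xc))  # |c| scaling
    expect_equal(pooledSd(xd, xc), pooledSd(xc, xd))
    expect_error(pooledSd(1, c(0, 0)), "at least 2")
})

test_that("the moderated gene statistic matches hand evaluation", {
    expect_equal(samStatistic(c(2, 2), c(0, 0), s0 = 1), 2)
    expect_equal(samStatistic(c(5, 5, 5), c(5, 5, 5), s0 = 0.1), 0)
    set.seed(6)
    xd <- rnorm(4); xc <- rnorm(4)
    expect_equal(samStatistic(xd, xc, 0.2), -samStatistic(xc, xd, 0.2))
    expect_error(samStatistic(c(1, 1), c(0, 0), s0 = 0), "degenerate")
    expect_error(samStatistic(c(1, 2), c(0, 1), s0 = -1), "nonnegative")
})

test_that("fudge-constant selection: quantile and fixed modes", {
    expect_equal(chooseS0(rep(1, 4)), 1)
    expect_equal(chooseS0(c(2, 9), method = "fixed", fixedValue = 0.3), 0.3)
    # type-7 empirical quantile of 0..100 at q = 0.05 is exactly 5
    expect_equal(chooseS0(0:100, q = 0.05), 5)
    expect_error(chooseS0(numeric(0)), "empty")
})

test_that("set statistic is the sum of squares, order-invariant, additive", {
    d <- c(a = 1, b = 2, c = 2, e = 0)
    expect_equal(samgsStatistic(d, c("a", "b", "c")), 9)
    expect_equal(samgsStatistic(d, c("c", "a", "b")), 9)
    expect_equal(samgsStatistic(d, "e"), 0)
    expect_equal(samgsStatistic(d, c("a", "b")) + samgsStatistic(d, c("c", "e")),
                 samgsStatistic(d, names(d)))
    expect_error(samgsStatistic(d, c("a", "zz")), "unknown gene")
})

test_that("permutation p-value conventions: add-one floor and tie saturation", {
    perm <- matrix(c(1:10) / 10, ncol = 1)
    expect_equal(GSReduce:::.permPvalue(perm, 2, exhaustive = FALSE),
                 1 / 11)                     # above every permuted value
    expect_equal(GSReduce:::.permPvalue(perm, 0, exhaustive = FALSE), 1)
    tied <- matrix(rep(3, 7), ncol = 1)
    expect_equal(GSReduce:::.permPvalue(tied, 3, exhaustive = FALSE), 1)
})

test_that("observed statistics agree with the brute-force oracle", {
    for (seed in 1:8) {
        set.seed(seed)
        G <- sample(4:20, 1); n <- 2 * sample(2:6, 1)
        ds <- makeToyDataset(G, n, seed = seed + 100)
        coll <- GeneSetCollection(list(SA = geneIds(ds)[1:3],
                                       SB = geneIds(ds)[3:G]))
        res <- samGsPermutation(ds, coll, B = 3, seed = 1)
        orc <- oracleSamStats(exprValues(ds), labelSigns(ds))
        expect_equal(geneStatistics(res)$d, unname(orc$d), tolerance = 1e-12)
        expect_equal(geneStatistics(res)$s, unname(orc$s), tolerance = 1e-12)
        expect_equal(fudgeFactor(res), orc$s0, tolerance = 1e-12)
        expect_equal(setStatistics(res)["SA", "samgs"],
                     oracleSamgs(orc$d, coll[["SA"]]), tolerance = 1e-12)
    }
})

test_that("exhaustive 3-vs-3 p-values equal full enumeration", {
    ds <- makeToyDataset(G = 6, n = 6, seed = 42, shift = 2,
                         shiftGenes = c("g01", "g02"))
    coll <- GeneSetCollection(list(S = c("g01", "g02", "g03")))
    res <- samGsPermutation(ds, coll, exhaustive = TRUE)
    expect_identical(res@B, 20L)  # choose(6, 3) label splits
    orc <- oracleExhaustiveP(exprValues(ds), labelSigns(ds), coll[["S"]])
    expect_equal(geneStatistics(res)$geneP, unname(orc$geneP))
    expect_equal(setStatistics(res)["S", "setP"], orc$setP)
})

test_that("permutation run is bit-reproducible for a fixed seed", {
    ds <- makeToyDataset(G = 8, n = 8, seed = 3)
    coll <- GeneSetCollection(list(S = geneIds(ds)[1:4]))
    r1 <- samGsPermutation(ds, coll, B = 25, seed = 9)
    r2 <- samGsPermutation(ds, coll, B = 25, seed = 9)
    expect_identical(r1@permD, r2@permD)
    expect_identical(setStatistics(r1), setStatistics(r2))
})

test_that("stronger mean shifts do not lower the median set statistic", {
    shifts <- c(0, 1, 2)
    med <- vapply(shifts, function(dl) {
        stats <- vapply(1:6, function(rep) {
            ds <- makeToyDataset(G = 12, n = 16, seed = 1000 * dl + rep,
                                 shift = dl, shiftGenes = c("g01", "g02", "g03"))
            coll <- GeneSetCollection(list(S = c("g01", "g02", "g03")))
            res <- samGsPermutation(ds, coll, B = 1, seed = 1)
            setStatistics(res)["S", "samgs"]
        }, 0)
        median(stats)
    }, 0)
    expect_true(all(diff(med) >= 0))
})

test_that("sets referencing unmeasured genes are rejected up front", {
    ds <- makeToyDataset(G = 5, n = 6)
    coll <- GeneSetCollection(list(S = c("g01", "nope")))
    expect_error(samGsPermutation(ds, coll, B = 5), "restrictCollection")
})
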