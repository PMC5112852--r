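# A hand-built SamGsResult whose stored permutations give exactly known
# residual p-values: genes A, B, C with observed d = (2, 2, 0.1) and
# permuted statistics chosen so c_1 = 3/5 and c_2 = 1/5.
.manualSamGs <- function() {
    genes <- c("A", "B", "C")
    geneStats <- data.frame(gene = genes, d = c(2, 2, 0.1),
                            meanDiseased = 0, meanControl = 0, s = 1,
                            geneP = c(0.01, 0.02, 0.5),
                            row.names = genes, stringsAsFactors = FALSE)
    permD <- cbind(A = c(0, 0, 0, 0), B = c(1, 3, 0, 2.1),
                   C = c(0, 0, 0, 0))
    new("SamGsResult", geneStats = geneStats, s0 = 0.1,
        setStats = data.frame(setId = "S", size = 3L, samgs = 8.01,
                              setP = 0.2, row.names = "S",
                              stringsAsFactors = FALSE),
        permD = permD, B = 4L, seed = 1L, exhaustive = FALSE,
        s0Recomputed = TRUE, s0Method = list())
}

test_that("peeling follows the stored permutations, step by step", {
    res <- .manualSamGs()
    coll <- GeneSetCollection(list(S = c("A", "B", "C")))
    tr <- reduceSet(res, coll, "S", cutoff = 0.3)
    # residual {B, C}: observed 2^2 + 0.1^2 = 4.01, permuted row sums
    # (1, 9, 0, 4.41) -> 2 exceedances -> c_1 = (1+2)/5; residual {C}:
    # observed 0.01, permuted (0,0,0,0) -> c_2 = 1/5
    expect_equal(tr@ck, c(3 / 5, 1 / 5))
    expect_identical(coreSubset(tr), "A")       # first c_k above 0.3
    expect_identical(residualGenes(tr), c("B", "C"))

    # the c_k sequence is non-monotone here (0.6 then 0.2); the smallest-k
    # rule must not assume monotonicity
    tr2 <- reduceSet(res, coll, "S", cutoff = 0.5)
    expect_identical(tr2@chosenK, 1L)

    # exhaustion: no c_k above 0.7 -> the whole set is the core
    tr3 <- reduceSet(res, coll, "S", cutoff = 0.7)
    expect_identical(coreSubset(tr3), c("A", "B", "C"))
    expect_identical(residualGenes(tr3), character(0))
})

test_that("gene ordering: ascending p, ties by |d| descending then id", {
    genes <- c("P", "Q", "R")
    geneStats <- data.frame(gene = genes, d = c(1, -2, 1),
                            meanDiseased = 0, meanControl = 0, s = 1,
                            geneP = c(0.5, 0.5, 0.5), row.names = genes,
                            stringsAsFactors = FALSE)
    res <- .manualSamGs()
    res@geneStats <- geneStats
    res@permD <- cbind(P = c(0, 0, 0, 0), Q = c(0, 0, 0, 0),
                       R = c(0, 0, 0, 0))
    coll <- GeneSetCollection(list(S = c("R", "P", "Q")))
    tr <- reduceSet(res, coll, "S", cutoff = 0.5)
    expect_identical(tr@orderedGenes, c("Q", "P", "R"))
})

test_that("reduceSet validates its inputs", {
    res <- .manualSamGs()
    coll <- GeneSetCollection(list(S = c("A", "B", "C"), tiny = "A"))
    expect_error(reduceSet(res, coll, "S", cutoff = 0), "inside")
    expect_error(reduceSet(res, coll, "S", cutoff = 1), "inside")
    expect_error(reduceSet(res, coll, "tiny", cutoff = 0.3), "fewer than 2")
})

test_that("cutoff tuning prefers low error, then fewer genes", {
    ds <- makeToyDataset(G = 20, n = 24, seed = 7, shift = 3,
                         shiftGenes = c("g01", "g02", "g03"))
    coll <- GeneSetCollection(list(S1 = geneIds(ds)[1:6],
                                   S2 = geneIds(ds)[7:12]))
    res <- samGsPermutation(ds, coll, B = 99, seed = 2)
    tuned <- tuneCutoff(ds, res, coll, sigSets = "S1",
                        grid = c(0.05, 0.45))
    expect_identical(nrow(tuned$table), 2L)
    # larger cutoffs can only enlarge the core; with perfect training
    # separation at both cutoffs the tie goes to the smaller panel
    expect_true(tuned$table$nGenes[1] <= tuned$table$nGenes[2])
    best <- tuned$table[order(tuned$table$error, tuned$table$nGenes,
                              tuned$table$cutoff), ][1, ]
    expect_equal(tuned$cutoff, best$cutoff)
    expect_equal(tuneCutoff(ds, res, coll, "S1", grid = 0.2)$cutoff, 0.2)
    expect_error(tuneCutoff(ds, res, coll, character(0)), "no significant")
})

test_that("end-to-end reduction pipeline: selection, model, reproducibility", {
    ds <- makeToyDataset(G = 30, n = 24, seed = 11, shift = 2.5,
                         shiftGenes = c("g01", "g02", "g03"))
    coll <- GeneSetCollection(list(S1 = geneIds(ds)[1:6],
                                   S2 = geneIds(ds)[7:12],
                                   S3 = geneIds(ds)[13:18]))
    fit <- samgsrSelect(ds, coll, B = 99, seed = 5)
    expect_s4_class(fit, "PipelineResult")
    expect_true(length(fit@selectedGenes) >= 1)
    expect_true(all(fit@selectedGenes %in% fit@candidateGenes))
    expect_s4_class(fit@model, "PlattSvmModel")
    pr <- predictBeliefs(fit@model, ds)
    expect_true(all(beliefs(pr) > 0 & beliefs(pr) < 1))

    fit2 <- samgsrSelect(ds, coll, B = 99, seed = 5)
    expect_identical(fit2@selectedGenes, fit@selectedGenes)
    expect_identical(fit2@manifest$cutoff, fit@manifest$cutoff)
})

test_that("zero significant sets yields an explicit empty selection", {
    ds <- makeToyDataset(G = 12, n = 12, seed = 21)  # pure noise
    coll <- GeneSetCollection(list(S1 = geneIds(ds)[1:5],
                                   S2 = geneIds(ds)[6:10]))
    # with B = 99 the smallest attainable p is 1/100, so a threshold of
    # 0.005 cannot be met: the empty path is exercised deterministically
    fit <- samgsrSelect(ds, coll, B = 99, seed = 1, setPThreshold = 0.005)
    expect_identical(fit@selectedGenes, character(0))
    expect_null(fit@model)
    expect_identical(fit@significantSets, character(0))
})
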