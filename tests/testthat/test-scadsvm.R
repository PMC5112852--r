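test_that("SCAD penalty closed forms and shape", {
    expect_equal(scadPenalty(0, 1), 0)
    expect_equal(scadPenalty(2, 1), 9.8 / 5.4)    # middle branch, alpha 3.7
    expect_equal(scadPenalty(10, 1), 2.35)        # flat branch: 4.7/2
    expect_equal(scadPenalty(-2, 1), scadPenalty(2, 1))  # even
    w <- seq(0, 6, by = 0.01)
    expect_true(all(diff(scadPenalty(w, 1.3, 3.7)) >= 0))  # nondecreasing
    expect_error(scadPenalty(1, lambda = 0), "positive")
    expect_error(scadPenalty(1, lambda = 1, alpha = 2), "> 2")
})

test_that("SCAD derivative: LASSO region, linear decay, plateau", {
    expect_equal(scadDerivative(0, 2), 2)
    expect_equal(scadDerivative(2, 1), 1.7 / 2.7)
    expect_equal(scadDerivative(5, 1), 0)
    expect_error(scadDerivative(-1, 1), "nonnegative")
})

test_that("compiled and reference subproblem solvers agree", {
    set.seed(31)
    for (rep in 1:5) {
        n <- 20; p <- 6
        X <- matrix(rnorm(n * p), n, p)
        y <- rep(c(1, -1), each = n / 2)
        u <- runif(p, 0.1, 2)
        rRes <- GSReduce:::.wl1HingeCDr(X, y, u, rep(0, p), 0, 0.5,
                                        maxCycles = 5000, tol = 1e-9)
        cRes <- GSReduce:::.wl1HingeCDcpp(X, y, u, rep(0, p), 0, 0.5,
                                          5000L, 1e-9)
        expect_equal(rRes$w, cRes$w, tolerance = 1e-6)
        expect_equal(rRes$b, cRes$b, tolerance = 1e-6)
    }
})

test_that("total shrinkage at huge lambda; majority class carries the intercept", {
    set.seed(8)
    m <- matrix(rnorm(10 * 12), 10, 12,
                dimnames = list(sprintf("g%02d", 1:10), sprintf("s%02d", 1:12)))
    ds <- ExpressionDataset(m, rep(c("diseased", "control"), c(8, 4)))
    fit <- scadSvmFit(ds, lambda = 2^14)
    expect_true(all(fit@w == 0))
    expect_gt(fit@b, 0)  # majority class is diseased (+1)
    expect_identical(selectedGenes(fit), character(0))
})

test_that("vanishing penalty recovers an unpenalized linear separator", {
    set.seed(9)
    n <- 20
    x1 <- c(rnorm(n / 2, 3), rnorm(n / 2, -3))
    x2 <- rnorm(n)
    m <- rbind(gA = x1, gB = x2)
    colnames(m) <- sprintf("s%02d", 1:n)
    y <- rep(c("diseased", "control"), each = n / 2)
    ds <- ExpressionDataset(m, y)
    fit <- scadSvmFit(ds, lambda = 1e-6)
    svmRef <- e1071::svm(t(m), factor(y, levels = c("control", "diseased")),
                         kernel = "linear", cost = 1, scale = TRUE)
    refCall <- as.character(predict(svmRef, t(m)))
    myCall <- ifelse(decisionValues(fit, ds) > 0, "diseased", "control")
    expect_identical(unname(myCall), refCall)
    expect_gt(fit@w[["gA"]], 0)  # separating gene dominates, correct sign
})

test_that("LLA objective is non-increasing and sparsity is exact", {
    set.seed(12)
    m <- matrix(rnorm(15 * 30), 15, 30,
                dimnames = list(sprintf("g%02d", 1:15), sprintf("s%02d", 1:30)))
    m["g01", 1:15] <- m["g01", 1:15] + 3
    ds <- ExpressionDataset(m, rep(c("diseased", "control"), each = 15))
    fit <- scadSvmFit(ds, lambda = 4)
    expect_true(all(diff(fit@objective) <= 1e-8))
    expect_true(fit@w[["g01"]] != 0)
    expect_true(sum(fit@w == 0) > 0)
    # weights below the hard-zero tolerance are exactly zero, not tiny
    expect_true(all(fit@w[fit@w != 0] != 0 & abs(fit@w[fit@w != 0]) >= 1e-6))
})

test_that("beliefs are proper probabilities, monotone in the decision value", {
    set.seed(13)
    m <- matrix(rnorm(6 * 16), 6, 16,
                dimnames = list(sprintf("g%02d", 1:6), sprintf("s%02d", 1:16)))
    m["g01", 1:8] <- m["g01", 1:8] + 2
    ds <- ExpressionDataset(m, rep(c("diseased", "control"), each = 8))
    fit <- scadSvmFit(ds, lambda = 1)
    pr <- predictBeliefs(fit, ds)
    b <- beliefs(pr)
    expect_true(all(b > 0 & b < 1))
    expect_equal(unname(rowSums(b)), rep(1, nrow(b)))
    f <- decisionValues(fit, ds)
    ord <- order(f)
    expect_true(all(diff(b[ord, "diseased"]) >= 0))  # sigmoid monotone
})

test_that("lambda tuning: singleton grid, sparser-model tie-break, fold guards", {
    set.seed(14)
    m <- matrix(rnorm(8 * 30), 8, 30,
                dimnames = list(sprintf("g%02d", 1:8), sprintf("s%02d", 1:30)))
    m["g01", 1:15] <- m["g01", 1:15] + 4
    ds <- ExpressionDataset(m, rep(c("diseased", "control"), each = 15))
    tuned <- tuneLambda(ds, lambdaGrid = 0.5, folds = 3, seed = 2)
    expect_equal(tuned$lambda, 0.5)
    tuned2 <- tuneLambda(ds, lambdaGrid = 2^(-2:6), folds = 3, seed = 2)
    tab <- tuned2$table
    expect_equal(tuned2$lambda,
                 max(tab$lambda[tab$cvError == min(tab$cvError)]))
    # 2 samples per class: any 2-fold split leaves a single sample per
    # class in training, which the fold guard must reject
    tiny <- ExpressionDataset(
        matrix(rnorm(8), 2, 4, dimnames = list(c("gA", "gB"), paste0("s", 1:4))),
        c(1, 1, -1, -1))
    expect_error(tuneLambda(tiny, lambdaGrid = 1, folds = 2, seed = 1),
                 "fold")
})

test_that("prediction refuses datasets missing model genes", {
    set.seed(15)
    m <- matrix(rnorm(4 * 12), 4, 12,
                dimnames = list(paste0("g", 1:4), paste0("s", 1:12)))
    ds <- ExpressionDataset(m, rep(c(1, -1), each = 6))
    fit <- scadSvmFit(ds, lambda = 1)
    dsSmall <- ExpressionDataset(m[1:2, ], rep(c(1, -1), each = 6))
    expect_error(predictBeliefs(fit, dsSmall), "absent")
})
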