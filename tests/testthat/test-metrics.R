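.predFrom <- function(pDiseased, truth) {
    PredictionSet(cbind(control = 1 - pDiseased, diseased = pDiseased),
                  truth, classNames = c("control", "diseased"))
}

test_that("error rate counts argmax mismatches deterministically", {
    p <- .predFrom(c(0.9, 0.8, 0.2), c("diseased", "diseased", "control"))
    expect_equal(errorRate(p), 0)
    expect_equal(errorRate(.predFrom(c(0.1, 0.9), c("diseased", "control"))), 1)
    p10 <- .predFrom(c(rep(0.9, 7), rep(0.9, 3)),
                     c(rep("diseased", 7), rep("control", 3)))
    expect_equal(errorRate(p10), 0.3)
    # exact tie: first class (control) wins
    expect_equal(errorRate(.predFrom(0.5, "control")), 0)
    expect_equal(errorRate(.predFrom(0.5, "diseased")), 1)
})

test_that("Brier score closed forms", {
    perfect <- .predFrom(c(1, 0), c("diseased", "control"))
    expect_equal(gbs(perfect), 0)
    expect_equal(gbs(.predFrom(c(0.5, 0.5, 0.5), c("diseased", "control",
                                                   "diseased"))), 0.25)
    # worked 2-sample case: truths (control, diseased), beliefs rows
    # (0.8, 0.2) and (0.4, 0.6): (0.08 + 0.32) / 4 = 0.1
    p <- PredictionSet(rbind(c(0.8, 0.2), c(0.4, 0.6)), c(1L, 2L),
                       c("control", "diseased"))
    expect_equal(gbs(p), 0.1)
    antiperfect <- .predFrom(c(0, 1), c("diseased", "control"))
    expect_equal(gbs(antiperfect), 1)
})

test_that("belief confusion metric averages true-class beliefs per class", {
    expect_equal(bcm(.predFrom(c(1, 0), c("diseased", "control"))), 1)
    expect_equal(bcm(.predFrom(c(0.5, 0.5), c("diseased", "control"))), 0.5)
    # class-1 (diseased) beliefs 0.8, 0.6; class-2 belief-for-control 0.9
    p <- .predFrom(c(0.8, 0.6, 0.1),
                   c("diseased", "diseased", "control"))
    expect_equal(bcm(p), (0.7 + 0.9) / 2)
    expect_warning(bcm(.predFrom(c(0.9, 0.8), c("diseased", "diseased"))),
                   "omitted")
})

test_that("average-precision AUPR on hand-ranked lists", {
    # perfect ranking in both classes
    p <- .predFrom(c(0.9, 0.8, 0.2, 0.1),
                   c("diseased", "diseased", "control", "control"))
    expect_equal(aupr(p), 1)
    # diseased class: beliefs 0.9(+), 0.8(-), 0.7(+), 0.1(-):
    # precisions at the positives are 1/1 and 2/3 -> AP = 5/6
    expect_equal(GSReduce:::.averagePrecision(
        c(0.9, 0.8, 0.7, 0.1), c(TRUE, FALSE, TRUE, FALSE)), 5 / 6)
    # single positive ranked last among m samples -> AP = 1/m
    expect_equal(GSReduce:::.averagePrecision(
        c(0.9, 0.8, 0.7, 0.2), c(FALSE, FALSE, FALSE, TRUE)), 1 / 4)
    expect_warning(aupr(.predFrom(c(0.5, 0.5), c("diseased", "control"))),
                   "ties")
})

test_that("metrics are invariant to sample order", {
    set.seed(77)
    pd <- runif(12)
    truth <- sample(c("control", "diseased"), 12, replace = TRUE,
                    prob = c(0.5, 0.5))
    truth[1:2] <- c("control", "diseased")   # both classes present
    p <- .predFrom(pd, truth)
    perm <- sample(12)
    p2 <- .predFrom(pd[perm], truth[perm])
    expect_equal(errorRate(p2), errorRate(p))
    expect_equal(gbs(p2), gbs(p))
    expect_equal(bcm(p2), bcm(p))
    expect_equal(aupr(p2), aupr(p))
})

test_that("random beliefs give near-0.5 macro AUPR on balanced data", {
    # average precision carries a positive O(1/n) bias under random
    # ranking, so the 0.5 expectation is checked at a sample size where
    # that bias is negligible
    set.seed(101)
    vals <- replicate(200, {
        pd <- runif(100)
        aupr(.predFrom(pd, rep(c("diseased", "control"), each = 50)))
    })
    expect_lt(abs(mean(vals) - 0.5), 0.05)
})

test_that("prediction-set validity is enforced", {
    expect_error(PredictionSet(rbind(c(0.7, 0.2)), 1L, c("a", "b")),
                 "sum to 1")
    expect_error(PredictionSet(rbind(c(0.5, 0.5)), 3L, c("a", "b")),
                 "address")
    expect_error(PredictionSet(rbind(c(0.5, 0.5)), "c", c("a", "b")),
                 "not found")
})
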