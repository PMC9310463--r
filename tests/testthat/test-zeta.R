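test_that("Z transform uses negative-control moments per column", {
    m <- matrix(c(1, 2, 3), 3, 1, dimnames = list(c("a", "b", "c"), "r1"))
    ## second column keeps the curve range usable downstream
    m <- cbind(m, r2 = c(0, 5, -5))
    se <- makeScreen(m, c("negative_control", "sample",
                          "negative_control"))
    z <- zScores(zTransform(se))
    ## negatives {1, 3}: mu = 2, sample sd = sqrt(2)
    expect_equal(z[, "r1"], c(a = -1, b = 0, c = 1) / sqrt(2),
                 tolerance = 1e-12)

    ## negative-control rows self-normalise: per-column mean 0, sd 1
    set.seed(11)
    big <- makeScreen(matrix(rnorm(200), 20, 10),
                      rep("negative_control", 20))
    zb <- zScores(zTransform(big))
    expect_equal(unname(colMeans(zb)), rep(0, 10), tolerance = 1e-12)
    expect_equal(unname(apply(zb, 2, sd)), rep(1, 10), tolerance = 1e-12)

    ## constant column among negatives is dropped with a warning
    mc <- cbind(big0 = c(1, 1, 5), r2 = c(0, 2, 9))
    rownames(mc) <- c("n1", "n2", "s1")
    sec <- makeScreen(mc, c("negative_control", "negative_control",
                            "sample"))
    expect_warning(out <- zTransform(sec), "constant")
    expect_identical(colnames(out), "r2")

    expect_error(zTransform(makeScreen(mc, c("negative_control",
                                             "sample", "sample"))),
                 ">= 2")
})

test_that("survival curves count readouts beyond each cutoff", {
    ## 10 readouts, 3 with Z = 5; at cutoff 4 the fraction is 0.3
    z <- rbind(hit = c(rep(5, 3), rep(0, 7)),
               dull = rep(1.5, 10),
               wide = c(-8, 8, rep(0, 8)))
    cs <- buildZetaCurves(z, "positive", nBins = 100)
    i4 <- which.min(abs(curveCutoffs(cs) - 4))
    expect_equal(unname(curveMatrix(cs)["hit", i4]), 0.3)

    ## everything below |Z| = 2 never survives, in either direction
    expect_true(all(curveMatrix(cs)["dull", ] == 0))
    csn <- buildZetaCurves(z, "negative")
    expect_true(all(curveMatrix(csn)["dull", ] == 0))

    ## survival is monotone in cutoff stringency
    P <- curveMatrix(cs)
    expect_true(all(diff(t(P)) <= 1e-12))

    ## range must exceed the |Z| = 2 noise region
    expect_error(buildZetaCurves(matrix(rep(1, 100), 10), "positive"),
                 "noise threshold")
})

test_that("zeta area sums match the scalar brute-force oracle to 1e-12", {
    set.seed(5)
    cutoffs <- seq(2, 12, length.out = 101)
    for (rep in 1:100) {
        P <- sort(runif(101), decreasing = TRUE)
        S <- sort(runif(101, 0, 0.5), decreasing = TRUE)
        cs <- makeCurves(matrix(P, 1), cutoffs)
        bd <- makeBoundary(S, cutoffs)
        for (w in c(TRUE, FALSE)) {
            expect_equal(unname(zetaScores(cs, bd, weighted = w)),
                         zetaBruteForce(P, S, cutoffs, weighted = w),
                         tolerance = 1e-12)
            expect_equal(unname(zetaScores(cs, NULL, weighted = w)),
                         zetaBruteForce(P, NULL, cutoffs, weighted = w),
                         tolerance = 1e-12)
        }
    }
})

test_that("flat curve on [2,12] integrates to 5 without a boundary", {
    cutoffs <- seq(2, 12, length.out = 101)
    cs <- makeCurves(matrix(0.5, 1, 101), cutoffs)
    expect_equal(unname(zetaScores(cs, NULL, weighted = FALSE)), 5,
                 tolerance = 1e-12)
    ## a curve lying on the boundary scores zero
    bd <- makeBoundary(rep(0.5, 101), cutoffs)
    expect_equal(unname(zetaScores(cs, bd, weighted = FALSE)), 0)
})

test_that("zeta invariants: boundary subtraction, permutation, monotonicity", {
    set.seed(9)
    z <- matrix(rnorm(30 * 40, 0, 2), 30, 40,
                dimnames = list(sprintf("g%02d", 1:30), NULL))
    cs <- buildZetaCurves(z, "positive")
    S <- sort(runif(101, 0, 0.2), decreasing = TRUE)
    bd <- makeBoundary(S, curveCutoffs(cs))
    zNo <- zetaScores(cs, NULL)
    zSvm <- zetaScores(cs, bd)
    expect_true(all(zSvm >= 0))
    expect_true(all(zNo >= zSvm - 1e-12))

    ## column permutation leaves every score unchanged
    zp <- z[, sample(ncol(z))]
    expect_equal(zetaScores(buildZetaCurves(zp, "positive"), NULL), zNo,
                 tolerance = 1e-12)

    ## an extra readout beyond every cutoff never decreases zeta
    zAug <- cbind(z, extra = max(abs(z)) + 1)
    grew <- zetaScores(buildZetaCurves(zAug, "positive"), NULL)
    ## compare on the shared scale: recompute the original on the same
    ## cutoff grid as the augmented matrix
    cs2 <- buildZetaCurves(zAug, "positive")
    base <- matrix(0, nrow(z), 101, dimnames = list(rownames(z), NULL))
    for (m in seq_len(101))
        base[, m] <- rowMeans(z >= curveCutoffs(cs2)[m])
    zBase <- zetaScores(makeCurves(base, curveCutoffs(cs2)), NULL)
    expect_true(all(grew >= zBase - 1e-12))
})

test_that("directional scores combine additively", {
    pos <- c(a = 1.2, b = 0.3)
    neg <- c(a = 0.8, b = 0)
    comb <- combineDirections(pos, neg)
    expect_equal(comb$zeta, c(2.0, 0.3))
    sep <- combineDirections(pos, neg, combine = FALSE)
    expect_null(sep$zeta)
    expect_equal(sep$zeta_pos + sep$zeta_neg, c(2.0, 0.3))
})
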