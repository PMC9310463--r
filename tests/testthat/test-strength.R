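test_that("Screen Strength equals an independent per-gene recount", {
    ## 10 genes, 5 non-expressors: bFDR = 0.5; a cutoff catching 4 hits
    ## of which 1 non-expressor gives aFDR = 0.25 and SS = 0.5
    zeta <- c(s1 = 10, s2 = 9, s3 = 8, ne1 = 7, s4 = 2, ne2 = 1.5,
              ne3 = 1, s5 = 0.5, ne4 = 0.2, ne5 = 0)
    cls <- setNames(ifelse(startsWith(names(zeta), "ne"),
                           "non_expressor", "sample"), names(zeta))
    ss <- suppressWarnings(screenStrength(zeta, cls))  # < 20 non-expressors
    expect_equal(baselineFDR(ss), 0.5)
    tab <- ssTable(ss)
    row4 <- tab[tab$n_hits == 4, ][1, ]
    expect_equal(row4$aFDR, 0.25)
    expect_equal(row4$SS, 0.5)

    ## brute-force recount over genes at every cutoff
    for (i in seq_len(nrow(tab))) {
        hits <- zeta >= tab$cutoff[i]
        expect_identical(tab$n_hits[i], sum(hits))
        expect_equal(tab$SS[i],
                     1 - mean(cls[hits] == "non_expressor") / 0.5)
    }

    expect_error(screenStrength(zeta, setNames(rep("sample", 10),
                                               names(zeta))),
                 "non-expressors")
})

test_that("balance points sit at plateau onsets of constructed curves", {
    ## rise to 0.8, plateau, rise to 0.95, plateau: exactly two BPs
    cut <- seq(0, 1, length.out = 100)
    ss <- c(seq(0, 0.8, length.out = 30), rep(0.8, 25),
            seq(0.8, 0.95, length.out = 20), rep(0.95, 25))
    df <- data.frame(cutoff = cut, n_hits = 1000 - seq_len(100),
                     n_ne_hits = 0, aFDR = 0, SS = ss)
    bps <- findBalancePoints(df)
    expect_length(bps, 2)
    ## onsets at cutoffs 30 and 75, within the smoothing window
    expect_lt(abs(bps[1] - cut[30]), 5 * diff(cut)[1] + 1e-9)
    expect_lt(abs(bps[2] - cut[75]), 5 * diff(cut)[1] + 1e-9)

    ## strictly rising curve has no plateau
    lin <- data.frame(cutoff = cut, n_hits = 1000 - seq_len(100),
                      n_ne_hits = 0, aFDR = 0,
                      SS = seq(0, 1, length.out = 100))
    expect_length(findBalancePoints(lin), 0)
})

test_that("permuted score rankings yield no balance point", {
    set.seed(31)
    sim <- simulateScreen(nReadouts = 80, nRegulators = 150,
                          nNonExpressors = 60, seed = 31)
    se <- zTransform(sim$screen)
    res <- computeZeta(se, svm = TRUE, seed = 31)
    ann <- perturbClass(se)
    ## the real ranking has at least one balance point ...
    expect_gte(length(balancePoints(screenStrength(res$scores, ann))), 1)
    ## ... permuted rankings lose it in at least 4 of 5 permutations
    z <- setNames(res$scores$zeta, res$scores$gene_id)
    noBp <- replicate(5, {
        zp <- setNames(sample(z), names(z))
        ssp <- suppressWarnings(screenStrength(zp, ann))
        length(findBalancePoints(ssp)) == 0
    })
    expect_gte(sum(noBp), 4)
})

test_that("FPL cutoffs control the non-expressor exceedance fraction", {
    set.seed(13)
    nez <- runif(100)
    zeta <- c(setNames(nez, sprintf("ne%03d", 1:100)),
              setNames(runif(100, 2, 3), sprintf("s%03d", 1:100)))
    cls <- setNames(rep(c("non_expressor", "sample"), each = 100),
                    names(zeta))
    cut <- fplCutoffs(zeta, cls, levels = c(0.05, 1.0))
    ## order-statistic check: at most 5 of 100 non-expressors at or above
    expect_lte(sum(nez >= cut[["0.05"]]), 5)
    expect_gt(cut[["0.05"]], sort(nez, decreasing = TRUE)[6])
    ## level 1.0 filters nothing
    expect_equal(cut[["1"]], min(zeta))
    expect_error(fplCutoffs(zeta, cls, levels = 1.5), "levels")

    ## fully separable scores: smallest positive grid value wins
    zsep <- c(setNames(rep(0, 30), sprintf("ne%02d", 1:30)),
              setNames(rep(5, 30), sprintf("s%02d", 1:30)))
    csep <- setNames(rep(c("non_expressor", "sample"), each = 30),
                     names(zsep))
    grid <- seq(0, 5, length.out = 100)
    cs <- fplCutoffs(zsep, csep, levels = 0.05, grid = grid)
    expect_equal(cs[["0.05"]], grid[2])
})

test_that("hit calling respects BP and FPL modes", {
    zeta <- setNames(c(5, 3, 1.5, 0.5, 0.1), paste0("g", 1:5))
    cls <- setNames(c(rep("sample", 4), "non_expressor"), names(zeta))
    curve <- new("ScreenStrengthCurve",
                 curve = data.frame(cutoff = 1:5, n_hits = 5:1,
                                    n_ne_hits = 0, aFDR = 0, SS = 0.5),
                 bFDR = 0.2, balancePoints = c(1, 4),
                 fpl = c("0.05" = 2))
    hits <- callHits(zeta, curve, cls, mode = "BP1")
    expect_identical(hits$call[hits$gene_id == "g1"], "high_confidence")
    expect_identical(hits$call[hits$gene_id == "g2"], "candidate")
    expect_identical(hits$call[hits$gene_id == "g4"], "none")
    expect_false(is.unsorted(rev(hits$zeta)))

    fplHits <- callHits(zeta, curve, cls, mode = "FPL:0.05")
    expect_identical(sum(fplHits$call != "none"), 2L)

    curve1 <- curve; curve1@balancePoints <- 1
    expect_error(callHits(zeta, curve1, cls, mode = "BP2"), "FPL")

    ## all genes below the cutoff: a valid empty hit list
    none <- callHits(zeta, curve, cls, mode = "manual:10")
    expect_identical(sum(none$call != "none"), 0L)
})
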