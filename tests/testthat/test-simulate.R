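test_that("screen simulation is deterministic and class-faithful", {
    a <- simulateScreen(nReadouts = 40, nRegulators = 30,
                        nNonExpressors = 20, nOfftargetPlants = 1,
                        seed = 12)
    b <- simulateScreen(nReadouts = 40, nRegulators = 30,
                        nNonExpressors = 20, nOfftargetPlants = 1,
                        seed = 12)
    expect_identical(screenValues(a$screen), screenValues(b$screen))
    expect_identical(a$library@guides, b$library@guides)
    expect_identical(a$secondary, b$secondary)
    c <- simulateScreen(nReadouts = 40, nRegulators = 30,
                        nNonExpressors = 20, seed = 13)
    expect_false(identical(screenValues(a$screen),
                           screenValues(c$screen)))

    tab <- table(perturbClass(a$screen))
    expect_identical(as.integer(tab[c("negative_control", "non_expressor",
                                      "positive_control", "sample")]),
                     c(30L, 20L, 10L, 30L))
})

test_that("simulated negative controls self-normalise under Z transform", {
    sim <- simulateScreen(nReadouts = 60, nRegulators = 40,
                          nNonExpressors = 30, nNegControls = 40,
                          seed = 15)
    z <- zScores(zTransform(sim$screen))
    neg <- rowsOfClass(sim$screen, "negative_control")
    mu <- colMeans(z[neg, ])
    expect_true(all(abs(mu) <= 3 / sqrt(length(neg))))
})

test_that("a null screen (zero effect) loses its balance point", {
    simNull <- simulateScreen(nReadouts = 60, nRegulators = 120,
                              nNonExpressors = 60, effectSize = 0,
                              seed = 18)
    se <- zTransform(simNull$screen)
    res <- suppressWarnings(computeZeta(se, svm = TRUE, seed = 18))
    ss <- suppressWarnings(screenStrength(res$scores, perturbClass(se)))
    expect_length(balancePoints(ss), 0)
})

test_that("droplet classes are generated as described", {
    a <- simulateDroplets(nHighQuality = 300, nEmpty = 300,
                          nBroken = 150, nStrippedNuclei = 100,
                          nGenes = 400, nMitoGenes = 10,
                          nRiboGenes = 30, seed = 25)
    b <- simulateDroplets(nHighQuality = 300, nEmpty = 300,
                          nBroken = 150, nStrippedNuclei = 100,
                          nGenes = 400, nMitoGenes = 10,
                          nRiboGenes = 30, seed = 25)
    expect_identical(as.matrix(a$counts), as.matrix(b$counts))

    tab <- cellQCTable(a$counts, a$genes,
                       cutoff = 0)        # metrics only, no density fit
    byClass <- split(tab, a$labels)
    ## broken cells keep elevated mitochondrial share by construction
    expect_gt(median(byClass$broken$pct_mt),
              median(byClass$high_quality$pct_mt))
    ## stripped nuclei are depleted of both mito and ribo content
    expect_lt(median(byClass$stripped_nucleus$pct_mt),
              median(byClass$high_quality$pct_mt))
    expect_lt(median(byClass$stripped_nucleus$pct_ribo),
              median(byClass$high_quality$pct_ribo))
    ## empty droplets score the lowest zeta of all classes
    med <- vapply(byClass, function(d) median(d$zeta_cell), numeric(1))
    expect_identical(names(which.min(med)), "empty")

    ## MTX output is reproducible byte for byte
    d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
    writeCountsMtx(a$counts, d1)
    writeCountsMtx(b$counts, d2)
    expect_identical(readLines(file.path(d1, "matrix.mtx")),
                     readLines(file.path(d2, "matrix.mtx")))
})

test_that("planted off-target guides are the only flagged ones", {
    flagged <- vapply(1:10, function(s) {
        sim <- simulateScreen(nReadouts = 60, nRegulators = 40,
                              nNonExpressors = 25,
                              nOfftargetPlants = 1, seed = 100 + s)
        se <- zTransform(sim$screen)
        z <- zScores(se)
        pools <- rownames(z)[perturbClass(se) %in%
                             c("sample", "non_expressor")]
        rpt <- flagOfftargets(z, sim$library, hits = pools,
                              secondary = sim$secondary)
        identical(unique(rpt$suspect_sirna_id), sim$planted$sirna_id)
    }, logical(1))
    expect_gte(mean(flagged), 0.9)
})
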