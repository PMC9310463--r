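test_that("response similarity is Pearson correlation over readouts", {
    set.seed(17)
    z <- matrix(rnorm(36), 3, 12,
                dimnames = list(c("a", "b", "c"), NULL))
    z["b", ] <- -z["a", ]
    expect_equal(responseSimilarity(z, "a", "a"), 1)
    expect_equal(responseSimilarity(z, "a", "b"), -1)
    ## textbook formula, computed by hand from sums
    x <- z["a", ]; y <- z["c", ]
    manual <- sum((x - mean(x)) * (y - mean(y))) /
        sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(responseSimilarity(z, "a", "c"), manual,
                 tolerance = 1e-12)
    zshort <- z[, 1:5]
    expect_error(responseSimilarity(zshort, "a", "c"), "10")
    zflat <- z; zflat["c", ] <- 2
    expect_error(responseSimilarity(zflat, "a", "c"), "variance")
})

test_that("complementarity scan finds planted islands exactly", {
    set.seed(23)
    tx <- randDna(400)
    ## guide fully reverse-complementary to a transcript 19-mer
    g19 <- revcompChr(substr(tx, 101, 119))
    full <- complementarityScan(g19, tx, minLen = 19)
    expect_identical(nrow(full), 1L)
    expect_identical(full$length[1], 19L)
    expect_identical(c(full$t_start[1], full$t_end[1]), c(101L, 119L))

    ## planted 11-nt island inside an otherwise non-matching guide
    repeat {
        guide <- randDna(21)
        island <- substr(tx, 201, 211)
        guide <- paste0(substr(guide, 1, 5), revcompChr(island),
                        substr(guide, 17, 21))
        hits <- complementarityScan(guide, tx, minLen = 11)
        ## rejection-sample flanks that accidentally extend or duplicate
        ## the planted match
        if (nrow(hits) == 1 && hits$length[1] == 11) break
    }
    expect_identical(hits$length[1], 11L)
    expect_identical(c(hits$t_start[1], hits$t_end[1]), c(201L, 211L))

    ## short input warns and returns an empty result
    expect_warning(none <- complementarityScan("ACGUACG", tx), "minLen")
    expect_identical(nrow(none), 0L)
})

test_that("scan agrees with the quadratic common-substring oracle", {
    set.seed(29)
    nFlag <- 0
    for (i in 1:300) {
        guide <- randDna(21)
        tx <- randDna(300)
        hits <- complementarityScan(guide, tx, minLen = 1)
        best <- if (nrow(hits)) max(hits$length) else 0L
        expect_identical(best, lcsLength(revcompChr(guide), tx))
        if (best >= 11) nFlag <- nFlag + 1
    }
    ## random 21-nt guides essentially never reach 11 nt by chance
    expect_lte(nFlag, 3)
})

test_that("single-siRNA attribution separates related function from off-target", {
    set.seed(37)
    M <- 50
    base <- rnorm(M)
    primary <- rbind(poolB = base + rnorm(M, 0, 0.2))
    colnames(primary) <- sprintf("r%02d", 1:M)
    mk <- function(nLike, nNoise) {
        n <- nLike + nNoise
        rows <- matrix(rnorm(n * M), n, M)
        if (nLike > 0)
            rows[seq_len(nLike), ] <- rep(base, each = nLike) +
                rnorm(nLike * M, 0, 0.2)
        rownames(rows) <- sprintf("s%d", seq_len(n))
        colnames(rows) <- colnames(primary)
        rows
    }
    related <- attributeToSingleSirna(primary, mk(3, 1),
                                      sprintf("s%d", 1:4), "poolB")
    expect_identical(related$attribution, "related_function")
    off <- attributeToSingleSirna(primary, mk(1, 3),
                                  sprintf("s%d", 1:4), "poolB")
    expect_identical(off$attribution, "off_target_candidate")
    expect_identical(off$suspect, "s1")
    none <- attributeToSingleSirna(primary, mk(0, 4),
                                   sprintf("s%d", 1:4), "poolB")
    expect_identical(none$attribution, "none")
    expect_identical(
        attributeToSingleSirna(primary, mk(0, 4), "missing",
                               "poolB")$attribution,
        "unattributable")
})

test_that("flagging needs both complementarity and correlation", {
    set.seed(41)
    M <- 40
    base <- rnorm(M, 0, 3)
    z <- rbind(GENE = base,
               CORR_ONLY = base + rnorm(M, 0, 0.5),
               COMP_ONLY = rnorm(M, 0, 3),
               BOTH = base + rnorm(M, 0, 0.5))
    colnames(z) <- sprintf("r%02d", 1:M)
    tx <- setNames(randDna(300), "GENE")
    matchGuide <- revcompChr(substr(tx[["GENE"]], 51, 71))
    guides <- data.frame(
        sirna_id = c("CORR_ONLY_s1", "COMP_ONLY_s1", "BOTH_s1"),
        pool_id = c("CORR_ONLY", "COMP_ONLY", "BOTH"),
        guide = c(randDna(21), matchGuide, matchGuide))
    lib <- SirnaLibrary(guides, tx)
    ## only GENE carries a transcript; the others warn and are skipped
    rpt <- suppressWarnings(flagOfftargets(z, lib, hits = rownames(z)))
    expect_identical(rpt$pool_id, "BOTH")
    expect_identical(rpt$offended_gene, "GENE")
    expect_identical(rpt$suspect_sirna_id, "BOTH_s1")
    expect_gte(rpt$match_length, 21L)
    expect_identical(rpt$evidence, "pool")

    ## flagging is directional: the offended gene keeps its own rows
    expect_false("GENE" %in% rpt$pool_id)

    ## a missing transcript skips the pair with a warning
    expect_warning(
        flagOfftargets(z, lib, hits = rownames(z),
                       againstGenes = c("GENE", "NOPE")),
        "NOPE")
})

test_that("removing a flagged non-expressor never lowers Screen Strength", {
    sim <- simulateScreen(nReadouts = 100, nRegulators = 60,
                          nNonExpressors = 40, nOfftargetPlants = 1,
                          seed = 5)
    se <- zTransform(sim$screen)
    res <- computeZeta(se, svm = TRUE, seed = 5)
    ann <- perturbClass(se)
    ss <- screenStrength(res$scores, ann)
    z <- setNames(res$scores$zeta, res$scores$gene_id)
    fpl <- fplCutoffValues(ss)[["0.05"]]
    genes <- names(z)[ann[names(z)] %in% c("sample", "non_expressor")]
    hits <- genes[z[genes] >= fpl]
    expect_true(sim$planted$pool_id %in% hits)
    rpt <- flagOfftargets(se, sim$library, hits,
                          secondary = sim$secondary)
    ## uniquely the planted siRNA is flagged
    expect_identical(unique(rpt$pool_id), sim$planted$pool_id)
    expect_identical(unique(rpt$suspect_sirna_id), sim$planted$sirna_id)
    expect_gte(rpt$match_length[1], 11L)
    grid <- ssTable(ss)$cutoff
    after <- removeOfftargets(res$scores, ann, rpt, cutoffs = grid)
    merged <- merge(ssTable(ss), ssTable(after), by = "cutoff")
    expect_true(all(merged$SS.y >= merged$SS.x - 1e-12))
})
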