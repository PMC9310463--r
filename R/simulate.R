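#' Simulate a two-dimensional perturbation screen
#'
#' Generates a perturbation x readout matrix mimicking a genome-wide pool
#' screen read out on hundreds of functional measurements. Negative
#' controls and non-expressors are pure noise around the per-readout
#' baseline; each regulator adds \code{effectSize} (in measurement units,
#' so about \code{effectSize / noiseSd} Z units) to a random
#' \code{effectFraction} subset of readouts, with signs split by
#' \code{directionBias}; positive controls are replicates of one strong
#' regulator profile, as repeated wells of a reference siRNA would be.
#' Optionally plants off-target artefacts: a non-expressor pool whose
#' primary response copies a regulator's, with one of its four single
#' siRNAs carrying the response in the secondary screen and a 21-nt
#' reverse-complement island to the regulator's transcript in its guide.
#'
#' @param nReadouts number of readout columns (default 300).
#' @param nRegulators true regulators (default 1800).
#' @param effectFraction fraction of readouts a regulator perturbs
#'   (default 0.3).
#' @param effectSize effect in measurement units (default 6).
#' @param directionBias probability a perturbed readout moves in the
#'   positive direction (default 0.5).
#' @param nNonExpressors internal true negatives (default 200).
#' @param nPosControls,nNegControls control rows (defaults 10 and 30).
#' @param noiseSd measurement noise sd (default 1).
#' @param nOfftargetPlants planted off-target pools (default 0); when > 0
#'   a siRNA library and a secondary screen are also generated.
#' @param guidesPerPool single siRNAs per pool in the library (default 4).
#' @param transcriptLength transcript length for the library (default 500).
#' @param seed RNG seed; identical seeds give bit-identical output.
#' @return list: \code{screen} (a \linkS4class{ScreenExperiment}),
#'   \code{truth} (data.frame row_id, role, regulator),
#'   \code{library} (a \linkS4class{SirnaLibrary} or NULL),
#'   \code{secondary} (single-siRNA x readout matrix or NULL),
#'   \code{planted} (data.frame describing the planted off-targets).
#' @export
simulateScreen <- function(nReadouts = 300, nRegulators = 1800,
                           effectFraction = 0.3, effectSize = 6,
                           directionBias = 0.5, nNonExpressors = 200,
                           nPosControls = 10, nNegControls = 30,
                           noiseSd = 1, nOfftargetPlants = 0,
                           guidesPerPool = 4, transcriptLength = 500,
                           seed = 1L) {
    stopifnot(nReadouts >= 1, nRegulators >= 1, noiseSd > 0,
              effectFraction > 0, effectFraction <= 1,
              directionBias >= 0, directionBias <= 1,
              nOfftargetPlants <= nNonExpressors,
              nOfftargetPlants < nRegulators)
    .withSeed(seed, {
        M <- nReadouts
        colBase <- stats::rnorm(M, 0, 0.5)
        ids <- list(reg = sprintf("REG%04d", seq_len(nRegulators)),
                    ne = sprintf("NE%04d", seq_len(nNonExpressors)),
                    pos = sprintf("POS%02d", seq_len(nPosControls)),
                    neg = sprintf("NEG%02d", seq_len(nNegControls)))
        nEff <- max(1L, round(effectFraction * M))
        ## deterministic effect pattern per regulator (readout subset and
        ## direction signs); noise is added on top
        patterns <- matrix(0, nRegulators, M)
        for (i in seq_len(nRegulators)) {
            cols <- sample.int(M, nEff)
            signs <- ifelse(stats::runif(nEff) < directionBias, 1, -1)
            patterns[i, cols] <- effectSize * signs
        }
        noise <- function(n) matrix(stats::rnorm(n * M, 0, noiseSd), n, M)
        reg <- sweep(patterns + noise(nRegulators), 2, colBase, "+")
        ne <- sweep(noise(nNonExpressors), 2, colBase, "+")
        neg <- sweep(noise(nNegControls), 2, colBase, "+")
        ## positive controls replicate the first regulator's pattern
        pos <- sweep(matrix(rep(patterns[1, ], each = nPosControls),
                            nPosControls, M) + noise(nPosControls),
                     2, colBase, "+")
        planted <- data.frame(pool_id = character(0),
                              sirna_id = character(0),
                              source_regulator = character(0),
                              match_start = integer(0),
                              match_end = integer(0))
        lib <- NULL
        secondary <- NULL
        if (nOfftargetPlants > 0) {
            alph <- c("A", "C", "G", "T")
            randSeq <- function(n, len) vapply(seq_len(n), function(i)
                paste(sample(alph, len, replace = TRUE), collapse = ""),
                character(1))
            allPools <- c(ids$reg, ids$ne)
            guides <- data.frame(
                sirna_id = paste0(rep(allPools, each = guidesPerPool), "_s",
                                  seq_len(guidesPerPool)),
                pool_id = rep(allPools, each = guidesPerPool),
                guide = randSeq(length(allPools) * guidesPerPool, 21))
            transcripts <- randSeq(length(allPools), transcriptLength)
            names(transcripts) <- allPools
            ## secondary screen: singles of a pool reproduce the pool's
            ## response (on-target); planted singles copy the regulator
            secondary <- matrix(stats::rnorm(nrow(guides) * M, 0, noiseSd),
                                nrow(guides), M,
                                dimnames = list(guides$sirna_id, NULL))
            for (gidx in seq_len(nrow(guides))) {
                p <- guides$pool_id[gidx]
                if (startsWith(p, "REG"))
                    secondary[gidx, ] <- secondary[gidx, ] +
                        patterns[match(p, ids$reg), ]
            }
            for (k in seq_len(nOfftargetPlants)) {
                nePool <- ids$ne[k]
                srcReg <- ids$reg[k + 1L]   # regulator 1 backs positives
                ri <- match(srcReg, ids$reg)
                ## the pool inherits the regulator's response
                ne[k, ] <- patterns[ri, ] + stats::rnorm(M, 0, noiseSd) +
                    colBase
                ## exactly one single siRNA carries the response ...
                sid <- paste0(nePool, "_s1")
                secondary[sid, ] <- patterns[ri, ] +
                    stats::rnorm(M, 0, noiseSd)
                ## ... and a planted 21-nt reverse-complement island to
                ## the regulator's transcript
                pos0 <- sample.int(transcriptLength - 21L, 1)
                island <- substr(transcripts[[srcReg]], pos0, pos0 + 20L)
                guides$guide[guides$sirna_id == sid] <-
                    as.character(Biostrings::reverseComplement(
                        Biostrings::DNAString(island)))
                planted <- rbind(planted, data.frame(
                    pool_id = nePool, sirna_id = sid,
                    source_regulator = srcReg,
                    match_start = pos0, match_end = pos0 + 20L))
            }
            lib <- SirnaLibrary(guides, transcripts)
        }
        values <- rbind(reg, ne, pos, neg)
        rownames(values) <- c(ids$reg, ids$ne, ids$pos, ids$neg)
        colnames(values) <- sprintf("RD%03d", seq_len(M))
        if (!is.null(secondary)) colnames(secondary) <- colnames(values)
        ann <- data.frame(
            row_id = rownames(values),
            class = c(rep("sample", nRegulators),
                      rep("non_expressor", nNonExpressors),
                      rep("positive_control", nPosControls),
                      rep("negative_control", nNegControls)))
        truth <- data.frame(
            row_id = rownames(values),
            role = c(rep("regulator", nRegulators),
                     rep("non_expressor", nNonExpressors),
                     rep("positive_control", nPosControls),
                     rep("negative_control", nNegControls)))
        truth$regulator <- truth$role == "regulator"
        list(screen = ScreenExperiment(values, ann), truth = truth,
             library = lib, secondary = secondary, planted = planted)
    })
}

#' Simulate droplet single-cell count data with quality classes
#'
#' Four droplet classes over a shared gene expression profile (log-normal
#' gene weights, with the mitochondrial and ribosomal gene groups fixed at
#' realistic count shares): high-quality cells (negative-binomial counts
#' at full depth, moderate mitochondrial share), empty droplets (shallow
#' Poisson counts from the ambient pool released by lysed cells), broken
#' cells, and stripped nuclei (mitochondrial and ribosomal content
#' strongly depleted at reduced depth). Broken cells leak cytoplasmic
#' mRNA selectively: abundant transcripts sit mostly in the cytoplasm and
#' are lost in proportion to the cell's lysis severity, low-copy (largely
#' nuclear) transcripts and the mitochondrial genes are retained. Total
#' counts therefore stay moderate and the mitochondrial share rises,
#' while the number of detected genes barely moves - which is what makes
#' nFeature a weak discriminator for this class. Every droplet, not only
#' the empty ones, additionally captures ambient RNA.
#'
#' @param nHighQuality,nEmpty,nBroken,nStrippedNuclei class sizes
#'   (defaults 4000, 4000, 1000, 1000).
#' @param nGenes total genes (default 2000), of which \code{nMitoGenes}
#'   (20) are mitochondrial ("MT-") and \code{nRiboGenes} (100) ribosomal
#'   ("RPL"/"RPS").
#' @param mitoShare,riboShare expected fraction of counts on the
#'   mitochondrial / ribosomal gene groups in intact cells (defaults 0.08
#'   and 0.25).
#' @param depthHigh,depthNuclei median cell-derived depths (defaults 4000
#'   and 600); cell depths are log-normal with sdlog \code{depthSpread}
#'   (default 0.25 for high-quality, 0.4 otherwise).
#' @param depthAmbient median ambient depth captured by every droplet
#'   (default 250; empty droplets contain only this component).
#' @param brokenSeverity range of the per-cell lysis severity (fraction
#'   of the cytoplasmic pool lost; default 0.5 to 0.95). A gene's loss is
#'   severity times its cytoplasmic fraction, which grows with abundance
#'   rank from 0.3 to 0.9 (mitochondrial genes 0).
#' @param overdispersion negative-binomial overdispersion (default 0.5;
#'   NB size = 1 / overdispersion).
#' @param depthSpread sdlog of the high-quality depth distribution.
#' @param seed RNG seed; identical seeds give identical matrices.
#' @return list: \code{counts} (sparse gene x cell matrix), \code{labels}
#'   (class per cell), \code{genes} (annotation data.frame).
#' @export
simulateDroplets <- function(nHighQuality = 4000, nEmpty = 4000,
                             nBroken = 1000, nStrippedNuclei = 1000,
                             nGenes = 2000, nMitoGenes = 20,
                             nRiboGenes = 100, depthHigh = 4000,
                             depthNuclei = 600, depthAmbient = 250,
                             brokenSeverity = c(0.5, 0.95),
                             mitoShare = 0.08, riboShare = 0.25,
                             overdispersion = 0.5,
                             depthSpread = 0.12, seed = 1L) {
    stopifnot(nGenes > nMitoGenes + nRiboGenes, overdispersion > 0)
    .withSeed(seed, {
        ids <- c(sprintf("MT-G%02d", seq_len(nMitoGenes)),
                 sprintf("RPL%03d", seq_len(nRiboGenes)),
                 sprintf("GENE%04d", seq_len(nGenes - nMitoGenes -
                                             nRiboGenes)))
        isMito <- startsWith(ids, "MT-")
        isRibo <- startsWith(ids, "RPL")
        w <- stats::rlnorm(nGenes, 0, 1.5)
        w[isMito] <- w[isMito] / sum(w[isMito]) * mitoShare
        w[isRibo] <- w[isRibo] / sum(w[isRibo]) * riboShare
        rest <- !(isMito | isRibo)
        w[rest] <- w[rest] / sum(w[rest]) * (1 - mitoShare - riboShare)
        size <- 1 / overdispersion
        simClass <- function(n, depthMed, sdlog, geneScale,
                             poisson = FALSE, retainMatrix = NULL) {
            if (n == 0)
                return(Matrix::Matrix(0, nGenes, 0, sparse = TRUE))
            depth <- stats::rlnorm(n, log(depthMed), sdlog)
            mu <- (w * geneScale) %o% depth     # genes x cells
            if (!is.null(retainMatrix))
                mu <- mu * retainMatrix
            x <- if (poisson) stats::rpois(length(mu), mu)
                 else stats::rnbinom(length(mu), size = size, mu = mu)
            Matrix::Matrix(matrix(x, nGenes, n), sparse = TRUE)
        }
        one <- rep(1, nGenes)
        nucleiScale <- ifelse(isMito, 0.05, ifelse(isRibo, 0.1, 1))
        ## cytoplasmic fraction grows with abundance rank; mito exempt
        cytoFrac <- 0.3 + 0.6 * (rank(w) - 1) / (nGenes - 1)
        cytoFrac[isMito] <- 0
        severity <- stats::runif(nBroken, brokenSeverity[1],
                                 brokenSeverity[2])
        retain <- 1 - outer(cytoFrac, severity)    # genes x broken cells
        blocks <- list(
            high_quality = simClass(nHighQuality, depthHigh, depthSpread,
                                    one),
            empty = Matrix::Matrix(0, nGenes, nEmpty, sparse = TRUE),
            broken = simClass(nBroken, depthHigh, depthSpread, one,
                              retainMatrix = retain),
            stripped_nucleus = simClass(nStrippedNuclei, depthNuclei, 0.4,
                                        nucleiScale))
        counts <- do.call(cbind, blocks)
        labels <- rep(names(blocks), vapply(blocks, ncol, integer(1)))
        ## every droplet sits in the same ambient soup
        ambient <- simClass(ncol(counts), depthAmbient, 0.4, one,
                            poisson = TRUE)
        counts <- counts + ambient
        colnames(counts) <- sprintf("BC%05d", seq_len(ncol(counts)))
        rownames(counts) <- ids
        list(counts = methods::as(counts, "CsparseMatrix"),
             labels = labels,
             genes = data.frame(gene_id = ids, is_mito = isMito,
                                is_ribo = isRibo))
    })
}
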