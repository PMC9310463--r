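#' Run the screen-scoring pipeline end to end and write its artifacts
#'
#' Reads (or accepts) a screen, optionally filters drop-outs and imputes,
#' Z-transforms against negative controls (skippable when the input is
#' already a Z matrix), scores every perturbation with the zeta statistic,
#' builds the Screen Strength curve and calls hits. Artifacts are written
#' as TSV plus a JSON run manifest recording all parameter values and the
#' seed, so two runs with the same inputs and seed are byte-identical.
#'
#' @param x a \linkS4class{ScreenExperiment}, or a matrix file path (then
#'   \code{annotationPath} is required).
#' @param annotationPath annotation TSV (row_id, class) when \code{x} is a
#'   path.
#' @param outDir output directory (created if needed).
#' @param zscore Z-transform the input (set FALSE when the input matrix
#'   already holds Z scores; mirrors the \code{-z no} flag convention).
#' @param svm subtract the control-separating SVM boundary (\code{--svm
#'   no} skips it).
#' @param combine sum the directional zeta scores (\code{-c no} reports
#'   them separately).
#' @param weighted weight bin areas by |Z| (default TRUE).
#' @param preprocess run drop-out filtering and KNN imputation first.
#' @param k KNN imputation neighbours (default 10).
#' @param nBins Z-cutoff bins per direction (default 100).
#' @param fplLevels empirical false-positive levels (default 0.05, 0.01).
#' @param hitMode cutoff mode for \code{\link{callHits}}; default uses
#'   BP1/BP2 when found, falling back to "FPL:0.05".
#' @param seed RNG seed (SVM fit).
#' @return invisibly, a list with \code{scores}, \code{strength},
#'   \code{hits}, \code{qc} and the manifest.
#' @export
runScreenPipeline <- function(x, annotationPath = NULL, outDir = ".",
                              zscore = TRUE, svm = TRUE, combine = TRUE,
                              weighted = TRUE, preprocess = TRUE, k = 10,
                              nBins = 100, fplLevels = c(0.05, 0.01),
                              hitMode = NULL, seed = 1L) {
    if (is.character(x)) {
        if (is.null(annotationPath))
            stop("annotationPath is required when x is a file path")
        x <- readScreenMatrix(x, annotationPath)
    }
    stopifnot(methods::is(x, "ScreenExperiment"))
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    if (preprocess && anyNA(screenValues(x))) {
        x <- filterDropouts(x)
        x <- imputeKNN(x, k = k)
    }
    qc <- tryCatch(qcScreen(x), error = function(e) NULL)
    ann <- perturbClass(x)
    if (zscore) {
        x <- zTransform(x)
        z <- zScores(x)
        ann <- perturbClass(x)
    } else {
        z <- screenValues(x)
    }
    res <- computeZeta(z, annotation = ann, svm = svm,
                       weighted = weighted, combine = combine,
                       nBins = nBins, seed = seed)
    utils::write.table(res$scores, file.path(outDir, "zeta_scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    strength <- hits <- NULL
    if (combine && any(ann == "non_expressor")) {
        strength <- screenStrength(res$scores, ann,
                                   fplLevels = fplLevels)
        utils::write.table(ssTable(strength),
                           file.path(outDir, "screen_strength.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        jsonlite::write_json(
            list(bFDR = baselineFDR(strength),
                 balance_points = balancePoints(strength),
                 fpl_cutoffs = as.list(fplCutoffValues(strength))),
            file.path(outDir, "screen_strength.json"),
            auto_unbox = TRUE, digits = NA)
        if (is.null(hitMode))
            hitMode <- if (length(balancePoints(strength))) "BP1"
                       else "FPL:0.05"
        hits <- callHits(res$scores, strength, ann, mode = hitMode)
        utils::write.table(hits, file.path(outDir, "hits.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    }
    manifest <- list(
        package = "ZetaScreen",
        version = as.character(utils::packageVersion("ZetaScreen")),
        seed = seed,
        parameters = list(zscore = zscore, svm = svm, combine = combine,
                          weighted = weighted, preprocess = preprocess,
                          k = k, nBins = nBins, fplLevels = fplLevels,
                          hitMode = hitMode),
        n_perturbations = nrow(x), n_readouts = ncol(x),
        qc_pass = if (is.null(qc)) NA else qc$pass)
    jsonlite::write_json(manifest, file.path(outDir, "run_manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    invisible(list(scores = res$scores, strength = strength, hits = hits,
                   qc = qc, manifest = manifest))
}

#' Run the droplet QC pipeline and write its artifacts
#'
#' Reads a count matrix, computes the per-cell QC table (zeta, nCount,
#' nFeature, mitochondrial and ribosomal shares), places the data-driven
#' zeta cutoff and writes the table plus a pass-list of barcodes.
#'
#' @param path 10x MTX directory or dense TSV (see
#'   \code{\link{readCountsMtx}}), or a list as returned by it.
#' @param outDir output directory.
#' @param nBins expression bins for the cell zeta score (default 10).
#' @return invisibly, the QC table (cutoff attached as attribute).
#' @export
runCellQC <- function(path, outDir = ".", nBins = 10) {
    dat <- if (is.list(path)) path else readCountsMtx(path)
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    tab <- cellQCTable(dat$counts, dat$genes, nBins = nBins)
    utils::write.table(tab, file.path(outDir, "cell_qc.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    writeLines(tab$barcode[tab$pass],
               file.path(outDir, "pass_barcodes.txt"))
    co <- attr(tab, "cutoff")
    jsonlite::write_json(
        list(cutoff = co$cutoff, method = co$method,
             bimodal = co$bimodal, n_cells = nrow(tab),
             n_pass = sum(tab$pass)),
        file.path(outDir, "cell_qc.json"), auto_unbox = TRUE, digits = NA)
    invisible(tab)
}
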