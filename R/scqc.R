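#' Read a droplet count matrix (10x Matrix Market triplet or dense TSV)
#'
#' For a directory, expects \code{matrix.mtx}, \code{barcodes.tsv} and
#' \code{features.tsv} (or \code{genes.tsv}); for a file, a dense TSV with
#' gene ids in the first column and barcodes in the header. Genes are
#' classified mitochondrial / ribosomal by configurable id prefixes.
#'
#' @param path directory with the MTX triplet, or a dense TSV file.
#' @param mitoPrefix prefixes marking mitochondrial genes
#'   (default "MT-", "mt-").
#' @param riboPrefix prefixes marking ribosomal protein genes
#'   (default "RPL", "RPS", "Rpl", "Rps").
#' @return list: \code{counts} (sparse integer gene x cell matrix),
#'   \code{genes} (data.frame gene_id, is_mito, is_ribo).
#' @export
readCountsMtx <- function(path, mitoPrefix = c("MT-", "mt-"),
                          riboPrefix = c("RPL", "RPS", "Rpl", "Rps")) {
    if (dir.exists(path)) {
        mtx <- file.path(path, "matrix.mtx")
        bc <- file.path(path, "barcodes.tsv")
        ft <- file.path(path, "features.tsv")
        if (!file.exists(ft)) ft <- file.path(path, "genes.tsv")
        counts <- Matrix::readMM(mtx)
        barcodes <- readLines(bc)
        feats <- utils::read.delim(ft, header = FALSE,
                                   colClasses = "character")
        if (length(barcodes) != ncol(counts))
            stop("barcode count (", length(barcodes),
                 ") does not match matrix columns (", ncol(counts), ")")
        if (nrow(feats) != nrow(counts))
            stop("feature count (", nrow(feats),
                 ") does not match matrix rows (", nrow(counts), ")")
        dimnames(counts) <- list(feats[[1]], barcodes)
    } else {
        df <- utils::read.delim(path, check.names = FALSE)
        counts <- Matrix::Matrix(as.matrix(df[, -1, drop = FALSE]),
                                 sparse = TRUE)
        rownames(counts) <- as.character(df[[1]])
    }
    if (any(counts@x != round(counts@x)) || any(counts@x < 0))
        stop("count matrix must contain non-negative integers")
    counts <- methods::as(counts, "CsparseMatrix")
    ids <- rownames(counts)
    pref <- function(p) Reduce(`|`, lapply(p, function(q) startsWith(ids, q)))
    list(counts = counts,
         genes = data.frame(gene_id = ids, is_mito = pref(mitoPrefix),
                            is_ribo = pref(riboPrefix)))
}

#' Write a count matrix as a 10x-style Matrix Market triplet
#'
#' @param counts sparse gene x cell matrix with dimnames.
#' @param dir output directory (created if needed).
#' @return invisibly, \code{dir}.
#' @export
writeCountsMtx <- function(counts, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    Matrix::writeMM(methods::as(counts, "CsparseMatrix"),
                    file.path(dir, "matrix.mtx"))
    writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
    utils::write.table(data.frame(rownames(counts), rownames(counts)),
                       file.path(dir, "features.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    invisible(dir)
}

#' Global expression-bin thresholds for the per-cell zeta score
#'
#' Ten (by default) log-spaced count thresholds from 1 to the 99.9th
#' percentile of the pooled nonzero counts; shared by all cells so that
#' per-cell scores are comparable.
#'
#' @param counts sparse gene x cell count matrix.
#' @param nBins number of thresholds (default 10).
#' @return ascending numeric thresholds t_1 < ... < t_nBins.
#' @export
cellZetaBins <- function(counts, nBins = 10) {
    xs <- counts@x
    if (!length(xs)) stop("count matrix is all zero")
    hi <- max(stats::quantile(xs, 0.999, names = FALSE), 2)
    exp(seq(log(1), log(hi), length.out = nBins))
}

#' Per-cell zeta score from the binned count/feature curve
#'
#' For each cell, the curve \code{y_b} = number of genes with count at or
#' above threshold \code{t_b} links the cell's depth (nCount) to its gene
#' diversity (nFeature); the cell's zeta is the trapezoid area under
#' \code{(t_b, y_b)} - no boundary subtraction and no weighting. An
#' all-zero cell scores 0.
#'
#' @param counts sparse gene x cell count matrix.
#' @param nBins number of expression bins when \code{binEdges} is NULL.
#' @param binEdges global thresholds from \code{\link{cellZetaBins}}
#'   (computed from \code{counts} when NULL).
#' @return named numeric vector of per-cell zeta scores (>= 0).
#' @export
cellZeta <- function(counts, nBins = 10, binEdges = NULL) {
    counts <- methods::as(counts, "CsparseMatrix")
    if (is.null(binEdges)) binEdges <- cellZetaBins(counts, nBins)
    stopifnot(!is.unsorted(binEdges), length(binEdges) >= 2)
    Y <- vapply(binEdges, function(t) Matrix::colSums(counts >= t),
                numeric(ncol(counts)))
    if (is.null(dim(Y))) Y <- matrix(Y, nrow = 1)   # single-cell input
    B <- length(binEdges)
    widths <- diff(binEdges)
    zeta <- as.numeric((Y[, -B, drop = FALSE] + Y[, -1, drop = FALSE]) %*%
                       widths / 2)
    stats::setNames(zeta, colnames(counts))
}

#' Data-driven zeta cutoff from the bimodal per-cell zeta density
#'
#' Kernel-density estimate (Silverman bandwidth) of \code{log1p(zeta)};
#' the two largest density modes are located (ambient/empty droplets form
#' the low mode, intact cells the high mode) and the cutoff is placed at
#' the inflection point (second-derivative sign change) on the low flank
#' of the higher-zeta mode, falling back to the inter-mode density minimum
#' when no inflection is found. A unimodal density triggers a warning and
#' an interquartile fallback, flagged \code{bimodal = FALSE}.
#'
#' @param zeta per-cell zeta scores from \code{\link{cellZeta}}.
#' @param minCells warn below this number of cells (default 500).
#' @return list: \code{cutoff} (on the zeta scale), \code{method} (one of
#'   "inflection", "valley", "fallback"), \code{bimodal}, \code{density}.
#' @export
zetaCutoff <- function(zeta, minCells = 500) {
    if (length(zeta) < minCells)
        warning("only ", length(zeta), " cells; the zeta density cutoff ",
                "is recommended for >= ", minCells)
    lz <- log1p(zeta)
    d <- stats::density(lz, bw = "nrd0", n = 512)
    y <- d$y; x <- d$x
    n <- length(y)
    peaks <- which(y > c(-Inf, y[-n]) & y >= c(y[-1], Inf))
    peaks <- peaks[y[peaks] > max(y) * 0.01]    # ignore numerical ripples
    if (length(peaks) < 2) {
        warning("no bimodality in the zeta density; using an ",
                "interquartile fallback cutoff")
        q <- stats::quantile(zeta, c(0.25, 0.75), names = FALSE)
        return(list(cutoff = max(min(zeta), q[1] - 1.5 * (q[2] - q[1])),
                    method = "fallback", bimodal = FALSE, density = d))
    }
    top2 <- peaks[order(y[peaks], decreasing = TRUE)[1:2]]
    lowPeak <- min(top2); highPeak <- max(top2)
    valley <- which.min(y[lowPeak:highPeak]) + lowPeak - 1L
    ## inflection at the base of the high mode: the first convex-to-concave
    ## transition of the density after the valley marks where the second
    ## population starts to rise
    seg <- valley:highPeak
    if (length(seg) >= 4) {
        d2 <- diff(y[seg], differences = 2)     # curvature at seg[i + 1]
        cross <- which(d2[-length(d2)] > 0 & d2[-1] <= 0)
        if (length(cross))
            return(list(cutoff = expm1(x[seg[min(cross) + 1L]]),
                        method = "inflection", bimodal = TRUE,
                        density = d))
    }
    list(cutoff = expm1(x[valley]), method = "valley", bimodal = TRUE,
         density = d)
}

#' Per-cell QC table integrating zeta with conventional droplet metrics
#'
#' @param counts sparse gene x cell count matrix.
#' @param genes gene annotation data.frame from \code{\link{readCountsMtx}}
#'   (columns \code{is_mito}, \code{is_ribo}); inferred from rownames by
#'   prefix when NULL.
#' @param nBins expression bins for the zeta score (default 10).
#' @param cutoff optional fixed zeta cutoff; computed by
#'   \code{\link{zetaCutoff}} when NULL.
#' @return data.frame (barcode, nCount, nFeature, pct_mt, pct_ribo,
#'   zeta_cell, pass); the cutoff object is attached as
#'   \code{attr(x, "cutoff")}.
#' @export
cellQCTable <- function(counts, genes = NULL, nBins = 10, cutoff = NULL) {
    counts <- methods::as(counts, "CsparseMatrix")
    if (is.null(genes)) {
        ids <- rownames(counts)
        genes <- data.frame(
            gene_id = ids,
            is_mito = startsWith(ids, "MT-") | startsWith(ids, "mt-"),
            is_ribo = startsWith(ids, "RPL") | startsWith(ids, "RPS"))
    }
    nCount <- Matrix::colSums(counts)
    nFeature <- Matrix::colSums(counts > 0)
    mt <- Matrix::colSums(counts[genes$is_mito, , drop = FALSE])
    rb <- Matrix::colSums(counts[genes$is_ribo, , drop = FALSE])
    zeta <- cellZeta(counts, nBins = nBins)
    co <- if (is.null(cutoff)) zetaCutoff(zeta)
          else list(cutoff = cutoff, method = "manual", bimodal = NA)
    out <- data.frame(
        barcode = colnames(counts),
        nCount = as.numeric(nCount), nFeature = as.numeric(nFeature),
        pct_mt = ifelse(nCount > 0, 100 * mt / nCount, 0),
        pct_ribo = ifelse(nCount > 0, 100 * rb / nCount, 0),
        zeta_cell = unname(zeta),
        pass = unname(zeta) >= co$cutoff,
        stringsAsFactors = FALSE)
    attr(out, "cutoff") <- co
    out
}

#' Compare QC metrics by ROC/AUC against reference labels
#'
#' @param table a \code{\link{cellQCTable}} data.frame.
#' @param labels logical (or two-level) vector, TRUE = high quality, in
#'   cell order.
#' @param metrics columns of \code{table} to evaluate.
#' @return data.frame (metric, auc, direction): AUC is reported with the
#'   orientation that makes it >= 0.5, recorded in \code{direction}
#'   ("high" when larger metric values mark high-quality cells).
#' @export
compareMetrics <- function(table, labels,
                           metrics = c("zeta_cell", "nCount", "nFeature",
                                       "pct_mt")) {
    labels <- as.logical(labels)
    if (length(unique(labels)) < 2)
        stop("labels must contain both classes")
    res <- lapply(metrics, function(mc) {
        r <- pROC::roc(response = labels, predictor = table[[mc]],
                       quiet = TRUE, direction = "auto",
                       levels = c(FALSE, TRUE))
        data.frame(metric = mc, auc = as.numeric(pROC::auc(r)),
                   direction = ifelse(r$direction == "<", "high", "low"))
    })
    do.call(rbind, res)
}
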