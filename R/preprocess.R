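#' Remove rows and columns dominated by drop-outs
#'
#' A row (then, on the reduced matrix, a column) is removed when its count
#' of missing entries exceeds Q3 + 3 * (Q3 - Q1), where Q1 and Q3 are the
#' lower and upper quartiles (linear-interpolation quantiles) of the per-row
#' (resp. per-column) missing counts. Single pass, rows first.
#'
#' @param x a \linkS4class{ScreenExperiment}.
#' @return The reduced \code{ScreenExperiment}; ids of removed rows and
#'   columns are recorded in \code{metadata(x)$dropout_filter}.
#' @export
filterDropouts <- function(x) {
    stopifnot(methods::is(x, "ScreenExperiment"))
    miss <- is.na(screenValues(x))
    keepRows <- !.dropoutFlag(rowSums(miss))
    if (!any(keepRows))
        stop("matrix empty after filtering")
    removedRows <- rownames(x)[!keepRows]
    x2 <- x[keepRows, ]
    miss <- is.na(screenValues(x2))
    keepCols <- !.dropoutFlag(colSums(miss))
    if (!any(keepCols))
        stop("matrix empty after filtering")
    removedCols <- colnames(x2)[!keepCols]
    x2 <- x2[, keepCols]
    S4Vectors::metadata(x2)$dropout_filter <-
        list(removed_rows = removedRows, removed_cols = removedCols)
    x2
}

.dropoutFlag <- function(counts) {
    q <- stats::quantile(counts, c(0.25, 0.75), names = FALSE, type = 7)
    counts > q[2] + 3 * (q[2] - q[1])
}

#' Impute missing screen values by k nearest neighbours
#'
#' Each missing entry is replaced by the mean, over the k nearest rows that
#' observe that column, of the column's values. Row-row distance is the
#' Euclidean distance over mutually observed columns, scaled up by the
#' fraction of columns observed (so sparser overlaps are not favoured);
#' distance ties are broken by row order.
#'
#' @param x a \linkS4class{ScreenExperiment}.
#' @param k number of neighbours (default 10). Reduced with a warning if
#'   fewer candidate rows observe the column.
#' @return \code{ScreenExperiment} with a complete values assay.
#' @export
imputeKNN <- function(x, k = 10) {
    stopifnot(methods::is(x, "ScreenExperiment"), k >= 1)
    m <- screenValues(x)
    miss <- is.na(m)
    if (!any(miss)) return(x)
    if (any(rowSums(!miss) == 0))
        stop("row(s) with zero observed values: ",
             paste(rownames(m)[rowSums(!miss) == 0], collapse = ", "))
    M <- ncol(m)
    filled <- m
    for (i in which(rowSums(miss) > 0)) {
        d <- .rowDistances(m, i, miss)
        for (j in which(miss[i, ])) {
            cand <- which(!miss[, j] & is.finite(d))
            if (!length(cand))
                stop("no rows observe column ", colnames(m)[j])
            kk <- k
            if (length(cand) < k) {
                warning("reducing k from ", k, " to ", length(cand),
                        " for column ", colnames(m)[j])
                kk <- length(cand)
            }
            ord <- cand[order(d[cand], cand)[seq_len(kk)]]
            filled[i, j] <- mean(m[ord, j])
        }
    }
    SummarizedExperiment::assay(x, "values") <- filled
    x
}

## distances from row i to all rows over mutually observed columns,
## scaled by the fraction of columns in the overlap; Inf when no overlap
.rowDistances <- function(m, i, miss) {
    obs_i <- !miss[i, ]
    obs <- !miss
    shared <- obs %*% obs_i                      # overlap size per row
    diffs <- sweep(m, 2, m[i, ], "-")
    diffs[miss | matrix(miss[i, ], nrow(m), ncol(m), byrow = TRUE)] <- 0
    ss <- rowSums(diffs^2)
    d <- sqrt(ss / (as.vector(shared) / ncol(m)))
    d[as.vector(shared) == 0] <- Inf
    d[i] <- Inf
    d
}

#' Control-based quality control of a screen
#'
#' Computes the strictly standardized mean difference per readout,
#' \code{SSMD_j = (mean_pos_j - mean_neg_j) / sqrt(sd_pos_j^2 + sd_neg_j^2)}
#' (sample standard deviations), the fraction of high-quality readouts
#' (SSMD > 2), and an advisory 2-D embedding (classical MDS) of the control
#' rows for visual inspection of control separation. The screen passes when
#' more than 5\% of readouts have SSMD > 2.
#'
#' @param x a \linkS4class{ScreenExperiment} with at least two positive and
#'   two negative control rows.
#' @param ssmdThreshold per-readout quality threshold (default 2).
#' @param minFracHighQuality pass threshold on the fraction of readouts
#'   exceeding \code{ssmdThreshold} (default 0.05, exclusive).
#' @return list with \code{ssmd_per_readout}, \code{frac_high_quality},
#'   \code{pass}, and \code{separation_embedding} (control rows x 2).
#' @export
qcScreen <- function(x, ssmdThreshold = 2, minFracHighQuality = 0.05) {
    stopifnot(methods::is(x, "ScreenExperiment"))
    pos <- rowsOfClass(x, "positive_control")
    neg <- rowsOfClass(x, "negative_control")
    if (length(pos) < 2 || length(neg) < 2)
        stop("need >= 2 positive and >= 2 negative control rows")
    m <- screenValues(x)
    mp <- m[pos, , drop = FALSE]
    mn <- m[neg, , drop = FALSE]
    ssmd <- (colMeans(mp, na.rm = TRUE) - colMeans(mn, na.rm = TRUE)) /
        sqrt(apply(mp, 2, stats::sd, na.rm = TRUE)^2 +
             apply(mn, 2, stats::sd, na.rm = TRUE)^2)
    frac <- mean(ssmd > ssmdThreshold, na.rm = TRUE)
    ctrl <- m[c(pos, neg), , drop = FALSE]
    ctrl[is.na(ctrl)] <- 0
    emb <- stats::cmdscale(stats::dist(ctrl), k = 2)
    rownames(emb) <- c(pos, neg)
    list(ssmd_per_readout = ssmd,
         frac_high_quality = frac,
         pass = frac > minFracHighQuality,
         separation_embedding = emb)
}
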