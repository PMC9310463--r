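#' Z-transform a screen matrix against its negative controls
#'
#' Each column j is centred and scaled by the mean and sample standard
#' deviation of the negative-control rows in that column:
#' \code{Z_ij = (N_ij - mu_j) / sigma_j}. Columns whose negative controls
#' are constant (sigma_j = 0) are dropped with a warning.
#'
#' @param x a \linkS4class{ScreenExperiment} with no missing values and at
#'   least two negative-control rows.
#' @return The \code{ScreenExperiment} with an added \code{"zscore"} assay;
#'   \code{metadata(x)$zscale} records mu, sigma and dropped columns.
#' @export
zTransform <- function(x) {
    stopifnot(methods::is(x, "ScreenExperiment"))
    neg <- rowsOfClass(x, "negative_control")
    if (length(neg) < 2)
        stop("need >= 2 negative-control rows to Z-transform")
    m <- screenValues(x)
    if (anyNA(m))
        stop("missing values present; run imputeKNN() first")
    mu <- colMeans(m[neg, , drop = FALSE])
    sigma <- apply(m[neg, , drop = FALSE], 2, stats::sd)
    drop <- sigma == 0
    if (any(drop)) {
        warning("dropping ", sum(drop),
                " column(s) with constant negative controls: ",
                paste(colnames(m)[drop], collapse = ", "))
        x <- x[, !drop]
        m <- m[, !drop, drop = FALSE]
        mu <- mu[!drop]
        sigma <- sigma[!drop]
    }
    z <- sweep(sweep(m, 2, mu, "-"), 2, sigma, "/")
    SummarizedExperiment::assay(x, "zscore") <- z
    S4Vectors::metadata(x)$zscale <-
        list(mu = mu, sigma = sigma, dropped = names(drop)[drop])
    x
}

#' Build per-perturbation survival curves over a Z-cutoff grid
#'
#' The grid spans \code{[2, Zmax]} (positive direction) or
#' \code{[-Zmax, -2]} (negative), where \code{Zmax} is the entry of rank
#' \code{floor(N * M * 0.999)} in the ascending absolute Z scores (extreme
#' outliers excluded; |Z| < 2 excluded as experimental noise). The grid has
#' \code{nBins + 1} edges; at each edge the fraction of readouts with Z at
#' or beyond the cutoff is recorded per perturbation.
#'
#' @param z Z-score matrix (perturbations x readouts), or a
#'   \linkS4class{ScreenExperiment} carrying a \code{"zscore"} assay.
#' @param direction "positive" or "negative".
#' @param nBins number of bins (default 100).
#' @return A \linkS4class{ZetaCurveSet}.
#' @export
buildZetaCurves <- function(z, direction = c("positive", "negative"),
                            nBins = 100) {
    direction <- match.arg(direction)
    z <- .asZMatrix(z)
    if (!all(is.finite(z)))
        stop("Z matrix must be finite")
    absZ <- sort(abs(z))
    zmax <- absZ[max(1L, floor(length(absZ) * 0.999))]
    if (zmax <= 2)
        stop("signal range does not exceed noise threshold (|Z| 99.9th ",
             "percentile = ", signif(zmax, 4), " <= 2)")
    cutoffs <- if (direction == "positive")
        seq(2, zmax, length.out = nBins + 1)
    else seq(-zmax, -2, length.out = nBins + 1)
    P <- matrix(0, nrow(z), nBins + 1,
                dimnames = list(rownames(z), NULL))
    for (m in seq_along(cutoffs)) {
        P[, m] <- if (direction == "positive")
            rowMeans(z >= cutoffs[m])
        else rowMeans(z <= cutoffs[m])
    }
    methods::new("ZetaCurveSet", P = P, cutoffs = cutoffs,
                 direction = direction, step = (max(cutoffs) - min(cutoffs)) / nBins)
}

#' Fit the SVM boundary between positive- and negative-control curves
#'
#' Trains a radial-kernel SVM on the (cutoff, survival fraction) points of
#' the control curves and extracts, per cutoff, the fraction at which the
#' decision function changes sign (bisection to 1e-6). Where the decision
#' function does not change sign over [0, 1] the boundary is clamped to 0
#' (whole bin on the positive-control side) or 1.
#'
#' @param curvesPos \linkS4class{ZetaCurveSet} of positive-control rows.
#' @param curvesNeg \linkS4class{ZetaCurveSet} of negative-control rows
#'   (same direction and grid).
#' @param seed integer seed recorded in the model parameters.
#' @param cost SVM cost parameter (default 1).
#' @return A \linkS4class{ZetaBoundary}.
#' @export
fitSvmBoundary <- function(curvesPos, curvesNeg, seed = 1L, cost = 1) {
    stopifnot(methods::is(curvesPos, "ZetaCurveSet"),
              methods::is(curvesNeg, "ZetaCurveSet"))
    if (curvesPos@direction != curvesNeg@direction ||
        length(curvesPos@cutoffs) != length(curvesNeg@cutoffs) ||
        any(abs(curvesPos@cutoffs - curvesNeg@cutoffs) > 1e-8))
        stop("control curve sets must share direction and cutoff grid")
    if (nrow(curvesPos@P) < 2 || nrow(curvesNeg@P) < 2)
        stop("need at least 2 control curves per class")
    if (nrow(curvesPos@P) < 5 || nrow(curvesNeg@P) < 5)
        warning("fewer than 5 control curves per class; boundary may be ",
                "unstable")
    cut_raw <- curvesPos@cutoffs
    xmu <- mean(cut_raw); xsd <- stats::sd(cut_raw)
    xs <- (cut_raw - xmu) / xsd
    dat <- data.frame(
        x = c(rep(xs, each = nrow(curvesPos@P)),
              rep(xs, each = nrow(curvesNeg@P))),
        y = c(as.vector(curvesPos@P), as.vector(curvesNeg@P)))
    lab <- factor(c(rep("pos", nrow(curvesPos@P) * length(xs)),
                    rep("neg", nrow(curvesNeg@P) * length(xs))),
                  levels = c("pos", "neg"))
    gamma <- .withSeed(seed, .medianHeuristicGamma(dat))
    fit <- .withSeed(seed,
        e1071::svm(dat, lab, kernel = "radial", cost = cost,
                   gamma = gamma, scale = FALSE))
    acc <- mean(stats::predict(fit, dat) == lab)
    if (acc < 0.6)
        warning("control classes are poorly separable (training accuracy ",
                signif(acc, 3), "); boundary returned anyway")
    decide <- function(y) {
        nd <- data.frame(x = xs, y = y)
        as.numeric(attr(stats::predict(fit, nd, decision.values = TRUE),
                        "decision.values"))
    }
    f0 <- decide(rep(0, length(xs)))
    f1 <- decide(rep(1, length(xs)))
    S <- numeric(length(xs))
    crossing <- sign(f0) != sign(f1)
    ## no crossing: bin entirely on one side of the boundary
    pred0 <- stats::predict(fit, data.frame(x = xs, y = rep(0, length(xs))))
    S[!crossing] <- ifelse(pred0[!crossing] == "pos", 0, 1)
    if (any(crossing)) {
        lo <- rep(0, sum(crossing)); hi <- rep(1, sum(crossing))
        flo <- f0[crossing]
        xcr <- xs[crossing]
        for (iter in seq_len(25)) {        # 2^-25 < 1e-7
            mid <- (lo + hi) / 2
            nd <- data.frame(x = xcr, y = mid)
            fm <- as.numeric(attr(stats::predict(fit, nd,
                                                 decision.values = TRUE),
                                  "decision.values"))
            same <- sign(fm) == sign(flo)
            lo[same] <- mid[same]; flo[same] <- fm[same]
            hi[!same] <- mid[!same]
            if (max(hi - lo) < 1e-6) break
        }
        S[crossing] <- (lo + hi) / 2
    }
    methods::new("ZetaBoundary", S = pmin(pmax(S, 0), 1),
                 cutoffs = cut_raw, direction = curvesPos@direction,
                 params = list(kernel = "radial", cost = cost,
                               gamma = gamma, seed = seed, accuracy = acc))
}

.medianHeuristicGamma <- function(dat, maxPoints = 800) {
    idx <- if (nrow(dat) > maxPoints)
        sample.int(nrow(dat), maxPoints) else seq_len(nrow(dat))
    d <- stats::dist(dat[idx, ])
    med <- stats::median(d[d > 0])
    if (!is.finite(med) || med == 0) return(0.5)
    1 / (2 * med^2)
}

## evaluate expr under a local RNG seed, restoring global state
.withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv())) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(rm(".Random.seed", envir = globalenv()))
    }
    set.seed(seed)
    expr
}

#' Zeta score of each perturbation from its survival curve
#'
#' Integrates the trapezoid area of the survival curve over the cutoff
#' grid. With a boundary, each bin's area is the excess of the curve's
#' trapezoid over the boundary's trapezoid, clamped at zero:
#' \code{Area_m = ((P_m + P_{m+1}) - (S_m + S_{m+1})) * step / 2} when
#' positive, else 0; without a boundary \code{Area_m = (P_m + P_{m+1}) *
#' step / 2}. The weighted score multiplies each bin's area by the absolute
#' Z value at the bin midpoint, emphasising responses at high |Z|.
#'
#' @param curves a \linkS4class{ZetaCurveSet}.
#' @param boundary a \linkS4class{ZetaBoundary} on the same grid, or NULL
#'   for the no-SVM variant.
#' @param weighted multiply bin areas by |bin midpoint Z| (default TRUE).
#' @return named numeric vector of zeta scores (all >= 0).
#' @export
zetaScores <- function(curves, boundary = NULL, weighted = TRUE) {
    stopifnot(methods::is(curves, "ZetaCurveSet"))
    P <- curves@P
    B <- ncol(P) - 1L
    step <- curves@step
    PP <- P[, seq_len(B), drop = FALSE] + P[, seq_len(B) + 1L, drop = FALSE]
    if (!is.null(boundary)) {
        stopifnot(methods::is(boundary, "ZetaBoundary"))
        if (length(boundary@S) != B + 1L ||
            any(abs(boundary@cutoffs - curves@cutoffs) > 1e-8))
            stop("boundary and curves are on different cutoff grids")
        S2 <- boundary@S[seq_len(B)] + boundary@S[seq_len(B) + 1L]
        area <- sweep(PP, 2, S2, "-") * step / 2
        area[area < 0] <- 0
    } else {
        area <- PP * step / 2
    }
    if (weighted) {
        w <- abs((curves@cutoffs[seq_len(B)] +
                  curves@cutoffs[seq_len(B) + 1L]) / 2)
        area <- sweep(area, 2, w, "*")
    }
    rowSums(area)
}

#' Combine directional zeta scores
#'
#' By default the two directional scores (both non-negative) are summed to
#' one global-activity score per gene; with \code{combine = FALSE} they are
#' reported separately.
#'
#' @param pos,neg named numeric vectors of directional zeta scores.
#' @param combine sum the directions (default TRUE).
#' @return data.frame with \code{gene_id}, \code{zeta_pos}, \code{zeta_neg}
#'   and, when combined, \code{zeta}.
#' @export
combineDirections <- function(pos, neg, combine = TRUE) {
    stopifnot(all(pos >= 0), all(neg >= 0),
              identical(names(pos), names(neg)))
    out <- data.frame(gene_id = names(pos), zeta_pos = unname(pos),
                      zeta_neg = unname(neg), stringsAsFactors = FALSE)
    if (combine) out$zeta <- out$zeta_pos + out$zeta_neg
    out
}

#' Score a whole screen: curves, SVM boundary and zeta per gene
#'
#' High-level driver: builds survival curves in both directions, optionally
#' fits the control-separating SVM boundary per direction, scores every
#' perturbation and combines directions.
#'
#' @param x Z-score matrix or \linkS4class{ScreenExperiment} with a
#'   \code{"zscore"} assay.
#' @param annotation optional named class vector (required when \code{x} is
#'   a bare matrix and \code{svm = TRUE}); taken from the object otherwise.
#' @param svm subtract an SVM background boundary fitted on control curves
#'   (default TRUE).
#' @param weighted weight bin areas by |Z| (default TRUE).
#' @param combine sum the directional scores (default TRUE).
#' @param nBins bins per direction (default 100).
#' @param seed RNG seed for the SVM fit.
#' @return list with \code{scores} (data.frame from
#'   \code{\link{combineDirections}}), \code{curves} and \code{boundaries}
#'   (per direction).
#' @export
computeZeta <- function(x, annotation = NULL, svm = TRUE, weighted = TRUE,
                        combine = TRUE, nBins = 100, seed = 1L) {
    z <- .asZMatrix(x)
    if (is.null(annotation) && methods::is(x, "ScreenExperiment"))
        annotation <- perturbClass(x)
    curves <- list(positive = buildZetaCurves(z, "positive", nBins),
                   negative = buildZetaCurves(z, "negative", nBins))
    boundaries <- list(positive = NULL, negative = NULL)
    if (svm) {
        if (is.null(annotation))
            stop("svm = TRUE requires a class annotation")
        pos <- names(annotation)[annotation == "positive_control"]
        neg <- names(annotation)[annotation == "negative_control"]
        if (length(pos) < 2 || length(neg) < 2)
            stop("svm = TRUE requires >= 2 control rows per class")
        for (d in names(curves)) {
            cs <- curves[[d]]
            boundaries[[d]] <- fitSvmBoundary(
                methods::new("ZetaCurveSet", P = cs@P[pos, , drop = FALSE],
                             cutoffs = cs@cutoffs, direction = d,
                             step = cs@step),
                methods::new("ZetaCurveSet", P = cs@P[neg, , drop = FALSE],
                             cutoffs = cs@cutoffs, direction = d,
                             step = cs@step),
                seed = seed)
        }
    }
    zp <- zetaScores(curves$positive, boundaries$positive, weighted)
    zn <- zetaScores(curves$negative, boundaries$negative, weighted)
    list(scores = combineDirections(zp, zn, combine),
         curves = curves, boundaries = boundaries)
}
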