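## Gene universe for Screen Strength: scored genes are samples plus
## non-expressors; engineered control rows are not screened genes.
.geneUniverse <- function(scores, classes) {
    z <- .asZetaVector(scores)
    cls <- .asClassVector(classes)
    keep <- names(z)[names(z) %in%
                     names(cls)[cls %in% c("sample", "non_expressor")]]
    list(zeta = z[keep], ne = cls[keep] == "non_expressor")
}

.asZetaVector <- function(scores) {
    if (is.data.frame(scores)) {
        col <- if ("zeta" %in% names(scores)) "zeta"
               else stop("score table has no 'zeta' column; run ",
                         "combineDirections(..., combine = TRUE)")
        stats::setNames(scores[[col]], scores$gene_id)
    } else scores
}

.asClassVector <- function(classes) {
    if (methods::is(classes, "ScreenExperiment")) perturbClass(classes)
    else classes
}

#' Screen Strength curve over an even grid of zeta cutoffs
#'
#' Zeta scores of the screened genes (samples and non-expressors; control
#' rows are excluded) are divided into 100 even cutoffs from the smallest
#' to the largest score. At each cutoff, hits are the genes scoring at or
#' above it; \code{aFDR} is the non-expressor fraction among hits,
#' \code{bFDR} the non-expressor fraction among all scored genes, and
#' \code{SS = 1 - aFDR / bFDR}. Cutoffs at the tail with no hits are
#' trimmed. Balance points and empirical false-positive-level cutoffs are
#' computed with the package defaults and stored in the returned object.
#'
#' @param scores named zeta vector or the data.frame from
#'   \code{\link{combineDirections}}.
#' @param classes named class vector or a \linkS4class{ScreenExperiment}.
#' @param nCutoffs grid size (default 100).
#' @param bFDR optionally fix the baseline FDR (used when re-scoring after
#'   off-target removal so the baseline of the original screen is kept).
#' @param cutoffs optional explicit cutoff grid (overrides \code{nCutoffs};
#'   used to compare curves before/after filtering on the same grid).
#' @param fplLevels empirical false-positive levels (default 0.05, 0.01).
#' @param slopeTol,window balance-point detection parameters, see
#'   \code{\link{findBalancePoints}}.
#' @return A \linkS4class{ScreenStrengthCurve}.
#' @export
screenStrength <- function(scores, classes, nCutoffs = 100, bFDR = NULL,
                           fplLevels = c(0.05, 0.01), slopeTol = 0.05,
                           window = 5, cutoffs = NULL) {
    u <- .geneUniverse(scores, classes)
    if (!any(u$ne))
        stop("no non-expressors among scored genes; Screen Strength ",
             "is undefined")
    if (!all(is.finite(u$zeta)))
        stop("zeta scores must be finite")
    if (is.null(bFDR)) bFDR <- mean(u$ne)
    if (is.null(cutoffs))
        cutoffs <- seq(min(u$zeta), max(u$zeta), length.out = nCutoffs)
    n_hits <- vapply(cutoffs, function(c) sum(u$zeta >= c), integer(1))
    n_ne <- vapply(cutoffs, function(c) sum(u$zeta >= c & u$ne), integer(1))
    keep <- n_hits > 0
    curve <- data.frame(cutoff = cutoffs[keep], n_hits = n_hits[keep],
                        n_ne_hits = n_ne[keep],
                        aFDR = n_ne[keep] / n_hits[keep])
    curve$SS <- 1 - curve$aFDR / bFDR
    obj <- methods::new("ScreenStrengthCurve", curve = curve, bFDR = bFDR,
                        balancePoints = numeric(0), fpl = numeric(0))
    obj@balancePoints <- findBalancePoints(obj, slopeTol = slopeTol,
                                           window = window)
    obj@fpl <- fplCutoffs(scores, classes, levels = fplLevels,
                          grid = cutoffs)
    obj
}

#' Detect balance points on a Screen Strength curve
#'
#' A balance point marks the onset of a plateau: further cutoff stringency
#' buys little additional Screen Strength. Operationally: SS is smoothed by
#' a centred moving average of width \code{window}; a balance point is the
#' first cutoff of each maximal run in which the absolute forward slope of
#' smoothed SS stays below \code{slopeTol * (SS range) / (cutoff range)}
#' for at least \code{window} consecutive steps, provided smoothed SS there
#' is positive and exceeds the value at the previous balance point, and -
#' for the first balance point - the curve has actually climbed to the
#' plateau: the net rise of smoothed SS from its minimum so far must reach
#' \code{minRise} of the SS range (a flat information-free curve hovering
#' near zero, as permuted score rankings produce, has plateaus but no
#' preceding gain and yields no balance point). Cutoffs with fewer than
#' \code{minHits} hits are discarded first (aFDR is unstable with tiny
#' denominators). An empty result is valid.
#'
#' @param curve a \linkS4class{ScreenStrengthCurve} (or its
#'   \code{ssTable()} data.frame).
#' @param slopeTol normalised slope tolerance (default 0.05).
#' @param window smoothing width and minimum run length (default 5).
#' @param minHits minimum hits for a cutoff to enter detection (default 5).
#' @param minRise required net SS gain before the first balance point, as
#'   a fraction of the SS range (default 0.25).
#' @return numeric vector of balance-point zeta cutoffs (BP1, BP2, ...).
#' @export
findBalancePoints <- function(curve, slopeTol = 0.05, window = 5,
                              minHits = 5, minRise = 0.25) {
    df <- if (methods::is(curve, "ScreenStrengthCurve")) curve@curve
          else curve
    df <- df[df$n_hits >= minHits, , drop = FALSE]
    n <- nrow(df)
    if (n < max(window + 1, 3)) return(numeric(0))
    sm <- .movingAverage(df$SS, window)
    ssRange <- max(sm) - min(sm)
    cutRange <- max(df$cutoff) - min(df$cutoff)
    if (ssRange <= 0 || cutRange <= 0) return(numeric(0))
    tol <- slopeTol * ssRange / cutRange
    slope <- diff(sm) / diff(df$cutoff)
    flat <- abs(slope) < tol
    runs <- rle(flat)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    bps <- numeric(0)
    lastSS <- 0        # first BP must improve on SS = 0 (random draw)
    runMin <- cummin(sm)
    for (r in which(runs$values & runs$lengths >= window)) {
        i0 <- starts[r]
        if (sm[i0] <= lastSS) next
        if (!length(bps) && sm[i0] - runMin[i0] < minRise * ssRange)
            next       # no preceding gain: not a real plateau
        bps <- c(bps, df$cutoff[i0])
        lastSS <- sm[i0]
    }
    bps
}

## centred moving average with shrinking window at the edges
.movingAverage <- function(x, window) {
    half <- (window - 1) %/% 2
    n <- length(x)
    vapply(seq_len(n), function(i) {
        lo <- max(1, i - half); hi <- min(n, i + half)
        mean(x[lo:hi])
    }, numeric(1))
}

#' Empirical false-positive-level cutoffs
#'
#' The false positive level of a zeta cutoff is the fraction of
#' non-expressors (internal true negatives) scoring at or above it. For
#' each requested level, the smallest cutoff on the even score grid whose
#' FPL does not exceed the level is returned.
#'
#' @param scores named zeta vector or combined score data.frame.
#' @param classes named class vector or \linkS4class{ScreenExperiment}.
#' @param levels FPL levels in (0, 1] (default 0.05 and 0.01).
#' @param grid optional cutoff grid; defaults to 100 even cutoffs over the
#'   scored-gene zeta range.
#' @return named numeric vector, one cutoff per level (NA with a warning
#'   if no grid cutoff attains the level).
#' @export
fplCutoffs <- function(scores, classes, levels = c(0.05, 0.01),
                       grid = NULL) {
    if (any(levels <= 0 | levels > 1))
        stop("FPL levels must lie in (0, 1]")
    u <- .geneUniverse(scores, classes)
    nez <- u$zeta[u$ne]
    if (!length(nez)) stop("no non-expressors among scored genes")
    if (length(nez) < 20)
        warning("only ", length(nez), " non-expressors; FPL cutoffs are ",
                "unstable below 20")
    if (is.null(grid))
        grid <- seq(min(u$zeta), max(u$zeta), length.out = 100)
    out <- vapply(levels, function(lv) {
        fpl <- vapply(grid, function(c) mean(nez >= c), numeric(1))
        ok <- which(fpl <= lv)
        if (!length(ok)) return(NA_real_)
        grid[min(ok)]
    }, numeric(1))
    if (anyNA(out)) warning("no grid cutoff attains level(s): ",
                            paste(levels[is.na(out)], collapse = ", "))
    stats::setNames(out, as.character(levels))
}

#' Call hits at a chosen cutoff mode
#'
#' Labels every scored gene \code{none}, \code{candidate} (between the BP1
#' and BP2 cutoffs) or \code{high_confidence} (at or above BP2). Modes:
#' \code{"BP1"} (uses both balance points when available), \code{"BP2"}
#' (high-confidence only; errors if fewer than two balance points were
#' found, advising FPL mode), \code{"FPL:<level>"} and
#' \code{"manual:<zeta>"} (single cutoff; genes above it are candidates).
#'
#' @param scores named zeta vector or combined score data.frame.
#' @param curve a \linkS4class{ScreenStrengthCurve}.
#' @param classes named class vector or \linkS4class{ScreenExperiment}.
#' @param mode cutoff mode string.
#' @return data.frame (gene_id, zeta, call) sorted by zeta descending; the
#'   empty set of hits is a valid result.
#' @export
callHits <- function(scores, curve, classes, mode = "BP1") {
    stopifnot(methods::is(curve, "ScreenStrengthCurve"))
    u <- .geneUniverse(scores, classes)
    bps <- curve@balancePoints
    c1 <- c2 <- NA_real_
    if (mode == "BP1") {
        if (length(bps) < 1)
            stop("no balance points found; consider FPL mode")
        c1 <- bps[1]
        if (length(bps) >= 2) c2 <- bps[2]
    } else if (mode == "BP2") {
        if (length(bps) < 2)
            stop("fewer than 2 balance points found; consider FPL mode ",
                 "(e.g. \"FPL:0.05\")")
        c2 <- bps[2]
        c1 <- c2
    } else if (grepl("^FPL:", mode)) {
        lv <- as.character(as.numeric(sub("^FPL:", "", mode)))
        if (!lv %in% names(curve@fpl))
            stop("FPL level ", lv, " not available in curve")
        c1 <- curve@fpl[[lv]]
    } else if (grepl("^manual:", mode)) {
        c1 <- as.numeric(sub("^manual:", "", mode))
    } else stop("unknown mode: ", mode)
    call <- rep("none", length(u$zeta))
    if (!is.na(c1)) call[u$zeta >= c1] <- "candidate"
    if (!is.na(c2)) call[u$zeta >= c2] <- "high_confidence"
    out <- data.frame(gene_id = names(u$zeta), zeta = unname(u$zeta),
                      call = call, stringsAsFactors = FALSE)
    out[order(-out$zeta), , drop = FALSE]
}
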