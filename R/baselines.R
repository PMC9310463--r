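#' Bonferroni-corrected Z threshold for a family of readout tests
#'
#' With m tests at family-wise level alpha, the per-test level is
#' \code{alpha / m} and the corresponding two-sided standard-normal
#' rejection threshold is \code{qnorm(1 - alpha / (2 m))}. Illustrates why
#' naive correction fails in two dimensions: the threshold grows only
#' logarithmically while noise accumulates linearly in the readout count.
#'
#' @param alpha family-wise error level in (0, 1).
#' @param mTests number of tests (>= 1).
#' @return list (method, alpha_family, per_test_p, z_cutoff).
#' @export
bonferroniZThreshold <- function(alpha, mTests) {
    if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
        stop("alpha must lie in (0, 1)")
    stopifnot(mTests >= 1)
    p <- alpha / mTests
    list(method = "bonferroni", alpha_family = alpha, per_test_p = p,
         z_cutoff = stats::qnorm(1 - p / 2))
}

## Gumbel distribution helpers (location mu, scale beta > 0)
.dgumbel <- function(x, mu, beta, log = FALSE) {
    z <- (x - mu) / beta
    lg <- -z - exp(-z) - log(beta)
    if (log) lg else exp(lg)
}
.pgumbel <- function(q, mu, beta) exp(-exp(-(q - mu) / beta))
.qgumbel <- function(p, mu, beta) mu - beta * log(-log(p))

#' Maximum-likelihood fit of a Gumbel distribution
#'
#' Moment-based starting values (beta = sqrt(6) sd / pi,
#' mu = mean - Euler-gamma beta) refined by BFGS on the negative
#' log-likelihood (relative tolerance 1e-8).
#'
#' @param x numeric sample.
#' @return list (mu, beta, loglik, convergence).
#' @export
fitGumbel <- function(x) {
    if (length(unique(x)) < 2)
        stop("degenerate sample: all values equal")
    beta0 <- sqrt(6) * stats::sd(x) / pi
    mu0 <- mean(x) - 0.5772156649 * beta0
    nll <- function(par) {
        if (par[2] <= 0) return(Inf)
        -sum(.dgumbel(x, par[1], par[2], log = TRUE))
    }
    fit <- stats::optim(c(mu0, beta0), nll, method = "BFGS",
                        control = list(reltol = 1e-8, maxit = 500))
    list(mu = fit$par[1], beta = fit$par[2], loglik = -fit$value,
         convergence = fit$convergence)
}

#' Extreme-value (Gumbel) threshold on per-row maximum |Z|
#'
#' Extracts the maximum absolute Z score of each perturbation, fits a
#' Gumbel distribution by maximum likelihood, converts each row maximum to
#' an upper-tail p value under the fit, applies the chosen multiple-testing
#' correction across rows and reports the |Z| cutoff attaining the family
#' alpha.
#'
#' @param zm Z matrix or \linkS4class{ScreenExperiment} (>= 100 rows
#'   recommended for a stable fit).
#' @param alpha family-wise (or FDR) level.
#' @param correction "bonferroni" or "bh".
#' @return list (method, alpha_family, per_test_p, z_cutoff,
#'   gumbel_params, p_values).
#' @export
gumbelThreshold <- function(zm, alpha = 0.01,
                            correction = c("bonferroni", "bh")) {
    correction <- match.arg(correction)
    if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
    z <- .asZMatrix(zm)
    mx <- apply(abs(z), 1, max)
    fit <- fitGumbel(mx)
    p <- 1 - .pgumbel(mx, fit$mu, fit$beta)
    if (correction == "bonferroni") {
        pt <- alpha / length(mx)
        cut <- .qgumbel(1 - pt, fit$mu, fit$beta)
    } else {
        padj <- stats::p.adjust(p, "BH")
        rej <- padj <= alpha
        pt <- if (any(rej)) max(p[rej]) else alpha / length(mx)
        cut <- if (any(rej)) min(mx[rej])
               else .qgumbel(1 - pt, fit$mu, fit$beta)
    }
    list(method = paste0("gumbel_", correction), alpha_family = alpha,
         per_test_p = pt, z_cutoff = cut,
         gumbel_params = c(mu = fit$mu, beta = fit$beta), p_values = p)
}

#' Hit recovery under readout down-sampling
#'
#' Samples readout columns without replacement at each requested size,
#' reruns the zeta scoring pipeline on the reduced matrix and reports the
#' fraction of the reference hits recovered at the FPL cutoff.
#'
#' @param x \linkS4class{ScreenExperiment} with a \code{"zscore"} assay
#'   (columns are resampled on the Z matrix; the Z scaling is per column
#'   and therefore unaffected by column subsetting).
#' @param referenceHits hit gene ids from the full-readout run.
#' @param sizes readout counts to down-sample to.
#' @param reps replicates per size (default 3).
#' @param seed RNG seed.
#' @param fplLevel FPL level used to call hits on each subsample.
#' @param svm fit the SVM boundary on each subsample (default TRUE).
#' @return data.frame (size, rep, n_hits, recovery).
#' @export
downsampleReadoutEval <- function(x, referenceHits,
                                  sizes = c(50, 100, 150, 200, 250, 300),
                                  reps = 3, seed = 1L, fplLevel = 0.05,
                                  svm = TRUE) {
    z <- .asZMatrix(x)
    ann <- if (methods::is(x, "ScreenExperiment")) perturbClass(x)
           else stop("x must be a ScreenExperiment")
    if (any(sizes > ncol(z)))
        stop("down-sample size exceeds the number of readouts (",
             ncol(z), ")")
    out <- NULL
    .withSeed(seed, {
        for (size in sizes) for (r in seq_len(reps)) {
            cols <- sample.int(ncol(z), size, replace = FALSE)
            res <- computeZeta(z[, cols, drop = FALSE], annotation = ann,
                               svm = svm, seed = seed)
            fpl <- fplCutoffs(res$scores, ann, levels = fplLevel)
            zv <- .geneUniverse(res$scores, ann)$zeta
            hits <- names(zv)[zv >= fpl[[1]]]
            out <- rbind(out, data.frame(
                size = size, rep = r, n_hits = length(hits),
                recovery = mean(referenceHits %in% hits)))
        }
    })
    out
}
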