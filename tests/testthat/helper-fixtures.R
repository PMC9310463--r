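## Shared fixture builders; everything is generated in code.

## tiny screen with explicit values and classes
makeScreen <- function(values, classes) {
    if (is.null(rownames(values)))
        rownames(values) <- sprintf("g%02d", seq_len(nrow(values)))
    if (is.null(colnames(values)))
        colnames(values) <- sprintf("r%02d", seq_len(ncol(values)))
    ScreenExperiment(values,
                     data.frame(row_id = rownames(values),
                                class = classes))
}

## screen with controls whose readouts separate cleanly
makeControlScreen <- function(nSample = 20, nPos = 5, nNeg = 6, M = 12,
                              posShift = 10, seed = 42) {
    set.seed(seed)
    n <- nSample + nPos + nNeg
    m <- matrix(rnorm(n * M), n, M)
    cls <- c(rep("sample", nSample), rep("positive_control", nPos),
             rep("negative_control", nNeg))
    m[cls == "positive_control", ] <-
        m[cls == "positive_control", ] + posShift
    makeScreen(m, cls)
}

## curve set built directly from a survival matrix
makeCurves <- function(P, cutoffs, direction = "positive") {
    new("ZetaCurveSet", P = P, cutoffs = cutoffs, direction = direction,
        step = (max(cutoffs) - min(cutoffs)) / (length(cutoffs) - 1))
}

makeBoundary <- function(S, cutoffs, direction = "positive") {
    new("ZetaBoundary", S = S, cutoffs = cutoffs, direction = direction,
        params = list(kernel = "radial", seed = 1, accuracy = 1))
}

## independent scalar oracle for the trapezoid area sums
zetaBruteForce <- function(P, S = NULL, cutoffs, weighted = FALSE) {
    B <- length(cutoffs) - 1
    step <- (max(cutoffs) - min(cutoffs)) / B
    total <- 0
    for (m in seq_len(B)) {
        pp <- P[m] + P[m + 1]
        a <- if (is.null(S)) pp * step / 2
             else {
                 ss <- S[m] + S[m + 1]
                 if (pp > ss) (pp - ss) * step / 2 else 0
             }
        if (weighted) a <- a * abs((cutoffs[m] + cutoffs[m + 1]) / 2)
        total <- total + a
    }
    total
}

## quadratic-time longest-common-substring oracle (dynamic programming)
lcsLength <- function(a, b) {
    av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
    prev <- integer(length(bv))
    best <- 0L
    for (i in seq_along(av)) {
        cur <- ifelse(av[i] == bv, 1L, 0L) *
            (1L + c(0L, prev[-length(prev)]))
        best <- max(best, cur)
        prev <- cur
    }
    best
}

revcompChr <- function(x) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

randDna <- function(len) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
          collapse = "")
}

## scalar oracle for the per-cell binned-curve area
cellZetaBruteForce <- function(counts1, edges) {
    y <- vapply(edges, function(t) sum(counts1 >= t), numeric(1))
    total <- 0
    for (b in seq_len(length(edges) - 1))
        total <- total + (y[b] + y[b + 1]) / 2 * (edges[b + 1] - edges[b])
    total
}
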