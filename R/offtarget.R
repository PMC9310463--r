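#' siRNA library: pools, guide sequences and target transcripts
#'
#' Holds the mapping from single siRNAs to their pools (one pool per gene),
#' the 19-23 nt guide sequences, and the transcript sequences scanned for
#' off-target complementarity. Guides may be given in the RNA or DNA
#' alphabet (U and T are equivalent); sequences are upper-cased and
#' validated on construction.
#'
#' @slot guides data.frame with columns \code{sirna_id}, \code{pool_id},
#'   \code{guide}.
#' @slot transcripts a \link[Biostrings]{DNAStringSet} named by gene id.
#' @aliases SirnaLibrary-class
#' @exportClass SirnaLibrary
setClass("SirnaLibrary",
         representation(guides = "data.frame", transcripts = "ANY"))

setValidity("SirnaLibrary", function(object) {
    msg <- NULL
    g <- object@guides
    if (!all(c("sirna_id", "pool_id", "guide") %in% names(g)))
        msg <- c(msg, "guides needs columns sirna_id, pool_id, guide")
    else {
        if (anyDuplicated(g$sirna_id))
            msg <- c(msg, "sirna ids must be unique")
        if (any(nchar(g$guide) < 11))
            msg <- c(msg, "guide sequences must be >= 11 nt")
        if (any(grepl("[^ACGTU]", g$guide)))
            msg <- c(msg, "guides must use the ACGU/ACGT alphabet")
    }
    if (is.null(msg)) TRUE else msg
})

#' @param guides data.frame with columns \code{sirna_id}, \code{pool_id},
#'   \code{guide} (sequences, RNA or DNA alphabet).
#' @param transcripts named character vector or
#'   \link[Biostrings]{DNAStringSet} of target transcripts per gene.
#' @return A \linkS4class{SirnaLibrary}.
#' @describeIn SirnaLibrary-class constructor.
#' @export
SirnaLibrary <- function(guides, transcripts) {
    guides$guide <- toupper(guides$guide)
    if (is.character(transcripts))
        transcripts <- Biostrings::DNAStringSet(
            gsub("U", "T", toupper(transcripts)))
    methods::new("SirnaLibrary", guides = guides,
                 transcripts = transcripts)
}

setMethod("show", "SirnaLibrary", function(object) {
    cat("SirnaLibrary:", nrow(object@guides), "guides in",
        length(unique(object@guides$pool_id)), "pools;",
        length(object@transcripts), "transcripts\n")
})

#' Pearson similarity of two perturbations' response profiles
#'
#' @param zm Z-score matrix (or \linkS4class{ScreenExperiment} with a
#'   zscore assay).
#' @param a,b row ids of the two perturbations.
#' @return Pearson correlation over the shared readouts.
#' @export
responseSimilarity <- function(zm, a, b) {
    z <- .asZMatrix(zm)
    va <- z[a, ]; vb <- z[b, ]
    ok <- is.finite(va) & is.finite(vb)
    if (sum(ok) < 10)
        stop("fewer than 10 shared readouts between ", a, " and ", b)
    if (stats::sd(va[ok]) == 0 || stats::sd(vb[ok]) == 0)
        stop("zero variance in a response profile")
    stats::cor(va[ok], vb[ok])
}

#' Scan a guide for contiguous complementarity to a transcript
#'
#' Finds every maximal run in which the reverse complement of the guide
#' matches the transcript contiguously for at least \code{minLen}
#' nucleotides (U and T equivalent; strict Watson-Crick, no G-U wobble).
#' Coordinates are 1-based and inclusive on the transcript.
#'
#' @param guide guide sequence (RNA or DNA alphabet).
#' @param transcript transcript sequence.
#' @param minLen minimum reported run length (default 11).
#' @return data.frame (length, t_start, t_end, g_start, g_end) sorted by
#'   decreasing length; zero rows when no run reaches \code{minLen}. Guide
#'   coordinates are on the guide as given (5' to 3').
#' @export
complementarityScan <- function(guide, transcript, minLen = 11) {
    guide <- gsub("U", "T", toupper(guide))
    transcript <- gsub("U", "T", toupper(transcript))
    if (grepl("[^ACGT]", guide) || grepl("[^ACGT]", transcript))
        stop("sequences must use the ACGU/ACGT alphabet")
    empty <- data.frame(length = integer(0), t_start = integer(0),
                        t_end = integer(0), g_start = integer(0),
                        g_end = integer(0))
    m <- nchar(guide); n <- nchar(transcript)
    if (m < minLen || n < minLen) {
        warning("sequence shorter than minLen (", minLen, " nt)")
        return(empty)
    }
    rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(guide)))
    rcv <- strsplit(rc, "")[[1]]
    tv <- strsplit(transcript, "")[[1]]
    acc <- vector("list", m + n - 1L)
    ai <- 0L
    for (d in seq(-(m - 1L), n - 1L)) {    # diagonal: rc pos i ~ t pos i+d
        i <- seq(max(1L, 1L - d), min(m, n - d))
        if (length(i) < minLen) next
        eq <- rcv[i] == tv[i + d]
        r <- rle(eq)
        keep <- r$values & r$lengths >= minLen
        if (!any(keep)) next
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
        i0 <- i[starts[keep]]; i1 <- i[ends[keep]]
        ai <- ai + 1L
        acc[[ai]] <- cbind(length = i1 - i0 + 1L,
                           t_start = i0 + d, t_end = i1 + d,
                           ## rc position p maps to guide position m-p+1
                           g_start = m - i1 + 1L, g_end = m - i0 + 1L)
    }
    if (ai == 0L) return(empty)
    hits <- as.data.frame(do.call(rbind, acc[seq_len(ai)]))
    hits[order(-hits$length), , drop = FALSE]
}

#' Attribute a pool-pool similarity to single siRNAs
#'
#' Given two correlated pools from the primary screen, checks which single
#' siRNAs of the first pool reproduce the second pool's response in the
#' secondary screen. Two or more correlated singles indicate genes of
#' related function; exactly one suggests that single siRNA acts off-target.
#'
#' @param primary primary-screen Z matrix (pools x readouts).
#' @param secondary secondary-screen Z matrix (single siRNAs x readouts,
#'   shared readout columns with \code{primary}).
#' @param singles row ids in \code{secondary} of the first pool's siRNAs.
#' @param poolB row id of the second pool in \code{primary}.
#' @param rMin correlation threshold (default 0.6).
#' @return list: \code{attribution} (one of \code{related_function},
#'   \code{off_target_candidate}, \code{none}, \code{unattributable}),
#'   \code{correlations} (named, per single), \code{suspect} (the single
#'   siRNA id when exactly one passes).
#' @export
attributeToSingleSirna <- function(primary, secondary, singles, poolB,
                                   rMin = 0.6) {
    primary <- .asZMatrix(primary); secondary <- .asZMatrix(secondary)
    singles <- intersect(singles, rownames(secondary))
    if (!length(singles))
        return(list(attribution = "unattributable",
                    correlations = numeric(0), suspect = NA_character_))
    shared <- intersect(colnames(secondary), colnames(primary))
    rb <- primary[poolB, shared]
    rs <- vapply(singles, function(s)
        stats::cor(secondary[s, shared], rb), numeric(1))
    nPass <- sum(rs >= rMin)
    att <- if (nPass >= 2) "related_function"
           else if (nPass == 1) "off_target_candidate"
           else "none"
    list(attribution = att, correlations = rs,
         suspect = if (nPass == 1) singles[which(rs >= rMin)]
                   else NA_character_)
}

#' Flag hit pools whose activity is explained by off-target silencing
#'
#' A pool is flagged when (i) one of its single siRNA guides carries at
#' least \code{minLen} nt of contiguous complementarity to another hit
#' gene's transcript, and (ii) that same siRNA (from the secondary screen;
#' or, lacking secondary data, the pool itself, reported at lower
#' confidence) correlates with that gene's primary response at
#' \code{r >= rMin}.
#'
#' @param zm primary Z-score matrix or \linkS4class{ScreenExperiment}.
#' @param lib a \linkS4class{SirnaLibrary}.
#' @param hits character vector of hit gene/pool ids (scan targets default
#'   to all hits; pass a shorter \code{againstGenes} to restrict to a
#'   user-defined list of well-known genes).
#' @param secondary optional secondary-screen Z matrix (singles x readouts).
#' @param againstGenes genes whose transcripts are scanned (default
#'   \code{hits}).
#' @param rMin correlation threshold (default 0.6).
#' @param minLen minimum complementarity (default 11 nt).
#' @return data.frame report, one row per flagged (pool, gene) pair:
#'   \code{pool_id}, \code{suspect_sirna_id}, \code{offended_gene},
#'   \code{match_length}, \code{match_start}, \code{match_end} (1-based,
#'   inclusive, on the transcript), \code{single_vs_pool_correlation},
#'   \code{pool_pool_correlation}, \code{evidence} ("single" or "pool").
#' @export
flagOfftargets <- function(zm, lib, hits, secondary = NULL,
                           againstGenes = hits, rMin = 0.6, minLen = 11) {
    stopifnot(methods::is(lib, "SirnaLibrary"))
    z <- .asZMatrix(zm)
    if (!is.null(secondary)) secondary <- .asZMatrix(secondary)
    rep0 <- data.frame(pool_id = character(0),
                       suspect_sirna_id = character(0),
                       offended_gene = character(0),
                       match_length = integer(0),
                       match_start = integer(0), match_end = integer(0),
                       single_vs_pool_correlation = numeric(0),
                       pool_pool_correlation = numeric(0),
                       evidence = character(0))
    out <- rep0
    tx <- lib@transcripts
    pools <- intersect(hits, unique(lib@guides$pool_id))
    pools <- intersect(pools, rownames(z))
    noTx <- setdiff(againstGenes, names(tx))
    if (length(noTx)) {
        warning("no transcript for candidate gene(s) ",
                paste(utils::head(noTx, 5), collapse = ", "),
                if (length(noTx) > 5) " ..." else "", "; pairs skipped")
    }
    genes <- intersect(setdiff(againstGenes, noTx), rownames(z))
    if (!length(pools) || !length(genes)) return(out)
    ## the correlation requirement (criterion ii) is cheap and is checked
    ## first; complementarity scans run only on the surviving pairs
    poolR <- stats::cor(t(z[pools, , drop = FALSE]),
                        t(z[genes, , drop = FALSE]))
    singleR <- NULL
    if (!is.null(secondary)) {
        shared <- intersect(colnames(secondary), colnames(z))
        sIds <- intersect(lib@guides$sirna_id, rownames(secondary))
        if (length(sIds))
            singleR <- stats::cor(
                t(secondary[sIds, shared, drop = FALSE]),
                t(z[genes, shared, drop = FALSE]))
    }
    for (pool in pools) {
        gs <- lib@guides[lib@guides$pool_id == pool, , drop = FALSE]
        for (si in seq_len(nrow(gs))) {
            sid <- gs$sirna_id[si]
            useSingle <- !is.null(singleR) && sid %in% rownames(singleR)
            for (gene in setdiff(genes, pool)) {
                r <- if (useSingle) singleR[sid, gene]
                     else poolR[pool, gene]
                if (is.na(r) || r < rMin) next
                mt <- complementarityScan(gs$guide[si],
                                          as.character(tx[[gene]]),
                                          minLen = minLen)
                if (!nrow(mt)) next
                out <- rbind(out, data.frame(
                    pool_id = pool, suspect_sirna_id = sid,
                    offended_gene = gene,
                    match_length = mt$length[1],
                    match_start = mt$t_start[1], match_end = mt$t_end[1],
                    single_vs_pool_correlation = r,
                    pool_pool_correlation = poolR[pool, gene],
                    evidence = if (useSingle) "single" else "pool"))
            }
        }
    }
    out
}

#' Remove flagged pools from a score table and recompute Screen Strength
#'
#' Drops the flagged pools from the scored-gene table and rebuilds the
#' Screen Strength curve with the baseline FDR fixed at the original
#' screen's value (removal acts on the hit side only, so Screen Strength
#' can only improve where a flagged non-expressor was a hit).
#'
#' @param scores named zeta vector or combined score data.frame.
#' @param classes named class vector or \linkS4class{ScreenExperiment}.
#' @param report the data.frame from \code{\link{flagOfftargets}}.
#' @param ... passed to \code{\link{screenStrength}}.
#' @return A \linkS4class{ScreenStrengthCurve} on the filtered scores.
#' @export
removeOfftargets <- function(scores, classes, report, ...) {
    u <- .geneUniverse(scores, classes)
    bFDR <- mean(u$ne)
    z <- .asZetaVector(scores)
    keep <- !names(z) %in% unique(report$pool_id)
    screenStrength(z[keep], classes, bFDR = bFDR, ...)
}
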