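#' Consensus-clustered functional-similarity network among hits
#'
#' Builds two gene-gene distance matrices from the hits' Z-score profiles,
#' \code{D = 1 - |r|} under Pearson and Spearman correlation; for each
#' distance and each k in \code{kRange}, runs \code{nRuns} seeded k-means
#' restarts on classical MDS coordinates of D. The consensus score of a
#' gene pair is the fraction of runs in which it is co-clustered. Final
#' cluster labels come from hierarchical clustering (average linkage) of
#' \code{1 - consensus}, cut at the k chosen by the elbow of the total
#' within-cluster sum of squares (maximum second difference across
#' \code{kRange}). Edges are kept where consensus >= \code{edgeThreshold},
#' signed by the Pearson correlation; disconnected nodes are trimmed.
#'
#' @param zm Z matrix restricted to hit rows (>= 10), or a
#'   \linkS4class{ScreenExperiment}.
#' @param zeta named zeta scores used as node size attribute (defaults to
#'   1 for all nodes).
#' @param kRange candidate cluster counts (default 2:8, clipped to
#'   n_hits / 2).
#' @param nRuns k-means restarts per (distance, k) (default 50).
#' @param seed RNG seed.
#' @param edgeThreshold consensus threshold for edges (default 0.5).
#' @return list: \code{graph} (igraph with node attributes \code{zeta},
#'   \code{cluster}; edge attributes \code{weight} = consensus,
#'   \code{sign}), \code{consensus} matrix, \code{clusters} (named vector),
#'   \code{k} (chosen cluster count), \code{wss} (total within-cluster sum
#'   of squares per k).
#' @export
consensusCluster <- function(zm, zeta = NULL, kRange = 2:8, nRuns = 50,
                             seed = 1L, edgeThreshold = 0.5) {
    z <- .asZMatrix(zm)
    n <- nrow(z)
    if (n < 10) stop("need >= 10 hits to build a network")
    kRange <- kRange[kRange >= 2 & kRange <= floor(n / 2)]
    if (!length(kRange)) stop("k range infeasible for ", n, " hits")
    if (is.null(zeta)) zeta <- stats::setNames(rep(1, n), rownames(z))
    rp <- stats::cor(t(z), method = "pearson")
    rs <- stats::cor(t(z), method = "spearman")
    co <- matrix(0, n, n, dimnames = list(rownames(z), rownames(z)))
    total <- 0L
    wss <- stats::setNames(numeric(length(kRange)), kRange)
    .withSeed(seed, {
        for (D in list(1 - abs(rp), 1 - abs(rs))) {
            ## duplicate profiles give degenerate distances; cmdscale then
            ## returns fewer informative axes, which is fine for k-means
            coords <- suppressWarnings(
                stats::cmdscale(stats::as.dist(D), k = min(n - 1L, 10L)))
            for (ki in seq_along(kRange)) {
                k <- kRange[ki]
                for (run in seq_len(nRuns)) {
                    km <- stats::kmeans(coords, centers = k,
                                        nstart = 1, iter.max = 50)
                    lab <- km$cluster
                    co <- co + outer(lab, lab, "==")
                    wss[ki] <- wss[ki] + km$tot.withinss
                    total <- total + 1L
                }
            }
        }
    })
    co <- co / total
    wss <- wss / (2 * nRuns)
    kStar <- .elbowK(kRange, wss)
    hc <- stats::hclust(stats::as.dist(1 - co), method = "average")
    clusters <- stats::cutree(hc, k = kStar)
    g <- .consensusGraph(co, rp, clusters, zeta, edgeThreshold)
    list(graph = g, consensus = co, clusters = clusters, k = kStar,
         wss = wss)
}

## elbow: k with the largest second difference of total WSS; for fewer
## than 3 candidate k values, the smallest k wins
.elbowK <- function(kRange, wss) {
    if (length(kRange) < 3) return(kRange[1])
    d2 <- diff(diff(wss))          # positive where the drop levels off
    kRange[which.max(d2) + 1L]
}

.consensusGraph <- function(co, rp, clusters, zeta, edgeThreshold) {
    n <- nrow(co)
    idx <- which(upper.tri(co) & co >= edgeThreshold, arr.ind = TRUE)
    edges <- data.frame(
        from = rownames(co)[idx[, 1]], to = rownames(co)[idx[, 2]],
        weight = co[idx],
        sign = ifelse(rp[idx] >= 0, "correlated", "anti-correlated"))
    g <- igraph::graph_from_data_frame(
        edges, directed = FALSE,
        vertices = data.frame(name = rownames(co),
                              zeta = unname(zeta[rownames(co)]),
                              cluster = unname(clusters[rownames(co)])))
    iso <- which(igraph::degree(g) == 0)
    if (length(iso)) g <- igraph::delete_vertices(g, iso)
    g
}

#' Export a gene network as GraphML (optionally GEXF-ready edge table)
#'
#' Writes the graph with node attributes \code{zeta} (size) and
#' \code{cluster} (colour) and edge attributes \code{weight} (consensus)
#' and \code{sign}. Disconnected nodes were already trimmed at
#' construction; a graph without edges is written with a warning.
#'
#' @param net result of \code{\link{consensusCluster}} or an igraph.
#' @param path output file path.
#' @param format "graphml" (default) or "gml".
#' @return invisibly, \code{path}.
#' @export
exportNetwork <- function(net, path, format = c("graphml", "gml")) {
    format <- match.arg(format)
    g <- if (igraph::is_igraph(net)) net else net$graph
    if (igraph::ecount(g) == 0)
        warning("network has no edges; writing an empty graph")
    igraph::write_graph(g, path, format = format)
    invisible(path)
}
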