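#' Induce the DE sub-network
#'
#' Vertex-induced subgraph of the interaction network on a gene set
#' (optionally keeping the seed gene). Isolated nodes are retained; an
#' empty intersection yields an empty graph with a warning.
#'
#' @param net an [InteractionNetwork-class].
#' @param genes character gene set.
#' @param seed_gene optional seed id always kept (e.g. the p38 gene).
#' @param annotations optional named character vector (node -> label, e.g.
#'   the Venn region the gene came from); unnamed genes get `"none"`.
#' @return a [SubNetwork-class].
#' @export
induceSubnetwork <- function(net, genes, seed_gene = NULL,
                             annotations = NULL) {
    stopifnot(length(genes) >= 1)
    g <- interactionGraph(net)
    keep <- intersect(unique(c(genes, seed_gene)), igraph::V(g)$name)
    if (!length(keep))
        warning("gene set is disjoint from the network; empty sub-network")
    sg <- igraph::induced_subgraph(g, keep)
    ann <- rep("none", length(keep))
    names(ann) <- keep
    if (!is.null(annotations)) {
        hit <- intersect(names(annotations), keep)
        ann[hit] <- annotations[hit]
    }
    if (!is.null(seed_gene) && seed_gene %in% keep)
        ann[seed_gene] <- "seed"
    methods::new("SubNetwork", graph = sg,
                 annotations = S4Vectors::DataFrame(
                     venn_region = unname(ann[igraph::V(sg)$name]),
                     row.names = igraph::V(sg)$name))
}

#' Node and edge betweenness centrality
#'
#' Exact betweenness on the undirected, unweighted sub-network (Brandes
#' accumulation via igraph), unnormalized: each unordered source-target
#' pair is counted once, so a path's middle node scores 1 and a star
#' center scores choose(k, 2). Setting `weighted = TRUE` uses
#' 1000 / score as the edge length so higher-confidence edges are shorter.
#'
#' @param sub a [SubNetwork-class] (or [InteractionNetwork-class]).
#' @param weighted use confidence-derived edge lengths (default FALSE,
#'   matching common STRING/Cytoscape practice).
#' @return list with `nodes` (data.frame node, betweenness) and `edges`
#'   (data.frame from, to, betweenness).
#' @export
betweennessTable <- function(sub, weighted = FALSE) {
    g <- interactionGraph(sub)
    w <- if (weighted && igraph::ecount(g) > 0)
        1000 / igraph::E(g)$score else NA
    nb <- igraph::betweenness(g, directed = FALSE, weights = w,
                              normalized = FALSE)
    eb <- igraph::edge_betweenness(g, directed = FALSE, weights = w)
    el <- igraph::as_edgelist(g)
    list(nodes = data.frame(node = igraph::V(g)$name,
                            betweenness = unname(nb),
                            stringsAsFactors = FALSE),
         edges = data.frame(from = el[, 1], to = el[, 2],
                            betweenness = eb, stringsAsFactors = FALSE))
}

#' Greedy-modularity community detection
#'
#' Partitions the sub-network by fast greedy modularity optimization
#' (Clauset-Newman-Moore), the package's stand-in for the Cytoscape GLay
#' clustering used in the original figure styling. The algorithm is
#' deterministic; `rng_seed` is accepted for interface uniformity.
#'
#' @param sub a [SubNetwork-class] or [InteractionNetwork-class].
#' @param rng_seed unused by the deterministic algorithm; kept so all
#'   pipeline stages share the seeded calling convention.
#' @return list with `membership` (named integer vector node -> community)
#'   and `modularity` (Q of the returned partition).
#' @export
detectCommunities <- function(sub, rng_seed = 1L) {
    g <- interactionGraph(sub)
    if (igraph::vcount(g) == 0) stop("empty graph")
    if (igraph::ecount(g) == 0)
        return(list(membership = stats::setNames(
            seq_len(igraph::vcount(g)), igraph::V(g)$name),
            modularity = NaN))
    cl <- igraph::cluster_fast_greedy(g, weights = NULL)
    # cut the dendrogram at the level of maximum recomputed Q; on ties
    # prefer fewer communities (the greedy merge stops at zero gain, which
    # would otherwise leave e.g. a single clique split in two)
    steps <- 0:nrow(cl$merges)
    q <- vapply(steps, function(s)
        igraph::modularity(g, igraph::cut_at(cl, steps = s)), numeric(1))
    best <- max(which(q >= max(q) - 1e-12))
    mem <- igraph::cut_at(cl, steps = steps[best])
    list(membership = stats::setNames(as.integer(mem),
                                      igraph::V(g)$name),
         modularity = unname(q[best]))
}

#' Export a styled GraphML of the sub-network
#'
#' Writes the sub-network with node attributes `betweenness` (node size),
#' `community` (color key) and `venn_region` (shape key), and the edge
#' attribute `betweenness` (line thickness), for downstream rendering.
#'
#' @param sub a [SubNetwork-class].
#' @param centrality output of [betweennessTable()].
#' @param partition output of [detectCommunities()].
#' @param path destination `.graphml`.
#' @export
exportStyledGraph <- function(sub, centrality, partition, path) {
    g <- interactionGraph(sub)
    ids <- igraph::V(g)$name
    miss <- setdiff(ids, centrality$nodes$node)
    if (length(miss))
        stop("node missing from centrality table: ", miss[1])
    miss <- setdiff(ids, names(partition$membership))
    if (length(miss))
        stop("node missing from community partition: ", miss[1])
    igraph::V(g)$betweenness <-
        centrality$nodes$betweenness[match(ids, centrality$nodes$node)]
    igraph::V(g)$community <- as.integer(partition$membership[ids])
    igraph::V(g)$venn_region <- nodeAnnotations(sub)$venn_region
    if (igraph::ecount(g) > 0) {
        el <- igraph::as_edgelist(g)
        key <- function(a, b) ifelse(a < b, paste(a, b), paste(b, a))
        ck <- key(centrality$edges$from, centrality$edges$to)
        igraph::E(g)$betweenness <-
            centrality$edges$betweenness[match(key(el[, 1], el[, 2]), ck)]
    }
    igraph::write_graph(g, path, format = "graphml")
    invisible(path)
}
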