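#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
#' @importClassesFrom S4Vectors DFrame
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom stats setNames
#' @importFrom utils combn
NULL

#' Gene-by-sample count container with group assignments
#'
#' `CountExperiment` extends [SummarizedExperiment::SummarizedExperiment] with
#' the invariants the pipeline relies on: a single `"counts"` assay of
#' non-negative integral values, unique gene and sample identifiers, and a
#' `group` column in `colData` assigning every sample to exactly one
#' experimental group (e.g. `RPE`, `TNT`, `PVR`).
#'
#' @slot .Data inherited SummarizedExperiment structure.
#' @export
setClass("CountExperiment", contains = "SummarizedExperiment")

setValidity("CountExperiment", function(object) {
    msg <- character()
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'counts' is required")
    else {
        m <- SummarizedExperiment::assay(object, "counts")
        if (any(!is.finite(m)))
            msg <- c(msg, "counts must be finite")
        else {
            if (any(m < 0)) msg <- c(msg, "counts must be non-negative")
            if (any(abs(m - round(m)) > 1e-8))
                msg <- c(msg, "counts must be integral")
        }
    }
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "gene identifiers must be present and unique")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "sample identifiers must be present and unique")
    if (!"group" %in% colnames(SummarizedExperiment::colData(object)))
        msg <- c(msg, "colData must contain a 'group' column")
    else if (anyNA(SummarizedExperiment::colData(object)$group))
        msg <- c(msg, "every sample needs a group label")
    if (length(msg)) msg else TRUE
})

#' Construct a CountExperiment
#'
#' @param counts numeric matrix of non-negative integral counts with gene
#'   rownames and sample colnames.
#' @param groups character or factor of group labels, either named by sample
#'   or in column order of `counts`.
#' @return A validated [CountExperiment-class] object.
#' @examples
#' m <- matrix(rpois(12, 20), nrow = 4,
#'             dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
#' ce <- CountExperiment(m, c("RPE", "RPE", "TNT"))
#' groupLabels(ce)
#' @export
CountExperiment <- function(counts, groups) {
    counts <- as.matrix(counts)
    if (!is.null(names(groups))) {
        missing <- setdiff(colnames(counts), names(groups))
        if (length(missing))
            stop("samples absent from group table: ",
                 paste(missing, collapse = ", "))
        groups <- groups[colnames(counts)]
    } else if (length(groups) != ncol(counts)) {
        stop("length of 'groups' must match the number of samples")
    }
    cd <- S4Vectors::DataFrame(group = factor(as.character(groups)),
                               row.names = colnames(counts))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = S4Vectors::SimpleList(counts = counts), colData = cd)
    methods::new("CountExperiment", se)
}

#' Per-gene differential-expression result
#'
#' A [S4Vectors::DataFrame]-derived table with one row per tested gene and
#' columns `logFC` (log2 fold-change of group B over group A on the
#' CPM + prior scale), `pvalue` and `qvalue` (Benjamini-Hochberg). The method
#' tag (`"exactNB"` or `"welchLogCPM"`) and the comparison label live in
#' `metadata()`.
#'
#' @export
setClass("DEResult", contains = "DFrame")

setValidity("DEResult", function(object) {
    msg <- character()
    need <- c("logFC", "pvalue", "qvalue")
    if (!all(need %in% colnames(object)))
        return(paste("columns required:", paste(need, collapse = ", ")))
    p <- object$pvalue; q <- object$qvalue
    if (any(p < 0 | p > 1, na.rm = TRUE)) msg <- c(msg, "p-values outside [0,1]")
    if (any(q < 0 | q > 1, na.rm = TRUE)) msg <- c(msg, "q-values outside [0,1]")
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "one uniquely named row per gene required")
    if (length(msg)) msg else TRUE
})

.DEResult <- function(genes, logFC, pvalue, qvalue, method, comparison) {
    df <- S4Vectors::DataFrame(logFC = logFC, pvalue = pvalue,
                               qvalue = qvalue, row.names = genes)
    res <- methods::new("DEResult", df)
    S4Vectors::metadata(res) <- list(method = method, comparison = comparison)
    res
}

#' Weighted undirected interaction network
#'
#' Wraps an [igraph::igraph] graph and enforces the STRING-style contract:
#' undirected, simple (no self-loops, no parallel edges), with a numeric
#' `score` edge attribute on the STRING combined-score scale (0-1000).
#'
#' @slot graph the underlying igraph object.
#' @export
setClass("InteractionNetwork", representation(graph = "ANY"))

setValidity("InteractionNetwork", function(object) {
    g <- object@graph
    if (!igraph::is_igraph(g)) return("'graph' must be an igraph object")
    msg <- character()
    if (igraph::is_directed(g)) msg <- c(msg, "network must be undirected")
    if (any(igraph::which_loop(g))) msg <- c(msg, "self-loops not allowed")
    if (any(igraph::which_multiple(g))) msg <- c(msg, "parallel edges not allowed")
    if (igraph::ecount(g) > 0) {
        sc <- igraph::edge_attr(g, "score")
        if (is.null(sc) || !is.numeric(sc))
            msg <- c(msg, "numeric 'score' edge attribute required")
        else if (any(sc < 0 | sc > 1000))
            msg <- c(msg, "scores must lie in [0, 1000]")
    }
    if (length(msg)) msg else TRUE
})

#' Construct an InteractionNetwork from an edge table
#'
#' Duplicate pairs (either orientation) are collapsed keeping the maximum
#' score; self-loops are dropped.
#'
#' @param edges data.frame with columns protein1, protein2, combined_score
#'   (names are positional; any 3-column frame works).
#' @param nodes optional character vector of node ids to include even when
#'   isolated.
#' @export
InteractionNetwork <- function(edges, nodes = NULL) {
    stopifnot(ncol(edges) >= 3)
    a <- as.character(edges[[1]]); b <- as.character(edges[[2]])
    s <- as.numeric(edges[[3]])
    if (anyNA(s)) stop("non-numeric combined_score")
    keep <- a != b
    a <- a[keep]; b <- b[keep]; s <- s[keep]
    key <- ifelse(a < b, paste(a, b, sep = "\r"), paste(b, a, sep = "\r"))
    if (length(key)) {
        smax <- tapply(s, key, max)
        parts <- strsplit(names(smax), "\r", fixed = TRUE)
        a <- vapply(parts, `[`, "", 1L)
        b <- vapply(parts, `[`, "", 2L)
        s <- as.numeric(smax)
    }
    allnodes <- union(nodes, union(a, b))
    g <- igraph::graph_from_data_frame(
        data.frame(from = a, to = b, score = s, stringsAsFactors = FALSE),
        directed = FALSE, vertices = allnodes)
    methods::new("InteractionNetwork", graph = g)
}

#' DE-intersected sub-network with node annotations
#'
#' An [InteractionNetwork-class] restricted to a gene set, carrying per-node
#' annotations (e.g. which Venn region / comparison each gene came from).
#'
#' @slot annotations a [S4Vectors::DataFrame] with one row per node.
#' @export
setClass("SubNetwork", contains = "InteractionNetwork",
         representation(annotations = "DFrame"))

setValidity("SubNetwork", function(object) {
    ids <- igraph::V(object@graph)$name
    if (!setequal(rownames(object@annotations), ids))
        return("annotations must cover exactly the retained nodes")
    TRUE
})

#' Eigengene/eigenarray decomposition of an expression matrix
#'
#' Singular value decomposition X = U diag(s) V' of a gene x sample
#' expression matrix: columns of U are eigenarrays (basis over genes),
#' columns of V are eigengenes (basis over samples), and the eigenexpression
#' fraction of mode k is s_k^2 / sum_j s_j^2.
#'
#' @slot eigenarrays gene x mode matrix (left singular vectors).
#' @slot eigengenes sample x mode matrix (right singular vectors).
#' @slot d singular values, non-increasing.
#' @slot fractions eigenexpression (variance) fractions, summing to 1.
#' @export
setClass("EigenDecomposition",
         representation(eigenarrays = "matrix", eigengenes = "matrix",
                        d = "numeric", fractions = "numeric"))

setValidity("EigenDecomposition", function(object) {
    msg <- character()
    d <- object@d
    if (any(d < 0)) msg <- c(msg, "singular values must be >= 0")
    if (is.unsorted(rev(d), strict = FALSE))
        msg <- c(msg, "singular values must be non-increasing")
    if (abs(sum(object@fractions) - 1) > 1e-10)
        msg <- c(msg, "fractions must sum to 1")
    U <- object@eigenarrays; V <- object@eigengenes
    if (max(abs(crossprod(U) - diag(ncol(U)))) > 1e-8)
        msg <- c(msg, "eigenarrays not orthonormal")
    if (max(abs(crossprod(V) - diag(ncol(V)))) > 1e-8)
        msg <- c(msg, "eigengenes not orthonormal")
    if (length(msg)) msg else TRUE
})

#' Seed-network enrichment result
#'
#' Holds the observed overlap between a significant-gene set and a network
#' gene set, its hypergeometric expectation, the resampling null draws, the
#' add-one-corrected empirical p, and the proportion Bayes factor (natural
#' log; log10 derived).
#'
#' @slot observed observed overlap x.
#' @slot expected hypergeometric mean |de||net|/|universe|.
#' @slot nullOverlaps the B null overlap draws.
#' @slot pEmpirical (1 + #\{null >= x\}) / (B + 1).
#' @slot lnBF natural-log Bayes factor, alternative over point null.
#' @slot sizes named integer vector (de, network, universe).
#' @slot iterations number of resampling draws B.
#' @slot seed RNG seed used for the null.
#' @export
setClass("EnrichmentResult",
         representation(observed = "integer", expected = "numeric",
                        nullOverlaps = "integer", pEmpirical = "numeric",
                        lnBF = "numeric", sizes = "integer",
                        iterations = "integer", seed = "integer"))

setValidity("EnrichmentResult", function(object) {
    msg <- character()
    if (object@observed < 0 ||
        object@observed > min(object@sizes[c("de", "network")]))
        msg <- c(msg, "observed overlap outside [0, min(set sizes)]")
    if (object@pEmpirical <= 0 || object@pEmpirical > 1)
        msg <- c(msg, "empirical p must lie in (0, 1]")
    if (length(object@nullOverlaps) != object@iterations)
        msg <- c(msg, "null draws must equal declared iterations")
    if (length(msg)) msg else TRUE
})

#' Coefficient-of-variation report for membrane counts
#'
#' Per-line CVs, the pooled inter-line CV over all experiments, the focal
#' line's intra-line CV, and the non-genetic variability fraction
#' 100 * intra / inter. A fraction above 100% is flagged, never clipped.
#'
#' @slot perLine DataFrame with per-line CV% and n.
#' @slot interline pooled CV% across all experiments.
#' @slot interlineN total experiment count.
#' @slot focalLine id of the designated line.
#' @slot intraline focal line's CV%.
#' @slot intralineN focal line's experiment count.
#' @slot nongeneticFraction 100 * intraline / interline (%).
#' @slot flagged TRUE when the fraction exceeds 100%.
#' @export
setClass("CVReport",
         representation(perLine = "DFrame", interline = "numeric",
                        interlineN = "integer", focalLine = "character",
                        intraline = "numeric", intralineN = "integer",
                        nongeneticFraction = "numeric", flagged = "logical"))
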