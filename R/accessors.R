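#' @describeIn CountExperiment group label of every sample, as a factor
#'   named by sample id.
#' @param x,object a `CountExperiment`.
#' @export
setGeneric("groupLabels", function(x) standardGeneric("groupLabels"))

#' @export
setMethod("groupLabels", "CountExperiment", function(x) {
    g <- SummarizedExperiment::colData(x)$group
    names(g) <- colnames(x)
    g
})

#' Raw counts of a CountExperiment
#' @param object a [CountExperiment-class].
#' @return the integer count matrix.
#' @export
setGeneric("countsMatrix", function(object) standardGeneric("countsMatrix"))

#' @rdname countsMatrix
#' @export
setMethod("countsMatrix", "CountExperiment",
          function(object) SummarizedExperiment::assay(object, "counts"))

#' Underlying igraph of an InteractionNetwork
#' @param object an [InteractionNetwork-class] or [SubNetwork-class].
#' @export
setGeneric("interactionGraph",
           function(object) standardGeneric("interactionGraph"))

#' @rdname interactionGraph
#' @export
setMethod("interactionGraph", "InteractionNetwork",
          function(object) object@graph)

#' Node annotations of a SubNetwork
#' @param object a [SubNetwork-class].
#' @export
setGeneric("nodeAnnotations",
           function(object) standardGeneric("nodeAnnotations"))

#' @rdname nodeAnnotations
#' @export
setMethod("nodeAnnotations", "SubNetwork",
          function(object) object@annotations)

#' @describeIn EigenDecomposition eigenarray basis (genes x modes).
#' @param object,x an `EigenDecomposition`.
#' @export
setGeneric("eigenarrays", function(object) standardGeneric("eigenarrays"))

#' @export
setMethod("eigenarrays", "EigenDecomposition",
          function(object) object@eigenarrays)

#' @describeIn EigenDecomposition eigengene basis (samples x modes).
#' @export
setGeneric("eigengenes", function(object) standardGeneric("eigengenes"))

#' @export
setMethod("eigengenes", "EigenDecomposition",
          function(object) object@eigengenes)

#' @describeIn EigenDecomposition singular values, non-increasing.
#' @export
setGeneric("singularValues",
           function(object) standardGeneric("singularValues"))

#' @export
setMethod("singularValues", "EigenDecomposition", function(object) object@d)

#' @describeIn EigenDecomposition eigenexpression (variance) fractions
#'   s_k^2 / sum s_j^2.
#' @export
setGeneric("eigenexpressionFractions",
           function(object) standardGeneric("eigenexpressionFractions"))

#' @export
setMethod("eigenexpressionFractions", "EigenDecomposition",
          function(object) object@fractions)

#' @describeIn EnrichmentResult observed overlap count.
#' @param object an `EnrichmentResult`.
#' @export
setGeneric("observedOverlap",
           function(object) standardGeneric("observedOverlap"))

#' @export
setMethod("observedOverlap", "EnrichmentResult",
          function(object) object@observed)

#' @describeIn EnrichmentResult the B null overlap draws.
#' @export
setGeneric("nullOverlaps", function(object) standardGeneric("nullOverlaps"))

#' @export
setMethod("nullOverlaps", "EnrichmentResult",
          function(object) object@nullOverlaps)

#' @describeIn EnrichmentResult add-one-corrected empirical p-value.
#' @export
setGeneric("empiricalP", function(object) standardGeneric("empiricalP"))

#' @export
setMethod("empiricalP", "EnrichmentResult", function(object) object@pEmpirical)

#' @describeIn EnrichmentResult natural-log Bayes factor; use
#'   `lnBF(x)/log(10)` for base 10.
#' @export
setGeneric("lnBF", function(object) standardGeneric("lnBF"))

#' @export
setMethod("lnBF", "EnrichmentResult", function(object) object@lnBF)

#' @describeIn CVReport non-genetic variability fraction in percent.
#' @param object a `CVReport`.
#' @export
setGeneric("nongeneticFractionPct",
           function(object) standardGeneric("nongeneticFractionPct"))

#' @export
setMethod("nongeneticFractionPct", "CVReport",
          function(object) object@nongeneticFraction)

setMethod("show", "CountExperiment", function(object) {
    methods::callNextMethod()
    cat("groups:", paste(sprintf("%s(%d)", levels(groupLabels(object)),
        tabulate(groupLabels(object))), collapse = " "), "\n")
})

setMethod("show", "InteractionNetwork", function(object) {
    g <- object@graph
    cat(sprintf("%s with %d nodes and %d edges\n", class(object),
                igraph::vcount(g), igraph::ecount(g)))
    if (igraph::ecount(g) > 0)
        cat(sprintf("  combined score range: [%g, %g]\n",
                    min(igraph::E(g)$score), max(igraph::E(g)$score)))
})

setMethod("show", "EigenDecomposition", function(object) {
    k <- min(3L, length(object@d))
    cat(sprintf("EigenDecomposition: %d genes x %d samples\n",
                nrow(object@eigenarrays), nrow(object@eigengenes)))
    cat(sprintf("  leading eigenexpression fractions: %s\n",
                paste(sprintf("%.1f%%", 100 * object@fractions[seq_len(k)]),
                      collapse = ", ")))
})

setMethod("show", "EnrichmentResult", function(object) {
    cat("EnrichmentResult\n")
    cat(sprintf("  de %d / network %d / universe %d\n",
                object@sizes["de"], object@sizes["network"],
                object@sizes["universe"]))
    cat(sprintf("  overlap %d (expected %.2f), empirical p = %.4g (B = %d)\n",
                object@observed, object@expected, object@pEmpirical,
                object@iterations))
    cat(sprintf("  Bayes factor: ln BF = %.2f (log10 BF = %.2f)\n",
                object@lnBF, object@lnBF / log(10)))
})

setMethod("show", "CVReport", function(object) {
    cat("CVReport\n")
    cat(sprintf("  inter-line CV = %.2f%% (n = %d, pooled)\n",
                object@interline, object@interlineN))
    cat(sprintf("  intra-line CV [line %s] = %.2f%% (n = %d)\n",
                object@focalLine, object@intraline, object@intralineN))
    cat(sprintf("  non-genetic fraction = %.1f%%%s\n",
                object@nongeneticFraction,
                if (object@flagged) "  [exceeds 100% - intra > inter]" else ""))
})
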