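#' Pipeline configuration
#'
#' Bundles the tunable parameters shared across the pipeline stages. Defaults
#' follow common practice in the field: a 2-fold change cutoff, BH FDR 0.05,
#' 1000 resampling iterations, 2-hop seed neighborhoods, and a STRING
#' combined-score floor of 700 ("high confidence").
#'
#' @param fc_threshold linear fold-change cutoff (> 1); significance requires
#'   |log2FC| >= log2(fc_threshold), inclusive.
#' @param fdr_alpha Benjamini-Hochberg q-value threshold in (0, 1).
#' @param n_iterations resampling-null draw count (>= 1).
#' @param k_hops neighborhood depth around the seed gene (>= 1).
#' @param score_min minimum STRING combined score for an edge to be kept.
#' @param rng_seed integer seed used by every randomized stage.
#' @param min_cpm,min_samples expression filter: keep genes with
#'   CPM > `min_cpm` in at least `min_samples` samples (`min_samples = NULL`
#'   means the smallest group size of the comparison).
#' @return a validated list of class `pvr_config`.
#' @examples
#' cfg <- pvrConfig(fdr_alpha = 0.01)
#' cfg$fc_threshold
#' @export
pvrConfig <- function(fc_threshold = 2, fdr_alpha = 0.05,
                      n_iterations = 1000L, k_hops = 2L, score_min = 700,
                      rng_seed = 1L, min_cpm = 1, min_samples = NULL) {
    stopifnot(fc_threshold > 1, fdr_alpha > 0, fdr_alpha < 1,
              n_iterations >= 1, k_hops >= 1, score_min >= 0, min_cpm >= 0)
    structure(list(fc_threshold = fc_threshold, fdr_alpha = fdr_alpha,
                   n_iterations = as.integer(n_iterations),
                   k_hops = as.integer(k_hops), score_min = score_min,
                   rng_seed = as.integer(rng_seed), min_cpm = min_cpm,
                   min_samples = min_samples),
              class = "pvr_config")
}

# counts-per-million; libsize from column sums unless supplied
.cpm <- function(counts, lib_size = colSums(counts)) {
    sweep(counts, 2, lib_size / 1e6, "/")
}

#' Expression filter
#'
#' Keep genes with CPM above `min_cpm` in at least `min_samples` samples —
#' the conventional pre-filter applied before dispersion estimation and
#' testing.
#'
#' @param ce a [CountExperiment-class].
#' @param min_cpm CPM threshold (strict inequality).
#' @param min_samples minimum number of samples exceeding it; defaults to
#'   the smallest group size.
#' @return the filtered `CountExperiment`.
#' @export
filterByExpression <- function(ce, min_cpm = 1, min_samples = NULL) {
    stopifnot(methods::is(ce, "CountExperiment"))
    if (is.null(min_samples))
        min_samples <- min(tabulate(groupLabels(ce)))
    keep <- rowSums(.cpm(countsMatrix(ce)) > min_cpm) >= min_samples
    ce[keep, ]
}
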