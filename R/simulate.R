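#' Simulation design for the three-group RNA-seq experiment
#'
#' Describes a synthetic bulk RNA-seq study with groups RPE (control), TNT
#' (TGFb1 + TNFa treated) and PVR (patient membrane). Counts are negative
#' binomial with variance mu + phi * mu^2. A fraction `de_fraction` of genes
#' carries a planted log2 fold-change in TNT versus RPE; the PVR group mean
#' is a linear-scale mixture `(1 - pvr_mixture) * TNT + pvr_mixture * RPE`,
#' emulating membranes that still contain an RPE-like cell population.
#'
#' @param n_genes number of genes.
#' @param samples_per_group named integer vector for RPE, TNT, PVR (each
#'   >= 2). Default 3 per group.
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of the
#'   baseline per-gene expression level, on the counts-at-1e6-library scale.
#' @param lib_size_range library sizes are drawn log-uniformly over this
#'   range (default 0.5e6 to 2e6, exercising CPM normalization).
#' @param phi NB dispersion, scalar or per-gene vector (>= 0; 0 gives
#'   Poisson counts).
#' @param de_fraction fraction of genes differentially expressed in TNT vs
#'   RPE.
#' @param lfc_mean,lfc_sd magnitude of planted |log2FC| is N(lfc_mean,
#'   lfc_sd) truncated below at 0.1; signs are balanced at random. The
#'   defaults center effects at 4-fold with substantial spread, emulating
#'   the broad transcriptome remodeling seen in treated and diseased
#'   samples.
#' @param pvr_mixture RPE admixture proportion pi in [0, 1] for the PVR
#'   group mean.
#' @param rng_seed integer seed.
#' @return a list of class `pvr_sim_design`.
#' @export
simulationDesign <- function(n_genes = 12000,
                             samples_per_group = c(RPE = 3, TNT = 3, PVR = 3),
                             baseline_meanlog = log(50), baseline_sdlog = 1.2,
                             lib_size_range = c(5e5, 2e6),
                             phi = 0.05, de_fraction = 0.35,
                             lfc_mean = 2, lfc_sd = 0.7,
                             pvr_mixture = 0.3, rng_seed = 1L) {
    stopifnot(n_genes >= 1, all(samples_per_group >= 2),
              all(phi >= 0), de_fraction >= 0, de_fraction <= 1,
              pvr_mixture >= 0, pvr_mixture <= 1,
              length(lib_size_range) == 2, all(lib_size_range > 0))
    if (is.null(names(samples_per_group)))
        names(samples_per_group) <- c("RPE", "TNT", "PVR")
    structure(list(n_genes = as.integer(n_genes),
                   samples_per_group = samples_per_group,
                   baseline_meanlog = baseline_meanlog,
                   baseline_sdlog = baseline_sdlog,
                   lib_size_range = lib_size_range, phi = phi,
                   de_fraction = de_fraction, lfc_mean = lfc_mean,
                   lfc_sd = lfc_sd, pvr_mixture = pvr_mixture,
                   rng_seed = as.integer(rng_seed)),
              class = "pvr_sim_design")
}

# NB draw that degrades gracefully to Poisson at phi = 0
.rnb <- function(n, mu, phi) {
    out <- numeric(n)
    pois <- phi == 0 | mu == 0
    if (any(pois)) out[pois] <- stats::rpois(sum(pois), mu[pois])
    if (any(!pois)) out[!pois] <- stats::rnbinom(sum(!pois),
                                                 size = 1 / phi[!pois],
                                                 mu = mu[!pois])
    out
}

#' Simulate three-group NB counts with planted effects
#'
#' @param design a [simulationDesign()] object.
#' @return a list with `counts` (a [CountExperiment-class]) and `truth`, a
#'   data.frame with per-gene DE status, the planted log2FC in TNT vs RPE,
#'   and the implied log2FC in PVR vs RPE after admixture.
#' @examples
#' sim <- simulateCounts(simulationDesign(n_genes = 100, rng_seed = 7))
#' table(sim$truth$de)
#' @export
simulateCounts <- function(design) {
    stopifnot(inherits(design, "pvr_sim_design"))
    set.seed(design$rng_seed)
    n <- design$n_genes
    genes <- sprintf("gene%05d", seq_len(n))
    phi <- rep_len(design$phi, n)

    base <- stats::rlnorm(n, design$baseline_meanlog, design$baseline_sdlog)
    de <- stats::runif(n) < design$de_fraction
    mag <- pmax(stats::rnorm(n, design$lfc_mean, design$lfc_sd), 0.1)
    lfc <- ifelse(de, mag * sample(c(-1, 1), n, replace = TRUE), 0)

    mu_rpe <- base
    mu_tnt <- base * 2^lfc
    pi <- design$pvr_mixture
    mu_pvr <- (1 - pi) * mu_tnt + pi * mu_rpe

    spg <- design$samples_per_group
    groups <- rep(names(spg), spg)
    samples <- paste0(groups, "_", unlist(lapply(spg, seq_len)))
    lsr <- log(design$lib_size_range)
    lib <- exp(stats::runif(length(samples), lsr[1], lsr[2]))

    mu_group <- cbind(RPE = mu_rpe, TNT = mu_tnt, PVR = mu_pvr)
    m <- matrix(0, n, length(samples), dimnames = list(genes, samples))
    for (j in seq_along(samples))
        m[, j] <- .rnb(n, mu_group[, groups[j]] * lib[j] / 1e6, phi)

    truth <- data.frame(gene = genes, de = de, true_lfc_tnt = lfc,
                        true_lfc_pvr = log2(((1 - pi) * 2^lfc + pi)),
                        stringsAsFactors = FALSE)
    list(counts = CountExperiment(m, stats::setNames(groups, samples)),
         truth = truth)
}

#' Simulate a scale-free interaction network with planted seed-neighborhood
#' enrichment
#'
#' Builds a preferential-attachment topology, places the seed gene on the
#' network's founding node, and assigns the remaining gene ids to node slots
#' so that genes flagged DE in `truth` enter the seed's <= 2-hop
#' neighborhood with `rho`-fold the probability of non-DE genes
#' (`rho = 1` is the uniform null).
#'
#' @param n_nodes number of network nodes (<= number of genes in `truth`).
#' @param m_attach edges added per new node (preferential attachment).
#' @param seed_gene gene id to place at the network seed; must occur in
#'   `truth$gene`.
#' @param rho enrichment ratio >= 1.
#' @param truth truth table from [simulateCounts()].
#' @param rng_seed integer seed.
#' @return an [InteractionNetwork-class] whose node names are gene ids;
#'   edge scores are drawn uniformly on the STRING high-confidence band
#'   [700, 999].
#' @export
simulateNetwork <- function(n_nodes, m_attach, seed_gene, rho, truth,
                            rng_seed = 1L) {
    stopifnot(rho >= 1, n_nodes >= m_attach + 1,
              n_nodes <= nrow(truth))
    if (!seed_gene %in% truth$gene)
        stop("seed gene '", seed_gene, "' not in the gene universe")
    set.seed(as.integer(rng_seed))
    g <- igraph::sample_pa(n_nodes, m = m_attach, directed = FALSE)

    hood <- as.integer(igraph::ego(g, order = 2, nodes = 1)[[1]])
    others <- setdiff(truth$gene, seed_gene)
    w <- ifelse(truth$de[match(others, truth$gene)], rho, 1)
    hood_genes <- sample(others, length(hood) - 1L, prob = w)
    rest_slots <- setdiff(seq_len(n_nodes), hood)
    rest_genes <- sample(setdiff(others, hood_genes), length(rest_slots))

    name <- character(n_nodes)
    name[1] <- seed_gene
    name[setdiff(hood, 1L)] <- hood_genes
    name[rest_slots] <- rest_genes
    igraph::V(g)$name <- name
    igraph::E(g)$score <- round(stats::runif(igraph::ecount(g), 700, 999))
    g <- igraph::simplify(g, edge.attr.comb = list(score = "max"))
    methods::new("InteractionNetwork", graph = g)
}

#' Flag truth-table genes by network and seed-neighborhood membership
#'
#' @param truth truth table from [simulateCounts()].
#' @param net an [InteractionNetwork-class] over the same gene universe.
#' @param seed_gene seed gene id.
#' @param k neighborhood depth.
#' @return `truth` with logical columns `in_network` and `in_neighborhood`.
#' @export
annotateTruthWithNetwork <- function(truth, net, seed_gene, k = 2) {
    hood <- kHopNeighborhood(net, seed_gene, k)
    truth$in_network <- truth$gene %in% igraph::V(interactionGraph(net))$name
    truth$in_neighborhood <- truth$gene %in% hood
    truth
}

#' Simulate replicate membrane-count tables
#'
#' Line means are log-normal around `grand_mean` with coefficient of
#' variation `between_line_cv`; per-experiment counts are log-normal around
#' the line mean with CV `within_line_cv`, rounded to integers. Log-normal
#' draws are mean-corrected so the targeted means are preserved.
#'
#' @param n_lines number of donor lines.
#' @param experiments_per_line scalar or length-`n_lines` vector (>= 1);
#'   the default reproduces the study layout of 26 experiments over 11
#'   lines with one heavily replicated focal line (n = 6).
#' @param grand_mean expected membrane count per experiment (> 0).
#' @param between_line_cv,within_line_cv CVs on the natural (not percent)
#'   scale, >= 0.
#' @param rng_seed integer seed.
#' @return data.frame with columns `line`, `experiment`, `count`.
#' @export
simulateMembraneCounts <- function(n_lines = 11,
                                   experiments_per_line = c(6, rep(2, 10)),
                                   grand_mean = 300, between_line_cv = 0.5,
                                   within_line_cv = 0.7, rng_seed = 1L) {
    stopifnot(grand_mean > 0, between_line_cv >= 0, within_line_cv >= 0,
              n_lines >= 1)
    set.seed(as.integer(rng_seed))
    npl <- rep_len(experiments_per_line, n_lines)
    sdl_b <- sqrt(log1p(between_line_cv^2))
    sdl_w <- sqrt(log1p(within_line_cv^2))
    lines <- LETTERS[seq_len(min(n_lines, 26))]
    if (n_lines > 26)
        lines <- c(lines, paste0("L", seq(27, n_lines)))
    line_mean <- grand_mean * exp(stats::rnorm(n_lines, -sdl_b^2 / 2, sdl_b))
    out <- do.call(rbind, lapply(seq_len(n_lines), function(i) {
        v <- line_mean[i] * exp(stats::rnorm(npl[i], -sdl_w^2 / 2, sdl_w))
        data.frame(line = lines[i], experiment = seq_len(npl[i]),
                   count = as.integer(round(v)), stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
}
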