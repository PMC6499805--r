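test_that("count simulator hits the Poisson limit at phi = 0", {
    d <- simulationDesign(n_genes = 1, baseline_meanlog = log(100),
                          baseline_sdlog = 0, phi = 0, de_fraction = 0,
                          lib_size_range = c(1e6, 1e6),
                          samples_per_group = c(RPE = 5000, TNT = 2,
                                                PVR = 2),
                          rng_seed = 3)
    sim <- simulateCounts(d)
    x <- countsMatrix(sim$counts)[1, groupLabels(sim$counts) == "RPE"]
    se <- sqrt(100 / length(x))       # Poisson s.e. of the mean
    expect_lt(abs(mean(x) - 100), 3 * se)
})

test_that("simulator is deterministic and honors the mixture endpoints", {
    d <- simulationDesign(n_genes = 80, rng_seed = 9)
    expect_identical(countsMatrix(simulateCounts(d)$counts),
                     countsMatrix(simulateCounts(d)$counts))

    # pi = 1: PVR group mean vector equals the RPE mean vector exactly,
    # so the implied PVR log2FC vanishes for every gene
    d1 <- simulationDesign(n_genes = 60, pvr_mixture = 1, de_fraction = 0.5,
                           rng_seed = 5)
    tr <- simulateCounts(d1)$truth
    expect_equal(tr$true_lfc_pvr, rep(0, nrow(tr)))
})

test_that("per-gene variance tracks the NB mean-variance relation", {
    d <- simulationDesign(n_genes = 60, phi = 0.2, de_fraction = 0,
                          baseline_meanlog = log(200), baseline_sdlog = 0.5,
                          lib_size_range = c(1e6, 1e6),
                          samples_per_group = c(RPE = 500, TNT = 2, PVR = 2),
                          rng_seed = 21)
    sim <- simulateCounts(d)
    m <- countsMatrix(sim$counts)[, groupLabels(sim$counts) == "RPE"]
    mu <- rowMeans(m)
    v <- apply(m, 1, var)
    rel <- abs(mean(v) - mean(mu + 0.2 * mu^2)) / mean(mu + 0.2 * mu^2)
    expect_lt(rel, 0.15)
})

test_that("PVR-to-RPE mean distance shrinks monotonically in the admixture",
{
    dist_at <- function(pi) {
        d <- simulationDesign(n_genes = 200, pvr_mixture = pi,
                              de_fraction = 0.3, rng_seed = 77)
        tr <- simulateCounts(d)$truth
        sqrt(sum(tr$true_lfc_pvr^2))
    }
    dists <- vapply(c(0, 0.25, 0.5, 0.75, 1), dist_at, numeric(1))
    expect_true(all(diff(dists) < 0))
    expect_equal(dists[5], 0)
})

test_that("network simulator obeys the attachment arithmetic", {
    tr <- data.frame(gene = paste0("g", 1:10), de = FALSE,
                     stringsAsFactors = FALSE)
    net <- simulateNetwork(5, 1, "g1", rho = 1, truth = tr, rng_seed = 2)
    g <- interactionGraph(net)
    expect_equal(igraph::vcount(g), 5)
    expect_equal(igraph::ecount(g), 4)          # tree on 5 nodes
    expect_true(igraph::is_connected(g))
    expect_error(simulateNetwork(5, 1, "absent", 1, tr), "not in")
    # larger m still connected, deterministic under a fixed seed
    tr2 <- data.frame(gene = paste0("g", 1:200), de = FALSE)
    n1 <- simulateNetwork(150, 3, "g7", 1, tr2, rng_seed = 8)
    n2 <- simulateNetwork(150, 3, "g7", 1, tr2, rng_seed = 8)
    expect_true(igraph::is_connected(interactionGraph(n1)))
    expect_identical(igraph::as_data_frame(interactionGraph(n1)),
                     igraph::as_data_frame(interactionGraph(n2)))
})

test_that("at rho = 1 DE genes fall in the 2-hop neighborhood at the
           uniform rate", {
    set.seed(101)
    tr <- data.frame(gene = paste0("g", 1:150),
                     de = rep(c(TRUE, FALSE), c(30, 120)))
    frac_de <- hood_frac <- numeric(200)
    for (i in seq_len(200)) {
        net <- simulateNetwork(100, 2, "g100", rho = 1, truth = tr,
                               rng_seed = 1000 + i)
        hood <- kHopNeighborhood(net, "g100", 2)
        frac_de[i] <- mean(tr$gene[tr$de] %in% hood)
        hood_frac[i] <- length(hood) / nrow(tr)
    }
    # Monte-Carlo mean vs expected uniform proportion
    expect_lt(abs(mean(frac_de) - mean(hood_frac)), 0.02)
})

test_that("membrane-count simulator honors zero noise, determinism and
           CV recovery", {
    t0 <- simulateMembraneCounts(4, 3, grand_mean = 250,
                                 between_line_cv = 0, within_line_cv = 0,
                                 rng_seed = 1)
    expect_true(all(t0$count == 250))
    expect_identical(simulateMembraneCounts(rng_seed = 6),
                     simulateMembraneCounts(rng_seed = 6))

    big <- simulateMembraneCounts(6, 200, grand_mean = 400,
                                  between_line_cv = 0.5,
                                  within_line_cv = 0.3, rng_seed = 31)
    cvs <- sapply(split(big$count, big$line),
                  function(v) coefficientOfVariation(v) / 100)
    expect_lt(abs(mean(cvs) - 0.3) / 0.3, 0.1)
})

test_that("a null pipeline yields uniform-ish enrichment p-values", {
    # de_fraction = 0 and rho = 1: gene lists carry no signal and the
    # network places them uniformly, so the resampling p should be flat
    pvals <- numeric(100)
    for (i in seq_len(100)) {
        d <- simulationDesign(n_genes = 300, de_fraction = 0, phi = 0.05,
                              samples_per_group = c(RPE = 3, TNT = 3,
                                                    PVR = 2),
                              rng_seed = 5000 + i)
        sim <- simulateCounts(d)
        ce <- filterByExpression(sim$counts)
        res <- exactTestNB(ce, c("RPE", "TNT"),
                           estimateCommonDispersion(ce, c("RPE", "TNT")))
        de <- rownames(res)[order(res$pvalue)][1:30]
        net <- simulateNetwork(200, 2, sim$truth$gene[1], rho = 1,
                               truth = sim$truth, rng_seed = 6000 + i)
        hood <- kHopNeighborhood(net, sim$truth$gene[1], 2)
        er <- networkEnrichment(de, intersect(hood, rownames(res)),
                                rownames(res), B = 500,
                                rng_seed = 7000 + i)
        pvals[i] <- empiricalP(er)
    }
    ks <- suppressWarnings(ks.test(pvals, "punif"))
    expect_gt(ks$p.value, 0.01)
})
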