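test_that("common dispersion: degenerate inputs give phi = 0, simulation
           recovers the truth", {
    # replicate-identical counts within groups -> zero residual variance
    m <- cbind(a1 = c(10, 40), a2 = c(10, 40), b1 = c(30, 8),
               b2 = c(30, 8))
    rownames(m) <- c("g1", "g2")
    ce <- CountExperiment(m, c("A", "A", "B", "B"))
    expect_equal(estimateCommonDispersion(ce, c("A", "B")), 0)

    # single gene, equal counts and library sizes
    m1 <- matrix(10, 1, 4, dimnames = list("g", paste0("s", 1:4)))
    ce1 <- CountExperiment(m1, c("A", "A", "B", "B"))
    expect_equal(estimateCommonDispersion(ce1, c("A", "B")), 0)

    expect_error(estimateCommonDispersion(
        CountExperiment(m[, 1:3], c("A", "A", "B")), c("A", "B")),
        ">= 2 samples")

    # recovery: 200 + 200 samples at phi = 0.1
    d <- simulationDesign(n_genes = 300, phi = 0.1, de_fraction = 0,
                          samples_per_group = c(RPE = 200, TNT = 200,
                                                PVR = 2),
                          rng_seed = 13)
    ceS <- filterByExpression(simulateCounts(d)$counts)
    phihat <- estimateCommonDispersion(ceS, c("RPE", "TNT"))
    expect_gt(phihat, 0.07)
    expect_lt(phihat, 0.13)
})

test_that("exact NB test reproduces hand-enumerated binomial cases", {
    # library sizes equal by construction (35 each), so pseudo-counts
    # coincide with raw counts
    m <- rbind(g1 = c(0, 10), g2 = c(5, 5), pad = c(30, 20))
    colnames(m) <- c("A1", "B1")
    ce <- CountExperiment(m, c("A", "B"))
    res <- exactTestNB(ce, c("A", "B"), phi = 0)
    expect_equal(unname(res["g1", "pvalue"]), 2 * 0.5^10, tolerance = 1e-12)
    expect_equal(unname(res["g2", "pvalue"]), 1)  # symmetric, tail doubling caps
    expect_error(exactTestNB(ce, c("A", "B"), phi = -1), ">= 0")
})

test_that("exact test p-values match exhaustive conditional-pmf enumeration",
{
    set.seed(19)
    for (phi in c(0, 0.05, 0.3)) {
        nA <- 3; nB <- 4
        m <- matrix(rpois(10 * (nA + nB), 4), nrow = 10)   # totals <= ~60
        rownames(m) <- paste0("g", 1:10)
        colnames(m) <- paste0("s", 1:(nA + nB))
        # equal library sizes so pseudo-counts equal raw counts
        m[10, ] <- m[10, ] + (max(colSums(m)) - colSums(m))
        ce <- CountExperiment(m, rep(c("A", "B"), c(nA, nB)))
        res <- exactTestNB(ce, c("A", "B"), phi = phi)
        for (i in seq_len(10)) {
            sA <- sum(m[i, 1:nA]); t <- sum(m[i, ])
            expect_equal(res$pvalue[i], exactPOracle(sA, t, nA, nB, phi),
                         tolerance = 1e-10,
                         info = sprintf("phi=%g gene=%d", phi, i))
        }
    }
})

test_that("swapping group labels negates log2FC and preserves p", {
    ce <- makeTinyCounts(40, seed = 23)
    phi <- estimateCommonDispersion(ce, c("RPE", "TNT"))
    fwd <- exactTestNB(ce, c("RPE", "TNT"), phi)
    rev <- exactTestNB(ce, c("TNT", "RPE"), phi)
    expect_equal(rev$logFC, -fwd$logFC, tolerance = 1e-12)
    expect_equal(rev$pvalue, fwd$pvalue, tolerance = 1e-12)
    wf <- logcpmWelchTest(ce, c("RPE", "TNT"))
    wr <- logcpmWelchTest(ce, c("TNT", "RPE"))
    expect_equal(wr$logFC, -wf$logFC, tolerance = 1e-12)
    expect_equal(wr$pvalue, wf$pvalue, tolerance = 1e-12)
})

test_that("Welch route agrees with the textbook computation and stats::t.test",
{
    m <- rbind(g1 = c(12, 25, 40, 80, 110, 140),
               g2 = c(30, 30, 30, 30, 30, 30),
               g3 = c(5, 9, 14, 50, 75, 60))
    colnames(m) <- paste0("s", 1:6)
    m <- rbind(m, pad = max(colSums(m)) - colSums(m) + 100)  # equal libs
    ce <- CountExperiment(m, rep(c("A", "B"), each = 3))
    res <- logcpmWelchTest(ce, c("A", "B"), prior_count = 0.5)

    lib <- colSums(m)
    x <- log2(sweep(m, 2, lib / 1e6, "/") + 0.5)
    for (g in c("g1", "g3")) {
        a <- x[g, 1:3]; b <- x[g, 4:6]
        # hand-worked Welch statistic and Satterthwaite df
        se2 <- var(a) / 3 + var(b) / 3
        tt <- (mean(b) - mean(a)) / sqrt(se2)
        df <- se2^2 / ((var(a) / 3)^2 / 2 + (var(b) / 3)^2 / 2)
        expect_equal(unname(res[g, "pvalue"]), 2 * pt(-abs(tt), df),
                     tolerance = 1e-8)
        expect_equal(unname(res[g, "pvalue"]),
                     t.test(b, a)$p.value, tolerance = 1e-8)
        expect_equal(unname(res[g, "logFC"]), mean(b) - mean(a), tolerance = 1e-10)
    }
    # identical distributions in both groups
    expect_equal(unname(res["g2", "pvalue"]), 1)
    expect_equal(unname(res["g2", "logFC"]), 0)

    # permuting sample order changes nothing
    perm <- c(3, 1, 2, 6, 4, 5)
    ce2 <- CountExperiment(m[, perm], rep(c("A", "B"), each = 3)[perm])
    res2 <- logcpmWelchTest(ce2, c("A", "B"))
    expect_equal(unname(res2[rownames(res), "pvalue"]),
                 unname(res$pvalue), tolerance = 1e-12)
})

test_that("BH adjustment matches the step-up definition", {
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.5)),
                 c(0.04, 0.04, 0.04, 0.5))
    expect_equal(bhAdjust(rep(0.2, 5)), rep(0.2, 5))
    expect_equal(bhAdjust(0.37), 0.37)
    expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
    set.seed(4)
    for (i in 1:20) {
        p <- runif(sample(3:40, 1))
        expect_equal(bhAdjust(p), bhOracle(p), tolerance = 1e-12)
    }
})

test_that("significant-gene intersection applies both-method q, inclusive
           fold-change and sign concordance", {
    mk <- function(genes, lfc, q)
        pvrnet:::.DEResult(genes, lfc, q, q, "m", "A_vs_B")
    g <- c("g1", "g2", "g3", "g4")
    # q significant in only one method -> excluded
    a <- mk(g, c(2, 2, 2, 2), c(0.01, 0.01, 0.2, 0.01))
    b <- mk(g, c(2, 2, 2, -2), c(0.01, 0.2, 0.01, 0.01))
    expect_equal(significantGenes(a, b), "g1")  # g4 fails sign concordance

    # inclusive linear threshold at 2-fold
    fc <- log2(c(1.5, 2.0, 4.0))
    a2 <- mk(g[1:3], fc, rep(0, 3)); b2 <- mk(g[1:3], fc, rep(0, 3))
    expect_setequal(significantGenes(a2, b2), c("g2", "g3"))

    expect_error(significantGenes(a, mk(c("x", "y"), c(1, 1), c(0, 0))),
                 "universes")
})

test_that("null simulations keep the intersection's type-I rate in check", {
    fp <- numeric(20)
    for (i in seq_len(20)) {
        d <- simulationDesign(n_genes = 400, de_fraction = 0, phi = 0.05,
                              samples_per_group = c(RPE = 4, TNT = 4,
                                                    PVR = 2),
                              rng_seed = 300 + i)
        ce <- filterByExpression(simulateCounts(d)$counts)
        phi <- estimateCommonDispersion(ce, c("RPE", "TNT"))
        sg <- significantGenes(exactTestNB(ce, c("RPE", "TNT"), phi),
                               logcpmWelchTest(ce, c("RPE", "TNT")))
        fp[i] <- length(sg) / nrow(ce)
    }
    expect_lte(mean(fp), 0.05 + 3 * sd(fp) / sqrt(20))
})

test_that("Venn regions are exact for constructed and random sets", {
    v <- vennOverlap(list(S1 = c("A", "B"), S2 = c("B", "C")))
    expect_equal(unname(v[c("S1", "S2", "S1&S2")]), c(1L, 1L, 1L))
    same <- vennOverlap(list(X = c("a", "b"), Y = c("a", "b")))
    expect_equal(unname(same["X&Y"]), 2L)
    expect_equal(sum(same), 2L)
    expect_error(vennOverlap(list(1:2, 1:2, 1:2, 1:2)), "2 or 3")

    set.seed(8)
    u <- paste0("g", 1:40)
    sets <- list(A = sample(u, 15), B = sample(u, 20), C = sample(u, 10))
    v3 <- vennOverlap(sets)
    expect_equal(sum(v3), length(unique(unlist(sets))))
    # brute-force membership tabulation per region
    inA <- u %in% sets$A; inB <- u %in% sets$B; inC <- u %in% sets$C
    expect_equal(unname(v3["A"]), sum(inA & !inB & !inC))
    expect_equal(unname(v3["A&B"]), sum(inA & inB & !inC))
    expect_equal(unname(v3["A&B&C"]), sum(inA & inB & inC))
})
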