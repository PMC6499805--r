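# pvrnet

Transcriptome and network analysis pipeline for models of proliferative
vitreoretinopathy (PVR).

PVR is a blinding complication of retinal detachment: retinal pigment
epithelium (RPE) cells transform and build contractile epiretinal
membranes. A standard culture model treats adult human RPE with
TGFβ1 + TNFα ("TNT"). pvrnet implements, as a tested R package, the
computational analysis used to implicate the p38-MAPK interaction
network in this transformation, for anyone running the three-group
design (control RPE / TNT-treated RPE / patient PVR membrane):

* **Dual-method differential expression** — a conditional
  negative-binomial exact test (common dispersion φ, variance
  μ + φμ², binomial split at φ = 0) and an independent Welch *t*-test on
  log₂(CPM + 0.5); a gene is "significantly changing" only when BH
  q ≤ α in **both** methods with |log₂FC| ≥ 1 in both, sign-concordant.
* **SVD eigengene analysis** — X = U diag(s) Vᵀ of the significant-gene
  expression matrix; eigenexpression fractions s²ₖ/Σs²ⱼ; polar
  eigenspace coordinates (r, θ) for genes, samples, and per-group sums.
* **Seed-gene network enrichment** — the ≤2-hop neighborhood of a seed
  gene (e.g. p38) in a STRING-style network, overlap with the DE set, a
  B-iteration resampling null with add-one empirical p, and a
  binomial-proportion Bayes factor: ln BF for x hits in n = |de| trials
  against p₀ = |network|/|universe| under a logistic prior on logit(p)
  (scale 1/2), by adaptive quadrature.
* **Sub-network statistics** — exact node/edge betweenness (unnormalized,
  each unordered pair once) and greedy-modularity communities, exported
  as styled GraphML.
* **CV decomposition** — inter-line (all experiments pooled) versus
  intra-line coefficient of variation of membrane counts, and the
  non-genetic variability fraction 100·CVintra/CVinter.

A first-class synthetic-data module generates NB counts with planted
fold-changes, a PVR group built as a linear mixture
(1 − π)·TNT + π·RPE (membranes retain an RPE-like population), a
scale-free network with tunable seed-neighborhood enrichment ρ, and
replicate membrane-count tables — so every stage is testable offline.

## Worked example

```r
library(pvrnet)

design <- simulationDesign(n_genes = 4000, rng_seed = 42)
sim <- simulateCounts(design)
ce  <- filterByExpression(sim$counts)

phi  <- estimateCommonDispersion(ce, c("RPE", "TNT"))   # 0.0475
resA <- exactTestNB(ce, c("RPE", "TNT"), phi)
resB <- logcpmWelchTest(ce, c("RPE", "TNT"))
sig  <- significantGenes(resA, resB)                    # 589 genes

dec <- eigenDecompose(transformExpression(ce), sig)
dec
#> EigenDecomposition: 589 genes x 9 samples
#>   leading eigenexpression fractions: 97.9%, 1.9%, 0.1%
eigenspaceCoordinates(dec, "group_sums", groups = groupLabels(ce))
#>     entity        x         y        r      theta
#> PVR    PVR 544.2187  21.33241 544.6366   2.244744
#> RPE    RPE 552.7973 -96.51958 561.1603 350.095876
#> TNT    TNT 508.2300  82.14300 514.8255   9.181071
```

Mode 1 carries the shared expression program (the transform is an SVD of
log₂(CPM+1), not a centered PCA), and on the (SVD1, SVD2) plane the PVR
group-sum angle (2.2°) falls between RPE (−9.9°) and TNT (9.2°) — the
signature of the planted RPE admixture in PVR.

```r
seedGene <- rownames(ce)[1]
net  <- simulateNetwork(1500, 3, seedGene, rho = 5,
                        truth = sim$truth[sim$truth$gene %in% rownames(ce), ],
                        rng_seed = 43)
hood <- intersect(kHopNeighborhood(net, seedGene, 2), rownames(ce))
networkEnrichment(sig, hood, rownames(ce), B = 1000, rng_seed = 44)
#> EnrichmentResult
#>   de 589 / network 619 / universe 4000
#>   overlap 171 (expected 91.15), empirical p = 0.000999 (B = 1000)
#>   Bayes factor: ln BF = 31.76 (log10 BF = 13.79)
```

171 significant genes fall in the seed's 2-hop neighborhood where 91
were expected; none of 1000 random gene lists did as well, and the
Bayes factor (ln BF ≈ 32) says the data overwhelmingly favor enrichment
over the null proportion.

```r
mt <- simulateMembraneCounts(rng_seed = 45)
cvReport(mt, "A")
#> CVReport
#>   inter-line CV = 106.23% (n = 26, pooled)
#>   intra-line CV [line A] = 49.91% (n = 6)
#>   non-genetic fraction = 47.0%

nongeneticFraction(70.67, 86.7)
#> [1] 81.5
```

The last call is the published worked ratio: an intra-line CV of 70.67%
against a pooled inter-line CV of 86.7% attributes at least 81.5% of the
membrane-count variability to non-genetic influences.

See `vignettes/pvrnet-methods.Rmd` for the models, parameter defaults,
and the design decisions behind each stage.

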