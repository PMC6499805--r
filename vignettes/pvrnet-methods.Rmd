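---
title: "Methods: transcriptome and network analysis of a PVR model"
author: "pvrnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transcriptome and network analysis of a PVR model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvrnet)
```

## The scientific problem

Proliferative vitreoretinopathy (PVR) is a blinding complication of
retinal detachment in which retinal pigment epithelium (RPE) cells
transform, migrate and build contractile epiretinal membranes. A widely
used culture model treats adult human RPE with TGF&beta;1 plus TNF&alpha;
("TNT"), which drives membrane-like aggregate formation. pvrnet packages
the downstream computational analysis of that model as a tested pipeline:

1. **Dual-method differential expression** between the groups (control
   RPE, TNT-treated RPE, patient PVR membranes) with a 2-fold-change
   intersection rule;
2. **SVD eigengene analysis** of the significantly changing genes, with
   polar eigenspace coordinates for genes and per-group sample sums;
3. **Seed-gene network-neighborhood enrichment** (the p38-MAPK
   neighborhood in a STRING-style network) with a resampling null and a
   binomial-proportion Bayes factor;
4. **Sub-network structure**: betweenness centrality and community
   detection on the DE-intersected neighborhood;
5. **CV decomposition** of membrane counts into inter- versus intra-line
   variability.

Everything runs on synthetic data with the statistical structure the
analysis assumes, so the whole pipeline is exercisable and testable
without any external download.

## Differential expression: two routes, one intersection

Published analyses of this design ran two established DE tools and kept
genes that changed at least 2-fold. pvrnet preserves that *two methods
must agree* logic with two deliberately independent procedures of its
own — this is a documented fidelity gap, not a reimplementation of
edgeR or DESeq2:

* **Method A, `exactTestNB()`** — a conditional negative-binomial exact
  test in the classic edgeR spirit. Library sizes are equalized to their
  geometric mean by scaling counts to pseudo-counts (rounded half away
  from zero). For each gene, the group-A pseudo-count sum is compared
  with its conditional distribution given the gene total, under
  NB(variance $= \mu + \phi\mu^2$) with a common dispersion $\hat\phi$;
  sums of $n$ i.i.d. NB$(\mu,\phi)$ variables are NB$(n\mu,\phi/n)$, and
  at $\phi = 0$ the conditional law reduces to a binomial split.
  Two-sided p-values double the smaller tail, capped at 1; all-zero
  genes get $p = 1$.
* **Method B, `logcpmWelchTest()`** — a Welch unequal-variance $t$-test
  per gene on $\log_2(\mathrm{CPM} + 0.5)$, with the Satterthwaite
  degrees of freedom, vectorised over genes.

$\hat\phi$ comes from `estimateCommonDispersion()`: a method-of-moments
fit that regresses the pooled within-group residual variance in excess of
the scale-adjusted Poisson part on the squared group means, through the
origin, floored at zero. It recovers $\phi$ within roughly 10% at
hundreds of samples and degrades gracefully (to 0) on replicate-identical
data.

`significantGenes()` intersects the two: BH $q \le \alpha$ (default
0.05) in **both** methods, $|\log_2\mathrm{FC}| \ge \log_2 2$
(inclusive) in both, with concordant sign. Both methods share one
fold-change definition — difference of group means of
$\log_2(\mathrm{CPM} + 0.5)$ — so the sign-concordance test compares like
with like. Whether the original analysis required agreement in both tools
or either is not documented; the intersection is the stricter, more
reproducible reading and is the package's convention. An expression
filter (CPM > 1 in at least min-group-size samples) is applied before
dispersion estimation, following common practice.

## SVD eigengenes and polar coordinates

`eigenDecompose()` computes $X = U\,\mathrm{diag}(s)\,V^\top$ of the
expression matrix restricted to the significant genes. Columns of $U$
are *eigenarrays*, columns of $V$ *eigengenes*, and the eigenexpression
fraction of mode $k$ is $s_k^2 / \sum_j s_j^2$ — the variance convention
behind statements like "SVD1 represents 82.5% of the variance". The
default transform is $\log_2(\mathrm{CPM}+1)$ **without centering**: this
is an SVD of expression, not a PCA, so mode 1 typically captures the
shared expression program and is large by construction; a row-centered
option is available when a PCA-like view is wanted. Sign indeterminacy is
fixed by making the first nonzero loading of each eigenarray positive, so
outputs are reproducible across linear-algebra backends.

`eigenspaceCoordinates()` projects genes ($d_k u_{ik}$), samples
($d_k v_{jk}$), or per-group sums of sample coordinates onto a chosen
mode pair (default 1, 2) and reports polar $(r, \theta)$ with $\theta$
in degrees, counter-clockwise, and $\theta = 0$ at the degenerate origin.
Group sums are literally vector sums of member-sample Cartesian
coordinates (projection is linear), which the tests assert to $10^{-8}$.
On synthetic data with a partly RPE-like PVR group, the PVR group-sum
angle falls between RPE and TNT — the admixture signature.

## Network enrichment

`kHopNeighborhood()` takes all nodes within $k$ hops of a seed gene
(default $k = 2$: "first and second-degree neighbors"), seed included;
exclusion is a flag. The enrichment question is: does the significant
gene list contain more neighborhood genes than chance? Three answers are
computed on the same universe (all expression-filtered genes; network
membership is the success property):

* the hypergeometric expectation $|de| \cdot |net| / |U|$;
* an empirical p from `resamplingNull()` — $B$ draws (study convention
  1000) of $|de|$ genes without replacement, with the add-one correction
  $p = (1 + \#\{ \text{null} \ge x\}) / (B+1)$, which agrees with the
  exact hypergeometric tail to Monte-Carlo error;
* `lnBayesFactorProportion()` — the Bayes factor for $x$ successes in
  $n = |de|$ trials against the point null $p_0 = |net|/|U|$, with a
  logistic prior on $\mathrm{logit}(p)$ centered at
  $\mathrm{logit}(p_0)$, scale $r = 1/2$ (the convention of the standard
  proportion Bayes-factor test). The marginal likelihood is integrated by
  adaptive quadrature in standardized prior units
  $z = (\mathrm{logit}(p) - \mathrm{logit}(p_0))/r$; because the
  log-integrand is concave (binomial log-likelihood plus logistic
  log-prior, both concave in the logit), its peak sits at modest $|z|$
  for every $r$, making the quadrature stable from collapsing priors
  ($r \to 0$, $\ln\mathrm{BF} \to 0$) to diffuse ones.

The published value is printed as "log 46.10" without a base; pvrnet
reports the natural log and the base-10 value side by side and never
claims either is the original's convention.

## Sub-network statistics

`induceSubnetwork()` restricts the network to the DE &cap; neighborhood
genes (optionally keeping the seed), retaining isolated nodes and
carrying per-node annotations (Venn region of origin).
`betweennessTable()` computes exact node and edge betweenness,
undirected, unweighted, unnormalized, each unordered source–target pair
counted once — so a path's middle node scores 1 and a star hub scores
$\binom{k}{2}$; confidence scores are ignored for path counting (typical
STRING/Cytoscape default), with a weighted option using $1000/\mathrm{score}$
as edge length. `detectCommunities()` is greedy modularity
(Clauset–Newman–Moore), the documented stand-in for the original
figure's GLay clustering: the claim being exercised is "communities
exist and are color-coded", not a specific partition. Because the greedy
merge stops at zero gain, the dendrogram is re-cut at the maximum
recomputed $Q$ with ties broken toward fewer communities (a single
clique is then one community, as it should be).
`exportStyledGraph()` writes GraphML with betweenness (node size),
community (color), Venn region (shape) and edge betweenness (thickness).

## CV decomposition of membrane counts

`cvReport()` computes the inter-line CV over **all experiments pooled**
— the only reading consistent with a single "CV across all experiments"
on $n = 26$ — and the focal line's intra-line CV, both as
$100 \cdot \mathrm{sd}/\mathrm{mean}$ with the sample ($n-1$) sd. The
non-genetic fraction is $100 \cdot \mathrm{CV_{intra}}/\mathrm{CV_{inter}}$,
rounded to one decimal; with the published pair (70.67, 86.7) this is
81.5%. Pooling inflates the inter-line CV by between-line spread, so the
ratio is an "at least" statement; a fraction above 100% (intra > inter)
is flagged, never clipped.

## The synthetic-data generator

`simulateCounts()` draws NB counts with variance $\mu + \phi\mu^2$
(edgeR parameterization, matching the DE stage). Baseline per-gene
levels are log-normal; library sizes log-uniform over 0.5–2 million to
exercise CPM normalization; a fraction of genes carries planted
$\log_2$FC in TNT vs RPE with balanced signs; and the PVR group mean is
the linear-scale mixture $(1-\pi)\,\mu_{TNT} + \pi\,\mu_{RPE}$,
emulating membranes that still contain an RPE-like population. The
mixture acts on means, not sampled counts — simpler, and it preserves NB
marginals approximately. Defaults are anchored to the study's scale of
effect: ~12,000 expressed genes, 3 samples per group, $\phi = 0.05$
(biological CV ≈ 0.22, cultured-line replicates), 35% of genes DE with
$|\log_2\mathrm{FC}| \sim N(2, 0.7)$ truncated at 0.1, $\pi = 0.3$. With
these settings a default run yields roughly two thousand significant
RPE-vs-TNT genes, a much smaller RPE-vs-PVR set (admixture dilution),
and a substantial overlap — the qualitative pattern the real comparisons
show. Group sizes are a choice (the sequencing group sizes are not
published); so is $\pi$.

`simulateNetwork()` builds a preferential-attachment (scale-free-like)
topology, places the seed gene on the founding node, then assigns gene
ids to node slots so that DE-flagged genes enter the seed's 2-hop
neighborhood with $\rho$-fold the probability of non-DE genes
($\rho = 1$ is the uniform null; tests confirm DE genes then land in the
neighborhood at rate neighborhood-size/universe-size). Edge scores are
uniform on the STRING high-confidence band 700–999.

`simulateMembraneCounts()` uses mean-corrected log-normals for line
means (between-line CV) and per-experiment counts (within-line CV),
rounded to integers; log-normal rather than gamma purely for
two-parameter transparency — CV is scale-free, so either satisfies the
CV module. The default layout mirrors the study: 11 lines, 26
experiments, one focal line with 6, within-line CV 0.7 and between-line
CV 0.5, giving a pooled CV near 0.87.

What the generator does **not** emulate: gene-length/GC bias, tagwise
dispersion, batch effects, single-cell zero inflation, and any real
correlation structure between expression and network topology beyond the
planted enrichment. Passing tests therefore demonstrate correctness of
the statistical machinery under the stated model, not performance on any
particular real data set.

## Numerical choices and degenerate inputs

* Pseudo-counts are rounded half away from zero; base `round()` is
  banker's rounding and would bias totals.
* All-zero genes: exact test returns $p = 1$, $\log_2$FC 0. Welch on
  within-group-constant data returns $p = 1$ when group means agree and
  $p = 0$ when a noiseless separation exists.
* Tail doubling is capped at 1; a perfectly symmetric split has $p = 1$.
* Duplicate network edges collapse to the maximum score
  (order-independent for symmetric STRING exports); self-loops drop.
* Resampling and all simulators take explicit integer seeds; identical
  seeds give bitwise-identical output.
* The STRING score floor defaults to 700 ("high confidence"); the value
  used originally is not published, so this is configurable and never
  claimed faithful.

## Problem sizes used by the test suite

The suite verifies oracle equivalence on small exact cases (conditional
pmf enumeration at totals ≤ ~60; all-shortest-path betweenness at ≤ 25
nodes; dense-trapezoid Bayes-factor quadrature) and statistical behavior
at deliberately modest simulation sizes: 20 replicates of 5,000 genes at
5 vs 5 for DE sensitivity/FDR, 100 replicates of a 600-gene pipeline for
enrichment sign rates at $\rho = 5$ versus $\rho = 1$ (B = 500), 200
experiments/line for CV recovery, and 50,000 draws for the resampling
null's hypergeometric moments. These sizes give comfortable margins for
the assertions they support while keeping a full run to a couple of
minutes on one core.

## Known limitations

The DE stand-ins are not edgeR/DESeq2; numeric reproduction of the
published gene counts, SVD percentages, or the "log 46.10" Bayes factor
would require the original accession and tool versions and is not
claimed. Dispersion is common, not tagwise; designs beyond two-group
comparisons are out of scope; GLay is approximated by greedy modularity;
and annotation-database enrichment (IPA/DAVID/KEGG) is deliberately
excluded.
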