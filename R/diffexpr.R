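#' Method-of-moments common NB dispersion
#'
#' Estimates a single dispersion phi (variance = mu + phi * mu^2) shared by
#' all genes of a two-group comparison. Counts are scaled to the geometric
#' mean library size; the pooled within-group residual variance in excess of
#' the (scale-adjusted) Poisson part is regressed through the origin on the
#' squared group means, and the slope is floored at zero.
#'
#' @param ce a [CountExperiment-class] (already expression-filtered).
#' @param comparison character pair of group labels, `c(A, B)`.
#' @return non-negative scalar phi-hat.
#' @export
estimateCommonDispersion <- function(ce, comparison) {
    m <- .comparisonCounts(ce, comparison)
    nA <- ncol(m$A); nB <- ncol(m$B)
    if (nA < 2 || nB < 2)
        stop("need >= 2 samples per group to estimate dispersion")
    lib <- colSums(cbind(m$A, m$B))
    gm <- exp(mean(log(lib)))
    f <- gm / lib
    yA <- sweep(m$A, 2, f[seq_len(nA)], "*")
    yB <- sweep(m$B, 2, f[nA + seq_len(nB)], "*")
    fbar <- mean(f)
    muA <- rowMeans(yA); muB <- rowMeans(yB)
    vA <- apply(yA, 1, stats::var); vB <- apply(yB, 1, stats::var)
    wA <- (nA - 1) / (nA + nB - 2); wB <- 1 - wA
    pooledVar <- wA * vA + wB * vB
    num <- sum(pooledVar - fbar * (wA * muA + wB * muB))
    den <- sum(wA * muA^2 + wB * muB^2)
    max(0, num / den)
}

# split a comparison into the two per-group count matrices
.comparisonCounts <- function(ce, comparison) {
    stopifnot(methods::is(ce, "CountExperiment"), length(comparison) == 2)
    g <- as.character(groupLabels(ce))
    if (!all(comparison %in% g))
        stop("groups absent from data: ",
             paste(setdiff(comparison, g), collapse = ", "))
    m <- countsMatrix(ce)
    list(A = m[, g == comparison[1], drop = FALSE],
         B = m[, g == comparison[2], drop = FALSE])
}

# shared log2FC definition: difference of group means of log2(CPM + prior)
.log2fc <- function(A, B, prior_count) {
    cA <- .cpm(A); cB <- .cpm(B)
    rowMeans(log2(cB + prior_count)) - rowMeans(log2(cA + prior_count))
}

# round half away from zero (base round() is banker's)
.roundHalfUp <- function(x) floor(x + 0.5)

# conditional two-sided p for group-A sum sA given total t, under NB(phi)
# with nA, nB samples per group. phi = 0 reduces to the binomial split.
.exactCondP <- function(sA, t, nA, nB, phi) {
    if (t == 0) return(1)
    s <- 0:t
    if (phi == 0) {
        pmf <- stats::dbinom(s, t, nA / (nA + nB))
    } else {
        mu <- t / (nA + nB)
        lp <- stats::dnbinom(s, size = nA / phi, mu = nA * mu, log = TRUE) +
            stats::dnbinom(t - s, size = nB / phi, mu = nB * mu, log = TRUE)
        lp <- lp - max(lp)
        pmf <- exp(lp) / sum(exp(lp))
    }
    lower <- sum(pmf[s <= sA])
    upper <- sum(pmf[s >= sA])
    min(1, 2 * min(lower, upper))
}

#' Conditional NB exact test (method A)
#'
#' Two-group per-gene test in the classic edgeR spirit: library sizes are
#' equalized to their geometric mean by scaling counts to pseudo-counts
#' (rounded half away from zero), then the group-A pseudo-count sum is
#' tested against its conditional distribution given the gene total under a
#' common-dispersion NB model. Two-sided p-values double the smaller tail,
#' capped at 1. All-zero genes get p = 1 and log2FC = 0.
#'
#' @param ce a [CountExperiment-class].
#' @param comparison character pair `c(A, B)`; fold-changes are B over A.
#' @param phi common dispersion (>= 0), e.g. from
#'   [estimateCommonDispersion()].
#' @param prior_count prior added on the CPM scale for the fold-change.
#' @return a [DEResult-class].
#' @export
exactTestNB <- function(ce, comparison, phi, prior_count = 0.5) {
    if (phi < 0) stop("dispersion must be >= 0")
    m <- .comparisonCounts(ce, comparison)
    A <- m$A; B <- m$B
    nA <- ncol(A); nB <- ncol(B)
    lib <- colSums(cbind(A, B))
    gm <- exp(mean(log(lib)))
    pseudo <- .roundHalfUp(sweep(cbind(A, B), 2, gm / lib, "*"))
    pA <- rowSums(pseudo[, seq_len(nA), drop = FALSE])
    pT <- rowSums(pseudo)
    p <- vapply(seq_len(nrow(A)), function(i)
        .exactCondP(pA[i], pT[i], nA, nB, phi), numeric(1))
    lfc <- .log2fc(A, B, prior_count)
    lfc[pT == 0] <- 0
    .DEResult(rownames(A), lfc, p, bhAdjust(p), method = "exactNB",
              comparison = paste(comparison, collapse = "_vs_"))
}

#' Welch test on log2 CPM (method B)
#'
#' Independent second differential-expression route: per-gene Welch
#' unequal-variance two-sample test on log2(CPM + prior), with the log2FC
#' defined as the difference of group means of that transform. Genes whose
#' transformed values are constant within both groups get p = 1 when the
#' group means agree (no evidence) and p = 0 when they differ (a noiseless
#' separation).
#'
#' @inheritParams exactTestNB
#' @param prior_count prior added to CPM before the log (> 0, default 0.5).
#' @return a [DEResult-class].
#' @export
logcpmWelchTest <- function(ce, comparison, prior_count = 0.5) {
    stopifnot(prior_count > 0)
    m <- .comparisonCounts(ce, comparison)
    xA <- log2(.cpm(m$A) + prior_count)
    xB <- log2(.cpm(m$B) + prior_count)
    nA <- ncol(xA); nB <- ncol(xB)
    if (nA < 2 || nB < 2) stop("need >= 2 samples per group")
    mA <- rowMeans(xA); mB <- rowMeans(xB)
    vA <- apply(xA, 1, stats::var); vB <- apply(xB, 1, stats::var)
    se2 <- vA / nA + vB / nB
    tstat <- (mB - mA) / sqrt(se2)
    df <- se2^2 / ((vA / nA)^2 / (nA - 1) + (vB / nB)^2 / (nB - 1))
    p <- 2 * stats::pt(-abs(tstat), df)
    degen <- se2 == 0
    p[degen] <- ifelse(mB[degen] == mA[degen], 1, 0)
    .DEResult(rownames(xA), mB - mA, p, bhAdjust(p), method = "welchLogCPM",
              comparison = paste(comparison, collapse = "_vs_"))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment; a thin validated front over
#' `stats::p.adjust(method = "BH")`.
#'
#' @param p numeric p-values in [0, 1].
#' @export
bhAdjust <- function(p) {
    if (any(p < 0 | p > 1, na.rm = TRUE))
        stop("p-values must lie in [0, 1]")
    stats::p.adjust(p, method = "BH")
}

#' Significantly changing genes from two methods
#'
#' Implements the dual-method construction: a gene is called significant
#' when it passes the BH threshold in BOTH methods AND shows at least the
#' fold-change cutoff (inclusive) in both, with concordant direction.
#'
#' @param resA,resB [DEResult-class] objects over the same comparison and
#'   gene universe.
#' @param config a [pvrConfig()]; `fc_threshold` and `fdr_alpha` are used.
#' @return character vector of significant gene ids.
#' @export
significantGenes <- function(resA, resB, config = pvrConfig()) {
    if (!setequal(rownames(resA), rownames(resB)))
        stop("gene universes of the two results differ")
    resB <- resB[rownames(resA), ]
    lth <- log2(config$fc_threshold)
    ok <- resA$qvalue <= config$fdr_alpha & resB$qvalue <= config$fdr_alpha &
        abs(resA$logFC) >= lth & abs(resB$logFC) >= lth &
        sign(resA$logFC) == sign(resB$logFC)
    rownames(resA)[which(ok)]
}

#' Venn region counts for 2 or 3 gene sets
#'
#' @param sets named list of 2 or 3 character vectors.
#' @return named integer vector of exclusive-region counts; names join the
#'   member sets with `&` (e.g. `"A&B"` is the region in A and B only).
#' @export
vennOverlap <- function(sets) {
    if (!length(sets) %in% 2:3) stop("2 or 3 sets supported")
    if (is.null(names(sets))) names(sets) <- LETTERS[seq_along(sets)]
    universe <- unique(unlist(sets))
    member <- vapply(sets, function(s) universe %in% s,
                     logical(length(universe)))
    member <- matrix(member, ncol = length(sets),
                     dimnames = list(NULL, names(sets)))
    pat <- apply(member, 1, function(r)
        paste(names(sets)[r], collapse = "&"))
    regions <- unlist(lapply(seq_along(sets), function(k)
        utils::combn(names(sets), k, paste, collapse = "&")))
    counts <- stats::setNames(integer(length(regions)), regions)
    tab <- table(pat)
    counts[names(tab)] <- as.integer(tab)
    counts
}
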