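#' Expression transform for eigen-analysis
#'
#' @param ce a [CountExperiment-class].
#' @param method `"log2cpm"` (default; log2(CPM + 1), no centering — an SVD
#'   of expression, not a PCA), `"raw"` counts, or `"centered"`
#'   (log2(CPM + 1) with each gene row centered to mean zero).
#' @return numeric gene x sample matrix with a `"transform"` attribute
#'   recording the provenance.
#' @export
transformExpression <- function(ce, method = c("log2cpm", "raw", "centered")) {
    method <- match.arg(method)
    m <- countsMatrix(ce)
    x <- switch(method,
                raw = m,
                log2cpm = log2(.cpm(m) + 1),
                centered = {
                    y <- log2(.cpm(m) + 1)
                    y - rowMeans(y)
                })
    attr(x, "transform") <- method
    x
}

#' Eigengene / eigenarray decomposition
#'
#' SVD of the expression matrix restricted to a gene subset. Sign
#' convention: the first nonzero loading of each eigenarray is made
#' positive, so results are reproducible across linear-algebra backends.
#'
#' @param expr numeric gene x sample matrix (e.g. from
#'   [transformExpression()]).
#' @param gene_subset optional character vector; the decomposition is of
#'   `expr[gene_subset, ]`. Default: all rows.
#' @return an [EigenDecomposition-class].
#' @examples
#' x <- matrix(rnorm(60), 10, 6, dimnames = list(paste0("g", 1:10), NULL))
#' eigenexpressionFractions(eigenDecompose(x))
#' @export
eigenDecompose <- function(expr, gene_subset = NULL) {
    if (!is.null(gene_subset)) {
        hit <- intersect(gene_subset, rownames(expr))
        if (length(hit) < 2)
            stop("fewer than 2 subset genes present in the matrix")
        expr <- expr[hit, , drop = FALSE]
    }
    if (ncol(expr) < 2) stop("need >= 2 samples")
    sv <- svd(expr)
    U <- sv$u; V <- sv$v; d <- sv$d
    for (k in seq_along(d)) {
        nz <- which(abs(U[, k]) > 1e-12)[1]
        if (!is.na(nz) && U[nz, k] < 0) {
            U[, k] <- -U[, k]
            V[, k] <- -V[, k]
        }
    }
    rownames(U) <- rownames(expr)
    rownames(V) <- colnames(expr)
    colnames(U) <- colnames(V) <- paste0("SVD", seq_along(d))
    methods::new("EigenDecomposition", eigenarrays = U, eigengenes = V,
                 d = d, fractions = d^2 / sum(d^2))
}

.toPolar <- function(x, y) {
    r <- sqrt(x^2 + y^2)
    theta <- (atan2(y, x) * 180 / pi) %% 360
    theta[r == 0] <- 0  # degenerate point: angle fixed at 0 by convention
    data.frame(x = x, y = y, r = r, theta = theta)
}

#' Polar eigenspace coordinates
#'
#' Projects genes, samples, or per-group sample sums of the decomposed
#' matrix onto two eigen-dimensions and converts to polar form (r, theta in
#' degrees, counter-clockwise from the + axis of the first requested
#' dimension).
#'
#' Genes project onto the eigengene basis (their coordinates in eigenarray
#' space, `d_k u_ik`); samples onto the eigenarray basis (`d_k v_jk`).
#' `"group_sums"` gives the coordinates of the per-sample column sums over
#' the decomposed genes, aggregated by group — the "sum of the
#' significantly changing genes from each sample" view.
#'
#' @param dec an [EigenDecomposition-class].
#' @param entity `"genes"`, `"samples"` or `"group_sums"`.
#' @param dims integer pair of eigen-dimensions (1-based), default c(1, 2).
#' @param groups factor/character named by sample, required for
#'   `"group_sums"`.
#' @return data.frame with columns `entity`, `x`, `y`, `r`, `theta`.
#' @export
eigenspaceCoordinates <- function(dec, entity = c("genes", "samples",
                                                  "group_sums"),
                                  dims = c(1, 2), groups = NULL) {
    entity <- match.arg(entity)
    stopifnot(length(dims) == 2)
    if (any(dims < 1 | dims > length(dec@d)))
        stop("dims out of range 1..", length(dec@d))
    d <- dec@d[dims]
    if (entity == "genes") {
        proj <- sweep(dec@eigenarrays[, dims, drop = FALSE], 2, d, "*")
        ids <- rownames(dec@eigenarrays)
    } else {
        proj <- sweep(dec@eigengenes[, dims, drop = FALSE], 2, d, "*")
        ids <- rownames(dec@eigengenes)
        if (entity == "group_sums") {
            if (is.null(groups)) stop("'groups' required for group_sums")
            groups <- as.character(groups[ids])
            proj <- rowsum(proj, groups)
            ids <- rownames(proj)
        }
    }
    out <- .toPolar(proj[, 1], proj[, 2])
    cbind(entity = ids, out, stringsAsFactors = FALSE)
}
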