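# Independent brute-force oracles used across the suite. These deliberately
# re-derive each quantity from first principles (definitional formulas,
# exhaustive enumeration) rather than calling the package's code paths.

# Benjamini-Hochberg by the step-up definition
bhOracle <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- pmin(1, m * p[o] / seq_len(m))
    adj <- rev(cummin(rev(adj)))
    out <- numeric(m)
    out[o] <- adj
    out
}

# NB pmf from the gamma-function form (independent of dnbinom)
nbLogPmf <- function(k, size, mu) {
    lgamma(k + size) - lgamma(size) - lgamma(k + 1) +
        size * (log(size) - log(size + mu)) +
        k * (log(mu) - log(size + mu))
}

# conditional two-sided exact p by exhaustive enumeration of the pmf
exactPOracle <- function(sA, t, nA, nB, phi) {
    s <- 0:t
    if (phi == 0) {
        lw <- lchoose(t, s) + s * log(nA / (nA + nB)) +
            (t - s) * log(nB / (nA + nB))
    } else {
        mu <- t / (nA + nB)
        lw <- nbLogPmf(s, nA / phi, nA * mu) +
            nbLogPmf(t - s, nB / phi, nB * mu)
    }
    pmf <- exp(lw - max(lw))
    pmf <- pmf / sum(pmf)
    min(1, 2 * min(sum(pmf[s <= sA]), sum(pmf[s >= sA])))
}

# all-pairs shortest-path distances by Floyd-Warshall on an adjacency matrix
fwDistances <- function(adj) {
    n <- nrow(adj)
    d <- matrix(Inf, n, n)
    d[adj > 0] <- 1
    diag(d) <- 0
    for (k in seq_len(n))
        for (i in seq_len(n))
            for (j in seq_len(n))
                if (d[i, k] + d[k, j] < d[i, j])
                    d[i, j] <- d[i, k] + d[k, j]
    d
}

# shortest-path counts sigma(s, t) by DP over distances
spCounts <- function(adj, d) {
    n <- nrow(adj)
    sigma <- matrix(0, n, n)
    diag(sigma) <- 1
    ord <- order(as.vector(d))
    for (idx in ord) {
        i <- (idx - 1) %% n + 1
        j <- (idx - 1) %/% n + 1
        if (i == j || !is.finite(d[i, j])) next
        pred <- which(adj[, j] > 0 & d[i, ] == d[i, j] - 1)
        sigma[i, j] <- sum(sigma[i, pred])
    }
    sigma
}

# node and edge betweenness by the definitional pair-sum formula,
# each unordered pair counted once
betweennessOracle <- function(adj) {
    n <- nrow(adj)
    d <- fwDistances(adj)
    sigma <- spCounts(adj, d)
    nodeB <- numeric(n)
    edges <- which(adj > 0 & upper.tri(adj), arr.ind = TRUE)
    edgeB <- numeric(nrow(edges))
    for (s in seq_len(n - 1)) for (t in (s + 1):n) {
        if (!is.finite(d[s, t]) || sigma[s, t] == 0) next
        for (v in seq_len(n)) {
            if (v == s || v == t) next
            if (is.finite(d[s, v]) && is.finite(d[v, t]) &&
                d[s, v] + d[v, t] == d[s, t])
                nodeB[v] <- nodeB[v] +
                    sigma[s, v] * sigma[v, t] / sigma[s, t]
        }
        for (e in seq_len(nrow(edges))) {
            u <- edges[e, 1]; v <- edges[e, 2]
            thr <- 0
            if (is.finite(d[s, u]) && is.finite(d[v, t]) &&
                d[s, u] + 1 + d[v, t] == d[s, t])
                thr <- thr + sigma[s, u] * sigma[v, t]
            if (is.finite(d[s, v]) && is.finite(d[u, t]) &&
                d[s, v] + 1 + d[u, t] == d[s, t])
                thr <- thr + sigma[s, v] * sigma[u, t]
            edgeB[e] <- edgeB[e] + thr / sigma[s, t]
        }
    }
    list(node = nodeB, edges = edges, edge = edgeB)
}

# dense-trapezoid marginal likelihood for the proportion Bayes factor
lnBFOracle <- function(x, n, p0, r, npts = 1e6) {
    mu <- log(p0 / (1 - p0))
    u <- seq(mu - 30 * r - 15, mu + 30 * r + 15, length.out = npts)
    p <- 1 / (1 + exp(-u))
    lf <- dbinom(x, n, p, log = TRUE) +
        stats::dlogis(u, mu, r, log = TRUE)
    M <- max(lf)
    f <- exp(lf - M)
    h <- u[2] - u[1]
    marg <- M + log(h * (sum(f) - (f[1] + f[npts]) / 2))
    marg - dbinom(x, n, p0, log = TRUE)
}

# definitional modularity of a partition on an unweighted graph
modularityOracle <- function(adj, membership) {
    m2 <- sum(adj)            # 2m for a symmetric adjacency matrix
    deg <- rowSums(adj)
    q <- 0
    for (i in seq_len(nrow(adj))) for (j in seq_len(nrow(adj)))
        if (membership[i] == membership[j])
            q <- q + adj[i, j] - deg[i] * deg[j] / m2
    unname(q / m2)
}

# chain graph a-b-c-... as an InteractionNetwork
pathNetwork <- function(ids) {
    n <- length(ids)
    InteractionNetwork(data.frame(a = ids[-n], b = ids[-1], score = 900))
}

# small deterministic three-group CountExperiment
makeTinyCounts <- function(n_genes = 30, seed = 42,
                           groups = c(RPE = 3, TNT = 3, PVR = 3)) {
    set.seed(seed)
    g <- rep(names(groups), groups)
    m <- matrix(rpois(n_genes * length(g), 50), nrow = n_genes,
                dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                paste0(g, "_", seq_along(g))))
    CountExperiment(m, setNames(g, colnames(m)))
}

# random simple undirected graph as InteractionNetwork + adjacency matrix
makeRandomNetwork <- function(n, p_edge, seed) {
    set.seed(seed)
    adj <- matrix(0, n, n)
    adj[upper.tri(adj)] <- rbinom(n * (n - 1) / 2, 1, p_edge)
    adj <- adj + t(adj)
    ids <- paste0("n", seq_len(n))
    e <- which(adj > 0 & upper.tri(adj), arr.ind = TRUE)
    edges <- data.frame(a = ids[e[, 1]], b = ids[e[, 2]],
                        score = 900, stringsAsFactors = FALSE)
    list(net = InteractionNetwork(edges, nodes = ids), adj = adj, ids = ids)
}
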