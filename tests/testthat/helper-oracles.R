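# Independent brute-force / closed-form oracles. Each is written directly
# from the published definition and shares no code with the implementation.

# biweight midcorrelation of two complete vectors, straight from the formula
oracleBicor <- function(x, y) {
    bw <- function(v) {
        med <- median(v)
        mad0 <- median(abs(v - med))
        u <- (v - med) / (9 * mad0)
        w <- (1 - u^2)^2 * (abs(u) < 1)
        w * (v - med)
    }
    a <- bw(x); b <- bw(y)
    sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

# topological overlap by double loop
oracleTom <- function(A, denom) {
    n <- nrow(A)
    k <- sapply(seq_len(n), function(i) sum(A[i, -i]))
    tom <- diag(n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
        if (i == j) next
        cross <- sum(sapply(setdiff(seq_len(n), c(i, j)),
                            function(u) A[i, u] * A[u, j]))
        f <- if (denom == "mean") (k[i] + k[j]) / 2 else min(k[i], k[j])
        tom[i, j] <- (cross + A[i, j]) / (f - A[i, j] + 1)
    }
    tom
}

# Benjamini-Hochberg step-up by direct definition
oracleBH <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- numeric(m)
    prev <- 1
    for (i in m:1) {
        prev <- min(prev, p[o[i]] * m / i)
        adj[o[i]] <- prev
    }
    pmin(adj, 1)
}

# hypergeometric upper tail P(X >= a) by explicit summation
oracleHyperTail <- function(a, setSize, moduleSize, N) {
    ks <- a:min(setSize, moduleSize)
    sum(choose(setSize, ks) * choose(N - setSize, moduleSize - ks)) /
        choose(N, moduleSize)
}

# exhaustive permutation p for a mean-statistic module test, (b+1)/(m+1)
oraclePermExact <- function(tstat, moduleIdx) {
    k <- length(moduleIdx)
    Tobs <- mean(tstat[moduleIdx])
    Tnull <- combn(length(tstat), k, FUN = function(i) mean(tstat[i]))
    (sum(Tnull >= Tobs) + 1) / (length(Tnull) + 1)
}

# adjusted Rand index (Hubert & Arabie), independent of the package internals
oracleARI <- function(a, b) {
    if (requireNamespace("mclust", quietly = TRUE))
        return(mclust::adjustedRandIndex(a, b))
    tab <- table(a, b)
    sij <- sum(choose(tab, 2)); si <- sum(choose(rowSums(tab), 2))
    sj <- sum(choose(colSums(tab), 2)); n2 <- choose(sum(tab), 2)
    (sij - si * sj / n2) / ((si + sj) / 2 - si * sj / n2)
}
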