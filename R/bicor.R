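#' Biweight midcorrelation
#'
#' Robust correlation based on Tukey biweights. For a vector `x` with median
#' `med(x)` and (unscaled) median absolute deviation `MAD(x)`, define
#' `u_i = (x_i - med(x)) / (9 MAD(x))` and weights
#' `w_i = (1 - u_i^2)^2 I(|u_i| < 1)`. The biweight midcorrelation of `x` and
#' `y` is the cross-product of `w_i (x_i - med(x))` and `w_i (y_i - med(y))`
#' normalized by the corresponding root sums of squares.
#'
#' Vectors with zero MAD cannot be biweighted; any pair involving such a
#' vector falls back to the Pearson correlation for that pair, and is flagged
#' in the `"fallback"` attribute. Pairs with fewer than 4 pairwise-complete
#' observations are undefined (`NA`) and flagged in `"insufficient"`.
#'
#' Missing values: each vector's median and MAD are computed from its own
#' non-missing entries; cross-products run over pairwise-complete
#' observations.
#'
#' @param x matrix (variables in rows, observations in columns), or a
#'   [ProteoSet-class] (proteins correlated across samples).
#' @param y optional second matrix with the same number of columns; if
#'   supplied, the cross-correlation rows(x) x rows(y) is returned.
#' @return correlation matrix with attributes `"nObs"` (pairwise-complete
#'   counts), `"fallback"` and `"insufficient"` (logical matrices).
#' @examples
#' set.seed(1)
#' m <- matrix(rnorm(60), 3, 20)
#' bicorMatrix(m)[1, 2]
#' @export
bicorMatrix <- function(x, y = NULL) {
    X <- if (is(x, "ProteoSet")) abundance(x) else as.matrix(x)
    cross <- !is.null(y)
    Y <- if (cross) {
        if (is(y, "ProteoSet")) abundance(y) else as.matrix(y)
    } else X
    if (ncol(X) != ncol(Y))
        stop("x and y must have the same number of observations (columns)")
    if (ncol(X) < 4L)
        stop("bicor requires at least 4 observations")

    px <- .bicorPrep(X)
    py <- if (cross) .bicorPrep(Y) else px

    num <- tcrossprod(px$A, py$A)
    d1 <- tcrossprod(px$A^2, py$M)   # sum over complete pairs of a_x^2
    d2 <- tcrossprod(px$M, py$A^2)   # sum over complete pairs of a_y^2
    r <- num / sqrt(d1 * d2)

    anyFb <- any(px$zeroMad) || any(py$zeroMad)
    fb <- outer(px$zeroMad, py$zeroMad, "|")
    if (anyFb) {
        nP <- tcrossprod(px$P, py$P)
        dp1 <- tcrossprod(px$P^2, py$M)
        dp2 <- tcrossprod(px$M, py$P^2)
        rP <- nP / sqrt(dp1 * dp2)
        r[fb] <- rP[fb]
    }

    n <- tcrossprod(px$M, py$M)
    insuf <- n < 4L
    r[insuf] <- NA_real_
    r[!is.na(r)] <- pmin(1, pmax(-1, r[!is.na(r)]))
    if (!cross) {
        # exact unit diagonal for non-degenerate rows
        d <- diag(r)
        diag(r) <- ifelse(is.na(d), NA_real_, 1)
        dimnames(r) <- list(rownames(X), rownames(X))
    } else dimnames(r) <- list(rownames(X), rownames(Y))
    attr(r, "nObs") <- n
    attr(r, "fallback") <- fb & !insuf
    attr(r, "insufficient") <- insuf
    r
}

## per-row biweight (and Pearson) transforms; NA -> 0 with indicator M
.bicorPrep <- function(X) {
    M <- !is.na(X)
    med <- apply(X, 1L, stats::median, na.rm = TRUE)
    ctr <- X - med
    madv <- apply(abs(ctr), 1L, stats::median, na.rm = TRUE)
    zeroMad <- !is.finite(madv) | madv == 0
    u <- ctr / (9 * madv)
    w <- (1 - u^2)^2 * (abs(u) < 1)
    A <- w * ctr
    A[!M] <- 0
    A[zeroMad, ] <- 0
    mu <- rowMeans(X, na.rm = TRUE)
    P <- X - mu
    P[!M] <- 0
    list(A = A, P = P, M = 1 * M, zeroMad = zeroMad)
}

#' Student-t p-value for a correlation
#'
#' Two-sided p-value from the transform `t = r sqrt((n - 2) / (1 - r^2))`
#' with `n - 2` degrees of freedom. p-values below 1e-300 are floored at
#' 1e-300 (reported as "< 1e-300").
#'
#' @param r correlation(s) in `[-1, 1]`.
#' @param n number(s) of observations used.
#' @return p-value(s), same shape as `r`.
#' @export
corPvalue <- function(r, n) {
    t <- abs(r) * sqrt((n - 2) / pmax(1 - r^2, 1e-300))
    p <- 2 * stats::pt(t, df = n - 2, lower.tail = FALSE)
    p[!is.finite(r) | n < 3] <- NA_real_
    pmax(p, 1e-300)
}
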