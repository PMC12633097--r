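#' Sum-scale raw intensities across samples
#'
#' Zero intensities are treated as missing values (converted to `NA`) before
#' scaling. Each sample's present-value intensities are then divided by the
#' sample's intensity sum and multiplied by the maximum intensity sum across
#' samples, so that after scaling every sample's present-value total equals
#' the largest pre-scaling total.
#'
#' @param x a raw [ProteoSet-class].
#' @return a `ProteoSet` with `scaleTag = "sum_scaled"`.
#' @export
sumScale <- function(x) {
    stopifnot(is(x, "ProteoSet"))
    if (scaleTag(x) != "raw") stop("sumScale expects a raw ProteoSet")
    v <- abundance(x)
    v[v == 0] <- NA_real_
    tot <- colSums(v, na.rm = TRUE)
    if (any(tot == 0))
        stop("sample(s) with zero present-value intensity sum: ",
             paste(colnames(v)[tot == 0], collapse = ", "))
    v <- sweep(v, 2L, max(tot) / tot, `*`)
    .advance(x, v, "sum_scaled")
}

#' Filter proteins by missing fraction
#'
#' Retains proteins whose fraction of missing samples is strictly less than
#' `maxMissingFrac` (the "< 50 percent missing" rule at the default).
#'
#' @param x a [ProteoSet-class].
#' @param maxMissingFrac threshold in (0, 1]; strict inequality.
#' @return the filtered `ProteoSet`; the number of removed proteins is
#'   reported via `message()` and stored in `metadata(x)$filter_removed`.
#' @export
filterMissing <- function(x, maxMissingFrac = 0.5) {
    stopifnot(is(x, "ProteoSet"))
    if (!is.numeric(maxMissingFrac) || maxMissingFrac <= 0 ||
        maxMissingFrac > 1)
        stop("maxMissingFrac must lie in (0, 1]")
    frac <- rowMeans(is.na(abundance(x)))
    keep <- frac < maxMissingFrac
    message(sprintf("filterMissing: removed %d of %d proteins (>= %.0f%% missing)",
                    sum(!keep), length(keep), 100 * maxMissingFrac))
    out <- x[keep, ]
    S4Vectors::metadata(out)$filter_removed <- sum(!keep)
    out
}

#' Log2-transform a sum-scaled abundance matrix
#'
#' @param x a sum-scaled [ProteoSet-class]; all present values must be > 0.
#' @return a `ProteoSet` with `scaleTag = "log2"`; missingness preserved.
#' @export
log2Transform <- function(x) {
    stopifnot(is(x, "ProteoSet"))
    if (scaleTag(x) != "sum_scaled")
        stop("log2Transform expects a sum_scaled ProteoSet")
    v <- abundance(x)
    if (any(v <= 0, na.rm = TRUE))
        stop("nonpositive present values cannot be log2-transformed")
    .advance(x, log2(v), "log2")
}

#' Flag principal-component sample outliers
#'
#' Missing values are imputed by the per-protein mean for the decomposition
#' only (never written back). A sample is flagged if its score on any of the
#' first `nComponents` principal components exceeds `sdThreshold` standard
#' deviations of that component's scores (strict inequality). The input is
#' untouched; removal is an explicit separate step (subset with `x[, keep]`).
#'
#' @param x a log2-or-later [ProteoSet-class] with >= 3 samples.
#' @param nComponents number of leading components examined.
#' @param sdThreshold score threshold in component standard deviations.
#' @return character vector of flagged sample ids, with the score matrix in
#'   attribute `"scores"`.
#' @export
pcaOutlierFlag <- function(x, nComponents = 2L, sdThreshold = 4) {
    stopifnot(is(x, "ProteoSet"))
    if (!scaleTag(x) %in% c("log2", "tampor_corrected", "regressed"))
        stop("pcaOutlierFlag expects a log2 (or later) ProteoSet")
    v <- abundance(x)
    if (ncol(v) < 3L) stop("need at least 3 samples")
    mu <- rowMeans(v, na.rm = TRUE)
    ok <- is.finite(mu)
    v <- v[ok, , drop = FALSE]
    mu <- mu[ok]
    nas <- which(is.na(v), arr.ind = TRUE)
    if (nrow(nas)) v[nas] <- mu[nas[, 1L]]
    k <- min(nComponents, ncol(v) - 1L, nrow(v))
    pc <- stats::prcomp(t(v), center = TRUE, scale. = FALSE)
    sc <- pc$x[, seq_len(k), drop = FALSE]
    sds <- apply(sc, 2L, stats::sd)
    bad <- abs(sc) > matrix(sdThreshold * sds, nrow(sc), k, byrow = TRUE)
    flagged <- colnames(abundance(x))[rowSums(bad) > 0]
    attr(flagged, "scores") <- sc
    flagged
}
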