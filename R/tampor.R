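#' Batch correction by iterative median polish of GIS ratios (TAMPOR)
#'
#' Two steps, all arithmetic additive in log2 space:
#'
#' 1. *Ratio step*: for every protein g and sample s in batch b, the log2
#'    ratio `R_gs = log2value_gs - D_gb`, where `D_gb` is the within-batch
#'    median log2 value over the batch's GIS channels
#'    (`useAllNonGIS = FALSE`) or over all non-GIS samples of the batch
#'    (`useAllNonGIS = TRUE`). A missing denominator propagates missingness.
#' 2. *Median polish*: iterate subtracting each protein row's median (over
#'    the denominator-defining samples) and then each sample column's median
#'    until `max(|row medians|, |column medians|) < tol` or `maxIterations`.
#'
#' Proteins missing in all denominator samples of any batch are dropped with
#' a warning. GIS columns are corrected alongside but excluded from the
#' output by default.
#'
#' @param x a log2-scale [ProteoSet-class]; `colData` must contain `batch`
#'   and logical `is_gis`.
#' @param useAllNonGIS use all non-GIS samples of the batch as the ratio
#'   denominator instead of the GIS channels.
#' @param tol convergence tolerance on the centering medians (log2 units).
#' @param maxIterations cap on polish iterations.
#' @param dropGis exclude GIS channels from the returned object.
#' @return `list(data = ProteoSet (scaleTag "tampor_corrected"),
#'   state = TamporState)` where the state records `iterations`, per-iteration
#'   `history` of `max(|row medians|, |col medians|)`, `converged`, and the
#'   ids of dropped proteins.
#' @export
tamporCorrect <- function(x, useAllNonGIS = FALSE, tol = 1e-8,
                          maxIterations = 250L, dropGis = TRUE) {
    stopifnot(is(x, "ProteoSet"))
    if (scaleTag(x) != "log2")
        stop("tamporCorrect expects a log2 ProteoSet")
    man <- sampleInfo(x)
    if (!all(c("batch", "is_gis") %in% colnames(man)))
        stop("manifest must contain 'batch' and 'is_gis' columns")
    v <- abundance(x)
    batch <- as.character(man$batch)
    isGis <- as.logical(man$is_gis)

    denomCols <- if (useAllNonGIS) !isGis else isGis
    for (b in unique(batch))
        if (!any(denomCols & batch == b))
            stop("batch ", b, " has no usable denominator samples")

    ## ratio step
    R <- v
    dropped <- character()
    for (b in unique(batch)) {
        dc <- denomCols & batch == b
        D <- apply(v[, dc, drop = FALSE], 1L, stats::median, na.rm = TRUE)
        allMiss <- !is.finite(D)
        if (any(allMiss)) dropped <- union(dropped, rownames(v)[allMiss])
        R[, batch == b] <- v[, batch == b, drop = FALSE] - D
    }
    if (length(dropped)) {
        warning(sprintf(
            "tamporCorrect: dropping %d protein(s) missing in all denominator samples of a batch",
            length(dropped)))
        R <- R[!rownames(R) %in% dropped, , drop = FALSE]
    }
    if (any(rowSums(!is.na(R)) == 0))
        stop("all-missing protein row after ratio step")

    ## iterative two-way median centering; convergence is verified on the
    ## current state before any further subtraction
    history <- numeric()
    converged <- FALSE
    iter <- 0L
    repeat {
        iter <- iter + 1L
        rm <- apply(R[, denomCols, drop = FALSE], 1L, stats::median,
                    na.rm = TRUE)
        cmPre <- apply(R, 2L, stats::median, na.rm = TRUE)
        m <- max(abs(rm), abs(cmPre))
        history[iter] <- m
        if (m < tol) { converged <- TRUE; break }
        if (iter > maxIterations) break
        R <- R - rm
        cm <- apply(R, 2L, stats::median, na.rm = TRUE)
        R <- sweep(R, 2L, cm, `-`)
    }

    keepCols <- if (dropGis) !isGis else rep(TRUE, ncol(R))
    out <- .advance(x[rownames(R), keepCols], R[, keepCols, drop = FALSE],
                    "tampor_corrected")
    state <- list(iterations = iter, history = history, converged = converged,
                  use_all_non_gis = useAllNonGIS, tol = tol,
                  dropped_proteins = dropped)
    class(state) <- "TamporState"
    list(data = out, state = state)
}

#' @export
print.TamporState <- function(x, ...) {
    cat(sprintf("TamporState: %d iteration(s), converged = %s (tol %.1e)\n",
                x$iterations, x$converged, x$tol))
    if (length(x$dropped_proteins))
        cat(sprintf("  dropped %d protein(s) with all-missing denominators\n",
                    length(x$dropped_proteins)))
    invisible(x)
}
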