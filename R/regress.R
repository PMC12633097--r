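#' Remove covariate variance by nonparametric bootstrap regression
#'
#' For every protein, an ordinary least-squares model of log2 abundance on
#' the covariates to remove (plus any protected terms, which are fitted but
#' never subtracted) is refit on `nBootstrap` resamples of the samples with
#' replacement. The median bootstrap coefficient of each removed covariate is
#' then subtracted times the *centered* covariate, so the protein's grand
#' mean is preserved:
#' `out_gs = value_gs - sum_c beta_gc (z_cs - mean(z_c))`.
#'
#' Categorical covariates (e.g. `batch`, `sex`) are one-hot encoded against a
#' reference level. Missing abundance values are skipped per protein and stay
#' missing in the output.
#'
#' @param x a [ProteoSet-class] with `scaleTag` `"tampor_corrected"` or
#'   `"log2"`.
#' @param covariates manifest columns whose variance is removed.
#' @param protected manifest columns fitted alongside but not removed
#'   (disjoint from `covariates`).
#' @param nBootstrap number of bootstrap resamples (>= 1).
#' @param seed RNG seed for the resampling.
#' @param resample internal test hook; `FALSE` with `nBootstrap = 1` reduces
#'   the procedure to plain OLS residualization of the removed covariates.
#' @return a `ProteoSet` with `scaleTag = "regressed"`; the median
#'   coefficients are stored in `metadata(out)$regress_coefficients`.
#' @export
bootstrapRegress <- function(x, covariates, protected = character(),
                             nBootstrap = 1000L, seed = NULL,
                             resample = TRUE) {
    stopifnot(is(x, "ProteoSet"))
    if (!scaleTag(x) %in% c("tampor_corrected", "log2"))
        stop("bootstrapRegress expects a tampor_corrected or log2 ProteoSet")
    if (length(intersect(covariates, protected)))
        stop("covariates and protected terms must be disjoint")
    if (nBootstrap < 1L) stop("nBootstrap must be >= 1")
    man <- sampleInfo(x)
    miss <- setdiff(c(covariates, protected), colnames(man))
    if (length(miss)) stop("manifest lacks column(s): ",
                           paste(miss, collapse = ", "))
    if (anyNA(man[, c(covariates, protected), drop = FALSE]))
        stop("covariates must be present for all samples")

    Zrm <- .encodeCovariates(man, covariates)
    Zpr <- if (length(protected)) .encodeCovariates(man, protected) else
        matrix(0, nrow(man), 0L)
    X <- cbind(`(Intercept)` = 1, Zrm, Zpr)
    if (qr(X)$rank < ncol(X))
        stop("rank-deficient design after covariate encoding")

    Y <- abundance(x)
    n <- ncol(Y)
    pRm <- ncol(Zrm)
    rmIdx <- 1L + seq_len(pRm)

    doFit <- function() {
        idx <- if (resample)
            matrix(sample.int(n, n * nBootstrap, replace = TRUE),
                   nBootstrap, n)
        else matrix(rep(seq_len(n), nBootstrap), nBootstrap, n, byrow = TRUE)
        B <- matrix(NA_real_, nrow(Y), pRm,
                    dimnames = list(rownames(Y), colnames(Zrm)))
        complete <- !apply(is.na(Y), 1L, any)
        if (any(complete)) {
            Yc <- t(Y[complete, , drop = FALSE])
            coefs <- array(NA_real_, c(nBootstrap, pRm, sum(complete)))
            for (b in seq_len(nBootstrap)) {
                i <- idx[b, ]
                cf <- tryCatch(qr.coef(qr(X[i, , drop = FALSE]),
                                       Yc[i, , drop = FALSE]),
                               error = function(e) NULL)
                if (!is.null(cf)) coefs[b, , ] <- cf[rmIdx, , drop = FALSE]
            }
            B[complete, ] <- t(apply(coefs, c(2L, 3L), stats::median,
                                     na.rm = TRUE))
        }
        for (g in which(!complete)) {
            cc <- which(!is.na(Y[g, ]))
            if (length(cc) <= ncol(X)) next   # unestimable; leave NA
            cf <- matrix(NA_real_, nBootstrap, pRm)
            for (b in seq_len(nBootstrap)) {
                i <- cc[if (resample)
                    sample.int(length(cc), length(cc), replace = TRUE)
                    else seq_along(cc)]
                fit <- tryCatch(qr.coef(qr(X[i, , drop = FALSE]), Y[g, i]),
                                error = function(e) NULL)
                if (!is.null(fit)) cf[b, ] <- fit[rmIdx]
            }
            B[g, ] <- apply(cf, 2L, stats::median, na.rm = TRUE)
        }
        B
    }
    B <- if (is.null(seed)) doFit() else withr::with_seed(seed, doFit())
    B[is.na(B)] <- 0

    Zc <- scale(Zrm, scale = FALSE)          # centered covariates
    out <- Y - B %*% t(Zc)
    out[is.na(Y)] <- NA_real_
    res <- .advance(x, out, "regressed")
    S4Vectors::metadata(res)$regress_coefficients <- B
    res
}

## one-hot encode a covariate set with reference levels; continuous passthrough
.encodeCovariates <- function(man, vars) {
    cols <- lapply(vars, function(v) {
        z <- man[[v]]
        if (is.numeric(z) && length(unique(z)) > 2L) {
            m <- matrix(z, ncol = 1L, dimnames = list(NULL, v))
        } else {
            f <- factor(z)
            if (nlevels(f) < 2L) stop("covariate with zero variance: ", v)
            m <- stats::model.matrix(~f)[, -1L, drop = FALSE]
            colnames(m) <- paste0(v, levels(f)[-1L])
        }
        if (any(apply(m, 2L, stats::var) == 0))
            stop("covariate with zero variance: ", v)
        m
    })
    do.call(cbind, cols)
}

#' Per-protein variance explained by single factors
#'
#' Marginal R-squared of each protein's abundance regressed on each factor
#' alone (categorical factors are dummy-coded), the diagnostic used to gauge
#' the success of each cleanup step.
#'
#' The raw R-squared of a B-level factor has a finite-sample floor of about
#' `(B - 1) / (n - 1)` even for factor-free data; `adjusted = TRUE` applies
#' the usual degrees-of-freedom correction (clipped at 0), which is unbiased
#' near zero and therefore the right scale for testing that a correction
#' step has removed a factor's variance.
#'
#' @param x a [ProteoSet-class].
#' @param factors manifest column names.
#' @param adjusted report the degrees-of-freedom-adjusted R-squared.
#' @return long `data.frame` with columns `protein`, `factor`, `r2`.
#' @export
varianceExplained <- function(x, factors, adjusted = FALSE) {
    stopifnot(is(x, "ProteoSet"))
    man <- sampleInfo(x)
    miss <- setdiff(factors, colnames(man))
    if (length(miss)) stop("manifest lacks column(s): ",
                           paste(miss, collapse = ", "))
    Y <- abundance(x)
    out <- list()
    for (f in factors) {
        M <- cbind(1, .encodeCovariates(man, f))
        r2 <- vapply(seq_len(nrow(Y)), function(g) {
            y <- Y[g, ]
            cc <- !is.na(y)
            if (sum(cc) <= ncol(M)) return(NA_real_)
            fit <- stats::lm.fit(M[cc, , drop = FALSE], y[cc])
            sst <- sum((y[cc] - mean(y[cc]))^2)
            if (sst == 0) return(NA_real_)
            r2 <- 1 - sum(fit$residuals^2) / sst
            if (adjusted) {
                n <- sum(cc); p <- ncol(M) - 1L
                r2 <- 1 - (1 - r2) * (n - 1) / (n - p - 1)
            }
            max(0, min(1, r2))
        }, numeric(1))
        out[[f]] <- data.frame(protein = rownames(Y), factor = f, r2 = r2,
                               row.names = NULL)
    }
    do.call(rbind, out)
}
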