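#' Module eigenprotein / trait correlations
#'
#' Biweight midcorrelation of every module eigenprotein with every requested
#' trait (numeric-coded: binary as 0/1, ordinal as integers), with Student-t
#' p-values. Complete-case per module x trait pair.
#'
#' @param ME eigenprotein matrix (modules x samples) or a
#'   [NetworkModel-class].
#' @param manifest per-sample `data.frame` (rows matching ME columns).
#' @param traits manifest column names to correlate.
#' @return `data.frame` with `module`, `trait`, `r`, `p`, `n_used`.
#' @export
meTraitAssociation <- function(ME, manifest, traits) {
    if (is(ME, "NetworkModel")) ME <- eigenproteins(ME)
    miss <- setdiff(traits, colnames(manifest))
    if (length(miss)) stop("manifest lacks trait(s): ",
                           paste(miss, collapse = ", "))
    tm <- t(as.matrix(manifest[colnames(ME), traits, drop = FALSE]))
    storage.mode(tm) <- "double"
    cv <- apply(tm, 1L, stats::var, na.rm = TRUE)
    if (any(!is.na(cv) & cv == 0)) stop("constant trait: ",
        paste(traits[!is.na(cv) & cv == 0], collapse = ", "))
    r <- bicorMatrix(ME, tm)
    n <- attr(r, "nObs")
    p <- corPvalue(r, n)
    data.frame(module = rep(rownames(ME), ncol(r)),
               trait = rep(colnames(r), each = nrow(r)),
               model = "bicor",
               r = as.vector(r), p = as.vector(p),
               n_used = as.vector(n), row.names = NULL)
}

#' Group-wise differential protein abundance
#'
#' `mode = "ttest"`: Welch two-sample t-test per protein with the difference
#' of group means as the log2 fold change (second group minus first).
#' `mode = "anova_tukey"`: one-way ANOVA, then Tukey HSD pairwise p-values;
#' any Tukey p below `10^-8.5` is replaced by the Bonferroni-corrected
#' pooled-variance pairwise p for that comparison. Proteins with fewer than 2
#' non-missing values in any group are skipped and flagged.
#'
#' @param x a [ProteoSet-class].
#' @param group manifest column defining groups.
#' @param mode `"ttest"` or `"anova_tukey"`.
#' @param groups optional subset/order of group levels (first = reference for
#'   the t-test fold change).
#' @param tukeyFallback Tukey p threshold below which the Bonferroni pairwise
#'   p is substituted.
#' @return `data.frame` per protein (and per comparison for ANOVA) with
#'   `log2FC`, `p`, `neg_log10_p`, and a `flagged` column for skipped
#'   proteins.
#' @export
differentialAbundance <- function(x, group, mode = c("ttest", "anova_tukey"),
                                  groups = NULL, tukeyFallback = 10^-8.5) {
    mode <- match.arg(mode)
    stopifnot(is(x, "ProteoSet"))
    man <- sampleInfo(x)
    g <- man[[group]]
    keep <- !is.na(g)
    if (!is.null(groups)) keep <- keep & g %in% groups
    g <- factor(g[keep], levels = if (is.null(groups)) sort(unique(g[keep]))
                                  else groups)
    V <- abundance(x)[, keep, drop = FALSE]
    if (nlevels(g) < 2L) stop("need at least 2 groups")
    if (mode == "ttest" && nlevels(g) != 2L)
        stop("ttest mode needs exactly 2 groups (use 'groups=')")

    if (mode == "ttest") {
        res <- lapply(rownames(V), function(pr) {
            y <- V[pr, ]
            n1 <- sum(!is.na(y[g == levels(g)[1L]]))
            n2 <- sum(!is.na(y[g == levels(g)[2L]]))
            if (n1 < 2L || n2 < 2L)
                return(data.frame(protein = pr, log2FC = NA_real_,
                                  p = NA_real_, flagged = TRUE))
            tt <- stats::t.test(y[g == levels(g)[2L]], y[g == levels(g)[1L]])
            data.frame(protein = pr,
                       log2FC = unname(diff(rev(tt$estimate))),
                       p = tt$p.value, flagged = FALSE)
        })
        out <- do.call(rbind, res)
    } else {
        res <- lapply(rownames(V), function(pr) {
            y <- V[pr, ]
            cc <- !is.na(y)
            cnt <- table(g[cc])
            if (any(cnt < 2L) || sum(cnt > 0) < 2L)
                return(data.frame(protein = pr, comparison = NA_character_,
                                  log2FC = NA_real_, p = NA_real_,
                                  anova_p = NA_real_, flagged = TRUE))
            d <- data.frame(y = y[cc], g = droplevels(g[cc]))
            fit <- stats::aov(y ~ g, data = d)
            ap <- summary(fit)[[1L]][["Pr(>F)"]][1L]
            tk <- stats::TukeyHSD(fit)$g
            cmp <- rownames(tk)
            p <- tk[, "p adj"]
            low <- which(p < tukeyFallback)
            if (length(low)) {
                mse <- sum(fit$residuals^2) / fit$df.residual
                ns <- table(d$g)
                for (i in low) {
                    pair <- strsplit(cmp[i], "-", fixed = TRUE)[[1L]]
                    se <- sqrt(mse * (1 / ns[pair[1L]] + 1 / ns[pair[2L]]))
                    tstat <- tk[i, "diff"] / se
                    praw <- 2 * stats::pt(abs(tstat), fit$df.residual,
                                          lower.tail = FALSE)
                    p[i] <- min(1, praw * length(cmp))
                }
            }
            data.frame(protein = pr, comparison = cmp,
                       log2FC = unname(tk[, "diff"]), p = unname(p),
                       anova_p = ap, flagged = FALSE, row.names = NULL)
        })
        out <- do.call(rbind, res)
    }
    out$neg_log10_p <- -log10(pmax(out$p, 1e-300))
    rownames(out) <- NULL
    out
}

#' Proteome-wide trait association scan
#'
#' Fits, per protein, `outcome ~ protein + covariates` with the protein
#' abundance as the exposure: a linear model for continuous outcomes, a
#' logistic model for binary outcomes, or a proportional-odds (ordinal
#' logistic) model for ordered 0..3 outcomes, each with a Wald p-value for
#' the protein term. Protein abundances are standardized within the
#' complete cases before ordinal/logistic fits (betas are on the standardized
#' scale). Non-converging fits are flagged and excluded from the adjusted
#' ranking. The Bonferroni significance cutoff `0.05 / m` (m = proteins
#' tested) is reported in attribute `"bonferroni_cutoff"`.
#'
#' @param x a [ProteoSet-class].
#' @param outcome manifest column name.
#' @param model `"linear"`, `"logistic"`, or `"ordinal"`.
#' @param covariates manifest columns adjusted for.
#' @param adjust `"bonferroni"` or `"BH"`.
#' @param standardize standardize the protein predictor (default `TRUE` for
#'   ordinal/logistic, `FALSE` for linear).
#' @return `data.frame` with `protein`, `beta`, `se`, `p`, `p_adj`,
#'   `n_used`, `flagged`.
#' @export
proteomewideScan <- function(x, outcome,
                             model = c("linear", "logistic", "ordinal"),
                             covariates = character(),
                             adjust = c("bonferroni", "BH"),
                             standardize = NULL) {
    model <- match.arg(model)
    adjust <- match.arg(adjust)
    if (is.null(standardize)) standardize <- model != "linear"
    stopifnot(is(x, "ProteoSet"))
    man <- sampleInfo(x)
    need <- c(outcome, covariates)
    miss <- setdiff(need, colnames(man))
    if (length(miss)) stop("manifest lacks column(s): ",
                           paste(miss, collapse = ", "))
    V <- abundance(x)
    y0 <- man[[outcome]]
    cov0 <- man[, covariates, drop = FALSE]

    fitOne <- function(pr) {
        d <- data.frame(.y = y0, .prot = V[pr, ], cov0)
        d <- d[stats::complete.cases(d), , drop = FALSE]
        n <- nrow(d)
        bad <- data.frame(protein = pr, beta = NA_real_, se = NA_real_,
                          p = NA_real_, n_used = n, flagged = TRUE)
        if (n < length(covariates) + 4L) return(bad)
        if (standardize) {
            if (stats::sd(d$.prot) == 0) return(bad)
            d$.prot <- as.numeric(scale(d$.prot))
        }
        form <- stats::reformulate(c(".prot", covariates), response = ".y")
        est <- tryCatch(switch(model,
            linear = {
                cf <- summary(stats::lm(form, data = d))$coefficients
                cf[".prot", c(1L, 2L, 4L)]
            },
            logistic = {
                d$.y <- as.integer(d$.y)
                if (length(unique(d$.y)) != 2L) stop("degenerate outcome")
                fit <- stats::glm(form, data = d, family = stats::binomial())
                if (!fit$converged) stop("non-convergence")
                cf <- summary(fit)$coefficients
                cf[".prot", c(1L, 2L, 4L)]
            },
            ordinal = {
                d$.y <- factor(d$.y, ordered = TRUE)
                if (nlevels(droplevels(d$.y)) < 3L) stop("degenerate outcome")
                d$.y <- droplevels(d$.y)
                fit <- MASS::polr(form, data = d, Hess = TRUE)
                cf <- summary(fit)$coefficients
                b <- cf[".prot", "Value"]; se <- cf[".prot", "Std. Error"]
                c(b, se, 2 * stats::pnorm(abs(b / se), lower.tail = FALSE))
            }), error = function(e) NULL, warning = function(w) NULL)
        if (is.null(est) || anyNA(est)) return(bad)
        data.frame(protein = pr, beta = est[1L], se = est[2L], p = est[3L],
                   n_used = n, flagged = FALSE)
    }
    out <- do.call(rbind, lapply(rownames(V), fitOne))
    rownames(out) <- NULL
    m <- sum(!out$flagged)
    out$p_adj <- NA_real_
    if (m > 0)
        out$p_adj[!out$flagged] <- adjustPvalues(out$p[!out$flagged],
            method = if (adjust == "bonferroni") "bonferroni" else "BH")
    attr(out, "bonferroni_cutoff") <- 0.05 / max(m, 1L)
    attr(out, "m_tested") <- m
    out
}

#' Per-protein biweight midcorrelation with a trait
#'
#' @param x a [ProteoSet-class].
#' @param trait numeric manifest column name.
#' @return `data.frame` with `protein`, `r`, `p`, `n_used`; counts of
#'   significantly (p < 0.05) positively/negatively correlated proteins are
#'   in attributes `"n_positive"` / `"n_negative"`.
#' @export
proteinTraitBicor <- function(x, trait) {
    stopifnot(is(x, "ProteoSet"))
    man <- sampleInfo(x)
    tv <- as.numeric(man[[trait]])
    r <- bicorMatrix(abundance(x), rbind(tv))
    n <- attr(r, "nObs")
    p <- corPvalue(r, n)
    out <- data.frame(protein = rownames(abundance(x)),
                      r = as.vector(r), p = as.vector(p),
                      n_used = as.vector(n), row.names = NULL)
    attr(out, "n_positive") <- sum(out$p < 0.05 & out$r > 0, na.rm = TRUE)
    attr(out, "n_negative") <- sum(out$p < 0.05 & out$r < 0, na.rm = TRUE)
    out
}

#' Adjust p-values for multiple testing
#'
#' Bonferroni (`min(1, p * m)`) or Benjamini-Hochberg step-up.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @param method `"bonferroni"` or `"BH"`.
#' @return adjusted p-values.
#' @export
adjustPvalues <- function(p, method = c("bonferroni", "BH")) {
    method <- match.arg(method)
    if (any(p < 0 | p > 1, na.rm = TRUE))
        stop("p-values must lie in [0, 1]")
    stats::p.adjust(p, method = if (method == "BH") "BH" else "bonferroni")
}
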