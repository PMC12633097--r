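#' Permutation-null module enrichment of gene-level statistics
#'
#' For each module, the observed statistic `T_m` is the mean transformed
#' gene-level p-value over the module's genes. The null is built from
#' `nPerm` seeded draws of the same number of genes, without replacement,
#' from the background (all genes carrying both a statistic and a label,
#' including unassigned/grey genes). The enrichment Z is
#' `(T_m - mean(T*)) / sd(T*)` and the one-sided exact permutation p is
#' `(#{T* >= T_m} + 1) / (nPerm + 1)`. When the number of distinct subsets
#' `choose(N, n_m)` is at most `10 * nPerm`, the null is enumerated
#' exhaustively (the observed subset enters the enumeration once) and the
#' same `(b + 1) / (m + 1)` estimator is applied over all subsets.
#'
#' The default transform is `-log10(p)`, so larger statistics mean stronger
#' significance and a positive Z means enrichment; `"raw_p"` uses the mean
#' raw p (there a *negative* Z indicates enrichment), and `"signed_logp"`
#' multiplies `-log10(p)` by the sign supplied in `effects`.
#'
#' @param geneStats named numeric vector of per-gene p-values.
#' @param labels named integer module labels (0 = grey).
#' @param nPerm number of permutations.
#' @param transform `"neglog10p"`, `"raw_p"`, or `"signed_logp"`.
#' @param effects named numeric effect sizes (required for `"signed_logp"`).
#' @param seed RNG seed.
#' @param exhaustiveLimit enumerate exhaustively when the number of distinct
#'   subsets is at most `exhaustiveLimit * nPerm`; set 0 to force Monte-Carlo
#'   sampling.
#' @return `data.frame` with one row per tested module: `module`,
#'   `n_genes_with_stats`, `observed_T`, `perm_mean`, `perm_sd`, `Z`,
#'   `p_perm`, `p_fdr`, `fdr_sig_05`, `fdr_sig_10`, `degenerate`,
#'   `exhaustive`, `n_perm`.
#' @export
permutationModuleEnrichment <- function(geneStats, labels, nPerm = 10000L,
                                        transform = c("neglog10p", "raw_p",
                                                      "signed_logp"),
                                        effects = NULL, seed = NULL,
                                        exhaustiveLimit = 10) {
    transform <- match.arg(transform)
    bg <- intersect(names(geneStats)[!is.na(geneStats)], names(labels))
    if (!length(bg)) stop("empty background")
    p <- geneStats[bg]
    if (any(p < 0 | p > 1)) stop("gene statistics must be p-values in [0, 1]")
    tstat <- switch(transform,
        neglog10p = -log10(pmax(p, 1e-300)),
        raw_p = p,
        signed_logp = {
            if (is.null(effects)) stop("signed_logp requires 'effects'")
            sign(effects[bg]) * -log10(pmax(p, 1e-300))
        })
    lab <- labels[bg]
    mods <- sort(unique(lab[lab > 0L]))
    mods <- mods[vapply(mods, function(m) sum(lab == m) >= 2L, logical(1))]
    if (!length(mods)) stop("no module with >= 2 genes carrying statistics")
    N <- length(bg)

    run <- function() lapply(mods, function(m) {
        k <- sum(lab == m)
        Tobs <- mean(tstat[lab == m])
        exhaustive <- choose(N, k) <= exhaustiveLimit * nPerm
        Tnull <- if (exhaustive) {
            utils::combn(N, k, FUN = function(i) mean(tstat[i]))
        } else {
            vapply(seq_len(nPerm), function(b)
                mean(tstat[sample.int(N, k)]), numeric(1))
        }
        mu <- mean(Tnull); sdv <- stats::sd(Tnull)
        degenerate <- !is.finite(sdv) || sdv < 1e-12
        data.frame(module = m, n_genes_with_stats = k, observed_T = Tobs,
                   perm_mean = mu, perm_sd = sdv,
                   Z = if (degenerate) NA_real_ else (Tobs - mu) / sdv,
                   p_perm = if (degenerate) 1 else
                       (sum(Tnull >= Tobs) + 1) / (length(Tnull) + 1),
                   degenerate = degenerate, exhaustive = exhaustive,
                   n_perm = length(Tnull))
    })
    res <- if (is.null(seed)) run() else withr::with_seed(seed, run())
    out <- do.call(rbind, res)
    out$p_fdr <- adjustPvalues(out$p_perm, "BH")
    out$fdr_sig_05 <- out$p_fdr < 0.05
    out$fdr_sig_10 <- out$p_fdr < 0.10
    out
}

#' One-sided Fisher exact set enrichment of modules
#'
#' Hypergeometric upper-tail (enrichment) test of the overlap between each
#' module and each gene set, on a common background; sets are intersected
#' with the background first. The reported odds ratio is the sample odds
#' ratio `ad / bc` (`Inf` when `bc = 0` and `ad > 0`). BH adjustment runs
#' across the full module x set grid.
#'
#' @param labels named integer module labels (0 = grey; grey is excluded from
#'   modules but counts toward the background).
#' @param sets named list of character vectors (e.g. from [readGmt()]).
#' @param background character vector of gene ids; default all labelled genes.
#' @return `data.frame` with `module`, `set`, `overlap`, `module_size`,
#'   `set_size`, `background_size`, `odds_ratio`, `p`, `p_BH`, plus skipped
#'   sets in attribute `"skipped_sets"`.
#' @export
fisherSetEnrichment <- function(labels, sets, background = NULL) {
    if (is.null(background)) background <- names(labels)
    background <- unique(background)
    if (!length(background)) stop("empty background")
    if (!all(names(labels) %in% background))
        stop("module genes must be a subset of the background")
    N <- length(background)
    mods <- sort(unique(labels[labels > 0L]))
    skipped <- character()
    rows <- list()
    for (sn in names(sets)) {
        set <- intersect(unique(sets[[sn]]), background)
        if (!length(set)) { skipped <- c(skipped, sn); next }
        for (m in mods) {
            mg <- names(labels)[labels == m]
            a <- length(intersect(mg, set))
            b <- length(mg) - a
            cc <- length(set) - a
            d <- N - length(mg) - length(set) + a
            or <- if (b * cc == 0) {
                if (a * d > 0) Inf else NA_real_
            } else (a * d) / (b * cc)
            pv <- stats::phyper(a - 1, length(set), N - length(set),
                                length(mg), lower.tail = FALSE)
            rows[[length(rows) + 1L]] <- data.frame(
                module = m, set = sn, overlap = a, module_size = length(mg),
                set_size = length(set), background_size = N,
                odds_ratio = or, p = pv)
        }
    }
    if (!length(rows)) stop("no testable module x set pair")
    out <- do.call(rbind, rows)
    out$p_BH <- adjustPvalues(out$p, "BH")
    attr(out, "skipped_sets") <- skipped
    out
}

#' Read a GMT gene-set file
#'
#' @param path GMT file (set name, description, tab-separated members).
#' @return named list of character vectors.
#' @export
readGmt <- function(path) fgsea::gmtPathways(path)

#' Write a GMT gene-set file
#'
#' @param sets named list of character vectors.
#' @param path output file.
#' @param descriptions optional descriptions (default `"na"`).
#' @return `path`, invisibly.
#' @export
writeGmt <- function(sets, path, descriptions = NULL) {
    if (is.null(descriptions)) descriptions <- rep("na", length(sets))
    lines <- vapply(seq_along(sets), function(i)
        paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
        character(1))
    writeLines(lines, path)
    invisible(path)
}
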