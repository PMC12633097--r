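#' Module preservation between a reference and a test dataset
#'
#' Quantifies whether modules defined in the reference dataset retain their
#' density and connectivity structure in the test dataset, with a permutation
#' Zsummary. Four observed statistics per module, all computed on the test
#' data using the reference labels (correlations are biweight
#' midcorrelations throughout):
#'
#' * `meanCor` - mean within-module |correlation| in test (density);
#' * `meanKME` - mean |kME| of members to the module eigenprotein computed in
#'   test (density);
#' * `cor.kIM` - correlation of intramodular connectivities (row sums of the
#'   within-module correlation submatrix) between reference and test
#'   (connectivity);
#' * `cor.cor` - correlation of the within-module correlation entries between
#'   reference and test (connectivity).
#'
#' The null replaces the module by `nPerm` random gene sets of matched size
#' drawn from the shared genes; per statistic `Z = (obs - null mean) / null
#' sd`. `Zdensity` / `Zconnectivity` are the medians of their two Zs,
#' `Zsummary = (Zdensity + Zconnectivity) / 2`, and modules are classified
#' `not_preserved` (< 1.96), `preserved` (>= 1.96), or `highly_preserved`
#' (>= 10).
#'
#' @param ref,test [ProteoSet-class]s or matrices (proteins x samples); gene
#'   identifiers are intersected.
#' @param labels named integer module labels defined on the reference
#'   (0 = grey, excluded).
#' @param nPerm number of permutations.
#' @param seed RNG seed.
#' @return `data.frame` with one row per retained module: observed
#'   statistics, per-statistic Zs, `Zdensity`, `Zconnectivity`, `Zsummary`,
#'   `classification`; skipped modules (< 5 shared genes) listed in attribute
#'   `"skipped_modules"`.
#' @export
modulePreservation <- function(ref, test, labels, nPerm = 500L, seed = NULL) {
    Vr <- if (is(ref, "ProteoSet")) abundance(ref) else as.matrix(ref)
    Vt <- if (is(test, "ProteoSet")) abundance(test) else as.matrix(test)
    shared <- intersect(rownames(Vr), rownames(Vt))
    shared <- intersect(shared, names(labels))
    if (length(shared) < 5L) stop("fewer than 5 shared genes")
    Vr <- Vr[shared, , drop = FALSE]
    Vt <- Vt[shared, , drop = FALSE]
    lab <- labels[shared]

    mods <- sort(unique(lab[lab > 0L]))
    keep <- vapply(mods, function(m) sum(lab == m) >= 5L, logical(1))
    skipped <- mods[!keep]
    mods <- mods[keep]
    if (!length(mods)) stop("no module with >= 5 shared genes")

    corRef <- .stripAttrs(bicorMatrix(Vr))
    corTest <- .stripAttrs(bicorMatrix(Vt))

    stats4 <- function(genes) {
        sr <- corRef[genes, genes]
        st <- corTest[genes, genes]
        ut <- upper.tri(sr)
        kr <- rowSums(sr, na.rm = TRUE) - 1
        kt <- rowSums(st, na.rm = TRUE) - 1
        me <- moduleEigenproteins(Vt[genes, , drop = FALSE],
                                  stats::setNames(rep(1L, length(genes)),
                                                  genes))$ME
        kme <- bicorMatrix(Vt[genes, , drop = FALSE], me)
        c(meanCor = mean(abs(st[ut]), na.rm = TRUE),
          meanKME = mean(abs(kme), na.rm = TRUE),
          cor.kIM = bicorMatrix(rbind(kr), rbind(kt))[1L, 1L],
          cor.cor = bicorMatrix(rbind(sr[ut]), rbind(st[ut]))[1L, 1L])
    }

    run <- function() lapply(mods, function(m) {
        genes <- shared[lab == m]
        k <- length(genes)
        obs <- stats4(genes)
        null <- t(vapply(seq_len(nPerm), function(b)
            stats4(sample(shared, k)), numeric(4L)))
        mu <- colMeans(null, na.rm = TRUE)
        sdv <- apply(null, 2L, stats::sd, na.rm = TRUE)
        z <- (obs - mu) / sdv
        z[!is.finite(z)] <- NA_real_
        zd <- stats::median(z[c("meanCor", "meanKME")], na.rm = TRUE)
        zc <- stats::median(z[c("cor.kIM", "cor.cor")], na.rm = TRUE)
        zsum <- (zd + zc) / 2
        data.frame(module = m, module_size = k,
                   meanCor = obs["meanCor"], meanKME = obs["meanKME"],
                   cor.kIM = obs["cor.kIM"], cor.cor = obs["cor.cor"],
                   Z.meanCor = z["meanCor"], Z.meanKME = z["meanKME"],
                   Z.cor.kIM = z["cor.kIM"], Z.cor.cor = z["cor.cor"],
                   Zdensity = zd, Zconnectivity = zc, Zsummary = zsum,
                   classification = if (is.na(zsum)) NA_character_
                       else if (zsum >= 10) "highly_preserved"
                       else if (zsum >= 1.96) "preserved"
                       else "not_preserved",
                   row.names = NULL)
    })
    res <- if (is.null(seed)) run() else withr::with_seed(seed, run())
    out <- do.call(rbind, res)
    attr(out, "skipped_modules") <- skipped
    attr(out, "n_perm") <- nPerm
    out
}
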