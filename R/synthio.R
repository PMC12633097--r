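#' Configuration for the synthetic multiplexed proteome generator
#'
#' Defines the generative model used by [simulateProteomics()]: planted
#' co-expression modules driven by latent factors, multiplicative (log2
#' additive) batch effects, pooled global-internal-standard (GIS) channels,
#' covariate effects, missing-not-at-random dropout, and traits generated
#' from the planted factors through ordinal, binary, or linear links.
#'
#' The log2 abundance of protein g in sample s is
#' `base_g + lambda_g * f_(m(g), s) + b_(batch(s)) + covariate terms + eps`,
#' with `eps ~ N(0, noise_sd^2)`; the emitted intensity is `2^log2abundance`.
#' A cell is set missing with probability
#' `plogis(missing_steepness * (missing_midpoint - log2abundance))`;
#' set `missing_midpoint = -Inf` to disable missingness. Zeros are never
#' emitted.
#'
#' Defaults are the package's reference study conditions: 6 modules of 50
#' proteins embedded in a 1000-protein proteome (700 uncorrelated background
#' proteins, so that per-sample summary statistics such as intensity totals
#' and polish medians are dominated by non-module signal, as in a real
#' proteome), 120 biological samples across 7 batches each carrying one GIS
#' channel, and trait links planting an ordinal 0-3 severity trait ("caa")
#' on module 1, binary lesion traits on module 2, and a continuous imaging
#' burden ("wmh") on module 3.
#'
#' @param n_proteins total number of proteins.
#' @param module_sizes integer vector of planted module sizes (each >= 3);
#'   their sum must not exceed `n_proteins`; leftover proteins are
#'   uncorrelated background.
#' @param n_samples number of biological (non-GIS) samples.
#' @param n_batches number of multiplexed batches.
#' @param gis_per_batch GIS channels per batch.
#' @param loading_mean,loading_sd loading distribution `N(mean, sd^2)`,
#'   truncated away from zero (|lambda| >= 0.1) so planted membership is
#'   recoverable.
#' @param noise_sd residual log2 noise (biological + technical).
#' @param gis_noise_sd technical measurement noise of the pooled GIS
#'   channels, in log2 units (default 0.08, about a 5-6% CV: a pooled
#'   standard averages away biological variation, leaving reporter-ion
#'   measurement noise only).
#' @param batch_effect_sd sd of per-batch additive log2 offsets.
#' @param batch_offsets optional fixed per-batch log2 offsets (overrides
#'   `batch_effect_sd` draws).
#' @param batch_protein_sd sd of additional protein-specific batch offsets
#'   (`b_gb ~ N(0, batch_protein_sd^2)`), modelling per-protein batch
#'   distortions that whole-sample normalization cannot remove; default 0
#'   (sample-level offsets only).
#' @param base_abundance_range range of per-protein base log2 abundance.
#' @param missing_steepness,missing_midpoint logistic MNAR parameters.
#' @param trait_links named list; each element
#'   `list(module =, link = "ordinal4"|"binary"|"linear", beta =)`.
#' @param covariate_effects named list over `age`, `pmi`, `cellprop`; each a
#'   `c(mean =, sd =)` pair for the per-protein effect distribution. Empty
#'   list disables covariate injection.
#' @param seed integer RNG seed; identical seeds give bit-identical output.
#' @return object of class `SynthConfig`.
#' @export
synthConfig <- function(n_proteins = 1000L,
                        module_sizes = rep(50L, 6L),
                        n_samples = 120L,
                        n_batches = 7L,
                        gis_per_batch = 1L,
                        loading_mean = 1, loading_sd = 0.2,
                        noise_sd = 0.8,
                        gis_noise_sd = 0.08,
                        batch_effect_sd = 0.4,
                        batch_offsets = NULL,
                        batch_protein_sd = 0,
                        base_abundance_range = c(14, 20),
                        missing_steepness = 1, missing_midpoint = 11,
                        trait_links = list(
                            caa         = list(module = 1L, link = "ordinal4", beta = 0.8),
                            microbleeds = list(module = 2L, link = "binary",   beta = 0.8),
                            infarcts    = list(module = 2L, link = "binary",   beta = 0.5),
                            wmh         = list(module = 3L, link = "linear",   beta = 0.5)),
                        covariate_effects = list(
                            age      = c(mean = 0, sd = 0.01),
                            pmi      = c(mean = 0, sd = 0.02),
                            cellprop = c(mean = 0, sd = 0.5)),
                        seed = 1L) {
    if (missing(trait_links))   # default links adapt to fewer planted modules
        trait_links <- Filter(function(tl) tl$module <= length(module_sizes),
                              trait_links)
    cfg <- list(n_proteins = as.integer(n_proteins),
                module_sizes = as.integer(module_sizes),
                n_modules = length(module_sizes),
                n_samples = as.integer(n_samples),
                n_batches = as.integer(n_batches),
                gis_per_batch = as.integer(gis_per_batch),
                loading_mean = loading_mean, loading_sd = loading_sd,
                noise_sd = noise_sd, gis_noise_sd = gis_noise_sd,
                batch_effect_sd = batch_effect_sd,
                batch_offsets = batch_offsets,
                batch_protein_sd = batch_protein_sd,
                base_abundance_range = base_abundance_range,
                missing_steepness = missing_steepness,
                missing_midpoint = missing_midpoint,
                trait_links = trait_links,
                covariate_effects = covariate_effects,
                seed = as.integer(seed))
    class(cfg) <- "SynthConfig"
    validateSynthConfig(cfg)
    cfg
}

#' Validate a SynthConfig
#' @param cfg a `SynthConfig`.
#' @return `cfg`, invisibly; errors on violation.
#' @export
validateSynthConfig <- function(cfg) {
    if (sum(cfg$module_sizes) > cfg$n_proteins)
        stop("sum(module_sizes) exceeds n_proteins")
    if (any(cfg$module_sizes < 3L))
        stop("all module_sizes must be >= 3")
    sds <- c(cfg$loading_sd, cfg$noise_sd, cfg$gis_noise_sd,
             cfg$batch_effect_sd, cfg$batch_protein_sd)
    if (any(sds < 0)) stop("sd parameters must be >= 0")
    if (cfg$n_batches < 1L || cfg$n_samples < cfg$n_batches)
        stop("need n_samples >= n_batches >= 1")
    if (!is.null(cfg$batch_offsets) &&
        length(cfg$batch_offsets) != cfg$n_batches)
        stop("batch_offsets must have length n_batches")
    for (nm in names(cfg$trait_links)) {
        tl <- cfg$trait_links[[nm]]
        if (!tl$link %in% c("ordinal4", "binary", "linear"))
            stop("unknown trait link: ", tl$link)
        if (tl$module < 1L || tl$module > cfg$n_modules)
            stop(sprintf("trait '%s' references nonexistent module %d",
                         nm, tl$module))
    }
    badCov <- setdiff(names(cfg$covariate_effects),
                      c("age", "pmi", "cellprop"))
    if (length(badCov))
        stop("unknown covariate_effects entries: ",
             paste(badCov, collapse = ", "))
    invisible(cfg)
}

## equally spaced proportional-odds cutpoints for the 4-level ordinal trait
.ORDINAL_CUTPOINTS <- c(-1.2, 0, 1.2)

#' Generate a synthetic multiplexed proteomic dataset
#'
#' Draws a raw intensity [ProteoSet-class] (with GIS channels and MNAR
#' missingness), a sample manifest in its `colData`, and a `SyntheticTruth`
#' list recording everything that was planted (module labels, latent factors,
#' batch offsets, loadings, covariate betas, trait betas). Deterministic under
#' a fixed `cfg$seed`.
#'
#' GIS channel intensities are the within-batch per-protein mean of the
#' non-GIS intensities, perturbed by log2 noise with sd `gis_noise_sd`,
#' modelling a pooled all-sample mixture channel measured with technical
#' noise only.
#'
#' @param cfg a [synthConfig()] object.
#' @return `list(data = ProteoSet (raw intensities), truth = SyntheticTruth)`.
#' @examples
#' sim <- simulateProteomics(synthConfig(n_proteins = 20,
#'     module_sizes = c(5, 5), n_samples = 24, n_batches = 2, seed = 7))
#' sim$data
#' @export
simulateProteomics <- function(cfg) {
    validateSynthConfig(cfg)
    withr::with_seed(cfg$seed, .simulate(cfg))
}

.simulate <- function(cfg) {
    P <- cfg$n_proteins; S <- cfg$n_samples; B <- cfg$n_batches
    K <- cfg$n_modules
    prot <- sprintf("P%04d", seq_len(P))
    samp <- sprintf("S%03d", seq_len(S))

    labels <- integer(P)
    idx <- 1L
    for (m in seq_len(K)) {
        labels[idx:(idx + cfg$module_sizes[m] - 1L)] <- m
        idx <- idx + cfg$module_sizes[m]
    }
    names(labels) <- prot

    batch <- rep(seq_len(B), length.out = S)
    batch <- sort(batch)                      # contiguous batches

    ## latent factors: exact zero mean / unit variance per module
    Fm <- matrix(stats::rnorm(K * S), K, S, dimnames = list(NULL, samp))
    Fm <- t(scale(t(Fm)))

    lambda <- stats::rnorm(P, cfg$loading_mean, cfg$loading_sd)
    while (any(abs(lambda) < 0.1))            # truncate away from zero
        lambda[abs(lambda) < 0.1] <-
            stats::rnorm(sum(abs(lambda) < 0.1), cfg$loading_mean,
                         cfg$loading_sd)
    lambda[labels == 0L] <- 0

    base <- stats::runif(P, cfg$base_abundance_range[1],
                         cfg$base_abundance_range[2])
    bOff <- if (is.null(cfg$batch_offsets))
        stats::rnorm(B, 0, cfg$batch_effect_sd) else cfg$batch_offsets
    names(bOff) <- paste0("b", seq_len(B))

    ## covariates
    age <- stats::rnorm(S, 75, 8)
    pmi <- pmax(1, stats::rnorm(S, 8, 3))
    cellprop <- stats::rbeta(S, 5, 15)
    sex <- stats::rbinom(S, 1, 0.5)
    apoe4 <- sample(0:2, S, replace = TRUE, prob = c(0.6, 0.3, 0.1))
    covs <- cbind(age = age, pmi = pmi, cellprop = cellprop)

    covNames <- names(cfg$covariate_effects)
    covBeta <- matrix(0, P, length(covNames),
                      dimnames = list(prot, covNames))
    for (cn in covNames)
        covBeta[, cn] <- stats::rnorm(P, cfg$covariate_effects[[cn]]["mean"],
                                      cfg$covariate_effects[[cn]]["sd"])

    L <- base +
        lambda * rbind(0, Fm)[labels + 1L, , drop = FALSE] +
        matrix(bOff[batch], P, S, byrow = TRUE) +
        matrix(stats::rnorm(P * S, 0, cfg$noise_sd), P, S)
    bProt <- matrix(0, P, cfg$n_batches, dimnames = list(prot, names(bOff)))
    if (cfg$batch_protein_sd > 0) {
        bProt[] <- stats::rnorm(P * cfg$n_batches, 0, cfg$batch_protein_sd)
        L <- L + bProt[, batch]
    }
    if (length(covNames))
        L <- L + covBeta %*% t(scale(covs[, covNames, drop = FALSE],
                                     scale = FALSE))
    dimnames(L) <- list(prot, samp)
    intens <- 2^L

    ## GIS channels: within-batch per-protein mean intensity + small noise
    gisCols <- list(); gisMeta <- list()
    for (b in seq_len(B)) {
        mb <- rowMeans(intens[, batch == b, drop = FALSE])
        for (g in seq_len(cfg$gis_per_batch)) {
            gl <- log2(mb) + stats::rnorm(P, 0, cfg$gis_noise_sd)
            nm <- sprintf("GIS_b%d_%d", b, g)
            gisCols[[nm]] <- 2^gl
            gisMeta[[nm]] <- b
        }
    }
    gisMat <- do.call(cbind, gisCols)
    allInt <- cbind(intens, gisMat)
    allBatch <- c(batch, unlist(gisMeta))
    isGis <- c(rep(FALSE, S), rep(TRUE, ncol(gisMat)))

    ## traits from the planted factors
    traits <- list()
    traitBeta <- numeric(0)
    for (nm in names(cfg$trait_links)) {
        tl <- cfg$trait_links[[nm]]
        f <- Fm[tl$module, ]
        eta <- tl$beta * f
        traits[[nm]] <- switch(tl$link,
            ordinal4 = {
                cp <- stats::plogis(outer(.ORDINAL_CUTPOINTS, eta, "-"))
                u <- stats::runif(S)
                colSums(cp < rep(u, each = 3L))   # category 0..3
            },
            binary = stats::rbinom(S, 1, stats::plogis(eta)),
            linear = if (nm == "wmh")
                pmax(0, 5 + eta + stats::rnorm(S)) else
                eta + stats::rnorm(S))
        traitBeta[nm] <- tl$beta
    }
    caa <- if (!is.null(traits$caa)) traits$caa else
        sample(0:3, S, replace = TRUE)
    group <- c("control", "other", "AD", "AD")[caa + 1L]
    cerad <- pmin(3L, pmax(0L, caa + sample(c(-1L, 0L, 1L), S, TRUE,
                                            prob = c(0.2, 0.6, 0.2))))
    braak <- pmin(6L, pmax(0L, 2L * caa + sample(-1L:1L, S, TRUE)))

    manifest <- data.frame(
        batch = factor(paste0("b", allBatch), levels = paste0("b", seq_len(B))),
        is_gis = isGis,
        group = c(group, rep(NA, sum(isGis))),
        caa = c(caa, rep(NA, sum(isGis))),
        cerad = c(cerad, rep(NA, sum(isGis))),
        braak = c(braak, rep(NA, sum(isGis))),
        wmh = c(if (is.null(traits$wmh)) rep(NA_real_, S) else traits$wmh,
                rep(NA, sum(isGis))),
        microbleeds = c(if (is.null(traits$microbleeds)) rep(NA_integer_, S)
                        else traits$microbleeds, rep(NA, sum(isGis))),
        infarcts = c(if (is.null(traits$infarcts)) rep(NA_integer_, S)
                     else traits$infarcts, rep(NA, sum(isGis))),
        age = c(age, rep(NA, sum(isGis))),
        pmi = c(pmi, rep(NA, sum(isGis))),
        sex = c(sex, rep(NA, sum(isGis))),
        apoe4 = c(apoe4, rep(NA, sum(isGis))),
        cellprop = c(cellprop, rep(NA, sum(isGis))),
        row.names = colnames(allInt))

    ## MNAR dropout on every channel
    logAll <- log2(allInt)
    pMiss <- stats::plogis(cfg$missing_steepness *
                           (cfg$missing_midpoint - logAll))
    drop <- matrix(stats::runif(length(allInt)), nrow(allInt)) < pMiss
    allInt[drop] <- NA_real_

    truth <- list(planted_labels = labels,
                  latent_factors = Fm,
                  loadings = stats::setNames(lambda, prot),
                  batch_offsets = bOff,
                  batch_protein_offsets = bProt,
                  covariate_betas = covBeta,
                  trait_betas = traitBeta,
                  trait_links = cfg$trait_links,
                  ordinal_cutpoints = .ORDINAL_CUTPOINTS)
    class(truth) <- "SyntheticTruth"

    list(data = ProteoSet(allInt, manifest, scaleTag = "raw"), truth = truth)
}
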