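#' Default end-to-end run configuration
#'
#' Nested list of stage toggles and parameters. Defaults are the reference
#' analysis values: network power 8, deepSplit 3, minimum module size 10,
#' merge cut height 0.07, mean TOM denominator, kME rules {0.10, 0.30, 30
#' iterations}, 10,000 enrichment permutations, 500 preservation
#' permutations, 1000 bootstrap regressions. Override entries by name;
#' unknown keys are rejected by [runPipeline()] before any computation.
#'
#' @param ... named overrides, possibly nested lists
#'   (e.g. `network = list(power = 6)`).
#' @return a `RunConfig` list.
#' @export
runConfig <- function(...) {
    cfg <- list(
        seed = 1L,
        outdir = NULL,
        input = list(abundance = NULL, manifest = NULL),
        stages = list(simulate = TRUE, preprocess = TRUE, tampor = TRUE,
                      regress = TRUE, network = TRUE, associate = TRUE,
                      enrich = TRUE, preserve = FALSE),
        synth = list(),
        preprocess = list(max_missing_frac = 0.5, pca_components = 2L,
                          pca_sd_threshold = 4, remove_outliers = TRUE),
        tampor = list(use_all_non_gis = FALSE, tol = 1e-8,
                      max_iterations = 250L),
        regress = list(covariates = c("age", "pmi", "cellprop", "batch"),
                       protected = character(), n_bootstrap = 1000L),
        network = networkParams(),
        associate = list(me_traits = c("caa", "cerad", "braak", "apoe4",
                                       "sex", "wmh"),
                         scan_outcome = "caa", scan_model = "ordinal",
                         scan_covariates = c("age", "sex"),
                         scan_adjust = "bonferroni"),
        enrich = list(n_perm = 10000L, transform = "neglog10p"),
        preserve = list(n_perm = 500L))
    overrides <- list(...)
    if (length(overrides) == 1L && is.null(names(overrides)) &&
        is.list(overrides[[1L]]))
        overrides <- overrides[[1L]]
    out <- .mergeConfig(cfg, overrides, path = "")
    class(out) <- c("RunConfig", "list")
    out
}

## strict recursive merge: any key absent from the template is an error
.mergeConfig <- function(template, overrides, path) {
    if (!length(overrides)) return(template)
    nm <- names(overrides)
    if (is.null(nm) || any(nm == ""))
        stop("config overrides must be named")
    unknown <- setdiff(nm, names(template))
    if (length(unknown))
        stop("unknown config key(s): ",
             paste0(sub("^\\.", "", paste0(path, ".", unknown)),
                    collapse = ", "))
    for (k in nm) {
        if (is.list(template[[k]]) && is.list(overrides[[k]]) &&
            !is.null(names(template[[k]])))
            template[[k]] <- .mergeConfig(template[[k]], overrides[[k]],
                                          paste0(path, ".", k))
        else template[k] <- overrides[k]
    }
    template
}

#' Load a run configuration from a YAML file
#'
#' @param path YAML file of overrides to [runConfig()] defaults.
#' @return a `RunConfig` list; unknown keys are rejected.
#' @export
readRunConfig <- function(path) runConfig(yaml::read_yaml(path))

#' Run the full analysis pipeline
#'
#' Executes (per the stage toggles) simulate-or-ingest -> sum scaling,
#' missingness filtering, log2 transform, PCA outlier removal -> TAMPOR batch
#' correction -> bootstrap covariate regression -> signed network
#' construction -> module/protein trait associations -> permutation module
#' enrichment of the proteome-wide scan -> module preservation against an
#' independently simulated replicate. Every stage writes its artifact
#' (TSV/JSON) under `outdir` and the machine-readable run report aggregates
#' parameters, derived seeds, and counts. A fixed seed gives byte-identical
#' artifacts.
#'
#' @param config a `RunConfig` from [runConfig()] or [readRunConfig()], or a
#'   list of overrides.
#' @param outdir output directory (overrides `config$outdir`); created if
#'   needed.
#' @return the run report (named list), invisibly; also written as
#'   `run_report.json`.
#' @export
runPipeline <- function(config = runConfig(), outdir = NULL) {
    if (!inherits(config, "RunConfig")) config <- runConfig(config)
    if (!is.null(outdir)) config$outdir <- outdir
    if (is.null(config$outdir)) stop("an output directory is required")
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    out <- function(f) file.path(config$outdir, f)
    seed <- as.integer(config$seed)
    seeds <- list(simulate = seed, regress = seed + 1L, enrich = seed + 2L,
                  preserve = seed + 3L, replicate = seed + 4L)
    report <- list(seed = seed, derived_seeds = seeds, stages = list())
    st <- config$stages

    truth <- NULL
    synthArgs <- config$synth[setdiff(names(config$synth), "seed")]
    if (st$simulate) {
        scfg <- do.call(synthConfig, c(synthArgs,
                                       list(seed = seeds$simulate)))
        sim <- simulateProteomics(scfg)
        ps <- sim$data
        truth <- sim$truth
        writeAbundanceTsv(ps, out("abundance_raw.tsv"))
        writeManifestTsv(sampleInfo(ps), out("manifest.tsv"))
        .writeJson(list(planted_labels = as.list(truth$planted_labels),
                        batch_offsets = as.list(truth$batch_offsets),
                        trait_betas = as.list(truth$trait_betas)),
                   out("truth.json"))
        report$stages$simulate <- list(n_proteins = nrow(ps),
                                       n_samples = ncol(ps),
                                       n_gis = sum(sampleInfo(ps)$is_gis))
    } else {
        if (is.null(config$input$abundance))
            stop("stages$simulate is off and no input abundance path given")
        V <- readAbundanceTsv(config$input$abundance)
        man <- readManifestTsv(config$input$manifest)
        ps <- ProteoSet(V, man, scaleTag = "raw")
        report$stages$ingest <- list(n_proteins = nrow(ps),
                                     n_samples = ncol(ps))
    }

    if (st$preprocess) {
        pp <- config$preprocess
        ps <- suppressMessages(
            filterMissing(sumScale(ps), pp$max_missing_frac))
        ps <- log2Transform(ps)
        flagged <- pcaOutlierFlag(ps, pp$pca_components, pp$pca_sd_threshold)
        if (pp$remove_outliers && length(flagged))
            ps <- ps[, setdiff(colnames(ps), flagged)]
        writeAbundanceTsv(ps, out("abundance_log2.tsv"))
        report$stages$preprocess <- list(
            n_proteins = nrow(ps), n_samples = ncol(ps),
            outliers_flagged = as.character(flagged))
    }

    tamporState <- NULL
    if (st$tampor) {
        tp <- config$tampor
        veBefore <- varianceExplained(ps, "batch", adjusted = TRUE)
        tc <- tamporCorrect(ps, useAllNonGIS = tp$use_all_non_gis,
                            tol = tp$tol,
                            maxIterations = tp$max_iterations)
        ps <- tc$data
        tamporState <- tc$state
        veAfter <- varianceExplained(ps, "batch", adjusted = TRUE)
        writeAbundanceTsv(ps, out("abundance_tampor.tsv"))
        report$stages$tampor <- list(
            iterations = tamporState$iterations,
            converged = tamporState$converged,
            dropped_proteins = length(tamporState$dropped_proteins),
            median_batch_r2_before = stats::median(veBefore$r2, na.rm = TRUE),
            median_batch_r2_after = stats::median(veAfter$r2, na.rm = TRUE))
    }

    if (st$regress) {
        rg <- config$regress
        man0 <- sampleInfo(ps)
        if ("is_gis" %in% colnames(man0) && any(man0$is_gis))
            ps <- ps[, !man0$is_gis]   # GIS channels carry no covariates
        covs <- intersect(rg$covariates, colnames(sampleInfo(ps)))
        ps <- bootstrapRegress(ps, covariates = covs,
                               protected = rg$protected,
                               nBootstrap = rg$n_bootstrap,
                               seed = seeds$regress)
        writeAbundanceTsv(ps, out("abundance_regressed.tsv"))
        report$stages$regress <- list(covariates_removed = covs,
                                      n_bootstrap = rg$n_bootstrap)
    }

    if ("batch" %in% colnames(sampleInfo(ps)))
        report$final_median_batch_r2 <-
            stats::median(varianceExplained(ps, "batch",
                                            adjusted = TRUE)$r2, na.rm = TRUE)

    net <- NULL
    if (st$network) {
        net <- buildNetwork(ps, config$network)
        writeLabelsTsv(moduleLabels(net), out("module_labels.tsv"))
        writeAbundanceTsv(eigenproteins(net), out("module_eigenproteins.tsv"))
        writeAbundanceTsv(kME(net), out("kme_table.tsv"))
        k <- max(0L, moduleLabels(net))
        report$stages$network <- list(
            n_modules = k,
            module_sizes = if (k) as.integer(
                tabulate(moduleLabels(net)[moduleLabels(net) > 0L], k))
                else integer(),
            n_grey = sum(moduleLabels(net) == 0L),
            reassign_iterations = net@info$reassign_iterations,
            reassign_converged = net@info$reassign_converged)
        if (!is.null(truth)) {
            shared <- intersect(names(moduleLabels(net)),
                                names(truth$planted_labels))
            report$stages$network$ari_vs_planted <-
                .adjustedRand(truth$planted_labels[shared],
                              moduleLabels(net)[shared])
        }
    }

    scan <- NULL
    if (st$associate) {
        if (is.null(net)) stop("associate stage requires the network stage")
        as_ <- config$associate
        man <- sampleInfo(ps)
        traits <- intersect(as_$me_traits, colnames(man))
        meAssoc <- meTraitAssociation(eigenproteins(net), man, traits)
        utils::write.table(meAssoc, out("me_trait_association.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        scan <- proteomewideScan(ps, as_$scan_outcome,
                                 model = as_$scan_model,
                                 covariates = intersect(as_$scan_covariates,
                                                        colnames(man)),
                                 adjust = as_$scan_adjust)
        utils::write.table(scan, out("proteomewide_scan.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        report$stages$associate <- list(
            me_trait_sig_005 = sum(meAssoc$p < 0.05, na.rm = TRUE),
            scan_m_tested = attr(scan, "m_tested"),
            scan_bonferroni_cutoff = attr(scan, "bonferroni_cutoff"),
            scan_sig_bonferroni = sum(scan$p_adj < 0.05, na.rm = TRUE))
    }

    if (st$enrich) {
        if (is.null(scan) || is.null(net))
            stop("enrich stage requires the network and associate stages")
        en <- config$enrich
        gs <- stats::setNames(scan$p, scan$protein)
        enr <- permutationModuleEnrichment(gs[!is.na(gs)],
                                           moduleLabels(net),
                                           nPerm = en$n_perm,
                                           transform = en$transform,
                                           seed = seeds$enrich)
        utils::write.table(enr, out("module_enrichment.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        report$stages$enrich <- list(
            n_modules_tested = nrow(enr),
            top_module = enr$module[which.max(enr$Z)],
            sig_fdr_05 = sum(enr$fdr_sig_05))
    }

    if (st$preserve) {
        if (is.null(net)) stop("preserve stage requires the network stage")
        pv <- config$preserve
        scfg2 <- do.call(synthConfig, c(synthArgs,
                                        list(seed = seeds$replicate)))
        sim2 <- simulateProteomics(scfg2)
        ps2 <- log2Transform(suppressMessages(filterMissing(
            sumScale(sim2$data), config$preprocess$max_missing_frac)))
        ps2 <- tamporCorrect(ps2)$data
        pres <- modulePreservation(ps, ps2, moduleLabels(net),
                                   nPerm = pv$n_perm, seed = seeds$preserve)
        utils::write.table(pres, out("module_preservation.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        report$stages$preserve <- list(
            n_modules = nrow(pres),
            n_preserved = sum(pres$Zsummary >= 1.96, na.rm = TRUE),
            n_highly_preserved = sum(pres$Zsummary >= 10, na.rm = TRUE))
    }

    report$parameters <- config[setdiff(names(config), "outdir")]
    .writeJson(report, out("run_report.json"))
    invisible(report)
}

.writeJson <- function(x, path)
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")

## adjusted Rand index between two labelings (Hubert & Arabie)
.adjustedRand <- function(a, b) {
    tab <- table(a, b)
    sij <- sum(choose(tab, 2))
    si <- sum(choose(rowSums(tab), 2))
    sj <- sum(choose(colSums(tab), 2))
    n2 <- choose(sum(tab), 2)
    exp_ <- si * sj / n2
    maxidx <- (si + sj) / 2
    if (maxidx == exp_) return(1)
    (sij - exp_) / (maxidx - exp_)
}
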