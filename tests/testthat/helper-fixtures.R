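# Shared fixtures, memoised so expensive objects are built once per session.

.fixtures <- new.env(parent = emptyenv())

# compact planted-module dataset for unit tests
smallConfig <- function(...) {
    synthConfig(n_proteins = 160L, module_sizes = c(25L, 25L),
                n_samples = 48L, n_batches = 3L, seed = 101L, ...)
}

smallSim <- function() {
    if (is.null(.fixtures$smallSim))
        .fixtures$smallSim <- simulateProteomics(smallConfig())
    .fixtures$smallSim
}

# small dataset taken through preprocess + TAMPOR
smallCorrected <- function() {
    if (is.null(.fixtures$smallCorrected)) {
        sim <- smallSim()
        ps <- log2Transform(suppressMessages(filterMissing(sumScale(sim$data))))
        .fixtures$smallCorrected <- suppressWarnings(tamporCorrect(ps))
    }
    .fixtures$smallCorrected
}

# full-default pipeline fit (the reference study conditions), used by the
# module-recovery and enrichment acceptance checks
defaultFit <- function() {
    if (is.null(.fixtures$defaultFit)) {
        sim <- simulateProteomics(synthConfig(seed = 3L))
        ps <- log2Transform(suppressMessages(filterMissing(sumScale(sim$data))))
        ps <- suppressWarnings(tamporCorrect(ps))$data
        ps <- bootstrapRegress(ps,
                               covariates = c("age", "pmi", "cellprop", "batch"),
                               nBootstrap = 1000L, seed = 11L)
        net <- buildNetwork(ps)
        .fixtures$defaultFit <- list(sim = sim, ps = ps, net = net)
    }
    .fixtures$defaultFit
}

# map each planted module to the detected module with maximal overlap
matchModules <- function(planted, detected) {
    shared <- intersect(names(planted), names(detected))
    vapply(sort(unique(planted[planted > 0L])), function(m) {
        tab <- table(detected[shared][planted[shared] == m])
        as.integer(names(tab)[which.max(tab)])
    }, integer(1))
}
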