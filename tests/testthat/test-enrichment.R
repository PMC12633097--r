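test_that("the exhaustive permutation p matches full enumeration on the worked case", {
    # transformed stats (5, 4, 1, 1, 1, 0); module = the two largest
    gs <- setNames(10^-c(5, 4, 1, 1, 1, 0), paste0("g", 1:6))
    lab <- setNames(c(1L, 1L, 0L, 0L, 0L, 0L), names(gs))
    res <- permutationModuleEnrichment(gs, lab, nPerm = 1000, seed = 1)
    expect_true(res$exhaustive)
    expect_equal(res$n_perm, choose(6, 2))
    expect_equal(res$observed_T, 4.5)
    expect_equal(res$p_perm, (1 + 1) / (15 + 1))      # unique maximum
    expect_equal(res$p_perm, oraclePermExact(-log10(gs), 1:2))
})

test_that("identical statistics give a degenerate null with p = 1", {
    gs <- setNames(rep(0.2, 8), paste0("g", 1:8))
    lab <- setNames(rep(c(1L, 0L), 4), names(gs))
    res <- permutationModuleEnrichment(gs, lab, nPerm = 100, seed = 1)
    expect_true(res$degenerate)
    expect_true(is.na(res$Z))
    expect_equal(res$p_perm, 1)
})

test_that("Monte-Carlo and exhaustive estimates agree within the binomial envelope", {
    set.seed(28)
    for (i in 1:5) {
        gs <- setNames(runif(11)^2, paste0("g", 1:11))
        lab <- setNames(c(rep(1L, 4), rep(0L, 7)), names(gs))
        ex <- permutationModuleEnrichment(gs, lab, nPerm = 100, seed = 2)
        mc <- permutationModuleEnrichment(gs, lab, nPerm = 10000, seed = 2,
                                          exhaustiveLimit = 0)
        expect_true(ex$exhaustive)
        expect_false(mc$exhaustive)
        env <- 4 * sqrt(ex$p_perm * (1 - ex$p_perm) / 10000) + 2e-4
        expect_lt(abs(mc$p_perm - ex$p_perm), env)
    }
})

test_that("random-label modules are calibrated at the nominal 5% level", {
    set.seed(29)
    hits <- vapply(1:1000, function(i) {
        gs <- setNames(runif(50), paste0("g", 1:50))
        lab <- setNames(c(rep(1L, 8), rep(0L, 42)), names(gs))
        permutationModuleEnrichment(gs, lab, nPerm = 400,
                                    exhaustiveLimit = 0)$p_perm < 0.05
    }, logical(1))
    ci <- 1.96 * sqrt(0.05 * 0.95 / 1000)
    expect_gte(mean(hits), 0.05 - ci - 0.003)   # (b+1)/(m+1) is conservative
    expect_lte(mean(hits), 0.05 + ci)
})

test_that("Z is invariant to affine transforms of the transformed statistics", {
    gs <- setNames(c(0.001, 0.01, 0.2, 0.4, 0.6, 0.8, 0.9, 0.95),
                   paste0("g", 1:8))
    lab <- setNames(c(1L, 1L, 1L, 0L, 0L, 0L, 0L, 0L), names(gs))
    a <- permutationModuleEnrichment(gs, lab, nPerm = 200, seed = 3)
    # p -> p^2 / 10 maps -log10 p to 2 t + 1: affine
    b <- permutationModuleEnrichment(gs^2 / 10, lab, nPerm = 200, seed = 3)
    expect_equal(a$Z, b$Z, tolerance = 1e-10)
})

test_that("Fisher set enrichment matches the hypergeometric closed form", {
    bg <- paste0("g", 1:100)
    lab <- setNames(c(rep(1L, 10), rep(0L, 90)), bg)
    # overlap 3 between a module of 10 and a set of 10 in background 100
    set1 <- c(paste0("g", 1:3), paste0("g", 51:57))
    res <- fisherSetEnrichment(lab, list(s1 = set1))
    expect_equal(res$overlap, 3L)
    expect_equal(res$p, oracleHyperTail(3, 10, 10, 100), tolerance = 1e-12)
    expect_equal(res$p,
                 fisher.test(matrix(c(3, 7, 7, 83), 2),
                             alternative = "greater")$p.value,
                 tolerance = 1e-9)
    expect_equal(res$odds_ratio, (3 * 83) / (7 * 7), tolerance = 1e-12)
    # disjoint set: upper tail at 0 overlap is 1
    res0 <- fisherSetEnrichment(lab, list(s0 = paste0("g", 60:69)))
    expect_equal(res0$p, 1)
    # module = set = background is degenerate with p = 1
    labAll <- setNames(rep(1L, 10), paste0("h", 1:10))
    resAll <- fisherSetEnrichment(labAll, list(sAll = paste0("h", 1:10)))
    expect_equal(resAll$p, 1)
    expect_equal(resAll$overlap, 10L)
})

test_that("Fisher p is nonincreasing in overlap at fixed margins", {
    ps <- vapply(0:10, function(a) oracleHyperTail(max(a, 0), 10, 10, 100),
                 numeric(1))
    bg <- paste0("g", 1:100)
    got <- vapply(0:10, function(a) {
        lab <- setNames(c(rep(1L, 10), rep(0L, 90)), bg)
        set <- c(paste0("g", seq_len(a)), paste0("g", 50 + seq_len(10 - a)))
        fisherSetEnrichment(lab, list(s = set))$p
    }, numeric(1))
    expect_true(all(diff(got) <= 1e-12))
    expect_equal(got, ps, tolerance = 1e-12)
})

test_that("GMT round-trip preserves the gene sets", {
    sets <- list(alpha = c("g1", "g2", "g3"), beta = c("g4", "g5"))
    path <- tempfile(fileext = ".gmt")
    writeGmt(sets, path)
    expect_equal(readGmt(path), sets)
    # BH runs across the full module x set grid
    lab <- setNames(c(rep(1L, 3), rep(2L, 3), rep(0L, 4)), paste0("g", 1:10))
    res <- fisherSetEnrichment(lab, sets)
    expect_equal(nrow(res), 4L)
    expect_equal(res$p_BH, p.adjust(res$p, "BH"))
})
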