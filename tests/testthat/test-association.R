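test_that("eigenprotein-trait correlation handles identity, nulls, and the t oracle", {
    set.seed(20)
    me <- matrix(rnorm(240), 2, 120,
                 dimnames = list(c("ME1", "ME2"), paste0("S", 1:120)))
    man <- data.frame(t1 = me[1, ], t2 = rnorm(120),
                      row.names = colnames(me))
    res <- meTraitAssociation(me, man, c("t1", "t2"))
    r1 <- res[res$module == "ME1" & res$trait == "t1", ]
    expect_equal(r1$r, 1, tolerance = 1e-12)
    expect_lte(r1$p, 1e-300)
    # p equals the closed-form t tail for (r, n)
    r2 <- res[res$module == "ME2" & res$trait == "t2", ]
    tstat <- abs(r2$r) * sqrt((r2$n_used - 2) / (1 - r2$r^2))
    expect_equal(r2$p, 2 * pt(tstat, r2$n_used - 2, lower.tail = FALSE),
                 tolerance = 1e-12)
    expect_error(meTraitAssociation(me, transform(man, t3 = 1), "t3"),
                 "constant")
})

test_that("null eigenprotein-trait correlations are calibrated at 5%", {
    set.seed(21)
    me <- rbind(rnorm(120))
    rownames(me) <- "ME1"; colnames(me) <- paste0("S", 1:120)
    traits <- matrix(rnorm(120 * 1000), 1000)
    r <- bicorMatrix(traits, me)
    p <- corPvalue(r, attr(r, "nObs"))
    frac <- mean(p < 0.05)
    ci <- 1.96 * sqrt(0.05 * 0.95 / 1000)
    expect_gte(frac, 0.05 - ci)
    expect_lte(frac, 0.05 + ci)
})

mkGrouped <- function(m, group) {
    dimnames(m) <- list(paste0("P", seq_len(nrow(m))),
                        paste0("S", seq_len(ncol(m))))
    ProteoSet(m, data.frame(group = group, row.names = colnames(m)),
              scaleTag = "log2")
}

test_that("Welch differential abundance: identity, planted effect, and skip flag", {
    m0 <- matrix(rep(rnorm(10), 2), 1, 20)
    res0 <- differentialAbundance(mkGrouped(m0, rep(c("a", "b"), each = 10)),
                                  "group")
    expect_equal(res0$log2FC, 0, tolerance = 1e-12)
    set.seed(22)
    m <- matrix(rnorm(5 * 60, sd = 0.3), 5, 60)
    m[, 31:60] <- m[, 31:60] + 1                  # planted 1 log2 unit
    res <- differentialAbundance(mkGrouped(m, rep(c("ctl", "AD"), each = 30)),
                                 "group", groups = c("ctl", "AD"))
    expect_true(all(res$log2FC > 0.8 & res$log2FC < 1.2))
    expect_true(all(res$p < 1e-6))
    # a group with < 2 non-missing values is flagged
    m2 <- m
    m2[1, 1:29] <- NA
    res2 <- differentialAbundance(mkGrouped(m2, rep(c("ctl", "AD"), each = 30)),
                                  "group", groups = c("ctl", "AD"))
    expect_true(res2$flagged[1])
    expect_false(any(res2$flagged[-1]))
})

test_that("Tukey HSD matches a studentized-range oracle, with Bonferroni fallback", {
    set.seed(23)
    g <- rep(c("a", "b", "c"), each = 8)
    y <- rnorm(24) + rep(c(0, 0.5, 1.2), each = 8)
    res <- differentialAbundance(mkGrouped(rbind(y), g), "group",
                                 mode = "anova_tukey")
    mse <- sum(residuals(aov(y ~ factor(g)))^2) / 21
    for (i in seq_len(nrow(res))) {
        pair <- strsplit(res$comparison[i], "-")[[1]]
        d <- mean(y[g == pair[1]]) - mean(y[g == pair[2]])
        q <- abs(d) / sqrt(mse / 8)               # balanced: se = sqrt(MSE/n)
        expect_equal(res$p[i], ptukey(q, 3, 21, lower.tail = FALSE),
                     tolerance = 1e-8)
    }
    # extreme separation triggers the Bonferroni fallback
    y2 <- c(rnorm(8, 0, 0.05), rnorm(8, 30, 0.05), rnorm(8, 60, 0.05))
    res2 <- differentialAbundance(mkGrouped(rbind(y2), g), "group",
                                  mode = "anova_tukey")
    mse2 <- sum(residuals(aov(y2 ~ factor(g)))^2) / 21
    i <- which(res2$comparison == "b-a")
    tstat <- (mean(y2[g == "b"]) - mean(y2[g == "a"])) / sqrt(mse2 * 2 / 8)
    expect_equal(res2$p[i],
                 min(1, 3 * 2 * pt(abs(tstat), 21, lower.tail = FALSE)),
                 tolerance = 1e-8)
})

test_that("proteome-wide scans estimate planted ordinal effects without bias", {
    set.seed(24)
    betas <- vapply(1:50, function(i) {
        n <- 500
        x <- rnorm(n)
        eta <- 0.8 * x
        u <- runif(n)
        cp <- plogis(outer(c(-1.2, 0, 1.2), eta, "-"))
        y <- colSums(cp < rep(u, each = 3))
        man <- data.frame(y = y, row.names = paste0("S", 1:n))
        ps <- ProteoSet(matrix(x, 1, dimnames = list("P1", rownames(man))),
                        man, scaleTag = "log2")
        suppressMessages(proteomewideScan(ps, "y", model = "ordinal"))$beta
    }, numeric(1))
    expect_gte(median(betas), 0.6)
    expect_lte(median(betas), 1.0)
})

test_that("scan bookkeeping: Bonferroni cutoff, flags, and covariates", {
    set.seed(25)
    n <- 80
    man <- data.frame(y = rnorm(n), age = rnorm(n),
                      row.names = paste0("S", 1:n))
    m <- matrix(rnorm(20 * n), 20, dimnames = list(paste0("P", 1:20),
                                                   rownames(man)))
    m[1, ] <- 0                                   # constant: flagged
    ps <- ProteoSet(m, man, scaleTag = "log2")
    res <- proteomewideScan(ps, "y", model = "linear", covariates = "age",
                            standardize = TRUE)
    expect_true(res$flagged[1])
    expect_equal(attr(res, "m_tested"), 19L)
    expect_equal(attr(res, "bonferroni_cutoff"), 0.05 / 19)
    expect_true(all(res$p_adj >= res$p, na.rm = TRUE))
})

test_that("per-protein trait bicor reports identity and matches the oracle", {
    set.seed(26)
    n <- 60
    m <- matrix(rnorm(5 * n), 5, dimnames = list(paste0("P", 1:5),
                                                 paste0("S", 1:n)))
    man <- data.frame(tr = m[3, ], row.names = colnames(m))
    ps <- ProteoSet(m, man, scaleTag = "log2")
    res <- proteinTraitBicor(ps, "tr")
    expect_equal(res$r[3], 1, tolerance = 1e-12)
    expect_equal(res$r[1], oracleBicor(m[1, ], man$tr), tolerance = 1e-12)
    tstat <- abs(res$r[1]) * sqrt((n - 2) / (1 - res$r[1]^2))
    expect_equal(res$p[1], 2 * pt(tstat, n - 2, lower.tail = FALSE),
                 tolerance = 1e-12)
    expect_true(attr(res, "n_positive") >= 1)
})

test_that("p-value adjustment matches the brute-force step-up and containment", {
    expect_equal(adjustPvalues(0.03, "BH"), 0.03)
    expect_equal(adjustPvalues(0.03, "bonferroni"), 0.03)
    expect_equal(adjustPvalues(c(0.01, 0.02, 0.03, 0.04), "BH"),
                 rep(0.04, 4))
    set.seed(27)
    for (i in 1:20) {
        p <- runif(sample(3:30, 1))
        expect_equal(adjustPvalues(p, "BH"), oracleBH(p), tolerance = 1e-12)
        expect_equal(adjustPvalues(p, "bonferroni"),
                     pmin(1, p * length(p)), tolerance = 1e-12)
        # Bonferroni-significant set is contained in the BH-significant set
        expect_true(all(which(adjustPvalues(p, "bonferroni") < 0.05) %in%
                        which(adjustPvalues(p, "BH") < 0.05)))
    }
    expect_error(adjustPvalues(c(0.5, 1.2)), "\\[0, 1\\]")
})
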