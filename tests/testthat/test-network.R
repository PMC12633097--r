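test_that("bicor matches its published definition on random instances", {
    set.seed(10)
    for (i in 1:20) {
        m <- matrix(rnorm(40, sd = runif(1, 0.5, 3)), 2, 20)
        got <- bicorMatrix(m)[1, 2]
        expect_equal(got, oracleBicor(m[1, ], m[2, ]), tolerance = 1e-12)
    }
})

test_that("bicor is reflexive, affine-equivariant, and falls back on zero MAD", {
    set.seed(11)
    x <- rnorm(30)
    expect_equal(bicorMatrix(rbind(x, x))[1, 2], 1, tolerance = 1e-12)
    expect_equal(bicorMatrix(rbind(x, 2 + 3 * x))[1, 2], 1, tolerance = 1e-12)
    expect_equal(bicorMatrix(rbind(x, 2 - 3 * x))[1, 2], -1, tolerance = 1e-12)
    # zero-MAD vector: the pair falls back to Pearson and is flagged
    z <- c(rep(0, 28), 5, -5)       # MAD 0, sd > 0
    r <- bicorMatrix(rbind(z, x))
    expect_true(attr(r, "fallback")[1, 2])
    expect_equal(r[1, 2], cor(z, x), tolerance = 1e-12)
    # < 4 pairwise-complete observations: undefined and flagged
    y <- c(x[1:3], rep(NA, 27))
    r2 <- bicorMatrix(rbind(x, y))
    expect_true(is.na(r2[1, 2]))
    expect_true(attr(r2, "insufficient")[1, 2])
    expect_error(bicorMatrix(rbind(x[1:3], x[1:3])), "at least 4")
})

test_that("bicor pairwise-complete handling matches its documented policy", {
    set.seed(12)
    m <- matrix(rnorm(80), 4, 20)
    m[sample(length(m), 15)] <- NA
    r <- bicorMatrix(m)
    slow <- function(x, y) {
        bw <- function(v) {
            med <- median(v, na.rm = TRUE)
            mad0 <- median(abs(v - med), na.rm = TRUE)
            u <- (v - med) / (9 * mad0)
            w <- (1 - u^2)^2 * (abs(u) < 1)
            w * (v - med)
        }
        a <- bw(x); b <- bw(y)
        ok <- !is.na(a) & !is.na(b)
        sum(a[ok] * b[ok]) / sqrt(sum(a[ok]^2) * sum(b[ok]^2))
    }
    for (i in 1:3) for (j in (i + 1):4)
        expect_equal(r[i, j], slow(m[i, ], m[j, ]), tolerance = 1e-12)
})

test_that("signed adjacency follows the soft-threshold formula", {
    C <- matrix(c(1, 1, -1, 0, 1, 1, NA, 0.5,
                  -1, NA, 1, 0, 0, 0.5, 0, 1), 4, 4)
    A <- signedAdjacency(C, power = 8)
    expect_equal(A[1, 2], 1)
    expect_equal(A[1, 3], 0)
    expect_equal(A[1, 4], 0.5^8)
    expect_equal(A[2, 3], 0)                  # undefined -> 0
    expect_true(attr(A, "undefined")[2, 3])
    expect_equal(diag(A), rep(1, 4))
})

test_that("topological overlap matches a double-loop oracle and its edge cases", {
    n <- 5
    A0 <- diag(n)
    expect_equal(unname(tomSimilarity(A0)), diag(n))   # zero numerator
    A1 <- matrix(1, n, n)
    expect_equal(unname(tomSimilarity(A1)), matrix(1, n, n))
    set.seed(13)
    for (i in 1:20) {
        A <- matrix(runif(36), 6, 6)
        A <- (A + t(A)) / 2
        diag(A) <- 1
        for (d in c("mean", "min"))
            expect_equal(unname(tomSimilarity(A, d)), oracleTom(A, d),
                         tolerance = 1e-12)
    }
})

test_that("increasing the soft power decreases adjacency below perfect correlation", {
    set.seed(14)
    C <- bicorMatrix(matrix(rnorm(100), 5, 20))
    A6 <- signedAdjacency(C, 6)
    A12 <- signedAdjacency(C, 12)
    off <- upper.tri(C) & C < 1
    expect_true(all(A12[off] <= A6[off]))
})

test_that("perfectly correlated proteins form a single module", {
    set.seed(15)
    v <- rnorm(30)
    m <- outer(runif(12, 0.5, 2), v) + rnorm(12)   # affine copies of v
    rownames(m) <- paste0("P", 1:12)
    colnames(m) <- paste0("S", 1:30)
    tom <- tomSimilarity(signedAdjacency(bicorMatrix(m), 8))
    det <- detectModules(tom, networkParams())
    expect_equal(unname(det$labels), rep(1L, 12))
    expect_error(detectModules(tom[1:4, 1:4], networkParams()),
                 "minModuleSize")
})

test_that("two planted orthogonal blocks are recovered exactly", {
    set.seed(16)
    f1 <- rnorm(60); f2 <- rnorm(60)
    m <- rbind(outer(rep(1, 50), f1), outer(rep(1, 50), f2)) +
        matrix(rnorm(100 * 60, sd = 0.3), 100)
    rownames(m) <- paste0("P", 1:100)
    colnames(m) <- paste0("S", 1:60)
    net <- buildNetwork(m)
    lab <- moduleLabels(net)
    expect_equal(max(lab), 2L)
    expect_equal(length(unique(lab[1:50])), 1L)
    expect_equal(length(unique(lab[51:100])), 1L)
    expect_false(lab[1] == lab[51])
})

test_that("module eigenproteins match an independent eigendecomposition", {
    set.seed(17)
    # identical copies of one profile: ME is the standardized profile, ve = 1
    v <- rnorm(25)
    m <- matrix(rep(v, each = 5), 5, byrow = FALSE)
    m <- outer(1:5, rep(1, 25)) + m * outer(rep(2, 5), rep(1, 25))
    dimnames(m) <- list(paste0("P", 1:5), paste0("S", 1:25))
    eg <- moduleEigenproteins(m, setNames(rep(1L, 5), rownames(m)))
    expect_equal(unname(eg$ME[1, ]), as.numeric(scale(v)), tolerance = 1e-10)
    expect_equal(unname(eg$varExplained), 1, tolerance = 1e-12)
    # 4-protein toy vs direct eigendecomposition of the member matrix
    m2 <- matrix(rnorm(4 * 10), 4, 10,
                 dimnames = list(paste0("P", 1:4), paste0("S", 1:10)))
    eg2 <- moduleEigenproteins(m2, setNames(rep(1L, 4), rownames(m2)))
    z <- t(scale(t(m2)))
    ev <- eigen(crossprod(z))
    ref <- as.numeric(scale(ev$vectors[, 1]))
    if (cor(ref, colMeans(z)) < 0) ref <- -ref
    expect_equal(unname(eg2$ME[1, ]), ref, tolerance = 1e-8)
    expect_equal(unname(eg2$varExplained), ev$values[1] / sum(ev$values),
                 tolerance = 1e-10)
    # sign convention holds on random modules
    for (i in 1:5) {
        m3 <- matrix(rnorm(60), 6, 10,
                     dimnames = list(paste0("P", 1:6), paste0("S", 1:10)))
        eg3 <- moduleEigenproteins(m3, setNames(rep(1L, 6), rownames(m3)))
        z3 <- t(scale(t(m3)))
        expect_gte(bicorMatrix(eg3$ME, rbind(colMeans(z3)))[1, 1], 0)
    }
    expect_error(moduleEigenproteins(m2, setNames(c(1L, 0L, 0L, 0L),
                                                  rownames(m2))),
                 "fewer than 2")
})

test_that("kME is the bicor of profiles with eigenproteins", {
    fit <- smallCorrected()$data
    lab <- smallSim()$truth$planted_labels[rownames(fit)]
    eg <- moduleEigenproteins(fit, lab)
    k <- kmeTable(fit, eg$ME)
    v <- abundance(fit)
    # a pseudo-protein equal to the eigenprotein has kME exactly 1
    aug <- rbind(v, ME_copy = eg$ME[1, ])
    k2 <- kmeTable(aug, eg$ME)
    expect_equal(unname(k2["ME_copy", 1]), 1, tolerance = 1e-12)
    # random entries match the direct bicor oracle (complete-data protein)
    g <- rownames(v)[!apply(is.na(v), 1, any)][5]
    expect_equal(unname(k[g, 2]),
                 oracleBicor(v[g, ], eg$ME[2, ]), tolerance = 1e-12)
    expect_true(!is.null(attr(k, "p")))
})

test_that("the three reassignment rules act as specified on crafted kME tables", {
    kme <- matrix(c(0.2, 0.8,     # R1: gap 0.6 > 0.10, move 1 -> 2
                    0.25, 0.25,   # R3: all below 0.30, grey out
                    0.5, 0.45,    # stable: gap 0.05 < 0.10
                    0.1, 0.6),    # R2 candidate if grey
                  4, 2, byrow = TRUE,
                  dimnames = list(paste0("P", 1:4), c("ME1", "ME2")))
    lab <- setNames(c(1L, 1L, 1L, 0L), rownames(kme))
    new <- ProteoVasc:::.applyReassignRules(kme, lab, networkParams())
    expect_identical(unname(new), c(2L, 0L, 1L, 2L))
    # a labeling already satisfying the rules is a fixed point
    expect_identical(ProteoVasc:::.applyReassignRules(kme, new,
                                                      networkParams()), new)
})

test_that("iterative reassignment converges to an auditable fixed point", {
    set.seed(18)
    f1 <- rnorm(40); f2 <- rnorm(40)
    m <- rbind(outer(rep(1, 15), f1), outer(rep(1, 15), f2),
               matrix(rnorm(5 * 40), 5)) +
        matrix(rnorm(35 * 40, sd = 0.5), 35)
    dimnames(m) <- list(paste0("P", 1:35), paste0("S", 1:40))
    # start from deliberately wrong labels: one f2 protein labeled module 1,
    # noise proteins labeled module 2
    lab <- setNames(c(rep(1L, 16), rep(2L, 14), rep(2L, 5)), rownames(m))
    re <- reassignMembers(m, lab, networkParams())
    expect_true(re$converged)
    expect_true(auditReassignmentRules(m, re$labels))
    expect_equal(unname(re$labels[16]), unname(re$labels[17]))  # moved to f2
    # noise proteins are grey unless a kME legitimately clears the 0.30 floor
    for (i in 31:35) {
        if (re$labels[i] == 0L) next
        expect_gte(re$kME[i, paste0("ME", re$labels[i])], 0.30)
    }
    expect_gte(sum(re$labels[31:35] == 0L), 3)
})

test_that("modules with near-identical eigenproteins merge by average linkage", {
    set.seed(19)
    n <- 40
    # three target profiles with pairwise correlations ~ (0.95, 0.95, 0.94)
    S <- matrix(c(1, 0.95, 0.95, 0.95, 1, 0.94, 0.95, 0.94, 1), 3, 3)
    P <- matrix(rnorm(3 * n), 3, n)
    P <- t(chol(S)) %*% t(scale(t(P), scale = FALSE))
    P <- t(scale(t(P)))
    m <- P[rep(1:3, each = 4), ] + matrix(rnorm(12 * n, sd = 1e-3), 12)
    dimnames(m) <- list(paste0("P", 1:12), paste0("S", 1:n))
    lab <- setNames(rep(1:3, each = 4), rownames(m))
    merged <- mergeCloseModules(m, lab, cutHeight = 0.07)
    expect_equal(length(unique(merged)), 1L)
    # uncorrelated eigenproteins do not merge
    m2 <- rbind(outer(rep(1, 4), rnorm(n)), outer(rep(1, 4), rnorm(n))) +
        matrix(rnorm(8 * n, sd = 0.01), 8)
    dimnames(m2) <- list(paste0("P", 1:8), paste0("S", 1:n))
    lab2 <- setNames(rep(1:2, each = 4), rownames(m2))
    expect_equal(mergeCloseModules(m2, lab2, 0.07), lab2)
})

test_that("modules are renumbered by decreasing size with deterministic ties", {
    lab <- setNames(c(rep(5L, 2), rep(9L, 4), rep(2L, 2), 0L),
                    paste0("P", 1:9))
    out <- renumberModules(lab)
    expect_equal(unname(out), c(3L, 3L, 1L, 1L, 1L, 1L, 2L, 2L, 0L))
    sizes <- table(out[out > 0])
    expect_true(all(diff(as.integer(sizes)) <= 0))
})
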