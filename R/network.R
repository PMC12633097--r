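#' Network construction parameters
#'
#' Defaults reproduce the reference parameterization of the signed weighted
#' co-expression analysis: soft-thresholding power 8, deepSplit 3, minimum
#' module size 10, module merge cut height 0.07, mean-denominator topological
#' overlap, PAM staging respecting the dendrogram, and the three iterative
#' kME reassignment rules (gap 0.10, assignment floor 0.30, at most 30
#' sweeps).
#'
#' @param power soft-thresholding exponent (>= 1).
#' @param deepSplit split sensitivity in `0..4`; mapped to the static cut
#'   quantile `0.99 - 0.02 * deepSplit` of the dendrogram merge heights.
#' @param minModuleSize smallest branch kept as a module.
#' @param mergeCutHeight eigenprotein dissimilarity below which modules merge.
#' @param tomDenom `"mean"` or `"min"` connectivity denominator for TOM.
#' @param pamStage assign leftover proteins by closest average dissimilarity.
#' @param pamRespectsDendro restrict PAM assignment to modules sharing the
#'   object's dendrogram branch.
#' @param reassignKmeGap rule R1 gap: reassign when the kME to the current
#'   module trails the best kME by more than this.
#' @param kmeAssignFloor rule R2/R3 floor: assign if any kME exceeds this,
#'   grey out if none does.
#' @param maxReassignIterations cap on reassignment sweeps.
#' @return a named `list` of parameters.
#' @export
networkParams <- function(power = 8, deepSplit = 3L, minModuleSize = 10L,
                          mergeCutHeight = 0.07,
                          tomDenom = c("mean", "min"),
                          pamStage = TRUE, pamRespectsDendro = TRUE,
                          reassignKmeGap = 0.10, kmeAssignFloor = 0.30,
                          maxReassignIterations = 30L) {
    tomDenom <- match.arg(tomDenom)
    stopifnot(power >= 1, deepSplit %in% 0:4,
              mergeCutHeight > 0, mergeCutHeight < 1,
              kmeAssignFloor > 0, kmeAssignFloor < 1)
    list(power = power, deepSplit = as.integer(deepSplit),
         minModuleSize = as.integer(minModuleSize),
         mergeCutHeight = mergeCutHeight, tomDenom = tomDenom,
         pamStage = pamStage, pamRespectsDendro = pamRespectsDendro,
         reassignKmeGap = reassignKmeGap, kmeAssignFloor = kmeAssignFloor,
         maxReassignIterations = as.integer(maxReassignIterations))
}

#' Signed adjacency from a correlation matrix
#'
#' `A_ij = ((1 + C_ij) / 2)^power`; the diagonal is set to 1. Undefined
#' correlations give zero adjacency and are flagged in the `"undefined"`
#' attribute.
#'
#' @param C correlation matrix.
#' @param power soft-thresholding exponent.
#' @return adjacency matrix in `[0, 1]`.
#' @export
signedAdjacency <- function(C, power = 8) {
    A <- ((1 + C) / 2)^power
    und <- is.na(A)
    A[und] <- 0
    diag(A) <- 1
    attr(A, "undefined") <- und
    A
}

#' Topological overlap similarity
#'
#' `TOM_ij = (sum_u A_iu A_uj + A_ij) / (f(k_i, k_j) - A_ij + 1)` for
#' `i != j`, where the numerator sum runs over `u != i, j`, connectivity
#' `k_i = sum_{u != i} A_iu`, and `f` is the mean or the min of the two
#' connectivities. `TOM_ii = 1`. Downstream clustering uses `1 - TOM`.
#'
#' @param A adjacency matrix (symmetric, unit diagonal, entries in `[0, 1]`).
#' @param denom `"mean"` or `"min"`.
#' @return TOM matrix.
#' @export
tomSimilarity <- function(A, denom = c("mean", "min")) {
    denom <- match.arg(denom)
    A <- unclass(A)
    attr(A, "undefined") <- NULL
    k <- rowSums(A) - 1                       # diag(A) == 1
    ## (A %*% A)_ij = sum_u A_iu A_uj = cross(i,j) + 2 A_ij for unit diagonal,
    ## so the numerator cross(i,j) + A_ij equals (A %*% A)_ij - A_ij
    num <- (A %*% A) - A
    f <- if (denom == "mean") outer(k, k, `+`) / 2 else outer(k, k, pmin)
    tom <- num / (f - A + 1)
    diag(tom) <- 1
    dimnames(tom) <- dimnames(A)
    tom
}

#' Detect initial modules from a TOM
#'
#' Average-linkage hierarchical clustering on `1 - TOM`, a static cut at the
#' fraction `0.99 - 0.02 * deepSplit` of the merge-height range, dissolution
#' of branches
#' smaller than `minModuleSize` into the unassigned pool, and an optional PAM
#' stage: each unassigned object joins the module with the smallest average
#' dissimilarity, provided that is smaller than its average dissimilarity to
#' the unassigned pool and (when `pamRespectsDendro`) the module shares the
#' object's dendrogram branch (the smallest enclosing cluster that contains
#' any assigned object). Labels are renumbered by decreasing module size.
#'
#' @param tom TOM matrix.
#' @param params [networkParams()].
#' @return `list(dendro = hclust, labels = named integer (0 = grey),
#'   cutHeight = static cut height used)`.
#' @export
detectModules <- function(tom, params = networkParams()) {
    n <- nrow(tom)
    if (n < params$minModuleSize) stop("fewer proteins than minModuleSize")
    dissim <- 1 - tom
    hc <- stats::hclust(stats::as.dist(dissim), method = "average")
    ## static cut at the (0.99 - 0.02 deepSplit) point of the merge-height
    ## range: robust when background merges dominate the top of the tree
    q <- 0.99 - 0.02 * params$deepSplit
    # epsilon keeps degenerate trees (all heights equal) in one cluster
    h0 <- min(hc$height) + q * diff(range(hc$height)) + 1e-12
    cl <- stats::cutree(hc, h = h0)
    sizes <- table(cl)
    labels <- ifelse(sizes[as.character(cl)] >= params$minModuleSize, cl, 0L)
    labels <- as.integer(factor(ifelse(labels == 0L, NA, labels)))
    labels[is.na(labels)] <- 0L
    names(labels) <- rownames(tom)

    if (params$pamStage && any(labels == 0L) && any(labels > 0L)) {
        unass <- which(labels == 0L)
        allMods <- sort(unique(labels[labels > 0L]))
        ## dendrogram-branch candidates: for each unassigned object, the
        ## modules present in the smallest enclosing cluster that contains
        ## any assigned object, found by walking the cut upward from h0
        cand <- rep(list(allMods), n)
        if (params$pamRespectsDendro) {
            heights <- sort(unique(hc$height))
            heights <- heights[heights > h0]
            cmat <- stats::cutree(hc, h = heights)
            if (is.null(dim(cmat))) cmat <- matrix(cmat, ncol = 1L)
            cand <- vector("list", n)
            remaining <- unass
            for (j in seq_len(ncol(cmat))) {
                if (!length(remaining)) break
                cj <- cmat[, j]
                modsBy <- lapply(split(labels, cj), function(l)
                    sort(unique(l[l > 0L])))
                found <- vapply(remaining, function(i)
                    length(modsBy[[as.character(cj[i])]]) > 0L, logical(1))
                for (i in remaining[found])
                    cand[[i]] <- modsBy[[as.character(cj[i])]]
                remaining <- remaining[!found]
            }
        }
        newLab <- labels
        for (i in unass) {
            ci <- cand[[i]]
            if (is.null(ci) || !length(ci)) next
            dMod <- vapply(ci, function(m)
                mean(dissim[i, labels == m]), numeric(1))
            pool <- setdiff(unass, i)
            dGrey <- if (length(pool)) mean(dissim[i, pool]) else Inf
            if (min(dMod) < dGrey)
                newLab[i] <- ci[which.min(dMod)]
        }
        labels <- newLab
    }
    labels <- renumberModules(labels)
    list(dendro = hc, labels = labels, cutHeight = h0)
}

#' Renumber module labels by decreasing size
#'
#' Modules are relabelled 1..K in order of nonincreasing size (ties broken by
#' the smallest original label); 0 (grey) is preserved.
#'
#' @param labels named integer vector.
#' @return relabelled vector.
#' @export
renumberModules <- function(labels) {
    ids <- sort(unique(labels[labels > 0L]))
    if (!length(ids)) return(labels)
    sizes <- vapply(ids, function(m) sum(labels == m), integer(1))
    ord <- ids[order(-sizes, ids)]
    map <- stats::setNames(seq_along(ord), ord)
    out <- labels
    out[labels > 0L] <- map[as.character(labels[labels > 0L])]
    storage.mode(out) <- "integer"
    out
}

#' Module eigenproteins
#'
#' Each module member is z-scored across samples (missing values imputed by
#' the protein mean for the decomposition only); the module eigenprotein is
#' the first right-singular vector of the member x sample matrix, scaled to
#' unit variance and sign-oriented so that its bicor with the module's mean
#' z-score profile is nonnegative. `varExplained` is the first squared
#' singular value over the total.
#'
#' @param x [ProteoSet-class] or numeric matrix (proteins x samples).
#' @param labels named integer module labels (0 = grey, skipped).
#' @return `list(ME = modules x samples matrix with rownames "ME<k>",
#'   varExplained = named numeric)`.
#' @export
moduleEigenproteins <- function(x, labels) {
    V <- if (is(x, "ProteoSet")) abundance(x) else as.matrix(x)
    ids <- sort(unique(labels[labels > 0L]))
    if (!length(ids)) stop("no modules to summarize")
    ME <- matrix(NA_real_, length(ids), ncol(V),
                 dimnames = list(paste0("ME", ids), colnames(V)))
    ve <- stats::setNames(numeric(length(ids)), paste0("ME", ids))
    for (j in seq_along(ids)) {
        memb <- names(labels)[labels == ids[j]]
        if (length(memb) < 2L)
            stop("module ", ids[j], " has fewer than 2 members")
        Xm <- V[memb, , drop = FALSE]
        mu <- rowMeans(Xm, na.rm = TRUE)
        nas <- which(is.na(Xm), arr.ind = TRUE)
        if (nrow(nas)) Xm[nas] <- mu[nas[, 1L]]
        z <- t(scale(t(Xm)))
        z <- z[apply(is.finite(z), 1L, all), , drop = FALSE]  # drop constants
        sv <- svd(z, nu = 0L, nv = 1L)
        me <- as.numeric(scale(sv$v[, 1L]))
        prof <- colMeans(z)
        s <- bicorMatrix(rbind(me), rbind(prof))[1L, 1L]
        if (is.na(s)) s <- sum(me * prof)
        if (s < 0) me <- -me
        ME[j, ] <- me
        ve[j] <- sv$d[1L]^2 / sum(sv$d^2)
    }
    list(ME = ME, varExplained = ve)
}

#' kME table: protein-to-eigenprotein bicor
#'
#' @param x [ProteoSet-class] or matrix (proteins x samples).
#' @param ME eigenprotein matrix (modules x samples).
#' @return protein x module bicor matrix with the Student-t p-values in
#'   attribute `"p"`.
#' @export
kmeTable <- function(x, ME) {
    V <- if (is(x, "ProteoSet")) abundance(x) else as.matrix(x)
    k <- bicorMatrix(V, ME)
    p <- corPvalue(k, attr(k, "nObs"))
    attr(k, "p") <- p
    k
}

#' Iterative kME-based module membership reassignment
#'
#' Sweeps the three reassignment rules until a fixed point (or the iteration
#' cap): with `m* = argmax_m kME_gm`,
#' * R3: if `max kME < kmeAssignFloor`, the protein goes grey;
#' * R2: else, a grey protein is assigned to `m*`;
#' * R1: else, an assigned protein whose kME to its current module trails
#'   `max kME` by more than `reassignKmeGap` moves to `m*`.
#'
#' Eigenproteins and kMEs are recomputed after every sweep. Final labels are
#' renumbered by decreasing size.
#'
#' @param x [ProteoSet-class] or matrix.
#' @param labels named integer module labels.
#' @param params [networkParams()].
#' @return `list(labels, iterations, converged, ME, varExplained, kME)`.
#' @export
reassignMembers <- function(x, labels, params = networkParams()) {
    iter <- 0L
    converged <- FALSE
    while (iter < params$maxReassignIterations) {
        iter <- iter + 1L
        eg <- moduleEigenproteins(x, labels)
        kme <- kmeTable(x, eg$ME)
        new <- .applyReassignRules(kme, labels, params)
        if (!any(new != labels)) { converged <- TRUE; break }
        labels <- new
        if (!any(labels > 0L)) break
    }
    labels <- renumberModules(labels)
    if (!any(labels > 0L))
        return(list(labels = labels, iterations = iter, converged = converged,
                    ME = matrix(numeric(0), 0, 0), varExplained = numeric(0),
                    kME = matrix(numeric(0), 0, 0)))
    eg <- moduleEigenproteins(x, labels)
    kme <- kmeTable(x, eg$ME)
    list(labels = labels, iterations = iter, converged = converged,
         ME = eg$ME, varExplained = eg$varExplained, kME = kme)
}

## one sweep of rules R1-R3 given a kME table whose columns are "ME<id>"
.applyReassignRules <- function(kme, labels, params) {
    modIds <- as.integer(sub("^ME", "", colnames(kme)))
    km <- kme
    km[is.na(km)] <- -Inf
    best <- max.col(km, ties.method = "first")
    kmax <- km[cbind(seq_len(nrow(km)), best)]
    new <- labels
    for (i in seq_along(labels)) {
        if (kmax[i] < params$kmeAssignFloor) { new[i] <- 0L; next }   # R3
        if (labels[i] == 0L) { new[i] <- modIds[best[i]]; next }      # R2
        cur <- match(paste0("ME", labels[i]), colnames(km))
        kcur <- if (is.na(cur)) -Inf else km[i, cur]
        if (kcur < kmax[i] - params$reassignKmeGap)                    # R1
            new[i] <- modIds[best[i]]
    }
    new
}

#' Audit the three reassignment rules
#'
#' Verifies that `labels` are a fixed point of the reassignment rules with
#' respect to the kME table computed from those labels.
#'
#' @inheritParams reassignMembers
#' @return `TRUE` if no rule would change any label, else `FALSE` with the
#'   offending proteins in attribute `"violations"`.
#' @export
auditReassignmentRules <- function(x, labels, params = networkParams()) {
    eg <- moduleEigenproteins(x, labels)
    kme <- kmeTable(x, eg$ME)
    new <- .applyReassignRules(kme, labels, params)
    ok <- !any(new != labels)
    if (!ok) attr(ok, "violations") <- names(labels)[new != labels]
    ok
}

#' Merge modules with close eigenproteins
#'
#' Average-linkage clustering of modules on `1 - cor(ME_i, ME_j)`; clusters
#' formed below `cutHeight` are merged (taking the smallest module id),
#' eigenproteins are recomputed, and the procedure repeats until no merge
#' occurs.
#'
#' @param x [ProteoSet-class] or matrix.
#' @param labels named integer module labels.
#' @param cutHeight eigenprotein dissimilarity threshold.
#' @return relabelled named integer vector (not renumbered).
#' @export
mergeCloseModules <- function(x, labels, cutHeight = 0.07) {
    repeat {
        ids <- sort(unique(labels[labels > 0L]))
        if (length(ids) < 2L) return(labels)
        ME <- moduleEigenproteins(x, labels)$ME
        dis <- 1 - stats::cor(t(ME))
        hc <- stats::hclust(stats::as.dist(dis), method = "average")
        cl <- stats::cutree(hc, h = cutHeight)
        if (max(cl) == length(ids)) return(labels)
        for (grp in unique(cl)) {
            members <- ids[cl == grp]
            if (length(members) > 1L)
                labels[labels %in% members] <- min(members)
        }
    }
}

#' Build the full signed co-expression network
#'
#' Runs bicor -> signed adjacency -> TOM -> average-linkage clustering with
#' the static quantile cut and PAM stage -> eigenprotein merge (cut height
#' `mergeCutHeight`) -> iterative three-rule kME reassignment, and returns a
#' [NetworkModel-class].
#'
#' @param x a [ProteoSet-class] (log2 or later) or numeric matrix.
#' @param params [networkParams()].
#' @param keepTom retain the TOM matrix in the model object.
#' @return a [NetworkModel-class].
#' @export
buildNetwork <- function(x, params = networkParams(), keepTom = FALSE) {
    V <- if (is(x, "ProteoSet")) abundance(x) else as.matrix(x)
    C <- bicorMatrix(V)
    A <- signedAdjacency(C, params$power)
    tom <- tomSimilarity(A, params$tomDenom)
    det <- detectModules(tom, params)
    labels <- mergeCloseModules(V, det$labels, params$mergeCutHeight)
    labels <- renumberModules(labels)
    re <- reassignMembers(V, labels, params)
    new("NetworkModel",
        correlation = .stripAttrs(C),
        tom = if (keepTom) tom else matrix(numeric(0), 0, 0),
        dendro = det$dendro,
        labels = re$labels,
        ME = re$ME,
        varExplained = re$varExplained,
        kME = .stripAttrs(re$kME),
        params = params,
        info = list(cut_height = det$cutHeight,
                    reassign_iterations = re$iterations,
                    reassign_converged = re$converged))
}

.stripAttrs <- function(m) {
    attributes(m) <- attributes(m)[c("dim", "dimnames")]
    m
}
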