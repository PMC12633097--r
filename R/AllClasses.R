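#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<- colData
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

.SCALE_TAGS <- c("raw", "sum_scaled", "log2", "tampor_corrected", "regressed")

#' ProteoSet: a protein abundance matrix with sample metadata
#'
#' `ProteoSet` extends [SummarizedExperiment::SummarizedExperiment] with a
#' single `"abundance"` assay (proteins in rows, samples in columns, `NA` =
#' missing) and a `scaleTag` slot recording where the matrix sits in the
#' processing state machine `raw -> sum_scaled -> log2 -> tampor_corrected ->
#' regressed`. The sample manifest (batch, GIS flag, diagnosis group, traits,
#' covariates) lives in `colData`.
#'
#' Raw abundances are nonnegative (a zero intensity means "missing" and is
#' converted to `NA` by [sumScale()]); sum-scaled abundances are strictly
#' positive where present.
#'
#' @slot scaleTag character(1), one of `"raw"`, `"sum_scaled"`, `"log2"`,
#'   `"tampor_corrected"`, `"regressed"`.
#' @export
setClass("ProteoSet",
    contains = "SummarizedExperiment",
    slots = c(scaleTag = "character"))

setValidity("ProteoSet", function(object) {
    msg <- character()
    if (length(object@scaleTag) != 1L || !object@scaleTag %in% .SCALE_TAGS)
        msg <- c(msg, sprintf("scaleTag must be one of: %s",
                              paste(.SCALE_TAGS, collapse = ", ")))
    if (!"abundance" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'abundance' is required")
    else {
        v <- SummarizedExperiment::assay(object, "abundance")
        if (!is.numeric(v))
            msg <- c(msg, "abundance values must be numeric")
        if (object@scaleTag == "raw" && any(v < 0, na.rm = TRUE))
            msg <- c(msg, "raw abundances must be nonnegative (0 = missing)")
        if (object@scaleTag == "sum_scaled" && any(v <= 0, na.rm = TRUE))
            msg <- c(msg, "sum_scaled abundances must be strictly positive where present")
    }
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "protein identifiers must be unique")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "sample identifiers must be unique")
    if (length(msg)) msg else TRUE
})

#' Construct a ProteoSet
#'
#' @param values numeric matrix, proteins x samples; `NA` encodes a missing
#'   measurement. Row and column names are required and must be unique.
#' @param manifest `data.frame` or `DataFrame` of per-sample metadata, one row
#'   per column of `values` (matched by row name or by order).
#' @param scaleTag processing state of `values` (default `"raw"`).
#' @return A [ProteoSet-class] object.
#' @examples
#' m <- matrix(2^rnorm(12, 16), 4, 3,
#'             dimnames = list(paste0("P", 1:4), paste0("S", 1:3)))
#' ps <- ProteoSet(m, data.frame(batch = c(1, 1, 2),
#'                               row.names = colnames(m)))
#' scaleTag(ps)
#' @export
ProteoSet <- function(values, manifest = NULL, scaleTag = "raw") {
    values <- as.matrix(values)
    if (is.null(rownames(values)) || is.null(colnames(values)))
        stop("'values' must have protein row names and sample column names")
    if (is.null(manifest))
        manifest <- S4Vectors::DataFrame(row.names = colnames(values))
    manifest <- S4Vectors::DataFrame(manifest)
    if (is.null(rownames(manifest)) && nrow(manifest) == ncol(values))
        rownames(manifest) <- colnames(values)
    if (!identical(sort(rownames(manifest)), sort(colnames(values))))
        stop("manifest rows must match the sample columns of 'values'")
    manifest <- manifest[colnames(values), , drop = FALSE]
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(abundance = values), colData = manifest)
    new("ProteoSet", se, scaleTag = scaleTag)
}

#' @describeIn ProteoSet-class abundance matrix (proteins x samples)
#' @param x,object a `ProteoSet`
#' @export
setGeneric("abundance", function(x) standardGeneric("abundance"))

#' @rdname ProteoSet-class
#' @export
setMethod("abundance", "ProteoSet", function(x)
    SummarizedExperiment::assay(x, "abundance"))

#' @describeIn ProteoSet-class processing-state tag
#' @export
setGeneric("scaleTag", function(x) standardGeneric("scaleTag"))

#' @rdname ProteoSet-class
#' @export
setMethod("scaleTag", "ProteoSet", function(x) x@scaleTag)

#' @describeIn ProteoSet-class sample manifest as a plain `data.frame`
#' @export
setGeneric("sampleInfo", function(x) standardGeneric("sampleInfo"))

#' @rdname ProteoSet-class
#' @export
setMethod("sampleInfo", "ProteoSet", function(x)
    as.data.frame(SummarizedExperiment::colData(x)))

#' @describeIn ProteoSet-class protein identifiers
#' @export
setGeneric("proteinIds", function(x) standardGeneric("proteinIds"))

#' @rdname ProteoSet-class
#' @export
setMethod("proteinIds", "ProteoSet", function(x) rownames(x))

#' @describeIn ProteoSet-class sample identifiers
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname ProteoSet-class
#' @export
setMethod("sampleIds", "ProteoSet", function(x) colnames(x))

setMethod("show", "ProteoSet", function(object) {
    v <- abundance(object)
    cat(sprintf("ProteoSet: %d proteins x %d samples [%s]\n",
                nrow(v), ncol(v), object@scaleTag))
    cat(sprintf("  missing: %.2f%%\n", 100 * mean(is.na(v))))
    if ("is_gis" %in% colnames(SummarizedExperiment::colData(object)))
        cat(sprintf("  GIS channels: %d\n",
                    sum(SummarizedExperiment::colData(object)$is_gis)))
    invisible(NULL)
})

## internal: replace abundance values + advance the scale tag, preserving
## colData/metadata; enforces the legal state transitions
.advance <- function(x, values, newTag) {
    fromOk <- switch(newTag,
        sum_scaled       = "raw",
        log2             = "sum_scaled",
        tampor_corrected = "log2",
        regressed        = c("tampor_corrected", "log2"),
        stop("unknown scale tag: ", newTag))
    if (!x@scaleTag %in% fromOk)
        stop(sprintf("cannot move from scale '%s' to '%s'", x@scaleTag, newTag))
    out <- x
    SummarizedExperiment::assay(out, "abundance") <- values
    out@scaleTag <- newTag
    validObject(out)
    out
}

#' Network model for a signed weighted co-expression network
#'
#' Holds the fitted network: the biweight midcorrelation matrix, the
#' module labels (`0` = unassigned/grey; modules numbered 1..K by decreasing
#' size), module eigenproteins (first principal component of each module's
#' standardized member profiles, unit variance, sign-oriented), per-module
#' variance explained, the protein x module kME table, and the clustering
#' dendrogram.
#'
#' @slot correlation bicor matrix used to build the network.
#' @slot tom topological overlap matrix (possibly empty if not retained).
#' @slot dendro the average-linkage `hclust` tree on 1 - TOM.
#' @slot labels named integer vector, protein -> module id (0 = grey).
#' @slot ME module eigenprotein matrix (modules x samples).
#' @slot varExplained numeric, per-module fraction of variance explained.
#' @slot kME protein x module bicor table.
#' @slot params `list` of network parameters (see [networkParams()]).
#' @slot info `list` of fitting diagnostics (reassignment iterations, flags).
#' @export
setClass("NetworkModel",
    slots = c(correlation = "matrix", tom = "matrix", dendro = "ANY",
              labels = "integer", ME = "matrix", varExplained = "numeric",
              kME = "matrix", params = "list", info = "list"))

setValidity("NetworkModel", function(object) {
    msg <- character()
    k <- sort(unique(object@labels[object@labels > 0L]))
    if (length(k) && !identical(k, seq_along(k)))
        msg <- c(msg, "module ids must be 1..K")
    if (length(k)) {
        sizes <- tabulate(object@labels[object@labels > 0L], length(k))
        if (is.unsorted(rev(sizes)))
            msg <- c(msg, "modules must be numbered by nonincreasing size")
    }
    if (length(msg)) msg else TRUE
})

#' @describeIn NetworkModel-class module labels (named integer, 0 = grey)
#' @param x,object a `NetworkModel`
#' @export
setGeneric("moduleLabels", function(x) standardGeneric("moduleLabels"))

#' @rdname NetworkModel-class
#' @export
setMethod("moduleLabels", "NetworkModel", function(x) x@labels)

#' @describeIn NetworkModel-class eigenprotein matrix (modules x samples)
#' @export
setGeneric("eigenproteins", function(x) standardGeneric("eigenproteins"))

#' @rdname NetworkModel-class
#' @export
setMethod("eigenproteins", "NetworkModel", function(x) x@ME)

#' @describeIn NetworkModel-class protein x module kME (bicor) table
#' @export
setGeneric("kME", function(x) standardGeneric("kME"))

#' @rdname NetworkModel-class
#' @export
setMethod("kME", "NetworkModel", function(x) x@kME)

setMethod("show", "NetworkModel", function(object) {
    k <- max(0L, object@labels)
    sizes <- if (k > 0) tabulate(object@labels[object@labels > 0L], k) else integer()
    cat(sprintf("NetworkModel: %d proteins, %d modules (grey: %d)\n",
                length(object@labels), k, sum(object@labels == 0L)))
    if (k > 0)
        cat("  module sizes: ", paste(sizes, collapse = ", "), "\n", sep = "")
    if (!is.null(object@info$reassign_iterations))
        cat(sprintf("  kME reassignment: %d iteration(s), converged = %s\n",
                    object@info$reassign_iterations,
                    object@info$reassign_converged))
    invisible(NULL)
})
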