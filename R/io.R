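#' Write an abundance matrix as TSV
#'
#' First column `protein`, header row of sample ids, empty cells for missing
#' values.
#'
#' @param x [ProteoSet-class] or matrix.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeAbundanceTsv <- function(x, path) {
    V <- if (is(x, "ProteoSet")) abundance(x) else as.matrix(x)
    df <- data.frame(protein = rownames(V), V, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
    invisible(path)
}

#' Read an abundance TSV
#'
#' @param path TSV written by [writeAbundanceTsv()] (first column protein id,
#'   empty cell = missing).
#' @return numeric matrix, proteins x samples.
#' @export
readAbundanceTsv <- function(path) {
    df <- utils::read.delim(path, check.names = FALSE,
                            na.strings = c("", "NA"))
    m <- as.matrix(df[, -1L, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- df[[1L]]
    m
}

#' Write a sample manifest as TSV
#' @param manifest `data.frame` with sample ids as row names.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeManifestTsv <- function(manifest, path) {
    df <- data.frame(sample_id = rownames(manifest), manifest,
                     check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    invisible(path)
}

#' Read a sample manifest TSV
#' @param path TSV with a `sample_id` column.
#' @return `data.frame` with sample ids as row names.
#' @export
readManifestTsv <- function(path) {
    df <- utils::read.delim(path, check.names = FALSE)
    rownames(df) <- df$sample_id
    df$sample_id <- NULL
    df
}

#' Write module labels as a two-column TSV (protein, module; 0 = grey)
#' @param labels named integer vector.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeLabelsTsv <- function(labels, path) {
    utils::write.table(data.frame(protein = names(labels), module = labels),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
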