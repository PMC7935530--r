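# Plain-text IO: FASTA via Biostrings, tab-separated tables for counts,
# annotations, profiles, cluster membership and environment metadata.

#' Write named DNA sequences to FASTA
#' @param seqs Named character vector of DNA sequences.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#' @param path Input path.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write a count or profile matrix as TSV (feature id column + samples)
#' @param mat Matrix with feature row names and sample column names.
#' @param path Output path.
#' @param id_col Name of the feature id column.
#' @export
write_matrix_tsv <- function(mat, path, id_col = "gene_id") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_matrix_tsv()] back as a matrix
#' @param path Input path.
#' @export
read_matrix_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1L, drop = FALSE])
  rownames(mat) <- df[[1L]]
  mat
}

#' Write an annotation table (gene_id, lineage, ko) as TSV
#' @param annotations Annotation `data.frame`.
#' @param path Output path.
#' @export
write_annotation_tsv <- function(annotations, path) {
  write.table(annotations[, c("gene_id", "lineage", "ko")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an annotation TSV
#' @param path Input path.
#' @export
read_annotation_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE,
             colClasses = c("character", "character", "character"))
}

#' Write cluster membership of a gene catalog as TSV
#'
#' One row per member: `representative_id`, `member_id`.
#'
#' @param catalog A `gene_catalog`.
#' @param path Output path.
#' @export
write_cluster_tsv <- function(catalog, path) {
  df <- data.frame(
    representative_id = rep(names(catalog$clusters),
                            lengths(catalog$clusters)),
    member_id = unlist(catalog$clusters, use.names = FALSE),
    stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
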