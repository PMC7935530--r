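# Length-normalized relative-abundance profiling at gene, KO and taxon
# level, and cross-sample core-feature fractions.

.LINEAGE_RANKS <- c("domain", "phylum", "class", "order", "family", "genus")

.as_profile <- function(mat, level) {
  mat <- as.matrix(mat)
  attr(mat, "level") <- level
  mat
}

#' Level of an abundance profile
#' @param profile A profile matrix produced by [gene_abundance()],
#'   [ko_profile()] or [taxon_profile()].
#' @export
profile_level <- function(profile) attr(profile, "level")

.check_counts <- function(counts) {
  if (!is.matrix(counts) || is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must be a matrix with gene row names and sample column names")
  if (any(counts < 0))
    stop("counts must be non-negative")
  invisible(counts)
}

#' Gene-level length-normalized relative abundance
#'
#' Read counts are first divided by gene length (`a_g = c_g / L_g`), then
#' each sample is normalized by the total so that gene relative abundances
#' sum to 1 per sample. An all-zero sample yields an all-zero column with
#' a warning.
#'
#' @param counts Integer matrix of unique-mapped read counts,
#'   genes x samples.
#' @param lengths Named numeric vector of gene lengths in bp; every
#'   counted gene must have a positive length.
#' @return A numeric matrix genes x samples with profile level `"gene"`.
#' @examples
#' counts <- matrix(c(10L, 10L), 2, 1,
#'                  dimnames = list(c("g1", "g2"), "s1"))
#' gene_abundance(counts, c(g1 = 100, g2 = 200))[, 1]
#' @export
gene_abundance <- function(counts, lengths) {
  .check_counts(counts)
  missing <- setdiff(rownames(counts), names(lengths))
  if (length(missing))
    stop("no length for counted gene(s): ", paste(head(missing, 5), collapse = ", "))
  len <- lengths[rownames(counts)]
  if (any(len <= 0))
    stop("gene lengths must be positive")
  a <- counts / len
  tot <- colSums(a)
  if (any(tot == 0))
    warning("all-zero sample(s): ",
            paste(colnames(counts)[tot == 0], collapse = ", "))
  rel <- sweep(a, 2, ifelse(tot > 0, tot, 1), "/")
  .as_profile(rel, "gene")
}

#' Aggregate a gene profile to KEGG Orthology level
#'
#' KO abundance is the sum of the relative abundances of the genes
#' annotated to that KO. A gene with no KO contributes to no KO; a gene
#' carrying k KOs contributes its full abundance to each of the k (so KO
#' abundances may total more than 1 - presence per KO is what downstream
#' route analysis consumes).
#'
#' @param profile A gene-level profile from [gene_abundance()].
#' @param ko_map Named list, gene id to character vector of KO ids.
#' @return A numeric matrix KOs x samples with profile level `"ko"`.
#' @export
ko_profile <- function(profile, ko_map) {
  if (!identical(profile_level(profile), "gene"))
    stop("ko_profile expects a gene-level profile")
  ko_map <- ko_map[!vapply(ko_map, function(k) length(k) == 0L || all(is.na(k)),
                           logical(1))]
  genes <- intersect(rownames(profile), names(ko_map))
  if (!length(genes)) {
    out <- matrix(0, 0, ncol(profile),
                  dimnames = list(character(), colnames(profile)))
    return(.as_profile(out, "ko"))
  }
  reps <- lengths(ko_map[genes])
  pairs_gene <- rep(genes, reps)
  pairs_ko <- unlist(ko_map[genes], use.names = FALSE)
  out <- rowsum(profile[pairs_gene, , drop = FALSE], group = pairs_ko)
  .as_profile(out, "ko")
}

#' Aggregate a gene profile to a taxonomic rank
#'
#' Taxon abundance at the chosen rank is the sum of the abundances of the
#' genes whose lineage names that taxon; genes unclassified at the rank
#' are pooled under `"unassigned"` (reported, never dropped, so the
#' profile still sums to 1 per sample).
#'
#' @param profile A gene-level profile from [gene_abundance()].
#' @param lineage_map Named character vector, gene id to
#'   semicolon-delimited lineage (domain to genus); `NA` allowed.
#' @param rank One of `"domain"`, `"phylum"`, `"class"`, `"order"`,
#'   `"family"`, `"genus"`.
#' @param ranks The ordered rank names of the lineage strings.
#' @return A numeric matrix taxa x samples with profile level `"taxon"`.
#' @export
taxon_profile <- function(profile, lineage_map, rank = "genus",
                          ranks = .LINEAGE_RANKS) {
  if (!identical(profile_level(profile), "gene"))
    stop("taxon_profile expects a gene-level profile")
  idx <- match(rank, ranks)
  if (is.na(idx))
    stop("unknown rank '", rank, "'; expected one of ",
         paste(ranks, collapse = ", "))
  lin <- lineage_map[rownames(profile)]
  taxon <- vapply(lin, function(s) {
    if (is.na(s) || !nzchar(s)) return("unassigned")
    parts <- strsplit(s, ";", fixed = TRUE)[[1L]]
    if (length(parts) < idx || !nzchar(parts[idx]) || is.na(parts[idx]))
      "unassigned"
    else
      parts[idx]
  }, character(1), USE.NAMES = FALSE)
  out <- rowsum(profile, group = taxon)
  .as_profile(out, "taxon")
}

#' Fraction of features shared by all samples
#'
#' The core fraction is the number of features present (abundance
#' strictly greater than zero) in every sample divided by the number of
#' features present in at least one sample.
#'
#' @param profile A profile matrix (any level), features x samples, with
#'   at least two samples.
#' @return A fraction in \[0, 1\].
#' @export
core_fraction <- function(profile) {
  if (ncol(profile) < 2L)
    stop("core_fraction needs at least two samples")
  present <- profile > 0
  observed <- rowSums(present) > 0
  if (!any(observed))
    stop("no feature observed in any sample")
  sum(rowSums(present) == ncol(profile)) / sum(observed)
}

#' Parse the KO column of an annotation table into a gene-to-KO map
#' @param annotations Annotation `data.frame` with `gene_id` and `ko`
#'   (comma-delimited KO ids, `NA` where unannotated).
#' @return Named list, gene id to character vector of KO ids.
#' @export
ko_map_from_annotation <- function(annotations) {
  out <- lapply(annotations$ko, function(k) {
    if (is.na(k) || !nzchar(k)) character() else strsplit(k, ",", fixed = TRUE)[[1L]]
  })
  names(out) <- annotations$gene_id
  out
}

#' Extract the lineage column of an annotation table as a named vector
#' @param annotations Annotation `data.frame` with `gene_id` and `lineage`.
#' @return Named character vector, gene id to lineage string.
#' @export
lineage_map_from_annotation <- function(annotations) {
  setNames(as.character(annotations$lineage), annotations$gene_id)
}
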