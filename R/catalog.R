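# Nonredundant gene-catalog construction: pairwise identity/coverage,
# greedy incremental clustering, and merging of independently derived
# gene sets with overlap statistics.

#' Create a table of gene records
#'
#' A gene record holds a predicted coding sequence together with its
#' annotation metadata. Records are the common currency of the catalog,
#' profiler and synthetic-data modules.
#'
#' @param gene_id Character vector of unique gene identifiers.
#' @param sequence Character vector of DNA sequences (ACGT only).
#' @param lineage Optional character vector of semicolon-delimited taxonomy
#'   lineages (domain to genus); `NA` where unannotated.
#' @param ko Optional character vector of comma-delimited KEGG Orthology
#'   identifiers; `NA` where unannotated.
#' @param source Source tag per record, `"mapped"` or `"assembled"`.
#' @param min_len Minimum gene length in bp. Predicted genes shorter than
#'   150 bp are conventionally discarded upstream, hence the default floor.
#' @return A `data.frame` with columns `gene_id`, `sequence`, `length`,
#'   `lineage`, `ko`, `source`.
#' @examples
#' gene_records("g1", paste(rep("ACGT", 40), collapse = ""))
#' @export
gene_records <- function(gene_id, sequence, lineage = NA_character_,
                         ko = NA_character_, source = "assembled",
                         min_len = 150L) {
  if (length(gene_id) != length(sequence))
    stop("gene_id and sequence must have the same length")
  if (anyDuplicated(gene_id))
    stop("gene ids must be unique within a catalog")
  for (s in sequence) .check_dna(s)
  len <- nchar(sequence)
  if (any(len < min_len))
    stop("all gene sequences must be at least ", min_len, " bp")
  if (!all(source %in% c("mapped", "assembled")))
    stop("source must be 'mapped' or 'assembled'")
  data.frame(gene_id = as.character(gene_id), sequence = sequence,
             length = len,
             lineage = rep_len(as.character(lineage), length(gene_id)),
             ko = rep_len(as.character(ko), length(gene_id)),
             source = rep_len(source, length(gene_id)),
             stringsAsFactors = FALSE)
}

#' Global-alignment identity and coverage of two DNA sequences
#'
#' Aligns two sequences end to end (Needleman-Wunsch with affine gap
#' costs) and reports the two quantities that drive redundancy removal:
#' identity, the fraction of identical aligned positions relative to the
#' shorter sequence, and coverage, the fraction of the shorter sequence
#' falling inside the aligned (non-terminal-gap) span. Both are symmetric
#' in the arguments.
#'
#' @param a,b DNA sequences (character scalars, ACGT only).
#' @param match,mismatch Match reward and mismatch penalty (alignment
#'   scoring configuration; defaults +1/-1).
#' @param gap_open,gap_extend Affine gap costs (non-negative; a gap of
#'   length L costs `gap_open + L * gap_extend`).
#' @return A list with elements `identity` and `coverage`, both fractions.
#' @examples
#' align_identity("ACGTACGT", "ACGTACGT")
#' align_identity("AAAA", "TTTT")$identity
#' @export
align_identity <- function(a, b, match = 1, mismatch = -1,
                           gap_open = 2, gap_extend = 1) {
  .check_dna(a, "a")
  .check_dna(b, "b")
  short_len <- min(nchar(a), nchar(b))
  if (identical(a, b))
    return(list(identity = 1, coverage = 1))
  # canonical argument order guarantees symmetry of the result
  swap <- nchar(a) > nchar(b) || (nchar(a) == nchar(b) && a > b)
  s <- if (swap) b else a
  l <- if (swap) a else b
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                     mismatch = mismatch,
                                                     baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(s, l, substitutionMatrix = submat,
                                       gapOpening = gap_open,
                                       gapExtension = gap_extend,
                                       type = "global")
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
  q <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
  paired <- p != "-" & q != "-"
  if (!any(paired))
    return(list(identity = 0, coverage = 0))
  core <- range(which(paired))
  list(identity = sum(paired & p == q) / short_len,
       coverage = sum(p[seq(core[1L], core[2L])] != "-") / short_len)
}

#' Construct a gene catalog object
#'
#' @param records Gene record `data.frame` (see [gene_records()]).
#' @param clusters Named list mapping representative gene id to the
#'   character vector of member gene ids (the representative included).
#' @return An object of class `gene_catalog`.
#' @export
gene_catalog <- function(records, clusters) {
  members <- unlist(clusters, use.names = FALSE)
  if (anyDuplicated(members))
    stop("cluster memberships must be disjoint")
  if (length(members) && !setequal(members, records$gene_id))
    stop("clusters must cover exactly the catalog's gene ids")
  ok <- vapply(names(clusters), function(r) r %in% clusters[[r]], logical(1))
  if (length(clusters) && !all(ok))
    stop("each representative must be a member of its own cluster")
  structure(list(records = records, clusters = clusters),
            class = "gene_catalog")
}

#' @export
print.gene_catalog <- function(x, ...) {
  cat("gene_catalog:", nrow(x$records), "genes in",
      length(x$clusters), "clusters\n")
  invisible(x)
}

#' Number of clusters (nonredundant genes) in a catalog
#' @param catalog A `gene_catalog`.
#' @export
n_clusters <- function(catalog) length(catalog$clusters)

#' Records of the cluster representatives (the nonredundant gene set)
#' @param catalog A `gene_catalog`.
#' @export
representative_records <- function(catalog) {
  recs <- catalog$records
  recs[match(names(catalog$clusters), recs$gene_id), , drop = FALSE]
}

.check_thresholds <- function(id_thresh, cov_thresh) {
  .check_fraction(id_thresh, "id_thresh", lo = 0, lo_open = TRUE)
  .check_fraction(cov_thresh, "cov_thresh", lo = 0, lo_open = TRUE)
}

#' Greedy identity/coverage clustering of gene sequences
#'
#' Removes redundancy the way incremental greedy clustering tools do:
#' sequences are visited longest first (ties broken by gene id); each
#' sequence joins the first existing representative it matches at
#' `identity >= id_thresh` and `coverage >= cov_thresh`, otherwise it
#' founds a new cluster. The representatives form the nonredundant set.
#' The defaults are the conventional 95% identity / 90% coverage cutoffs.
#'
#' @param records Gene record `data.frame` with at least `gene_id` and
#'   `sequence` columns.
#' @param id_thresh,cov_thresh Identity and coverage thresholds in (0, 1].
#' @param ... Passed to [align_identity()] (alignment scoring).
#' @return A [gene_catalog()].
#' @export
cluster_genes <- function(records, id_thresh = 0.95, cov_thresh = 0.90, ...) {
  .check_thresholds(id_thresh, cov_thresh)
  if (is.null(records) || nrow(records) == 0L)
    return(gene_catalog(gene_records(character(), character()), list()))
  ord <- order(-nchar(records$sequence), records$gene_id)
  rec <- records[ord, , drop = FALSE]
  n <- nrow(rec)
  rep_idx <- integer(0)
  membership <- character(n)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (r in rep_idx) {
      al <- align_identity(rec$sequence[i], rec$sequence[r], ...)
      if (al$identity >= id_thresh && al$coverage >= cov_thresh) {
        membership[i] <- rec$gene_id[r]
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      rep_idx <- c(rep_idx, i)
      membership[i] <- rec$gene_id[i]
    }
  }
  clusters <- split(rec$gene_id,
                    factor(membership, levels = rec$gene_id[rep_idx]))
  gene_catalog(records = records, clusters = as.list(clusters))
}

#' Merge two nonredundant gene sets with overlap statistics
#'
#' Representatives of `set_b` are searched against the representatives of
#' `set_a` at the given thresholds; matching genes are the shared set.
#' The merged catalog is `set_a`'s representatives plus `set_b`'s
#' non-matching representatives, re-deduplicated by [cluster_genes()].
#'
#' @param set_a,set_b `gene_catalog` objects, each internally nonredundant.
#' @param id_thresh,cov_thresh Identity and coverage thresholds in (0, 1].
#' @param ... Passed to [align_identity()].
#' @return A list with `merged` (a `gene_catalog`) and `overlap`, a list
#'   holding `shared_count`, `frac_of_a` and `frac_of_b` (shared count
#'   divided by the representative counts of each input).
#' @export
merge_gene_sets <- function(set_a, set_b, id_thresh = 0.95,
                            cov_thresh = 0.90, ...) {
  .check_thresholds(id_thresh, cov_thresh)
  stopifnot(inherits(set_a, "gene_catalog"), inherits(set_b, "gene_catalog"))
  reps_a <- representative_records(set_a)
  reps_b <- representative_records(set_b)
  matches <- logical(nrow(reps_b))
  for (i in seq_len(nrow(reps_b))) {
    for (j in seq_len(nrow(reps_a))) {
      al <- align_identity(reps_b$sequence[i], reps_a$sequence[j], ...)
      if (al$identity >= id_thresh && al$coverage >= cov_thresh) {
        matches[i] <- TRUE
        break
      }
    }
  }
  shared <- sum(matches)
  merged_records <- rbind(reps_a, reps_b[!matches, , drop = FALSE])
  merged <- cluster_genes(merged_records, id_thresh = id_thresh,
                          cov_thresh = cov_thresh, ...)
  list(merged = merged,
       overlap = list(shared_count = shared,
                      frac_of_a = shared / nrow(reps_a),
                      frac_of_b = shared / nrow(reps_b)))
}
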