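# Pangenome read-recruitment strain detection: a strain is called present
# in a sample when strictly more than a presence fraction (default 50%)
# of its pangenome genes received at least one unique-mapped read.

#' Call strain presence in one sample from pangenome read recruitment
#'
#' For each strain, the detected gene fraction is the number of pangenome
#' genes with a nonzero count divided by the pangenome size; the strain
#' is called present when that fraction strictly exceeds `presence_frac`
#' ("more than 50%" at the default). Abundance (mean count/length over
#' detected genes, see [strain_abundance()]) is reported only for present
#' strains.
#'
#' A truly absent strain sharing more than `presence_frac` of its genes
#' with present strains will be called present - an accepted limit of
#' recruitment-based detection, asserted in the test suite.
#'
#' @param pangenomes List of [strain_pangenome()] objects; every pangenome
#'   gene must be a row of `counts` (possibly zero).
#' @param counts Integer count matrix, genes x samples.
#' @param sample Sample (column) id.
#' @param lengths Named numeric vector of gene lengths in bp (used for the
#'   abundance of present strains).
#' @param presence_frac Presence threshold, strict (default 0.5).
#' @return A `data.frame` with columns `strain_id`, `ecotype`,
#'   `detected_gene_fraction`, `present`, `abundance` (`NA` when absent).
#' @export
detect_strains <- function(pangenomes, counts, sample, lengths,
                           presence_frac = 0.5) {
  .check_counts(counts)
  .check_fraction(presence_frac, "presence_frac")
  if (!sample %in% colnames(counts))
    stop("sample '", sample, "' not found in the count table")
  calls <- lapply(pangenomes, function(pg) {
    stopifnot(inherits(pg, "strain_pangenome"))
    missing <- setdiff(pg$gene_ids, rownames(counts))
    if (length(missing))
      stop("pangenome gene(s) absent from the count table: ",
           paste(head(missing, 5), collapse = ", "))
    frac <- sum(counts[pg$gene_ids, sample] > 0) / length(pg$gene_ids)
    present <- frac > presence_frac
    data.frame(strain_id = pg$strain_id,
               ecotype = pg$ecotype,
               detected_gene_fraction = frac,
               present = present,
               abundance = if (present)
                 strain_abundance(pg, counts, lengths, sample)
               else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, calls)
}

#' Mean length-normalized abundance of a detected strain
#'
#' The abundance of each detected gene is its read count divided by its
#' length; the strain abundance is the mean over the genes with a nonzero
#' count (zero-count genes are excluded from the mean). Values are in
#' reads/bp and are not renormalized across strains, so cross-sample
#' comparison assumes equal sequencing depth.
#'
#' @param strain A [strain_pangenome()].
#' @param counts Integer count matrix, genes x samples.
#' @param lengths Named numeric vector of gene lengths in bp.
#' @param sample Sample (column) id.
#' @return Mean count/length over detected genes (reads/bp).
#' @export
strain_abundance <- function(strain, counts, lengths, sample) {
  stopifnot(inherits(strain, "strain_pangenome"))
  c_s <- counts[strain$gene_ids, sample]
  detected <- c_s > 0
  if (!any(detected))
    stop("strain '", strain$strain_id,
         "' has no detected gene in sample '", sample, "'")
  genes <- strain$gene_ids[detected]
  mean(c_s[detected] / lengths[genes])
}
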