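# Synthetic community generator. Read counts are simulated directly at
# gene level (no read sequences): per sample a multinomial draw with gene
# probability proportional to gene length times the summed abundance of
# the strains carrying it, i.e. uniform read starts over shared genes.

.BASES <- c("A", "C", "G", "T")

#' Uniform-random DNA sequence
#' @param n Length in bp.
#' @return A character scalar over {A,C,G,T}.
#' @export
random_dna <- function(n) {
  n <- .check_count(n, "n", min = 1L)
  paste(sample(.BASES, n, replace = TRUE), collapse = "")
}

#' Construct a strain pangenome
#'
#' @param strain_id Strain identifier.
#' @param gene_ids Non-empty character vector of member gene ids.
#' @param ecotype Optional ecotype label (e.g. `"HLI"`, `"HLII"`, `"LLI"`).
#' @return An object of class `strain_pangenome`.
#' @export
strain_pangenome <- function(strain_id, gene_ids, ecotype = NA_character_) {
  if (!length(gene_ids))
    stop("a pangenome must contain at least one gene")
  structure(list(strain_id = as.character(strain_id),
                 gene_ids = unique(as.character(gene_ids)),
                 ecotype = as.character(ecotype)),
            class = "strain_pangenome")
}

#' Generate strain pangenomes with core and accessory genes
#'
#' Builds `n_strains` pangenomes sharing `core_size` core genes, each
#' strain additionally carrying `accessory_size` private accessory genes.
#' Sequences are uniform random DNA; lengths are drawn uniformly from
#' `gene_len_range`. Deterministic for a fixed seed.
#'
#' @param n_strains Number of strains (>= 1).
#' @param core_size Number of core genes shared by every strain.
#' @param accessory_size Number of private accessory genes per strain.
#' @param gene_len_range Length range in bp, `c(min, max)`; the lower
#'   bound must respect the 150 bp predicted-gene floor.
#' @param seed RNG seed.
#' @param genera Optional character vector (length `n_strains`) of genus
#'   names; when given, every gene of a strain receives the lineage
#'   `"Bacteria;Cyanobacteria;Cyanophyceae;Synechococcales;Prochloraceae;<genus>"`
#'   (core genes take the first strain's genus).
#' @return A list with `pangenomes` (list of [strain_pangenome()]) and
#'   `records` (a [gene_records()] `data.frame`).
#' @examples
#' pg <- generate_pangenomes(3, core_size = 10, accessory_size = 4, seed = 1)
#' lengths(lapply(pg$pangenomes, `[[`, "gene_ids"))
#' @export
generate_pangenomes <- function(n_strains, core_size, accessory_size,
                                gene_len_range = c(500L, 1500L), seed = 1L,
                                genera = NULL) {
  n_strains <- .check_count(n_strains, "n_strains", min = 1L)
  core_size <- .check_count(core_size, "core_size")
  accessory_size <- .check_count(accessory_size, "accessory_size")
  if (length(gene_len_range) != 2L || any(gene_len_range <= 0))
    stop("gene_len_range must be two positive lengths")
  if (gene_len_range[1] < 150L)
    stop("gene_len_range must start at or above the 150 bp gene floor")
  if (gene_len_range[1] > gene_len_range[2])
    stop("gene_len_range must be increasing")
  if (!is.null(genera) && length(genera) != n_strains)
    stop("genera must have one entry per strain")
  set.seed(seed)
  strain_ids <- sprintf("strain_%02d", seq_len(n_strains))
  core_ids <- if (core_size) sprintf("core_%04d", seq_len(core_size)) else character()
  gene_id <- core_ids
  gene_genus <- rep(if (is.null(genera)) NA_character_ else genera[1L], core_size)
  pangenomes <- vector("list", n_strains)
  for (i in seq_len(n_strains)) {
    acc <- if (accessory_size)
      sprintf("acc_%s_%04d", strain_ids[i], seq_len(accessory_size))
    else character()
    gene_id <- c(gene_id, acc)
    gene_genus <- c(gene_genus,
                    rep(if (is.null(genera)) NA_character_ else genera[i],
                        accessory_size))
    pangenomes[[i]] <- strain_pangenome(strain_ids[i], c(core_ids, acc))
  }
  if (!length(gene_id))
    stop("pangenome generation produced no genes; increase core or accessory size")
  len <- sample(seq(gene_len_range[1], gene_len_range[2]), length(gene_id),
                replace = TRUE)
  seqs <- vapply(len, random_dna, character(1))
  lineage <- ifelse(is.na(gene_genus), NA_character_,
                    paste("Bacteria", "Cyanobacteria", "Cyanophyceae",
                          "Synechococcales", "Prochloraceae", gene_genus,
                          sep = ";"))
  list(pangenomes = pangenomes,
       records = gene_records(gene_id, seqs, lineage = lineage))
}

#' Substitute bases at a fixed per-site divergence
#'
#' Each position is independently replaced, with probability `divergence`,
#' by a base drawn uniformly from the three alternatives, so the expected
#' identity to the input is exactly `1 - divergence`. Length is preserved
#' (no indels).
#'
#' @param seq DNA sequence (ACGT only).
#' @param divergence Per-site substitution probability in \[0, 1\].
#' @param seed Optional RNG seed; `NULL` uses the current RNG state.
#' @return The mutated sequence, same length as the input.
#' @examples
#' mutate_sequence("ACGTACGT", divergence = 0, seed = 1)
#' @export
mutate_sequence <- function(seq, divergence, seed = NULL) {
  .check_dna(seq)
  .check_fraction(divergence, "divergence")
  if (!is.null(seed)) set.seed(seed)
  chars <- strsplit(seq, "")[[1L]]
  hit <- which(runif(length(chars)) < divergence)
  if (length(hit)) {
    chars[hit] <- vapply(chars[hit],
                         function(b) sample(setdiff(.BASES, b), 1L),
                         character(1), USE.NAMES = FALSE)
  }
  paste(chars, collapse = "")
}

#' Define a synthetic community
#'
#' @param strains Character vector of strain ids.
#' @param true_abundance Per-strain relative abundances; non-negative,
#'   summing to 1 within 1e-9.
#' @param pangenomes List of [strain_pangenome()] objects, one per strain.
#' @param gene_lengths Named numeric vector, gene id to length in bp
#'   (>= 150).
#' @param annotations Optional annotation `data.frame` with columns
#'   `gene_id`, `lineage`, `ko`.
#' @return An object of class `community_spec`.
#' @export
community_spec <- function(strains, true_abundance, pangenomes,
                           gene_lengths, annotations = NULL) {
  if (length(strains) != length(true_abundance) ||
      length(strains) != length(pangenomes))
    stop("strains, true_abundance and pangenomes must align")
  if (any(true_abundance < 0))
    stop("abundances must be non-negative")
  if (abs(sum(true_abundance) - 1) > 1e-9)
    stop("abundances must sum to 1 within 1e-9")
  all_genes <- unique(unlist(lapply(pangenomes, `[[`, "gene_ids")))
  missing <- setdiff(all_genes, names(gene_lengths))
  if (length(missing))
    stop("genes without a length entry: ", paste(head(missing, 5), collapse = ", "))
  if (any(gene_lengths < 150))
    stop("gene lengths must be at least 150 bp")
  structure(list(strains = as.character(strains),
                 true_abundance = as.numeric(true_abundance),
                 pangenomes = pangenomes,
                 gene_lengths = gene_lengths,
                 annotations = annotations),
            class = "community_spec")
}

#' Expected length-weighted gene sampling probabilities of a community
#'
#' The probability of a unique-mapped read landing on gene g is
#' proportional to `length(g)` times the summed relative abundance of the
#' strains carrying g (uniform read start positions over shared genes).
#'
#' @param spec A [community_spec()].
#' @return Named numeric vector over all community genes, summing to 1.
#' @export
community_gene_probs <- function(spec) {
  stopifnot(inherits(spec, "community_spec"))
  genes <- sort(unique(unlist(lapply(spec$pangenomes, `[[`, "gene_ids"))))
  carrier_ab <- setNames(numeric(length(genes)), genes)
  for (i in seq_along(spec$pangenomes)) {
    g <- spec$pangenomes[[i]]$gene_ids
    carrier_ab[g] <- carrier_ab[g] + spec$true_abundance[i]
  }
  w <- carrier_ab * spec$gene_lengths[genes]
  w / sum(w)
}

#' Simulate unique-mapped read counts for a community
#'
#' Per sample, counts are a multinomial draw of `n_reads_per_sample`
#' reads over the community genes with probabilities from
#' [community_gene_probs()]; column sums therefore equal the read depth.
#'
#' @param spec A [community_spec()].
#' @param n_reads_per_sample Reads per sample (>= 0).
#' @param n_samples Number of samples.
#' @param seed RNG seed.
#' @return An integer count matrix, genes x samples.
#' @export
simulate_counts <- function(spec, n_reads_per_sample, n_samples, seed = 1L) {
  stopifnot(inherits(spec, "community_spec"))
  n_reads_per_sample <- .check_count(n_reads_per_sample, "n_reads_per_sample")
  n_samples <- .check_count(n_samples, "n_samples", min = 1L)
  p <- community_gene_probs(spec)
  if (!length(p))
    stop("community contains no genes")
  set.seed(seed)
  counts <- if (n_reads_per_sample == 0L)
    matrix(0L, nrow = length(p), ncol = n_samples)
  else
    rmultinom(n_samples, size = n_reads_per_sample, prob = p)
  dimnames(counts) <- list(names(p), sprintf("sample_%02d", seq_len(n_samples)))
  storage.mode(counts) <- "integer"
  counts
}

#' Generate an environmental covariate table
#'
#' Temperature is a strictly increasing linear transform of the supplied
#' taxon abundance vector (rank correlation with it is therefore +1 when
#' the abundances are untied); the remaining variables are independent
#' noise within oceanographically plausible surface-water ranges.
#'
#' @param n_samples Number of samples (>= 3, so correlations are defined).
#' @param linked_taxon_abundance Numeric vector of length `n_samples`.
#' @param seed RNG seed.
#' @return A `data.frame` with `sample_id`, `temperature` (degrees C),
#'   `salinity` (PSU), `pH`, `phosphate`, `silicate`, `ammonium`,
#'   `nitrite`, `nitrate` (all micromolar) and `chlorophyll_a` (ug/L).
#' @export
generate_env_table <- function(n_samples, linked_taxon_abundance, seed = 1L) {
  n_samples <- .check_count(n_samples, "n_samples", min = 3L)
  a <- as.numeric(linked_taxon_abundance)
  if (length(a) != n_samples)
    stop("linked_taxon_abundance must have one value per sample")
  set.seed(seed)
  spread <- max(a) - min(a)
  temperature <- if (spread > 0) 16 + 12 * (a - min(a)) / spread else rep(22, n_samples)
  env <- data.frame(
    sample_id = sprintf("sample_%02d", seq_len(n_samples)),
    temperature = temperature,
    salinity = rnorm(n_samples, 35, 0.4),
    pH = runif(n_samples, 7.9, 8.15),
    phosphate = pmax(rnorm(n_samples, 0.20, 0.08), 0),
    silicate = pmax(rnorm(n_samples, 1.8, 0.6), 0),
    ammonium = pmax(rnorm(n_samples, 0.08, 0.04), 0),
    nitrite = pmax(rnorm(n_samples, 0.03, 0.015), 0),
    nitrate = pmax(rnorm(n_samples, 0.15, 0.08), 0),
    chlorophyll_a = pmax(rnorm(n_samples, 0.15, 0.07), 0.01),
    stringsAsFactors = FALSE)
  stopifnot(all(env$pH >= 6 & env$pH <= 10))
  env
}
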