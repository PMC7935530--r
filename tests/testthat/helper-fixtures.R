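# Shared fixtures and independent oracles, all generated in code.

# A family of near-duplicate genes: one parent plus `n_mutants` mutants,
# ids chosen so the parent sorts first lexicographically among equal
# lengths (the greedy tie-break).
mutant_family <- function(prefix, len = 1000L, n_mutants = 5L,
                          divergence = 0.02) {
  parent <- random_dna(len)
  seqs <- c(parent,
            vapply(seq_len(n_mutants),
                   function(i) mutate_sequence(parent, divergence),
                   character(1)))
  names(seqs) <- c(sprintf("%s_a_parent", prefix),
                   sprintf("%s_m_%02d", prefix, seq_len(n_mutants)))
  seqs
}

# Independent brute-force greedy clustering: computes the full pairwise
# identity/coverage matrices first, then replays the greedy rule over
# them. Returns the membership map (gene id -> representative id).
brute_force_greedy <- function(records, id_thresh, cov_thresh) {
  ord <- order(-nchar(records$sequence), records$gene_id)
  rec <- records[ord, , drop = FALSE]
  n <- nrow(rec)
  idm <- covm <- matrix(0, n, n)
  for (i in seq_len(n)) {
    idm[i, i] <- covm[i, i] <- 1
    for (j in seq_len(i - 1L)) {
      al <- align_identity(rec$sequence[i], rec$sequence[j])
      idm[i, j] <- idm[j, i] <- al$identity
      covm[i, j] <- covm[j, i] <- al$coverage
    }
  }
  reps <- integer(0)
  member <- character(n)
  for (i in seq_len(n)) {
    hit <- reps[idm[i, reps] >= id_thresh & covm[i, reps] >= cov_thresh]
    if (length(hit)) {
      member[i] <- rec$gene_id[hit[1L]]
    } else {
      reps <- c(reps, i)
      member[i] <- rec$gene_id[i]
    }
  }
  setNames(member, rec$gene_id)
}

catalog_membership <- function(catalog) {
  m <- setNames(rep(names(catalog$clusters), lengths(catalog$clusters)),
                unlist(catalog$clusters, use.names = FALSE))
  m[order(names(m))]
}

# A community of strains with fully disjoint pangenomes (no shared genes),
# so per-strain truths are unambiguous.
disjoint_community <- function(abundances, genes_per_strain = 20L,
                               gene_len = 600L, seed = 11L,
                               genera = NULL) {
  set.seed(seed)
  n <- length(abundances)
  strain_ids <- sprintf("strain_%02d", seq_len(n))
  pangenomes <- list()
  gene_id <- character()
  genus_of_gene <- character()
  for (i in seq_len(n)) {
    g <- sprintf("g_%s_%03d", strain_ids[i], seq_len(genes_per_strain))
    pangenomes[[i]] <- strain_pangenome(strain_ids[i], g)
    gene_id <- c(gene_id, g)
    genus_of_gene <- c(genus_of_gene,
                       rep(if (is.null(genera)) strain_ids[i] else genera[i],
                           genes_per_strain))
  }
  lengths <- setNames(rep(gene_len, length(gene_id)), gene_id)
  lineage <- paste("Bacteria", "Cyanobacteria", "Cyanophyceae",
                   "Synechococcales", "Prochloraceae", genus_of_gene,
                   sep = ";")
  spec <- community_spec(strain_ids, abundances, pangenomes, lengths)
  list(spec = spec, lengths = lengths,
       lineage_map = setNames(lineage, gene_id),
       pangenomes = pangenomes)
}

# Independent permutation generator (insertion construction) for the
# exhaustive Spearman oracle; deliberately different from the package's.
all_perms_insert <- function(n) {
  out <- list(1L)
  for (k in 2L:n) {
    nxt <- list()
    for (p in out)
      for (pos in seq_len(k))
        nxt[[length(nxt) + 1L]] <- append(p, k, after = pos - 1L)
    out <- nxt
  }
  out
}
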