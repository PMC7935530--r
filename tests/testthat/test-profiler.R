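# Length-normalized relative abundance at gene, KO and taxon level, and
# cross-sample core fractions.

make_counts <- function(x, genes, samples) {
  matrix(as.integer(x), length(genes), length(samples),
         dimnames = list(genes, samples))
}

test_that("gene abundance is length-normalized and scale invariant", {
  cts <- make_counts(c(10, 10), c("g1", "g2"), "s1")
  prof <- gene_abundance(cts, c(g1 = 100, g2 = 200))
  expect_equal(unname(prof[, 1]), c(2 / 3, 1 / 3))
  expect_equal(profile_level(prof), "gene")

  # single counted gene
  one <- gene_abundance(make_counts(7, "g1", "s1"), c(g1 = 500))
  expect_equal(unname(one[1, 1]), 1.0)

  # doubling every count leaves the profile unchanged
  prof2 <- gene_abundance(cts * 2L, c(g1 = 100, g2 = 200))
  expect_equal(prof, prof2)

  # all-zero sample warns and yields zeros
  z <- make_counts(c(0, 0), c("g1", "g2"), "s1")
  expect_warning(pz <- gene_abundance(z, c(g1 = 100, g2 = 200)), "all-zero")
  expect_true(all(pz == 0))

  expect_error(gene_abundance(cts, c(g1 = 100)), "no length")
  expect_error(gene_abundance(cts, c(g1 = 100, g2 = 0)), "positive")
})

test_that("profiles sum to one per sample at gene and taxon level", {
  com <- disjoint_community(c(0.5, 0.3, 0.2), genes_per_strain = 15)
  cts <- simulate_counts(com$spec, 5e4, 3, seed = 4)
  prof <- gene_abundance(cts, com$lengths)
  expect_equal(unname(colSums(prof)), rep(1, 3), tolerance = 1e-9)
  tax <- taxon_profile(prof, com$lineage_map, "genus")
  expect_equal(unname(colSums(tax)), rep(1, 3), tolerance = 1e-9)
})

test_that("KO aggregation matches brute-force summation", {
  set.seed(6)
  genes <- sprintf("g%03d", 1:200)
  cts <- make_counts(rpois(400, 50), genes, c("s1", "s2"))
  lens <- setNames(sample(300:900, 200, replace = TRUE), genes)
  prof <- gene_abundance(cts, lens)
  kos <- sprintf("K%05d", 1:30)
  ko_map <- setNames(lapply(genes, function(g)
    sample(kos, sample(1:3, 1))), genes)
  ko_map[sample(200, 20)] <- list(character())  # unannotated genes

  kp <- ko_profile(prof, ko_map)

  # independent brute-force per-KO summation
  for (k in sample(rownames(kp), 10)) {
    carriers <- names(ko_map)[vapply(ko_map, function(x) k %in% x, logical(1))]
    expect_equal(unname(kp[k, ]),
                 unname(colSums(prof[carriers, , drop = FALSE])))
  }

  # conservation when every gene has exactly one KO
  ko1 <- setNames(as.list(sample(kos, 200, replace = TRUE)), genes)
  kp1 <- ko_profile(prof, ko1)
  expect_equal(unname(colSums(kp1)), rep(1, 2), tolerance = 1e-9)

  # two genes sharing one KO accumulate both abundances
  p2 <- gene_abundance(make_counts(c(40, 60), c("gA", "gB"), "s1"),
                       c(gA = 100, gB = 100))
  k2 <- ko_profile(p2, list(gA = "K00001", gB = "K00001"))
  expect_equal(unname(k2["K00001", 1]), 1.0)
})

test_that("taxon aggregation pools unclassified genes under 'unassigned'", {
  cts <- make_counts(c(70, 30, 10), c("g1", "g2", "g3"), "s1")
  lens <- c(g1 = 100, g2 = 100, g3 = 100)
  prof <- gene_abundance(cts, lens)
  lin <- c(g1 = "Bacteria;Proteobacteria", g2 = "Bacteria;Cyanobacteria",
           g3 = NA)
  ph <- taxon_profile(prof, lin, "phylum")
  expect_equal(ph["Proteobacteria", 1], 70 / 110)
  expect_equal(ph["Cyanobacteria", 1], 30 / 110)
  expect_equal(ph["unassigned", 1], 10 / 110)
  expect_equal(sum(ph[, 1]), 1.0)

  expect_error(taxon_profile(prof, lin, "strain"), "unknown rank")
})

test_that("genus profile recovers carrier-weighted community truth", {
  com <- disjoint_community(c(0.6, 0.4), genes_per_strain = 25,
                            genera = c("Prochlorococcus", "Synechococcus"))
  cts <- simulate_counts(com$spec, 2e5, 1, seed = 15)
  prof <- gene_abundance(cts, com$lengths)
  tax <- taxon_profile(prof, com$lineage_map, "genus")
  expect_lt(abs(tax["Prochlorococcus", 1] - 0.6),
            3 * sqrt(0.6 * 0.4 / 2e5) + 0.01)
  # aggregation consistency against brute-force summation
  pro_genes <- names(com$lineage_map)[grepl("Prochlorococcus",
                                            com$lineage_map)]
  expect_equal(unname(tax["Prochlorococcus", 1]),
               sum(prof[pro_genes, 1]))
})

test_that("core fraction counts features shared by every sample", {
  m <- matrix(1, 4, 3, dimnames = list(sprintf("f%d", 1:4), sprintf("s%d", 1:3)))
  expect_equal(core_fraction(m), 1.0)

  d <- diag(3)
  dimnames(d) <- list(sprintf("f%d", 1:3), sprintf("s%d", 1:3))
  expect_equal(core_fraction(d), 0.0)

  # 50 universal genes out of 200 observed; the rest private to one sample
  n_samples <- 10L
  m2 <- matrix(0, 200, n_samples,
               dimnames = list(sprintf("g%03d", 1:200),
                               sprintf("s%02d", 1:n_samples)))
  m2[1:50, ] <- 1
  m2[cbind(51:200, rep(seq_len(n_samples), length.out = 150))] <- 1
  expect_equal(core_fraction(m2), 0.25)

  expect_error(core_fraction(m[, 1, drop = FALSE]), "two samples")
  zero <- matrix(0, 2, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(core_fraction(zero), "no feature")
})

test_that("annotation tables parse into KO and lineage maps", {
  ann <- data.frame(gene_id = c("g1", "g2", "g3"),
                    lineage = c("Bacteria;Proteobacteria", NA, "Bacteria"),
                    ko = c("K00001,K00002", NA, "K00003"),
                    stringsAsFactors = FALSE)
  km <- ko_map_from_annotation(ann)
  expect_equal(km$g1, c("K00001", "K00002"))
  expect_length(km$g2, 0L)
  lm <- lineage_map_from_annotation(ann)
  expect_identical(lm[["g1"]], "Bacteria;Proteobacteria")
  expect_true(is.na(lm[["g2"]]))
})
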