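# Marker selection, p-distances, neighbor-joining, clade assignment, ANI.

test_that("marker family selection filters by length and breaks ties", {
  set.seed(51)
  mk <- function(id, n, len) {
    s <- vapply(seq_len(n), function(i) random_dna(len), character(1))
    names(s) <- sprintf("%s_m%02d", id, seq_len(n))
    marker_family(id, s)
  }
  one <- mk("COG0001", 4, 900)
  expect_equal(select_marker_family(list(one))$family_id, "COG0001")

  # survivors 5, 9, 9 with ids C, A, B: lexicographic tie-break picks A
  fams <- list(mk("C", 5, 900), mk("A", 9, 900), mk("B", 9, 900))
  expect_equal(select_marker_family(fams)$family_id, "A")

  # members at or below the floor are dropped before counting
  short_heavy <- marker_family("S", c(s1 = random_dna(400), s2 = random_dna(400),
                                      s3 = random_dna(400), s4 = random_dna(801)))
  long_light <- mk("L", 2, 900)
  picked <- select_marker_family(list(short_heavy, long_light))
  expect_equal(picked$family_id, "L")
  expect_length(select_marker_family(list(short_heavy))$sequences, 1L)

  # brute-force max over random survivor counts
  set.seed(52)
  counts <- sample(0:8, 6, replace = TRUE)
  counts[2] <- 9L
  fams2 <- lapply(seq_along(counts), function(i)
    mk(sprintf("F%02d", i), max(counts[i], 1L),
       if (counts[i] == 0L) 500 else 900))
  best <- select_marker_family(fams2)
  survivors <- vapply(fams2, function(f) sum(nchar(f$sequences) > 800),
                      integer(1))
  expect_equal(best$family_id, sprintf("F%02d", which.max(survivors)))

  expect_error(select_marker_family(list(mk("X", 3, 500))), "length filter")
  expect_error(select_marker_family(list()), "at least one")
})

test_that("p-distances count mismatches over gap-free positions", {
  expect_true(all(p_distance_matrix(c(a = "AAAA", b = "AAAA", c = "AAAA")) == 0))
  d <- p_distance_matrix(c(a = "AAAA", b = "AATT", c = "TTTT"))
  expect_equal(d["a", "b"], 0.5)
  expect_equal(d["a", "c"], 1.0)
  expect_equal(d, t(d))

  # gapped positions are excluded pairwise
  dg <- p_distance_matrix(c(a = "AA-A", b = "AATA", c = "CATA"))
  expect_equal(dg["a", "b"], 0)
  expect_equal(dg["a", "c"], 1 / 3)

  # oracle: ape's raw distance with pairwise gap deletion
  set.seed(53)
  seqs <- c(x = random_dna(300), y = random_dna(300), z = random_dna(300),
            w = mutate_sequence(random_dna(300), 0.1))
  dm <- p_distance_matrix(seqs)
  bin <- ape::as.DNAbin(lapply(seqs, function(s) strsplit(tolower(s), "")[[1]]))
  ref <- as.matrix(ape::dist.dna(bin, model = "raw", pairwise.deletion = TRUE))
  expect_equal(dm, ref[rownames(dm), colnames(dm)], tolerance = 1e-12)

  expect_error(p_distance_matrix(c(a = "AA", b = "AA")), "three")
  expect_error(p_distance_matrix(c(a = "AA", b = "AAA", c = "AA")), "equal length")
  expect_error(p_distance_matrix(c(a = "--A", b = "A--", c = "AAA")),
               "no comparable")
})

test_that("neighbor-joining solves the three-taxon case in closed form", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(d)
  expect_setequal(tr$tip.label, c("A", "B", "C"))
  bl <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])],
                 tr$tip.label)
  expect_equal(bl[["A"]], 1)
  expect_equal(bl[["B"]], 2)
  expect_equal(bl[["C"]], 3)
})

test_that("neighbor-joining reconstructs additive trees exactly", {
  set.seed(54)
  ref <- ape::rtree(8)
  d <- cophenetic(ref)
  tr <- nj_tree(d)
  expect_setequal(tr$tip.label, ref$tip.label)
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(ref), tr)), 0)
  back <- cophenetic(tr)[rownames(d), colnames(d)]
  expect_lt(max(abs(back - d)), 1e-9)
})

test_that("neighbor-joining honors the four-point condition", {
  # additive distances for the split AB|CD
  lab <- c("A", "B", "C", "D")
  d <- matrix(c(0, 2, 4, 4,
                2, 0, 4, 4,
                4, 4, 0, 2,
                4, 4, 2, 0), 4, 4, dimnames = list(lab, lab))
  tr <- nj_tree(d)
  # the internal edge separates {A,B} from {C,D}
  expected <- ape::unroot(ape::read.tree(text = "((A:1,B:1):2,(C:1,D:1):0);"))
  expect_equal(as.numeric(ape::dist.topo(tr, expected)), 0)
})

test_that("neighbor-joining agrees with an independent implementation", {
  set.seed(55)
  base <- cophenetic(ape::rtree(7))
  noise <- matrix(runif(49, 0, 0.05), 7, 7)
  noise <- (noise + t(noise)) / 2
  diag(noise) <- 0
  d <- base + noise
  mine <- nj_tree(d)
  ref <- ape::nj(as.dist(d))
  expect_equal(as.numeric(ape::dist.topo(mine, ape::unroot(ref))), 0)

  bad <- d
  bad[1, 2] <- -1
  expect_error(nj_tree(bad), "symmetric|non-negative")
  bad2 <- d
  bad2[1, 2] <- bad2[2, 1] <- NaN
  expect_error(nj_tree(bad2), "finite")
})

test_that("trees round-trip through Newick and keep their leaf set", {
  set.seed(56)
  d <- cophenetic(ape::rtree(6))
  tr <- nj_tree(d)
  tmp <- tempfile(fileext = ".nwk")
  ape::write.tree(tr, tmp)
  back <- ape::read.tree(tmp)
  expect_setequal(back$tip.label, rownames(d))
  expect_equal(as.numeric(ape::dist.topo(tr, back)), 0)
  expect_equal(sort(tr$edge.length), sort(back$edge.length), tolerance = 1e-9)
})

test_that("clade assignment follows the nearest labeled reference", {
  set.seed(57)
  root_a <- random_dna(600)
  root_b <- mutate_sequence(root_a, 0.15)
  seqs <- c(refA1 = mutate_sequence(root_a, 0.01),
            refA2 = mutate_sequence(root_a, 0.01),
            refB1 = mutate_sequence(root_b, 0.01),
            refB2 = mutate_sequence(root_b, 0.01),
            q1 = mutate_sequence(root_a, 0.02),
            q2 = mutate_sequence(root_a, 0.02),
            q3 = mutate_sequence(root_a, 0.02))
  tr <- nj_tree(p_distance_matrix(seqs))
  labels <- c(refA1 = "HLII", refA2 = "HLII", refB1 = "LLI", refB2 = "LLI")
  got <- assign_clade(c("q1", "q2", "q3"), labels, tr)
  expect_true(all(got == "HLII"))

  # a single reference label propagates to every query
  one <- assign_clade(c("q1", "q2"), c(refB1 = "LLI"), tr)
  expect_true(all(one == "LLI"))

  expect_error(assign_clade("q1", setNames(character(), character()), tr),
               "labeled reference")
  expect_error(assign_clade("absent_tip", labels, tr), "absent from the tree")
})

test_that("ANI is the mean identity of reciprocal best gene pairs", {
  set.seed(58)
  genes_a <- lapply(1:5, function(i) random_dna(400))
  expect_equal(genome_ani(genes_a, genes_a), 100.0)

  genes_b <- lapply(genes_a, function(g) mutate_sequence(g, 0.05))
  ani <- genome_ani(genes_a, genes_b)
  tol <- 3 * sqrt(0.05 * 0.95 / (5 * 400)) * 100
  expect_lt(abs(ani - 95), tol)

  # no pair clears an extreme floor: informative failure
  genes_c <- lapply(1:4, function(i) random_dna(400))
  expect_error(genome_ani(genes_a, genes_c, min_identity = 0.99),
               "no reciprocal best pair")
  expect_error(genome_ani(list(), genes_a), "non-empty")
})
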