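# Single-copy marker-gene phylogenetics: marker family selection,
# p-distances, neighbor-joining, ecotype clade assignment and average
# nucleotide identity. The distance + NJ stage is implemented here
# (ape is used for Newick IO, patristic distances and as an independent
# oracle in the tests, never as the tree builder).

#' Construct a single-copy marker gene family
#'
#' @param family_id Family identifier (e.g. a COG-style id).
#' @param sequences Named character vector of member DNA sequences; names
#'   are the member (genome/catalog) ids.
#' @param source Optional character vector of member source labels
#'   (reference genome, catalog, external gene set).
#' @return An object of class `marker_family`.
#' @export
marker_family <- function(family_id, sequences, source = NULL) {
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
    stop("sequences must be uniquely named by member id")
  structure(list(family_id = as.character(family_id),
                 sequences = sequences,
                 source = source),
            class = "marker_family")
}

#' Select the best-populated single-copy marker family
#'
#' Drops members whose sequence length is not strictly greater than
#' `min_len` (short fragments carry too little signal for the tree) and
#' returns the family with the most surviving members, ties broken by
#' lexicographic family id. The returned family contains the survivors
#' only.
#'
#' @param families List of [marker_family()] objects.
#' @param min_len Minimum sequence length in bp (default 800, the
#'   conventional floor for marker-gene trees from fragmented catalogs).
#' @return The selected, filtered `marker_family`.
#' @export
select_marker_family <- function(families, min_len = 800L) {
  if (!length(families))
    stop("at least one marker family is required")
  filtered <- lapply(families, function(f) {
    stopifnot(inherits(f, "marker_family"))
    keep <- nchar(f$sequences) > min_len
    marker_family(f$family_id, f$sequences[keep],
                  source = if (is.null(f$source)) NULL else f$source[keep])
  })
  survivors <- vapply(filtered, function(f) length(f$sequences), integer(1))
  if (all(survivors == 0L))
    stop("no marker family retains members after the length filter")
  ids <- vapply(filtered, `[[`, character(1), "family_id")
  best <- order(-survivors, ids)[1L]
  filtered[[best]]
}

#' Pairwise p-distance matrix of aligned sequences
#'
#' The p-distance between two aligned sequences is the proportion of
#' differing sites among the positions where neither sequence carries a
#' gap character (`-`).
#'
#' @param seqs Named character vector of equal-length aligned sequences
#'   (>= 3).
#' @return A symmetric numeric matrix with zero diagonal.
#' @examples
#' p_distance_matrix(c(a = "AAAA", b = "AATT", c = "TTTT"))
#' @export
p_distance_matrix <- function(seqs) {
  n <- length(seqs)
  if (n < 3L)
    stop("at least three sequences are required")
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("sequences must be uniquely named")
  if (length(unique(nchar(seqs))) != 1L)
    stop("sequences must be aligned to equal length")
  mat <- do.call(rbind, strsplit(seqs, ""))
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      comp <- mat[i, ] != "-" & mat[j, ] != "-"
      if (!any(comp))
        stop("no comparable (gap-free) positions between '", names(seqs)[i],
             "' and '", names(seqs)[j], "'")
      d[i, j] <- d[j, i] <- mean(mat[i, comp] != mat[j, comp])
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor-joining agglomeration: at each step the pair
#' minimizing the Q criterion is joined, branch lengths are solved from
#' the three-point equations, and distances to the new node are averaged.
#' On an additive matrix the input distances are reproduced exactly as
#' path lengths. Negative branch-length estimates are clamped to zero and
#' the total deficit reported via a message. The final join leaves the
#' conventional root trifurcation, so the tree is unrooted.
#'
#' @param dist Symmetric numeric matrix with zero diagonal, no negative
#'   or non-finite off-diagonal entries, and >= 3 labeled taxa.
#' @return An unrooted `phylo` tree (ape format).
#' @export
nj_tree <- function(dist) {
  d <- as.matrix(dist)
  n <- nrow(d)
  if (n < 3L) stop("at least three taxa are required")
  if (is.null(rownames(d))) stop("the distance matrix must be labeled")
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-12)))
    stop("the distance matrix must be symmetric")
  if (any(diag(d) != 0)) stop("the diagonal must be zero")
  off <- d[upper.tri(d)]
  if (any(!is.finite(off)) || any(off < 0))
    stop("off-diagonal distances must be finite and non-negative")
  fmt <- function(x) sprintf("%.12g", x)
  deficit <- 0
  clamp <- function(x) {
    if (x < 0) {
      deficit <<- deficit - x
      0
    } else x
  }
  nodes <- as.list(rownames(d))
  D <- unname(d)
  while (length(nodes) > 3L) {
    N <- nrow(D)
    r <- rowSums(D)
    Q <- (N - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    pick <- which(Q == min(Q), arr.ind = TRUE)[1L, ]
    i <- min(pick)
    j <- max(pick)
    li <- clamp(D[i, j] / 2 + (r[i] - r[j]) / (2 * (N - 2)))
    lj <- clamp(D[i, j] - (D[i, j] / 2 + (r[i] - r[j]) / (2 * (N - 2))))
    frag <- sprintf("(%s:%s,%s:%s)", nodes[[i]], fmt(li), nodes[[j]], fmt(lj))
    keep <- setdiff(seq_len(N), c(i, j))
    dnew <- (D[i, keep] + D[j, keep] - D[i, j]) / 2
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dnew), c(dnew, 0))
    nodes <- c(nodes[keep], frag)
  }
  x <- clamp((D[1, 2] + D[1, 3] - D[2, 3]) / 2)
  y <- clamp((D[1, 2] + D[2, 3] - D[1, 3]) / 2)
  z <- clamp((D[1, 3] + D[2, 3] - D[1, 2]) / 2)
  if (deficit > 0)
    message(sprintf("clamped negative branch lengths (total deficit %.3g)",
                    deficit))
  newick <- sprintf("(%s:%s,%s:%s,%s:%s);", nodes[[1]], fmt(x),
                    nodes[[2]], fmt(y), nodes[[3]], fmt(z))
  ape::read.tree(text = newick)
}

#' Assign ecotype clades to query leaves by nearest labeled reference
#'
#' Each query tip receives the ecotype label of the labeled reference tip
#' nearest to it by patristic (path-length) distance on the tree; exact
#' ties go to the label of the reference with the lexicographically
#' smallest id.
#'
#' @param query_ids Character vector of query tip labels.
#' @param ref_labels Named character vector: reference tip id -> ecotype
#'   label (at least one reference per candidate label).
#' @param tree A `phylo` tree containing all query and reference tips.
#' @return Named character vector, query id -> ecotype label.
#' @export
assign_clade <- function(query_ids, ref_labels, tree) {
  if (!length(ref_labels))
    stop("at least one labeled reference is required")
  missing <- setdiff(c(query_ids, names(ref_labels)), tree$tip.label)
  if (length(missing))
    stop("tip(s) absent from the tree: ", paste(head(missing, 5), collapse = ", "))
  pd <- cophenetic(tree)
  refs <- sort(names(ref_labels))
  out <- vapply(query_ids, function(q) {
    dq <- pd[q, refs]
    ref_labels[[refs[which(dq <= min(dq) + 1e-12)[1L]]]]
  }, character(1))
  setNames(out, query_ids)
}

#' Average nucleotide identity between two genomes' gene sets
#'
#' Every gene of genome A is aligned against every gene of genome B with
#' [align_identity()]; reciprocal best pairs with identity at or above
#' `min_identity` are retained, and the ANI is the mean identity of the
#' retained pairs, in percent. Reciprocal best hits over genes are the
#' standard desk-scale ANI approximation.
#'
#' @param genes_a,genes_b Non-empty character vectors of gene sequences.
#' @param min_identity Minimum identity floor for a pair to count
#'   (default 0.3).
#' @return ANI in percent (0-100).
#' @export
genome_ani <- function(genes_a, genes_b, min_identity = 0.3) {
  if (!length(genes_a) || !length(genes_b))
    stop("both gene lists must be non-empty")
  .check_fraction(min_identity, "min_identity")
  na <- length(genes_a)
  nb <- length(genes_b)
  id <- matrix(0, na, nb)
  for (i in seq_len(na))
    for (j in seq_len(nb))
      id[i, j] <- align_identity(genes_a[[i]], genes_b[[j]])$identity
  best_ab <- apply(id, 1L, which.max)
  best_ba <- apply(id, 2L, which.max)
  kept <- vapply(seq_len(na), function(i) {
    j <- best_ab[i]
    best_ba[j] == i && id[i, j] >= min_identity
  }, logical(1))
  if (!any(kept))
    stop("no reciprocal best pair above the identity floor (",
         min_identity, "); the genomes may be unrelated")
  mean(id[cbind(which(kept), best_ab[kept])]) * 100
}
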