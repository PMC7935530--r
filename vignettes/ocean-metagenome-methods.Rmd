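---
title: "Methods: gene catalogs, strain detection and nitrogen-pathway analysis for surface-ocean metagenomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene catalogs, strain detection and nitrogen-pathway analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pelagomics)
```

# Scope

`pelagomics` implements the downstream, post-mapping stages of a
surface-ocean metagenome survey as tested, reusable components. Everything
upstream — read quality control, read mapping, assembly, gene prediction and
homology annotation — is out of scope: annotations (taxonomy lineages, KO
assignments, pangenome memberships) enter as plain-text input tables, and
read mapping enters as a genes × samples table of unique-mapped counts.
A synthetic-data module generates communities with known ground truth so
that every stage can be exercised and validated without external downloads.

# Gene catalog construction

## Pairwise identity and coverage

`align_identity()` performs an end-to-end (Needleman–Wunsch) alignment with
affine gap costs. The scoring configuration is fixed: match +1, mismatch −1,
gap opening 2 and gap extension 1 (as costs). Two derived quantities feed
redundancy removal:

* **identity** — identical aligned positions divided by the length of the
  *shorter* sequence;
* **coverage** — the fraction of the shorter sequence lying inside the
  aligned span after trimming terminal gaps.

The shorter-sequence denominator is the convention of the incremental
clustering tools used to build published marine gene catalogs; it makes a
perfect substring score (identity 1, coverage 1) against any container
sequence. Arguments are ordered canonically internally, so the function is
exactly symmetric. Sequences are assumed to be predicted coding sequences in
a consistent orientation; no reverse-complement comparison is attempted.

## Greedy clustering

`cluster_genes()` removes redundancy greedily: sequences are visited longest
first (ties broken by lexicographic gene id, for determinism); each sequence
joins the *first* representative it matches at identity ≥ 0.95 and
coverage ≥ 0.90 (defaults), otherwise it founds a new cluster. "First match
wins" — not best hit — is a deliberate behavioral contract matching
incremental greedy clustering semantics; the test suite verifies the result
against an independent brute-force replay over the full pairwise matrix.
The representatives form the nonredundant catalog; memberships are a
partition (disjoint and exhaustive, tested as an invariant).

`merge_gene_sets()` combines two internally nonredundant catalogs: genes of
the second set matching a representative of the first at the same thresholds
are counted as shared (reported as counts and as fractions of either set),
and the union of the first set's representatives with the second set's
non-matching representatives is re-deduplicated to produce the merged
catalog.

# Abundance profiling

Gene relative abundance is computed in two steps: counts are divided by gene
length (reads/bp), then each sample is normalized to sum to one. An
all-zero sample produces an all-zero column with a warning rather than an
error, because transect data sets occasionally contain failed libraries.

Aggregation conventions, chosen where the field has no single standard and
recorded here because they change totals:

* A gene annotated to *k* KOs contributes its **full** abundance to each of
  the *k* KOs, so KO abundances can total more than 1 per sample. Route and
  module analysis consumes per-KO presence/abundance, which this convention
  preserves; dividing by *k* would instead preserve the total.
* Genes unclassified at the requested taxonomic rank are pooled under an
  explicit `unassigned` category, never dropped, so taxon profiles still sum
  to one and conservation is testable.
* `core_fraction()` counts a feature as present at abundance strictly
  greater than zero (no minimum-abundance cutoff), and its denominator is
  the union of features observed in at least one sample — not the full
  catalog — which is the convention that makes the statistic independent of
  unobserved catalog size.

# Strain detection by pangenome recruitment

A strain is called present in a sample when strictly more than
`presence_frac` (default 0.5) of its pangenome genes have a nonzero count;
"mapped" is operationalized as count ≥ 1, as no minimum-read threshold is
part of the rule. The boundary case — exactly half the genes detected — is
*not* present, and is pinned by a test.

The abundance of a present strain is the mean of count/length over its
*detected* genes only (zero-count genes are excluded from the mean). Values
are in reads/bp and are deliberately not renormalized across strains;
comparing them across samples assumes equal sequencing depth, which the
caller must ensure.

Two limits of the method are asserted as expected behavior in the tests
rather than hidden: (i) a truly absent strain sharing more than
`presence_frac` of its genes with present strains will be called present
(recruitment cannot distinguish shared genes); (ii) presence is monotone in
reads — adding reads can never flip a strain from present to absent.

# The pathway engine

The route database (`inst/extdata/nitrogen_routes.json`) is a human-editable
JSON file validated on load: every enzyme id referenced anywhere must appear
in the controlled vocabulary, and the amino-acid table must cover the 20
proteinogenic amino acids. Primary ids are gene symbols, because the
relevant literature names enzymes (*gdhA*, *NarB*, *NirA*) rather than KO
numbers; a vocabulary column maps symbols to optional KO aliases
(`resolve_enzymes()` accepts either). The database serializes and re-parses
to an identical structure (round-trip contract, tested).

## Nitrogen-assimilation routes

Six routes are encoded for oligotrophic *Prochlorococcus* populations:
urea → ammonia (urease), nitrile → ammonia (nitrilase),
glutamine/glutamate → ammonia (*gdhA*), direct ammonium import (*amt*),
nitrite reduction (entry by nitrite/nitrate transport *or* nitroalkane
oxidation by nitronate monooxygenase, then *NirA*), and cyanate → ammonia
(cyanate lyase). Folding the nitroalkane entry into the nitrite route as a
variant — rather than counting it as a seventh route — is the only encoding
consistent with a six-route total, and is the package's settled reading.
A route is complete iff every ordered step has at least one present member.

## Nitrogen-cycle modules

Module presence (dissimilatory and assimilatory nitrate reduction,
denitrification, nitrification, nitrogen fixation, anammox) is an
intersection test between a marker OR-set and the present enzymes. This is
a detection statement, not a completeness statement — one marker suffices —
matching how module presence is reported from metagenome annotation tables.

## Amino-acid gap analysis

Each amino acid carries one or more alternative routes of ordered OR-steps;
it is `complete` iff some route is fully satisfied. For an incomplete
pathway, the reported `missing_steps` come from the route with the fewest
missing steps. Status escalates to `incomplete_with_uptake` only when a
transporter *for that amino acid* is present. Bidirectional conversion
edges (serine ↔ glycine via *glyA*; glycine ↔ threonine via *ltaE*) are
traversed from the directly imported amino acids, and reachability is
reported in a separate `importable_via` column without changing the status —
import compensation and metabolic salvage are different claims and are kept
apart.

Two encodings deserve a note. First, glycine's de novo route is encoded as
the serine pathway plus *glyA*, with *ltaE* (from threonine) as the
alternative; *glyA* alone is not a de novo route, because its serine
substrate must itself be synthesizable. Second, the curated table that the
engine ships follows the key-enzyme table convention in which *ltaE*
mediates the threonine ↔ glycine conversion and *glyA* the serine ↔ glycine
conversion; a conflicting prose formulation of the same pattern exists in
the literature, and the table was taken as authoritative. Amino acids
outside the six-gap pattern are encoded as single-step presence checks over
one representative committed enzyme each — their completeness is asserted by
the source material without reaction lists, so a deeper encoding would be
invented detail.

## Marker-KO pathway abundance

`pathway_abundance()` is the total abundance of a pathway's marker KOs
divided by the number of marker KOs — an arithmetic mean in which absent
markers count as zero. The denominator is *all* markers, not detected ones;
the statistic is therefore bounded by the maximum marker abundance and
comparable across samples with different detection patterns. Marker lists
for broad "typical pathway" panels are user-supplied; the package ships no
canned panel because published panels do not enumerate their KO lists.

# Phylogenetics

The phylogenetic stage is implemented, not delegated: `p_distance_matrix()`
computes pairwise mismatch proportions over gap-free positions of aligned,
equal-length sequences, and `nj_tree()` performs standard neighbor-joining,
returning an unrooted `phylo` tree with the conventional root trifurcation.
On additive matrices the input distances are reproduced exactly as path
lengths (tested to 1e-9 on 8-leaf trees), and topology agrees with an
independent implementation on noisy matrices. Negative branch-length
estimates — a known NJ artifact on non-additive input — are clamped to zero
and the total deficit is reported via a message. Tie-breaks in the Q-matrix
minimization take the first (column-major) minimum, making results
deterministic.

`select_marker_family()` drops members with sequence length ≤ 800 bp (short
catalog fragments carry too little signal) and picks the family with the
most survivors, ties to the lexicographically smallest id — the same rule
that selects seryl-tRNA-synthetase-type families in practice, where that
family is typically the best populated across data sources. Marker trees
are built in nucleotide space.

`assign_clade()` labels each query tip with the ecotype of its nearest
labeled reference by patristic distance, ties toward the lexicographically
smallest reference id. In simulations, planted labels are recovered at 100%
whenever between-clade divergence is at least three times the within-clade
divergence (tested).

`genome_ani()` uses reciprocal best hits over genes with a configurable
identity floor (default 0.3) and reports the mean identity of retained pairs
in percent — the standard desk-scale ANI approximation; values near 95% mark
the conventional species boundary, and values around 70% indicate a
different genus, the situation in which a mislabeled reference genome is
reassigned.

# Association statistics

`spearman_test()` computes the rank correlation on mid-ranks and obtains a
two-sided p-value by permutation: exhaustive over all n! permutations for
n ≤ 7 (exact, the default at transect-survey scale), otherwise by random
permutations with the add-one correction, seeded for reproducibility. A
permutation null was chosen over the large-sample approximation because
station counts in transect surveys are small (of order 20).

`welch_t()` wraps the unequal-variance t-test with Welch–Satterthwaite
degrees of freedom; pooled variance was rejected because oceanic station
groups (coastal vs. central) have no reason to share a variance. The
degenerate identical-constant-groups case returns t = 0, p = 1 rather than
erroring. Empirical type-I error at α = 0.05 is verified over 10⁴ null
replicates in the test suite.

# The synthetic-data module

The generator emulates exactly the statistical structure the downstream
math consumes:

* **Pangenomes** — a shared core plus private accessory genes per strain,
  uniform-random sequences, lengths uniform in a range bounded below by the
  150 bp predicted-gene floor (defaults 500–1500 bp, a realistic prokaryotic
  gene-length band).
* **Near-duplicates** — substitution-only mutation at a fixed per-site rate,
  so expected identity is analytically 1 − divergence; no indels, keeping
  the clustering oracle exact (indel robustness is exercised separately via
  containment tests in the catalog module).
* **Counts** — per sample, one multinomial draw with gene probability
  proportional to length × summed carrier abundance, modelling uniform read
  starts over shared genes. This is an assumption, not an inherited fact:
  the true depth distribution of unique-mapping reads across shared versus
  private genes is not specified by the upstream mapping procedure.
* **Environment tables** — temperature is a strictly increasing linear
  transform of a supplied taxon-abundance vector (rank correlation +1 by
  construction); salinity, pH, nutrients and chlorophyll-a are independent
  noise within plausible oligotrophic surface-water ranges (pH 7.9–8.15,
  salinity ≈ 35 PSU, nutrients at sub-micromolar means).

What the simulator does **not** model — sequencing error, chimeras, mapping
ambiguity, assembly artifacts, uneven coverage along genes, compositional
coupling between environmental variables — bounds what passing tests prove:
they validate the mathematics of the pipeline on its stated input model,
not robustness to upstream noise in real data.

# Problem sizes and numerical conventions

The test suite runs at desk scale by design: clustering oracles use tens of
sequences of 350–1000 bp; parameter-recovery simulations use 10⁵–10⁶ reads
over 30–100 genes (at 10⁶ reads the gene-level L1 recovery error is below
0.01 for a 100-gene community); calibration uses 10⁴ null replicates.
Stochastic assertions use 3-standard-deviation tolerances derived from the
relevant binomial or multinomial variance, never tuned constants.
Floating-point comparisons of permutation statistics use a 1e-12 slack to
absorb rank-arithmetic rounding. Abundance conservation is asserted to
1e-9.

# Known limitations

* Greedy clustering is order-dependent by contract; a different visiting
  order can produce a different (equally valid) partition.
* The alignment stage is quadratic per pair and the clustering stage is
  quadratic in catalog size in the worst case; the implementation targets
  method correctness at tool-validation scale, not million-gene production
  runs.
* Strain abundances are comparable across samples only at equal depth.
* The amino-acid encodings outside the six-gap pattern are single-enzyme
  proxies; they are sufficient for counting complete pathways under the
  shipped patterns but are not reaction-level reconstructions.
* ANI by reciprocal best hits over whole genes is coarser than
  fragment-based ANI; it is intended for clear-cut decisions (95% vs 70%),
  not borderline species delineation.
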