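# Declarative pathway engine: marker-KO pathway abundance, completeness
# of nitrogen-assimilation routes, nitrogen-cycle module presence and
# amino-acid biosynthesis gap analysis with transporter compensation.
#
# Route semantics: a route is an ordered list of steps, each step an
# OR-set of enzyme ids; a route is complete iff every step has at least
# one present member. An amino-acid pathway may carry several alternative
# routes and is complete iff any one of them is.

.AA_20 <- c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly", "His",
            "Ile", "Leu", "Lys", "Met", "Phe", "Pro", "Ser", "Thr", "Trp",
            "Tyr", "Val")

.steps_from_json <- function(x) lapply(x, function(s) unlist(s, use.names = FALSE))

#' Load a route database
#'
#' Reads the JSON route database describing nitrogen-assimilation routes,
#' nitrogen-cycle modules, amino-acid biosynthesis pathways, bidirectional
#' conversion edges and amino-acid transporters, and validates it: every
#' referenced enzyme must appear in the controlled vocabulary and the
#' amino-acid table must cover the 20 proteinogenic amino acids. The
#' package ships a curated database for oligotrophic surface-ocean
#' communities as its default.
#'
#' @param path Path to the JSON file; defaults to the shipped database.
#' @return An object of class `route_db`.
#' @examples
#' db <- load_route_db()
#' names(db$routes)
#' @export
load_route_db <- function(path = system.file("extdata", "nitrogen_routes.json",
                                             package = "pelagomics")) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  vocab <- vapply(raw$vocabulary,
                  function(v) if (is.null(v)) NA_character_ else as.character(v),
                  character(1))
  routes <- setNames(
    lapply(raw$routes, function(r) .steps_from_json(r$steps)),
    vapply(raw$routes, `[[`, character(1), "route_id"))
  modules <- setNames(
    lapply(raw$modules, function(m) unlist(m$markers, use.names = FALSE)),
    vapply(raw$modules, `[[`, character(1), "module_id"))
  aa <- setNames(
    lapply(raw$aa_pathways, function(p) lapply(p$routes, .steps_from_json)),
    vapply(raw$aa_pathways, `[[`, character(1), "amino_acid"))
  conversions <- lapply(raw$conversions, function(cv)
    list(enzyme = cv$enzyme, between = unlist(cv$between, use.names = FALSE)))
  transporters <- lapply(raw$transporters, function(t) unlist(t, use.names = FALSE))
  db <- structure(list(vocabulary = vocab, routes = routes, modules = modules,
                       aa_pathways = aa, conversions = conversions,
                       transporters = transporters),
                  class = "route_db")
  validate_route_db(db)
  db
}

#' Validate a route database
#'
#' Checks the vocabulary closure (every enzyme id referenced by a route,
#' module, amino-acid pathway, conversion edge or transporter set must be
#' a vocabulary entry) and that the amino-acid table covers exactly the
#' 20 proteinogenic amino acids.
#'
#' @param db A `route_db`.
#' @return `db`, invisibly; errors on violation.
#' @export
validate_route_db <- function(db) {
  stopifnot(inherits(db, "route_db"))
  referenced <- unique(c(
    unlist(db$routes, use.names = FALSE),
    unlist(db$modules, use.names = FALSE),
    unlist(db$aa_pathways, use.names = FALSE),
    vapply(db$conversions, `[[`, character(1), "enzyme"),
    unlist(db$transporters, use.names = FALSE)))
  unknown <- setdiff(referenced, names(db$vocabulary))
  if (length(unknown))
    stop("enzyme id(s) outside the controlled vocabulary: ",
         paste(unknown, collapse = ", "))
  if (!setequal(names(db$aa_pathways), .AA_20))
    stop("the amino-acid table must cover the 20 proteinogenic amino acids")
  invisible(db)
}

#' Write a route database back to JSON
#'
#' Serializes a `route_db` so that [load_route_db()] on the written file
#' reproduces an identical structure (round-trip contract).
#'
#' @param db A `route_db`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_route_db <- function(db, path) {
  stopifnot(inherits(db, "route_db"))
  wrap_steps <- function(steps) lapply(steps, I)
  raw <- list(
    vocabulary = lapply(db$vocabulary,
                        function(v) if (is.na(v)) NULL else jsonlite::unbox(v)),
    routes = lapply(names(db$routes), function(id)
      list(route_id = jsonlite::unbox(id),
           steps = wrap_steps(db$routes[[id]]))),
    modules = lapply(names(db$modules), function(id)
      list(module_id = jsonlite::unbox(id), markers = I(db$modules[[id]]))),
    aa_pathways = lapply(names(db$aa_pathways), function(aa)
      list(amino_acid = jsonlite::unbox(aa),
           routes = lapply(db$aa_pathways[[aa]], wrap_steps))),
    conversions = lapply(db$conversions, function(cv)
      list(enzyme = jsonlite::unbox(cv$enzyme), between = I(cv$between))),
    transporters = lapply(db$transporters, I))
  jsonlite::write_json(raw, path, null = "null", auto_unbox = FALSE,
                       pretty = TRUE)
  invisible(path)
}

#' Resolve enzyme ids against the vocabulary
#'
#' Accepts gene symbols (primary ids) or their KO aliases and returns the
#' corresponding symbols; unknown ids raise an error naming the offender.
#'
#' @param ids Character vector of enzyme ids or KO aliases.
#' @param db A `route_db`.
#' @return Character vector of vocabulary symbols.
#' @export
resolve_enzymes <- function(ids, db) {
  stopifnot(inherits(db, "route_db"))
  alias <- db$vocabulary[!is.na(db$vocabulary)]
  by_alias <- setNames(names(alias), alias)
  out <- ifelse(ids %in% names(db$vocabulary), ids, by_alias[ids])
  if (anyNA(out))
    stop("unknown enzyme id(s): ", paste(ids[is.na(out)], collapse = ", "))
  unique(unname(out))
}

#' Marker-KO pathway abundance
#'
#' The abundance of a pathway in each sample is the total abundance of
#' its marker KOs divided by the number of marker KOs - the arithmetic
#' mean counting absent markers as zero.
#'
#' @param ko_prof KO-level profile matrix ([ko_profile()]), KOs x samples.
#' @param pathway A list with `pathway_id` and `marker_kos` (non-empty
#'   character vector).
#' @return Named numeric vector of abundances, one per sample.
#' @export
pathway_abundance <- function(ko_prof, pathway) {
  markers <- pathway$marker_kos
  if (!length(markers))
    stop("pathway '", pathway$pathway_id, "' has an empty marker set")
  hit <- intersect(markers, rownames(ko_prof))
  tot <- if (length(hit)) colSums(ko_prof[hit, , drop = FALSE])
         else setNames(numeric(ncol(ko_prof)), colnames(ko_prof))
  tot / length(markers)
}

.route_complete <- function(steps, present) {
  all(vapply(steps, function(s) any(s %in% present), logical(1)))
}

#' Enumerate complete nitrogen-assimilation routes
#'
#' A route is complete iff every one of its ordered steps has at least
#' one present enzyme. Routes are returned in database order.
#'
#' @param present Character vector of present enzyme ids (symbols or KO
#'   aliases); unknown ids are rejected.
#' @param db A `route_db`.
#' @return Character vector of complete route ids.
#' @examples
#' db <- load_route_db()
#' enumerate_routes(c("urease", "amt"), db)
#' @export
enumerate_routes <- function(present, db) {
  stopifnot(inherits(db, "route_db"))
  present <- resolve_enzymes(present, db)
  ok <- vapply(db$routes, .route_complete, logical(1), present = present)
  names(db$routes)[ok]
}

#' Presence of nitrogen-cycle modules
#'
#' A module (dissimilatory/assimilatory nitrate reduction,
#' denitrification, nitrification, nitrogen fixation, anammox) is called
#' present iff its marker OR-set intersects the present enzyme set.
#'
#' @inheritParams enumerate_routes
#' @return Named logical vector over the database's modules.
#' @export
module_presence <- function(present, db) {
  stopifnot(inherits(db, "route_db"))
  present <- resolve_enzymes(present, db)
  vapply(db$modules, function(markers) any(markers %in% present), logical(1))
}

#' Amino-acid biosynthesis gap analysis with transporter compensation
#'
#' For each of the 20 proteinogenic amino acids, the required steps of
#' each alternative biosynthesis route are walked; the pathway is
#' `complete` iff some route has every step satisfied. An incomplete
#' pathway is flagged `incomplete_with_uptake` when a transporter for
#' that amino acid is present (compensatory import). Independently of
#' status, the bidirectional conversion edges (e.g. serine-glycine via
#' glyA) are traversed from the imported amino acids, and amino acids
#' reachable that way are annotated in `importable_via` - the route by
#' which, e.g., serine can still be obtained from imported glycine.
#'
#' @param present Character vector of present biosynthesis enzyme ids.
#' @param transporters_present Character vector of present transporter ids.
#' @param db A `route_db`.
#' @return A `data.frame` with one row per amino acid: `amino_acid`,
#'   `status` (`complete`, `incomplete`, `incomplete_with_uptake`),
#'   `missing_steps` (semicolon-joined OR-sets of the best route, empty
#'   when complete) and `importable_via` (`NA` when not applicable).
#' @export
aa_gap_analysis <- function(present, transporters_present, db) {
  stopifnot(inherits(db, "route_db"))
  present <- resolve_enzymes(present, db)
  transporters_present <- if (length(transporters_present))
    resolve_enzymes(transporters_present, db)
  else character()
  imported <- names(db$transporters)[vapply(db$transporters,
                                            function(t) any(t %in% transporters_present),
                                            logical(1))]
  reach <- .conversion_closure(imported, present, db)
  rows <- lapply(names(db$aa_pathways), function(aa) {
    routes <- db$aa_pathways[[aa]]
    missing_by_route <- lapply(routes, function(steps) {
      unsat <- !vapply(steps, function(s) any(s %in% present), logical(1))
      vapply(steps[unsat], paste, character(1), collapse = "|")
    })
    best <- missing_by_route[[which.min(lengths(missing_by_route))]]
    complete <- length(best) == 0L
    has_transporter <- any(db$transporters[[aa]] %in% transporters_present)
    status <- if (complete) "complete"
              else if (has_transporter) "incomplete_with_uptake"
              else "incomplete"
    importable <- if (!complete && aa %in% names(reach)) reach[[aa]] else NA_character_
    data.frame(amino_acid = aa, status = status,
               missing_steps = paste(best, collapse = ";"),
               importable_via = importable, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[match(.AA_20, out$amino_acid), , drop = FALSE]
}

# Breadth-first closure over bidirectional conversion edges whose enzyme
# is present, starting from directly imported amino acids. Returns a
# named list: amino acid -> human-readable provenance string.
.conversion_closure <- function(imported, present, db) {
  reach <- setNames(as.list(paste("imported via",
                                  vapply(db$transporters[imported], paste,
                                         character(1), collapse = "/"))),
                    imported)
  repeat {
    grew <- FALSE
    for (cv in db$conversions) {
      if (!cv$enzyme %in% present) next
      a <- cv$between[1L]
      b <- cv$between[2L]
      if (a %in% names(reach) && !b %in% names(reach)) {
        reach[[b]] <- paste0("from ", a, " via ", cv$enzyme)
        grew <- TRUE
      }
      if (b %in% names(reach) && !a %in% names(reach)) {
        reach[[a]] <- paste0("from ", b, " via ", cv$enzyme)
        grew <- TRUE
      }
    }
    if (!grew) break
  }
  reach
}

#' Load the shipped Indian Ocean enzyme presence/absence patterns
#'
#' Returns the published presence/absence patterns used as worked-example
#' inputs for the pathway engine: the enzyme sets observed in the
#' whole-community metagenome and in the *Prochlorococcus* population of
#' oligotrophic Indian Ocean surface waters (nitrogen-metabolism enzymes,
#' amino-acid biosynthesis key-enzyme gaps, amino-acid transporters).
#'
#' @param path Path to the JSON file; defaults to the shipped copy.
#' @return A nested list with elements `prochlorococcus_metagenome`
#'   (`present`, `aa_enzymes_absent`, `transporters`) and
#'   `community_metagenome` (`present`).
#' @export
load_enzyme_sets <- function(path = system.file("extdata",
                                                "indian_ocean_enzyme_sets.json",
                                                package = "pelagomics")) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  raw$comment <- NULL
  raw
}

#' All enzyme ids referenced by the amino-acid biosynthesis table
#' @param db A `route_db`.
#' @return Character vector of enzyme symbols.
#' @export
aa_pathway_enzymes <- function(db) {
  stopifnot(inherits(db, "route_db"))
  unique(unlist(db$aa_pathways, use.names = FALSE))
}
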