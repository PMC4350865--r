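#' Construct a merged drug knowledge base
#'
#' A knowledge base holds six entity types — drugs, drug-drug interactions,
#' side effects, drug-molecule links, pathways and diseases — merged from one
#' or more sources, with every assertion carrying its provenance (the set of
#' source tags asserting it). Most users will not call this constructor
#' directly but obtain a knowledge base from [merge_sources()] or
#' [read_kb()]; it is exported so small fixture bases can be built in code.
#'
#' @param drugs tibble with columns `drug_id`, `name` (both character),
#'   `synonyms`, `atc_codes` (list-columns of character vectors) and
#'   `source_ids` (list-column of named character vectors, source tag ->
#'   native identifier).
#' @param interactions tibble with `drug_a`, `drug_b` (canonical order:
#'   `drug_a < drug_b`), `effects` (list-column of named character vectors,
#'   source tag -> effect text), `severity` (character, `NA` allowed) and
#'   `provenance` (list-column of character vectors).
#' @param side_effects tibble with `drug_id`, `term` (canonical side-effect
#'   term), `frequency` (character, `NA` allowed) and `provenance`.
#' @param molecule_links tibble with `drug_id`, `molecule_id`,
#'   `molecule_role` (one of target/enzyme/transporter/carrier), `action`
#'   (one of inhibitor/inducer/substrate/unknown) and `provenance`.
#' @param pathways tibble with `pathway_id`, `name`, and list-columns
#'   `member_molecule_ids`, `linked_drug_ids`, `linked_disease_ids`.
#' @param diseases tibble with `disease_id`, `name`, `synonyms` (list-column).
#' @param source_tags character vector of registered source names.
#' @param synonym_table tibble with `raw`, `canonical` columns mapping raw
#'   side-effect terms to canonical ones (both stored normalized).
#' @return an object of class `drug_kb`.
#' @seealso [resolve_drug()], [suggest_drugs()], [merge_sources()]
#' @export
knowledge_base <- function(drugs = empty_drugs(),
                           interactions = empty_interactions(),
                           side_effects = empty_side_effects(),
                           molecule_links = empty_molecule_links(),
                           pathways = empty_pathways(),
                           diseases = empty_diseases(),
                           source_tags = character(),
                           synonym_table = empty_synonym_table()) {
  kb <- structure(
    list(
      drugs = as_tibble(drugs),
      interactions = as_tibble(interactions),
      side_effects = as_tibble(side_effects),
      molecule_links = as_tibble(molecule_links),
      pathways = as_tibble(pathways),
      diseases = as_tibble(diseases),
      source_tags = source_tags,
      synonym_table = as_tibble(synonym_table)
    ),
    class = "drug_kb"
  )
  kb$name_index <- build_name_index(kb$drugs)
  validate_kb(kb)
}

empty_drugs <- function() {
  tibble(drug_id = character(), name = character(),
         synonyms = list(), atc_codes = list(), source_ids = list())
}
empty_interactions <- function() {
  tibble(drug_a = character(), drug_b = character(),
         effects = list(), severity = character(), provenance = list())
}
empty_side_effects <- function() {
  tibble(drug_id = character(), term = character(),
         frequency = character(), provenance = list())
}
empty_molecule_links <- function() {
  tibble(drug_id = character(), molecule_id = character(),
         molecule_role = character(), action = character(), provenance = list())
}
empty_pathways <- function() {
  tibble(pathway_id = character(), name = character(),
         member_molecule_ids = list(), linked_drug_ids = list(),
         linked_disease_ids = list())
}
empty_diseases <- function() {
  tibble(disease_id = character(), name = character(), synonyms = list())
}
empty_synonym_table <- function() {
  tibble(raw = character(), canonical = character())
}

MOLECULE_ROLES <- c("target", "enzyme", "transporter", "carrier")
MOLECULE_ACTIONS <- c("inhibitor", "inducer", "substrate", "unknown")

build_name_index <- function(drugs) {
  if (nrow(drugs) == 0) return(tibble(key = character(), drug_id = character()))
  tibble(
    key = c(normalize_name(drugs$name),
            unlist(map(drugs$synonyms, normalize_name), use.names = FALSE)),
    drug_id = c(drugs$drug_id,
                rep(drugs$drug_id, times = map_int(drugs$synonyms, length)))
  ) |>
    filter(nzchar(.data$key)) |>
    distinct()
}

# Enforce the structural invariants of a knowledge base; returns the kb or
# aborts with the first violation found.
validate_kb <- function(kb) {
  d <- kb$drugs
  if (anyDuplicated(d$drug_id)) {
    abort(paste0("Duplicate drug_id in knowledge base: ",
                 paste(unique(d$drug_id[duplicated(d$drug_id)]), collapse = ", ")))
  }
  if (any(!nzchar(d$name) | is.na(d$name))) abort("Every drug needs a nonempty name.")
  bad_atc <- unlist(d$atc_codes)[!is_valid_atc(unlist(d$atc_codes))]
  if (length(bad_atc) > 0) {
    abort(paste0("Invalid ATC code(s): ", paste(unique(bad_atc), collapse = ", ")))
  }
  ia <- kb$interactions
  if (nrow(ia) > 0) {
    if (any(ia$drug_a >= ia$drug_b)) {
      abort("Interaction pairs must be in canonical order (drug_a < drug_b).")
    }
    if (anyDuplicated(paste(ia$drug_a, ia$drug_b))) {
      abort("Duplicate canonical interaction pair; provenance must be merged instead.")
    }
  }
  referenced <- unique(c(ia$drug_a, ia$drug_b, kb$side_effects$drug_id,
                         kb$molecule_links$drug_id))
  missing <- setdiff(referenced, d$drug_id)
  if (length(missing) > 0) {
    abort(paste0("Assertions reference unknown drug_id(s): ",
                 paste(missing, collapse = ", ")))
  }
  prov <- c(ia$provenance, kb$side_effects$provenance, kb$molecule_links$provenance)
  if (length(prov) > 0) {
    if (any(map_int(prov, length) == 0)) abort("Every assertion needs nonempty provenance.")
    unknown <- setdiff(unique(unlist(prov)), kb$source_tags)
    if (length(unknown) > 0) {
      abort(paste0("Provenance names unregistered source(s): ",
                   paste(unknown, collapse = ", ")))
    }
  }
  ml <- kb$molecule_links
  if (nrow(ml) > 0) {
    if (!all(ml$molecule_role %in% MOLECULE_ROLES)) {
      abort(paste0("molecule_role must be one of: ", paste(MOLECULE_ROLES, collapse = ", ")))
    }
    if (!all(ml$action %in% MOLECULE_ACTIONS)) {
      abort(paste0("action must be one of: ", paste(MOLECULE_ACTIONS, collapse = ", ")))
    }
  }
  if (nrow(kb$diseases) > 0 && any(!nzchar(kb$diseases$name))) {
    abort("Every disease needs a nonempty name.")
  }
  kb
}

#' @export
print.drug_kb <- function(x, ...) {
  cat("<drug_kb>", "\n")
  cat("  sources:       ", paste(x$source_tags, collapse = ", "), "\n")
  cat("  drugs:         ", nrow(x$drugs), "\n")
  cat("  interactions:  ", nrow(x$interactions), "\n")
  cat("  side effects:  ", nrow(x$side_effects), "\n")
  cat("  molecule links:", nrow(x$molecule_links), "\n")
  cat("  pathways:      ", nrow(x$pathways), "\n")
  cat("  diseases:      ", nrow(x$diseases), "\n")
  invisible(x)
}

#' Resolve a drug name, synonym or identifier to its drug_id
#'
#' Matches the query against drug identifiers first, then against the
#' normalized name/synonym index. Exactly one matching drug is required;
#' if two distinct drugs share the normalized name an ambiguity error
#' listing the candidates is raised.
#'
#' @param kb a `drug_kb`.
#' @param query a single name, synonym or drug_id.
#' @return the matching `drug_id`, or `NA_character_` if nothing matches.
#' @examples
#' kb <- knowledge_base(
#'   drugs = tibble::tibble(
#'     drug_id = "D1", name = "Clonazepam",
#'     synonyms = list(character()), atc_codes = list("N03AE01"),
#'     source_ids = list(c(PHARM = "P1"))),
#'   source_tags = "PHARM")
#' resolve_drug(kb, "clonazepam")
#' @export
resolve_drug <- function(kb, query) {
  stopifnot(inherits(kb, "drug_kb"))
  if (length(query) != 1 || is.na(query) || !nzchar(stringr::str_trim(query))) {
    abort("Query must be a single nonempty string.", class = "drugkb_bad_query")
  }
  if (query %in% kb$drugs$drug_id) return(query)
  key <- normalize_name(query)
  hits <- unique(kb$name_index$drug_id[kb$name_index$key == key])
  if (length(hits) == 0) return(NA_character_)
  if (length(hits) > 1) {
    names <- kb$drugs$name[match(hits, kb$drugs$drug_id)]
    abort(
      paste0("Ambiguous drug query '", query, "': matches ",
             paste(paste0(names, " (", hits, ")"), collapse = ", ")),
      class = "drugkb_ambiguous",
      candidates = hits
    )
  }
  hits
}

#' Suggest drug names for a prefix (auto-completion)
#'
#' @param kb a `drug_kb`.
#' @param prefix query prefix; an empty prefix returns the alphabetically
#'   first `limit` names.
#' @param limit maximum number of suggestions (>= 1).
#' @return character vector of display names, alphabetically sorted, whose
#'   normalized form starts with the normalized prefix.
#' @export
suggest_drugs <- function(kb, prefix = "", limit = 10L) {
  stopifnot(inherits(kb, "drug_kb"), limit >= 1)
  key <- normalize_name(prefix %||% "")
  names <- sort_c(unique(kb$drugs$name))
  hits <- if (nzchar(key)) {
    names[startsWith(normalize_name(names), key)]
  } else names
  head(hits, limit)
}
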