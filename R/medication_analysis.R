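#' Build a medication profile
#'
#' A profile collects everything known about one patient's medication:
#' the prescribed drugs, current diagnoses, side effects the patient has
#' actually reported, and CYP enzymes known to be defective (e.g. from a
#' metabolizer phenotype). Drug entries are resolved against the knowledge
#' base and deduplicated; unresolvable entries are kept in `unresolved`
#' with a warning rather than failing the whole profile.
#'
#' @param kb a `drug_kb`.
#' @param drugs character vector of drug names, synonyms or ids.
#' @param diagnoses character vector of disease names or ids.
#' @param observed_effects side-effect terms reported by the patient; these
#'   only annotate report findings, they never create findings.
#' @param defective_cyps molecule ids of defective CYP enzymes.
#' @return an object of class `medication_profile`.
#' @export
medication_profile <- function(kb, drugs, diagnoses = character(),
                               observed_effects = character(),
                               defective_cyps = character()) {
  stopifnot(inherits(kb, "drug_kb"))
  ids <- map_chr(drugs, function(q) {
    tryCatch(resolve_drug(kb, q), drugkb_bad_query = function(e) NA_character_)
  })
  unresolved <- drugs[is.na(ids)]
  if (length(unresolved) > 0) {
    warn(paste0("Unresolved drug entries dropped from profile: ",
                paste(unresolved, collapse = ", ")))
  }
  ids <- unique(ids[!is.na(ids)])
  structure(
    list(drug_ids = ids,
         drug_names = kb$drugs$name[match(ids, kb$drugs$drug_id)],
         diagnoses = unique(diagnoses),
         observed_effects = unique(observed_effects),
         defective_cyps = unique(defective_cyps),
         unresolved = unresolved),
    class = "medication_profile"
  )
}

#' @export
print.medication_profile <- function(x, ...) {
  cat("<medication_profile> ", length(x$drug_ids), " drugs",
      if (length(x$diagnoses)) paste0(", ", length(x$diagnoses), " diagnoses"),
      if (length(x$observed_effects))
        paste0(", ", length(x$observed_effects), " observed effects"),
      if (length(x$defective_cyps))
        paste0(", defective CYPs: ", paste(x$defective_cyps, collapse = ", ")),
      "\n", sep = "")
  invisible(x)
}

as_profile <- function(kb, profile) {
  if (inherits(profile, "medication_profile")) return(profile)
  medication_profile(kb, profile)
}

# default pair of compared sources for an assertion kind: the registered
# tags that actually assert it, in registered order
default_sources <- function(kb, kind) {
  prov <- switch(kind, interactions = kb$interactions$provenance,
                 side_effects = kb$side_effects$provenance)
  present <- kb$source_tags[kb$source_tags %in% unique(unlist(prov))]
  if (length(present) < 2) present <- kb$source_tags
  if (length(present) < 2) abort("Need two registered sources to partition by provenance.")
  present[1:2]
}

new_provenance_partition <- function(center_id, center_label, kind,
                                     source_a, source_b, items) {
  structure(
    list(center_id = center_id, center_label = center_label, kind = kind,
         source_a = source_a, source_b = source_b,
         shared = items$label[items$part == "shared"],
         only_a = items$label[items$part == "only_a"],
         only_b = items$label[items$part == "only_b"],
         items = items),
    class = "provenance_partition"
  )
}

#' @export
print.provenance_partition <- function(x, ...) {
  cat("<provenance_partition> ", x$kind, " of ", x$center_label, "\n",
      "  shared (", x$source_a, "+", x$source_b, "): ",
      paste(x$shared, collapse = ", "), "\n",
      "  ", x$source_a, " only: ", paste(x$only_a, collapse = ", "), "\n",
      "  ", x$source_b, " only: ", paste(x$only_b, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.provenance_partition <- function(x, ...) x$items

#' @export
glance.provenance_partition <- function(x, ...) {
  tibble(center = x$center_label, kind = x$kind,
         source_a = x$source_a, source_b = x$source_b,
         n_shared = length(x$shared), n_only_a = length(x$only_a),
         n_only_b = length(x$only_b))
}

#' @export
autoplot.provenance_partition <- function(object, ...) {
  autoplot(build_radial_network(object, NULL), ...)
}

#' Interaction partners of a single drug, partitioned by source agreement
#'
#' Collects all interaction partners of one drug and splits them into
#' partners asserted by both compared sources, by the first only, and by
#' the second only — the three rings of the radial result view. Each part
#' is sorted alphabetically by partner name.
#'
#' @param kb a `drug_kb`.
#' @param drug drug name, synonym or id.
#' @param sources length-2 character vector of compared source tags;
#'   defaults to the two registered sources asserting interactions.
#' @return a `provenance_partition` with fields `shared`, `only_a`,
#'   `only_b` (partner display names) and an `items` tibble.
#' @export
single_drug_interactions <- function(kb, drug, sources = NULL) {
  id <- resolve_drug(kb, drug)
  if (is.na(id)) abort(paste0("Unknown drug: ", drug), class = "drugkb_not_found")
  sources <- sources %||% default_sources(kb, "interactions")
  ia <- kb$interactions
  hit <- ia$drug_a == id | ia$drug_b == id
  partner <- ifelse(ia$drug_a[hit] == id, ia$drug_b[hit], ia$drug_a[hit])
  items <- partition_items(
    id = partner,
    label = kb$drugs$name[match(partner, kb$drugs$drug_id)],
    prov = ia$provenance[hit], sources = sources
  )
  new_provenance_partition(id, kb$drugs$name[match(id, kb$drugs$drug_id)],
                           "interactions", sources[1], sources[2], items)
}

partition_items <- function(id, label, prov, sources) {
  part <- map_chr(prov, function(p) {
    has_a <- sources[1] %in% p; has_b <- sources[2] %in% p
    if (has_a && has_b) "shared"
    else if (has_a) "only_a"
    else if (has_b) "only_b"
    else NA_character_
  })
  items <- tibble(item_id = as.character(id), label = as.character(label),
                  part = part) |>
    filter(!is.na(.data$part)) |>
    distinct(.data$label, .keep_all = TRUE)
  items[order(items$part, items$label, method = "radix"), , drop = FALSE]
}

#' Pairwise drug-drug interactions within a medication
#'
#' Returns exactly the knowledge-base interactions whose canonical pair is
#' contained in the profile drugs, in canonical pair order. A profile with
#' fewer than two drugs yields an empty result with a notice (not an error).
#'
#' @param kb a `drug_kb`.
#' @param profile a `medication_profile` or character vector of drug
#'   names/ids.
#' @return tibble of interaction assertions with partner names attached.
#' @export
combined_drug_interactions <- function(kb, profile) {
  profile <- as_profile(kb, profile)
  if (length(profile$drug_ids) < 2) {
    inform("Fewer than two resolvable drugs in profile; no pairwise check possible.")
    return(mutate(empty_interactions(), name_a = character(), name_b = character()))
  }
  kb$interactions |>
    filter(.data$drug_a %in% profile$drug_ids, .data$drug_b %in% profile$drug_ids) |>
    mutate(name_a = kb$drugs$name[match(.data$drug_a, kb$drugs$drug_id)],
           name_b = kb$drugs$name[match(.data$drug_b, kb$drugs$drug_id)]) |>
    arrange(.data$drug_a, .data$drug_b)
}

#' Molecule interaction partners of a drug
#'
#' Lists the drug's molecule links (targets, enzymes, transporters,
#' carriers) grouped in fixed role order target, enzyme, transporter,
#' carrier, each group sorted by molecule id.
#'
#' @param kb a `drug_kb`.
#' @param drug drug name, synonym or id.
#' @return tibble with `molecule_id`, `molecule_role` (factor in role
#'   order), `action`, `provenance`.
#' @export
drug_molecule_interactions <- function(kb, drug) {
  id <- resolve_drug(kb, drug)
  if (is.na(id)) abort(paste0("Unknown drug: ", drug), class = "drugkb_not_found")
  kb$molecule_links |>
    filter(.data$drug_id == id) |>
    mutate(molecule_role = factor(.data$molecule_role, levels = MOLECULE_ROLES)) |>
    arrange(.data$molecule_role, .data$molecule_id, .data$action) |>
    select("molecule_id", "molecule_role", "action", "provenance")
}

#' CYP-mediated dosage flags for a medication
#'
#' Screens every ordered pair of profile drugs for cytochrome-P450
#' perpetrator/victim constellations. If one drug induces an enzyme through
#' which another profile drug is metabolized, the victim's clearance rises
#' and its dosage may need to be raised to stay therapeutic; if it inhibits
#' the enzyme, clearance falls and the dosage may be lowered. A defective
#' CYP listed in the profile flags every profile drug metabolized by it as
#' at risk. Flags are advisory annotations, not dose computations.
#'
#' @param kb a `drug_kb`.
#' @param profile a `medication_profile` (or drug name vector).
#' @return tibble with `perpetrator`, `cyp`, `victim`, `direction`
#'   (`raise_dose`, `lower_dose` or `risk`) and `rationale`.
#' @export
cyp_dosage_flags <- function(kb, profile) {
  profile <- as_profile(kb, profile)
  ml <- filter(kb$molecule_links, .data$drug_id %in% profile$drug_ids,
               .data$molecule_role == "enzyme")
  nm <- function(id) kb$drugs$name[match(id, kb$drugs$drug_id)]
  flags <- list()
  add <- function(p, m, v, dir, why) {
    flags[[length(flags) + 1]] <<- tibble(perpetrator = p, cyp = m, victim = v,
                                          direction = dir, rationale = why)
  }
  subs <- filter(ml, .data$action == "substrate")
  for (act in c("inducer", "inhibitor")) {
    perp <- filter(ml, .data$action == act)
    if (nrow(perp) == 0 || nrow(subs) == 0) next
    hits <- dplyr::inner_join(perp, subs, by = "molecule_id",
                              suffix = c("_p", "_v"), relationship = "many-to-many") |>
      filter(.data$drug_id_p != .data$drug_id_v)
    for (k in seq_len(nrow(hits))) {
      p <- hits$drug_id_p[k]; v <- hits$drug_id_v[k]; m <- hits$molecule_id[k]
      if (act == "inducer") {
        add(p, m, v, "raise_dose",
            paste0(nm(p), " induces ", m, ", which metabolizes ", nm(v),
                   "; the victim drug's dosage may need to be raised to keep a therapeutic effect."))
      } else {
        add(p, m, v, "lower_dose",
            paste0(nm(p), " inhibits ", m, ", which metabolizes ", nm(v),
                   "; the victim drug's dosage may be reduced, which also decreases side effects."))
      }
    }
  }
  known_cyps <- unique(kb$molecule_links$molecule_id[kb$molecule_links$molecule_role == "enzyme"])
  for (d in profile$defective_cyps) {
    if (!(d %in% known_cyps)) {
      warn(paste0("Defective CYP '", d, "' is not a known enzyme molecule; skipped."))
      next
    }
    vics <- unique(subs$drug_id[subs$molecule_id == d])
    for (v in vics) {
      add(v, d, v, "risk",
          paste0(nm(v), " is metabolized by the defective enzyme ", d,
                 "; accumulation and adverse reactions are possible."))
    }
  }
  out <- if (length(flags)) bind_rows(flags) else
    tibble(perpetrator = character(), cyp = character(), victim = character(),
           direction = character(), rationale = character())
  out[order(out$direction, out$perpetrator, out$cyp, out$victim, method = "radix"), ]
}

#' Side effects of a single drug, partitioned by source agreement
#'
#' @param kb a `drug_kb`.
#' @param drug drug name, synonym or id.
#' @param sources length-2 character vector of compared source tags;
#'   defaults to the two registered sources asserting side effects.
#' @return a `provenance_partition` of canonical side-effect terms.
#' @export
single_drug_side_effects <- function(kb, drug, sources = NULL) {
  id <- resolve_drug(kb, drug)
  if (is.na(id)) abort(paste0("Unknown drug: ", drug), class = "drugkb_not_found")
  sources <- sources %||% default_sources(kb, "side_effects")
  se <- filter(kb$side_effects, .data$drug_id == id)
  items <- partition_items(id = rep(NA_character_, nrow(se)), label = se$term,
                           prov = se$provenance, sources = sources)
  new_provenance_partition(id, kb$drugs$name[match(id, kb$drugs$drug_id)],
                           "side_effects", sources[1], sources[2], items)
}

#' Cumulative side effects of a medication
#'
#' A cumulative side effect is a canonical term asserted for at least two
#' of the profile's drugs; its occurrence probability grows with the number
#' of drugs sharing it. A drug counts once per term regardless of how many
#' sources assert it.
#'
#' @param kb a `drug_kb`.
#' @param profile a `medication_profile` (or drug name vector).
#' @return tibble with `term`, `drug_ids` (list-column), `drug_names`
#'   (list-column) and `n_drugs` (>= 2), sorted by term.
#' @export
cumulative_side_effects <- function(kb, profile) {
  profile <- as_profile(kb, profile)
  kb$side_effects |>
    filter(.data$drug_id %in% profile$drug_ids) |>
    distinct(.data$term, .data$drug_id) |>
    group_by(.data$term) |>
    summarise(drug_ids = list(sort_c(.data$drug_id)), n_drugs = n(), .groups = "drop") |>
    filter(.data$n_drugs >= 2) |>
    mutate(drug_names = map(.data$drug_ids, function(ids) {
      kb$drugs$name[match(ids, kb$drugs$drug_id)]
    })) |>
    select("term", "drug_ids", "drug_names", "n_drugs") |>
    arrange(.data$term)
}

#' Screen diagnoses for drug-induced diseases
#'
#' A diagnosis is a drug-induced disease candidate when its normalized name
#' (or any synonym of the matching disease record, or its canonical form
#' under the side-effect synonym table) equals a canonical side-effect term
#' of at least one profile drug. Candidates matched by two or more drugs
#' form the cumulative subset — for these, the disease could have been
#' promoted by several drugs at once. Matching is exact on normalized
#' terms.
#'
#' @param kb a `drug_kb`.
#' @param profile a `medication_profile` with diagnoses.
#' @return object of class `induced_disease_screen`: `matches` tibble
#'   (`diagnosis`, `drug_ids`, `drug_names`, `n_drugs`, `cumulative`),
#'   `fraction` of diagnoses flagged, and `unresolved` diagnosis strings
#'   absent from the disease catalogue (reported, not fatal).
#' @export
drug_induced_diseases <- function(kb, profile) {
  profile <- as_profile(kb, profile)
  if (length(profile$diagnoses) == 0) {
    abort("Profile has no diagnoses to screen.", class = "drugkb_bad_query")
  }
  se <- kb$side_effects |>
    filter(.data$drug_id %in% profile$drug_ids) |>
    distinct(.data$term, .data$drug_id)
  dz_keys <- map(seq_len(nrow(kb$diseases)), function(i) {
    unique(normalize_name(c(kb$diseases$name[i], kb$diseases$synonyms[[i]])))
  })
  rows <- list(); unresolved <- character()
  for (dx in profile$diagnoses) {
    keys <- normalize_name(dx)
    hit_dz <- which(kb$diseases$disease_id == dx |
                      map_lgl(dz_keys, function(k) keys %in% k))
    if (length(hit_dz) > 0) {
      keys <- unique(c(keys, unlist(dz_keys[hit_dz])))
    } else {
      unresolved <- c(unresolved, dx)
    }
    keys <- unique(as.character(canonicalize_term(keys, kb$synonym_table)))
    drugs <- sort_c(unique(se$drug_id[se$term %in% keys]))
    if (length(drugs) > 0) {
      rows[[length(rows) + 1]] <- tibble(
        diagnosis = dx, drug_ids = list(drugs),
        drug_names = list(kb$drugs$name[match(drugs, kb$drugs$drug_id)]),
        n_drugs = length(drugs), cumulative = length(drugs) >= 2)
    }
  }
  matches <- if (length(rows)) bind_rows(rows) else
    tibble(diagnosis = character(), drug_ids = list(), drug_names = list(),
           n_drugs = integer(), cumulative = logical())
  structure(
    list(matches = arrange(matches, .data$diagnosis),
         fraction = nrow(matches) / length(profile$diagnoses),
         unresolved = unresolved),
    class = "induced_disease_screen"
  )
}

#' @export
print.induced_disease_screen <- function(x, ...) {
  cat("<induced_disease_screen> ", nrow(x$matches), " drug-induced candidate(s), ",
      sum(x$matches$cumulative), " cumulative; fraction of diagnoses flagged: ",
      format(round(x$fraction, 4)), "\n", sep = "")
  invisible(x)
}

#' Map drugs of one source onto a metabolic pathway
#'
#' Resolves a pathway by id or normalized name and returns the drugs of the
#' chosen source linked to it, total hit counts for the remaining sources,
#' and the diseases linked to the pathway.
#'
#' @param kb a `drug_kb`.
#' @param query pathway id or name.
#' @param source source tag whose drugs are listed in full.
#' @return object of class `pathway_network`: `pathway_id`, `name`,
#'   `drugs` tibble (chosen source), `other_counts` named vector of hit
#'   counts per remaining source, `diseases` tibble.
#' @export
pathway_network <- function(kb, query, source) {
  stopifnot(inherits(kb, "drug_kb"))
  if (!source %in% kb$source_tags) abort(paste0("Unknown source tag: ", source))
  hit <- which(kb$pathways$pathway_id == query)
  if (length(hit) == 0) hit <- which(normalize_name(kb$pathways$name) == normalize_name(query))
  if (length(hit) == 0) abort(paste0("Unknown pathway: ", query), class = "drugkb_not_found")
  if (length(hit) > 1) {
    abort(paste0("Ambiguous pathway query '", query, "': matches ",
                 paste(kb$pathways$pathway_id[hit], collapse = ", ")),
          class = "drugkb_ambiguous", candidates = kb$pathways$pathway_id[hit])
  }
  pw <- kb$pathways[hit, ]
  linked <- pw$linked_drug_ids[[1]]
  d <- kb$drugs[match(linked, kb$drugs$drug_id), ]
  has_tag <- function(tag) map_lgl(d$source_ids, function(s) tag %in% names(s))
  chosen <- d[has_tag(source), c("drug_id", "name")]
  others <- setdiff(kb$source_tags, source)
  other_counts <- setNames(map_int(others, function(t) sum(has_tag(t))), others)
  dz <- kb$diseases[match(pw$linked_disease_ids[[1]], kb$diseases$disease_id), ]
  structure(
    list(pathway_id = pw$pathway_id, name = pw$name, source = source,
         drugs = arrange(as_tibble(chosen), .data$name),
         other_counts = other_counts,
         diseases = as_tibble(dz[!is.na(dz$disease_id), c("disease_id", "name")])),
    class = "pathway_network"
  )
}

#' @export
print.pathway_network <- function(x, ...) {
  cat("<pathway_network> ", x$name, " (", x$pathway_id, ")\n",
      "  drugs from ", x$source, ": ", paste(x$drugs$name, collapse = ", "), "\n",
      "  other sources: ",
      paste(paste0(names(x$other_counts), "=", x$other_counts), collapse = ", "), "\n",
      "  diseases: ", paste(x$diseases$name, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Molecular medication analysis
#'
#' The composite risk check of a whole medication: pairwise drug-drug
#' interactions, CYP dosage flags, cumulative side effects, and (when the
#' profile carries diagnoses) drug-induced disease screening, in a single
#' report. Profile drugs appearing in no finding are listed as drugs
#' without potential risks. Observed side effects in the profile are
#' annotated with the profile drugs known to cause them; they never create
#' findings on their own.
#'
#' @param kb a `drug_kb`.
#' @param profile a `medication_profile` (or drug name vector); must
#'   contain at least one resolvable drug.
#' @return object of class `medication_report` with elements `profile`,
#'   `interactions`, `cyp_flags`, `cumulative_effects`, `induced_diseases`
#'   (or `NULL`), `observed_explained`, `no_risk_drugs`.
#' @export
molecular_medication_analysis <- function(kb, profile) {
  profile <- as_profile(kb, profile)
  if (length(profile$drug_ids) == 0) {
    abort("Profile contains no resolvable drugs.", class = "drugkb_bad_query")
  }
  interactions <- if (length(profile$drug_ids) >= 2) {
    combined_drug_interactions(kb, profile)
  } else {
    mutate(empty_interactions(), name_a = character(), name_b = character())
  }
  flags <- cyp_dosage_flags(kb, profile)
  cumulative <- cumulative_side_effects(kb, profile)
  induced <- if (length(profile$diagnoses) > 0) drug_induced_diseases(kb, profile) else NULL

  se <- kb$side_effects |>
    filter(.data$drug_id %in% profile$drug_ids) |>
    distinct(.data$term, .data$drug_id)
  observed_explained <- tibble(
    effect = profile$observed_effects,
    term = as.character(canonicalize_term(profile$observed_effects, kb$synonym_table))
  ) |>
    mutate(drug_ids = map(.data$term, function(t) sort_c(unique(se$drug_id[se$term == t]))),
           explained = map_int(.data$drug_ids, length) > 0)

  at_risk <- unique(c(
    interactions$drug_a, interactions$drug_b,
    flags$perpetrator, flags$victim,
    unlist(cumulative$drug_ids),
    if (!is.null(induced)) unlist(induced$matches$drug_ids)
  ))
  no_risk <- setdiff(profile$drug_ids, at_risk)
  structure(
    list(profile = profile, interactions = interactions, cyp_flags = flags,
         cumulative_effects = cumulative, induced_diseases = induced,
         observed_explained = observed_explained,
         no_risk_drugs = tibble(
           drug_id = sort_c(no_risk),
           name = kb$drugs$name[match(sort_c(no_risk), kb$drugs$drug_id)])),
    class = "medication_report"
  )
}

#' @export
tidy.medication_report <- function(x, ...) {
  out <- bind_rows(
    if (nrow(x$interactions) > 0) tibble(
      finding = "interaction",
      subject = x$interactions$name_a, object = x$interactions$name_b,
      detail = map_chr(x$interactions$provenance, paste, collapse = "+")),
    if (nrow(x$cyp_flags) > 0) {
      nm <- function(id) {
        i <- match(id, x$profile$drug_ids)
        ifelse(is.na(i), id, x$profile$drug_names[i])
      }
      tibble(finding = paste0("cyp_", x$cyp_flags$direction),
             subject = nm(x$cyp_flags$perpetrator),
             object = nm(x$cyp_flags$victim),
             detail = x$cyp_flags$cyp)
    },
    if (nrow(x$cumulative_effects) > 0) tibble(
      finding = "cumulative_side_effect",
      subject = map_chr(x$cumulative_effects$drug_names, paste, collapse = "+"),
      object = x$cumulative_effects$term,
      detail = paste0(x$cumulative_effects$n_drugs, " drugs")),
    if (!is.null(x$induced_diseases) && nrow(x$induced_diseases$matches) > 0) tibble(
      finding = "induced_disease",
      subject = map_chr(x$induced_diseases$matches$drug_names, paste, collapse = "+"),
      object = x$induced_diseases$matches$diagnosis,
      detail = ifelse(x$induced_diseases$matches$cumulative, "cumulative", "single"))
  )
  if (ncol(out) == 0) {
    out <- tibble(finding = character(), subject = character(),
                  object = character(), detail = character())
  }
  out
}

#' @export
glance.medication_report <- function(x, ...) {
  tibble(
    n_drugs = length(x$profile$drug_ids),
    n_interactions = nrow(x$interactions),
    n_cyp_flags = nrow(x$cyp_flags),
    n_cumulative_effects = nrow(x$cumulative_effects),
    n_induced_diseases = if (is.null(x$induced_diseases)) NA_integer_ else
      nrow(x$induced_diseases$matches),
    induced_fraction = if (is.null(x$induced_diseases)) NA_real_ else
      x$induced_diseases$fraction,
    n_no_risk = nrow(x$no_risk_drugs))
}

#' @export
autoplot.medication_report <- function(object, ...) {
  autoplot(build_radial_network(object, NULL), ...)
}

#' @export
print.medication_report <- function(x, ...) {
  cat("<medication_report> for ", length(x$profile$drug_ids), " drugs\n", sep = "")
  cat("  pairwise interactions: ", nrow(x$interactions), "\n", sep = "")
  if (nrow(x$interactions) > 0) {
    for (k in seq_len(nrow(x$interactions))) {
      cat("    - ", x$interactions$name_a[k], " <-> ", x$interactions$name_b[k],
          " [", paste(x$interactions$provenance[[k]], collapse = ","), "]\n", sep = "")
    }
  }
  cat("  CYP dosage flags: ", nrow(x$cyp_flags), "\n", sep = "")
  if (nrow(x$cyp_flags) > 0) {
    for (k in seq_len(nrow(x$cyp_flags))) {
      cat("    - [", x$cyp_flags$direction[k], "] ", x$cyp_flags$rationale[k], "\n", sep = "")
    }
  }
  cat("  cumulative side effects: ", nrow(x$cumulative_effects), "\n", sep = "")
  if (nrow(x$cumulative_effects) > 0) {
    for (k in seq_len(nrow(x$cumulative_effects))) {
      cat("    - ", x$cumulative_effects$term[k], " (",
          paste(x$cumulative_effects$drug_names[[k]], collapse = ", "), ")\n", sep = "")
    }
  }
  if (!is.null(x$induced_diseases)) {
    cat("  drug-induced disease candidates: ", nrow(x$induced_diseases$matches),
        " (fraction of diagnoses: ", format(round(x$induced_diseases$fraction, 4)),
        ")\n", sep = "")
  }
  cat("  drugs without potential risks: ",
      paste(x$no_risk_drugs$name, collapse = ", "), "\n", sep = "")
  invisible(x)
}
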