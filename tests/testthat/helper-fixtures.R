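# Hand-built fixture knowledge base used across the unit tests. Small enough
# that every expected value can be read off the tables by eye or recomputed
# with the brute-force oracles below.
make_fixture_kb <- function() {
  lst <- function(...) list(c(...))
  drugs <- dplyr::bind_rows(
    tibble::tibble(drug_id = "D1", name = "Clonazepam", synonyms = list(character()),
                   atc_codes = list("N03AE01"), source_ids = lst(PHARM = "P1", MOLDB = "M1")),
    tibble::tibble(drug_id = "D2", name = "Clopidogrel", synonyms = list(character()),
                   atc_codes = list("B01AC04"), source_ids = lst(PHARM = "P2", MOLDB = "M2")),
    tibble::tibble(drug_id = "D3", name = "Aspirin",
                   synonyms = list(c("ASS", "Acetylsalicylic acid")),
                   atc_codes = list("N02BA01"), source_ids = lst(PHARM = "P3", MOLDB = "M3")),
    tibble::tibble(drug_id = "D4", name = "Atenolol", synonyms = list(character()),
                   atc_codes = list("C07AB03"), source_ids = lst(PHARM = "P4", MOLDB = "M4")),
    tibble::tibble(drug_id = "D5", name = "Zolpidem", synonyms = list(character()),
                   atc_codes = list("N05CF02"), source_ids = lst(PHARM = "P5", SEDB = "S5"))
  )
  ia <- function(a, b, prov) {
    tibble::tibble(drug_a = a, drug_b = b,
                   effects = list(stats::setNames(rep("effect", length(prov)), prov)),
                   severity = NA_character_, provenance = list(prov))
  }
  interactions <- dplyr::bind_rows(
    ia("D1", "D2", "PHARM"), ia("D1", "D3", "MOLDB"),
    ia("D1", "D4", c("MOLDB", "PHARM")), ia("D2", "D3", c("MOLDB", "PHARM")),
    ia("D4", "D5", "PHARM"))
  se <- function(d, term, prov, freq = NA_character_) {
    tibble::tibble(drug_id = d, term = term, frequency = freq, provenance = list(prov))
  }
  side_effects <- dplyr::bind_rows(
    se("D1", "nausea", c("PHARM", "SEDB")), se("D1", "headache", "PHARM"),
    se("D1", "dizziness", "SEDB"), se("D2", "nausea", "SEDB"),
    se("D3", "nausea", "PHARM"), se("D3", "rash", "PHARM"),
    se("D4", "headache", "SEDB"), se("D4", "hypertension", "SEDB"))
  ml <- function(d, m, role, action) {
    tibble::tibble(drug_id = d, molecule_id = m, molecule_role = role,
                   action = action, provenance = list("MOLDB"))
  }
  molecule_links <- dplyr::bind_rows(
    ml("D1", "CYP3A4", "enzyme", "substrate"),
    ml("D2", "CYP3A4", "enzyme", "inducer"),
    ml("D3", "CYP2C9", "enzyme", "inhibitor"),
    ml("D4", "CYP2C9", "enzyme", "substrate"),
    ml("D1", "TARGET_01", "target", "unknown"),
    ml("D3", "PGP1", "transporter", "substrate"))
  pathways <- tibble::tibble(
    pathway_id = "PW1", name = "Drug metabolism",
    member_molecule_ids = list(c("CYP2C9", "CYP3A4")),
    linked_drug_ids = list(c("D1", "D3", "D5")),
    linked_disease_ids = list("Z1"))
  diseases <- dplyr::bind_rows(
    tibble::tibble(disease_id = "Z1", name = "Hypertension", synonyms = list(character())),
    tibble::tibble(disease_id = "Z2", name = "Nausea", synonyms = list("sickness")))
  knowledge_base(
    drugs = drugs, interactions = interactions, side_effects = side_effects,
    molecule_links = molecule_links, pathways = pathways, diseases = diseases,
    source_tags = c("PHARM", "MOLDB", "SEDB"),
    synonym_table = tibble::tibble(raw = c("emesis", "vomiting", "sickness"),
                                   canonical = c("vomiting", "vomiting", "nausea")))
}

# Random fixture knowledge base built directly from tables (not via ingest),
# for property-style comparisons against the brute-force oracles.
make_random_kb <- function(n_drugs = 40, seed = 1) {
  withr::with_seed(seed, {
    ids <- sprintf("D%03d", seq_len(n_drugs))
    drugs <- tibble::tibble(
      drug_id = ids, name = sprintf("Randdrug%03d", seq_len(n_drugs)),
      synonyms = replicate(n_drugs, character(), simplify = FALSE),
      atc_codes = replicate(n_drugs, character(), simplify = FALSE),
      source_ids = lapply(ids, function(i) c(PHARM = i)))
    pick_prov <- function(pool) {
      sort(sample(pool, sample.int(length(pool), 1)))
    }
    pairs <- t(combn(ids, 2))
    take <- sample(nrow(pairs), min(4 * n_drugs, nrow(pairs)))
    interactions <- tibble::tibble(
      drug_a = pairs[take, 1], drug_b = pairs[take, 2],
      effects = replicate(length(take), c(PHARM = "x"), simplify = FALSE),
      severity = NA_character_,
      provenance = replicate(length(take), pick_prov(c("MOLDB", "PHARM")),
                             simplify = FALSE))
    terms <- c("nausea", "headache", "rash", "fatigue", "seizure", "anaemia",
               "vomiting", "dizziness")
    se_keys <- expand.grid(drug_id = ids, term = terms, stringsAsFactors = FALSE)
    se_take <- sample(nrow(se_keys), 5 * n_drugs)
    side_effects <- tibble::tibble(
      drug_id = se_keys$drug_id[se_take], term = se_keys$term[se_take],
      frequency = NA_character_,
      provenance = replicate(length(se_take), pick_prov(c("PHARM", "SEDB")),
                             simplify = FALSE))
    cyps <- c("CYP3A4", "CYP2D6", "CYP2C9")
    ml_keys <- expand.grid(drug_id = ids, molecule_id = cyps, stringsAsFactors = FALSE)
    ml_take <- sample(nrow(ml_keys), 2 * n_drugs)
    molecule_links <- tibble::tibble(
      drug_id = ml_keys$drug_id[ml_take], molecule_id = ml_keys$molecule_id[ml_take],
      molecule_role = "enzyme",
      action = sample(c("substrate", "inducer", "inhibitor"), length(ml_take),
                      replace = TRUE),
      provenance = replicate(length(ml_take), "MOLDB", simplify = FALSE))
    diseases <- tibble::tibble(
      disease_id = sprintf("Z%02d", seq_along(terms)),
      name = c("Nausea", "Headache", "Rash", "Fatigue", "Seizure", "Anaemia",
               "Vomiting", "Dizziness"),
      synonyms = replicate(length(terms), character(), simplify = FALSE))
    knowledge_base(
      drugs = drugs, interactions = interactions, side_effects = side_effects,
      molecule_links = molecule_links, diseases = diseases,
      source_tags = c("MOLDB", "PHARM", "SEDB"),
      synonym_table = tibble::tibble(raw = c("emesis", "vomiting"),
                                     canonical = c("vomiting", "vomiting")))
  })
}

# ---- brute-force oracles: plain row scans, independent of the package's
# dplyr pipelines ----

oracle_combined <- function(kb, ids) {
  found <- list()
  ids <- sort(ids)
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (i >= j) next
      for (r in seq_len(nrow(kb$interactions))) {
        if (kb$interactions$drug_a[r] == min(ids[i], ids[j]) &&
            kb$interactions$drug_b[r] == max(ids[i], ids[j])) {
          found[[length(found) + 1]] <- c(kb$interactions$drug_a[r],
                                          kb$interactions$drug_b[r])
        }
      }
    }
  }
  if (length(found) == 0) return(character())
  keys <- vapply(found, paste, "", collapse = "|")
  sort(unique(keys))
}

oracle_cumulative <- function(kb, ids) {
  out <- stats::setNames(list(), character())
  for (term in sort(unique(kb$side_effects$term))) {
    contributing <- character()
    for (r in seq_len(nrow(kb$side_effects))) {
      if (kb$side_effects$term[r] == term && kb$side_effects$drug_id[r] %in% ids) {
        contributing <- union(contributing, kb$side_effects$drug_id[r])
      }
    }
    if (length(contributing) >= 2) out[[term]] <- sort(contributing)
  }
  out
}

oracle_cyp_flags <- function(kb, profile) {
  ml <- kb$molecule_links
  has_link <- function(d, m, act) {
    any(ml$drug_id == d & ml$molecule_id == m & ml$molecule_role == "enzyme" &
          ml$action == act)
  }
  mols <- unique(ml$molecule_id[ml$molecule_role == "enzyme"])
  keys <- character()
  for (p in profile$drug_ids) for (v in profile$drug_ids) {
    if (p == v) next
    for (m in mols) {
      if (has_link(p, m, "inducer") && has_link(v, m, "substrate")) {
        keys <- c(keys, paste(p, m, v, "raise_dose"))
      }
      if (has_link(p, m, "inhibitor") && has_link(v, m, "substrate")) {
        keys <- c(keys, paste(p, m, v, "lower_dose"))
      }
    }
  }
  for (d in profile$defective_cyps) {
    if (!(d %in% mols)) next
    for (v in profile$drug_ids) {
      if (has_link(v, d, "substrate")) keys <- c(keys, paste(v, d, v, "risk"))
    }
  }
  sort(unique(keys))
}

oracle_induced <- function(kb, profile) {
  canon <- function(x) {
    key <- normalize_name(x)
    i <- match(key, kb$synonym_table$raw)
    ifelse(is.na(i), key, kb$synonym_table$canonical[i])
  }
  out <- stats::setNames(list(), character())
  for (dx in profile$diagnoses) {
    keys <- normalize_name(dx)
    for (r in seq_len(nrow(kb$diseases))) {
      if (kb$diseases$disease_id[r] == dx ||
          normalize_name(kb$diseases$name[r]) == keys ||
          keys %in% normalize_name(kb$diseases$synonyms[[r]])) {
        keys <- unique(c(keys, normalize_name(kb$diseases$name[r]),
                         normalize_name(kb$diseases$synonyms[[r]])))
      }
    }
    keys <- unique(canon(keys))
    drugs <- character()
    for (r in seq_len(nrow(kb$side_effects))) {
      if (kb$side_effects$drug_id[r] %in% profile$drug_ids &&
          kb$side_effects$term[r] %in% keys) {
        drugs <- union(drugs, kb$side_effects$drug_id[r])
      }
    }
    if (length(drugs) > 0) out[[dx]] <- sort(drugs)
  }
  out
}

# Write a tiny source directory; `tables` is a named list of data frames,
# names become "<file>.tsv".
write_source_dir <- function(dir, tables) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(tables)) {
    readr::write_tsv(tables[[nm]], file.path(dir, paste0(nm, ".tsv")), na = "",
                     progress = FALSE)
  }
  dir
}
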