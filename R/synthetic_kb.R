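# 50-term MedDRA-like side-effect vocabulary with fixed synonym pairs.
# Terms are stored normalized (lower case); synonyms map raw -> canonical.
SE_TERMS <- c(
  "nausea", "vomiting", "headache", "dizziness", "fatigue", "insomnia",
  "somnolence", "diarrhoea", "constipation", "dyspepsia", "abdominal pain",
  "rash", "pruritus", "urticaria", "alopecia", "dry mouth", "tremor",
  "anxiety", "depression", "confusion", "hallucination", "hypertension",
  "hypotension", "tachycardia", "bradycardia", "arrhythmia", "oedema",
  "weight gain", "weight loss", "anorexia", "myalgia", "arthralgia",
  "back pain", "cough", "dyspnoea", "bronchospasm", "epistaxis",
  "tinnitus", "blurred vision", "dysgeusia", "fever", "chills",
  "sweating", "flushing", "syncope", "seizure", "paraesthesia",
  "anaemia", "thrombocytopenia", "hepatotoxicity"
)
SE_SYNONYMS <- c(
  "emesis" = "vomiting", "cephalalgia" = "headache", "vertigo" = "dizziness",
  "tiredness" = "fatigue", "sleeplessness" = "insomnia",
  "drowsiness" = "somnolence", "loose stools" = "diarrhoea",
  "indigestion" = "dyspepsia", "stomach ache" = "abdominal pain",
  "itching" = "pruritus", "hives" = "urticaria", "hair loss" = "alopecia",
  "xerostomia" = "dry mouth", "high blood pressure" = "hypertension",
  "low blood pressure" = "hypotension", "swelling" = "oedema",
  "loss of appetite" = "anorexia", "muscle pain" = "myalgia",
  "joint pain" = "arthralgia", "shortness of breath" = "dyspnoea",
  "nosebleed" = "epistaxis", "ringing in ears" = "tinnitus",
  "taste disturbance" = "dysgeusia", "pyrexia" = "fever",
  "perspiration" = "sweating", "fainting" = "syncope",
  "convulsion" = "seizure", "pins and needles" = "paraesthesia"
)
CYP_IDS <- c("CYP1A2", "CYP2B6", "CYP2C9", "CYP2C19", "CYP2D6", "CYP3A4")

#' Parameters for the synthetic source generator
#'
#' Bundles and validates the knobs of [generate_sources()]. The defaults
#' describe the integration setting the package targets: four sources with
#' broad but incomplete drug coverage, an interaction concordance of 12%
#' and a side-effect concordance of 9% between the paired sources, frequent
#' synonym usage in the MedDRA-style source, and a fifth of cross-source
#' drugs lacking shared identifiers (so ATC or name mapping must step in).
#'
#' @param n_drugs total distinct drugs in the universe.
#' @param coverage named fractions of the universe covered per source tag
#'   (PHARM, MOLDB, SEDB, PATHDB).
#' @param overlap_fraction_interactions,overlap_fraction_side_effects
#'   fraction of each assertion universe asserted by both paired sources;
#'   planted as exact counts `floor(fraction * n)`.
#' @param n_interactions,n_side_effects number of distinct interaction /
#'   side-effect hits across both paired sources (union size).
#' @param n_molecules,n_pathways,n_diseases entity counts.
#' @param synonym_rate fraction of side-effect mentions in the MedDRA-style
#'   source written as a raw synonym instead of the canonical term.
#' @param mapping_noise fraction of PHARM/MOLDB shared drugs lacking a
#'   shared identifier, forcing ATC-based mapping.
#' @param seed integer random seed; everything is reproducible from it.
#' @return a validated `generator_params` list.
#' @export
generator_params <- function(n_drugs = 150,
                             coverage = c(PHARM = 0.8, MOLDB = 0.9,
                                          SEDB = 0.7, PATHDB = 0.3),
                             overlap_fraction_interactions = 0.12,
                             overlap_fraction_side_effects = 0.09,
                             n_interactions = 200,
                             n_side_effects = 300,
                             n_molecules = 12,
                             n_pathways = 6,
                             n_diseases = 12,
                             synonym_rate = 0.3,
                             mapping_noise = 0.2,
                             seed = 1L) {
  p <- list(n_drugs = as.integer(n_drugs), coverage = coverage,
            overlap_fraction_interactions = overlap_fraction_interactions,
            overlap_fraction_side_effects = overlap_fraction_side_effects,
            n_interactions = as.integer(n_interactions),
            n_side_effects = as.integer(n_side_effects),
            n_molecules = as.integer(n_molecules),
            n_pathways = as.integer(n_pathways),
            n_diseases = as.integer(n_diseases),
            synonym_rate = synonym_rate, mapping_noise = mapping_noise,
            seed = as.integer(seed))
  fr <- c(p$coverage, p$overlap_fraction_interactions,
          p$overlap_fraction_side_effects, p$synonym_rate, p$mapping_noise)
  if (any(fr < 0 | fr > 1)) abort("All fractions must lie in [0, 1].")
  if (any(c(p$n_drugs, p$n_interactions, p$n_side_effects, p$n_molecules,
            p$n_pathways, p$n_diseases) < 0)) {
    abort("All counts must be >= 0.")
  }
  if (!all(c("PHARM", "MOLDB", "SEDB", "PATHDB") %in% names(p$coverage))) {
    abort("coverage must name the four source tags PHARM, MOLDB, SEDB, PATHDB.")
  }
  structure(p, class = "generator_params")
}

# run code under a seed without disturbing the caller's RNG stream
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# deterministic, collision-free 7-character ATC code for universe index i
atc_for_index <- function(i) {
  i <- i - 1L
  d2 <- i %% 100L; i <- i %/% 100L
  l2 <- i %% 26L; i <- i %/% 26L
  l1 <- i %% 26L; i <- i %/% 26L
  d1 <- i %% 100L; i <- i %/% 100L
  a <- i %% 26L
  sprintf("%s%02d%s%s%02d", LETTERS[a + 1L], d1, LETTERS[l1 + 1L],
          LETTERS[l2 + 1L], d2)
}

# split the non-shared remainder of a hit universe into per-source
# exclusive counts (the pharmaceutical-style source gets the larger half)
split_exclusive <- function(n_union, shared) {
  rem <- n_union - shared
  a_only <- ceiling(rem / 2)
  c(a_only = a_only, b_only = rem - a_only)
}

# Assign provenance parts to n hits under exact budgets: `shared` hits in
# both sources, the rest split between the exclusives. The first
# length(planted) rows prefer their requested part; if its budget is gone
# they fall back to whichever budget remains (the hit still exists, only
# its provenance display differs).
assign_parts <- function(n, shared, planted = character()) {
  ex <- split_exclusive(n, shared)
  budget <- c(shared = shared, a_only = unname(ex["a_only"]),
              b_only = unname(ex["b_only"]))
  out <- character(n)
  take <- function(pref) {
    p <- if (budget[[pref]] > 0) pref else names(budget)[budget > 0][1]
    budget[[p]] <<- budget[[p]] - 1
    p
  }
  for (k in seq_len(n)) {
    out[k] <- take(if (k <= length(planted)) planted[k] else "shared")
  }
  out
}

#' Generate the four synthetic source file sets
#'
#' Writes a complete, internally consistent set of source files in the
#' package's TSV dialects: a pharmaceutical interaction/side-effect source
#' (`PHARM`), a molecular drug source with drug-molecule links (`MOLDB`),
#' a MedDRA-style side-effect source (`SEDB`) and a pathway/disease source
#' (`PATHDB`), plus `synonyms.tsv`, a `config.yaml` ready for
#' [build_kb_from_config()], a `params.yaml` echo and `ground_truth.json`.
#' Cross-source overlap is planted by exact counts, so recovered
#' intersection counts can be checked exactly, and a demo medication
#' profile with known expected findings (at least two pairwise
#' interactions, one cumulative side effect, one CYP inducer/substrate
#' pair, one drug-induced disease) is embedded. Identical parameters and
#' seed produce byte-identical files.
#'
#' @param params a [generator_params()] object.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the ground-truth list (also written as JSON).
#' @export
generate_sources <- function(params = generator_params(), out_dir) {
  stopifnot(inherits(params, "generator_params"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  gt <- with_local_seed(params$seed, build_synthetic(params))
  write_synthetic(gt, params, out_dir)
  invisible(gt)
}

build_synthetic <- function(p) {
  n <- p$n_drugs
  idx <- seq_len(n)
  uname <- sprintf("Drug%04d", idx)
  atc <- atc_for_index(idx)

  members <- map(p$coverage, function(f) sort(sample(idx, floor(f * n))))
  both_pm <- intersect(members$PHARM, members$MOLDB)
  # side-effect hits are planted on drugs covered by the molecular source as
  # well: the pharmaceutical and MedDRA-style sources are linked through it,
  # so only such drugs can fuse across all three
  both_ps <- intersect(intersect(members$PHARM, members$SEDB), members$MOLDB)
  demo_pool <- intersect(both_pm, members$SEDB)
  if (length(demo_pool) < 7) {
    abort("Unsatisfiable params: fewer than 7 drugs shared by PHARM, MOLDB and SEDB.")
  }
  demo <- sort(sample(demo_pool, 7))

  # --- interactions: distinct unordered pairs over PHARM/MOLDB shared drugs
  shared_ia <- floor(p$overlap_fraction_interactions * p$n_interactions)
  if (p$n_interactions > 0) {
    if (p$n_interactions < 2) {
      abort("Unsatisfiable params: need n_interactions = 0 or >= 2 (two demo pairs are planted).")
    }
    if (choose(length(both_pm), 2) < p$n_interactions) {
      abort("Unsatisfiable params: interaction universe smaller than n_interactions.")
    }
    # plant two demo pairs first: one dual-provenance, one PHARM-only
    planted <- tibble(i = c(demo[1], demo[3]), j = c(demo[2], demo[4]))
    pool_i <- rep(both_pm, each = length(both_pm))
    pool_j <- rep(both_pm, times = length(both_pm))
    ok <- pool_i < pool_j & !(paste(pool_i, pool_j) %in% paste(planted$i, planted$j))
    pick <- sample(which(ok), p$n_interactions - 2)
    interactions <- bind_rows(planted, tibble(i = pool_i[pick], j = pool_j[pick]))
    interactions$part <- assign_parts(p$n_interactions, shared_ia,
                                      planted = c("shared", "a_only"))
    interactions$effect <- sprintf("Combined use of %s and %s may alter drug response.",
                                   uname[interactions$i], uname[interactions$j])
    interactions$severity <- sample(c("minor", "moderate", "severe"),
                                    nrow(interactions), replace = TRUE)
  } else {
    interactions <- tibble(i = integer(), j = integer(), part = character(),
                           effect = character(), severity = character())
  }

  # --- side effects: distinct (drug, canonical term) hits over PHARM/SEDB drugs
  shared_se <- floor(p$overlap_fraction_side_effects * p$n_side_effects)
  if (p$n_side_effects > 0) {
    if (p$n_side_effects < 3) {
      abort("Unsatisfiable params: need n_side_effects = 0 or >= 3 (three demo hits are planted).")
    }
    if (length(both_ps) * length(SE_TERMS) < p$n_side_effects) {
      abort("Unsatisfiable params: side-effect universe smaller than n_side_effects.")
    }
    # plant: a cumulative term for demo drugs 1 and 5, and a term equal to a
    # disease name for demo drug 2
    planted_se <- tibble(d = c(demo[1], demo[5], demo[2]),
                         term = c("hypertension", "hypertension", "seizure"))
    pool_d <- rep(both_ps, each = length(SE_TERMS))
    pool_t <- rep(SE_TERMS, times = length(both_ps))
    ok <- !(paste(pool_d, pool_t) %in% paste(planted_se$d, planted_se$term))
    pick <- sample(which(ok), p$n_side_effects - 3)
    side_effects <- bind_rows(planted_se, tibble(d = pool_d[pick], term = pool_t[pick]))
    side_effects$part <- assign_parts(p$n_side_effects, shared_se,
                                      planted = c("shared", "shared", "a_only"))
    side_effects$frequency <- sample(c("very common", "common", "uncommon", "rare"),
                                     nrow(side_effects), replace = TRUE)
  } else {
    side_effects <- tibble(d = integer(), term = character(), part = character(),
                           frequency = character())
  }

  # --- molecules and drug-molecule links (MOLDB only)
  mol_ids <- c(CYP_IDS, sprintf("TARGET_%02d", seq_len(max(p$n_molecules - length(CYP_IDS), 0))))
  mol_ids <- head(mol_ids, max(p$n_molecules, 2))
  links <- tibble(d = integer(), molecule_id = character(),
                  molecule_role = character(), action = character())
  if (p$n_molecules > 0 && length(members$MOLDB) > 0) {
    # plant the demo perpetrator/victim pair on CYP3A4
    links <- bind_rows(
      tibble(d = demo[6], molecule_id = "CYP3A4", molecule_role = "enzyme",
             action = "inducer"),
      tibble(d = demo[7], molecule_id = "CYP3A4", molecule_role = "enzyme",
             action = "substrate")
    )
    extra_d <- sample(members$MOLDB, min(3 * length(mol_ids), length(members$MOLDB)),
                      replace = FALSE)
    extra <- tibble(
      d = extra_d,
      molecule_id = sample(mol_ids, length(extra_d), replace = TRUE),
      molecule_role = ifelse(startsWith(sample(mol_ids, length(extra_d), replace = TRUE), "CYP"),
                             "enzyme", "target"),
      action = sample(c("substrate", "inhibitor", "unknown"), length(extra_d),
                      replace = TRUE)
    )
    extra$molecule_role <- ifelse(startsWith(extra$molecule_id, "CYP"), "enzyme", "target")
    extra$action <- ifelse(extra$molecule_role == "target", "unknown", extra$action)
    links <- distinct(bind_rows(links, extra), .data$d, .data$molecule_id,
                      .data$molecule_role, .data$action)
    # keep the planted CYP3A4 relationship unambiguous for the demo drugs
    links <- filter(links, !(.data$d %in% c(demo[6], demo[7]) &
                               .data$molecule_id == "CYP3A4" &
                               !(paste(.data$d, .data$action) %in%
                                   paste(c(demo[6], demo[7]), c("inducer", "substrate")))))
  }

  # --- diseases (PATHDB): first few named after side-effect terms so
  # drug-induced disease screening can fire; the rest synthetic
  n_dz <- p$n_diseases
  dz_terms <- head(c("hypertension", "seizure", "depression", "anaemia"), n_dz)
  dz_names <- c(stringr::str_to_title(dz_terms),
                sprintf("Synthetic disease %02d", seq_len(max(n_dz - length(dz_terms), 0))))
  diseases <- tibble(native_id = sprintf("DIS_%02d", seq_len(n_dz)),
                     name = head(dz_names, n_dz))

  # --- pathways (PATHDB): members from the molecule list, drugs from the
  # PATHDB drug table, diseases from the disease table
  pathways <- tibble(pathway_id = character(), name = character(),
                     member_molecules = list(), drugs = list(), diseases = list())
  if (p$n_pathways > 0 && length(members$PATHDB) > 0) {
    pathways <- bind_rows(map(seq_len(p$n_pathways), function(k) {
      dset <- sort(sample(members$PATHDB, min(4, length(members$PATHDB))))
      tibble(pathway_id = sprintf("path_%03d", k),
             name = sprintf("Synthetic pathway %03d", k),
             member_molecules = list(sort_c(sample(mol_ids, min(3, length(mol_ids))))),
             drugs = list(sprintf("K%04d", dset)),
             diseases = list(if (n_dz > 0) {
               sort_c(sample(diseases$native_id, min(2, n_dz)))
             } else character()))
    }))
  }

  list(
    params = p, idx = idx, uname = uname, atc = atc, members = members,
    both_pm = both_pm, both_ps = both_ps, demo = demo,
    interactions = interactions, side_effects = side_effects,
    molecule_links = links, diseases = diseases, pathways = pathways,
    counts = list(
      interactions = list(
        a_only = sum(interactions$part == "a_only"),
        b_only = sum(interactions$part == "b_only"),
        shared = sum(interactions$part == "shared"),
        union = nrow(interactions)),
      side_effects = list(
        a_only = sum(side_effects$part == "a_only"),
        b_only = sum(side_effects$part == "b_only"),
        shared = sum(side_effects$part == "shared"),
        union = nrow(side_effects))
    )
  )
}

write_synthetic <- function(gt, p, out_dir) {
  uname <- gt$uname; atc <- gt$atc; members <- gt$members
  pid <- function(i) sprintf("P%04d", i)
  mid <- function(i) sprintf("MB%04d", i)
  sid <- function(i) sprintf("S%04d", i)
  kid <- function(i) sprintf("K%04d", i)
  wt <- function(df, file) {
    readr::write_tsv(df, file.path(out_dir, file), na = "", progress = FALSE)
  }

  # identifier gaps: a fixed fraction of PHARM/MOLDB shared drugs carries no
  # cross-reference and must be recovered through ATC codes
  n_noise <- floor(p$mapping_noise * length(gt$both_pm))
  noisy <- head(gt$both_pm, n_noise)
  xref_for <- function(i) {
    ifelse(i %in% gt$both_pm & !(i %in% noisy), paste0("moldb:", mid(i)), "")
  }

  wt(tibble(native_id = pid(members$PHARM), name = uname[members$PHARM],
            synonyms = "", atc_codes = atc[members$PHARM],
            xrefs = xref_for(members$PHARM)), "PHARM_drugs.tsv")
  wt(tibble(native_id = mid(members$MOLDB), name = uname[members$MOLDB],
            synonyms = "", atc_codes = atc[members$MOLDB], xrefs = ""),
     "MOLDB_drugs.tsv")
  wt(tibble(native_id = sid(members$SEDB), name = uname[members$SEDB],
            synonyms = "", atc_codes = "", xrefs = ""), "SEDB_drugs.tsv")
  wt(tibble(native_id = kid(members$PATHDB), name = uname[members$PATHDB],
            synonyms = "", atc_codes = "",
            xrefs = ifelse(members$PATHDB %in% members$MOLDB,
                           paste0("moldb:", mid(members$PATHDB)), "")),
     "PATHDB_drugs.tsv")

  ia <- gt$interactions
  wt(tibble(native_id_a = pid(ia$i[ia$part != "b_only"]),
            native_id_b = pid(ia$j[ia$part != "b_only"]),
            effect = ia$effect[ia$part != "b_only"],
            severity = ia$severity[ia$part != "b_only"]),
     "PHARM_interactions.tsv")
  wt(tibble(native_id_a = mid(ia$i[ia$part != "a_only"]),
            native_id_b = mid(ia$j[ia$part != "a_only"]),
            effect = ia$effect[ia$part != "a_only"],
            severity = ia$severity[ia$part != "a_only"]),
     "MOLDB_interactions.tsv")

  se <- gt$side_effects
  pharm_se <- se[se$part != "b_only", , drop = FALSE]
  wt(tibble(native_id = pid(pharm_se$d), term = pharm_se$term,
            frequency = pharm_se$frequency), "PHARM_side_effects.tsv")
  sedb_se <- se[se$part != "a_only", , drop = FALSE]
  # a fixed fraction of MedDRA-style mentions uses a raw synonym
  syn_of <- function(term) {
    hits <- names(SE_SYNONYMS)[SE_SYNONYMS == term]
    if (length(hits) == 0) term else hits[1]
  }
  n_syn <- floor(p$synonym_rate * nrow(sedb_se))
  use_syn <- seq_len(nrow(sedb_se)) <= n_syn
  wt(tibble(native_id = sid(sedb_se$d),
            term = ifelse(use_syn, map_chr(sedb_se$term, syn_of), sedb_se$term),
            frequency = sedb_se$frequency), "SEDB_side_effects.tsv")

  ml <- gt$molecule_links
  wt(tibble(native_id = mid(ml$d), molecule_id = ml$molecule_id,
            molecule_role = ml$molecule_role, action = ml$action),
     "MOLDB_molecule_links.tsv")

  pw <- gt$pathways
  wt(tibble(pathway_id = pw$pathway_id, name = pw$name,
            member_molecules = join_pipe(pw$member_molecules),
            drugs = join_pipe(pw$drugs),
            diseases = join_pipe(pw$diseases)), "PATHDB_pathways.tsv")
  wt(tibble(native_id = gt$diseases$native_id, name = gt$diseases$name,
            synonyms = ""), "PATHDB_diseases.tsv")

  wt(tibble(raw_term = names(SE_SYNONYMS),
            canonical_term = unname(SE_SYNONYMS)), "synonyms.tsv")

  demo_truth <- NULL
  if (p$n_interactions > 0 && p$n_side_effects > 0 && p$n_molecules > 0) {
    demo_truth <- list(
      drugs = uname[gt$demo],
      observed_effects = c("hypertension", "nausea"),
      diagnoses = c("Seizure", "Synthetic disease 01"),
      defective_cyps = character(),
      expected = list(
        min_interactions = 2,
        # planted findings the report must contain (random hits may add more
        # contributing drugs, hence "must include" semantics)
        interaction_pairs = list(
          sort_c(uname[c(gt$demo[1], gt$demo[2])]),
          sort_c(uname[c(gt$demo[3], gt$demo[4])])
        ),
        cumulative_term = "hypertension",
        cumulative_drugs_include = sort_c(uname[c(gt$demo[1], gt$demo[5])]),
        cyp_flag = list(perpetrator = uname[gt$demo[6]], cyp = "CYP3A4",
                        victim = uname[gt$demo[7]], direction = "raise_dose"),
        induced_disease = list(diagnosis = "Seizure",
                               drugs_include = uname[gt$demo[2]])
      )
    )
  }
  truth <- list(
    mapping_pharm_moldb = list(id_a = pid(gt$both_pm), id_b = mid(gt$both_pm)),
    mapping_moldb_sedb = list(id_a = mid(intersect(members$MOLDB, members$SEDB)),
                              id_b = sid(intersect(members$MOLDB, members$SEDB))),
    counts = gt$counts,
    demo_profile = demo_truth
  )
  jsonlite::write_json(truth, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  yaml::write_yaml(unclass(p), file.path(out_dir, "params.yaml"))
  # paths are relative to the config file so the file set is relocatable
  # (and byte-identical for identical params and seed)
  yaml::write_yaml(list(
    sources = list(PHARM = ".", MOLDB = ".", SEDB = ".", PATHDB = "."),
    mappings = list(
      list(a = "PHARM", b = "MOLDB", method = "atc_and_identifier"),
      list(a = "MOLDB", b = "PATHDB", method = "atc_and_identifier"),
      list(a = "MOLDB", b = "SEDB", method = "name")
    ),
    synonyms = "synonyms.tsv",
    rounding = "two_decimal"
  ), file.path(out_dir, "config.yaml"))
  invisible(truth)
}

#' Read the ground truth written next to a generated file set
#'
#' @param dir directory passed to [generate_sources()].
#' @return the ground-truth list.
#' @export
read_ground_truth <- function(dir) {
  jsonlite::read_json(file.path(dir, "ground_truth.json"), simplifyVector = TRUE,
                      simplifyMatrix = FALSE)
}

#' Demo medication profile for a generated knowledge base
#'
#' Builds the seven-drug profile embedded by [generate_sources()]: it
#' carries at least two planted pairwise interactions, one planted
#' cumulative side effect, one planted CYP inducer/substrate pair, two
#' observed side effects and two diagnoses (one of which is a planted
#' drug-induced disease). Expected findings are recorded in the ground
#' truth.
#'
#' @param kb the `drug_kb` ingested from the generated file set.
#' @param ground_truth list from [read_ground_truth()] (or the return value
#'   of [generate_sources()]).
#' @return a `medication_profile`.
#' @export
demo_profile <- function(kb, ground_truth) {
  d <- ground_truth$demo_profile
  if (is.null(d) || length(d$drugs) == 0) {
    abort(paste0("No demo profile in ground truth; the generator needs nonzero ",
                 "side-effect and interaction counts to plant one."))
  }
  medication_profile(kb, drugs = d$drugs, diagnoses = d$diagnoses,
                     observed_effects = d$observed_effects,
                     defective_cyps = d$defective_cyps %||% character())
}
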