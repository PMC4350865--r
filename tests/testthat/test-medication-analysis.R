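test_that("single-drug interactions partition partners by provenance", {
  kb <- make_fixture_kb()
  part <- single_drug_interactions(kb, "Clonazepam", sources = c("PHARM", "MOLDB"))
  # oracle: scan all assertions containing D1 and inspect provenance
  expect_equal(part$shared, "Atenolol")
  expect_equal(part$only_a, "Clopidogrel")
  expect_equal(part$only_b, "Aspirin")
  # each part sorted alphabetically
  part4 <- single_drug_interactions(kb, "Atenolol", sources = c("PHARM", "MOLDB"))
  expect_equal(part4$only_a, sort(part4$only_a))
  expect_error(single_drug_interactions(kb, "Qwertymab"), class = "drugkb_not_found")
  # a drug with no interactions yields three empty parts
  kb_lone <- knowledge_base(drugs = kb$drugs, source_tags = kb$source_tags)
  lone <- single_drug_interactions(kb_lone, "Zolpidem", sources = c("PHARM", "MOLDB"))
  expect_equal(lengths(lone[c("shared", "only_a", "only_b")]),
               c(shared = 0L, only_a = 0L, only_b = 0L))
})

test_that("combined interactions return exactly the in-profile pairs", {
  kb <- make_fixture_kb()
  # oracle: test all C(3,2) pairs of {D1,D2,D3} against the KB
  got <- combined_drug_interactions(kb, c("Clonazepam", "Clopidogrel", "Aspirin"))
  expect_equal(paste(got$drug_a, got$drug_b, sep = "|"),
               oracle_combined(kb, c("D1", "D2", "D3")))
  # single-drug profile: empty result with a notice, not an error
  expect_message(one <- combined_drug_interactions(kb, "Aspirin"), "Fewer than two")
  expect_equal(nrow(one), 0)
  # dual provenance preserved on the dedup'd assertion
  both <- combined_drug_interactions(kb, c("Clonazepam", "Atenolol"))
  expect_equal(nrow(both), 1)
  expect_setequal(both$provenance[[1]], c("MOLDB", "PHARM"))
  # invariant under permutation of the drug list
  perm <- combined_drug_interactions(kb, c("Aspirin", "Clonazepam", "Clopidogrel"))
  expect_equal(got, perm)
})

test_that("molecule links come grouped in fixed role order", {
  kb <- make_fixture_kb()
  got <- drug_molecule_interactions(kb, "Aspirin")
  expect_equal(as.character(got$molecule_role), c("enzyme", "transporter"))
  got1 <- drug_molecule_interactions(kb, "Clonazepam")
  expect_equal(as.character(got1$molecule_role), c("target", "enzyme"))
  expect_equal(got1$molecule_id, c("TARGET_01", "CYP3A4"))
  expect_equal(nrow(drug_molecule_interactions(kb, "Zolpidem")), 0)
})

test_that("CYP flags cover induction, inhibition and defective enzymes", {
  kb <- make_fixture_kb()
  prof <- medication_profile(kb, c("Clonazepam", "Clopidogrel", "Aspirin", "Atenolol"))
  flags <- cyp_dosage_flags(kb, prof)
  expect_setequal(
    paste(flags$perpetrator, flags$cyp, flags$victim, flags$direction),
    oracle_cyp_flags(kb, prof))
  # D2 induces CYP3A4, D1 is a substrate: raise the victim's dose
  expect_true(any(flags$perpetrator == "D2" & flags$victim == "D1" &
                    flags$direction == "raise_dose"))
  # D3 inhibits CYP2C9, D4 is a substrate: lower the victim's dose
  expect_true(any(flags$perpetrator == "D3" & flags$victim == "D4" &
                    flags$direction == "lower_dose"))
  # defective CYP flags each substrate drug in the profile
  prof2 <- medication_profile(kb, "Clonazepam", defective_cyps = "CYP3A4")
  flags2 <- cyp_dosage_flags(kb, prof2)
  expect_equal(nrow(flags2), 1)
  expect_equal(flags2$direction, "risk")
  expect_equal(flags2$victim, "D1")
  # unknown defective CYP: warning, entry skipped
  prof3 <- medication_profile(kb, "Clonazepam", defective_cyps = "CYP9Z9")
  expect_warning(flags3 <- cyp_dosage_flags(kb, prof3), "not a known enzyme")
  expect_equal(nrow(flags3), 0)
})

test_that("single-drug side effects canonicalize and partition terms", {
  kb <- make_fixture_kb()
  part <- single_drug_side_effects(kb, "Clonazepam", sources = c("PHARM", "SEDB"))
  expect_equal(part$shared, "nausea")
  expect_equal(part$only_a, "headache")
  expect_equal(part$only_b, "dizziness")
  expect_equal(part$only_a, sort(part$only_a))
})

test_that("cumulative side effects need at least two contributing drugs", {
  kb <- make_fixture_kb()
  got <- cumulative_side_effects(kb, c("Clonazepam", "Clopidogrel", "Aspirin"))
  # oracle: term-indexed count over all profile assertions
  exp <- oracle_cumulative(kb, c("D1", "D2", "D3"))
  expect_equal(got$term, names(exp))
  expect_equal(got$drug_ids, unname(lapply(exp, identity)))
  expect_true(all(got$n_drugs >= 2))
  # single-drug profile: threshold unreachable
  expect_equal(nrow(cumulative_side_effects(kb, "Clonazepam")), 0)
  # a drug counts once even when two sources assert the same term
  expect_equal(got$drug_ids[got$term == "nausea"][[1]], c("D1", "D2", "D3"))
})

test_that("drug-induced disease screening matches diagnoses to terms", {
  kb <- make_fixture_kb()
  prof <- medication_profile(kb, c("Atenolol", "Clonazepam"),
                             diagnoses = c("Hypertension", "sickness", "Gout"))
  got <- drug_induced_diseases(kb, prof)
  exp <- oracle_induced(kb, prof)
  expect_equal(got$matches$diagnosis, sort(names(exp)))
  expect_equal(got$matches$drug_ids,
               unname(lapply(exp[sort(names(exp))], identity)))
  # "sickness" is a synonym of the disease "Nausea", whose name matches the
  # canonical term nausea asserted for Clonazepam
  expect_true("sickness" %in% got$matches$diagnosis)
  expect_equal(got$fraction, 2 / 3)
  expect_true("Gout" %in% got$unresolved)
  # no diagnoses: explicit error
  expect_error(drug_induced_diseases(kb, medication_profile(kb, "Aspirin")),
               class = "drugkb_bad_query")
  # no overlap: empty result, zero fraction
  none <- drug_induced_diseases(kb, medication_profile(kb, "Zolpidem",
                                                       diagnoses = "Gout"))
  expect_equal(nrow(none$matches), 0)
  expect_equal(none$fraction, 0)
})

test_that("pathway networks list the chosen source's drugs plus hit counts", {
  kb <- make_fixture_kb()
  pn <- pathway_network(kb, "drug METABOLISM", source = "MOLDB")
  # oracle: filter linked drugs by source membership; sorted by name
  expect_setequal(pn$drugs$drug_id, c("D1", "D3"))  # D5 has no MOLDB id
  expect_equal(pn$drugs$name, c("Aspirin", "Clonazepam"))
  expect_equal(unname(pn$other_counts["PHARM"]), 3L)
  expect_equal(unname(pn$other_counts["SEDB"]), 1L)
  expect_equal(pn$diseases$name, "Hypertension")
  expect_error(pathway_network(kb, "no such pathway", "MOLDB"),
               class = "drugkb_not_found")
  expect_error(pathway_network(kb, "PW1", "NOPE"), "Unknown source")
})

test_that("the composite report agrees with its components", {
  kb <- make_fixture_kb()
  prof <- medication_profile(kb, c("Clonazepam", "Clopidogrel", "Aspirin", "Atenolol"),
                             diagnoses = "Hypertension",
                             observed_effects = c("emesis", "nausea"))
  rep <- molecular_medication_analysis(kb, prof)
  expect_equal(rep$interactions, combined_drug_interactions(kb, prof))
  expect_equal(rep$cyp_flags, cyp_dosage_flags(kb, prof))
  expect_equal(rep$cumulative_effects, cumulative_side_effects(kb, prof))
  expect_equal(rep$induced_diseases$matches, drug_induced_diseases(kb, prof)$matches)
  # observed "nausea" is explained (three profile drugs cause it), "emesis"
  # canonicalizes to vomiting which no profile drug causes
  expect_true(rep$observed_explained$explained[rep$observed_explained$effect == "nausea"])
  expect_false(rep$observed_explained$explained[rep$observed_explained$effect == "emesis"])
  expect_error(molecular_medication_analysis(kb, medication_profile(kb, character())),
               class = "drugkb_bad_query")
})

test_that("drugs with no findings land on the no-risk list", {
  kb <- make_fixture_kb()
  rep1 <- suppressMessages(molecular_medication_analysis(kb, "Zolpidem"))
  expect_equal(rep1$no_risk_drugs$name, "Zolpidem")
  rep2 <- molecular_medication_analysis(kb, c("Clonazepam", "Atenolol"))
  expect_false("Clonazepam" %in% rep2$no_risk_drugs$name)
})

test_that("operations match brute-force scans on random profiles", {
  kb <- make_random_kb(n_drugs = 40, seed = 11)
  withr::with_seed(99, {
    for (k in seq_len(30)) {
      ids <- sample(kb$drugs$drug_id, sample(2:7, 1))
      prof <- medication_profile(kb, ids,
                                 diagnoses = sample(kb$diseases$name, 2),
                                 defective_cyps = sample(c("CYP3A4", "CYP2D6"), 1))
      got_ia <- combined_drug_interactions(kb, prof)
      expect_equal(paste(got_ia$drug_a, got_ia$drug_b, sep = "|"),
                   oracle_combined(kb, ids))
      got_cum <- cumulative_side_effects(kb, prof)
      exp_cum <- oracle_cumulative(kb, ids)
      expect_equal(got_cum$term, names(exp_cum))
      got_cyp <- cyp_dosage_flags(kb, prof)
      expect_setequal(paste(got_cyp$perpetrator, got_cyp$cyp, got_cyp$victim,
                            got_cyp$direction),
                      oracle_cyp_flags(kb, prof))
      got_ind <- drug_induced_diseases(kb, prof)
      expect_equal(got_ind$matches$diagnosis, sort(names(oracle_induced(kb, prof))))
    }
  })
})

test_that("adding a drug to a profile never removes findings", {
  kb <- make_random_kb(n_drugs = 30, seed = 5)
  withr::with_seed(7, {
    for (k in seq_len(10)) {
      ids <- sample(kb$drugs$drug_id, 4)
      extra <- sample(setdiff(kb$drugs$drug_id, ids), 1)
      small <- combined_drug_interactions(kb, ids)
      big <- combined_drug_interactions(kb, c(ids, extra))
      expect_true(all(paste(small$drug_a, small$drug_b) %in%
                        paste(big$drug_a, big$drug_b)))
      small_c <- cumulative_side_effects(kb, ids)
      big_c <- cumulative_side_effects(kb, c(ids, extra))
      expect_true(all(small_c$term %in% big_c$term))
    }
  })
})
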