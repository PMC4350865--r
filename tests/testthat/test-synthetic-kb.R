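test_that("generator parameters are validated", {
  expect_error(generator_params(synonym_rate = 1.5), "fractions")
  expect_error(generator_params(n_interactions = -1), "counts")
  expect_s3_class(generator_params(), "generator_params")
})

test_that("same seed gives byte-identical files; different seeds differ", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir(); d3 <- withr::local_tempdir()
  p <- generator_params(n_drugs = 60, n_interactions = 40, n_side_effects = 50,
                        seed = 5)
  generate_sources(p, d1)
  generate_sources(p, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f), warn = FALSE),
                     readLines(file.path(d2, f), warn = FALSE), label = f)
  }
  generate_sources(generator_params(n_drugs = 60, n_interactions = 40,
                                    n_side_effects = 50, seed = 6), d3)
  expect_false(identical(readLines(file.path(d1, "PHARM_interactions.tsv")),
                         readLines(file.path(d3, "PHARM_interactions.tsv"))))
})

test_that("planted overlap counts are recovered exactly from emitted files", {
  dir <- withr::local_tempdir()
  generate_sources(generator_params(seed = 3), dir)
  truth <- read_ground_truth(dir)
  # oracle: recount hits straight from the emitted TSVs
  ph <- readr::read_tsv(file.path(dir, "PHARM_interactions.tsv"),
                        show_col_types = FALSE)
  mo <- readr::read_tsv(file.path(dir, "MOLDB_interactions.tsv"),
                        show_col_types = FALSE)
  idx <- function(x) as.integer(substring(x, nchar(x) - 3))
  key <- function(a, b) paste(pmin(idx(a), idx(b)), pmax(idx(a), idx(b)))
  a_set <- key(ph$native_id_a, ph$native_id_b)
  b_set <- key(mo$native_id_a, mo$native_id_b)
  expect_equal(length(intersect(a_set, b_set)), truth$counts$interactions$shared)
  expect_equal(length(union(a_set, b_set)), truth$counts$interactions$union)
  # shared = floor(fraction * universe), exactly
  expect_equal(truth$counts$interactions$shared, floor(0.12 * 200))
  expect_equal(truth$counts$side_effects$shared, floor(0.09 * 300))
})

test_that("zero-interaction and unsatisfiable parameter sets are handled", {
  dir <- withr::local_tempdir()
  generate_sources(generator_params(n_interactions = 0, seed = 2), dir)
  expect_equal(nrow(readr::read_tsv(file.path(dir, "PHARM_interactions.tsv"),
                                    show_col_types = FALSE)), 0)
  kb <- build_kb_from_config(read_config(file.path(dir, "config.yaml")))
  expect_equal(nrow(kb$interactions), 0)
  # demo profile is only planted when all its ingredients exist
  dir2 <- withr::local_tempdir()
  generate_sources(generator_params(n_side_effects = 0, seed = 2), dir2)
  kb2 <- build_kb_from_config(read_config(file.path(dir2, "config.yaml")))
  expect_error(demo_profile(kb2, read_ground_truth(dir2)), "No demo profile")
  # a universe too small for the requested hits fails before writing
  expect_error(generate_sources(generator_params(n_drugs = 8, n_interactions = 500),
                                withr::local_tempdir()),
               "Unsatisfiable")
})

test_that("end-to-end: ingest recovers ground truth exactly", {
  dir <- withr::local_tempdir()
  generate_sources(generator_params(seed = 9), dir)
  truth <- read_ground_truth(dir)
  kb <- build_kb_from_config(read_config(file.path(dir, "config.yaml")))
  s_ia <- kb_overlap(kb, "interactions", sources = c("PHARM", "MOLDB"))
  expect_equal(s_ia$shared, truth$counts$interactions$shared)
  expect_equal(s_ia$union, truth$counts$interactions$union)
  expect_equal(s_ia$a_only, truth$counts$interactions$a_only)
  expect_equal(s_ia$b_only, truth$counts$interactions$b_only)
  s_se <- kb_overlap(kb, "side_effects", sources = c("PHARM", "SEDB"))
  expect_equal(s_se$shared, truth$counts$side_effects$shared)
  expect_equal(s_se$union, truth$counts$side_effects$union)
})

test_that("mapping recovery is exact with and without identifier gaps", {
  for (noise in c(0, 0.2)) {
    dir <- withr::local_tempdir()
    generate_sources(generator_params(mapping_noise = noise, synonym_rate = 0,
                                      seed = 21), dir)
    truth <- read_ground_truth(dir)
    ph <- parse_source(dir, "PHARM"); mo <- parse_source(dir, "MOLDB")
    sd <- parse_source(dir, "SEDB")
    m1 <- map_by_atc_and_id(ph, mo)
    expect_setequal(paste(m1$pairs$id_a, m1$pairs$id_b),
                    paste(truth$mapping_pharm_moldb$id_a,
                          truth$mapping_pharm_moldb$id_b))
    m2 <- map_by_name(mo, sd)
    expect_setequal(paste(m2$pairs$id_a, m2$pairs$id_b),
                    paste(truth$mapping_moldb_sedb$id_a,
                          truth$mapping_moldb_sedb$id_b))
    if (noise == 0) {
      expect_true(all(m1$pairs$method == "shared_identifier"))
    } else {
      expect_true(any(m1$pairs$method == "atc_and_identifier"))
    }
  }
})

test_that("the demo profile carries all planted findings", {
  dir <- withr::local_tempdir()
  generate_sources(generator_params(seed = 13), dir)
  truth <- read_ground_truth(dir)
  kb <- build_kb_from_config(read_config(file.path(dir, "config.yaml")))
  prof <- demo_profile(kb, truth)
  expect_length(prof$drug_ids, 7)
  expect_length(prof$observed_effects, 2)
  rep <- molecular_medication_analysis(kb, prof)
  exp <- truth$demo_profile$expected
  expect_gte(nrow(rep$interactions), exp$min_interactions)
  got_pairs <- mapply(function(a, b) paste(sort(c(a, b)), collapse = "|"),
                      rep$interactions$name_a, rep$interactions$name_b)
  for (pair in exp$interaction_pairs) {
    expect_true(paste(pair, collapse = "|") %in% got_pairs)
  }
  cum <- rep$cumulative_effects
  expect_true(exp$cumulative_term %in% cum$term)
  expect_true(all(exp$cumulative_drugs_include %in%
                    cum$drug_names[[match(exp$cumulative_term, cum$term)]]))
  fl <- rep$cyp_flags
  nm <- function(id) kb$drugs$name[match(id, kb$drugs$drug_id)]
  expect_true(any(nm(fl$perpetrator) == exp$cyp_flag$perpetrator &
                    fl$cyp == exp$cyp_flag$cyp &
                    nm(fl$victim) == exp$cyp_flag$victim &
                    fl$direction == exp$cyp_flag$direction))
  m <- rep$induced_diseases$matches
  expect_true(exp$induced_disease$diagnosis %in% m$diagnosis)
  expect_true(all(exp$induced_disease$drugs_include %in%
                    unlist(m$drug_names[m$diagnosis == exp$induced_disease$diagnosis])))
})
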