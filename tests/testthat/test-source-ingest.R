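drug_row <- function(id, name, synonyms = "", atc = "", xrefs = "") {
  tibble::tibble(native_id = id, name = name, synonyms = synonyms,
                 atc_codes = atc, xrefs = xrefs)
}

test_that("parse_source loads well-formed rows and skips malformed ones", {
  dir <- withr::local_tempdir()
  write_source_dir(dir, list(
    PHARM_drugs = drug_row(c("P1", "P2", "P3"),
                           c("Clonazepam", "Clopidogrel", "Aspirin"),
                           atc = c("N03AE01", "B01AC04", "N02BA01"))))
  rs <- parse_source(dir, "PHARM")
  expect_equal(nrow(rs$drugs), 3)
  expect_equal(nrow(rs$issues), 0)

  # one malformed row (missing name) among 10: hand count of valid rows = 9
  dir2 <- withr::local_tempdir()
  tab <- drug_row(sprintf("P%02d", 1:10), sprintf("Name%02d", 1:10))
  tab$name[4] <- NA
  write_source_dir(dir2, list(PHARM_drugs = tab))
  rs2 <- parse_source(dir2, "PHARM")
  expect_equal(nrow(rs2$drugs), 9)
  expect_equal(nrow(rs2$issues), 1)
  expect_equal(rs2$issues$line, 5L)  # header is line 1

  # header-only file: empty record set, no error
  dir3 <- withr::local_tempdir()
  write_source_dir(dir3, list(PHARM_drugs = drug_row(character(), character())))
  expect_equal(nrow(parse_source(dir3, "PHARM")$drugs), 0)
})

test_that("parse_source is strict on schema", {
  dir <- withr::local_tempdir()
  write_source_dir(dir, list(PHARM_drugs = tibble::tibble(native_id = "P1", nm = "X")))
  expect_error(parse_source(dir, "PHARM"), "missing required column.*name")
  expect_error(parse_source(dir, "NOPE"), "No files for dialect")
  expect_error(parse_source(dir, ""), "unknown dialect")
})

test_that("interaction endpoints must exist; partial ATC codes are dropped", {
  dir <- withr::local_tempdir()
  write_source_dir(dir, list(
    PHARM_drugs = drug_row(c("P1", "P2"), c("A", "B"), atc = c("N03AE01", "N03AE")),
    PHARM_interactions = tibble::tibble(
      native_id_a = c("P1", "P1", "P1"), native_id_b = c("P2", "P9", "P1"),
      effect = "x", severity = "")))
  rs <- parse_source(dir, "PHARM")
  expect_equal(nrow(rs$interactions), 1)          # P9 unknown, P1-P1 self
  expect_equal(rs$drugs$atc_codes[[2]], character())  # N03AE is class-level
  expect_true(any(grepl("self-interaction", rs$issues$reason)))
  expect_true(any(grepl("ATC", rs$issues$reason)))
})

test_that("identifier mapping links by xref, then by full ATC, 1:1", {
  dir_a <- withr::local_tempdir(); dir_b <- withr::local_tempdir()
  write_source_dir(dir_a, list(A_drugs = drug_row(
    c("A1", "A2", "A3", "A4"), c("Alpha", "Beta", "Gamma", "Delta"),
    atc = c("", "N03AE01", "N02BA01", "N02BA01"),
    xrefs = c("moldb:DBX001", "", "", ""))))
  write_source_dir(dir_b, list(B_drugs = drug_row(
    c("DBX001", "DBX002", "DBX003"), c("Alephium", "Bethium", "Gammium"),
    atc = c("", "N03AE01", "N02BA01"))))
  m <- map_by_atc_and_id(parse_source(dir_a, "A"), parse_source(dir_b, "B"))
  got <- m$pairs
  # xref value equal to the b-side native id
  expect_equal(got$method[got$id_a == "A1"], "shared_identifier")
  expect_equal(got$id_b[got$id_a == "A1"], "DBX001")
  # shared full ATC code
  expect_equal(got$method[got$id_a == "A2"], "atc_and_identifier")
  expect_equal(got$id_b[got$id_a == "A2"], "DBX002")
  # two a-drugs share N02BA01 with one b-drug: lexicographically smallest
  # native-id pair wins, the other stays unlinked
  expect_equal(got$id_b[got$id_a == "A3"], "DBX003")
  expect_false("A4" %in% got$id_a)
  expect_equal(nrow(got), 3)
})

test_that("name mapping normalizes and uses synonyms; mapping is symmetric", {
  dir_a <- withr::local_tempdir(); dir_b <- withr::local_tempdir()
  write_source_dir(dir_a, list(A_drugs = drug_row(
    c("A1", "A2", "A3"), c("Clonazepam", "Aspirin", "Clobazam"))))
  write_source_dir(dir_b, list(B_drugs = drug_row(
    c("B1", "B2", "B3"), c("CLONAZEPAM ", "Acetylsalicylic acid", "Zonisamide"),
    synonyms = c("", "aspirin", ""))))
  a <- parse_source(dir_a, "A"); b <- parse_source(dir_b, "B")
  m <- map_by_name(a, b)
  expect_setequal(paste(m$pairs$id_a, m$pairs$id_b), c("A1 B1", "A2 B2"))
  # symmetry: map(b, a) links the same pairs
  m2 <- map_by_name(b, a)
  expect_setequal(paste(m2$pairs$id_b, m2$pairs$id_a),
                  paste(m$pairs$id_a, m$pairs$id_b))
})

test_that("canonicalize_term maps synonyms, fixes canonicals, flags unknowns", {
  tab <- tibble::tibble(raw = c("emesis", "vomiting"),
                        canonical = c("vomiting", "vomiting"))
  out <- canonicalize_term(c("emesis", "vomiting", "Qwertyitis"), tab)
  expect_equal(as.character(out), c("vomiting", "vomiting", "qwertyitis"))
  expect_equal(attr(out, "unmapped"), c(FALSE, FALSE, TRUE))
})

make_two_sources <- function() {
  dir_a <- file.path(withr::local_tempdir(.local_envir = parent.frame()), "a")
  dir_b <- file.path(withr::local_tempdir(.local_envir = parent.frame()), "b")
  write_source_dir(dir_a, list(
    PHARM_drugs = drug_row(sprintf("P%d", 1:5), sprintf("Drug%d", 1:5),
                           atc = sprintf("N03AE%02d", 1:5)),
    PHARM_interactions = tibble::tibble(
      native_id_a = c("P1", "P2"), native_id_b = c("P2", "P3"),
      effect = c("pharm effect 12", "pharm effect 23"), severity = c("minor", "")),
    PHARM_side_effects = tibble::tibble(
      native_id = c("P1", "P1"), term = c("emesis", "headache"), frequency = "")))
  write_source_dir(dir_b, list(
    MOLDB_drugs = drug_row(sprintf("M%d", 1:5), c(sprintf("Drug%d", 1:3), "Other4", "Other5"),
                           atc = c(sprintf("N03AE%02d", 1:3), "C01CA01", "C01CA02")),
    MOLDB_interactions = tibble::tibble(
      native_id_a = "M1", native_id_b = "M2",
      effect = "mol effect 12", severity = ""),
    MOLDB_side_effects = tibble::tibble(
      native_id = "M1", term = "vomiting", frequency = "common")))
  list(a = parse_source(dir_a, "PHARM"), b = parse_source(dir_b, "MOLDB"))
}

test_that("merge fuses mapped drugs and unions provenance", {
  src <- make_two_sources()
  m <- map_by_atc_and_id(src$a, src$b)
  expect_equal(nrow(m$pairs), 3)
  syn <- tibble::tibble(raw = c("emesis", "vomiting"), canonical = c("vomiting", "vomiting"))
  kb <- merge_sources(list(src$a, src$b), list(m), synonym_table = syn)
  # |A| + |B| - |mapping| drugs
  expect_equal(nrow(kb$drugs), 5 + 5 - 3)
  # same pair asserted by both sources: one assertion, provenance of size 2
  fused1 <- resolve_drug(kb, "Drug1"); fused2 <- resolve_drug(kb, "Drug2")
  row <- dplyr::filter(kb$interactions,
                       drug_a == min(fused1, fused2), drug_b == max(fused1, fused2))
  expect_equal(nrow(row), 1)
  expect_setequal(row$provenance[[1]], c("MOLDB", "PHARM"))
  # both effect texts retained, keyed by source
  expect_setequal(names(row$effects[[1]]), c("MOLDB", "PHARM"))
  # side effect under two synonyms fuses to one canonical assertion
  se <- dplyr::filter(kb$side_effects, drug_id == fused1, term == "vomiting")
  expect_equal(nrow(se), 1)
  expect_setequal(se$provenance[[1]], c("MOLDB", "PHARM"))
  # fused id is "KB:" + smallest native id
  expect_equal(fused1, "KB:M1")
})

test_that("merge is order-independent and loses no assertion", {
  src <- make_two_sources()
  m <- map_by_atc_and_id(src$a, src$b)
  syn <- tibble::tibble(raw = c("emesis", "vomiting"), canonical = c("vomiting", "vomiting"))
  kb1 <- merge_sources(list(src$a, src$b), list(m), synonym_table = syn)
  kb2 <- merge_sources(list(src$b, src$a), list(m), synonym_table = syn)
  for (tb in c("drugs", "interactions", "side_effects", "molecule_links",
               "pathways", "diseases")) {
    expect_equal(kb1[[tb]], kb2[[tb]], label = tb)
  }
  # no assertion loss: every raw row is represented exactly once
  n_raw_pairs <- length(unique(c("P1|P2", "P2|P3", "M1|M2->fused(P1|P2)")))
  expect_equal(nrow(kb1$interactions), 2)  # P1-P2 (= M1-M2) and P2-P3
  expect_equal(sum(lengths(kb1$interactions$provenance)), 3)  # 3 raw rows
  expect_equal(nrow(kb1$side_effects), 2)  # (Drug1, vomiting) + (Drug1, headache)
  expect_equal(sum(lengths(kb1$side_effects$provenance)), 3)
})

test_that("provenance equals exactly the sources holding a fusing raw record", {
  src <- make_two_sources()
  m <- map_by_atc_and_id(src$a, src$b)
  kb <- merge_sources(list(src$a, src$b), list(m),
                      synonym_table = tibble::tibble(raw = c("emesis", "vomiting"),
                                                     canonical = c("vomiting", "vomiting")))
  # brute force: recompute provenance for every merged interaction
  native_of <- function(fused_id, tag) {
    s <- kb$drugs$source_ids[[match(fused_id, kb$drugs$drug_id)]]
    unname(s[tag])
  }
  for (r in seq_len(nrow(kb$interactions))) {
    expected <- character()
    for (rs in list(src$a, src$b)) {
      na_ <- native_of(kb$interactions$drug_a[r], rs$source_tag)
      nb_ <- native_of(kb$interactions$drug_b[r], rs$source_tag)
      raw <- rs$interactions
      hit <- !is.na(na_) && !is.na(nb_) &&
        any((raw$native_id_a == na_ & raw$native_id_b == nb_) |
              (raw$native_id_a == nb_ & raw$native_id_b == na_))
      if (hit) expected <- c(expected, rs$source_tag)
    }
    expect_setequal(kb$interactions$provenance[[r]], expected)
  }
})

test_that("contradictory mappings abort before merging", {
  src <- make_two_sources()
  bad <- drugkb:::new_drug_mapping(
    tibble::tibble(id_a = c("P1", "P1"), id_b = c("M1", "M2"),
                   method = "shared_identifier"),
    "PHARM", "MOLDB", "atc_and_identifier")
  expect_error(merge_sources(list(src$a, src$b), list(bad)), "Contradictory")
})

test_that("merging empty inputs yields an empty knowledge base", {
  dir <- withr::local_tempdir()
  write_source_dir(dir, list(PHARM_drugs = drug_row(character(), character())))
  kb <- merge_sources(list(parse_source(dir, "PHARM")))
  expect_equal(nrow(kb$drugs), 0)
  expect_equal(nrow(kb$interactions), 0)
})
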