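#' Parse one source's TSV file set
#'
#' Each source is a directory of UTF-8 tab-separated files sharing the
#' source tag as filename prefix: `<tag>_drugs.tsv`, `<tag>_interactions.tsv`,
#' `<tag>_side_effects.tsv`, `<tag>_molecule_links.tsv`, `<tag>_pathways.tsv`
#' and optionally `<tag>_diseases.tsv`. Empty string means missing; list
#' cells are pipe-separated; `xrefs` cells are pipe-separated `key:value`
#' pairs. Missing files yield empty tables. Parsing is strict on schema
#' (a missing required column is a hard error naming the column) and lenient
#' on content: malformed rows are skipped and reported with their line
#' numbers in the `issues` table of the result.
#'
#' @param path directory containing the source's TSV files.
#' @param source_tag the source tag, e.g. `"PHARM"`; also the filename prefix.
#' @return an object of class `source_record_set` with elements
#'   `source_tag`, `drugs`, `interactions`, `side_effects`, `molecule_links`,
#'   `pathways`, `diseases` (tibbles keyed by native ids) and `issues`
#'   (tibble of skipped rows: file, line, reason).
#' @export
parse_source <- function(path, source_tag) {
  if (length(source_tag) != 1 || !nzchar(source_tag)) {
    abort("source_tag must be a single nonempty string (unknown dialect).")
  }
  if (!dir.exists(path)) abort(paste0("Source directory not found: ", path))
  files <- list.files(path, pattern = paste0("^", source_tag, "_.*\\.tsv$"))
  if (length(files) == 0) {
    abort(paste0("No files for dialect '", source_tag, "' under ", path,
                 " (expected e.g. ", source_tag, "_drugs.tsv)"))
  }
  issues <- list()
  note <- function(file, line, reason) {
    issues[[length(issues) + 1]] <<- tibble(file = file, line = line, reason = reason)
  }

  tab <- function(kind, required) {
    file <- paste0(source_tag, "_", kind, ".tsv")
    fp <- file.path(path, file)
    if (!file.exists(fp)) {
      return(tibble(!!!setNames(rep(list(character()), length(required)), required)))
    }
    df <- suppressWarnings(readr::read_tsv(
      fp, col_types = readr::cols(.default = readr::col_character()),
      na = "", quote = "", progress = FALSE, show_col_types = FALSE,
      skip_empty_rows = FALSE
    ))
    missing_col <- setdiff(required, names(df))
    if (length(missing_col) > 0) {
      abort(paste0(file, ": missing required column(s): ",
                   paste(missing_col, collapse = ", ")))
    }
    bad <- unique(readr::problems(df)$row)
    if (length(bad) > 0) {
      for (r in bad) note(file, r + 1L, "malformed row (wrong field count)")
      df <- df[-bad, , drop = FALSE]
    }
    attr(df, "line") <- setdiff(seq_len(nrow(df) + length(bad)), bad) + 1L
    df
  }

  # keep rows satisfying `ok`; log the rest with their original line numbers
  sieve <- function(df, ok, file, reason) {
    ok[is.na(ok)] <- FALSE
    lines <- attr(df, "line")
    for (r in which(!ok)) note(file, lines[r], reason)
    out <- df[ok, , drop = FALSE]
    attr(out, "line") <- lines[ok]
    out
  }

  d <- tab("drugs", c("native_id", "name", "synonyms", "atc_codes", "xrefs"))
  d <- sieve(d, nzchar(d$native_id %||% character()) & !is.na(d$native_id) &
               nzchar(d$name %||% character()) & !is.na(d$name),
             paste0(source_tag, "_drugs.tsv"), "missing native_id or name")
  d <- sieve(d, !duplicated(d$native_id),
             paste0(source_tag, "_drugs.tsv"), "duplicate native_id")
  atc <- map(split_pipe(d$atc_codes), function(v) stringr::str_to_upper(v))
  dropped <- unique(unlist(map(atc, function(v) v[!is_valid_atc(v)])))
  if (length(dropped) > 0) {
    note(paste0(source_tag, "_drugs.tsv"), NA_integer_,
         paste0("dropped non-conforming ATC code(s): ", paste(sort_c(dropped), collapse = ", ")))
  }
  drugs <- tibble(
    native_id = d$native_id,
    name = d$name,
    synonyms = split_pipe(d$synonyms),
    atc_codes = map(atc, function(v) sort_c(v[is_valid_atc(v)])),
    xrefs = parse_xrefs(d$xrefs)
  )

  i <- tab("interactions", c("native_id_a", "native_id_b", "effect", "severity"))
  fi <- paste0(source_tag, "_interactions.tsv")
  i <- sieve(i, !is.na(i$native_id_a) & !is.na(i$native_id_b) &
               nzchar(i$native_id_a %||% character()) & nzchar(i$native_id_b %||% character()),
             fi, "missing endpoint id")
  i <- sieve(i, i$native_id_a != i$native_id_b, fi, "self-interaction")
  i <- sieve(i, i$native_id_a %in% drugs$native_id & i$native_id_b %in% drugs$native_id,
             fi, "endpoint not in this source's drug table")
  interactions <- tibble(native_id_a = i$native_id_a, native_id_b = i$native_id_b,
                         effect = i$effect, severity = i$severity)

  s <- tab("side_effects", c("native_id", "term", "frequency"))
  fs <- paste0(source_tag, "_side_effects.tsv")
  s <- sieve(s, !is.na(s$native_id) & !is.na(s$term) &
               nzchar(s$native_id %||% character()) & nzchar(s$term %||% character()),
             fs, "missing native_id or term")
  s <- sieve(s, s$native_id %in% drugs$native_id, fs, "drug not in this source's drug table")
  side_effects <- tibble(native_id = s$native_id, term = s$term, frequency = s$frequency)

  m <- tab("molecule_links", c("native_id", "molecule_id", "molecule_role", "action"))
  fm <- paste0(source_tag, "_molecule_links.tsv")
  m <- sieve(m, !is.na(m$native_id) & !is.na(m$molecule_id), fm, "missing id")
  m <- sieve(m, m$molecule_role %in% MOLECULE_ROLES & m$action %in% MOLECULE_ACTIONS,
             fm, "molecule_role or action outside closed vocabulary")
  m <- sieve(m, m$native_id %in% drugs$native_id, fm, "drug not in this source's drug table")
  molecule_links <- tibble(native_id = m$native_id, molecule_id = m$molecule_id,
                           molecule_role = m$molecule_role, action = m$action)

  p <- tab("pathways", c("pathway_id", "name", "member_molecules", "drugs", "diseases"))
  p <- sieve(p, !is.na(p$pathway_id) & !is.na(p$name),
             paste0(source_tag, "_pathways.tsv"), "missing pathway_id or name")
  pathways <- tibble(pathway_id = p$pathway_id, name = p$name,
                     member_molecules = split_pipe(p$member_molecules),
                     drugs = split_pipe(p$drugs),
                     diseases = split_pipe(p$diseases))

  z <- tab("diseases", c("native_id", "name", "synonyms"))
  z <- sieve(z, !is.na(z$native_id) & !is.na(z$name) & nzchar(z$name %||% character()),
             paste0(source_tag, "_diseases.tsv"), "missing native_id or name")
  diseases <- tibble(native_id = z$native_id, name = z$name, synonyms = split_pipe(z$synonyms))

  structure(
    list(source_tag = source_tag, drugs = drugs, interactions = interactions,
         side_effects = side_effects, molecule_links = molecule_links,
         pathways = pathways, diseases = diseases,
         issues = if (length(issues)) bind_rows(issues) else
           tibble(file = character(), line = integer(), reason = character())),
    class = "source_record_set"
  )
}

#' @export
print.source_record_set <- function(x, ...) {
  cat("<source_record_set ", x$source_tag, "> ",
      nrow(x$drugs), " drugs, ", nrow(x$interactions), " interactions, ",
      nrow(x$side_effects), " side effects, ", nrow(x$issues), " skipped rows\n",
      sep = "")
  invisible(x)
}

new_drug_mapping <- function(pairs, source_a, source_b, method) {
  structure(list(pairs = pairs, source_a = source_a, source_b = source_b,
                 method = method),
            class = "drug_mapping")
}

#' @export
print.drug_mapping <- function(x, ...) {
  cat("<drug_mapping ", x$source_a, " <-> ", x$source_b, "> ",
      nrow(x$pairs), " links (", x$method, ")\n", sep = "")
  invisible(x)
}

# Greedy 1:1 resolution of candidate links. Candidates are scored
# (shared identifier > shared ATC > shared name); ties broken by the
# lexicographically smallest native-id pair, compared symmetrically so
# map(a, b) and map(b, a) select the same links. Losers stay unlinked.
resolve_candidates <- function(cand) {
  if (nrow(cand) == 0) {
    return(tibble(id_a = character(), id_b = character(), method = character()))
  }
  lo <- pmin(cand$id_a, cand$id_b)
  hi <- pmax(cand$id_a, cand$id_b)
  ord <- order(-cand$score, lo, hi, method = "radix")
  cand <- cand[ord, , drop = FALSE]
  used_a <- character(); used_b <- character()
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    if (!(cand$id_a[k] %in% used_a) && !(cand$id_b[k] %in% used_b)) {
      keep[k] <- TRUE
      used_a <- c(used_a, cand$id_a[k])
      used_b <- c(used_b, cand$id_b[k])
    }
  }
  out <- cand[keep, c("id_a", "id_b", "method")]
  out[order(out$id_a, method = "radix"), , drop = FALSE]
}

#' Map drugs across two sources by shared identifiers and ATC codes
#'
#' Links drug pairs that share a native cross-reference identifier (an
#' `xrefs` value of one source equal to the other's native id, or an
#' identical `key:value` xref in both); among the remaining drugs, links
#' pairs sharing at least one full 7-character ATC code. Partial ATC codes
#' never match. Conflicts are resolved 1:1 (identifier beats ATC, then the
#' lexicographically smallest native-id pair wins); unmapped drugs stay
#' unlinked and still enter the knowledge base as single-source drugs.
#'
#' @param a,b `source_record_set` objects.
#' @return a `drug_mapping` whose `pairs` tibble has columns `id_a`, `id_b`,
#'   `method` (`shared_identifier` or `atc_and_identifier` per link).
#' @export
map_by_atc_and_id <- function(a, b) {
  stopifnot(inherits(a, "source_record_set"), inherits(b, "source_record_set"))
  da <- a$drugs; db <- b$drugs
  cand <- list()
  if (nrow(da) > 0 && nrow(db) > 0) {
    keyed <- function(v) {
      if (length(v) == 0) return(character())
      unique(c(unname(v), paste0(names(v), ":", v)))
    }
    xa <- map(da$xrefs, keyed)
    xb <- map(db$xrefs, keyed)
    for (i in seq_len(nrow(da))) {
      for (j in seq_len(nrow(db))) {
        shared_id <- db$native_id[j] %in% xa[[i]] ||
          da$native_id[i] %in% xb[[j]] ||
          length(intersect(xa[[i]], xb[[j]])) > 0
        if (shared_id) {
          cand[[length(cand) + 1]] <- tibble(
            id_a = da$native_id[i], id_b = db$native_id[j],
            method = "shared_identifier", score = 2)
        } else if (length(intersect(da$atc_codes[[i]], db$atc_codes[[j]])) > 0) {
          cand[[length(cand) + 1]] <- tibble(
            id_a = da$native_id[i], id_b = db$native_id[j],
            method = "atc_and_identifier", score = 1)
        }
      }
    }
  }
  pairs <- resolve_candidates(if (length(cand)) bind_rows(cand) else
    tibble(id_a = character(), id_b = character(), method = character(), score = numeric()))
  new_drug_mapping(pairs, a$source_tag, b$source_tag, "atc_and_identifier")
}

#' Map drugs across two sources by normalized names
#'
#' Links drug pairs whose normalized display names or synonyms are equal
#' (see [normalize_name()]); used for source pairs without corresponding
#' identifiers. 1:1 conflicts are resolved by the lexicographically smallest
#' native-id pair.
#'
#' @param a,b `source_record_set` objects.
#' @return a `drug_mapping` with per-link method `"name"`.
#' @export
map_by_name <- function(a, b) {
  stopifnot(inherits(a, "source_record_set"), inherits(b, "source_record_set"))
  da <- a$drugs; db <- b$drugs
  cand <- list()
  if (nrow(da) > 0 && nrow(db) > 0) {
    na_ <- map2(da$name, da$synonyms, function(n, s) unique(normalize_name(c(n, s))))
    nb_ <- map2(db$name, db$synonyms, function(n, s) unique(normalize_name(c(n, s))))
    for (i in seq_len(nrow(da))) {
      for (j in seq_len(nrow(db))) {
        if (length(intersect(na_[[i]], nb_[[j]])) > 0) {
          cand[[length(cand) + 1]] <- tibble(
            id_a = da$native_id[i], id_b = db$native_id[j],
            method = "name", score = 1)
        }
      }
    }
  }
  pairs <- resolve_candidates(if (length(cand)) bind_rows(cand) else
    tibble(id_a = character(), id_b = character(), method = character(), score = numeric()))
  new_drug_mapping(pairs, a$source_tag, b$source_tag, "name")
}

#' Read a raw-to-canonical side-effect synonym table
#'
#' @param path a `synonyms.tsv` with columns `raw_term`, `canonical_term`.
#' @return tibble with normalized `raw`, `canonical` columns; every
#'   canonical term also maps to itself.
#' @export
read_synonym_table <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        na = "", quote = "", progress = FALSE, show_col_types = FALSE)
  missing_col <- setdiff(c("raw_term", "canonical_term"), names(df))
  if (length(missing_col) > 0) {
    abort(paste0(basename(path), ": missing required column(s): ",
                 paste(missing_col, collapse = ", ")))
  }
  tab <- tibble(raw = normalize_name(df$raw_term),
                canonical = normalize_name(df$canonical_term))
  bind_rows(tab, tibble(raw = unique(tab$canonical), canonical = unique(tab$canonical))) |>
    distinct() |>
    arrange(.data$raw)
}

#' Canonicalize side-effect terms
#'
#' Maps raw terms to their canonical form through a synonym table; terms
#' absent from the table pass through normalized. The canonical form of a
#' canonical term is itself.
#'
#' @param raw character vector of raw terms.
#' @param synonym_table tibble with `raw`, `canonical` columns (normalized),
#'   e.g. from [read_synonym_table()].
#' @return character vector of canonical terms, with attribute `unmapped`
#'   (logical vector) marking pass-through terms.
#' @examples
#' tab <- tibble::tibble(raw = c("emesis", "vomiting"),
#'                       canonical = c("vomiting", "vomiting"))
#' canonicalize_term(c("Emesis", "vomiting", "Qwertyitis"), tab)
#' @export
canonicalize_term <- function(raw, synonym_table) {
  key <- normalize_name(raw)
  idx <- match(key, synonym_table$raw)
  out <- ifelse(is.na(idx), key, synonym_table$canonical[idx])
  attr(out, "unmapped") <- is.na(idx)
  out
}

# first element after deterministic ordering by source tag
first_by_tag <- function(values, tags) {
  ok <- !is.na(values)
  if (!any(ok)) return(NA_character_)
  values <- values[ok]; tags <- tags[ok]
  values[order(tags, values, method = "radix")][1]
}

#' Merge parsed sources into one provenance-tagged knowledge base
#'
#' Fuses drugs linked by the supplied cross-source mappings into single
#' records (union of names, synonyms, ATC codes; native identifiers kept per
#' source), re-expresses all assertions over the fused drug identifiers,
#' deduplicates interactions by canonical pair and side effects by
#' (drug, canonical term), and unions provenance. Diseases are fused across
#' sources by normalized name. The fused drug id is `"KB:"` plus the
#' lexicographically smallest native id across the fused records, so ids are
#' stable across re-runs.
#'
#' @param record_sets list of `source_record_set` objects.
#' @param mappings list of `drug_mapping` objects between pairs of the
#'   supplied sources. Contradictory mappings (a native id linked to two
#'   different ids of the same other source) are a hard error.
#' @param synonym_table optional normalized synonym table
#'   ([read_synonym_table()]) used to canonicalize side-effect terms.
#' @return a `drug_kb`; its `attr(, "ingest_report")` lists per-source
#'   counts, fused drug counts, skipped rows and unmapped side-effect terms.
#' @export
merge_sources <- function(record_sets, mappings = list(), synonym_table = NULL) {
  stopifnot(all(map_lgl(record_sets, inherits, "source_record_set")))
  if (is.null(synonym_table)) synonym_table <- empty_synonym_table()
  tags <- map_chr(record_sets, "source_tag")
  if (anyDuplicated(tags)) abort("Duplicate source tags in record_sets.")
  names(record_sets) <- tags
  ord <- order(tags, method = "radix")
  record_sets <- record_sets[ord]
  tags <- tags[ord]

  for (m in mappings) {
    stopifnot(inherits(m, "drug_mapping"))
    if (!all(c(m$source_a, m$source_b) %in% tags)) {
      abort("Mapping references a source not present in record_sets.")
    }
    if (anyDuplicated(m$pairs$id_a) || anyDuplicated(m$pairs$id_b)) {
      abort(paste0("Contradictory mapping between ", m$source_a, " and ",
                   m$source_b, ": a native id links to two ids of the other source."))
    }
    ok_a <- m$pairs$id_a %in% record_sets[[m$source_a]]$drugs$native_id
    ok_b <- m$pairs$id_b %in% record_sets[[m$source_b]]$drugs$native_id
    if (!all(ok_a & ok_b)) abort("Mapping references native ids absent from the record sets.")
  }

  # union-find over (tag, native_id) nodes, mapping links as edges
  nodes <- bind_rows(map(record_sets, function(rs) {
    tibble(tag = rs$source_tag, native_id = rs$drugs$native_id)
  }))
  if (nrow(nodes) == 0) {
    kb <- knowledge_base(source_tags = tags, synonym_table = synonym_table)
    attr(kb, "ingest_report") <- list(
      per_source_drugs = setNames(integer(length(tags)), tags),
      fused_drugs = 0L, links = 0L,
      skipped_rows = bind_rows(map(record_sets, "issues")),
      unmapped_terms = character())
    return(kb)
  }
  key <- paste0(nodes$tag, "\r", nodes$native_id)
  parent <- seq_len(nrow(nodes))
  names(parent) <- key
  find <- function(i) {
    while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }
    i
  }
  unite <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  for (m in mappings) {
    ka <- match(paste0(m$source_a, "\r", m$pairs$id_a), key)
    kb_ <- match(paste0(m$source_b, "\r", m$pairs$id_b), key)
    for (k in seq_along(ka)) unite(ka[k], kb_[k])
  }
  root <- map_int(seq_len(nrow(nodes)), find)

  # fused drug records
  comp <- split(seq_len(nrow(nodes)), root)
  fused <- map(comp, function(ix) {
    tg <- nodes$tag[ix]; nid <- nodes$native_id[ix]
    o <- order(nid, tg, method = "radix")
    tg <- tg[o]; nid <- nid[o]
    recs <- map2(tg, nid, function(t, n) {
      d <- record_sets[[t]]$drugs
      d[d$native_id == n, , drop = FALSE]
    })
    primary <- recs[[1]]
    all_names <- unlist(map(recs, function(r) c(r$name, r$synonyms[[1]])))
    syn <- all_names[normalize_name(all_names) != normalize_name(primary$name)]
    syn <- syn[!duplicated(normalize_name(syn))]
    tibble(
      drug_id = paste0("KB:", nid[1]),
      name = primary$name,
      synonyms = list(sort_c(syn)),
      atc_codes = list(sort_c(unique(unlist(map(recs, function(r) r$atc_codes[[1]]))))),
      source_ids = list(setNames(nid, tg)[order(tg, method = "radix")])
    )
  })
  drugs <- bind_rows(fused)
  # disambiguate rare fused-id collisions (distinct components whose smallest
  # native ids coincide across namespaces)
  if (anyDuplicated(drugs$drug_id)) {
    dup <- duplicated(drugs$drug_id) | duplicated(drugs$drug_id, fromLast = TRUE)
    drugs$drug_id[dup] <- paste0(drugs$drug_id[dup], "#",
                                 map_chr(drugs$source_ids[dup], function(s) names(s)[1]))
  }
  drugs <- drugs[order(drugs$drug_id, method = "radix"), , drop = FALSE]

  # native (tag, id) -> fused drug_id
  lut <- tibble(
    tag = unlist(map(drugs$source_ids, names)),
    native_id = unlist(drugs$source_ids),
    drug_id = rep(drugs$drug_id, times = map_int(drugs$source_ids, length))
  )
  to_fused <- function(tag, native) {
    if (length(native) == 0) return(character())
    lut$drug_id[match(paste0(tag, "\r", native), paste0(lut$tag, "\r", lut$native_id))]
  }

  # interactions: dedupe by canonical pair, union provenance, keep each
  # source's effect text
  raw_ia <- bind_rows(map(record_sets, function(rs) {
    if (nrow(rs$interactions) == 0) return(NULL)
    tibble(tag = rs$source_tag,
           a = to_fused(rs$source_tag, rs$interactions$native_id_a),
           b = to_fused(rs$source_tag, rs$interactions$native_id_b),
           effect = rs$interactions$effect, severity = rs$interactions$severity)
  }))
  interactions <- empty_interactions()
  if (!is.null(raw_ia) && nrow(raw_ia) > 0) {
    cp <- canonical_pair(raw_ia$a, raw_ia$b)
    raw_ia$drug_a <- cp$drug_a; raw_ia$drug_b <- cp$drug_b
    interactions <- raw_ia |>
      group_by(.data$drug_a, .data$drug_b) |>
      summarise(
        effects = list({
          e <- first_by_tag_each(.data$effect, .data$tag)
          e[!is.na(e)]
        }),
        severity = first_by_tag(.data$severity, .data$tag),
        provenance = list(sort_c(unique(.data$tag))),
        .groups = "drop"
      ) |>
      arrange(.data$drug_a, .data$drug_b)
  }

  # side effects: canonical term, dedupe by (drug, term)
  raw_se <- bind_rows(map(record_sets, function(rs) {
    if (nrow(rs$side_effects) == 0) return(NULL)
    tibble(tag = rs$source_tag,
           drug_id = to_fused(rs$source_tag, rs$side_effects$native_id),
           raw_term = rs$side_effects$term, frequency = rs$side_effects$frequency)
  }))
  side_effects <- empty_side_effects()
  unmapped_terms <- character()
  if (!is.null(raw_se) && nrow(raw_se) > 0) {
    term <- canonicalize_term(raw_se$raw_term, synonym_table)
    unmapped_terms <- sort_c(unique(term[attr(term, "unmapped")]))
    raw_se$term <- as.character(term)
    side_effects <- raw_se |>
      group_by(.data$drug_id, .data$term) |>
      summarise(frequency = first_by_tag(.data$frequency, .data$tag),
                provenance = list(sort_c(unique(.data$tag))), .groups = "drop") |>
      arrange(.data$drug_id, .data$term)
  }

  raw_ml <- bind_rows(map(record_sets, function(rs) {
    if (nrow(rs$molecule_links) == 0) return(NULL)
    tibble(tag = rs$source_tag,
           drug_id = to_fused(rs$source_tag, rs$molecule_links$native_id),
           molecule_id = rs$molecule_links$molecule_id,
           molecule_role = rs$molecule_links$molecule_role,
           action = rs$molecule_links$action)
  }))
  molecule_links <- empty_molecule_links()
  if (!is.null(raw_ml) && nrow(raw_ml) > 0) {
    molecule_links <- raw_ml |>
      group_by(.data$drug_id, .data$molecule_id, .data$molecule_role, .data$action) |>
      summarise(provenance = list(sort_c(unique(.data$tag))), .groups = "drop") |>
      arrange(.data$drug_id, .data$molecule_id, .data$molecule_role, .data$action)
  }

  # diseases fused across sources by normalized name
  raw_dz <- bind_rows(map(record_sets, function(rs) {
    if (nrow(rs$diseases) == 0) return(NULL)
    tibble(tag = rs$source_tag, native_id = rs$diseases$native_id,
           name = rs$diseases$name, synonyms = rs$diseases$synonyms)
  }))
  diseases <- empty_diseases()
  dz_lut <- tibble(tag = character(), native_id = character(), disease_id = character())
  if (!is.null(raw_dz) && nrow(raw_dz) > 0) {
    raw_dz$key <- normalize_name(raw_dz$name)
    raw_dz <- raw_dz[order(raw_dz$native_id, raw_dz$tag, method = "radix"), ]
    diseases <- raw_dz |>
      group_by(.data$key) |>
      summarise(
        disease_id = paste0("KBD:", .data$native_id[1]),
        name = .data$name[1],
        synonyms = list(sort_c(unique(unlist(.data$synonyms)))),
        .groups = "drop") |>
      select(-"key") |>
      arrange(.data$disease_id)
    dz_lut <- raw_dz |>
      group_by(.data$key) |>
      mutate(disease_id = paste0("KBD:", .data$native_id[1])) |>
      ungroup() |>
      select("tag", "native_id", "disease_id")
  }

  pathways <- bind_rows(map(record_sets, function(rs) {
    if (nrow(rs$pathways) == 0) return(NULL)
    tibble(
      pathway_id = rs$pathways$pathway_id,
      name = rs$pathways$name,
      member_molecule_ids = map(rs$pathways$member_molecules, sort_c),
      linked_drug_ids = map(rs$pathways$drugs, function(v) {
        f <- to_fused(rs$source_tag, v)
        sort_c(unique(f[!is.na(f)]))
      }),
      linked_disease_ids = map(rs$pathways$diseases, function(v) {
        idx <- match(paste0(rs$source_tag, "\r", v), paste0(dz_lut$tag, "\r", dz_lut$native_id))
        sort_c(unique(dz_lut$disease_id[idx][!is.na(idx)]))
      })
    )
  }))
  if (is.null(pathways)) pathways <- empty_pathways()
  if (nrow(pathways) > 0) {
    pathways <- pathways[order(pathways$pathway_id, method = "radix"), , drop = FALSE]
  }

  kb <- knowledge_base(
    drugs = drugs, interactions = interactions, side_effects = side_effects,
    molecule_links = molecule_links, pathways = pathways, diseases = diseases,
    source_tags = tags, synonym_table = synonym_table
  )
  attr(kb, "ingest_report") <- list(
    per_source_drugs = setNames(map_int(record_sets, function(rs) nrow(rs$drugs)), tags),
    fused_drugs = nrow(drugs),
    links = sum(map_int(mappings, function(m) nrow(m$pairs))),
    skipped_rows = bind_rows(map(record_sets, "issues")),
    unmapped_terms = unmapped_terms
  )
  kb
}

# per-group variant of first_by_tag: one effect text per asserting source
first_by_tag_each <- function(values, tags) {
  o <- order(tags, values, method = "radix")
  values <- values[o]; tags <- tags[o]
  keep <- !duplicated(tags)
  setNames(values[keep], tags[keep])
}
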