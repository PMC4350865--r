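#' Inter-source overlap summaries
#'
#' Two sources asserting the same kind of hit (distinct canonical drug
#' pairs for interactions, distinct (drug, canonical term) pairs for side
#' effects) agree on some hits and disagree on others. An overlap summary
#' records the full set algebra: per-source totals, exclusive counts, the
#' intersection ("correlative" hits), the union of distinct hits, and the
#' multiset total (sum of the two per-source totals, counting shared hits
#' twice). Percentages:
#' \itemize{
#'   \item `a_share`, `b_share` — per-source total over the union;
#'   \item `a_only_share`, `b_only_share`, `shared_share` — exclusive and
#'     correlative counts over the union (these three sum to 100);
#'   \item `noncorrelative_share` — hits not asserted by both, over the union;
#'   \item `unmatched_share` — unmatched hits over the multiset total.
#' }
#' Percentages are rounded half-up; `rounding = "integer"` gives whole
#' percentages (distribution-style reports), `"two_decimal"` gives two
#' decimals (per-drug reports), `"none"` leaves them unrounded.
#'
#' `summary_from_exclusive()` builds the summary from exclusive counts and
#' the intersection; `summary_from_inclusive()` from per-source totals and
#' the union. Both describe the same object and agree field by field when
#' built from the same underlying sets.
#'
#' @param a_only,b_only hits asserted by exactly one source.
#' @param shared hits asserted by both sources.
#' @param a_total,b_total per-source hit counts including shared hits.
#' @param union_size number of distinct hits across both sources.
#' @param rounding `"integer"`, `"two_decimal"` or `"none"`.
#' @return an object of class `overlap_summary`.
#' @examples
#' summary_from_exclusive(29854, 15518, 6148, rounding = "integer")
#' summary_from_inclusive(1392, 396, 1567, rounding = "two_decimal")
#' @export
summary_from_exclusive <- function(a_only, b_only, shared, rounding = "integer") {
  stopifnot(a_only >= 0, b_only >= 0, shared >= 0)
  new_overlap_summary(a_only = a_only, b_only = b_only, shared = shared,
                      rounding = rounding)
}

#' @rdname summary_from_exclusive
#' @export
summary_from_inclusive <- function(a_total, b_total, union_size, rounding = "two_decimal") {
  stopifnot(a_total >= 0, b_total >= 0)
  if (union_size > a_total + b_total || union_size < max(a_total, b_total)) {
    abort(paste0("Inconsistent counts: union must lie in [max(a_total, b_total), ",
                 "a_total + b_total]."))
  }
  shared <- a_total + b_total - union_size
  new_overlap_summary(a_only = a_total - shared, b_only = b_total - shared,
                      shared = shared, rounding = rounding)
}

new_overlap_summary <- function(a_only, b_only, shared, rounding,
                                source_a = "a", source_b = "b", kind = NA_character_) {
  rounding <- match.arg(rounding, c("integer", "two_decimal", "none"))
  union_size <- a_only + b_only + shared
  a_total <- a_only + shared
  b_total <- b_only + shared
  multiset_total <- a_total + b_total
  pct <- function(x, denom) {
    if (denom == 0) return(0)
    p <- 100 * x / denom
    switch(rounding,
           integer = round_half_up(p, 0),
           two_decimal = round_half_up(p, 2),
           none = p)
  }
  structure(
    list(source_a = source_a, source_b = source_b, kind = kind,
         a_total = a_total, b_total = b_total,
         a_only = a_only, b_only = b_only,
         shared = shared, union = union_size,
         noncorrelative = a_only + b_only,
         multiset_total = multiset_total,
         a_share = pct(a_total, union_size),
         b_share = pct(b_total, union_size),
         a_only_share = pct(a_only, union_size),
         b_only_share = pct(b_only, union_size),
         shared_share = pct(shared, union_size),
         noncorrelative_share = pct(a_only + b_only, union_size),
         unmatched_share = pct(a_only + b_only, multiset_total),
         rounding = rounding),
    class = "overlap_summary"
  )
}

#' @export
print.overlap_summary <- function(x, ...) {
  cat("<overlap_summary", if (!is.na(x$kind)) paste0(" ", x$kind), "> ",
      x$source_a, " vs ", x$source_b, "\n", sep = "")
  cat("  union ", x$union, " | ", x$source_a, " ", x$a_total,
      " (", x$a_share, "%) | ", x$source_b, " ", x$b_total,
      " (", x$b_share, "%)\n", sep = "")
  cat("  shared ", x$shared, " (", x$shared_share, "%) | non-correlative ",
      x$noncorrelative, " (", x$noncorrelative_share,
      "%) | unmatched of multiset ", x$unmatched_share, "%\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.overlap_summary <- function(x, ...) {
  tibble(
    part = c("only_a", "only_b", "shared"),
    source = c(x$source_a, x$source_b, paste0(x$source_a, "+", x$source_b)),
    count = c(x$a_only, x$b_only, x$shared),
    share_of_union = c(x$a_only_share, x$b_only_share, x$shared_share)
  )
}

#' @export
glance.overlap_summary <- function(x, ...) {
  as_tibble(x[c("source_a", "source_b", "kind", "a_total", "b_total", "a_only",
                "b_only", "shared", "union", "noncorrelative", "multiset_total",
                "a_share", "b_share", "a_only_share", "b_only_share",
                "shared_share", "noncorrelative_share", "unmatched_share",
                "rounding")])
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.overlap_summary <- function(object, ...) {
  d <- tidy(object)
  d$part <- factor(d$part, levels = c("only_a", "shared", "only_b"))
  ggplot2::ggplot(d, ggplot2::aes(x = "hits", y = .data$count, fill = .data$part)) +
    ggplot2::geom_col(position = "stack", width = 0.6) +
    ggplot2::scale_fill_manual(values = c(only_a = "#d73027", shared = "#1a9850",
                                          only_b = "#fee08b"),
                               labels = setNames(d$source, d$part)) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "distinct hits", fill = "asserted by",
                  title = paste0("Source overlap",
                                 if (!is.na(object$kind)) paste0(": ", object$kind))) +
    ggplot2::theme_minimal()
}

kb_hit_sets <- function(kb, assertion_kind, sources) {
  if (!all(sources %in% kb$source_tags)) {
    abort(paste0("Unknown source tag(s): ",
                 paste(setdiff(sources, kb$source_tags), collapse = ", ")))
  }
  keys_prov <- switch(
    assertion_kind,
    interactions = list(key = paste0(kb$interactions$drug_a, "\r", kb$interactions$drug_b),
                        prov = kb$interactions$provenance),
    side_effects = list(key = paste0(kb$side_effects$drug_id, "\r", kb$side_effects$term),
                        prov = kb$side_effects$provenance),
    abort("assertion_kind must be 'interactions' or 'side_effects'.")
  )
  list(
    a = keys_prov$key[map_lgl(keys_prov$prov, function(p) sources[1] %in% p)],
    b = keys_prov$key[map_lgl(keys_prov$prov, function(p) sources[2] %in% p)]
  )
}

#' Concordance of two sources within a knowledge base
#'
#' Builds each source's distinct hit set (canonical drug pairs for
#' interactions, (drug, canonical term) pairs for side effects) from
#' assertion provenance and summarises their overlap with inclusive counts.
#'
#' @param kb a `drug_kb`.
#' @param assertion_kind `"interactions"` or `"side_effects"`.
#' @param sources length-2 character vector of compared source tags.
#' @param rounding percentage rounding mode (see [summary_from_exclusive()]).
#' @return an `overlap_summary`.
#' @export
kb_overlap <- function(kb, assertion_kind = c("interactions", "side_effects"),
                       sources = NULL, rounding = "two_decimal") {
  stopifnot(inherits(kb, "drug_kb"))
  assertion_kind <- match.arg(assertion_kind)
  sources <- sources %||% default_sources(kb, assertion_kind)
  hs <- kb_hit_sets(kb, assertion_kind, sources)
  s <- summary_from_inclusive(length(hs$a), length(hs$b),
                              length(union(hs$a, hs$b)), rounding = rounding)
  s$source_a <- sources[1]; s$source_b <- sources[2]; s$kind <- assertion_kind
  s
}

#' Per-drug hit counts for a list of leading drugs
#'
#' For each listed drug, counts its hits per source and the shared hits;
#' the aggregate summary covers the distinct hits involving at least one
#' listed drug. Unresolvable drug names are reported and excluded; drugs
#' with no assertions keep an explicit zero row.
#'
#' @param kb a `drug_kb`.
#' @param drugs character vector of drug names or ids (e.g. a top-20 list).
#' @param assertion_kind `"interactions"` or `"side_effects"`.
#' @param sources length-2 character vector of compared source tags.
#' @param rounding percentage rounding mode.
#' @return object of class `top_hits`: `per_drug` tibble (`drug`, `a_hits`,
#'   `b_hits`, `shared_hits`) and `summary` (`overlap_summary` over
#'   distinct hits).
#' @export
top_n_evaluation <- function(kb, drugs, assertion_kind = c("interactions", "side_effects"),
                             sources = NULL, rounding = "two_decimal") {
  stopifnot(inherits(kb, "drug_kb"))
  assertion_kind <- match.arg(assertion_kind)
  sources <- sources %||% default_sources(kb, assertion_kind)
  ids <- map_chr(drugs, function(q) {
    tryCatch(resolve_drug(kb, q), drugkb_bad_query = function(e) NA_character_)
  })
  if (any(is.na(ids))) {
    warn(paste0("Unresolvable drug(s) excluded from evaluation: ",
                paste(drugs[is.na(ids)], collapse = ", ")))
  }
  keep <- !is.na(ids)
  ids <- ids[keep]; labels <- drugs[keep]
  hs <- kb_hit_sets(kb, assertion_kind, sources)
  involves <- function(keys, id) {
    parts <- stringr::str_split(keys, stringr::fixed("\r"))
    map_lgl(parts, function(p) id %in% p)
  }
  per_drug <- bind_rows(map(seq_along(ids), function(k) {
    a_k <- hs$a[involves(hs$a, ids[k])]
    b_k <- hs$b[involves(hs$b, ids[k])]
    tibble(drug = labels[k], drug_id = ids[k],
           a_hits = length(a_k), b_hits = length(b_k),
           shared_hits = length(intersect(a_k, b_k)))
  }))
  if (is.null(per_drug) || nrow(per_drug) == 0) {
    per_drug <- tibble(drug = character(), drug_id = character(),
                       a_hits = integer(), b_hits = integer(), shared_hits = integer())
  }
  any_listed_a <- hs$a[map_lgl(involves_any(hs$a, ids), isTRUE)]
  any_listed_b <- hs$b[map_lgl(involves_any(hs$b, ids), isTRUE)]
  s <- summary_from_inclusive(length(any_listed_a), length(any_listed_b),
                              length(union(any_listed_a, any_listed_b)),
                              rounding = rounding)
  s$source_a <- sources[1]; s$source_b <- sources[2]; s$kind <- assertion_kind
  structure(list(per_drug = per_drug, summary = s), class = "top_hits")
}

involves_any <- function(keys, ids) {
  parts <- stringr::str_split(keys, stringr::fixed("\r"))
  map_lgl(parts, function(p) any(p %in% ids))
}

#' @export
print.top_hits <- function(x, ...) {
  cat("<top_hits> ", nrow(x$per_drug), " drugs\n", sep = "")
  print(x$per_drug)
  print(x$summary)
  invisible(x)
}

#' @export
tidy.top_hits <- function(x, ...) x$per_drug

#' @export
glance.top_hits <- function(x, ...) glance(x$summary)

#' @export
autoplot.top_hits <- function(object, ...) {
  d <- tidyr::pivot_longer(object$per_drug, c("a_hits", "b_hits", "shared_hits"),
                           names_to = "set", values_to = "hits")
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$drug, .data$hits),
                                  y = .data$hits, fill = .data$set)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "hits",
                  fill = NULL, title = "Per-drug hits by source") +
    ggplot2::theme_minimal()
}
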