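#' @importFrom rlang abort warn inform %||% .data
#' @importFrom dplyr filter mutate select arrange group_by summarise ungroup
#'   distinct bind_rows left_join anti_join semi_join rename n row_number across
#' @importFrom tibble tibble as_tibble
#' @importFrom purrr map map_chr map_int map_lgl map2 pmap imap keep
#' @importFrom stats setNames
#' @importFrom utils head
NULL

#' Normalize a drug, disease or side-effect name
#'
#' Case-folds, trims, strips punctuation and collapses internal whitespace.
#' This is the single normalization rule used everywhere a name or term is
#' compared: drug resolution, cross-source name mapping, synonym lookup and
#' diagnosis/side-effect matching. Salt or stereo suffixes are deliberately
#' not stripped.
#'
#' @param x character vector of raw names.
#' @return character vector of normalized names.
#' @examples
#' normalize_name(c("  Clonazepam ", "ACETYL-salicylic   Acid"))
#' @export
normalize_name <- function(x) {
  x <- stringr::str_to_lower(x)
  x <- stringr::str_replace_all(x, "[[:punct:]]+", " ")
  x <- stringr::str_squish(x)
  x
}

# 7-character ATC pattern: letter, 2 digits, 2 letters, 2 digits
ATC_PATTERN <- "^[A-Z][0-9]{2}[A-Z]{2}[0-9]{2}$"

#' Check ATC code validity
#'
#' A valid code has the full 7-character anatomical-therapeutic-chemical
#' shape (e.g. \code{N03AE01}). Partial class-level codes never validate:
#' class-level matches must not fuse distinct substances.
#'
#' @param x character vector of candidate codes.
#' @return logical vector.
#' @export
is_valid_atc <- function(x) {
  stringr::str_detect(stringr::str_to_upper(x %||% character()), ATC_PATTERN)
}

# Round half away from zero, the convention used for all printed percentages
# (base round() is half-even and would print 14.1 where 14.10 is expected).
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Locale-independent character sort; all deterministic ordering goes through
# this so output is byte-identical across machines.
sort_c <- function(x, decreasing = FALSE) {
  sort(x, decreasing = decreasing, method = "radix")
}

# Canonical unordered drug pair: lexicographically smaller id first.
canonical_pair <- function(a, b) {
  if (any(a == b)) abort("A drug cannot interact with itself (self-pair).")
  tibble(drug_a = pmin(a, b), drug_b = pmax(a, b))
}

# Split pipe-separated list cells; "" and NA give character(0).
split_pipe <- function(x) {
  map(x, function(v) {
    if (is.na(v) || !nzchar(v)) return(character())
    unique(stringr::str_trim(stringr::str_split_1(v, stringr::fixed("|"))))
  })
}

join_pipe <- function(x) {
  map_chr(x, function(v) paste(v, collapse = "|"))
}

# Parse "key:value" xref strings into a named character vector.
parse_xrefs <- function(x) {
  map(split_pipe(x), function(v) {
    if (length(v) == 0) return(setNames(character(), character()))
    key <- stringr::str_extract(v, "^[^:]+")
    val <- stringr::str_remove(v, "^[^:]+:")
    ok <- !is.na(key) & nzchar(val) & stringr::str_detect(v, ":")
    setNames(val[ok], key[ok])
  })
}
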