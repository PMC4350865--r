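#' Radial network documents
#'
#' Analysis results are exported as radial, level-coded network documents
#' for downstream visualization: the query inputs sit at level 0 in the
#' centre, results form concentric rings whose level and symbolic color
#' encode which sources support them. The document is topology plus levels
#' only — layout coordinates are left to the rendering library.
#'
#' For provenance-partitioned results the ring scheme is: hits asserted by
#' both compared sources on ring 1 (green), first-source-only hits on ring
#' 2 (red), second-source-only hits on ring 3 (yellow). For composite
#' medication reports: interacting profile drugs are red and no-risk drugs
#' blue at level 0; CYP enzymes ring 1 (violet); cumulative side effects
#' ring 2 (yellow); drug-induced disease candidates ring 3 (orange). One
#' edge is emitted per finding. Nodes are ordered by level then label.
#'
#' @param result an analysis result: a `provenance_partition` or a
#'   `medication_report`.
#' @param kb the `drug_kb` the result was computed from.
#' @param ... passed to methods.
#' @return an object of class `radial_network_doc` with tibbles `nodes`
#'   (`node_id`, `label`, `entity_type`, `level`, `color_code`), `edges`
#'   (`from`, `to`, `relation`, `provenance`, `detail`) and `legend`
#'   (`level`, `meaning`).
#' @export
build_radial_network <- function(result, kb, ...) {
  UseMethod("build_radial_network")
}

new_radial_doc <- function(nodes, edges, legend) {
  nodes <- nodes[order(nodes$level, nodes$label, nodes$node_id, method = "radix"), , drop = FALSE]
  edges <- edges[order(edges$from, edges$to, edges$relation,
                       edges$detail, method = "radix"), , drop = FALSE]
  structure(list(nodes = as_tibble(nodes), edges = as_tibble(edges),
                 legend = as_tibble(legend)),
            class = "radial_network_doc")
}

empty_nodes <- function() {
  tibble(node_id = character(), label = character(), entity_type = character(),
         level = integer(), color_code = character())
}
empty_edges <- function() {
  tibble(from = character(), to = character(), relation = character(),
         provenance = list(), detail = character())
}

#' @rdname build_radial_network
#' @export
build_radial_network.provenance_partition <- function(result, kb, ...) {
  entity <- if (result$kind == "interactions") "drug" else "side_effect"
  relation <- if (result$kind == "interactions") "interacts" else "causes"
  items <- result$items
  lvl <- c(shared = 1L, only_a = 2L, only_b = 3L)
  col <- c(shared = "green", only_a = "red", only_b = "yellow")
  prov <- list(shared = sort_c(c(result$source_a, result$source_b)),
               only_a = result$source_a, only_b = result$source_b)
  ring_id <- if (entity == "drug") items$item_id else paste0("se:", normalize_name(items$label))
  nodes <- bind_rows(
    tibble(node_id = result$center_id, label = result$center_label,
           entity_type = "drug", level = 0L, color_code = "blue"),
    tibble(node_id = ring_id, label = items$label, entity_type = entity,
           level = unname(lvl[items$part]), color_code = unname(col[items$part]))
  )
  edges <- tibble(from = result$center_id, to = ring_id, relation = relation,
                  provenance = unname(prov[items$part]), detail = NA_character_)
  if (nrow(items) == 0) edges <- empty_edges()
  legend <- tibble(
    level = 0:3,
    meaning = c("input", paste0("shared by ", result$source_a, " and ", result$source_b),
                paste0(result$source_a, " only"), paste0(result$source_b, " only"))
  )
  new_radial_doc(nodes, edges, legend)
}

#' @rdname build_radial_network
#' @export
build_radial_network.medication_report <- function(result, kb, ...) {
  prof <- result$profile
  risky <- setdiff(prof$drug_ids, result$no_risk_drugs$drug_id)
  nodes <- tibble(
    node_id = prof$drug_ids,
    label = prof$drug_names,
    entity_type = "drug", level = 0L,
    color_code = ifelse(prof$drug_ids %in% risky, "red", "blue")
  )
  edges <- empty_edges()
  ia <- result$interactions
  if (nrow(ia) > 0) {
    edges <- bind_rows(edges, tibble(
      from = ia$drug_a, to = ia$drug_b, relation = "interacts",
      provenance = ia$provenance,
      detail = map_chr(ia$effects, function(e) {
        if (length(e) == 0) NA_character_ else paste(e, collapse = " / ")
      })
    ))
  }
  fl <- result$cyp_flags
  if (nrow(fl) > 0) {
    nodes <- bind_rows(nodes, tibble(
      node_id = paste0("mol:", unique(fl$cyp)),
      label = unique(fl$cyp), entity_type = "molecule",
      level = 1L, color_code = "violet"))
    edges <- bind_rows(edges, tibble(
      from = fl$perpetrator, to = paste0("mol:", fl$cyp), relation = "metabolizes",
      provenance = list(character()), detail = fl$rationale))
  }
  cm <- result$cumulative_effects
  if (nrow(cm) > 0) {
    nodes <- bind_rows(nodes, tibble(
      node_id = paste0("se:", normalize_name(cm$term)),
      label = cm$term, entity_type = "side_effect",
      level = 2L, color_code = "yellow"))
    contrib <- tidyr::unnest(select(cm, "term", "drug_ids"), "drug_ids")
    edges <- bind_rows(edges, tibble(
      from = contrib$drug_ids, to = paste0("se:", normalize_name(contrib$term)),
      relation = "causes", provenance = list(character()), detail = NA_character_))
  }
  idz <- result$induced_diseases
  if (!is.null(idz) && nrow(idz$matches) > 0) {
    nodes <- bind_rows(nodes, tibble(
      node_id = paste0("dz:", normalize_name(idz$matches$diagnosis)),
      label = idz$matches$diagnosis, entity_type = "disease",
      level = 3L, color_code = "orange"))
    contrib <- tidyr::unnest(select(idz$matches, "diagnosis", "drug_ids"), "drug_ids")
    edges <- bind_rows(edges, tibble(
      from = contrib$drug_ids, to = paste0("dz:", normalize_name(contrib$diagnosis)),
      relation = "induces_disease", provenance = list(character()),
      detail = NA_character_))
  }
  legend <- tibble(
    level = 0:3,
    meaning = c("input drugs (red: interacting, blue: without potential risks)",
                "CYP enzymes (violet)", "cumulative side effects (yellow)",
                "drug-induced disease candidates (orange)")
  )
  new_radial_doc(distinct(nodes), edges, legend)
}

#' @export
print.radial_network_doc <- function(x, ...) {
  cat("<radial_network_doc> ", nrow(x$nodes), " nodes, ", nrow(x$edges),
      " edges, levels 0..", max(c(0L, x$nodes$level)), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.radial_network_doc <- function(x, ...) x$nodes

#' @export
autoplot.radial_network_doc <- function(object, ...) {
  n <- object$nodes |>
    group_by(.data$level) |>
    mutate(angle = 2 * pi * (row_number() - 1) / n()) |>
    ungroup() |>
    mutate(x = .data$level * cos(.data$angle), y = .data$level * sin(.data$angle))
  e <- object$edges |>
    left_join(select(n, "node_id", xf = "x", yf = "y"), by = c(from = "node_id")) |>
    left_join(select(n, "node_id", xt = "x", yt = "y"), by = c(to = "node_id"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = e, ggplot2::aes(x = .data$xf, y = .data$yf,
                                                 xend = .data$xt, yend = .data$yt),
                          color = "grey70") +
    ggplot2::geom_point(data = n, ggplot2::aes(x = .data$x, y = .data$y,
                                               color = .data$color_code), size = 4) +
    ggplot2::geom_text(data = n, ggplot2::aes(x = .data$x, y = .data$y,
                                              label = .data$label),
                       vjust = -1.2, size = 3) +
    ggplot2::scale_color_identity() +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(title = "Radial result network")
}

#' Serialize a radial network document to canonical JSON
#'
#' Produces deterministic JSON: keys sorted, nodes ordered by level then
#' label, edges by endpoints. Identical documents serialize to identical
#' bytes, and parse/serialize is a fixed point.
#'
#' @param doc a `radial_network_doc`.
#' @return a single JSON string (class `json`).
#' @seealso [parse_network()]
#' @export
serialize_network <- function(doc) {
  stopifnot(inherits(doc, "radial_network_doc"))
  nodes <- map(seq_len(nrow(doc$nodes)), function(i) {
    list(color_code = doc$nodes$color_code[i],
         entity_type = doc$nodes$entity_type[i],
         label = doc$nodes$label[i],
         level = doc$nodes$level[i],
         node_id = doc$nodes$node_id[i])
  })
  edges <- map(seq_len(nrow(doc$edges)), function(i) {
    list(detail = doc$edges$detail[i],
         from = doc$edges$from[i],
         provenance = as.list(doc$edges$provenance[[i]]),
         relation = doc$edges$relation[i],
         to = doc$edges$to[i])
  })
  legend <- setNames(as.list(doc$legend$meaning), as.character(doc$legend$level))
  jsonlite::toJSON(list(edges = edges, legend = legend, nodes = nodes),
                   auto_unbox = TRUE, null = "null", na = "null", digits = NA,
                   pretty = TRUE)
}

#' Parse a serialized radial network document
#'
#' @param json JSON text produced by [serialize_network()].
#' @return a `radial_network_doc`.
#' @export
parse_network <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  nodes <- if (length(x$nodes)) bind_rows(map(x$nodes, function(n) {
    tibble(node_id = n$node_id, label = n$label, entity_type = n$entity_type,
           level = as.integer(n$level), color_code = n$color_code)
  })) else empty_nodes()
  edges <- if (length(x$edges)) bind_rows(map(x$edges, function(e) {
    tibble(from = e$from, to = e$to, relation = e$relation,
           provenance = list(unlist(e$provenance) %||% character()),
           detail = e$detail %||% NA_character_)
  })) else empty_edges()
  legend <- tibble(level = as.integer(names(x$legend)),
                   meaning = unlist(x$legend, use.names = FALSE) %||% character())
  new_radial_doc(nodes, edges, legend)
}
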