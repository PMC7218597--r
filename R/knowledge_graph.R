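# Combination-centric knowledge graph: drugs are bound into a combination
# node that is directed at a disease, with the supporting conclusive claims
# attached to the treatment edge as evidence.

drug_node_id <- function(cui) paste0("drug:", cui)
disease_node_id <- function(cui) paste0("dis:", cui)

# Deterministic combination identity: the same drug set treating two
# different diseases (or under two predicates) is two distinct combinations.
combination_node_id <- function(member_cuis, predicate, object_cui) {
  paste0("cmb:", paste(sort(member_cuis), collapse = "+"), ":", predicate, ":", object_cui)
}

empty_evidence <- function() {
  tibble::tibble(pmid = character(), sentence_id = character(),
                 claim_text = character(), markers = list(), any_inferred = logical())
}

empty_kg <- function() {
  structure(list(
    nodes = tibble::tibble(id = character(), kind = character(), label = character(),
                           cui = character(), member_cuis = list()),
    edges = tibble::tibble(source = character(), target = character(), kind = character(),
                           predicate = character(), evidence = list())
  ), class = "combo_kg")
}

#' Build the combination knowledge graph from candidate groups
#'
#' Each candidate group contributes a combination node (its drugs bound
#' together), `member_of` edges from each drug node, and a `treats_like`
#' edge directed at the disease node, labeled with the base predicate and
#' carrying the conclusive claim as evidence. Identical combinations (same
#' sorted member CUIs, predicate, and disease) asserted in different claims
#' merge into one combination node whose treatment edge accumulates all
#' supporting claims. Drug and disease nodes are unique per CUI.
#'
#' @param groups Candidate-group tibble (see [discover_combinations()]).
#' @return A `combo_kg` object: a list of `nodes` (`id`, `kind` in
#'   drug/combination/disease, `label`, `cui`, `member_cuis`) and `edges`
#'   (`source`, `target`, `kind`, `predicate`, `evidence`), both in sorted
#'   deterministic order.
#' @export
build_graph <- function(groups) {
  if (nrow(groups) == 0L) return(empty_kg())
  cmb_id <- purrr::pmap_chr(
    list(groups$subjects, groups$predicate_base, groups$object_cui),
    function(s, p, o) combination_node_id(s$cui, p, o)
  )
  drug_tbl <- dplyr::bind_rows(groups$subjects)
  drug_tbl <- drug_tbl[!duplicated(drug_tbl$cui), , drop = FALSE]
  drug_nodes <- tibble::tibble(
    id = drug_node_id(drug_tbl$cui), kind = "drug", label = drug_tbl$name,
    cui = drug_tbl$cui, member_cuis = rep(list(character(0)), nrow(drug_tbl))
  )
  dis_tbl <- tibble::tibble(cui = groups$object_cui, name = groups$object_name)
  dis_tbl <- dis_tbl[!duplicated(dis_tbl$cui), , drop = FALSE]
  disease_nodes <- tibble::tibble(
    id = disease_node_id(dis_tbl$cui), kind = "disease", label = dis_tbl$name,
    cui = dis_tbl$cui, member_cuis = rep(list(character(0)), nrow(dis_tbl))
  )

  first_of <- !duplicated(cmb_id)
  cmb_nodes <- tibble::tibble(
    id = cmb_id[first_of],
    kind = "combination",
    label = purrr::map_chr(groups$subjects[first_of],
                           ~ paste(.x$name[order(.x$cui)], collapse = " + ")),
    cui = "",
    member_cuis = purrr::map(groups$subjects[first_of], ~ sort(.x$cui))
  )

  member_edges <- dplyr::bind_rows(purrr::map(which(first_of), function(i) {
    tibble::tibble(
      source = drug_node_id(sort(groups$subjects[[i]]$cui)),
      target = cmb_id[i], kind = "member_of", predicate = "",
      evidence = rep(list(empty_evidence()), groups$n_subjects[i])
    )
  }))
  treat_edges <- dplyr::bind_rows(purrr::map(unique(cmb_id), function(id) {
    idx <- which(cmb_id == id)
    ev <- tibble::tibble(
      pmid = sub("\\.ab\\.[0-9]+$", "", groups$sentence_id[idx]),
      sentence_id = groups$sentence_id[idx],
      claim_text = groups$claim_text[idx],
      markers = purrr::map(groups$markers[idx], ~ sort(unique(.x))),
      any_inferred = groups$any_inferred[idx]
    )
    ev <- ev[order(ev$sentence_id), , drop = FALSE]
    tibble::tibble(
      source = id, target = disease_node_id(groups$object_cui[idx[1L]]),
      kind = "treats_like", predicate = groups$predicate_base[idx[1L]],
      evidence = list(ev)
    )
  }))

  nodes <- dplyr::bind_rows(drug_nodes, cmb_nodes, disease_nodes)
  nodes <- nodes[order(nodes$kind, nodes$id), , drop = FALSE]
  edges <- dplyr::bind_rows(member_edges, treat_edges)
  edges <- edges[order(edges$kind, edges$source, edges$target), , drop = FALSE]
  structure(list(nodes = nodes, edges = edges), class = "combo_kg")
}

#' @export
print.combo_kg <- function(x, ...) {
  kinds <- table(x$nodes$kind)
  cat("Combination knowledge graph\n")
  cat(sprintf("  nodes: %d (%s)\n", nrow(x$nodes),
              paste(sprintf("%s: %d", names(kinds), kinds), collapse = ", ")))
  cat(sprintf("  edges: %d (%d evidence items)\n", nrow(x$edges),
              sum(purrr::map_int(x$edges$evidence, nrow))))
  invisible(x)
}

#' Disease-centered subgraph
#'
#' Returns the disease node matching `disease` (by CUI, or case-insensitive
#' exact label), every combination node whose treatment edge targets it,
#' the member drugs of those combinations, and all connecting edges with
#' their evidence. An unknown disease yields an empty graph.
#'
#' @param graph A `combo_kg`.
#' @param disease Disease CUI or preferred name.
#' @return A `combo_kg` subgraph.
#' @export
query_by_disease <- function(graph, disease) {
  stopifnot(inherits(graph, "combo_kg"))
  nodes <- graph$nodes
  dis <- nodes[nodes$kind == "disease" &
                 (nodes$cui == disease | tolower(nodes$label) == tolower(disease)), , drop = FALSE]
  if (nrow(dis) == 0L) return(empty_kg())
  treat <- graph$edges[graph$edges$kind == "treats_like" &
                         graph$edges$target %in% dis$id, , drop = FALSE]
  cmb_ids <- unique(treat$source)
  member <- graph$edges[graph$edges$kind == "member_of" &
                          graph$edges$target %in% cmb_ids, , drop = FALSE]
  keep_ids <- c(member$source, cmb_ids, dis$id)
  out_nodes <- nodes[nodes$id %in% keep_ids, , drop = FALSE]
  out_edges <- dplyr::bind_rows(member, treat)
  out_edges <- out_edges[order(out_edges$kind, out_edges$source, out_edges$target), , drop = FALSE]
  structure(list(nodes = out_nodes, edges = out_edges), class = "combo_kg")
}

evidence_to_list <- function(ev) {
  purrr::map(seq_len(nrow(ev)), function(i) {
    list(
      any_inferred = ev$any_inferred[i],
      claim_text = ev$claim_text[i],
      markers = as.list(ev$markers[[i]]),
      pmid = ev$pmid[i],
      sentence_id = ev$sentence_id[i]
    )
  })
}

#' Export the graph as D3-style JSON
#'
#' Serializes to the nodes/links document consumed by force-layout
#' renderers: `{"links": [...], "nodes": [...]}` with keys in sorted order
#' and rows in the graph's deterministic node/edge order, so identical
#' graphs always serialize byte-identically.
#'
#' @param graph A `combo_kg`.
#' @param path Optional output file; when `NULL` the JSON string is
#'   returned.
#' @return The JSON string (invisibly when `path` is given).
#' @export
export_d3_json <- function(graph, path = NULL) {
  stopifnot(inherits(graph, "combo_kg"))
  nodes <- purrr::map(seq_len(nrow(graph$nodes)), function(i) {
    list(
      cui = graph$nodes$cui[i],
      id = graph$nodes$id[i],
      kind = graph$nodes$kind[i],
      label = graph$nodes$label[i],
      member_cuis = as.list(graph$nodes$member_cuis[[i]])
    )
  })
  links <- purrr::map(seq_len(nrow(graph$edges)), function(i) {
    list(
      evidence = evidence_to_list(graph$edges$evidence[[i]]),
      kind = graph$edges$kind[i],
      predicate = graph$edges$predicate[i],
      source = graph$edges$source[i],
      target = graph$edges$target[i]
    )
  })
  json <- jsonlite::toJSON(list(links = links, nodes = nodes),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
  json <- paste0(as.character(json), "\n")
  if (!is.null(path)) {
    writeLines(json, path, sep = "", useBytes = TRUE)
    return(invisible(json))
  }
  json
}

#' Import a graph from D3-style JSON
#'
#' Inverse of [export_d3_json()]: `import_kg_json(export_d3_json(g))`
#' reconstructs `g` exactly, and re-exporting is byte-identical.
#'
#' @param x Path to a JSON file, or a JSON string.
#' @return A `combo_kg`.
#' @export
import_kg_json <- function(x) {
  doc <- jsonlite::fromJSON(x, simplifyVector = FALSE)
  if (length(doc$nodes) == 0L) return(empty_kg())
  nodes <- tibble::tibble(
    id = purrr::map_chr(doc$nodes, "id"),
    kind = purrr::map_chr(doc$nodes, "kind"),
    label = purrr::map_chr(doc$nodes, "label"),
    cui = purrr::map_chr(doc$nodes, "cui"),
    member_cuis = purrr::map(doc$nodes, ~ as.character(unlist(.x$member_cuis)))
  )
  edges <- tibble::tibble(
    source = purrr::map_chr(doc$links, "source"),
    target = purrr::map_chr(doc$links, "target"),
    kind = purrr::map_chr(doc$links, "kind"),
    predicate = purrr::map_chr(doc$links, "predicate"),
    evidence = purrr::map(doc$links, function(l) {
      if (length(l$evidence) == 0L) return(empty_evidence())
      tibble::tibble(
        pmid = purrr::map_chr(l$evidence, "pmid"),
        sentence_id = purrr::map_chr(l$evidence, "sentence_id"),
        claim_text = purrr::map_chr(l$evidence, "claim_text"),
        markers = purrr::map(l$evidence, ~ as.character(unlist(.x$markers))),
        any_inferred = purrr::map_lgl(l$evidence, "any_inferred")
      )
    })
  )
  structure(list(nodes = nodes, edges = edges), class = "combo_kg")
}

#' Export the graph as flat triples TSV
#'
#' One row per drug membership (`drug, MEMBER_OF, combination`) and one per
#' treatment assertion (`combination, <predicate>, disease`) with the
#' supporting PMIDs semicolon-joined; a flat interchange format for loading
#' the combinations into downstream knowledge bases.
#'
#' @param graph A `combo_kg`.
#' @param path Optional output file.
#' @return Character vector of TSV lines (invisibly when `path` is given).
#' @export
export_triples_tsv <- function(graph, path = NULL) {
  stopifnot(inherits(graph, "combo_kg"))
  header <- "subject\tpredicate\tobject\tevidence_pmids"
  member <- graph$edges[graph$edges$kind == "member_of", , drop = FALSE]
  treat <- graph$edges[graph$edges$kind == "treats_like", , drop = FALSE]
  lines <- c(
    header,
    sprintf("%s\tMEMBER_OF\t%s\t", member$source, member$target),
    sprintf("%s\t%s\t%s\t%s", treat$source, treat$predicate, treat$target,
            purrr::map_chr(treat$evidence, ~ paste(sort(unique(.x$pmid)), collapse = ";")))
  )
  if (!is.null(path)) {
    writeLines(lines, path, useBytes = TRUE)
    return(invisible(lines))
  }
  lines
}
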