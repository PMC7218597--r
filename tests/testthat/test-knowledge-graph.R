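worked_groups <- function() {
  we <- worked_example()
  claims <- extract_conclusive_claims(we$abstracts)
  discover_corpus(claims, we$predications, lists = build_filter_lists(we$mesh))
}

two_drug_group <- function(sentence_id, drug_cuis = c("C1", "C2"),
                           object_cui = "C9", object_name = "Glioblastoma") {
  claim <- make_claim(sentence_id,
                      text = "In conclusion, the combination was effective.")
  preds <- dplyr::bind_rows(lapply(seq_along(drug_cuis), function(i) {
    make_pred(drug_cuis[i], paste0("drug", drug_cuis[i]), "TREATS",
              object_cui, object_name, sentence_id = sentence_id)
  }))
  discover_combinations(claim, preds)
}

test_that("one three-drug group builds a five-node, four-edge graph", {
  kg <- build_graph(worked_groups())
  expect_identical(nrow(kg$nodes), 5L)
  expect_identical(sum(kg$nodes$kind == "drug"), 3L)
  expect_identical(sum(kg$nodes$kind == "combination"), 1L)
  expect_identical(sum(kg$nodes$kind == "disease"), 1L)
  expect_identical(nrow(kg$edges), 4L)
  expect_identical(sum(kg$edges$kind == "member_of"), 3L)
  treat <- kg$edges[kg$edges$kind == "treats_like", ]
  expect_identical(nrow(treat), 1L)
  expect_identical(nrow(treat$evidence[[1]]), 1L)
  expect_identical(treat$evidence[[1]]$pmid, "19322566")
  cmb <- kg$nodes[kg$nodes$kind == "combination", ]
  expect_identical(cmb$id, "cmb:C0069717+C0671970+C1518922:TREATS:C2931852")
  expect_identical(cmb$member_cuis[[1]], c("C0069717", "C0671970", "C1518922"))
})

test_that("an empty group list builds an empty graph", {
  kg <- build_graph(worked_groups()[0, ])
  expect_identical(nrow(kg$nodes), 0L)
  expect_identical(nrow(kg$edges), 0L)
  expect_match(export_d3_json(kg), '"links": \\[\\]')
  expect_match(export_d3_json(kg), '"nodes": \\[\\]')
})

test_that("identical combinations from different claims merge with accumulated evidence", {
  groups <- dplyr::bind_rows(
    two_drug_group("10000001.ab.5"),
    two_drug_group("10000002.ab.7")
  )
  kg <- build_graph(groups)
  expect_identical(sum(kg$nodes$kind == "combination"), 1L)
  treat <- kg$edges[kg$edges$kind == "treats_like", ]
  expect_identical(nrow(treat), 1L)
  expect_identical(treat$evidence[[1]]$sentence_id, c("10000001.ab.5", "10000002.ab.7"))
  # evidence conservation: one item per input group
  expect_identical(sum(vapply(kg$edges$evidence, nrow, integer(1))), nrow(groups))
  # member_of edge count equals total combination membership
  cmb <- kg$nodes[kg$nodes$kind == "combination", ]
  expect_identical(sum(kg$edges$kind == "member_of"),
                   sum(lengths(cmb$member_cuis)))
})

test_that("the same drug pair treating two diseases yields two combination nodes", {
  groups <- dplyr::bind_rows(
    two_drug_group("10000001.ab.5", object_cui = "C9", object_name = "Glioblastoma"),
    two_drug_group("10000002.ab.7", object_cui = "C8", object_name = "Breast Carcinoma")
  )
  kg <- build_graph(groups)
  expect_identical(sum(kg$nodes$kind == "combination"), 2L)
  expect_identical(sum(kg$nodes$kind == "drug"), 2L)
})

test_that("disease-centered queries return exactly the attached combinations", {
  groups <- dplyr::bind_rows(
    two_drug_group("10000001.ab.5", c("C1", "C2"), "C9", "Glioblastoma"),
    two_drug_group("10000002.ab.7", c("C3", "C4"), "C9", "Glioblastoma"),
    two_drug_group("10000003.ab.2", c("C1", "C5"), "C8", "Breast Carcinoma")
  )
  kg <- build_graph(groups)
  sub <- query_by_disease(kg, "C9")
  expect_identical(sum(sub$nodes$kind == "combination"), 2L)
  expect_identical(sum(sub$nodes$kind == "disease"), 1L)
  expect_setequal(sub$nodes$cui[sub$nodes$kind == "drug"], c("C1", "C2", "C3", "C4"))
  # name query, case-insensitive, equals CUI query
  expect_identical(query_by_disease(kg, "gLiObLaStOmA"), sub)
  empty <- query_by_disease(kg, "No Such Disease")
  expect_identical(nrow(empty$nodes), 0L)
})

test_that("the JSON export round-trips exactly and byte-identically", {
  groups <- dplyr::bind_rows(worked_groups(), two_drug_group("10000001.ab.5"))
  kg <- build_graph(groups)
  json <- export_d3_json(kg)
  back <- import_kg_json(json)
  expect_identical(back, kg)
  expect_identical(export_d3_json(back), json)
  f <- withr::local_tempfile(fileext = ".json")
  export_d3_json(kg, f)
  expect_identical(import_kg_json(f), kg)
})

test_that("the triples export flattens memberships and treatment assertions", {
  kg <- build_graph(worked_groups())
  lines <- export_triples_tsv(kg)
  expect_length(lines, 5L)  # header + 3 memberships + 1 treatment
  expect_identical(sum(grepl("\tMEMBER_OF\t", lines)), 3L)
  expect_identical(sum(grepl("\tTREATS\t", lines)), 1L)
  expect_match(lines[5], "19322566$")
  expect_identical(export_triples_tsv(build_graph(worked_groups()[0, ])),
                   "subject\tpredicate\tobject\tevidence_pmids")
})
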