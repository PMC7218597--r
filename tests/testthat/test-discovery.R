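test_that("the worked example yields one three-drug combination group", {
  we <- worked_example()
  claims <- extract_conclusive_claims(we$abstracts)
  claim <- claims[claims$sentence_id == "19322566.ab.15", ]
  groups <- discover_combinations(claim, we$predications,
                                  lists = build_filter_lists(we$mesh))
  expect_identical(nrow(groups), 1L)
  expect_identical(groups$predicate_base, "TREATS")
  expect_identical(groups$object_name, "Advanced Malignant Solid Neoplasm")
  expect_setequal(groups$subjects[[1]]$name, c("GTI2040", "capecitabine", "oxaliplatin"))
  expect_true(groups$any_inferred)
  expect_identical(groups$markers[[1]], "combin*")
  expect_false(groups$comparison_flag)
})

test_that("degenerate claims yield no groups", {
  claim <- make_claim()
  one <- make_pred("C1", "x", "TREATS", "C2", "y")
  expect_identical(nrow(discover_combinations(claim, one)), 0L)
  # same subject, different objects: grouping key separates them
  two <- dplyr::bind_rows(
    make_pred("C1", "x", "TREATS", "C2", "y"),
    make_pred("C1", "x", "TREATS", "C3", "z")
  )
  expect_identical(nrow(discover_combinations(claim, two)), 0L)
  # duplicate subject CUI under one key never inflates the subject set
  dup <- dplyr::bind_rows(
    make_pred("C1", "x", "TREATS", "C2", "y"),
    make_pred("C1", "x", "TREATS(INFER)", "C2", "y")
  )
  expect_identical(nrow(discover_combinations(claim, dup)), 0L)
})

test_that("predications from another sentence are rejected", {
  claim <- make_claim("10000001.ab.5")
  stray <- make_pred("C1", "x", "TREATS", "C2", "y", sentence_id = "10000001.ab.6")
  expect_error(discover_combinations(claim, stray), "does not match")
})

test_that("either-or multi-combination claims surface as one group (a known false-positive mode)", {
  claim <- make_claim(
    text = "CONCLUSION: Custirsen plus either docetaxel or mitoxantrone was feasible in patients with progressive mCRPC.")
  preds <- dplyr::bind_rows(
    make_pred("C1", "Custirsen", "TREATS", "C9", "Hormone refractory prostate cancer"),
    make_pred("C2", "docetaxel", "TREATS", "C9", "Hormone refractory prostate cancer"),
    make_pred("C3", "Mitoxantrone", "TREATS", "C9", "Hormone refractory prostate cancer")
  )
  groups <- discover_combinations(claim, preds)
  expect_identical(nrow(groups), 1L)
  expect_identical(groups$n_subjects, 3L)
  expect_identical(groups$markers[[1]], character(0))
})

test_that("comparison flagging requires a COMPARED_WITH link between two group members", {
  claim <- make_claim(
    text = "CONCLUSION: Both pemetrexed and erlotinib had comparable efficacy in pre-treated patients.")
  base <- dplyr::bind_rows(
    make_pred("C1", "pemetrexed", "TREATS", "C9", "Non-small cell lung cancer metastatic"),
    make_pred("C2", "erlotinib", "TREATS", "C9", "Non-small cell lung cancer metastatic")
  )
  with_cmp <- dplyr::bind_rows(base,
    make_pred("C1", "pemetrexed", "COMPARED_WITH", "C2", "erlotinib",
              object_semtypes = "phsu"))
  g <- discover_combinations(claim, with_cmp)
  expect_true(g$comparison_flag)
  expect_identical(nrow(g), 1L)  # flagged, never deleted

  expect_false(discover_combinations(claim, base)$comparison_flag)

  outside <- dplyr::bind_rows(base,
    make_pred("C1", "pemetrexed", "COMPARED_WITH", "C7", "placebo",
              object_semtypes = "phsu"))
  expect_false(discover_combinations(claim, outside)$comparison_flag)
})

test_that("discovery is invariant under permutation of the input predications", {
  set.seed(101)
  claim <- make_claim()
  for (rep in 1:25) {
    preds <- random_predications(sample(2:8, 1))
    g1 <- discover_combinations(claim, preds)
    g2 <- discover_combinations(claim, preds[sample(nrow(preds)), ])
    expect_identical(g1[, setdiff(names(g1), "source_predication_count")],
                     g2[, setdiff(names(g2), "source_predication_count")])
  }
})

test_that("discovery agrees with brute-force subset enumeration on random claims", {
  set.seed(202)
  claim <- make_claim()
  for (rep in 1:200) {
    preds <- random_predications(sample(0:6, 1))
    filtered <- filter_treatment_predications(preds)
    expect_identical(group_keys(discover_combinations(claim, preds)),
                     oracle_group_keys(filtered))
  }
})

test_that("group summaries count sizes, markers, and comparison flags", {
  claim3 <- make_claim("10000001.ab.5")
  claim2a <- make_claim("10000002.ab.3",
                        text = "In conclusion, the regimen of A plus B was effective.")
  claim2b <- make_claim("10000003.ab.4",
                        text = "We conclude that A and B can be co-administered safely.")
  groups <- dplyr::bind_rows(
    discover_combinations(claim3, dplyr::bind_rows(
      make_pred("C1", "a", "TREATS", "C9", "d", sentence_id = "10000001.ab.5"),
      make_pred("C2", "b", "TREATS", "C9", "d", sentence_id = "10000001.ab.5"),
      make_pred("C3", "c", "TREATS", "C9", "d", sentence_id = "10000001.ab.5"))),
    discover_combinations(claim2a, dplyr::bind_rows(
      make_pred("C1", "a", "TREATS", "C9", "d", sentence_id = "10000002.ab.3"),
      make_pred("C2", "b", "TREATS", "C9", "d", sentence_id = "10000002.ab.3"))),
    discover_combinations(claim2b, dplyr::bind_rows(
      make_pred("C1", "a", "TREATS", "C9", "d", sentence_id = "10000003.ab.4"),
      make_pred("C2", "b", "TREATS", "C9", "d", sentence_id = "10000003.ab.4")))
  )
  s <- summarize_groups(groups)
  expect_identical(s$n_groups, 3L)
  expect_identical(s$by_size$n_groups[s$by_size$n_subjects == 2L], 2L)
  expect_identical(s$by_size$n_groups[s$by_size$n_subjects == 3L], 1L)
  expect_identical(s$markers$n[s$markers$marker == "regimen"], 1L)
  expect_identical(s$markers$n[s$markers$marker == "co-administered"], 1L)
  empty <- summarize_groups(groups[0, ])
  expect_identical(empty$n_groups, 0L)
  expect_identical(sum(empty$markers$n), 0L)
})

test_that("mechanism patterns are order-insensitive with Other for unmapped drugs", {
  claim <- make_claim()
  g <- function(...) {
    preds <- dplyr::bind_rows(...)
    discover_combinations(claim, preds)
  }
  groups <- dplyr::bind_rows(
    g(make_pred("C1", "cisplatin", "TREATS", "C9", "d"),
      make_pred("C2", "docetaxel", "TREATS", "C9", "d")),
    g(make_pred("C3", "erlotinib", "TREATS", "C9", "d"),
      make_pred("C1", "cisplatin", "TREATS", "C9", "d"),
      make_pred("C2", "docetaxel", "TREATS", "C9", "d")),
    g(make_pred("C4", "mystery", "TREATS", "C9", "d"),
      make_pred("C3", "erlotinib", "TREATS", "C9", "d"))
  )
  class_map <- tibble::tibble(
    cui = c("C1", "C2", "C3"),
    name = c("cisplatin", "docetaxel", "erlotinib"),
    class = c("Cytotoxic", "Cytotoxic", "Targeted")
  )
  pat <- count_patterns(groups, class_map)
  expect_identical(pat$n[pat$pattern == "Cytotoxic + Cytotoxic"], 1L)
  expect_identical(pat$n[pat$pattern == "Targeted + Cytotoxic + Cytotoxic"], 1L)
  expect_identical(pat$n[pat$pattern == "Targeted + Other"], 1L)
})

test_that("candidate groups round-trip through the TSV dialect", {
  we <- worked_example()
  claims <- extract_conclusive_claims(we$abstracts)
  groups <- discover_corpus(claims, we$predications, lists = build_filter_lists(we$mesh))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_candidates_tsv(groups, f)
  back <- read_candidates_tsv(f)
  keep <- setdiff(names(groups), "source_predication_count")
  expect_identical(back[, keep], groups[, keep])
})
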