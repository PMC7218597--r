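# Combination discovery: within one conclusive claim, predications sharing a
# treatment predicate and a disease object but differing in drug subject are
# grouped into a combination candidate.

empty_groups <- function() {
  tibble::tibble(
    sentence_id = character(), claim_text = character(),
    predicate_base = character(), object_cui = character(), object_name = character(),
    subjects = list(), n_subjects = integer(), any_inferred = logical(),
    markers = list(), comparison_flag = logical(),
    source_predication_count = integer()
  )
}

# Group the (already filtered) predications of ONE claim by
# (predicate_base, object_cui); keys with >= 2 distinct subject CUIs become
# candidates. Grouping uses the object CUI, not its name, so synonymous
# object strings cannot split a combination.
group_claim_predications <- function(filtered) {
  if (nrow(filtered) == 0L) return(empty_groups())
  keys <- paste(filtered$predicate_base, filtered$object_cui, sep = "\r")
  out <- purrr::map(unique(keys), function(k) {
    rows <- filtered[keys == k, , drop = FALSE]
    subj <- tibble::tibble(cui = rows$subject_cui, name = rows$subject_name)
    subj <- subj[order(subj$cui, subj$name), , drop = FALSE]
    subj <- subj[!duplicated(subj$cui), , drop = FALSE]
    if (nrow(subj) < 2L) return(NULL)
    tibble::tibble(
      sentence_id = rows$sentence_id[1L],
      claim_text = NA_character_,
      predicate_base = rows$predicate_base[1L],
      object_cui = rows$object_cui[1L],
      object_name = rows$object_name[1L],
      subjects = list(subj),
      n_subjects = nrow(subj),
      any_inferred = any(rows$inferred),
      markers = list(character(0)),
      comparison_flag = FALSE,
      source_predication_count = nrow(rows)
    )
  })
  dplyr::bind_rows(purrr::compact(out))
}

#' Discover combination candidates within one conclusive claim
#'
#' Applies the discovery rule to a single claim: after restricting its
#' predications to treatment assertions ([filter_treatment_predications()])
#' and dropping broad concepts ([apply_filters()]), predications are grouped
#' by `(predicate_base, object_cui)`; every group with at least two distinct
#' subject CUIs becomes one candidate. Inferred (`TREATS(INFER)`) and direct
#' (`TREATS`) predications merge under the shared base predicate -- this is
#' what lets the per-drug `TREATS(INFER)` chains of a multi-drug claim fall
#' into a single group. Subjects are deduplicated by CUI and sorted; claims
#' with comparative `COMPARED_WITH` structure are flagged, never dropped.
#'
#' @param claim One-row claims tibble (see [extract_conclusive_claims()]).
#' @param preds Predications of that claim; every `sentence_id` must equal
#'   the claim's, otherwise an error is raised.
#' @param cfg A [type_config()].
#' @param lists Optional [filter_lists()]; `NULL` skips broad-concept
#'   filtering.
#' @return A candidate-group tibble: `sentence_id`, `claim_text`,
#'   `predicate_base`, `object_cui`, `object_name`, `subjects` (list-column
#'   of `cui`/`name` tibbles sorted by CUI), `n_subjects`, `any_inferred`,
#'   `markers`, `comparison_flag`, `source_predication_count`; rows sorted
#'   by `(sentence_id, predicate_base, object_cui)`.
#' @export
discover_combinations <- function(claim, preds, cfg = type_config(), lists = NULL) {
  stopifnot(nrow(claim) == 1L)
  if (nrow(preds) > 0L && any(preds$sentence_id != claim$sentence_id)) {
    stop("predication sentence_id does not match claim ", claim$sentence_id)
  }
  filtered <- filter_treatment_predications(preds, cfg)
  if (!is.null(lists)) filtered <- apply_filters(filtered, lists)
  groups <- group_claim_predications(filtered)
  if (nrow(groups) == 0L) return(groups)
  groups$claim_text <- claim$text
  groups$markers <- rep(claim$markers, nrow(groups))
  groups$comparison_flag <- purrr::map_lgl(
    groups$subjects, ~ flag_comparisons(.x$cui, preds)
  )
  groups[order(groups$sentence_id, groups$predicate_base, groups$object_cui), , drop = FALSE]
}

#' Flag comparative claims
#'
#' Returns `TRUE` iff any predication of the claim has base predicate
#' `COMPARED_WITH` linking two of the group's subject CUIs (either
#' direction). Comparative single-therapy studies ("Both X and Y had
#' comparable efficacy...") are the dominant false-positive mode of the
#' discovery rule; the flag supports downstream triage or hard filtering
#' without silently deleting candidates.
#'
#' @param subject_cuis Character vector of the group's subject CUIs.
#' @param all_preds All predications of the claim (pre-filter; the
#'   `COMPARED_WITH` records never survive the treatment filter).
#' @return Logical scalar.
#' @export
flag_comparisons <- function(subject_cuis, all_preds) {
  if (nrow(all_preds) == 0L) return(FALSE)
  cmp <- all_preds[all_preds$predicate_base == "COMPARED_WITH", , drop = FALSE]
  any(cmp$subject_cui %in% subject_cuis &
        cmp$object_cui %in% subject_cuis &
        cmp$subject_cui != cmp$object_cui)
}

#' Run discovery over a whole corpus
#'
#' Joins claims with their predications by `sentence_id` and applies
#' [discover_combinations()] claim by claim. Predications whose sentence is
#' not a conclusive claim are ignored. One claim may yield several groups
#' (one per `(predicate, object)` key).
#'
#' @param claims Claims tibble.
#' @param predications Predication tibble for the corpus.
#' @inheritParams discover_combinations
#' @param drop_comparisons If `TRUE`, discard groups whose
#'   `comparison_flag` is set instead of merely flagging them.
#' @return Candidate-group tibble, sorted.
#' @export
discover_corpus <- function(claims, predications, cfg = type_config(),
                            lists = NULL, drop_comparisons = FALSE) {
  by_sid <- split(seq_len(nrow(predications)), predications$sentence_id)
  out <- purrr::map(seq_len(nrow(claims)), function(i) {
    idx <- by_sid[[claims$sentence_id[i]]]
    if (is.null(idx)) return(NULL)
    discover_combinations(claims[i, , drop = FALSE],
                          predications[idx, , drop = FALSE], cfg, lists)
  })
  groups <- dplyr::bind_rows(purrr::compact(out))
  if (nrow(groups) == 0L) return(empty_groups())
  if (drop_comparisons) groups <- groups[!groups$comparison_flag, , drop = FALSE]
  groups[order(groups$sentence_id, groups$predicate_base, groups$object_cui), , drop = FALSE]
}

#' Summarize discovered candidate groups
#'
#' @param groups Candidate-group tibble.
#' @return A list with `n_groups`, `n_claims` (distinct claims yielding a
#'   group), `by_size` (counts of groups per subject-set size), `markers`
#'   (marker tabulation over groups, with the regimen-exclusion rule of
#'   [tabulate_markers()]), and `n_comparison_flagged`.
#' @export
summarize_groups <- function(groups) {
  by_size <- if (nrow(groups) == 0L) {
    tibble::tibble(n_subjects = integer(), n_groups = integer())
  } else {
    dplyr::count(groups, .data$n_subjects, name = "n_groups")
  }
  list(
    n_groups = nrow(groups),
    n_claims = length(unique(groups$sentence_id)),
    by_size = by_size,
    markers = tabulate_markers(groups$markers),
    n_comparison_flagged = sum(groups$comparison_flag)
  )
}

#' Count mechanism-of-action combination patterns
#'
#' Maps each group's member drugs to mechanism classes (cytotoxic,
#' targeted, immunotherapy, ...) through a user-supplied map and counts the
#' resulting order-insensitive patterns, e.g. `"Targeted + Cytotoxic"`.
#' Drugs absent from the map contribute the class `"Other"`. Patterns are
#' canonicalized by a class precedence (then alphabetically for classes not
#' listed), so `{Cytotoxic, Targeted}` and `{Targeted, Cytotoxic}` count as
#' one pattern.
#'
#' @param groups Candidate-group tibble.
#' @param class_map A data frame with a `class` column and at least one of
#'   `cui` / `name`; matching tries CUI first, then case-folded name.
#' @param precedence Class ordering used to print patterns.
#' @return A tibble `pattern` / `n`, sorted by decreasing count.
#' @export
count_patterns <- function(groups, class_map,
                           precedence = c("Immunotherapy", "Targeted", "Cytotoxic",
                                          "Hormonal", "Other antineoplastic agent/adjuvant drugs",
                                          "Other")) {
  stopifnot(is.data.frame(class_map), "class" %in% names(class_map))
  by_cui <- if ("cui" %in% names(class_map)) {
    stats::setNames(class_map$class, class_map$cui)
  } else c()
  by_name <- if ("name" %in% names(class_map)) {
    stats::setNames(class_map$class, tolower(class_map$name))
  } else c()
  classify <- function(cui, name) {
    cls <- by_cui[cui]
    miss <- is.na(cls)
    cls[miss] <- by_name[tolower(name)][miss]
    cls[is.na(cls)] <- "Other"
    unname(cls)
  }
  rank <- function(cls) {
    r <- match(cls, precedence)
    r[is.na(r)] <- length(precedence) + 1L
    r
  }
  patterns <- purrr::map_chr(groups$subjects, function(s) {
    cls <- classify(s$cui, s$name)
    cls <- cls[order(rank(cls), cls)]
    paste(cls, collapse = " + ")
  })
  if (length(patterns) == 0L) return(tibble::tibble(pattern = character(), n = integer()))
  tab <- dplyr::count(tibble::tibble(pattern = patterns), .data$pattern, name = "n")
  tab[order(-tab$n, tab$pattern), , drop = FALSE]
}

format_subjects <- function(subjects) {
  purrr::map_chr(subjects, ~ paste(paste0(.x$cui, ":", .x$name), collapse = "+"))
}

parse_subjects <- function(x) {
  purrr::map(x, function(s) {
    if (!nzchar(s)) return(tibble::tibble(cui = character(), name = character()))
    items <- strsplit(s, "+", fixed = TRUE)[[1L]]
    cui <- sub(":.*$", "", items)
    name <- sub("^[^:]*:", "", items)
    tibble::tibble(cui = cui, name = name)
  })
}

#' Write / read candidate groups as TSV
#'
#' Columns: `sentence_id`, `predicate`, `object_cui`, `object_name`,
#' `subjects` (sorted `CUI:name` pairs, `+`-joined), `n_subjects`,
#' `any_inferred`, `markers` (semicolon-joined), `comparison_flag`,
#' `claim_text`.
#'
#' @param groups Candidate-group tibble.
#' @param path File path.
#' @return `path` invisibly (writer); a candidate-group tibble (reader; the
#'   `source_predication_count` column is not serialized and reads back as
#'   `NA`).
#' @export
write_candidates_tsv <- function(groups, path) {
  header <- paste("sentence_id", "predicate", "object_cui", "object_name",
                  "subjects", "n_subjects", "any_inferred", "markers",
                  "comparison_flag", "claim_text", sep = "\t")
  lines <- c(header, sprintf(
    "%s\t%s\t%s\t%s\t%s\t%d\t%s\t%s\t%s\t%s",
    groups$sentence_id, groups$predicate_base, groups$object_cui, groups$object_name,
    format_subjects(groups$subjects), as.integer(groups$n_subjects),
    ifelse(groups$any_inferred, "true", "false"),
    purrr::map_chr(groups$markers, ~ paste(.x, collapse = ";")),
    ifelse(groups$comparison_flag, "true", "false"),
    gsub("[\t\n\r]", " ", groups$claim_text)
  ))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_candidates_tsv
#' @export
read_candidates_tsv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) <= 1L) return(empty_groups())
  parts <- strsplit(lines[-1L], "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 9L)
  if (length(bad) > 0L) stop("malformed candidates TSV at line ", bad[1L] + 1L)
  f <- function(i) purrr::map_chr(parts, ~ if (length(.x) >= i) .x[i] else "")
  tibble::tibble(
    sentence_id = f(1L),
    claim_text = f(10L),
    predicate_base = f(2L),
    object_cui = f(3L),
    object_name = f(4L),
    subjects = parse_subjects(f(5L)),
    n_subjects = as.integer(f(6L)),
    any_inferred = f(7L) == "true",
    markers = purrr::map(f(8L), ~ if (nzchar(.x)) strsplit(.x, ";", fixed = TRUE)[[1L]] else character(0)),
    comparison_flag = f(9L) == "true",
    source_predication_count = NA_integer_
  )
}
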