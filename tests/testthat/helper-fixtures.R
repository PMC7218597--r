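# Shared builders for unit and property tests. Everything is generated in
# code; no binary fixtures.

# Minimal predication row(s) with sensible defaults.
make_pred <- function(subject_cui, subject_name, predicate_raw,
                      object_cui, object_name,
                      subject_semtypes = "phsu", object_semtypes = "neop",
                      sentence_id = "10000001.ab.5",
                      pmid = sub("\\.ab\\.[0-9]+$", "", sentence_id)) {
  norm <- combokg::normalize_predicate(predicate_raw)
  tibble::tibble(
    pmid = pmid, sentence_id = sentence_id,
    subject_cui = subject_cui, subject_name = subject_name,
    subject_semtypes = subject_semtypes,
    predicate_raw = predicate_raw,
    object_cui = object_cui, object_name = object_name,
    object_semtypes = object_semtypes,
    predicate_base = norm$base, inferred = norm$inferred, negated = norm$negated,
    line = NA_integer_
  )
}

make_claim <- function(sentence_id = "10000001.ab.5",
                       text = "CONCLUSION: A combination of X and Y is feasible.",
                       markers = NULL) {
  tibble::tibble(
    sentence_id = sentence_id,
    pmid = sub("\\.ab\\.[0-9]+$", "", sentence_id),
    sentence_index = as.integer(sub("^.*\\.ab\\.", "", sentence_id)),
    text = text,
    markers = if (is.null(markers)) combokg::detect_markers(text) else list(markers)
  )
}

# Random predication set for property tests: small concept pools so that
# shared (predicate, object) keys and duplicate subjects actually occur.
random_predications <- function(n, sentence_id = "10000001.ab.5") {
  if (n == 0L) {
    return(make_pred(character(0), character(0), character(0),
                     character(0), character(0),
                     subject_semtypes = character(0), object_semtypes = character(0),
                     sentence_id = character(0), pmid = character(0)))
  }
  subj_pool <- tibble::tibble(
    cui = sprintf("CS%04d", 1:5),
    name = paste0("drug", 1:5),
    semtypes = c("phsu", "phsu,orch", "orch", "topp", "phsu")  # one non-drug
  )
  obj_pool <- tibble::tibble(
    cui = sprintf("CO%04d", 1:3),
    name = paste0("disease", 1:3),
    semtypes = c("neop", "dsyn", "podg")  # one non-disease
  )
  preds <- c("TREATS", "TREATS(INFER)", "NEG_TREATS", "INHIBITS",
             "PROCESS_OF", "COMPARED_WITH")
  rows <- lapply(seq_len(n), function(i) {
    s <- subj_pool[sample(nrow(subj_pool), 1L), ]
    o <- obj_pool[sample(nrow(obj_pool), 1L), ]
    make_pred(s$cui, s$name, sample(preds, 1L), o$cui, o$name,
              subject_semtypes = s$semtypes, object_semtypes = o$semtypes,
              sentence_id = sentence_id)
  })
  dplyr::bind_rows(rows)
}

# Independent oracle for the discovery rule: brute-force subset enumeration.
# A subset of the filtered predications is a candidate when all rows share
# one (predicate_base, object_cui) key and it contains >= 2 distinct subject
# CUIs; maximal candidate subsets define the expected groups. Returns a
# sorted key string per group for easy comparison.
oracle_group_keys <- function(filtered) {
  n <- nrow(filtered)
  if (n < 2L) return(character(0))
  found <- character(0)
  for (size in n:2) {
    for (idx in utils::combn(n, size, simplify = FALSE)) {
      rows <- filtered[idx, , drop = FALSE]
      key <- unique(paste(rows$predicate_base, rows$object_cui, sep = "\r"))
      if (length(key) != 1L) next
      subj <- sort(unique(rows$subject_cui))
      if (length(subj) < 2L) next
      cand <- paste(key, paste(subj, collapse = "+"), sep = "\r")
      # keep only maximal subsets: a smaller subset whose subjects are
      # contained in an already-found group under the same key is dominated
      dominated <- any(vapply(found, function(f) {
        fk <- strsplit(f, "\r", fixed = TRUE)[[1L]]
        ck <- strsplit(cand, "\r", fixed = TRUE)[[1L]]
        identical(fk[1:2], ck[1:2]) &&
          all(strsplit(ck[3], "+", fixed = TRUE)[[1L]] %in%
                strsplit(fk[3], "+", fixed = TRUE)[[1L]])
      }, logical(1)))
      if (!dominated) found <- c(found, cand)
    }
  }
  sort(unique(found))
}

group_keys <- function(groups) {
  if (nrow(groups) == 0L) return(character(0))
  sort(paste(groups$predicate_base, groups$object_cui,
             vapply(groups$subjects, function(s) paste(sort(s$cui), collapse = "+"),
                    character(1)),
             sep = "\r"))
}

extdata <- function(name) {
  path <- system.file("extdata", name, package = "combokg")
  if (!nzchar(path)) path <- file.path("..", "..", "inst", "extdata", name)
  path
}
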