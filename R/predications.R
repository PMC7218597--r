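# SemRep-style semantic predications: parsing, predicate normalization, and
# restriction to treatment predications with drug subjects / disease objects.

PREDICATION_HEADER <- paste0(
  "#pmid|sentence_id|subject_cui|subject_name|subject_semtypes|",
  "predicate|object_cui|object_name|object_semtypes"
)

#' Normalize a raw predicate string
#'
#' SemRep emits inferred predications with a trailing `(INFER)` (a predicate
#' derived by chaining two extracted predications, e.g. drug TREATS patients
#' plus disease PROCESS_OF patients yields drug `TREATS(INFER)` disease) and
#' negated predications with a leading `NEG_` (e.g. `NEG_TREATS`). This
#' strips exactly one of each and upper-cases the base predicate.
#'
#' @param raw Character vector of raw predicate strings.
#' @return A tibble with columns `base`, `inferred`, `negated`.
#' @export
normalize_predicate <- function(raw) {
  stopifnot(all(nzchar(raw)))
  inferred <- stringr::str_detect(raw, stringr::fixed("(INFER)", ignore_case = TRUE))
  base <- stringr::str_remove(raw, stringr::regex("\\(INFER\\)\\s*$", ignore_case = TRUE))
  negated <- stringr::str_detect(base, stringr::regex("^NEG_", ignore_case = TRUE))
  base <- stringr::str_remove(base, stringr::regex("^NEG_", ignore_case = TRUE))
  tibble::tibble(base = toupper(trimws(base)), inferred = inferred, negated = negated)
}

#' Treatment-predication filter configuration
#'
#' Holds the predicate whitelist and the UMLS semantic-type abbreviations
#' that qualify a subject as a drug and an object as a disease. Defaults:
#' the four treatment predicates TREATS, INHIBITS, PREVENTS, DISRUPTS; the
#' "Chemicals and Drugs" group abbreviations for drugs; "Disease or
#' Syndrome" plus its child types (`dsyn`, `neop`, `mobd`) for diseases.
#' Which child types of the disease parent to include is corpus-dependent,
#' so the lists are configuration, not constants.
#'
#' @param treatment_predicates Character set of base predicates to keep.
#' @param drug_semtypes Semantic-type abbreviations accepted for subjects.
#' @param disease_semtypes Semantic-type abbreviations accepted for objects.
#' @param exclude_negated Drop `NEG_`-prefixed predications (default `TRUE`).
#' @return A `type_config` list.
#' @export
type_config <- function(treatment_predicates = c("TREATS", "INHIBITS", "PREVENTS", "DISRUPTS"),
                        drug_semtypes = c("phsu", "orch", "antb", "clnd", "aapp",
                                          "bacs", "horm", "imft", "vita", "enzy"),
                        disease_semtypes = c("dsyn", "neop", "mobd"),
                        exclude_negated = TRUE) {
  stopifnot(length(treatment_predicates) > 0, length(drug_semtypes) > 0,
            length(disease_semtypes) > 0, is.logical(exclude_negated))
  structure(
    list(
      treatment_predicates = toupper(treatment_predicates),
      drug_semtypes = tolower(drug_semtypes),
      disease_semtypes = tolower(disease_semtypes),
      exclude_negated = isTRUE(exclude_negated)
    ),
    class = "type_config"
  )
}

empty_predications <- function() {
  tibble::tibble(
    pmid = character(), sentence_id = character(),
    subject_cui = character(), subject_name = character(), subject_semtypes = character(),
    predicate_raw = character(), object_cui = character(), object_name = character(),
    object_semtypes = character(),
    predicate_base = character(), inferred = logical(), negated = logical(),
    line = integer()
  )
}

#' Parse a pipe-delimited predication file
#'
#' One record per line, nine `|`-separated fields:
#' `pmid|sentence_id|subject_cui|subject_name|subject_semtypes|predicate|`
#' `object_cui|object_name|object_semtypes`, with semantic types
#' comma-joined and `sentence_id` in the form `PMID.ab.N`. Lines starting
#' with `#` are headers/comments. The format is modeled on the SemMedDB
#' PREDICATION columns; converting real SemRep fielded output to it is a
#' one-liner per record (see the package vignette).
#'
#' @param path Path to the predication file.
#' @return A tibble with the nine raw fields plus normalized
#'   `predicate_base`, `inferred`, `negated` (see [normalize_predicate()])
#'   and the source `line` number.
#' @export
parse_predications <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(lines, "#")
  lineno <- which(keep)
  if (length(lineno) == 0L) return(empty_predications())
  parts <- strsplit(lines[keep], "|", fixed = TRUE)
  bad <- which(lengths(parts) != 9L)
  if (length(bad) > 0L) {
    stop("malformed predication at line ", lineno[bad[1L]], ": expected 9 '|'-separated fields, got ",
         lengths(parts)[bad[1L]])
  }
  field <- function(i) purrr::map_chr(parts, i)
  preds <- tibble::tibble(
    pmid = field(1L), sentence_id = field(2L),
    subject_cui = field(3L), subject_name = field(4L), subject_semtypes = field(5L),
    predicate_raw = field(6L), object_cui = field(7L), object_name = field(8L),
    object_semtypes = field(9L), line = lineno
  )
  bad_sid <- which(!grepl("^.+\\.ab\\.[0-9]+$", preds$sentence_id))
  if (length(bad_sid) > 0L) {
    stop("unrecognized sentence_id '", preds$sentence_id[bad_sid[1L]],
         "' at line ", preds$line[bad_sid[1L]], " (expected PMID.ab.N)")
  }
  mism <- which(!startsWith(preds$sentence_id, paste0(preds$pmid, ".ab.")))
  if (length(mism) > 0L) {
    stop("sentence_id does not match pmid at line ", preds$line[mism[1L]])
  }
  norm <- normalize_predicate(preds$predicate_raw)
  preds$predicate_base <- norm$base
  preds$inferred <- norm$inferred
  preds$negated <- norm$negated
  preds[, names(empty_predications())]
}

#' Write predications back to the pipe-delimited dialect
#'
#' Emits the standard header line followed by one record per row, using the
#' raw predicate string, so that parse -> write -> parse round-trips
#' byte-identically.
#'
#' @param preds Predication tibble (see [parse_predications()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_predications <- function(preds, path) {
  lines <- c(PREDICATION_HEADER, sprintf(
    "%s|%s|%s|%s|%s|%s|%s|%s|%s",
    preds$pmid, preds$sentence_id,
    preds$subject_cui, preds$subject_name, preds$subject_semtypes,
    preds$predicate_raw, preds$object_cui, preds$object_name, preds$object_semtypes
  ))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

semtypes_intersect <- function(semtypes, accepted) {
  purrr::map_lgl(strsplit(tolower(semtypes), ",", fixed = TRUE),
                 ~ any(trimws(.x) %in% accepted))
}

#' Restrict predications to treatment assertions
#'
#' Keeps a predication iff its base predicate is in the treatment whitelist,
#' at least one subject semantic type is a drug type, at least one object
#' semantic type is a disease type, and (when `exclude_negated`) it is not
#' negated. Inferred predications pass on their base predicate, so `TREATS`
#' and `TREATS(INFER)` are treated alike. Idempotent; output is always a
#' subset of the input.
#'
#' @param preds Predication tibble.
#' @param cfg A [type_config()].
#' @return The surviving rows of `preds`.
#' @export
filter_treatment_predications <- function(preds, cfg = type_config()) {
  stopifnot(inherits(cfg, "type_config"))
  if (nrow(preds) == 0L) return(preds)
  keep <- preds$predicate_base %in% cfg$treatment_predicates &
    semtypes_intersect(preds$subject_semtypes, cfg$drug_semtypes) &
    semtypes_intersect(preds$object_semtypes, cfg$disease_semtypes)
  if (cfg$exclude_negated) keep <- keep & !preds$negated
  preds[keep, , drop = FALSE]
}
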