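# Conclusive-claim extraction from abstract records.

CONCLUSIVE_PATTERN <- "(?i)\\bconclu(sion|d)\\w*"

# Marker labels follow the field's wildcard convention: "combin*" matches any
# token starting with "combin" (combination, combined, combining, ...).
MARKER_PATTERNS <- c(
  "combin*"         = "(?i)\\bcombin\\w*",
  "coadministration" = "(?i)\\bcoadministration\\b",
  "co-administered" = "(?i)\\bco-administered\\b",
  "regimen"         = "(?i)\\bregimens?\\b"
)

#' Read abstract records
#'
#' Reads abstracts either from JSON Lines (one object per line with fields
#' `pmid` and `abstract`) or from a two-column TSV (`pmid<TAB>abstract`).
#' Both formats are UTF-8.
#'
#' @param path Path to the abstract file.
#' @param format `"auto"` (decide by extension: `.jsonl`/`.json` vs anything
#'   else), `"jsonl"`, or `"tsv"`.
#' @return A tibble with columns `pmid` and `text`.
#' @export
read_abstracts <- function(path, format = c("auto", "jsonl", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.jsonl?$", path, ignore.case = TRUE)) "jsonl" else "tsv"
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (format == "jsonl") {
    recs <- purrr::map(lines, jsonlite::fromJSON)
    out <- tibble::tibble(
      pmid = purrr::map_chr(recs, ~ as.character(.x$pmid)),
      text = purrr::map_chr(recs, ~ as.character(.x$abstract))
    )
  } else {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(parts) < 2L)
    if (length(bad) > 0L) {
      stop("malformed abstract TSV at line ", bad[1L], ": expected pmid<TAB>abstract")
    }
    out <- tibble::tibble(
      pmid = purrr::map_chr(parts, 1L),
      text = purrr::map_chr(parts, ~ paste(.x[-1L], collapse = "\t"))
    )
  }
  validate_abstracts(out)
  out
}

validate_abstracts <- function(abstracts) {
  stopifnot(is.data.frame(abstracts), all(c("pmid", "text") %in% names(abstracts)))
  if (any(!nzchar(abstracts$pmid))) stop("abstract record with empty pmid")
  if (any(!nzchar(abstracts$text))) stop("abstract record with empty text")
  invisible(abstracts)
}

# Periods protected from the sentence splitter. Single-letter initials are
# deliberately not protected ("A. B. C." is three sentences).
.SENT_ABBREVS <- c(
  "vs", "Dr", "Mr", "Mrs", "Ms", "Prof", "St", "Fig", "Figs", "Ref", "Refs",
  "ca", "cf", "approx", "etc", "resp"
)

#' Split an abstract into sentences
#'
#' Deterministic rule-based segmentation: sentences end at `.`, `?` or `!`
#' followed by whitespace and an upper-case letter, digit, or opening
#' quote/bracket. Decimal points, "e.g."/"i.e.", "et al." and a fixed list of
#' common abbreviations are protected. Rule-based splitting keeps downstream
#' sentence identifiers (`PMID.ab.N`) reproducible across runs.
#'
#' @param text A single abstract string.
#' @return Character vector of sentences in document order (empty for empty
#'   input); concatenation of the result equals the input modulo whitespace.
#' @export
split_sentences <- function(text) {
  stopifnot(length(text) == 1L)
  if (is.na(text) || !nzchar(trimws(text))) return(character(0))
  guard <- "\x01"
  prot <- text
  prot <- gsub("(?<=[0-9])\\.(?=[0-9])", guard, prot, perl = TRUE)
  prot <- gsub("\\b([eE])\\.([gG])\\.", paste0("\\1", guard, "\\2", guard), prot)
  prot <- gsub("\\b([iI])\\.([eE])\\.", paste0("\\1", guard, "\\2", guard), prot)
  prot <- gsub("\\bet al\\.", paste0("et al", guard), prot)
  abbrev_re <- paste0("\\b(", paste(.SENT_ABBREVS, collapse = "|"), ")\\.")
  prot <- gsub(abbrev_re, paste0("\\1", guard), prot)
  pieces <- strsplit(prot, "(?<=[.?!])\\s+(?=[\"'(\\[]?[A-Z0-9])", perl = TRUE)[[1L]]
  pieces <- gsub(guard, ".", pieces, fixed = TRUE)
  pieces <- trimws(pieces)
  pieces[nzchar(pieces)]
}

#' Detect combined-medication markers in claim text
#'
#' Four surface cues signal a combined-drug claim: `combin*` (any token
#' beginning "combin"), `coadministration`, `co-administered`, and `regimen`.
#' Matching is case-insensitive on word boundaries. The raw detector reports
#' every marker present; the tabulation rule that counts `regimen` only in
#' the absence of the other three lives in [tabulate_markers()].
#'
#' @param text Character vector of sentences.
#' @return A list (same length as `text`) of character vectors of marker
#'   labels, possibly empty.
#' @export
detect_markers <- function(text) {
  purrr::map(text, function(s) {
    hits <- purrr::map_lgl(MARKER_PATTERNS, ~ stringr::str_detect(s, .x))
    names(MARKER_PATTERNS)[hits]
  })
}

#' Extract conclusive claims from abstracts
#'
#' Selects every sentence whose text matches the wildcard keywords
#' `conclusion*` or `conclude*` (case-insensitive; "conclusions",
#' "concluded", "concluding" all match). Structured-abstract labels such as
#' `CONCLUSION:` are retained as part of the sentence. All matching
#' sentences of an abstract are kept, each as its own claim.
#'
#' @param abstracts A tibble with columns `pmid` and `text` (see
#'   [read_abstracts()]).
#' @return A tibble of claims with columns `sentence_id` (`PMID.ab.N`, N
#'   1-based over the whole abstract), `pmid`, `sentence_index`, `text`, and
#'   `markers` (list-column of marker labels).
#' @export
extract_conclusive_claims <- function(abstracts) {
  validate_abstracts(abstracts)
  rows <- purrr::map2(abstracts$pmid, abstracts$text, function(pmid, text) {
    sents <- split_sentences(text)
    hit <- stringr::str_detect(sents, CONCLUSIVE_PATTERN)
    idx <- which(hit)
    tibble::tibble(
      sentence_id = paste0(pmid, ".ab.", idx),
      pmid = rep(pmid, length(idx)),
      sentence_index = idx,
      text = sents[idx]
    )
  })
  claims <- dplyr::bind_rows(rows)
  if (nrow(claims) == 0L) {
    claims <- tibble::tibble(
      sentence_id = character(), pmid = character(),
      sentence_index = integer(), text = character()
    )
  }
  claims$markers <- detect_markers(claims$text)
  claims
}

#' Tabulate marker occurrences over claims or candidate groups
#'
#' Counts how many rows carry each marker. `regimen` is counted only for
#' rows carrying none of the other three markers, mirroring how the marker
#' table is conventionally reported ("regimen without markers above"); the
#' raw per-row detection is left untouched.
#'
#' @param markers A list-column of marker label vectors.
#' @return A tibble with columns `marker` and `n`.
#' @export
tabulate_markers <- function(markers) {
  labels <- names(MARKER_PATTERNS)
  others <- setdiff(labels, "regimen")
  n <- purrr::map_int(labels, function(lab) {
    if (lab == "regimen") {
      sum(purrr::map_lgl(markers, ~ "regimen" %in% .x && !any(others %in% .x)))
    } else {
      sum(purrr::map_lgl(markers, ~ lab %in% .x))
    }
  })
  tibble::tibble(marker = labels, n = n)
}

#' Write / read claims as TSV
#'
#' Columns: `sentence_id`, `pmid`, `sentence_index`, `text`, `markers`
#' (semicolon-joined). Tabs and newlines inside claim text are replaced by
#' spaces on write.
#'
#' @param claims Claims tibble from [extract_conclusive_claims()].
#' @param path Output file path.
#' @return `path`, invisibly (for the writer); a claims tibble (reader).
#' @export
write_claims_tsv <- function(claims, path) {
  header <- "sentence_id\tpmid\tsentence_index\ttext\tmarkers"
  lines <- c(header, sprintf(
    "%s\t%s\t%d\t%s\t%s",
    claims$sentence_id, claims$pmid, as.integer(claims$sentence_index),
    gsub("[\t\n\r]", " ", claims$text),
    purrr::map_chr(claims$markers, ~ paste(.x, collapse = ";"))
  ))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_claims_tsv
#' @export
read_claims_tsv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) <= 1L) {
    return(tibble::tibble(
      sentence_id = character(), pmid = character(),
      sentence_index = integer(), text = character(), markers = list()
    ))
  }
  parts <- strsplit(lines[-1L], "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 4L)
  if (length(bad) > 0L) stop("malformed claims TSV at line ", bad[1L] + 1L)
  tibble::tibble(
    sentence_id = purrr::map_chr(parts, 1L),
    pmid = purrr::map_chr(parts, 2L),
    sentence_index = as.integer(purrr::map_chr(parts, 3L)),
    text = purrr::map_chr(parts, 4L),
    markers = purrr::map(parts, function(p) {
      if (length(p) < 5L || !nzchar(p[5L])) character(0) else strsplit(p[5L], ";", fixed = TRUE)[[1L]]
    })
  )
}
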