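# Broad-concept exclusion lists derived from a MeSH descriptor table:
# pharmacologic actions (a chemicals-and-drugs tree branch) and generic
# disease names (category-C roots).

TREE_CODE_RE <- "^[A-Z][0-9]+(\\.[0-9]+)*$"

#' Load a MeSH descriptor table
#'
#' Reads the three-column TSV distillate
#' `ui<TAB>name<TAB>tree_numbers` (tree numbers semicolon-joined, e.g.
#' `D27.505.954.248` or `C04;C23.550`). A short recipe for producing this
#' distillate from the NLM MeSH ASCII/XML release is given in the vignette;
#' the package itself never parses MeSH XML.
#'
#' @param path Path to the descriptor TSV. Lines starting with `#` are
#'   skipped.
#' @return A tibble with columns `ui`, `name`, and `tree_numbers`
#'   (list-column of character vectors).
#' @export
load_mesh <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(lines, "#")
  lineno <- which(keep)
  if (length(lineno) == 0L) {
    return(tibble::tibble(ui = character(), name = character(), tree_numbers = list()))
  }
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 3L)
  if (length(bad) > 0L) {
    stop("malformed MeSH descriptor at line ", lineno[bad[1L]], ": expected 3 tab-separated fields")
  }
  trees <- purrr::map(parts, ~ trimws(strsplit(.x[3L], ";", fixed = TRUE)[[1L]]))
  for (i in seq_along(trees)) {
    bad_code <- trees[[i]][!grepl(TREE_CODE_RE, trees[[i]])]
    if (length(bad_code) > 0L) {
      stop("malformed tree number '", bad_code[1L], "' at line ", lineno[i])
    }
  }
  out <- tibble::tibble(
    ui = purrr::map_chr(parts, 1L),
    name = purrr::map_chr(parts, 2L),
    tree_numbers = trees
  )
  dup <- out$ui[duplicated(out$ui)]
  if (length(dup) > 0L) stop("duplicate MeSH descriptor UI: ", dup[1L])
  out
}

# Segment-wise tree descent: "D27.505" covers "D27.505" and "D27.505.954.248"
# but not "D27.5059".
tree_descends <- function(codes, prefix) {
  codes == prefix | startsWith(codes, paste0(prefix, "."))
}

#' Collect pharmacologic-action headings from a MeSH tree branch
#'
#' Pharmacologic actions ("Antineoplastic Agents", "Anti-Inflammatory
#' Agents", ...) name what a chemical does rather than a specific drug, so
#' predications whose subject is such a heading carry no combinable drug
#' identity. This walks the descriptor table and returns every heading with
#' at least one tree number equal to or descending from one of `prefixes`.
#'
#' @param descriptors Descriptor tibble from [load_mesh()].
#' @param prefixes Tree-code prefixes of the pharmacologic-actions branch
#'   (default `"D27.505"`); descent is segment-wise, never raw string
#'   prefixing.
#' @return Sorted set of case-folded heading names.
#' @export
build_pharmacologic_actions <- function(descriptors, prefixes = c("D27.505")) {
  stopifnot(length(prefixes) > 0)
  if (nrow(descriptors) == 0L) return(character(0))
  hit <- purrr::map_lgl(descriptors$tree_numbers, function(codes) {
    any(purrr::map_lgl(prefixes, ~ any(tree_descends(codes, .x))))
  })
  sort(unique(tolower(descriptors$name[hit])))
}

#' Collect generic disease names (category-C roots)
#'
#' The top-level disease classes -- the category-C root plus its direct
#' hyponyms C01..C26 -- are classes of disorders, not specific diseases, so
#' objects matching them are filtered. A descriptor qualifies when it has an
#' undotted category-C tree number (`^C[0-9]+$`); "Lung Neoplasms" at
#' `C04.588` does not. The category root itself ("Diseases") is not a MeSH
#' descriptor, hence the `root_labels` argument; with the 26 direct
#' hyponyms it completes the 27-term generic-disease list.
#'
#' @param descriptors Descriptor tibble from [load_mesh()].
#' @param root_labels Names of the category root to always include (default
#'   `c("diseases", "disease")`).
#' @return Sorted set of case-folded names.
#' @export
build_generic_diseases <- function(descriptors, root_labels = c("diseases", "disease")) {
  top_c <- if (nrow(descriptors) == 0L) character(0) else {
    hit <- purrr::map_lgl(descriptors$tree_numbers, ~ any(grepl("^C[0-9]+$", .x)))
    descriptors$name[hit]
  }
  sort(unique(tolower(c(root_labels, top_c))))
}

#' Bundle the two broad-concept exclusion lists
#'
#' @param pharmacologic_actions Case-folded action names
#'   ([build_pharmacologic_actions()]).
#' @param generic_diseases Case-folded generic disease names
#'   ([build_generic_diseases()]).
#' @param provenance Free-text note on how the lists were built.
#' @return A `filter_lists` object.
#' @export
filter_lists <- function(pharmacologic_actions, generic_diseases, provenance = "") {
  structure(
    list(
      pharmacologic_actions = sort(unique(tolower(pharmacologic_actions))),
      generic_diseases = sort(unique(tolower(generic_diseases))),
      provenance = provenance
    ),
    class = "filter_lists"
  )
}

#' Build both exclusion lists from one descriptor table
#'
#' @inheritParams build_pharmacologic_actions
#' @inheritParams build_generic_diseases
#' @return A [filter_lists()] object.
#' @export
build_filter_lists <- function(descriptors, prefixes = c("D27.505"),
                               root_labels = c("diseases", "disease")) {
  filter_lists(
    build_pharmacologic_actions(descriptors, prefixes),
    build_generic_diseases(descriptors, root_labels),
    provenance = sprintf("prefixes=%s; root_labels=%s",
                         paste(prefixes, collapse = ","),
                         paste(root_labels, collapse = ","))
  )
}

#' Drop predications naming broad concepts
#'
#' Removes any predication whose case-folded subject name is a
#' pharmacologic action or whose case-folded object name is a generic
#' disease class. Matching is by preferred-name string: SemRep emits UMLS
#' preferred names, which coincide with MeSH headings for the broad
#' concepts targeted here (a documented approximation that avoids requiring
#' a UMLS license). Idempotent and order-independent.
#'
#' @param preds Predication tibble (normally already treatment-filtered).
#' @param lists A [filter_lists()] object.
#' @return The surviving rows of `preds`.
#' @export
apply_filters <- function(preds, lists) {
  stopifnot(inherits(lists, "filter_lists"))
  if (nrow(preds) == 0L) return(preds)
  drop <- tolower(preds$subject_name) %in% lists$pharmacologic_actions |
    tolower(preds$object_name) %in% lists$generic_diseases
  preds[!drop, , drop = FALSE]
}

#' Write / read a filter list as one name per line
#'
#' @param names Character vector of names.
#' @param path File path.
#' @return `path` invisibly (writer); character vector (reader).
#' @export
write_filter_list <- function(names, path) {
  writeLines(sort(unique(tolower(names))), path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_filter_list
#' @export
read_filter_list <- function(path) {
  x <- readLines(path, encoding = "UTF-8", warn = FALSE)
  sort(unique(tolower(x[nzchar(trimws(x))])))
}
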