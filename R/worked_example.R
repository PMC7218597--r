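# A small reference corpus around a canonical worked example: a phase-I
# conclusion reporting a three-drug combination, whose SemRep interpretation
# yields per-drug TREATS -> Patients predications plus TREATS(INFER) chains
# onto the disease -- exactly the shape the discovery rule binds into one
# combination candidate.

WE_AMSN <- list(cui = "C2931852", name = "Advanced Malignant Solid Neoplasm", semtypes = "neop")
WE_DRUGS <- list(
  list(cui = "C1518922", name = "GTI2040", semtypes = "phsu"),
  list(cui = "C0671970", name = "capecitabine", semtypes = "phsu,orch"),
  list(cui = "C0069717", name = "oxaliplatin", semtypes = "phsu,orch")
)

we_pad <- function(n) {
  sprintf("Study detail %d of the trial protocol was recorded in this sentence.", seq_len(n))
}

#' Built-in worked-example corpus
#'
#' Four abstract records whose conclusive sentences are drawn from real
#' PubMed trial abstracts, padded with synthetic filler sentences so that
#' each conclusion lands at its published sentence index (e.g. sentence 15
#' of abstract 19322566). The first claim -- "A combination of GTI-2040,
#' capecitabine and oxaliplatin is feasible in patients with advanced solid
#' tumors" -- comes with the 7 semantic predications a SemRep run yields for
#' it: the disease `PROCESS_OF` Patients, and for each of the three drugs a
#' direct `TREATS` Patients plus an inferred `TREATS(INFER)` onto the
#' disease. Concept identifiers are illustrative. A small MeSH descriptor
#' table ([synthetic_mesh_table()]) completes the fixture.
#'
#' @return A list with tibbles `abstracts`, `predications` (7 rows), and
#'   `mesh`.
#' @export
worked_example <- function() {
  claims <- list(
    list(pmid = "19322566", index = 15L,
         text = "CONCLUSION: A combination of GTI-2040, capecitabine and oxaliplatin is feasible in patients with advanced solid tumors."),
    list(pmid = "28101592", index = 10L,
         text = "In conclusion, FCM regimen allows excellent long-lasting response in previously untreated patients with FL."),
    list(pmid = "21198717", index = 10L,
         text = "WHAT IS NEW AND CONCLUSION: The use of novel agents such as thalidomide, bortezomib and lenalidomide for RRMM is highly prevalent in France from the first relapse."),
    list(pmid = "23197589", index = 8L,
         text = "We conclude that intraventricular rituximab in combination with MTX is feasible and highly active in the treatment of drug-resistant CNS NHL that is refractory or unresponsive to IV rituximab.")
  )
  abstracts <- dplyr::bind_rows(purrr::map(claims, function(cl) {
    tibble::tibble(
      pmid = cl$pmid,
      text = paste(c(we_pad(cl$index - 1L), cl$text), collapse = " ")
    )
  }))
  sid <- "19322566.ab.15"
  rows <- list(pred_row("19322566", sid, WE_AMSN, "PROCESS_OF", PATIENTS))
  for (d in WE_DRUGS) {
    rows <- c(rows, list(
      pred_row("19322566", sid, d, "TREATS", PATIENTS),
      pred_row("19322566", sid, d, "TREATS(INFER)", WE_AMSN)
    ))
  }
  predications <- dplyr::bind_rows(rows)
  norm <- normalize_predicate(predications$predicate_raw)
  predications$predicate_base <- norm$base
  predications$inferred <- norm$inferred
  predications$negated <- norm$negated
  predications$line <- seq_len(nrow(predications)) + 1L
  list(abstracts = abstracts, predications = predications, mesh = synthetic_mesh_table())
}

#' Write the worked-example corpus to disk
#'
#' Emits `abstracts.jsonl`, `predications.psv`, and `mesh.tsv` in the
#' package's input dialects.
#'
#' @param dir Output directory (created if needed).
#' @return Named list of file paths, invisibly.
#' @export
write_worked_example <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  we <- worked_example()
  files <- list(
    abstracts = file.path(dir, "abstracts.jsonl"),
    predications = file.path(dir, "predications.psv"),
    mesh = file.path(dir, "mesh.tsv")
  )
  write_abstracts_jsonl(we$abstracts, files$abstracts)
  write_predications(we$predications, files$predications)
  write_mesh_tsv(we$mesh, files$mesh)
  invisible(files)
}
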