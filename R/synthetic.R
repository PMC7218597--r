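# Synthetic corpus generator: template abstracts plus the SemRep-style
# predications they would plausibly yield, with a planted truth table, so
# every pipeline stage is testable without any external download.

# Concept pools. CUIs are illustrative identifiers in UMLS format; the
# drug names are real antineoplastic agents so that claim templates read
# like genuine trial conclusions.
synthetic_drug_pool <- function() {
  names <- c(
    "capecitabine", "oxaliplatin", "gemcitabine", "cisplatin", "carboplatin",
    "paclitaxel", "docetaxel", "pemetrexed", "erlotinib", "gefitinib",
    "bevacizumab", "rituximab", "trastuzumab", "cetuximab", "sorafenib",
    "sunitinib", "lenalidomide", "bortezomib", "thalidomide", "irinotecan",
    "etoposide", "vinorelbine", "cyclophosphamide", "doxorubicin", "fluorouracil",
    "mitoxantrone", "temozolomide", "nivolumab", "pembrolizumab", "ipilimumab"
  )
  tibble::tibble(
    cui = sprintf("C1%06d", seq_along(names)),
    name = names,
    semtypes = "phsu,orch"
  )
}

synthetic_disease_pool <- function() {
  names <- c(
    "Non-Small Cell Lung Carcinoma", "Breast Carcinoma", "Colorectal Carcinoma",
    "Pancreatic Carcinoma", "Ovarian Carcinoma", "Glioblastoma",
    "Multiple Myeloma", "Follicular Lymphoma", "Hepatocellular Carcinoma",
    "Gastric Carcinoma"
  )
  tibble::tibble(
    cui = sprintf("C2%06d", seq_along(names)),
    name = names,
    semtypes = "neop"
  )
}

# Broad concepts used as contamination: a pharmacologic action (generic drug
# subject) and a top-level disease class (generic object).
GENERIC_SUBJECT <- list(cui = "C3000001", name = "Antineoplastic Agents", semtypes = "phsu")
GENERIC_OBJECT <- list(cui = "C3000002", name = "Neoplasms", semtypes = "neop")
PATIENTS <- list(cui = "C0030705", name = "Patients", semtypes = "podg")

# The 26 top-level category-C disease classes (undotted tree numbers) plus a
# small pharmacologic-actions branch under D27.505.
synthetic_mesh_table <- function() {
  c_names <- c(
    "Infections", "Virus Diseases", "Parasitic Diseases", "Neoplasms",
    "Musculoskeletal Diseases", "Digestive System Diseases",
    "Stomatognathic Diseases", "Respiratory Tract Diseases",
    "Otorhinolaryngologic Diseases", "Nervous System Diseases",
    "Eye Diseases", "Male Urogenital Diseases",
    "Female Urogenital Diseases and Pregnancy Complications",
    "Cardiovascular Diseases", "Hemic and Lymphatic Diseases",
    "Congenital, Hereditary, and Neonatal Diseases and Abnormalities",
    "Skin and Connective Tissue Diseases", "Nutritional and Metabolic Diseases",
    "Endocrine System Diseases", "Immune System Diseases",
    "Disorders of Environmental Origin", "Animal Diseases",
    "Pathological Conditions, Signs and Symptoms", "Occupational Diseases",
    "Chemically-Induced Disorders", "Wounds and Injuries"
  )
  diseases <- tibble::tibble(
    ui = sprintf("D%06d", 1000L + seq_along(c_names)),
    name = c_names,
    tree = sprintf("C%02d", seq_along(c_names))
  )
  actions <- tibble::tibble(
    ui = sprintf("D%06d", 2000L + 1:5),
    name = c("Antineoplastic Agents", "Anti-Inflammatory Agents",
             "Lipid Regulating Agents", "Antineoplastic Agents, Hormonal",
             "Immunologic Factors"),
    tree = c("D27.505.954.248", "D27.505.954.158", "D27.505.954.502",
             "D27.505.954.248.500", "D27.505.696.477")
  )
  specific <- tibble::tibble(
    ui = c("D000069287", "D009944"),
    name = c("Capecitabine", "Oxaliplatin"),
    tree = c("D03.383.129.154", "D02.455.426.559")
  )
  tab <- dplyr::bind_rows(diseases, actions, specific)
  tibble::tibble(ui = tab$ui, name = tab$name,
                 tree_numbers = as.list(tab$tree))
}

write_mesh_tsv <- function(tab, path) {
  trees <- purrr::map_chr(tab$tree_numbers, paste, collapse = ";")
  writeLines(c("#ui\tname\ttree_numbers",
               sprintf("%s\t%s\t%s", tab$ui, tab$name, trees)),
             path, useBytes = TRUE)
  invisible(path)
}

#' Configure the synthetic corpus generator
#'
#' The defaults describe a clinical-trial-like corpus: most conclusive
#' claims report a drug combination, the combination sizes follow the
#' 2:3:4-drug proportions 210:43:2 observed in curated trial corpora, and a
#' minority of claims are comparative single-therapy studies, negated
#' findings, or are contaminated with overly generic concepts -- the noise
#' modes a discovery pipeline must survive.
#'
#' @param n_abstracts Number of abstracts to generate.
#' @param p_combination_claim Probability that an abstract's conclusive
#'   claim reports a planted drug combination.
#' @param combo_size_dist Named probabilities over combination sizes
#'   `2`/`3`/`4`; must sum to 1.
#' @param p_single_comparison Probability of a comparative single-therapy
#'   claim ("Both X and Y had comparable efficacy...") instead.
#' @param p_negation Probability that a planted combination claim is
#'   negated (predications carry `NEG_`).
#' @param p_generic_subject,p_generic_object Probability that one planted
#'   subject (object) is replaced by a broad concept ("Antineoplastic
#'   Agents" / "Neoplasms").
#' @param n_filler_sentences Non-conclusive sentences preceding the claim.
#' @param seed Integer seed; identical seeds yield byte-identical corpora.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(n_abstracts = 100,
                              p_combination_claim = 0.7,
                              combo_size_dist = c("2" = 210, "3" = 43, "4" = 2) / 255,
                              p_single_comparison = 0.12,
                              p_negation = 0.05,
                              p_generic_subject = 0.05,
                              p_generic_object = 0.05,
                              n_filler_sentences = 6,
                              seed = 1L) {
  probs <- c(p_combination_claim, p_single_comparison, p_negation,
             p_generic_subject, p_generic_object)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (p_combination_claim + p_single_comparison > 1) {
    stop("p_combination_claim + p_single_comparison must not exceed 1")
  }
  if (abs(sum(combo_size_dist) - 1) > 1e-8) stop("combo_size_dist must sum to 1")
  if (!all(names(combo_size_dist) %in% c("2", "3", "4"))) {
    stop("combo_size_dist names must be among 2, 3, 4")
  }
  stopifnot(n_abstracts >= 1, n_filler_sentences >= 0)
  structure(list(
    n_abstracts = as.integer(n_abstracts),
    p_combination_claim = p_combination_claim,
    combo_size_dist = combo_size_dist,
    p_single_comparison = p_single_comparison,
    p_negation = p_negation,
    p_generic_subject = p_generic_subject,
    p_generic_object = p_generic_object,
    n_filler_sentences = as.integer(n_filler_sentences),
    seed = as.integer(seed)
  ), class = "simulation_config")
}

filler_sentences <- function(n, rng_pool) {
  templates <- c(
    "Patients were enrolled at participating centers between 2009 and 2019.",
    "The primary endpoint was progression-free survival.",
    "Treatment was administered in 21-day cycles.",
    "Adverse events were graded according to standard criteria.",
    "The median follow-up was 18 months.",
    "Dose escalation followed a standard 3+3 design.",
    "Baseline characteristics were balanced between arms.",
    "Pharmacokinetic sampling was performed during the first cycle.",
    "Tumor response was assessed every two cycles.",
    "Quality of life was measured with validated questionnaires."
  )
  sample(templates, n, replace = TRUE)
}

combo_claim_text <- function(drugs, disease, negated) {
  listed <- if (length(drugs) == 2L) paste(drugs, collapse = " and ") else {
    paste0(paste(drugs[-length(drugs)], collapse = ", "), " and ", drugs[length(drugs)])
  }
  if (negated) {
    sprintf("CONCLUSION: The combination of %s failed to improve outcomes in patients with %s.",
            listed, disease)
  } else {
    sprintf("CONCLUSION: A combination of %s is feasible in patients with %s.",
            listed, disease)
  }
}

comparison_claim_text <- function(drugs, disease) {
  sprintf("CONCLUSION: Both %s and %s had comparable efficacy in patients with %s.",
          drugs[1L], drugs[2L], disease)
}

pred_row <- function(pmid, sid, s, pred, o) {
  tibble::tibble(
    pmid = pmid, sentence_id = sid,
    subject_cui = s$cui, subject_name = s$name, subject_semtypes = s$semtypes,
    predicate_raw = pred,
    object_cui = o$cui, object_name = o$name, object_semtypes = o$semtypes
  )
}

as_concepts <- function(tbl) {
  purrr::map(seq_len(nrow(tbl)), ~ as.list(tbl[.x, c("cui", "name", "semtypes")]))
}

#' Generate a synthetic corpus with planted ground truth
#'
#' Emits abstract records, the SemRep-style predications they would
#' plausibly yield, a MeSH descriptor fixture, and a truth table labeling
#' every conclusive claim. Combination claims reproduce the canonical
#' inference shape: each drug `TREATS` Patients plus `TREATS(INFER)` the
#' disease, with the disease `PROCESS_OF` Patients; comparative claims emit
#' two direct `TREATS` plus a `COMPARED_WITH`; negated claims emit
#' `NEG_TREATS`. The same seed yields byte-identical files.
#'
#' @param cfg A [simulation_config()].
#' @param dir Optional output directory; when given, writes
#'   `abstracts.jsonl`, `predications.psv`, `mesh.tsv`, `truth.tsv`.
#' @return Invisibly (when `dir` is given) or visibly, a list with tibbles
#'   `abstracts`, `predications`, `mesh`, `truth`, and `files` (paths, when
#'   written).
#' @export
generate_corpus <- function(cfg = simulation_config(), dir = NULL) {
  stopifnot(inherits(cfg, "simulation_config"))
  drugs <- synthetic_drug_pool()
  diseases <- synthetic_disease_pool()
  out <- withr::with_seed(cfg$seed, {
    abstracts <- vector("list", cfg$n_abstracts)
    preds <- vector("list", cfg$n_abstracts)
    truth <- vector("list", cfg$n_abstracts)
    for (i in seq_len(cfg$n_abstracts)) {
      pmid <- sprintf("%d", 90000000L + i)
      claim_idx <- cfg$n_filler_sentences + 1L
      sid <- sprintf("%s.ab.%d", pmid, claim_idx)
      u <- stats::runif(1)
      kind <- if (u < cfg$p_combination_claim) "combination"
              else if (u < cfg$p_combination_claim + cfg$p_single_comparison) "single_comparison"
              else "none"
      disease <- as_concepts(diseases[sample(nrow(diseases), 1L), ])[[1L]]
      claim_preds <- NULL
      if (kind == "combination") {
        size <- as.integer(sample(names(cfg$combo_size_dist), 1L, prob = cfg$combo_size_dist))
        members <- as_concepts(drugs[sample(nrow(drugs), size), ])
        negated <- stats::runif(1) < cfg$p_negation
        contam_s <- !negated && stats::runif(1) < cfg$p_generic_subject
        contam_o <- !negated && !contam_s && stats::runif(1) < cfg$p_generic_object
        if (contam_s) members[[1L]] <- GENERIC_SUBJECT
        if (contam_o) disease <- GENERIC_OBJECT
        label <- if (negated) "negated" else if (contam_s || contam_o) "contaminated" else "combination"
        drug_names <- purrr::map_chr(members, "name")
        text <- combo_claim_text(drug_names, disease$name, negated)
        rows <- list(pred_row(pmid, sid, disease, "PROCESS_OF", PATIENTS))
        for (m in members) {
          if (negated) {
            rows <- c(rows, list(pred_row(pmid, sid, m, "NEG_TREATS", disease)))
          } else {
            rows <- c(rows, list(
              pred_row(pmid, sid, m, "TREATS", PATIENTS),
              pred_row(pmid, sid, m, "TREATS(INFER)", disease)
            ))
          }
        }
        claim_preds <- dplyr::bind_rows(rows)
        truth[[i]] <- tibble::tibble(
          sentence_id = sid, true_label = label,
          planted_subjects = paste(sort(purrr::map_chr(members, "cui")), collapse = "+"),
          planted_object_cui = disease$cui, planted_object_name = disease$name,
          planted_predicate = if (negated) "NEG_TREATS" else "TREATS"
        )
      } else if (kind == "single_comparison") {
        members <- as_concepts(drugs[sample(nrow(drugs), 2L), ])
        text <- comparison_claim_text(purrr::map_chr(members, "name"), disease$name)
        claim_preds <- dplyr::bind_rows(
          pred_row(pmid, sid, members[[1L]], "TREATS", disease),
          pred_row(pmid, sid, members[[2L]], "TREATS", disease),
          pred_row(pmid, sid, members[[1L]], "COMPARED_WITH", members[[2L]])
        )
        truth[[i]] <- tibble::tibble(
          sentence_id = sid, true_label = "single_comparison",
          planted_subjects = paste(sort(purrr::map_chr(members, "cui")), collapse = "+"),
          planted_object_cui = disease$cui, planted_object_name = disease$name,
          planted_predicate = "TREATS"
        )
      } else {
        text <- "In conclusion, further prospective studies are warranted."
        truth[[i]] <- tibble::tibble(
          sentence_id = sid, true_label = "none",
          planted_subjects = "", planted_object_cui = "", planted_object_name = "",
          planted_predicate = ""
        )
      }
      body <- c(filler_sentences(cfg$n_filler_sentences, NULL), text)
      abstracts[[i]] <- tibble::tibble(pmid = pmid, text = paste(body, collapse = " "))
      preds[[i]] <- claim_preds
    }
    list(
      abstracts = dplyr::bind_rows(abstracts),
      predications = dplyr::bind_rows(preds),
      truth = dplyr::bind_rows(truth)
    )
  })
  norm <- normalize_predicate(out$predications$predicate_raw)
  out$predications$predicate_base <- norm$base
  out$predications$inferred <- norm$inferred
  out$predications$negated <- norm$negated
  out$predications$line <- seq_len(nrow(out$predications)) + 1L
  out$mesh <- synthetic_mesh_table()
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    files <- list(
      abstracts = file.path(dir, "abstracts.jsonl"),
      predications = file.path(dir, "predications.psv"),
      mesh = file.path(dir, "mesh.tsv"),
      truth = file.path(dir, "truth.tsv")
    )
    write_abstracts_jsonl(out$abstracts, files$abstracts)
    write_predications(out$predications, files$predications)
    write_mesh_tsv(out$mesh, files$mesh)
    writeLines(c(
      paste(names(out$truth), collapse = "\t"),
      do.call(sprintf, c(list(paste(rep("%s", ncol(out$truth)), collapse = "\t")),
                         as.list(out$truth)))
    ), files$truth, useBytes = TRUE)
    out$files <- files
    return(invisible(out))
  }
  out
}

#' Write abstracts as JSON Lines
#'
#' @param abstracts Tibble with `pmid` and `text`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_abstracts_jsonl <- function(abstracts, path) {
  lines <- purrr::map2_chr(abstracts$pmid, abstracts$text, function(p, t) {
    as.character(jsonlite::toJSON(list(pmid = p, abstract = t), auto_unbox = TRUE))
  })
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a synthetic truth table
#'
#' @param path Path to `truth.tsv` as written by [generate_corpus()].
#' @return Truth tibble.
#' @export
read_truth_tsv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  cols <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (length(lines) == 1L) {
    return(tibble::as_tibble(stats::setNames(rep(list(character(0)), length(cols)), cols)))
  }
  parts <- strsplit(lines[-1L], "\t", fixed = TRUE)
  tibble::as_tibble(stats::setNames(
    purrr::map(seq_along(cols), function(i) purrr::map_chr(parts, ~ if (length(.x) >= i) .x[i] else "")),
    cols
  ))
}

#' Score discovered groups against planted truth
#'
#' A discovered group matches a planted combination when its sentence, its
#' sorted subject CUIs, and its disease object all equal the plant. Only
#' claims labeled `combination` count as recoverable truth; groups arising
#' from comparison, negated, or contaminated claims are false positives.
#'
#' @param groups Candidate-group tibble.
#' @param truth Truth tibble from [generate_corpus()].
#' @return A list with `precision`, `recall`, `n_true`, `n_discovered`,
#'   `n_matched`. Precision (recall) is `NA` when nothing was discovered
#'   (planted).
#' @export
evaluate_recovery <- function(groups, truth) {
  pos <- truth[truth$true_label == "combination", , drop = FALSE]
  truth_keys <- paste(pos$sentence_id, pos$planted_subjects, pos$planted_object_cui)
  group_keys <- paste(
    groups$sentence_id,
    purrr::map_chr(groups$subjects, ~ paste(sort(.x$cui), collapse = "+")),
    groups$object_cui
  )
  n_matched <- sum(group_keys %in% truth_keys)
  list(
    precision = if (nrow(groups) == 0L) NA_real_ else n_matched / nrow(groups),
    recall = if (nrow(pos) == 0L) NA_real_ else n_matched / nrow(pos),
    n_true = nrow(pos),
    n_discovered = nrow(groups),
    n_matched = n_matched
  )
}
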