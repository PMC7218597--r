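---
title: "Discovering combination drug therapies from semantic predications"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering combination drug therapies from semantic predications}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(combokg)
```

## The discovery rule

Clinical trial abstracts condense their validated finding into one or two
conclusive sentences — the sentences containing `conclusion*` or
`conclude*`. When such a sentence reports a drug combination ("A
combination of GTI-2040, capecitabine and oxaliplatin is feasible in
patients with advanced solid tumors"), an NLP predication extractor such as
SemRep represents it as several subject–predicate–object triples that share
a predicate and an object but differ in subject: each drug `TREATS` the
patient population directly, and `TREATS(INFER)` the disease through the
inference chain *drug TREATS patients* + *disease PROCESS_OF patients*.

`combokg` turns that observation into a discovery rule. Within a single
conclusive claim, predications are

1. restricted to the four treatment predicates `TREATS`, `INHIBITS`,
   `PREVENTS`, `DISRUPTS` (inferred forms merge with their base predicate),
   with a drug-typed subject and a disease-typed object;
2. purged of overly generic concepts (below);
3. grouped by `(predicate, object CUI)`.

Every group with at least two distinct subject CUIs is a **combination
candidate**: the drugs S1…Si bound to one predicate P and one disease O,
i.e. `(S1+Si)-P-O`. Grouping on the object CUI rather than its display name
prevents synonym strings from splitting a combination; merging inferred and
direct predications is what lets the per-drug inference chains of a
multi-drug claim collapse into one group (the worked example would
otherwise yield three singletons and nothing else).

The rule is deliberately recall-oriented. Its two known false-positive
modes are surfaced, not hidden:

* **comparative single-therapy claims** ("Both pemetrexed and erlotinib had
  comparable efficacy…") produce the same multi-subject shape; when a
  `COMPARED_WITH` predication links two group members, the group's
  `comparison_flag` is set. Flagging rather than deleting keeps the
  decision with the analyst (`drop_comparisons = TRUE` hard-filters).
* **multi-combination claims** ("X plus either Y or Z…") surface as one
  oversized group; disambiguating them needs syntax the predication format
  does not carry, so they are left to downstream triage.

Negated predications (`NEG_TREATS`) are excluded by default
(`exclude_negated`), since a claim that a combination *failed* is not
evidence for it; switching the flag off restores the raw extractor
behaviour for error analysis.

## Semantic-type and broad-concept filters

The subject/object type restriction is configurable via `type_config()`.
Defaults: the "Chemicals and Drugs" group abbreviations (`phsu`, `orch`,
`antb`, `clnd`, `aapp`, `bacs`, `horm`, `imft`, `vita`, `enzy`) for
subjects, and `dsyn`/`neop`/`mobd` for objects. Exactly which child types
of "Disease or Syndrome" a corpus needs is an assumption, so the lists are
arguments, not constants; a concept qualifies when its type set
*intersects* the configured set, because UMLS concepts routinely carry
several types.

Two families of concepts are individually well-typed yet useless for
combination discovery, and are removed by name:

* **pharmacologic actions** ("Antineoplastic Agents", "Anti-Inflammatory
  Agents") — headings that say what a chemical does, not which chemical it
  is. They are collected from a MeSH descriptor table as every heading
  under the configured tree prefix (default `D27.505`). Prefix matching is
  segment-wise: `D27.505` covers `D27.505.954.248` but not `D27.5059`.
* **generic disease names** — the category-C root plus its 26 direct
  hyponyms (undotted tree numbers `C01`…`C26`), 27 terms in all. "Lung
  Neoplasms" at `C04.588` is specific and survives.

Matching is by case-folded preferred name. SemRep emits UMLS preferred
names and MeSH headings largely coincide with them for these broad
concepts; string matching therefore avoids requiring a UMLS licence, at
the cost of missing a synonym here and there — a documented limitation.
The MeSH input is a three-column TSV distillate
(`ui<TAB>name<TAB>tree;numbers`); producing it from the NLM ASCII release
is a one-line awk over the `MH`/`UI`/`MN` fields, and the package ships a
synthetic table (`synthetic_mesh_table()`) so nothing need be downloaded.

## The knowledge graph

A conventional triple store would scatter a combination across independent
drug→disease edges. `build_graph()` instead binds the member drugs into a
**combination node** directed at the disease, with the supporting
conclusive claims attached to that single treatment edge as evidence
(PMID, sentence id, claim text, markers, whether inference contributed).
Combination identity is the deterministic id
`cmb:<sorted member CUIs>:<predicate>:<object CUI>`, so the same drug set
asserted for two diseases is two nodes, and the same combination asserted
in two trials merges into one node whose edge accumulates both claims.
`query_by_disease()` returns the disease-centred subgraph;
`export_d3_json()` emits the nodes/links document a force-layout renderer
consumes (sorted keys, deterministic order, byte-stable round trip through
`import_kg_json()`), and `export_triples_tsv()` flattens the graph for
ingestion into conventional triple stores.

## Sentence segmentation and markers

The sentence splitter is a deterministic regex: boundaries at `.?!`
followed by whitespace and an upper-case letter/digit, protecting decimal
points, "e.g."/"i.e.", "et al." and a short abbreviation list. A
statistical segmenter would be marginally better on prose but would make
the `PMID.ab.N` sentence identifiers depend on a model version; stable
identifiers matter more here, because they are the provenance key joining
claims, predications, truth records, and graph evidence. Structured-
abstract labels (`CONCLUSION:`) stay part of the sentence, and numbering is
1-based over the whole abstract.

Marker detection looks for the four surface cues of combined-medication
claims — `combin*`, `coadministration`, `co-administered`, `regimen` — case-
insensitively on word boundaries. The detector reports every cue present;
`tabulate_markers()` applies the reporting convention that `regimen` is
counted only when none of the other three is present. The keyword stems
for conclusive sentences are `conclusion`/`conclud`, so "conclusions",
"concluded" and "concluding" all qualify.

## The synthetic corpus and what it does (not) show

`generate_corpus()` emulates the input side of the pipeline: template
abstracts whose conclusive sentence is planted as a combination claim, a
comparative single-therapy claim, a negated claim, or a drug-free
conclusion, together with the predications an extractor would plausibly
emit for each (the inference-chain shape for combinations, `COMPARED_WITH`
for comparisons, `NEG_TREATS` for negations), a MeSH fixture, and a truth
table. Defaults, chosen once as a realistic trial corpus: 70% of claims
carry a combination, sized 2/3/4 in the proportions 210:43:2 observed in
curated trial corpora; 12% are comparative single-therapy claims (the
dominant error mode in such corpora); 5% negations; 5% each
generic-subject/object contamination; six filler sentences per abstract.
Identical seeds give byte-identical files.

Passing the recovery suites shows that the *rule and plumbing* are correct:
with all noise at zero, precision = recall = 1 against the truth table, and
with negation noise on, no negated plant ever surfaces. It does **not**
show field performance on real abstracts, which is dominated by upstream
extractor quality (entity recognition, missed negations) and by claim
phrasings the templates do not cover. The package consumes extractor
output; it cannot be better than that input.

## Numerical and interface choices

* Problem sizes in the shipped test-suite: 1,000 random ≤6-record claims
  for the brute-force oracle comparison, 200-abstract corpora for
  recovery — large enough for every template and noise path to occur,
  small enough that the whole suite runs in well under a minute.
* Determinism everywhere: subjects sorted by CUI, groups by
  `(sentence_id, predicate, object)`, nodes/edges by kind and id; all
  serializers are byte-stable and all filters idempotent, so re-running a
  pipeline can never silently change an artifact.
* Degenerate inputs: empty files parse to empty typed tables; an empty
  graph exports as valid empty JSON; a claim whose predications all fail
  the filters simply yields no groups.
* Mechanism-pattern counting (`count_patterns()`) canonicalizes each
  group's class multiset with the precedence Immunotherapy > Targeted >
  Cytotoxic > Hormonal > other classes, so "Targeted + Cytotoxic" and
  "Cytotoxic + Targeted" are one pattern; unmapped drugs count as "Other".
  The drug→class map is user-supplied — mechanism classification is expert
  knowledge, not something the package invents.

## Worked example

```{r}
we <- worked_example()
claims <- extract_conclusive_claims(we$abstracts)
claims[, c("sentence_id", "markers")]

lists <- build_filter_lists(we$mesh)
groups <- discover_corpus(claims, we$predications, type_config(), lists)
groups[, c("sentence_id", "predicate_base", "object_name", "n_subjects")]
groups$subjects[[1]]

build_graph(groups)
```

## Known limitations

Abstracts only, no full text; no entity linking or concept normalization
(upstream's job); name-based broad-concept matching as discussed;
either/or claims not disambiguated; no statistical claim classifier — the
markers are exported precisely so that one can be trained downstream.
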