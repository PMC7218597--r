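# combokg

Automated discovery of **combination drug therapies** from the biomedical
literature, and their organisation into a combination-centric knowledge
graph.

Clinical trial reports state their validated finding in the conclusive
sentences of the abstract ("…we conclude that…", "CONCLUSION: …"). When
such a claim reports a drug combination, a semantic-predication extractor
(SemRep-style subject–predicate–object triples over UMLS concepts)
represents it as several predications that share a predicate and a disease
object but differ in their drug subject. `combokg` implements the
discovery rule built on that observation: within one conclusive claim,
after restricting predications to the treatment predicates
`TREATS`/`INHIBITS`/`PREVENTS`/`DISRUPTS` (inferred `(INFER)` forms merged,
`NEG_` forms excluded), to drug-typed subjects and disease-typed objects,
and after removing overly generic concepts (MeSH pharmacologic actions;
top-level disease classes C01–C26), every group of predications

```
S1-P-O, S2-P-O, …, Si-P-O   (i ≥ 2, distinct drug subjects Sk)
```

becomes a combination candidate `(S1+…+Si)-P-O`. Candidates are assembled
into a knowledge graph in which the member drugs are bound into a
combination node directed at the disease, with the supporting conclusive
claims attached to the treatment edge as evidence.

The package is aimed at literature-mining and knowledge-base builders: it
consumes extractor *output* (a documented pipe-delimited predication
dialect), never runs NLP itself, and ships a synthetic corpus generator
with planted ground truth so the whole pipeline is testable offline.

## Worked example

A built-in reference corpus contains four real trial conclusions, among
them sentence 15 of abstract 19322566 — *"CONCLUSION: A combination of
GTI-2040, capecitabine and oxaliplatin is feasible in patients with
advanced solid tumors."* — together with the seven predications an
extractor yields for it (each drug `TREATS` Patients and `TREATS(INFER)`
the disease; the disease `PROCESS_OF` Patients).

```r
library(combokg)

we     <- worked_example()
claims <- extract_conclusive_claims(we$abstracts)
lists  <- build_filter_lists(we$mesh)          # pharmacologic actions + generic diseases
groups <- discover_corpus(claims, we$predications, type_config(), lists)

groups[, c("sentence_id", "predicate_base", "object_name", "n_subjects", "any_inferred")]
#> # A tibble: 1 × 5
#>   sentence_id    predicate_base object_name                       n_subjects any_inferred
#>   <chr>          <chr>          <chr>                                  <int> <lgl>
#> 1 19322566.ab.15 TREATS         Advanced Malignant Solid Neoplasm          3 TRUE

groups$subjects[[1]]
#> # A tibble: 3 × 2
#>   cui      name
#>   <chr>    <chr>
#> 1 C0069717 oxaliplatin
#> 2 C0671970 capecitabine
#> 3 C1518922 GTI2040

build_graph(groups)
#> Combination knowledge graph
#>   nodes: 5 (combination: 1, disease: 1, drug: 3)
#>   edges: 4 (1 evidence items)
```

The seven predications collapse into exactly one three-drug candidate —
the two `TREATS → Patients` triples per drug fail the disease-object test,
`PROCESS_OF` fails the predicate test, and the three `TREATS(INFER)`
triples onto the disease merge under their shared `(TREATS, disease)` key.
The graph binds the three drug nodes into one combination node pointing at
the disease, the claim riding on the treatment edge as evidence.
`export_d3_json()` / `export_triples_tsv()` serialize it;
`query_by_disease()` returns disease-centred subgraphs.

## Command line

A thin wrapper over the same functions is installed at `exec/combokg`:

```sh
combokg simulate       --outdir corpus --seed 7 --n-abstracts 100
combokg extract-claims --abstracts corpus/abstracts.jsonl --out claims.tsv
combokg build-filters  --mesh corpus/mesh.tsv --out-actions actions.txt --out-diseases diseases.txt
combokg discover       --claims claims.tsv --predications corpus/predications.psv \
                       --actions actions.txt --diseases diseases.txt --out candidates.tsv
combokg build-kg       --candidates candidates.tsv --out-json kg.json --out-tsv triples.tsv
```

Each stage logs its record funnel (claims found, predications parsed,
survivors of each filter, groups discovered) and is deterministic given
its inputs.

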