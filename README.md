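# repurposeR

Mining patient drug reviews for drug-repurposing candidates.

Patients describe their medication experiences in free text on health
forums. Mostly they report the condition being treated or a known side
effect — but occasionally an unexpected benefit: *"I use it for acne. go
figure it works"*, written about a diuretic. repurposeR surfaces such
statements systematically. It is aimed at pharmacovigilance and drug
discovery researchers who want a transparent, fully testable baseline
pipeline over patient-generated text, where every stage is a plain
function that can be inspected or swapped.

## The method

Given a review corpus, a disease lexicon (concept id → spelling
variants, UMLS-style) and a drug knowledge base (per drug: synonyms,
brands, known indications, known side effects — DrugBank/SIDER-style),
the pipeline runs four stages:

1. **Exact dictionary NER.** A disease mention is a contiguous token
   sequence whose normalized form (lowercase, NFKC, whitespace
   collapsed) equals a lexicon entry; leftmost-longest non-overlapping
   selection; no stemming, no fuzzy matching.
2. **Known-effect filtering.** Each mention is labeled
   `known_indication` > `known_side_effect` > `novel` against the
   *reviewed* drug's concept sets. Explained mentions are removed, and
   reviews in which every mention is explained are discarded.
3. **Pattern mining.** Ten token templates with an optional bounded
   wildcard — `I use * for`, `I use it for`, `It helps with`, `It help
   with`, `I take it`, `I take it for`, `It works for`, `It is useful
   for`, `Useful for`, `Prescribed for` — are matched case-insensitively
   within sentences, counted per comment or per occurrence.
4. **Candidate aggregation.** A pattern match followed within a 10-token
   same-sentence window by a novel mention contributes a supporting
   comment to that (drug, disease) pair; pairs are ranked by distinct
   supporting comments.

A seeded synthetic-study generator (`generate_study()`) emulates all
three inputs with planted known/novel mentions, pattern statements,
misspellings and an ambiguous lexicon term, and records every plant in a
ground-truth ledger — the oracle for the package's end-to-end tests.

## A worked example

```r
library(repurposeR)
ext <- system.file("extdata", package = "repurposeR")
lex    <- load_lexicon(file.path(ext, "demo_lexicon.tsv"))
kb     <- load_knowledge_base(file.path(ext, "demo_kb.json"), lexicon = lex)
corpus <- load_corpus(file.path(ext, "demo_corpus.csv"))
run <- run_pipeline(corpus, lex, kb)
summary(run)
#> Repurposing-candidate mining run
#>   reviews in:             5
#>   disease mentions:      7 (1 explained, 6 novel)
#>   reviews discarded:      0
#>   pattern matches kept:   3
#>   candidate signals:      2
#>
#> Top candidate signals:
#>   Methadone + Diabetic neuropathy (1 supporting comment)
#>   Spironolactone + Acne (1 supporting comment)
```

The demo corpus is five reviews of five drugs. Seven disease mentions
are found; one ("pain"-type mentions of known indications) is explained
by the knowledge base and removed. Two reviews contain a beneficial
pattern directly followed by a novel disease, so exactly two candidate
signals emerge: methadone for diabetic neuropathy (the review spells it
"neuopathy", and the demo lexicon carries that variant — the matcher is
exact by design) and spironolactone for acne. `run$candidates` holds the
full evidence, including spans and a verbatim example comment per pair;
`render_reports(run, "reports/")` writes the standard TSV/JSONL report
set.

The same pipeline is scriptable via `inst/scripts/repurpose-miner`
(subcommands `simulate | validate | ner | filter | mine | run`, YAML
config plus flag overrides).

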