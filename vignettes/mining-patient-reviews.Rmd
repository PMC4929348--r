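---
title: "Mining patient drug reviews for repurposing candidates: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining patient drug reviews for repurposing candidates: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repurposeR)
```

## The problem

Patients write free-text reviews of their medications on health forums.
Most of what they report is expected — the condition the drug treats, or
its known side effects — but a minority of comments describe an
*unexpected benefit*: "I use it for acne. go figure it works", written
about a diuretic. Such statements are weak, noisy, individually
unreliable signals, yet in aggregate they are exactly the kind of lead
that drug-repurposing programmes screen for. repurposeR implements a
deliberately transparent pipeline for surfacing them:

1. **Disease recognition.** Exact dictionary matching of review text
   against a lexicon of disease spelling variants (UMLS-style: many
   surface forms per concept identifier).
2. **Known-effect filtering.** Every mention is classified against the
   reviewed drug's known indications (DrugBank-style) and known side
   effects (SIDER-style), at the concept level. Mentions explained this
   way are removed, and reviews in which *every* mention is explained are
   discarded.
3. **Beneficial-statement detection.** Ten short token templates — e.g.
   `I use * for`, `It helps with`, `Prescribed for` — are matched against
   the surviving reviews.
4. **Candidate aggregation.** A pattern match followed closely by a novel
   disease mention yields a supporting comment for that (drug, disease)
   pair; pairs are ranked by their number of distinct supporting
   comments.

Every stage is exposed as a plain function over plain containers, so any
step can be inspected, replaced or re-run in isolation.

## The matching model and its assumptions

### Normalization and tokens

All string comparison goes through one canonicalisation
(`normalize_text()`): lowercase, Unicode NFKC, whitespace collapsed,
ends trimmed. There is deliberately **no stemming, lemmatisation or
spelling correction**: the dictionary arm is an exact matcher, and its
failure modes are part of what the package makes measurable. A lexicon
holding only "dizzy" will not find "dizziness"; an over-broad variant
like "down" (from *Down syndrome*) will happily fire inside "lay down,
or stand". Both behaviours are asserted by the test suite rather than
hidden.

Tokens are maximal runs of letters, digits and apostrophes, with hyphens
kept only word-internally. Punctuation always splits, so "M.S." becomes
the tokens `M`, `S` — which is why a pattern can still fire in "I use
this for M.S. pain". Sentences are delimited by `.`, `!`, `?` or a
newline; informal review prose does not reward anything more elaborate.

### Dictionary NER

A mention is reported where a contiguous token sequence, normalized and
joined with single spaces, equals a lexicon entry, with both ends on
token boundaries and nothing but whitespace between the tokens (so
"dry  mouth" matches a "dry mouth" entry but "dry, mouth" does not —
this makes the invariant *normalize(surface) = matched variant* hold
exactly). At each starting token the longest entry wins, and scanning is
left-to-right over non-overlapping spans. Leftmost-longest selection is
the standard convention for exact matchers and makes counts well
defined; the test suite checks it against a brute-force enumerator of
every token window. A surface mapping to several concepts keeps all of
them; downstream, a mention counts as "known" if *any* of its concepts
is known for the drug — the conservative choice, since an explained
reading should disqualify a candidate.

### Known-effect classification

Labels follow the precedence *known indication > known side effect >
novel*. The precedence only matters when a concept appears in both
lists; either way the mention is removed, so results do not depend on
it. The "known" test is strictly per reviewed drug: a disease that is
some other drug's indication is still novel here. A drug absent from a
resource has an empty concept set for it, and filtering removes nothing
on that axis — which is how partial resource coverage (e.g. 74 of 180
drugs with side-effect data) propagates honestly through the pipeline.

Two filtering views exist because both are useful: mention-level
(`filter_mentions()`, for disease-frequency tables after filtering) and
comment-level (`discard_explained_comments()`). A review is discarded
iff it has at least one mention and all of them are explained. Reviews
with *no* disease mention are kept: a comment that names no disease
cannot be "explained by known effects", and it may still carry pattern
evidence useful in occurrence counting. This was a genuinely open design
point; the choice is recorded here and reflected in `FilterReport`.

### Pattern matching

Templates are whitespace-separated token lists with at most one `*`
wildcard. Matching is case-insensitive over the token stream; a wildcard
consumes 1 to `wildcard_max` tokens (default **3** — observed fills in
real reviews are one or two tokens: "this", "this med", "this
medication"); the shortest completing fill wins. The entire match must
lie within one sentence — slightly stronger than only constraining the
wildcard, but it avoids matches assembled across a full stop, and no
realistic phrasing is lost. Rules match independently: "I take it for
pain" supports both `I take it` and `I take it for`, because the two
templates are separate rules and nothing in their definition says
otherwise; counting them exclusively is a reporting decision that the
`comments`/`occurrences` modes leave to the analyst. The default
counting mode is `comments` (distinct reviews per rule).

`It is useful for` stays in the shipped set even though such stilted
phrasing is rare enough that its count is often zero: the set of ten is
a fixed, documented vocabulary, not a tuned one.

### Candidate linking

The package automates the step that, done manually, turns tagged
comments into candidates: a pattern match links to a novel mention in
the same review when the mention starts after the match ends, within
`link_window` tokens (default **10**), in the same sentence. The window
is conservative — in the canonical phrasing the disease immediately
follows the pattern ("I use it for *acne*", gap 1) — but 10 tokens
allows qualifiers ("I use it for my very stubborn hormonal adult acne").
Supporting evidence is grouped by (drug, concept), ranked by distinct
supporting reviews, ties broken alphabetically, and each candidate
carries one verbatim example comment plus span-level provenance that can
be re-checked against the text.

## The synthetic study generator

Real review corpora and licensed resources cannot ship with a package,
so `generate_study()` builds complete studies — lexicon, knowledge base,
corpus — whose every planted fact is recorded in a ground-truth ledger.
The generator is a pure function of `(config, seed)`; per-review seeds
are derived arithmetically from the root seed, so any single review can
be regenerated in isolation.

What it emulates, and the defaults chosen once for the reference study:

* **Scale**: 50 drugs × 20 reviews over 100 disease concepts with 1–3
  spelling variants each — large enough for every pipeline path to be
  exercised, small enough that exhaustive checks stay cheap.
* **Resource coverage**: 164/180 of drugs carry indications and 74/180
  carry side effects, the coverage profile of a knowledge base built
  from one indication resource and one side-effect resource.
* **Reporting imbalance**: side-effect mentions are planted more often
  (0.45 per review) than beneficial statements (0.12), because patients
  report adverse events far more readily than benefits; indication
  mentions sit at 0.35.
* **Pattern usage** is weighted by the relative frequencies at which the
  ten templates occur in real review corpora, so common phrasings
  dominate.
* **Known-pattern statements** (probability 0.10): pattern sentences
  about a *known* indication ("prescribed for <its indication>"). These
  are what make post-discard pattern counts drop below pre-discard
  counts, as they do in real corpora.
* **Adversarial plants**: a one-character misspelling of a disease term
  (must *never* be matched — the no-fuzziness property), and the
  ambiguous token "down", which is both a lexicon variant and an
  ordinary filler word; every occurrence is a ledger-tracked false
  positive of the exact-matching design.

The generator deliberately does **not** model realistic patient prose:
filler text is drawn from a fixed vocabulary that excludes every pattern
literal and every lexicon word (except "down"). That exclusion is what
makes the ledger *exact* — a planted count is the true count, so tests
can demand equality rather than tolerance. The corresponding limitation
is that passing tests demonstrate correctness of the machinery, not
recall on real prose: real reviews contain inflections, misspellings and
negations that an exact matcher misses by design. The same holds for
demographics: age, sex and duration fields are sampled uniformly and
carry no signal.

## Numerical and degenerate-input choices

* Character offsets are 0-based half-open throughout; token indices are
  1-based (R convention) and never serialized.
* Ties in frequency tables break alphabetically (by preferred name, or
  drug then concept), making every report byte-deterministic.
* Empty inputs are values, not errors: an empty corpus flows through the
  whole pipeline and produces well-formed empty reports; an unknown drug
  name in `resolve_drug()` is `NA`, not an error — but running the full
  pipeline over a review whose drug is absent from the knowledge base
  *is* an error, because its mentions cannot be classified.
* With an empty knowledge base, both filtering operations are the
  identity; `discard_explained_comments()` is idempotent; kept plus
  removed mentions always partition the input. These are tested as
  properties over seeded random studies, not single examples.

## Problem sizes used by the test suite

The suite cross-checks both matchers against brute-force oracles on
1,000 random instances each (texts up to ~500 characters / 60 tokens,
lexicons up to 50 entries), replays the full pipeline against the ledger
on the 50 × 20 reference study, and sweeps 20 random generator
configurations for filtering monotonicity. These sizes were chosen so
the whole suite completes in about a minute and a half on one CPU while
still visiting every code path; the oracle instance counts matter more
than instance size, since each instance exercises a full
enumerate-and-select cycle.

## Known limitations

* No negation or coreference handling: "I use it for nose allergies and
  it does not clear up my nostrils" links allergies as a candidate, because
  a token-template matcher cannot see the retraction later in the
  sentence.
* Exact matching undercounts: inflected or misspelled disease names are
  invisible unless the lexicon carries them as variants.
* Candidate signals are leads, not findings: they require expert review
  and experimental validation, and the package makes no attempt to rank
  by review scores or clinical plausibility.
* The linking window is a heuristic; a mention 11 tokens after a pattern
  is silently ignored at the default setting. The window is a config
  knob precisely because no principled value exists.

## A worked run

```{r demo}
ext <- system.file("extdata", package = "repurposeR")
lex <- load_lexicon(file.path(ext, "demo_lexicon.tsv"))
kb <- load_knowledge_base(file.path(ext, "demo_kb.json"), lexicon = lex)
corpus <- load_corpus(file.path(ext, "demo_corpus.csv"))
run <- run_pipeline(corpus, lex, kb)
summary(run)
```

The demonstration study is five drugs, five reviews; the pipeline
surfaces the two pairs whose reviews contain a pattern-linked novel
disease — methadone for diabetic neuropathy (spelled "neuopathy" in the
review and therefore carried as a variant in the demo lexicon) and
spironolactone for acne — and nothing else.
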