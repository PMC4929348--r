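Package: repurposeR
Title: Mining Patient Drug Reviews for Drug-Repurposing Candidates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for mining patient-written drug reviews for
    drug-repurposing signals. Implements exact dictionary-based disease
    named-entity recognition against a UMLS-style lexicon of spelling
    variants, concept-level filtering of mentions that are explained by a
    drug's known indications (DrugBank-style) or known side effects
    (SIDER-style), discarding of reviews that contain only explained
    mentions, rule-based detection of beneficial-effect statements via ten
    wildcard token patterns, and aggregation of the surviving
    pattern-linked disease mentions into ranked drug-disease candidate
    signals. Includes a fully seeded synthetic-data generator (lexicon,
    knowledge base, review corpus) that plants known and novel mentions
    and keeps a ground-truth ledger, so every stage of the pipeline can be
    tested against exact expectations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stringi,
    yaml,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
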