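small_cfg <- function(seed = 13L, ...)
  generator_config(seed = seed, n_drugs = 10L, n_diseases = 20L,
                   n_reviews_per_drug = c(5L, 10L), ...)

test_that("the generated study is a pure function of (config, seed)", {
  a <- generate_study(small_cfg(seed = 21L))
  b <- generate_study(small_cfg(seed = 21L))
  expect_identical(a$lexicon, b$lexicon)
  expect_identical(a$kb$drugs, b$kb$drugs)
  expect_identical(a$corpus$records, b$corpus$records)
  expect_identical(a$ledger, b$ledger)
  c <- generate_study(small_cfg(seed = 22L))
  expect_false(identical(a$corpus$records$text, c$corpus$records$text))
})

test_that("generated lexicons have the advertised structure", {
  cfg <- small_cfg()
  lex <- generate_lexicon(cfg)
  expect_equal(lex$n_concepts, 20L)
  vars <- names(lex$entries)
  expect_true(any(grepl(" ", vars)))              # multi-token variant
  # a variant that is a token-prefix of another (longest-match exercise)
  multi <- strsplit(vars[grepl(" ", vars)], " ", fixed = TRUE)
  expect_true(any(vapply(multi, function(m) m[1] %in% vars, logical(1))))
  expect_true("down" %in% vars)                   # ambiguous filler-shared
  expect_true("Down syndrome" %in% lex$concepts)
  cfg100 <- generator_config(seed = 1L, n_diseases = 100L)
  expect_equal(generate_lexicon(cfg100)$n_concepts, 100L)
})

test_that("generated knowledge bases hit the requested resource coverage", {
  cfg <- generator_config(seed = 3L, n_drugs = 180L, n_diseases = 30L,
                          frac_indication_coverage = 164 / 180,
                          frac_side_effect_coverage = 74 / 180)
  kb <- generate_kb(cfg, generate_lexicon(cfg))
  cov <- kb_coverage(kb)
  expect_equal(cov$n_covered, c(164L, 74L))
  # disjoint known sets per drug; uncovered drugs have empty sets
  for (d in kb$drugs) {
    expect_length(intersect(d$known_indications, d$known_side_effects), 0L)
    if (!d$in_side_effect_resource)
      expect_length(d$known_side_effects, 0L)
  }
})

test_that("null models behave as planted: no beneficials means no candidates", {
  st0 <- generate_study(small_cfg(p_novel_beneficial = 0,
                                  p_known_pattern = 0))
  expect_equal(nrow(st0$ledger$planted_candidates), 0L)
  run0 <- run_pipeline(st0$corpus, st0$lexicon, st0$kb)
  expect_equal(nrow(run0$candidates), 0L)
  # certain indication mentions, nothing novel: every mention-bearing
  # review is discarded
  st1 <- generate_study(generator_config(
    seed = 4L, n_drugs = 6L, n_diseases = 15L,
    n_reviews_per_drug = c(4L, 6L), p_indication_mention = 1,
    p_side_effect_mention = 0, p_novel_beneficial = 0,
    p_known_pattern = 0, p_misspelled_plant = 0,
    frac_indication_coverage = 1, frac_side_effect_coverage = 0))
  run1 <- run_pipeline(st1$corpus, st1$lexicon, st1$kb)
  men_ids <- unique(run1$labeled_mentions$review_id[
    run1$labeled_mentions$label != "novel"])
  novel_ids <- unique(run1$labeled_mentions$review_id[
    run1$labeled_mentions$label == "novel"])
  expect_identical(sort(run1$discarded_ids),
                   sort(setdiff(men_ids, novel_ids)))
  expect_identical(sort(run1$discarded_ids),
                   st1$ledger$expected_discards)
})

test_that("replaying the pipeline reproduces every ledger field exactly", {
  st <- generate_study(small_cfg(seed = 31L))
  run <- run_pipeline(st$corpus, st$lexicon, st$kb)
  led <- st$ledger
  # mentions with labels, as a multiset of (review, concept, label)
  lab <- run$labeled_mentions
  got <- sort(paste(lab$review_id,
                    vapply(lab$concept_ids, paste, character(1),
                           collapse = "|"), lab$label))
  planted <- sort(paste(led$planted_mentions$review_id,
                        led$planted_mentions$concept_id,
                        led$planted_mentions$label))
  expect_identical(got, planted)
  expect_identical(sort(run$discarded_ids), led$expected_discards)
  cnt <- setNames(run$pattern_counts_pre$count,
                  run$pattern_counts_pre$rule_id)
  expect_identical(as.integer(cnt[names(led$expected_pattern_counts)]),
                   unname(led$expected_pattern_counts))
  cntp <- setNames(run$pattern_counts_post$count,
                   run$pattern_counts_post$rule_id)
  expect_identical(as.integer(cntp[names(led$expected_pattern_counts_post)]),
                   unname(led$expected_pattern_counts_post))
  got_cand <- run$candidates[order(run$candidates$drug_id,
                                   run$candidates$concept_id),
                             c("drug_id", "concept_id")]
  rownames(got_cand) <- NULL
  expect_identical(got_cand, led$planted_candidates)
})

test_that("misspelled plants are never detected and imbalance matches the design", {
  st <- generate_study(small_cfg(seed = 77L, p_misspelled_plant = 0.8))
  expect_gt(nrow(st$ledger$planted_misspellings), 0L)
  men <- find_corpus_mentions(st$corpus, st$lexicon)
  for (k in seq_len(nrow(st$ledger$planted_misspellings))) {
    bad <- st$ledger$planted_misspellings[k, ]
    hit <- men[men$review_id == bad$review_id, ]
    expect_false(bad$surface %in% hit$matched_variant)
  }
  # adverse-event mentions outnumber beneficial ones under the defaults
  st2 <- generate_study(generator_config(seed = 8L, n_drugs = 25L,
                                         n_diseases = 30L,
                                         n_reviews_per_drug = c(10L, 10L)))
  pm <- st2$ledger$planted_mentions
  n_ade <- sum(pm$label == "known_side_effect")
  n_beneficial <- sum(pm$label == "novel" & pm$surface != "down")
  expect_gt(n_ade, n_beneficial)
})
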