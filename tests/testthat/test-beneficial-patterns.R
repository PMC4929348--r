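test_that("the shipped rule set compiles to exactly ten known templates", {
  rules <- compile_rules()
  expect_length(rules, 10L)
  expect_identical(vapply(rules, `[[`, character(1), "rule_id"),
                   c("I use * for", "I use it for", "It helps with",
                     "It help with", "I take it", "I take it for",
                     "It works for", "It is useful for", "Useful for",
                     "Prescribed for"))
  r1 <- rules[[1]]
  expect_true(r1$has_wildcard)
  expect_identical(r1$pre, c("i", "use"))
  expect_identical(r1$post, "for")
  useful <- rules[[9]]
  expect_false(useful$has_wildcard)
  expect_identical(useful$pre, c("useful", "for"))
  expect_error(compile_rules("a * b * c"), "more than one wildcard")
  expect_error(compile_rules(""), "empty pattern")
  # the same set ships as a parseable rules file
  shipped <- load_rules(system.file("extdata", "patterns_default.txt",
                                    package = "repurposeR"))
  expect_identical(shipped, rules)
})

test_that("patterns match the phrasings patients actually write", {
  rules <- compile_rules()
  m1 <- match_patterns(
    "I use this for diabetic neuopathy. works well with very little side effects.",
    rules)
  expect_identical(m1$rule_id, "I use * for")
  expect_identical(m1$wildcard_fill[[1]], "this")
  m2 <- match_patterns("I use this med for peripheral neuropathy pain.",
                       rules)
  expect_identical(m2$wildcard_fill[[1]], c("this", "med"))
  # the ungrammatical variant is its own rule and does not bleed over
  m3 <- match_patterns("it help with muscle spasms", rules)
  expect_identical(m3$rule_id, "It help with")
  m4 <- match_patterns("It helps with my pain from surgery", rules)
  expect_identical(m4$rule_id, "It helps with")
  expect_equal(nrow(match_patterns("this drug was great", rules)), 0L)
  # nested rules count independently
  m5 <- match_patterns("I take it for pain", rules)
  expect_setequal(m5$rule_id, c("I take it", "I take it for"))
  # wildcards never cross a sentence boundary
  expect_equal(nrow(match_patterns("I use this. for pain", rules)), 0L)
  # wildcard width is bounded
  expect_equal(nrow(match_patterns(
    "I use one two three four for pain", rules, wildcard_max = 3L)), 0L)
  expect_equal(nrow(match_patterns(
    "I use one two three for pain", rules, wildcard_max = 3L)), 1L)
})

test_that("pattern matching agrees with exhaustive wildcard enumeration on random texts", {
  rules <- compile_rules()
  set.seed(202)
  for (i in seq_len(200)) {
    text <- random_text(sample(3:60, 1), pool = .pattern_word_pool)
    got <- match_patterns(text, rules)
    exp <- pattern_oracle(text, rules)
    got_key <- sort(paste(got$rule_id, got$start, got$end))
    exp_key <- sort(paste(exp$rule_id, exp$start, exp$end))
    expect_identical(got_key, exp_key, info = paste("instance", i))
    expect_identical(match_patterns(text, rules), got) # deterministic
  }
})

test_that("pattern frequencies count comments or occurrences as requested", {
  rules <- compile_rules()
  corp <- review_corpus(data.frame(
    review_id = c("a", "b", "c"), drug_name = "x",
    text = c("I take it for pain",
             "nothing to see",
             "useful for sleep. also useful for mood"),
    stringsAsFactors = FALSE))
  com <- count_pattern_frequencies(corp, rules, mode = "comments")
  expect_identical(com$rule_id,
                   vapply(rules, `[[`, character(1), "rule_id"))
  cnt <- setNames(com$count, com$rule_id)
  expect_equal(cnt[["I take it"]], 1L)
  expect_equal(cnt[["I take it for"]], 1L)
  expect_equal(cnt[["Useful for"]], 1L)
  occ <- count_pattern_frequencies(corp, rules, mode = "occurrences")
  expect_equal(setNames(occ$count, occ$rule_id)[["Useful for"]], 2L)
  # three separate comments each carrying the pattern count three times
  corp3 <- review_corpus(data.frame(
    review_id = c("u1", "u2", "u3"), drug_name = "x",
    text = c("very useful for chronic and severe pain",
             "has been very useful for my depression.",
             "this med has been very useful for my hip and back pain."),
    stringsAsFactors = FALSE))
  com3 <- count_pattern_frequencies(corp3, rules, mode = "comments")
  expect_equal(setNames(com3$count, com3$rule_id)[["Useful for"]], 3L)
})

test_that("candidate linking respects order, window and sentence boundaries", {
  rules <- compile_rules()
  lex <- mini_lexicon()
  kb <- mini_kb()
  corp <- review_corpus(data.frame(
    review_id = c("r1", "r2"), drug_name = "Spironolactone",
    text = c("I use it for acne. go figure it works",
             "I use it for relief. acne got better"),  # next sentence: no link
    stringsAsFactors = FALSE))
  labeled <- classify_mentions(find_corpus_mentions(corp, lex),
                               "spironolactone", kb)
  novel <- filter_mentions(labeled)$kept
  matches <- do.call(rbind, lapply(1:2, function(i)
    match_patterns(corp$records$text[i], rules,
                   review_id = corp$records$review_id[i])))
  cand <- link_candidates(matches, novel, corp)
  expect_equal(nrow(cand), 1L)
  expect_identical(cand$drug_id, "spironolactone")
  expect_identical(cand$concept_id, "C_ACNE")
  expect_identical(sort(unique(cand$supporting[[1]]$review_id)), "r1")
  expect_identical(cand$example_text, corp$records$text[1])
  # a window too small to reach the mention yields nothing
  far <- review_corpus(data.frame(
    review_id = "r3", drug_name = "Spironolactone",
    text = "I use it for my very stubborn hormonal adult acne",
    stringsAsFactors = FALSE))
  lab3 <- classify_mentions(find_corpus_mentions(far, lex),
                            "spironolactone", kb)
  m3 <- match_patterns(far$records$text[1], rules, review_id = "r3")
  expect_equal(nrow(link_candidates(m3, lab3, far, window = 2L)), 0L)
  expect_equal(nrow(link_candidates(m3, lab3, far, window = 10L)), 1L)
})

test_that("reports are deterministic, well-formed files", {
  st <- generate_study(generator_config(seed = 9L, n_drugs = 6L,
                                        n_diseases = 12L,
                                        n_reviews_per_drug = c(4L, 8L)))
  run <- run_pipeline(st$corpus, st$lexicon, st$kb)
  d1 <- file.path(tempdir(), "rep1"); d2 <- file.path(tempdir(), "rep2")
  f1 <- render_reports(run, d1); f2 <- render_reports(run, d2)
  expect_setequal(basename(f1),
                  c("disease_freq.tsv", "per_drug_top.tsv",
                    "pattern_counts_pre.tsv", "pattern_counts_post.tsv",
                    "candidates.tsv", "candidates.jsonl"))
  for (k in seq_along(f1))
    expect_identical(readLines(f1[k]), readLines(f2[k]),
                     info = basename(f1[k]))
  # empty corpus: all tables empty but well-formed with headers
  empty <- review_corpus(st$corpus$records[0, ])
  run0 <- run_pipeline(empty, st$lexicon, st$kb)
  d0 <- file.path(tempdir(), "rep0")
  f0 <- render_reports(run0, d0)
  for (f in grep("tsv$", f0, value = TRUE))
    expect_gte(length(readLines(f)), 1L)
  expect_equal(nrow(run0$candidates), 0L)
})
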