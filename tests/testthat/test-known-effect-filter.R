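mention_row <- function(rid, cids, variant = "x") {
  m <- data.frame(review_id = rid, start = 0L, end = nchar(variant),
                  surface = variant, matched_variant = variant,
                  stringsAsFactors = FALSE)
  m$concept_ids <- list(cids)
  m
}

test_that("mention labels follow the indication > side effect > novel precedence", {
  kb <- mini_kb()
  lab <- classify_mentions(rbind(mention_row("r1", "C_PAIN", "pain"),
                                 mention_row("r2", "C_FEVER", "fever"),
                                 mention_row("r3", "C_ACNE", "acne")),
                           "methadone", kb)
  expect_identical(lab$label,
                   c("known_indication", "known_side_effect", "novel"))
  # acne is spironolactone's neither-indication-nor-side-effect
  lab2 <- classify_mentions(mention_row("r4", "C_ACNE", "acne"),
                            "spironolactone", kb)
  expect_identical(lab2$label, "novel")
  # a concept in both lists takes the indication label
  kb2 <- knowledge_base(list(list(drug_id = "d", name = "D",
                                  known_indications = list("C1"),
                                  known_side_effects = list("C1"))))
  expect_identical(classify_mentions(mention_row("r", "C1"), "d", kb2)$label,
                   "known_indication")
  # ambiguous mention counts as known if ANY of its concepts is known
  expect_identical(classify_mentions(
    mention_row("r", c("C_ACNE", "C_FEVER")), "methadone", kb)$label,
    "known_side_effect")
  expect_error(classify_mentions(mention_row("r", "C1"), "nope", kb),
               "unresolvable drug_id")
})

test_that("filter_mentions keeps exactly the novel mentions with consistent arithmetic", {
  kb <- mini_kb()
  men <- do.call(rbind, c(
    lapply(1:4, function(i) mention_row(paste0("i", i), "C_PAIN")),
    lapply(1:2, function(i) mention_row(paste0("s", i), "C_FEVER")),
    lapply(1:4, function(i) mention_row(paste0("n", i), "C_ACNE"))))
  fm <- filter_mentions(classify_mentions(men, "methadone", kb))
  expect_equal(fm$report$n_mentions_in, 10L)
  expect_equal(fm$report$n_mentions_removed, 6L)
  expect_equal(fm$report$n_mentions_kept, 4L)
  expect_true(all(fm$kept$label == "novel"))
  # partition: kept + removed = input, no duplicates
  expect_equal(nrow(fm$kept) + nrow(fm$removed), 10L)
  expect_identical(sort(c(fm$kept$review_id, fm$removed$review_id)),
                   sort(men$review_id))
  expect_identical(fm$report$per_drug_kept_mention_counts,
                   c(methadone = 4L))
  # a drug absent from the side-effect resource loses nothing to it
  fm2 <- filter_mentions(classify_mentions(
    mention_row("r", "C_FEVER", "fever"), "strattera", kb))
  expect_equal(fm2$report$n_mentions_removed, 0L)
})

test_that("comment discarding keeps novel-bearing and mention-free reviews only", {
  kb <- mini_kb()
  lex <- mini_lexicon()
  corp <- review_corpus(data.frame(
    review_id = c("r1", "r2", "r3"),
    drug_name = "Methadone",
    text = c("this treats my pain",                 # only known indication
             "pain but also diabetic neuopathy",    # known + novel
             "no diseases in here at all"),         # zero mentions
    stringsAsFactors = FALSE))
  labeled <- classify_mentions(find_corpus_mentions(corp, lex),
                               "methadone", kb)
  disc <- discard_explained_comments(corp, labeled)
  expect_identical(disc$discarded_ids, "r1")
  expect_identical(disc$kept$records$review_id, c("r2", "r3"))
  expect_equal(disc$report$n_comments_kept,
               disc$report$n_comments_in - disc$report$n_comments_discarded)
  # idempotent: filtering its own output changes nothing
  labeled2 <- labeled[labeled$review_id %in% disc$kept$records$review_id, ]
  disc2 <- discard_explained_comments(disc$kept, labeled2)
  expect_identical(disc2$kept$records, disc$kept$records)
  expect_length(disc2$discarded_ids, 0L)
  expect_error(discard_explained_comments(
    corp, mention_row("ghost", "C_PAIN")), "absent from the corpus")
})

test_that("with an empty knowledge base the filter is the identity", {
  lex <- mini_lexicon()
  kb0 <- knowledge_base(list(list(drug_id = "d", name = "Anydrug",
                                  in_indication_resource = FALSE,
                                  in_side_effect_resource = FALSE)))
  corp <- review_corpus(data.frame(
    review_id = c("a", "b"), drug_name = "Anydrug",
    text = c("pain and fever and acne", "adhd again"),
    stringsAsFactors = FALSE))
  labeled <- classify_mentions(find_corpus_mentions(corp, lex), "d", kb0)
  fm <- filter_mentions(labeled)
  expect_equal(fm$report$n_mentions_removed, 0L)
  expect_equal(nrow(fm$kept), nrow(labeled))
  disc <- discard_explained_comments(corp, labeled)
  expect_identical(disc$kept$records, corp$records)
  expect_length(disc$discarded_ids, 0L)
})
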