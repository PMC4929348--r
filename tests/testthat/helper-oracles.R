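# Brute-force oracles, independent re-derivations of the matching
# contracts: enumerate everything, then select. Used to cross-check the
# scanning implementations on random instances.

# Dictionary NER oracle: test every token window by normalizing the raw
# substring it covers (the mention invariant itself), then apply
# leftmost-longest non-overlapping selection.
ner_oracle <- function(text, lexicon) {
  toks <- tokenize(text)
  n <- nrow(toks)
  out <- data.frame(start = integer(0), end = integer(0),
                    matched_variant = character(0), stringsAsFactors = FALSE)
  if (n == 0L) return(out)
  keys <- names(lexicon$entries)
  cand <- list()
  for (i in seq_len(n)) for (j in i:n) {
    key <- normalize_text(substring(text, toks$start[i] + 1L, toks$end[j]))
    if (key %in% keys)
      cand[[length(cand) + 1L]] <- list(i = i, j = j, key = key)
  }
  pos <- 1L
  while (pos <= n) {
    here <- Filter(function(c) c$i == pos, cand)
    if (length(here)) {
      best <- here[[which.max(vapply(here, `[[`, integer(1), "j"))]]
      out <- rbind(out, data.frame(start = toks$start[best$i],
                                   end = toks$end[best$j],
                                   matched_variant = best$key,
                                   stringsAsFactors = FALSE))
      pos <- best$j + 1L
    } else pos <- pos + 1L
  }
  out
}

# Pattern oracle: enumerate every (start, wildcard width) combination whose
# literals line up and whose span stays in one sentence; then, per rule,
# select leftmost non-overlapping, preferring the shortest span at a start.
pattern_oracle <- function(text, rules, wildcard_max = 3L) {
  toks <- tokenize(text)
  n <- nrow(toks)
  out <- data.frame(rule_id = character(0), start = integer(0),
                    end = integer(0), stringsAsFactors = FALSE)
  if (n == 0L) return(out)
  norm <- normalize_text(toks$surface)
  for (rule in rules) {
    p <- length(rule$pre); q <- length(rule$post)
    cand <- list()
    for (s in seq_len(n)) {
      if (p > 0L && (s + p - 1L > n ||
                     !all(norm[s:(s + p - 1L)] == rule$pre))) next
      if (!rule$has_wildcard) {
        e <- s + p - 1L
        if (toks$sentence[s] == toks$sentence[e])
          cand[[length(cand) + 1L]] <- c(s, e)
      } else {
        for (w in seq_len(wildcard_max)) {
          e <- s + p + w - 1L + q
          if (e > n) next
          if (q > 0L &&
              !all(norm[(s + p + w):(s + p + w - 1L + q)] == rule$post)) next
          if (toks$sentence[s] != toks$sentence[e]) next
          cand[[length(cand) + 1L]] <- c(s, e)
        }
      }
    }
    pos <- 1L
    while (pos <= n) {
      here <- Filter(function(c) c[1] == pos, cand)
      if (length(here)) {
        best <- here[[which.min(vapply(here, `[`, integer(1), 2))]]
        out <- rbind(out, data.frame(rule_id = rule$rule_id,
                                     start = toks$start[best[1]],
                                     end = toks$end[best[2]],
                                     stringsAsFactors = FALSE))
        pos <- best[2] + 1L
      } else pos <- pos + 1L
    }
  }
  out
}

# Random instance builders for the property tests -------------------------

.oracle_word_pool <- c("pain", "itch", "rash", "dry", "mouth", "chronic",
                       "panic", "attack", "mood", "swing", "my", "the",
                       "and", "so", "very", "bad", "down", "leg", "head",
                       "ms", "a1c", "don't")

random_lexicon <- function(n_entries = 8L, pool = .oracle_word_pool) {
  n_entries <- max(1L, n_entries)
  vars <- unique(vapply(seq_len(n_entries), function(i)
    paste(sample(pool, sample(1:3, 1), replace = TRUE), collapse = " "),
    character(1)))
  disease_lexicon(concept_id = sprintf("C%03d", seq_along(vars)),
                  preferred_name = toupper(vars), variant = vars)
}

random_text <- function(n_tokens = 30L, pool = .oracle_word_pool) {
  seps <- c(" ", " ", " ", ". ", ", ", "! ", "? ", "\n", " - ")
  words <- sample(pool, n_tokens, replace = TRUE)
  paste0(paste0(words, sample(seps, n_tokens, replace = TRUE)),
         collapse = "")
}

# Pool that exercises the pattern literals heavily.
.pattern_word_pool <- c("i", "use", "it", "for", "helps", "help", "with",
                        "take", "works", "is", "useful", "prescribed",
                        "this", "med", "them", "my", "pain", "acne", "and",
                        "the", "well")

# tiny handcrafted knowledge base used across filter tests
mini_kb <- function() {
  knowledge_base(list(
    list(drug_id = "methadone", name = "Methadone",
         synonyms = list("methadone hydrochloride"),
         brand_names = list("Dolophine"),
         known_indications = list("C_PAIN", "C_OPIOID"),
         known_side_effects = list("C_FEVER")),
    list(drug_id = "spironolactone", name = "Spironolactone",
         known_indications = list("C_HTN", "C_HYPOK"),
         known_side_effects = list("C_HYPERK")),
    list(drug_id = "strattera", name = "Strattera",
         known_indications = list("C_ADHD"),
         in_side_effect_resource = FALSE)))
}

mini_lexicon <- function() {
  disease_lexicon(
    concept_id = c("C_PAIN", "C_OPIOID", "C_FEVER", "C_HTN", "C_HYPOK",
                   "C_HYPERK", "C_ADHD", "C_ACNE", "C_NEURO", "C_NEURO"),
    preferred_name = c("Pain", "Opioid dependence", "Fever",
                       "Hypertension", "Hypokalemia", "Hyperkalemia",
                       "ADHD", "Acne", "Diabetic neuropathy",
                       "Diabetic neuropathy"),
    variant = c("pain", "opioid dependence", "fever", "hypertension",
                "hypokalemia", "hyperkalemia", "adhd", "acne",
                "diabetic neuropathy", "diabetic neuopathy"))
}
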