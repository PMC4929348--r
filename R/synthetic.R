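# Synthetic study generator: seedable lexicons, drug knowledge bases and
# review corpora with planted known/novel disease mentions, planted
# beneficial-effect pattern statements and controlled noise. Every plant is
# recorded in a ground-truth ledger so downstream stages can be checked
# against exact expectations.

.pseudo_cons <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "s",
                  "t", "v", "z")
.pseudo_vow <- c("a", "e", "i", "o", "u")
.disease_suffixes <- c("itis", "osis", "algia", "emia", "opathy", "oma")
.drug_suffixes <- c("olol", "pril", "idone", "azine", "oxetine", "amide")
.disease_modifiers <- c("chronic", "acute", "severe", "recurrent",
                        "peripheral", "nocturnal")

# Words reviews are padded with. Deliberately excludes every literal token
# of the shipped patterns and every word that can occur inside a generated
# disease variant, except the single deliberately ambiguous token "down" —
# a lexicon variant shared with everyday language, the classic
# dictionary-NER false-positive mechanism.
.filler_words <- c(
  "the", "a", "my", "me", "and", "but", "so", "really", "very", "quite",
  "been", "have", "had", "was", "feel", "felt", "better", "worse", "good",
  "bad", "day", "night", "week", "month", "year", "since", "started",
  "stopped", "doctor", "nurse", "gave", "told", "after", "before", "while",
  "now", "then", "still", "only", "just", "also", "about", "again", "every",
  "morning", "evening", "sleep", "awake", "tired", "energy", "mood", "dose",
  "pill", "tablet", "water", "food", "stomach", "head", "lay", "down")

# Wildcard fills used when rendering a pattern statement; mirrors the kind
# of fills patients actually write ("this", "this med", "this medication").
.fill_phrases <- list("this", c("this", "med"), c("this", "medication"),
                      "them", c("my", "pills"))

.default_pattern_weights <- function()
  stats::setNames(c(307, 42, 131, 11, 1161, 91, 258, 0, 18, 319),
                  default_patterns())

.rint <- function(range) {
  if (range[1] >= range[2]) return(as.integer(range[1]))
  sample(range[1]:range[2], 1L)
}

.cap <- function(x) paste0(toupper(substring(x, 1, 1)), substring(x, 2))

.make_pseudowords <- function(n, suffixes, taken = character(0)) {
  out <- character(0)
  while (length(out) < n) {
    w <- paste0(sample(.pseudo_cons, 1), sample(.pseudo_vow, 1),
                sample(.pseudo_cons, 1), sample(.pseudo_vow, 1),
                sample(suffixes, 1))
    if (!(w %in% out) && !(w %in% taken)) out <- c(out, w)
  }
  out
}

#' Configuration for the synthetic study generator
#'
#' Defaults define the reference synthetic study: 50 drugs with 20 reviews
#' each over a 100-disease lexicon; known-side-effect mentions are planted
#' more often than beneficial statements (patients report adverse events
#' more readily than benefits); resource coverage mirrors a knowledge base
#' in which 164 of 180 drugs carry indications and 74 of 180 carry side
#' effects; and pattern usage is weighted by the relative frequencies at
#' which the ten templates occur in real review corpora.
#'
#' @param seed integer root seed; the whole generated study is a pure
#'   function of (config, seed).
#' @param n_drugs number of drugs (>= 1).
#' @param n_diseases number of disease concepts (>= 3; one is always the
#'   ambiguous "Down syndrome" concept whose variant "down" is shared with
#'   the filler vocabulary).
#' @param variants_per_disease integer range (lo, hi) of spelling variants
#'   per concept.
#' @param n_reviews_per_drug integer range (lo, hi) of reviews per drug.
#' @param p_indication_mention probability a review mentions one of its
#'   drug's known indications.
#' @param p_side_effect_mention probability a review mentions a known side
#'   effect.
#' @param p_novel_beneficial probability a review carries a beneficial
#'   pattern statement about a novel (unexplained) disease.
#' @param p_known_pattern probability a review carries a pattern statement
#'   about a known indication (these reviews can be discarded by the
#'   comment filter, which is what makes post-filter pattern counts drop).
#' @param p_misspelled_plant probability a review carries a one-character
#'   misspelling of a disease term, which the exact matcher must not find.
#' @param pattern_usage_weights named non-negative weights (template ->
#'   weight) for which pattern a beneficial statement uses; at least one
#'   must be positive.
#' @param filler_vocabulary_size number of filler words to use (>= 10,
#'   capped at the built-in vocabulary; the ambiguous word "down" is always
#'   retained).
#' @param frac_indication_coverage fraction of drugs present in the
#'   indication resource.
#' @param frac_side_effect_coverage fraction of drugs present in the
#'   side-effect resource.
#' @return a validated list of class `generator_config`.
#' @export
generator_config <- function(seed = 42L,
                             n_drugs = 50L,
                             n_diseases = 100L,
                             variants_per_disease = c(1L, 3L),
                             n_reviews_per_drug = c(20L, 20L),
                             p_indication_mention = 0.35,
                             p_side_effect_mention = 0.45,
                             p_novel_beneficial = 0.12,
                             p_known_pattern = 0.10,
                             p_misspelled_plant = 0.05,
                             pattern_usage_weights = NULL,
                             filler_vocabulary_size = 60L,
                             frac_indication_coverage = 164 / 180,
                             frac_side_effect_coverage = 74 / 180) {
  if (is.null(pattern_usage_weights))
    pattern_usage_weights <- .default_pattern_weights()
  probs <- c(p_indication_mention, p_side_effect_mention, p_novel_beneficial,
             p_known_pattern, p_misspelled_plant,
             frac_indication_coverage, frac_side_effect_coverage)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1))
    stop("all probabilities and coverage fractions must lie in [0, 1]")
  if (n_drugs < 1L || n_diseases < 3L)
    stop("need n_drugs >= 1 and n_diseases >= 3")
  rng_ok <- function(r) length(r) == 2L && r[1] >= 1L && r[2] >= r[1]
  if (!rng_ok(variants_per_disease) || !rng_ok(n_reviews_per_drug))
    stop("variants_per_disease and n_reviews_per_drug must be (lo, hi) with 1 <= lo <= hi")
  if (is.null(names(pattern_usage_weights)) ||
      any(pattern_usage_weights < 0) || !any(pattern_usage_weights > 0))
    stop("pattern_usage_weights must be named, non-negative, with at least one positive weight")
  compile_rules(names(pattern_usage_weights))  # templates must compile
  if (filler_vocabulary_size < 10L)
    stop("filler_vocabulary_size must be >= 10")
  structure(list(
    seed = as.integer(seed), n_drugs = as.integer(n_drugs),
    n_diseases = as.integer(n_diseases),
    variants_per_disease = as.integer(variants_per_disease),
    n_reviews_per_drug = as.integer(n_reviews_per_drug),
    p_indication_mention = p_indication_mention,
    p_side_effect_mention = p_side_effect_mention,
    p_novel_beneficial = p_novel_beneficial,
    p_known_pattern = p_known_pattern,
    p_misspelled_plant = p_misspelled_plant,
    pattern_usage_weights = pattern_usage_weights,
    filler_vocabulary_size = as.integer(filler_vocabulary_size),
    frac_indication_coverage = frac_indication_coverage,
    frac_side_effect_coverage = frac_side_effect_coverage),
    class = "generator_config")
}

.filler_vocab <- function(config) {
  k <- min(config$filler_vocabulary_size, length(.filler_words))
  unique(c(.filler_words[seq_len(k - 1L)], "down"))
}

.down_concept_id <- function(lexicon)
  names(lexicon$concepts)[lexicon$concepts == "Down syndrome"]

#' Generate a synthetic disease lexicon
#'
#' Concepts carry pseudoword names (so they can never collide with filler
#' text) plus spelling variants built from modifiers and compounds. The
#' lexicon always contains: a multi-token variant, a variant that is a
#' token-prefix of another (to exercise longest-match selection), and the
#' ambiguous concept "Down syndrome" whose variant "down" is an everyday
#' filler word — a deliberate, ledger-tracked false-positive surface.
#'
#' @param config a `generator_config`.
#' @return a `disease_lexicon` with `config$n_diseases` concepts;
#'   deterministic under `(config, config$seed)`.
#' @export
generate_lexicon <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n <- config$n_diseases
  bases <- .make_pseudowords(n - 1L, .disease_suffixes)
  cid <- character(0); pn <- character(0); var <- character(0)
  add <- function(id, name, v) {
    cid <<- c(cid, rep(id, length(v)))
    pn <<- c(pn, rep(name, length(v)))
    var <<- c(var, v)
  }
  for (i in seq_len(n - 1L)) {
    id <- sprintf("C%05d", i)
    base <- bases[i]
    if (i == 1L) {
      # forced prefix pair: "base" is a token-prefix of "base disorder"
      v <- c(base, paste(base, "disorder"))
    } else {
      k <- .rint(config$variants_per_disease)
      pool <- unique(c(paste(sample(.disease_modifiers), base),
                       paste(base, "disorder")))
      v <- c(base, if (k > 1L) pool[seq_len(min(k - 1L, length(pool)))])
    }
    add(id, .cap(base), v)
  }
  add(sprintf("C%05d", n), "Down syndrome", c("down syndrome", "down"))
  disease_lexicon(cid, pn, var)
}

#' Generate a synthetic drug knowledge base
#'
#' Each drug gets a canonical name, one synonym and one brand name (all
#' globally unique pseudowords) and, when covered by the respective
#' resource, disjoint sets of known indications and known side effects
#' drawn from the lexicon's concepts (never the ambiguous concept).
#'
#' @param config a `generator_config`.
#' @param lexicon the `disease_lexicon` from [generate_lexicon()].
#' @return a `knowledge_base`; deterministic under `(config, config$seed)`.
#' @export
generate_kb <- function(config, lexicon) {
  stopifnot(inherits(config, "generator_config"),
            inherits(lexicon, "disease_lexicon"))
  set.seed(config$seed + 1L)
  nd <- config$n_drugs
  concepts <- setdiff(names(lexicon$concepts), .down_concept_id(lexicon))
  names_all <- .make_pseudowords(3L * nd, .drug_suffixes)
  covered_ind <- sample(nd) <= round(config$frac_indication_coverage * nd)
  covered_se <- sample(nd) <= round(config$frac_side_effect_coverage * nd)
  drugs <- vector("list", nd)
  for (i in seq_len(nd)) {
    ind <- se <- character(0)
    if (covered_ind[i])
      ind <- sample(concepts, min(.rint(c(1L, 3L)), length(concepts)))
    if (covered_se[i]) {
      rest <- setdiff(concepts, ind)
      se <- sample(rest, min(.rint(c(1L, 4L)), length(rest)))
    }
    drugs[[i]] <- list(
      drug_id = sprintf("D%03d", i),
      name = .cap(names_all[3L * i - 2L]),
      synonyms = list(paste(names_all[3L * i - 1L], "hydrochloride")),
      brand_names = list(.cap(names_all[3L * i])),
      known_indications = as.list(ind),
      known_side_effects = as.list(se),
      in_indication_resource = covered_ind[i],
      in_side_effect_resource = covered_se[i])
  }
  knowledge_base(drugs, lexicon = lexicon)
}

# Which rule templates are present in one rendered sentence (token vector)?
# Deliberately simple enumeration over start positions and wildcard widths;
# this is the ledger's own bookkeeping, independent of the package matcher.
.rules_present <- function(tokens, rules, wildcard_max = 3L) {
  n <- length(tokens)
  hit <- vapply(rules, function(rule) {
    p <- length(rule$pre); q <- length(rule$post)
    for (s in seq_len(n)) {
      if (s + p - 1L > n || !all(tokens[s:(s + p - 1L)] == rule$pre)) next
      if (!rule$has_wildcard) return(TRUE)
      for (w in seq_len(wildcard_max)) {
        e <- s + p + w - 1L
        if (e + q > n) break
        if (q == 0L || all(tokens[(e + 1L):(e + q)] == rule$post))
          return(TRUE)
      }
    }
    FALSE
  }, logical(1))
  vapply(rules, `[[`, character(1), "rule_id")[hit]
}

# One character edit inside a single-token disease variant that provably
# escapes the lexicon, the filler vocabulary and the pattern literals.
.misspell <- function(word, forbidden) {
  pos <- max(2L, nchar(word) %/% 2L)
  for (repl in c("x", "q", "w", "j")) {
    cand <- paste0(substring(word, 1, pos - 1L), repl,
                   substring(word, pos + 1L))
    if (cand != word && !(cand %in% forbidden)) return(cand)
  }
  NULL
}

#' Generate a synthetic review corpus with a ground-truth ledger
#'
#' Each review is a shuffled handful of filler sentences into which, with
#' the configured probabilities, the generator plants at most one of each:
#' a known-indication mention, a known-side-effect mention, a beneficial
#' pattern statement followed immediately by a novel disease variant, a
#' pattern statement about a known indication, and a one-character
#' misspelled disease term that the exact matcher must not detect. Every
#' occurrence of the ambiguous filler word "down" is also tracked. The
#' ledger records every plant together with the exact downstream outcome
#' it implies: mention labels, pattern hits per rule (comments mode, before
#' and after comment discarding), the discard set, and the candidate
#' (drug, concept) pairs.
#'
#' @param config a `generator_config`.
#' @param lexicon from [generate_lexicon()].
#' @param kb from [generate_kb()].
#' @return list with `corpus` (a `review_corpus`) and `ledger` (class
#'   `ground_truth_ledger`: `planted_mentions`, `planted_pattern_hits`,
#'   `planted_candidates`, `planted_misspellings`,
#'   `expected_pattern_counts`, `expected_pattern_counts_post`,
#'   `expected_discards`). Fully deterministic under `(config, config$seed)`.
#' @export
generate_corpus <- function(config, lexicon, kb) {
  stopifnot(inherits(config, "generator_config"),
            inherits(lexicon, "disease_lexicon"),
            inherits(kb, "knowledge_base"))
  filler <- .filler_vocab(config)
  down_cid <- .down_concept_id(lexicon)
  templates <- names(config$pattern_usage_weights)
  rules <- compile_rules(templates)
  weights <- config$pattern_usage_weights

  # concept -> its variants; single-token variants for misspelling plants
  entry_names <- names(lexicon$entries)
  vmap <- split(rep(entry_names, lengths(lexicon$entries)),
                unlist(lexicon$entries, use.names = FALSE))
  single_tok <- entry_names[!grepl(" ", entry_names) & entry_names != "down"]
  misspell_forbidden <- c(entry_names, filler, "disorder", "syndrome",
                          unlist(lapply(rules, function(r) c(r$pre, r$post))))
  all_concepts <- setdiff(names(lexicon$concepts), down_cid)

  render_pattern <- function(template) {
    rule <- rules[[match(template, templates)]]
    fill <- if (rule$has_wildcard) .fill_phrases[[.rint(c(1L, length(.fill_phrases)))]]
            else character(0)
    c(rule$pre, fill, rule$post)
  }

  recs <- list(); men <- list(); hits <- list(); cands <- list()
  miss <- list(); rid_count <- 0L
  drug_ids <- names(kb$drugs)

  for (di in seq_len(config$n_drugs)) {
    d <- kb$drugs[[drug_ids[di]]]
    set.seed(as.integer((config$seed + 104729 * di) %% 2147483647))
    n_rev <- .rint(config$n_reviews_per_drug)
    use_brand <- stats::runif(n_rev) < 0.2
    for (ri in seq_len(n_rev)) {
      set.seed(as.integer((config$seed + 7919 * di + ri) %% 2147483647))
      rid_count <- rid_count + 1L
      rid <- sprintf("r%05d", rid_count)
      sentences <- list()
      add_mention <- function(cid, label, surface)
        men[[length(men) + 1L]] <<- data.frame(
          review_id = rid, drug_id = d$drug_id, concept_id = cid,
          label = label, surface = surface, stringsAsFactors = FALSE)
      add_hits <- function(tokens) {
        for (rl in .rules_present(tokens, rules))
          hits[[length(hits) + 1L]] <<- data.frame(
            review_id = rid, rule_id = rl, stringsAsFactors = FALSE)
      }
      fill_sent <- function(lo, hi)
        sample(filler, .rint(c(lo, hi)), replace = TRUE)
      plant_sent <- function(var)
        c(fill_sent(1L, 2L), strsplit(var, " ", fixed = TRUE)[[1]],
          fill_sent(0L, 2L))

      for (k in seq_len(.rint(c(1L, 3L))))
        sentences[[length(sentences) + 1L]] <- fill_sent(3L, 8L)

      if (stats::runif(1) < config$p_indication_mention &&
          length(d$known_indications)) {
        cid <- sample(d$known_indications, 1L)
        var <- sample(vmap[[cid]], 1L)
        sentences[[length(sentences) + 1L]] <- plant_sent(var)
        add_mention(cid, "known_indication", var)
      }
      if (stats::runif(1) < config$p_side_effect_mention &&
          length(d$known_side_effects)) {
        cid <- sample(d$known_side_effects, 1L)
        var <- sample(vmap[[cid]], 1L)
        sentences[[length(sentences) + 1L]] <- plant_sent(var)
        add_mention(cid, "known_side_effect", var)
      }
      if (stats::runif(1) < config$p_novel_beneficial) {
        novel_pool <- setdiff(all_concepts,
                              c(d$known_indications, d$known_side_effects))
        if (length(novel_pool)) {
          cid <- sample(novel_pool, 1L)
          var <- sample(vmap[[cid]], 1L)
          template <- sample(templates, 1L, prob = weights)
          toks <- c(render_pattern(template),
                    strsplit(var, " ", fixed = TRUE)[[1]])
          sentences[[length(sentences) + 1L]] <- toks
          add_mention(cid, "novel", var)
          add_hits(toks)
          cands[[length(cands) + 1L]] <- data.frame(
            drug_id = d$drug_id, concept_id = cid, stringsAsFactors = FALSE)
        }
      }
      if (stats::runif(1) < config$p_known_pattern &&
          length(d$known_indications)) {
        cid <- sample(d$known_indications, 1L)
        var <- sample(vmap[[cid]], 1L)
        template <- sample(templates, 1L, prob = weights)
        toks <- c(render_pattern(template),
                  strsplit(var, " ", fixed = TRUE)[[1]])
        sentences[[length(sentences) + 1L]] <- toks
        add_mention(cid, "known_indication", var)
        add_hits(toks)
      }
      if (stats::runif(1) < config$p_misspelled_plant) {
        bad <- .misspell(sample(single_tok, 1L), misspell_forbidden)
        if (!is.null(bad)) {
          sentences[[length(sentences) + 1L]] <-
            c(fill_sent(1L, 2L), bad, fill_sent(1L, 2L))
          miss[[length(miss) + 1L]] <- data.frame(
            review_id = rid, surface = bad, stringsAsFactors = FALSE)
        }
      }

      sentences <- sentences[sample(length(sentences))]
      text <- paste0(paste(vapply(sentences, paste, character(1),
                                  collapse = " "), collapse = ". "), ".")
      # every occurrence of the ambiguous word is a known false positive
      n_down <- sum(unlist(sentences) == "down")
      for (k in seq_len(n_down)) {
        lbl <- if (down_cid %in% d$known_indications) "known_indication"
        else if (down_cid %in% d$known_side_effects) "known_side_effect"
        else "novel"
        add_mention(down_cid, lbl, "down")
      }

      recs[[rid_count]] <- data.frame(
        review_id = rid,
        drug_name = if (use_brand[ri]) d$brand_names[1] else d$canonical_name,
        text = text,
        effectiveness = sample(c(NA_integer_, 1:5), 1L),
        ease_of_use = sample(c(NA_integer_, 1:5), 1L),
        satisfaction = sample(c(NA_integer_, 1:5), 1L),
        age_band = sample(c(NA, "19-24", "25-34", "35-44", "45-54",
                            "55-64", "65-74"), 1L),
        sex = sample(c("female", "male", "unspecified"), 1L),
        duration = sample(c(NA, "less than 1 month", "1 to 6 months",
                            "6 months to 1 year", "1 to 2 years"), 1L),
        stringsAsFactors = FALSE)
    }
  }

  bind <- function(lst, proto) {
    if (length(lst)) do.call(rbind, c(lst, list(make.row.names = FALSE)))
    else proto
  }
  mentions <- bind(men, data.frame(review_id = character(0),
                                   drug_id = character(0),
                                   concept_id = character(0),
                                   label = character(0),
                                   surface = character(0),
                                   stringsAsFactors = FALSE))
  pattern_hits <- bind(hits, data.frame(review_id = character(0),
                                        rule_id = character(0),
                                        stringsAsFactors = FALSE))
  pattern_hits <- unique(pattern_hits)
  rownames(pattern_hits) <- NULL
  candidates <- bind(cands, data.frame(drug_id = character(0),
                                       concept_id = character(0),
                                       stringsAsFactors = FALSE))
  candidates <- unique(candidates)
  candidates <- candidates[order(candidates$drug_id, candidates$concept_id), ,
                           drop = FALSE]
  rownames(candidates) <- NULL
  misspellings <- bind(miss, data.frame(review_id = character(0),
                                        surface = character(0),
                                        stringsAsFactors = FALSE))

  # discard a review iff it has mentions and none of them is novel
  per_review <- split(mentions$label, mentions$review_id)
  expected_discards <- names(per_review)[
    vapply(per_review, function(l) !any(l == "novel"), logical(1))]

  count_mode_comments <- function(keep_ids) {
    h <- pattern_hits[pattern_hits$review_id %in% keep_ids, , drop = FALSE]
    cnt <- stats::setNames(integer(length(templates)), templates)
    if (nrow(h)) {
      tab <- table(h$rule_id)
      cnt[names(tab)] <- as.integer(tab)
    }
    cnt
  }
  corpus <- review_corpus(bind(recs, NULL))
  all_ids <- corpus$records$review_id
  ledger <- structure(list(
    planted_mentions = mentions,
    planted_pattern_hits = pattern_hits,
    planted_candidates = candidates,
    planted_misspellings = misspellings,
    expected_pattern_counts = count_mode_comments(all_ids),
    expected_pattern_counts_post =
      count_mode_comments(setdiff(all_ids, expected_discards)),
    expected_discards = sort(expected_discards)),
    class = "ground_truth_ledger")
  list(corpus = corpus, ledger = ledger)
}

#' Generate a full synthetic study (lexicon, knowledge base, corpus, ledger)
#' @param config a `generator_config`.
#' @return list with `lexicon`, `kb`, `corpus`, `ledger`.
#' @export
generate_study <- function(config = generator_config()) {
  lexicon <- generate_lexicon(config)
  kb <- generate_kb(config, lexicon)
  cl <- generate_corpus(config, lexicon, kb)
  list(lexicon = lexicon, kb = kb, corpus = cl$corpus, ledger = cl$ledger)
}
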