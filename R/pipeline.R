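.read_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  config
}

.per_drug_top <- function(mentions, lexicon, phase, top_k = 3L) {
  empty <- data.frame(drug_id = character(0), phase = character(0),
                      rank = integer(0), concept_id = character(0),
                      preferred_name = character(0), count = integer(0),
                      stringsAsFactors = FALSE)
  if (nrow(mentions) == 0L) return(empty)
  parts <- lapply(split(mentions, mentions$drug_id), function(m) {
    f <- mention_frequencies(m, lexicon, top_k = top_k)
    if (nrow(f) == 0L) return(NULL)
    data.frame(drug_id = m$drug_id[1], phase = phase,
               rank = seq_len(nrow(f)), concept_id = f$concept_id,
               preferred_name = f$preferred_name, count = f$count,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(parts, list(make.row.names = FALSE)))
  if (is.null(out)) empty else out
}

#' Run the full repurposing-candidate mining pipeline
#'
#' Executes the stages in their canonical order: resolve each review's drug
#' against the knowledge base, find disease mentions by exact dictionary
#' matching, classify every mention against the drug's known indications
#' and side effects, filter explained mentions, discard reviews explained
#' entirely by known effects, count the beneficial-effect patterns before
#' and after discarding, and link surviving pattern matches to novel
#' mentions to form ranked drug-disease candidate signals.
#'
#' @param corpus a `review_corpus`, or a path to a YAML config file, or a
#'   config list. A config has sections `inputs` (`lexicon`, `kb`,
#'   `corpus`, `corpus_format`, optional `rules`), `patterns`
#'   (`wildcard_max`, `link_window`, `mode`) and `output` (`dir`); explicit
#'   arguments override config values.
#' @param lexicon a `disease_lexicon` (ignored when `corpus` is a config).
#' @param kb a `knowledge_base` (ignored when `corpus` is a config).
#' @param rules a `pattern_rules` object; default the ten shipped patterns.
#' @param wildcard_max maximum wildcard width in tokens.
#' @param link_window maximum token distance from a pattern match to the
#'   disease mention it supports.
#' @param mode pattern counting mode, `"comments"` or `"occurrences"`.
#' @param out_dir if non-NULL, [render_reports()] is called on the result.
#' @return an object of class `repurposing_run` holding the mention tables
#'   (`mentions`, `novel_mentions`), filter output (`filter_report`,
#'   `discard_report`, `discarded_ids`, `kept_corpus`), pattern counts
#'   (`pattern_counts_pre`, `pattern_counts_post`), disease frequency
#'   tables, the candidate table (`candidates`), and a `manifest` with
#'   stage counts, input digests, config snapshot, package version and
#'   timestamp.
#' @export
run_pipeline <- function(corpus, lexicon = NULL, kb = NULL,
                         rules = compile_rules(),
                         wildcard_max = 3L, link_window = 10L,
                         mode = c("comments", "occurrences"),
                         out_dir = NULL) {
  mode <- match.arg(mode)
  digests <- list()
  if (!inherits(corpus, "review_corpus")) {
    cfg <- .read_config(corpus)
    inp <- cfg$inputs
    if (is.null(inp$lexicon) || is.null(inp$kb) || is.null(inp$corpus))
      stop("config stage: inputs must name lexicon, kb and corpus files")
    for (f in c(inp$lexicon, inp$kb, inp$corpus, inp$rules))
      digests[[f]] <- unname(tools::md5sum(f))
    lexicon <- load_lexicon(inp$lexicon)
    kb <- load_knowledge_base(inp$kb, lexicon = lexicon)
    corpus <- load_corpus(inp$corpus,
                          format = inp$corpus_format %||% "csv")
    if (!is.null(inp$rules)) rules <- load_rules(inp$rules)
    pat <- cfg$patterns
    if (!is.null(pat$wildcard_max)) wildcard_max <- pat$wildcard_max
    if (!is.null(pat$link_window)) link_window <- pat$link_window
    if (!is.null(pat$mode)) mode <- match.arg(pat$mode,
                                              c("comments", "occurrences"))
    if (is.null(out_dir)) out_dir <- cfg$output$dir
  }
  stopifnot(inherits(lexicon, "disease_lexicon"),
            inherits(kb, "knowledge_base"),
            inherits(rules, "pattern_rules"))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage ", name, ": ", conditionMessage(e), call. = FALSE))
  }

  drug_of_review <- stage("resolve_drugs", {
    d <- resolve_drug(corpus$records$drug_name, kb)
    bad <- unique(corpus$records$drug_name[is.na(d)])
    if (length(bad))
      stop("drug name(s) not in the knowledge base: ",
           paste(bad, collapse = ", "))
    stats::setNames(d, corpus$records$review_id)
  })

  mentions <- stage("ner", find_corpus_mentions(corpus, lexicon))
  labeled <- stage("classify", classify_mentions(
    mentions, unname(drug_of_review[mentions$review_id]), kb))
  fm <- stage("filter_mentions", filter_mentions(labeled))
  disc <- stage("discard_comments",
                discard_explained_comments(corpus, labeled))
  kept <- disc$kept

  pre_counts <- stage("pattern_counts_pre",
                      count_pattern_frequencies(corpus, rules, mode = mode,
                                                wildcard_max = wildcard_max))
  post_counts <- stage("pattern_counts_post",
                       count_pattern_frequencies(kept, rules, mode = mode,
                                                 wildcard_max = wildcard_max))

  kept_ids <- kept$records$review_id
  novel_kept <- fm$kept[fm$kept$review_id %in% kept_ids, , drop = FALSE]
  matches <- stage("match_patterns", {
    parts <- lapply(seq_len(kept$n_records), function(i)
      match_patterns(kept$records$text[i], rules,
                     review_id = kept$records$review_id[i],
                     wildcard_max = wildcard_max))
    if (!length(parts)) match_patterns("", rules)
    else do.call(rbind, c(parts, list(make.row.names = FALSE)))
  })
  candidates <- stage("link_candidates",
                      link_candidates(matches, novel_kept, kept,
                                      window = link_window))

  freq_pre <- mention_frequencies(mentions, lexicon, top_k = 10L)
  freq_post <- if (nrow(fm$kept)) {
    mention_frequencies(fm$kept, lexicon, top_k = 10L)
  } else freq_pre[0, ]
  per_drug_top <- rbind(.per_drug_top(labeled, lexicon, "pre"),
                        .per_drug_top(fm$kept, lexicon, "post"))

  manifest <- list(
    input_digests = digests,
    config = list(wildcard_max = wildcard_max, link_window = link_window,
                  mode = mode),
    rule_set = vapply(rules, `[[`, character(1), "rule_id"),
    counts = list(
      n_reviews_in = corpus$n_records,
      n_mentions_found = nrow(mentions),
      n_mentions_removed = fm$report$n_mentions_removed,
      n_mentions_kept = fm$report$n_mentions_kept,
      n_comments_discarded = disc$report$n_comments_discarded,
      n_comments_kept = disc$report$n_comments_kept,
      n_pattern_hits = nrow(matches),
      n_candidates = nrow(candidates)),
    tool_version = as.character(utils::packageVersion("repurposeR")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))

  run <- structure(list(
    lexicon = lexicon, kb = kb, corpus = corpus,
    mentions = mentions, labeled_mentions = labeled,
    novel_mentions = fm$kept, removed_mentions = fm$removed,
    filter_report = fm$report,
    discard_report = disc$report, discarded_ids = disc$discarded_ids,
    kept_corpus = kept,
    pattern_counts_pre = pre_counts, pattern_counts_post = post_counts,
    matches = matches, candidates = candidates,
    disease_freq_pre = freq_pre, disease_freq_post = freq_post,
    per_drug_top = per_drug_top,
    manifest = manifest), class = "repurposing_run")
  if (!is.null(out_dir)) render_reports(run, out_dir)
  run
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate pipeline inputs without running the pipeline
#'
#' Checks that the configured lexicon, knowledge base, corpus and rules
#' load cleanly, that the knowledge base's concept ids all exist in the
#' lexicon, and that every pattern template compiles. Inputs are never
#' mutated.
#'
#' @param config a YAML config path or config list (see [run_pipeline()]).
#' @return data.frame with columns `stage` and `problem`; zero rows means
#'   the inputs validate.
#' @export
validate_inputs <- function(config) {
  cfg <- .read_config(config)
  problems <- data.frame(stage = character(0), problem = character(0),
                         stringsAsFactors = FALSE)
  note <- function(stage, msg)
    problems <<- rbind(problems, data.frame(stage = stage, problem = msg,
                                            stringsAsFactors = FALSE))
  inp <- cfg$inputs
  lexicon <- NULL
  if (is.null(inp$lexicon)) note("lexicon", "no lexicon path configured")
  else lexicon <- tryCatch(load_lexicon(inp$lexicon),
                           error = function(e) {
                             note("lexicon", conditionMessage(e)); NULL })
  if (is.null(inp$kb)) note("kb", "no knowledge base path configured")
  else tryCatch(load_knowledge_base(inp$kb, lexicon = lexicon),
                error = function(e) note("kb", conditionMessage(e)))
  if (is.null(inp$corpus)) note("corpus", "no corpus path configured")
  else tryCatch(load_corpus(inp$corpus,
                            format = inp$corpus_format %||% "csv"),
                error = function(e) note("corpus", conditionMessage(e)))
  if (!is.null(inp$rules))
    tryCatch(load_rules(inp$rules),
             error = function(e) note("rules", conditionMessage(e)))
  problems
}

#' @export
print.repurposing_run <- function(x, ...) {
  cn <- x$manifest$counts
  cat("Repurposing-candidate mining run\n")
  cat("  reviews in:            ", cn$n_reviews_in, "\n")
  cat("  disease mentions:      ", cn$n_mentions_found,
      " (", cn$n_mentions_removed, " explained, ", cn$n_mentions_kept,
      " novel)\n", sep = "")
  cat("  reviews discarded:     ", cn$n_comments_discarded, "\n")
  cat("  pattern matches kept:  ", cn$n_pattern_hits, "\n")
  cat("  candidate signals:     ", cn$n_candidates, "\n")
  invisible(x)
}

#' @export
summary.repurposing_run <- function(object, n = 10L, ...) {
  print(object)
  if (nrow(object$candidates)) {
    cat("\nTop candidate signals:\n")
    top <- utils::head(object$candidates, n)
    for (i in seq_len(nrow(top))) {
      cat(sprintf("  %s + %s (%d supporting comment%s)\n",
                  object$kb$drugs[[top$drug_id[i]]]$canonical_name,
                  unname(object$lexicon$concepts[top$concept_id[i]]),
                  top$n_supporting_comments[i],
                  if (top$n_supporting_comments[i] > 1) "s" else ""))
    }
  }
  invisible(object)
}
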