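#' Link beneficial-effect pattern matches to novel disease mentions
#'
#' A pattern match and a disease mention link when they sit in the same
#' review, the mention starts after the match ends, the mention's first
#' token is within `window` tokens of the match's last token, and both lie
#' in the same sentence. Linked pairs are aggregated by (drug, concept)
#' into candidate signals — the automated stand-in for the manual review
#' that turns tagged comments into repurposing candidates.
#'
#' @param matches a pattern-match data.frame from [match_patterns()] /
#'   the pipeline (must carry `review_id`, `rule_id`, `last_token`, `end`).
#' @param novel_mentions a labeled mention data.frame restricted to novel
#'   mentions (must carry `review_id`, `drug_id`, `start`, `end`,
#'   `concept_ids`).
#' @param corpus the `review_corpus` both refer to (texts are needed to
#'   place mentions on the token stream).
#' @param window maximum token distance from match end to mention start
#'   (default 10; must be >= 1).
#' @return data.frame of candidate signals ranked by
#'   `n_supporting_comments` descending, ties alphabetical by drug then
#'   concept: `drug_id`, `concept_id`, `n_supporting_comments`,
#'   `supporting` (list column of data.frames with `review_id`, `rule_id`,
#'   `mention_start`, `mention_end`), `example_text` (one verbatim
#'   supporting comment).
#' @export
link_candidates <- function(matches, novel_mentions, corpus, window = 10L) {
  stopifnot(inherits(corpus, "review_corpus"))
  if (!is.numeric(window) || window < 1) stop("window must be >= 1")
  window <- as.integer(window)
  empty <- data.frame(drug_id = character(0), concept_id = character(0),
                      n_supporting_comments = integer(0),
                      stringsAsFactors = FALSE)
  empty$supporting <- list()
  empty$example_text <- character(0)
  if (nrow(matches) == 0L || nrow(novel_mentions) == 0L) return(empty)

  texts <- stats::setNames(corpus$records$text, corpus$records$review_id)
  links <- list()
  for (rid in intersect(unique(matches$review_id),
                        unique(novel_mentions$review_id))) {
    toks <- tokenize(texts[[rid]])
    m <- matches[matches$review_id == rid, , drop = FALSE]
    men <- novel_mentions[novel_mentions$review_id == rid, , drop = FALSE]
    # mention spans start on token boundaries by construction
    men_tok <- match(men$start, toks$start)
    for (i in seq_len(nrow(m))) {
      for (j in seq_len(nrow(men))) {
        mt <- men_tok[j]
        if (is.na(mt)) next
        gap <- mt - m$last_token[i]
        if (gap < 1L || gap > window) next
        if (toks$sentence[mt] != toks$sentence[m$last_token[i]]) next
        for (cid in men$concept_ids[[j]]) {
          links[[length(links) + 1L]] <- data.frame(
            drug_id = men$drug_id[j], concept_id = cid, review_id = rid,
            rule_id = m$rule_id[i], mention_start = men$start[j],
            mention_end = men$end[j], stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(links)) return(empty)
  links <- do.call(rbind, links)
  links <- links[!duplicated(links), , drop = FALSE]

  key <- paste0(links$drug_id, "\r", links$concept_id)
  groups <- split(links, key)
  out <- do.call(rbind, lapply(groups, function(g) {
    data.frame(drug_id = g$drug_id[1], concept_id = g$concept_id[1],
               n_supporting_comments = length(unique(g$review_id)),
               stringsAsFactors = FALSE)
  }))
  out$supporting <- lapply(groups, function(g) {
    s <- g[, c("review_id", "rule_id", "mention_start", "mention_end")]
    rownames(s) <- NULL
    s
  })
  # example: the supporting review that appears first in the corpus
  corder <- stats::setNames(seq_len(corpus$n_records),
                            corpus$records$review_id)
  out$example_text <- vapply(out$supporting, function(s)
    unname(texts[s$review_id[which.min(corder[s$review_id])]]), character(1))
  out <- out[order(-out$n_supporting_comments, out$drug_id, out$concept_id), ]
  rownames(out) <- NULL
  out
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Write the standard report files for a pipeline run
#'
#' Emits deterministic TSV reports into `out_dir`: global disease
#' frequencies pre/post filtering (`disease_freq.tsv`), per-drug top
#' diseases pre/post filtering (`per_drug_top.tsv`), pattern counts before
#' and after discarding explained comments (`pattern_counts_pre.tsv`,
#' `pattern_counts_post.tsv`), and the ranked candidate table
#' (`candidates.tsv` with one verbatim example comment per row, plus
#' `candidates.jsonl` with full supporting evidence).
#'
#' @param run a `repurposing_run` from [run_pipeline()].
#' @param out_dir output directory (created if absent).
#' @return character vector of the files written, invisibly.
#' @export
render_reports <- function(run, out_dir) {
  stopifnot(inherits(run, "repurposing_run"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  add <- function(df, name) {
    p <- file.path(out_dir, name)
    .write_tsv(df, p)
    files <<- c(files, p)
  }
  freq <- rbind(
    cbind(phase = rep("pre", nrow(run$disease_freq_pre)),
          run$disease_freq_pre),
    cbind(phase = rep("post", nrow(run$disease_freq_post)),
          run$disease_freq_post))
  add(freq, "disease_freq.tsv")
  add(run$per_drug_top, "per_drug_top.tsv")
  add(run$pattern_counts_pre, "pattern_counts_pre.tsv")
  add(run$pattern_counts_post, "pattern_counts_post.tsv")

  cand <- run$candidates
  flat <- data.frame(
    drug_id = cand$drug_id,
    drug_name = vapply(cand$drug_id, function(d)
      run$kb$drugs[[d]]$canonical_name, character(1)),
    disease = unname(run$lexicon$concepts[cand$concept_id]),
    concept_id = cand$concept_id,
    n_supporting_comments = cand$n_supporting_comments,
    rule_ids = vapply(cand$supporting, function(s)
      paste(sort(unique(s$rule_id)), collapse = "; "), character(1)),
    example_text = cand$example_text,
    stringsAsFactors = FALSE)
  add(flat, "candidates.tsv")

  jl <- file.path(out_dir, "candidates.jsonl")
  lines <- vapply(seq_len(nrow(cand)), function(i)
    as.character(jsonlite::toJSON(list(
      drug_id = cand$drug_id[i], concept_id = cand$concept_id[i],
      n_supporting_comments = cand$n_supporting_comments[i],
      supporting = cand$supporting[[i]],
      example_text = cand$example_text[i]), auto_unbox = TRUE,
      dataframe = "rows")), character(1))
  writeLines(lines, jl, useBytes = TRUE)
  files <- c(files, jl)
  invisible(files)
}
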