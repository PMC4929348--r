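#' Find disease mentions in text by exact dictionary matching
#'
#' The dictionary arm of disease named-entity recognition: a mention is
#' reported wherever a contiguous token sequence, normalized and joined with
#' single spaces, exactly equals a lexicon entry, with both ends on token
#' boundaries. Only whitespace may separate the tokens of a multi-token
#' match (so "dry  mouth" matches a "dry mouth" entry but "dry, mouth" does
#' not), which guarantees that the mention's surface itself normalizes to
#' the lexicon entry. At each starting token the longest match wins;
#' reported mentions are mutually non-overlapping, scanned left to right.
#' There is no
#' stemming, no fuzzy matching and no spelling correction: a lexicon holding
#' only "dizzy" never matches "dizziness", while an over-broad variant like
#' "down" happily fires inside "lay down, or stand" — both behaviours are
#' deliberate properties of an exact matcher.
#'
#' @param text a single string (a review's free text).
#' @param review_id identifier recorded with each mention.
#' @param lexicon a `disease_lexicon`.
#' @return a data.frame of mentions in left-to-right order: `review_id`,
#'   `start`/`end` (0-based half-open character offsets), `surface` (exact
#'   substring), `matched_variant` (the normalized lexicon form), and
#'   `concept_ids` (list column; all concept ids the variant maps to).
#' @export
find_disease_mentions <- function(text, review_id, lexicon) {
  stopifnot(inherits(lexicon, "disease_lexicon"))
  empty <- data.frame(review_id = character(0), start = integer(0),
                      end = integer(0), surface = character(0),
                      matched_variant = character(0),
                      stringsAsFactors = FALSE)
  empty$concept_ids <- list()
  toks <- tokenize(text)
  n <- nrow(toks)
  if (n == 0L || lexicon$n_entries == 0L) return(empty)
  norm <- normalize_text(toks$surface)
  lmax <- lexicon_max_tokens(lexicon)
  keys <- names(lexicon$entries)

  # a multi-token window is only usable when nothing but whitespace sits
  # between its tokens, so that the surface itself normalizes to the entry
  gap_bad <- if (n > 1L) {
    vapply(seq_len(n - 1L), function(k)
      !grepl("^\\s*$", substring(text, toks$end[k] + 1L,
                                 toks$start[k + 1L])), logical(1))
  } else logical(0)
  bad_cum <- c(0L, cumsum(gap_bad))

  hits <- list(); i <- 1L
  while (i <= n) {
    matched_len <- 0L
    for (len in seq(min(lmax, n - i + 1L), 1L)) {
      if (bad_cum[i + len - 1L] - bad_cum[i] > 0L) next
      key <- paste(norm[i:(i + len - 1L)], collapse = " ")
      if (key %in% keys) { matched_len <- len; matched_key <- key; break }
    }
    if (matched_len > 0L) {
      j <- i + matched_len - 1L
      hits[[length(hits) + 1L]] <-
        list(start = toks$start[i], end = toks$end[j], key = matched_key)
      i <- j + 1L
    } else i <- i + 1L
  }
  if (!length(hits)) return(empty)
  start <- vapply(hits, `[[`, integer(1), "start")
  end <- vapply(hits, `[[`, integer(1), "end")
  key <- vapply(hits, `[[`, character(1), "key")
  out <- data.frame(review_id = review_id, start = start, end = end,
                    surface = substring(text, start + 1L, end),
                    matched_variant = key, stringsAsFactors = FALSE)
  out$concept_ids <- unname(lexicon$entries[key])
  out
}

#' Find disease mentions across a whole corpus
#'
#' Applies [find_disease_mentions()] to every review and row-binds the
#' results in corpus order.
#'
#' @param corpus a `review_corpus`.
#' @param lexicon a `disease_lexicon`.
#' @return a mention data.frame as in [find_disease_mentions()].
#' @export
find_corpus_mentions <- function(corpus, lexicon) {
  stopifnot(inherits(corpus, "review_corpus"))
  parts <- lapply(seq_len(corpus$n_records), function(i)
    find_disease_mentions(corpus$records$text[i],
                          corpus$records$review_id[i], lexicon))
  if (!length(parts)) return(find_disease_mentions("", "x", lexicon))
  do.call(rbind, c(parts, list(make.row.names = FALSE)))
}

#' Rank diseases by mention frequency
#'
#' Groups mentions by the preferred name of their concept; a mention whose
#' surface is ambiguous (maps to several concepts) contributes one count to
#' each. Ordered by count descending, ties broken alphabetically by
#' preferred name.
#'
#' @param mentions a mention data.frame from [find_corpus_mentions()].
#' @param lexicon the `disease_lexicon` the mentions were found with.
#' @param top_k how many rows to keep (>= 1).
#' @return data.frame with columns `preferred_name`, `concept_id`, `count`.
#' @export
mention_frequencies <- function(mentions, lexicon, top_k = 10L) {
  stopifnot(inherits(lexicon, "disease_lexicon"))
  if (!is.numeric(top_k) || length(top_k) != 1L || top_k < 1)
    stop("top_k must be a single count >= 1")
  empty <- data.frame(preferred_name = character(0),
                      concept_id = character(0), count = integer(0),
                      stringsAsFactors = FALSE)
  if (nrow(mentions) == 0L) return(empty)
  cid <- unlist(mentions$concept_ids, use.names = FALSE)
  tab <- table(cid)
  out <- data.frame(preferred_name = unname(lexicon$concepts[names(tab)]),
                    concept_id = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$preferred_name), ]
  rownames(out) <- NULL
  utils::head(out, as.integer(top_k))
}
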