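#' Classify disease mentions against a drug's known effects
#'
#' Labels each mention relative to the drug under review:
#' `known_indication` if any of the mention's concepts is among that drug's
#' known indications, else `known_side_effect` if any concept is among its
#' known side effects, else `novel`. The indication label takes precedence
#' when a concept sits in both lists; either way such a mention is
#' "explained" and will be filtered. The test is strictly per reviewed drug
#' — a disease that is some other drug's indication is still novel here.
#'
#' @param mentions a mention data.frame (see [find_corpus_mentions()]).
#' @param drug_id character vector (length 1 or `nrow(mentions)`): the drug
#'   each mention's review is about. Every id must exist in `kb`.
#' @param kb a `knowledge_base`.
#' @return the mention data.frame with columns `drug_id` and `label` added.
#' @export
classify_mentions <- function(mentions, drug_id, kb) {
  stopifnot(inherits(kb, "knowledge_base"))
  n <- nrow(mentions)
  drug_id <- as.character(drug_id)
  if (length(drug_id) == 1L) drug_id <- rep(drug_id, n)
  stopifnot(length(drug_id) == n)
  unknown <- setdiff(unique(drug_id), names(kb$drugs))
  if (length(unknown))
    stop("unresolvable drug_id: ", paste(unknown, collapse = ", "))
  label <- character(n)
  for (i in seq_len(n)) {
    d <- kb$drugs[[drug_id[i]]]
    cids <- mentions$concept_ids[[i]]
    label[i] <- if (any(cids %in% d$known_indications)) "known_indication"
    else if (any(cids %in% d$known_side_effects)) "known_side_effect"
    else "novel"
  }
  mentions$drug_id <- drug_id
  mentions$label <- label
  mentions
}

#' Filter explained mentions, keeping the novel ones
#'
#' Mention-level filtering: removes every mention labeled as a known
#' indication or known side effect of its drug, and reports the arithmetic.
#'
#' @param labeled a labeled mention data.frame from [classify_mentions()].
#' @return a list with `kept` (the novel mentions, original order),
#'   `removed`, and `report`: `n_mentions_in`, `n_mentions_removed`,
#'   `n_mentions_kept`, and `per_drug_kept_mention_counts` (named integer
#'   vector).
#' @export
filter_mentions <- function(labeled) {
  stopifnot(all(c("label", "drug_id") %in% names(labeled)))
  keep <- labeled$label == "novel"
  kept <- labeled[keep, , drop = FALSE]
  removed <- labeled[!keep, , drop = FALSE]
  rownames(kept) <- rownames(removed) <- NULL
  per_drug <- if (nrow(kept)) table(kept$drug_id) else table(character(0))
  list(kept = kept, removed = removed,
       report = list(n_mentions_in = nrow(labeled),
                     n_mentions_removed = nrow(removed),
                     n_mentions_kept = nrow(kept),
                     per_drug_kept_mention_counts =
                       stats::setNames(as.integer(per_drug),
                                       names(per_drug))))
}

#' Discard reviews explained entirely by known effects
#'
#' Comment-level filtering: a review is discarded iff it has at least one
#' disease mention and every one of its mentions is a known indication or
#' known side effect of the reviewed drug. Reviews with at least one novel
#' mention survive, as do reviews with no mentions at all (a review that
#' names no disease cannot be "explained"). Order is preserved; the
#' operation is idempotent.
#'
#' @param corpus a `review_corpus`.
#' @param labeled a labeled mention data.frame from [classify_mentions()];
#'   every `review_id` in it must exist in `corpus`.
#' @return a list with `kept` (a `review_corpus`), `discarded_ids`
#'   (character vector of discarded review ids) and `report`:
#'   `n_comments_in`, `n_comments_discarded`, `n_comments_kept`.
#' @export
discard_explained_comments <- function(corpus, labeled) {
  stopifnot(inherits(corpus, "review_corpus"))
  ids <- corpus$records$review_id
  dangling <- setdiff(unique(labeled$review_id), ids)
  if (length(dangling))
    stop("labels reference review_id(s) absent from the corpus: ",
         paste(dangling, collapse = ", "))
  explained <- labeled$label %in% c("known_indication", "known_side_effect")
  has_mention <- ids %in% labeled$review_id
  has_novel <- ids %in% labeled$review_id[!explained]
  discard <- has_mention & !has_novel
  kept <- review_corpus(corpus$records[!discard, , drop = FALSE])
  list(kept = kept,
       discarded_ids = ids[discard],
       report = list(n_comments_in = corpus$n_records,
                     n_comments_discarded = sum(discard),
                     n_comments_kept = corpus$n_records - sum(discard)))
}
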