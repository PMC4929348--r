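# The ten beneficial-effect templates shipped by default, in canonical
# order. '*' is a wildcard over 1..wildcard_max tokens. Note that the set
# deliberately keeps near-duplicates apart ("It helps with" vs the
# ungrammatical but frequent "It help with") and keeps "It is useful for"
# even though such stilted phrasing is rare in informal reviews.
.default_patterns <- c(
  "I use * for",
  "I use it for",
  "It helps with",
  "It help with",
  "I take it",
  "I take it for",
  "It works for",
  "It is useful for",
  "Useful for",
  "Prescribed for")

#' The default beneficial-effect pattern set
#' @return character vector of the ten shipped pattern templates.
#' @export
default_patterns <- function() .default_patterns

#' Compile textual pattern templates into rules
#'
#' Each spec is a whitespace-separated token template in which `*` marks a
#' wildcard over one or more consecutive tokens; at most one wildcard is
#' allowed per template. Literal tokens are normalized, so matching is
#' case-insensitive.
#'
#' @param specs character vector of templates (default: the ten shipped
#'   patterns).
#' @return a list of rules of class `pattern_rules`; each rule has
#'   `rule_id` (the original template string), `pre` (normalized literal
#'   tokens before the wildcard), `post` (literals after it) and
#'   `has_wildcard`.
#' @export
compile_rules <- function(specs = default_patterns()) {
  rules <- lapply(specs, function(spec) {
    toks <- strsplit(trimws(spec), "\\s+", perl = TRUE)[[1]]
    if (!length(toks) || !nzchar(spec))
      stop("empty pattern template")
    wc <- which(toks == "*")
    if (length(wc) > 1L)
      stop("pattern '", spec, "' has more than one wildcard")
    lit <- normalize_text(toks[toks != "*"])
    if (any(!nzchar(lit)))
      stop("pattern '", spec, "' has an empty literal token")
    if (length(wc)) {
      list(rule_id = spec, pre = lit[seq_len(wc - 1L)],
           post = if (wc <= length(lit)) lit[wc:length(lit)] else character(0),
           has_wildcard = TRUE)
    } else {
      list(rule_id = spec, pre = lit, post = character(0),
           has_wildcard = FALSE)
    }
  })
  ids <- vapply(rules, `[[`, character(1), "rule_id")
  if (anyDuplicated(ids))
    stop("duplicate pattern template(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  structure(rules, class = "pattern_rules")
}

#' Load pattern rules from a text file
#'
#' One template per line; `#` comment lines and blank lines are ignored.
#' @param path path to the rules file.
#' @return a `pattern_rules` object.
#' @export
load_rules <- function(path) {
  if (!file.exists(path)) stop("rules file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(lines)
  compile_rules(lines[nzchar(lines) & !startsWith(lines, "#")])
}

# Match one rule against the normalized token stream of one text.
# toks: tokenize() output; norm: normalized surfaces. Candidate matches are
# enumerated at every start token; a wildcard tries 1..wildcard_max fills,
# shortest first; the whole match must sit inside one sentence. Within the
# rule, matches are selected leftmost non-overlapping.
.match_rule <- function(rule, toks, norm, wildcard_max) {
  n <- length(norm)
  p <- length(rule$pre); q <- length(rule$post)
  sent <- toks$sentence
  out <- list(); s <- 1L
  while (s <= n) {
    endtok <- NA_integer_; fill <- character(0)
    pre_ok <- p == 0L ||
      (s + p - 1L <= n && all(norm[s:(s + p - 1L)] == rule$pre))
    if (pre_ok) {
      if (!rule$has_wildcard) {
        e <- s + p - 1L
        if (sent[s] == sent[e]) endtok <- e
      } else {
        for (w in seq_len(wildcard_max)) {
          e <- s + p + w - 1L            # last wildcard token
          if (e + q > n) break
          if (sent[s] != sent[e + q]) break  # longer fills only cross further
          if (q > 0L && !all(norm[(e + 1L):(e + q)] == rule$post)) next
          endtok <- e + q
          fill <- norm[(s + p):e]
          break
        }
      }
    }
    if (!is.na(endtok)) {
      out[[length(out) + 1L]] <- list(
        first = s, last = endtok,
        start = toks$start[s], end = toks$end[endtok],
        wildcard_fill = fill)
      s <- endtok + 1L
    } else s <- s + 1L
  }
  out
}

#' Match beneficial-effect patterns in text
#'
#' Matching is case-insensitive over the token stream from [tokenize()]. A
#' wildcard consumes 1 to `wildcard_max` consecutive tokens (shortest fill
#' that completes the rule), and a match never crosses a sentence boundary
#' (`.`, `!`, `?` or newline). All rules are matched independently — a
#' region saying "I take it for pain" supports both "I take it" and
#' "I take it for". Within one rule, matches are leftmost non-overlapping.
#'
#' @param text a single string.
#' @param rules a `pattern_rules` object.
#' @param review_id identifier recorded with each match.
#' @param wildcard_max maximum tokens one wildcard may consume (default 3).
#' @return data.frame of matches: `review_id`, `rule_id`, `start`/`end`
#'   (0-based half-open character offsets), `first_token`/`last_token`
#'   (1-based token indices), `surface`, and `wildcard_fill` (list column
#'   of normalized fill tokens, empty for literal-only rules).
#' @export
match_patterns <- function(text, rules, review_id = "", wildcard_max = 3L) {
  stopifnot(inherits(rules, "pattern_rules"), wildcard_max >= 1L)
  empty <- data.frame(review_id = character(0), rule_id = character(0),
                      start = integer(0), end = integer(0),
                      first_token = integer(0), last_token = integer(0),
                      surface = character(0), stringsAsFactors = FALSE)
  empty$wildcard_fill <- list()
  toks <- tokenize(text)
  if (nrow(toks) == 0L) return(empty)
  norm <- normalize_text(toks$surface)
  out <- empty
  for (rule in rules) {
    hits <- .match_rule(rule, toks, norm, as.integer(wildcard_max))
    if (!length(hits)) next
    df <- data.frame(
      review_id = review_id, rule_id = rule$rule_id,
      start = vapply(hits, `[[`, integer(1), "start"),
      end = vapply(hits, `[[`, integer(1), "end"),
      first_token = vapply(hits, `[[`, integer(1), "first"),
      last_token = vapply(hits, `[[`, integer(1), "last"),
      stringsAsFactors = FALSE)
    df$surface <- substring(text, df$start + 1L, df$end)
    df$wildcard_fill <- lapply(hits, `[[`, "wildcard_fill")
    out <- rbind(out, df)
  }
  rownames(out) <- NULL
  out
}

#' Count pattern frequencies over a corpus
#'
#' @param corpus a `review_corpus` (pre- or post-filtering).
#' @param rules a `pattern_rules` object.
#' @param mode `"comments"` counts distinct reviews containing at least one
#'   match of the rule (the default reporting mode); `"occurrences"` counts
#'   every match.
#' @param wildcard_max passed to [match_patterns()].
#' @return data.frame with columns `rule_id` and `count`, in rule order.
#' @export
count_pattern_frequencies <- function(corpus, rules,
                                      mode = c("comments", "occurrences"),
                                      wildcard_max = 3L) {
  stopifnot(inherits(corpus, "review_corpus"))
  mode <- match.arg(mode)
  ids <- vapply(rules, `[[`, character(1), "rule_id")
  counts <- stats::setNames(integer(length(ids)), ids)
  for (i in seq_len(corpus$n_records)) {
    m <- match_patterns(corpus$records$text[i], rules,
                        review_id = corpus$records$review_id[i],
                        wildcard_max = wildcard_max)
    if (!nrow(m)) next
    if (mode == "comments") {
      hit <- unique(m$rule_id)
      counts[hit] <- counts[hit] + 1L
    } else {
      tab <- table(m$rule_id)
      counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
    }
  }
  data.frame(rule_id = ids, count = unname(counts), stringsAsFactors = FALSE)
}
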