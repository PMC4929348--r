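#' Normalize free text for exact matching
#'
#' Canonical normalization used everywhere strings are compared: lowercase,
#' Unicode NFKC compatibility folding, whitespace runs collapsed to a single
#' space, and leading/trailing whitespace stripped. The dictionary matcher is
#' exact by design (no stemming, no spelling correction), so this is the
#' whole of the string canonicalisation the package performs.
#'
#' @param raw character vector of arbitrary Unicode strings.
#' @return character vector of the same length; normalization is idempotent
#'   (`normalize_text(normalize_text(x))` equals `normalize_text(x)`).
#' @examples
#' normalize_text("Dry  Mouth ")  # "dry mouth"
#' @export
normalize_text <- function(raw) {
  if (length(raw) == 0L) return(character(0))
  x <- stringi::stri_trans_nfkc(as.character(raw))
  x <- stringi::stri_trans_tolower(x)
  x <- gsub("\\s+", " ", x, perl = TRUE)
  trimws(x)
}

# Regex for one token: a maximal run of letters/digits/apostrophes, with
# hyphens allowed only internally (joining two such runs).
.token_regex <- "[\\p{L}\\p{N}']+(?:-[\\p{L}\\p{N}']+)*"

# Characters that end a sentence for the purposes of pattern matching and
# candidate linking. Informal review text gets no sentence model beyond this.
.sentence_break_regex <- "[.!?\n]"

#' Tokenize text into word spans
#'
#' Tokens are maximal runs of letters, digits and apostrophes; hyphens are
#' kept only when internal (so "well-known" is one token but a leading or
#' trailing hyphen is not part of any token). All other punctuation and
#' whitespace separates tokens, so "M.S." yields the two tokens "M" and "S".
#' Offsets are 0-based, half-open character positions into `text`.
#'
#' @param text a single string.
#' @return a data.frame with one row per token: `start` (0-based,
#'   inclusive), `end` (exclusive), `surface` (the exact substring), and
#'   `sentence` (0-based sentence index; sentences are delimited by
#'   `.`, `!`, `?` or newline).
#' @examples
#' tokenize("dry mouth.")$surface  # c("dry", "mouth")
#' @export
tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  empty <- data.frame(start = integer(0), end = integer(0),
                      surface = character(0), sentence = integer(0),
                      stringsAsFactors = FALSE)
  if (is.na(text) || !nzchar(text)) return(empty)
  m <- gregexpr(.token_regex, text, perl = TRUE)[[1]]
  if (m[1] == -1L) return(empty)
  start <- as.integer(m) - 1L
  len <- attr(m, "match.length")
  end <- start + as.integer(len)
  surface <- substring(text, start + 1L, end)

  # sentence index = number of sentence-break characters before token start
  b <- gregexpr(.sentence_break_regex, text, perl = TRUE)[[1]]
  if (b[1] == -1L) {
    sentence <- integer(length(start))
  } else {
    breaks <- as.integer(b) - 1L  # 0-based positions of break chars
    sentence <- findInterval(start, breaks + 1L)
  }
  data.frame(start = start, end = end, surface = surface,
             sentence = as.integer(sentence), stringsAsFactors = FALSE)
}
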