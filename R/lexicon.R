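#' Construct a disease lexicon from concept/variant records
#'
#' A disease lexicon maps normalized surface forms (spelling variants) to
#' CUI-like concept identifiers, emulating a UMLS-derived dictionary of
#' disease names. One surface form may map to several concepts (ambiguity is
#' preserved); one concept typically owns several variants.
#'
#' @param concept_id character vector, one element per (concept, variant)
#'   record.
#' @param preferred_name character vector parallel to `concept_id`; every
#'   record of a concept must carry the same preferred name.
#' @param variant character vector of surface forms, parallel to
#'   `concept_id`; variants are normalized with [normalize_text()] before
#'   indexing and duplicate (variant, concept) pairs are collapsed.
#' @return an object of class `disease_lexicon`: a list with `entries`
#'   (named list: normalized variant -> character vector of concept ids),
#'   `concepts` (named character vector: concept id -> preferred name),
#'   `n_entries` and `n_concepts`.
#' @export
disease_lexicon <- function(concept_id, preferred_name, variant) {
  concept_id <- as.character(concept_id)
  preferred_name <- as.character(preferred_name)
  variant <- as.character(variant)
  n <- length(concept_id)
  stopifnot(length(preferred_name) == n, length(variant) == n)
  if (n > 0 && (any(!nzchar(concept_id)) || any(!nzchar(preferred_name))))
    stop("concept_id and preferred_name must be non-empty")

  pn <- tapply(preferred_name, concept_id, unique, simplify = FALSE)
  bad <- names(pn)[lengths(pn) > 1L]
  if (length(bad))
    stop("conflicting preferred_name for concept id(s): ",
         paste(bad, collapse = ", "))
  concepts <- vapply(pn, `[`, character(1), 1L)

  v <- normalize_text(variant)
  keep <- nzchar(v)
  v <- v[keep]; cid <- concept_id[keep]
  dup <- duplicated(paste0(v, "\r", cid))
  v <- v[!dup]; cid <- cid[!dup]
  entries <- split(cid, v)
  entries <- lapply(entries, function(x) sort(unique(x)))

  structure(list(entries = entries,
                 concepts = concepts,
                 n_entries = length(entries),
                 n_concepts = length(concepts)),
            class = "disease_lexicon")
}

#' Load a disease lexicon from a 3-column TSV file
#'
#' File dialect: UTF-8 tab-separated values with columns
#' `concept_id`, `preferred_name`, `variant`, no header, `#` comment lines
#' and blank lines ignored.
#'
#' @param path path to the TSV file.
#' @return a [disease_lexicon()] object.
#' @export
load_lexicon <- function(path) {
  if (!file.exists(path)) stop("lexicon file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lineno <- seq_along(lines)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]; lineno <- lineno[keep]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 3L)
  if (length(bad))
    stop("malformed lexicon record (expected 3 tab-separated fields) at line ",
         lineno[bad[1]], " of ", path)
  m <- do.call(rbind, parts)
  disease_lexicon(m[, 1], m[, 2], m[, 3])
}

#' Write a disease lexicon to the 3-column TSV dialect
#'
#' Inverse of [load_lexicon()]: records are written one normalized variant
#' per line, ordered by variant then concept id, so output is deterministic
#' and `load_lexicon(write_lexicon(lex, f))` equals `lex`.
#'
#' @param lexicon a `disease_lexicon`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_lexicon <- function(lexicon, path) {
  stopifnot(inherits(lexicon, "disease_lexicon"))
  v <- rep(names(lexicon$entries), lengths(lexicon$entries))
  cid <- unlist(lexicon$entries, use.names = FALSE)
  ord <- order(v, cid)
  lines <- paste(cid[ord], unname(lexicon$concepts[cid[ord]]), v[ord],
                 sep = "\t")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @export
print.disease_lexicon <- function(x, ...) {
  cat("Disease lexicon: ", x$n_entries, " surface forms for ",
      x$n_concepts, " concepts\n", sep = "")
  invisible(x)
}

# Longest entry length in tokens; used by the matcher to bound its windows.
lexicon_max_tokens <- function(lexicon) {
  if (lexicon$n_entries == 0L) return(0L)
  max(lengths(strsplit(names(lexicon$entries), " ", fixed = TRUE)))
}
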