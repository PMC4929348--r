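.corpus_cols <- c("review_id", "drug_name", "text", "effectiveness",
                  "ease_of_use", "satisfaction", "age_band", "sex",
                  "duration")
.score_cols <- c("effectiveness", "ease_of_use", "satisfaction")
.sex_levels <- c("female", "male", "unspecified")

#' Construct a review corpus
#'
#' A corpus holds patient reviews in a health-forum-style schema: one free-text
#' comment per record, the drug it reviews, three optional 1-5 scores
#' (effectiveness, ease of use, satisfaction) and optional demographics.
#' Comment text is kept verbatim, misspellings included — the downstream
#' matchers are exact, so nothing may be cleaned at load time.
#'
#' @param records a data.frame with columns `review_id`, `drug_name`,
#'   `text` and optionally `effectiveness`, `ease_of_use`, `satisfaction`
#'   (integer 1-5 or NA), `age_band`, `sex` (one of "female", "male",
#'   "unspecified"; NA becomes "unspecified") and `duration`. Missing
#'   optional columns are filled with NA.
#' @return an object of class `review_corpus`: list with `records`
#'   (data.frame, input order preserved), `n_records`, `drugs_covered`.
#' @export
review_corpus <- function(records) {
  stopifnot(is.data.frame(records))
  missing_req <- setdiff(c("review_id", "drug_name", "text"), names(records))
  if (length(missing_req))
    stop("corpus records missing required column(s): ",
         paste(missing_req, collapse = ", "))
  for (col in setdiff(.corpus_cols, names(records)))
    records[[col]] <- if (col %in% .score_cols) NA_integer_ else NA_character_
  records <- records[, .corpus_cols]
  records$review_id <- as.character(records$review_id)
  records$drug_name <- as.character(records$drug_name)
  records$text <- as.character(records$text)
  records$text[is.na(records$text)] <- ""
  for (col in c("age_band", "duration"))
    records[[col]] <- as.character(records[[col]])
  if (anyDuplicated(records$review_id))
    stop("duplicate review_id: ",
         paste(unique(records$review_id[duplicated(records$review_id)]),
               collapse = ", "))
  if (any(is.na(records$drug_name) | !nzchar(records$drug_name)))
    stop("drug_name must be non-empty for every record")
  for (col in .score_cols) {
    raw <- records[[col]]
    if (is.character(raw)) raw[!is.na(raw) & !nzchar(trimws(raw))] <- NA
    s <- suppressWarnings(as.integer(raw))
    bad_parse <- which(!is.na(raw) & is.na(s))
    if (length(bad_parse))
      stop("non-integer score '", col, "' in record(s): ",
           paste(records$review_id[bad_parse], collapse = ", "))
    bad <- which(!is.na(s) & (s < 1L | s > 5L))
    if (length(bad))
      stop("score '", col, "' outside 1-5 in record(s): ",
           paste(records$review_id[bad], collapse = ", "))
    records[[col]] <- s
  }
  sex <- as.character(records$sex)
  sex[is.na(sex) | !nzchar(sex)] <- "unspecified"
  bad_sex <- setdiff(unique(sex), .sex_levels)
  if (length(bad_sex))
    stop("invalid sex value(s): ", paste(bad_sex, collapse = ", "))
  records$sex <- sex
  rownames(records) <- NULL
  structure(list(records = records,
                 n_records = nrow(records),
                 drugs_covered = sort(unique(records$drug_name))),
            class = "review_corpus")
}

#' Load a review corpus from CSV or JSON-lines
#'
#' CSV dialect: RFC-4180 quoting, UTF-8, mandatory header row; missing
#' optional values are empty fields. JSONL dialect: one JSON object per
#' line; missing optional values are absent keys.
#'
#' @param path path to the corpus file.
#' @param format `"csv"` or `"jsonl"`.
#' @return a `review_corpus`; record order follows file order.
#' @export
load_corpus <- function(path, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("corpus file not found: ", path)
  if (format == "csv") {
    df <- utils::read.csv(path, colClasses = "character",
                          fileEncoding = "UTF-8", check.names = TRUE)
    missing_req <- setdiff(c("review_id", "drug_name", "text"), names(df))
    if (length(missing_req))
      stop("corpus CSV ", path, " missing required column(s): ",
           paste(missing_req, collapse = ", "))
    for (col in .score_cols)
      if (col %in% names(df)) df[[col]][!nzchar(df[[col]])] <- NA
    for (col in c("age_band", "sex", "duration"))
      if (col %in% names(df)) df[[col]][!nzchar(df[[col]])] <- NA
  } else {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    rows <- lapply(seq_along(lines), function(i) {
      obj <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
                      error = function(e)
                        stop("malformed JSON at line ", i, " of ", path,
                             ": ", conditionMessage(e), call. = FALSE))
      as.data.frame(c(obj,
                      sapply(setdiff(.corpus_cols, names(obj)),
                             function(x) NA, simplify = FALSE)),
                    stringsAsFactors = FALSE)[, .corpus_cols]
    })
    df <- if (length(rows)) do.call(rbind, rows) else
      as.data.frame(sapply(.corpus_cols, function(x) character(0),
                           simplify = FALSE), stringsAsFactors = FALSE)
  }
  tryCatch(review_corpus(df),
           error = function(e) stop("invalid corpus ", path, ": ",
                                    conditionMessage(e), call. = FALSE))
}

#' Write a review corpus to CSV or JSON-lines
#'
#' Mirrors [load_corpus()] so that a load/write/load round trip reproduces
#' the corpus field for field.
#'
#' @param corpus a `review_corpus`.
#' @param path output file path.
#' @param format `"csv"` or `"jsonl"`.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path, format = c("csv", "jsonl")) {
  stopifnot(inherits(corpus, "review_corpus"))
  format <- match.arg(format)
  df <- corpus$records
  if (format == "csv") {
    out <- df
    for (col in names(out)) {
      out[[col]] <- as.character(out[[col]])
      out[[col]][is.na(out[[col]])] <- ""
    }
    utils::write.csv(out, path, row.names = FALSE, quote = TRUE,
                     fileEncoding = "UTF-8")
  } else {
    lines <- vapply(seq_len(nrow(df)), function(i) {
      rec <- as.list(df[i, ])
      rec <- rec[!vapply(rec, function(v) is.na(v), logical(1))]
      jsonlite::toJSON(rec, auto_unbox = TRUE)
    }, character(1))
    writeLines(lines, path, useBytes = TRUE)
  }
  invisible(path)
}

#' Summarise a corpus: per-drug review counts and mean posts per drug
#'
#' @param corpus a `review_corpus`.
#' @return a list with `per_drug` (data.frame `drug_name`, `n_reviews`,
#'   sorted by count descending then name), `n_total`, and
#'   `mean_per_drug` (arithmetic mean reviews per drug, rounded to 2
#'   decimals; `NA` for an empty corpus).
#' @export
corpus_summary <- function(corpus) {
  stopifnot(inherits(corpus, "review_corpus"))
  if (corpus$n_records == 0L) {
    return(list(per_drug = data.frame(drug_name = character(0),
                                      n_reviews = integer(0),
                                      stringsAsFactors = FALSE),
                n_total = 0L, mean_per_drug = NA_real_))
  }
  tab <- table(corpus$records$drug_name)
  per_drug <- data.frame(drug_name = names(tab),
                         n_reviews = as.integer(tab),
                         stringsAsFactors = FALSE)
  per_drug <- per_drug[order(-per_drug$n_reviews, per_drug$drug_name), ]
  rownames(per_drug) <- NULL
  list(per_drug = per_drug,
       n_total = corpus$n_records,
       mean_per_drug = round(corpus$n_records / nrow(per_drug), 2))
}

#' @export
print.review_corpus <- function(x, ...) {
  cat("Review corpus: ", x$n_records, " reviews of ",
      length(x$drugs_covered), " drugs\n", sep = "")
  invisible(x)
}
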