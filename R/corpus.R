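#' Tokenize text under the corpus analysis conventions
#'
#' The token statistics stage needs a deterministic word-level tokenization.
#' The convention is: lowercase; split on any run of non-alphanumeric
#' characters (so hyphenated drug names split into their components); drop
#' pure-number tokens (report identifiers, doses and times are noise for
#' category discrimination); keep only tokens of length >= 2.
#'
#' @param text Character vector of texts.
#' @return For a single string, a character vector of tokens; for a longer
#'   input, a list of token vectors (one per element).
#' @examples
#' tokenize("Patient fell twice.")
#' tokenize("trimethoprim-sulfamethoxazole")
#' @export
tokenize <- function(text) {
  if (length(text) == 0) return(list())
  pieces <- strsplit(tolower(text), "[^[:alnum:]]+")
  out <- lapply(pieces, function(toks) {
    toks <- toks[nzchar(toks)]
    toks <- toks[!grepl("^[0-9]+$", toks)]
    toks[nchar(toks) >= 2L]
  })
  if (length(text) == 1L) out[[1L]] else out
}

# Word tokens immediately preceding a period that do not end a sentence.
# Fixed and versioned here so segmentation is reproducible.
.default_abbreviations <- c(
  "dr", "mr", "mrs", "ms", "prof", "st", "vs", "etc", "approx",
  "fig", "dept", "no", "jr", "sr"
)

#' Segment a report text into sentences
#'
#' Rule-based, abbreviation-aware segmentation: sentence boundaries are runs
#' of \code{.}, \code{!} or \code{?} followed by whitespace, except when the
#' period terminates a known abbreviation (e.g. "Dr.", "Mrs."). Decimal
#' numbers never split because the period is not followed by whitespace.
#' The segmenter is deterministic; concatenating the returned sentences with
#' single spaces recovers the input up to whitespace normalization.
#'
#' @param text A single report text (nonempty).
#' @param report_id Identifier attached to each returned sentence.
#' @param abbreviations Character vector of lowercase abbreviation stems whose
#'   trailing period is not a boundary.
#' @return A data.frame with columns \code{report_id}, \code{sent_index}
#'   (0-based), \code{text}.
#' @export
segment_sentences <- function(text, report_id = NA_character_,
                              abbreviations = .default_abbreviations) {
  stopifnot(is.character(text), length(text) == 1L)
  txt <- squish(text)
  if (!nzchar(txt)) config_error("segment_sentences: report text is empty")
  # protect abbreviation periods with a sentinel byte, split, then restore
  marker <- "\x01"
  pat <- paste0("\\b(", paste(abbreviations, collapse = "|"), ")\\.")
  protected <- gsub(pat, paste0("\\1", marker), txt, ignore.case = TRUE, perl = TRUE)
  parts <- strsplit(protected, "(?<=[.!?])\\s+", perl = TRUE)[[1L]]
  parts <- gsub(marker, ".", parts, fixed = TRUE)
  parts <- parts[nzchar(squish(parts))]
  if (length(parts) == 0L) parts <- txt
  data.frame(
    report_id = rep(report_id, length(parts)),
    sent_index = seq_along(parts) - 1L,
    text = parts,
    stringsAsFactors = FALSE
  )
}

#' Segment every report of a corpus
#'
#' @param corpus A \code{pse_corpus}.
#' @return A data.frame of sentences with columns \code{report_id},
#'   \code{sent_index}, \code{category}, \code{text}.
#' @export
corpus_sentences <- function(corpus) {
  stopifnot(inherits(corpus, "pse_corpus"))
  reps <- corpus$reports
  out <- vector("list", nrow(reps))
  for (i in seq_len(nrow(reps))) {
    s <- segment_sentences(reps$text[i], report_id = reps$report_id[i])
    s$category <- reps$category[i]
    out[[i]] <- s
  }
  res <- do.call(rbind, out)
  res[, c("report_id", "sent_index", "category", "text")]
}

new_corpus <- function(reports) {
  vocab <- sort(unique(unlist(tokenize(reports$text), use.names = FALSE)))
  structure(
    list(
      reports = reports,
      categories = sort(unique(reports$category)),
      vocabulary = vocab
    ),
    class = "pse_corpus"
  )
}

#' Build a corpus from in-memory records
#'
#' @param report_id,category,text Parallel character vectors.
#' @return A \code{pse_corpus}: list with \code{reports} (data.frame),
#'   \code{categories} (ordered label set) and \code{vocabulary} (all analysis
#'   tokens produced by \code{\link{tokenize}}).
#' @export
corpus <- function(report_id, category, text) {
  reports <- data.frame(
    report_id = as.character(report_id),
    category = as.character(category),
    text = as.character(text),
    stringsAsFactors = FALSE
  )
  validate_reports(reports)
}

validate_reports <- function(reports, quiet = FALSE) {
  blank <- !nzchar(squish(reports$text)) | is.na(reports$text)
  if (any(blank)) {
    if (!quiet) {
      message(sprintf("Dropping %d report(s) with empty text", sum(blank)))
    }
    reports <- reports[!blank, , drop = FALSE]
  }
  if (nrow(reports) == 0L) input_error("corpus contains zero valid reports")
  dup <- unique(reports$report_id[duplicated(reports$report_id)])
  if (length(dup) > 0L) {
    input_error(sprintf(
      "duplicate report_id(s): %s", paste(utils::head(dup, 5L), collapse = ", ")
    ))
  }
  rownames(reports) <- NULL
  new_corpus(reports)
}

#' @export
print.pse_corpus <- function(x, ...) {
  cat(sprintf(
    "<pse_corpus> %d reports, %d categories (%s), vocabulary %d tokens\n",
    nrow(x$reports), length(x$categories),
    paste(x$categories, collapse = ", "), length(x$vocabulary)
  ))
  invisible(x)
}

#' Load a labelled report corpus from CSV or JSON-lines
#'
#' @param path File path.
#' @param format "csv" (RFC 4180, UTF-8) or "jsonl" (one JSON object per
#'   line). Defaults from the file extension.
#' @param column_map Named list mapping the canonical field names
#'   \code{report_id}, \code{category}, \code{text} to the columns present in
#'   the file.
#' @return A validated \code{pse_corpus}. Records with empty or
#'   whitespace-only text are dropped with a message; duplicate report ids are
#'   an error.
#' @export
load_corpus <- function(path,
                        format = c("auto", "csv", "jsonl"),
                        column_map = list(report_id = "report_id",
                                          category = "category",
                                          text = "text")) {
  format <- match.arg(format)
  if (!file.exists(path)) input_error(sprintf("corpus file not found: %s", path))
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("jsonl", "ndjson", "json")) "jsonl" else "csv"
  }
  raw <- if (format == "csv") {
    utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8",
                    colClasses = "character")
  } else {
    jsonlite::stream_in(file(path), verbose = FALSE)
  }
  needed <- c("report_id", "category", "text")
  cols <- vapply(needed, function(f) column_map[[f]] %||% f, character(1))
  missing <- cols[!cols %in% names(raw)]
  if (length(missing) > 0L) {
    config_error(sprintf(
      "mapped column(s) absent from %s: %s", path, paste(missing, collapse = ", ")
    ))
  }
  reports <- data.frame(
    report_id = as.character(raw[[cols[["report_id"]]]]),
    category = as.character(raw[[cols[["category"]]]]),
    text = as.character(raw[[cols[["text"]]]]),
    stringsAsFactors = FALSE
  )
  validate_reports(reports)
}

#' Write a corpus as canonical JSON-lines
#'
#' One object per report with fields \code{report_id}, \code{category},
#' \code{text}. \code{\link{load_corpus}} on the result reproduces an equal
#' corpus.
#'
#' @param corpus A \code{pse_corpus}.
#' @param path Output path.
#' @export
write_corpus_jsonl <- function(corpus, path) {
  stopifnot(inherits(corpus, "pse_corpus"))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  jsonlite::stream_out(corpus$reports, con, verbose = FALSE)
  invisible(path)
}

#' Write a corpus as CSV
#' @param corpus A \code{pse_corpus}.
#' @param path Output path.
#' @export
write_corpus_csv <- function(corpus, path) {
  stopifnot(inherits(corpus, "pse_corpus"))
  utils::write.csv(corpus$reports, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write segmented sentences as JSON-lines (one object per sentence)
#' @param sentences Data.frame from \code{\link{corpus_sentences}}.
#' @param path Output path.
#' @export
write_sentences_jsonl <- function(sentences, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  jsonlite::stream_out(sentences, con, verbose = FALSE)
  invisible(path)
}
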