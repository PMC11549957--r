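#' Perplexity of one sentence under a backend
#'
#' Perplexity is the exponential of the mean negative log-probability the
#' model assigns to the sentence's tokens: exp(-(1/n) * sum_i log p(w_i |
#' w_<i)). The backend's own tokenizer is used; sequences longer than the
#' backend's \code{max_sequence_length} are truncated to their prefix; a
#' start-of-sequence context is supplied by every backend so the first real
#' token receives a positive conditional probability.
#'
#' @param backend An \code{lm_backend}.
#' @param sentence_text A single nonempty string.
#' @param report_id,sent_index,category Optional identifiers carried into
#'   the result row.
#' @return One-row data.frame: report_id, sent_index, category, model_id,
#'   perplexity, n_scored_tokens.
#' @export
compute_perplexity <- function(backend, sentence_text,
                               report_id = NA_character_,
                               sent_index = NA_integer_,
                               category = NA_character_) {
  stopifnot(inherits(backend, "lm_backend"))
  if (!is.null(backend$score_text)) {
    sc <- backend$score_text(sentence_text, backend$max_sequence_length)
    lp <- sc$logprobs
    if (length(lp) == 0L) {
      scoring_error(sprintf("empty tokenization for sentence: %.60s", sentence_text))
    }
  } else {
    toks <- backend_tokenize(backend, sentence_text)
    if (length(toks) == 0L) {
      scoring_error(sprintf("empty tokenization for sentence: %.60s", sentence_text))
    }
    if (length(toks) > backend$max_sequence_length) {
      toks <- toks[seq_len(backend$max_sequence_length)]
    }
    lp <- token_logprobs(backend, toks)
  }
  data.frame(
    report_id = report_id, sent_index = sent_index, category = category,
    model_id = backend$model_id,
    perplexity = exp(-mean(lp)),
    n_scored_tokens = length(lp),
    stringsAsFactors = FALSE
  )
}

#' Score a set of sentences under a backend, in batches
#'
#' Batching is throughput bookkeeping only: results are identical to
#' sentence-by-sentence scoring, in input order. Per-sentence failures are
#' collected (with a warning), not fatal.
#'
#' @param backend An \code{lm_backend}.
#' @param sentences Data.frame with columns \code{report_id},
#'   \code{sent_index}, \code{text} and optionally \code{category}.
#' @param batch_size Positive integer (default 16).
#' @param progress Emit a message per batch.
#' @return Data.frame of per-sentence results (failed sentences omitted),
#'   with attribute \code{"failures"} listing any failed sentence refs.
#' @export
batch_score <- function(backend, sentences, batch_size = 16L, progress = FALSE) {
  stopifnot(inherits(backend, "lm_backend"), batch_size >= 1L)
  n <- nrow(sentences)
  empty <- data.frame(
    report_id = character(), sent_index = integer(), category = character(),
    model_id = character(), perplexity = numeric(), n_scored_tokens = integer(),
    stringsAsFactors = FALSE
  )
  if (is.null(n) || n == 0L) return(empty)
  category <- if ("category" %in% names(sentences)) sentences$category else NA_character_
  if (length(category) == 1L) category <- rep(category, n)
  out <- vector("list", n)
  failures <- list()
  starts <- seq(1L, n, by = batch_size)
  for (b in seq_along(starts)) {
    idx <- starts[b]:min(starts[b] + batch_size - 1L, n)
    if (isTRUE(progress)) {
      message(sprintf("[%s] batch %d/%d (%d sentences)",
                      backend$model_id, b, length(starts), length(idx)))
    }
    for (i in idx) {
      out[[i]] <- tryCatch(
        compute_perplexity(backend, sentences$text[i],
                           report_id = sentences$report_id[i],
                           sent_index = sentences$sent_index[i],
                           category = category[i]),
        error = function(e) {
          failures[[length(failures) + 1L]] <<- list(
            report_id = sentences$report_id[i],
            sent_index = sentences$sent_index[i],
            message = conditionMessage(e)
          )
          NULL
        }
      )
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- empty
  if (length(failures) > 0L) {
    warning(sprintf("%d sentence(s) failed to score under %s",
                    length(failures), backend$model_id), call. = FALSE)
  }
  attr(res, "failures") <- failures
  res
}

#' Score sentences under several backends
#'
#' @param backends List of \code{lm_backend}s (names override model_id for
#'   labelling).
#' @param sentences Sentence data.frame as for \code{\link{batch_score}}.
#' @param batch_size Passed through.
#' @param progress Passed through.
#' @return Row-bound perplexity table over all backends.
#' @export
score_models <- function(backends, sentences, batch_size = 16L, progress = FALSE) {
  if (inherits(backends, "lm_backend")) backends <- list(backends)
  rows <- lapply(backends, batch_score, sentences = sentences,
                 batch_size = batch_size, progress = progress)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a perplexity table as CSV
#' @param results Data.frame from \code{\link{batch_score}}/\code{\link{score_models}}.
#' @param path Output path.
#' @export
write_perplexity_csv <- function(results, path) {
  utils::write.csv(
    results[, c("report_id", "sent_index", "category", "model_id",
                "perplexity", "n_scored_tokens")],
    path, row.names = FALSE
  )
  invisible(path)
}
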