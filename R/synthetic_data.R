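#' Configuration for the synthetic report-corpus generator
#'
#' The generator emulates the structure the pipeline needs from a labelled
#' incident-report corpus: several event categories sharing one background
#' vocabulary, each category with a disjoint set of planted signal tokens
#' whose sampling probability is boosted in their home category, and
#' multi-sentence free-text reports. Defaults: 4 categories of 200 reports,
#' a 300-token shared vocabulary, 10 signal tokens per category with their
#' probability boosted 20-fold at home, report length ~ Poisson(4) sentences
#' (min 1) of ~ Poisson(8) tokens (min 3).
#'
#' @param n_categories Number of categories (>= 2).
#' @param reports_per_category Reports per category.
#' @param sentences_per_report Poisson mean number of sentences (min 1).
#' @param tokens_per_sentence Poisson mean tokens per sentence (min 3).
#' @param shared_vocab_size Size of the shared vocabulary; must be at least
#'   \code{n_categories * signal_tokens_per_category}.
#' @param signal_tokens_per_category Planted signal tokens per category.
#' @param signal_boost Multiplier (>= 1) on a signal token's probability in
#'   its home category; 1 plants no signal.
#' @param seed RNG seed; the corpus is a deterministic function of the
#'   config.
#' @return A \code{generator_config} list.
#' @export
generator_config <- function(n_categories = 4L,
                             reports_per_category = 200L,
                             sentences_per_report = 4,
                             tokens_per_sentence = 8,
                             shared_vocab_size = 300L,
                             signal_tokens_per_category = 10L,
                             signal_boost = 20,
                             seed = 20260920L) {
  cfg <- list(
    n_categories = as.integer(n_categories),
    reports_per_category = as.integer(reports_per_category),
    sentences_per_report = sentences_per_report,
    tokens_per_sentence = tokens_per_sentence,
    shared_vocab_size = as.integer(shared_vocab_size),
    signal_tokens_per_category = as.integer(signal_tokens_per_category),
    signal_boost = signal_boost,
    seed = as.integer(seed)
  )
  if (cfg$n_categories < 2L) config_error("n_categories must be >= 2")
  if (cfg$signal_boost < 1) config_error("signal_boost must be >= 1")
  if (cfg$shared_vocab_size < cfg$n_categories * cfg$signal_tokens_per_category) {
    config_error("shared_vocab_size smaller than the total number of signal tokens")
  }
  structure(cfg, class = "generator_config")
}

# zero-truncated-ish Poisson: Poisson draw clamped below at `min`
.rpois_min <- function(n, lambda, min) pmax(stats::rpois(n, lambda), min)

#' Generate a seeded synthetic corpus with planted category structure
#'
#' Each category samples tokens from the shared unigram distribution
#' (uniform over the vocabulary) with its own signal tokens' weights
#' multiplied by \code{signal_boost} and the result renormalized. Reports
#' are sentences of sampled tokens joined by periods, so the corpus
#' round-trips exactly through the corpus reader, tokenizer and segmenter.
#'
#' @param config A \code{generator_config}.
#' @return List with \code{corpus} (a \code{pse_corpus}) and
#'   \code{ground_truth} (list: \code{planted} — category to signal tokens —
#'   and \code{config} echo).
#' @export
generate_corpus <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  vocab <- sprintf("tok%04d", seq_len(config$shared_vocab_size))
  cats <- sprintf("cat%d", seq_len(config$n_categories))
  sig_idx <- split(
    seq_len(config$n_categories * config$signal_tokens_per_category),
    rep(seq_len(config$n_categories), each = config$signal_tokens_per_category)
  )
  planted <- lapply(sig_idx, function(i) vocab[i])
  names(planted) <- cats

  weights <- lapply(cats, function(cat_) {
    w <- rep(1, config$shared_vocab_size)
    w[sig_idx[[match(cat_, cats)]]] <- config$signal_boost
    w / sum(w)
  })
  names(weights) <- cats

  rows <- vector("list", config$n_categories * config$reports_per_category)
  k <- 0L
  for (cat_ in cats) {
    n_sents <- .rpois_min(config$reports_per_category,
                          config$sentences_per_report, 1L)
    for (r in seq_len(config$reports_per_category)) {
      lens <- .rpois_min(n_sents[r], config$tokens_per_sentence, 3L)
      sents <- vapply(lens, function(l) {
        paste(sample(vocab, l, replace = TRUE, prob = weights[[cat_]]),
              collapse = " ")
      }, character(1))
      k <- k + 1L
      rows[[k]] <- data.frame(
        report_id = sprintf("%s_r%04d", cat_, r),
        category = cat_,
        text = paste0(paste(sents, collapse = ". "), "."),
        stringsAsFactors = FALSE
      )
    }
  }
  reports <- do.call(rbind, rows)
  list(
    corpus = validate_reports(reports, quiet = TRUE),
    ground_truth = list(planted = planted, config = unclass(config))
  )
}

#' Write generator ground truth as a JSON sidecar
#' @param ground_truth The \code{ground_truth} element of
#'   \code{\link{generate_corpus}}'s result.
#' @param path Output path.
#' @export
write_ground_truth <- function(ground_truth, path) {
  jsonlite::write_json(ground_truth, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Precision/recall of selected tokens against planted ground truth
#'
#' @param sets A \code{target_token_sets}.
#' @param ground_truth Ground truth from \code{\link{generate_corpus}}.
#' @return List with \code{precision}, \code{recall}, \code{n_selected},
#'   \code{n_planted}. A token counts as recovered only if selected for its
#'   home category.
#' @export
recovery_metrics <- function(sets, ground_truth) {
  stopifnot(inherits(sets, "target_token_sets"))
  planted <- ground_truth$planted
  cats <- intersect(names(sets$by_category), names(planted))
  tp <- sum(vapply(cats, function(cat_) {
    length(intersect(sets$by_category[[cat_]], planted[[cat_]]))
  }, numeric(1)))
  n_sel <- sum(lengths(sets$by_category))
  n_planted <- sum(lengths(planted))
  list(
    precision = if (n_sel > 0) tp / n_sel else NA_real_,
    recall = if (n_planted > 0) tp / n_planted else NA_real_,
    n_selected = n_sel,
    n_planted = n_planted
  )
}

#' Fit one n-gram backend per category
#'
#' Trains an additive-smoothed n-gram model on each category's reports only,
#' giving a family of category-matched reference models. Used to exercise
#' the matched-vs-mismatched perplexity contrast (a stand-in for comparing
#' domain-adapted against general-purpose language models).
#'
#' @param corpus A \code{pse_corpus} with >= 2 categories.
#' @param order N-gram order (default 2).
#' @param smoothing Additive constant (default 0.1).
#' @param exclude_reports Optional report_ids to hold out from training.
#' @return Named list of \code{lm_backend}s, one per category.
#' @export
make_matched_backends <- function(corpus, order = 2L, smoothing = 0.1,
                                  exclude_reports = character(0)) {
  stopifnot(inherits(corpus, "pse_corpus"))
  if (length(corpus$categories) < 2L) {
    config_error("make_matched_backends needs >= 2 categories")
  }
  reps <- corpus$reports
  reps <- reps[!reps$report_id %in% exclude_reports, , drop = FALSE]
  backends <- lapply(corpus$categories, function(cat_) {
    texts <- reps$text[reps$category == cat_]
    if (length(texts) == 0L) {
      warning(sprintf("category %s has no training reports after exclusions", cat_),
              call. = FALSE)
      return(NULL)
    }
    fit_ngram_backend(texts, order = order, smoothing = smoothing,
                      model_id = paste0("ngram", order, "_", cat_))
  })
  names(backends) <- corpus$categories
  backends[!vapply(backends, is.null, logical(1))]
}
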