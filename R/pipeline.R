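# Stage functions couple through flat CSV/JSONL artifacts so curated token
# lists (the expert-review step) can be injected between stages, and every
# stage is runnable standalone on hand-authored files.

artifact_paths <- function(out_dir) {
  list(
    corpus = file.path(out_dir, "corpus.csv"),
    ground_truth = file.path(out_dir, "ground_truth.json"),
    tokens = file.path(out_dir, "target_tokens.csv"),
    sentences = file.path(out_dir, "target_sentences.csv"),
    uncovered = file.path(out_dir, "target_sentences_uncovered.csv"),
    perplexity = file.path(out_dir, "perplexity.csv"),
    summary = file.path(out_dir, "model_summary.csv"),
    ranking = file.path(out_dir, "sentence_ranking.csv"),
    config = file.path(out_dir, "run_config.json")
  )
}

require_artifact <- function(path, producer) {
  if (!file.exists(path)) {
    input_error(sprintf("missing upstream artifact %s; run the '%s' stage first",
                        path, producer))
  }
  path
}

#' Pipeline stage: simulate a synthetic corpus
#'
#' @param out_dir Output directory (created if absent).
#' @param config A \code{\link{generator_config}}.
#' @return Invisibly, the artifact paths written (corpus.csv,
#'   ground_truth.json).
#' @export
stage_simulate <- function(out_dir, config = generator_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- artifact_paths(out_dir)
  sim <- generate_corpus(config)
  write_corpus_csv(sim$corpus, paths$corpus)
  write_ground_truth(sim$ground_truth, paths$ground_truth)
  invisible(paths[c("corpus", "ground_truth")])
}

#' Pipeline stage: select target tokens
#'
#' @param corpus_path Corpus CSV/JSONL artifact.
#' @param out_dir Output directory.
#' @param estimator,min_count Passed to \code{\link{token_stats}} /
#'   \code{\link{select_target_tokens}}.
#' @param denylist_dir,allowlist_dir Optional directories of per-category
#'   plain-text token lists (see \code{\link{read_token_lists}}).
#' @return Invisibly, the target-token CSV path.
#' @export
stage_tokens <- function(corpus_path, out_dir, estimator = "token",
                         min_count = 3L, denylist_dir = NULL,
                         allowlist_dir = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- artifact_paths(out_dir)
  corp <- load_corpus(require_artifact(corpus_path, "simulate"))
  sets <- select_target_tokens(token_stats(corp, estimator = estimator),
                               min_count = min_count)
  deny <- if (!is.null(denylist_dir)) read_token_lists(denylist_dir)
  allow <- if (!is.null(allowlist_dir)) read_token_lists(allowlist_dir)
  if (!is.null(deny) || !is.null(allow)) {
    sets <- apply_expert_filter(sets, denylist = deny, allowlist = allow)
  }
  write_token_sets(sets, paths$tokens)
  invisible(paths["tokens"])
}

#' Pipeline stage: select target sentences (per-category cover)
#'
#' @param corpus_path Corpus artifact.
#' @param tokens_path Target-token CSV from \code{\link{stage_tokens}}.
#' @param out_dir Output directory.
#' @param max_expansions Search cap per category.
#' @return Invisibly, the sentence CSV and uncovered sidecar paths.
#' @export
stage_sentences <- function(corpus_path, tokens_path, out_dir,
                            max_expansions = 10000L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- artifact_paths(out_dir)
  corp <- load_corpus(require_artifact(corpus_path, "simulate"))
  sets <- read_token_sets(require_artifact(tokens_path, "tokens"))
  sents <- corpus_sentences(corp)
  sols <- list()
  for (cat_ in names(sets$by_category)) {
    W <- sets$by_category[[cat_]]
    if (length(W) == 0L) next
    inst <- build_cover_instance(corp, W, cat_, sentences = sents)
    sols[[cat_]] <- solve_cover(inst, max_expansions = max_expansions)
  }
  write_cover_solution(sols, paths$sentences, paths$uncovered)
  invisible(paths[c("sentences", "uncovered")])
}

# build backends from a registry spec: model_id -> list(type = "ngram",
# order, smoothing, max_sequence_length) or list(type = "transformer",
# checkpoint_ref, max_sequence_length). n-gram backends train on the corpus.
build_backends <- function(registry, corpus) {
  out <- lapply(names(registry), function(id) {
    spec <- registry[[id]]
    type <- spec$type %||% "ngram"
    if (type == "ngram") {
      fit_ngram_backend(
        corpus$reports$text,
        order = spec$order %||% 2L,
        smoothing = spec$smoothing %||% 0.1,
        model_id = id,
        max_sequence_length = spec$max_sequence_length %||% 1024L
      )
    } else if (type == "transformer") {
      transformer_backend(spec$checkpoint_ref,
                          max_sequence_length = spec$max_sequence_length %||% 1024L)
    } else {
      config_error(sprintf("unknown backend type '%s' for model '%s'", type, id))
    }
  })
  names(out) <- names(registry)
  out
}

#' Pipeline stage: score target sentences under each model
#'
#' @param corpus_path Corpus artifact (n-gram backends train on it).
#' @param sentences_path Target-sentence CSV from
#'   \code{\link{stage_sentences}}.
#' @param out_dir Output directory.
#' @param backends Either a list of ready \code{lm_backend}s or a registry
#'   spec (named list; see Details in \code{\link{run_pipeline}}).
#' @param batch_size Scoring batch size (default 16).
#' @return Invisibly, the perplexity CSV path.
#' @export
stage_score <- function(corpus_path, sentences_path, out_dir,
                        backends = default_registry(), batch_size = 16L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- artifact_paths(out_dir)
  sel <- utils::read.csv(require_artifact(sentences_path, "sentences"),
                         stringsAsFactors = FALSE,
                         colClasses = c(category = "character",
                                        report_id = "character"))
  if (nrow(sel) == 0L) input_error("no target sentences to score")
  sentences <- data.frame(
    report_id = sel$report_id, sent_index = sel$sent_index,
    category = sel$category, text = sel$sentence_text,
    stringsAsFactors = FALSE
  )
  if (!all(vapply(backends, inherits, logical(1), "lm_backend"))) {
    corp <- load_corpus(require_artifact(corpus_path, "simulate"))
    backends <- build_backends(backends, corp)
  }
  res <- score_models(backends, sentences, batch_size = batch_size)
  write_perplexity_csv(res, paths$perplexity)
  invisible(paths["perplexity"])
}

#' Pipeline stage: per-category model comparison and sentence ranking
#'
#' @param perplexity_path Perplexity CSV from \code{\link{stage_score}}.
#' @param sentences_path Target-sentence CSV (supplies token provenance for
#'   the ranking).
#' @param out_dir Output directory.
#' @param scale ANOVA scale, "raw" or "log".
#' @param top_k Ranking depth per category.
#' @return Invisibly, the summary and ranking CSV paths.
#' @export
stage_compare <- function(perplexity_path, sentences_path, out_dir,
                          scale = "raw", top_k = 5L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- artifact_paths(out_dir)
  res <- utils::read.csv(require_artifact(perplexity_path, "score"),
                         stringsAsFactors = FALSE,
                         colClasses = c(report_id = "character",
                                        category = "character",
                                        model_id = "character"))
  summary <- summarize_perplexity(res, scale = scale)
  write_summary_csv(summary, paths$summary)
  sel <- utils::read.csv(require_artifact(sentences_path, "sentences"),
                         stringsAsFactors = FALSE,
                         colClasses = c(category = "character",
                                        report_id = "character"))
  # reconstruct minimal cover solutions per category for the token join
  sols <- lapply(split(sel, sel$category), function(d) {
    structure(list(
      S = data.frame(report_id = d$report_id, sent_index = d$sent_index,
                     text = d$sentence_text, tokens_covered = d$tokens_covered,
                     stringsAsFactors = FALSE),
      R = unique(d$report_id),
      covered = character(0),
      uncovered = data.frame(token = character(), reason = character()),
      backtrack_count = 0L, node_expansions = 0L, cap_hit = FALSE,
      category = d$category[1]
    ), class = "cover_solution")
  })
  ranking <- rank_lowest(res, sols, top_k = top_k)
  write_ranking_csv(ranking, paths$ranking)
  invisible(paths[c("summary", "ranking")])
}

#' Default backend registry: two reference n-gram models
#' @return Named list of backend specs (a unigram and a bigram model).
#' @export
default_registry <- function() {
  list(
    unigram = list(type = "ngram", order = 1L, smoothing = 0.1),
    bigram = list(type = "ngram", order = 2L, smoothing = 0.1)
  )
}

#' Run the full pipeline
#'
#' Chains simulate (optional) -> tokens -> sentences -> score -> compare.
#' With \code{corpus_path = NULL} a synthetic corpus is generated from
#' \code{config}; otherwise the user corpus is used and the simulate stage
#' skipped. A JSON snapshot of the run configuration is written beside the
#' artifacts; config plus seed fully determine every artifact's contents.
#'
#' @param out_dir Output directory.
#' @param corpus_path Optional existing corpus CSV/JSONL.
#' @param config Generator config (used when \code{corpus_path} is NULL).
#' @param seed Seed overriding \code{config$seed}.
#' @param estimator,min_count,denylist_dir,allowlist_dir,max_expansions,backends,batch_size,scale,top_k
#'   Stage parameters, passed through.
#' @return Invisibly, the named list of artifact paths.
#' @export
run_pipeline <- function(out_dir, corpus_path = NULL,
                         config = generator_config(), seed = NULL,
                         estimator = "token", min_count = 3L,
                         denylist_dir = NULL, allowlist_dir = NULL,
                         max_expansions = 10000L,
                         backends = default_registry(), batch_size = 16L,
                         scale = "raw", top_k = 5L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- artifact_paths(out_dir)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  snapshot <- list(
    corpus_path = corpus_path, generator = unclass(config),
    estimator = estimator, min_count = min_count,
    max_expansions = max_expansions,
    backends = lapply(backends, function(b) {
      if (inherits(b, "lm_backend")) list(type = class(b)[1], model_id = b$model_id)
      else b
    }),
    batch_size = batch_size, scale = scale, top_k = top_k
  )
  jsonlite::write_json(snapshot, paths$config, auto_unbox = TRUE, pretty = TRUE)
  if (is.null(corpus_path)) {
    stage_simulate(out_dir, config)
    corpus_path <- paths$corpus
  }
  stage_tokens(corpus_path, out_dir, estimator = estimator,
               min_count = min_count, denylist_dir = denylist_dir,
               allowlist_dir = allowlist_dir)
  stage_sentences(corpus_path, paths$tokens, out_dir,
                  max_expansions = max_expansions)
  stage_score(corpus_path, paths$sentences, out_dir,
              backends = backends, batch_size = batch_size)
  stage_compare(paths$perplexity, paths$sentences, out_dir,
                scale = scale, top_k = top_k)
  invisible(paths)
}
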