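# One-way fixed-effects ANOVA with a guard for degenerate inputs: when the
# total sum of squares is (numerically) zero every group mean is identical
# and the test carries no evidence against the null, so F = 0, p = 1.
anova_oneway <- function(values, groups) {
  groups <- factor(groups)
  sst <- sum((values - mean(values))^2)
  if (sst < 1e-12 * max(1, mean(values)^2)) {
    return(list(F = 0, p = 1,
                df1 = nlevels(groups) - 1L,
                df2 = length(values) - nlevels(groups)))
  }
  fit <- stats::aov(values ~ groups)
  tab <- summary(fit)[[1]]
  F <- tab[["F value"]][1]
  p <- tab[["Pr(>F)"]][1]
  if (!is.finite(F)) { F <- 0; p <- 1 }
  list(F = F, p = p, df1 = tab[["Df"]][1], df2 = tab[["Df"]][2])
}

#' Per-category model comparison: means, SEM and one-way ANOVA
#'
#' For each event category, computes each model's mean perplexity and
#' standard error of the mean (sample sd / sqrt(n)) over the category's
#' target sentences, then tests whether mean perplexity differs between
#' models with a one-way fixed-effects ANOVA (model as the factor,
#' sentence-level perplexity as the response). Sentences not scored by every
#' model are excluded first (with a message). Perplexities are analysed on
#' the raw scale by default; \code{scale = "log"} analyses log perplexity
#' for skew-robust inference while still reporting raw-scale means.
#'
#' @param results Perplexity table (rows from \code{\link{score_models}}).
#' @param scale "raw" (default) or "log" — scale on which the ANOVA is run.
#' @return A data.frame with one row per (category, model): columns
#'   \code{category}, \code{model_id}, \code{n}, \code{mean_perplexity},
#'   \code{sem}, \code{anova_F}, \code{anova_p} (repeated within category)
#'   and \code{best_model} (lowest mean) flag column \code{is_best}.
#' @export
summarize_perplexity <- function(results, scale = c("raw", "log")) {
  scale <- match.arg(scale)
  req <- c("report_id", "sent_index", "category", "model_id", "perplexity")
  stopifnot(all(req %in% names(results)))
  models <- sort(unique(results$model_id))
  results$sent_key <- paste(results$report_id, results$sent_index, sep = "\x1f")
  # keep only sentences scored by the full model set
  per_sent <- tapply(results$model_id, results$sent_key,
                     function(m) length(unique(m)))
  complete <- names(per_sent)[per_sent == length(models)]
  dropped <- length(per_sent) - length(complete)
  if (dropped > 0L) {
    message(sprintf("summarize_perplexity: excluding %d sentence(s) not scored by every model",
                    dropped))
    results <- results[results$sent_key %in% complete, , drop = FALSE]
  }
  out <- list()
  for (cat_ in sort(unique(results$category))) {
    sub <- results[results$category == cat_, , drop = FALSE]
    agg <- do.call(rbind, lapply(models, function(m) {
      x <- sub$perplexity[sub$model_id == m]
      data.frame(category = cat_, model_id = m, n = length(x),
                 mean_perplexity = mean(x),
                 sem = stats::sd(x) / sqrt(length(x)),
                 stringsAsFactors = FALSE)
    }))
    n_sent <- length(unique(sub$sent_key))
    if (length(models) >= 2L && n_sent >= 2L) {
      y <- if (scale == "log") log(sub$perplexity) else sub$perplexity
      av <- anova_oneway(y, sub$model_id)
      agg$anova_F <- av$F
      agg$anova_p <- av$p
    } else {
      warning(sprintf("category %s: ANOVA skipped (needs >= 2 models and >= 2 sentences)",
                      cat_), call. = FALSE)
      agg$anova_F <- NA_real_
      agg$anova_p <- NA_real_
    }
    agg$is_best <- agg$mean_perplexity == min(agg$mean_perplexity)
    out[[cat_]] <- agg
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Rank target sentences by average perplexity across models
#'
#' Averages each sentence's perplexity over the full model set, joins the
#' target token(s) the sentence covered in its category's cover solution,
#' and returns the top_k lowest-perplexity sentences per category,
#' ascending. Ties break by (report_id, sent_index).
#'
#' @param results Perplexity table.
#' @param cover A \code{cover_solution}, or list of them (one per category).
#' @param top_k Rows to keep per category (clamped to availability).
#' @return Data.frame: category, target_tokens, report_id, sent_index,
#'   avg_perplexity, sentence_text — sorted ascending within category.
#' @export
rank_lowest <- function(results, cover, top_k = 5L) {
  stopifnot(nrow(results) > 0L, top_k >= 1L)
  if (inherits(cover, "cover_solution")) cover <- list(cover)
  cov_rows <- do.call(rbind, lapply(cover, function(sol) {
    if (nrow(sol$S) == 0L) return(NULL)
    data.frame(category = sol$category, report_id = sol$S$report_id,
               sent_index = sol$S$sent_index,
               target_tokens = sol$S$tokens_covered,
               sentence_text = sol$S$text, stringsAsFactors = FALSE)
  }))
  key <- function(d) paste(d$category, d$report_id, d$sent_index, sep = "\x1f")
  avg <- stats::aggregate(perplexity ~ category + report_id + sent_index,
                          data = results, FUN = mean)
  names(avg)[names(avg) == "perplexity"] <- "avg_perplexity"
  merged <- merge(cov_rows, avg, by = c("category", "report_id", "sent_index"))
  merged <- merged[order(merged$category, merged$avg_perplexity,
                         merged$report_id, merged$sent_index), , drop = FALSE]
  out <- do.call(rbind, lapply(split(merged, merged$category), utils::head, n = top_k))
  rownames(out) <- NULL
  out[, c("category", "target_tokens", "report_id", "sent_index",
          "avg_perplexity", "sentence_text")]
}

#' Calibration of the ANOVA wiring by simulation
#'
#' Validates the model-comparison machinery: draws \code{n_reps} synthetic
#' perplexity tables of \code{n_sentences} sentences by \code{n_models}
#' models from a shared Gaussian (null), optionally shifting one model's
#' mean by \code{effect_size} standard deviations (Cohen's d), runs the
#' per-category ANOVA on each, and summarizes the p-value distribution.
#'
#' @param n_sentences Sentences per model group.
#' @param n_models Number of models.
#' @param n_reps Number of replicates (>= 200 for a stable calibration).
#' @param seed RNG seed.
#' @param effect_size Mean shift, in sd units, applied to the last model
#'   (0 = null).
#' @param mean,sd Gaussian parameters of the simulated perplexities.
#' @return List: \code{p_values}, \code{frac_below_05}, \code{ks_distance}
#'   (empirical p distribution vs uniform), \code{n_reps}.
#' @export
null_calibration <- function(n_sentences, n_models, n_reps, seed,
                             effect_size = 0, mean = 100, sd = 15) {
  stopifnot(n_reps >= 1L)
  set.seed(seed)
  p_values <- vapply(seq_len(n_reps), function(r) {
    vals <- stats::rnorm(n_sentences * n_models, mean = mean, sd = sd)
    grp <- rep(seq_len(n_models), each = n_sentences)
    if (effect_size != 0) {
      vals[grp == n_models] <- vals[grp == n_models] + effect_size * sd
    }
    anova_oneway(vals, grp)$p
  }, numeric(1))
  sp <- sort(p_values)
  i <- seq_along(sp)
  ks <- max(pmax(i / length(sp) - sp, sp - (i - 1) / length(sp)))
  list(
    p_values = p_values,
    frac_below_05 = mean(p_values < 0.05),
    ks_distance = ks,
    n_reps = n_reps
  )
}

#' Write the per-category model summary as CSV
#'
#' Layout mirrors a models-by-categories comparison table: one row per
#' (category, model) with mean, SEM, n, the category's omnibus ANOVA F and
#' p, and an is_best flag marking the lowest-mean model per category.
#'
#' @param summary Data.frame from \code{\link{summarize_perplexity}}.
#' @param path Output path.
#' @export
write_summary_csv <- function(summary, path) {
  utils::write.csv(summary, path, row.names = FALSE)
  invisible(path)
}

#' Write the sentence ranking as CSV
#' @param ranking Data.frame from \code{\link{rank_lowest}}.
#' @param path Output path.
#' @export
write_ranking_csv <- function(ranking, path) {
  utils::write.csv(ranking, path, row.names = FALSE)
  invisible(path)
}
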