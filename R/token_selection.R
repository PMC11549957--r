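#' Per-category conditional token probabilities
#'
#' Estimates p(t | n) for every analysis token t and event category n. The
#' default estimator is token relative frequency: occurrences of t among all
#' tokens of category n, divided by the category's total token count, so the
#' probabilities of each category sum to one. The alternative
#' \code{estimator = "report"} uses report-level document frequency (share of
#' the category's reports containing t at least once); its columns do not sum
#' to one and it is provided for sensitivity analysis.
#'
#' @param corpus A \code{pse_corpus} with at least two categories.
#' @param estimator "token" (default) or "report".
#' @return A \code{token_stats} object: list with \code{counts} and
#'   \code{probs} (token x category matrices), \code{category_totals}, and
#'   \code{estimator}.
#' @export
token_stats <- function(corpus, estimator = c("token", "report")) {
  stopifnot(inherits(corpus, "pse_corpus"))
  estimator <- match.arg(estimator)
  if (length(corpus$categories) < 2L) {
    config_error("token_stats needs >= 2 categories (the dominance rule compares categories)")
  }
  toks <- tokenize(corpus$reports$text)
  if (nrow(corpus$reports) == 1L) toks <- list(toks)
  lens <- lengths(toks)
  tok_vec <- unlist(toks, use.names = FALSE)
  cat_vec <- rep(corpus$reports$category, lens)
  if (estimator == "report") {
    # document frequency: count each (token, report) pair once
    rep_vec <- rep(corpus$reports$report_id, lens)
    keep <- !duplicated(paste(rep_vec, tok_vec, sep = "\x1f"))
    tok_vec <- tok_vec[keep]
    cat_vec <- cat_vec[keep]
    totals <- table(factor(corpus$reports$category, levels = corpus$categories))
  }
  counts <- table(
    factor(tok_vec, levels = corpus$vocabulary),
    factor(cat_vec, levels = corpus$categories)
  )
  counts <- matrix(as.integer(counts), nrow = nrow(counts),
                   dimnames = dimnames(counts))
  if (estimator == "token") totals <- colSums(counts)
  totals <- as.numeric(totals)
  names(totals) <- corpus$categories
  if (any(totals == 0)) {
    input_error(sprintf(
      "category with no tokens: %s",
      paste(corpus$categories[totals == 0], collapse = ", ")
    ))
  }
  probs <- sweep(counts, 2L, totals, "/")
  structure(
    list(counts = counts, category_totals = totals, probs = probs,
         estimator = estimator),
    class = "token_stats"
  )
}

#' Build token statistics from a precomputed count matrix
#'
#' Constructor for workflows where (token x category) counts already exist
#' (or are simulated); normalizes each category column to conditional
#' probabilities.
#'
#' @param counts Integer matrix, rows = tokens (rownames required), columns
#'   = categories (colnames required, >= 2).
#' @return A \code{token_stats} object.
#' @export
token_stats_from_counts <- function(counts) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)),
            !is.null(colnames(counts)), all(counts >= 0))
  if (ncol(counts) < 2L) config_error("token_stats needs >= 2 categories")
  totals <- colSums(counts)
  if (any(totals == 0)) input_error("category with zero total count")
  structure(
    list(counts = counts, category_totals = totals,
         probs = sweep(counts, 2L, totals, "/"), estimator = "token"),
    class = "token_stats"
  )
}

#' @export
print.token_stats <- function(x, ...) {
  cat(sprintf("<token_stats> %d tokens x %d categories (%s estimator)\n",
              nrow(x$probs), ncol(x$probs), x$estimator))
  invisible(x)
}

#' Select category-discriminative target tokens
#'
#' A token t is selected for category j when its conditional probability
#' there strictly exceeds the sum of its conditional probabilities in every
#' other category: p(t|j) > sum over k != j of p(t|k). A token satisfying the
#' rule holds more than half its total conditional mass in one category, so
#' the per-category sets are pairwise disjoint by construction. Ties (strict
#' inequality failing) select nothing. A minimum raw count filters hapax
#' artifacts before the rule applies.
#'
#' @param stats A \code{token_stats} object.
#' @param min_count Minimum occurrences of the token in its candidate
#'   category before it is eligible (default 3).
#' @return A \code{target_token_sets} object: list with \code{by_category}
#'   (named list of token vectors) and \code{provenance} (data.frame with
#'   columns category, token, margin, status).
#' @export
select_target_tokens <- function(stats, min_count = 3L) {
  stopifnot(inherits(stats, "token_stats"))
  p <- stats$probs
  if (nrow(p) == 0L) {
    return(new_target_token_sets(colnames(p), empty_provenance()))
  }
  tot <- rowSums(p)
  # margin[t, j] = p(t|j) - sum_{k != j} p(t|k)
  margin <- 2 * p - tot
  eligible <- margin > 0 & stats$counts >= min_count
  hits <- which(eligible, arr.ind = TRUE)
  # hits arrive in column-major order, i.e. grouped by category
  prov <- data.frame(
    category = colnames(p)[hits[, 2L]],
    token = rownames(p)[hits[, 1L]],
    margin = margin[hits],
    status = rep("kept", nrow(hits)),
    stringsAsFactors = FALSE
  )
  new_target_token_sets(colnames(p), prov)
}

empty_provenance <- function() {
  data.frame(category = character(), token = character(),
             margin = numeric(), status = character(),
             stringsAsFactors = FALSE)
}

new_target_token_sets <- function(categories, provenance) {
  kept_i <- provenance$status == "kept"
  by_category <- split(provenance$token[kept_i],
                       factor(provenance$category[kept_i], levels = categories))
  structure(
    list(by_category = by_category, provenance = provenance),
    class = "target_token_sets"
  )
}

#' @export
print.target_token_sets <- function(x, ...) {
  n <- vapply(x$by_category, length, integer(1))
  cat("<target_token_sets>\n")
  for (cat_ in names(n)) cat(sprintf("  %s: %d tokens\n", cat_, n[[cat_]]))
  invisible(x)
}

#' Apply an expert review filter to selected tokens
#'
#' Emulates the expert curation step as a reproducible, file-drivable
#' operation: denylisted tokens are marked \code{expert_removed} (provenance
#' retained) and excluded from the downstream target sets; an allowlist, if
#' given, restricts each category to the listed tokens.
#'
#' @param sets A \code{target_token_sets} object.
#' @param denylist Named list (by category) of token vectors to remove, or a
#'   plain character vector applied to every category.
#' @param allowlist Optional; same shape as \code{denylist}. Tokens not on
#'   the list are marked \code{expert_removed}.
#' @return A filtered \code{target_token_sets}.
#' @export
apply_expert_filter <- function(sets, denylist = NULL, allowlist = NULL) {
  stopifnot(inherits(sets, "target_token_sets"))
  prov <- sets$provenance
  cats <- names(sets$by_category)
  per_cat <- function(lst, cat_) {
    if (is.null(lst)) return(NULL)
    if (is.list(lst)) lst[[cat_]] else lst
  }
  for (cat_ in cats) {
    in_cat <- prov$category == cat_ & prov$status == "kept"
    deny <- per_cat(denylist, cat_)
    if (length(deny) > 0L) {
      absent <- setdiff(deny, prov$token[in_cat])
      if (length(absent) > 0L) {
        warning(sprintf("denylist token(s) not selected for %s: %s",
                        cat_, paste(absent, collapse = ", ")), call. = FALSE)
      }
      prov$status[in_cat & prov$token %in% deny] <- "expert_removed"
    }
    allow <- per_cat(allowlist, cat_)
    if (!is.null(allow)) {
      in_cat <- prov$category == cat_ & prov$status == "kept"
      prov$status[in_cat & !prov$token %in% allow] <- "expert_removed"
    }
  }
  out <- new_target_token_sets(cats, prov)
  if (!is.null(allowlist) && all(lengths(out$by_category) == 0L)) {
    warning("expert filter removed every selected token", call. = FALSE)
  }
  out
}

#' Read per-category deny/allow lists from plain-text files
#'
#' Each file holds one token per line and is named \code{<category>.txt}.
#'
#' @param dir Directory containing the files.
#' @return Named list of token vectors (possibly empty).
#' @export
read_token_lists <- function(dir) {
  files <- list.files(dir, pattern = "\\.txt$", full.names = TRUE)
  out <- lapply(files, function(f) {
    x <- readLines(f, warn = FALSE)
    x[nzchar(squish(x))]
  })
  names(out) <- sub("\\.txt$", "", basename(files))
  out
}

#' Write target token sets as CSV (columns category, token, margin, status)
#' @param sets A \code{target_token_sets}.
#' @param path Output path.
#' @export
write_token_sets <- function(sets, path) {
  stopifnot(inherits(sets, "target_token_sets"))
  utils::write.csv(sets$provenance, path, row.names = FALSE)
  invisible(path)
}

#' Read target token sets from the CSV written by \code{write_token_sets}
#' @param path CSV path.
#' @return A \code{target_token_sets}.
#' @export
read_token_sets <- function(path) {
  prov <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = c(category = "character",
                                         token = "character",
                                         margin = "numeric",
                                         status = "character"))
  new_target_token_sets(sort(unique(prov$category)), prov)
}
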