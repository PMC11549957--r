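#' Build a cover instance for one category
#'
#' Restricts the corpus to sentences of reports labelled with the category
#' that contain at least one target token, and annotates each candidate
#' sentence with its subset of the target tokens.
#'
#' @param corpus A \code{pse_corpus}.
#' @param target_tokens Nonempty character vector of target tokens (one
#'   category's W).
#' @param category Category label; only that category's reports are
#'   candidates.
#' @param sentences Optional precomputed sentence table from
#'   \code{\link{corpus_sentences}} (avoids re-segmenting per category).
#' @return A \code{cover_instance}: list with \code{W} (tokens),
#'   \code{sentences} (data.frame report_id, sent_index, text), \code{tokens}
#'   (list of each sentence's target-token subset) and \code{category}.
#' @export
build_cover_instance <- function(corpus, target_tokens, category,
                                 sentences = NULL) {
  stopifnot(inherits(corpus, "pse_corpus"))
  if (length(target_tokens) == 0L) {
    config_error("build_cover_instance: target_tokens is empty")
  }
  if (is.null(sentences)) sentences <- corpus_sentences(corpus)
  sents <- sentences[sentences$category == category, , drop = FALSE]
  tks <- if (nrow(sents) > 0L) tokenize(sents$text) else list()
  if (nrow(sents) == 1L) tks <- list(tks)
  tok_sets <- lapply(tks, function(tk) sort(unique(intersect(tk, target_tokens))))
  keep <- lengths(tok_sets) > 0L
  sents <- sents[keep, , drop = FALSE]
  tok_sets <- tok_sets[keep]
  # canonical deterministic order
  ord <- order(sents$report_id, sents$sent_index)
  sents <- sents[ord, , drop = FALSE]
  rownames(sents) <- NULL
  structure(
    list(W = sort(unique(target_tokens)),
         sentences = sents[, c("report_id", "sent_index", "text")],
         tokens = tok_sets[ord],
         category = category),
    class = "cover_instance"
  )
}

#' @export
print.cover_instance <- function(x, ...) {
  cat(sprintf("<cover_instance> category %s: %d target tokens, %d candidate sentences\n",
              x$category, length(x$W), nrow(x$sentences)))
  invisible(x)
}

new_cover_solution <- function(instance, sel_idx, covered, uncovered_df,
                               backtracks, expansions, cap_hit) {
  sents <- instance$sentences[sel_idx, , drop = FALSE]
  sents$tokens_covered <- vapply(
    instance$tokens[sel_idx], paste, character(1), collapse = ";"
  )
  rownames(sents) <- NULL
  structure(
    list(
      S = sents,
      R = unique(sents$report_id),
      covered = sort(covered),
      uncovered = uncovered_df,
      backtrack_count = backtracks,
      node_expansions = expansions,
      cap_hit = cap_hit,
      category = instance$category
    ),
    class = "cover_solution"
  )
}

#' @export
print.cover_solution <- function(x, ...) {
  cat(sprintf(
    "<cover_solution> %s: %d sentences / %d reports, %d covered, %d uncovered, %d backtracks%s\n",
    x$category %||% "?", nrow(x$S), length(x$R), length(x$covered),
    nrow(x$uncovered), x$backtrack_count,
    if (isTRUE(x$cap_hit)) " (search cap hit)" else ""
  ))
  invisible(x)
}

# Canonical representation of a covered-token set, used to break ties
# between distinct maximal-coverage solutions deterministically: among
# equal-cardinality covered sets, the lexicographically smallest wins.
.covered_key <- function(tokens) paste(sort(tokens), collapse = "\x1f")

# Candidate order at a decision point: sentences from unvisited reports,
# carrying >= 1 still-uncovered token, by gain descending then
# (report_id, sent_index). Sentence rows are pre-sorted by (report_id,
# sent_index), so a stable sort on -gain realizes the tie-break.
.ordered_candidates <- function(instance, avail, W, R) {
  gain <- vapply(instance$tokens, function(tk) sum(tk %in% W), integer(1))
  ok <- which(avail & gain > 0L & !(instance$sentences$report_id %in% R))
  ok[order(-gain[ok])]
}

#' Select target sentences by greedy depth-first search with backtracking
#'
#' Repeatedly takes the candidate sentence covering the most still-uncovered
#' target tokens, subject to the constraint that each report contributes at
#' most one sentence. When no valid sentence remains while tokens are still
#' uncovered, the most recent selection is reverted (its tokens restored,
#' its report freed) and the next-best alternative at that decision point is
#' tried, so the search traverses the space depth first in greedy order.
#' Tokens contained in no candidate sentence are reported uncoverable up
#' front; if the search exhausts (or hits the node-expansion cap) without a
#' full cover, the best solution seen — maximal coverage, earliest in greedy
#' order — is returned and its residual tokens reported uncovered.
#'
#' @param instance A \code{cover_instance}.
#' @param max_expansions Node-expansion cap guaranteeing termination on
#'   adversarial instances (default 10000); hitting it degrades gracefully to
#'   the best solution found.
#' @return A \code{cover_solution}: \code{S} (selected sentences, in
#'   selection order, with the tokens each contributed), \code{R} (visited
#'   reports), \code{covered}, \code{uncovered} (token + reason code),
#'   \code{backtrack_count}, \code{node_expansions}, \code{cap_hit}.
#' @export
solve_cover <- function(instance, max_expansions = 10000L) {
  stopifnot(inherits(instance, "cover_instance"))
  all_cand_tokens <- unique(unlist(instance$tokens, use.names = FALSE))
  no_cand <- setdiff(instance$W, all_cand_tokens)
  W0 <- intersect(instance$W, all_cand_tokens)

  n_sent <- nrow(instance$sentences)
  avail <- rep(TRUE, n_sent)
  W <- W0
  R <- character(0)
  sel <- integer(0)          # selected sentence row indices, in order
  # frames[[d]]: candidate list at depth d and position of the next untried one
  frames <- list()
  best_sel <- integer(0)
  best_covered <- character(0)
  best_key <- ""
  backtracks <- 0L
  expansions <- 0L
  cap_hit <- FALSE

  consider_best <- function(sel_now, covered_now) {
    key <- .covered_key(covered_now)
    if (length(covered_now) > length(best_covered) ||
        (length(covered_now) == length(best_covered) &&
         length(best_covered) > 0L && key < best_key)) {
      best_sel <<- sel_now
      best_covered <<- covered_now
      best_key <<- key
    }
  }

  repeat {
    if (length(W) == 0L && length(W0) > 0L) {  # full cover
      best_sel <- sel
      best_covered <- W0
      break
    }
    if (length(W0) == 0L) break
    cands <- .ordered_candidates(instance, avail, W, R)
    if (length(cands) > 0L && expansions < max_expansions) {
      # descend: take the top candidate, remember the alternatives
      frames[[length(frames) + 1L]] <- list(cands = cands, nxt = 2L)
      i <- cands[[1L]]
      sel <- c(sel, i)
      avail[i] <- FALSE
      R <- c(R, instance$sentences$report_id[i])
      W <- setdiff(W, instance$tokens[[i]])
      expansions <- expansions + 1L
      next
    }
    if (expansions >= max_expansions) cap_hit <- TRUE
    consider_best(sel, setdiff(W0, W))
    # backtrack: revert the most recent selection, try its next alternative
    repeat {
      if (length(frames) == 0L || cap_hit) break
      d <- length(frames)
      # revert selection made at depth d
      i <- sel[[d]]
      sel <- sel[-d]
      avail[i] <- TRUE
      R <- R[-d]
      W <- union(W, setdiff(instance$tokens[[i]],
                            unlist(instance$tokens[sel], use.names = FALSE)))
      backtracks <- backtracks + 1L
      fr <- frames[[d]]
      if (fr$nxt <= length(fr$cands)) {
        j <- fr$cands[[fr$nxt]]
        frames[[d]]$nxt <- fr$nxt + 1L
        # re-descend along the alternative
        sel <- c(sel, j)
        avail[j] <- FALSE
        R <- c(R, instance$sentences$report_id[j])
        W <- setdiff(W, instance$tokens[[j]])
        expansions <- expansions + 1L
        break
      }
      frames[[d]] <- NULL  # exhausted this depth; pop and continue upward
    }
    if (length(frames) == 0L || cap_hit) break
    if (expansions >= max_expansions) cap_hit <- TRUE
  }

  covered <- best_covered
  residual <- setdiff(W0, covered)
  uncovered_df <- rbind(
    if (length(no_cand) > 0L)
      data.frame(token = no_cand, reason = "no_candidate_sentence",
                 stringsAsFactors = FALSE),
    if (length(residual) > 0L)
      data.frame(token = residual, reason = "report_conflict",
                 stringsAsFactors = FALSE)
  )
  if (is.null(uncovered_df)) {
    uncovered_df <- data.frame(token = character(), reason = character(),
                               stringsAsFactors = FALSE)
  }
  if (isTRUE(cap_hit)) {
    message(sprintf("solve_cover: node-expansion cap (%d) hit for category %s; best partial solution kept",
                    max_expansions, instance$category %||% "?"))
  }
  new_cover_solution(instance, best_sel, covered, uncovered_df,
                     backtracks, expansions, cap_hit)
}

#' Exact cover by exhaustive enumeration (test oracle)
#'
#' Enumerates every one-sentence-per-report selection and returns a
#' provably maximal-coverage, minimum-cardinality solution. Exponential in
#' the number of reports; refuse instances above \code{max_reports}.
#'
#' @param instance A \code{cover_instance}.
#' @param max_reports Hard size limit (default 10 reports).
#' @return A \code{cover_solution} (backtrack_count is 0; not a search).
#' @export
exact_cover <- function(instance, max_reports = 10L) {
  stopifnot(inherits(instance, "cover_instance"))
  reports <- unique(instance$sentences$report_id)
  if (length(reports) > max_reports) {
    size_error(sprintf("exact_cover: %d reports exceeds max_reports = %d",
                       length(reports), max_reports))
  }
  all_cand_tokens <- unique(unlist(instance$tokens, use.names = FALSE))
  no_cand <- setdiff(instance$W, all_cand_tokens)
  W0 <- intersect(instance$W, all_cand_tokens)

  by_report <- lapply(reports, function(r) which(instance$sentences$report_id == r))
  n_rep <- length(by_report)
  # suffix_tokens[[k]]: tokens still reachable from reports k..n (for pruning)
  suffix_tokens <- vector("list", n_rep + 1L)
  suffix_tokens[[n_rep + 1L]] <- character(0)
  for (k in rev(seq_len(n_rep))) {
    suffix_tokens[[k]] <- unique(c(
      suffix_tokens[[k + 1L]],
      unlist(instance$tokens[by_report[[k]]], use.names = FALSE)
    ))
  }
  best <- list(sel = integer(0), covered = character(0), key = "")
  better <- function(sel, covered, key) {
    if (length(covered) != length(best$covered)) {
      return(length(covered) > length(best$covered))
    }
    if (key != best$key) return(key < best$key)
    length(sel) < length(best$sel)
  }
  recurse <- function(k, sel, covered) {
    if (k > n_rep) {
      key <- .covered_key(covered)
      if (better(sel, covered, key)) {
        best <<- list(sel = sel, covered = covered, key = key)
      }
      return(invisible())
    }
    # prune: even covering everything still reachable cannot beat best
    if (length(union(covered, suffix_tokens[[k]])) < length(best$covered)) {
      return(invisible())
    }
    recurse(k + 1L, sel, covered)            # skip this report
    for (i in by_report[[k]]) {
      recurse(k + 1L, c(sel, i), union(covered, instance$tokens[[i]]))
    }
  }
  recurse(1L, integer(0), character(0))

  residual <- setdiff(W0, best$covered)
  uncovered_df <- rbind(
    if (length(no_cand) > 0L)
      data.frame(token = no_cand, reason = "no_candidate_sentence",
                 stringsAsFactors = FALSE),
    if (length(residual) > 0L)
      data.frame(token = residual, reason = "report_conflict",
                 stringsAsFactors = FALSE)
  )
  if (is.null(uncovered_df)) {
    uncovered_df <- data.frame(token = character(), reason = character(),
                               stringsAsFactors = FALSE)
  }
  new_cover_solution(instance, best$sel, best$covered, uncovered_df,
                     0L, 0L, FALSE)
}

#' Write a cover solution (and its uncovered-token sidecar) as CSV
#'
#' @param solutions A \code{cover_solution} or list of them (one per
#'   category).
#' @param path Main CSV path (columns category, report_id, sent_index,
#'   sentence_text, tokens_covered).
#' @param uncovered_path Sidecar CSV path (columns category, token, reason);
#'   default derived from \code{path}.
#' @export
write_cover_solution <- function(solutions, path,
                                 uncovered_path = sub("(\\.csv)?$", "_uncovered.csv",
                                                      path)[1]) {
  if (inherits(solutions, "cover_solution")) solutions <- list(solutions)
  rows <- do.call(rbind, lapply(solutions, function(sol) {
    if (nrow(sol$S) == 0L) return(NULL)
    data.frame(category = sol$category, report_id = sol$S$report_id,
               sent_index = sol$S$sent_index, sentence_text = sol$S$text,
               tokens_covered = sol$S$tokens_covered, stringsAsFactors = FALSE)
  }))
  if (is.null(rows)) {
    rows <- data.frame(category = character(), report_id = character(),
                       sent_index = integer(), sentence_text = character(),
                       tokens_covered = character(), stringsAsFactors = FALSE)
  }
  utils::write.csv(rows, path, row.names = FALSE)
  unc <- do.call(rbind, lapply(solutions, function(sol) {
    if (nrow(sol$uncovered) == 0L) return(NULL)
    cbind(data.frame(category = sol$category, stringsAsFactors = FALSE),
          sol$uncovered)
  }))
  if (is.null(unc)) {
    unc <- data.frame(category = character(), token = character(),
                      reason = character(), stringsAsFactors = FALSE)
  }
  utils::write.csv(unc, uncovered_path, row.names = FALSE)
  invisible(path)
}
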