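# Fixtures built in code: tiny hand corpora, fuzz generators, and
# independent brute-force oracles kept deliberately dumb (loops, no reuse of
# package internals).

tiny_corpus <- function() {
  corpus(
    report_id = c("r01", "r02", "r03", "r04", "r05", "r06"),
    category = c("med", "med", "fall", "fall", "conduct", "conduct"),
    text = c(
      "Patient received heparin drip. Dose exceeded protocol limits.",
      "Pharmacy flagged heparin order. Nurse held the dose.",
      "Pt fell near the bed. Bed alarm was off.",
      "Patient found on floor. Fall risk band missing.",
      "Staff member raised voice at colleague. Manager notified.",
      "Unprofessional remark during handoff. Colleague reported concern."
    )
  )
}

# random mini corpus whose sentences are target-token bags; returns the
# corpus, the category, and the token pool used as W
fuzz_cover_input <- function(seed, n_reports = NULL) {
  set.seed(seed)
  pool <- paste0("t", letters[seq_len(sample(4:8, 1))])
  n_rep <- n_reports %||% sample(3:7, 1)
  ids <- sprintf("r%02d", seq_len(n_rep))
  texts <- vapply(ids, function(id) {
    n_sent <- sample(1:3, 1)
    sents <- vapply(seq_len(n_sent), function(s) {
      paste(sample(pool, sample(1:3, 1)), collapse = " ")
    }, character(1))
    paste0(paste(sents, collapse = ". "), ".")
  }, character(1))
  corp <- corpus(ids, rep("cat", n_rep), texts)
  list(corpus = corp, W = pool, category = "cat")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent oracle: apply the dominance inequality per (token, category)
# with plain loops over the probability matrix
brute_select <- function(stats, min_count = 3L) {
  p <- stats$probs
  out <- list()
  for (j in colnames(p)) {
    sel <- character(0)
    for (t in rownames(p)) {
      others <- sum(p[t, setdiff(colnames(p), j)])
      if (p[t, j] > others && stats$counts[t, j] >= min_count) {
        sel <- c(sel, t)
      }
    }
    out[[j]] <- sel
  }
  out
}

# independent oracle: per-category token counts by naive splitting
brute_category_counts <- function(corp) {
  counts <- list()
  for (i in seq_len(nrow(corp$reports))) {
    cat_ <- corp$reports$category[i]
    toks <- strsplit(tolower(corp$reports$text[i]), "[^[:alnum:]]+")[[1]]
    toks <- toks[nzchar(toks) & !grepl("^[0-9]+$", toks) & nchar(toks) >= 2]
    for (t in toks) {
      key <- paste(cat_, t, sep = "|")
      counts[[key]] <- (counts[[key]] %||% 0) + 1
    }
  }
  counts
}

expect_one_per_report <- function(sol) {
  expect_equal(nrow(sol$S), length(unique(sol$S$report_id)))
  expect_setequal(sol$R, unique(sol$S$report_id))
}

fixture_path <- function(file) {
  system.file("extdata", file, package = "psefit")
}
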