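test_that("uniform and constant backends reproduce closed-form perplexities", {
  ub <- uniform_backend(10)
  res <- compute_perplexity(ub, "one two three four five")
  expect_equal(res$perplexity, 10, tolerance = 1e-9)
  expect_equal(res$n_scored_tokens, 5L)
  # vocabulary size regardless of sentence
  expect_equal(compute_perplexity(ub, "aa bb")$perplexity, 10, tolerance = 1e-9)

  cb <- constant_backend(0.25)
  expect_equal(compute_perplexity(cb, "alpha beta gamma")$perplexity, 4,
               tolerance = 1e-9)
  expect_gte(compute_perplexity(cb, "alpha")$perplexity, 1)
})

test_that("empty tokenization raises a scoring error naming the sentence", {
  expect_error(compute_perplexity(uniform_backend(10), "1 2 3 !"),
               class = "psefit_scoring_error")
})

test_that("unigram backend matches the hand-computed vanishing-smoothing limit", {
  bk <- fit_ngram_backend("a1x a1x b2y", order = 1, smoothing = 1e-9)
  # p(a1x) -> 2/3, p(b2y) -> 1/3
  expect_equal(compute_perplexity(bk, "a1x b2y")$perplexity,
               exp(-(log(2 / 3) + log(1 / 3)) / 2), tolerance = 1e-6)
})

test_that("bigram probabilities equal hand counts on a ten-token corpus", {
  # training tokens: the bed alarm was off the bed rail was up
  bk <- fit_ngram_backend("the bed alarm was off the bed rail was up",
                          order = 2, smoothing = 0.5)
  v1 <- length(bk$vocab) + 1  # 7 types + unk
  # p(bed | the) = (2 + 0.5) / (2 + 0.5 * 9); p(alarm | bed) = (1 + 0.5) / (2 + 0.5 * 9)
  p_bed_given_the <- (2 + 0.5) / (2 + 0.5 * v1)
  p_alarm_given_bed <- (1 + 0.5) / (2 + 0.5 * v1)
  p_the_given_start <- (1 + 0.5) / (1 + 0.5 * v1)
  got <- compute_perplexity(bk, "the bed alarm")$perplexity
  expect_equal(got,
               exp(-mean(log(c(p_the_given_start, p_bed_given_the,
                               p_alarm_given_bed)))),
               tolerance = 1e-12)
})

test_that("n-gram conditional distributions sum to one for random contexts", {
  bk1 <- fit_ngram_backend(c("fall risk band", "bed alarm off"), order = 1,
                           smoothing = 0.7)
  bk2 <- fit_ngram_backend(c("fall risk band", "bed alarm off"), order = 2,
                           smoothing = 0.7)
  bk3 <- fit_ngram_backend(c("fall risk band missing now", "bed alarm off"),
                           order = 3, smoothing = 0.7)
  set.seed(77)
  for (i in 1:25) {
    ctx <- sample(c(bk3$vocab, "zzz-unseen"), 2, replace = TRUE)
    expect_equal(sum(ngram_conditional_distribution(bk1)), 1, tolerance = 1e-12)
    expect_equal(sum(ngram_conditional_distribution(bk2, ctx[1])), 1,
                 tolerance = 1e-12)
    expect_equal(sum(ngram_conditional_distribution(bk3, ctx)), 1,
                 tolerance = 1e-12)
  }
})

test_that("training text scores no worse than shuffled text in most trials", {
  wins <- 0L
  for (seed in 1:20) {
    set.seed(seed)
    words <- c("patient", "fell", "near", "bed", "alarm", "was", "off",
               "nurse", "notified", "team")
    train <- replicate(12, paste(
      words[pmin(pmax(round(stats::rnorm(8, 5, 2)), 1), 10)], collapse = " "))
    bk <- fit_ngram_backend(train, order = 2, smoothing = 0.2)
    shuffled <- vapply(train, function(s) {
      paste(sample(strsplit(s, " ")[[1]]), collapse = " ")
    }, character(1))
    p_train <- mean(vapply(train, function(s)
      compute_perplexity(bk, s)$perplexity, numeric(1)))
    p_shuf <- mean(vapply(shuffled, function(s)
      compute_perplexity(bk, s)$perplexity, numeric(1)))
    if (p_train <= p_shuf) wins <- wins + 1L
  }
  expect_gte(wins, 19L)
})

test_that("growing smoothing drives perplexity toward the uniform limit", {
  bk <- function(k) fit_ngram_backend("aa bb aa cc aa", order = 1, smoothing = k)
  v1 <- 4  # 3 types + unk
  sent <- "aa bb"
  gaps <- vapply(c(0.1, 10, 1000), function(k) {
    abs(compute_perplexity(bk(k), sent)$perplexity - v1)
  }, numeric(1))
  expect_true(all(diff(gaps) < 0))
  expect_lt(gaps[3], 0.05)
})

test_that("long inputs truncate to the backend's maximum sequence length", {
  bk <- fit_ngram_backend("aa bb cc", order = 1, smoothing = 1,
                          max_sequence_length = 6L)
  long <- paste(rep("aa", 50), collapse = " ")
  expect_equal(compute_perplexity(bk, long)$n_scored_tokens, 6L)
})

test_that("batching never changes values and preserves input order", {
  sents <- data.frame(
    report_id = sprintf("r%03d", 1:120),
    sent_index = 0L,
    category = rep(c("A", "B"), 60),
    text = replicate(120, paste(sample(c("aa", "bb", "cc", "dd"), 5,
                                       replace = TRUE), collapse = " ")),
    stringsAsFactors = FALSE
  )
  bk <- fit_ngram_backend(sents$text[1:40], order = 2, smoothing = 0.3)
  batched <- batch_score(bk, sents, batch_size = 16)
  one_by_one <- do.call(rbind, lapply(seq_len(nrow(sents)), function(i) {
    compute_perplexity(bk, sents$text[i], report_id = sents$report_id[i],
                       sent_index = sents$sent_index[i],
                       category = sents$category[i])
  }))
  expect_equal(nrow(batched), 120L)
  expect_equal(batched$report_id, sents$report_id)  # order-stable
  expect_equal(batched$perplexity, one_by_one$perplexity, tolerance = 1e-12)
  # batch size must not matter
  expect_equal(batch_score(bk, sents, batch_size = 7)$perplexity,
               batched$perplexity, tolerance = 1e-12)
  # empty input gives an empty, well-formed result
  expect_equal(nrow(batch_score(bk, sents[0, ])), 0L)
})

test_that("per-sentence failures are collected without aborting the batch", {
  bk <- fit_ngram_backend("aa bb", order = 1, smoothing = 1)
  sents <- data.frame(report_id = c("r1", "r2"), sent_index = 0L,
                      text = c("aa bb", "1 2 3"), stringsAsFactors = FALSE)
  expect_warning(res <- batch_score(bk, sents), "failed")
  expect_equal(nrow(res), 1L)
  expect_length(attr(res, "failures"), 1L)
})

test_that("scoring the same sentence twice is deterministic", {
  bk <- fit_ngram_backend(c("fall near bed", "bed alarm"), order = 2,
                          smoothing = 0.4)
  a <- compute_perplexity(bk, "fall near bed alarm")
  b <- compute_perplexity(bk, "fall near bed alarm")
  expect_identical(a$perplexity, b$perplexity)
})

test_that("the transformer adapter degrades to a classed environment error", {
  # constructor must validate its runtime without breaking anything else
  err <- tryCatch(
    transformer_backend("gpt2", max_sequence_length = 1024L,
                        python = Sys.which("python")),
    psefit_environment_error = function(e) e,
    error = function(e) e
  )
  if (inherits(err, "psefit_environment_error")) {
    expect_match(conditionMessage(err), "transformers")
  } else {
    # runtime present: the constructor must return a conforming backend
    expect_s3_class(err, "lm_backend")
  }
})
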