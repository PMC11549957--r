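test_that("build_cover_instance keeps only token-bearing sentences of the category", {
  corp <- corpus(c("r1", "r2", "r3"), c("X", "X", "Y"),
                 c("alpha here. nothing useful.", "alpha again", "alpha wrong category"))
  inst <- build_cover_instance(corp, "alpha", "X")
  expect_equal(nrow(inst$sentences), 2L)
  expect_true(all(vapply(inst$tokens, function(t) "alpha" %in% t, logical(1))))
  # a token present in no sentence never appears in the annotations
  inst2 <- build_cover_instance(corp, c("alpha", "ghost"), "X")
  expect_false("ghost" %in% unlist(inst2$tokens))
  expect_error(build_cover_instance(corp, character(0), "X"),
               class = "psefit_config_error")
})

test_that("instance annotations equal brute-force membership on fuzzed corpora", {
  for (seed in 401:410) {
    inp <- fuzz_cover_input(seed)
    inst <- build_cover_instance(inp$corpus, inp$W, inp$category)
    sents <- corpus_sentences(inp$corpus)
    for (i in seq_len(nrow(inst$sentences))) {
      row <- inst$sentences[i, ]
      txt <- sents$text[sents$report_id == row$report_id &
                        sents$sent_index == row$sent_index]
      toks <- strsplit(tolower(txt), "[^[:alnum:]]+")[[1]]
      expect_setequal(inst$tokens[[i]], intersect(unique(toks), inp$W))
    }
  }
})

test_that("a single sentence covering all tokens is selected alone", {
  corp <- corpus(c("r1", "r2"), c("X", "X"), c("aa bb", "aa"))
  sol <- solve_cover(build_cover_instance(corp, c("aa", "bb"), "X"))
  expect_equal(nrow(sol$S), 1L)
  expect_equal(sol$S$report_id, "r1")
  expect_setequal(sol$covered, c("aa", "bb"))
  expect_equal(nrow(sol$uncovered), 0L)
})

test_that("one-per-report conflicts force backtracking to a full cover", {
  # r1 holds "aa" and "bb" in separate sentences; r2 holds only "aa".
  # Greedy first takes r1's "aa" sentence, discovers "bb" lives only in the
  # already-visited r1, and must backtrack; the unique feasible full cover
  # (confirmed by exhaustive enumeration below) uses r1's "bb" sentence and
  # r2's "aa" sentence.
  corp <- corpus(c("r1", "r2"), c("X", "X"),
                 c("token aa here. token bb here.", "token aa again."))
  inst <- build_cover_instance(corp, c("aa", "bb"), "X")
  sol <- solve_cover(inst)
  expect_gte(sol$backtrack_count, 1L)
  expect_setequal(sol$covered, c("aa", "bb"))
  expect_equal(nrow(sol$S), 2L)
  expect_setequal(paste(sol$S$report_id, sol$S$sent_index),
                  c("r1 1", "r2 0"))
  exact <- exact_cover(inst)
  expect_setequal(exact$covered, c("aa", "bb"))
  expect_equal(nrow(exact$S), 2L)
  expect_setequal(paste(exact$S$report_id, exact$S$sent_index),
                  c("r1 1", "r2 0"))
})

test_that("one report suffices when a token only occurs there twice", {
  corp <- corpus("r1", "X", "aa first. aa second.")
  sol <- solve_cover(build_cover_instance(corp, "aa", "X"))
  expect_equal(nrow(sol$S), 1L)
  expect_equal(sol$covered, "aa")
})

test_that("tokens with no candidate sentence are reported uncoverable", {
  corp <- corpus("r1", "X", "aa bb")
  sol <- solve_cover(build_cover_instance(corp, c("aa", "bb", "cc"), "X"))
  expect_setequal(sol$covered, c("aa", "bb"))
  expect_equal(sol$uncovered$token, "cc")
  expect_equal(sol$uncovered$reason, "no_candidate_sentence")
})

test_that("greedy can exceed the exact minimum cardinality but not coverage", {
  # three 2-token sentences arranged so the greedy tie-break picks the one
  # sentence that belongs to no optimal pair
  corp <- corpus(c("r1", "r2", "r3"), rep("X", 3),
                 c("tb tc", "ta tb", "tc td"))
  inst <- build_cover_instance(corp, c("ta", "tb", "tc", "td"), "X")
  greedy <- solve_cover(inst)
  exact <- exact_cover(inst)
  expect_setequal(greedy$covered, c("ta", "tb", "tc", "td"))
  expect_setequal(exact$covered, greedy$covered)
  expect_equal(nrow(exact$S), 2L)
  expect_equal(nrow(greedy$S), 3L)
})

test_that("exact_cover refuses oversized instances", {
  inp <- fuzz_cover_input(999, n_reports = 7)
  inst <- build_cover_instance(inp$corpus, inp$W, inp$category)
  expect_error(exact_cover(inst, max_reports = 3), class = "psefit_size_error")
})

test_that("greedy matches exact coverage on fuzzed instances; one per report", {
  for (seed in 501:540) {
    inp <- fuzz_cover_input(seed)
    inst <- build_cover_instance(inp$corpus, inp$W, inp$category)
    g <- solve_cover(inst)
    e <- exact_cover(inst)
    expect_setequal(g$covered, e$covered)
    expect_gte(nrow(g$S), nrow(e$S))
    expect_lte(nrow(g$S), nrow(inp$corpus$reports))
    expect_one_per_report(g)
    expect_one_per_report(e)
    expect_setequal(c(g$covered, g$uncovered$token), inst$W)
    expect_length(intersect(g$covered, g$uncovered$token), 0)
  }
})

test_that("the solver is deterministic and terminates on large instances", {
  inp <- fuzz_cover_input(601, n_reports = 200)
  inst <- build_cover_instance(inp$corpus, inp$W, inp$category)
  s1 <- solve_cover(inst)
  s2 <- solve_cover(inst)
  expect_identical(s1$S, s2$S)
  expect_identical(s1$covered, s2$covered)

  # wider instance: 200 reports x up to 50 tokens
  set.seed(602)
  pool <- sprintf("tk%02d", 1:50)
  ids <- sprintf("r%03d", 1:200)
  texts <- vapply(ids, function(id) {
    paste(sample(pool, sample(2:6, 1)), collapse = " ")
  }, character(1))
  corp <- corpus(ids, rep("cat", 200), texts)
  inst2 <- build_cover_instance(corp, pool, "cat")
  sol <- solve_cover(inst2)
  expect_lte(sol$node_expansions, 10000L)
  expect_one_per_report(sol)
})

test_that("hitting the expansion cap degrades to the best partial solution", {
  # every token lives only in report r1, so no full cover exists and the
  # search must stop at the cap instead of looping
  corp <- corpus(c("r1", "r2", "r3"), rep("X", 3),
                 c("ta only. tb only. tc only.", "ta again", "ta more"))
  inst <- build_cover_instance(corp, c("ta", "tb", "tc"), "X")
  sol <- suppressMessages(solve_cover(inst, max_expansions = 2L))
  expect_true(sol$cap_hit)
  expect_one_per_report(sol)
  expect_setequal(c(sol$covered, sol$uncovered$token), c("ta", "tb", "tc"))

  full <- solve_cover(inst)
  expect_false(full$cap_hit)
  # maximal coverage: two of the three tokens are lost to the conflict
  expect_setequal(full$covered, exact_cover(inst)$covered)
  expect_true(all(full$uncovered$reason == "report_conflict"))
})

test_that("cover solutions and uncovered sidecars write as CSV", {
  corp <- corpus(c("r1", "r2"), c("X", "X"), c("aa bb", "aa"))
  sol <- solve_cover(build_cover_instance(corp, c("aa", "bb", "zz"), "X"))
  path <- withr::local_tempfile(fileext = ".csv")
  side <- withr::local_tempfile(fileext = ".csv")
  write_cover_solution(sol, path, side)
  main <- utils::read.csv(path, stringsAsFactors = FALSE)
  expect_equal(main$category, "X")
  expect_equal(main$tokens_covered, "aa;bb")
  unc <- utils::read.csv(side, stringsAsFactors = FALSE)
  expect_equal(unc$token, "zz")
})
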