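test_that("bracket extraction drops width-1 and full-sentence spans", {
  flat <- sexpr_to_tree("(S w1 w2 w3)")
  expect_equal(nrow(extract_brackets(flat)$spans), 0L)
  t2 <- sexpr_to_tree("(S (X w1 w2) w3)")
  expect_equal(unclass(extract_brackets(t2)$spans),
               cbind(start = 0L, end = 2L), ignore_attr = TRUE)
  # two nested nodes over the same span collapse to one (set semantics)
  t3 <- sexpr_to_tree("(S (X (Y w1 w2)) w3)")
  expect_equal(nrow(extract_brackets(t3)$spans), 1L)
  # preterminal nodes are width-1 and never scored
  t4 <- sexpr_to_tree("(S (A w1) (B w2))")
  expect_equal(nrow(extract_brackets(t4)$spans), 0L)
})

test_that("precision/recall/F follow the stated conventions", {
  gold <- bracket_set(rbind(c(0, 2), c(2, 5)), 5)
  pred <- bracket_set(rbind(c(0, 2), c(1, 5)), 5)
  expect_equal(bracket_prf(gold, pred),
               c(precision = 0.5, recall = 0.5, f = 0.5))
  expect_equal(bracket_prf(gold, gold),
               c(precision = 1, recall = 1, f = 1))
  empty <- bracket_set(NULL, 5)
  expect_equal(bracket_prf(gold, empty),
               c(precision = 1, recall = 0, f = 0))
  expect_equal(bracket_prf(empty, empty),
               c(precision = 1, recall = 1, f = 1))
  expect_error(bracket_prf(gold, bracket_set(NULL, 4)), "length")
  # duplicate gold spans collapse under set semantics
  dup <- bracket_set(rbind(c(0, 2), c(0, 2), c(2, 5)), 5)
  expect_equal(bracket_prf(dup, pred), bracket_prf(gold, pred))
  expect_error(bracket_set(rbind(c(3, 2)), 5), "invalid span")
})

test_that("evaluation micro-averages and reports novel parse rates", {
  p <- reference_pcfg("tiny")
  test <- corpus(c("det n v", "n v n", "det n"))
  gold <- list(
    bracket_set(rbind(c(0, 2)), 3),   # (det n) v
    NULL,
    NULL
  )
  ev <- evaluate_parses(p, test, gold = gold,
                        train_sentences = corpus(c("det n v", "n")))
  expect_equal(ev$parsed_count, 3)
  expect_equal(ev$noparse_count, 0)
  # two novel sentences, both parsed
  expect_equal(ev$novel_parse_rate, 1)
  expect_true(ev$precision >= 0 && ev$precision <= 1)
  expect_true(ev$f_measure <= max(ev$precision, ev$recall) + 1e-12)

  # all test sentences in training: novelty is undefined
  ev2 <- evaluate_parses(p, corpus("det n"), train_sentences = corpus("det n"))
  expect_true(is.na(ev2$novel_parse_rate))

  # micro-average equals harmonic mean of micro P and R by construction
  expect_equal(ev$f_measure,
               clingram:::harmonic_f(ev$precision, ev$recall))
})

test_that("unparsed sentences cost recall but not precision (unless skipped)", {
  # grammar that cannot parse the second sentence
  g <- cfg(c("S -> A B", "A -> a", "B -> b"))
  p <- init_uniform(g)
  test <- corpus(c("a b", "b a"))
  gold <- list(bracket_set(NULL, 2), bracket_set(NULL, 2))
  ev <- evaluate_parses(p, test, gold = gold)
  expect_equal(ev$noparse_count, 1)
  expect_equal(ev$precision, 1)  # no predicted spans at all (width-2 flat)
  ev_skip <- evaluate_parses(p, test, gold = gold, skip_unparsed = TRUE)
  expect_equal(ev_skip$precision, 1)
  # order invariance
  ev_r <- evaluate_parses(p, corpus(c("b a", "a b")), gold = rev(gold))
  expect_equal(ev_r$f_measure, ev$f_measure)
})

test_that("evaluation against sampled gold brackets is internally consistent", {
  prof <- corpus_profile("clinical_like", n_train = 40, n_test = 15,
                         seed = 5)
  data <- sample_corpus(prof)
  # parsing the gold trees' own yields with the reference grammar scores
  # perfectly when the gold trees themselves are the predictions
  for (k in seq_len(3)) {
    b <- data$gold_brackets[[k]]
    expect_equal(unname(bracket_prf(b, b)["f"]), 1)
  }
  ev <- evaluate_parses(data$profile$pcfg, data$test,
                        gold = data$gold_brackets,
                        train_sentences = data$train)
  expect_equal(ev$noparse_count, 0)  # every sampled sentence is parsable
  expect_gte(ev$f_measure, 0.5)      # reference grammar should score high
})
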