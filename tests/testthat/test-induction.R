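test_that("initial grammar has one S-production per unique sentence and shared preterminals", {
  st <- build_initial_grammar(corpus(c("a b", "a c")))
  g <- st$grammar
  expect_equal(sigma_size(g), 7L)  # S, 3 preterminals, 3 terminals
  expect_equal(sum(g$lhs == g$start), 2L)
  expect_setequal(terminals(g), c("a", "b", "c"))
  expect_setequal(language_up_to(g, 5), c("a b", "a c"))

  # duplicates: same grammar, but weighted derivations
  st2 <- build_initial_grammar(corpus(c("a b", "a b")))
  expect_equal(length(st2$grammar$lhs), 2L + 1L)  # one S rule + 2 pts
  expect_equal(st2$trees[[1]]$count, 2)
  expect_equal(unname(st2$u[st2$grammar$start]), 2)

  # single one-token sentence: no choice points anywhere
  st3 <- build_initial_grammar(corpus("a"))
  expect_equal(length(st3$grammar$lhs), 2L)
  expect_equal(corpus_derivation_cost(st3$trees, st3$grammar), 0)
  expect_error(build_initial_grammar(corpus(character(0))), "empty")
  expect_state_consistent(st)
})

test_that("combine candidates are contiguous nonterminal n-grams with tiled counts", {
  st <- build_initial_grammar(corpus(c("a b c", "a b")))
  cands <- enumerate_combine_candidates(st, 4)
  key <- vapply(cands, function(x) paste(x$instance$operands, collapse = " "),
                character(1))
  cnt <- setNames(vapply(cands, function(x) x$count, numeric(1)), key)
  expect_equal(unname(cnt["W.a W.b"]), 2)
  expect_equal(unname(cnt["W.b W.c"]), 1)
  expect_equal(unname(cnt["W.a W.b W.c"]), 1)
  expect_equal(length(cands), 3L)

  # non-overlapping tiling: A A A A contains "A A" twice
  st4 <- build_initial_grammar(corpus("a a a a"))
  c4 <- enumerate_combine_candidates(st4, 2)
  expect_equal(c4[[1]]$count, 2)

  # no RHS longer than 1 -> no candidates
  st1 <- build_initial_grammar(corpus(c("a", "b")))
  expect_length(enumerate_combine_candidates(st1, 4), 0)
})

test_that("merge candidates are unordered nonterminal pairs excluding the start", {
  st <- build_initial_grammar(corpus(c("a b", "a c")))
  m <- enumerate_merge_candidates(st)
  expect_length(m, choose(3, 2))
  ops <- lapply(m, function(x) x$operands)
  expect_false(any(vapply(ops, function(o) st$grammar$start %in% o,
                          logical(1))))
  st1 <- build_initial_grammar(corpus("a"))
  expect_length(enumerate_merge_candidates(st1), 0)
})

test_that("worked merge delta matches the closed-form toy computation", {
  st <- build_initial_grammar(corpus(c("a b", "a c")))
  inst <- operator_instance("merge", c("W.b", "W.c"))
  expect_equal(estimate_delta(st, inst, cost_weights(1)),
               9 * log2(6) - 12 * log2(7), tolerance = 1e-9)
  expect_equal(estimate_delta(st, inst, cost_weights(0)), 0,
               tolerance = 1e-9)
  # combining a once-occurring n-gram adds symbols and removes nothing net
  st1 <- build_initial_grammar(corpus("a b"))
  d <- estimate_delta(st1, operator_instance("combine", c("W.a", "W.b")),
                      cost_weights(1))
  expect_gt(d, 0)
  expect_error(
    estimate_delta(st, operator_instance("merge", c("W.b", "nope")),
                   cost_weights(1)), "stale")
})

test_that("estimated deltas equal apply-and-recompute on random states", {
  set.seed(7)
  for (rep in 1:20) {
    corp <- random_corpus(sample(3:7, 1))
    st <- random_state(corp, n_ops = sample(0:2, 1))
    cands <- c(
      lapply(enumerate_combine_candidates(st, 3), function(x) x$instance),
      enumerate_merge_candidates(st)
    )
    f <- runif(1)
    before <- oracle_total_cost(st, f)
    for (inst in cands) {
      d <- estimate_delta(st, inst, cost_weights(f))
      st2 <- apply_operator(st, inst)
      expect_equal(d, oracle_total_cost(st2, f) - before, tolerance = 1e-9)
    }
  }
})

test_that("apply_operator rewrites productions and derivations consistently", {
  st <- build_initial_grammar(corpus(c("d n v d n", "d n v")))
  inst <- operator_instance("combine", c("W.d", "W.n"))
  st2 <- apply_operator(st, inst)
  keys <- clingram:::production_keys(st2$grammar)
  expect_true("S -> C1 W.v C1" %in% keys)
  expect_true("S -> C1 W.v" %in% keys)
  expect_true("C1 -> W.d W.n" %in% keys)
  expect_state_consistent(st2)
  # combine preserves the language
  expect_identical(language_up_to(st2$grammar, 8),
                   language_up_to(st$grammar, 8))

  # merge collapses duplicate productions and generalizes
  stm <- build_initial_grammar(corpus(c("a b", "a c")))
  stm2 <- apply_operator(stm, operator_instance("merge", c("W.b", "W.c")))
  expect_setequal(clingram:::production_keys(stm2$grammar),
                  c("S -> W.a M1", "W.a -> a", "M1 -> b", "M1 -> c"))
  expect_state_consistent(stm2)
  before <- language_up_to(stm$grammar, 6)
  after <- language_up_to(stm2$grammar, 6)
  expect_true(all(before %in% after))
})

test_that("structural constraints block recursion and non-initial blocked tags", {
  cfg_block <- induction_config(blocked_tags = c("verb", "det"))
  st <- build_initial_grammar(corpus(c("det verb noun", "noun verb det noun")))
  # blocked tag at operand position >= 2 of the new production
  v <- violates_constraints(
    st, operator_instance("combine", c("W.det", "W.verb")), cfg_block)
  expect_true(v$violates)
  # blocked tag first is fine (the rule is "second or later" only)
  v2 <- violates_constraints(
    st, operator_instance("combine", c("W.verb", "W.noun")), cfg_block)
  expect_false(v2$violates)
  # merging a verb-preterminal into a symbol used at position >= 2 is blocked
  st3 <- apply_operator(st, operator_instance("combine",
                                              c("W.verb", "W.noun")))
  v3 <- violates_constraints(
    st3, operator_instance("merge", c("W.noun", "W.verb")), cfg_block)
  expect_true(v3$violates)

  # recursion: merging a symbol into its own expansion chain
  str <- build_initial_grammar(corpus(c("a b", "b")))
  str2 <- apply_operator(str, operator_instance("combine", c("W.a", "W.b")))
  # merge C1 with W.a puts the merged symbol inside its own rule
  vr <- violates_constraints(
    str2, operator_instance("merge", c("C1", "W.a")), induction_config())
  expect_true(vr$violates)
  expect_match(vr$reason, "recursion")
  vr2 <- violates_constraints(
    str2, operator_instance("merge", c("C1", "W.a")),
    induction_config(forbid_recursion = FALSE, enforce_blocklist = FALSE))
  expect_false(vr2$violates)
})

test_that("greedy induction strictly decreases cost and parses all training sentences", {
  set.seed(11)
  for (rep in 1:5) {
    corp <- random_corpus(sample(8:20, 1))
    f <- runif(1, 0.2, 0.9)
    fit <- induce_grammar(corp, induction_config(f = f))
    tr <- fit$trace
    expect_true(all(diff(tr$total) < 0) || nrow(tr) == 1)
    # recorded deltas match the realised cost drops
    if (nrow(tr) > 1) {
      expect_equal(diff(tr$total), tr$delta[-1], tolerance = 1e-9)
    }
    # final grammar parses every training sentence
    res <- clingram:::parse_corpus(fit$grammar, corp, mode = "first")
    expect_true(all(vapply(res, function(r) r$status == "ok", logical(1))))
    expect_state_consistent(fit$state)
  }
})

test_that("induction on a single unique sentence never increases cost", {
  fit <- induce_grammar(corpus(rep("a b a b", 3)),
                        induction_config(f = 0.4))
  expect_true(all(diff(fit$trace$total) <= 0))
  expect_setequal(language_up_to(fit$grammar, 4), "a b a b")
})

test_that("tie-breaking between equal-delta instances is deterministic", {
  corp <- corpus(c("a b", "c d", "a b", "c d"))
  f1 <- induce_grammar(corp, induction_config(f = 0.8))
  f2 <- induce_grammar(corp, induction_config(f = 0.8))
  expect_identical(f1$trace, f2$trace)
  expect_identical(clingram:::production_keys(f1$grammar),
                   clingram:::production_keys(f2$grammar))
})
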