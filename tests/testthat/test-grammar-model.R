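test_that("production cost follows the (1 + |rhs|) * log2(|Sigma|) rule", {
  expect_equal(production_cost(list(rhs = c("A", "B", "C")), 16), 16.0)
  expect_equal(production_cost(list(rhs = "a"), 2), 2.0)
  expect_equal(production_cost(list(rhs = c("A", "B")), 7), 3 * log2(7),
               tolerance = 1e-3)
  expect_error(production_cost(list(rhs = "a"), 1), "invalid inventory")
  expect_error(production_cost(list(rhs = character(0)), 4), "empty")
})

test_that("grammar cost sums production costs at the current |Sigma|", {
  g <- cfg(c("S -> A B", "S -> A C", "A -> a", "B -> b", "C -> c"))
  expect_equal(sigma_size(g), 7L)
  expect_equal(grammar_cost(g), 12 * log2(7))
  # order invariance: permuting production creation order leaves cost alone
  g2 <- cfg(c("A -> a", "C -> c", "S -> A C", "B -> b", "S -> A B"))
  expect_equal(grammar_cost(g2), grammar_cost(g))
  # empty production set
  g0 <- new_grammar(start = "S", lhs = "S", rhs = list("x"))
  g0$lhs <- character(0); g0$rhs <- list(); g0$id <- integer(0)
  expect_equal(grammar_cost(g0), 0)
})

test_that("grammar invariants are enforced", {
  expect_error(cfg(c("S -> A", "S -> A", "A -> a")), "duplicate")
  expect_error(cfg("S ->"), "malformed")
  g <- cfg(c("S -> A", "A -> a"))
  expect_identical(unname(g$kind[g$start]), "nonterminal")
  expect_identical(sum(g$origin == "start"), 1L)
})

test_that("grammar cost matches an independent evaluation on random grammars", {
  set.seed(41)
  for (rep in 1:25) {
    corp <- random_corpus(sample(3:8, 1))
    st <- random_state(corp, n_ops = sample(0:3, 1))
    expect_equal(grammar_cost(st$grammar), oracle_grammar_cost(st$grammar),
                 tolerance = 1e-9)
  }
})

test_that("derivation cost counts log2 |P(s)| per expansion, zero when unique", {
  g <- cfg(c("S -> A B", "S -> A C", "S -> B C", "S -> C C",
             "A -> a", "A -> x", "B -> b", "C -> c"))
  # choice points with |P| = 4 (S), 2 (A), 1 (B): cost 2 + 1 + 0
  tree <- derivation_tree("S", 1L, list(
    derivation_tree("A", 5L, list(derivation_tree("a"))),
    derivation_tree("B", 7L, list(derivation_tree("b")))
  ))
  expect_equal(derivation_cost(tree, g), 2 + 1 + 0)
  # uniquely expandable everywhere -> zero bits
  g1 <- cfg(c("S -> A B", "A -> a", "B -> b"))
  t1 <- derivation_tree("S", 1L, list(
    derivation_tree("A", 2L, list(derivation_tree("a"))),
    derivation_tree("B", 3L, list(derivation_tree("b")))
  ))
  expect_equal(derivation_cost(t1, g1), 0)
  # duplicates contribute once per occurrence
  expect_equal(corpus_derivation_cost(list(list(tree = tree, count = 2)), g),
               2 * derivation_cost(tree, g))
  # stale derivation: rule id absent
  t_bad <- derivation_tree("S", 99L, list(derivation_tree("A", 5L,
    list(derivation_tree("a"))), derivation_tree("B", 7L,
    list(derivation_tree("b")))))
  expect_error(derivation_cost(t_bad, g), "stale")
})

test_that("derivation cost is additive over corpus concatenation", {
  set.seed(42)
  corp <- random_corpus(8)
  st <- build_initial_grammar(corp)
  a <- st$trees[1:2]; b <- st$trees[-(1:2)]
  expect_equal(corpus_derivation_cost(c(a, b), st$grammar),
               corpus_derivation_cost(a, st$grammar) +
                 corpus_derivation_cost(b, st$grammar))
})

test_that("total cost weighs the components linearly in f", {
  set.seed(43)
  st <- build_initial_grammar(random_corpus(6))
  cg <- grammar_cost(st$grammar)
  cd <- corpus_derivation_cost(st$trees, st$grammar)
  expect_equal(total_cost(st$grammar, st$trees, cost_weights(1)), cg)
  expect_equal(total_cost(st$grammar, st$trees, cost_weights(0)), cd)
  expect_equal(total_cost(st$grammar, st$trees, cost_weights(0.5)),
               0.5 * (cg + cd))
  # C_G = 100, C_D = 40, f = 0.15 -> 49
  expect_equal(0.15 * 100 + (1 - 0.15) * 40, 49)
  f <- runif(5)
  vals <- vapply(f, function(x) {
    total_cost(st$grammar, st$trees, cost_weights(x))
  }, numeric(1))
  expect_equal(vals, f * cg + (1 - f) * cd, tolerance = 1e-12)
  expect_error(cost_weights(1.2), "in \\[0, 1\\]")
})

test_that("leftmost derivation steps replay to the sentence", {
  corp <- corpus(c("a b a", "c"))
  st <- build_initial_grammar(corp)
  for (e in st$trees) {
    steps <- derivation_steps(e$tree)
    expect_identical(steps$sym[1], "S")
    expect_identical(tree_yield(e$tree), e$sentence)
    expect_equal(nrow(steps), 1 + length(e$sentence))
  }
})
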