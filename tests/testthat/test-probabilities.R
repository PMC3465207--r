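test_that("uniform initialisation splits mass evenly per left-hand side", {
  g <- cfg(c("NP -> a", "NP -> b", "NP -> c", "NP -> d", "S -> NP"))
  p <- init_uniform(g)
  expect_equal(p$prob[g$lhs == "NP"], rep(0.25, 4))
  expect_equal(p$prob[g$lhs == "S"], 1.0)
  sums <- tapply(p$prob, g$lhs, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  # nonterminal with no production
  g2 <- cfg(c("S -> A B", "A -> a", "B -> b"))
  g2$lhs <- g2$lhs[-3]; g2$rhs <- g2$rhs[-3]; g2$id <- g2$id[-3]
  expect_error(init_uniform(g2), "malformed grammar")
})

test_that("one EM step counts best-parse usages as relative frequencies", {
  # S -> A A; A -> a | b. Corpus drives usage of A -> a to 3 of 4.
  g <- cfg(c("S -> A A", "A -> a", "A -> b"))
  p <- init_uniform(g)
  p1 <- em_step(p, corpus(c("a a", "a b")))
  expect_equal(p1$prob[2], 0.75)
  expect_equal(p1$prob[3], 0.25)
  expect_equal(p1$prob[1], 1.0)
  # unambiguous grammar: one step reaches a fixed point
  p2 <- em_step(p1, corpus(c("a a", "a b")))
  expect_equal(p2$prob, p1$prob)
  # unparsable corpus: degenerate estimation
  expect_error(em_step(p, corpus("a a a")), "degenerate")
})

test_that("fractional mode splits counts by normalised parse probability", {
  g <- cfg(c("S -> X b", "S -> a Y", "X -> a", "Y -> b"))
  p <- new_pcfg(g, c(0.6, 0.4, 1, 1))
  pv <- em_step(p, corpus("a b"), em_config(mode = "viterbi"))
  pf <- em_step(p, corpus("a b"), em_config(mode = "fractional"))
  # viterbi credits the best parse alone; fractional splits 0.6 / 0.4
  expect_equal(pv$prob[1:2], c(1, 0))
  expect_equal(pf$prob[1:2], c(0.6, 0.4))
})

test_that("a zero-count left-hand side keeps its previous distribution", {
  g <- cfg(c("S -> A", "S -> B", "A -> a", "B -> b", "B -> a"))
  p <- new_pcfg(g, c(0.9, 0.1, 1, 0.3, 0.7))
  p1 <- em_step(p, corpus("a"))
  # best parse uses S -> A, so B is never expanded; its distribution stays
  expect_equal(p1$prob[g$lhs == "B"], c(0.3, 0.7))
  expect_equal(p1$prob[g$lhs == "S"], c(1, 0))
})

test_that("estimate: iterations = 0 returns the uniform initialisation", {
  g <- cfg(c("S -> A A", "A -> a", "A -> b"))
  p <- estimate_pcfg(g, corpus(c("a b")), em_config(iterations = 0))
  expect_equal(p$prob, init_uniform(g)$prob)
  expect_equal(nrow(attr(p, "diagnostics")), 0)
})

test_that("hard EM keeps normalisation and never decreases the Viterbi log-likelihood", {
  set.seed(31)
  for (rep in 1:8) {
    corp <- random_corpus(sample(10:25, 1))
    fit <- induce_grammar(corp, induction_config(f = runif(1, 0.5, 0.95),
                                                 keep_derivations = FALSE))
    p <- estimate_pcfg(fit$grammar, corp, em_config(iterations = 4))
    sums <- tapply(p$prob, p$grammar$lhs, sum)
    expect_true(all(abs(sums - 1) < 1e-9))
    d <- attr(p, "diagnostics")
    expect_true(all(diff(d$loglik) >= -1e-9))
    # with alpha = 0, unused productions of counted LHS drop to zero
    cnt <- expansion_counts(p$grammar)
  }
})

test_that("additive smoothing keeps unused productions alive", {
  g <- cfg(c("S -> A A", "A -> a", "A -> b"))
  p <- init_uniform(g)
  ps <- em_step(p, corpus("a a"), em_config(smoothing_alpha = 1))
  expect_equal(ps$prob[2], (2 + 1) / (2 + 2))
  expect_equal(ps$prob[3], (0 + 1) / (2 + 2))
  p0 <- em_step(p, corpus("a a"), em_config(smoothing_alpha = 0))
  expect_equal(p0$prob[3], 0)
})
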