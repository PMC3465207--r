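test_that("viterbi parse maximises the product of production probabilities", {
  p <- init_uniform(cfg(c("S -> A A", "A -> a", "A -> b")))
  r <- viterbi_parse(p, "a b")
  expect_identical(r$status, "ok")
  expect_equal(r$prob, 0.25)
  expect_identical(tree_to_sexpr(r$tree), "(S (A a) (A b))")

  p2 <- new_pcfg(cfg(c("S -> X b", "S -> a Y", "X -> a", "Y -> b")),
                 c(0.4, 0.6, 1, 1))
  r2 <- viterbi_parse(p2, "a b")
  expect_equal(r2$prob, 0.6)
  expect_identical(tree_to_sexpr(r2$tree), "(S a (Y b))")

  expect_identical(viterbi_parse(p, "a z")$status, "unknown_token")
  expect_identical(viterbi_parse(p, "a a a")$status, "noparse")
  expect_error(viterbi_parse(p, character(0)), "empty")
})

test_that("enumeration oracle lists all distinct parse trees", {
  g <- cfg(c("S -> A", "A -> a"))
  expect_length(enumerate_parses(g, "a"), 1)
  g2 <- cfg(c("S -> X b", "S -> a Y", "X -> a", "Y -> b"))
  expect_length(enumerate_parses(g2, "a b"), 2)
  expect_length(enumerate_parses(g2, "b a"), 0)
  # parse trees validate and yield the sentence
  for (t in enumerate_parses(g2, "a b")) {
    clingram:::tree_validate(t, g2)
    expect_identical(tree_yield(t), c("a", "b"))
  }
})

test_that("viterbi agrees with the enumeration oracle on random grammars", {
  set.seed(23)
  checked <- 0L
  while (checked < 120L) {
    pc <- random_acyclic_pcfg()
    lang <- language_up_to(pc$grammar, 6)
    terms <- terminals(pc$grammar)
    # half in-language, half arbitrary strings
    sent <- if (checked %% 2 == 0 && length(lang)) {
      strsplit(sample(lang, 1), " ")[[1]]
    } else {
      sample(terms, sample(1:5, 1), replace = TRUE)
    }
    trees <- enumerate_parses(pc$grammar, sent, limit = 5000)
    r <- viterbi_parse(pc, sent)
    expect_identical(r$status == "ok", length(trees) > 0)
    if (length(trees)) {
      probs <- vapply(trees, function(t) tree_probability(pc, t), numeric(1))
      expect_equal(r$logprob, log(max(probs)), tolerance = 1e-9)
      # the viterbi probability dominates every enumerated parse
      expect_true(all(log(probs) <= r$logprob + 1e-9))
      # in-language check: the sentence really is derivable
      expect_identical(tree_yield(r$tree), sent)
    }
    checked <- checked + 1L
  }
})

test_that("first-parse mode reproduces the canonical enumeration order exactly", {
  set.seed(29)
  for (rep in 1:40) {
    pc <- random_acyclic_pcfg()
    lang <- language_up_to(pc$grammar, 6)
    if (!length(lang)) next
    sent <- strsplit(sample(lang, 1), " ")[[1]]
    first <- viterbi_parse(pc$grammar, sent, mode = "first")
    trees <- enumerate_parses(pc$grammar, sent, limit = 5000)
    expect_identical(tree_to_sexpr(first$tree), tree_to_sexpr(trees[[1]]))
  }
})

test_that("parsing is invariant to production file order up to the tie-break", {
  # same grammar, different creation order: probabilities decide, and only
  # genuine ties fall back to creation order
  pa <- new_pcfg(cfg(c("S -> X b", "S -> a Y", "X -> a", "Y -> b")),
                 c(0.4, 0.6, 1, 1))
  pb <- new_pcfg(cfg(c("S -> a Y", "S -> X b", "Y -> b", "X -> a")),
                 c(0.6, 0.4, 1, 1))
  ra <- viterbi_parse(pa, "a b"); rb <- viterbi_parse(pb, "a b")
  expect_identical(tree_to_sexpr(ra$tree), tree_to_sexpr(rb$tree))
  # exact tie: creation order decides, so the two orders differ
  pa2 <- new_pcfg(pa$grammar, c(0.5, 0.5, 1, 1))
  pb2 <- new_pcfg(pb$grammar, c(0.5, 0.5, 1, 1))
  expect_identical(tree_to_sexpr(viterbi_parse(pa2, "a b")$tree),
                   "(S (X a) b)")
  expect_identical(tree_to_sexpr(viterbi_parse(pb2, "a b")$tree),
                   "(S a (Y b))")
})

test_that("language enumeration is exact and refuses recursive grammars", {
  g <- cfg(c("S -> A", "A -> a"))
  expect_identical(language_up_to(g, 3), "a")
  g2 <- cfg(c("S -> A B", "S -> A C", "A -> a", "B -> b", "C -> c"))
  expect_setequal(language_up_to(g2, 6), c("a b", "a c"))
  gr <- cfg(c("S -> A", "A -> a S", "A -> a"))
  expect_true(grammar_is_cyclic(gr))
  expect_error(language_up_to(gr, 4), "recursive")
  expect_error(enumerate_parses(gr, "a a", limit = Inf), "finite limit")
  # with a finite limit recursive grammars still return parses
  got <- enumerate_parses(gr, c("a", "a"), limit = 10)
  expect_gte(length(got), 1)
})
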