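# Independent from-scratch oracles and random fixtures. These deliberately
# avoid the package's cached/incremental code paths: costs are recomputed
# by direct loops over productions and tree nodes.

oracle_grammar_cost <- function(g) {
  sig <- length(g$kind)
  total <- 0
  for (k in seq_along(g$lhs)) {
    total <- total + (1 + length(g$rhs[[k]])) * log2(sig)
  }
  total
}

oracle_lhs_count <- function(g, sym) {
  n <- 0L
  for (l in g$lhs) if (l == sym) n <- n + 1L
  n
}

oracle_tree_cost <- function(tree, g) {
  if (!length(tree$children)) return(0)
  cost <- log2(oracle_lhs_count(g, tree$sym))
  for (ch in tree$children) cost <- cost + oracle_tree_cost(ch, g)
  cost
}

oracle_corpus_cost <- function(trees, g) {
  total <- 0
  for (e in trees) total <- total + e$count * oracle_tree_cost(e$tree, g)
  total
}

oracle_total_cost <- function(state, f) {
  f * oracle_grammar_cost(state$grammar) +
    (1 - f) * oracle_corpus_cost(state$trees, state$grammar)
}

# Random duplicate-heavy corpus over a small tag alphabet.
random_corpus <- function(n_sentences, alphabet = letters[1:5],
                          max_len = 6, n_types = NULL) {
  if (is.null(n_types)) n_types <- max(2L, ceiling(n_sentences / 3))
  types <- replicate(n_types, {
    paste(sample(alphabet, sample(seq_len(max_len), 1), replace = TRUE),
          collapse = " ")
  })
  corpus(sample(types, n_sentences, replace = TRUE))
}

# Random induction state: initial grammar plus a few random legal operator
# applications (deltas need not be negative; validity is what matters).
random_state <- function(corp, n_ops = 2, config = induction_config(),
                         seedless = TRUE) {
  st <- build_initial_grammar(corp)
  for (i in seq_len(n_ops)) {
    cands <- c(
      lapply(enumerate_combine_candidates(st, config$max_n),
             function(x) x$instance),
      enumerate_merge_candidates(st)
    )
    cands <- Filter(function(inst) {
      !violates_constraints(st, inst, config)$violates
    }, cands)
    if (!length(cands)) break
    st <- apply_operator(st, cands[[sample.int(length(cands), 1)]])
  }
  st
}

# Random acyclic grammar with probabilities: preterminals over the
# alphabet, then layered nonterminals drawing only on strictly lower
# layers, so the grammar is productive and acyclic by construction.
random_acyclic_pcfg <- function(alphabet = letters[1:4], n_nt = 4,
                                max_rhs = 3, rules_per_nt = 2) {
  pre <- paste0("P", seq_along(alphabet))
  lhs <- pre
  rhs <- as.list(alphabet)
  lower <- pre
  nts <- paste0("N", seq_len(n_nt))
  for (k in seq_len(n_nt)) {
    for (r in seq_len(sample.int(rules_per_nt, 1) + 1L)) {
      len <- sample.int(max_rhs, 1)
      rhs[[length(rhs) + 1L]] <- sample(lower, len, replace = TRUE)
      lhs <- c(lhs, nts[k])
    }
    lower <- c(lower, nts[k])
  }
  # start expands the topmost nonterminal(s)
  lhs <- c(lhs, "S")
  rhs[[length(rhs) + 1L]] <- nts[n_nt]
  keys <- paste(lhs, vapply(rhs, paste, character(1), collapse = " "))
  keep <- !duplicated(keys)
  g <- new_grammar(start = "S", lhs = lhs[keep], rhs = rhs[keep])
  prob <- stats::ave(runif(length(g$lhs), 0.05, 1), g$lhs,
                     FUN = function(x) x / sum(x))
  new_pcfg(g, prob)
}

expect_state_consistent <- function(st) {
  validate_grammar(st$grammar)
  for (e in st$trees) {
    clingram:::tree_validate(e$tree, st$grammar)
    expect_identical(tree_yield(e$tree), e$sentence)
  }
  counts <- clingram:::state_counts_from_trees(st)
  expect_equal(counts$u[sort(names(counts$u))],
               st$u[sort(names(st$u))], tolerance = 1e-12)
  expect_equal(counts$usage[sort(names(counts$usage))],
               st$usage[sort(names(st$usage))], tolerance = 1e-12)
  expect_equal(st$T, clingram:::grammar_symbol_total(st$grammar))
}

withr_local_tempfile <- function() tempfile()

withr_local_tempdir <- function() {
  d <- tempfile()
  dir.create(d)
  d
}

# canonical comparator used to check viterbi tie-breaking against the
# enumeration order: maximum probability, first in canonical order.
best_enumerated <- function(pcfg, sentence, limit = 2000) {
  trees <- enumerate_parses(pcfg$grammar, sentence, limit = limit)
  if (!length(trees)) return(NULL)
  probs <- vapply(trees, function(t) tree_probability(pcfg, t), numeric(1))
  trees[[which.max(probs)]]  # which.max returns the first maximum
}
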