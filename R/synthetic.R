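#' Bundled reference PCFGs for synthetic corpora
#'
#' Stand-ins for restricted clinical corpora: fixed, versioned, acyclic
#' PCFGs over opaque tag alphabets. `"tiny"` is a three-nonterminal toy
#' whose language is enumerable at small lengths. `"clinical_like"` mimics
#' tagged clinical-report sentences: part-of-speech-like tags plus
#' semantic-class tags (finding, disease, bodypart, device, ...) arranged
#' into determiner + noun-group constructions, prepositional attachments,
#' conjunctions, measurements and auxiliary/participle verb groups.
#'
#' @param name `"tiny"` or `"clinical_like"`.
#' @return a `clg_pcfg` (acyclic; right-hand sides of length <= 4).
#' @export
reference_pcfg <- function(name = c("clinical_like", "tiny")) {
  name <- match.arg(name)
  if (name == "tiny") {
    g <- cfg(c(
      "S -> NP VP",
      "S -> NP",
      "NP -> det n",
      "NP -> n",
      "VP -> v",
      "VP -> v NP"
    ), start = "S")
    return(new_pcfg(g, c(0.7, 0.3, 0.5, 0.5, 0.6, 0.4)))
  }
  rules <- c(
    "S -> NP VP",          # 0.40
    "S -> NP VP PP",       # 0.13
    "S -> NP",             # 0.12
    "S -> NP VP adv",      # 0.10
    "S -> NP MEAS adv",    # 0.08
    "S -> vbn PP",         # 0.06
    "S -> adv NP VP",      # 0.06
    "S -> pron VP",        # 0.05
    "NP -> NG",            # 0.44
    "NP -> NG PP",         # 0.32
    "NP -> NG conj NG",    # 0.24
    "NG -> NHEAD",         # 0.22
    "NG -> det NHEAD",     # 0.30
    "NG -> det adj NHEAD", # 0.16
    "NG -> adj NHEAD",     # 0.10
    "NG -> num NHEAD",     # 0.08
    "NG -> NHEAD NHEAD",   # 0.14
    "PP -> prep NG",       # 1.00
    "MEAS -> num unit",    # 1.00
    "VP -> verb NP",       # 0.26
    "VP -> verb NP PP",    # 0.14
    "VP -> aux vbn",       # 0.16
    "VP -> verb",          # 0.10
    "VP -> aux vbn PP",    # 0.14
    "VP -> verb adv",      # 0.10
    "VP -> aux neg vbn",   # 0.10
    "NHEAD -> noun",       # 0.30
    "NHEAD -> finding",    # 0.14
    "NHEAD -> disease",    # 0.13
    "NHEAD -> bodypart",   # 0.11
    "NHEAD -> medication", # 0.10
    "NHEAD -> device",     # 0.08
    "NHEAD -> procedure",  # 0.08
    "NHEAD -> symptom"     # 0.06
  )
  prob <- c(0.40, 0.13, 0.12, 0.10, 0.08, 0.06, 0.06, 0.05,
            0.44, 0.32, 0.24,
            0.22, 0.30, 0.16, 0.10, 0.08, 0.14,
            1.00, 1.00,
            0.26, 0.14, 0.16, 0.10, 0.14, 0.10, 0.10,
            0.30, 0.14, 0.13, 0.11, 0.10, 0.08, 0.08, 0.06)
  new_pcfg(cfg(rules, start = "S"), prob)
}

# Sample one derivation tree from a pcfg, top down.
sample_tree <- function(pcfg, depth_cap = 200L) {
  g <- pcfg$grammar
  rules_of <- split(seq_along(g$lhs), g$lhs)
  rec <- function(sym, depth) {
    if (depth > depth_cap) stop("profile error: sampling depth exceeded")
    if (g$kind[sym] == "terminal") return(derivation_tree(sym))
    idx <- rules_of[[sym]]
    r <- if (length(idx) == 1) idx else
      sample(idx, 1L, prob = pcfg$prob[idx])
    kids <- lapply(g$rhs[[r]], rec, depth = depth + 1L)
    derivation_tree(sym, g$id[r], kids)
  }
  rec(g$start, 1L)
}

#' A synthetic-corpus profile
#'
#' Describes the world a synthetic corpus is drawn from: a reference PCFG,
#' a sentence-length cap enforced by rejection (truncation would break
#' gold trees), a pool of unique sentence types reused with Zipfian
#' weights (clinical reports repeat many sentences verbatim), and a seed.
#'
#' @param name bundled profile name, see [reference_pcfg()].
#' @param n_train,n_test number of training / test sentence occurrences.
#' @param max_len maximum sentence length in tokens (default 10; most
#'   clinical-report sentences are short).
#' @param zipf_s Zipf exponent for sentence-type reuse (0 = all types
#'   equally likely; 1 = strong duplication, the default).
#' @param pool_size number of sentence-type draws forming the reuse pool;
#'   defaults to 1.25 times the requested occurrences (at least 40), which
#'   together with `zipf_s = 1` reproduces the 60-80% test/train sentence
#'   overlap typical of discharge-summary corpora.
#' @param seed RNG seed; all sampling is reproducible from it.
#' @param max_tries rejection-sampling cap per pool slot.
#' @return a `clg_profile`.
#' @export
corpus_profile <- function(name = "clinical_like", n_train = 500L,
                           n_test = 100L, max_len = 10L, zipf_s = 1.0,
                           pool_size = NULL, seed = 1L,
                           max_tries = 10000L) {
  if (is.null(pool_size)) {
    pool_size <- max(40L, as.integer(round(1.25 * (n_train + n_test))))
  }
  structure(list(name = name, pcfg = reference_pcfg(name),
                 n_train = as.integer(n_train), n_test = as.integer(n_test),
                 max_len = as.integer(max_len), zipf_s = zipf_s,
                 pool_size = as.integer(pool_size), seed = as.integer(seed),
                 max_tries = as.integer(max_tries)),
            class = "clg_profile")
}

# Rejection-sample a tree whose yield respects max_len.
sample_tree_capped <- function(pcfg, max_len, max_tries) {
  for (t in seq_len(max_tries)) {
    tree <- sample_tree(pcfg)
    if (length(tree_yield(tree)) <= max_len) return(tree)
  }
  stop("profile error: rejection cap exceeded (max_len too small?)")
}

#' Sample a synthetic train/test corpus with gold trees
#'
#' Draws a pool of sentence types from the profile's reference PCFG
#' (rejection-sampled to the length cap), assigns Zipfian reuse weights by
#' draw order, then samples train and test sentence occurrences from the
#' pool. The split is by occurrence, so test sentences may duplicate
#' training ones — as in real clinical corpora. Gold trees (and bracket
#' sets) are returned for every test sentence.
#'
#' With `zipf_s = 0` the pool is bypassed and every occurrence is an
#' independent draw from the PCFG.
#'
#' @param profile a [corpus_profile()].
#' @return a list with `train` and `test` (`clg_corpus`), `train_trees`
#'   (gold trees of the training occurrences), `gold_trees` and
#'   `gold_brackets` (parallel to `test`), `train_overlap` (fraction of
#'   test occurrences whose string also occurs in training), and `profile`.
#' @export
sample_corpus <- function(profile) {
  stopifnot(inherits(profile, "clg_profile"))
  with_seed(profile$seed, {
    n <- profile$n_train + profile$n_test
    if (profile$zipf_s == 0) {
      # duplication off: every occurrence is an independent draw
      draw_trees <- lapply(seq_len(n), function(i) {
        sample_tree_capped(profile$pcfg, profile$max_len, profile$max_tries)
      })
      draw_strs <- vapply(draw_trees, function(t) {
        paste(tree_yield(t), collapse = " ")
      }, character(1))
    } else {
      pool <- lapply(seq_len(profile$pool_size), function(i) {
        sample_tree_capped(profile$pcfg, profile$max_len, profile$max_tries)
      })
      strs <- vapply(pool, function(t) paste(tree_yield(t), collapse = " "),
                     character(1))
      first <- !duplicated(strs)
      types <- pool[first]
      tstr <- strs[first]
      K <- length(types)
      w <- (seq_len(K))^(-profile$zipf_s)
      w <- w / sum(w)
      draw <- sample.int(K, n, replace = TRUE, prob = w)
      draw_trees <- types[draw]
      draw_strs <- tstr[draw]
    }
    tr <- seq_len(profile$n_train)
    te <- profile$n_train + seq_len(profile$n_test)
    gold_trees <- draw_trees[te]
    list(train = corpus(draw_strs[tr]), test = corpus(draw_strs[te]),
         train_trees = draw_trees[tr],
         gold_trees = gold_trees,
         gold_brackets = lapply(gold_trees, extract_brackets),
         train_overlap = mean(draw_strs[te] %in% draw_strs[tr]),
         profile = profile)
  })
}
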