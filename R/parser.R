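#' Probabilistic parsing of tag sentences
#'
#' Grammars are parsed as induced, without binarisation: the chart parser
#' handles right-hand sides of arbitrary length directly. The Viterbi parse
#' maximises the product of production probabilities; ties are broken
#' deterministically by preferring the production with the lowest creation
#' order at the topmost decision, then recursively on children left to
#' right, with earlier split points preferred.
#'
#' @name parsing
NULL

# Integer-code a grammar (or pcfg) for the C++ kernels. Rules are sorted by
# creation id so that rule order in C++ is creation order (the tie-break).
code_grammar <- function(g, prob = NULL) {
  nts <- nonterminals(g)
  terms <- terminals(g)
  sym_id <- setNames(seq_along(c(nts, terms)), c(nts, terms))
  ord <- order(g$id)
  r_rhs <- lapply(g$rhs[ord], function(r) unname(sym_id[r]))
  logp <- if (is.null(prob)) rep(0, length(ord)) else log(prob[ord])
  list(
    n_nt = length(nts),
    sym_id = sym_id,
    start = unname(sym_id[g$start]),
    r_lhs = unname(sym_id[g$lhs[ord]]),
    r_rhs = r_rhs,
    r_logp = logp,
    ord = ord,                # position in g vectors per coded rule
    ids = g$id[ord],          # creation id per coded rule
    lhs = g$lhs[ord],
    rhs = g$rhs[ord]
  )
}

code_sentence <- function(coded, sentence) {
  ids <- coded$sym_id[sentence]
  if (anyNA(ids) || any(ids <= coded$n_nt)) return(NULL)
  as.integer(unname(ids))
}

# Rebuild a derivation tree from the preorder (rule, i, j) output of
# cpp_parse. Terminal children are implied by the rule right-hand sides.
decode_tree <- function(coded, res) {
  ptr <- 0L
  rec <- function() {
    ptr <<- ptr + 1L
    r <- res$rule[ptr]
    rhs <- coded$rhs[[r]]
    kids <- vector("list", length(rhs))
    for (d in seq_along(rhs)) {
      sym <- rhs[d]
      sid <- coded$sym_id[sym]
      if (sid > coded$n_nt) {
        kids[[d]] <- derivation_tree(sym)
      } else {
        kids[[d]] <- rec()
      }
    }
    derivation_tree(coded$lhs[r], coded$ids[r], kids)
  }
  rec()
}

#' Viterbi (maximum-probability) parse of a sentence
#'
#' @param x a `clg_pcfg`, or a bare `clg_grammar` (then all productions are
#'   treated as equally weighted and the deterministic first parse is
#'   returned, the "no probabilities" baseline).
#' @param sentence a character vector of tags, or a single string split on
#'   whitespace.
#' @param mode `"viterbi"` (use probabilities) or `"first"` (ignore
#'   probabilities; return the first parse under the tie-break order).
#' @return a list with `status` (`"ok"`, `"noparse"` or `"unknown_token"`),
#'   and for `"ok"` also `tree`, `prob` and `logprob`.
#' @examples
#' g <- cfg(c("S -> A A", "A -> a", "A -> b"))
#' p <- init_uniform(g)
#' viterbi_parse(p, "a b")$prob  # 0.25
#' @export
viterbi_parse <- function(x, sentence, mode = c("viterbi", "first")) {
  mode <- match.arg(mode)
  if (inherits(x, "clg_grammar")) {
    g <- x
    prob <- NULL
    mode <- "first"
  } else {
    stopifnot(inherits(x, "clg_pcfg"))
    g <- x$grammar
    prob <- if (mode == "viterbi") x$prob else NULL
  }
  if (is.character(sentence) && length(sentence) == 1 &&
      grepl("[[:space:]]", sentence)) {
    sentence <- strsplit(trimws(sentence), "[[:space:]]+")[[1]]
  }
  if (!length(sentence)) stop("input error: empty sentence")
  coded <- code_grammar(g, prob)
  parse_coded(coded, sentence)
}

parse_coded <- function(coded, sentence) {
  sent <- code_sentence(coded, sentence)
  if (is.null(sent)) {
    bad <- sentence[!(sentence %in% names(coded$sym_id)) |
                      coded$sym_id[sentence] <= coded$n_nt]
    return(list(status = "unknown_token",
                reason = paste("unknown token:",
                               paste(unique(bad), collapse = " "))))
  }
  res <- cpp_parse(coded$n_nt, coded$r_lhs, coded$r_rhs, coded$r_logp,
                   coded$start, sent)
  if (!isTRUE(res$ok)) return(list(status = "noparse", reason = "no parse"))
  list(status = "ok",
       tree = decode_tree(coded, res),
       logprob = res$logprob,
       prob = exp(res$logprob),
       rules = coded$ids[res$rule])
}

# Batch parse: code the grammar once, parse a list of sentences.
# Returns a list of parse results as in viterbi_parse().
parse_corpus <- function(x, sentences, mode = c("viterbi", "first"),
                         decode = TRUE) {
  mode <- match.arg(mode)
  if (inherits(x, "clg_grammar")) {
    coded <- code_grammar(x, NULL)
  } else {
    coded <- code_grammar(x$grammar, if (mode == "viterbi") x$prob else NULL)
  }
  if (is.character(sentences)) sentences <- corpus(sentences)
  out <- vector("list", length(sentences))
  codes <- lapply(sentences, function(s) code_sentence(coded, s))
  ok <- !vapply(codes, is.null, logical(1))
  if (any(ok)) {
    res <- cpp_parse_batch(coded$n_nt, coded$r_lhs, coded$r_rhs,
                           coded$r_logp, coded$start, codes[ok])
    idx <- which(ok)
    for (k in seq_along(idx)) {
      r <- res[[k]]
      out[[idx[k]]] <- if (!isTRUE(r$ok)) {
        list(status = "noparse", reason = "no parse")
      } else {
        list(status = "ok",
             tree = if (decode) decode_tree(coded, r) else NULL,
             logprob = r$logprob, prob = exp(r$logprob),
             rules = coded$ids[r$rule])
      }
    }
  }
  for (k in which(!ok)) {
    out[[k]] <- list(status = "unknown_token", reason = "unknown token")
  }
  out
}

# ---- enumeration oracles ----------------------------------------------

# Does any nonterminal derive itself (directly or indirectly)?
#' @export
grammar_is_cyclic <- function(g) {
  has_cycle_rules(g$lhs, g$rhs, nonterminals(g))
}

has_cycle_rules <- function(lhs, rhs, nts) {
  adj <- lapply(setNames(nm = nts), function(s) character(0))
  for (k in seq_along(lhs)) {
    kids <- intersect(unique(rhs[[k]]), nts)
    adj[[lhs[k]]] <- union(adj[[lhs[k]]], kids)
  }
  color <- setNames(rep(0L, length(nts)), nts)  # 0 new, 1 open, 2 done
  found <- FALSE
  visit <- function(s) {
    if (found || color[s] == 2L) return(invisible())
    if (color[s] == 1L) { found <<- TRUE; return(invisible()) }
    color[s] <<- 1L
    for (t in adj[[s]]) {
      if (color[t] == 1L) { found <<- TRUE; break }
      if (color[t] == 0L) visit(t)
      if (found) break
    }
    color[s] <<- 2L
  }
  for (s in nts) { if (!found) visit(s) }
  found
}

#' Enumerate all parse trees of a sentence
#'
#' Test oracle. Trees are generated in a canonical order: productions in
#' creation order, split points ascending, with earlier children varying
#' more slowly — so the first tree is the deterministic "first parse" and
#' the maximum-probability tree in this order equals the Viterbi parse.
#'
#' @param g a `clg_grammar` (a `clg_pcfg` is accepted; its grammar is used).
#' @param sentence character vector of tags (or a single string).
#' @param limit maximum number of trees per chart cell; if exceeded the
#'   result carries attribute `truncated = TRUE`.
#' @return list of parse trees (possibly empty).
#' @export
enumerate_parses <- function(g, sentence, limit = 1000L) {
  if (inherits(g, "clg_pcfg")) g <- g$grammar
  stopifnot(inherits(g, "clg_grammar"))
  if (is.character(sentence) && length(sentence) == 1 &&
      grepl("[[:space:]]", sentence)) {
    sentence <- strsplit(trimws(sentence), "[[:space:]]+")[[1]]
  }
  if (!length(sentence)) stop("input error: empty sentence")
  cyclic <- grammar_is_cyclic(g)
  if (cyclic && !is.finite(limit)) {
    stop("recursive grammar: a finite limit is required")
  }
  n <- length(sentence)
  ord <- order(g$id)
  lhs <- g$lhs[ord]; rhs <- g$rhs[ord]; ids <- g$id[ord]
  rules_of <- split(seq_along(lhs), lhs)
  memo <- new.env(parent = emptyenv())
  open <- new.env(parent = emptyenv())
  truncated <- FALSE
  is_term <- g$kind == "terminal"

  cell <- function(sym, i, j) {  # spans 0-based half-open
    key <- paste(sym, i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    if (!is.null(open[[key]])) { truncated <<- truncated || cyclic; return(list()) }
    open[[key]] <- TRUE
    out <- list()
    for (r in rules_of[[sym]]) {
      R <- rhs[[r]]
      if (length(R) > j - i) next
      # children sequences covering tokens i..j with symbols R
      seqs <- tile(R, 1L, i, j)
      for (kids in seqs) {
        if (length(out) >= limit) { truncated <<- TRUE; break }
        out[[length(out) + 1L]] <- derivation_tree(sym, ids[r], kids)
      }
      if (length(out) >= limit) break
    }
    rm(list = key, envir = open)
    memo[[key]] <- out
    out
  }
  tile <- function(R, d, p, j) {
    if (d > length(R)) {
      return(if (p == j) list(list()) else list())
    }
    sym <- R[d]
    out <- list()
    if (is_term[sym]) {
      if (p < j && sentence[p + 1] == sym) {
        rest <- tile(R, d + 1L, p + 1L, j)
        for (tail in rest) {
          out[[length(out) + 1L]] <- c(list(derivation_tree(sym)), tail)
        }
      }
      return(out)
    }
    for (q in seq_len(j - p) + p) {
      subtrees <- cell(sym, p, q)
      if (!length(subtrees)) next
      rest <- tile(R, d + 1L, q, j)
      if (!length(rest)) next
      for (st in subtrees) {
        for (tail in rest) {
          if (length(out) >= limit) { truncated <<- TRUE; return(out) }
          out[[length(out) + 1L]] <- c(list(st), tail)
        }
      }
    }
    out
  }
  res <- cell(g$start, 0L, n)
  attr(res, "truncated") <- truncated
  res
}

#' Probability of a parse tree under a PCFG
#' @param pcfg a `clg_pcfg`.
#' @param tree a derivation tree with rule ids from `pcfg$grammar`.
#' @return product of used production probabilities.
#' @export
tree_probability <- function(pcfg, tree) {
  stopifnot(inherits(pcfg, "clg_pcfg"))
  pos <- setNames(seq_along(pcfg$grammar$id), pcfg$grammar$id)
  steps <- derivation_steps(tree)
  prod(pcfg$prob[pos[as.character(steps$rule)]])
}

#' Exact language of a grammar up to a length bound
#'
#' Memoised bottom-up expansion; refuses recursive grammars (their language
#' is potentially infinite at every length once unit cycles exist).
#'
#' @param g a `clg_grammar` (or `clg_pcfg`).
#' @param max_len maximum string length (in tokens).
#' @return sorted character vector of derivable strings (tokens joined by
#'   single spaces).
#' @export
language_up_to <- function(g, max_len) {
  if (inherits(g, "clg_pcfg")) g <- g$grammar
  stopifnot(inherits(g, "clg_grammar"), max_len >= 1)
  if (grammar_is_cyclic(g)) {
    stop("recursive grammar: language enumeration refused")
  }
  rules_of <- split(seq_along(g$lhs), g$lhs)
  memo <- new.env(parent = emptyenv())
  strings <- function(sym) {
    if (g$kind[sym] == "terminal") return(sym)
    if (!is.null(memo[[sym]])) return(memo[[sym]])
    token_count <- function(x) lengths(strsplit(x, " ", fixed = TRUE))
    out <- character(0)
    for (r in rules_of[[sym]]) {
      parts <- lapply(g$rhs[[r]], strings)
      cur <- ""
      for (p in parts) {
        if (!length(p) || !length(cur)) { cur <- character(0); break }
        comb <- as.vector(t(outer(cur, p, paste)))
        comb <- unique(trimws(comb))
        cur <- comb[token_count(comb) <= max_len]
      }
      out <- union(out, cur)
    }
    memo[[sym]] <- out
    out
  }
  sort(strings(g$start))
}
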