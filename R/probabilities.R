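#' Probabilistic context-free grammars
#'
#' A `clg_pcfg` pairs a grammar with one probability per production,
#' normalised per left-hand side.
#'
#' @param g a `clg_grammar`.
#' @param prob numeric vector parallel to the grammar's productions.
#' @param validate check per-LHS normalisation (tolerance 1e-9).
#' @return a `clg_pcfg`.
#' @export
new_pcfg <- function(g, prob, validate = TRUE) {
  stopifnot(inherits(g, "clg_grammar"), length(prob) == length(g$lhs))
  prob <- as.numeric(prob)
  if (validate) {
    if (any(is.na(prob)) || any(prob < -1e-12) || any(prob > 1 + 1e-12)) {
      stop("probabilities must lie in [0, 1]")
    }
    sums <- tapply(prob, g$lhs, sum)
    if (any(abs(sums - 1) > 1e-9)) {
      stop("probabilities must sum to 1 per left-hand side")
    }
  }
  structure(list(grammar = g, prob = prob), class = "clg_pcfg")
}

#' @export
print.clg_pcfg <- function(x, ...) {
  cat("<clg_pcfg>\n")
  print(x$grammar)
  invisible(x)
}

#' EM configuration for production-probability estimation
#'
#' @param iterations number of EM iterations (default 5, within which the
#'   procedure converges in practice; 0 returns the uniform initialisation).
#' @param mode `"viterbi"` (hard EM: count only each sentence's best parse)
#'   or `"fractional"` (count all parses, weighted by their normalised
#'   probabilities).
#' @param smoothing_alpha additive smoothing count (default 0: the raw
#'   usage fraction is the probability).
#' @param max_parses enumeration cap per sentence in fractional mode.
#' @return a `clg_emconfig`.
#' @export
em_config <- function(iterations = 5L, mode = c("viterbi", "fractional"),
                      smoothing_alpha = 0, max_parses = 500L) {
  mode <- match.arg(mode)
  stopifnot(iterations >= 0, smoothing_alpha >= 0)
  structure(list(iterations = as.integer(iterations), mode = mode,
                 smoothing_alpha = smoothing_alpha,
                 max_parses = as.integer(max_parses)),
            class = "clg_emconfig")
}

#' Uniform probability initialisation
#'
#' Each production of a nonterminal with `k` expansions gets probability
#' `1/k`.
#'
#' @param g a `clg_grammar`.
#' @return a `clg_pcfg`.
#' @export
init_uniform <- function(g) {
  stopifnot(inherits(g, "clg_grammar"))
  cnt <- expansion_counts(g)
  if (any(cnt == 0)) {
    stop("malformed grammar: nonterminal without productions: ",
         paste(names(cnt)[cnt == 0], collapse = ", "))
  }
  new_pcfg(g, 1 / cnt[g$lhs])
}

# Usage counts per production (by position) for one corpus pass.
em_counts <- function(pcfg, uniq, weights, config) {
  g <- pcfg$grammar
  pos_by_id <- setNames(seq_along(g$id), g$id)
  counts <- numeric(length(g$id))
  loglik <- 0
  parsed <- 0
  if (config$mode == "viterbi") {
    res <- parse_corpus(pcfg, uniq, mode = "viterbi", decode = FALSE)
    for (k in seq_along(uniq)) {
      r <- res[[k]]
      if (!identical(r$status, "ok")) next
      w <- weights[k]
      tab <- table(r$rules)
      p <- pos_by_id[names(tab)]
      counts[p] <- counts[p] + w * as.numeric(tab)
      loglik <- loglik + w * r$logprob
      parsed <- parsed + w
    }
  } else {
    for (k in seq_along(uniq)) {
      trees <- enumerate_parses(g, uniq[[k]], limit = config$max_parses)
      if (!length(trees)) next
      w <- weights[k]
      probs <- vapply(trees, function(t) tree_probability(pcfg, t),
                      numeric(1))
      if (sum(probs) <= 0) next
      frac <- probs / sum(probs)
      for (t in seq_along(trees)) {
        if (frac[t] == 0) next
        steps <- derivation_steps(trees[[t]])
        tab <- table(steps$rule)
        p <- pos_by_id[names(tab)]
        counts[p] <- counts[p] + w * frac[t] * as.numeric(tab)
      }
      loglik <- loglik + w * log(max(probs))
      parsed <- parsed + w
    }
  }
  list(counts = counts, loglik = loglik, parsed = parsed)
}

#' One EM iteration
#'
#' Parses every corpus sentence (duplicates weighted by multiplicity),
#' counts production usages in the best parse (or fractionally over all
#' parses), and re-normalises per left-hand side:
#' `prob = (usage + alpha) / (lhs_total + alpha * k)`. Unparsable sentences
#' contribute nothing; a left-hand side with zero total count keeps its
#' previous distribution.
#'
#' @param pcfg a normalised `clg_pcfg`.
#' @param corp the training corpus.
#' @param config an [em_config()].
#' @return the re-estimated `clg_pcfg`, with attribute `"info"` carrying
#'   the pass's Viterbi log-likelihood and parsed-sentence count.
#' @export
em_step <- function(pcfg, corp, config = em_config()) {
  corp <- corpus(unclass(corp))
  strs <- sentence_strings(corp)
  first <- !duplicated(strs)
  uniq <- corp[first]
  weights <- as.numeric(tabulate(match(strs, strs[first]),
                                 nbins = sum(first)))
  pass <- em_counts(pcfg, uniq, weights, config)
  if (pass$parsed == 0) {
    stop("estimation degenerate: no corpus sentence is parsable")
  }
  g <- pcfg$grammar
  a <- config$smoothing_alpha
  prob <- pcfg$prob
  for (s in unique(g$lhs)) {
    idx <- which(g$lhs == s)
    tot <- sum(pass$counts[idx])
    if (tot + a * length(idx) > 0) {
      prob[idx] <- (pass$counts[idx] + a) / (tot + a * length(idx))
    }  # zero-count LHS keeps its previous distribution
  }
  out <- new_pcfg(g, prob)
  attr(out, "info") <- list(loglik = pass$loglik, parsed = pass$parsed)
  out
}

#' Estimate production probabilities from an unannotated corpus
#'
#' Uniform initialisation followed by `iterations` EM passes.
#'
#' @param g a `clg_grammar` (or an induction result; its grammar is used).
#' @param corp the training corpus.
#' @param config an [em_config()].
#' @return a `clg_pcfg` with attribute `"diagnostics"`: a data.frame with
#'   one row per iteration (Viterbi log-likelihood under the entering
#'   probabilities, maximum absolute probability change, and the
#'   duplicate-weighted number of parsed sentences).
#' @export
estimate_pcfg <- function(g, corp, config = em_config()) {
  if (inherits(g, "clg_induction")) g <- g$grammar
  pcfg <- init_uniform(g)
  diag <- data.frame(iteration = integer(0), loglik = numeric(0),
                     max_delta = numeric(0), parsed = numeric(0))
  for (it in seq_len(config$iterations)) {
    nxt <- em_step(pcfg, corp, config)
    info <- attr(nxt, "info")
    diag <- rbind(diag, data.frame(
      iteration = it, loglik = info$loglik,
      max_delta = max(abs(nxt$prob - pcfg$prob)), parsed = info$parsed))
    pcfg <- nxt
  }
  attr(pcfg, "diagnostics") <- diag
  pcfg
}
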