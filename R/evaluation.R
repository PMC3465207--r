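#' Unlabeled bracket sets
#'
#' A bracket set is the set of constituent spans of a parse, 0-based
#' half-open, with width-1 spans and the full-sentence span excluded at
#' construction (they are trivially correct and not scored). Labels are
#' discarded: an induced grammar can only produce system-generated labels.
#'
#' @param spans a 2-column matrix (start, end) of candidate spans.
#' @param sentence_length sentence length in tokens.
#' @return an object of class `clg_brackets`: a list with
#'   `sentence_length` and `spans` (deduplicated matrix).
#' @export
bracket_set <- function(spans, sentence_length) {
  if (is.null(spans) || !length(spans)) {
    spans <- matrix(integer(0), ncol = 2)
  }
  spans <- matrix(as.integer(spans), ncol = 2)
  if (any(spans[, 1] < 0) || any(spans[, 2] > sentence_length) ||
      any(spans[, 1] >= spans[, 2])) {
    stop("invalid span: need 0 <= start < end <= sentence_length")
  }
  keep <- (spans[, 2] - spans[, 1] > 1L) &
    !(spans[, 1] == 0L & spans[, 2] == sentence_length)
  spans <- spans[keep, , drop = FALSE]
  spans <- unique(spans)
  structure(list(sentence_length = as.integer(sentence_length),
                 spans = spans), class = "clg_brackets")
}

span_keys <- function(b) {
  if (!nrow(b$spans)) return(character(0))
  paste(b$spans[, 1], b$spans[, 2])
}

#' Extract the unlabeled bracket set of a parse tree
#' @param tree a parse/derivation tree.
#' @return a [bracket_set()] over the tree's yield.
#' @export
extract_brackets <- function(tree) {
  n <- length(tree_yield(tree))
  bracket_set(tree_internal_spans(tree), n)
}

#' Bracketing precision, recall and F-measure
#'
#' `precision = |gold intersect pred| / |pred|` (1 when the prediction is
#' empty), `recall = |gold intersect pred| / |gold|` (1 when the gold set
#' is empty), `f` their harmonic mean (0 when both are 0).
#'
#' @param gold,predicted [bracket_set()] objects over the same sentence.
#' @return named numeric vector `(precision, recall, f)`.
#' @export
bracket_prf <- function(gold, predicted) {
  stopifnot(inherits(gold, "clg_brackets"), inherits(predicted, "clg_brackets"))
  if (gold$sentence_length != predicted$sentence_length) {
    stop("input error: bracket sets over different sentence lengths")
  }
  inter <- length(intersect(span_keys(gold), span_keys(predicted)))
  p <- if (nrow(predicted$spans)) inter / nrow(predicted$spans) else 1
  r <- if (nrow(gold$spans)) inter / nrow(gold$spans) else 1
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, f = f)
}

harmonic_f <- function(p, r) if (p + r > 0) 2 * p * r / (p + r) else 0

#' Parse and score a test set
#'
#' Parses every sentence, micro-averages bracketing precision/recall/F over
#' the sentences with gold bracketings (summing intersection and set sizes
#' across the corpus), and reports the novel-sentence parse rate, where a
#' sentence is novel iff it is not string-identical to any training
#' sentence.
#'
#' @param x a `clg_pcfg` or `clg_grammar`.
#' @param sentences test corpus (`clg_corpus` or character vector).
#' @param gold optional list parallel to `sentences`: each element `NULL`,
#'   a [bracket_set()], or a gold tree (converted via
#'   [extract_brackets()]).
#' @param train_sentences optional training corpus, used only to flag
#'   novelty.
#' @param mode `"viterbi"` or `"first"` (no probabilities).
#' @param skip_unparsed if `TRUE`, unparsed sentences are dropped from the
#'   micro-average instead of contributing empty predictions (which cost
#'   recall but not precision).
#' @return an object of class `clg_eval`: a list with `precision`,
#'   `recall`, `f_measure`, `parsed_count`, `noparse_count`,
#'   `novel_parse_rate` (NA when there are no novel sentences), and the
#'   per-sentence parse results.
#' @export
evaluate_parses <- function(x, sentences, gold = NULL,
                            train_sentences = NULL,
                            mode = c("viterbi", "first"),
                            skip_unparsed = FALSE) {
  mode <- match.arg(mode)
  sentences <- corpus(unclass(sentences))
  res <- parse_corpus(x, sentences, mode = mode)
  ok <- vapply(res, function(r) identical(r$status, "ok"), logical(1))

  novel_rate <- NA_real_
  if (!is.null(train_sentences)) {
    train_strs <- unique(sentence_strings(corpus(unclass(train_sentences))))
    novel <- !(sentence_strings(sentences) %in% train_strs)
    if (any(novel)) novel_rate <- mean(ok[novel])
  }

  inter <- pred_n <- gold_n <- 0
  if (!is.null(gold)) {
    stopifnot(length(gold) == length(sentences))
    for (k in seq_along(sentences)) {
      gk <- gold[[k]]
      if (is.null(gk)) next
      if (!inherits(gk, "clg_brackets")) gk <- extract_brackets(gk)
      if (!ok[k] && skip_unparsed) next
      pk <- if (ok[k]) extract_brackets(res[[k]]$tree) else
        bracket_set(NULL, length(sentences[[k]]))
      if (gk$sentence_length != pk$sentence_length) {
        stop("input error: gold brackets do not match sentence length at ", k)
      }
      inter <- inter + length(intersect(span_keys(gk), span_keys(pk)))
      pred_n <- pred_n + nrow(pk$spans)
      gold_n <- gold_n + nrow(gk$spans)
    }
  }
  p <- if (pred_n > 0) inter / pred_n else 1
  r <- if (gold_n > 0) inter / gold_n else 1
  structure(list(precision = p, recall = r, f_measure = harmonic_f(p, r),
                 parsed_count = sum(ok), noparse_count = sum(!ok),
                 novel_parse_rate = novel_rate, results = res),
            class = "clg_eval")
}

#' @export
print.clg_eval <- function(x, ...) {
  cat(sprintf(
    "<clg_eval> P=%.3f R=%.3f F=%.3f | parsed=%d noparse=%d | novel parse rate=%s\n",
    x$precision, x$recall, x$f_measure, x$parsed_count, x$noparse_count,
    if (is.na(x$novel_parse_rate)) "NA" else
      sprintf("%.3f", x$novel_parse_rate)))
  invisible(x)
}

#' Read gold bracketings from a tree file
#'
#' One bracketed s-expression per line; labels are ignored.
#' @param path file of s-expressions.
#' @return list of [bracket_set()] objects (NULL for NOPARSE lines).
#' @export
read_gold_brackets <- function(path) {
  lapply(read_trees(path), function(t) {
    if (is.null(t)) NULL else extract_brackets(t)
  })
}
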