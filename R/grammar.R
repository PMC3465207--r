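#' Context-free grammars over tag alphabets
#'
#' A grammar is stored as a start symbol, a symbol inventory (terminals and
#' nonterminals, each with a provenance tag), and an ordered set of
#' productions `lhs -> rhs`. Creation order of productions is retained and
#' used for deterministic tie-breaking everywhere (parsing, deduplication).
#'
#' @param rules a character vector of rules like `"S -> NP VP"`, or a list of
#'   `list(lhs =, rhs =)` pairs.
#' @param start name of the start symbol (must be a nonterminal).
#' @param origin optional named character vector giving the provenance of
#'   symbols; recognised values are `"start"`, `"preterminal"`, `"sentence"`,
#'   `"combined"`, `"merged"`, `"terminal"` and `"user"`. Symbols not named
#'   get `"user"` (nonterminals) or `"terminal"` (terminals).
#' @return an object of class `clg_grammar`.
#' @examples
#' g <- cfg(c("S -> A B", "S -> A C", "A -> a", "B -> b", "C -> c"))
#' grammar_cost(g)  # 12 * log2(7)
#' @export
cfg <- function(rules, start = "S", origin = NULL) {
  if (is.character(rules)) rules <- lapply(rules, parse_rule_text)
  stopifnot(length(rules) >= 1 || is.character(start))
  lhs <- vapply(rules, function(r) as.character(r$lhs), character(1))
  rhs <- lapply(rules, function(r) as.character(r$rhs))
  new_grammar(start = start, lhs = lhs, rhs = rhs, origin = origin)
}

parse_rule_text <- function(line) {
  parts <- strsplit(trimws(line), "->", fixed = TRUE)[[1]]
  if (length(parts) != 2) stop("malformed rule: ", line, call. = FALSE)
  lhs <- trimws(parts[1])
  rhs <- strsplit(trimws(parts[2]), "[[:space:]]+")[[1]]
  if (lhs == "" || length(rhs) == 0 || any(rhs == "")) {
    stop("malformed rule: ", line, call. = FALSE)
  }
  list(lhs = lhs, rhs = rhs)
}

# Low-level constructor shared by cfg(), the induction engine and readers.
new_grammar <- function(start, lhs, rhs, origin = NULL, id = NULL,
                        next_id = NULL, next_c = 1L, next_m = 1L,
                        validate = TRUE) {
  nts <- unique(c(start, lhs))
  all_syms <- unique(c(nts, unlist(rhs, use.names = FALSE)))
  terms <- setdiff(all_syms, nts)
  kind <- c(
    setNames(rep("nonterminal", length(nts)), nts),
    setNames(rep("terminal", length(terms)), terms)
  )
  org <- setNames(ifelse(kind == "terminal", "terminal", "user"), names(kind))
  org[start] <- "start"
  if (!is.null(origin)) {
    keep <- intersect(names(origin), names(org))
    org[keep] <- origin[keep]
  }
  if (is.null(id)) id <- seq_along(lhs)
  if (is.null(next_id)) next_id <- if (length(id)) max(id) + 1L else 1L
  g <- structure(
    list(
      start = start, kind = kind, origin = org,
      lhs = as.character(lhs), rhs = rhs, id = as.integer(id),
      next_id = as.integer(next_id),
      next_c = as.integer(next_c), next_m = as.integer(next_m)
    ),
    class = "clg_grammar"
  )
  if (validate) validate_grammar(g)
  g
}

#' Validate the structural invariants of a grammar
#'
#' Checks that the start symbol is a nonterminal, every production symbol is
#' in the inventory, right-hand sides are non-empty, and no two productions
#' are identical.
#'
#' @param g a `clg_grammar`.
#' @return `g`, invisibly; errors otherwise.
#' @export
validate_grammar <- function(g) {
  stopifnot(inherits(g, "clg_grammar"))
  if (anyDuplicated(names(g$kind))) stop("duplicate symbol names in inventory")
  if (!identical(unname(g$kind[g$start]), "nonterminal")) {
    stop("start symbol must be a nonterminal")
  }
  if (length(g$lhs) != length(g$rhs)) stop("lhs/rhs length mismatch")
  if (any(lengths(g$rhs) < 1)) stop("empty production right-hand side")
  syms <- unique(c(g$lhs, unlist(g$rhs, use.names = FALSE)))
  missing <- setdiff(syms, names(g$kind))
  if (length(missing)) stop("symbols missing from inventory: ",
                            paste(missing, collapse = ", "))
  if (any(g$kind[g$lhs] != "nonterminal")) {
    stop("production with terminal left-hand side")
  }
  if (anyDuplicated(production_keys(g))) stop("duplicate productions")
  if (anyDuplicated(g$id)) stop("duplicate production ids")
  invisible(g)
}

production_keys <- function(g) {
  paste(g$lhs, vapply(g$rhs, paste, character(1), collapse = " "), sep = " -> ")
}

#' @export
print.clg_grammar <- function(x, ...) {
  cat(sprintf("<clg_grammar> start=%s, |Sigma|=%d (%d nonterminals, %d terminals), %d productions\n",
              x$start, length(x$kind), sum(x$kind == "nonterminal"),
              sum(x$kind == "terminal"), length(x$lhs)))
  n <- min(length(x$lhs), 12L)
  for (i in seq_len(n)) {
    cat("  ", x$lhs[i], "->", paste(x$rhs[[i]], collapse = " "), "\n")
  }
  if (length(x$lhs) > n) cat("  ...", length(x$lhs) - n, "more\n")
  invisible(x)
}

#' Symbol inventory size
#'
#' `|Sigma|` counts terminals and nonterminals together.
#' @param g a `clg_grammar`.
#' @return integer inventory size.
#' @export
sigma_size <- function(g) length(g$kind)

#' @export
nonterminals <- function(g) names(g$kind)[g$kind == "nonterminal"]

#' @export
terminals <- function(g) names(g$kind)[g$kind == "terminal"]

#' Number of expansions |P(s)| for every nonterminal
#'
#' @param g a `clg_grammar`.
#' @return named integer vector over all nonterminals (0 for nonterminals
#'   with no production).
#' @export
expansion_counts <- function(g) {
  nts <- nonterminals(g)
  cnt <- setNames(integer(length(nts)), nts)
  tab <- table(g$lhs)
  cnt[names(tab)] <- as.integer(tab)
  cnt
}

# Total number of encoded symbols over all productions: sum of (1 + |rhs|).
grammar_symbol_total <- function(g) {
  if (!length(g$rhs)) return(0L)
  sum(1L + lengths(g$rhs))
}

#' Encoding cost of one production, in bits
#'
#' Each of the `1 + |rhs|` symbols of a production (left-hand side included)
#' takes `log2(|Sigma|)` bits, so the production costs
#' `(1 + |rhs|) * log2(|Sigma|)` bits.
#'
#' @param production a `list(lhs =, rhs =)` pair (or any object with those
#'   fields); only the right-hand-side length is used.
#' @param sigma_size size of the symbol inventory, at least 2.
#' @return cost in bits.
#' @examples
#' production_cost(list(lhs = "S", rhs = c("A", "B", "C")), 16)  # 16 bits
#' @export
production_cost <- function(production, sigma_size) {
  if (!is.numeric(sigma_size) || length(sigma_size) != 1 || sigma_size < 2) {
    stop("invalid inventory: sigma_size must be a single number >= 2")
  }
  rhs <- production$rhs
  if (length(rhs) < 1) stop("empty production right-hand side")
  (1 + length(rhs)) * log2(sigma_size)
}

#' Encoding cost of an entire grammar, in bits
#'
#' Sum of [production_cost()] over all productions, evaluated with the
#' grammar's current inventory size. The inventory is dynamic: adding or
#' removing a symbol changes the per-symbol cost of every production.
#'
#' @param g a `clg_grammar`.
#' @return cost in bits (0 for an empty production set).
#' @export
grammar_cost <- function(g) {
  if (!length(g$lhs)) return(0)
  n <- sigma_size(g)
  if (n < 2) stop("invalid inventory: fewer than 2 symbols")
  grammar_symbol_total(g) * log2(n)
}

#' Cost weights for the combined objective
#'
#' @param f weight in `[0, 1]` put on the grammar cost; `1 - f` is put on the
#'   derivation cost. `f = 0.5` is order-equivalent to the unweighted sum.
#' @return an object of class `clg_weights`.
#' @export
cost_weights <- function(f) {
  if (!is.numeric(f) || length(f) != 1 || is.na(f) || f < 0 || f > 1) {
    stop("f must be a single number in [0, 1]")
  }
  structure(list(f = f), class = "clg_weights")
}

#' Combined encoding cost
#'
#' `f * grammar_cost + (1 - f) * derivation_cost`, all in bits.
#'
#' @param g a `clg_grammar`.
#' @param derivations a list of derivation trees (see [derivation_tree()]),
#'   or of `list(tree =, count =)` entries for duplicate-weighted corpora.
#' @param weights a [cost_weights()] object (or a bare number in `[0,1]`).
#' @return total cost in bits.
#' @export
total_cost <- function(g, derivations, weights) {
  if (is.numeric(weights)) weights <- cost_weights(weights)
  stopifnot(inherits(weights, "clg_weights"))
  weights$f * grammar_cost(g) +
    (1 - weights$f) * corpus_derivation_cost(derivations, g)
}
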