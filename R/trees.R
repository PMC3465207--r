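#' Derivation and parse trees
#'
#' Trees are nested lists. An internal node is
#' `list(sym = <nonterminal>, rule = <production id>, children = list(...))`;
#' a leaf is `list(sym = <terminal>, rule = NA, children = list())`.
#' Replaying the internal nodes of a tree in preorder gives the leftmost
#' derivation of its yield.
#'
#' @param sym symbol name at this node.
#' @param rule integer production id (NA for terminal leaves).
#' @param children list of child nodes.
#' @return a tree node.
#' @export
derivation_tree <- function(sym, rule = NA_integer_, children = list()) {
  list(sym = sym, rule = as.integer(rule), children = children)
}

is_leaf <- function(node) length(node$children) == 0L

#' Terminal yield of a tree
#' @param tree a tree node.
#' @return character vector of leaf symbols, left to right.
#' @export
tree_yield <- function(tree) {
  if (is_leaf(tree)) return(tree$sym)
  unlist(lapply(tree$children, tree_yield), use.names = FALSE)
}

# Preorder list of internal nodes as (sym, rule) -- the leftmost derivation.
#' Leftmost derivation steps of a tree
#' @param tree a tree node.
#' @return data.frame with columns `sym` and `rule`, one row per expansion
#'   in leftmost order; `nrow` is the derivation length.
#' @export
derivation_steps <- function(tree) {
  syms <- character(0); rules <- integer(0)
  walk <- function(node) {
    if (is_leaf(node)) return(invisible())
    syms[[length(syms) + 1L]] <<- node$sym
    rules[[length(rules) + 1L]] <<- node$rule
    for (ch in node$children) walk(ch)
  }
  walk(tree)
  data.frame(sym = syms, rule = rules, stringsAsFactors = FALSE)
}

# Check that a tree is a valid derivation under g: every internal node uses
# an existing production whose lhs is the node symbol and whose rhs matches
# the child symbols.
tree_validate <- function(tree, g) {
  key_by_id <- setNames(seq_along(g$id), g$id)
  walk <- function(node) {
    if (is_leaf(node)) {
      if (!identical(unname(g$kind[node$sym]), "terminal")) {
        stop("leaf with non-terminal symbol: ", node$sym)
      }
      return(invisible())
    }
    pos <- key_by_id[as.character(node$rule)]
    if (is.na(pos)) stop("stale derivation: production ", node$rule,
                         " absent from grammar")
    if (!identical(g$lhs[pos], node$sym)) {
      stop("derivation rule lhs mismatch at ", node$sym)
    }
    kid_syms <- vapply(node$children, function(ch) ch$sym, character(1))
    if (!identical(g$rhs[[pos]], kid_syms)) {
      stop("derivation rule rhs mismatch at ", node$sym)
    }
    for (ch in node$children) walk(ch)
  }
  walk(tree)
  invisible(TRUE)
}

#' Encoding cost of one derivation, in bits
#'
#' Each expansion of a nonterminal `s` costs `log2(|P(s)|)` bits, where
#' `|P(s)|` is the number of productions with `s` on the left-hand side;
#' uniquely expandable nonterminals cost zero bits.
#'
#' @param tree a derivation tree.
#' @param g the grammar the derivation is drawn from.
#' @return cost in bits.
#' @export
derivation_cost <- function(tree, g) {
  cnt <- expansion_counts(g)
  steps <- derivation_steps(tree)
  if (!nrow(steps)) return(0)
  key_by_id <- setNames(seq_along(g$id), g$id)
  if (anyNA(key_by_id[as.character(steps$rule)])) {
    stop("stale derivation: production absent from grammar")
  }
  sum(log2(cnt[steps$sym]))
}

#' Encoding cost of all corpus derivations, in bits
#'
#' @param derivations a list whose elements are either derivation trees or
#'   `list(tree =, count =)` entries (duplicate sentences contribute their
#'   cost once per occurrence).
#' @param g the grammar.
#' @return total cost in bits.
#' @export
corpus_derivation_cost <- function(derivations, g) {
  if (!length(derivations)) return(0)
  total <- 0
  for (d in derivations) {
    if (!is.null(d$tree)) {
      total <- total + d$count * derivation_cost(d$tree, g)
    } else {
      total <- total + derivation_cost(d, g)
    }
  }
  total
}

# ---- spans and brackets ------------------------------------------------

# Spans of all internal nodes, 0-based half-open, as a 2-column matrix.
tree_internal_spans <- function(tree) {
  starts <- integer(0); ends <- integer(0)
  walk <- function(node, pos) {
    if (is_leaf(node)) return(pos + 1L)
    begin <- pos
    for (ch in node$children) pos <- walk(ch, pos)
    starts[[length(starts) + 1L]] <<- begin
    ends[[length(ends) + 1L]] <<- pos
    pos
  }
  n <- walk(tree, 0L)
  cbind(start = starts, end = ends)
}

# ---- s-expression serialisation ---------------------------------------

#' Serialise a tree as a bracketed s-expression
#' @param tree a tree node.
#' @return a single string like `"(S (C1 det nn) vbd)"`.
#' @export
tree_to_sexpr <- function(tree) {
  if (is_leaf(tree)) return(tree$sym)
  paste0("(", tree$sym, " ",
         paste(vapply(tree$children, tree_to_sexpr, character(1)),
               collapse = " "), ")")
}

#' Parse a bracketed s-expression into a tree
#'
#' Rule ids are not recoverable from text and are set to `NA`; use
#' [tree_attach_rules()] to re-link a tree to a grammar.
#'
#' @param text a single s-expression string.
#' @return a tree node.
#' @export
sexpr_to_tree <- function(text) {
  toks <- regmatches(text, gregexpr("\\(|\\)|[^()[:space:]]+", text))[[1]]
  pos <- 1L
  parse_node <- function() {
    if (pos > length(toks)) stop("unbalanced s-expression")
    tok <- toks[pos]
    if (tok == "(") {
      pos <<- pos + 1L
      label <- toks[pos]
      if (label %in% c("(", ")")) stop("malformed s-expression")
      pos <<- pos + 1L
      children <- list()
      while (pos <= length(toks) && toks[pos] != ")") {
        children[[length(children) + 1L]] <- parse_node()
      }
      if (pos > length(toks)) stop("unbalanced s-expression")
      pos <<- pos + 1L  # consume ')'
      derivation_tree(label, NA_integer_, children)
    } else if (tok == ")") {
      stop("malformed s-expression")
    } else {
      pos <<- pos + 1L
      derivation_tree(tok)
    }
  }
  out <- parse_node()
  if (pos <= length(toks)) stop("trailing content in s-expression")
  out
}

#' Re-link a rule-less tree to a grammar's production ids
#' @param tree a tree (e.g. from [sexpr_to_tree()]).
#' @param g a `clg_grammar`.
#' @return the tree with `rule` fields filled in.
#' @export
tree_attach_rules <- function(tree, g) {
  keys <- production_keys(g)
  lookup <- setNames(g$id, keys)
  walk <- function(node) {
    if (is_leaf(node)) return(node)
    node$children <- lapply(node$children, walk)
    kid_syms <- vapply(node$children, function(ch) ch$sym, character(1))
    key <- paste(node$sym, paste(kid_syms, collapse = " "), sep = " -> ")
    id <- lookup[key]
    if (is.na(id)) stop("tree uses production absent from grammar: ", key)
    node$rule <- unname(id)
    node
  }
  walk(tree)
}

#' Write trees (or no-parse markers) one per line
#' @param trees list of tree nodes or `NULL` entries.
#' @param path output file.
#' @param reasons character vector of reasons for `NULL` entries.
#' @export
write_trees <- function(trees, path, reasons = NULL) {
  lines <- vapply(seq_along(trees), function(i) {
    t <- trees[[i]]
    if (is.null(t)) {
      r <- if (!is.null(reasons) && !is.na(reasons[i])) reasons[i] else "noparse"
      paste0("NOPARSE\t", r)
    } else tree_to_sexpr(t)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read trees written by [write_trees()]
#' @param path input file.
#' @return list of tree nodes (`NULL` for NOPARSE lines).
#' @export
read_trees <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(l) {
    if (startsWith(l, "NOPARSE")) NULL else sexpr_to_tree(l)
  })
}
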