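#' Induction configuration
#'
#' @param f weight in `[0, 1]` on the grammar cost in the combined
#'   objective (`1 - f` weighs the derivation cost). `f = 1` drives the
#'   search toward the smallest, most general grammar; `f = 0` leaves the
#'   near-trivial most specific grammar.
#' @param max_n maximum length of the nonterminal n-grams considered by the
#'   combine operator (default 4).
#' @param forbid_recursion disallow operator applications that would create
#'   a recursive production chain, direct or indirect (default `TRUE`).
#' @param blocked_tags terminal tags that must never be derivable from the
#'   second or later right-hand-side position of a learned production.
#' @param enforce_blocklist whether to enforce `blocked_tags`.
#' @param keep_derivations maintain explicit derivation trees through the
#'   search (needed to inspect final derivations; costs a constant factor).
#' @param tol numerical tolerance: candidates with delta above `-tol` are
#'   treated as non-improving.
#' @param max_steps hard cap on greedy steps.
#' @return an object of class `clg_config`.
#' @export
induction_config <- function(f = 0.5, max_n = 4L, forbid_recursion = TRUE,
                             blocked_tags = c("verb", "det", "prep",
                                              "aux", "conj"),
                             enforce_blocklist = TRUE,
                             keep_derivations = TRUE,
                             tol = 1e-9, max_steps = 100000L) {
  stopifnot(max_n >= 2)
  structure(list(weights = cost_weights(f), max_n = as.integer(max_n),
                 forbid_recursion = isTRUE(forbid_recursion),
                 blocked_tags = as.character(blocked_tags),
                 enforce_blocklist = isTRUE(enforce_blocklist),
                 keep_derivations = isTRUE(keep_derivations),
                 tol = tol, max_steps = as.integer(max_steps)),
            class = "clg_config")
}

#' An operator instance
#'
#' @param kind `"combine"` or `"merge"`.
#' @param operands for combine, an ordered nonterminal n-gram (length 2 to
#'   `max_n`); for merge, two distinct nonterminals (neither the start
#'   symbol).
#' @return an object of class `clg_op`.
#' @export
operator_instance <- function(kind = c("combine", "merge"), operands) {
  kind <- match.arg(kind)
  operands <- as.character(operands)
  if (kind == "combine" && length(operands) < 2) {
    stop("combine needs at least two operands")
  }
  if (kind == "merge" &&
      (length(operands) != 2 || operands[1] == operands[2])) {
    stop("merge needs two distinct operands")
  }
  structure(list(kind = kind, operands = operands), class = "clg_op")
}

#' @export
print.clg_op <- function(x, ...) {
  cat(sprintf("<%s: %s>\n", x$kind, paste(x$operands, collapse = " ")))
  invisible(x)
}

# ---- initial grammar ---------------------------------------------------

#' Build the trivial initial grammar and its derivations
#'
#' One production `S -> W1 ... Wn` per unique training sentence, plus one
#' shared pre-terminal production `W -> w` per unique terminal tag. Every
#' corpus sentence (duplicates included) gets a derivation; the grammar
#' parses exactly the set of unique training sentences.
#'
#' @param corp a `clg_corpus` (or coercible character vector).
#' @param start name for the start symbol.
#' @param keep_derivations maintain explicit derivation trees in the state.
#' @return an induction state (class `clg_state`) with fields `grammar`,
#'   `trees` (one per unique sentence with its multiplicity), `u`
#'   (derivation-step counts per nonterminal), `usage` (derivation usage
#'   counts per production id) and `map` (corpus index to unique index).
#' @export
build_initial_grammar <- function(corp, start = "S",
                                  keep_derivations = TRUE) {
  corp <- corpus(unclass(corp))
  strs <- sentence_strings(corp)
  first <- !duplicated(strs)
  uniq <- corp[first]
  ustr <- strs[first]
  map <- match(strs, ustr)
  counts <- as.numeric(tabulate(map, nbins = length(ustr)))

  terms <- unique(unlist(corp, use.names = FALSE))
  if (start %in% terms) stop("start symbol name collides with a terminal")
  pt <- setNames(paste0("W.", terms), terms)
  while (any(pt %in% c(terms, start)) || anyDuplicated(pt)) {
    clash <- pt %in% c(terms, start) | duplicated(pt)
    pt[clash] <- paste0(pt[clash], "'")
  }

  lhs <- c(rep(start, length(uniq)), unname(pt))
  rhs <- c(lapply(uniq, function(s) unname(pt[s])), as.list(terms))
  origin <- c(setNames(rep("preterminal", length(pt)), unname(pt)),
              setNames(rep("terminal", length(terms)), terms))
  g <- new_grammar(start = start, lhs = lhs, rhs = rhs, origin = origin)

  # usage and expansion counts, duplicate-weighted
  usage <- setNames(numeric(length(g$id)), g$id)
  usage[seq_along(uniq)] <- counts
  term_tot <- setNames(numeric(length(terms)), terms)
  for (k in seq_along(uniq)) {
    tab <- table(uniq[[k]])
    term_tot[names(tab)] <- term_tot[names(tab)] + counts[k] * as.numeric(tab)
  }
  usage[as.character(length(uniq) + seq_along(terms))] <- unname(term_tot)
  u <- setNames(numeric(length(nonterminals(g))), nonterminals(g))
  u[start] <- sum(counts)
  u[unname(pt)] <- unname(term_tot)

  trees <- NULL
  if (keep_derivations) {
    pt_rule <- setNames(length(uniq) + seq_along(terms), terms)
    trees <- lapply(seq_along(uniq), function(k) {
      kids <- lapply(uniq[[k]], function(w) {
        derivation_tree(pt[[w]], pt_rule[[w]],
                        list(derivation_tree(w)))
      })
      list(tree = derivation_tree(start, k, kids), count = counts[k],
           sentence = uniq[[k]])
    })
  }
  new_state(g, trees, u, usage, map)
}

new_state <- function(g, trees, u, usage, map = NULL) {
  structure(list(grammar = g, trees = trees, u = u, usage = usage,
                 map = map, T = grammar_symbol_total(g),
                 pcount = expansion_counts(g)),
            class = "clg_state")
}

#' @export
print.clg_state <- function(x, ...) {
  cat("<clg_state>\n")
  print(x$grammar)
  invisible(x)
}

# Recompute u/usage from the stored trees; used by consistency checks.
state_counts_from_trees <- function(state) {
  g <- state$grammar
  u <- setNames(numeric(length(nonterminals(g))), nonterminals(g))
  usage <- setNames(numeric(length(g$id)), g$id)
  for (entry in state$trees) {
    steps <- derivation_steps(entry$tree)
    tab_s <- table(steps$sym)
    u[names(tab_s)] <- u[names(tab_s)] + entry$count * as.numeric(tab_s)
    tab_r <- table(steps$rule)
    usage[names(tab_r)] <- usage[names(tab_r)] +
      entry$count * as.numeric(tab_r)
  }
  list(u = u, usage = usage)
}

state_costs <- function(state, weights = NULL) {
  g <- state$grammar
  cg <- state$T * log2(sigma_size(g))
  cd <- sum(state$u * log2(pmax(state$pcount[names(state$u)], 1)))
  out <- c(C_G = cg, C_D = cd)
  if (!is.null(weights)) {
    if (is.numeric(weights)) weights <- cost_weights(weights)
    out <- c(out, total = weights$f * cg + (1 - weights$f) * cd)
  }
  out
}

# ---- candidate enumeration --------------------------------------------

greedy_match_starts <- function(seq, gram) {
  n <- length(gram)
  starts <- integer(0)
  i <- 1L
  while (i + n - 1L <= length(seq)) {
    if (all(seq[i:(i + n - 1L)] == gram)) {
      starts <- c(starts, i)
      i <- i + n
    } else {
      i <- i + 1L
    }
  }
  starts
}

#' Enumerate combine candidates
#'
#' Every contiguous nonterminal n-gram (2 <= n <= `max_n`) occurring on at
#' least one production right-hand side, with its corpus-wide occurrence
#' count. Occurrences within one right-hand side are counted left-to-right
#' non-overlapping, matching how replacement rewrites them.
#'
#' @param state a `clg_state`.
#' @param max_n maximum n-gram length.
#' @return a list of `list(instance =, count =)`, with per-production
#'   breakdowns (`prods`, `occ`) as extra fields.
#' @export
enumerate_combine_candidates <- function(state, max_n = 4L) {
  g <- state$grammar
  env <- new.env(parent = emptyenv())
  order_keys <- character(0)
  is_nt <- g$kind == "nonterminal"
  for (idx in seq_along(g$lhs)) {
    r <- g$rhs[[idx]]
    if (length(r) < 2) next
    ntpos <- is_nt[r]
    # maximal runs of nonterminals
    runs <- rle(as.vector(ntpos))
    stops <- cumsum(runs$lengths)
    starts <- stops - runs$lengths + 1L
    for (ri in which(runs$values & runs$lengths >= 2)) {
      seg <- r[starts[ri]:stops[ri]]
      L <- length(seg)
      for (n in 2:min(max_n, L)) {
        keys <- vapply(seq_len(L - n + 1L), function(s) {
          paste(seg[s:(s + n - 1L)], collapse = " ")
        }, character(1))
        for (key in unique(keys)) {
          gram <- strsplit(key, " ", fixed = TRUE)[[1]]
          cnt <- length(greedy_match_starts(seg, gram))
          if (cnt == 0L) next
          cur <- env[[key]]
          if (is.null(cur)) {
            env[[key]] <- list(operands = gram, count = cnt,
                               prods = idx, occ = cnt)
            order_keys <- c(order_keys, key)
          } else {
            # an n-gram may span several runs? no: runs are maximal and
            # grams are all-nonterminal, so counts per rhs live in one run,
            # but the same gram can recur in different runs of one rhs.
            if (idx %in% cur$prods) {
              w <- which(cur$prods == idx)
              cur$occ[w] <- cur$occ[w] + cnt
            } else {
              cur$prods <- c(cur$prods, idx)
              cur$occ <- c(cur$occ, cnt)
            }
            cur$count <- cur$count + cnt
            env[[key]] <- cur
          }
        }
      }
    }
  }
  lapply(order_keys, function(key) {
    cand <- env[[key]]
    list(instance = operator_instance("combine", cand$operands),
         count = cand$count, prods = cand$prods, occ = cand$occ)
  })
}

#' Enumerate merge candidates
#'
#' All unordered pairs of distinct nonterminals, excluding the start symbol
#' (which is preserved and never merged).
#'
#' @param state a `clg_state`.
#' @return list of `clg_op` merge instances.
#' @export
enumerate_merge_candidates <- function(state) {
  nts <- setdiff(nonterminals(state$grammar), state$grammar$start)
  if (length(nts) < 2) return(list())
  pairs <- combn(nts, 2)
  lapply(seq_len(ncol(pairs)), function(k) {
    operator_instance("merge", pairs[, k])
  })
}

# ---- deltas ------------------------------------------------------------

combine_delta_closed_form <- function(state, n, count, f) {
  sig <- sigma_size(state$grammar)
  T2 <- state$T - (n - 1) * count + (n + 1)
  f * (T2 * log2(sig + 1) - state$T * log2(sig))
}

merge_deltas_batch <- function(state, pair_matrix, f) {
  g <- state$grammar
  coded <- code_grammar(g)
  ids <- coded$sym_id[pair_matrix]
  dim(ids) <- dim(pair_matrix)
  u_vec <- numeric(coded$n_nt)
  u_vec[coded$sym_id[names(state$u)]] <- unname(state$u)
  cpp_merge_deltas(coded$n_nt, coded$r_lhs, coded$r_rhs,
                   matrix(as.integer(ids), ncol = 2), u_vec,
                   length(terminals(g)), f)
}

#' Exact cost delta of applying an operator instance
#'
#' Returns `total_cost(after) - total_cost(before)` exactly, including the
#' inventory-size change rippling through every production's cost,
#' production deduplication after a merge, and the induced `|P(.)|` changes
#' in the derivation cost. Negative means improvement. Equals the
#' brute-force difference obtained by applying the operator to a copy and
#' recomputing all costs from scratch.
#'
#' @param state a `clg_state`.
#' @param instance a `clg_op`.
#' @param weights a [cost_weights()] object or bare `f`.
#' @return signed delta in bits.
#' @export
estimate_delta <- function(state, instance, weights) {
  if (is.numeric(weights)) weights <- cost_weights(weights)
  g <- state$grammar
  ops <- instance$operands
  if (!all(ops %in% nonterminals(g))) {
    stop("stale candidate: operand no longer a nonterminal in the grammar")
  }
  if (instance$kind == "combine") {
    total <- 0L
    for (r in g$rhs) total <- total + length(greedy_match_starts(r, ops))
    if (total == 0L) stop("stale candidate: n-gram no longer occurs")
    combine_delta_closed_form(state, length(ops), total, weights$f)
  } else {
    if (any(ops == g$start)) stop("stale candidate: cannot merge the start symbol")
    as.numeric(merge_deltas_batch(state, matrix(ops, ncol = 2), weights$f))
  }
}

# ---- applying operators ------------------------------------------------

fresh_symbol <- function(g, prefix, counter) {
  repeat {
    name <- paste0(prefix, counter)
    if (!(name %in% names(g$kind))) return(list(name = name,
                                                counter = counter + 1L))
    counter <- counter + 1L
  }
}

#' Apply a combine or merge operator to an induction state
#'
#' Combine introduces `NEW -> operands` and replaces every left-to-right
#' non-overlapping occurrence of the operand sequence on any right-hand
#' side (other than the new production's own) with `NEW`; derivations gain
#' the corresponding expansion step. Merge replaces both operands by `NEW`
#' everywhere, collapses productions made identical (keeping the earliest),
#' and retires the merged symbols from the inventory. All indexes and
#' maintained counts are updated; the returned state is consistent.
#'
#' @param state a `clg_state`.
#' @param instance a `clg_op`.
#' @return the updated state.
#' @export
apply_operator <- function(state, instance) {
  if (instance$kind == "combine") {
    apply_combine(state, instance$operands)
  } else {
    apply_merge(state, instance$operands)
  }
}

apply_combine <- function(state, gram) {
  g <- state$grammar
  if (!all(gram %in% nonterminals(g))) {
    stop("stale candidate: operand no longer a nonterminal")
  }
  n <- length(gram)
  fs <- fresh_symbol(g, "C", g$next_c)
  new_sym <- fs$name
  new_id <- g$next_id

  starts_by_prod <- list()
  total <- 0L
  for (idx in seq_along(g$lhs)) {
    st <- greedy_match_starts(g$rhs[[idx]], gram)
    if (length(st)) {
      starts_by_prod[[as.character(idx)]] <- st
      total <- total + length(st)
    }
  }
  if (total == 0L) stop("stale candidate: n-gram no longer occurs")

  rhs <- g$rhs
  for (key in names(starts_by_prod)) {
    idx <- as.integer(key)
    r <- rhs[[idx]]
    st <- starts_by_prod[[key]]
    keep <- rep(TRUE, length(r))
    for (s in st) {
      r[s] <- new_sym
      if (n > 1) keep[(s + 1L):(s + n - 1L)] <- FALSE
    }
    rhs[[idx]] <- r[keep]
  }
  lhs <- c(g$lhs, new_sym)
  rhs[[length(rhs) + 1L]] <- gram
  id <- c(g$id, new_id)

  g2 <- new_grammar(
    start = g$start, lhs = lhs, rhs = rhs,
    origin = c(g$origin, setNames("combined", new_sym)),
    id = id, next_id = new_id + 1L, next_c = fs$counter, next_m = g$next_m,
    validate = FALSE
  )
  # duplicate collapse after combine cannot occur (the rewrite is
  # injective on rhs strings), but guard the invariant anyway
  if (anyDuplicated(production_keys(g2))) {
    stop("internal error: combine produced duplicate productions")
  }

  # counts: the new symbol is expanded once per replaced occurrence
  affected <- as.integer(names(starts_by_prod))
  occs <- lengths(starts_by_prod)
  u_new <- sum(occs * unname(state$usage[as.character(g$id[affected])]))
  u <- c(state$u, setNames(u_new, new_sym))
  usage <- c(state$usage, setNames(u_new, new_id))

  trees <- state$trees
  if (!is.null(trees)) {
    aff_ids <- g$id[affected]
    starts_by_id <- setNames(starts_by_prod, as.character(aff_ids))
    rewrite <- function(node) {
      if (is_leaf(node)) return(node)
      node$children <- lapply(node$children, rewrite)
      key <- as.character(node$rule)
      st <- starts_by_id[[key]]
      if (!is.null(st)) {
        kids <- node$children
        out <- list()
        i <- 1L
        while (i <= length(kids)) {
          if (i %in% st) {
            out[[length(out) + 1L]] <-
              derivation_tree(new_sym, new_id, kids[i:(i + n - 1L)])
            i <- i + n
          } else {
            out[[length(out) + 1L]] <- kids[[i]]
            i <- i + 1L
          }
        }
        node$children <- out
      }
      node
    }
    trees <- lapply(trees, function(e) { e$tree <- rewrite(e$tree); e })
  }
  new_state(g2, trees, u, usage, state$map)
}

apply_merge <- function(state, ops) {
  g <- state$grammar
  X <- ops[1]; Y <- ops[2]
  if (!all(c(X, Y) %in% nonterminals(g)) || X == Y) {
    stop("stale candidate: merge operands invalid")
  }
  if (g$start %in% c(X, Y)) stop("cannot merge the start symbol")
  fs <- fresh_symbol(g, "M", g$next_m)
  new_sym <- fs$name

  relabel <- function(x) { x[x %in% c(X, Y)] <- new_sym; x }
  lhs <- relabel(g$lhs)
  rhs <- lapply(g$rhs, relabel)
  id <- g$id

  keys <- paste(lhs, vapply(rhs, paste, character(1), collapse = " "),
                sep = " -> ")
  usage <- state$usage
  rule_remap <- NULL
  if (anyDuplicated(keys)) {
    groups <- split(seq_along(keys), keys)
    drop <- integer(0)
    for (grp in groups) {
      if (length(grp) < 2) next
      keep <- grp[which.min(id[grp])]
      rem <- setdiff(grp, keep)
      usage[as.character(id[keep])] <- usage[as.character(id[keep])] +
        sum(usage[as.character(id[rem])])
      rule_remap <- c(rule_remap, setNames(rep(id[keep], length(rem)),
                                           id[rem]))
      drop <- c(drop, rem)
    }
    keep_mask <- !(seq_along(keys) %in% drop)
    lhs <- lhs[keep_mask]; rhs <- rhs[keep_mask]; id <- id[keep_mask]
    usage <- usage[as.character(id)]
  }

  kind_keep <- !(names(g$kind) %in% c(X, Y))
  origin <- c(g$origin[kind_keep], setNames("merged", new_sym))

  g2 <- new_grammar(start = g$start, lhs = lhs, rhs = rhs, origin = origin,
                    id = id, next_id = g$next_id, next_c = g$next_c,
                    next_m = fs$counter, validate = FALSE)
  validate_grammar(g2)

  u <- state$u
  u_new <- unname(u[X] + u[Y])
  u <- c(u[!(names(u) %in% c(X, Y))], setNames(u_new, new_sym))

  trees <- state$trees
  if (!is.null(trees)) {
    rewrite <- function(node) {
      if (node$sym %in% c(X, Y)) node$sym <- new_sym
      if (is_leaf(node)) return(node)
      if (!is.null(rule_remap)) {
        rm2 <- rule_remap[as.character(node$rule)]
        if (!is.na(rm2)) node$rule <- unname(rm2)
      }
      node$children <- lapply(node$children, rewrite)
      node
    }
    trees <- lapply(trees, function(e) { e$tree <- rewrite(e$tree); e })
  }
  new_state(g2, trees, u, usage, state$map)
}

# ---- constraints -------------------------------------------------------

# Simulate the post-application production set (lhs, rhs) of an instance
# without building a full state. Deduplication is irrelevant for
# reachability, so duplicates may remain.
simulate_rules <- function(state, instance) {
  g <- state$grammar
  if (instance$kind == "combine") {
    gram <- instance$operands
    new_sym <- fresh_symbol(g, "C", g$next_c)$name
    rhs <- lapply(g$rhs, function(r) {
      st <- greedy_match_starts(r, gram)
      if (!length(st)) return(r)
      keep <- rep(TRUE, length(r))
      n <- length(gram)
      for (s in st) {
        r[s] <- new_sym
        if (n > 1) keep[(s + 1L):(s + n - 1L)] <- FALSE
      }
      r[keep]
    })
    list(lhs = c(g$lhs, new_sym), rhs = c(rhs, list(gram)),
         nts = c(nonterminals(g), new_sym), start = g$start)
  } else {
    new_sym <- fresh_symbol(g, "M", g$next_m)$name
    relabel <- function(x) { x[x %in% instance$operands] <- new_sym; x }
    list(lhs = relabel(g$lhs), rhs = lapply(g$rhs, relabel),
         nts = c(setdiff(nonterminals(g), instance$operands), new_sym),
         start = g$start)
  }
}

#' Would applying an instance violate the structural constraints?
#'
#' Checks (a) recursion: the instance must not create a derives-relation
#' cycle, direct or indirect; and (b) the tag blocklist: no production
#' (other than expansions of the start symbol, which carry raw sentence
#' templates) may hold a blocked symbol at right-hand-side position 2 or
#' later, where a symbol is blocked iff a blocked terminal tag is derivable
#' from it.
#'
#' @param state a `clg_state`.
#' @param instance a `clg_op`.
#' @param config an [induction_config()].
#' @return `list(violates =, reason =)`.
#' @export
violates_constraints <- function(state, instance, config) {
  sim <- simulate_rules(state, instance)
  if (config$forbid_recursion &&
      has_cycle_rules(sim$lhs, sim$rhs, sim$nts)) {
    return(list(violates = TRUE, reason = "recursion"))
  }
  if (config$enforce_blocklist && length(config$blocked_tags)) {
    blocked <- config$blocked_tags
    repeat {
      grew <- FALSE
      for (k in seq_along(sim$lhs)) {
        if (sim$lhs[k] %in% blocked) next
        if (any(sim$rhs[[k]] %in% blocked)) {
          blocked <- c(blocked, sim$lhs[k])
          grew <- TRUE
        }
      }
      if (!grew) break
    }
    for (k in seq_along(sim$lhs)) {
      if (sim$lhs[k] == sim$start) next
      r <- sim$rhs[[k]]
      if (length(r) >= 2 && any(r[-1] %in% blocked)) {
        return(list(violates = TRUE,
                    reason = paste("blocked tag in non-initial position of",
                                   sim$lhs[k])))
      }
    }
  }
  list(violates = FALSE, reason = NA_character_)
}

# ---- greedy search -----------------------------------------------------

#' Induce a grammar by greedy cost reduction
#'
#' Starts from [build_initial_grammar()] and repeatedly evaluates all
#' combine and merge candidates in a single loop, applying the legal
#' instance with the most negative exact cost delta, until no instance
#' improves the f-weighted total cost. Ties are broken deterministically:
#' combine before merge, longer n-grams first, then lexicographic operand
#' order.
#'
#' @param corp training corpus (`clg_corpus` or character vector).
#' @param config an [induction_config()].
#' @return an object of class `clg_induction` with fields `grammar`,
#'   `derivations` (per unique sentence, with multiplicities; `NULL` unless
#'   `keep_derivations`), `trace` (one row per step with the operator, its
#'   delta and the cost components) and `state`.
#' @export
induce_grammar <- function(corp, config = induction_config()) {
  stopifnot(inherits(config, "clg_config"))
  f <- config$weights$f
  state <- build_initial_grammar(corp,
                                 keep_derivations = config$keep_derivations)
  cost0 <- state_costs(state, config$weights)
  trace <- data.frame(step = 0L, operator = "init", operands = "",
                      delta = 0, C_G = cost0[["C_G"]], C_D = cost0[["C_D"]],
                      total = cost0[["total"]], stringsAsFactors = FALSE)
  step <- 0L
  repeat {
    if (step >= config$max_steps) break
    combs <- enumerate_combine_candidates(state, config$max_n)
    merges <- enumerate_merge_candidates(state)

    n_c <- length(combs); n_m <- length(merges)
    if (n_c + n_m == 0L) break
    delta <- numeric(n_c + n_m)
    kindv <- c(rep(1L, n_c), rep(2L, n_m))  # combine preferred on ties
    nlen <- integer(n_c + n_m)
    opstr <- character(n_c + n_m)
    if (n_c) {
      cc <- vapply(combs, function(x) x$count, numeric(1))
      cn <- vapply(combs, function(x) length(x$instance$operands), numeric(1))
      sig <- sigma_size(state$grammar)
      T2 <- state$T - (cn - 1) * cc + (cn + 1)
      delta[seq_len(n_c)] <- f * (T2 * log2(sig + 1) - state$T * log2(sig))
      nlen[seq_len(n_c)] <- cn
      opstr[seq_len(n_c)] <- vapply(combs, function(x) {
        paste(x$instance$operands, collapse = " ")
      }, character(1))
    }
    if (n_m) {
      pm <- t(vapply(merges, function(x) x$operands, character(2)))
      delta[n_c + seq_len(n_m)] <- merge_deltas_batch(state, pm, f)
      nlen[n_c + seq_len(n_m)] <- 2L
      opstr[n_c + seq_len(n_m)] <- apply(pm, 1, paste, collapse = " ")
    }
    ord <- order(delta, kindv, -nlen, opstr, method = "radix")
    applied <- FALSE
    for (k in ord) {
      if (delta[k] >= -config$tol) break
      inst <- if (k <= n_c) combs[[k]]$instance else merges[[k - n_c]]
      chk <- violates_constraints(state, inst, config)
      if (chk$violates) next
      state <- apply_operator(state, inst)
      step <- step + 1L
      cost <- state_costs(state, config$weights)
      trace <- rbind(trace, data.frame(
        step = step, operator = inst$kind,
        operands = paste(inst$operands, collapse = " "),
        delta = delta[k], C_G = cost[["C_G"]], C_D = cost[["C_D"]],
        total = cost[["total"]], stringsAsFactors = FALSE))
      applied <- TRUE
      break
    }
    if (!applied) break
  }
  structure(list(grammar = state$grammar, derivations = state$trees,
                 trace = trace, state = state, config = config),
            class = "clg_induction")
}

#' @export
print.clg_induction <- function(x, ...) {
  cat(sprintf("<clg_induction> %d greedy steps, final cost %.2f bits\n",
              nrow(x$trace) - 1L, x$trace$total[nrow(x$trace)]))
  print(x$grammar)
  invisible(x)
}
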