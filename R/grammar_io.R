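#' Grammar text format
#'
#' Round-trippable plain-text format: a `#start: S` header, one `#symbol:`
#' header per inventory symbol recording its kind and provenance, then one
#' production per line as `LHS -> SYM SYM ...`, with an optional trailing
#' tab-separated probability field written with 15 significant digits (used
#' when serialising a PCFG).
#'
#' @param g a `clg_grammar` or `clg_pcfg`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_grammar <- function(g, path) {
  prob <- NULL
  if (inherits(g, "clg_pcfg")) {
    prob <- g$prob
    g <- g$grammar
  }
  stopifnot(inherits(g, "clg_grammar"))
  header <- c(
    paste0("#start: ", g$start),
    paste0("#symbol: ", names(g$kind), " ", unname(g$kind), " ",
           unname(g$origin))
  )
  body <- paste(g$lhs, "->",
                vapply(g$rhs, paste, character(1), collapse = " "))
  if (!is.null(prob)) {
    body <- paste0(body, "\t", formatC(prob, digits = 15, format = "g"))
  }
  writeLines(c(header, body), path, useBytes = TRUE)
  invisible(path)
}

#' Read a grammar (or PCFG) text file
#'
#' @param path file written by [write_grammar()], or any file in the same
#'   format; `#symbol:` headers are optional (kinds are then inferred from
#'   usage: symbols occurring as a left-hand side are nonterminals).
#' @return a `clg_grammar`, or a `clg_pcfg` if probability fields are
#'   present on every production line.
#' @export
read_grammar <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("parse error: empty grammar file")
  start <- NULL
  origin <- character(0)
  body <- character(0)
  body_ln <- integer(0)
  for (i in seq_along(lines)) {
    line <- lines[i]
    if (startsWith(line, "#start:")) {
      start <- trimws(sub("^#start:", "", line))
    } else if (startsWith(line, "#symbol:")) {
      parts <- strsplit(trimws(sub("^#symbol:", "", line)),
                        "[[:space:]]+")[[1]]
      if (length(parts) != 3) {
        stop("parse error at line ", i, ": bad #symbol header")
      }
      origin[parts[1]] <- parts[3]
    } else if (startsWith(line, "#")) {
      # other comments ignored
    } else {
      body <- c(body, line)
      body_ln <- c(body_ln, i)
    }
  }
  if (is.null(start)) stop("parse error: missing '#start:' header")
  lhs <- character(0); rhs <- list(); prob <- numeric(0)
  has_prob <- logical(0)
  for (k in seq_along(body)) {
    parts <- strsplit(body[k], "\t", fixed = TRUE)[[1]]
    rule <- tryCatch(parse_rule_text(parts[1]), error = function(e) {
      stop("parse error at line ", body_ln[k], ": ", conditionMessage(e),
           call. = FALSE)
    })
    lhs <- c(lhs, rule$lhs)
    rhs[[length(rhs) + 1L]] <- rule$rhs
    p <- if (length(parts) >= 2) suppressWarnings(as.numeric(parts[2])) else NA_real_
    if (length(parts) >= 2 && is.na(p)) {
      stop("parse error at line ", body_ln[k], ": bad probability field")
    }
    prob <- c(prob, p)
    has_prob <- c(has_prob, length(parts) >= 2)
  }
  keys <- paste(lhs, vapply(rhs, paste, character(1), collapse = " "),
                sep = " -> ")
  if (anyDuplicated(keys)) {
    stop("parse error at line ",
         body_ln[which(duplicated(keys))[1]], ": duplicate production")
  }
  g <- new_grammar(start = start, lhs = lhs, rhs = rhs,
                   origin = if (length(origin)) origin else NULL)
  if (length(has_prob) && all(has_prob)) {
    return(new_pcfg(g, prob))
  }
  if (any(has_prob)) {
    stop("parse error: probability field present on some lines only")
  }
  g
}
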