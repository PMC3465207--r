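#' Tagged-sentence corpora
#'
#' A corpus is an ordered list of sentences, each a character vector of
#' whitespace-free tags. Duplicate sentences are kept: the derivation cost
#' sums over all `q` sentences including repeats.
#'
#' @param x a character vector of sentence strings (tokens separated by
#'   whitespace), or a list of token vectors.
#' @return an object of class `clg_corpus` (a list of token vectors).
#' @export
corpus <- function(x) {
  if (is.character(x)) {
    x <- strsplit(trimws(x), "[[:space:]]+")
  }
  stopifnot(is.list(x))
  if (!length(x)) stop("empty corpus")
  for (s in x) {
    if (!length(s) || any(!nzchar(s)) || any(grepl("[[:space:]]", s))) {
      stop("corpus sentences must be non-empty, whitespace-free token vectors")
    }
  }
  structure(x, class = "clg_corpus")
}

#' @export
print.clg_corpus <- function(x, ...) {
  cat(sprintf("<clg_corpus> %d sentences (%d unique), %d tag types\n",
              length(x), length(unique(sentence_strings(x))),
              length(unique(unlist(x, use.names = FALSE)))))
  for (i in seq_len(min(5L, length(x)))) {
    cat("  ", paste(x[[i]], collapse = " "), "\n")
  }
  if (length(x) > 5L) cat("  ...", length(x) - 5L, "more\n")
  invisible(x)
}

sentence_strings <- function(corp) {
  vapply(corp, paste, character(1), collapse = " ")
}

#' Read a corpus file
#'
#' One sentence per non-blank line, tokens separated by whitespace (tabs
#' included); blank lines are skipped; trailing whitespace is ignored.
#'
#' @param path UTF-8 text file.
#' @return a `clg_corpus`; line numbers of the original file are kept in
#'   attribute `"lines"` for diagnostics.
#' @export
read_corpus <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- nzchar(trimws(lines))
  if (!any(keep)) stop("input error: corpus file ", path, " has no sentences")
  corp <- corpus(trimws(lines[keep]))
  attr(corp, "lines") <- which(keep)
  corp
}

#' Write a corpus file (one sentence per line)
#' @param corp a `clg_corpus` or coercible input.
#' @param path output file.
#' @export
write_corpus <- function(corp, path) {
  corp <- corpus(unclass(corp))
  writeLines(sentence_strings(corp), path, useBytes = TRUE)
  invisible(path)
}
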