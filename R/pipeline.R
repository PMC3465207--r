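#' Run the full synthetic end-to-end experiment
#'
#' `simulate -> induce -> estimate -> parse -> evaluate` in one call. All
#' randomness flows from the profile's seed, so the same configuration
#' reproduces the same report exactly.
#'
#' @param profile a [corpus_profile()] (or `NULL` to use defaults).
#' @param f grammar-cost weight for the induction objective.
#' @param em_iterations number of EM iterations (0 = the deterministic
#'   first-parse baseline with no probabilities).
#' @param mode parse mode for evaluation; forced to `"first"` when
#'   `em_iterations` is 0.
#' @param config optional [induction_config()] override (its `f` is set
#'   from the `f` argument).
#' @param outdir optional directory: corpora, grammar, PCFG, parses,
#'   report JSON and a manifest are written there.
#' @return a list with `eval` (a `clg_eval`), `fit` (the induction
#'   result), `pcfg`, `data` (the sampled corpus) and `report` (a plain
#'   list, what gets serialised).
#' @export
run_pipeline <- function(profile = corpus_profile(), f = 0.5,
                         em_iterations = 5L, mode = "viterbi",
                         config = NULL, outdir = NULL) {
  if (is.null(config)) {
    config <- induction_config(f = f, keep_derivations = FALSE)
  } else {
    config$weights <- cost_weights(f)
  }
  data <- sample_corpus(profile)
  fit <- induce_grammar(data$train, config)
  if (em_iterations >= 1) {
    pcfg <- estimate_pcfg(fit$grammar, data$train,
                          em_config(iterations = em_iterations))
    eval_mode <- mode
    x <- pcfg
  } else {
    pcfg <- init_uniform(fit$grammar)
    eval_mode <- "first"
    x <- fit$grammar
  }
  ev <- evaluate_parses(x, data$test, gold = data$gold_brackets,
                        train_sentences = data$train, mode = eval_mode)
  report <- list(
    profile = profile$name, seed = profile$seed, f = f,
    em_iterations = em_iterations, mode = eval_mode,
    n_train = length(data$train), n_test = length(data$test),
    train_overlap = data$train_overlap,
    precision = ev$precision, recall = ev$recall,
    f_measure = ev$f_measure,
    parsed_count = ev$parsed_count, noparse_count = ev$noparse_count,
    novel_parse_rate = ev$novel_parse_rate,
    grammar_size = length(fit$grammar$lhs),
    sigma = sigma_size(fit$grammar),
    steps = nrow(fit$trace) - 1L,
    final_cost = fit$trace$total[nrow(fit$trace)]
  )
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_corpus(data$train, file.path(outdir, "train.txt"))
    write_corpus(data$test, file.path(outdir, "test.txt"))
    write_trees(data$gold_trees, file.path(outdir, "gold.trees"))
    write_grammar(fit$grammar, file.path(outdir, "grammar.txt"))
    write_grammar(pcfg, file.path(outdir, "pcfg.txt"))
    write.csv(fit$trace, file.path(outdir, "trace.csv"), row.names = FALSE)
    trees <- lapply(ev$results, function(r) r$tree)
    reasons <- vapply(ev$results, function(r) {
      if (identical(r$status, "ok")) NA_character_ else r$reason
    }, character(1))
    write_trees(trees, file.path(outdir, "parses.trees"), reasons)
    jsonlite::write_json(report, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_manifest(outdir, report)
  }
  list(eval = ev, fit = fit, pcfg = pcfg, data = data, report = report)
}

write_manifest <- function(outdir, config_list) {
  files <- setdiff(list.files(outdir), "manifest.json")
  digests <- tools::md5sum(file.path(outdir, files))
  manifest <- list(
    package = "clingram",
    version = as.character(utils::packageVersion("clingram")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config_list,
    files = as.list(setNames(unname(digests), files))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Sweep the grammar/derivation cost weight f
#'
#' Runs the end-to-end experiment at each `f` for each seed and tabulates
#' bracketing scores and novel-sentence parse rates (the machinery behind
#' precision/recall-versus-f curves).
#'
#' @param f_values numeric vector of weights in `[0, 1]`.
#' @param profile a [corpus_profile()]; its seed is replaced by each
#'   element of `seeds`.
#' @param seeds integer vector of seeds.
#' @param em_iterations EM iterations per run.
#' @return data.frame with one row per (seed, f).
#' @export
f_sweep <- function(f_values = c(0.05, 0.15, 0.3, 0.5, 0.7, 0.95),
                    profile = corpus_profile(), seeds = 1L,
                    em_iterations = 5L) {
  rows <- list()
  for (seed in seeds) {
    profile$seed <- as.integer(seed)
    for (f in f_values) {
      res <- run_pipeline(profile, f = f, em_iterations = em_iterations)
      rows[[length(rows) + 1L]] <- data.frame(
        seed = seed, f = f,
        precision = res$report$precision, recall = res$report$recall,
        f_measure = res$report$f_measure,
        novel_parse_rate = res$report$novel_parse_rate,
        parsed = res$report$parsed_count,
        noparse = res$report$noparse_count,
        grammar_size = res$report$grammar_size)
    }
  }
  do.call(rbind, rows)
}

#' Sweep the number of EM iterations
#'
#' Iteration 0 is the no-probability baseline (the deterministic first
#' parse); iteration `k >= 1` evaluates with probabilities after `k - 1`
#' EM passes over the uniform initialisation (so iteration 1 is uniform
#' probabilities).
#'
#' @param iterations integer vector of iteration counts.
#' @param f induction weight.
#' @param profile a [corpus_profile()].
#' @param seeds integer vector of seeds.
#' @return data.frame with one row per (seed, iterations).
#' @export
em_sweep <- function(iterations = 0:5, f = 0.5,
                     profile = corpus_profile(), seeds = 1L) {
  rows <- list()
  for (seed in seeds) {
    profile$seed <- as.integer(seed)
    data <- sample_corpus(profile)
    fit <- induce_grammar(data$train,
                          induction_config(f = f, keep_derivations = FALSE))
    for (it in iterations) {
      if (it == 0) {
        ev <- evaluate_parses(fit$grammar, data$test,
                              gold = data$gold_brackets,
                              train_sentences = data$train, mode = "first")
      } else {
        pcfg <- estimate_pcfg(fit$grammar, data$train,
                              em_config(iterations = it - 1L))
        ev <- evaluate_parses(pcfg, data$test, gold = data$gold_brackets,
                              train_sentences = data$train,
                              mode = "viterbi")
      }
      rows[[length(rows) + 1L]] <- data.frame(
        seed = seed, iterations = it,
        precision = ev$precision, recall = ev$recall,
        f_measure = ev$f_measure,
        novel_parse_rate = ev$novel_parse_rate)
    }
  }
  do.call(rbind, rows)
}
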