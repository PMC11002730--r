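read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config))
      stop("config file not found: ", config, call. = FALSE)
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config) else
      jsonlite::fromJSON(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  config
}

require_fields <- function(config, fields, command) {
  missing <- fields[!vapply(fields, function(f) !is.null(config[[f]]), logical(1))]
  if (length(missing) > 0L)
    stop(sprintf("command '%s' requires config field(s): %s", command,
                 paste(missing, collapse = ", ")), call. = FALSE)
  for (f in intersect(fields, c("dataset", "reader_spec", "params",
                                "estimator", "triplets", "a", "b"))) {
    if (is.character(config[[f]]) && !file.exists(config[[f]]))
      stop(sprintf("config field '%s': file not found: %s", f, config[[f]]),
           call. = FALSE)
  }
  invisible(config)
}

config_hash <- function(config) {
  config$out_dir <- NULL  # run identity = inputs + seed, not output location
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

write_manifest <- function(out_dir, command, config) {
  manifest <- list(command = command,
                   seed = if (is.null(config$seed)) NA else config$seed,
                   config_hash = config_hash(config),
                   package_version = as.character(utils::packageVersion("sentex")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest
}

load_dataset <- function(config) {
  fmt <- if (!is.null(config$format)) config$format else "squad"
  if (fmt == "bioasq") load_bioasq_json(config$dataset) else
    load_squad_json(config$dataset)
}

build_scorer <- function(name, reader = NULL, estimator = NULL,
                         embedder = hashed_embedder()) {
  switch(name,
    "oracle-u1" = oracle_scorer(reader, signals = "u1"),
    "oracle-u2" = oracle_scorer(reader, signals = "u2"),
    "estimator" = estimator_scorer(estimator, embedder),
    "cosine" = cosine_scorer(embedder),
    stop("unknown scorer: ", name, call. = FALSE))
}

#' Run one pipeline command
#'
#' The unified entry point tying the modules together. Commands:
#' `simulate` (synthetic corpus), `gen-triplets`, `fit-estimator`,
#' `optimize` (parameter search), `extract` (contexts for a dataset),
#' `evaluate` (a context policy), `compare` (significant-change tally
#' between two evaluation record files). Every command writes its artifacts
#' plus a `manifest.json` (command, seed, config hash, package version) into
#' the configured output directory. All randomness flows from the single
#' `seed` field.
#'
#' @param command one of `"simulate"`, `"gen-triplets"`, `"fit-estimator"`,
#'   `"optimize"`, `"extract"`, `"evaluate"`, `"compare"`.
#' @param config a named list, or a path to a YAML/JSON config file. Common
#'   fields: `out_dir`, `seed`, `dataset` (SQuAD-dialect path), `format`
#'   (`"squad"`/`"bioasq"`), `reader_spec` (scripted reader JSON), `scorer`
#'   (`"oracle-u1"`, `"oracle-u2"`, `"estimator"`, `"cosine"`), `params`
#'   (extraction-parameter JSON path or list), `estimator` (weights JSON),
#'   plus per-command fields documented in the examples.
#' @return the command's result, invisibly (also written to `out_dir`).
#' @export
run_pipeline <- function(command = c("simulate", "gen-triplets",
                                     "fit-estimator", "optimize", "extract",
                                     "evaluate", "compare"),
                         config = list()) {
  command <- match.arg(command)
  config <- read_run_config(config)
  require_fields(config, "out_dir", command)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- if (is.null(config$seed)) 0L else as.integer(config$seed)

  result <- switch(command,
    "simulate" = {
      gen <- config$generator
      gen$seed <- seed
      cfg <- do.call(corpus_config, gen[names(gen) %in%
                                          names(formals(corpus_config))])
      make_corpus(cfg, out_dir = config$out_dir)
    },
    "gen-triplets" = {
      require_fields(config, c("dataset", "reader_spec"), command)
      ds <- load_dataset(config)
      reader <- read_reader_spec(config$reader_spec)
      per_q <- if (!is.null(config$per_question))
        unlist(config$per_question) else
          c(target_paragraph = 1L, neighborhood_excl_gold = 2L,
            adjacent_paragraph = 1L, distant_or_foreign = 1L)
      tri <- generate_triplets(ds$examples, ds$articles, reader,
                               per_question = per_q, seed = seed)
      write_triplets(tri, file.path(config$out_dir, "triplets.jsonl"))
      jsonlite::write_json(
        list(n_triplets = nrow(tri), seed = seed,
             skips = attr(tri, "skips")),
        file.path(config$out_dir, "triplet_report.json"),
        auto_unbox = TRUE, digits = NA, dataframe = "rows")
      tri
    },
    "fit-estimator" = {
      require_fields(config, "triplets", command)
      tri <- read_triplets(config$triplets)
      label <- if (is.null(config$label)) "u2" else config$label
      est <- fit_utility_estimator(tri, label = label)
      write_estimator(est, file.path(config$out_dir, "estimator.json"))
      est
    },
    "optimize" = {
      require_fields(config, c("dataset", "reader_spec"), command)
      ds <- load_dataset(config)
      reader <- read_reader_spec(config$reader_spec)
      scorer <- build_scorer(if (is.null(config$scorer)) "oracle-u2" else
                               config$scorer, reader = reader)
      sc_args <- list(seed = seed)
      for (f in c("budget", "backend", "alpha_grid", "sign_convention"))
        if (!is.null(config[[f]])) sc_args[[f]] <- config[[f]]
      sc <- do.call(search_config, sc_args)
      res <- search_params(ds$examples, ds$articles, scorer, sc)
      jsonlite::write_json(
        list(k = res$best$params$k, w = res$best$params$w,
             h = res$best$params$h, weights = res$best$params$weights,
             alpha = res$best$alpha, obj1 = res$best$obj1,
             obj2 = res$best$obj2, loss = res$best$loss),
        file.path(config$out_dir, "best_params.json"),
        auto_unbox = TRUE, digits = NA)
      utils::write.csv(res$trace, file.path(config$out_dir, "trace.csv"),
                       row.names = FALSE)
      res
    },
    "extract" = {
      require_fields(config, c("dataset", "scorer"), command)
      ds <- load_dataset(config)
      reader <- if (!is.null(config$reader_spec))
        read_reader_spec(config$reader_spec) else NULL
      estimator <- if (!is.null(config$estimator))
        read_estimator(config$estimator) else NULL
      scorer <- build_scorer(config$scorer, reader = reader,
                             estimator = estimator)
      params <- pipeline_params(config)
      out_path <- file.path(config$out_dir, "contexts.jsonl")
      con <- file(out_path, open = "wt")
      contexts <- list()
      for (ex in ds$examples) {
        ec <- extract_context(ex$question, ds$articles[[ex$article_ref]],
                              params, scorer, golds = ex$gold_answers)
        contexts[[ex$qid]] <- ec
        writeLines(jsonlite::toJSON(
          list(qid = ex$qid, sent_indices = ec$sent_indices,
               peak_indices = ec$peak_indices, text = ec$text),
          auto_unbox = TRUE, digits = NA), con)
      }
      close(con)
      contexts
    },
    "evaluate" = {
      require_fields(config, c("dataset", "policy", "reader_spec"), command)
      ds <- load_dataset(config)
      reader <- read_reader_spec(config$reader_spec)
      scorer <- if (identical(config$policy, "extraction"))
        build_scorer(if (is.null(config$scorer)) "oracle-u2" else
                       config$scorer, reader = reader) else NULL
      params <- if (identical(config$policy, "extraction"))
        pipeline_params(config) else NULL
      res <- evaluate_policy(ds$examples, ds$articles, reader,
                             policy = config$policy, params = params,
                             scorer = scorer, seed = seed)
      write_eval_records(res$records, file.path(config$out_dir, "eval.jsonl"))
      jsonlite::write_json(
        list(policy = config$policy, mean_f1 = res$mean_f1,
             mean_em = res$mean_em, n = nrow(res$records)),
        file.path(config$out_dir, "summary.json"), auto_unbox = TRUE,
        digits = NA)
      res
    },
    "compare" = {
      require_fields(config, c("a", "b"), command)
      ra <- read_eval_records(config$a)
      rb <- read_eval_records(config$b)
      thr <- if (is.null(config$threshold)) 0.5 else config$threshold
      tally <- significant_changes(ra, rb, threshold = thr)
      jsonlite::write_json(unclass(tally),
                           file.path(config$out_dir, "tally.json"),
                           auto_unbox = TRUE, digits = NA)
      tally
    })

  write_manifest(config$out_dir, command, config)
  invisible(result)
}

pipeline_params <- function(config) {
  p <- config$params
  if (is.character(p)) p <- jsonlite::fromJSON(p)
  if (is.null(p)) return(extraction_params())
  extraction_params(k = if (is.null(p$k)) 3L else p$k,
                    w = if (is.null(p$w)) 2L else p$w,
                    h = if (is.null(p$h)) 0.8 else p$h,
                    weights = if (is.null(p$weights)) c(1, 1, 1) else
                      as.numeric(unlist(p$weights)))
}
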