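#' Context-level word F1 against the target paragraph
#'
#' Words are lowercased, punctuation-stripped whitespace tokens (plain word
#' counts — unlike answer scoring, no article removal). Correct words are the
#' multiset intersection between the selected context and the target
#' paragraph; precision divides by the selected word count, recall by the
#' target word count. An empty selection scores all zeros; an empty target is
#' an error.
#'
#' @param selected_text the selected context string.
#' @param target_text the target paragraph string (non-empty).
#' @return a list with `precision`, `recall`, `f1`.
#' @export
context_f1 <- function(selected_text, target_text) {
  tt <- tokenize_words(target_text)
  if (length(tt) == 0L) stop("empty target paragraph", call. = FALSE)
  st <- tokenize_words(selected_text)
  if (length(st) == 0L) return(list(precision = 0, recall = 0, f1 = 0))
  ov <- multiset_overlap(st, tt)
  p <- ov / length(st)
  r <- ov / length(tt)
  f1 <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  list(precision = p, recall = r, f1 = f1)
}

#' Gold-sentence selection accuracy (obj1)
#'
#' Fraction of examples whose gold sentence index appears in the selected
#' context's sentence indices.
#'
#' @param contexts a named list (by qid) of [extract_context()] results, or
#'   of integer vectors of selected sentence indices.
#' @param examples list of [qa_example()] objects with gold sentences.
#' @return numeric scalar in \[0, 1\].
#' @export
obj1_accuracy <- function(contexts, examples) {
  qids <- vapply(examples, function(e) e$qid, character(1))
  missing <- setdiff(qids, names(contexts))
  if (length(missing) > 0L)
    stop("missing contexts for qids: ", paste(missing, collapse = ", "),
         call. = FALSE)
  hits <- vapply(examples, function(e) {
    ctx <- contexts[[e$qid]]
    idx <- if (inherits(ctx, "extracted_context")) ctx$sent_indices else
      as.integer(ctx)
    any(e$gold_sent_indices %in% idx)
  }, logical(1))
  mean(hits)
}

#' Scalarized optimization loss over the two context objectives
#'
#' Combines gold-sentence selection accuracy (obj1) and mean context F1
#' against the target paragraph (obj2) with trade-off weight `alpha`. Two
#' sign conventions are provided: `maximize_both` rewards both objectives,
#' `L = -(alpha*obj1 + (1-alpha)*obj2)`; `as_printed` keeps
#' `L = -(alpha*obj1) + (1-alpha)*obj2`, which penalizes context F1. The
#' conventions agree whenever obj2 = 0; `maximize_both` is the default.
#'
#' @param obj1,obj2 objective values in \[0, 1\].
#' @param alpha trade-off weight in \[0, 1\].
#' @param sign_convention `"maximize_both"` (default) or `"as_printed"`.
#' @return numeric loss (lower is better).
#' @export
extraction_loss <- function(obj1, obj2, alpha,
                            sign_convention = c("maximize_both", "as_printed")) {
  sign_convention <- match.arg(sign_convention)
  stopifnot(obj1 >= 0, obj1 <= 1, obj2 >= 0, obj2 <= 1,
            alpha >= 0, alpha <= 1)
  if (sign_convention == "maximize_both") {
    -(alpha * obj1 + (1 - alpha) * obj2)
  } else {
    -(alpha * obj1) + (1 - alpha) * obj2
  }
}

#' Evaluate the extraction objectives for one parameter set
#'
#' Runs [extract_context()] over every example and measures obj1 (fraction
#' of contexts containing the gold sentence) and obj2 (mean context F1
#' against the target paragraph).
#'
#' @param examples list of [qa_example()] objects.
#' @param articles named list of [qa_article()] objects.
#' @param params an [extraction_params()].
#' @param scorer a sentence scorer.
#' @param embedder embedder for retrieval.
#' @return a list with `obj1`, `obj2`, and `contexts` (named by qid).
#' @export
extraction_objectives <- function(examples, articles, params, scorer,
                                  embedder = hashed_embedder()) {
  contexts <- list()
  cf1 <- numeric(0)
  for (ex in examples) {
    art <- articles[[ex$article_ref]]
    ec <- extract_context(ex$question, art, params, scorer,
                          golds = ex$gold_answers, embedder = embedder)
    contexts[[ex$qid]] <- ec
    cf1 <- c(cf1, context_f1(ec$text, target_paragraph_text(ex, art))$f1)
  }
  list(obj1 = obj1_accuracy(contexts, examples), obj2 = mean(cf1),
       contexts = contexts)
}

#' Search configuration for the extraction-parameter optimization
#'
#' @param budget evaluations per alpha value (>= 1).
#' @param seed integer seed driving all draws.
#' @param backend `"random"` (seeded uniform search, default) or
#'   `"model_based"` (half the budget random, then local refinement around
#'   the incumbent).
#' @param alpha_grid the alpha sweep (default 0.05 to 0.95 in steps of 0.05).
#' @param bounds list with elements `k` (integer range), `w` (integer range),
#'   `h` (range in \[0, 1\]) and `omega` (range in (0, 1\]) for each weight.
#' @param sign_convention forwarded to [extraction_loss()].
#' @return an object of class `search_config`.
#' @export
search_config <- function(budget = 25L, seed = 0L,
                          backend = c("random", "model_based"),
                          alpha_grid = seq(0.05, 0.95, by = 0.05),
                          bounds = list(k = c(1L, 10L), w = c(1L, 5L),
                                        h = c(0, 1), omega = c(0.05, 1)),
                          sign_convention = c("maximize_both", "as_printed")) {
  backend <- match.arg(backend)
  sign_convention <- match.arg(sign_convention)
  stopifnot(budget >= 1L, all(alpha_grid >= 0), all(alpha_grid <= 1))
  structure(list(budget = as.integer(budget), seed = as.integer(seed),
                 backend = backend, alpha_grid = alpha_grid, bounds = bounds,
                 sign_convention = sign_convention),
            class = "search_config")
}

draw_params_uniform <- function(bounds) {
  extraction_params(
    k = sample(bounds$k[1]:bounds$k[2], 1L),
    w = sample(bounds$w[1]:bounds$w[2], 1L),
    h = stats::runif(1, bounds$h[1], bounds$h[2]),
    weights = stats::runif(3, bounds$omega[1], bounds$omega[2]))
}

draw_params_local <- function(bounds, incumbent) {
  clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  jit_int <- function(v, rng) {
    as.integer(clip(v + sample(-1:1, 1L), rng[1], rng[2]))
  }
  extraction_params(
    k = jit_int(incumbent$k, bounds$k),
    w = jit_int(incumbent$w, bounds$w),
    h = clip(incumbent$h + stats::rnorm(1, 0, 0.1 * diff(bounds$h)),
             bounds$h[1], bounds$h[2]),
    weights = clip(incumbent$weights +
                     stats::rnorm(3, 0, 0.1 * diff(bounds$omega)),
                   bounds$omega[1], bounds$omega[2]))
}

#' Seeded search over the extraction parameters with an alpha sweep
#'
#' For each alpha on the grid, runs `budget` evaluations of
#' extract -> (obj1, obj2) -> loss and returns the global minimum-loss
#' breakdown plus the full evaluation trace. The default backend is seeded
#' uniform random search; the `model_based` backend spends half the budget
#' uniformly and then refines locally around the incumbent. Deterministic
#' given the config seed.
#'
#' @inheritParams extraction_objectives
#' @param config a [search_config()].
#' @return a list with `best` (list of `params`, `obj1`, `obj2`, `alpha`,
#'   `loss`) and `trace` (data.frame, one row per evaluation).
#' @export
search_params <- function(examples, articles, scorer, config = search_config(),
                          embedder = hashed_embedder()) {
  stopifnot(inherits(config, "search_config"))
  trace <- list()
  best <- NULL
  n_failed <- 0L
  with_seed(config$seed, {
    for (alpha in config$alpha_grid) {
      incumbent <- NULL
      incumbent_loss <- Inf
      for (b in seq_len(config$budget)) {
        explore <- config$backend == "random" || is.null(incumbent) ||
          b <= ceiling(config$budget / 2)
        params <- if (explore) draw_params_uniform(config$bounds) else
          draw_params_local(config$bounds, incumbent)
        obj <- tryCatch(
          extraction_objectives(examples, articles, params, scorer, embedder),
          error = function(e) NULL)
        if (is.null(obj)) {
          n_failed <- n_failed + 1L
          next
        }
        loss <- extraction_loss(obj$obj1, obj$obj2, alpha,
                                config$sign_convention)
        trace[[length(trace) + 1L]] <- data.frame(
          alpha = alpha, eval = b, k = params$k, w = params$w, h = params$h,
          w1 = params$weights[1], w2 = params$weights[2],
          w3 = params$weights[3], obj1 = obj$obj1, obj2 = obj$obj2,
          loss = loss, stringsAsFactors = FALSE)
        if (loss < incumbent_loss) {
          incumbent <- params
          incumbent_loss <- loss
        }
        if (is.null(best) || loss < best$loss) {
          best <- list(params = params, obj1 = obj$obj1, obj2 = obj$obj2,
                       alpha = alpha, loss = loss)
        }
      }
    }
  })
  if (is.null(best))
    stop("all ", n_failed, " parameter evaluations failed", call. = FALSE)
  list(best = best, trace = do.call(rbind, trace))
}
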