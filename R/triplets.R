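# Run code under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

triplet_scenarios <- function() {
  c("target_paragraph", "neighborhood_excl_gold", "adjacent_paragraph",
    "distant_or_foreign")
}

# Build one scenario context for an example. Returns list(sentences, article_id)
# or NULL with attribute "reason" when the scenario is unsatisfiable.
build_scenario_context <- function(scenario, example, article, articles) {
  para <- article$paragraphs
  sent <- article$sentences
  tp <- example$target_para_indices[1L]
  g <- example$gold_sent_indices[1L]
  para_sents <- function(art, p) {
    art$sentences$text[art$sentences$para_index == p]
  }
  unsat <- function(reason) structure(list(), unsat = reason)

  if (scenario == "target_paragraph") {
    return(list(sentences = para_sents(article, tp), article_id = article$article_id))
  }
  if (scenario == "neighborhood_excl_gold") {
    pos <- sent$sent_index[sent$para_index == tp]
    if (length(pos) <= 1L)
      return(unsat("target paragraph has only the gold sentence"))
    for (try in 1:20) {
      L <- sample(1:5, 1L)
      L <- min(L, length(pos))
      start <- sample(seq_len(length(pos) - L + 1L), 1L)
      run <- pos[start:(start + L - 1L)]
      run <- setdiff(run, g)
      if (length(run) > 0L)
        return(list(sentences = sent$text[sent$sent_index %in% run],
                    article_id = article$article_id))
    }
    return(unsat("could not place a run excluding the gold sentence"))
  }
  if (scenario == "adjacent_paragraph") {
    if (nrow(para) <= 1L) return(unsat("single-paragraph article"))
    adj <- if (tp > 0L) tp - 1L else tp + 1L  # prefer the preceding paragraph
    return(list(sentences = para_sents(article, adj),
                article_id = article$article_id))
  }
  if (scenario == "distant_or_foreign") {
    other_ids <- setdiff(names(articles), article$article_id)
    use_foreign <- length(other_ids) > 0L && stats::runif(1) < 0.5
    if (use_foreign) {
      oa <- articles[[sample(other_ids, 1L)]]
      p <- sample(oa$paragraphs$para_index, 1L)
      return(list(sentences = para_sents(oa, p), article_id = oa$article_id))
    }
    if (nrow(para) <= 1L) return(unsat("single-paragraph article, no other article"))
    dist <- abs(para$para_index - tp)
    far <- para$para_index[which.max(dist)]
    return(list(sentences = para_sents(article, far),
                article_id = article$article_id))
  }
  stop("unknown scenario: ", scenario, call. = FALSE)
}

#' Generate question-sentence-context utility triplets
#'
#' Builds labeled training samples for a utility estimator under four
#' context-quality scenarios per question: (1) `target_paragraph` — the
#' target paragraph verbatim (sufficient information); (2)
#' `neighborhood_excl_gold` — a contiguous run of 1 to 5 sentences within the
#' target paragraph with the gold sentence removed (relevant but
#' insufficient); (3) `adjacent_paragraph` — a paragraph adjacent to the
#' target (somewhat relevant, not needed); (4) `distant_or_foreign` — with
#' probability 0.5 each, the paragraph furthest from the target or a
#' paragraph from another article (irrelevant). One focus sentence is drawn
#' uniformly from each built context and its u1/u2 labels are computed by
#' leave-one-out with the supplied reader. Deterministic given the seed;
#' unsatisfiable scenarios are skipped and tallied.
#'
#' @param examples list of [qa_example()] objects with derived gold sentences
#'   and target paragraphs.
#' @param articles named list of [qa_article()] objects.
#' @param reader a reader (see [read_answer()]).
#' @param per_question named integer vector: draws per scenario per question
#'   (names must be the four scenario tags).
#' @param seed integer seed.
#' @param cache a [reader_cache()].
#' @return a data.frame of triplets (columns `qid`, `question`, `scenario`,
#'   `context_article`, `context_text`, `focus_text`, `focus_pos`,
#'   `u1_label`, `u2_label`, `seed`, `draw`) with a `"skips"` attribute
#'   (data.frame of `qid`, `scenario`, `reason`).
#' @export
generate_triplets <- function(examples, articles, reader,
                              per_question = c(target_paragraph = 1L,
                                               neighborhood_excl_gold = 2L,
                                               adjacent_paragraph = 1L,
                                               distant_or_foreign = 1L),
                              seed = 0L, cache = reader_cache()) {
  stopifnot(all(names(per_question) %in% triplet_scenarios()))
  rows <- list()
  skips <- list()
  with_seed(seed, {
    for (ex in examples) {
      if (length(ex$gold_sent_indices) == 0L ||
          length(ex$target_para_indices) == 0L) {
        skips[[length(skips) + 1L]] <-
          data.frame(qid = ex$qid, scenario = NA_character_,
                     reason = "no locatable gold sentence / target paragraph",
                     stringsAsFactors = FALSE)
        next
      }
      art <- articles[[ex$article_ref]]
      for (scen in names(per_question)) {
        for (draw in seq_len(per_question[[scen]])) {
          ctx <- build_scenario_context(scen, ex, art, articles)
          reason <- attr(ctx, "unsat")
          if (!is.null(reason)) {
            skips[[length(skips) + 1L]] <-
              data.frame(qid = ex$qid, scenario = scen, reason = reason,
                         stringsAsFactors = FALSE)
            next
          }
          sents <- ctx$sentences
          fpos <- sample(length(sents), 1L)
          lab <- sentence_utilities(ex$question, sents, reader,
                                    golds = ex$gold_answers,
                                    signals = c("u1", "u2"), cache = cache)
          rows[[length(rows) + 1L]] <- data.frame(
            qid = ex$qid, question = ex$question, scenario = scen,
            context_article = ctx$article_id,
            context_text = render_context(sents),
            focus_text = sents[fpos], focus_pos = fpos,
            u1_label = lab$u1[fpos], u2_label = lab$u2[fpos],
            seed = seed, draw = draw, stringsAsFactors = FALSE)
        }
      }
    }
  })
  out <- if (length(rows) == 0L) {
    data.frame(qid = character(0), question = character(0),
               scenario = character(0), context_article = character(0),
               context_text = character(0), focus_text = character(0),
               focus_pos = integer(0), u1_label = numeric(0),
               u2_label = numeric(0), seed = integer(0), draw = integer(0),
               stringsAsFactors = FALSE)
  } else do.call(rbind, rows)
  attr(out, "skips") <- if (length(skips) == 0L) {
    data.frame(qid = character(0), scenario = character(0),
               reason = character(0), stringsAsFactors = FALSE)
  } else do.call(rbind, skips)
  out
}

#' Recompute a triplet's labels from its stored context
#'
#' Re-segments the stored context text and recomputes u1/u2 for the focus
#' sentence; used to assert label consistency.
#'
#' @param triplet one row of a [generate_triplets()] data.frame.
#' @param reader the reader used at generation time.
#' @param golds the example's gold answers.
#' @return a list with `u1` and `u2`.
#' @export
recompute_triplet_labels <- function(triplet, reader, golds) {
  segs <- segment_sentences(triplet$context_text)
  lab <- sentence_utilities(triplet$question, segs$text, reader, golds = golds,
                            signals = c("u1", "u2"))
  list(u1 = lab$u1[triplet$focus_pos], u2 = lab$u2[triplet$focus_pos])
}

#' Per-scenario label distribution summary
#'
#' Mean and standard deviation of the u1/u2 labels per generation scenario.
#' With a scripted reader the mean ordering follows context quality:
#' target paragraph > gold-excluded neighborhood > adjacent paragraph >=
#' distant/foreign.
#'
#' @param triplets a [generate_triplets()] data.frame.
#' @return a data.frame with one row per scenario present.
#' @export
label_distribution_report <- function(triplets) {
  if (nrow(triplets) == 0L) {
    return(data.frame(scenario = character(0), n = integer(0),
                      u1_mean = numeric(0), u1_sd = numeric(0),
                      u2_mean = numeric(0), u2_sd = numeric(0),
                      stringsAsFactors = FALSE))
  }
  scens <- intersect(triplet_scenarios(), unique(triplets$scenario))
  do.call(rbind, lapply(scens, function(s) {
    g <- triplets[triplets$scenario == s, ]
    data.frame(scenario = s, n = nrow(g),
               u1_mean = mean(g$u1_label), u1_sd = stats::sd(g$u1_label),
               u2_mean = mean(g$u2_label), u2_sd = stats::sd(g$u2_label),
               stringsAsFactors = FALSE)
  }))
}

#' Write triplets as JSON-lines
#' @param triplets a [generate_triplets()] data.frame.
#' @param path output `.jsonl` path.
#' @return `path`, invisibly.
#' @export
write_triplets <- function(triplets, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(triplets))) {
    writeLines(jsonlite::toJSON(as.list(triplets[i, ]), auto_unbox = TRUE,
                                digits = NA), con)
  }
  invisible(path)
}

#' Read triplets from JSON-lines
#' @param path path written by [write_triplets()].
#' @return a data.frame.
#' @export
read_triplets <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) return(generate_triplets(list(), list(), NULL))
  do.call(rbind, lapply(lines, function(l) {
    as.data.frame(jsonlite::fromJSON(l), stringsAsFactors = FALSE)
  }))
}
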