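policy_names <- function() {
  c("original", "retriever_topk", "target_paragraph", "extraction",
    "random_paragraph")
}

# Selected sentence indices for the non-extraction policies.
policy_sentences <- function(example, article, policy, k, embedder,
                             random_para = NULL) {
  s <- article$sentences
  switch(policy,
    original = s$sent_index,
    retriever_topk = {
      sel <- rank_paragraphs(example$question, article, k, embedder)$para_index
      s$sent_index[s$para_index %in% sel]
    },
    target_paragraph = {
      sel <- target_paragraphs(example, article)$para_index
      s$sent_index[s$para_index %in% sel]
    },
    random_paragraph = s$sent_index[s$para_index == random_para])
}

#' Evaluate a context policy on a dataset
#'
#' Builds the context for every example under the chosen policy, runs the
#' reader, and scores the answers (best-over-references token F1 and exact
#' match). `random_paragraph` — a uniformly drawn single paragraph — is a
#' floor policy for ordering checks. Reader failures on single examples are
#' recorded as abstentions (with a warning), not raised.
#'
#' @param examples list of [qa_example()] objects.
#' @param articles named list of [qa_article()] objects.
#' @param reader a reader (see [read_answer()]).
#' @param policy one of `"original"`, `"retriever_topk"`,
#'   `"target_paragraph"`, `"extraction"`, `"random_paragraph"`.
#' @param params an [extraction_params()] (required for `"extraction"`).
#' @param scorer a sentence scorer (required for `"extraction"`).
#' @param k paragraphs for `"retriever_topk"`.
#' @param embedder embedder for retrieval-based policies.
#' @param seed seed for the `"random_paragraph"` draw.
#' @return a list with `mean_f1`, `mean_em` and `records` (one data.frame row
#'   per example: `qid`, `policy`, `answer_text`, `confidence`, `abstained`,
#'   `answer_f1`, `exact_match`, `context_len_sentences`, `gold_in_context`).
#' @export
evaluate_policy <- function(examples, articles, reader,
                            policy = policy_names(), params = NULL,
                            scorer = NULL, k = 6L,
                            embedder = hashed_embedder(), seed = 0L) {
  policy <- match.arg(policy)
  if (policy == "extraction")
    stopifnot(inherits(params, "extraction_params"), is.function(scorer))
  random_paras <- if (policy == "random_paragraph") {
    with_seed(seed, lapply(examples, function(ex) {
      sample(articles[[ex$article_ref]]$paragraphs$para_index, 1L)
    }))
  } else NULL

  rows <- list()
  for (i in seq_along(examples)) {
    ex <- examples[[i]]
    art <- articles[[ex$article_ref]]
    if (policy == "extraction") {
      ec <- extract_context(ex$question, art, params, scorer,
                            golds = ex$gold_answers, embedder = embedder)
      idx <- ec$sent_indices
      context <- ec$text
    } else {
      idx <- policy_sentences(ex, art, policy, k, embedder,
                              random_para = random_paras[[i]])
      context <- render_context(art$sentences$text[art$sentences$sent_index %in% idx])
    }
    pred <- tryCatch(read_answer(reader, ex$question, context),
                     error = function(e) {
                       warning(sprintf("reader failed on '%s': %s", ex$qid,
                                       conditionMessage(e)), call. = FALSE)
                       reader_prediction(abstain_marker(), NA_real_)
                     })
    sc <- best_over_references(pred$answer_text, ex$gold_answers)
    rows[[length(rows) + 1L]] <- data.frame(
      qid = ex$qid, policy = policy,
      answer_text = if (pred$abstained) NA_character_ else pred$answer_text,
      confidence = pred$confidence, abstained = pred$abstained,
      answer_f1 = sc$f1,
      exact_match = exact_match(pred$answer_text, ex$gold_answers),
      context_len_sentences = length(idx),
      gold_in_context = any(ex$gold_sent_indices %in% idx),
      stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, rows)
  list(mean_f1 = mean(records$answer_f1),
       mean_em = mean(records$exact_match),
       records = records)
}

#' Tally significant prediction changes between two policies
#'
#' Compares per-example answer F1 of a candidate policy (`records_b`) against
#' a reference policy (`records_a`, typically the original article). A change
#' is significant when |delta F1| exceeds the threshold strictly (ties at the
#' threshold count in neither direction). Among the worse cases, those whose
#' candidate context still contained the gold sentence are tallied
#' separately: there the drop is not attributable to context selection.
#'
#' @param records_a,records_b record data.frames from [evaluate_policy()]
#'   over the same qids.
#' @param threshold significance threshold on |delta F1| (default 0.5).
#' @return a list of class `change_tally` with `better`, `worse`,
#'   `worse_with_good_context`, `threshold`, `n`.
#' @export
significant_changes <- function(records_a, records_b, threshold = 0.5) {
  if (!setequal(records_a$qid, records_b$qid))
    stop("record sets cover different qids", call. = FALSE)
  b <- records_b[match(records_a$qid, records_b$qid), ]
  d <- b$answer_f1 - records_a$answer_f1
  worse <- d < -threshold
  structure(list(better = sum(d > threshold),
                 worse = sum(worse),
                 worse_with_good_context = sum(worse & b$gold_in_context),
                 threshold = threshold, n = nrow(records_a)),
            class = "change_tally")
}

#' @export
print.change_tally <- function(x, ...) {
  cat(sprintf(paste0("<change_tally over %d cases (|dF1| > %.2g): ",
                     "%d better, %d worse (%d with the gold sentence selected)>\n"),
              x$n, x$threshold, x$better, x$worse, x$worse_with_good_context))
  invisible(x)
}

#' Write evaluation records as JSON-lines
#' @param records a record data.frame from [evaluate_policy()].
#' @param path output `.jsonl` path.
#' @return `path`, invisibly.
#' @export
write_eval_records <- function(records, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    writeLines(jsonlite::toJSON(as.list(records[i, ]), auto_unbox = TRUE,
                                digits = NA, na = "null"), con)
  }
  invisible(path)
}

#' Read evaluation records from JSON-lines
#' @param path path written by [write_eval_records()].
#' @return a data.frame.
#' @export
read_eval_records <- function(path) {
  do.call(rbind, lapply(readLines(path), function(l) {
    x <- jsonlite::fromJSON(l)
    x$answer_text <- if (is.null(x$answer_text)) NA_character_ else x$answer_text
    as.data.frame(x, stringsAsFactors = FALSE)
  }))
}
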