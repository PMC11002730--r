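#' Context-extraction parameters
#'
#' The six tunable parameters of the peak-and-window extraction algorithm:
#' `k` retrieved paragraphs, window radius `w` (sentences), relative peak
#' threshold `h` in \[0, 1\], and the three positive ensemble weights.
#'
#' @param k number of paragraphs retrieved as candidates (>= 1).
#' @param w window radius in sentences around each peak (>= 1).
#' @param h peak threshold as a fraction of the tallest score, in \[0, 1\].
#' @param weights positive ensemble weights `c(w1, w2, w3)` for u1, u2, u3.
#' @return an object of class `extraction_params`.
#' @export
extraction_params <- function(k = 3L, w = 2L, h = 0.8, weights = c(1, 1, 1)) {
  stopifnot(k >= 1L, w >= 1L, h >= 0, h <= 1,
            length(weights) == 3L, all(weights > 0))
  structure(list(k = as.integer(k), w = as.integer(w), h = as.numeric(h),
                 weights = as.numeric(weights)),
            class = "extraction_params")
}

#' @export
print.extraction_params <- function(x, ...) {
  cat(sprintf("<extraction_params k=%d w=%d h=%.3g weights=(%s)>\n",
              x$k, x$w, x$h, paste(signif(x$weights, 3), collapse = ", ")))
  invisible(x)
}

# ---- scorer constructors ---------------------------------------------------
# A sentence scorer is a function (question, sentences, golds) -> named list
# holding any of u1, u2, u3 as numeric vectors over `sentences`.

#' Oracle sentence scorer from a reader
#'
#' Scores candidate sentences by true leave-one-sentence-out utility
#' computed with the supplied reader: u1 (needs golds at call time) and/or u2.
#'
#' @param reader a reader (see [read_answer()]).
#' @param signals subset of `c("u1", "u2")`.
#' @param cache a [reader_cache()] shared across questions.
#' @return a sentence scorer function.
#' @export
oracle_scorer <- function(reader, signals = "u2", cache = reader_cache()) {
  signals <- match.arg(signals, c("u1", "u2"), several.ok = TRUE)
  function(question, sentences, golds = NULL) {
    sentence_utilities(question, sentences, reader, golds = golds,
                       signals = signals, cache = cache)
  }
}

#' Cosine-similarity sentence scorer (u3)
#'
#' @param embedder an embedder function.
#' @return a sentence scorer function producing `u3`.
#' @export
cosine_scorer <- function(embedder = hashed_embedder()) {
  function(question, sentences, golds = NULL) {
    list(u3 = vapply(sentences, cosine_score, numeric(1), question = question,
                     embedder = embedder, USE.NAMES = FALSE))
  }
}

#' Estimator-based sentence scorer
#'
#' Scores sentences with a fitted utility estimator; the estimates fill the
#' utility slot the estimator was trained on (u1 or u2).
#'
#' @param estimator a [fit_utility_estimator()] model.
#' @param embedder an embedder function.
#' @return a sentence scorer function.
#' @export
estimator_scorer <- function(estimator, embedder = hashed_embedder()) {
  slot <- estimator$label
  function(question, sentences, golds = NULL) {
    ctx <- render_context(sentences)
    est <- vapply(sentences, estimate_utility, numeric(1),
                  estimator = estimator, question = question, context = ctx,
                  embedder = embedder, USE.NAMES = FALSE)
    stats::setNames(list(est), slot)
  }
}

#' Merge several sentence scorers
#'
#' @param ... sentence scorer functions; later scorers win on slot clashes.
#' @return a sentence scorer function producing the union of their signals.
#' @export
combine_scorers <- function(...) {
  scorers <- list(...)
  function(question, sentences, golds = NULL) {
    out <- list()
    for (sc in scorers) out <- utils::modifyList(out, sc(question, sentences, golds))
    out
  }
}

# ---- the extraction algorithm ---------------------------------------------

#' Extract a short context around sentence-utility peaks
#'
#' The core extraction algorithm: (1) retrieve the top-`k` paragraphs as the
#' candidate set; (2) score every candidate sentence with the supplied
#' scorer and combine the signals with [ensemble_utility()]; (3) mark as
#' peaks all candidates whose score is at least `h` times the tallest score;
#' (4) add the sentences within `w` article positions of each peak,
#' restricted to the candidate set (a window never imports sentences from
#' non-retrieved paragraphs); (5) the context is the union, in document
#' order, joined by single spaces.
#'
#' If the tallest combined score is not positive (degenerate all-equal raw
#' scores rescale to all zeros), a relative threshold is meaningless; the
#' fallback keeps only the earliest argmax and its window rather than the
#' whole candidate set. With `rescale = FALSE`, equal positive scores all tie
#' as peaks and every candidate is selected.
#'
#' @param question the question string.
#' @param article a [qa_article()].
#' @param params an [extraction_params()].
#' @param scorer a sentence scorer (see [oracle_scorer()],
#'   [cosine_scorer()], [estimator_scorer()], [combine_scorers()]).
#' @param golds gold answers, forwarded to the scorer (needed for u1).
#' @param embedder embedder for the paragraph retrieval step.
#' @param rescale rescale each signal per question before the ensemble.
#' @param peak_mode `"global"` (relative-threshold peaks, default) or
#'   `"local"` (additionally require a local maximum), kept for comparison.
#' @return an object of class `extracted_context`: `sent_indices` (0-based,
#'   strictly increasing), `peak_indices`, `text`, and `scores` (data.frame
#'   of per-candidate signals and combined utility).
#' @export
extract_context <- function(question, article, params, scorer, golds = NULL,
                            embedder = hashed_embedder(), rescale = TRUE,
                            peak_mode = c("global", "local")) {
  peak_mode <- match.arg(peak_mode)
  stopifnot(inherits(params, "extraction_params"))
  if (nrow(article$sentences) == 0L)
    stop("article has no sentences; nothing to extract", call. = FALSE)
  ranked <- rank_paragraphs(question, article, params$k, embedder)
  cand <- article$sentences[article$sentences$para_index %in% ranked$para_index,
                            , drop = FALSE]
  if (nrow(cand) == 0L)
    stop("retrieved paragraphs contain no sentences", call. = FALSE)

  signals <- scorer(question, cand$text, golds)
  u <- ensemble_utility(signals$u1, signals$u2, signals$u3,
                        weights = params$weights, rescale = rescale)

  m <- max(u)
  peaks_pos <- if (m > 0) {
    which(u >= params$h * m)
  } else {
    which.max(u)  # degenerate scores: earliest argmax only
  }
  if (peak_mode == "local" && length(u) > 1L) {
    is_locmax <- vapply(seq_along(u), function(i) {
      left <- if (i == 1L) -Inf else u[i - 1L]
      right <- if (i == length(u)) -Inf else u[i + 1L]
      u[i] >= left && u[i] >= right
    }, logical(1))
    keep <- peaks_pos[is_locmax[peaks_pos]]
    if (length(keep) > 0L) peaks_pos <- keep
  }

  cs <- cand$sent_index
  sel_pos <- sort(unique(unlist(lapply(peaks_pos, function(p) {
    which(abs(cs - cs[p]) <= params$w)
  }))))

  scores <- data.frame(sent_index = cs, stringsAsFactors = FALSE)
  for (slot in c("u1", "u2", "u3"))
    scores[[slot]] <- if (is.null(signals[[slot]])) NA_real_ else signals[[slot]]
  scores$u <- u

  structure(list(sent_indices = cs[sel_pos],
                 peak_indices = cs[peaks_pos],
                 candidate_sent_indices = cs,
                 text = render_context(cand$text[sel_pos]),
                 scores = scores),
            class = "extracted_context")
}

#' @export
print.extracted_context <- function(x, ...) {
  cat(sprintf("<extracted_context: %d of %d candidate sentences, %d peak(s)>\n",
              length(x$sent_indices), length(x$candidate_sent_indices),
              length(x$peak_indices)))
  invisible(x)
}

#' Baseline context policies
#'
#' The three reference context designs against which extraction is compared:
#' `original` feeds the whole article; `retriever_topk` concatenates the
#' top-`k` retrieved paragraphs (default `k = 6`) in document order with the
#' paragraph separator; `target_paragraph` feeds the target paragraph(s) —
#' the near-ideal, human-like selection (aggregated paragraphs joined for
#' offset-free examples).
#'
#' @param example a [qa_example()].
#' @param article the owning [qa_article()].
#' @param mode one of `"original"`, `"retriever_topk"`, `"target_paragraph"`.
#' @param k paragraphs to retrieve for `retriever_topk`.
#' @param embedder embedder for `retriever_topk`.
#' @return the context string.
#' @export
baseline_context <- function(example, article,
                             mode = c("original", "retriever_topk",
                                      "target_paragraph"),
                             k = 6L, embedder = hashed_embedder()) {
  mode <- match.arg(mode)
  switch(mode,
    original = article$raw_text,
    retriever_topk = paste(
      rank_paragraphs(example$question, article, k, embedder)$text,
      collapse = paragraph_separator()),
    target_paragraph = target_paragraph_text(example, article))
}
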