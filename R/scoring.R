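#' Deterministic hashed bag-of-words embedder
#'
#' The default text embedder: a term-frequency vector over normalized tokens,
#' hashed into a fixed number of buckets with a seeded polynomial rolling
#' hash, L2-normalized. A deterministic, dependency-light stand-in for a
#' trained bi-encoder; unit norm holds to 1e-9 for any non-empty token set.
#'
#' @param dim number of hash buckets (default 2^16).
#' @param seed integer hash seed (part of the embedding definition, fixed by
#'   default).
#' @return a function `(text) -> named numeric vector` (names are bucket ids;
#'   empty vector when the text has no tokens).
#' @export
hashed_embedder <- function(dim = 65536L, seed = 17L) {
  force(dim); force(seed)
  hash_token <- function(tok) {
    h <- seed
    for (code in utf8ToInt(tok)) h <- (h * 31 + code) %% dim
    h
  }
  function(text) {
    toks <- normalize_answer(text)
    if (length(toks) == 0L) return(numeric(0))
    buckets <- vapply(toks, hash_token, numeric(1))
    tf <- tapply(rep(1, length(buckets)), as.character(buckets), sum)
    v <- as.numeric(tf)
    names(v) <- names(tf)
    v / sqrt(sum(v^2))
  }
}

#' Cosine similarity between a question and a text
#'
#' Dot product of the unit embeddings, in \[-1, 1\]; 0 when either text embeds
#' to the zero vector. With the default embedder this is the third sentence
#' utility signal, u3.
#'
#' @param question,text character scalars.
#' @param embedder an embedder function (see [hashed_embedder()]).
#' @return numeric scalar in \[-1, 1\].
#' @export
cosine_score <- function(question, text, embedder = hashed_embedder()) {
  va <- embedder(question)
  vb <- embedder(text)
  if (length(va) == 0L || length(vb) == 0L) return(0)
  common <- intersect(names(va), names(vb))
  if (length(common) == 0L) return(0)
  sum(va[common] * vb[common])
}

#' Rank an article's paragraphs against a question
#'
#' Paragraphs are scored by cosine similarity between the question and the
#' paragraph text, and the top `k` are selected (ties broken by document
#' order; all paragraphs when the article has fewer than `k`). By default the
#' selection is returned in document order, preserving article flow for
#' concatenated retrieval contexts; `order = "rank"` returns descending-score
#' order instead.
#'
#' @param question the question string.
#' @param article a [qa_article()].
#' @param k number of paragraphs to retrieve (>= 1).
#' @param embedder an embedder function.
#' @param order `"document"` (default) or `"rank"`.
#' @return the selected rows of `article$paragraphs`, with a `score` column.
#' @export
rank_paragraphs <- function(question, article, k, embedder = hashed_embedder(),
                            order = c("document", "rank")) {
  order <- match.arg(order)
  stopifnot(k >= 1L)
  para <- article$paragraphs
  scores <- vapply(para$text, cosine_score, numeric(1), question = question,
                   embedder = embedder, USE.NAMES = FALSE)
  ord <- base::order(-scores, para$para_index)  # ties: document order
  keep <- ord[seq_len(min(k, nrow(para)))]
  if (order == "document") keep <- sort(keep)
  out <- para[keep, , drop = FALSE]
  out$score <- scores[keep]
  rownames(out) <- NULL
  out
}

#' Top-k paragraph retrieval accuracy
#'
#' Fraction of examples whose any target paragraph appears among the `k`
#' highest-scoring paragraphs of its article, for each requested `k`;
#' monotone non-decreasing in `k`. Examples without a locatable target are
#' skipped and tallied.
#'
#' @param examples list of [qa_example()] objects with derived
#'   `target_para_indices`.
#' @param articles named list of [qa_article()] objects.
#' @param ks integer vector of cutoffs.
#' @param embedder an embedder function.
#' @return a list with `accuracy` (named numeric, one entry per k),
#'   `n_evaluated` and `n_excluded`.
#' @export
top_k_accuracy <- function(examples, articles, ks = 1:10,
                           embedder = hashed_embedder()) {
  stopifnot(all(ks >= 1L))
  kmax <- max(ks)
  hits <- matrix(NA, nrow = 0L, ncol = length(ks))
  n_excluded <- 0L
  for (ex in examples) {
    if (length(ex$target_para_indices) == 0L) {
      n_excluded <- n_excluded + 1L
      next
    }
    art <- articles[[ex$article_ref]]
    ranked <- rank_paragraphs(ex$question, art, k = kmax, embedder = embedder,
                              order = "rank")
    row <- vapply(ks, function(k) {
      any(utils::head(ranked$para_index, k) %in% ex$target_para_indices)
    }, logical(1))
    hits <- rbind(hits, row)
  }
  acc <- if (nrow(hits) == 0L) stats::setNames(rep(NA_real_, length(ks)), ks) else
    stats::setNames(colMeans(hits), ks)
  list(accuracy = acc, n_evaluated = nrow(hits), n_excluded = n_excluded)
}

#' A fresh reader-call cache
#'
#' Keyed on the exact (question, context string) pair, so utility computation
#' over S sentences costs S + 1 reader calls and repeated evaluations share
#' work.
#'
#' @return an environment usable as the `cache` argument of the utility
#'   functions.
#' @export
reader_cache <- function() new.env(parent = emptyenv())

cached_read <- function(reader, question, context, cache = NULL) {
  if (is.null(cache)) return(read_answer(reader, question, context))
  key <- paste(question, context, sep = "\x1f")
  hit <- cache[[key]]
  if (!is.null(hit)) return(hit)
  pred <- read_answer(reader, question, context)
  assign(key, pred, envir = cache)
  pred
}

render_context <- function(sentences) paste(sentences, collapse = " ")

#' Leave-one-sentence-out utility signals
#'
#' For a question q and a context D given as an ordered vector of sentences,
#' the utility of sentence c is the drop in answer quality when c is deleted
#' from D (remaining sentences joined in order by single spaces):
#' u1 = F1(q, D) - F1(q, D \\ c) uses the answer F1 against the gold
#' references; u2 = Conf(q, D) - Conf(q, D \\ c) uses the reader's confidence
#' and needs no golds. The full-context prediction is computed once and
#' shared across sentences (S + 1 reader calls for S sentences when a cache
#' is supplied).
#'
#' @param question the question string.
#' @param sentences character vector: the context sentences, in order.
#' @param reader a reader (see [read_answer()]).
#' @param golds gold answer strings (required for u1).
#' @param signals subset of `c("u1", "u2")`.
#' @param cache optional environment from [reader_cache()] shared across
#'   calls; reader failures are annotated with the offending sentence index.
#' @return a list with the requested signals, each a numeric vector over
#'   `sentences`.
#' @export
sentence_utilities <- function(question, sentences, reader, golds = NULL,
                               signals = c("u1", "u2"), cache = reader_cache()) {
  signals <- match.arg(signals, several.ok = TRUE)
  stopifnot(length(sentences) >= 1L)
  if ("u1" %in% signals && (is.null(golds) || length(golds) == 0L))
    stop("u1 requires non-empty gold references", call. = FALSE)
  full <- cached_read(reader, question, render_context(sentences), cache)
  f1_full <- if ("u1" %in% signals)
    best_over_references(full$answer_text, golds)$f1 else NA_real_
  out <- list()
  n <- length(sentences)
  u1 <- numeric(n); u2 <- numeric(n)
  for (i in seq_len(n)) {
    ctx <- render_context(sentences[-i])
    pred <- tryCatch(cached_read(reader, question, ctx, cache),
                     error = function(e) {
                       stop(sprintf("reader failed with sentence %d removed: %s",
                                    i, conditionMessage(e)), call. = FALSE)
                     })
    if ("u1" %in% signals)
      u1[i] <- f1_full - best_over_references(pred$answer_text, golds)$f1
    u2[i] <- full$confidence - pred$confidence
  }
  if ("u1" %in% signals) out$u1 <- u1
  if ("u2" %in% signals) out$u2 <- u2
  out
}

#' F1-based utility of one sentence (u1)
#'
#' @inheritParams sentence_utilities
#' @param sent_pos 1-based position of the focus sentence within `sentences`.
#' @return numeric scalar.
#' @export
utility_f1 <- function(question, sentences, sent_pos, reader, golds,
                       cache = reader_cache()) {
  stopifnot(sent_pos >= 1L, sent_pos <= length(sentences))
  u <- sentence_utilities(question, sentences, reader, golds, signals = "u1",
                          cache = cache)
  u$u1[sent_pos]
}

#' Confidence-based utility of one sentence (u2)
#'
#' @inheritParams utility_f1
#' @return numeric scalar.
#' @export
utility_conf <- function(question, sentences, sent_pos, reader,
                         cache = reader_cache()) {
  stopifnot(sent_pos >= 1L, sent_pos <= length(sentences))
  u <- sentence_utilities(question, sentences, reader, signals = "u2",
                          cache = cache)
  u$u2[sent_pos]
}

#' Min-max rescaling to \[0, 1\]
#'
#' Per-question calibration applied to each utility signal before the
#' ensemble: u2 is unbounded and reader-scaled while u3 lies in \[-1, 1\];
#' rescaling makes the ensemble weights interpretable and the peak threshold
#' h a meaningful relative quantity. An all-equal vector rescales to all
#' zeros.
#'
#' @param x numeric vector.
#' @return numeric vector in \[0, 1\].
#' @export
rescale01 <- function(x) {
  r <- range(x)
  if (!is.finite(r[1]) || !is.finite(r[2]) || r[1] == r[2])
    return(rep(0, length(x)))
  (x - r[1]) / (r[2] - r[1])
}

#' Weighted ensemble of sentence-utility signals
#'
#' u = (w1 u1 + w2 u2 + w3 u3) / (w1 + w2 + w3), over whichever signals are
#' present (`NULL` signals drop out of both numerator and denominator).
#' Weights must be positive; the nominal weight domain is (0, 1) but any
#' positive weights are accepted since only their ratios matter.
#'
#' @param u1,u2,u3 numeric vectors of equal length, or `NULL` when a signal
#'   is unavailable.
#' @param weights numeric vector `c(w1, w2, w3)` of positive weights.
#' @param rescale rescale each signal with [rescale01()] first (default).
#' @return numeric vector of ensembled utilities.
#' @export
ensemble_utility <- function(u1 = NULL, u2 = NULL, u3 = NULL,
                             weights = c(1, 1, 1), rescale = TRUE) {
  sig <- list(u1, u2, u3)
  present <- !vapply(sig, is.null, logical(1))
  if (!any(present)) stop("no utility signals supplied", call. = FALSE)
  stopifnot(length(weights) == 3L)
  w <- weights[present]
  if (any(w <= 0) || sum(w) <= 0)
    stop("ensemble weights must be positive", call. = FALSE)
  sig <- sig[present]
  n <- unique(vapply(sig, length, integer(1)))
  stopifnot(length(n) == 1L)
  if (rescale) sig <- lapply(sig, rescale01)
  num <- Reduce(`+`, Map(function(s, wi) wi * s, sig, w))
  num / sum(w)
}

# ---- baseline utility estimator -------------------------------------------

estimator_features <- function(question, sentence, context_text,
                               embedder = hashed_embedder()) {
  qt <- normalize_answer(question)
  st <- normalize_answer(sentence)
  segs <- segment_sentences(context_text)
  pos <- if (nrow(segs) == 0L) 0 else {
    hit <- which(segs$text == sentence)
    if (length(hit) == 0L) 0 else (hit[1L] - 1L) / max(1L, nrow(segs) - 1L)
  }
  c(overlap = multiset_overlap(st, qt),
    sent_len = length(st),
    position = pos,
    cosine = cosine_score(question, sentence, embedder))
}

#' Fit the baseline lexical utility estimator
#'
#' A ridge regression on four lexical features of (question, sentence,
#' context) — token overlap with the question, sentence length, relative
#' position in the context, and cosine similarity to the question — trained
#' on generated utility triplets (see [generate_triplets()]). It is the
#' desk-scale stand-in for a learned utility model behind the estimator
#' contract: any deterministic regressor with the same signature can replace
#' it.
#'
#' @param triplets a triplet data.frame from [generate_triplets()].
#' @param label which label to regress on: `"u2"` (default) or `"u1"`.
#' @param lambda ridge penalty (default 1e-3).
#' @param embedder an embedder function for the cosine feature.
#' @return an object of class `utility_estimator`.
#' @export
fit_utility_estimator <- function(triplets, label = c("u2", "u1"),
                                  lambda = 1e-3, embedder = hashed_embedder()) {
  label <- match.arg(label)
  stopifnot(nrow(triplets) >= 2L)
  y <- triplets[[paste0(label, "_label")]]
  X <- t(vapply(seq_len(nrow(triplets)), function(i) {
    estimator_features(triplets$question[i], triplets$focus_text[i],
                       triplets$context_text[i], embedder)
  }, numeric(4)))
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv == 0] <- 1
  Xs <- cbind(1, sweep(sweep(X, 2, mu), 2, sdv, "/"))
  p <- ncol(Xs)
  pen <- diag(lambda, p); pen[1, 1] <- 0  # intercept unpenalized
  w <- solve(crossprod(Xs) + pen, crossprod(Xs, y))
  structure(list(weights = as.numeric(w), feature_means = mu,
                 feature_sds = sdv, label = label),
            class = "utility_estimator")
}

#' Estimate the utility of a sentence in a context
#'
#' The estimator contract: `(question, sentence, context) -> real`.
#'
#' @param estimator a fitted [fit_utility_estimator()] model.
#' @param question,sentence,context character scalars.
#' @param embedder an embedder function (must match the one used at fit time).
#' @return numeric scalar.
#' @export
estimate_utility <- function(estimator, question, sentence, context,
                             embedder = hashed_embedder()) {
  stopifnot(inherits(estimator, "utility_estimator"))
  f <- estimator_features(question, sentence, context, embedder)
  fs <- (f - estimator$feature_means) / estimator$feature_sds
  sum(estimator$weights * c(1, fs))
}

#' @export
print.utility_estimator <- function(x, ...) {
  cat(sprintf("<utility_estimator on %s: weights %s>\n", x$label,
              paste(signif(x$weights, 3), collapse = ", ")))
  invisible(x)
}

#' Serialize estimator weights to JSON
#' @param estimator a [fit_utility_estimator()] model.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_estimator <- function(estimator, path) {
  jsonlite::write_json(unclass(estimator), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read estimator weights from JSON
#' @param path path written by [write_estimator()].
#' @return a `utility_estimator`.
#' @export
read_estimator <- function(path) {
  x <- jsonlite::fromJSON(path)
  structure(list(weights = as.numeric(x$weights),
                 feature_means = stats::setNames(as.numeric(x$feature_means),
                                                 names(x$feature_means)),
                 feature_sds = stats::setNames(as.numeric(x$feature_sds),
                                               names(x$feature_sds)),
                 label = x$label),
            class = "utility_estimator")
}
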