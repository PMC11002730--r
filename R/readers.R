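#' Reader predictions
#'
#' All readers return a `reader_prediction`: the answer text (or the
#' abstention marker), a real-valued confidence comparable across contexts for
#' the same question, and optionally the character span of the answer in the
#' supplied context.
#'
#' @param answer_text answer string or [abstain_marker()].
#' @param confidence numeric scalar.
#' @param char_span optional 0-based half-open span into the context.
#' @return an object of class `reader_prediction`.
#' @export
reader_prediction <- function(answer_text, confidence, char_span = NULL) {
  abst <- is_abstention(answer_text)
  if (abst && !is.null(char_span))
    stop("an abstention carries no char_span", call. = FALSE)
  structure(list(answer_text = if (abst) abstain_marker() else answer_text,
                 confidence = as.numeric(confidence),
                 abstained = abst,
                 char_span = char_span),
            class = "reader_prediction")
}

#' @export
print.reader_prediction <- function(x, ...) {
  cat(sprintf("<reader_prediction %s (confidence %.3g)>\n",
              if (x$abstained) "[abstained]" else shQuote(x$answer_text),
              x$confidence))
  invisible(x)
}

#' Answer a question from a context
#'
#' The pluggable reader contract: deterministic readers must return identical
#' predictions for identical `(question, context)` pairs, and confidences
#' must be comparable across contexts for a fixed question. An empty context
#' yields an abstention, never an error. An adapter for a transformer
#' extractive reader fits this seam by returning the predicted span and the
#' sum of its start and end scores as the confidence; no such adapter is
#' required by the package.
#'
#' @param reader a reader object (see [scripted_reader()],
#'   [overlap_reader()], [lookup_reader()]).
#' @param question a non-empty question string.
#' @param context the context string (may be empty).
#' @return a [reader_prediction()].
#' @export
read_answer <- function(reader, question, context) {
  stopifnot(is.character(question), length(question) == 1L, nzchar(question))
  if (length(context) != 1L || is.na(context)) context <- ""
  UseMethod("read_answer")
}

#' @export
read_answer.default <- function(reader, question, context) {
  if (is.function(reader)) return(reader(question, context))
  stop("not a reader: ", paste(class(reader), collapse = "/"), call. = FALSE)
}

#' A scripted reader with planted answer and support sentences
#'
#' A deterministic test double for an extractive reader. For each known
#' question it holds the answer text, the answer sentence, a set of support
#' sentences and a support threshold. The answer is emitted iff the answer
#' sentence is present in the context (exact sentence-text containment) and at
#' least `min_support` support sentences are present; confidence is then
#' `c_base + c_per_support * n_supports_present`. Otherwise the reader
#' abstains with confidence `c_abstain`. This mimics the qualitative behavior
#' of transformer readers on long articles: the answer sentence alone is
#' often insufficient, and confidence grows as corroborating sentences are
#' added.
#'
#' @param entries a named list keyed by question string; each element a list
#'   with `answer_text`, `answer_sentence` (the sentence's full text),
#'   `support_sentences` (character vector, possibly empty) and optionally
#'   per-question `min_support`.
#' @param min_support default support threshold (overridable per entry).
#' @param c_base,c_per_support,c_abstain confidence constants
#'   (`c_base >= 0`, `c_per_support >= 0`, typically `c_abstain < c_base`).
#' @return an object of classes `scripted_reader`, `qa_reader`.
#' @examples
#' rd <- scripted_reader(list(
#'   "What is x?" = list(answer_text = "x is y", answer_sentence = "x is y.",
#'                       support_sentences = c("y exists.", "x too."))),
#'   min_support = 1)
#' read_answer(rd, "What is x?", "y exists. x is y.")  # answered, conf 3.5
#' @export
scripted_reader <- function(entries, min_support = 1L, c_base = 2,
                            c_per_support = 1.5, c_abstain = 0.5) {
  stopifnot(is.list(entries), length(names(entries)) == length(entries),
            c_base >= 0, c_per_support >= 0)
  for (q in names(entries)) {
    e <- entries[[q]]
    stopifnot(!is.null(e$answer_text), !is.null(e$answer_sentence))
    if (is.null(e$support_sentences)) entries[[q]]$support_sentences <- character(0)
    if (!is.null(e$min_support))
      stopifnot(e$min_support <= length(e$support_sentences))
    stopifnot(!e$answer_sentence %in% e$support_sentences)
  }
  structure(list(entries = entries, min_support = as.integer(min_support),
                 c_base = c_base, c_per_support = c_per_support,
                 c_abstain = c_abstain),
            class = c("scripted_reader", "qa_reader"))
}

#' @export
read_answer.scripted_reader <- function(reader, question, context) {
  if (length(context) != 1L || is.na(context)) context <- ""
  e <- reader$entries[[question]]
  if (is.null(e) || !nzchar(context))
    return(reader_prediction(abstain_marker(), reader$c_abstain))
  ms <- if (!is.null(e$min_support)) e$min_support else reader$min_support
  ans_in <- grepl(e$answer_sentence, context, fixed = TRUE)
  n_sup <- if (length(e$support_sentences) == 0L) 0L else
    sum(vapply(e$support_sentences, grepl, logical(1), x = context, fixed = TRUE))
  if (ans_in && n_sup >= ms) {
    reader_prediction(e$answer_text,
                      reader$c_base + reader$c_per_support * n_sup)
  } else {
    reader_prediction(abstain_marker(), reader$c_abstain)
  }
}

#' A lexical-overlap reader
#'
#' An unscripted deterministic fallback for randomized property tests: picks
#' the context sentence with maximal normalized-token multiset overlap with
#' the question (ties go to the earliest sentence), answers with that
#' sentence's tokens minus the question's tokens, and uses the overlap count
#' as the confidence. Abstains when no sentence shares a token with the
#' question.
#'
#' @return an object of classes `overlap_reader`, `qa_reader`.
#' @export
overlap_reader <- function() {
  structure(list(), class = c("overlap_reader", "qa_reader"))
}

#' @export
read_answer.overlap_reader <- function(reader, question, context) {
  if (length(context) != 1L || is.na(context)) context <- ""
  if (!nzchar(trimws(context)))
    return(reader_prediction(abstain_marker(), 0))
  qt <- normalize_answer(question)
  segs <- segment_sentences(context)
  if (nrow(segs) == 0L) return(reader_prediction(abstain_marker(), 0))
  ov <- vapply(segs$text, function(s) multiset_overlap(normalize_answer(s), qt),
               integer(1))
  if (max(ov) == 0L) return(reader_prediction(abstain_marker(), 0))
  best <- which.max(ov)  # earliest maximal
  stoks <- normalize_answer(segs$text[best])
  ans_toks <- stoks[!stoks %in% qt]
  ans <- paste(ans_toks, collapse = " ")
  if (!nzchar(ans)) ans <- segs$text[best]
  reader_prediction(ans, as.numeric(ov[best]))
}

#' A lookup reader over exact context strings
#'
#' Maps exact context strings to fixed (answer, confidence) pairs; any other
#' context yields an abstention with the fallback confidence. Useful for
#' replaying observed reader behavior (for instance, a printed table of
#' predictions under different contexts) through the utility computations.
#'
#' @param table a named list keyed by context string; each element a list
#'   with `answer_text` (string or [abstain_marker()]) and `confidence`.
#' @param default_confidence confidence reported for unknown contexts.
#' @return an object of classes `lookup_reader`, `qa_reader`.
#' @export
lookup_reader <- function(table, default_confidence = 0) {
  stopifnot(is.list(table), length(names(table)) == length(table))
  structure(list(table = table, default_confidence = default_confidence),
            class = c("lookup_reader", "qa_reader"))
}

#' @export
read_answer.lookup_reader <- function(reader, question, context) {
  if (length(context) != 1L || is.na(context)) context <- ""
  e <- reader$table[[context]]
  if (is.null(e))
    return(reader_prediction(abstain_marker(), reader$default_confidence))
  reader_prediction(e$answer_text, e$confidence)
}

#' Serialize a scripted reader specification to JSON
#'
#' The "answer key" written beside a synthetic corpus so any session can
#' rebuild the same reader.
#'
#' @param reader a [scripted_reader()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_reader_spec <- function(reader, path) {
  stopifnot(inherits(reader, "scripted_reader"))
  jsonlite::write_json(
    list(min_support = reader$min_support, c_base = reader$c_base,
         c_per_support = reader$c_per_support, c_abstain = reader$c_abstain,
         entries = reader$entries),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a scripted reader specification from JSON
#' @param path path written by [write_reader_spec()].
#' @return a [scripted_reader()].
#' @export
read_reader_spec <- function(path) {
  spec <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  entries <- lapply(spec$entries, function(e) {
    e$support_sentences <- as.character(unlist(e$support_sentences))
    e
  })
  scripted_reader(entries, min_support = spec$min_support,
                  c_base = spec$c_base, c_per_support = spec$c_per_support,
                  c_abstain = spec$c_abstain)
}
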