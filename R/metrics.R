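#' Answer-string normalization and token-level scoring
#'
#' Extractive question-answering predictions are compared with gold answers on
#' normalized token multisets: lowercase, strip punctuation (so hyphenated
#' tokens merge into one), drop the English articles "a", "an", "the", and
#' split on whitespace.
#'
#' @param text a character scalar (may be empty or `NA` for an abstention).
#' @return a character vector of normalized tokens (length zero for empty or
#'   abstained input).
#' @examples
#' normalize_answer("T-UCstem1 KD")      # "tucstem1" "kd"
#' normalize_answer("An Apple, the!")    # "apple"
#' @export
normalize_answer <- function(text) {
  normalize_tokens(text, remove_articles = TRUE)
}

#' Word tokenization for context-level F1
#'
#' Same pipeline as [normalize_answer()] but without article removal: the
#' context-level objective counts plain words.
#'
#' @inheritParams normalize_answer
#' @return a character vector of lowercased, punctuation-stripped words.
#' @export
tokenize_words <- function(text) {
  normalize_tokens(text, remove_articles = FALSE)
}

# Shared normalization core. Punctuation (Unicode \p{P}, which includes the
# hyphen and dashes) plus the ASCII symbol characters of the usual punctuation
# set is deleted outright, so "adjuvant-like" becomes one token "adjuvantlike".
normalize_tokens <- function(text, remove_articles) {
  stopifnot(length(text) == 1L)
  if (is.na(text)) return(character(0))
  x <- tolower(text)
  x <- gsub("[\\p{P}$+<=>^`|~]", "", x, perl = TRUE)
  toks <- strsplit(trimws(x), "\\s+")[[1]]
  toks <- toks[nzchar(toks)]
  if (remove_articles) toks <- toks[!toks %in% c("a", "an", "the")]
  toks
}

#' The abstention marker
#'
#' Readers that decline to answer return this marker as their answer text.
#' Scoring treats it as an empty prediction: zero against a non-empty gold,
#' a full match against an empty gold.
#'
#' @return `NA_character_`.
#' @export
abstain_marker <- function() NA_character_

is_abstention <- function(text) {
  length(text) != 1L || is.na(text)
}

multiset_overlap <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) return(0L)
  ta <- table(a)
  tb <- table(b)
  common <- intersect(names(ta), names(tb))
  if (length(common) == 0L) return(0L)
  sum(pmin(as.integer(ta[common]), as.integer(tb[common])))
}

#' Token-level answer F1 against a single gold string
#'
#' Precision is the multiset token overlap divided by the number of predicted
#' tokens; recall divides by the number of gold tokens; F1 is their harmonic
#' mean. An abstention (or empty prediction) scores 0 against a non-empty gold
#' and 1 against an empty/abstained gold.
#'
#' @param prediction predicted answer string, or [abstain_marker()].
#' @param gold gold answer string.
#' @return a list with elements `precision`, `recall`, `f1` (all in
#'   \[0, 1\]) and `exact_match` (logical).
#' @examples
#' token_f1("phase I clinical trials on SARS or",
#'          "phase I clinical trials on SARS or MERS vaccines")$f1  # 0.875
#' @export
token_f1 <- function(prediction, gold) {
  pt <- normalize_answer(if (is_abstention(prediction)) NA_character_ else prediction)
  gt <- normalize_answer(if (is_abstention(gold)) NA_character_ else gold)
  if (length(pt) == 0L && length(gt) == 0L) {
    return(list(precision = 1, recall = 1, f1 = 1, exact_match = TRUE))
  }
  if (length(pt) == 0L || length(gt) == 0L) {
    return(list(precision = 0, recall = 0, f1 = 0, exact_match = FALSE))
  }
  ov <- multiset_overlap(pt, gt)
  precision <- ov / length(pt)
  recall <- ov / length(gt)
  f1 <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f1 = f1,
       exact_match = identical(pt, gt))
}

#' Best answer score over multiple gold references
#'
#' Scores the prediction against every reference and returns the score with
#' the maximal F1 (ties keep the first reference).
#'
#' @param prediction predicted answer string, or [abstain_marker()].
#' @param golds non-empty character vector of gold reference strings.
#' @return as [token_f1()].
#' @examples
#' best_over_references("PP1", c("protein phosphatase 1", "PP1"))$f1  # 1
#' @export
best_over_references <- function(prediction, golds) {
  stopifnot(length(golds) >= 1L)
  scores <- lapply(golds, function(g) token_f1(prediction, g))
  f1s <- vapply(scores, function(s) s$f1, numeric(1))
  scores[[which.max(f1s)]]
}

#' Exact match against any gold reference
#'
#' TRUE iff the normalized token sequence of the prediction equals that of at
#' least one reference.
#'
#' @inheritParams best_over_references
#' @return logical scalar.
#' @export
exact_match <- function(prediction, golds) {
  stopifnot(length(golds) >= 1L)
  any(vapply(golds, function(g) token_f1(prediction, g)$exact_match, logical(1)))
}
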