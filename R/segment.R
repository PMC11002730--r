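#' Rule-based sentence segmentation with character-offset provenance
#'
#' Splits text at runs of sentence-final punctuation (`.`, `?`, `!`) followed
#' by whitespace or end of text, unless the word ending at the terminator is a
#' guarded abbreviation ("e.g.", "i.e.", "et al.", "Fig.", ...). Trailing text
#' without a terminator still forms a sentence. The segmenter is deterministic,
#' so every downstream number is reproducible.
#'
#' @param raw_text a character scalar.
#' @return a data.frame with columns `text`, `char_start`, `char_end`
#'   (0-based, half-open into `raw_text`); zero rows for empty or
#'   whitespace-only input. Spans are trimmed to non-whitespace characters and
#'   strictly increasing.
#' @examples
#' segment_sentences("A b. C d.")         # two sentences, spans [0,4) [5,9)
#' segment_sentences("e.g. x. Next.")     # two sentences (guard keeps "e.g.")
#' @export
segment_sentences <- function(raw_text) {
  stopifnot(is.character(raw_text), length(raw_text) == 1L, !is.na(raw_text))
  empty <- data.frame(text = character(0), char_start = integer(0),
                      char_end = integer(0), stringsAsFactors = FALSE)
  if (!nzchar(trimws(raw_text))) return(empty)

  chars <- strsplit(raw_text, "", fixed = FALSE)[[1]]
  n <- length(chars)
  is_term <- chars %in% c(".", "?", "!")
  is_ws <- grepl("^\\s$", chars)

  breaks <- integer(0)  # 1-based index of the last char of each sentence
  for (i in seq_len(n)) {
    if (!is_term[i]) next
    if (i < n && (is_term[i + 1L] || !is_ws[i + 1L])) next  # mid-run or mid-token
    # word ending at i (walk back to previous whitespace)
    j <- i
    while (j > 1L && !is_ws[j - 1L]) j <- j - 1L
    word <- tolower(paste(chars[j:i], collapse = ""))
    if (word %in% abbreviation_guard()) next
    breaks <- c(breaks, i)
  }
  if (length(breaks) == 0L || breaks[length(breaks)] < n) breaks <- c(breaks, n)

  starts <- integer(0); ends <- integer(0); texts <- character(0)
  cursor <- 1L
  for (b in breaks) {
    seg <- cursor:b
    seg <- seg[!is_ws[seg]]
    if (length(seg) > 0L) {
      s <- min(seg); e <- max(seg)
      starts <- c(starts, s - 1L)          # to 0-based
      ends <- c(ends, e)                   # half-open
      texts <- c(texts, substring(raw_text, s, e))
    }
    cursor <- b + 1L
  }
  data.frame(text = texts, char_start = starts, char_end = ends,
             stringsAsFactors = FALSE)
}

# Lowercased abbreviation tokens (including their trailing period) that never
# end a sentence.
abbreviation_guard <- function() {
  c("e.g.", "i.e.", "etc.", "cf.", "vs.", "al.", "et al.", "fig.", "figs.",
    "eq.", "eqs.", "no.", "nos.", "dr.", "mr.", "mrs.", "ms.", "st.",
    "ca.", "approx.", "resp.")
}
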