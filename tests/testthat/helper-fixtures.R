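# Shared fixtures and independent oracles, built in code at test time.

# Explicit greedy-matching multiset F1 oracle (independent of token_f1's
# table-based counting).
counting_f1_oracle <- function(pred_toks, gold_toks) {
  if (length(pred_toks) == 0L && length(gold_toks) == 0L) return(1)
  if (length(pred_toks) == 0L || length(gold_toks) == 0L) return(0)
  used <- rep(FALSE, length(gold_toks))
  ov <- 0L
  for (t in pred_toks) {
    for (j in seq_along(gold_toks)) {
      if (!used[j] && gold_toks[j] == t) {
        used[j] <- TRUE
        ov <- ov + 1L
        break
      }
    }
  }
  p <- ov / length(pred_toks)
  r <- ov / length(gold_toks)
  if (p + r == 0) 0 else 2 * p * r / (p + r)
}

# A three-sentence scripted context: sentence 3 answers, sentences 1-2 support.
tiny_scripted <- function(min_support = 1L, ...) {
  sents <- c("Support alpha sentence here.", "Support beta sentence here.",
             "Answer gamma sentence here.")
  rd <- scripted_reader(
    list("what is gamma?" = list(answer_text = "gamma value",
                                 answer_sentence = sents[3],
                                 support_sentences = sents[1:2])),
    min_support = min_support, ...)
  list(reader = rd, sentences = sents, question = "what is gamma?",
       golds = "gamma value")
}

# Lookup reader replaying an observed table of (context -> prediction,
# confidence) for a real biomedical question about lactic acid bacteria as an
# influenza vaccine vector.
lab_vaccine_fixture <- function() {
  s1 <- "Recently, LAB presenting influenza virus antigens have been studied [3,18,19]."
  s2 <- "For mucosal immunization, LAB is a more attractive delivery system than other live vaccine vectors, such as Shigella, Salmonella, and Listeria [20,21]."
  s3 <- "It is considered safe and exhibits an adjuvant-like effect on mucosal and systemic immunity [18,22,23]."
  ans3 <- "It is considered safe and exhibits an adjuvant-like effect on mucosal and systemic immunity"
  tab <- list()
  tab[[s1]] <- list(answer_text = abstain_marker(), confidence = 2.12)
  tab[[s2]] <- list(answer_text = abstain_marker(), confidence = 0.84)
  tab[[s3]] <- list(answer_text = abstain_marker(), confidence = 2.75)
  tab[[paste(s1, s2)]] <- list(answer_text = "For mucosal immunization",
                               confidence = 3.70)
  tab[[paste(s2, s3)]] <- list(answer_text = ans3, confidence = 5.53)
  tab[[paste(s1, s3)]] <- list(answer_text = ans3, confidence = 3.48)
  tab[[paste(s1, s2, s3)]] <- list(answer_text = ans3, confidence = 11.18)
  list(reader = lookup_reader(tab), sentences = c(s1, s2, s3),
       question = "Why are lactic acid bacteria considered an attractive delivery system for a live influenza vaccine?",
       gold = "considered safe and exhibits an adjuvant-like effect on mucosal and systemic immunity")
}

# Cached small synthetic corpus shared across test files.
small_corpus <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_corpus(corpus_config(n_articles = 6L, seed = 0L))
    cache
  }
})

# A scorer injecting a fixed score vector (as u2) regardless of the question.
fixed_scorer <- function(scores) {
  function(question, sentences, golds = NULL) {
    stopifnot(length(sentences) == length(scores))
    list(u2 = scores)
  }
}

# One-paragraph article with n unambiguous sentences of distinct words.
flat_article <- function(n, id = "flat") {
  words <- vapply(seq_len(n), function(i) paste0("word", letters[i]), "")
  qa_article(id, paste(sprintf("Sentence %s item %d.", words, seq_len(n)),
                       collapse = " "))
}
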