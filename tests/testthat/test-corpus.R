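write_squad_fixture <- function(path, paragraphs, qas_by_para) {
  doc <- list(data = list(list(
    title = "fixture",
    paragraphs = lapply(seq_along(paragraphs), function(i) {
      list(context = paragraphs[[i]], qas = qas_by_para[[i]])
    }))))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  path
}

test_that("minimal SQuAD fixture loads into one article and one example", {
  path <- withr::local_tempfile(fileext = ".json")
  write_squad_fixture(path,
    paragraphs = list("The drug works well. It binds the receptor."),
    qas_by_para = list(list(list(
      id = "q1", question = "what binds?",
      answers = list(list(text = "It binds the receptor", answer_start = 21L))))))
  ds <- load_squad_json(path)
  expect_length(ds$articles, 1L)
  expect_length(ds$examples, 1L)
  expect_equal(ds$examples[[1]]$gold_sent_indices, 1L)
  expect_equal(ds$examples[[1]]$target_para_indices, 0L)
})

test_that("answer offsets remap under the two-newline paragraph join", {
  # paragraphs of 10 and 20 characters; answer_start 3 in the second
  p1 <- "Aaaa bbbb."                 # 10 chars
  p2 <- "Cccc dddd eeee ffff."       # 20 chars
  path <- withr::local_tempfile(fileext = ".json")
  write_squad_fixture(path, list(p1, p2), list(
    list(),
    list(list(id = "q1", question = "what?",
              answers = list(list(text = "c dddd", answer_start = 3L))))))
  ds <- load_squad_json(path)
  expect_equal(ds$examples[[1]]$answer_char_start, 10L + 2L + 3L)
  expect_equal(ds$articles[[1]]$raw_text, paste(p1, p2, sep = "\n\n"))
})

test_that("multiple answers become multiple gold references", {
  path <- withr::local_tempfile(fileext = ".json")
  write_squad_fixture(path, list("PP1 binds HSP20 here."), list(list(list(
    id = "q1", question = "which phosphatase?",
    answers = list(list(text = "PP1", answer_start = 0L),
                   list(text = "protein phosphatase 1", answer_start = 0L))))))
  ds <- load_squad_json(path)
  expect_length(ds$examples[[1]]$gold_answers, 2L)
})

test_that("schema violations and out-of-paragraph offsets raise named errors", {
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(nodata = 1), path, auto_unbox = TRUE)
  expect_error(load_squad_json(path), "missing 'data'")
  write_squad_fixture(path, list("Short text."), list(list(list(
    id = "q1", question = "what?",
    answers = list(list(text = "x", answer_start = 99L))))))
  expect_error(load_squad_json(path), "outside its paragraph")
})

test_that("SQuAD round-trip preserves sentence spans and examples", {
  corp <- make_corpus(corpus_config(n_articles = 2L, seed = 3L))
  path <- withr::local_tempfile(fileext = ".json")
  write_squad_json(corp$articles, corp$examples, path)
  ds <- load_squad_json(path)
  expect_equal(length(ds$examples), length(corp$examples))
  for (id in names(corp$articles)) {
    expect_equal(ds$articles[[id]]$sentences, corp$articles[[id]]$sentences)
  }
  # the loader emits examples in paragraph order; match by qid
  by_qid <- stats::setNames(ds$examples,
                            vapply(ds$examples, function(e) e$qid, ""))
  for (orig in corp$examples) {
    reloaded <- by_qid[[orig$qid]]
    expect_equal(reloaded$answer_char_start, orig$answer_char_start)
    expect_equal(reloaded$gold_sent_indices, orig$gold_sent_indices)
    expect_equal(reloaded$gold_answers, orig$gold_answers)
  }
})

test_that("gold sentence location handles boundaries and whitespace gaps", {
  art <- qa_article("a", "A b. C d. E f.")
  ex <- function(off) qa_example("q", "?", "a", "x", answer_char_start = off)
  expect_equal(locate_gold_sentence(ex(6L), art), 1L)   # inside sentence 2
  expect_equal(locate_gold_sentence(ex(5L), art), 1L)   # first character
  expect_equal(locate_gold_sentence(ex(4L), art), 1L)   # inter-sentence gap
  expect_error(locate_gold_sentence(ex(99L), art), "outside")
})

test_that("an answer spanning two sentences anchors at its start sentence", {
  fix <- make_degenerate_cases()$span_answer
  expect_equal(fix$example$gold_sent_indices, 0L)
})

test_that("token matching finds every sentence containing the answer tokens", {
  art <- qa_article("a", paste("PP1 binds HSP20 strongly.",
                               "Nothing relevant here.",
                               "The role of PP1 is debated."))
  ex <- qa_example("q", "?", "a", "PP1")
  expect_equal(find_answer_sentences_by_token_match(ex, art), c(0L, 2L))
  ex2 <- qa_example("q", "?", "a", "absent")
  expect_equal(find_answer_sentences_by_token_match(ex2, art), integer(0))
  # punctuation-merged token still matches
  art3 <- qa_article("a3", "T-UCstem1 KD reduced self-renewal.")
  ex3 <- qa_example("q", "?", "a3", "T-UCstem1")
  expect_equal(find_answer_sentences_by_token_match(ex3, art3), 0L)
})

test_that("target paragraphs aggregate token matches in document order", {
  parts <- c("Filler one here.", "PP1 mentioned here.", "More filler.",
             "Extra filler text.", "Again PP1 appears.")
  art <- qa_article("a", parts)
  ex <- qa_example("q", "?", "a", "PP1")
  ex$gold_sent_indices <- find_answer_sentences_by_token_match(ex, art)
  tp <- target_paragraphs(ex, art)
  expect_equal(tp$para_index, c(1L, 4L))
  ex_none <- qa_example("q2", "?", "a", "missing")
  ex_none$gold_sent_indices <- find_answer_sentences_by_token_match(ex_none, art)
  expect_error(target_paragraphs(ex_none, art), "no locatable gold sentence")
})

test_that("BioASQ-style records load with token-matched gold sentences", {
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(list(
    question = "which phosphatase?", answers = list("PP1"),
    article = list(id = "a1", paragraphs = list(
      "Unrelated text here.", "PP1 interacts with HSP20.")))),
    path, auto_unbox = TRUE)
  ds <- load_bioasq_json(path)
  expect_true(is.na(ds$examples[[1]]$answer_char_start))
  expect_equal(ds$examples[[1]]$target_para_indices, 1L)
})

test_that("loaded gold sentences contain the gold answer tokens", {
  corp <- small_corpus()
  for (ex in corp$examples[1:10]) {
    art <- corp$articles[[ex$article_ref]]
    sent <- art$sentences$text[art$sentences$sent_index == ex$gold_sent_indices]
    expect_true(grepl(ex$gold_answers[1], sent, fixed = TRUE))
  }
})
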