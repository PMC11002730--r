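test_that("scenario constructions respect their defining constraints", {
  corp <- small_corpus()
  tri <- generate_triplets(corp$examples, corp$articles, corp$reader, seed = 0L)
  expect_true(all(tri$scenario %in% c("target_paragraph",
                                      "neighborhood_excl_gold",
                                      "adjacent_paragraph",
                                      "distant_or_foreign")))
  # every focus sentence occurs in its context
  expect_true(all(mapply(grepl, tri$focus_text, tri$context_text,
                         MoreArgs = list(fixed = TRUE))))
  truth <- corp$truth
  for (i in which(tri$scenario == "neighborhood_excl_gold")) {
    n_sent <- nrow(segment_sentences(tri$context_text[i]))
    expect_lte(n_sent, 5L)
    expect_gte(n_sent, 1L)
    # never contains the gold sentence
    gold_txt <- corp$reader$entries[[tri$question[i]]]$answer_sentence
    expect_false(grepl(gold_txt, tri$context_text[i], fixed = TRUE))
  }
  for (i in which(tri$scenario == "distant_or_foreign")) {
    ex <- Filter(function(e) e$qid == tri$qid[i], corp$examples)[[1]]
    if (tri$context_article[i] != ex$article_ref) succeed() else {
      # furthest-paragraph branch: context never overlaps the target paragraph
      tp_txt <- corp$articles[[ex$article_ref]]$paragraphs$text[
        ex$target_para_indices + 1L]
      expect_false(grepl(tri$context_text[i], tp_txt, fixed = TRUE))
    }
  }
})

test_that("triplet counts follow the per-question configuration", {
  corp <- small_corpus()
  ex10 <- corp$examples[1:10]
  tri <- generate_triplets(ex10, corp$articles, corp$reader,
                           per_question = c(target_paragraph = 1L,
                                            neighborhood_excl_gold = 2L,
                                            adjacent_paragraph = 1L,
                                            distant_or_foreign = 1L),
                           seed = 1L)
  skips <- attr(tri, "skips")
  expect_equal(nrow(tri) + nrow(skips), 50L)
})

test_that("generation is reproducible and labels are recomputable", {
  corp <- small_corpus()
  ex <- corp$examples[1:6]
  t1 <- generate_triplets(ex, corp$articles, corp$reader, seed = 21L)
  t2 <- generate_triplets(ex, corp$articles, corp$reader, seed = 21L)
  expect_identical(t1, t2)
  t3 <- generate_triplets(ex, corp$articles, corp$reader, seed = 22L)
  expect_false(identical(t1$context_text, t3$context_text))
  # stored labels equal labels recomputed from the stored context
  golds <- stats::setNames(lapply(corp$examples, function(e) e$gold_answers),
                           vapply(corp$examples, function(e) e$qid, ""))
  for (i in seq_len(min(10L, nrow(t1)))) {
    lab <- recompute_triplet_labels(t1[i, ], corp$reader, golds[[t1$qid[i]]])
    expect_identical(lab$u1, t1$u1_label[i])
    expect_identical(lab$u2, t1$u2_label[i])
  }
})

test_that("triplet files round-trip byte-identically for a fixed seed", {
  corp <- small_corpus()
  ex <- corp$examples[1:4]
  p1 <- withr::local_tempfile(fileext = ".jsonl")
  p2 <- withr::local_tempfile(fileext = ".jsonl")
  write_triplets(generate_triplets(ex, corp$articles, corp$reader, seed = 8L), p1)
  write_triplets(generate_triplets(ex, corp$articles, corp$reader, seed = 8L), p2)
  expect_identical(readLines(p1), readLines(p2))
  back <- read_triplets(p1)
  expect_equal(back$context_text,
               generate_triplets(ex, corp$articles, corp$reader, seed = 8L)$context_text)
})

test_that("mean labels order by context quality under the scripted reader", {
  corp <- make_corpus(corpus_config(n_articles = 34L, seed = 0L))
  ex <- corp$examples[seq_len(100L)]
  tri <- generate_triplets(ex, corp$articles, corp$reader, seed = 0L)
  rep <- label_distribution_report(tri)
  m <- stats::setNames(rep$u2_mean, rep$scenario)
  # only contexts containing the answer sentence move the scripted reader's
  # confidence, so the target scenario strictly dominates and the three
  # answer-less scenarios are weakly ordered
  expect_gt(m[["target_paragraph"]], m[["neighborhood_excl_gold"]])
  expect_gte(m[["neighborhood_excl_gold"]], m[["adjacent_paragraph"]])
  expect_gte(m[["adjacent_paragraph"]], m[["distant_or_foreign"]])
  # irrelevant contexts carry no F1-based utility
  expect_equal(rep$u1_mean[rep$scenario == "distant_or_foreign"], 0)
  # empty input: empty report
  expect_equal(nrow(label_distribution_report(tri[0, ])), 0L)
})

test_that("unsatisfiable scenarios are skipped with a reason", {
  art <- qa_article("solo", "Alpha beta gamma. Delta epsilon zeta.")
  ex <- qa_example("q1", "alpha?", "solo", "gamma", answer_char_start = 11L)
  ex$gold_sent_indices <- locate_gold_sentence(ex, art)
  ex$target_para_indices <- 0L
  tri <- generate_triplets(list(ex), list(solo = art), overlap_reader(),
                           per_question = c(adjacent_paragraph = 1L,
                                            distant_or_foreign = 1L),
                           seed = 0L)
  skips <- attr(tri, "skips")
  expect_equal(nrow(tri), 0L)
  expect_equal(nrow(skips), 2L)
  expect_true(all(grepl("single-paragraph", skips$reason)))
})
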