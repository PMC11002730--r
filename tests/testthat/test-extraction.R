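test_that("extraction parameters are validated", {
  p <- extraction_params(k = 3, w = 2, h = 0.8)
  expect_s3_class(p, "extraction_params")
  expect_error(extraction_params(k = 0), "k")
  expect_error(extraction_params(h = 1.2), "h")
  expect_error(extraction_params(weights = c(1, 0, 1)), "weights")
})

test_that("the peak-and-window trace selects all sentences on the reference vector", {
  art <- flat_article(5)
  scores <- c(0.1, 0.9, 0.2, 0.85, 0.1)
  # raw thresholding: peaks 1 and 3 (0-based) at threshold 0.81
  ec_raw <- extract_context("q?", art, extraction_params(k = 1, w = 1, h = 0.9),
                            fixed_scorer(scores), rescale = FALSE)
  expect_equal(ec_raw$peak_indices, c(1L, 3L))
  expect_equal(ec_raw$sent_indices, 0:4)
  # with per-question rescaling the same two peaks survive at h = 0.9
  ec <- extract_context("q?", art, extraction_params(k = 1, w = 1, h = 0.9),
                        fixed_scorer(scores))
  expect_equal(ec$peak_indices, c(1L, 3L))
  expect_equal(ec$sent_indices, 0:4)
  expect_equal(ec$text, paste(art$sentences$text, collapse = " "))
})

test_that("h = 1 keeps only the tallest peak and its window", {
  art <- flat_article(6)
  ec <- extract_context("q?", art, extraction_params(k = 1, w = 1, h = 1),
                        fixed_scorer(c(0.1, 0.2, 0.1, 0.3, 0.9, 0.2)))
  expect_equal(ec$peak_indices, 4L)
  expect_equal(ec$sent_indices, 3:5)
})

test_that("equal scores: all peaks without rescaling, argmax fallback with it", {
  art <- flat_article(5)
  eq <- fixed_scorer(rep(0.7, 5))
  ec_raw <- extract_context("q?", art, extraction_params(k = 1, w = 1, h = 0.9),
                            eq, rescale = FALSE)
  expect_equal(ec_raw$peak_indices, 0:4)
  expect_equal(ec_raw$sent_indices, 0:4)
  ec <- extract_context("q?", art, extraction_params(k = 1, w = 1, h = 0.9), eq)
  expect_equal(ec$peak_indices, 0L)  # earliest argmax only
  expect_equal(ec$sent_indices, 0:1)
})

test_that("selection is superset-monotone as h decreases and as w increases", {
  set.seed(9)
  art <- flat_article(12)
  for (rep in 1:25) {
    scores <- runif(12)
    sels <- lapply(c(1, 0.8, 0.5, 0.2, 0), function(h) {
      extract_context("q?", art, extraction_params(k = 1, w = 2, h = h),
                      fixed_scorer(scores))$sent_indices
    })
    for (i in seq_len(length(sels) - 1)) {
      expect_true(all(sels[[i]] %in% sels[[i + 1]]))
    }
    selw <- lapply(1:5, function(w) {
      extract_context("q?", art, extraction_params(k = 1, w = w, h = 0.7),
                      fixed_scorer(scores))$sent_indices
    })
    for (i in seq_len(length(selw) - 1)) {
      expect_true(all(selw[[i]] %in% selw[[i + 1]]))
    }
  }
})

test_that("the argmax sentence is always selected and limits behave", {
  set.seed(10)
  art <- flat_article(10)
  for (rep in 1:20) {
    scores <- runif(10)
    for (h in c(0, 0.3, 0.7, 1)) {
      sel <- extract_context("q?", art, extraction_params(k = 1, w = 1, h = h),
                             fixed_scorer(scores))$sent_indices
      expect_true((which.max(scores) - 1L) %in% sel)
    }
    # h = 0 selects every candidate
    expect_equal(extract_context("q?", art,
                                 extraction_params(k = 1, w = 1, h = 0),
                                 fixed_scorer(scores))$sent_indices, 0:9)
    # w >= candidate count selects every candidate
    expect_equal(extract_context("q?", art,
                                 extraction_params(k = 1, w = 10, h = 1),
                                 fixed_scorer(scores))$sent_indices, 0:9)
  }
})

test_that("windows never import sentences from non-retrieved paragraphs", {
  corp <- small_corpus()
  ex <- corp$examples[[1]]
  art <- corp$articles[[ex$article_ref]]
  ec <- extract_context(ex$question, art, extraction_params(k = 2, w = 5, h = 0.5),
                        oracle_scorer(corp$reader), golds = ex$gold_answers)
  expect_true(all(ec$sent_indices %in% ec$candidate_sent_indices))
  cand_paras <- unique(art$sentences$para_index[
    art$sentences$sent_index %in% ec$candidate_sent_indices])
  expect_lte(length(cand_paras), 2L)
})

test_that("single-sentence articles are returned whole for any parameters", {
  fix <- make_degenerate_cases()$single_sentence
  for (h in c(0, 0.5, 1)) {
    ec <- extract_context(fix$example$question, fix$article,
                          extraction_params(k = 3, w = 1, h = h),
                          cosine_scorer())
    expect_equal(ec$sent_indices, 0L)
    expect_equal(ec$text, fix$article$sentences$text[1])
  }
})

test_that("all-tied cosine scores trigger the degenerate fallback", {
  fix <- make_degenerate_cases()$all_ties
  ec <- extract_context(fix$question, fix$article,
                        extraction_params(k = 1, w = 1, h = 0.8),
                        cosine_scorer())
  expect_equal(ec$peak_indices, 0L)
})

test_that("baseline contexts realize the three reference designs", {
  corp <- small_corpus()
  ex <- corp$examples[[1]]
  art <- corp$articles[[ex$article_ref]]
  expect_identical(baseline_context(ex, art, "original"), art$raw_text)
  topall <- baseline_context(ex, art, "retriever_topk", k = 100L)
  expect_identical(topall, art$raw_text)  # k >= paragraph count
  tp <- baseline_context(ex, art, "target_paragraph")
  expect_identical(tp, art$paragraphs$text[ex$target_para_indices + 1L])
  ex_no <- qa_example("x", "?", art$article_id, "missing")
  expect_error(baseline_context(ex_no, art, "target_paragraph"))
})

test_that("local-maxima peak mode is at most as inclusive on peaks", {
  art <- flat_article(7)
  scores <- c(0.2, 0.9, 0.3, 0.88, 0.86, 0.1, 0.5)
  pg <- extract_context("q?", art, extraction_params(k = 1, w = 1, h = 0.9),
                        fixed_scorer(scores), peak_mode = "global")
  pl <- extract_context("q?", art, extraction_params(k = 1, w = 1, h = 0.9),
                        fixed_scorer(scores), peak_mode = "local")
  # index 4 clears the threshold but sits on the shoulder of the peak at 3
  expect_equal(pg$peak_indices, c(1L, 3L, 4L))
  expect_equal(pl$peak_indices, c(1L, 3L))
})
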