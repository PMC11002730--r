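#' Synthetic corpus generator configuration
#'
#' Controls the planted structure the generator emulates: articles of
#' paragraphs of sentences; per question one target paragraph holding a gold
#' answer sentence plus nearby support sentences; topically similar
#' distractor paragraphs that leak question tokens at rate `rho`; and a
#' scripted reader whose answer emission depends on which support sentences
#' are present.
#'
#' @param n_articles number of articles (default 67, giving about 200
#'   questions at the default 3 questions per article).
#' @param paragraphs_per_article paragraphs per article (default 8).
#' @param sentences_per_paragraph sentences per paragraph (default 6).
#' @param n_questions_per_article questions per article (default 3; must not
#'   exceed `paragraphs_per_article`).
#' @param n_support support sentences per question, placed next to the gold
#'   sentence in the target paragraph (default 2).
#' @param distractor_overlap_rate rho in \[0, 1\]: probability that each
#'   question token leaks into each distractor paragraph (default 0.2).
#' @param vocabulary_size total nonsense-word vocabulary (default 2000).
#' @param seed integer seed.
#' @return an object of class `corpus_config`.
#' @export
corpus_config <- function(n_articles = 67L, paragraphs_per_article = 8L,
                          sentences_per_paragraph = 6L,
                          n_questions_per_article = 3L, n_support = 2L,
                          distractor_overlap_rate = 0.2,
                          vocabulary_size = 2000L, seed = 0L) {
  stopifnot(n_articles >= 1L, paragraphs_per_article >= 1L,
            sentences_per_paragraph >= 1L, n_questions_per_article >= 1L,
            n_questions_per_article <= paragraphs_per_article,
            n_support >= 0L, n_support < sentences_per_paragraph,
            distractor_overlap_rate >= 0, distractor_overlap_rate <= 1,
            vocabulary_size >= 1L)
  structure(list(n_articles = as.integer(n_articles),
                 paragraphs_per_article = as.integer(paragraphs_per_article),
                 sentences_per_paragraph = as.integer(sentences_per_paragraph),
                 n_questions_per_article = as.integer(n_questions_per_article),
                 n_support = as.integer(n_support),
                 distractor_overlap_rate = distractor_overlap_rate,
                 vocabulary_size = as.integer(vocabulary_size),
                 seed = as.integer(seed)),
            class = "corpus_config")
}

# n unique random nonsense words of 5-7 lowercase letters
make_vocab <- function(n) {
  words <- character(0)
  while (length(words) < n) {
    need <- n - length(words)
    fresh <- vapply(seq_len(need * 2L), function(i) {
      paste(sample(letters, sample(5:7, 1L), replace = TRUE), collapse = "")
    }, character(1))
    words <- unique(c(words, fresh))
  }
  words[seq_len(n)]
}

#' Generate a synthetic QA corpus with planted answer and support structure
#'
#' Every question has one gold answer sentence (the answer is a globally
#' unique two-token span with its character offset recorded) and `n_support`
#' support sentences placed at the positions nearest the gold sentence within
#' the same target paragraph. The question shares three topic tokens with the
#' answer sentence (all three) and each support sentence (two each);
#' distractor paragraphs receive each question token independently with
#' probability `rho`. Sentences are unambiguously terminated for the
#' segmenter and all words are nonsense tokens, so answer location is free of
#' matching noise. A matching scripted reader (answer emitted iff the answer
#' sentence plus at least `ceiling(n_support / 2)` supports are in the
#' context) is wired from the same structure. Deterministic per seed.
#'
#' @param config a [corpus_config()].
#' @param out_dir optional directory; when given, writes `squad.json`,
#'   `bioasq.json` (offsets stripped), `reader_spec.json` and `truth.json`.
#' @return a list with `articles` (named list of [qa_article()]), `examples`
#'   (offset-bearing), `bioasq_examples` (offset-free variant), `reader`
#'   (a [scripted_reader()]), `truth` (data.frame manifest) and `config`.
#' @export
make_corpus <- function(config = corpus_config(), out_dir = NULL) {
  stopifnot(inherits(config, "corpus_config"))
  nq_total <- config$n_articles * config$n_questions_per_article
  n_topic <- nq_total * 5L   # 3 topic tokens + 2 question-only words each
  n_answer <- nq_total * 2L
  n_filler <- config$vocabulary_size - n_topic - n_answer
  if (n_filler < 50L)
    stop(sprintf(paste0("vocabulary_size %d too small to guarantee unique ",
                        "answers and topics (need > %d)"),
                 config$vocabulary_size, n_topic + n_answer + 50L),
         call. = FALSE)

  articles <- list()
  examples <- list()
  reader_entries <- list()
  truth <- list()

  with_seed(config$seed, {
    vocab <- make_vocab(config$vocabulary_size)
    topic_pool <- vocab[seq_len(n_topic)]
    answer_pool <- vocab[n_topic + seq_len(n_answer)]
    filler_pool <- vocab[(n_topic + n_answer + 1L):config$vocabulary_size]
    topic_next <- 0L
    answer_next <- 0L
    filler_sentence <- function(n_tok = 7L) {
      sample(filler_pool, n_tok, replace = TRUE)
    }

    for (ai in seq_len(config$n_articles)) {
      article_id <- sprintf("synth_%03d", ai)
      # token lists: para_toks[[p]][[s]]
      para_toks <- lapply(seq_len(config$paragraphs_per_article), function(p) {
        lapply(seq_len(config$sentences_per_paragraph), function(s) {
          filler_sentence()
        })
      })
      targets <- sample(config$paragraphs_per_article,
                        config$n_questions_per_article)
      qinfo <- list()
      for (qi in seq_len(config$n_questions_per_article)) {
        tp <- targets[qi]
        topics <- topic_pool[topic_next + 1:3]
        qwords <- topic_pool[topic_next + 4:5]
        topic_next <- topic_next + 5L
        ans <- answer_pool[answer_next + 1:2]
        answer_next <- answer_next + 2L

        np <- config$sentences_per_paragraph
        pa <- sample(np, 1L)
        others <- setdiff(seq_len(np), pa)
        sup <- others[order(abs(others - pa), others)][seq_len(min(config$n_support,
                                                                   length(others)))]
        para_toks[[tp]][[pa]] <- c(topics, ans, filler_sentence(2L))
        for (j in seq_along(sup)) {
          pair <- topics[c(1L + (j - 1L) %% 3L, 1L + j %% 3L)]
          para_toks[[tp]][[sup[j]]] <- c(pair, filler_sentence(5L))
        }
        question <- paste0(paste(c(topics, qwords), collapse = " "), "?")
        # leak question tokens into distractor paragraphs
        qtoks <- c(topics, qwords)
        for (p in setdiff(seq_len(config$paragraphs_per_article), targets)) {
          leaked <- qtoks[stats::runif(length(qtoks)) < config$distractor_overlap_rate]
          for (tok in leaked) {
            s <- sample(config$sentences_per_paragraph, 1L)
            para_toks[[p]][[s]] <- c(para_toks[[p]][[s]], tok)
          }
        }
        qinfo[[qi]] <- list(tp = tp, pa = pa, sup = sup, topics = topics,
                            question = question, ans = ans)
      }

      sent_texts <- lapply(para_toks, function(p) {
        vapply(p, function(toks) paste0(paste(toks, collapse = " "), "."),
               character(1))
      })
      ptexts <- vapply(sent_texts, function(ss) paste(ss, collapse = " "),
                       character(1))
      art <- qa_article(article_id, ptexts)
      articles[[article_id]] <- art

      for (qi in seq_along(qinfo)) {
        info <- qinfo[[qi]]
        qid <- sprintf("%s_q%d", article_id, qi)
        ans_text <- paste(info$ans, collapse = " ")
        # paragraph-local offset of the answer span
        ss <- sent_texts[[info$tp]]
        sent_off <- cumsum(c(0L, utils::head(nchar(ss), -1L) + 1L))
        within <- regexpr(ans_text, ss[info$pa], fixed = TRUE)[1] - 1L
        local_start <- sent_off[info$pa] + within
        global_start <- art$paragraphs$char_start[info$tp] + local_start
        ex <- qa_example(qid, info$question, article_id, ans_text,
                         answer_char_start = global_start)
        ex$gold_sent_indices <- locate_gold_sentence(ex, art)
        ex$target_para_indices <- target_paragraphs(ex, art)$para_index
        examples[[length(examples) + 1L]] <- ex

        gold_idx <- ex$gold_sent_indices[1L]
        sup_idx <- art$sentences$sent_index[
          art$sentences$para_index == info$tp - 1L][info$sup]
        reader_entries[[info$question]] <- list(
          answer_text = ans_text,
          answer_sentence = ss[info$pa],
          support_sentences = as.character(ss[info$sup]),
          answer_sent_index = gold_idx,
          support_sent_indices = as.integer(sup_idx))
        truth[[length(truth) + 1L]] <- data.frame(
          qid = qid, article_id = article_id, question = info$question,
          target_para = info$tp - 1L, gold_sent_index = gold_idx,
          support_sent_indices = paste(sup_idx, collapse = ","),
          answer_text = ans_text, stringsAsFactors = FALSE)
      }
    }
  })

  reader <- scripted_reader(reader_entries,
                            min_support = as.integer(ceiling(config$n_support / 2)))
  bioasq_examples <- lapply(examples, function(ex) {
    ex$answer_char_start <- NA_integer_
    art <- articles[[ex$article_ref]]
    ex$gold_sent_indices <- find_answer_sentences_by_token_match(ex, art)
    ex$target_para_indices <- if (length(ex$gold_sent_indices) > 0L)
      target_paragraphs(ex, art)$para_index else integer(0)
    ex
  })
  out <- list(articles = articles, examples = examples,
              bioasq_examples = bioasq_examples, reader = reader,
              truth = do.call(rbind, truth), config = config)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_squad_json(articles, examples, file.path(out_dir, "squad.json"))
    bio <- lapply(examples, function(ex) {
      art <- articles[[ex$article_ref]]
      list(question = ex$question, answers = as.list(ex$gold_answers),
           article = list(id = art$article_id,
                          paragraphs = as.list(art$paragraphs$text)))
    })
    jsonlite::write_json(bio, file.path(out_dir, "bioasq.json"),
                         auto_unbox = TRUE, digits = NA)
    write_reader_spec(reader, file.path(out_dir, "reader_spec.json"))
    jsonlite::write_json(out$truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  out
}

#' Degenerate edge-case fixtures
#'
#' Small hand-built fixtures exercising boundary behavior: a single-sentence
#' article; an answer spanning two sentences; an article whose sentences all
#' tie under the default embedder (triggering the degenerate-score fallback);
#' an empty-context reader call; and a multi-reference gold.
#'
#' @return a named list of fixtures; each has the pieces its case needs
#'   (article, example, reader, golds, ...).
#' @export
make_degenerate_cases <- function() {
  single_art <- qa_article("single", "Alpha beta gamma.")
  single_ex <- qa_example("single_q1", "alpha?", "single", "beta",
                          answer_char_start = 6L)
  single_ex$gold_sent_indices <- locate_gold_sentence(single_ex, single_art)
  single_ex$target_para_indices <- 0L

  span_art <- qa_article("span", "The drug binds receptors. It then blocks signaling.")
  span_ex <- qa_example("span_q1", "what does the drug do?", "span",
                        "binds receptors. It then blocks signaling",
                        answer_char_start = 9L)
  span_ex$gold_sent_indices <- locate_gold_sentence(span_ex, span_art)
  span_ex$target_para_indices <- 0L

  ties_art <- qa_article("ties", paste(rep("same words here.", 4), collapse = " "))

  multi_ex <- qa_example("multi_q1", "which phosphatase?", "none",
                         c("protein phosphatase 1", "PP1"))

  list(
    single_sentence = list(article = single_art, example = single_ex),
    span_answer = list(article = span_art, example = span_ex),
    all_ties = list(article = ties_art, question = "same words?"),
    empty_context = list(reader = overlap_reader(), question = "anything?",
                         context = ""),
    multi_reference = list(example = multi_ex)
  )
}
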