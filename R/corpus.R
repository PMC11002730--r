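#' Build an article from paragraph texts
#'
#' Paragraphs are joined with a fixed two-newline separator to give the
#' article-wide raw text; sentences are segmented per paragraph (so a sentence
#' never crosses a paragraph boundary) and their character spans are lifted to
#' article-wide 0-based half-open coordinates.
#'
#' @param article_id a character scalar identifying the article.
#' @param paragraph_texts a non-empty character vector, one paragraph each.
#' @return an object of class `qa_article`: a list with `article_id`,
#'   `raw_text`, `paragraphs` (data.frame: `para_index`, `char_start`,
#'   `char_end`, `sent_start`, `sent_end`, `text`) and `sentences`
#'   (data.frame: `sent_index`, `para_index`, `char_start`, `char_end`,
#'   `text`). All indices 0-based; all ranges half-open.
#' @export
qa_article <- function(article_id, paragraph_texts) {
  stopifnot(is.character(article_id), length(article_id) == 1L,
            is.character(paragraph_texts), length(paragraph_texts) >= 1L)
  sep <- paragraph_separator()
  raw_text <- paste(paragraph_texts, collapse = sep)

  offsets <- cumsum(c(0L, utils::head(nchar(paragraph_texts), -1L) + nchar(sep)))
  sent_list <- vector("list", length(paragraph_texts))
  para <- data.frame(para_index = seq_along(paragraph_texts) - 1L,
                     char_start = offsets,
                     char_end = offsets + nchar(paragraph_texts),
                     sent_start = NA_integer_, sent_end = NA_integer_,
                     text = paragraph_texts, stringsAsFactors = FALSE)
  n_sent <- 0L
  for (p in seq_along(paragraph_texts)) {
    segs <- segment_sentences(paragraph_texts[p])
    para$sent_start[p] <- n_sent
    para$sent_end[p] <- n_sent + nrow(segs)
    if (nrow(segs) > 0L) {
      segs$char_start <- segs$char_start + offsets[p]
      segs$char_end <- segs$char_end + offsets[p]
      segs$para_index <- p - 1L
      sent_list[[p]] <- segs
    }
    n_sent <- n_sent + nrow(segs)
  }
  sentences <- do.call(rbind, sent_list)
  if (is.null(sentences)) {
    sentences <- data.frame(text = character(0), char_start = integer(0),
                            char_end = integer(0), para_index = integer(0),
                            stringsAsFactors = FALSE)
  }
  sentences$sent_index <- seq_len(nrow(sentences)) - 1L
  sentences <- sentences[, c("sent_index", "para_index", "char_start",
                             "char_end", "text")]
  rownames(sentences) <- NULL
  structure(list(article_id = article_id, raw_text = raw_text,
                 paragraphs = para, sentences = sentences),
            class = "qa_article")
}

#' @export
print.qa_article <- function(x, ...) {
  cat(sprintf("<qa_article '%s': %d paragraphs, %d sentences, %d chars>\n",
              x$article_id, nrow(x$paragraphs), nrow(x$sentences),
              nchar(x$raw_text)))
  invisible(x)
}

#' The fixed paragraph join separator
#' @return the two-newline separator used for article-wide coordinates.
#' @export
paragraph_separator <- function() "\n\n"

#' Construct a question-answer example
#'
#' @param qid unique example id.
#' @param question the question string.
#' @param article_ref id of the article the question is about.
#' @param gold_answers non-empty character vector of gold answer strings.
#' @param answer_char_start optional 0-based offset of the answer into the
#'   article's raw text (`NA` for BioASQ-style records without offsets).
#' @return an object of class `qa_example`.
#' @export
qa_example <- function(qid, question, article_ref, gold_answers,
                       answer_char_start = NA_integer_) {
  stopifnot(length(gold_answers) >= 1L, all(nzchar(gold_answers)))
  structure(list(qid = qid, question = question, article_ref = article_ref,
                 gold_answers = gold_answers,
                 answer_char_start = as.integer(answer_char_start),
                 gold_sent_indices = integer(0),
                 target_para_indices = integer(0)),
            class = "qa_example")
}

#' @export
print.qa_example <- function(x, ...) {
  cat(sprintf("<qa_example '%s' on '%s': %d gold answer(s)%s>\n",
              x$qid, x$article_ref, length(x$gold_answers),
              if (is.na(x$answer_char_start)) "" else
                sprintf(", answer offset %d", x$answer_char_start)))
  invisible(x)
}

squad_error <- function(path_desc, msg) {
  stop(sprintf("SQuAD parse error at %s: %s", path_desc, msg), call. = FALSE)
}

#' Load a SQuAD-dialect JSON file
#'
#' Expects the v1 schema: `data` -> `paragraphs` (each with `context` and
#' `qas`) -> `qas` (each with `id`, `question` and `answers` holding `text`
#' and `answer_start`). One article is built per `data` entry; paragraph
#' boundaries are preserved and `answer_start` offsets are remapped from
#' paragraph-local to article-wide coordinates under the two-newline join.
#' Gold sentence and target paragraph are derived for every example.
#'
#' @param path path to the JSON file.
#' @return a list with `articles` (named list of [qa_article()] objects) and
#'   `examples` (list of [qa_example()] objects).
#' @export
load_squad_json <- function(path) {
  if (!file.exists(path)) stop("dataset file not found: ", path, call. = FALSE)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$data)) squad_error("$", "missing 'data'")
  articles <- list()
  examples <- list()
  for (ai in seq_along(doc$data)) {
    entry <- doc$data[[ai]]
    apath <- sprintf("data[%d]", ai)
    if (is.null(entry$paragraphs)) squad_error(apath, "missing 'paragraphs'")
    article_id <- if (!is.null(entry$title)) as.character(entry$title) else
      sprintf("article_%d", ai)
    ptexts <- vapply(seq_along(entry$paragraphs), function(pi) {
      ctx <- entry$paragraphs[[pi]]$context
      if (is.null(ctx)) squad_error(sprintf("%s.paragraphs[%d]", apath, pi),
                                    "missing 'context'")
      as.character(ctx)
    }, character(1))
    art <- qa_article(article_id, ptexts)
    articles[[article_id]] <- art

    for (pi in seq_along(entry$paragraphs)) {
      qas <- entry$paragraphs[[pi]]$qas
      if (is.null(qas)) next
      poff <- art$paragraphs$char_start[pi]
      plen <- nchar(ptexts[pi])
      for (qi in seq_along(qas)) {
        qa <- qas[[qi]]
        qpath <- sprintf("%s.paragraphs[%d].qas[%d]", apath, pi, qi)
        if (is.null(qa$question) || is.null(qa$answers) ||
            length(qa$answers) == 0L)
          squad_error(qpath, "missing 'question' or empty 'answers'")
        golds <- vapply(qa$answers, function(a) as.character(a$text), character(1))
        a1 <- qa$answers[[1L]]
        if (is.null(a1$answer_start))
          squad_error(paste0(qpath, ".answers[1]"), "missing 'answer_start'")
        local_start <- as.integer(a1$answer_start)
        if (local_start < 0L || local_start >= plen)
          squad_error(paste0(qpath, ".answers[1]"),
                      sprintf("answer_start %d outside its paragraph [0,%d)",
                              local_start, plen))
        ex <- qa_example(qid = if (!is.null(qa$id)) as.character(qa$id) else
                           sprintf("%s_q%d_%d", article_id, pi, qi),
                         question = as.character(qa$question),
                         article_ref = article_id,
                         gold_answers = golds,
                         answer_char_start = poff + local_start)
        ex$gold_sent_indices <- locate_gold_sentence(ex, art)
        ex$target_para_indices <- target_paragraphs(ex, art)$para_index
        examples[[length(examples) + 1L]] <- ex
      }
    }
  }
  list(articles = articles, examples = examples)
}

#' Write articles and examples back to SQuAD dialect
#'
#' Inverse of [load_squad_json()]: answer offsets are mapped back from
#' article-wide to paragraph-local coordinates.
#'
#' @param articles named list of [qa_article()] objects.
#' @param examples list of [qa_example()] objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_squad_json <- function(articles, examples, path) {
  data <- lapply(articles, function(art) {
    paragraphs <- lapply(seq_len(nrow(art$paragraphs)), function(pi) {
      prow <- art$paragraphs[pi, ]
      exs <- Filter(function(e) {
        identical(e$article_ref, art$article_id) &&
          !is.na(e$answer_char_start) &&
          e$answer_char_start >= prow$char_start &&
          e$answer_char_start < prow$char_end
      }, examples)
      qas <- lapply(exs, function(e) {
        list(id = e$qid, question = e$question,
             answers = lapply(e$gold_answers, function(g) {
               list(text = g,
                    answer_start = e$answer_char_start - prow$char_start)
             }))
      })
      list(context = prow$text, qas = qas)
    })
    list(title = art$article_id, paragraphs = paragraphs)
  })
  jsonlite::write_json(list(data = unname(data)), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Load a BioASQ-style flat JSON file
#'
#' Records of `{question, answers: [string], article: {id, paragraphs:
#' [string]}}`; no answer offsets. Gold sentences are derived by token
#' matching and target paragraphs by aggregation of every paragraph owning a
#' matched sentence.
#'
#' @inheritParams load_squad_json
#' @return as [load_squad_json()].
#' @export
load_bioasq_json <- function(path) {
  if (!file.exists(path)) stop("dataset file not found: ", path, call. = FALSE)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  articles <- list()
  examples <- list()
  for (ri in seq_along(doc)) {
    rec <- doc[[ri]]
    rpath <- sprintf("record[%d]", ri)
    if (is.null(rec$question) || is.null(rec$answers) || is.null(rec$article))
      squad_error(rpath, "missing 'question', 'answers' or 'article'")
    aid <- as.character(rec$article$id)
    if (is.null(articles[[aid]])) {
      ptexts <- vapply(rec$article$paragraphs, as.character, character(1))
      articles[[aid]] <- qa_article(aid, ptexts)
    }
    art <- articles[[aid]]
    ex <- qa_example(qid = sprintf("bioasq_%d", ri),
                     question = as.character(rec$question),
                     article_ref = aid,
                     gold_answers = vapply(rec$answers, as.character, character(1)))
    ex$gold_sent_indices <- find_answer_sentences_by_token_match(ex, art)
    if (length(ex$gold_sent_indices) > 0L)
      ex$target_para_indices <- target_paragraphs(ex, art)$para_index
    examples[[length(examples) + 1L]] <- ex
  }
  list(articles = articles, examples = examples)
}

#' Locate the gold sentence from an answer character offset
#'
#' Returns the single article-wide sentence index whose character span
#' contains the answer's start offset. An offset falling in inter-sentence
#' whitespace is assigned to the following sentence. A multi-sentence answer
#' is attributed to the sentence containing its start character.
#'
#' @param example a [qa_example()] with `answer_char_start` set.
#' @param article the owning [qa_article()].
#' @return an integer vector of length one (0-based sentence index).
#' @export
locate_gold_sentence <- function(example, article) {
  off <- example$answer_char_start
  if (is.na(off)) stop("example has no answer_char_start", call. = FALSE)
  if (off < 0L || off >= nchar(article$raw_text))
    stop(sprintf("answer offset %d outside article text [0,%d)", off,
                 nchar(article$raw_text)), call. = FALSE)
  s <- article$sentences
  hit <- which(s$char_start <= off & off < s$char_end)
  if (length(hit) == 1L) return(s$sent_index[hit])
  # inter-sentence whitespace: assign to the following sentence
  nxt <- which(s$char_start > off)
  if (length(nxt) == 0L)
    stop(sprintf("answer offset %d beyond the last sentence", off), call. = FALSE)
  s$sent_index[min(nxt)]
}

# contiguous-subsequence test on token vectors
is_contiguous_subseq <- function(needle, haystack) {
  n <- length(needle); m <- length(haystack)
  if (n == 0L || n > m) return(FALSE)
  for (i in seq_len(m - n + 1L)) {
    if (identical(haystack[i:(i + n - 1L)], needle)) return(TRUE)
  }
  FALSE
}

#' Find answer sentences by token matching
#'
#' For offset-free (BioASQ-style) examples: returns every sentence whose
#' normalized token sequence contains the normalized token sequence of any
#' gold answer as a contiguous run. May return several sentences (short
#' answers recur across an article) or none.
#'
#' @inheritParams locate_gold_sentence
#' @return integer vector of 0-based sentence indices (possibly empty).
#' @export
find_answer_sentences_by_token_match <- function(example, article) {
  golds <- lapply(example$gold_answers, normalize_answer)
  golds <- golds[vapply(golds, length, integer(1)) > 0L]
  if (length(golds) == 0L) return(integer(0))
  s <- article$sentences
  hits <- vapply(seq_len(nrow(s)), function(i) {
    stoks <- normalize_answer(s$text[i])
    any(vapply(golds, is_contiguous_subseq, logical(1), haystack = stoks))
  }, logical(1))
  s$sent_index[hits]
}

#' Target paragraph(s) of an example
#'
#' With an answer offset, the single paragraph owning the gold sentence; for
#' token-matched examples, every paragraph owning any matched sentence, in
#' document order (the aggregated target paragraph).
#'
#' @inheritParams locate_gold_sentence
#' @return the matching rows of `article$paragraphs`, in document order.
#' @export
target_paragraphs <- function(example, article) {
  gsi <- example$gold_sent_indices
  if (length(gsi) == 0L && !is.na(example$answer_char_start))
    gsi <- locate_gold_sentence(example, article)
  if (length(gsi) == 0L)
    stop(sprintf("example '%s' has no locatable gold sentence; unusable as a target",
                 example$qid), call. = FALSE)
  pidx <- sort(unique(article$sentences$para_index[
    article$sentences$sent_index %in% gsi]))
  article$paragraphs[article$paragraphs$para_index %in% pidx, , drop = FALSE]
}

#' Text of the target paragraph(s)
#'
#' Aggregated paragraphs are joined with the paragraph separator.
#' @inheritParams locate_gold_sentence
#' @return a character scalar.
#' @export
target_paragraph_text <- function(example, article) {
  paste(target_paragraphs(example, article)$text, collapse = paragraph_separator())
}
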