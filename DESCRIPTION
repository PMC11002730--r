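Package: sentex
Title: Sentence-Utility Context Extraction for Extractive Question Answering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for shrinking long biomedical articles to short, answerable
    contexts for extractive machine reading comprehension. Estimates a
    per-sentence utility signal for a question by leave-one-sentence-out
    differences in answer F1 or reader confidence, combines it with
    question-sentence cosine similarity in a weighted ensemble, and extracts a
    compact context around the utility peaks with a thresholded peak-and-window
    algorithm. Includes SQuAD-dialect and BioASQ-style corpus I/O with
    character-offset provenance, normalized token-level answer F1 and exact
    match scoring, deterministic scripted and lexical-overlap readers for
    testing, question-sentence-context training-triplet generation under four
    context-quality scenarios, a seeded parameter search over the extraction
    parameters against a gold-sentence-accuracy/context-F1 objective, and a
    seeded synthetic corpus generator with planted answer and support
    structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
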