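---
title: "Context extraction by sentence utility: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Context extraction by sentence utility: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sentex)
```

## The model

`sentex` shortens the input context of an extractive machine reading
comprehension (MRC) reader by keeping only the sentences estimated to be
useful for answering the question. The central quantity is the **utility of a
sentence within its context**, defined by leave-one-sentence-out
differencing. Writing $q$ for the question, $D$ for an ordered set of
sentences, and $D \setminus c$ for $D$ with sentence $c$ deleted (the
remainder re-joined in order by single spaces):

$$u_1(c) = \mathrm{F1}(q, D) - \mathrm{F1}(q, D \setminus c), \qquad
  u_2(c) = \mathrm{Conf}(q, D) - \mathrm{Conf}(q, D \setminus c),$$

where $\mathrm{F1}$ is the normalized token-level answer F1 of the reader's
prediction against the gold references and $\mathrm{Conf}$ is the reader's
confidence. $u_1$ requires known gold answers, so it is a training-time
signal; $u_2$ only requires running the reader. A third signal $u_3$ is the
cosine similarity between question and sentence embeddings. The three are
combined as a weighted mean,
$u = (\omega_1 u_1 + \omega_2 u_2 + \omega_3 u_3) / (\omega_1 + \omega_2 + \omega_3)$,
after a per-question min–max rescaling discussed below.

Extraction proceeds in five steps (`extract_context()`):

1. retrieve the top-$k$ paragraphs by question–paragraph cosine similarity;
2. score every sentence of the retrieved paragraphs;
3. mark as **peaks** the sentences whose combined score is at least
   $h \cdot \max(\text{scores})$;
4. add the sentences within $w$ positions of each peak, restricted to the
   retrieved set;
5. join the union in document order into the new context.

The working assumptions are those of the long-article biomedical setting:
answers are spans of single sentences (a multi-sentence answer is anchored at
the sentence containing its start character, and the window $w$ recovers the
remainder); the information needed to answer is concentrated in one target
paragraph but is not limited to the answer sentence itself; and reader
confidence is comparable across contexts for a fixed question.

## Parameters

| parameter | meaning | domain | default | rationale |
|---|---|---|---|---|
| $k$ | retrieved paragraphs | integer $\ge 1$ | 3 (6 for the retrieval baseline) | candidate pool large enough to cover retrieval misses without re-admitting the whole article |
| $w$ | window radius (sentences) | integer $\ge 1$ | 2 | covers the planted/typical support neighborhood of an answer sentence |
| $h$ | peak threshold (fraction of tallest score) | $[0, 1]$ | 0.8 | keeps only near-maximal peaks; 0 degenerates to "all candidates", 1 to "argmax only" |
| $\omega_{1..3}$ | ensemble weights | positive reals | $(1, 1, 1)$ | only ratios matter after rescaling; the nominal $(0,1)$ domain is relaxed to any positive weights, a documented deviation |
| $\alpha$ | objective trade-off | $[0, 1]$ grid | $0.05, 0.10, \ldots, 0.95$ | sweep over the scalarization of obj1 vs obj2 |

These defaults are starting points; `search_params()` tunes $(k, w, h,
\omega)$ against the validation objective.

## Numerical and design choices

**Answer-metric normalization.** Lowercase; delete punctuation outright, so a
hyphenated token like `T-UCstem1` becomes the single token `tucstem1`; remove
the articles *a*, *an*, *the*; split on whitespace; count token multisets
(not sets). This is the variant uniquely consistent with the worked scores
the tests reproduce (e.g. 0.14 and 0.92 for the lactic-acid-bacteria
example; without article removal those pairs give 0.13 and 0.93).
Multi-reference golds score by the maximum over references, ties to the
first.

**Context-level F1.** The optimization objective `context_f1()` counts plain
words — same lowercasing and punctuation stripping but **no** article
removal, since it measures textual overlap with the target paragraph, not
answer equivalence. The two metric layers deliberately differ.

**Per-question rescaling before the ensemble.** $u_2$ is unbounded and
scaled by the reader's confidence units, while $u_3 \in [-1, 1]$; combining
them raw would make the weights and the relative threshold $h$
uninterpretable. Each signal present is min–max rescaled to $[0, 1]$ within
the question's candidate set before the weighted mean.

**Degenerate scores.** An all-equal signal rescales to all zeros; a relative
threshold on a non-positive maximum is meaningless, so the fallback selects
the earliest argmax with its window only, rather than the entire candidate
set — uninformative scores should not silently disable extraction. With
`rescale = FALSE`, equal positive scores all tie as peaks and every candidate
is selected; both behaviors are tested.

**Peaks are a global relative threshold, not local maxima.** Since only the
tallest peaks matter, a plateau of near-maximal sentences should be kept even
where it is not a strict local maximum. A `peak_mode = "local"` variant is
exposed for comparison.

**Windows never cross out of the retrieved set.** Window membership is
measured in article sentence index but clipped to the candidate
(top-$k$-paragraph) sentences: only retrieved sentences were scored, and
importing unscored sentences would be inconsistent. Whether windows may
properly cross paragraph boundaries inside the retrieved set was genuinely
open; this clipped reading is one choice, flagged as such.

**Tie-breaking.** Paragraph ranking breaks score ties by document order;
retrieved paragraphs are returned in document order by default (a rank-order
flag exists) so that concatenated retrieval contexts preserve article flow;
the overlap reader takes the earliest maximal sentence; multi-reference
scoring takes the first best reference.

**Segmentation.** A deterministic rule-based splitter (sentence-final
punctuation followed by whitespace, with an abbreviation guard list) rather
than a learned model: every downstream number is then exactly reproducible,
and the synthetic generator writes unambiguous boundaries. Consequence:
sentence counts produced by other (unspecified or learned) segmenters will
not be matched exactly, and no assertion depends on them. Coordinates are 0-based and
half-open throughout; paragraphs join with a fixed two-newline separator and
all offsets are remapped at load.

**Reader-call caching.** Utilities over $S$ sentences need $S + 1$ reader
calls; the cache keys on the exact (question, context string) pair, keeping
oracle tests linear and repeated parameter evaluations cheap.

**Loss sign convention.** The scalarized loss is implemented in two forms:
`maximize_both`, $L = -(\alpha\,\mathrm{obj}_1 + (1-\alpha)\,\mathrm{obj}_2)$
(the default), and `as_printed`,
$L = -(\alpha\,\mathrm{obj}_1) + (1-\alpha)\,\mathrm{obj}_2$. The second form
is minimized by a *small* context F1, which contradicts treating the target
paragraph as a near-ideal selection; since the intended parenthesization is
ambiguous, both are available and the self-consistent one is the default.

**Search backend.** The default optimizer is seeded uniform random search
over bounded ranges ($k \in [1,10]$, $w \in [1,5]$, $h \in [0,1]$, weights in
$(0, 1]$): deterministic given the seed, trivially parallel over the $\alpha$
grid, and sufficient at the problem sizes the package targets. A
`model_based` backend spends half the budget exploring and then refines
locally around the incumbent. A full Bayesian optimizer was considered and
rejected as the default for reproducibility-first reasons.

**Estimator.** The shipped utility estimator is a ridge regression on four
lexical features (question-token overlap, sentence length, relative position,
cosine to the question) trained on generated triplets. It is a desk-scale
stand-in behind a contract — `estimate_utility(q, sentence, context) -> real`
— that any deterministic regressor can fill; an adapter seam for a
transformer reader (confidence = sum of start and end span scores) is
documented in `read_answer()` but required by nothing.

## The synthetic corpus: what it emulates, and what it does not

`make_corpus()` plants exactly the structure the method assumes: per
question, one target paragraph containing a gold answer sentence (a globally
unique two-token span with recorded character offset) and `n_support = 2`
support sentences at the nearest positions; the question shares three topic
tokens with the answer sentence and two each with the supports; every other
paragraph is a distractor that receives each question token independently
with probability `rho = 0.2`. The matching scripted reader answers iff the
answer sentence and at least `ceiling(n_support/2)` supports are present,
with confidence `2 + 1.5 * supports_present`, and abstains at confidence
`0.5` otherwise — mimicking the observed qualitative behavior of transformer
readers, whose correctness and confidence rise as corroborating sentences
join the answer sentence.

Chosen generation conditions (fixed once): 8 paragraphs per article, 6
sentences per paragraph, 3 questions per article, 67 articles by default
(about 200 questions), vocabulary of 2000 nonsense words, seed 0 for the
reference corpus. A 1-to-5-sentence run around the gold sentence (gold
excluded) realizes the "relevant but insufficient" triplet scenario; the
preceding paragraph is preferred for the "adjacent" scenario when both
neighbors exist; the "irrelevant" scenario flips a seeded coin between the
furthest paragraph and a foreign article. Triplet counts per scenario per
question default to (1, 2, 1, 1) — corpus-scale volumes (on the order of 120k triplets
from ~1500 questions) are configuration defaults, not hard-coded constants.

What the generator does **not** emulate: natural-language syntax and
paraphrase (tokens are nonsense words, so lexical overlap is a perfect
relevance proxy — real questions overlap their contexts far more weakly);
imperfect gold annotations; readers that answer *incorrectly* with high
confidence, or that exploit incidental phrases elsewhere in the article (the
scripted reader either answers exactly or abstains, and its abstention
confidence is constant — a consequence noted below); and answers recurring
across many paragraphs, beyond what the offset-free token-matching variant
exercises. Passing the planted-recovery simulations therefore demonstrates
the *algorithmic* correctness of retrieval, scoring, peak selection and
windowing under the method's assumptions — not performance on real
biomedical corpora, which requires external data and trained readers.

One consequence of the constant abstention confidence: every context lacking
the answer sentence yields $u_1 = u_2 = 0$, so among the four triplet
scenarios only the target-paragraph scenario has strictly positive mean
labels; the other three are weakly ordered. The label-distribution tests
assert exactly that.

## Problem sizes used by the test suite

The suite fixes sizes that exercise every code path while staying
desk-scale: exhaustive leave-one-out verification on all $2^{10}-1$ sentence
subsets of a 10-sentence planted article; 1000-draw randomized equivalence
checks of both F1 layers against an explicit counting oracle; the reference
planted-recovery simulation on 200 questions at seed 0 with the $u_2$ oracle
and $(k, w, h) = (3, 2, 0.8)$; and parameter searches with budgets of 3–6
evaluations per $\alpha$ on 6–8 questions. Search determinism, trace
non-domination and the default $\alpha$ grid are asserted directly.

## Known limitations

- The extraction operates within a single article; multi-article retrieval
  and token-budget-constrained extraction are out of scope.
- The hashed bag-of-words embedder is a deterministic stand-in; it carries
  no semantics beyond lexical overlap, and hash collisions (dimension
  $2^{16}$) can inflate similarity between unrelated rare tokens.
- The abstention marker carries no span; span-position-aware scoring and
  generative readers are not supported.
- Reported wall-clock behavior is environment-dependent and is never part of
  any assertion.
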