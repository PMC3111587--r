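---
title: "Token lattice tokenization: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Token lattice tokenization: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(tokenlattice)
```

## The problem

Biomedical text — clinical terminology entries, drug descriptions,
laboratory findings — breaks whitespace tokenizers in systematic ways.
A single whitespace-delimited string frequently contains several
meaningful tokens (`"50mg"`, `"patient's"`, `"(disorder)"`), while other
strings that *look* splittable must stay whole (`"Precorrin-3B"`,
`"47:k:1,5,7"`). Worse, the correct decision depends on context:
`"mg/ml"` abbreviates *mg per ml*, while `"organ/system"` abbreviates
*organ and system*. A pipeline of greedy rules has to commit at each
boundary before the context that disambiguates it has been seen.

This package separates the two concerns:

1. **Transducers** enumerate every defensible reading of each span.
2. A **token lattice** stores all of them compactly.
3. An **adapted Viterbi decoder** over a part-of-speech hidden Markov
   model (HMM) picks the single most probable tagged token sequence.

No rule ever has to be right on its own; it only has to *propose*. The
statistical model arbitrates.

## Transducers

A transducer is a deterministic function `(context, suffix)` that
examines the start of the remaining text and either declines or returns
`(consumed, tokens)`: how many characters it consumes and which tokens
it emits. Three shapes matter:

* **Epsilon**: the whitespace class consumes characters and emits
  nothing.
* **One-to-one**: word runs, numbers, standalone punctuation.
* **One-to-many**: the possessive class splits `"patient's"` into
  `("patient", "'s")`; the expansion class splits `"50mg"` into
  `("50", "mg")` and restores elided closed-class words: `"C1-4"`
  becomes `("C1", "to", "4")`, `"organ/system"` becomes
  `("organ", "and", "system")`, and a unit pair such as `"mg/ml"`
  additionally yields `("mg", "per", "ml")` — both readings enter the
  lattice.

```{r}
transduce_expansion(context(), "10mg of")
```

The expansion consumed 4 characters — exactly the fused dose, never the
following context. The substance class keeps chemical and serotype
names whole and explicitly declines identifier ranges, which belong to
the expansion class:

```{r}
transduce_substance(context(), "Precorrin-3B enzyme")$tokens
is_applicable(transduce_substance(context(), "C1-4"))
```

## The lattice

`build_lattice()` applies every transducer at every character position.
Vertices `p0 … pN` sit between characters (0-based, half-open spans);
an applicable result at position *i* consuming *l* characters
contributes a path from `p_i` to `p_(i+l)`.

Two design choices keep the lattice well-behaved:

* **Interior vertices.** When a multi-token output tiles its span as
  literal substrings (`"50mg"` → `"50"`, `"mg"`), the chain runs
  through the *position* vertices, so identical readings proposed by
  different transducers collapse into the same edges. Only transforming
  outputs (the inserted `"to"`/`"and"`/`"per"`) receive fresh auxiliary
  vertices. Together with edge deduplication this enforces the core
  invariant structurally: **no two complete paths read off the same
  token sequence**.
* **Pruning.** Edges that lie on no complete `p0 → pN` path are
  removed; a position no transducer covers is an error, not a silent
  gap.

```{r}
lat <- build_lattice(text_unit("The patient's 10mg tablet."),
                     default_transducers())
lat
seqs <- enumerate_token_sequences(lat)
length(seqs)
```

Eight candidate segmentations: the possessive split is independent of
the dose split and of whether the final period separates, and the
readings multiply (2 × 2 × 2). The lattice is a bounded DAG: every edge
moves strictly forward through the numeric vertex order, so decoding
can sweep it in one topological pass.

## The model

The decoder scores candidates with a POS-tag HMM of order 0 or 1,
trained from a slash-format tagged corpus (`token/TAG`, one sentence
per line) by `hmm_train()`.

* **Order 1** (default): the score of a tagged sequence is
  `sum log P(tag_i | tag_(i-1)) + log P(token_i | tag_i)`, with the
  first tag conditioned on a beginning-of-sentence symbol. There is no
  end-of-sequence factor.
* **Order 0**: transitions are replaced by the unigram tag prior — a
  deliberately context-free baseline.

**Smoothing.** All conditionals use additive (Lidstone) smoothing with
`alpha = 0.1` by default:
`P(token | tag) = (count + alpha) / (count(tag) + alpha * V)`, where
`V` is the vocabulary size plus one slot for a single unknown-token
bucket — every out-of-vocabulary token scores identically given a tag.
`alpha = 0` is allowed and yields exact relative frequencies with
`-Inf` for unseen events; `0.1` keeps all paths finite without drowning
the signal in pseudo-counts. All scoring is on the natural-log scale,
so products of small probabilities never underflow.

One property of this unknown model is worth knowing: `P(unknown | tag)`
grows as the tag's training count shrinks, so very rare tags can
attract unknown tokens. The fixture design below takes this into
account.

## The decoder

`viterbi_decode()` runs dynamic programming over *(vertex, tag)* states
in topological vertex order. Epsilon edges advance the vertex without
contributing score; a token edge extends every predecessor state by
transition + emission. Because the lattice is a DAG and the state space
is (vertices × tags), the sweep maximizes jointly over *all complete
paths and all tag assignments* — segmentation and tagging are decided
together, which is the point of the design: the tag context pays for
the right split.

```{r}
corpus <- generate_tagged_corpus(fixture_spec(seed = 42))$sentences
model <- hmm_train(corpus, order = 1)
tokenize_unit("Primary Sjogren's syndrome with organ/system involvement (disorder)",
              default_transducers(), model)
```

**Ties** are broken deterministically: higher score, then fewer tokens,
then lexicographically smaller token sequence, then tags. The same rule
is used by `brute_force_decode()`, the testing oracle that enumerates
every path and tagging exhaustively; the test suite checks the two
agree exactly on hundreds of seeded random lattices.

**Normalization.** `normalize = TRUE` compares candidates by mean
per-token log-probability instead of the raw joint. Because candidate
paths differ in length, the raw joint has a mild bias toward fewer
tokens. The DP state is augmented with the token count, so the
normalized search remains exact rather than heuristic.

## Synthetic fixtures: what they emulate and what they do not

Realistic evaluation corpora for this task (clinical terminologies,
tagged biomedical corpora) are licensed, so the package generates its
own study material. The generator defaults are the study conditions
used by the tests: `n_units = 500` evaluation units with ambiguity rate
`0.455`, and 1200 training sentences.

* `ground_truth_hmm("clinical")` is an explicit 10-tag generative chain
  over concept-description vocabulary. Design choices encode the
  domain: measurement units carry their own tag `NNU`, whose outgoing
  transitions hold the disambiguating signal (`NNU → IN` likely,
  `NNU → CC` rare — that is what makes `"mg/ml"` read as *per* while
  `"organ/system"` reads as *and*); there is **no determiner tag**,
  because concept descriptions lack articles — which also avoids the
  rare-tag unknown-token magnet described above; parentheses are
  frequent, matching semantic-tag suffixes like `"(disorder)"`.
* `ground_truth_hmm("general")` is a newspaper-style chain sharing tag
  conventions but lacking clinical vocabulary and the unit tag. Mixing
  the two via `domain_mix` emulates training on out-of-domain text
  versus augmenting it with in-domain material.
* `ground_truth_hmm("toy")` is a 3-tag chain for parameter-recovery
  checks: at roughly 10,000 sampled tokens, every estimated transition
  probability comes back within ±0.05 of the generating value with a
  wide margin, which would not be true of rare rows in a 10-tag chain
  at that sample size.

`generate_eval_set()` instantiates concept-description templates —
fused doses, possessive clitics, parenthesized semantic tags,
identifier ranges, unit slashes, plus lists — and builds each unit's
gold segmentation alongside its text, so gold is reachable in the
lattice by construction.

**Limitations.** These chains are caricatures: vocabulary is small,
sentence structure is first-order by construction, and accuracy numbers
obtained on them characterize the *implementation* (the decoder finds
the argmax; context helps exactly where it was designed to), not
expected performance on real clinical text. The honest claims are the
ordinal ones: order 1 beats order 0, and in-domain augmentation beats
out-of-domain training, on material whose ambiguity profile resembles
the motivating domain.

## Evaluation statistics

`exact_match_accuracy()` scores a unit correct only if its entire token
sequence matches gold. The confidence interval is the normal
approximation `p ± 1.96 * sqrt(p(1-p)/n)`, adequate at the sample sizes
used here (hundreds to thousands of units; not recommended for tiny
`n` or `p` near 0/1, where it degenerates). Agreement between two
segmentations uses Cohen's kappa with a *fixed* chance-agreement
probability of 0.5 — agreement on a unit is all-or-nothing, modeled
against a coin toss — rather than a marginal-frequency estimate, which
is not meaningful when the "categories" are unbounded sets of token
sequences.

```{r}
cohens_kappa(0.944)
round(100 * binomial_ci(0.539, 2781), 1)
```

## Numerical choices, summarized

* Natural-log scoring throughout; no probability products in linear
  space.
* Additive smoothing `alpha = 0.1`; single unknown bucket; vocabulary
  size counts one reserved unknown slot.
* No end-of-sequence transition factor (scores are comparable across
  the lattice's variable-length candidates without one; length
  preference can be made explicit with `normalize = TRUE`).
* Deterministic total order on decoded results (score, token count,
  token strings, tags) so decoding is reproducible and the oracle
  comparison is exact.
* Guard rails instead of silent truncation: path enumeration and the
  brute-force oracle refuse inputs beyond their combination bounds.
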