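# Shared generators for property tests: random small text units whose
# lattices stay within the brute-force oracle's combination bound for a
# 3-tag model, and small trained models.

# Fragments with at most 4 tokens per reading and at most 4 readings each;
# two fragments joined by a space keep sum(K^len) under 2e5 at K = 3.
oracle_fragment_pool <- function() {
  c("dog", "the", "runs", "cat's", "10mg", "C1-4", "III", "bone,", "(vet",
    "a", "1,000", "x/y", "mg/ml", "A + b", "sees.")
}

random_oracle_unit <- function(seed) {
  set.seed(seed)
  text <- paste(sample(oracle_fragment_pool(), 2L, replace = TRUE),
                collapse = " ")
  text_unit(text, paste0("rl", seed))
}

# A tiny hand-countable corpus:
#   the/DT dog/NN runs/VB
#   the/DT cat/NN
# counts: DT=2 NN=2 VB=1; vocab {cat, dog, runs, the} (V = 4 + 1 unknown)
tiny_corpus <- function() {
  list(
    data.frame(token = c("the", "dog", "runs"), tag = c("DT", "NN", "VB")),
    data.frame(token = c("the", "cat"), tag = c("DT", "NN"))
  )
}

toy_corpus <- function(seed = 5L, n_sentences = 300L) {
  set.seed(seed)
  sample_hmm_corpus(ground_truth_hmm("toy"), n_sentences)
}

toy_models <- function() {
  corp <- toy_corpus()
  list(
    hmm_train(corp, order = 1L, alpha = 0.1),
    hmm_train(corp, order = 0L, alpha = 0.1),
    hmm_train(corp, order = 1L, alpha = 0.5)
  )
}

# Run viterbi and the brute-force oracle on one seeded random lattice and
# check full agreement (tokens, tags, score).
expect_oracle_agreement <- function(seed, model, transducers,
                                    normalize = FALSE) {
  unit <- random_oracle_unit(seed)
  lat <- build_lattice(unit, transducers)
  got <- viterbi_decode(lat, model, normalize = normalize)
  want <- brute_force_decode(lat, model, normalize = normalize)
  expect_identical(got$tokens, want$tokens,
                   label = sprintf("tokens for unit '%s'", unit$text))
  expect_identical(got$tags, want$tags,
                   label = sprintf("tags for unit '%s'", unit$text))
  expect_equal(got$logprob, want$logprob, tolerance = 1e-9,
               label = sprintf("score for unit '%s'", unit$text))
  invisible(NULL)
}
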