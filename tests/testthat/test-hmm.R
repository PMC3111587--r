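# tiny_corpus() (see helper-generators.R):
#   the/DT dog/NN runs/VB
#   the/DT cat/NN
# counts: DT=2 NN=2 VB=1; vocab {cat, dog, runs, the} (V = 4 + 1 unknown)

test_that("smoothed emission probabilities match hand computation", {
  m <- hmm_train(tiny_corpus(), order = 1L, alpha = 0.1)
  expect_identical(m$tags, c("DT", "NN", "VB"))
  expect_identical(m$vocab_size, 5L)
  # P(the | DT) = (2 + .1) / (2 + .1 * 5)
  expect_equal(exp(emission_logprob(m, "the", "DT")), 2.1 / 2.5)
  # P(dog | NN) = (1 + .1) / (2 + .5)
  expect_equal(exp(emission_logprob(m, "dog", "NN")), 1.1 / 2.5)
  # unknown bucket: P(unseen | VB) = .1 / (1 + .5), equal for all unseen
  expect_equal(exp(emission_logprob(m, "zzz", "VB")), 0.1 / 1.5)
  expect_equal(emission_logprob(m, "zzz", "VB"),
               emission_logprob(m, "qqq", "VB"))
})

test_that("smoothed transitions and priors match hand computation", {
  m <- hmm_train(tiny_corpus(), order = 1L, alpha = 0.1)
  # BOS -> DT twice out of 2 sentence starts: (2 + .1) / (2 + .1 * 3)
  expect_equal(exp(transition_logprob(m, m$bos, "DT")), 2.1 / 2.3)
  # DT -> NN twice out of 2 DT contexts
  expect_equal(exp(transition_logprob(m, "DT", "NN")), 2.1 / 2.3)
  # NN -> VB once out of 1 non-final NN
  expect_equal(exp(transition_logprob(m, "NN", "VB")), 1.1 / 1.3)
  # unigram prior: P(NN) = (2 + .1) / (5 + .3)
  expect_equal(exp(tag_logprior(m, "NN")), 2.1 / 5.3)
})

test_that("emission and transition distributions are normalized", {
  m <- hmm_train(toy_corpus(), order = 1L, alpha = 0.1)
  for (t in m$tags) {
    # vocabulary plus one unknown slot sums to 1
    p <- sum(exp(emission_logprob(m, m$vocab, rep(t, length(m$vocab))))) +
      exp(emission_logprob(m, "\x01unseen\x01", t))
    expect_equal(p, 1, tolerance = 1e-12)
  }
  for (p0 in c(m$bos, m$tags)) {
    p <- sum(exp(transition_logprob(m, rep(p0, length(m$tags)), m$tags)))
    expect_equal(p, 1, tolerance = 1e-12)
  }
  expect_equal(sum(exp(tag_logprior(m, m$tags))), 1, tolerance = 1e-12)
})

test_that("alpha = 0 reproduces exact relative frequencies and -Inf", {
  m <- hmm_train(tiny_corpus(), order = 1L, alpha = 0)
  expect_equal(exp(transition_logprob(m, "DT", "NN")), 1)
  expect_identical(transition_logprob(m, "DT", "VB"), -Inf)
  expect_identical(emission_logprob(m, "zzz", "NN"), -Inf)
})

test_that("score_path sums transitions and emissions by order", {
  m1 <- hmm_train(tiny_corpus(), order = 1L, alpha = 0.1)
  m0 <- hmm_train(tiny_corpus(), order = 0L, alpha = 0.1)
  path <- data.frame(token = c("the", "dog"), tag = c("DT", "NN"))
  expect_equal(score_path(m1, path),
               transition_logprob(m1, m1$bos, "DT") +
                 emission_logprob(m1, "the", "DT") +
                 transition_logprob(m1, "DT", "NN") +
                 emission_logprob(m1, "dog", "NN"))
  expect_equal(score_path(m0, path),
               sum(tag_logprior(m0, c("DT", "NN"))) +
                 emission_logprob(m0, "the", "DT") +
                 emission_logprob(m0, "dog", "NN"))
  expect_identical(score_path(m1, tagged_tokens()), 0)
})

test_that("training rejects malformed input", {
  expect_error(hmm_train(list()), "empty")
  expect_error(hmm_train(list(data.frame(x = 1))), "malformed sentence")
  expect_error(hmm_train(list(data.frame(token = "", tag = "NN"))),
               "empty token or tag")
  expect_error(
    hmm_train(list(data.frame(token = "a", tag = "<BOS>"))),
    "BOS")
  expect_error(emission_logprob(hmm_train(tiny_corpus()), "a", "XX"),
               "not in the model's tag set")
})

test_that("a persisted model reproduces the trained one exactly", {
  m <- hmm_train(toy_corpus(n_sentences = 50L), order = 1L, alpha = 0.1)
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  write_hmm_model(m, path)
  m2 <- read_hmm_model(path)
  expect_identical(m2$tags, m$tags)
  expect_identical(m2$vocab, m$vocab)
  expect_equal(m2$emission, m$emission)
  expect_equal(m2$transition, m$transition)
  probe <- data.frame(token = c("the", "dog", "unknownword"),
                      tag = c("DET", "NOUN", "VERB"))
  expect_equal(score_path(m2, probe), score_path(m, probe))
  bad <- tempfile(fileext = ".json")
  on.exit(unlink(bad), add = TRUE)
  jsonlite::write_json(list(a = 1), bad, auto_unbox = TRUE)
  expect_error(read_hmm_model(bad), "not a tokenlattice HMM model")
})
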