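test_that("ground-truth parameter sets are proper distributions", {
  for (domain in c("clinical", "general", "toy")) {
    h <- ground_truth_hmm(domain)
    expect_equal(unname(rowSums(h$trans)), rep(1, length(h$tags)),
                 tolerance = 1e-9)
    expect_equal(sum(h$start), 1, tolerance = 1e-9)
    expect_identical(names(h$emissions), h$tags)
    for (t in h$tags) {
      expect_equal(sum(h$emissions[[t]]), 1, tolerance = 1e-9)
      expect_true(all(h$emissions[[t]] > 0))
    }
  }
})

test_that("the clinical and toy chains differ in scale as documented", {
  expect_length(ground_truth_hmm("toy")$tags, 3L)
  clin <- ground_truth_hmm("clinical")
  expect_true("NNU" %in% clin$tags)        # measurement-unit tag
  expect_false("NNU" %in% ground_truth_hmm("general")$tags)
  expect_false("DT" %in% clin$tags)        # concept descriptions: no articles
})

test_that("sampled corpora respect length bounds and vocabularies", {
  h <- ground_truth_hmm("toy")
  set.seed(3)
  corp <- sample_hmm_corpus(h, 50L, len_range = c(4L, 7L))
  lens <- vapply(corp, nrow, integer(1))
  expect_true(all(lens >= 4L & lens <= 7L))
  vocab <- unique(unlist(lapply(h$emissions, names)))
  for (s in corp) {
    expect_true(all(s$token %in% vocab))
    expect_true(all(s$tag %in% h$tags))
  }
})

test_that("worked examples cover the documented ambiguity sources", {
  ex <- example_descriptions()
  expect_length(ex, 7L)
  texts <- vapply(ex, `[[`, character(1), "text")
  expect_true(any(grepl("/", texts)))   # slash list
  expect_true(any(grepl("'s", texts)))  # possessive clitic
  expect_true(any(grepl("[0-9]mg", texts)))  # fused dose
  expect_true(any(grepl("C1-4", texts)))     # identifier range
  for (e in ex) expect_true(length(e$gold) >= 2L)
})

test_that("the evaluation set hits the ambiguity rate exactly", {
  spec <- fixture_spec(seed = 9L, n_units = 500L, ambiguity_rate = 0.455)
  es <- generate_eval_set(spec)
  expect_length(es$units, 500L)
  expect_identical(sum(es$ambiguous), 228L)  # floor(0.455 * 500 + 0.5)
  ids <- vapply(es$units, function(u) u$unit_id, character(1))
  expect_false(anyDuplicated(ids) > 0L)
  expect_identical(names(es$gold), ids)
})

test_that("fixture generation is reproducible and seed-sensitive", {
  spec <- fixture_spec(seed = 21L, n_units = 30L)
  a <- generate_eval_set(spec)
  b <- generate_eval_set(spec)
  expect_identical(a$gold, b$gold)
  other <- generate_eval_set(fixture_spec(seed = 22L, n_units = 30L))
  expect_false(identical(a$gold, other$gold))
  ca <- generate_tagged_corpus(spec)
  cb <- generate_tagged_corpus(spec)
  expect_identical(ca$sentences, cb$sentences)
})

test_that("generation restores the caller's RNG state", {
  set.seed(99)
  want <- stats::runif(5)
  set.seed(99)
  invisible(generate_eval_set(fixture_spec(seed = 4L, n_units = 10L)))
  invisible(generate_tagged_corpus(fixture_spec(seed = 4L,
                                                n_sentences = 5L)))
  expect_identical(stats::runif(5), want)
})

test_that("domain_mix controls the origin of training sentences", {
  out_only <- generate_tagged_corpus(fixture_spec(seed = 2L,
                                                  n_sentences = 120L,
                                                  domain_mix = 0))
  toks <- unlist(lapply(out_only$sentences, `[[`, "token"))
  tags <- unlist(lapply(out_only$sentences, `[[`, "tag"))
  expect_false("NNU" %in% tags)     # no clinical unit tag
  expect_false("mg" %in% toks)      # no clinical vocabulary
  in_only <- generate_tagged_corpus(fixture_spec(seed = 2L,
                                                 n_sentences = 120L,
                                                 domain_mix = 1))
  expect_true("NNU" %in% unlist(lapply(in_only$sentences, `[[`, "tag")))
})

test_that("fixture_spec validates its study-condition parameters", {
  expect_error(fixture_spec(ambiguity_rate = 1.5), "ambiguity_rate")
  expect_error(fixture_spec(domain_mix = -0.1), "domain_mix")
  expect_error(fixture_spec(n_units = 0))
  spec <- fixture_spec()
  expect_identical(spec$n_units, 500L)
  expect_equal(spec$ambiguity_rate, 0.455)
})
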