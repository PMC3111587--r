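ctx <- context()

test_that("transduce_result validates its invariants", {
  expect_s3_class(transduce_result(3L, "abc"), "transduce_result")
  expect_false(is_applicable(not_applicable()))
  expect_true(is_applicable(transduce_result(1L, "a")))
  expect_error(transduce_result(2L, NULL), "consume no text")
  expect_error(transduce_result(0L, "a"), "must consume text")
  expect_error(transduce_result(1L, ""), "non-empty")
})

test_that("whitespace consumes maximal runs and emits nothing", {
  r <- transduce_whitespace(ctx, "   abc")
  expect_identical(r$consumed, 3L)
  expect_identical(r$tokens, character(0))
  expect_false(is_applicable(transduce_whitespace(ctx, "abc")))
})

test_that("word runs keep whole whitespace-delimited strings", {
  r <- transduce_word_run(ctx, "organ/system involvement")
  expect_identical(r$consumed, 12L)
  expect_identical(r$tokens, "organ/system")
  expect_false(is_applicable(transduce_word_run(ctx, " x")))
})

test_that("alphabetic words keep internal hyphens and yield to clitics", {
  r <- transduce_alphabetic(ctx, "non-commissioned personnel")
  expect_identical(r$tokens, "non-commissioned")
  expect_identical(r$consumed, 16L)
  # the possessive class owns word + 's; the bare-word reading declines
  expect_false(is_applicable(transduce_alphabetic(ctx, "patient's chart")))
  # but a longer alphanumeric continuation is not a clitic boundary
  expect_true(is_applicable(transduce_alphabetic(ctx, "patients chart")))
})

test_that("numeric tokens cover integers, decimals, groups, fractions, romans", {
  expect_identical(transduce_numeric(ctx, "1500 g")$tokens, "1500")
  expect_identical(transduce_numeric(ctx, "1.2%")$tokens, "1.2")
  expect_identical(transduce_numeric(ctx, "10,000 units")$consumed, 6L)
  expect_identical(transduce_numeric(ctx, "1/2 dose")$tokens, "1/2")
  expect_identical(transduce_numeric(ctx, "III arizonae")$tokens, "III")
  expect_false(is_applicable(transduce_numeric(ctx, "abc")))
})

test_that("possessives split the clitic from its stem", {
  r <- transduce_possessive(ctx, "Sjogren's syndrome")
  expect_identical(r$tokens, c("Sjogren", "'s"))
  expect_identical(r$consumed, 9L)
  expect_false(is_applicable(transduce_possessive(ctx, "patients")))
  expect_false(is_applicable(transduce_possessive(ctx, "10mg")))
})

test_that("independent symbols are single punctuation tokens", {
  for (ch in c("(", ")", ",", ".", "-", ":")) {
    r <- transduce_independent(ctx, paste0(ch, "rest"))
    expect_identical(r$tokens, ch)
    expect_identical(r$consumed, 1L)
  }
  # apostrophes, slashes and plus belong to other classes
  expect_false(is_applicable(transduce_independent(ctx, "'s")))
  expect_false(is_applicable(transduce_independent(ctx, "/g")))
  expect_false(is_applicable(transduce_independent(ctx, "+ b")))
})

test_that("the quantity split consumes the fused dose only", {
  rs <- transduce_expansion(ctx, "10mg of")
  expect_length(rs, 1L)
  expect_identical(rs[[1L]]$consumed, 4L)
  expect_identical(rs[[1L]]$tokens, c("10", "mg"))
  rs2 <- transduce_expansion(ctx, "1.5ml dose")
  expect_identical(rs2[[1L]]$tokens, c("1.5", "ml"))
})

test_that("ranges expand the elided closed-class 'to'", {
  rs <- transduce_expansion(ctx, "C1-4")
  expect_length(rs, 1L)
  expect_identical(rs[[1L]]$tokens, c("C1", "to", "4"))
  expect_identical(rs[[1L]]$consumed, 4L)
})

test_that("slashes expand to 'and', and additionally to 'per' for units", {
  rs <- transduce_expansion(ctx, "organ/system involvement")
  expect_length(rs, 1L)
  expect_identical(rs[[1L]]$tokens, c("organ", "and", "system"))
  rs2 <- transduce_expansion(ctx, "ml/g solution")
  toks <- lapply(rs2, `[[`, "tokens")
  has <- function(x) any(vapply(toks, identical, logical(1), x))
  expect_true(has(c("ml", "and", "g")))
  expect_true(has(c("ml", "per", "g")))
})

test_that("plus lists expand to 'and'", {
  rs <- transduce_expansion(ctx, "Paracetamol + caffeine")
  expect_identical(rs[[1L]]$tokens, c("Paracetamol", "and", "caffeine"))
  expect_identical(rs[[1L]]$consumed, 22L)
})

test_that("substances and serotypes stay whole; ranges are declined", {
  expect_identical(transduce_substance(ctx, "Precorrin-3B enzyme")$tokens,
                   "Precorrin-3B")
  expect_identical(transduce_substance(ctx, "47:k:1,5,7")$tokens,
                   "47:k:1,5,7")
  expect_identical(transduce_substance(ctx, "O128:NM serotype")$tokens,
                   "O128:NM")
  expect_identical(transduce_substance(ctx, "H-987 compound")$tokens, "H-987")
  expect_false(is_applicable(transduce_substance(ctx, "C1-4")))
  expect_false(is_applicable(transduce_substance(ctx, "non-commissioned")))
})

test_that("transform tables rewrite emitted surface tokens", {
  td <- transducer("expansion", transduce_expansion,
                   transform_table = c(mg = "milligrams"))
  rs <- apply_transducer(td, ctx, "10mg of")
  expect_identical(rs[[1L]]$tokens, c("10", "milligrams"))
})

test_that("the default set is complete and subsettable", {
  tds <- default_transducers()
  expect_named(tds, c("whitespace", "word_run", "alphabetic", "numeric",
                      "possessive", "independent", "expansion", "substance"))
  sub <- default_transducers(enabled = c("whitespace", "word_run"))
  expect_named(sub, c("whitespace", "word_run"))
  expect_error(default_transducers(enabled = "nope"), "unknown transducer")
})

test_that("the closed-class inventory contains the expansion targets", {
  words <- closed_class_words()
  expect_true(all(c("to", "and", "per", "of", "with") %in% words))
  expect_true(all(nzchar(words)))
})
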