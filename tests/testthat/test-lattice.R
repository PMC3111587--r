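tds <- default_transducers()

test_that("the lattice is a bounded DAG over character positions", {
  lat <- build_lattice(text_unit("dental arch"), tds)
  expect_s3_class(lat, "token_lattice")
  expect_identical(lat$start, "p0")
  expect_identical(lat$end, "p11")
  # topological order: vertex keys are sorted and every edge goes forward
  expect_true(!is.unsorted(lat$vertex_key))
  expect_true(all(lat$vertex_key[lat$edges$from] <
                    lat$vertex_key[lat$edges$to]))
})

test_that("epsilon edges carry whitespace only and are elided on readoff", {
  lat <- build_lattice(text_unit("  dental  arch  "), tds)
  expect_true(all(lat$edges$label[lat$edges$epsilon] == ""))
  expect_true(all(nzchar(lat$edges$label[!lat$edges$epsilon])))
  seqs <- enumerate_token_sequences(lat)
  expect_identical(seqs, list(c("dental", "arch")))
})

test_that("no two complete paths yield the same token sequence", {
  for (seed in 301:340) {
    unit <- random_oracle_unit(seed)
    lat <- build_lattice(unit, tds)
    # count complete paths by dynamic programming over the DAG
    npaths <- stats::setNames(numeric(length(lat$vertex_key)),
                              names(lat$vertex_key))
    npaths[lat$start] <- 1
    for (v in names(lat$vertex_key)) {
      outs <- which(lat$edges$from == v)
      for (ei in outs) {
        npaths[lat$edges$to[ei]] <- npaths[lat$edges$to[ei]] + npaths[v]
      }
    }
    seqs <- enumerate_token_sequences(lat)
    expect_identical(length(seqs), as.integer(npaths[lat$end]),
                     label = sprintf("distinct sequences vs paths for '%s'",
                                     unit$text))
  }
})

test_that("every retained edge lies on a complete path", {
  for (seed in 341:360) {
    lat <- build_lattice(random_oracle_unit(seed), tds)
    # re-deriving reachability must keep every edge
    reach <- function(seed_v, src, dst) {
      seen <- seed_v; frontier <- seed_v
      repeat {
        nxt <- setdiff(unique(dst[src %in% frontier]), seen)
        if (length(nxt) == 0L) break
        seen <- c(seen, nxt); frontier <- nxt
      }
      seen
    }
    fwd <- reach(lat$start, lat$edges$from, lat$edges$to)
    bwd <- reach(lat$end, lat$edges$to, lat$edges$from)
    expect_true(all(lat$edges$from %in% fwd & lat$edges$to %in% bwd))
  }
})

test_that("ambiguous descriptions produce all documented readings", {
  lat <- build_lattice(text_unit("organ/system"), tds)
  seqs <- enumerate_token_sequences(lat)
  has <- function(x) any(vapply(seqs, identical, logical(1), x))
  expect_true(has("organ/system"))
  expect_true(has(c("organ", "and", "system")))
  lat2 <- build_lattice(text_unit("C1-4"), tds)
  seqs2 <- enumerate_token_sequences(lat2)
  has2 <- function(x) any(vapply(seqs2, identical, logical(1), x))
  expect_true(has2("C1-4"))
  expect_true(has2(c("C1", "to", "4")))
  expect_true(has2(c("C", "1", "-", "4")))
})

test_that("the empty unit has the empty tokenization", {
  lat <- build_lattice(text_unit(""), tds)
  expect_identical(lat$n_pos, 0L)
  expect_identical(enumerate_token_sequences(lat), list(character(0)))
})

test_that("uncovered positions are an error, not a silent gap", {
  expect_error(build_lattice(text_unit("abc"), list()),
               "uncovered position")
  ws_only <- default_transducers(enabled = "whitespace")
  expect_error(build_lattice(text_unit("abc def"), ws_only),
               "uncovered position")
})

test_that("enumeration respects its combinatorial bound", {
  lat <- build_lattice(text_unit("10mg C1-4 ml/g"), tds)
  expect_error(enumerate_token_sequences(lat, max_sequences = 2L),
               "enumeration bound")
})

test_that("DOT export and sequence files are well-formed", {
  lat <- build_lattice(text_unit("dental arch"), tds)
  dot <- lattice_to_dot(lat)
  expect_match(dot, "^digraph token_lattice")
  expect_match(dot, "\"p0\" \\[shape=doublecircle\\];")
  expect_match(dot, "label=\"dental\"")
  path <- tempfile(fileext = ".tsv")
  on.exit(unlink(path))
  write_token_sequences(enumerate_token_sequences(lat), path)
  expect_identical(readLines(path), "dental\tarch")
})

test_that("every gold segmentation of the evaluation set is in its lattice", {
  spec <- fixture_spec(seed = 11L, n_units = 40L)
  es <- generate_eval_set(spec)
  for (i in seq_along(es$units)) {
    unit <- es$units[[i]]
    seqs <- enumerate_token_sequences(build_lattice(unit, tds))
    expect_true(any(vapply(seqs, identical, logical(1),
                           unname(es$gold[[unit$unit_id]]))),
                label = sprintf("gold reachable for '%s'", unit$text))
  }
})
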