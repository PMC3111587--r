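# Token transducers: deterministic functions tau(context, suffix) that consume
# a prefix of the remaining text and emit a candidate token sequence for the
# lattice. A result with consumed = 0 and NULL tokens is the not-applicable
# marker; the whitespace transducer consumes characters while emitting no
# tokens (an epsilon contribution).

#' Create a transduce result
#'
#' @param consumed Number of characters of the input suffix consumed
#'   (`0 <= consumed <= nchar(suffix)`).
#' @param tokens Character vector of emitted tokens; `character(0)` for pure
#'   consumption (whitespace); `NULL` marks the transducer as not applicable
#'   (then `consumed` must be 0).
#' @return An object of class `transduce_result`.
#' @export
transduce_result <- function(consumed, tokens) {
  consumed <- as.integer(consumed)
  stopifnot(length(consumed) == 1L, consumed >= 0L)
  if (is.null(tokens)) {
    if (consumed != 0L) stop("not-applicable results consume no text",
                             call. = FALSE)
  } else {
    tokens <- as.character(tokens)
    if (any(!nzchar(tokens))) stop("emitted tokens must be non-empty",
                                   call. = FALSE)
    if (consumed == 0L && length(tokens) > 0L) {
      stop("a transducer that emits tokens must consume text", call. = FALSE)
    }
  }
  structure(list(consumed = consumed, tokens = tokens),
            class = "transduce_result")
}

#' @rdname transduce_result
#' @export
not_applicable <- function() transduce_result(0L, NULL)

#' @param x A `transduce_result`.
#' @rdname transduce_result
#' @export
is_applicable <- function(x) {
  inherits(x, "transduce_result") && (x$consumed > 0L)
}

# Normalize a transduce function's return value to a list of applicable
# results (a single result, a list of results, or not-applicable).
as_transduce_results <- function(x) {
  if (inherits(x, "transduce_result")) x <- list(x)
  stopifnot(is.list(x))
  Filter(is_applicable, x)
}

#' Create a token transducer
#'
#' A transducer couples a token-class name with a deterministic transduce
#' function `function(context, suffix)` operating on the suffix's first
#' character, and an optional transform table rewriting emitted surface
#' tokens (e.g. `c(mg = "milligrams")`).
#'
#' @param name Token-class name.
#' @param transduce Function `(context, suffix) -> transduce_result` (or a
#'   list of results when several readings apply at once).
#' @param transform_table Optional named character vector mapping surface
#'   tokens to emitted forms.
#' @return An object of class `transducer`.
#' @export
transducer <- function(name, transduce, transform_table = NULL) {
  stopifnot(is.character(name), length(name) == 1L, is.function(transduce))
  if (!is.null(transform_table)) {
    stopifnot(is.character(transform_table), !is.null(names(transform_table)))
  }
  structure(list(name = name, transduce = transduce,
                 transform_table = transform_table),
            class = "transducer")
}

#' Apply a transducer to a text suffix
#'
#' @param td A `transducer`.
#' @param ctx A [context()].
#' @param suffix Remaining text, starting at the position under consideration.
#' @return List of applicable `transduce_result`s (possibly empty), with the
#'   transducer's transform table applied to emitted tokens.
#' @export
apply_transducer <- function(td, ctx, suffix) {
  res <- as_transduce_results(td$transduce(ctx, suffix))
  if (!is.null(td$transform_table) && length(res) > 0L) {
    res <- lapply(res, function(r) {
      hit <- r$tokens %in% names(td$transform_table)
      if (any(hit)) r$tokens[hit] <- unname(td$transform_table[r$tokens[hit]])
      r
    })
  }
  res
}

match_prefix <- function(suffix, pattern) {
  m <- regexpr(pattern, suffix, perl = TRUE)
  if (m == -1L) return(NULL)
  substr(suffix, 1L, attr(m, "match.length"))
}

#' Built-in transduce functions
#'
#' The default biomedical-English token classes. Each function takes a
#' [context()] and the remaining text suffix, and returns one (or, for the
#' expansion class, possibly several) [transduce_result()]s; a result of
#' `(0, NULL)` means not applicable.
#'
#' * `transduce_whitespace()`: consumes a maximal whitespace run, emits
#'   nothing (epsilon).
#' * `transduce_word_run()`: consumes a maximal non-whitespace run as a
#'   single token -- the "keep whole" reading of every word.
#' * `transduce_alphabetic()`: maximal letter run, internal hyphens kept
#'   in-token ("non-commissioned"); declines when the run ends at a
#'   possessive clitic boundary, which `transduce_possessive()` owns.
#' * `transduce_numeric()`: one whole numeric token -- integer, decimal,
#'   comma-grouped, simple fraction or roman numeral; decimals are never
#'   split.
#' * `transduce_possessive()`: word ending in apostrophe-s, emitted as
#'   (word, "'s").
#' * `transduce_independent()`: exactly one standalone punctuation symbol.
#' * `transduce_expansion()`: closed-class expansions and quantity splits:
#'   ranges `"C1-4"` -> (`"C1"`, `"to"`, `"4"`), slash lists
#'   `"organ/system"` -> (`"organ"`, `"and"`, `"system"`) plus, for unit
#'   pairs such as `"ml/g"`, the (`"ml"`, `"per"`, `"g"`) reading as a
#'   second result, plus lists `"a + b"` -> (`"a"`, `"and"`, `"b"`), and
#'   digits fused to letters `"50mg"` -> (`"50"`, `"mg"`).
#' * `transduce_substance()`: chemical substances, serotypes and functional
#'   names (`"Precorrin-3B"`, `"O128:NM"`, `"47:k:1,5,7"`, `"H-987"`) kept
#'   as one token; declines identifier-number ranges like `"C1-4"`.
#'
#' @param ctx A [context()] (unused by the built-in classes).
#' @param suffix Remaining text.
#' @return A [transduce_result()] or a list of them.
#' @name transduce-functions
NULL

#' @rdname transduce-functions
#' @export
transduce_whitespace <- function(ctx, suffix) {
  m <- match_prefix(suffix, "^[[:space:]]+")
  if (is.null(m)) return(not_applicable())
  transduce_result(nchar(m), character(0))
}

#' @rdname transduce-functions
#' @export
transduce_word_run <- function(ctx, suffix) {
  m <- match_prefix(suffix, "^[^[:space:]]+")
  if (is.null(m)) return(not_applicable())
  transduce_result(nchar(m), m)
}

#' @rdname transduce-functions
#' @export
transduce_alphabetic <- function(ctx, suffix) {
  m <- match_prefix(suffix, "^[[:alpha:]]+(?:-[[:alpha:]]+)*")
  if (is.null(m)) return(not_applicable())
  rest <- substr(suffix, nchar(m) + 1L, nchar(suffix))
  if (grepl("^['’]s(?![[:alnum:]])", rest, perl = TRUE)) {
    return(not_applicable())  # clitic boundary: the possessive class owns it
  }
  transduce_result(nchar(m), m)
}

#' @rdname transduce-functions
#' @export
transduce_numeric <- function(ctx, suffix) {
  pats <- c(
    "^[0-9]{1,3}(?:,[0-9]{3})+",          # 10,000
    "^[0-9]+\\.[0-9]+",                   # 1.2
    "^[0-9]+/[0-9]+(?![[:alnum:]])",      # 1/2
    "^[0-9]+",                            # 1500
    "^[IVXLCDM]+(?![[:alnum:]])"          # III
  )
  best <- ""
  for (p in pats) {
    m <- match_prefix(suffix, p)
    if (!is.null(m) && nchar(m) > nchar(best)) best <- m
  }
  if (!nzchar(best)) return(not_applicable())
  transduce_result(nchar(best), best)
}

#' @rdname transduce-functions
#' @export
transduce_possessive <- function(ctx, suffix) {
  m <- regexpr("^([[:alpha:]]+(?:-[[:alpha:]]+)*)(['’]s)(?![[:alnum:]])",
               suffix, perl = TRUE)
  if (m == -1L) return(not_applicable())
  whole <- substr(suffix, 1L, attr(m, "match.length"))
  word <- sub("['’]s$", "", whole)
  clitic <- substr(whole, nchar(word) + 1L, nchar(whole))
  transduce_result(nchar(whole), c(word, clitic))
}

independent_symbols <- c("(", ")", "[", "]", "{", "}", ",", ".", ";", ":",
                         "?", "!", "-", "\"", "–", "—")

#' @rdname transduce-functions
#' @export
transduce_independent <- function(ctx, suffix) {
  ch <- substr(suffix, 1L, 1L)
  if (!nzchar(ch) || !(ch %in% independent_symbols)) return(not_applicable())
  transduce_result(1L, ch)
}

# Measurement units recognized for the slash "per" reading.
unit_words <- c("mg", "ml", "g", "kg", "mcg", "ug", "l", "dl", "cl", "mmol",
                "mol", "units", "unit", "u", "iu", "cm", "mm", "m", "h", "hr",
                "min", "s", "d", "day", "week", "cc")

#' @rdname transduce-functions
#' @export
transduce_expansion <- function(ctx, suffix) {
  out <- list()
  # quantity fused to its unit: 50mg -> 50 mg
  m <- regexpr("^([0-9]+(?:\\.[0-9]+)?|[0-9]{1,3}(?:,[0-9]{3})+)([[:alpha:]]+)(?![[:alnum:]])",
               suffix, perl = TRUE)
  if (m != -1L) {
    whole <- substr(suffix, 1L, attr(m, "match.length"))
    num <- sub("^([0-9.,]+).*$", "\\1", whole)
    out <- c(out, list(transduce_result(nchar(whole),
                                        c(num, substr(whole, nchar(num) + 1L,
                                                      nchar(whole))))))
  }
  # identifier-number range: C1-4 -> C1 to 4
  m <- regexpr("^([[:alpha:]]+[0-9]+)-([0-9]+)(?![[:alnum:]])", suffix,
               perl = TRUE)
  if (m != -1L) {
    whole <- substr(suffix, 1L, attr(m, "match.length"))
    parts <- strsplit(whole, "-", fixed = TRUE)[[1L]]
    out <- c(out, list(transduce_result(nchar(whole),
                                        c(parts[1L], "to", parts[2L]))))
  }
  # slash list: organ/system -> organ and system; ml/g -> also ml per g
  m <- regexpr("^([[:alpha:]]+)/([[:alpha:]]+)(?![[:alnum:]])", suffix,
               perl = TRUE)
  if (m != -1L) {
    whole <- substr(suffix, 1L, attr(m, "match.length"))
    parts <- strsplit(whole, "/", fixed = TRUE)[[1L]]
    out <- c(out, list(transduce_result(nchar(whole),
                                        c(parts[1L], "and", parts[2L]))))
    if (all(tolower(parts) %in% unit_words)) {
      out <- c(out, list(transduce_result(nchar(whole),
                                          c(parts[1L], "per", parts[2L]))))
    }
  }
  # plus list: Paracetamol + caffeine -> Paracetamol and caffeine
  m <- regexpr("^([[:alnum:]][[:alnum:].,-]*) \\+ ([[:alnum:]][[:alnum:].,-]*)(?![[:alnum:]])",
               suffix, perl = TRUE)
  if (m != -1L) {
    whole <- substr(suffix, 1L, attr(m, "match.length"))
    parts <- strsplit(whole, " + ", fixed = TRUE)[[1L]]
    out <- c(out, list(transduce_result(nchar(whole),
                                        c(parts[1L], "and", parts[2L]))))
  }
  if (length(out) == 0L) return(not_applicable())
  out
}

#' @rdname transduce-functions
#' @export
transduce_substance <- function(ctx, suffix) {
  m <- regexpr("^[[:alnum:]]+(?:[-:][[:alnum:]]+(?:,[[:alnum:]]+)*)+(?!['’[:alnum:]])",
               suffix, perl = TRUE)
  if (m == -1L) return(not_applicable())
  whole <- substr(suffix, 1L, attr(m, "match.length"))
  if (!grepl("[0-9]", whole)) return(not_applicable())
  if (grepl("^[[:alpha:]]+[0-9]+-[0-9]+$", whole)) {
    return(not_applicable())  # identifier-number range; expansion class owns it
  }
  transduce_result(nchar(whole), whole)
}

#' Default biomedical transducer set
#'
#' The bundled token classes covering whitespace-delimited biomedical English:
#' whitespace, word runs (the unsplit reading), alphabetic words, numerics,
#' possessives, standalone punctuation, closed-class expansions/quantity
#' splits, and substances/serotypes/functional names. All applicable readings
#' of every class enter the lattice; ambiguity is resolved by the decoder.
#'
#' @param enabled Character vector of class names to include (default: all).
#' @param transform_tables Optional named list of per-class transform tables,
#'   e.g. `list(expansion = c(mg = "milligrams"))`.
#' @return Named list of [transducer()]s.
#' @export
#' @examples
#' lat <- build_lattice(text_unit("Entire upper"), default_transducers())
#' enumerate_token_sequences(lat)
default_transducers <- function(enabled = NULL, transform_tables = NULL) {
  fns <- list(
    whitespace  = transduce_whitespace,
    word_run    = transduce_word_run,
    alphabetic  = transduce_alphabetic,
    numeric     = transduce_numeric,
    possessive  = transduce_possessive,
    independent = transduce_independent,
    expansion   = transduce_expansion,
    substance   = transduce_substance
  )
  if (!is.null(enabled)) {
    bad <- setdiff(enabled, names(fns))
    if (length(bad) > 0L) {
      stop("unknown transducer class(es): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    fns <- fns[intersect(names(fns), enabled)]
  }
  out <- lapply(names(fns), function(nm) {
    transducer(nm, fns[[nm]], transform_table = transform_tables[[nm]])
  })
  names(out) <- names(fns)
  out
}

#' Closed-class word list
#'
#' The packaged inventory of closed-class English words (prepositions,
#' conjunctions, determiners, pronouns) used by the gold segmentation
#' protocol: abbreviated forms ("-" for "to", "/" for "and"/"per", "+" for
#' "and") are expanded into members of this list.
#'
#' @return Character vector, one word per element.
#' @export
closed_class_words <- function() {
  path <- system.file("extdata", "closed_class_words.txt",
                      package = "tokenlattice", mustWork = TRUE)
  readLines(path, encoding = "UTF-8")
}
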