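#' Create a text unit
#'
#' A text unit is the atom of tokenization: one concept description, sentence
#' or input line, together with an opaque identifier. Character positions are
#' 0-based and spans are half-open, so a unit of `n` characters has positions
#' `0..n` between/around its characters.
#'
#' @param text Single character string (may be empty). Must be valid UTF-8.
#' @param unit_id Opaque identifier; coerced to character.
#' @return An object of class `text_unit` with fields `text` and `unit_id`.
#' @export
#' @examples
#' text_unit("Primidone 50mg tablet", "d1")
text_unit <- function(text, unit_id = "u1") {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  if (!all(validUTF8(text))) {
    stop("text is not valid UTF-8", call. = FALSE)
  }
  structure(list(text = text, unit_id = as.character(unit_id)),
            class = "text_unit")
}

#' @export
print.text_unit <- function(x, ...) {
  cat(sprintf("<text_unit %s> %s\n", x$unit_id, x$text))
  invisible(x)
}

#' Create a tokenization context
#'
#' A context is a tuple of tokenizer-instance information passed to every
#' transducer application. The default (and only context the bundled
#' transducers consult) is empty; callers may supply previously emitted
#' tokens or any other per-instance state. A context is treated as immutable
#' during one tokenization call.
#'
#' @param ... Context elements, stored in order.
#' @return An object of class `tok_context`.
#' @export
context <- function(...) {
  structure(list(...), class = "tok_context")
}

#' Create a tagged token sequence
#'
#' The tokenizer's output type: ordered (token, tag) pairs with a joint
#' log-probability on the natural-log scale. Tokens must be non-empty.
#'
#' @param tokens Character vector of non-empty tokens (possibly length 0).
#' @param tags Character vector of POS tags, same length as `tokens`.
#' @param logprob Joint natural-log probability of the sequence (<= 0, or
#'   `-Inf` for impossible sequences; 0 for the empty sequence).
#' @return An object of class `tagged_tokens`.
#' @export
tagged_tokens <- function(tokens = character(), tags = character(),
                          logprob = 0) {
  tokens <- as.character(tokens)
  tags <- as.character(tags)
  stopifnot(length(tokens) == length(tags), is.numeric(logprob),
            length(logprob) == 1L)
  if (any(!nzchar(tokens))) {
    stop("tagged token sequences exclude empty tokens", call. = FALSE)
  }
  structure(list(tokens = tokens, tags = tags, logprob = as.numeric(logprob)),
            class = "tagged_tokens")
}

#' @export
print.tagged_tokens <- function(x, ...) {
  if (length(x$tokens) == 0L) {
    cat("<tagged_tokens> (empty)\n")
  } else {
    cat(sprintf("<tagged_tokens> logprob %.4f\n", x$logprob))
    cat(paste0(x$tokens, "/", x$tags, collapse = " "), "\n")
  }
  invisible(x)
}

#' @export
format.tagged_tokens <- function(x, tagged = FALSE, ...) {
  if (tagged) paste0(x$tokens, "/", x$tags, collapse = " ")
  else paste(x$tokens, collapse = "\t")
}
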