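# POS-tag hidden Markov language model, order 0 or 1, with additive
# (Lidstone) smoothing and a single unknown-token bucket. All scoring is on
# the natural-log scale. The order-0 variant scores a token by its unigram
# tag prior times the emission (a joint P(tag, token)); the order-1 variant
# replaces the prior with a one-step tag transition, conditioning the first
# tag on a distinguished beginning-of-sentence symbol.

BOS <- "<BOS>"
US <- "\x1f"  # key separator for (tag, token) / (prev, tag) count tables

#' Train a POS-tag hidden Markov model
#'
#' Counts emissions, tag occurrences and (for any order) tag transitions from
#' a tagged corpus. The tag set is taken from the corpus (plus any extra tags
#' supplied); transitions include the beginning-of-sentence event. The
#' vocabulary size used by smoothing reserves one extra slot for the unknown
#' token bucket.
#'
#' @param corpus A list of tagged sentences; each sentence is a data frame
#'   with character columns `token` and `tag` (as returned by
#'   [read_tagged_corpus()]).
#' @param order HMM order: 0 (no transitions; unigram tag prior) or 1.
#' @param alpha Additive smoothing constant, >= 0. With `alpha > 0` every
#'   conditional probability is strictly positive; with `alpha = 0` unseen
#'   events score `-Inf`.
#' @param tags Optional extra tags to include in the tag set.
#' @return An object of class `hmm_model`.
#' @export
#' @examples
#' sent <- data.frame(token = c("a", "dog"), tag = c("DT", "NN"))
#' m <- hmm_train(list(sent), order = 1, alpha = 0)
#' exp(transition_logprob(m, "DT", "NN"))  # 1
hmm_train <- function(corpus, order = 1, alpha = 0.1, tags = NULL) {
  stopifnot(order %in% c(0L, 1L), is.numeric(alpha), alpha >= 0)
  if (!is.list(corpus) || length(corpus) == 0L) {
    stop("corpus is empty", call. = FALSE)
  }
  emis_keys <- character(); trans_keys <- character()
  tag_all <- character(); tok_all <- character(); first_tags <- character()
  for (k in seq_along(corpus)) {
    sent <- corpus[[k]]
    if (!is.data.frame(sent) || !all(c("token", "tag") %in% names(sent)) ||
        nrow(sent) == 0L) {
      stop(sprintf("malformed sentence at index %d", k), call. = FALSE)
    }
    tok <- as.character(sent$token); tg <- as.character(sent$tag)
    if (any(!nzchar(tok)) || any(is.na(tok)) || any(!nzchar(tg)) ||
        any(is.na(tg))) {
      stop(sprintf("empty token or tag in sentence %d", k), call. = FALSE)
    }
    emis_keys <- c(emis_keys, paste(tg, tok, sep = US))
    first_tags <- c(first_tags, tg[1L])
    if (length(tg) > 1L) {
      trans_keys <- c(trans_keys,
                      paste(tg[-length(tg)], tg[-1L], sep = US))
    }
    tag_all <- c(tag_all, tg); tok_all <- c(tok_all, tok)
  }
  trans_keys <- c(trans_keys, paste(BOS, first_tags, sep = US))
  emission <- table(emis_keys)
  transition <- table(trans_keys)
  tagset <- sort(unique(c(tag_all, tags)))
  if (BOS %in% tagset) stop("the BOS symbol cannot be an emitted tag",
                            call. = FALSE)
  tag_counts <- table(tag_all)
  prev <- sub(paste0(US, ".*$"), "", names(transition))
  context_counts <- tapply(as.numeric(transition), prev, sum)
  vocab <- sort(unique(tok_all))
  structure(list(
    order = as.integer(order), alpha = alpha, tags = tagset, bos = BOS,
    emission = stats::setNames(as.numeric(emission), names(emission)),
    transition = stats::setNames(as.numeric(transition), names(transition)),
    tag_counts = stats::setNames(as.numeric(tag_counts), names(tag_counts)),
    context_counts = stats::setNames(as.numeric(context_counts),
                                     names(context_counts)),
    vocab = vocab,
    vocab_size = length(vocab) + 1L,  # +1 unknown bucket
    total_tokens = length(tok_all),
    n_sentences = length(corpus),
    version = 1L
  ), class = "hmm_model")
}

count_or_zero <- function(tab, key) {
  v <- tab[key]
  v[is.na(v)] <- 0
  unname(v)
}

#' Emission log-probability
#'
#' `log P(token | tag)` with additive smoothing over the vocabulary plus one
#' unknown-token slot: `(count(tag, token) + alpha) / (count(tag) +
#' alpha * vocab_size)`. Tokens outside the training vocabulary fall into the
#' unknown bucket (count 0), so all unseen tokens score equally given a tag.
#'
#' @param model An `hmm_model`.
#' @param token Token string (vectorized).
#' @param tag A tag from the model's tag set (vectorized, recycled).
#' @return Natural-log probability; `-Inf` possible when `alpha = 0`.
#' @export
emission_logprob <- function(model, token, tag) {
  check_tags(model, tag)
  c_et <- count_or_zero(model$emission, paste(tag, token, sep = US))
  c_t <- count_or_zero(model$tag_counts, tag)
  log(c_et + model$alpha) - log(c_t + model$alpha * model$vocab_size)
}

#' Transition log-probability
#'
#' `log P(tag | prev_tag)` with additive smoothing over the tag set. The
#' previous tag may be the model's beginning-of-sentence symbol (`model$bos`).
#' A previous tag with no outgoing observations yields the uniform smoothed
#' distribution (or `-Inf` when `alpha = 0`).
#'
#' @inheritParams emission_logprob
#' @param prev_tag Conditioning tag or `model$bos`.
#' @return Natural-log probability.
#' @export
transition_logprob <- function(model, prev_tag, tag) {
  check_tags(model, tag)
  stopifnot(all(prev_tag %in% c(model$tags, model$bos)))
  c_tt <- count_or_zero(model$transition, paste(prev_tag, tag, sep = US))
  c_t <- count_or_zero(model$context_counts, prev_tag)
  den <- c_t + model$alpha * length(model$tags)
  out <- ifelse(den > 0, log(c_tt + model$alpha) - log(den), -Inf)
  unname(out)
}

#' Unigram tag log-prior
#'
#' `log P(tag)` from smoothed corpus tag frequencies; the order-0 score uses
#' it in place of transitions.
#'
#' @inheritParams emission_logprob
#' @return Natural-log probability.
#' @export
tag_logprior <- function(model, tag) {
  check_tags(model, tag)
  c_t <- count_or_zero(model$tag_counts, tag)
  log(c_t + model$alpha) - log(model$total_tokens +
                                 model$alpha * length(model$tags))
}

check_tags <- function(model, tag) {
  bad <- setdiff(unique(tag), model$tags)
  if (length(bad) > 0L) {
    stop("tag(s) not in the model's tag set: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Score a tagged token sequence
#'
#' The joint log-probability of a tagged path under the model. Order 1 sums
#' `log P(tag_i | tag_{i-1}) + log P(token_i | tag_i)` with the first tag
#' conditioned on the beginning-of-sentence symbol; order 0 sums
#' `log P(tag_i) + log P(token_i | tag_i)` (no transitions). The empty
#' sequence scores 0.
#'
#' @param model An `hmm_model`.
#' @param path A [tagged_tokens()] object, or a data frame with `token` and
#'   `tag` columns.
#' @return Natural-log probability; `-Inf` for impossible paths at
#'   `alpha = 0`.
#' @export
score_path <- function(model, path) {
  if (inherits(path, "tagged_tokens")) {
    tokens <- path$tokens; tags <- path$tags
  } else {
    tokens <- as.character(path$token); tags <- as.character(path$tag)
  }
  n <- length(tokens)
  if (n == 0L) return(0)
  emis <- sum(emission_logprob(model, tokens, tags))
  if (model$order == 0L) {
    emis + sum(tag_logprior(model, tags))
  } else {
    emis + sum(transition_logprob(model, c(model$bos, tags[-n]), tags))
  }
}

#' @export
print.hmm_model <- function(x, ...) {
  cat(sprintf(paste0("<hmm_model order=%d alpha=%g tags=%d vocab=%d ",
                     "tokens=%d sentences=%d>\n"),
              x$order, x$alpha, length(x$tags), length(x$vocab),
              x$total_tokens, x$n_sentences))
  invisible(x)
}

#' Persist / load an HMM model as JSON
#'
#' The model file is versioned JSON holding the raw counts, smoothing
#' constant, order and tag set, so a loaded model reproduces the trained one
#' exactly.
#'
#' @param model An `hmm_model`.
#' @param path File path.
#' @return `read_hmm_model()` returns the `hmm_model`; `write_hmm_model()`
#'   returns `path` invisibly.
#' @export
write_hmm_model <- function(model, path) {
  stopifnot(inherits(model, "hmm_model"))
  payload <- list(
    format = "tokenlattice-hmm", version = model$version,
    order = model$order, alpha = model$alpha, tags = model$tags,
    emission = as.list(model$emission),
    transition = as.list(model$transition),
    tag_counts = as.list(model$tag_counts),
    context_counts = as.list(model$context_counts),
    vocab = model$vocab, vocab_size = model$vocab_size,
    total_tokens = model$total_tokens, n_sentences = model$n_sentences
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_hmm_model
#' @export
read_hmm_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(p$format) || p$format != "tokenlattice-hmm") {
    stop("not a tokenlattice HMM model file: ", path, call. = FALSE)
  }
  as_counts <- function(x) {
    if (length(x) == 0L) return(stats::setNames(numeric(0), character(0)))
    unlist(x)
  }
  structure(list(
    order = as.integer(p$order), alpha = p$alpha, tags = p$tags, bos = BOS,
    emission = as_counts(p$emission), transition = as_counts(p$transition),
    tag_counts = as_counts(p$tag_counts),
    context_counts = as_counts(p$context_counts),
    vocab = p$vocab, vocab_size = as.integer(p$vocab_size),
    total_tokens = as.integer(p$total_tokens),
    n_sentences = as.integer(p$n_sentences),
    version = as.integer(p$version)
  ), class = "hmm_model")
}
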