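# Best-path selection over the token lattice. The adapted Viterbi decoder
# runs dynamic programming over (vertex, tag) states in topological vertex
# order, so it maximizes the joint path score over all complete paths and
# all tag assignments simultaneously. A brute-force decoder (path
# enumeration x exhaustive tagging) serves as the testing oracle.
#
# Tie-breaking, shared by both decoders: higher score first, then fewer
# tokens, then lexicographic token strings, then lexicographic tags.

# Transition structure as a matrix: rows = c(BOS, tags), cols = tags.
# Order 0 has no transitions; every row is the unigram tag prior, which
# makes the two orders share one DP implementation.
trans_matrix <- function(model) {
  tags <- model$tags
  if (model$order == 0L) {
    pri <- tag_logprior(model, tags)
    m <- matrix(rep(pri, each = length(tags) + 1L),
                nrow = length(tags) + 1L)
  } else {
    m <- t(vapply(c(model$bos, tags),
                  function(p) transition_logprob(model, rep(p, length(tags)),
                                                 tags),
                  numeric(length(tags))))
  }
  dimnames(m) <- list(c(model$bos, tags), tags)
  m
}

state_better <- function(score_a, key_a, score_b, key_b) {
  if (score_a != score_b) return(score_a > score_b)
  if (key_a$ntok != key_b$ntok) return(key_a$ntok < key_b$ntok)
  if (key_a$tokkey != key_b$tokkey) return(key_a$tokkey < key_b$tokkey)
  key_a$tagkey < key_b$tagkey
}

#' Adapted Viterbi decoding over a token lattice
#'
#' Chooses the complete lattice path and tag assignment maximizing the joint
#' log-probability under the model (the argmax over tagged token sequences).
#' Dynamic programming runs over (vertex, tag) states in topological order;
#' epsilon edges advance the vertex without contributing score. Ties are
#' broken deterministically: fewer tokens, then lexicographic tokens, then
#' lexicographic tags.
#'
#' @param lattice A `token_lattice` with at least one complete path.
#' @param model An `hmm_model`.
#' @param normalize If `TRUE`, compare candidate paths by per-token mean
#'   log-probability instead of the raw joint (the DP state is then
#'   augmented with the token count, keeping the search exact). The default
#'   `FALSE` is the literal argmax of the joint probability.
#' @return A [tagged_tokens()] with the winning path's raw joint log
#'   probability in `logprob`.
#' @export
#' @examples
#' sent <- data.frame(token = c("dental", "arch"), tag = c("JJ", "NN"))
#' m <- hmm_train(list(sent), alpha = 0.1)
#' lat <- build_lattice(text_unit("dental arch"), default_transducers())
#' viterbi_decode(lat, m)
viterbi_decode <- function(lattice, model, normalize = FALSE) {
  stopifnot(inherits(lattice, "token_lattice"), inherits(model, "hmm_model"))
  if (lattice$n_pos == 0L) return(tagged_tokens())
  tags <- model$tags
  TM <- trans_matrix(model)
  verts <- names(lattice$vertex_key)
  e_from <- lattice$edges$from; e_to <- lattice$edges$to
  e_label <- lattice$edges$label; e_eps <- lattice$edges$epsilon
  adj <- split(seq_along(e_from), factor(e_from, levels = verts))

  # states[[vertex]][[key]] = list(score, tag, ntok, tokkey, tagkey, back)
  states <- stats::setNames(vector("list", length(verts)), verts)
  skey <- function(tag, ntok) if (normalize) paste0(tag, "#", ntok) else tag
  states[[lattice$start]] <- stats::setNames(
    list(list(score = 0, tag = model$bos, ntok = 0L, tokkey = "",
              tagkey = "", back = NULL)),
    skey(model$bos, 0L))

  consider <- function(pool, key, cand) {
    old <- pool[[key]]
    if (is.null(old) ||
        state_better(cand$score, cand, old$score, old)) pool[[key]] <- cand
    pool
  }

  for (v in verts) {
    here <- states[[v]]
    if (is.null(here) || length(here) == 0L) next
    for (ei in adj[[v]]) {
      w <- e_to[ei]
      if (e_eps[ei]) {
        for (st in here) {
          cand <- st
          cand$back <- list(vertex = v, key = skey(st$tag, st$ntok),
                            label = NA_character_)
          states[[w]] <- consider(states[[w]], skey(st$tag, st$ntok), cand)
        }
      } else {
        lab <- e_label[ei]
        emis <- emission_logprob(model, rep(lab, length(tags)), tags)
        for (st in here) {
          step <- TM[st$tag, ] + emis
          sc <- st$score + step
          for (k in seq_along(tags)) {
            cand <- list(score = sc[k], tag = tags[k], ntok = st$ntok + 1L,
                         tokkey = paste0(st$tokkey, lab, "\x1f"),
                         tagkey = paste0(st$tagkey, tags[k], "\x1f"),
                         back = list(vertex = v, key = skey(st$tag, st$ntok),
                                     label = lab))
            states[[w]] <- consider(states[[w]], skey(tags[k], st$ntok + 1L),
                                    cand)
          }
        }
      }
    }
  }

  finals <- states[[lattice$end]]
  if (is.null(finals) || length(finals) == 0L) {
    stop("no complete path", call. = FALSE)
  }
  eff <- function(st) if (normalize) st$score / max(st$ntok, 1L) else st$score
  best <- NULL
  for (st in finals) {
    if (is.null(best) ||
        state_better(eff(st), st, eff(best), best)) best <- st
  }
  if (is.infinite(best$score) && best$score < 0 && best$ntok > 0L) {
    stop("all paths impossible under the model (score -Inf)", call. = FALSE)
  }

  # backtrace
  toks <- character(); tgs <- character()
  v <- lattice$end; st <- best
  while (!is.null(st$back)) {
    if (!is.na(st$back$label)) {
      toks <- c(st$back$label, toks)
      tgs <- c(st$tag, tgs)
    }
    v <- st$back$vertex
    st <- states[[v]][[st$back$key]]
  }
  tagged_tokens(toks, tgs, best$score)
}

#' Brute-force decoding oracle
#'
#' Exhaustively enumerates every complete lattice path and every tag
#' assignment, scores each with [score_path()], and returns the maximum
#' under the same tie-breaking as [viterbi_decode()]. Intended as a testing
#' oracle on small lattices.
#'
#' @inheritParams viterbi_decode
#' @param max_combinations Upper bound on (path, tagging) combinations;
#'   exceeding it is an error.
#' @return A [tagged_tokens()].
#' @export
brute_force_decode <- function(lattice, model, normalize = FALSE,
                               max_combinations = 200000) {
  stopifnot(inherits(lattice, "token_lattice"), inherits(model, "hmm_model"))
  if (lattice$n_pos == 0L) return(tagged_tokens())
  seqs <- enumerate_token_sequences(lattice)
  tags <- model$tags
  K <- length(tags)
  n_comb <- sum(K ^ vapply(seqs, length, integer(1)))
  if (n_comb > max_combinations) {
    stop(sprintf("combination bound exceeded (%g > %g)", n_comb,
                 max_combinations), call. = FALSE)
  }
  TM <- trans_matrix(model)
  best <- NULL
  for (toks in seqs) {
    n <- length(toks)
    if (n == 0L) {
      cand <- list(score = 0, eff = 0, ntok = 0L, tokens = character(),
                   tags = character(), tokkey = "", tagkey = "")
      if (is.null(best) ||
          state_better(cand$eff, cand, best$eff, best)) best <- cand
      next
    }
    E <- vapply(tags, function(t) {
      emission_logprob(model, toks, rep(t, n))
    }, numeric(n))
    E <- matrix(E, nrow = n)
    grid <- as.matrix(expand.grid(rep(list(seq_len(K)), n)))
    sc <- rep(0, nrow(grid))
    for (j in seq_len(n)) sc <- sc + E[j, ][grid[, j]]
    sc <- sc + TM[1L, ][grid[, 1L]]  # BOS row / prior
    if (n > 1L) {
      for (j in 2:n) sc <- sc + TM[cbind(grid[, j - 1L] + 1L, grid[, j])]
    }
    top <- which(sc == max(sc))
    tokkey <- paste0(paste(toks, collapse = "\x1f"), "\x1f")
    for (r in top) {
      tg <- tags[grid[r, ]]
      cand <- list(score = sc[r], eff = if (normalize) sc[r] / n else sc[r],
                   ntok = n, tokens = toks, tags = tg, tokkey = tokkey,
                   tagkey = paste0(paste(tg, collapse = "\x1f"), "\x1f"))
      if (is.null(best) ||
          state_better(cand$eff, cand, best$eff, best)) best <- cand
    }
  }
  if (is.null(best)) stop("no complete path", call. = FALSE)
  if (is.infinite(best$score) && best$ntok > 0L) {
    stop("all paths impossible under the model (score -Inf)", call. = FALSE)
  }
  tagged_tokens(best$tokens, best$tags, best$score)
}

#' Tokenize a text unit
#'
#' The full pipeline: build the token lattice with the given transducer set
#' and decode its best path under the model. The returned object carries
#' both tokens and tags; drop tags with `$tokens`.
#'
#' @param unit A [text_unit()] (or a plain string, which is wrapped).
#' @param transducers List of [transducer()]s.
#' @param model An `hmm_model`.
#' @param ctx A [context()].
#' @param normalize Passed to [viterbi_decode()].
#' @return A [tagged_tokens()].
#' @export
#' @examples
#' \dontrun{
#' tokenize_unit("Primidone 50mg tablet", default_transducers(), model)
#' }
tokenize_unit <- function(unit, transducers, model, ctx = context(),
                          normalize = FALSE) {
  if (is.character(unit)) unit <- text_unit(unit)
  if (nchar(unit$text) == 0L) return(tagged_tokens())
  lat <- build_lattice(unit, transducers, ctx)
  viterbi_decode(lat, model, normalize = normalize)
}

#' Tokenize a batch of lines
#'
#' Treats each element as one text unit (the line-as-unit convention for
#' concept descriptions) and returns one [tagged_tokens()] per line.
#'
#' @param lines Character vector of input units.
#' @param ids Optional unit identifiers (default `"u1"`, `"u2"`, ...).
#' @inheritParams tokenize_unit
#' @return Named list of [tagged_tokens()].
#' @export
tokenize_lines <- function(lines, transducers, model, ids = NULL,
                           ctx = context(), normalize = FALSE) {
  if (is.null(ids)) ids <- paste0("u", seq_along(lines))
  stopifnot(length(ids) == length(lines))
  out <- lapply(seq_along(lines), function(i) {
    tokenize_unit(text_unit(lines[[i]], ids[[i]]), transducers, model,
                  ctx = ctx, normalize = normalize)
  })
  stats::setNames(out, ids)
}
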