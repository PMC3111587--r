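# Token lattice: a bounded DAG over the character positions of one text unit.
# Position vertices p0..pN sit between characters; auxiliary vertices carry
# the interiors of multi-token transducer outputs whose tokens are not
# literal substrings of the consumed span. Complete p0 -> pN paths are the
# candidate tokenizations; epsilon edges consume whitespace and are elided
# when reading off token sequences.

EPSILON <- ""

new_token_lattice <- function(unit, n_pos, edges, vertex_key) {
  structure(list(unit = unit, n_pos = n_pos, edges = edges,
                 vertex_key = vertex_key,
                 start = "p0", end = paste0("p", n_pos)),
            class = "token_lattice")
}

#' Build the token lattice for a text unit
#'
#' Applies every transducer at every character position of the unit (spans
#' are 0-based, half-open). Each applicable result `(l, tokens)` at position
#' `i` contributes a path from the position vertex `p_i` to `p_{i+l}`:
#' a single edge for one-token results, an epsilon edge for pure whitespace
#' consumption, and a chain of edges for multi-token results. Interior
#' vertices of a multi-token chain reuse position vertices when the tokens
#' tile the consumed span as literal substrings (so identical readings from
#' different transducers collapse by edge deduplication); transforming
#' outputs (inserted "to"/"and"/"per") receive fresh auxiliary vertices.
#' Edges not lying on any complete path from `p_0` to `p_n` are pruned,
#' which leaves the set of complete paths unchanged.
#'
#' @param unit A [text_unit()].
#' @param transducers Non-empty list of [transducer()]s, e.g.
#'   [default_transducers()].
#' @param ctx A [context()] passed to every transducer application.
#' @return A `token_lattice`.
#' @seealso [enumerate_token_sequences()], [viterbi_decode()]
#' @export
#' @examples
#' lat <- build_lattice(text_unit("The patient's 10mg tablet."),
#'                      default_transducers())
#' length(enumerate_token_sequences(lat))  # 8
build_lattice <- function(unit, transducers, ctx = context()) {
  stopifnot(inherits(unit, "text_unit"))
  if (!is.list(transducers) || length(transducers) == 0L) {
    stop("uncovered position: transducer set is empty", call. = FALSE)
  }
  s <- unit$text
  n <- nchar(s)
  vertex_key <- stats::setNames(as.numeric(0:n), paste0("p", 0:n))
  if (n == 0L) {
    edges <- data.frame(from = character(), to = character(),
                        label = character(), epsilon = logical(),
                        stringsAsFactors = FALSE)
    return(new_token_lattice(unit, 0L, edges, vertex_key["p0"]))
  }

  seen_app <- new.env(parent = emptyenv())
  from <- character(); to <- character(); label <- character()
  epsilon <- logical()
  aux_i <- 0L
  add_edge <- function(f, t, lab, eps) {
    from[[length(from) + 1L]] <<- f
    to[[length(to) + 1L]] <<- t
    label[[length(label) + 1L]] <<- lab
    epsilon[[length(epsilon) + 1L]] <<- eps
  }

  for (i in 0:(n - 1L)) {
    suffix <- substr(s, i + 1L, n)
    for (td in transducers) {
      for (res in apply_transducer(td, ctx, suffix)) {
        l <- res$consumed
        if (l > nchar(suffix)) {
          stop(sprintf("transducer '%s' consumed beyond the input", td$name),
               call. = FALSE)
        }
        toks <- res$tokens
        key <- paste(i, l, paste(toks, collapse = "\x1f"), sep = "\x1e")
        if (!is.null(seen_app[[key]])) next  # dedup identical applications
        seen_app[[key]] <- TRUE
        v_from <- paste0("p", i)
        v_to <- paste0("p", i + l)
        m <- length(toks)
        if (m == 0L) {
          add_edge(v_from, v_to, EPSILON, TRUE)
        } else if (m == 1L) {
          add_edge(v_from, v_to, toks, FALSE)
        } else {
          cum <- cumsum(nchar(toks))
          tiles <- cum[m] == l &&
            all(vapply(seq_len(m), function(j) {
              substr(suffix, c(0L, cum)[j] + 1L, cum[j]) == toks[j]
            }, logical(1)))
          if (tiles) {
            inner <- paste0("p", i + cum[-m])
          } else {
            inner <- paste0("x", aux_i + seq_len(m - 1L))
            vertex_key[inner] <- i + l * seq_len(m - 1L) / m
            aux_i <- aux_i + m - 1L
          }
          chain <- c(v_from, inner, v_to)
          for (j in seq_len(m)) {
            add_edge(chain[j], chain[j + 1L], toks[j], FALSE)
          }
        }
      }
    }
  }

  edges <- data.frame(from = from, to = to, label = label, epsilon = epsilon,
                      stringsAsFactors = FALSE)
  edge_key <- paste(edges$from, edges$label, edges$to, sep = "\x1e")
  edges <- edges[!duplicated(edge_key), , drop = FALSE]

  keep <- complete_path_edges(edges, "p0", paste0("p", n))
  edges <- edges[keep, , drop = FALSE]
  if (nrow(edges) == 0L || !any(edges$to == paste0("p", n))) {
    stop(sprintf("uncovered position: no complete tokenization path for unit '%s'",
                 unit$unit_id), call. = FALSE)
  }
  vertex_key <- vertex_key[names(vertex_key) %in%
                             c("p0", edges$from, edges$to)]
  vertex_key <- sort(vertex_key)
  rownames(edges) <- NULL
  new_token_lattice(unit, n, edges, vertex_key)
}

# Logical index of edges both reachable from `start` and co-reachable to
# `end` (i.e. lying on at least one complete path).
complete_path_edges <- function(edges, start, end) {
  reach <- function(seed, src, dst) {
    seen <- seed
    frontier <- seed
    repeat {
      nxt <- setdiff(unique(dst[src %in% frontier]), seen)
      if (length(nxt) == 0L) break
      seen <- c(seen, nxt)
      frontier <- nxt
    }
    seen
  }
  fwd <- reach(start, edges$from, edges$to)
  bwd <- reach(end, edges$to, edges$from)
  edges$from %in% fwd & edges$to %in% fwd &
    edges$from %in% bwd & edges$to %in% bwd
}

lattice_adjacency <- function(lattice) {
  split(seq_len(nrow(lattice$edges)), lattice$edges$from)
}

#' Enumerate all candidate token sequences of a lattice
#'
#' Reads off the token sequence of every complete path from the lattice's
#' start vertex to its end vertex, eliding epsilon edges, and returns the
#' distinct sequences.
#'
#' @param lattice A `token_lattice` from [build_lattice()].
#' @param max_sequences Guard against combinatorial blow-up; enumeration
#'   stops with an error beyond this many complete paths.
#' @return List of character vectors (a set: no duplicates), in a
#'   deterministic order. The empty unit yields `list(character(0))`.
#' @export
enumerate_token_sequences <- function(lattice, max_sequences = 100000L) {
  stopifnot(inherits(lattice, "token_lattice"))
  if (lattice$n_pos == 0L) return(list(character(0)))
  adj <- lattice_adjacency(lattice)
  end <- lattice$end
  out <- list()
  walk <- function(v, toks) {
    if (v == end) {
      if (length(out) >= max_sequences) {
        stop("enumeration bound exceeded", call. = FALSE)
      }
      out[[length(out) + 1L]] <<- toks
      return(invisible())
    }
    for (ei in adj[[v]]) {
      e <- lattice$edges[ei, ]
      walk(e$to, if (e$epsilon) toks else c(toks, e$label))
    }
  }
  walk(lattice$start, character(0))
  if (length(out) == 0L) stop("no complete path", call. = FALSE)
  out <- unique(out)
  out[order(vapply(out, paste, character(1), collapse = "\x1f"))]
}

#' Export a lattice in DOT format
#'
#' Writes the lattice as a DOT graph for inspection with Graphviz. Epsilon
#' edges are drawn dashed with an empty label.
#'
#' @param lattice A `token_lattice`.
#' @param path Optional file path; if `NULL` the DOT text is returned.
#' @return The DOT source, invisibly when written to `path`.
#' @export
lattice_to_dot <- function(lattice, path = NULL) {
  stopifnot(inherits(lattice, "token_lattice"))
  esc <- function(x) gsub("\"", "\\\\\"", x)
  lines <- c(
    "digraph token_lattice {",
    "  rankdir=LR;",
    "  node [shape=circle fontsize=10];",
    sprintf("  \"%s\" [shape=doublecircle];", esc(lattice$start)),
    sprintf("  \"%s\" [shape=doublecircle];", esc(lattice$end)),
    vapply(seq_len(nrow(lattice$edges)), function(i) {
      e <- lattice$edges[i, ]
      style <- if (e$epsilon) " style=dashed" else ""
      sprintf("  \"%s\" -> \"%s\" [label=\"%s\"%s];",
              esc(e$from), esc(e$to), esc(e$label), style)
    }, character(1)),
    "}"
  )
  txt <- paste(lines, collapse = "\n")
  if (is.null(path)) return(txt)
  writeLines(txt, path, useBytes = TRUE)
  invisible(txt)
}

#' Write token sequences to a file
#'
#' One sequence per line, tokens TAB-separated (the package's token file
#' format).
#'
#' @param sequences List of character vectors.
#' @param path Output file path.
#' @export
write_token_sequences <- function(sequences, path) {
  writeLines(vapply(sequences, paste, character(1), collapse = "\t"),
             path, useBytes = TRUE)
  invisible(path)
}

#' @export
print.token_lattice <- function(x, ...) {
  cat(sprintf("<token_lattice unit=%s chars=%d vertices=%d edges=%d>\n",
              x$unit$unit_id, x$n_pos, length(x$vertex_key), nrow(x$edges)))
  invisible(x)
}
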