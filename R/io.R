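# File formats: slash-format tagged corpora ("token/TAG", one sentence per
# line), raw unit files (one unit per line, UTF-8), TAB-separated token
# files, gold/prediction TSV (unit_id TAB token TAB token ...), and the YAML
# run configuration. All readers reject invalid UTF-8 with a clear error.

read_utf8_lines <- function(path) {
  if (!file.exists(path)) stop("cannot read file: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  bad <- which(!validUTF8(lines))
  if (length(bad) > 0L) {
    stop(sprintf("invalid UTF-8 byte sequence in %s at line %d", path,
                 bad[1L]), call. = FALSE)
  }
  lines
}

#' Read a slash-format tagged corpus
#'
#' Parses Penn-Treebank/MedPost style text: whitespace-separated
#' `token/TAG` items, one sentence per line. The tag is taken after the last
#' slash, so tokens containing slashes are representable. Blank lines are
#' skipped. Malformed items are reported with their line number.
#'
#' @param path Corpus file path.
#' @return List of tagged sentences (data frames with `token` and `tag`),
#'   usable with [hmm_train()].
#' @export
read_tagged_corpus <- function(path) {
  lines <- read_utf8_lines(path)
  keep <- which(nzchar(trimws(lines)))
  if (length(keep) == 0L) stop("corpus is empty: ", path, call. = FALSE)
  lapply(keep, function(i) {
    items <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1L]]
    m <- regexpr("/[^/]+$", items)
    if (any(m == -1L)) {
      stop(sprintf("malformed token/TAG item '%s' at line %d of %s",
                   items[which(m == -1L)[1L]], i, path), call. = FALSE)
    }
    token <- substr(items, 1L, m - 1L)
    tag <- substr(items, m + 1L, nchar(items))
    if (any(!nzchar(token)) || any(!nzchar(tag))) {
      stop(sprintf("empty token or tag at line %d of %s", i, path),
           call. = FALSE)
    }
    data.frame(token = token, tag = tag, stringsAsFactors = FALSE)
  })
}

#' Write a tagged corpus in slash format
#'
#' @param sentences List of tagged sentences (data frames with `token`,
#'   `tag`).
#' @param path Output file path.
#' @export
write_tagged_corpus <- function(sentences, path) {
  writeLines(vapply(sentences, function(s) {
    paste(paste0(s$token, "/", s$tag), collapse = " ")
  }, character(1)), path, useBytes = TRUE)
  invisible(path)
}

#' Read raw text units
#'
#' One unit (concept description / sentence) per line, UTF-8.
#'
#' @param path Input file path.
#' @param ids Optional unit ids; default `"u1"`, `"u2"`, ...
#' @return List of [text_unit()]s.
#' @export
read_units <- function(path, ids = NULL) {
  lines <- read_utf8_lines(path)
  if (is.null(ids)) ids <- paste0("u", seq_along(lines))
  stopifnot(length(ids) == length(lines))
  mapply(text_unit, lines, ids, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Read / write gold or prediction token files
#'
#' TSV with one unit per line: `unit_id TAB token TAB token ...`.
#'
#' @param path File path.
#' @return `read_gold()` returns a named list of token vectors.
#' @export
read_gold <- function(path) {
  lines <- read_utf8_lines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate unit id in ", path, ": ",
         ids[anyDuplicated(ids)], call. = FALSE)
  }
  stats::setNames(lapply(parts, function(p) p[-1L]), ids)
}

#' @rdname read_gold
#' @param segmentations Named list: unit id -> token vector (or
#'   [tagged_tokens()]).
#' @export
write_gold <- function(segmentations, path) {
  toks <- lapply(segmentations, function(p) {
    if (inherits(p, "tagged_tokens")) p$tokens else as.character(p)
  })
  writeLines(paste(names(toks),
                   vapply(toks, paste, character(1), collapse = "\t"),
                   sep = "\t"),
             path, useBytes = TRUE)
  invisible(path)
}

#' Run configuration
#'
#' Bundles the knobs of a tokenization run: enabled transducer classes and
#' transform tables, model path, HMM order and smoothing, score
#' normalization, input/output paths, seed and log level. Round-trips
#' losslessly through YAML.
#'
#' @param transducers Character vector of enabled transducer class names.
#' @param transform_tables Named list of per-class surface -> emitted maps.
#' @param model_path,input_path,output_path File paths (may be `NULL`).
#' @param order HMM order (0 or 1).
#' @param alpha Smoothing constant.
#' @param normalize Per-token score normalization flag.
#' @param seed Integer seed.
#' @param log_level One of `"quiet"`, `"info"`, `"debug"`.
#' @return A `run_config` list.
#' @export
run_config <- function(transducers = names(default_transducers()),
                       transform_tables = NULL,
                       model_path = NULL, input_path = NULL,
                       output_path = NULL, order = 1L, alpha = 0.1,
                       normalize = FALSE, seed = 1L,
                       log_level = "info") {
  stopifnot(order %in% c(0L, 1L), alpha >= 0,
            log_level %in% c("quiet", "info", "debug"))
  structure(list(transducers = transducers,
                 transform_tables = transform_tables,
                 model_path = model_path, input_path = input_path,
                 output_path = output_path, order = as.integer(order),
                 alpha = alpha, normalize = isTRUE(normalize),
                 seed = as.integer(seed), log_level = log_level),
            class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  raw <- unclass(config)
  # length-1 named vectors would serialize as bare scalars; keep names
  if (!is.null(raw$transform_tables)) {
    raw$transform_tables <- lapply(raw$transform_tables, as.list)
  }
  yaml::write_yaml(raw, path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  tt <- raw$transform_tables
  if (!is.null(tt)) tt <- lapply(tt, function(x) unlist(x))
  run_config(transducers = unlist(raw$transducers),
             transform_tables = tt,
             model_path = raw$model_path, input_path = raw$input_path,
             output_path = raw$output_path, order = raw$order,
             alpha = raw$alpha, normalize = raw$normalize, seed = raw$seed,
             log_level = raw$log_level)
}
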