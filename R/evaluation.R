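# Evaluation statistics for tokenization: exact-match accuracy with a
# normal-approximation binomial confidence interval, and Cohen's kappa with
# a fixed chance-agreement probability (the coin-toss model, p_e = 0.5).

#' Exact-match tokenization accuracy
#'
#' A unit counts as correct iff its predicted token sequence equals the gold
#' sequence element-wise (case-sensitive); any other tokenization is an
#' error. Comparison is on surface strings after any transducer
#' transformation.
#'
#' @param predictions Named list: unit id -> character vector of tokens.
#'   [tagged_tokens()] elements are accepted (their `$tokens` are used).
#' @param gold Named list with the identical key set.
#' @param conf_z Normal quantile for the confidence interval (1.96 for 95%).
#' @return An `evaluation_report` with fields `n_units`, `n_correct`,
#'   `accuracy`, `ci_low`, `ci_high`, `per_unit` (named logical) and
#'   `disagreements` (list of `(unit_id, predicted, gold)`).
#' @export
exact_match_accuracy <- function(predictions, gold, conf_z = 1.96) {
  predictions <- lapply(predictions, function(p) {
    if (inherits(p, "tagged_tokens")) p$tokens else as.character(p)
  })
  gold <- lapply(gold, as.character)
  check_same_keys(predictions, gold)
  ids <- names(gold)
  ok <- vapply(ids, function(id) {
    identical(unname(predictions[[id]]), unname(gold[[id]]))
  }, logical(1))
  n <- length(ids)
  n_correct <- sum(ok)
  acc <- n_correct / n
  ci <- binomial_ci(acc, n, z = conf_z)
  disagreements <- lapply(ids[!ok], function(id) {
    list(unit_id = id, predicted = predictions[[id]], gold = gold[[id]])
  })
  structure(list(n_units = n, n_correct = n_correct, accuracy = acc,
                 ci_low = ci[[1L]], ci_high = ci[[2L]],
                 per_unit = stats::setNames(ok, ids),
                 disagreements = disagreements),
            class = "evaluation_report")
}

check_same_keys <- function(a, b) {
  ka <- names(a); kb <- names(b)
  if (is.null(ka) || is.null(kb) || !setequal(ka, kb) ||
      anyDuplicated(ka) || anyDuplicated(kb)) {
    missing_in_a <- setdiff(kb, ka); missing_in_b <- setdiff(ka, kb)
    stop("mismatched unit id sets",
         if (length(missing_in_a)) paste0("; missing in first: ",
                                          paste(missing_in_a, collapse = ", ")),
         if (length(missing_in_b)) paste0("; missing in second: ",
                                          paste(missing_in_b, collapse = ", ")),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Normal-approximation binomial confidence interval
#'
#' `p_hat +/- z * sqrt(p_hat * (1 - p_hat) / n)`, clamped to `[0, 1]`.
#' Degenerate at `p_hat` of 0 or 1 (zero variance).
#'
#' @param p_hat Observed proportion in `[0, 1]`.
#' @param n Number of trials, >= 1.
#' @param z Normal quantile (default 1.96, the 95% two-sided interval).
#' @return Numeric vector `c(low, high)`.
#' @export
#' @examples
#' round(100 * binomial_ci(0.539, 2781), 1)  # 52.0 55.8
binomial_ci <- function(p_hat, n, z = 1.96) {
  stopifnot(is.numeric(p_hat), p_hat >= 0, p_hat <= 1)
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("n must be a positive count", call. = FALSE)
  }
  half <- z * sqrt(p_hat * (1 - p_hat) / n)
  c(low = max(0, p_hat - half), high = min(1, p_hat + half))
}

#' Cohen's kappa with fixed chance agreement
#'
#' `(p_o - p_e) / (1 - p_e)`. Agreement between two segmentors on a unit is
#' all-or-nothing (identical segmentations), and chance agreement is modeled
#' as a fair coin toss, so `p_e` defaults to 0.5.
#'
#' @param p_o Observed agreement proportion in `[0, 1]`.
#' @param p_e Chance agreement probability in `[0, 1)`.
#' @return Kappa value.
#' @export
#' @examples
#' cohens_kappa(0.944)  # 0.888
cohens_kappa <- function(p_o, p_e = 0.5) {
  stopifnot(is.numeric(p_o), p_o >= 0, p_o <= 1, is.numeric(p_e), p_e >= 0)
  if (any(p_e >= 1)) stop("p_e must be < 1", call. = FALSE)
  (p_o - p_e) / (1 - p_e)
}

#' Pairwise segmentation agreement
#'
#' Percent agreement (fraction of units with identical token sequences) and
#' Cohen's kappa at the coin-toss chance level between two segmentations of
#' the same units.
#'
#' @param seg_a,seg_b Named lists: unit id -> token vector, identical key
#'   sets.
#' @param p_e Chance agreement passed to [cohens_kappa()].
#' @return List with `percent_agreement` and `kappa`.
#' @export
pairwise_agreement <- function(seg_a, seg_b, p_e = 0.5) {
  seg_a <- lapply(seg_a, as.character); seg_b <- lapply(seg_b, as.character)
  check_same_keys(seg_a, seg_b)
  ids <- names(seg_a)
  ok <- vapply(ids, function(id) {
    identical(unname(seg_a[[id]]), unname(seg_b[[id]]))
  }, logical(1))
  p_o <- mean(ok)
  list(percent_agreement = p_o, kappa = cohens_kappa(p_o, p_e))
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(format_report(x), sep = "\n")
  invisible(x)
}

#' Human-readable evaluation summary
#'
#' Display rounding follows the reporting convention: percentages to one
#' decimal, kappa to three decimals; raw values stay in the report object.
#'
#' @param report An `evaluation_report`.
#' @param kappa Optional kappa to include in the summary.
#' @return Character vector of summary lines.
#' @export
format_report <- function(report, kappa = NULL) {
  lines <- c(
    sprintf("units           %d", report$n_units),
    sprintf("correct         %d", report$n_correct),
    sprintf("accuracy (%%)    %.1f", 100 * report$accuracy),
    sprintf("95%% CI (%%)      %.1f, %.1f", 100 * report$ci_low,
            100 * report$ci_high)
  )
  if (!is.null(kappa)) lines <- c(lines, sprintf("kappa           %.3f", kappa))
  lines
}

#' Write an evaluation report as TSV
#'
#' A two-section TSV: summary rows (metric, value) followed by per-unit
#' match flags.
#'
#' @param report An `evaluation_report`.
#' @param path Output file path.
#' @export
write_report_tsv <- function(report, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(
    paste("metric", "value", sep = "\t"),
    paste("n_units", report$n_units, sep = "\t"),
    paste("n_correct", report$n_correct, sep = "\t"),
    paste("accuracy_pct", sprintf("%.1f", 100 * report$accuracy), sep = "\t"),
    paste("ci95_low_pct", sprintf("%.1f", 100 * report$ci_low), sep = "\t"),
    paste("ci95_high_pct", sprintf("%.1f", 100 * report$ci_high), sep = "\t"),
    "",
    paste("unit_id", "match", sep = "\t"),
    paste(names(report$per_unit), as.integer(report$per_unit), sep = "\t")
  ), con)
  invisible(path)
}
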