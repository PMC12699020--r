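#' Confusion counts for a target condition
#'
#' Cross-tabulates screen results against diagnosis labels for a target set
#' of conditions. With the default target (`SW_CAH`, the primary screening
#' target), a flagged variant-form case (simple-virilizing, nonclassical,
#' 3-BOHSD, 11-BOHD) counts as a false positive.
#'
#' @param results A `screen_results` data.frame.
#' @param labels Character vector of diagnosis labels, aligned with
#'   `results` by position and sample order; or a `steroid_cohort`, whose
#'   `diagnosis` column and `sample_id` alignment are used.
#' @param target Character vector of labels counted as the condition.
#' @return An object of class `confusion_counts` with fields `tp`, `fp`,
#'   `tn`, `fn`.
#' @export
confusion <- function(results, labels, target = "SW_CAH") {
  if (inherits(labels, "steroid_cohort") || is.data.frame(labels)) {
    if (!identical(as.character(labels$sample_id),
                   as.character(results$sample_id)))
      stop("results and cohort are misaligned (sample_id order differs)",
           call. = FALSE)
    labels <- labels$diagnosis
  }
  if (length(labels) != nrow(results))
    stop("results and labels are misaligned (different lengths)",
         call. = FALSE)
  stopifnot(all(target %in% diagnosis_levels()))
  is_case <- labels %in% target
  pos <- results$positive
  structure(list(tp = sum(pos & is_case),
                 fp = sum(pos & !is_case),
                 fn = sum(!pos & is_case),
                 tn = sum(!pos & !is_case)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("Confusion counts: TP=%d FP=%d FN=%d TN=%d (n=%d)\n",
              x$tp, x$fp, x$fn, x$tn, x$tp + x$fp + x$fn + x$tn))
  invisible(x)
}

#' Screening performance metrics from confusion counts
#'
#' PPV, NPV, sensitivity and specificity as exact ratios of counts. A metric
#' with a zero denominator is undefined and reported as `NA`, never coerced
#' to 0 or 1 (an empty stratum must not masquerade as perfect).
#'
#' @param counts A [confusion()] result, or a list with `tp`, `fp`, `fn`,
#'   `tn`.
#' @return An object of class `performance_result`: the counts,
#'   `n_positive`, and the four proportions at full precision. Use
#'   [format_percent()] for presentation rounding.
#' @export
#' @examples
#' screen_metrics(list(tp = 8, fp = 251, fn = 0, tn = 1451))
screen_metrics <- function(counts) {
  stopifnot(all(c("tp", "fp", "fn", "tn") %in% names(counts)))
  with(counts, {
    stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0)
    ratio <- function(num, den) if (den > 0) num / den else NA_real_
    structure(list(
      counts = structure(list(tp = tp, fp = fp, fn = fn, tn = tn),
                         class = "confusion_counts"),
      n_positive = tp + fp,
      ppv = ratio(tp, tp + fp),
      npv = ratio(tn, tn + fn),
      sensitivity = ratio(tp, tp + fn),
      specificity = ratio(tn, tn + fp)
    ), class = "performance_result")
  })
}

#' @export
print.performance_result <- function(x, ...) {
  cat(sprintf("Screening performance (n positive = %d)\n", x$n_positive))
  print(x$counts)
  fmt <- function(v) if (is.na(v)) "undefined" else format_percent(v, 1)
  cat("  PPV:", fmt(x$ppv), " NPV:", fmt(x$npv),
      " sensitivity:", fmt(x$sensitivity),
      " specificity:", fmt(x$specificity), "\n")
  invisible(x)
}

#' Presentation rounding of a proportion to a percent string
#'
#' @param p Proportion in `[0, 1]` (or `NA`).
#' @param digits Decimal places (1 for predictive values, 0 for reduction
#'   percentages).
#' @return Character string such as `"3.1%"`, or `NA` for undefined input.
#' @export
#' @examples
#' format_percent(8 / 259, 1)  # "3.1%"
format_percent <- function(p, digits = 1) {
  ifelse(is.na(p), NA_character_,
         paste0(formatC(round(100 * p, digits), format = "f",
                        digits = digits), "%"))
}

#' Gestational-age-stratified performance
#'
#' Splits the cohort at a gestational-age cutoff (preterm strictly below)
#' and computes performance per stratum. Profiles with missing gestational
#' age are excluded from both strata and counted.
#'
#' @param cohort A `steroid_cohort`.
#' @param results A `screen_results` data.frame aligned with the cohort.
#' @param target Labels counted as the condition.
#' @param cutoff_weeks Stratification cutoff in weeks, in (20, 45).
#' @return List with `preterm` and `term` ([screen_metrics()] results, or
#'   `NULL` for an empty stratum) and `excluded_n`.
#' @export
stratify_by_ga <- function(cohort, results, target = "SW_CAH",
                           cutoff_weeks = 37) {
  stopifnot(cutoff_weeks > 20, cutoff_weeks < 45)
  if (!identical(as.character(cohort$sample_id),
                 as.character(results$sample_id)))
    stop("results and cohort are misaligned (sample_id order differs)",
         call. = FALSE)
  ga <- cohort$ga_weeks
  known <- !is.na(ga)
  stratum_metrics <- function(idx) {
    if (!any(idx)) return(NULL)
    screen_metrics(confusion(results[idx, , drop = FALSE],
                             cohort$diagnosis[idx], target))
  }
  list(preterm = stratum_metrics(known & ga < cutoff_weeks),
       term = stratum_metrics(known & ga >= cutoff_weeks),
       excluded_n = sum(!known))
}

#' Reduction in patient retrievals
#'
#' Percentage reduction in screen-positive retrievals when moving from one
#' rule to another, `100 * (1 - n_new / n_old)`, presentation-rounded to the
#' nearest integer by [format_percent()] with 0 digits.
#'
#' @param n_old Positives under the old rule (> 0).
#' @param n_new Positives under the new rule.
#' @return Numeric percentage at full precision.
#' @export
#' @examples
#' retrieval_reduction(259, 11)                   # 95.75...
#' format_percent(retrieval_reduction(259, 11) / 100, 0)  # "96%"
retrieval_reduction <- function(n_old, n_new) {
  stopifnot(is.numeric(n_old), is.numeric(n_new), n_new >= 0)
  if (n_old <= 0)
    stop("n_old must be positive", call. = FALSE)
  100 * (1 - n_new / n_old)
}
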