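#' Threshold set for a three-component screening rule
#'
#' Binds cutoffs to the rule template: a 21-deoxycortisol gate (either the
#' sentinel `"detectable"`, meaning at or above the assay LoD, or a numeric
#' cutoff at or above the LoD), a cutoff on the pre-analyte sum, and a cutoff
#' on the ratio of the pre-analyte sum to the denominator steroid. All
#' comparisons in the package are inclusive (>=).
#'
#' @param df21_gate `"detectable"` or a numeric gate in nmol/L (>= LoD).
#' @param pre_cutoff Cutoff on the pre-analyte sum, nmol/L (> 0).
#' @param ratio_cutoff Cutoff on the pre/denominator ratio (> 0).
#' @param constants An [assay_constants()] object (validates the gate).
#' @return An object of class `threshold_set`.
#' @export
#' @examples
#' threshold_set()  # the proposed operating point: detectable / 40 / 0.3
threshold_set <- function(df21_gate = "detectable", pre_cutoff = 40,
                          ratio_cutoff = 0.3,
                          constants = assay_constants()) {
  if (identical(df21_gate, "detectable")) {
    gate <- constants$lod_21df
  } else {
    stopifnot(is.numeric(df21_gate), length(df21_gate) == 1)
    if (df21_gate < constants$lod_21df)
      stop("a numeric df21_gate below the LoD (", constants$lod_21df,
           " nmol/L) is not measurable", call. = FALSE)
    gate <- df21_gate
  }
  stopifnot(is.numeric(pre_cutoff), pre_cutoff > 0,
            is.numeric(ratio_cutoff), ratio_cutoff > 0)
  structure(list(df21_gate = gate, pre_cutoff = pre_cutoff,
                 ratio_cutoff = ratio_cutoff),
            class = "threshold_set")
}

#' @export
print.threshold_set <- function(x, ...) {
  cat(sprintf(
    "Thresholds: 21-DF gate >= %g nmol/L; pre-sum >= %g nmol/L; ratio >= %g\n",
    x$df21_gate, x$pre_cutoff, x$ratio_cutoff))
  invisible(x)
}

#' A candidate screening algorithm template
#'
#' A rule of the family: sum of "pre" analytes proximal to the 21-hydroxylase
#' block (17-OHP, androstenedione, 21-deoxycortisol) compared against a sum
#' cutoff, the same sum divided by a distal steroid (cortisol or
#' 11-deoxycortisol) compared against a ratio cutoff, and optionally a
#' detectability gate on 21-deoxycortisol.
#'
#' @param algorithm_id Short identifier string.
#' @param pre_analytes Non-empty subset of `c("OHP17", "A4", "DF21")`.
#' @param denominator `"CORTISOL"` or `"DC11"`.
#' @param uses_df21_gate Apply the 21-deoxycortisol gate?
#' @return An object of class `screening_algorithm`.
#' @export
screening_algorithm <- function(algorithm_id, pre_analytes,
                                denominator = c("CORTISOL", "DC11"),
                                uses_df21_gate = FALSE) {
  denominator <- match.arg(denominator)
  pre_analytes <- unique(toupper(pre_analytes))
  if (length(pre_analytes) == 0 ||
      !all(pre_analytes %in% c("OHP17", "A4", "DF21")))
    stop("pre_analytes must be a non-empty subset of OHP17, A4, DF21",
         call. = FALSE)
  structure(list(algorithm_id = algorithm_id,
                 pre_analytes = pre_analytes,
                 denominator = denominator,
                 uses_df21_gate = isTRUE(uses_df21_gate)),
            class = "screening_algorithm")
}

#' @export
print.screening_algorithm <- function(x, ...) {
  cat(sprintf("Algorithm %s: (%s)/%s%s\n", x$algorithm_id,
              paste(x$pre_analytes, collapse = "+"), x$denominator,
              if (x$uses_df21_gate) ", 21-DF gate" else ""))
  invisible(x)
}

#' Default registry of candidate algorithms
#'
#' Eight candidates: the four pre-analyte sets {17-OHP}, {17-OHP, A4},
#' {17-OHP, 21-DF}, {17-OHP, A4, 21-DF}, each with the 21-deoxycortisol gate
#' off and on, all over a cortisol denominator. The gated {17-OHP, 21-DF}
#' entry (`ohp17_df21_gated`) is the proposed-rule family.
#'
#' @return Named list of [screening_algorithm()] objects.
#' @export
default_registry <- function() {
  sets <- list(ohp17 = "OHP17",
               ohp17_a4 = c("OHP17", "A4"),
               ohp17_df21 = c("OHP17", "DF21"),
               ohp17_a4_df21 = c("OHP17", "A4", "DF21"))
  out <- list()
  for (nm in names(sets)) {
    out[[nm]] <- screening_algorithm(nm, sets[[nm]], "CORTISOL", FALSE)
    gated_id <- paste0(nm, "_gated")
    out[[gated_id]] <- screening_algorithm(gated_id, sets[[nm]], "CORTISOL",
                                           TRUE)
  }
  out
}

analyte_column <- c(OHP17 = "ohp17_nmol_l", A4 = "a4_nmol_l",
                    DF21 = "df21_nmol_l", CORTISOL = "cortisol_nmol_l",
                    DC11 = "dc11_nmol_l")

#' Apply an algorithm template at given thresholds to a cohort
#'
#' Evaluates one candidate algorithm on every profile. Censored
#' 21-deoxycortisol contributes 0 to pre-analyte sums (a gated rule is
#' already negative through the gate; for non-gated candidates 0 is the
#' conservative substitution). The gate passes iff 21-deoxycortisol is
#' detectable and at or above the gate value.
#'
#' @param algo A [screening_algorithm()].
#' @param thresholds A [threshold_set()].
#' @param cohort A `steroid_cohort`.
#' @param constants An [assay_constants()] object.
#' @return A `screen_results` data.frame: `sample_id`, `positive`,
#'   `gate_passed` (`NA` when the algorithm has no gate), `pre_sum_nmol_l`,
#'   `ratio`.
#' @export
apply_algorithm <- function(algo, thresholds, cohort,
                            constants = assay_constants()) {
  stopifnot(inherits(algo, "screening_algorithm"),
            inherits(thresholds, "threshold_set"))
  denom_col <- analyte_column[[algo$denominator]]
  denom <- cohort[[denom_col]]
  if (anyNA(denom))
    stop("denominator analyte ", algo$denominator,
         " missing for sample(s): ",
         paste(cohort$sample_id[is.na(denom)], collapse = ", "),
         call. = FALSE)
  if (any(denom <= 0))
    stop("denominator analyte ", algo$denominator,
         " must be positive; offending sample(s): ",
         paste(cohort$sample_id[denom <= 0], collapse = ", "),
         call. = FALSE)
  pre_sum <- rep(0, nrow(cohort))
  for (an in algo$pre_analytes) {
    v <- cohort[[analyte_column[[an]]]]
    if (an == "DF21") v <- censored_value(v, constants$lod_21df, "zero")
    pre_sum <- pre_sum + v
  }
  ratio <- pre_sum / denom
  positive <- (pre_sum >= thresholds$pre_cutoff) &
    (ratio >= thresholds$ratio_cutoff)
  if (algo$uses_df21_gate) {
    gate_passed <- cohort$df21_detectable &
      !is.na(cohort$df21_nmol_l) &
      censored_value(cohort$df21_nmol_l, constants$lod_21df, "zero") >=
        thresholds$df21_gate
    positive <- positive & gate_passed
  } else {
    gate_passed <- rep(NA, nrow(cohort))
  }
  structure(data.frame(sample_id = cohort$sample_id,
                       positive = positive,
                       gate_passed = gate_passed,
                       pre_sum_nmol_l = pre_sum,
                       ratio = ratio,
                       stringsAsFactors = FALSE),
            class = c("screen_results", "data.frame"),
            algorithm_id = algo$algorithm_id,
            thresholds = thresholds)
}

#' Evaluate the proposed three-component rule
#'
#' The proposed second-tier rule for salt-wasting CAH: detectable
#' 21-deoxycortisol (>= 2.1 nmol/L, the assay LoD), 17-OHP +
#' 21-deoxycortisol >= 40 nmol/L, and (17-OHP + 21-deoxycortisol)/cortisol
#' >= 0.3. All three comparisons inclusive. When the gate fails the result
#' is negative but the sum and ratio are still reported (with 0 substituted
#' for the censored 21-deoxycortisol).
#'
#' @param cohort A `steroid_cohort` (a single profile is a one-row cohort).
#' @param thresholds A [threshold_set()]; defaults to the proposed operating
#'   point (detectable / 40 / 0.3).
#' @param constants An [assay_constants()] object.
#' @return A `screen_results` data.frame.
#' @export
evaluate_proposed <- function(cohort, thresholds = threshold_set(),
                              constants = assay_constants()) {
  algo <- screening_algorithm("proposed", c("OHP17", "DF21"), "CORTISOL",
                              uses_df21_gate = TRUE)
  apply_algorithm(algo, thresholds, cohort, constants)
}

#' Evaluate the legacy second-tier rule
#'
#' The pre-existing second-tier rule: 17-OHP >= 10 nmol/L and
#' (17-OHP + androstenedione)/cortisol >= 0.33, both inclusive. It does not
#' use 21-deoxycortisol at all.
#'
#' @param cohort A `steroid_cohort`.
#' @return A `screen_results` data.frame (`pre_sum_nmol_l` is
#'   17-OHP + androstenedione; `gate_passed` is `NA`: there is no gate).
#' @export
evaluate_legacy <- function(cohort) {
  denom <- cohort$cortisol_nmol_l
  if (any(is.na(denom) | denom <= 0))
    stop("cortisol must be positive; offending sample(s): ",
         paste(cohort$sample_id[is.na(denom) | denom <= 0], collapse = ", "),
         call. = FALSE)
  pre_sum <- cohort$ohp17_nmol_l + cohort$a4_nmol_l
  ratio <- pre_sum / denom
  positive <- (cohort$ohp17_nmol_l >= 10) & (ratio >= 0.33)
  structure(data.frame(sample_id = cohort$sample_id,
                       positive = positive,
                       gate_passed = rep(NA, nrow(cohort)),
                       pre_sum_nmol_l = pre_sum,
                       ratio = ratio,
                       stringsAsFactors = FALSE),
            class = c("screen_results", "data.frame"),
            algorithm_id = "legacy")
}

#' Evaluate a 21-deoxycortisol-only rule
#'
#' Positive iff 21-deoxycortisol is detectable and at or above the cutoff.
#' Published single-analyte cutoffs of interest: 2.5 nmol/L (sensitive),
#' 6.56 nmol/L (specific), and 4.6 nmol/L (the lowest cutoff retaining 100%
#' sensitivity in the study population).
#'
#' @param cohort A `steroid_cohort`.
#' @param cutoff Cutoff in nmol/L (>= LoD).
#' @param constants An [assay_constants()] object.
#' @return A `screen_results` data.frame (`pre_sum_nmol_l` is the
#'   zero-substituted 21-deoxycortisol; `ratio` is `NA`).
#' @export
evaluate_df21_only <- function(cohort, cutoff,
                               constants = assay_constants()) {
  stopifnot(is.numeric(cutoff), length(cutoff) == 1)
  if (cutoff < constants$lod_21df)
    stop("cutoff below the LoD is not measurable", call. = FALSE)
  df21 <- censored_value(cohort$df21_nmol_l, constants$lod_21df, "zero")
  positive <- cohort$df21_detectable & df21 >= cutoff
  structure(data.frame(sample_id = cohort$sample_id,
                       positive = positive,
                       gate_passed = positive,
                       pre_sum_nmol_l = df21,
                       ratio = rep(NA_real_, nrow(cohort)),
                       stringsAsFactors = FALSE),
            class = c("screen_results", "data.frame"),
            algorithm_id = sprintf("df21_only_%g", cutoff))
}
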