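#' Assay constants for the second-tier steroid panel
#'
#' Bundles the analytical constants the screening rules depend on: the
#' 21-deoxycortisol limit of detection and limit of quantitation of the
#' LC-MS/MS panel, and the gestational-age cutoff defining prematurity.
#'
#' @param lod_21df Limit of detection for 21-deoxycortisol, nmol/L.
#' @param loq_21df Limit of quantitation for 21-deoxycortisol, nmol/L.
#' @param preterm_ga_cutoff Gestational age below which a newborn is
#'   considered preterm, completed weeks.
#'
#' @return An object of class `assay_constants`.
#' @export
#' @examples
#' assay_constants()
assay_constants <- function(lod_21df = 2.1, loq_21df = 3.4,
                            preterm_ga_cutoff = 37) {
  stopifnot(is.numeric(lod_21df), is.numeric(loq_21df),
            is.numeric(preterm_ga_cutoff))
  if (lod_21df <= 0 || loq_21df <= 0 || preterm_ga_cutoff <= 0)
    stop("assay constants must be strictly positive", call. = FALSE)
  if (lod_21df >= loq_21df)
    stop("lod_21df must be below loq_21df", call. = FALSE)
  structure(list(lod_21df = lod_21df, loq_21df = loq_21df,
                 preterm_ga_cutoff = preterm_ga_cutoff),
            class = "assay_constants")
}

#' @export
print.assay_constants <- function(x, ...) {
  cat("Assay constants: 21-DF LoD", x$lod_21df, "nmol/L, LoQ", x$loq_21df,
      "nmol/L; preterm < ", x$preterm_ga_cutoff, "weeks GA\n")
  invisible(x)
}

#' Recognised diagnosis labels
#'
#' Ground-truth classes for a screened newborn. `SW_CAH` (salt-wasting
#' 21-hydroxylase deficiency) is the primary screening target; the variant
#' forms (`SV_CAH`, `NC_CAH`, `BOHSD3`, `BOHD11`) count as false positives
#' when flagged under the SW target.
#'
#' @return Character vector of the six labels.
#' @export
diagnosis_levels <- function() {
  c("SW_CAH", "SV_CAH", "NC_CAH", "BOHSD3", "BOHD11", "UNAFFECTED")
}

# Column order of the on-disk cohort CSV and the in-memory data.frame.
cohort_columns <- function() {
  c("sample_id", "ga_weeks", "bw_grams", "ohp17_nmol_l", "a4_nmol_l",
    "cortisol_nmol_l", "dc11_nmol_l", "df21_nmol_l", "df21_detectable",
    "tier1_positive", "diagnosis")
}

#' Construct a steroid cohort
#'
#' A cohort is a data.frame with one row per newborn: sample id, gestational
#' age and birthweight (both may be missing), the five steroid concentrations
#' in nmol/L, the 21-deoxycortisol detectability flag, tier-1 status, and the
#' diagnosis label. Below-LoD 21-deoxycortisol is stored as `NA` with
#' `df21_detectable = FALSE`; on disk it is written as the literal token
#' `"<LOD"` so an unquantifiable value can never be used silently as a number.
#'
#' @param profiles A data.frame with the columns of [cohort_columns()].
#' @param provenance Free-text provenance (file path or generator settings).
#' @param constants An [assay_constants()] object used for validation.
#'
#' @return A validated data.frame of class `steroid_cohort` with a
#'   `provenance` attribute.
#' @export
new_cohort <- function(profiles, provenance = "in-memory",
                       constants = assay_constants()) {
  stopifnot(is.data.frame(profiles))
  missing_cols <- setdiff(cohort_columns(), names(profiles))
  if (length(missing_cols) > 0)
    stop("cohort is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  profiles <- as.data.frame(profiles)[, cohort_columns()]
  rownames(profiles) <- NULL
  cohort <- structure(profiles, class = c("steroid_cohort", "data.frame"),
                      provenance = provenance)
  validate_cohort(cohort, constants)
  cohort
}

#' Validate a steroid cohort
#'
#' Checks the cohort invariants: unique sample ids, non-negative
#' concentrations, gestational age within 20--45 weeks where present, and
#' consistency of the 21-deoxycortisol value with its detectability flag
#' (a stored value must be at or above the LoD; below-LoD measurements are
#' encoded as missing with the flag off).
#'
#' @param cohort A `steroid_cohort`.
#' @param constants An [assay_constants()] object.
#' @return The cohort, invisibly, if valid; otherwise an error.
#' @export
validate_cohort <- function(cohort, constants = assay_constants()) {
  stopifnot(is.data.frame(cohort))
  ids <- cohort$sample_id
  if (anyDuplicated(ids))
    stop("duplicate sample_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  for (col in c("ohp17_nmol_l", "a4_nmol_l", "cortisol_nmol_l",
                "dc11_nmol_l", "df21_nmol_l")) {
    v <- cohort[[col]]
    bad <- which(!is.na(v) & v < 0)
    if (length(bad) > 0)
      stop("negative concentration in ", col, " for sample(s): ",
           paste(ids[bad], collapse = ", "), call. = FALSE)
  }
  req_na <- c("ohp17_nmol_l", "a4_nmol_l", "cortisol_nmol_l")
  for (col in req_na) {
    if (anyNA(cohort[[col]]))
      stop(col, " must be present for every profile", call. = FALSE)
  }
  ga <- cohort$ga_weeks
  bad_ga <- which(!is.na(ga) & (ga < 20 | ga > 45))
  if (length(bad_ga) > 0)
    stop("ga_weeks outside [20, 45] for sample(s): ",
         paste(ids[bad_ga], collapse = ", "), call. = FALSE)
  df21 <- cohort$df21_nmol_l
  det <- cohort$df21_detectable
  if (anyNA(det))
    stop("df21_detectable must be TRUE or FALSE for every profile",
         call. = FALSE)
  bad_flag <- which(det != (!is.na(df21) & df21 >= constants$lod_21df))
  if (length(bad_flag) > 0)
    stop("df21_detectable inconsistent with df21_nmol_l (values below the ",
         "LoD must be encoded as \"<LOD\") for sample(s): ",
         paste(ids[bad_flag], collapse = ", "), call. = FALSE)
  bad_diag <- which(!cohort$diagnosis %in% diagnosis_levels())
  if (length(bad_diag) > 0)
    stop("unknown diagnosis label for sample(s): ",
         paste(ids[bad_diag], collapse = ", "), call. = FALSE)
  invisible(cohort)
}

#' @export
as.data.frame.steroid_cohort <- function(x, ...) {
  attr(x, "provenance") <- NULL
  class(x) <- "data.frame"
  x
}

#' @export
print.steroid_cohort <- function(x, ...) {
  tab <- table(factor(x$diagnosis, levels = diagnosis_levels()))
  cat("Steroid cohort:", nrow(x), "newborn profiles\n")
  cat("  provenance:", attr(x, "provenance"), "\n")
  cat("  diagnoses: ",
      paste(names(tab)[tab > 0], tab[tab > 0], sep = "=", collapse = ", "),
      "\n")
  cat("  21-DF detectable:", sum(x$df21_detectable), "of", nrow(x), "\n")
  invisible(x)
}

#' Read a steroid cohort from CSV
#'
#' Reads the documented cohort CSV schema. The `df21_nmol_l` column accepts
#' either a decimal value (at or above the LoD) or the token `"<LOD"`, which
#' is parsed as a censored measurement (`NA` value, `df21_detectable FALSE`).
#' A numeric 21-deoxycortisol below the LoD is rejected: such a measurement
#' is unquantifiable and must be encoded as `"<LOD"`.
#'
#' @param path CSV file path.
#' @param constants An [assay_constants()] object.
#' @return A `steroid_cohort`.
#' @export
read_cohort <- function(path, constants = assay_constants()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character",
                         na.strings = character(0),
                         check.names = FALSE)
  missing_cols <- setdiff(cohort_columns(), names(raw))
  if (length(missing_cols) > 0)
    stop("cohort CSV is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  num <- function(col) {
    v <- trimws(raw[[col]])
    v[v == ""] <- NA_character_
    out <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(out))
    if (length(bad) > 0)
      stop("non-numeric value in ", col, " at row(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    out
  }
  lgl <- function(col) {
    v <- toupper(trimws(raw[[col]]))
    out <- rep(NA, length(v))
    out[v %in% c("TRUE", "T", "1")] <- TRUE
    out[v %in% c("FALSE", "F", "0")] <- FALSE
    if (anyNA(out))
      stop("non-boolean value in ", col, call. = FALSE)
    out
  }
  df21_raw <- trimws(raw$df21_nmol_l)
  censored <- df21_raw == "<LOD"
  df21 <- rep(NA_real_, length(df21_raw))
  df21[!censored] <- {
    v <- df21_raw[!censored]
    v[v == ""] <- NA_character_
    out <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(out))
    if (length(bad) > 0)
      stop("df21_nmol_l must be a decimal or \"<LOD\" (row(s) ",
           paste(which(!censored)[bad], collapse = ", "), ")", call. = FALSE)
    out
  }
  low <- which(!is.na(df21) & df21 < constants$lod_21df)
  if (length(low) > 0)
    stop("df21_nmol_l below the LoD (", constants$lod_21df,
         " nmol/L) must be encoded as \"<LOD\"; offending sample(s): ",
         paste(raw$sample_id[low], collapse = ", "), call. = FALSE)
  profiles <- data.frame(
    sample_id = trimws(raw$sample_id),
    ga_weeks = num("ga_weeks"),
    bw_grams = num("bw_grams"),
    ohp17_nmol_l = num("ohp17_nmol_l"),
    a4_nmol_l = num("a4_nmol_l"),
    cortisol_nmol_l = num("cortisol_nmol_l"),
    dc11_nmol_l = num("dc11_nmol_l"),
    df21_nmol_l = df21,
    df21_detectable = lgl("df21_detectable"),
    tier1_positive = lgl("tier1_positive"),
    diagnosis = trimws(raw$diagnosis),
    stringsAsFactors = FALSE
  )
  new_cohort(profiles, provenance = path, constants = constants)
}

#' Write a steroid cohort to CSV
#'
#' Writes the cohort in the documented CSV schema; censored 21-deoxycortisol
#' is emitted as the token `"<LOD"`. `read_cohort()` of the written file
#' reproduces the cohort field for field.
#'
#' @param cohort A `steroid_cohort`.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  out <- as.data.frame(cohort)
  df21 <- ifelse(cohort$df21_detectable,
                 format_num(cohort$df21_nmol_l), "<LOD")
  out$df21_nmol_l <- df21
  for (col in c("ga_weeks", "bw_grams", "ohp17_nmol_l", "a4_nmol_l",
                "cortisol_nmol_l", "dc11_nmol_l")) {
    out[[col]] <- ifelse(is.na(out[[col]]), "", format_num(out[[col]]))
  }
  out$df21_detectable <- ifelse(cohort$df21_detectable, "TRUE", "FALSE")
  out$tier1_positive <- ifelse(cohort$tier1_positive, "TRUE", "FALSE")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

# Full-precision decimal formatting (no scientific notation) so that CSV
# round-trips are lossless for generated values.
format_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return("")
    format(v, digits = 17, scientific = FALSE, trim = TRUE)
  }, character(1))
  out
}

#' Substitute a value for a censored concentration
#'
#' Returns the measured concentration unchanged when it is present and at or
#' above the LoD; otherwise substitutes according to the policy: `"zero"`
#' (used in screening sums, conservative) or `"half_lod"` (used before log
#' transformation in the PCA, where zero is unusable).
#'
#' @param conc Numeric vector of concentrations; `NA` marks a censored value.
#' @param lod Limit of detection, nmol/L (> 0).
#' @param policy `"zero"` or `"half_lod"`.
#' @return Numeric vector with censored entries substituted.
#' @export
#' @examples
#' censored_value(c(NA, 49.5), lod = 2.1, policy = "zero")
#' censored_value(NA, lod = 2.1, policy = "half_lod")  # 1.05
censored_value <- function(conc, lod, policy = c("zero", "half_lod")) {
  policy <- match.arg(policy)
  stopifnot(is.numeric(lod), lod > 0)
  sub <- if (policy == "zero") 0 else lod / 2
  out <- as.numeric(conc)
  censored <- is.na(out) | out < lod
  out[censored] <- sub
  out
}
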