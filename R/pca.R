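#' Prepare the standardized log-steroid matrix for PCA
#'
#' Builds the n x 5 analysis matrix (17-OHP, androstenedione, cortisol,
#' 11-deoxycortisol, 21-deoxycortisol): concentrations are log10-transformed
#' with half-LoD substitution for censored 21-deoxycortisol (the log of zero
#' is unusable, and half the LoD is the conventional substitution for a
#' non-detect), then each column is standardized to zero mean and unit
#' variance, so the subsequent PCA is a correlation-matrix PCA. Rows with
#' missing 11-deoxycortisol are dropped and counted.
#'
#' @param cohort A `steroid_cohort`.
#' @param constants An [assay_constants()] object.
#' @return Numeric matrix with a `transform_spec` attribute recording the
#'   transform, the substitution value and `dropped_n`, and a `sample_id`
#'   attribute for the retained rows.
#' @export
prepare_matrix <- function(cohort, constants = assay_constants()) {
  if (nrow(cohort) == 0) stop("cohort is empty", call. = FALSE)
  keep <- !is.na(cohort$dc11_nmol_l)
  dropped <- sum(!keep)
  sub <- constants$lod_21df / 2
  x <- cbind(
    ohp17 = cohort$ohp17_nmol_l[keep],
    a4 = cohort$a4_nmol_l[keep],
    cortisol = cohort$cortisol_nmol_l[keep],
    dc11 = cohort$dc11_nmol_l[keep],
    df21 = censored_value(cohort$df21_nmol_l[keep], constants$lod_21df,
                          "half_lod")
  )
  if (any(x <= 0))
    stop("non-positive concentration cannot be log-transformed",
         call. = FALSE)
  x <- log10(x)
  sds <- apply(x, 2, stats::sd)
  zero_var <- names(which(sds == 0 | is.na(sds)))
  if (length(zero_var) > 0)
    stop("zero-variance analyte column(s): ",
         paste(zero_var, collapse = ", "), call. = FALSE)
  x <- scale(x)
  attr(x, "scaled:center") <- NULL
  attr(x, "scaled:scale") <- NULL
  attr(x, "transform_spec") <- list(transform = "log10",
                                    censored_substitution = sub,
                                    standardized = TRUE,
                                    dropped_n = dropped)
  attr(x, "sample_id") <- cohort$sample_id[keep]
  x
}

#' Principal components of the steroid matrix
#'
#' Singular value decomposition of the standardized matrix (equivalently, an
#' eigendecomposition of the correlation matrix of the log-steroids).
#' Components are ordered by variance explained. The sign of each component
#' is fixed so its largest-magnitude loading is positive, making results
#' run-to-run identical.
#'
#' @param x A matrix from [prepare_matrix()] (or any column-standardized
#'   matrix with at least as many rows as columns and at least 6 rows).
#' @return An object of class `pca_result`: `scores` (n x k), `loadings`
#'   (5 x k, orthonormal columns), `variance_explained` (k proportions,
#'   non-increasing), `sdev`, and the matrix's `transform_spec`.
#' @export
run_pca <- function(x) {
  stopifnot(is.matrix(x))
  if (nrow(x) < 6)
    stop("at least 6 rows are required for a stable PCA", call. = FALSE)
  if (nrow(x) < ncol(x))
    stop("fewer rows than analyte columns", call. = FALSE)
  s <- svd(x)
  k <- ncol(x)
  # sign convention: largest-|loading| entry of each component positive
  for (j in seq_len(k)) {
    i <- which.max(abs(s$v[, j]))
    if (s$v[i, j] < 0) {
      s$v[, j] <- -s$v[, j]
      s$u[, j] <- -s$u[, j]
    }
  }
  loadings <- s$v
  rownames(loadings) <- colnames(x)
  colnames(loadings) <- paste0("PC", seq_len(k))
  scores <- s$u %*% diag(s$d, k, k)
  colnames(scores) <- colnames(loadings)
  rownames(scores) <- attr(x, "sample_id")
  ve <- s$d^2 / sum(s$d^2)
  structure(list(scores = scores,
                 loadings = loadings,
                 variance_explained = ve,
                 sdev = s$d / sqrt(nrow(x) - 1),
                 transform_spec = attr(x, "transform_spec")),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("PCA of the five-steroid panel (", nrow(x$scores), "profiles )\n")
  cat("  variance explained:",
      paste(format_percent(x$variance_explained, 1), collapse = ", "), "\n")
  cat("  PC1+PC2:",
      format_percent(sum(x$variance_explained[1:2]), 1), "\n")
  invisible(x)
}

#' Angle between two loading vectors
#'
#' Convenience for biplot geometry: the angle, in degrees, between two
#' analytes' loading vectors in the first `k` components. Near-collinear
#' vectors (small angle) carry redundant information; near-orthogonal ones
#' are uncorrelated.
#'
#' @param result A [run_pca()] result.
#' @param analyte1,analyte2 Row names of the loadings matrix.
#' @param k Number of leading components to use (default 2, the biplot
#'   plane).
#' @return Angle in degrees in `[0, 180]`.
#' @export
loading_angle <- function(result, analyte1, analyte2, k = 2) {
  v1 <- result$loadings[analyte1, seq_len(k)]
  v2 <- result$loadings[analyte2, seq_len(k)]
  cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  acos(max(-1, min(1, cosang))) * 180 / pi
}

#' Export biplot data: scores with screening groups, and loadings
#'
#' Writes the component scores with each newborn's group relative to the
#' legacy rule (true-positive, false-positive, false-negative or
#' true-negative for the target condition) and the loadings matrix, as two
#' CSVs ready for plotting.
#'
#' @param result A [run_pca()] result.
#' @param cohort The `steroid_cohort` the matrix came from.
#' @param scores_path,loadings_path Output CSV paths.
#' @param target Labels counted as the condition.
#' @return Invisibly, a list with the two paths and the score table.
#' @export
biplot_export <- function(result, cohort, scores_path, loadings_path,
                          target = "SW_CAH") {
  legacy <- evaluate_legacy(cohort)
  idx <- match(rownames(result$scores), cohort$sample_id)
  if (anyNA(idx))
    stop("score rows not found in cohort", call. = FALSE)
  pos <- legacy$positive[idx]
  is_case <- cohort$diagnosis[idx] %in% target
  group <- ifelse(pos & is_case, "true_positive",
                  ifelse(pos & !is_case, "false_positive",
                         ifelse(!pos & is_case, "false_negative",
                                "true_negative")))
  scores <- data.frame(sample_id = rownames(result$scores),
                       result$scores,
                       diagnosis = cohort$diagnosis[idx],
                       group = group,
                       stringsAsFactors = FALSE)
  utils::write.csv(scores, scores_path, row.names = FALSE, quote = FALSE)
  loadings <- data.frame(analyte = rownames(result$loadings),
                         result$loadings,
                         stringsAsFactors = FALSE)
  utils::write.csv(loadings, loadings_path, row.names = FALSE, quote = FALSE)
  invisible(list(scores_path = scores_path, loadings_path = loadings_path,
                 scores = scores))
}
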