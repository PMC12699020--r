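#' Specification of a Monte Carlo threshold search
#'
#' For each candidate algorithm, thresholds are drawn independently from
#' uniform ranges and applied to the cohort; a draw is feasible when it
#' keeps every target case (100% sensitivity by exact count, `fn = 0`, when
#' `required_sensitivity` is 1) and reaches the PPV floor. Default ranges
#' bracket all cutoffs of practical interest: 21-deoxycortisol gate 2.1--20
#' nmol/L, pre-analyte sum 10--200 nmol/L, ratio 0.05--5.
#'
#' @param algorithms Named list of [screening_algorithm()] objects.
#' @param n_iterations Draws per algorithm (default 10000).
#' @param df21_gate_range,pre_cutoff_range,ratio_cutoff_range Length-2
#'   numeric ranges (lower < upper, or equal for a degenerate point).
#' @param min_ppv PPV floor in (0, 1].
#' @param required_sensitivity Required sensitivity in [0, 1]; 1 means a
#'   zero-false-negative count condition, not a floating comparison.
#' @param target Diagnosis labels counted as the condition.
#' @param seed Master seed; each algorithm gets an independent derived
#'   substream so adding or removing one does not perturb the others.
#' @return An object of class `search_spec`.
#' @export
search_spec <- function(algorithms = default_registry(),
                        n_iterations = 10000,
                        df21_gate_range = c(2.1, 20),
                        pre_cutoff_range = c(10, 200),
                        ratio_cutoff_range = c(0.05, 5),
                        min_ppv = 0.75,
                        required_sensitivity = 1,
                        target = "SW_CAH",
                        seed = 7L) {
  chk_range <- function(r, nm) {
    if (length(r) != 2 || r[1] > r[2])
      stop(nm, " must be c(lower, upper) with lower <= upper", call. = FALSE)
  }
  chk_range(df21_gate_range, "df21_gate_range")
  chk_range(pre_cutoff_range, "pre_cutoff_range")
  chk_range(ratio_cutoff_range, "ratio_cutoff_range")
  stopifnot(n_iterations >= 1, min_ppv > 0, min_ppv <= 1,
            required_sensitivity >= 0, required_sensitivity <= 1)
  if (is.null(names(algorithms)) || any(names(algorithms) == ""))
    names(algorithms) <- vapply(algorithms, `[[`, character(1),
                                "algorithm_id")
  structure(list(algorithms = algorithms,
                 n_iterations = as.integer(n_iterations),
                 df21_gate_range = df21_gate_range,
                 pre_cutoff_range = pre_cutoff_range,
                 ratio_cutoff_range = ratio_cutoff_range,
                 min_ppv = min_ppv,
                 required_sensitivity = required_sensitivity,
                 target = target,
                 seed = as.integer(seed)),
            class = "search_spec")
}

# Independent substream seed per algorithm, derived from the master seed and
# the algorithm id (not its registry position, so adding or removing other
# algorithms leaves this one's draws unchanged).
substream_seed <- function(seed, algorithm_id) {
  h <- 0
  for (code in utf8ToInt(algorithm_id)) h <- (h * 31 + code) %% (2^31 - 1)
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% (2^31 - 1))
}

#' Draw threshold sets uniformly from the search ranges
#'
#' Each component is drawn independently and uniformly on its range.
#' Not seeded: callers control the RNG state.
#'
#' @param spec A [search_spec()].
#' @param n Number of draws.
#' @return Data.frame with columns `df21_gate`, `pre_cutoff`,
#'   `ratio_cutoff`.
#' @export
sample_thresholds <- function(spec, n) {
  u <- function(r, n) stats::runif(n, r[1], r[2])
  data.frame(df21_gate = u(spec$df21_gate_range, n),
             pre_cutoff = u(spec$pre_cutoff_range, n),
             ratio_cutoff = u(spec$ratio_cutoff_range, n))
}

#' Run the Monte Carlo threshold search
#'
#' For every algorithm in the spec, draws `n_iterations` threshold sets and
#' evaluates each on the cohort, recording counts, PPV, sensitivity and
#' feasibility. The per-row metrics are identical to applying
#' [apply_algorithm()] and [screen_metrics()] at that row's thresholds; the
#' search merely vectorizes the comparisons over iterations.
#'
#' @param cohort A `steroid_cohort` containing at least one target-positive
#'   label.
#' @param spec A [search_spec()].
#' @param constants An [assay_constants()] object.
#' @return A `simulation_table` data.frame with one row per (algorithm,
#'   iteration): `algorithm_id`, `df21_gate`, `pre_cutoff`, `ratio_cutoff`,
#'   `n_positive`, `tp`, `fp`, `ppv`, `sensitivity`, `feasible`.
#' @export
run_search <- function(cohort, spec, constants = assay_constants()) {
  stopifnot(inherits(spec, "search_spec"))
  is_case <- cohort$diagnosis %in% spec$target
  n_case <- sum(is_case)
  if (n_case == 0)
    stop("cohort contains no ", paste(spec$target, collapse = "/"),
         " cases; the sensitivity constraint cannot be evaluated",
         call. = FALSE)
  df21_zero <- censored_value(cohort$df21_nmol_l, constants$lod_21df, "zero")
  df21_gateval <- ifelse(cohort$df21_detectable, df21_zero, -Inf)
  parts <- vector("list", length(spec$algorithms))
  for (k in seq_along(spec$algorithms)) {
    algo <- spec$algorithms[[k]]
    denom <- cohort[[analyte_column[[algo$denominator]]]]
    if (anyNA(denom))
      stop("denominator analyte ", algo$denominator,
           " missing for sample(s): ",
           paste(cohort$sample_id[is.na(denom)], collapse = ", "),
           call. = FALSE)
    pre_sum <- rep(0, nrow(cohort))
    for (an in algo$pre_analytes) {
      v <- cohort[[analyte_column[[an]]]]
      if (an == "DF21") v <- df21_zero
      pre_sum <- pre_sum + v
    }
    ratio <- pre_sum / denom
    draws <- withr::with_seed(substream_seed(spec$seed, algo$algorithm_id),
                              sample_thresholds(spec, spec$n_iterations))
    tp <- integer(spec$n_iterations)
    fp <- integer(spec$n_iterations)
    for (i in seq_len(spec$n_iterations)) {
      pos <- pre_sum >= draws$pre_cutoff[i] & ratio >= draws$ratio_cutoff[i]
      if (algo$uses_df21_gate) pos <- pos & (df21_gateval >= draws$df21_gate[i])
      tp[i] <- sum(pos & is_case)
      fp[i] <- sum(pos) - tp[i]
    }
    n_positive <- tp + fp
    ppv <- ifelse(n_positive > 0, tp / n_positive, NA_real_)
    sens <- tp / n_case
    feasible <- !is.na(ppv) & ppv >= spec$min_ppv &
      (if (spec$required_sensitivity >= 1) tp == n_case
       else sens >= spec$required_sensitivity)
    parts[[k]] <- data.frame(algorithm_id = algo$algorithm_id,
                             df21_gate = draws$df21_gate,
                             pre_cutoff = draws$pre_cutoff,
                             ratio_cutoff = draws$ratio_cutoff,
                             n_positive = n_positive,
                             tp = tp, fp = fp,
                             ppv = ppv, sensitivity = sens,
                             feasible = feasible,
                             stringsAsFactors = FALSE)
  }
  structure(do.call(rbind, parts),
            class = c("simulation_table", "data.frame"),
            min_ppv = spec$min_ppv,
            required_sensitivity = spec$required_sensitivity,
            n_case = n_case)
}

#' Summarize the feasible region for one algorithm
#'
#' Extracts the feasible rows of a simulation table for one algorithm and
#' reports axis-aligned bounding intervals per threshold and the feasible
#' fraction. Feasibility can be re-evaluated at a different PPV floor or
#' sensitivity requirement; an empty region is a valid result.
#'
#' @param table A [run_search()] result.
#' @param algorithm_id Algorithm to summarize.
#' @param min_ppv,required_sensitivity Optional overrides of the floors used
#'   when the table was built.
#' @return List with `algorithm_id`, `n_feasible`, `fraction_feasible`,
#'   `bounds` (per-threshold `c(min, max)` intervals, `NULL` when empty) and
#'   `rows` (the feasible subset).
#' @export
feasible_region <- function(table, algorithm_id, min_ppv = NULL,
                            required_sensitivity = NULL) {
  rows <- table[table$algorithm_id == algorithm_id, , drop = FALSE]
  if (nrow(rows) == 0)
    stop("unknown algorithm_id: ", algorithm_id, call. = FALSE)
  if (is.null(min_ppv) && is.null(required_sensitivity)) {
    feas <- rows$feasible
  } else {
    mp <- if (is.null(min_ppv)) attr(table, "min_ppv") else min_ppv
    rs <- if (is.null(required_sensitivity))
      attr(table, "required_sensitivity") else required_sensitivity
    n_case <- attr(table, "n_case")
    feas <- !is.na(rows$ppv) & rows$ppv >= mp &
      (if (rs >= 1) rows$tp == n_case else rows$sensitivity >= rs)
  }
  sel <- rows[feas, , drop = FALSE]
  bounds <- if (nrow(sel) == 0) NULL else
    lapply(sel[c("df21_gate", "pre_cutoff", "ratio_cutoff")], range)
  list(algorithm_id = algorithm_id,
       n_feasible = nrow(sel),
       fraction_feasible = nrow(sel) / nrow(rows),
       bounds = bounds,
       rows = sel)
}
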