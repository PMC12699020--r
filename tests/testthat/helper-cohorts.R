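# Build a small in-memory cohort from per-profile steroid values.
# df21 = NA means censored below the LoD.
toy_cohort <- function(ohp17, a4 = 0.1, cortisol, dc11 = 10, df21 = NA,
                       ga = 39, diagnosis = "UNAFFECTED", ids = NULL,
                       constants = assay_constants()) {
  n <- max(lengths(list(ohp17, a4, cortisol, dc11, df21, ga, diagnosis)))
  rep_n <- function(x) rep_len(x, n)
  df21 <- rep_n(df21)
  new_cohort(data.frame(
    sample_id = if (is.null(ids)) sprintf("S%03d", seq_len(n)) else ids,
    ga_weeks = rep_n(ga),
    bw_grams = rep_n(3100),
    ohp17_nmol_l = rep_n(ohp17),
    a4_nmol_l = rep_n(a4),
    cortisol_nmol_l = rep_n(cortisol),
    dc11_nmol_l = rep_n(dc11),
    df21_nmol_l = df21,
    df21_detectable = !is.na(df21) & df21 >= constants$lod_21df,
    tier1_positive = TRUE,
    diagnosis = rep_n(diagnosis),
    stringsAsFactors = FALSE
  ), provenance = "toy", constants = constants)
}

# Random valid cohort for property tests (values independent of any
# package sampler so it can serve as an oracle input).
random_cohort <- function(n, p_case = 0.2, p_censored = 0.5) {
  df21 <- ifelse(stats::runif(n) < p_censored, NA,
                 2.1 + stats::rexp(n, 1 / 20))
  toy_cohort(ohp17 = stats::rlnorm(n, 3, 1),
             a4 = stats::rlnorm(n, 2, 1),
             cortisol = stats::rlnorm(n, 4.5, 0.8),
             dc11 = stats::rlnorm(n, 2, 0.8),
             df21 = df21,
             ga = round(stats::runif(n, 24, 42), 1),
             diagnosis = ifelse(stats::runif(n) < p_case, "SW_CAH",
                                "UNAFFECTED"))
}
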