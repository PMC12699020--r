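#' Log-space parameters of a lognormal matched to arithmetic moments
#'
#' Closed-form moment matching: for a lognormal with arithmetic mean m and
#' standard deviation s, `sdlog^2 = log(1 + (s/m)^2)` and
#' `meanlog = log(m) - sdlog^2 / 2`.
#'
#' @param mean Target arithmetic mean (> 0).
#' @param sd Target arithmetic standard deviation (> 0).
#' @return List with `meanlog` and `sdlog`.
#' @export
#' @examples
#' p <- lognormal_params(49, 28)
#' exp(p$meanlog + p$sdlog^2 / 2)  # recovers 49
lognormal_params <- function(mean, sd) {
  stopifnot(is.numeric(mean), is.numeric(sd), mean > 0, sd > 0)
  sdlog2 <- log(1 + (sd / mean)^2)
  list(meanlog = log(mean) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

#' Class-conditional steroid distribution
#'
#' Describes how the five panel steroids are drawn for one diagnosis class.
#' Each steroid is lognormal, moment-matched to a target arithmetic mean and
#' SD in nmol/L; 17-OHP and androstenedione share a log-space correlation
#' (they carry largely redundant information in screen-positive newborns),
#' while cortisol is drawn independently of 21-deoxycortisol.
#'
#' @param label Diagnosis label, one of [diagnosis_levels()].
#' @param ohp17,a4,cortisol,dc11,df21 Length-2 numeric vectors
#'   `c(mean, sd)` in nmol/L. `df21` is the latent (pre-censoring)
#'   distribution.
#' @param df21_floor Lower truncation bound for the latent 21-deoxycortisol
#'   draw, nmol/L, or `NA` for none.
#' @param df21_below_lod_prob Probability that 21-deoxycortisol is censored
#'   below the LoD. With a value in (0, 1) a censoring coin is flipped per
#'   profile and detectable draws sit just above the LoD (near-LoD borderline
#'   values); with 0 the latent draw is used and censored only if it falls
#'   below the LoD; with 1 every draw is censored.
#' @param df21_detect_spread SD (nmol/L) of the half-normal spread above the
#'   LoD for detectable draws when `df21_below_lod_prob` is in (0, 1).
#' @param ohp17_a4_corr Log-space correlation of 17-OHP and androstenedione.
#' @param ohp17_dc11_corr Log-space correlation of 17-OHP and
#'   11-deoxycortisol: the precursor steroids co-vary with overall adrenal
#'   activation, though far less tightly than 17-OHP and androstenedione.
#' @param ga_preterm_prob Probability that a newborn of this class is preterm.
#' @param preterm_ohp17_logshift Additive log-space shift applied to the
#'   17-OHP mean for preterm newborns (androstenedione gets half the shift;
#'   21-deoxycortisol none — the gestational-age effect is concentrated on
#'   17-OHP).
#' @param require_rule_pass If `TRUE`, profiles are rejection-sampled until
#'   they pass the proposed three-component rule at its default thresholds.
#'   Used to reproduce observed 100% sensitivity for the classical forms; a
#'   calibration device, not a biological claim.
#'
#' @return An object of class `class_distribution`.
#' @export
class_distribution <- function(label,
                               ohp17, a4, cortisol, dc11, df21,
                               df21_floor = NA_real_,
                               df21_below_lod_prob = 0,
                               df21_detect_spread = 0.05,
                               ohp17_a4_corr = 0.9,
                               ohp17_dc11_corr = 0.45,
                               ga_preterm_prob = 0.5,
                               preterm_ohp17_logshift = 0,
                               require_rule_pass = FALSE) {
  stopifnot(label %in% diagnosis_levels(),
            df21_below_lod_prob >= 0, df21_below_lod_prob <= 1,
            ohp17_a4_corr >= -1, ohp17_a4_corr <= 1,
            ohp17_dc11_corr >= -1, ohp17_dc11_corr <= 1,
            ga_preterm_prob >= 0, ga_preterm_prob <= 1)
  as_ln <- function(x) {
    stopifnot(length(x) == 2, all(x > 0))
    lognormal_params(x[1], x[2])
  }
  structure(list(
    label = label,
    targets = list(ohp17 = ohp17, a4 = a4, cortisol = cortisol,
                   dc11 = dc11, df21 = df21),
    ln = list(ohp17 = as_ln(ohp17), a4 = as_ln(a4),
              cortisol = as_ln(cortisol), dc11 = as_ln(dc11),
              df21 = as_ln(df21)),
    df21_floor = df21_floor,
    df21_below_lod_prob = df21_below_lod_prob,
    df21_detect_spread = df21_detect_spread,
    ohp17_a4_corr = ohp17_a4_corr,
    ohp17_dc11_corr = ohp17_dc11_corr,
    ga_preterm_prob = ga_preterm_prob,
    preterm_ohp17_logshift = preterm_ohp17_logshift,
    require_rule_pass = require_rule_pass
  ), class = "class_distribution")
}

#' Default class-conditional distributions
#'
#' Calibration targets for the six diagnosis classes in a tier-1-positive
#' second-tier screening population. Values printed in published summaries
#' are used directly (salt-wasting 21-DF 49 (28) nmol/L with a 4.6 nmol/L
#' sensitivity floor; 93% of unaffected newborns below the 2.1 nmol/L LoD
#' with detectable values clustered at 2.1--2.2; nonclassical latent 21-DF
#' averaging 0.31 nmol/L; salt-wasting 17-OHP 174 (215.8) and cortisol
#' 50.8 (24.1)); the remaining per-class means follow the steroidogenesis
#' block each enzyme deficiency causes and are documented in the package
#' vignette.
#'
#' @param constants An [assay_constants()] object.
#' @return Named list of [class_distribution()] objects, one per diagnosis
#'   class, plus a `SV_CAH_historical` entry used only by
#'   [generate_historical_fixture()].
#' @export
default_class_distributions <- function(constants = assay_constants()) {
  list(
    SW_CAH = class_distribution(
      "SW_CAH",
      ohp17 = c(174.0, 215.8), a4 = c(80, 48), cortisol = c(50.8, 24.1),
      dc11 = c(15, 10), df21 = c(49, 28),
      df21_floor = 4.6, df21_below_lod_prob = 0,
      ga_preterm_prob = 0.25, require_rule_pass = TRUE),
    SV_CAH = class_distribution(
      "SV_CAH",
      ohp17 = c(25, 15), a4 = c(40, 25), cortisol = c(120, 80),
      dc11 = c(10, 6), df21 = c(5, 2.5),
      df21_below_lod_prob = 0, ga_preterm_prob = 0.25),
    NC_CAH = class_distribution(
      "NC_CAH",
      ohp17 = c(20, 12), a4 = c(15, 10), cortisol = c(130, 80),
      dc11 = c(8, 5), df21 = c(0.31, 0.2),
      df21_below_lod_prob = 1, ga_preterm_prob = 0.3),
    BOHSD3 = class_distribution(
      "BOHSD3",
      ohp17 = c(45, 25), a4 = c(30, 20), cortisol = c(40, 25),
      dc11 = c(5, 3), df21 = c(0.5, 0.4),
      df21_below_lod_prob = 1, ga_preterm_prob = 0.5),
    BOHD11 = class_distribution(
      "BOHD11",
      ohp17 = c(30, 20), a4 = c(25, 15), cortisol = c(30, 20),
      dc11 = c(120, 60), df21 = c(0.5, 0.4),
      df21_below_lod_prob = 1, ga_preterm_prob = 0.5),
    UNAFFECTED = class_distribution(
      "UNAFFECTED",
      ohp17 = c(12, 8), a4 = c(8, 5), cortisol = c(190, 150),
      dc11 = c(8, 5), df21 = c(1, 0.5),
      df21_below_lod_prob = 0.93, df21_detect_spread = 0.05,
      ga_preterm_prob = 0.545, preterm_ohp17_logshift = 0.45),
    SV_CAH_historical = class_distribution(
      "SV_CAH",
      ohp17 = c(90, 50), a4 = c(50, 30), cortisol = c(80, 40),
      dc11 = c(12, 7), df21 = c(12, 6),
      df21_floor = constants$lod_21df, df21_below_lod_prob = 0,
      ga_preterm_prob = 0.25, require_rule_pass = TRUE)
  )
}

#' Generator configuration
#'
#' Settings for [generate_cohort()]: cohort size, class prevalences, overall
#' preterm fraction, per-class distributions, the assay constants and the
#' seed. Defaults emulate a 1710-newborn tier-1-positive screening population
#' with 8 salt-wasting cases, 1 simple-virilizing case and 2 cases of
#' 3-beta-hydroxysteroid-dehydrogenase deficiency, 54% of samples from
#' preterm newborns.
#'
#' @param n_total Number of profiles to generate.
#' @param class_prevalences Named numeric vector over [diagnosis_levels()]
#'   (missing classes get prevalence 0); must sum to 1.
#' @param preterm_fraction_overall Target overall preterm fraction; the
#'   per-class preterm probabilities are rescaled to meet it (0 makes every
#'   newborn term).
#' @param class_distributions As [default_class_distributions()].
#' @param seed Integer seed; the generator is fully deterministic given the
#'   configuration and seed.
#' @param constants An [assay_constants()] object.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_total = 1710,
                             class_prevalences = c(SW_CAH = 8 / 1710,
                                                   SV_CAH = 1 / 1710,
                                                   BOHSD3 = 2 / 1710,
                                                   UNAFFECTED = 1699 / 1710),
                             preterm_fraction_overall = 0.54,
                             class_distributions =
                               default_class_distributions(constants),
                             seed = 42L,
                             constants = assay_constants()) {
  stopifnot(n_total >= 1)
  if (is.null(names(class_prevalences)) ||
      !all(names(class_prevalences) %in% diagnosis_levels()))
    stop("class_prevalences must be named with diagnosis labels",
         call. = FALSE)
  if (any(class_prevalences < 0))
    stop("class prevalences must be non-negative", call. = FALSE)
  if (abs(sum(class_prevalences) - 1) > 1e-9)
    stop("class prevalences must sum to 1 (got ",
         format(sum(class_prevalences), digits = 12), ")", call. = FALSE)
  prev <- stats::setNames(numeric(length(diagnosis_levels())),
                          diagnosis_levels())
  prev[names(class_prevalences)] <- class_prevalences
  structure(list(
    n_total = as.integer(n_total),
    class_prevalences = prev,
    preterm_fraction_overall = preterm_fraction_overall,
    class_distributions = class_distributions,
    seed = as.integer(seed),
    constants = constants
  ), class = "generator_config")
}

# Per-class preterm probabilities rescaled so the prevalence-weighted overall
# preterm fraction equals the configured target.
preterm_probs <- function(config) {
  prev <- config$class_prevalences
  p <- vapply(names(prev), function(lab) {
    d <- config$class_distributions[[lab]]
    if (is.null(d)) 0 else d$ga_preterm_prob
  }, numeric(1))
  base <- sum(prev * p)
  target <- config$preterm_fraction_overall
  if (base <= 0) {
    if (target > 0)
      stop("preterm_fraction_overall > 0 but all class preterm ",
           "probabilities are 0", call. = FALSE)
    return(p)
  }
  pmin(p * target / base, 1)
}

# Gestational ages: two-point mixture, preterm uniform on [24, 36.9] weeks
# and term uniform on [37, 41.9].
draw_ga <- function(n, preterm_prob) {
  preterm <- stats::runif(n) < preterm_prob
  ga <- numeric(n)
  ga[preterm] <- stats::runif(sum(preterm), 24, 36.9)
  ga[!preterm] <- stats::runif(sum(!preterm), 37, 41.9)
  round(ga, 1)
}

# Birthweight loosely tied to gestational age (not used by any screening
# rule; populated for realism and the CSV schema).
draw_bw <- function(ga) {
  mu <- pmax(3300 - 170 * pmax(40 - ga, 0), 550)
  round(pmax(stats::rnorm(length(ga), mu, 350), 450))
}

#' Draw steroid profiles from one class distribution
#'
#' The core class-conditional sampler: 17-OHP and androstenedione come from
#' a bivariate log-space Gaussian with the configured correlation, cortisol
#' and 11-deoxycortisol from independent lognormals, and 21-deoxycortisol
#' from the class's censoring-aware latent model (see
#' [class_distribution()]). Preterm newborns get the class's log-space
#' 17-OHP inflation. When `require_rule_pass` is set, draws failing the
#' proposed rule at (LoD, 40, 0.3) are rejected and redrawn.
#'
#' @param dist A [class_distribution()].
#' @param n Number of profiles.
#' @param ga_weeks Gestational ages (recycled to length `n`), or `NULL` to
#'   draw from the class's preterm probability.
#' @param constants An [assay_constants()] object.
#' @return A data.frame with the steroid columns of [cohort_columns()] plus
#'   `ga_weeks`; no sample ids are assigned. Not seeded: callers control the
#'   RNG state.
#' @export
sample_class_profiles <- function(dist, n, ga_weeks = NULL,
                                  constants = assay_constants()) {
  stopifnot(inherits(dist, "class_distribution"), n >= 0)
  if (n == 0) {
    return(data.frame(ga_weeks = numeric(0), ohp17_nmol_l = numeric(0),
                      a4_nmol_l = numeric(0), cortisol_nmol_l = numeric(0),
                      dc11_nmol_l = numeric(0), df21_nmol_l = numeric(0),
                      df21_detectable = logical(0)))
  }
  if (is.null(ga_weeks)) ga_weeks <- draw_ga(n, dist$ga_preterm_prob)
  ga_weeks <- rep_len(ga_weeks, n)
  preterm <- !is.na(ga_weeks) & ga_weeks < constants$preterm_ga_cutoff

  draw_block <- function(m, ga_pre) {
    ln <- dist$ln
    r <- dist$ohp17_a4_corr
    z1 <- stats::rnorm(m)
    z2 <- r * z1 + sqrt(1 - r^2) * stats::rnorm(m)
    shift1 <- ifelse(ga_pre, dist$preterm_ohp17_logshift, 0)
    ohp17 <- exp(ln$ohp17$meanlog + shift1 + ln$ohp17$sdlog * z1)
    a4 <- exp(ln$a4$meanlog + shift1 / 2 + ln$a4$sdlog * z2)
    cortisol <- stats::rlnorm(m, ln$cortisol$meanlog, ln$cortisol$sdlog)
    r2 <- dist$ohp17_dc11_corr
    z4 <- r2 * z1 + sqrt(1 - r2^2) * stats::rnorm(m)
    dc11 <- exp(ln$dc11$meanlog + ln$dc11$sdlog * z4)
    df21 <- stats::rlnorm(m, ln$df21$meanlog, ln$df21$sdlog)
    if (!is.na(dist$df21_floor)) {
      # truncate by redraw; the floor sits far in the lower tail for the
      # classical classes so this converges immediately
      low <- which(df21 < dist$df21_floor)
      guard <- 0
      while (length(low) > 0 && guard < 1000) {
        df21[low] <- stats::rlnorm(length(low), ln$df21$meanlog,
                                   ln$df21$sdlog)
        low <- which(df21 < dist$df21_floor)
        guard <- guard + 1
      }
      if (length(low) > 0) df21[low] <- dist$df21_floor
    }
    p <- dist$df21_below_lod_prob
    if (p >= 1) {
      censored <- rep(TRUE, m)
    } else if (p > 0) {
      censored <- stats::runif(m) < p
      n_det <- sum(!censored)
      df21[!censored] <- constants$lod_21df +
        abs(stats::rnorm(n_det, 0, dist$df21_detect_spread))
    } else {
      censored <- df21 < constants$lod_21df
    }
    df21[censored] <- NA_real_
    data.frame(ohp17_nmol_l = ohp17, a4_nmol_l = a4,
               cortisol_nmol_l = cortisol, dc11_nmol_l = dc11,
               df21_nmol_l = df21, df21_detectable = !censored)
  }

  out <- draw_block(n, preterm)
  if (isTRUE(dist$require_rule_pass)) {
    passes <- function(b) {
      p <- b$df21_detectable &
        (b$ohp17_nmol_l + b$df21_nmol_l >= 40) &
        ((b$ohp17_nmol_l + b$df21_nmol_l) / b$cortisol_nmol_l >= 0.3)
      p[is.na(p)] <- FALSE
      p
    }
    bad <- which(!passes(out))
    guard <- 0
    while (length(bad) > 0 && guard < 10000) {
      redraw <- draw_block(length(bad), preterm[bad])
      out[bad, ] <- redraw
      bad <- bad[!passes(redraw)]
      guard <- guard + 1
    }
    if (length(bad) > 0)
      stop("rejection sampling for class ", dist$label,
           " failed to satisfy the rule-pass constraint", call. = FALSE)
  }
  cbind(ga_weeks = ga_weeks, out)
}

#' Generate a synthetic tier-1-positive screening cohort
#'
#' Draws a full cohort under the configured class prevalences and
#' distributions. At an integer design point (every `n_total * prevalence`
#' is a whole number, as in the default 1710-profile configuration with
#' exactly 8 salt-wasting cases) class counts are fixed; otherwise they are
#' multinomial. Profile order is randomly permuted so class membership is
#' not positional. Fully deterministic given the configuration and seed.
#'
#' @param config A [generator_config()].
#' @return A `steroid_cohort`.
#' @export
#' @examples
#' cohort <- generate_cohort(generator_config(n_total = 200, seed = 1))
#' table(cohort$diagnosis)
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  constants <- config$constants
  prev <- config$class_prevalences
  expected <- config$n_total * prev
  withr::with_seed(config$seed, {
    if (all(abs(expected - round(expected)) < 1e-9)) {
      counts <- as.integer(round(expected))
    } else {
      counts <- as.integer(stats::rmultinom(1, config$n_total, prev))
    }
    names(counts) <- names(prev)
    p_pre <- preterm_probs(config)
    parts <- lapply(names(counts)[counts > 0], function(lab) {
      d <- config$class_distributions[[lab]]
      if (is.null(d))
        stop("no class distribution configured for ", lab, call. = FALSE)
      ga <- draw_ga(counts[[lab]], p_pre[[lab]])
      prof <- sample_class_profiles(d, counts[[lab]], ga_weeks = ga,
                                    constants = constants)
      prof$diagnosis <- lab
      prof
    })
    all <- do.call(rbind, parts)
    all <- all[sample.int(nrow(all)), , drop = FALSE]
    all$bw_grams <- draw_bw(all$ga_weeks)
    all$sample_id <- sprintf("NB%05d", seq_len(nrow(all)))
    all$tier1_positive <- TRUE
    new_cohort(all,
               provenance = sprintf("generate_cohort(n=%d, seed=%d)",
                                    config$n_total, config$seed),
               constants = constants)
  })
}

#' Generate the 26-case historical validation fixture
#'
#' A seeded stand-in for a historical cohort of 26 screen-positive newborns
#' with confirmed diagnoses: 13 salt-wasting and 6 simple-virilizing cases
#' drawn so every one passes the proposed rule, plus 7 variant-form cases
#' (1 11-beta-hydroxylase deficiency, 3 3-beta-hydroxysteroid-dehydrogenase
#' deficiency, 3 nonclassical 21-OHD) whose 21-deoxycortisol is censored
#' below the LoD, so the rule's gate filters all of them out.
#'
#' @param seed Integer seed.
#' @param constants An [assay_constants()] object.
#' @return A `steroid_cohort` of 26 profiles.
#' @export
generate_historical_fixture <- function(seed = 1L,
                                        constants = assay_constants()) {
  dists <- default_class_distributions(constants)
  plan <- list(SW_CAH = list(dist = dists$SW_CAH, n = 13),
               SV_CAH = list(dist = dists$SV_CAH_historical, n = 6),
               BOHD11 = list(dist = dists$BOHD11, n = 1),
               BOHSD3 = list(dist = dists$BOHSD3, n = 3),
               NC_CAH = list(dist = dists$NC_CAH, n = 3))
  withr::with_seed(as.integer(seed), {
    parts <- lapply(names(plan), function(lab) {
      p <- plan[[lab]]
      prof <- sample_class_profiles(p$dist, p$n, constants = constants)
      prof$diagnosis <- lab
      prof
    })
    all <- do.call(rbind, parts)
    all$bw_grams <- draw_bw(all$ga_weeks)
    all$sample_id <- sprintf("H%02d", seq_len(nrow(all)))
    all$tier1_positive <- TRUE
    new_cohort(all,
               provenance = sprintf("generate_historical_fixture(seed=%d)",
                                    as.integer(seed)),
               constants = constants)
  })
}
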