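# Independent per-profile oracle for the three-component rule family,
# written as a plain scalar loop (no shared code with apply_algorithm).
oracle_rule <- function(cohort, pre, denom, gate_on, gate, pre_cut,
                        ratio_cut, lod = 2.1) {
  sapply(seq_len(nrow(cohort)), function(i) {
    df21 <- cohort$df21_nmol_l[i]
    df21_use <- if (is.na(df21) || df21 < lod) 0 else df21
    vals <- c(OHP17 = cohort$ohp17_nmol_l[i], A4 = cohort$a4_nmol_l[i],
              DF21 = df21_use)
    s <- sum(vals[pre])
    den <- if (denom == "CORTISOL") cohort$cortisol_nmol_l[i]
           else cohort$dc11_nmol_l[i]
    ok <- s >= pre_cut && s / den >= ratio_cut
    if (gate_on) ok <- ok && cohort$df21_detectable[i] && df21_use >= gate
    ok
  })
}

test_that("proposed rule matches hand-computed reference profiles", {
  # profile 4 uses binary-exact values so the boundary comparisons are
  # exact: 37.875 + 2.125 = 40 and 40 / 125 = 0.32
  co <- toy_cohort(
    ohp17 = c(174.0, 93.4, 500, 37.875),
    cortisol = c(50.8, 176.0, 10, 125),
    df21 = c(49.5, 2.1, NA, 2.125),
    a4 = c(80, 10, 5, 1))
  res <- evaluate_proposed(co)
  # salt-wasting-like profile: sum 223.5, ratio 4.40, positive
  expect_true(res$positive[1])
  expect_equal(res$pre_sum_nmol_l[1], 223.5)
  expect_equal(res$ratio[1], 223.5 / 50.8, tolerance = 1e-12)
  # borderline-21-DF preterm-like false-positive phenotype: still positive
  expect_true(res$positive[2])
  expect_equal(res$pre_sum_nmol_l[2], 95.5)
  expect_equal(res$ratio[2], 95.5 / 176, tolerance = 1e-12)
  # censored 21-DF: negative regardless of extreme 17-OHP, sum/ratio still
  # reported under zero substitution
  expect_false(res$positive[3])
  expect_false(res$gate_passed[3])
  expect_equal(res$pre_sum_nmol_l[3], 500)
  # inclusive sum boundary: exactly 40 passes
  expect_true(res$positive[4])
  expect_identical(res$pre_sum_nmol_l[4], 40)
})

test_that("all three proposed-rule comparisons are inclusive at the boundary", {
  # binary-exact: sum 35 + 2.5 = 37.5, ratio 37.5 / 125 = 0.3, gate at LoD
  co <- toy_cohort(ohp17 = 35, cortisol = 125, df21 = 2.5, a4 = 0)
  th <- threshold_set(2.1, 37.5, 0.3)
  res <- evaluate_proposed(co, th)
  expect_true(res$positive)
  expect_identical(res$ratio, 0.3)
  # one ulp below any component fails
  expect_false(evaluate_proposed(co, threshold_set(2.1, 37.5,
    0.3 + 1e-12))$positive)
  expect_false(evaluate_proposed(co, threshold_set(2.1, 37.5 + 1e-9,
    0.3))$positive)
})

test_that("proposed rule rejects non-positive cortisol by sample", {
  co <- toy_cohort(ohp17 = 100, cortisol = 1, df21 = 10)
  co$cortisol_nmol_l <- 0
  expect_error(evaluate_proposed(co), "S001")
})

test_that("legacy rule applies 17-OHP >= 10 and (17-OHP+A4)/cortisol >= 0.33", {
  # profile 1 sits exactly on both boundaries with binary-exact arithmetic:
  # 17-OHP = 10 and (10 + 6.5) / 50 = 0.33
  co <- toy_cohort(ohp17 = c(10, 9.9, 174.0),
                   a4 = c(6.5, 1000, 80),
                   cortisol = c(50, 1, 50.8),
                   df21 = c(NA, NA, 49.5))
  res <- evaluate_legacy(co)
  expect_true(res$positive[1])     # both boundaries inclusive
  expect_false(res$positive[2])    # 17-OHP below 10 fails regardless of A4
  expect_true(res$positive[3])
  expect_equal(res$pre_sum_nmol_l[3], 254)
})

test_that("21-DF-only rule gates on detectability and cutoff", {
  co <- toy_cohort(ohp17 = 10, cortisol = 100,
                   df21 = c(49.5, NA, 4.6, 2.1))
  expect_equal(evaluate_df21_only(co, 2.5)$positive,
               c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(evaluate_df21_only(co, 4.6)$positive,
               c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(evaluate_df21_only(co, 6.56)$positive,
               c(TRUE, FALSE, FALSE, FALSE))
  expect_error(evaluate_df21_only(co, 1.0), "LoD")
})

test_that("threshold_set validates the gate against the LoD", {
  expect_equal(threshold_set("detectable")$df21_gate, 2.1)
  expect_equal(threshold_set(4.6)$df21_gate, 4.6)
  expect_error(threshold_set(1.0), "LoD")
  expect_error(threshold_set(pre_cutoff = -1), "pre_cutoff")
})

test_that("the default registry holds the 4 pre-sets x 2 gate settings", {
  reg <- default_registry()
  expect_length(reg, 8)
  expect_equal(sum(vapply(reg, `[[`, logical(1), "uses_df21_gate")), 4)
  pre_sets <- unique(lapply(reg, `[[`, "pre_analytes"))
  expect_length(pre_sets, 4)
  expect_true(all(vapply(reg, `[[`, character(1), "denominator") ==
                    "CORTISOL"))
  # the proposed-rule family is in the registry
  expect_equal(reg$ohp17_df21_gated$pre_analytes, c("OHP17", "DF21"))
})

test_that("apply_algorithm agrees with the per-profile oracle", {
  withr::with_seed(101, {
    co <- random_cohort(1000)
    for (algo in default_registry()) {
      th <- threshold_set(4.0, 35, 0.25)
      res <- apply_algorithm(algo, th, co)
      expected <- oracle_rule(co, algo$pre_analytes, algo$denominator,
                              algo$uses_df21_gate, 4.0, 35, 0.25)
      expect_equal(res$positive, expected)
    }
  })
})

test_that("apply_algorithm reproduces evaluate_proposed", {
  co <- withr::with_seed(55, random_cohort(200))
  algo <- screening_algorithm("p", c("OHP17", "DF21"), "CORTISOL", TRUE)
  expect_equal(apply_algorithm(algo, threshold_set(), co)$positive,
               evaluate_proposed(co)$positive)
})

test_that("raising any cutoff never increases the positive count", {
  co <- withr::with_seed(77, random_cohort(500))
  base <- threshold_set(2.1, 40, 0.3)
  n_base <- sum(evaluate_proposed(co, base)$positive)
  for (th in list(threshold_set(5, 40, 0.3), threshold_set(2.1, 80, 0.3),
                  threshold_set(2.1, 40, 0.6), threshold_set(8, 120, 1))) {
    n <- sum(evaluate_proposed(co, th)$positive)
    expect_lte(n, n_base)
  }
  # monotone along an increasing cutoff sequence
  counts <- sapply(seq(10, 200, by = 10), function(p)
    sum(evaluate_proposed(co, threshold_set(2.1, p, 0.3))$positive))
  expect_true(all(diff(counts) <= 0))
})

test_that("gate dominance: censored 21-DF is negative under the proposed rule", {
  co <- withr::with_seed(88, random_cohort(500, p_censored = 0.7))
  res <- evaluate_proposed(co)
  expect_false(any(res$positive[!co$df21_detectable]))
})

test_that("proposed rule is more specific than legacy on the synthetic cohort", {
  co <- generate_cohort(generator_config(seed = 42))
  leg <- evaluate_legacy(co)
  pro <- evaluate_proposed(co)
  # legacy flags profiles with undetectable 21-DF; the gate removes them all
  expect_gt(sum(leg$positive & !co$df21_detectable), 0)
  expect_equal(sum(pro$positive & !co$df21_detectable), 0)
  m_leg <- screen_metrics(confusion(leg, co))
  m_pro <- screen_metrics(confusion(pro, co))
  expect_gt(m_pro$specificity, m_leg$specificity)
  expect_equal(m_pro$sensitivity, 1)
})

test_that("DC11-denominator algorithms error when 11-DC is missing", {
  co <- toy_cohort(ohp17 = c(20, 30), cortisol = 100, df21 = 5)
  co$dc11_nmol_l[2] <- NA
  algo <- screening_algorithm("x", "OHP17", "DC11")
  expect_error(apply_algorithm(algo, threshold_set(), co), "S002")
})
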