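# Small calibrated cohort used across search tests (kept modest for speed;
# the full-scale design point is exercised in the acceptance suite).
search_test_cohort <- function(seed = 13) {
  generate_cohort(generator_config(
    n_total = 400,
    class_prevalences = c(SW_CAH = 4 / 400, SV_CAH = 1 / 400,
                          BOHSD3 = 1 / 400, UNAFFECTED = 394 / 400),
    seed = seed))
}

test_that("threshold draws are uniform on their ranges and seeded", {
  spec <- search_spec(n_iterations = 1)
  draws <- withr::with_seed(1, sample_thresholds(spec, 100000))
  expect_true(all(draws$pre_cutoff >= 10 & draws$pre_cutoff <= 200))
  expect_equal(mean(draws$pre_cutoff), 105, tolerance = 0.01)
  expect_equal(mean(draws$df21_gate), (2.1 + 20) / 2, tolerance = 0.01)
  # degenerate range collapses to a point
  spec0 <- search_spec(pre_cutoff_range = c(40, 40))
  d0 <- withr::with_seed(2, sample_thresholds(spec0, 50))
  expect_true(all(d0$pre_cutoff == 40))
  # identical seed, identical sequence
  a <- withr::with_seed(3, sample_thresholds(spec, 10))
  b <- withr::with_seed(3, sample_thresholds(spec, 10))
  expect_identical(a, b)
})

test_that("search specs validate their inputs", {
  expect_error(search_spec(pre_cutoff_range = c(5, 1)), "lower")
  expect_error(search_spec(min_ppv = 0), "min_ppv")
  expect_error(search_spec(n_iterations = 0), "n_iterations")
})

test_that("run_search is reproducible and sized per algorithm", {
  co <- search_test_cohort()
  spec <- search_spec(n_iterations = 50, seed = 5)
  t1 <- run_search(co, spec)
  t2 <- run_search(co, spec)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  expect_equal(nrow(t1), 50 * 8)
  expect_equal(unname(table(t1$algorithm_id)), rep(50L, 8),
               ignore_attr = TRUE)
  # single iteration: one row per algorithm
  expect_equal(nrow(run_search(co, search_spec(n_iterations = 1))), 8)
})

test_that("per-algorithm substreams are independent of registry composition", {
  co <- search_test_cohort()
  reg <- default_registry()
  full <- run_search(co, search_spec(algorithms = reg, n_iterations = 20,
                                     seed = 5))
  solo <- run_search(co, search_spec(algorithms = reg["ohp17_df21_gated"],
                                     n_iterations = 20, seed = 5))
  # dropping other algorithms must not perturb this one's draws
  expect_equal(
    solo[c("df21_gate", "pre_cutoff", "ratio_cutoff")],
    full[full$algorithm_id == "ohp17_df21_gated",
         c("df21_gate", "pre_cutoff", "ratio_cutoff")],
    ignore_attr = TRUE)
})

test_that("search rows agree with direct rule evaluation and metrics", {
  co <- search_test_cohort()
  tab <- run_search(co, search_spec(n_iterations = 30, seed = 9))
  reg <- default_registry()
  withr::with_seed(14, idx <- sample(nrow(tab), 100))
  for (i in idx) {
    row <- tab[i, ]
    th <- threshold_set(max(row$df21_gate, 2.1), row$pre_cutoff,
                        row$ratio_cutoff)
    res <- apply_algorithm(reg[[row$algorithm_id]], th, co)
    m <- screen_metrics(confusion(res, co))
    expect_equal(row$tp, m$counts$tp)
    expect_equal(row$fp, m$counts$fp)
    expect_equal(row$n_positive, m$n_positive)
    if (m$n_positive > 0) expect_equal(row$ppv, m$ppv)
    expect_equal(row$sensitivity, m$sensitivity)
  }
})

test_that("feasibility means zero false negatives and the PPV floor", {
  co <- search_test_cohort()
  tab <- run_search(co, search_spec(n_iterations = 200, seed = 21))
  n_sw <- sum(co$diagnosis == "SW_CAH")
  feas <- tab$feasible
  expect_equal(feas,
               !is.na(tab$ppv) & tab$ppv >= 0.75 & tab$tp == n_sw)
  # with no floors every defined-ppv row is feasible
  tab0 <- run_search(co, search_spec(n_iterations = 50, seed = 21,
                                     min_ppv = 1e-9,
                                     required_sensitivity = 0))
  expect_equal(tab0$feasible, !is.na(tab0$ppv))
})

test_that("feasible regions nest as the PPV floor rises", {
  co <- search_test_cohort()
  tab <- run_search(co, search_spec(n_iterations = 500, seed = 31))
  for (id in unique(tab$algorithm_id)) {
    hi <- feasible_region(tab, id, min_ppv = 0.75)
    lo <- feasible_region(tab, id, min_ppv = 0.5)
    expect_lte(hi$n_feasible, lo$n_feasible)
    # row-level subset, not just counts
    key <- function(r) paste(r$rows$df21_gate, r$rows$pre_cutoff,
                             r$rows$ratio_cutoff)
    expect_true(all(key(hi) %in% key(lo)))
  }
  expect_error(feasible_region(tab, "nope"), "unknown")
})

test_that("empty and single-row feasible regions are well-formed", {
  co <- search_test_cohort()
  tab <- run_search(co, search_spec(n_iterations = 20, seed = 41,
                                    min_ppv = 1))  # PPV 1 rarely reachable
  r <- feasible_region(tab, "ohp17")
  expect_equal(r$fraction_feasible, r$n_feasible / 20)
  if (r$n_feasible == 0) expect_null(r$bounds)
  if (r$n_feasible == 1) {
    expect_equal(r$bounds$pre_cutoff[1], r$bounds$pre_cutoff[2])
  }
})

test_that("a cohort without target cases cannot be searched", {
  co <- toy_cohort(ohp17 = c(10, 20), cortisol = 100, df21 = 5)
  expect_error(run_search(co, search_spec(n_iterations = 5)),
               "no SW_CAH")
})

test_that("gated 21-DF algorithms dominate the 17-OHP-only candidate", {
  co <- search_test_cohort()
  tab <- run_search(co, search_spec(n_iterations = 1000, seed = 51))
  frac <- function(id) feasible_region(tab, id)$fraction_feasible
  expect_gte(frac("ohp17_df21_gated"), frac("ohp17"))
  expect_gte(frac("ohp17_a4_df21_gated"), frac("ohp17"))
})
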