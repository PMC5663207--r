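test_that("codrug_profile normalizes pair counts by the target's exposure", {
  n1 <- as.data.table(list(key = c("met", "oxy"), size = 1L,
                           atleast_exposure_count = c(1000L, 400L)))
  n2 <- as.data.table(list(key = c("hctz|met", "met|statin", "alpra|oxy"),
                           size = 2L,
                           atleast_exposure_count = c(250L, 100L, 40L),
                           observe_per_expect_1s = c(2.2, 2.7, 3.7)))
  prof <- codrug_profile("met", n2, n1)
  expect_identical(names(prof),
                   c("codrug", "p_coexposure", "observed_expected"))
  expect_equal(prof[codrug == "hctz"]$p_coexposure, 0.25)
  expect_equal(prof[codrug == "hctz"]$observed_expected, 2.2)
  # partners never co-observed are absent, not zero rows
  expect_false("alpra" %in% prof$codrug)
  expect_identical(nrow(prof), 2L)
  expect_error(codrug_profile("ghost", n2, n1), "not found")
})

test_that("co-exposure probability is 1 only for always-present partners", {
  expo <- exposures_from_windows(list(c("A", "B"), c("A", "B"),
                                      c("A", "B", "C")))
  exact <- exact_combo_counts(expo)
  lv <- count_combos(exact, max_n = 2L, support_threshold = 1L)
  st <- combo_stats(lv, exact)
  prof <- codrug_profile("A", st[["2"]], st[["1"]])
  expect_equal(prof[codrug == "B"]$p_coexposure, 1.0)
  expect_equal(prof[codrug == "C"]$p_coexposure, 1 / 3)
  expect_true(all(prof$p_coexposure > 0 & prof$p_coexposure <= 1))
})

test_that("exposure-count distribution summarizes window sizes", {
  expo <- exposures_from_windows(list("A", c("A", "B"), c("A", "B", "C")))
  d <- exposure_count_distribution(expo)
  expect_identical(d$histogram$n_drugs, 1:3)
  expect_identical(d$histogram$n_windows, rep(1L, 3))
  expect_equal(d$median, 2)
  empty <- exposure_count_distribution(
    data.table(patient_id = character(), window_index = integer(),
               ingredient = character()))
  expect_identical(nrow(empty$histogram), 0L)
  expect_true(is.na(empty$median) && is.na(empty$p95))

  cfg <- cohort_config(30, seed = 6,
                       conditions = list(condition_spec("five", 1.0,
                                                        paste0("d", 1:5),
                                                        1.0)),
                       acute_rate = 0, combination_products = list())
  cohort <- simulate_cohort(cfg)
  ing <- expand_to_ingredients(cohort$claims, mapping_from_config(cfg))$claims
  d5 <- exposure_count_distribution(build_exposure_table(ing)$exposures)
  expect_identical(d5$histogram$n_drugs, 5L)
  expect_equal(d5$median, 5)
  expect_equal(d5$p95, 5)
})

test_that("outcome relative risk compares lookback to overall incidence", {
  # 4 patients with events; 2 exposed to A+B in the 30 days before the
  # event; overall incidence of A+B set to 0.25 -> RR = (2/4) / 0.25 = 2
  claims <- data.table(
    patient_id = c("P1", "P1", "P2", "P2", "P3", "P4"),
    ingredient = c("A", "B", "A", "B", "A", "C"),
    fill_age_days = c(100L, 100L, 200L, 200L, 300L, 400L),
    days_supply = 30L)
  events <- data.table(patient_id = c("P1", "P2", "P3", "P4"),
                       event_age_days = c(120L, 240L, 320L, 410L))
  stats_n <- as.data.table(list(key = "A|B", size = 2L,
                                atleast_exposure_count = 10L,
                                fraction_all_windows = 0.25))
  rr <- outcome_relative_risk(stats_n, claims, events, min_occurrences = 1L)
  expect_equal(rr$n_pre_exposed, 2L)
  expect_equal(rr$relative_risk, 2)
  # combos below the occurrence floor are excluded
  expect_identical(
    nrow(outcome_relative_risk(stats_n, claims, events,
                               min_occurrences = 100L)), 0L)
  # never seen pre-event -> RR = 0
  stats0 <- as.data.table(list(key = "C|D", size = 2L,
                               atleast_exposure_count = 10L,
                               fraction_all_windows = 0.1))
  rr0 <- outcome_relative_risk(stats0, claims, events, min_occurrences = 1L)
  expect_equal(rr0$relative_risk, 0)
  # no events -> empty table
  expect_identical(
    nrow(outcome_relative_risk(stats_n, claims, events[0L],
                               min_occurrences = 1L)), 0L)
  # only the first event per patient counts
  ev2 <- rbind(events, data.table(patient_id = "P4", event_age_days = 130L))
  rr2 <- outcome_relative_risk(stats_n, claims, ev2, min_occurrences = 1L)
  expect_equal(rr2$n_events, 4L)
})

test_that("events independent of prescribing give relative risk near 1", {
  cfg <- independent_config(800, seed = 31, acute_rate = 6,
                            drugs = c("x1", "x2"))
  cohort <- simulate_cohort(cfg)
  ing <- expand_to_ingredients(cohort$claims, mapping_from_config(cfg))$claims
  expo <- build_exposure_table(ing)$exposures
  exact <- exact_combo_counts(expo)
  lv <- count_combos(exact, max_n = 2L, support_threshold = 1L)
  st <- combo_stats(lv, exact)
  # one event per patient at a uniform age inside eligibility, drawn
  # independently of the claims
  set.seed(99)
  el <- cohort$eligibility
  events <- data.table(
    patient_id = el$patient_id,
    event_age_days = el$start_age_days + 31L +
      as.integer(floor(runif(nrow(el)) *
                         (el$end_age_days - el$start_age_days - 30L))))
  rr <- outcome_relative_risk(st[["1"]], ing, events, min_occurrences = 1L)
  expect_true(all(abs(rr$relative_risk - 1) < 0.35))
})

test_that("window-duration sensitivity is monotone and well-formed", {
  claims <- random_claims(600L, seed = 77L)
  res <- window_duration_sensitivity(claims, durations = c(10L, 30L, 90L))
  expect_identical(res$summary$window_days, c(10L, 30L, 90L))
  expect_true(all(diff(res$summary$mean_drugs_per_window) >= 0))
  # single aligned 30-day claim: exactly one exposed window at duration 30
  one <- data.table(patient_id = "P1", ingredient = "A",
                    fill_age_days = 60L, days_supply = 30L)
  r1 <- window_duration_sensitivity(one, durations = 30L)
  expect_identical(r1$summary$W_exposed, 1L)
  expect_identical(length(r1$rankings), 1L)
})

test_that("cohort-size sensitivity is deterministic and exact on full samples", {
  claims <- random_claims(800L, n_patients = 60L, seed = 13L)
  res <- cohort_size_sensitivity(claims, sample_sizes = c(60L, 25L),
                                 seed = 5L, top_k = 20L)
  full <- res[is.na(sample_size)]
  same <- res[sample_size == 60L]
  expect_equal(same$topk_overlap, 1.0)
  expect_equal(same$rank_correlation, 1.0)
  expect_equal(same$fraction_unique_windows, full$fraction_unique_windows)
  res2 <- cohort_size_sensitivity(claims, sample_sizes = c(60L, 25L),
                                  seed = 5L, top_k = 20L)
  expect_equal(res, res2)
  expect_error(cohort_size_sensitivity(claims, sample_sizes = 1000L,
                                       seed = 1L), "exceeds")
})
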