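# Synthetic multi-wave cohort generator.

test_that("baseline draws reproduce configured marginals and are reproducible", {
  specs <- tiny_specs()
  coh <- generate_baseline(100000, specs, seed = 11)
  expect_equal(nrow(coh), 100000L)
  expect_lt(abs(mean(coh$smoke == "never") - 0.629), 0.01)
  expect_lt(abs(mean(coh$smoke == "ex") - 0.299), 0.01)
  expect_lt(abs(mean(coh$active == "low") - 0.276), 0.01)
  one <- generate_baseline(1, specs, seed = 2)
  expect_equal(nrow(one), 1L)
  expect_false(anyNA(one))
  expect_identical(generate_baseline(500, specs, seed = 3),
                   generate_baseline(500, specs, seed = 3))
  expect_error(risk_factor_spec("x", c("a", "b"), c(0.5, 0.6)), "sum to")
})

test_that("intercept calibration matches the no-covariate closed form", {
  model <- attrition_model_spec(empty_coefficients())
  cal <- calibrate_intercepts(model, tiny_specs(), s5_targets(),
                              tol = 1e-12)
  closed <- log(s5_targets()[-1] / s5_targets()[["respondent"]])
  expect_equal(cal$intercepts, closed, tolerance = 1e-9)
  expect_equal(as.numeric(attr(cal, "achieved")),
               as.numeric(s5_targets()), tolerance = 1e-9)
})

test_that("calibration reaches the targets in exact expectation with shipped coefficients", {
  specs <- alswh_baseline_specs()
  model <- attrition_model_spec(alswh_coefficients())
  cal <- calibrate_intercepts(model, specs, s5_targets())
  # achieved marginals are the exact expectation over the 3600-cell
  # baseline distribution, not a Monte Carlo estimate
  expect_lt(max(abs(attr(cal, "achieved") - s5_targets())), 1e-4)
})

test_that("degenerate calibration targets are rejected", {
  model <- attrition_model_spec(empty_coefficients())
  expect_error(
    calibrate_intercepts(model, tiny_specs(),
                         c(respondent = 1, dead = 0, frail = 0,
                           withdrawn = 0, lost = 0)),
    "degenerate")
})

test_that("final-status sampling honours intercept-only marginals", {
  specs <- tiny_specs()
  cal <- calibrate_intercepts(attrition_model_spec(empty_coefficients()),
                              specs, s5_targets())
  coh <- generate_baseline(100000, specs, seed = 21)
  coh <- assign_final_status(coh, cal, seed = 22)
  shares <- prop.table(table(coh$status_s5))
  for (o in names(s5_targets())) {
    se <- sqrt(s5_targets()[[o]] * (1 - s5_targets()[[o]]) / 100000)
    expect_lt(abs(shares[[o]] - s5_targets()[[o]]), 4 * se)
  }
})

test_that("a planted log odds ratio is recovered by refitting", {
  specs <- tiny_specs()
  cf <- data.frame(factor = "smoke", category = "current", outcome = "dead",
                   log_or = log(2.73))
  cal <- calibrate_intercepts(attrition_model_spec(cf), specs, s5_targets())
  coh <- generate_baseline(30000, specs, seed = 31)
  coh <- assign_final_status(coh, cal, seed = 32)
  fit <- fit_attrition_model(coh, "smoke")
  est <- fit$or[fit$category == "current" & fit$outcome == "dead"]
  expect_gt(est, 2.2)
  expect_lt(est, 3.4)
})

test_that("coefficients referencing unknown categories are rejected", {
  specs <- tiny_specs()
  cf <- data.frame(factor = "smoke", category = "pipe", outcome = "dead",
                   log_or = 0.5)
  coh <- generate_baseline(100, specs, seed = 1)
  expect_error(assign_final_status(coh, attrition_model_spec(cf)),
               "unknown categories")
  expect_error(attrition_model_spec(data.frame(
    factor = "smoke", category = "current", outcome = "deceased",
    log_or = 1)), "unknown outcome")
})

test_that("interval rates derived from cumulative marginals hit later targets", {
  rates <- survey_transition_rates(alswh_attrition_marginals())
  ach <- attr(rates, "achieved")
  # final survey reproduced exactly; absorbing shares never decrease
  expect_equal(ach$dead[ach$survey == 5], 0.284, tolerance = 1e-9)
  expect_equal(ach$respondent[ach$survey == 5], 0.447, tolerance = 1e-9)
  for (s in c("dead", "frail", "withdrawn", "lost")) {
    expect_true(all(diff(ach[[s]]) >= 0))
  }
  # the printed lost-to-follow-up share dips between surveys 3 and 4; with
  # absorbing states the increment is clamped and the achieved share flat
  expect_equal(ach$lost[ach$survey == 4], ach$lost[ach$survey == 3])
  expect_gt(ach$lost[ach$survey == 4], 0.087)
})

test_that("forward survey expansion respects absorbing states and rates", {
  specs <- tiny_specs()
  rates <- survey_transition_rates(alswh_attrition_marginals())
  coh <- expand_to_surveys(generate_baseline(20000, specs, seed = 41),
                           rates, seed = 42)
  st <- sapply(paste0("status_s", 2:5), function(c) as.character(coh[[c]]))
  for (i in 1:3) {  # once out, never back (all states absorbing here)
    moved <- st[, i] != "respondent"
    expect_true(all(st[moved, i + 1] == st[moved, i]))
  }
  # zero attrition keeps everyone responding
  zero <- rates; zero[, c("dead", "frail", "withdrawn", "lost")] <- 0
  coh0 <- expand_to_surveys(generate_baseline(200, specs, seed = 1), zero,
                            seed = 2)
  expect_true(all(coh0$status_s5 == "respondent"))
})

test_that("expansion honours a pre-assigned final status", {
  specs <- tiny_specs()
  cal <- calibrate_intercepts(attrition_model_spec(empty_coefficients()),
                              specs, s5_targets())
  coh <- assign_final_status(generate_baseline(5000, specs, seed = 51), cal,
                             seed = 52)
  final <- coh$status_s5
  coh <- expand_to_surveys(coh,
                           survey_transition_rates(alswh_attrition_marginals()),
                           seed = 53)
  expect_identical(coh$status_s5, final)
  st <- sapply(paste0("status_s", 2:5), function(c) as.character(coh[[c]]))
  for (i in 1:3) {
    moved <- st[, i] != "respondent"
    expect_true(all(st[moved, i + 1] == st[moved, i]))
  }
})

test_that("missingness is imposed at the configured rates, statuses untouched", {
  specs <- tiny_specs()
  coh <- generate_baseline(100000, specs, seed = 61)
  rates <- c(smoke = 0.110, active = 0.05)
  out <- impose_missingness(coh, rates, seed = 62)
  expect_lt(abs(mean(is.na(out$smoke)) - 0.110), 0.005)
  expect_lt(abs(mean(is.na(out$active)) - 0.05), 0.005)
  # complete-case count agrees with direct enumeration of complete rows
  expect_equal(sum(stats::complete.cases(out[, c("smoke", "active")])),
               sum(!is.na(out$smoke) & !is.na(out$active)))
  expect_lt(abs(mean(stats::complete.cases(out[, c("smoke", "active")])) -
                  prod(1 - rates)), 0.006)
  expect_identical(impose_missingness(coh, c(smoke = 0), seed = 1), coh)
})

test_that("weights invert the sampling design and normalize to mean one", {
  specs <- tiny_specs()
  coh <- generate_baseline(50000, specs, seed = 71)
  shares <- c(city = 0.64, rural = 0.26, remote = 0.10)
  equal <- assign_weights(coh, shares, c(city = 1, rural = 1, remote = 1),
                          seed = 72)
  expect_true(all(equal$weight == 1))
  over <- assign_weights(coh, shares, c(city = 1, rural = 2, remote = 2),
                         seed = 73)
  w_city <- unique(over$weight[over$area_stratum == "city"])
  w_rural <- unique(over$weight[over$area_stratum == "rural"])
  expect_equal(w_rural / w_city, 0.5, tolerance = 1e-12)
  expect_equal(mean(over$weight), 1, tolerance = 1e-12)
  # weighted stratum shares recover the population composition
  for (s in names(shares)) {
    est <- weighted_prevalence(as.integer(over$area_stratum == s),
                               over$weight)
    expect_lt(abs(est - shares[[s]]), 0.01)
  }
  expect_error(assign_weights(coh, shares,
                              c(city = 0, rural = 1, remote = 1), seed = 1),
               "positive")
})

test_that("the end-to-end generator is deterministic under a fixed seed", {
  a <- simulate_alswh_cohort(n = 1500, seed = 81)
  b <- simulate_alswh_cohort(n = 1500, seed = 81)
  expect_identical(a, b)
  c <- simulate_alswh_cohort(n = 1500, seed = 82)
  expect_false(identical(a, c))
  expect_true(all(c("area_stratum", "weight", "status_s5") %in% names(a)))
})
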