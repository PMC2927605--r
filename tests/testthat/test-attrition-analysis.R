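# Attrition accounting and the multinomial logistic attrition model.

test_that("attrition accounting uses the initial denominator and sums to one", {
  coh <- make_binary_cohort(400)
  coh$status_s2 <- coh$status_s3 <- coh$status_s4 <-
    factor("respondent", levels = c("respondent", "dead", "frail",
                                    "withdrawn", "lost"))
  tab <- attrition_table(coh)
  expect_equal(rowSums(tab[, c("respondent", "dead", "frail", "withdrawn",
                               "lost")]),
               rep(1, nrow(tab)), ignore_attr = TRUE)
  expect_equal(tab$respondent[tab$survey == 2], 1)
  bad <- coh
  levels(bad$status_s2) <- c(levels(bad$status_s2), "deceased")
  bad$status_s2[1] <- "deceased"
  expect_error(attrition_table(bad), "unknown status")
})

test_that("a Table-1-parameterized simulation reproduces the printed rows", {
  rates <- survey_transition_rates(alswh_attrition_marginals())
  coh <- expand_to_surveys(generate_baseline(40000, tiny_specs(), seed = 1),
                           rates, seed = 2)
  tab <- attrition_table(coh)
  ach <- attr(rates, "achieved")
  for (k in seq_len(nrow(tab))) {
    for (s in c("respondent", "dead", "frail", "withdrawn", "lost")) {
      target <- ach[[s]][ach$survey == tab$survey[k]]
      se <- sqrt(max(target * (1 - target), 1e-6) / 40000)
      expect_lt(abs(tab[[s]][k] - target), 4 * se)
    }
  }
})

test_that("complete-case filtering reports missingness and retained fraction", {
  specs <- tiny_specs()
  coh <- generate_baseline(20000, specs, seed = 5)
  rates <- c(smoke = 0.074, active = 0.016)
  coh <- impose_missingness(coh, rates, seed = 6)
  cc <- complete_case_filter(coh, c("smoke", "active"))
  expect_false(anyNA(cc$cohort[, c("smoke", "active")]))
  expect_equal(cc$n_retained + sum(!stats::complete.cases(
    coh[, c("smoke", "active")])), cc$n_initial)
  # MCAR independence: retained fraction near prod(1 - rate)
  expect_lt(abs(cc$retained_fraction - prod(1 - rates)), 0.01)
  # no missingness: identity
  full <- complete_case_filter(generate_baseline(50, specs, seed = 1),
                               c("smoke", "active"))
  expect_equal(full$retained_fraction, 1)
  expect_equal(nrow(full$cohort), 50L)
})

test_that("a cohort losing 3494 of 12432 records retains 71.9 percent", {
  specs <- tiny_specs()
  coh <- generate_baseline(12432, specs, seed = 9)
  coh$smoke[seq_len(3494)] <- NA
  cc <- complete_case_filter(coh, c("smoke", "active"))
  expect_equal(cc$n_retained, 8938L)
  expect_equal(round(100 * cc$retained_fraction, 1), 71.9)
})

test_that("reference categories follow the modal/declared conventions", {
  specs <- alswh_baseline_specs()
  expect_equal(select_reference_category(specs$country_of_birth), "Australia")
  expect_equal(select_reference_category(specs$self_reported_health),
               "Excellent")
  expect_equal(select_reference_category(specs$alcohol), "Low-risk drinker")
  # observed counts override baseline shares for nominal factors
  expect_equal(select_reference_category(
    specs$smoking, counts = c(`Never smoker` = 10, `Ex-smoker` = 90,
                              Smoker = 5)), "Ex-smoker")
  tie <- risk_factor_spec("t", c("a", "b"), c(0.5, 0.5))
  expect_warning(ref <- select_reference_category(tie), "tie")
  expect_equal(ref, "a")
})

test_that("the fitted odds ratio equals the contingency-table oracle", {
  coh <- make_binary_cohort(4000, seed = 5)
  fit <- fit_attrition_model(coh, "exposure", reltol = 1e-14)
  or_cf <- oracle_2x2_or(coh$exposure, coh$status_s5, "dead", "yes")
  or_fit <- fit$or[fit$category == "yes" & fit$outcome == "dead"]
  expect_lt(abs(or_fit - or_cf), 1e-8)
})

test_that("odds-ratio tables satisfy their internal consistency rules", {
  coh <- simulate_alswh_cohort(n = 15000, seed = 17, missingness = FALSE,
                               weights = FALSE)
  fit <- fit_attrition_model(coh, c("smoking", "physical_activity"),
                             specs = alswh_baseline_specs())
  ref <- fit[fit$reference, ]
  expect_true(all(ref$or == 1))
  expect_true(all(is.na(ref$conf_low)))
  est <- fit[!fit$reference, ]
  expect_true(all(est$conf_low <= est$or & est$or <= est$conf_high))
  expect_equal(est$significant, est$conf_low > 1 | est$conf_high < 1)
  # one N and % per category, matching the complete-case table
  per_cat <- unique(fit[, c("factor", "category", "n")])
  expect_equal(sum(per_cat$n[per_cat$factor == "smoking"]), 15000L)
  # log-likelihood at the optimum beats nearby perturbations
  m <- attr(fit, "fit")
  expect_true(m$convergence == 0)
})

test_that("empty factor-by-outcome cells are a named error", {
  coh <- make_binary_cohort(300, seed = 7)
  coh$status_s5[coh$exposure == "yes" & coh$status_s5 == "dead"] <-
    "respondent"
  expect_error(fit_attrition_model(coh, "exposure"),
               "factor 'exposure', category 'yes', outcome 'dead'")
})

test_that("missing factor values must be filtered before fitting", {
  coh <- make_binary_cohort(300, seed = 8)
  coh$exposure[1] <- NA
  expect_error(fit_attrition_model(coh, "exposure"), "complete_case_filter")
})

test_that("a null generator gives near-unit odds ratios at nominal coverage", {
  specs <- tiny_specs()
  cal <- calibrate_intercepts(attrition_model_spec(empty_coefficients()),
                              specs, s5_targets())
  coh <- assign_final_status(generate_baseline(50000, specs, seed = 23),
                             cal, seed = 24)
  fit <- fit_attrition_model(coh, "active")
  est <- fit[!fit$reference, ]
  expect_true(all(est$or > 0.9 & est$or < 1.1))
  expect_lt(mean(est$significant), 0.3)
})

test_that("the retention screen keeps an active factor and drops it from nothing", {
  specs <- tiny_specs()
  cf <- data.frame(factor = "smoke", category = c("ex", "current"),
                   outcome = "dead", log_or = c(log(1.45), log(2.73)))
  cal <- calibrate_intercepts(attrition_model_spec(cf), specs, s5_targets())
  coh <- assign_final_status(generate_baseline(20000, specs, seed = 33),
                             cal, seed = 34)
  sc <- univariate_screen(coh, c("smoke", "active"))
  expect_true("smoke" %in% sc$retained)
  expect_true(sc$univariate[["smoke"]])
  expect_s3_class(sc$fit, "or_table")
  expect_true(all(sc$fit$factor %in% sc$retained))
})
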