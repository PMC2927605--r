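#' Specification of one categorical risk factor
#'
#' @param name Column name of the factor in a cohort table.
#' @param categories Ordered character vector of category labels.
#' @param baseline_probs Baseline category shares, summing to 1.
#' @param reference Reference category used when the factor enters a
#'   regression. For nominal factors it defaults to the modal category; for
#'   ordinal factors it must be declared (the end category with the best
#'   survival, a substantive judgement that is not inferred from data).
#' @param scale `"nominal"` or `"ordinal"`.
#' @param missing_rate Proportion of values blanked completely at random by
#'   [impose_missingness()].
#' @return An object of class `risk_factor_spec`.
#' @export
risk_factor_spec <- function(name, categories, baseline_probs,
                             reference = NULL,
                             scale = c("nominal", "ordinal"),
                             missing_rate = 0) {
  scale <- match.arg(scale)
  stopifnot(is.character(name), length(name) == 1L)
  if (length(categories) != length(baseline_probs)) {
    stop("'categories' and 'baseline_probs' lengths differ", call. = FALSE)
  }
  assert_proportion(baseline_probs, "baseline_probs")
  if (abs(sum(baseline_probs) - 1) > 1e-9) {
    stop(sprintf("baseline_probs for '%s' sum to %.6f, not 1",
                 name, sum(baseline_probs)), call. = FALSE)
  }
  if (anyDuplicated(categories)) {
    stop("duplicate category labels", call. = FALSE)
  }
  if (is.null(reference)) {
    if (scale == "ordinal") {
      stop(sprintf("ordinal factor '%s' needs a declared reference category",
                   name), call. = FALSE)
    }
    reference <- categories[which.max(baseline_probs)]
  }
  if (!reference %in% categories) {
    stop(sprintf("reference '%s' is not a category of '%s'", reference, name),
         call. = FALSE)
  }
  structure(list(name = name, categories = as.character(categories),
                 baseline_probs = as.numeric(baseline_probs),
                 reference = reference, scale = scale,
                 missing_rate = missing_rate),
            class = "risk_factor_spec")
}

#' Multinomial attrition model specification
#'
#' Parameterizes final (Survey 5) attrition status as a multinomial logit
#' over the five outcomes `respondent, dead, frail, withdrawn, lost`, with
#' respondent the reference: for each non-reference outcome the linear
#' predictor is an intercept plus one log odds ratio per non-reference
#' category of each risk factor. The same object is used generatively (to
#' sample statuses) and as ground truth when checking recovery by
#' [fit_attrition_model()].
#'
#' @param coefficients Data frame with columns `factor`, `category`,
#'   `outcome`, `log_or` (log odds ratio vs respondent; reference categories
#'   are implicitly 0 and must not appear).
#' @param intercepts Named numeric over the non-reference outcomes; defaults
#'   to 0 and is usually set by [calibrate_intercepts()].
#' @return An object of class `attrition_model_spec`.
#' @export
attrition_model_spec <- function(coefficients,
                                 intercepts = c(dead = 0, frail = 0,
                                                withdrawn = 0, lost = 0)) {
  need <- c("factor", "category", "outcome", "log_or")
  if (!all(need %in% names(coefficients))) {
    stop("'coefficients' needs columns factor, category, outcome, log_or",
         call. = FALSE)
  }
  bad <- setdiff(unique(coefficients$outcome), ATTRITION_OUTCOMES[-1L])
  if (length(bad)) {
    stop(sprintf("unknown outcome(s) in coefficients: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  non_ref <- ATTRITION_OUTCOMES[-1L]
  if (!all(non_ref %in% names(intercepts))) {
    stop("intercepts must be named over dead, frail, withdrawn, lost",
         call. = FALSE)
  }
  structure(list(outcomes = ATTRITION_OUTCOMES,
                 coefficients = as.data.frame(coefficients)[, need],
                 intercepts = intercepts[non_ref]),
            class = "attrition_model_spec")
}

# Linear predictors (n x 4, columns dead/frail/withdrawn/lost) for the rows
# of `data` under `model`; factors absent from the coefficient table
# contribute nothing, reference categories contribute 0.
attrition_eta <- function(data, model) {
  non_ref <- ATTRITION_OUTCOMES[-1L]
  eta <- matrix(rep(model$intercepts, each = nrow(data)), nrow = nrow(data),
                dimnames = list(NULL, non_ref))
  cf <- model$coefficients
  for (f in unique(cf$factor)) {
    if (!f %in% names(data)) {
      stop(sprintf("model references factor '%s' absent from the cohort", f),
           call. = FALSE)
    }
    vals <- as.character(data[[f]])
    cf_f <- cf[cf$factor == f, ]
    for (o in non_ref) {
      cf_fo <- cf_f[cf_f$outcome == o, ]
      if (!nrow(cf_fo)) next
      idx <- match(vals, cf_fo$category)
      add <- ifelse(is.na(idx), 0, cf_fo$log_or[idx])
      eta[, o] <- eta[, o] + add
    }
  }
  eta
}

# Outcome probabilities (n x 5, respondent first) from linear predictors.
attrition_probs <- function(eta) {
  ex <- cbind(respondent = 1, exp(eta))
  ex / rowSums(ex)
}

#' Draw baseline risk factors for a synthetic cohort
#'
#' Each factor is drawn independently from its baseline category
#' distribution (the joint distribution is the product of the marginals; a
#' dependence structure can be supplied afterwards by transforming the
#' returned table).
#'
#' @param n Number of participants.
#' @param specs List of [risk_factor_spec()] objects.
#' @param seed Integer seed; identical `(n, specs, seed)` give identical
#'   tables.
#' @return A `cohort_table` data frame with `id` and one factor column per
#'   spec.
#' @export
generate_baseline <- function(n, specs, seed = NULL) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1)
  specs <- validate_specs(specs)
  with_seed(seed, {
    out <- data.frame(id = seq_len(n))
    for (s in specs) {
      out[[s$name]] <- factor(
        sample(s$categories, n, replace = TRUE, prob = s$baseline_probs),
        levels = s$categories)
    }
    class(out) <- c("cohort_table", "data.frame")
    out
  })
}

validate_specs <- function(specs) {
  if (inherits(specs, "risk_factor_spec")) specs <- list(specs)
  ok <- vapply(specs, inherits, logical(1L), "risk_factor_spec")
  if (!all(ok)) stop("'specs' must be a list of risk_factor_spec objects",
                     call. = FALSE)
  names(specs) <- vapply(specs, `[[`, character(1L), "name")
  specs
}

# Exact enumeration of the independent baseline joint distribution: one row
# per category combination with its probability. Cell count is the product
# of category counts (3600 for the seven shipped factors).
enumerate_baseline <- function(specs) {
  specs <- validate_specs(specs)
  cats <- lapply(specs, function(s) factor(s$categories, levels = s$categories))
  cells <- expand.grid(cats, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  names(cells) <- names(specs)
  prob <- rep(1, nrow(cells))
  for (s in specs) {
    prob <- prob * s$baseline_probs[as.integer(cells[[s$name]])]
  }
  cells$.prob <- prob
  cells
}

#' Calibrate model intercepts to target outcome marginals
#'
#' Adjusts the four non-reference intercepts of an attrition model so that
#' the expected outcome distribution — taken exactly over the discrete
#' baseline covariate distribution implied by `specs` under independence —
#' matches `targets`. Uses an iterative proportional-fitting style update
#' (each intercept is shifted by the log ratio of target to achieved
#' marginal), which converges quickly for any interior target.
#'
#' With all coefficients zero the solution is the closed form
#' `log(target_k / target_respondent)`.
#'
#' @param model An [attrition_model_spec()].
#' @param specs Baseline risk-factor specs defining the covariate
#'   distribution.
#' @param targets Named (or ordered) proportions over
#'   `respondent, dead, frail, withdrawn, lost`, summing to 1 and strictly
#'   inside the simplex.
#' @param tol Convergence tolerance on the largest marginal discrepancy.
#' @param max_iter Iteration cap; non-convergence is an error reporting the
#'   achieved marginals.
#' @return The model with calibrated intercepts; the achieved expected
#'   marginals are attached as attribute `"achieved"`.
#' @export
calibrate_intercepts <- function(model, specs, targets, tol = 1e-6,
                                 max_iter = 500L) {
  stopifnot(inherits(model, "attrition_model_spec"))
  if (is.null(names(targets))) names(targets) <- ATTRITION_OUTCOMES
  targets <- targets[ATTRITION_OUTCOMES]
  if (anyNA(targets) || abs(sum(targets) - 1) > 1e-6) {
    stop("'targets' must cover the five outcomes and sum to 1", call. = FALSE)
  }
  if (any(targets <= 0) || any(targets >= 1)) {
    stop("degenerate target marginals: all five must be strictly between 0 and 1",
         call. = FALSE)
  }
  cells <- enumerate_baseline(specs)
  w <- cells$.prob
  eta0 <- attrition_eta(cells, model) -
    matrix(rep(model$intercepts, each = nrow(cells)), nrow = nrow(cells))
  alpha <- model$intercepts
  non_ref <- ATTRITION_OUTCOMES[-1L]
  for (it in seq_len(max_iter)) {
    pr <- attrition_probs(sweep(eta0, 2L, -alpha))
    achieved <- colSums(w * pr)
    if (max(abs(achieved - targets)) < tol) {
      model$intercepts <- alpha
      out <- model
      attr(out, "achieved") <- achieved
      attr(out, "iterations") <- it
      return(out)
    }
    alpha <- alpha + log(targets[non_ref] / achieved[non_ref])
  }
  stop(sprintf(
    "intercept calibration did not converge in %d iterations; achieved marginals: %s",
    max_iter, paste(sprintf("%s=%.5f", names(achieved), achieved),
                    collapse = ", ")), call. = FALSE)
}

#' Assign final (Survey 5) attrition status
#'
#' Samples one five-category status per participant from the multinomial
#' logit defined by `model`, evaluated at the participant's baseline risk
#' factors. Participants must have complete data on every factor the model
#' references.
#'
#' @param cohort A `cohort_table` from [generate_baseline()].
#' @param model An [attrition_model_spec()], usually calibrated.
#' @param seed Integer seed.
#' @return The cohort with a `status_s5` factor column added.
#' @export
assign_final_status <- function(cohort, model, seed = NULL) {
  stopifnot(inherits(model, "attrition_model_spec"))
  used <- unique(model$coefficients$factor)
  miss <- used[vapply(used, function(f) anyNA(cohort[[f]]), logical(1L))]
  if (length(miss)) {
    stop(sprintf("missing values in model factor(s): %s (assign status before imposing missingness)",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  bad <- character(0)
  for (f in used) {
    obs <- unique(as.character(cohort[[f]]))
    unknown <- setdiff(unique(model$coefficients$category[
      model$coefficients$factor == f]), c(obs, levels(cohort[[f]])))
    if (length(unknown)) bad <- c(bad, sprintf("%s: %s", f,
                                               paste(unknown, collapse = "/")))
  }
  if (length(bad)) {
    stop(sprintf("coefficients reference unknown categories — %s",
                 paste(bad, collapse = "; ")), call. = FALSE)
  }
  pr <- attrition_probs(attrition_eta(cohort, model))
  with_seed(seed, {
    idx <- sample_rowwise(pr)
    cohort$status_s5 <- factor(ATTRITION_OUTCOMES[idx],
                               levels = ATTRITION_OUTCOMES)
    cohort
  })
}

#' Per-interval transition rates from cumulative attrition marginals
#'
#' Converts a table of cumulative five-category attrition proportions per
#' survey into conditional per-interval transition probabilities (the
#' chance that a still-responding participant enters each absorbing state
#' between consecutive surveys). Rows are renormalized to sum to 1 before
#' use (printed tables carry rounding error). All four non-respondent
#' states are treated as absorbing; if a cumulative share dips between
#' surveys (possible for loss to follow up, where real cohorts allow
#' return) the interval increment is clamped to 0 and the achieved
#' cumulative table — attached as attribute `"achieved"` — deviates from
#' the input at that survey while later targets are still hit exactly.
#'
#' @param marginals Data frame with columns `survey` (2..5, increasing) and
#'   `respondent`, `dead`, `frail`, `withdrawn`, `lost` proportions.
#' @return Data frame of per-interval conditional probabilities with
#'   columns `survey`, `dead`, `frail`, `withdrawn`, `lost`.
#' @export
survey_transition_rates <- function(marginals) {
  states <- ATTRITION_OUTCOMES[-1L]
  need <- c("survey", "respondent", states)
  if (!all(need %in% names(marginals))) {
    stop("marginals need columns survey, respondent, dead, frail, withdrawn, lost",
         call. = FALSE)
  }
  marginals <- marginals[order(marginals$survey), ]
  m <- as.matrix(marginals[, c("respondent", states)])
  m <- m / rowSums(m)
  ach <- c(respondent = 1, dead = 0, frail = 0, withdrawn = 0, lost = 0)
  out <- marginals["survey"]
  achieved <- matrix(NA_real_, nrow(m), 5L,
                     dimnames = list(NULL, names(ach)))
  for (k in seq_len(nrow(m))) {
    inc <- pmax(0, m[k, states] - ach[states])
    if (sum(inc) > ach[["respondent"]] + 1e-12) {
      stop(sprintf("survey %d: cumulative increments exceed remaining respondents",
                   marginals$survey[k]), call. = FALSE)
    }
    h <- inc / ach[["respondent"]]
    out[k, states] <- h
    ach[states] <- ach[states] + inc
    ach[["respondent"]] <- 1 - sum(ach[states])
    achieved[k, ] <- ach
  }
  attr(out, "achieved") <- cbind(survey = marginals$survey,
                                 as.data.frame(achieved))
  out
}

#' Expand a cohort across surveys 2..5
#'
#' Fills the wave-by-wave status columns `status_s2 .. status_s5`. Two
#' modes:
#' \itemize{
#'   \item If the cohort has no `status_s5` column, statuses are simulated
#'     forward: at each survey a still-responding participant enters each
#'     absorbing state with the interval rates in `rates`.
#'   \item If `status_s5` is already present (from
#'     [assign_final_status()]), it is honoured: only the *timing* of each
#'     participant's exit is drawn, with interval probabilities
#'     proportional to the unconditional entry probabilities implied by
#'     `rates`. Survey-5 status is unchanged.
#' }
#' All four non-respondent states are absorbing.
#'
#' @param cohort A `cohort_table`.
#' @param rates Output of [survey_transition_rates()].
#' @param seed Integer seed.
#' @return The cohort with `status_s2 .. status_s5` factor columns.
#' @export
expand_to_surveys <- function(cohort, rates, seed = NULL) {
  states <- ATTRITION_OUTCOMES[-1L]
  if (!all(c("survey", states) %in% names(rates))) {
    stop("'rates' must come from survey_transition_rates()", call. = FALSE)
  }
  hmat <- as.matrix(rates[, states])
  if (any(hmat < 0) || any(rowSums(hmat) > 1 + 1e-9)) {
    stop("interval transition rows must be non-negative with total <= 1",
         call. = FALSE)
  }
  n <- nrow(cohort)
  n_int <- nrow(hmat)
  with_seed(seed, {
    if (is.null(cohort$status_s5)) {
      state <- rep.int(1L, n)                       # 1 = respondent
      for (k in seq_len(n_int)) {
        resp <- state == 1L
        if (any(resp)) {
          pr <- matrix(rep(c(1 - sum(hmat[k, ]), hmat[k, ]),
                           each = sum(resp)), nrow = sum(resp))
          state[resp] <- sample_rowwise(pr)
        }
        cohort[[paste0("status_s", k + 1L)]] <-
          factor(ATTRITION_OUTCOMES[state], levels = ATTRITION_OUTCOMES)
      }
    } else {
      final <- as.character(cohort$status_s5)
      # unconditional probability of entering state s in interval k:
      # rate times share still responding at the interval's start
      resp_before <- c(1, attr(rates, "achieved")$respondent[-n_int])
      if (is.null(resp_before)) resp_before <- rep(1, n_int)
      exit_int <- rep.int(n_int + 1L, n)            # respondents never exit
      for (s in states) {
        rows <- which(final == s)
        if (!length(rows)) next
        q <- hmat[, s] * resp_before
        if (sum(q) <= 0) q <- rep(1, n_int)         # timing uninformative
        exit_int[rows] <- sample.int(n_int, length(rows), replace = TRUE,
                                     prob = q / sum(q))
      }
      for (k in seq_len(n_int)) {
        st <- ifelse(exit_int > k, "respondent", final)
        cohort[[paste0("status_s", k + 1L)]] <-
          factor(st, levels = ATTRITION_OUTCOMES)
      }
    }
    cohort
  })
}

#' Blank risk-factor values completely at random
#'
#' Emulates item non-response at Survey 1: each listed factor is set to
#' missing independently at its rate. Statuses and weights are untouched.
#'
#' @param cohort A `cohort_table`.
#' @param rates Named proportions in `[0, 1)`, one per factor column.
#' @param seed Integer seed.
#' @return The cohort with `NA`s introduced.
#' @export
impose_missingness <- function(cohort, rates, seed = NULL) {
  if (is.null(names(rates)) || !all(names(rates) %in% names(cohort))) {
    stop("'rates' must be named after cohort factor columns", call. = FALSE)
  }
  assert_proportion(unname(rates), "rates", open_upper = TRUE)
  with_seed(seed, {
    for (f in names(rates)) {
      if (rates[[f]] <= 0) next
      cohort[[f]][runif(nrow(cohort)) < rates[[f]]] <- NA
    }
    cohort
  })
}

#' Assign area strata and sampling weights
#'
#' Emulates a design that over-samples rural and remote areas: each
#' participant is assigned a stratum with probability proportional to
#' `population_shares * sampling_factors` (the composition of the drawn
#' sample), and receives weight proportional to the inverse sampling
#' factor, normalized to mean 1. Weighted stratum shares then estimate the
#' population shares.
#'
#' @param cohort A `cohort_table`.
#' @param population_shares Named population proportions per stratum.
#' @param sampling_factors Relative sampling rates per stratum (same names);
#'   equal factors give all weights 1.
#' @param seed Integer seed.
#' @return The cohort with `area_stratum` and `weight` columns.
#' @export
assign_weights <- function(cohort, population_shares, sampling_factors,
                           seed = NULL) {
  if (is.null(names(population_shares)) ||
      !identical(sort(names(population_shares)), sort(names(sampling_factors)))) {
    stop("'population_shares' and 'sampling_factors' must share stratum names",
         call. = FALSE)
  }
  assert_positive(unname(sampling_factors), "sampling_factors")
  assert_proportion(unname(population_shares), "population_shares")
  if (abs(sum(population_shares) - 1) > 1e-9) {
    stop("population shares must sum to 1", call. = FALSE)
  }
  sampling_factors <- sampling_factors[names(population_shares)]
  q <- population_shares * sampling_factors
  q <- q / sum(q)
  with_seed(seed, {
    strata <- sample(names(q), nrow(cohort), replace = TRUE, prob = q)
    w_raw <- 1 / sampling_factors[strata]
    cohort$area_stratum <- factor(strata, levels = names(q))
    cohort$weight <- as.numeric(w_raw / mean(w_raw))
    cohort
  })
}

#' Simulate a complete ALSWH-like cohort
#'
#' End-to-end generator: baseline risk factors, Survey-5 status from the
#' shipped odds-ratio structure with intercepts calibrated to the shipped
#' Survey-5 attrition marginals, wave-by-wave expansion honouring the final
#' status, area strata with sampling weights, and item missingness.
#'
#' @param n Cohort size; the default is the size of the emulated cohort of
#'   women born 1921-26 at its 1996 baseline.
#' @param seed Integer seed (required: the generator is stochastic).
#' @param specs,model,marginals Override the shipped baseline specs,
#'   coefficient structure and cumulative attrition marginals.
#' @param missingness,weights Logical switches for the two optional stages.
#' @return A `cohort_table` with factors, `area_stratum`, `weight` and
#'   `status_s2 .. status_s5`.
#' @examples
#' coh <- simulate_alswh_cohort(n = 2000, seed = 42)
#' table(coh$status_s5)
#' @export
simulate_alswh_cohort <- function(n = 12432, seed,
                                  specs = alswh_baseline_specs(),
                                  model = NULL,
                                  marginals = alswh_attrition_marginals(),
                                  missingness = TRUE, weights = TRUE) {
  specs <- validate_specs(specs)
  if (is.null(model)) {
    targets <- as.numeric(marginals[marginals$survey == 5,
                                    ATTRITION_OUTCOMES])
    targets <- targets / sum(targets)
    model <- calibrate_intercepts(attrition_model_spec(alswh_coefficients()),
                                  specs, setNames(targets, ATTRITION_OUTCOMES))
  }
  with_seed(seed, {
    coh <- generate_baseline(n, specs)
    coh <- assign_final_status(coh, model)
    coh <- expand_to_surveys(coh, survey_transition_rates(marginals))
    if (weights) {
      st <- alswh_strata()
      coh <- assign_weights(coh, st$population_shares, st$sampling_factors)
    }
    if (missingness) {
      rates <- vapply(specs, `[[`, numeric(1L), "missing_rate")
      coh <- impose_missingness(coh, rates[rates > 0])
    }
    coh
  })
}
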