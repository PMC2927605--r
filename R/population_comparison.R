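#' External population prevalence series
#'
#' A prevalence series for one dichotomized risk factor at successive
#' calendar time points, from an external source (census, health survey) or
#' synthetic.
#'
#' @param label Series identifier (e.g. `"non_english_cob"`).
#' @param time Calendar time labels (e.g. `"1996"`, `"2001/2"`), in order,
#'   without duplicates within a label.
#' @param prevalence Proportions in `[0, 1]`.
#' @param source One of `"census"`, `"health-survey"`, `"cohort"`,
#'   `"synthetic"` per row.
#' @return A `population_series` data frame.
#' @export
population_series <- function(label, time, prevalence,
                              source = "synthetic") {
  assert_proportion(prevalence, "prevalence")
  out <- data.frame(label = as.character(label), time = as.character(time),
                    prevalence = as.numeric(prevalence),
                    source = as.character(source))
  bad <- setdiff(unique(out$source),
                 c("census", "health-survey", "cohort", "synthetic"))
  if (length(bad)) {
    stop(sprintf("unknown source tag(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  dup <- tapply(out$time, out$label, anyDuplicated)
  if (any(unlist(dup) > 0)) {
    stop("duplicated time points within a series", call. = FALSE)
  }
  class(out) <- c("population_series", "data.frame")
  out
}

#' Survey-weighted prevalence of a binary indicator
#'
#' Computes `sum(w * x) / sum(w)` over records with a non-missing
#' indicator; records with missing `x` are excluded from numerator and
#' denominator. Invariant to rescaling all weights by a positive constant.
#'
#' @param x Binary indicator (0/1, logical, or a two-level factor is not
#'   accepted — dichotomize first).
#' @param weights Positive sampling weights; default equal (unweighted
#'   mean).
#' @return A proportion.
#' @export
weighted_prevalence <- function(x, weights = NULL) {
  if (is.logical(x)) x <- as.integer(x)
  if (!is.numeric(x) || !all(x %in% c(0, 1, NA))) {
    stop("'x' must be a 0/1 indicator (use dichotomize() first)",
         call. = FALSE)
  }
  if (is.null(weights)) weights <- rep(1, length(x))
  if (length(weights) != length(x)) {
    stop("'x' and 'weights' lengths differ", call. = FALSE)
  }
  assert_positive(weights, "weights")
  keep <- !is.na(x)
  if (!any(keep)) stop("all indicator values are missing", call. = FALSE)
  sum(weights[keep] * x[keep]) / sum(weights[keep])
}

#' Dichotomize a categorical risk factor
#'
#' Collapses a multi-category factor to a 0/1 indicator: 1 for categories
#' in the positive set, 0 otherwise; missing stays missing. Every observed
#' category must be covered by `positive` together with `negative` (for
#' factors, the remaining levels are taken as negative automatically).
#'
#' The two published collapsings are available by name via
#' [dichotomy_rules()]: non-English speaking country of birth
#' (`"Other"` vs the rest) and current-or-ex smoking.
#'
#' @param values Factor or character vector of categories.
#' @param positive Categories mapped to 1.
#' @param negative Categories mapped to 0; defaults to the remaining factor
#'   levels.
#' @return Integer 0/1 vector with `NA` preserved.
#' @export
dichotomize <- function(values, positive, negative = NULL) {
  vals <- as.character(values)
  if (is.null(negative)) {
    if (is.factor(values)) negative <- setdiff(levels(values), positive)
    else negative <- setdiff(unique(vals[!is.na(vals)]), positive)
  }
  unmapped <- setdiff(unique(vals[!is.na(vals)]), c(positive, negative))
  if (length(unmapped)) {
    stop(sprintf("unmapped categor%s: %s",
                 if (length(unmapped) > 1) "ies" else "y",
                 paste(unmapped, collapse = ", ")), call. = FALSE)
  }
  out <- ifelse(is.na(vals), NA_integer_, as.integer(vals %in% positive))
  out
}

#' Named dichotomization rules
#'
#' @return A named list of `positive` category sets, keyed by series label.
#' @export
dichotomy_rules <- function() {
  list(non_english_cob = list(factor = "country_of_birth",
                              positive = "Other"),
       current_or_ex_smoker = list(factor = "smoking",
                                   positive = c("Smoker", "Ex-smoker")))
}

#' Signed bias between population and cohort prevalence series
#'
#' Aligns a cohort prevalence series with an external population series on
#' identical time labels and returns the signed bias
#' `population - cohort` per time point: positive bias means the cohort
#' under-represents the risk factor, negative means over-representation.
#'
#' @param cohort Data frame with columns `time` and `prevalence` (e.g. a
#'   `population_series` with source `"cohort"`), or a numeric vector of
#'   prevalences in the population series' time order.
#' @param population A [population_series()].
#' @param time_map Optional named character vector mapping cohort time
#'   labels to population time labels when calendars differ (e.g.
#'   `c("1995" = "1995/6")`); alignment is exact, never fuzzy.
#' @return A `bias_series` data frame with columns `time`, `p_pop`,
#'   `p_cohort`, `bias`, `direction`.
#' @export
bias_series <- function(cohort, population, time_map = NULL) {
  if (!inherits(population, "population_series") &&
      !all(c("time", "prevalence") %in% names(population))) {
    stop("'population' must be a population_series", call. = FALSE)
  }
  if (is.numeric(cohort)) {
    if (length(cohort) != nrow(population)) {
      stop("cohort prevalence vector length differs from population series",
           call. = FALSE)
    }
    cohort <- data.frame(time = population$time, prevalence = cohort)
  }
  if (!all(c("time", "prevalence") %in% names(cohort))) {
    stop("'cohort' needs columns time and prevalence", call. = FALSE)
  }
  ctime <- as.character(cohort$time)
  if (!is.null(time_map)) {
    hit <- ctime %in% names(time_map)
    ctime[hit] <- time_map[ctime[hit]]
  }
  if (!identical(sort(ctime), sort(as.character(population$time)))) {
    stop(sprintf("time axes differ after mapping: cohort {%s} vs population {%s}",
                 paste(ctime, collapse = ", "),
                 paste(population$time, collapse = ", ")), call. = FALSE)
  }
  idx <- match(as.character(population$time), ctime)
  out <- data.frame(time = as.character(population$time),
                    p_pop = population$prevalence,
                    p_cohort = cohort$prevalence[idx])
  out$bias <- out$p_pop - out$p_cohort
  out$direction <- ifelse(out$bias > 0, "under-representation",
                          ifelse(out$bias < 0, "over-representation",
                                 "none"))
  class(out) <- c("bias_series", "data.frame")
  out
}

#' @export
print.bias_series <- function(x, digits = 3, ...) {
  cat("Cohort-vs-population prevalence bias (population - cohort)\n")
  print.data.frame(cbind(x[, c("time", "p_pop", "p_cohort")],
                         bias = round(x$bias, digits),
                         direction = x$direction), row.names = FALSE)
  d <- abs(x$bias)
  trend <- if (all(diff(d) > 0)) "increasing" else if (all(diff(d) < 0))
    "decreasing" else "non-monotone"
  cat(sprintf("|bias| trend across %d time points: %s\n", nrow(x), trend))
  invisible(x)
}

#' Weighted cohort prevalence of a dichotomized factor by survey
#'
#' For each requested survey, restricts to participants still responding
#' at that survey, dichotomizes their baseline factor values and returns
#' the (optionally weighted) prevalence. Baseline values are used
#' throughout: the factor is treated as fixed at the individual level.
#'
#' @param cohort A `cohort_table` with status columns.
#' @param factor Factor column name.
#' @param positive Categories counted as exposed (see [dichotomize()]).
#' @param surveys Integer surveys to evaluate (subset of 2:5); survey 1 is
#'   the whole cohort.
#' @param weighted Use the `weight` column if present.
#' @return Data frame with columns `survey`, `n_respondents`, `prevalence`.
#' @export
cohort_prevalence_by_survey <- function(cohort, factor, positive,
                                        surveys = c(1L, 2:5),
                                        weighted = TRUE) {
  x_all <- dichotomize(cohort[[factor]], positive)
  w_all <- if (weighted && !is.null(cohort$weight)) cohort$weight
           else rep(1, nrow(cohort))
  rows <- lapply(surveys, function(s) {
    keep <- if (s == 1L) rep(TRUE, nrow(cohort))
            else cohort[[paste0("status_s", s)]] == "respondent"
    data.frame(survey = s, n_respondents = sum(keep),
               prevalence = weighted_prevalence(x_all[keep], w_all[keep]))
  })
  do.call(rbind, rows)
}
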