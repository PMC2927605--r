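extdata <- function(file) {
  path <- system.file("extdata", file, package = "cohortdrift")
  if (path == "") stop(sprintf("shipped data file '%s' not found", file),
                       call. = FALSE)
  path
}

#' Shipped baseline risk-factor specifications
#'
#' The seven Survey-1 risk factors of the emulated cohort of women born
#' 1921-26 — country of birth, highest qualification, BMI class, physical
#' activity, alcohol consumption, smoking status and self-reported health —
#' with their complete-case category shares, reference categories and item
#' missingness rates.
#'
#' @return Named list of [risk_factor_spec()] objects.
#' @export
alswh_baseline_specs <- function() {
  cfg <- yaml::read_yaml(extdata("baseline_specs.yaml"))
  specs <- lapply(cfg$factors, function(f) {
    risk_factor_spec(name = f$name,
                     categories = names(f$categories),
                     baseline_probs = unlist(f$categories),
                     reference = f$reference, scale = f$scale,
                     missing_rate = f$missing_rate)
  })
  names(specs) <- vapply(specs, `[[`, character(1L), "name")
  specs
}

#' Shipped stratum design
#'
#' City/rural/remote population shares and relative sampling rates used to
#' emulate intentional over-sampling of rural and remote areas.
#'
#' @return List with `population_shares` and `sampling_factors`, both named.
#' @export
alswh_strata <- function() {
  st <- yaml::read_yaml(extdata("baseline_specs.yaml"))$strata
  list(population_shares = setNames(unlist(st$population_shares), st$labels),
       sampling_factors = setNames(unlist(st$sampling_factors), st$labels))
}

#' Shipped cumulative attrition marginals by survey
#'
#' Five-category attrition proportions (respondent, dead, frail, withdrawn,
#' lost to follow up) at Surveys 2-5 of the emulated cohort, relative to
#' the Survey-1 sample.
#'
#' @return Data frame with columns `survey`, `respondent`, `dead`, `frail`,
#'   `withdrawn`, `lost`.
#' @export
alswh_attrition_marginals <- function() {
  read.csv(extdata("table1_attrition.csv"))
}

#' Shipped attrition odds-ratio table
#'
#' Published-style odds ratios (with 95% confidence limits) of each
#' attrition outcome vs continued response at Survey 5, for every
#' non-reference risk-factor category.
#'
#' @return Data frame with columns `factor`, `category`, `outcome`, `or`,
#'   `lcl`, `ucl`.
#' @export
alswh_odds_ratios <- function() {
  read.csv(extdata("table2_odds_ratios.csv"), check.names = FALSE)
}

#' Shipped generator coefficients (log odds ratios)
#'
#' The odds-ratio table of [alswh_odds_ratios()] on the log scale, in the
#' shape [attrition_model_spec()] expects.
#'
#' @return Data frame with columns `factor`, `category`, `outcome`,
#'   `log_or`.
#' @export
alswh_coefficients <- function() {
  tab <- alswh_odds_ratios()
  data.frame(factor = tab$factor, category = tab$category,
             outcome = tab$outcome, log_or = log(tab$or))
}

#' Shipped external population prevalence series
#'
#' Census prevalences of a non-English speaking country of birth (1996,
#' 2001/2, 2005/6) and National Health Survey prevalences of current or
#' ex-smoking (1995/6, 2005) for Australian women born 1921-26.
#'
#' @param label Optional filter (`"non_english_cob"` or
#'   `"current_or_ex_smoker"`).
#' @return A `population_series` data frame (see [population_series()]).
#' @export
alswh_population_series <- function(label = NULL) {
  tab <- read.csv(extdata("population_series.csv"))
  if (!is.null(label)) tab <- tab[tab$label == label, ]
  population_series(tab$label, tab$time, tab$prevalence, tab$source)
}

#' Shipped weighted cohort prevalence series
#'
#' The published survey-weighted cohort prevalences matching
#' [alswh_population_series()]: non-English speaking country of birth and
#' current-or-ex smoking among respondents at successive waves.
#'
#' @param label Optional filter as in [alswh_population_series()].
#' @return A `population_series` data frame with source `"cohort"`.
#' @export
alswh_cohort_prevalences <- function(label = NULL) {
  tab <- read.csv(extdata("alswh_cohort_prevalence.csv"))
  if (!is.null(label)) tab <- tab[tab$label == label, ]
  population_series(tab$label, tab$time, tab$prevalence, tab$source)
}
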