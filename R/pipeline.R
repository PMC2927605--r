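#' Run the full workflow from one configuration
#'
#' Executes any subset of the stages `scenario` (hypothetical prevalence
#' trajectories), `simulate` (synthetic cohort generation), `analyze`
#' (attrition table + multinomial odds ratios) and `compare` (weighted
#' prevalence vs an external population series), writing every output as
#' CSV plus a machine-readable run manifest. Identical configuration and
#' seed give byte-identical numeric outputs. A stage failure aborts the
#' run, removes that stage's partial outputs, and names the stage.
#'
#' @param config A named list, or the path of a YAML/JSON file holding
#'   one. Recognized top-level keys: `seed` (required when `simulate` is
#'   present), `out_dir`, and the stage subsections:
#'   \describe{
#'     \item{scenario}{`names`: canonical scenario keys (default all
#'       eight), or `config`: path of a single scenario file.}
#'     \item{simulate}{`n` (default 12432); missingness/weights switches.}
#'     \item{analyze}{`factors` (default: all shipped factors); `screen`
#'       logical (apply the retention screen, default `FALSE`).}
#'     \item{compare}{`label`: series label from [dichotomy_rules()];
#'       `population`: optional CSV path (defaults to the shipped series).}
#'   }
#' @param out_dir Output directory; overrides `config$out_dir`; default
#'   `"."`.
#' @return Invisibly, a list with the written file paths and the in-memory
#'   stage results.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  config_path <- NULL
  if (is.character(config) && length(config) == 1L) {
    config_path <- config
    config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else yaml::read_yaml(config)
  }
  if (is.null(out_dir)) out_dir <- config$out_dir %||% "."
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  results <- list()
  files <- character(0)

  run_stage <- function(stage, outputs, fn) {
    paths <- file.path(out_dir, outputs)
    tryCatch(fn(paths), error = function(e) {
      unlink(paths[file.exists(paths)])
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE)
    })
    files <<- c(files, paths)
    invisible(NULL)
  }

  if (!is.null(config$scenario)) {
    sc <- config$scenario
    params <- if (!is.null(sc$config)) {
      p <- list(read_scenario_config(sc$config))
      names(p) <- tools::file_path_sans_ext(basename(sc$config))
      p
    } else {
      all <- canonical_scenarios()
      all[intersect(sc$names %||% names(all), names(all))]
    }
    run_stage("scenario", sprintf("trajectory_%s.csv", names(params)),
              function(paths) {
      results$scenario <<- lapply(params, run_scenario)
      for (i in seq_along(paths)) {
        write_trajectory_csv(results$scenario[[i]], paths[i])
      }
    })
  }

  if (!is.null(config$simulate)) {
    if (is.null(seed)) stop("'seed' is required for the simulate stage",
                            call. = FALSE)
    sim <- config$simulate
    run_stage("simulate", "cohort.csv", function(paths) {
      results$cohort <<- simulate_alswh_cohort(
        n = sim$n %||% 12432, seed = seed,
        missingness = sim$missingness %||% TRUE,
        weights = sim$weights %||% TRUE)
      write_cohort_csv(results$cohort, paths)
    })
  }

  if (!is.null(config$analyze)) {
    an <- config$analyze
    specs <- alswh_baseline_specs()
    factors <- an$factors %||% names(specs)
    run_stage("analyze", c("attrition_table.csv", "or_table.csv"),
              function(paths) {
      cohort <- results$cohort %||% read_cohort_csv(an$cohort, specs = specs)
      results$attrition <<- attrition_table(cohort)
      write.csv(as.data.frame(results$attrition), paths[1L],
                row.names = FALSE)
      cc <- complete_case_filter(cohort, factors)
      results$or_table <<- if (isTRUE(an$screen)) {
        univariate_screen(cc$cohort, factors, specs = specs)$fit
      } else {
        fit_attrition_model(cc$cohort, factors, specs = specs)
      }
      tab <- as.data.frame(results$or_table)
      write.csv(tab, paths[2L], row.names = FALSE)
    })
  }

  if (!is.null(config$compare)) {
    cmp <- config$compare
    label <- cmp$label %||% "non_english_cob"
    rule <- dichotomy_rules()[[label]]
    if (is.null(rule)) stop(sprintf("no dichotomization rule for '%s'", label),
                            call. = FALSE)
    run_stage("compare", sprintf("bias_%s.csv", label), function(paths) {
      pop <- if (!is.null(cmp$population)) {
        tab <- read.csv(cmp$population)
        population_series(tab$label, tab$time, tab$prevalence, tab$source)
      } else alswh_population_series(label)
      cohort <- results$cohort %||%
        read_cohort_csv(cmp$cohort, specs = alswh_baseline_specs())
      prev <- cohort_prevalence_by_survey(cohort, rule$factor, rule$positive,
                                          surveys = cmp$surveys %||%
                                            c(1L, 3L, 5L))
      if (nrow(prev) != nrow(pop)) {
        stop(sprintf("%d cohort waves vs %d population time points",
                     nrow(prev), nrow(pop)))
      }
      results$bias <<- bias_series(
        data.frame(time = pop$time, prevalence = prev$prevalence), pop)
      write.csv(as.data.frame(results$bias), paths, row.names = FALSE)
    })
  }

  manifest <- list(
    package = "cohortdrift",
    version = as.character(packageVersion("cohortdrift")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = seed,
    config = config,
    outputs = as.list(setNames(unname(tools::md5sum(files)),
                               basename(files))))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(list(files = c(files, manifest_path), results = results))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
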