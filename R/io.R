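#' Write a cohort table to CSV
#'
#' Schema: `id`, one column per risk factor, optionally `area_stratum` and
#' `weight`, then `status_s2 .. status_s5`. Missing values are written as
#' empty fields.
#'
#' @param cohort A `cohort_table`.
#' @param path Output path.
#' @export
write_cohort_csv <- function(cohort, path) {
  write.csv(as.data.frame(cohort), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a cohort table from CSV
#'
#' Validates the schema and vocabulary: an `id` column must exist, status
#' columns may only hold the five attrition labels, and — when `specs` are
#' supplied — factor columns may only hold declared categories. Empty
#' fields become real missing values, never sentinel strings. Violations
#' are reported with 1-based data line numbers (header excluded).
#'
#' @param path CSV path.
#' @param specs Optional named list of [risk_factor_spec()]; matching
#'   columns are converted to factors with the declared level order.
#' @return A `cohort_table` data frame.
#' @export
read_cohort_csv <- function(path, specs = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  raw <- read.csv(path, colClasses = "character", check.names = FALSE,
                  na.strings = "")
  if (nrow(raw) == 0L) {
    stop(sprintf("empty cohort file: %s", path), call. = FALSE)
  }
  if (!"id" %in% names(raw)) {
    stop("cohort file lacks an 'id' column", call. = FALSE)
  }
  for (col in intersect(STATUS_COLUMNS, names(raw))) {
    vals <- raw[[col]]
    bad <- which(!is.na(vals) & !vals %in% ATTRITION_OUTCOMES)
    if (length(bad)) {
      stop(sprintf("invalid status in column %s, line %d: '%s' (allowed: %s)",
                   col, bad[1L], vals[bad[1L]],
                   paste(ATTRITION_OUTCOMES, collapse = ", ")),
           call. = FALSE)
    }
    raw[[col]] <- factor(vals, levels = ATTRITION_OUTCOMES)
  }
  if (!is.null(specs)) {
    specs <- validate_specs(specs)
    for (s in specs) {
      if (!s$name %in% names(raw)) next
      vals <- raw[[s$name]]
      bad <- which(!is.na(vals) & !vals %in% s$categories)
      if (length(bad)) {
        stop(sprintf("unknown category in column %s, line %d: '%s'",
                     s$name, bad[1L], vals[bad[1L]]), call. = FALSE)
      }
      raw[[s$name]] <- factor(vals, levels = s$categories)
    }
  }
  raw$id <- as.integer(raw$id)
  if ("weight" %in% names(raw)) {
    raw$weight <- as.numeric(raw$weight)
    if (any(!is.na(raw$weight) & raw$weight <= 0)) {
      stop("non-positive sampling weights in cohort file", call. = FALSE)
    }
  }
  if ("area_stratum" %in% names(raw)) {
    raw$area_stratum <- factor(raw$area_stratum)
  }
  class(raw) <- c("cohort_table", "data.frame")
  raw
}

#' Read a scenario configuration file
#'
#' YAML or JSON with keys matching the [scenario_params()] arguments.
#'
#' @param path Config path (`.yaml`/`.yml`/`.json`).
#' @return A [scenario_params()] object.
#' @export
read_scenario_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  allowed <- names(formals(scenario_params))
  extra <- setdiff(names(cfg), allowed)
  if (length(extra)) {
    stop(sprintf("unknown scenario key(s): %s", paste(extra, collapse = ", ")),
         call. = FALSE)
  }
  do.call(scenario_params, cfg)
}
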