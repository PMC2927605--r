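#' Attrition accounting by survey
#'
#' Tabulates the five attrition categories at each survey as proportions of
#' the initial cohort (the Survey-1 denominator), the standard attrition
#' summary for a multi-wave cohort.
#'
#' @param cohort A `cohort_table` with `status_s2 .. status_s5` columns.
#' @return An `attrition_summary` data frame with columns `survey`,
#'   `respondent`, `dead`, `frail`, `withdrawn`, `lost`; counts are
#'   attached as attribute `"counts"`.
#' @export
attrition_table <- function(cohort) {
  have <- intersect(STATUS_COLUMNS, names(cohort))
  if (!length(have)) {
    stop("cohort has no status_s2..status_s5 columns", call. = FALSE)
  }
  n0 <- nrow(cohort)
  rows <- lapply(have, function(col) {
    st <- cohort[[col]]
    bad <- setdiff(unique(as.character(st)), c(ATTRITION_OUTCOMES, NA))
    if (length(bad)) {
      stop(sprintf("unknown status label(s) in %s: %s", col,
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
    cnt <- table(factor(st, levels = ATTRITION_OUTCOMES))
    c(survey = as.integer(sub("status_s", "", col)), as.numeric(cnt) / n0)
  })
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- c("survey", ATTRITION_OUTCOMES)
  class(out) <- c("attrition_summary", "data.frame")
  attr(out, "counts") <- n0 * out[, ATTRITION_OUTCOMES]
  attr(out, "n_initial") <- n0
  out
}

#' @export
print.attrition_summary <- function(x, ...) {
  cat(sprintf("Attrition by survey (%% of %d initial participants)\n",
              attr(x, "n_initial")))
  disp <- x
  disp[ATTRITION_OUTCOMES] <- lapply(disp[ATTRITION_OUTCOMES],
                                     function(p) sprintf("%.1f%%", 100 * p))
  print.data.frame(disp, row.names = FALSE)
  invisible(x)
}

#' Restrict to complete cases on the analysis factors
#'
#' Drops every record with a missing value on any listed factor and reports
#' the per-factor missingness and the retained fraction.
#'
#' @param cohort A `cohort_table`.
#' @param factors Factor column names entering the analysis.
#' @return A list of class `complete_case_filter` with elements `cohort`
#'   (filtered), `report` (per-factor missingness), `n_initial`,
#'   `n_retained`, `retained_fraction`.
#' @export
complete_case_filter <- function(cohort, factors) {
  miss <- setdiff(factors, names(cohort))
  if (length(miss)) {
    stop(sprintf("factor(s) not in cohort: %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  n0 <- nrow(cohort)
  miss_n <- vapply(factors, function(f) sum(is.na(cohort[[f]])), integer(1L))
  keep <- complete.cases(cohort[, factors, drop = FALSE])
  out <- list(cohort = cohort[keep, , drop = FALSE],
              report = data.frame(factor = factors, n_missing = miss_n,
                                  missing_rate = miss_n / n0,
                                  row.names = NULL),
              n_initial = n0, n_retained = sum(keep),
              retained_fraction = sum(keep) / n0)
  if (out$n_retained == 0L) {
    warning("complete-case filter removed every record", call. = FALSE)
  }
  class(out) <- "complete_case_filter"
  out
}

#' @export
print.complete_case_filter <- function(x, ...) {
  cat(sprintf("Complete cases: %d of %d (%.1f%%)\n", x$n_retained,
              x$n_initial, 100 * x$retained_fraction))
  print.data.frame(x$report, row.names = FALSE)
  invisible(x)
}

#' Reference category for a risk factor
#'
#' Applies the standard conventions: for a nominal factor, the most
#' frequent category (observed counts if supplied, baseline shares
#' otherwise), ties broken deterministically by declared category order
#' with a warning; for an ordinal factor, the declared best-survival end
#' category from the spec.
#'
#' @param spec A [risk_factor_spec()].
#' @param counts Optional named observed counts per category.
#' @return A category label.
#' @export
select_reference_category <- function(spec, counts = NULL) {
  stopifnot(inherits(spec, "risk_factor_spec"))
  if (spec$scale == "ordinal") return(spec$reference)
  freq <- if (is.null(counts)) {
    setNames(spec$baseline_probs, spec$categories)
  } else {
    cnt <- counts[spec$categories]
    cnt[is.na(cnt)] <- 0
    setNames(as.numeric(cnt), spec$categories)
  }
  top <- names(freq)[freq == max(freq)]
  if (length(top) > 1L) {
    warning(sprintf("modal frequency tie for '%s' (%s); using first declared",
                    spec$name, paste(top, collapse = ", ")), call. = FALSE)
  }
  # first in declared category order among the tied maxima
  spec$categories[spec$categories %in% top][1L]
}

check_cells <- function(data, factors, status) {
  for (f in factors) {
    tab <- table(data[[f]], status)
    zero <- which(tab == 0, arr.ind = TRUE)
    if (nrow(zero)) {
      stop(sprintf(
        "empty cell: factor '%s', category '%s', outcome '%s' has no observations (separation risk)",
        f, rownames(tab)[zero[1, 1]], colnames(tab)[zero[1, 2]]),
        call. = FALSE)
    }
  }
}

#' Fit the multinomial logistic attrition model
#'
#' Maximum-likelihood multinomial logit of final (Survey 5) attrition
#' status — five outcomes with `respondent` as the reference — on baseline
#' risk factors, each releveled to its reference category. Returns
#' exponentiated coefficients (odds ratios) with Wald 95% confidence
#' intervals on the log-odds scale; a category is flagged significant when
#' its interval excludes 1.
#'
#' @param cohort A complete-case `cohort_table` (run
#'   [complete_case_filter()] first; missing values are an error).
#' @param factors Factor column names to include.
#' @param specs Optional named list of [risk_factor_spec()] used to pick
#'   reference categories; factors without a spec use their modal observed
#'   category.
#' @param conf_level Confidence level for the Wald intervals.
#' @param maxit,reltol Optimizer controls passed to [nnet::multinom()].
#' @return An `or_table` data frame with one row per (factor, category,
#'   outcome): columns `factor`, `category`, `outcome`, `n`, `pct`,
#'   `reference`, `or`, `conf_low`, `conf_high`, `significant`. The fitted
#'   `nnet` object is attached as attribute `"fit"`.
#' @export
fit_attrition_model <- function(cohort, factors, specs = NULL,
                                conf_level = 0.95, maxit = 500L,
                                reltol = 1e-10) {
  if (!"status_s5" %in% names(cohort)) {
    stop("cohort lacks a status_s5 column", call. = FALSE)
  }
  if (anyNA(cohort[, factors, drop = FALSE])) {
    stop("missing factor values: run complete_case_filter() before fitting",
         call. = FALSE)
  }
  status <- factor(as.character(cohort$status_s5), levels = ATTRITION_OUTCOMES)
  observed <- ATTRITION_OUTCOMES[table(status)[ATTRITION_OUTCOMES] > 0]
  if (length(observed) < 2L) {
    stop("need at least two observed outcome categories", call. = FALSE)
  }
  status <- factor(as.character(status), levels = observed)
  dat <- data.frame(.status = status)
  refs <- character(0)
  for (f in factors) {
    v <- droplevels(as.factor(cohort[[f]]))
    ref <- if (!is.null(specs) && f %in% names(specs)) {
      select_reference_category(specs[[f]], counts = table(v))
    } else names(which.max(table(v)))
    if (!ref %in% levels(v)) ref <- levels(v)[1L]
    dat[[f]] <- stats::relevel(v, ref = ref)
    refs[f] <- ref
  }
  check_cells(dat, factors, status)
  fml <- stats::as.formula(paste(".status ~",
                                 paste(sprintf("`%s`", factors),
                                       collapse = " + ")))
  fit <- nnet::multinom(fml, data = dat, Hess = TRUE, trace = FALSE,
                        maxit = maxit, reltol = reltol, model = FALSE)
  if (!is.null(fit$convergence) && fit$convergence != 0) {
    stop(sprintf("multinomial fit did not converge (code %d after %d iterations)",
                 fit$convergence, maxit), call. = FALSE)
  }
  co <- coef(fit); se <- summary(fit)$standard.errors
  if (is.null(dim(co))) {            # two observed outcomes: vectors
    co <- matrix(co, nrow = 1L, dimnames = list(levels(status)[2L], names(co)))
    se <- matrix(se, nrow = 1L, dimnames = dimnames(co))
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  n_cc <- nrow(dat)
  rows <- list()
  for (f in factors) {
    lev <- levels(dat[[f]])
    cnt <- table(dat[[f]])
    for (cg in lev) {
      is_ref <- cg == refs[f]
      term <- paste0("`", f, "`", cg)
      term_plain <- paste0(f, cg)
      for (o in setdiff(rownames(co), "respondent")) {
        if (is_ref) {
          b <- 0; s <- NA_real_
        } else {
          col <- if (term %in% colnames(co)) term else term_plain
          if (!col %in% colnames(co)) {
            stop(sprintf("internal: coefficient '%s' not found", col))
          }
          b <- co[o, col]; s <- se[o, col]
        }
        rows[[length(rows) + 1L]] <- data.frame(
          factor = f, category = cg, outcome = o,
          n = as.integer(cnt[[cg]]), pct = 100 * cnt[[cg]] / n_cc,
          reference = is_ref,
          or = exp(b),
          conf_low = if (is_ref) NA_real_ else exp(b - z * s),
          conf_high = if (is_ref) NA_real_ else exp(b + z * s))
      }
    }
  }
  out <- do.call(rbind, rows)
  out$significant <- !out$reference &
    (out$conf_low > 1 | out$conf_high < 1)
  class(out) <- c("or_table", "data.frame")
  attr(out, "fit") <- fit
  attr(out, "n_complete") <- n_cc
  attr(out, "references") <- refs
  attr(out, "conf_level") <- conf_level
  out
}

#' @export
print.or_table <- function(x, ...) {
  cat(sprintf("Odds ratios vs respondent (n = %d complete cases)\n",
              attr(x, "n_complete")))
  disp <- data.frame(factor = x$factor, category = x$category,
                     outcome = x$outcome, n = x$n,
                     pct = sprintf("%.1f", x$pct),
                     or = sprintf("%.2f", x$or),
                     ci = ifelse(x$reference, "(ref)",
                                 sprintf("(%.2f, %.2f)%s", x$conf_low,
                                         x$conf_high,
                                         ifelse(x$significant, " *", ""))))
  print.data.frame(disp, row.names = FALSE)
  invisible(x)
}

#' Two-stage variable retention screen
#'
#' Stage 1 fits each candidate factor alone and keeps those with at least
#' one category whose confidence interval excludes 1 for any outcome.
#' Stage 2 fits the joint model on the keepers and drops factors with no
#' significant category, refitting until the retained set is stable (at
#' most `max_rounds` rounds).
#'
#' @param cohort A complete-case `cohort_table`.
#' @param factors Candidate factor columns.
#' @param specs Optional reference-category specs, as in
#'   [fit_attrition_model()].
#' @param max_rounds Cap on stage-2 refits.
#' @param ... Passed to [fit_attrition_model()].
#' @return A list of class `screen_result`: `retained` (character),
#'   `univariate` (named logical of stage-1 keeps), `history` (factors
#'   dropped per round), and `fit` (the final joint `or_table`, or `NULL`
#'   if nothing was retained).
#' @export
univariate_screen <- function(cohort, factors, specs = NULL,
                              max_rounds = 10L, ...) {
  uni_keep <- vapply(factors, function(f) {
    tab <- fit_attrition_model(cohort, f, specs = specs, ...)
    any(tab$significant, na.rm = TRUE)
  }, logical(1L))
  retained <- factors[uni_keep]
  history <- list()
  fit <- NULL
  round <- 0L
  while (length(retained) && round < max_rounds) {
    round <- round + 1L
    fit <- fit_attrition_model(cohort, retained, specs = specs, ...)
    sig_by_factor <- tapply(fit$significant, fit$factor,
                            function(v) any(v, na.rm = TRUE))
    drop <- names(sig_by_factor)[!sig_by_factor]
    history[[round]] <- drop
    if (!length(drop)) break
    retained <- setdiff(retained, drop)
    fit <- NULL
  }
  if (length(retained) && is.null(fit)) {
    fit <- fit_attrition_model(cohort, retained, specs = specs, ...)
  }
  structure(list(retained = retained, univariate = uni_keep,
                 history = history, fit = fit),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat("Variable retention screen\n")
  cat("  univariate keeps:", paste(names(x$univariate)[x$univariate],
                                   collapse = ", "), "\n")
  cat("  retained:        ", paste(x$retained, collapse = ", "), "\n")
  invisible(x)
}
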