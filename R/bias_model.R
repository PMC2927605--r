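#' Scenario parameters for the prevalence-drift model
#'
#' Bundles every quantity driving the deterministic model of how the
#' prevalence of a fixed (individual-level) risk factor evolves in a target
#' population subject to death, and in a study cohort subject to both death
#' and non-death attrition (withdrawal, loss to follow up). Incidences are
#' per-step event probabilities for individuals *without* the risk factor;
#' relative risks multiply them for individuals *with* it.
#'
#' The product `RR * I` is the per-step event probability among the exposed
#' and must not exceed 1; violations are rejected at construction rather
#' than clamped.
#'
#' @param p_p0 Initial risk-factor prevalence in the target population.
#' @param p_c0 Initial prevalence in the study cohort.
#' @param I_pd Per-step death incidence in the population (unexposed).
#' @param I_cd Per-step death incidence in the cohort (unexposed).
#' @param I_ca Per-step non-death attrition incidence in the cohort
#'   (unexposed).
#' @param RR_pd,RR_cd,RR_ca Relative risks of death (population, cohort) and
#'   of non-death attrition (cohort) for exposed vs unexposed individuals.
#' @param n_steps Time horizon in steps; a step is any period for which the
#'   incidences apply (e.g. one year).
#' @return An object of class `scenario_params`.
#' @seealso [run_scenario()], [canonical_scenarios()]
#' @export
scenario_params <- function(p_p0, p_c0 = p_p0,
                            I_pd = 0.10, I_cd = 0.10, I_ca = 0.10,
                            RR_pd = 1, RR_cd = 1, RR_ca = 1,
                            n_steps = 10L) {
  assert_proportion(p_p0, "p_p0"); assert_proportion(p_c0, "p_c0")
  assert_proportion(I_pd, "I_pd", open_upper = TRUE)
  assert_proportion(I_cd, "I_cd", open_upper = TRUE)
  assert_proportion(I_ca, "I_ca", open_upper = TRUE)
  assert_positive(RR_pd, "RR_pd"); assert_positive(RR_cd, "RR_cd")
  assert_positive(RR_ca, "RR_ca")
  for (nm in c("pd", "cd", "ca")) {
    rr <- get(paste0("RR_", nm)); i <- get(paste0("I_", nm))
    if (rr * i > 1 + 1e-12) {
      stop(sprintf("RR_%s * I_%s = %.4f exceeds 1: exposed retention would be negative",
                   nm, nm, rr * i), call. = FALSE)
    }
  }
  if (!is.numeric(n_steps) || length(n_steps) != 1L || n_steps < 1 ||
      n_steps != round(n_steps)) {
    stop("'n_steps' must be a positive integer", call. = FALSE)
  }
  structure(list(p_p0 = p_p0, p_c0 = p_c0,
                 I_pd = I_pd, I_cd = I_cd, I_ca = I_ca,
                 RR_pd = RR_pd, RR_cd = RR_cd, RR_ca = RR_ca,
                 n_steps = as.integer(n_steps)),
            class = "scenario_params")
}

#' @export
print.scenario_params <- function(x, ...) {
  cat("Prevalence-drift scenario\n")
  cat(sprintf("  initial prevalence: population %.3f, cohort %.3f\n",
              x$p_p0, x$p_c0))
  cat(sprintf("  death:     I_pd = %.3f (RR %.2f), I_cd = %.3f (RR %.2f)\n",
              x$I_pd, x$RR_pd, x$I_cd, x$RR_cd))
  cat(sprintf("  non-death: I_ca = %.3f (RR %.2f)\n", x$I_ca, x$RR_ca))
  cat(sprintf("  horizon:   %d steps\n", x$n_steps))
  invisible(x)
}

#' One-step prevalence update in the target population
#'
#' Advances the risk-factor prevalence in the population across one time
#' step during which death removes a fraction `I_pd` of unexposed and
#' `RR_pd * I_pd` of exposed individuals. The returned value is the
#' prevalence among survivors:
#' \deqn{p' = \frac{A}{(1-p)(1-I_{pd}) + A}, \quad
#'       A = p\,[1 - RR_{pd} I_{pd}]}
#' With `RR_pd = 1` the prevalence is a fixed point: non-differential
#' mortality leaves composition unchanged.
#'
#' @param p_prev Prevalence at the previous step.
#' @param I_pd Death incidence among the unexposed.
#' @param RR_pd Relative risk of death for the exposed.
#' @return Prevalence among survivors, in `[0, 1]`.
#' @export
update_population_prevalence <- function(p_prev, I_pd, RR_pd) {
  assert_proportion(p_prev, "p_prev")
  assert_proportion(I_pd, "I_pd", open_upper = TRUE)
  assert_positive(RR_pd, "RR_pd")
  if (RR_pd * I_pd > 1 + 1e-12) {
    stop("RR_pd * I_pd exceeds 1: exposed retention would be negative",
         call. = FALSE)
  }
  A <- p_prev * (1 - RR_pd * I_pd)
  den <- (1 - p_prev) * (1 - I_pd) + A
  if (den <= 0) {
    stop("no survivors: population prevalence undefined (denominator 0)",
         call. = FALSE)
  }
  A / den
}

#' One-step prevalence update in the remaining cohort
#'
#' As [update_population_prevalence()], but the cohort loses members to two
#' independent processes per step: death (incidence `I_cd`, relative risk
#' `RR_cd`) and non-death attrition (incidence `I_ca`, relative risk
#' `RR_ca`). Retention of an individual is the product of surviving both:
#' \deqn{p' = \frac{B}{(1-p)(1-I_{cd})(1-I_{ca}) + B}, \quad
#'       B = p\,[1 - RR_{cd} I_{cd}]\,[1 - RR_{ca} I_{ca}]}
#'
#' @param p_prev Prevalence at the previous step.
#' @param I_cd,I_ca Death and non-death attrition incidences (unexposed).
#' @param RR_cd,RR_ca Relative risks for the exposed.
#' @return Prevalence among cohort members neither dead nor otherwise lost.
#' @export
update_cohort_prevalence <- function(p_prev, I_cd, I_ca, RR_cd, RR_ca) {
  assert_proportion(p_prev, "p_prev")
  assert_proportion(I_cd, "I_cd", open_upper = TRUE)
  assert_proportion(I_ca, "I_ca", open_upper = TRUE)
  assert_positive(RR_cd, "RR_cd"); assert_positive(RR_ca, "RR_ca")
  if (RR_cd * I_cd > 1 + 1e-12 || RR_ca * I_ca > 1 + 1e-12) {
    stop("RR * I exceeds 1 for an attrition process: exposed retention would be negative",
         call. = FALSE)
  }
  B <- p_prev * (1 - RR_cd * I_cd) * (1 - RR_ca * I_ca)
  den <- (1 - p_prev) * (1 - I_cd) * (1 - I_ca) + B
  if (den <= 0) {
    stop("no remaining cohort members: cohort prevalence undefined (denominator 0)",
         call. = FALSE)
  }
  B / den
}

#' Run a prevalence-drift scenario
#'
#' Iterates both one-step updates from the initial prevalences across the
#' scenario horizon. Bias is stored signed as `p_pop - p_cohort`: positive
#' when the cohort under-represents the risk factor.
#'
#' @param params A [scenario_params()] object.
#' @return A `prevalence_trajectory` data frame with columns `step`,
#'   `p_pop`, `p_cohort` and `bias`, one row per step `0..n_steps`.
#' @examples
#' traj <- run_scenario(scenario_params(0.25, 0.20, RR_pd = 2, RR_cd = 2))
#' head(traj)
#' @export
run_scenario <- function(params) {
  if (!inherits(params, "scenario_params")) {
    stop("'params' must be a scenario_params object", call. = FALSE)
  }
  n <- params$n_steps
  p_pop <- p_coh <- numeric(n + 1L)
  p_pop[1L] <- params$p_p0
  p_coh[1L] <- params$p_c0
  for (t in seq_len(n)) {
    p_pop[t + 1L] <- tryCatch(
      update_population_prevalence(p_pop[t], params$I_pd, params$RR_pd),
      error = function(e) stop(sprintf("step %d (population): %s",
                                       t, conditionMessage(e)), call. = FALSE))
    p_coh[t + 1L] <- tryCatch(
      update_cohort_prevalence(p_coh[t], params$I_cd, params$I_ca,
                               params$RR_cd, params$RR_ca),
      error = function(e) stop(sprintf("step %d (cohort): %s",
                                       t, conditionMessage(e)), call. = FALSE))
  }
  out <- data.frame(step = 0:n, p_pop = p_pop, p_cohort = p_coh,
                    bias = p_pop - p_coh)
  class(out) <- c("prevalence_trajectory", "data.frame")
  attr(out, "params") <- params
  out
}

#' The eight canonical hypothetical scenarios
#'
#' The standard grid of hypothetical situations: four association patterns
#' (1: none; 2: death only, shared by population and cohort; 3: non-death
#' attrition only; 4: both) crossed with two starting conditions (A: no
#' initial bias, cohort starts at the population prevalence 0.25; B: initial
#' bias, cohort starts at 0.20). All incidences are 0.10 per step, an
#' association means a relative risk of 2, and the horizon is 10 steps.
#'
#' @return A named list of eight [scenario_params()] objects, keyed
#'   `"1A"` .. `"4B"`.
#' @export
canonical_scenarios <- function() {
  rr <- list(`1` = c(1, 1, 1), `2` = c(2, 2, 1),
             `3` = c(1, 1, 2), `4` = c(2, 2, 2))
  out <- list()
  for (fig in names(rr)) {
    for (panel in c("A", "B")) {
      out[[paste0(fig, panel)]] <- scenario_params(
        p_p0 = 0.25, p_c0 = if (panel == "A") 0.25 else 0.20,
        I_pd = 0.10, I_cd = 0.10, I_ca = 0.10,
        RR_pd = rr[[fig]][1], RR_cd = rr[[fig]][2], RR_ca = rr[[fig]][3],
        n_steps = 10L)
    }
  }
  out
}

#' Plot a prevalence trajectory
#'
#' Simple line plot of population and cohort prevalence over time.
#'
#' @param x A `prevalence_trajectory`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.prevalence_trajectory <- function(x, ...) {
  graphics::matplot(x$step, cbind(x$p_pop, x$p_cohort), type = "l",
                    lty = c(1, 2), col = c("black", "grey40"),
                    xlab = "time step", ylab = "prevalence",
                    ylim = c(0, max(0.5, x$p_pop, x$p_cohort)), ...)
  graphics::legend("topright", c("population", "cohort"),
                   lty = c(1, 2), col = c("black", "grey40"), bty = "n")
  invisible(x)
}

#' Write a trajectory to CSV
#'
#' @param trajectory A `prevalence_trajectory`.
#' @param path Output file path.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  write.csv(as.data.frame(trajectory), path, row.names = FALSE)
  invisible(path)
}
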