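# Independent oracles and small builders shared across tests.

# Two-bucket survivor-count oracle for the one-step prevalence updates:
# exposed and unexposed masses each shrink by their retention probability,
# then prevalence is renormalized over survivors.
oracle_pop_update <- function(p, I, RR) {
  exposed <- p * (1 - RR * I)
  unexposed <- (1 - p) * (1 - I)
  exposed / (exposed + unexposed)
}

oracle_cohort_update <- function(p, I_d, I_a, RR_d, RR_a) {
  exposed <- p * (1 - RR_d * I_d) * (1 - RR_a * I_a)
  unexposed <- (1 - p) * (1 - I_d) * (1 - I_a)
  exposed / (exposed + unexposed)
}

# Closed-form contingency-table odds ratio (ad/bc) for a binary exposure
# and a binary outcome vs reference outcome.
oracle_2x2_or <- function(exposure, status, outcome, exposed_level) {
  a <- sum(exposure == exposed_level & status == outcome)
  b <- sum(exposure == exposed_level & status == "respondent")
  c <- sum(exposure != exposed_level & status == outcome)
  d <- sum(exposure != exposed_level & status == "respondent")
  (a * d) / (b * c)
}

# Minimal one-factor cohort with a given per-category death probability.
make_binary_cohort <- function(n, p_dead_no = 0.2, p_dead_yes = 0.35,
                               seed = 1) {
  set.seed(seed)
  x <- factor(sample(c("no", "yes"), n, TRUE), levels = c("no", "yes"))
  p <- ifelse(x == "yes", p_dead_yes, p_dead_no)
  st <- ifelse(runif(n) < p, "dead", "respondent")
  coh <- data.frame(
    id = seq_len(n), exposure = x,
    status_s5 = factor(st, levels = c("respondent", "dead", "frail",
                                      "withdrawn", "lost")))
  class(coh) <- c("cohort_table", "data.frame")
  coh
}

# Two small factors for generator tests.
tiny_specs <- function() {
  list(
    risk_factor_spec("smoke", c("never", "ex", "current"),
                     c(0.629, 0.299, 0.072), missing_rate = 0.074),
    risk_factor_spec("active", c("high", "low"), c(0.724, 0.276),
                     missing_rate = 0.016))
}

empty_coefficients <- function() {
  data.frame(factor = character(), category = character(),
             outcome = character(), log_or = numeric())
}

s5_targets <- function() {
  c(respondent = 0.447, dead = 0.284, frail = 0.051, withdrawn = 0.114,
    lost = 0.104)
}
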