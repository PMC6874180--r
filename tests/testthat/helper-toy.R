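# Toy-model builders and the exhaustive-enumeration oracle used to validate
# the microsimulation engine against exact expectations.

# A stripped-down parameter set: a single fracture kind (wrist) with constant
# annual probability, constant mortality, flat baseline utility, one
# first-year disutility multiplier, a single fracture treatment cost, and no
# drug/visit/LTC/productivity costs. Wrist carries no memory (subsequent-year
# multiplier 1), so cycles are independent and expectations have closed form.
toy_params <- function(p_frac = 0.1, q = 0.05, frac_cost = 1000,
                       u0 = 0.8, first_mult = 0.9) {
  p <- default_parameter_set()
  kinds <- fracture_kinds()
  for (k in kinds) {
    p$incidence[[k]] <- rep(if (k == "wrist") p_frac else 0,
                            nrow(p$incidence))
  }
  p$mortality$q <- rep(q, nrow(p$mortality))
  p$risks$rr_prior_vertebral[kinds] <- 1
  p$risks$rr_osteoporosis[kinds] <- 1
  p$risks$hip_excess_mortality_rr <- 1
  ut <- generate_utility_table(anchor_at_65 = u0, annual_decline = 0,
                               first_year = c(hip = 0.7, clinical_vertebral = 0.8,
                                              wrist = first_mult,
                                              other_osteoporotic = 0.9))
  p$utilities <- list(baseline = ut$baseline, first_year = ut$first_year,
                      subsequent = ut$subsequent)
  p$costs$fracture_treatment[kinds] <- c(0, 0, frac_cost, 0)
  p$costs$drug_annual[] <- 0
  p$costs$physician_visit <- 0
  p$costs$dxa <- 0
  p$costs$ltc_monthly <- 0
  p$costs$weekly_earnings <- 0
  validate_parameter_set(p)
  p
}

# Exact expectation for the toy model, by direct summation over cycles (the
# per-cycle events are independent: survive each cycle's death draw, then
# fracture independently; the wrist multiplier applies only in the fracture
# year). Death occurs before any accrual within a cycle.
toy_expectation <- function(p_frac, q, frac_cost, u0, first_mult,
                            n_cycles, rate = 0.03) {
  t <- seq_len(n_cycles) - 1
  alive <- (1 - q)^(t + 1)          # survived t+1 death draws
  disc <- (1 + rate)^-t
  list(
    cost = sum(alive * p_frac * frac_cost * disc),
    qaly = sum(alive * u0 * (1 - p_frac + p_frac * first_mult) * disc),
    mean_fractures = sum(alive * p_frac)
  )
}

toy_scenario <- function(n_cycles = 3, n = 20000, seed = 42,
                         strategy = "none", rate = 0.03, start_age = 65) {
  make_scenario(start_age = start_age, strategy = strategy,
                horizon_end_age = start_age + n_cycles, discount_rate = rate,
                n_individuals = n, master_seed = seed)
}

expect_within_3se <- function(est, truth, se) {
  expect_lt(abs(est - truth), 3 * se + 1e-12)
}
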