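# Engine mechanics: per-cycle probabilities, the competing-event draw,
# mortality adjustment, trajectory structure, determinism, and agreement with
# the exact enumeration oracle on the toy model.

test_that("fracture probability multiplies baseline and relative risks", {
  expect_equal(fracture_probability(0.01, 2.3, 2.0), 0.046)
  expect_equal(fracture_probability(0.01, 2.3, 2.0, 0.565), 0.02599)
  expect_equal(fracture_probability(0, 1, 1), 0)
  expect_equal(fracture_probability(0.9, 2, 2), 1) # clamped
})

test_that("mortality probability applies attributable excess after hip fracture", {
  expect_equal(mortality_probability(0.04, FALSE, 2, 0.25), 0.04)
  expect_equal(mortality_probability(0.04, TRUE, 1, 0.25), 0.04)  # null excess
  expect_equal(mortality_probability(0.04, TRUE, 2, 0.25), 0.05)
  expect_equal(mortality_probability(0.9, TRUE, 10, 1), 1)        # clamped
})

test_that("the competing-event draw matches its exact two-risk distribution", {
  # p = (0.1, 0.1, 0, 0): P(any) = 1 - 0.9^2 = 0.19, P(hip | any) = 0.5
  set.seed(7)
  n <- 50000
  u <- matrix(runif(2 * n), n, 2)
  draws <- vapply(seq_len(n), function(i) {
    draw_cycle_event(c(0.1, 0.1, 0, 0), u_any = u[i, 1], u_kind = u[i, 2])
  }, character(1))
  p_any <- mean(draws != "none")
  expect_within_3se(p_any, 0.19, sqrt(0.19 * 0.81 / n))
  p_hip <- mean(draws[draws != "none"] == "hip")
  n_any <- sum(draws != "none")
  expect_within_3se(p_hip, 0.5, sqrt(0.25 / n_any))
  # degenerate cases
  expect_equal(draw_cycle_event(c(0, 0, 0, 0)), "none")
  expect_equal(draw_cycle_event(c(1, 0, 0, 0)), "hip")
  expect_equal(draw_cycle_event(c(1, 0, 0, 0), hip_blocked = TRUE), "none")
})

test_that("individual trajectories are reproducible and structurally sound", {
  p <- default_parameter_set()
  sc <- make_scenario(start_age = 65, strategy = "sequential",
                      n_individuals = 1, master_seed = 3)
  t1 <- simulate_individual(p, sc, seed = 11)
  t2 <- simulate_individual(p, sc, seed = 11)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  # records stop at death or the horizon; at most one event per cycle
  expect_lte(nrow(t1), 40)
  expect_true(all(t1$event %in% c("none", "death", fracture_kinds())))
  if (attr(t1, "died")) expect_equal(t1$event[nrow(t1)], "death")
  # death accrues nothing
  dead_rows <- t1[t1$event == "death", ]
  if (nrow(dead_rows)) {
    expect_true(all(dead_rows[c("cost_treatment", "cost_fracture", "cost_ltc",
                                "cost_productivity", "utility")] == 0))
  }
})

test_that("certain immediate death yields a one-cycle trajectory", {
  p <- toy_params(q = 1)
  sc <- toy_scenario(n_cycles = 5, n = 1)
  tr <- simulate_individual(p, sc, seed = 1)
  expect_equal(nrow(tr), 1)
  expect_equal(tr$event, "death")
  expect_equal(attr(tr, "qaly"), 0)
})

test_that("hip fractures are capped at two per lifetime", {
  p <- default_parameter_set()
  kinds <- fracture_kinds()
  # force hip fractures every cycle: huge hip incidence, no death until horizon
  for (k in kinds) p$incidence[[k]] <- rep(if (k == "hip") 0.95 else 0,
                                           nrow(p$incidence))
  p$risks$rr_prior_vertebral[kinds] <- 1
  p$risks$rr_osteoporosis[kinds] <- 1
  p$risks$hip_excess_mortality_rr <- 1
  p$mortality$q <- rep(0, nrow(p$mortality))
  validate_parameter_set(p)
  sc <- make_scenario(start_age = 65, strategy = "none", n_individuals = 1,
                      horizon_end_age = 85, master_seed = 5)
  tr <- simulate_individual(p, sc, seed = 2)
  expect_equal(sum(tr$event == "hip"), 2)
  expect_equal(attr(tr, "fracture_counts")[["hip"]], 2)
})

test_that("toy-model cohort means match the enumeration oracle within 3 SE", {
  p_frac <- 0.1; q <- 0.05; cost <- 1000; u0 <- 0.8; mult <- 0.9
  p <- toy_params(p_frac, q, cost, u0, mult)
  sc <- toy_scenario(n_cycles = 3, n = 20000, seed = 12)
  coh <- run_cohort(p, sc)
  truth <- toy_expectation(p_frac, q, cost, u0, mult, 3)
  expect_within_3se(coh$mean_cost[["societal"]], truth$cost,
                    coh$se_cost[["societal"]])
  expect_within_3se(coh$mean_qaly, truth$qaly, coh$se_qaly)
  mf <- sum(coh$mean_fractures)
  se_mf <- stats::sd(rowSums(coh$counts)) / sqrt(coh$n)
  expect_within_3se(mf, truth$mean_fractures, se_mf)
})

test_that("two-cycle fracture-only toy model has mean fracture count 0.2", {
  p <- toy_params(p_frac = 0.1, q = 0)
  sc <- toy_scenario(n_cycles = 2, n = 20000, seed = 9)
  coh <- run_cohort(p, sc)
  est <- sum(coh$mean_fractures)
  expect_within_3se(est, 0.2, stats::sd(rowSums(coh$counts)) / sqrt(coh$n))
})

test_that("cohort runs are deterministic given the master seed", {
  p <- toy_params()
  sc <- toy_scenario(n_cycles = 3, n = 200, seed = 77)
  c1 <- run_cohort(p, sc)
  c2 <- run_cohort(p, sc)
  expect_identical(c1$totals, c2$totals)
})

test_that("n = 1 cohort equals that individual's totals", {
  p <- default_parameter_set()
  sc <- make_scenario(start_age = 65, strategy = "sequential",
                      n_individuals = 1, master_seed = 8)
  coh <- run_cohort(p, sc)
  tr <- simulate_individual(p, sc,
                            seed = osteosim:::substream_seed(8L, "individual", 1))
  expect_equal(coh$mean_cost[["societal"]],
               attr(tr, "cost_health_care") + attr(tr, "cost_non_health_care"))
  expect_equal(coh$mean_qaly, attr(tr, "qaly"))
})

test_that("survival is non-increasing and treatment RR=1 removes strategy effects", {
  p <- default_parameter_set()
  for (drug in c("teriparatide", "alendronate")) {
    p$efficacy[[drug]]$rr[fracture_kinds()] <- 1
    p$efficacy[[drug]]$high[fracture_kinds()] <- 1
  }
  validate_parameter_set(p)
  sc_a <- make_scenario(start_age = 75, strategy = "alendronate_alone",
                        n_individuals = 1500, master_seed = 21)
  sc_s <- sc_a; sc_s$strategy <- "sequential"
  ca <- run_cohort(p, sc_a)
  cs <- run_cohort(p, sc_s)
  # identical paired random streams + null efficacy => identical event histories
  expect_equal(ca$lifetime_risk, cs$lifetime_risk)
  expect_equal(ca$mean_qaly, cs$mean_qaly)
})

test_that("lowering a treatment relative risk never increases fracture counts", {
  # wrist-only toy under alendronate: no mortality feedback, paired seeds
  p_hi <- toy_params(p_frac = 0.15, q = 0.02)
  p_hi$efficacy$alendronate$rr[["wrist"]] <- 1
  p_hi$efficacy$alendronate$high[["wrist"]] <- 1
  p_lo <- p_hi
  p_lo$efficacy$alendronate$rr[["wrist"]] <- 0.3
  sc <- toy_scenario(n_cycles = 10, n = 4000, seed = 33,
                     strategy = "alendronate_alone")
  f_hi <- rowSums(run_cohort(p_hi, sc)$counts)
  f_lo <- rowSums(run_cohort(p_lo, sc)$counts)
  # with paired uniforms, each individual's count can only go down
  expect_true(all(f_lo <= f_hi))
  expect_lt(mean(f_lo), mean(f_hi))
})
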