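# Discounting, per-cycle cost components and sector tags, utility stacking,
# and ICER computation with dominance handling.

test_that("discounting follows 1/(1+r)^t with the first year undiscounted", {
  expect_equal(discount(100, 0, 0.03), 100)
  expect_equal(discount(103, 1, 0.03), 100)
  expect_equal(discount(100, 2, 0.03), 100 / 1.03^2)
  expect_equal(discount(100, 5, 0), 100)
})

test_that("hip-fracture-year costs include the sector-tagged components", {
  p <- default_parameter_set()
  soc <- cycle_costs(p, age = 67, event = "hip", entered_ltc = TRUE,
                     perspective = "societal")
  expect_equal(soc[["fracture"]], 29986)
  expect_equal(soc[["productivity"]], 757 * 8 * 0.279) # ~1690, ages 65-69
  expect_equal(soc[["ltc"]], 6 * 7159 * 0.25)          # acute 6 months
  # the same cycle from the health-care-sector perspective drops both
  hcs <- cycle_costs(p, age = 67, event = "hip", entered_ltc = TRUE,
                     perspective = "health_care_sector")
  expect_equal(hcs[["fracture"]], 29986)
  expect_equal(hcs[["ltc"]], 0)
  expect_equal(hcs[["productivity"]], 0)
  # age bands for productivity; none past 80
  expect_equal(cycle_costs(p, 72, "hip")[["productivity"]], 757 * 8 * 0.166)
  expect_equal(cycle_costs(p, 77, "hip")[["productivity"]], 757 * 8 * 0.059)
  expect_equal(cycle_costs(p, 81, "hip")[["productivity"]], 0)
  # steady-state post-hip long-term care: the averaged annual figure
  expect_equal(round(cycle_costs(p, 70, post_hip = TRUE)[["ltc"]]), 2577)
  # quiet year: nothing accrues
  expect_equal(sum(cycle_costs(p, 70)), 0)
  expect_error(cycle_costs(p, 70, event = "skull"), "unknown fracture kind")
})

test_that("utility multipliers stack multiplicatively across fracture kinds", {
  p <- default_parameter_set()
  p$utilities$subsequent[["hip"]] <- 0.8
  p$utilities$subsequent[["clinical_vertebral"]] <- 0.9
  base <- p$utilities$baseline$utility[p$utilities$baseline$age == 70]
  expect_equal(cycle_utility(p, 70), base)
  expect_equal(cycle_utility(p, 70, history = c("hip", "clinical_vertebral")),
               base * 0.8 * 0.9)
  # wrist or other fractures carry no disutility beyond the first year
  expect_equal(cycle_utility(p, 70, history = "wrist"), base)
  expect_equal(cycle_utility(p, 70, history = "other_osteoporotic"), base)
  # fracture year uses the first-year multiplier, replacing the kind's own
  # subsequent multiplier but stacking with other kinds' history
  expect_equal(cycle_utility(p, 70, event = "hip", history = "hip"),
               base * p$utilities$first_year[["hip"]])
  expect_equal(cycle_utility(p, 70, event = "wrist", history = "hip"),
               base * p$utilities$first_year[["wrist"]] * 0.8)
})

test_that("ICERs, dominance and undefined cases are labelled correctly", {
  mk <- function(cost, qaly) list(mean_cost = c(societal = cost), mean_qaly = qaly)
  ic <- compute_icer(mk(100, 1), mk(200, 2))
  expect_equal(ic$icer, 100)
  expect_equal(ic$label, "icer")
  expect_equal(compute_icer(mk(200, 1), mk(100, 2))$label, "dominant")
  expect_equal(compute_icer(mk(100, 2), mk(200, 1))$label, "dominated")
  expect_equal(compute_icer(mk(100, 1), mk(200, 1))$label, "undefined")
  # a base-case-sized example: rounding ICERs to the nearest $100
  ic <- compute_icer(mk(42830, 10.55416), mk(54060, 10.58001))
  expect_equal(round(ic$icer / 100) * 100, 434400)
  # antisymmetry of the deltas
  fwd <- compute_icer(mk(100, 1), mk(250, 3))
  rev <- compute_icer(mk(250, 3), mk(100, 1))
  expect_equal(fwd$delta_cost, -rev$delta_cost)
  expect_equal(fwd$delta_qaly, -rev$delta_qaly)
})

test_that("societal costs dominate health-care-sector costs per individual", {
  p <- default_parameter_set()
  coh <- run_cohort(p, make_scenario(start_age = 70, strategy = "sequential",
                                     n_individuals = 400, master_seed = 14))
  soc <- coh$totals[, "cost_hcs"] + coh$totals[, "cost_nhc"]
  expect_true(all(soc >= coh$totals[, "cost_hcs"]))
  expect_gte(coh$mean_cost[["societal"]], coh$mean_cost[["health_care_sector"]])
})

test_that("total QALYs never exceed years lived or the horizon span", {
  p <- default_parameter_set()
  sc <- make_scenario(start_age = 80, strategy = "alendronate_alone",
                      n_individuals = 300, master_seed = 6)
  coh <- run_cohort(p, sc)
  expect_true(all(coh$totals[, "qaly"] <= 105 - 80 + 1e-9))
  # per-trajectory: utility per cycle is at most 1
  tr <- simulate_individual(p, sc, seed = 4)
  lived <- sum(tr$event != "death")
  expect_lte(attr(tr, "qaly"), lived + 1e-9)
})

test_that("run_cea pairs strategies and summarises both perspectives", {
  p <- default_parameter_set()
  cea <- run_cea(p, make_scenario(start_age = 65, n_individuals = 400,
                                  master_seed = 2))
  expect_s3_class(cea, "osteo_cea")
  expect_equal(cea$reference$strategy, "alendronate_alone")
  expect_equal(cea$intervention$strategy, "sequential")
  s <- summary(cea)
  expect_equal(nrow(s), 4) # 2 strategies x 2 perspectives
  expect_true(all(c("societal", "health_care_sector") %in% s$perspective))
  # printing works
  expect_output(print(cea), "ICER")
})
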