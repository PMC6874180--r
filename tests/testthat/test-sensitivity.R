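# Distribution sampling, one-way DSA, price-threshold search, PSA and CEAC.

test_that("point-mass and triangular samplers behave as specified", {
  expect_equal(sample_parameter(list(kind = "point_mass", base = 0.42), 5),
               rep(0.42, 5))
  set.seed(11)
  n <- 50000
  x <- sample_parameter(list(kind = "triangular", base = 0.42,
                             low = 0.10, high = 1.0), n)
  expect_true(all(x >= 0.10 & x <= 1.0))
  truth <- (0.10 + 0.42 + 1.0) / 3
  expect_within_3se(mean(x), truth, sd(x) / sqrt(n))
})

test_that("log-normal draws have the base value as median", {
  set.seed(12)
  n <- 50000
  x <- sample_parameter(list(kind = "log_normal", base = 29986,
                             low = 25677, high = 42913), n)
  expect_true(all(x > 0))
  # order-statistic check: P(X < base) = 1/2
  expect_within_3se(mean(x < 29986), 0.5, sqrt(0.25 / n))
})

test_that("beta and gamma draws match their moment recipes", {
  set.seed(13)
  n <- 50000
  spec_b <- list(kind = "beta", base = 0.30, low = 0.16, high = 0.55)
  xb <- sample_parameter(spec_b, n)
  expect_true(all(xb > 0 & xb < 1))
  expect_within_3se(mean(xb), 0.30, sd(xb) / sqrt(n))
  spec_g <- list(kind = "gamma", base = 2.3, low = 2.0, high = 2.8)
  xg <- sample_parameter(spec_g, n)
  expect_true(all(xg > 0))
  expect_within_3se(mean(xg), 2.3, sd(xg) / sqrt(n))
})

test_that("unfittable specs are rejected", {
  expect_error(sample_parameter(list(kind = "triangular", base = 2,
                                     low = 0, high = 1)), "unfittable")
  expect_error(sample_parameter(list(kind = "beta", base = 0.5,
                                     low = 0, high = 4)), "beta")
  expect_error(sample_parameter(list(kind = "log_normal", base = 1,
                                     low = 0, high = 2)), "log-normal")
  expect_error(sample_parameter(list(kind = "cauchy", base = 1,
                                     low = 0, high = 2)), "unknown")
})

test_that("uncertainty specs cover the distribution-bearing parameters", {
  p <- default_parameter_set()
  specs <- default_uncertainty_specs(p)
  # 8 efficacy + 8 persistence/adherence + 2 drug costs + dxa + 4 fracture
  # treatments + ltc + 3 productivity + 4 prior-vertebral RRs
  expect_length(specs, 31)
  for (s in specs) {
    expect_true(s$low <= s$base && s$base <= s$high)
    expect_equal(get_parameter(p, s$path), s$base)
  }
  # a joint draw stays loadable and keeps within-drug monotonicity
  set.seed(4)
  pj <- osteosim:::draw_parameter_set(p, specs)
  expect_lte(pj$adherence$teriparatide[["p24"]], pj$adherence$teriparatide[["p12"]])
  expect_lte(pj$adherence$alendronate[["a24"]], pj$adherence$alendronate[["a12"]])
})

test_that("one-way DSA reproduces the base case and responds to the sweep", {
  p <- toy_params(p_frac = 0.12, q = 0.03)
  # give the treatment some efficacy and cost so the ICER is defined
  p$efficacy$alendronate$rr[["wrist"]] <- 0.5
  p$costs$drug_annual[["alendronate"]] <- 300
  sc <- toy_scenario(n_cycles = 8, n = 1500, seed = 19)
  base_cea <- run_cea(p, sc)
  base_ic <- compute_icer(base_cea$reference, base_cea$intervention)
  expect_equal(nrow(run_owsa(p, sc, "costs.drug_annual.alendronate",
                             numeric(0))), 0)
  tab <- run_owsa(p, sc, "costs.drug_annual.alendronate", c(150, 300, 600))
  # the base value reproduces the base-case deltas exactly (same seeds)
  expect_equal(tab$delta_cost[2], base_ic$delta_cost)
  expect_equal(tab$delta_qaly[2], base_ic$delta_qaly)
  expect_error(run_owsa(p, sc, "costs.bogus", 1), "unknown parameter path")
})

test_that("threshold search returns the smallest cost-effective discount", {
  p <- toy_params(p_frac = 0.12, q = 0.03)
  p$efficacy$alendronate$rr[["wrist"]] <- 0.5
  sc <- toy_scenario(n_cycles = 8, n = 1500, seed = 19)
  # infinite willingness to pay: the first grid point qualifies
  th <- threshold_discount(p, sc, wtp = Inf, discounts = c(0.3, 0.5, 0.7))
  expect_equal(as.numeric(th), 0.3)
  # impossible willingness to pay: none found, full curve still reported
  th2 <- threshold_discount(p, sc, wtp = -1e18, discounts = c(0.3, 0.5))
  expect_true(is.na(th2))
  expect_equal(nrow(attr(th2, "curve")), 2)
  # the curve's blended annual costs follow the pricing model
  cv <- attr(th2, "curve")
  expect_equal(cv$annual_cost,
               vapply(cv$discount, teriparatide_annual_cost, numeric(1), 0.9))
})

test_that("PSA is reproducible and point-mass specs collapse it to the base case", {
  p <- toy_params(p_frac = 0.12, q = 0.03)
  p$efficacy$alendronate$rr[["wrist"]] <- 0.5
  p$costs$drug_annual[["alendronate"]] <- 300
  sc <- toy_scenario(n_cycles = 6, n = 500, seed = 23)
  pm_specs <- list(list(path = "costs.drug_annual.alendronate",
                        kind = "point_mass", base = 300))
  psa <- run_psa(p, sc, n_simulations = 3, n_trials = 500, specs = pm_specs)
  # all simulations identical under point-mass draws and shared trial seeds
  expect_equal(psa$draws$delta_cost, rep(psa$draws$delta_cost[1], 3))
  expect_equal(psa$draws$delta_qaly, rep(psa$draws$delta_qaly[1], 3))
  # and identical to the base-case run at the same trial count and seed
  base_ic <- with(run_cea(p, sc), compute_icer(reference, intervention))
  expect_equal(psa$draws$delta_cost[1], base_ic$delta_cost)
  expect_equal(psa$draws$delta_qaly[1], base_ic$delta_qaly)
  # rerun: bit-identical
  psa2 <- run_psa(p, sc, n_simulations = 3, n_trials = 500, specs = pm_specs)
  expect_identical(psa$draws, psa2$draws)
})

test_that("CEAC fractions match hand-counted net-benefit comparisons", {
  draws <- data.frame(delta_cost = c(100, -50, 200, 400),
                      delta_qaly = c(0.01, 0.002, -0.01, 0.004))
  psa <- structure(list(draws = draws, n_simulations = 4, n_trials = 1,
                        seed = 1, perspective = "societal"),
                   class = "osteo_psa")
  cc <- ceac(psa, wtp_grid = c(0, 10000, 50000, 1e6))
  # wtp = 0: fraction with delta_cost <= 0
  expect_equal(cc$probability[1], 0.25)
  # wtp = 10000: NMB = (0, -30, -300, -360) -> 2/4
  expect_equal(cc$probability[2], 0.5)
  # wtp = 50000: NMB = (400, 50, -700, -200) -> 2/4
  expect_equal(cc$probability[3], 0.5)
  # wtp -> large: all positive-QALY draws qualify -> 3/4
  expect_equal(cc$probability[4], 0.75)
  expect_error(ceac(data.frame(delta_cost = numeric(),
                               delta_qaly = numeric())), "empty")
})

test_that("CEAC is non-decreasing in WTP when every QALY delta is positive", {
  draws <- data.frame(delta_cost = rnorm(50, 5000, 2000),
                      delta_qaly = runif(50, 0.001, 0.05))
  cc <- ceac(draws, wtp_grid = seq(0, 5e5, by = 5e4))
  expect_true(all(diff(cc$probability) >= 0))
})
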