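# Deterministic (one-way) sensitivity analysis, the teriparatide price
# threshold analysis, and two-level probabilistic sensitivity analysis (outer
# loop over parameter draws, inner loop of microsimulation trials) with
# cost-effectiveness acceptability curves.

#' Draw from a parameter's uncertainty distribution
#'
#' Distribution recipes (the base value anchors central tendency; the printed
#' interval is read as a 95% central interval except for the triangular,
#' where it is the support):
#' * `triangular`: min = low, mode = base, max = high (inverse-CDF draw).
#' * `beta`: mean = base, sd = (high - low)/3.92, on the natural \[0,1\] support.
#' * `log_normal`: median = base, (low, high) the central 95% interval.
#' * `gamma`: mean = base, sd = (high - low)/3.92.
#' * `point_mass`: always base.
#'
#' @param spec list with `kind` (one of the above), `base`, `low`, `high`.
#' @param n number of draws.
#' @return Numeric vector of `n` draws.
#' @export
#' @examples
#' set.seed(1)
#' sample_parameter(list(kind = "triangular", base = 0.42, low = 0.10, high = 1.0), 3)
sample_parameter <- function(spec, n = 1) {
  kind <- spec$kind
  base <- spec$base
  low <- spec$low %||% base
  high <- spec$high %||% base
  if (kind != "point_mass" && (low > base || base > high)) {
    stop(sprintf("unfittable distribution spec: base %g outside [%g, %g]",
                 base, low, high), call. = FALSE)
  }
  switch(kind,
    point_mass = rep(base, n),
    triangular = rtriangular(n, low, base, high),
    beta = {
      sd <- (high - low) / 3.92
      v <- sd^2
      if (base <= 0 || base >= 1 || v >= base * (1 - base)) {
        stop("unfittable beta spec: need 0 < mean < 1 and sd^2 < mean(1-mean)",
             call. = FALSE)
      }
      k <- base * (1 - base) / v - 1
      stats::rbeta(n, base * k, (1 - base) * k)
    },
    log_normal = {
      if (low <= 0 || base <= 0) {
        stop("unfittable log-normal spec: needs positive base and low",
             call. = FALSE)
      }
      sdlog <- (log(high) - log(low)) / 3.92
      stats::rlnorm(n, meanlog = log(base), sdlog = sdlog)
    },
    gamma = {
      sd <- (high - low) / 3.92
      if (base <= 0 || sd <= 0) {
        stop("unfittable gamma spec: needs positive mean and spread",
             call. = FALSE)
      }
      shape <- base^2 / sd^2
      stats::rgamma(n, shape = shape, rate = shape / base)
    },
    stop(sprintf("unknown distribution kind '%s'", kind), call. = FALSE)
  )
}

# Triangular inverse-CDF sampler (min a, mode m, max b).
rtriangular <- function(n, a, m, b) {
  stopifnot(a <= m, m <= b, a < b)
  u <- stats::runif(n)
  fc <- (m - a) / (b - a)
  ifelse(u < fc,
         a + sqrt(u * (b - a) * (m - a)),
         b - sqrt((1 - u) * (b - a) * (b - m)))
}

#' Uncertainty specifications for the probabilistic sensitivity analysis
#'
#' One entry per uncertain parameter: trial relative risks per drug and
#' fracture kind (beta or triangular as listed), persistence and adherence at
#' 12/24 months (triangular, +/-50%, capped at 1), annual drug costs and the
#' DXA fee (triangular over their printed ranges), fracture treatment costs
#' (log-normal), the monthly long-term-care cost (triangular, 0 to twice
#' base, which maps exactly onto the 0-5154 range of the annual averaged
#' figure), labor-force participation by age band (triangular, +/-50%), and
#' the prior-vertebral-fracture relative risks (gamma). Synthetic age-indexed
#' tables stay fixed. Each entry carries the dot path used by
#' [set_parameter()].
#'
#' @param params parameter set supplying the base values.
#' @return Named list of specs (`path`, `kind`, `base`, `low`, `high`).
#' @export
default_uncertainty_specs <- function(params = default_parameter_set()) {
  specs <- list()
  add <- function(path, kind, base, low, high) {
    specs[[path]] <<- list(path = path, kind = kind, base = base,
                           low = low, high = high)
  }
  for (drug in c("teriparatide", "alendronate")) {
    e <- params$efficacy[[drug]]
    for (k in fracture_kinds()) {
      add(sprintf("efficacy.%s.rr.%s", drug, k), e$dist[[k]],
          e$rr[[k]], e$low[[k]], e$high[[k]])
    }
    a <- params$adherence[[drug]]
    for (f in c("p12", "p24", "a12", "a24")) {
      add(sprintf("adherence.%s.%s", drug, f), "triangular",
          a[[f]], 0.5 * a[[f]], min(1, 1.5 * a[[f]]))
    }
  }
  add("costs.drug_annual.alendronate", "triangular",
      params$costs$drug_annual[["alendronate"]], 86, 324)
  add("costs.drug_annual.teriparatide", "triangular",
      params$costs$drug_annual[["teriparatide"]], 4005, 22646)
  add("costs.dxa", "triangular", params$costs$dxa, 49, 150)
  ft_ranges <- list(hip = c(25677, 42913), clinical_vertebral = c(5775, 15975),
                    wrist = c(2543, 10674), other_osteoporotic = c(10086, 26314))
  for (k in fracture_kinds()) {
    add(sprintf("costs.fracture_treatment.%s", k), "log_normal",
        params$costs$fracture_treatment[[k]], ft_ranges[[k]][1], ft_ranges[[k]][2])
  }
  add("costs.ltc_monthly", "triangular", params$costs$ltc_monthly,
      0, 2 * params$costs$ltc_monthly)
  for (b in c("65-69", "70-74", "75-80")) {
    v <- params$costs$labor_participation[[b]]
    add(sprintf("costs.labor_participation.%s", b), "triangular",
        v, 0.5 * v, min(1, 1.5 * v))
  }
  rr_ranges <- list(hip = c(2.0, 2.8), clinical_vertebral = c(3.6, 5.4),
                    wrist = c(1.2, 2.7), other_osteoporotic = c(1.7, 1.9))
  for (k in fracture_kinds()) {
    add(sprintf("risks.rr_prior_vertebral.%s", k), "gamma",
        params$risks$rr_prior_vertebral[[k]], rr_ranges[[k]][1], rr_ranges[[k]][2])
  }
  specs
}

# Apply one joint draw of all specs to a parameter set, then restore the
# within-drug monotonicity of persistence/adherence (independently sampled
# 24-month values are clamped to their 12-month counterparts).
draw_parameter_set <- function(params, specs) {
  p <- params
  for (s in specs) {
    p <- set_parameter(p, s$path, sample_parameter(s, 1))
  }
  for (drug in c("teriparatide", "alendronate")) {
    a <- p$adherence[[drug]]
    a[["p24"]] <- min(a[["p24"]], a[["p12"]])
    a[["a24"]] <- min(a[["a24"]], a[["a12"]])
    p$adherence[[drug]] <- a
  }
  p
}

#' One-way deterministic sensitivity analysis
#'
#' Rebuilds the parameter set with a single scalar substituted, runs both
#' strategies with the same paired seeds for every value, and returns the
#' incremental results in input order. With the base-case value among
#' `values`, its row reproduces the base-case ICER exactly.
#'
#' @param params base-case parameter set.
#' @param scenario an `osteo_scenario` (strategy field ignored; both run).
#' @param param_path dot path to one scalar, e.g.
#'   `"costs.drug_annual.teriparatide"`.
#' @param values values to substitute.
#' @param perspective cost perspective for the ICER.
#' @return data.frame of class `osteo_owsa`: value, delta_cost, delta_qaly,
#'   icer, label.
#' @export
run_owsa <- function(params, scenario, param_path, values,
                     perspective = "societal") {
  get_parameter(params, param_path) # validates the path up front
  rows <- lapply(values, function(v) {
    cea <- run_cea(set_parameter(params, param_path, v), scenario)
    ic <- compute_icer(cea$reference, cea$intervention, perspective)
    data.frame(value = v, delta_cost = ic$delta_cost,
               delta_qaly = ic$delta_qaly, icer = ic$icer, label = ic$label)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(value = numeric(), delta_cost = numeric(),
               delta_qaly = numeric(), icer = numeric(), label = character())
  attr(out, "param_path") <- param_path
  class(out) <- c("osteo_owsa", "data.frame")
  out
}

#' Teriparatide price-threshold analysis
#'
#' Walks the generic/biosimilar discount grid (30%..95% in 5% steps in the
#' source analyses), recomputes the blended annual teriparatide cost at the
#' given market share, reruns both strategies with paired seeds, and reports
#' the smallest discount at which the sequential strategy is cost-effective
#' at the willingness-to-pay threshold (net monetary benefit
#' `wtp * dQALY - dCost >= 0`, which equals ICER <= WTP whenever the QALY
#' gain is positive and also accepts dominance).
#'
#' @param params base-case parameter set.
#' @param scenario an `osteo_scenario`.
#' @param wtp willingness-to-pay threshold, $/QALY.
#' @param share generic/biosimilar market share.
#' @param discounts discount grid (fractions off brand).
#' @param perspective cost perspective.
#' @return The smallest cost-effective discount (NA if none), with the full
#'   grid curve attached as attribute `"curve"` (data.frame: discount,
#'   annual_cost, delta_cost, delta_qaly, icer, cost_effective).
#' @export
threshold_discount <- function(params, scenario, wtp, share = 0.9,
                               discounts = seq(0.30, 0.95, by = 0.05),
                               perspective = "societal") {
  stopifnot(length(discounts) > 0, all(discounts >= 0 & discounts <= 1))
  brand <- annual_drug_cost(params$pricing$teriparatide$brand_unit_price,
                            params$pricing$teriparatide$fills_per_year,
                            params$pricing$teriparatide$brand_price_factor)
  rows <- lapply(discounts, function(d) {
    ann <- teriparatide_annual_cost(d, share, brand)
    cea <- run_cea(set_parameter(params, "costs.drug_annual.teriparatide", ann),
                   scenario)
    ic <- compute_icer(cea$reference, cea$intervention, perspective)
    nmb <- wtp * ic$delta_qaly - ic$delta_cost
    data.frame(discount = d, annual_cost = ann, delta_cost = ic$delta_cost,
               delta_qaly = ic$delta_qaly, icer = ic$icer,
               cost_effective = nmb >= 0)
  })
  curve <- do.call(rbind, rows)
  hit <- curve$discount[curve$cost_effective]
  out <- if (length(hit)) min(hit) else NA_real_
  attr(out, "curve") <- curve
  out
}

#' Two-level probabilistic sensitivity analysis
#'
#' Outer loop: one joint draw of every uncertain parameter per simulation.
#' Inner loop: `n_trials` microsimulated individuals per strategy, with
#' individual-level seeds depending only on the trial index, so strategies
#' are paired within a simulation and the same underlying randomness is
#' reused across simulations (all variation between simulations comes from
#' the parameter draws; with all-point-mass specs every simulation reproduces
#' the base case exactly).
#'
#' @param params base-case parameter set.
#' @param scenario an `osteo_scenario`; `n_individuals` is overridden by
#'   `n_trials`.
#' @param n_simulations outer parameter draws (1000 in the source analyses).
#' @param n_trials microsimulation trials per simulation (10,000 in the
#'   source analyses).
#' @param specs uncertainty specs; default [default_uncertainty_specs()].
#' @param perspective cost perspective for the incremental pairs.
#' @return Object of class `osteo_psa`: data.frame `draws` with one
#'   (delta_cost, delta_qaly) pair per simulation, plus sizes and the seed.
#' @export
run_psa <- function(params, scenario, n_simulations = 1000, n_trials = 10000,
                    specs = default_uncertainty_specs(params),
                    perspective = "societal") {
  sc <- scenario
  sc$n_individuals <- as.integer(n_trials)
  draws <- vector("list", n_simulations)
  for (j in seq_len(n_simulations)) {
    set.seed(substream_seed(scenario$master_seed, "psa_outer", j))
    pj <- draw_parameter_set(params, specs)
    cea <- run_cea(pj, sc)
    ic <- compute_icer(cea$reference, cea$intervention, perspective)
    draws[[j]] <- data.frame(sim = j, delta_cost = ic$delta_cost,
                             delta_qaly = ic$delta_qaly)
  }
  out <- list(draws = do.call(rbind, draws), n_simulations = n_simulations,
              n_trials = as.integer(n_trials), seed = scenario$master_seed,
              perspective = perspective)
  class(out) <- "osteo_psa"
  out
}

#' @export
print.osteo_psa <- function(x, ...) {
  cat(sprintf("PSA: %d simulations x %s trials (seed %d, %s perspective)\n",
              x$n_simulations, format(x$n_trials, big.mark = ","), x$seed,
              x$perspective))
  cat(sprintf("  mean dCost $%s, mean dQALY %.5f\n",
              format(round(mean(x$draws$delta_cost)), big.mark = ","),
              mean(x$draws$delta_qaly)))
  invisible(x)
}

#' @export
plot.osteo_psa <- function(x, wtp = 150000, ...) {
  graphics::plot(x$draws$delta_qaly, x$draws$delta_cost,
                 xlab = "Incremental QALYs", ylab = "Incremental cost ($)",
                 main = "Cost-effectiveness plane", pch = 20,
                 col = "grey40", ...)
  graphics::abline(h = 0, v = 0, col = "grey70")
  graphics::abline(a = 0, b = wtp, lty = 2)
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the fraction of PSA simulations in
#' which the intervention has non-negative net monetary benefit,
#' `wtp * delta_qaly - delta_cost >= 0`.
#'
#' @param psa an `osteo_psa` object (or a data.frame with `delta_cost`,
#'   `delta_qaly`).
#' @param wtp_grid willingness-to-pay values, $/QALY.
#' @return data.frame of class `osteo_ceac`: wtp, probability.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 300000, by = 10000)) {
  draws <- if (inherits(psa, "osteo_psa")) psa$draws else psa
  if (nrow(draws) == 0) stop("ceac: empty PSA", call. = FALSE)
  prob <- vapply(wtp_grid, function(w) {
    mean(w * draws$delta_qaly - draws$delta_cost >= 0)
  }, numeric(1))
  out <- data.frame(wtp = wtp_grid, probability = prob)
  class(out) <- c("osteo_ceac", "data.frame")
  out
}

#' @export
plot.osteo_ceac <- function(x, ...) {
  graphics::plot(x$wtp, x$probability, type = "l", ylim = c(0, 1),
                 xlab = "Willingness to pay ($/QALY)",
                 ylab = "P(cost-effective)",
                 main = "Cost-effectiveness acceptability curve", ...)
  invisible(x)
}
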