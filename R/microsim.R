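# Annual-cycle individual-level simulation. Each woman is walked from the
# start age to death or age 105. Within a cycle the order is: death draw,
# fracture draw (at most one fracture per cycle, competing among the four
# kinds), tracker/state updates, then cost and utility accrual. Tracker
# variables carry memory: per-kind fracture history, hip fracture count
# (capped at two), post-hip-fracture state (absorbing until death), long-term
# care entry, and treatment status.

#' Per-cycle fracture probability after risk modifiers
#'
#' Baseline general-population incidence multiplied by the prior-vertebral-
#' fracture and osteoporosis relative risks (multiplicative combination) and
#' the effective treatment relative risk, clamped to \[0,1\].
#'
#' @param baseline_rate annual incidence for this age and fracture kind.
#' @param rr_prior_vertebral relative risk from prior vertebral fracture.
#' @param rr_osteoporosis relative risk from osteoporosis versus the general
#'   population.
#' @param treatment_rr effective treatment relative risk this cycle (1 when
#'   untreated).
#' @return Per-cycle fracture probability.
#' @export
#' @examples
#' fracture_probability(0.01, 2.3, 2.0)         # 0.046
#' fracture_probability(0.01, 2.3, 2.0, 0.565)  # 0.02599
fracture_probability <- function(baseline_rate, rr_prior_vertebral,
                                 rr_osteoporosis, treatment_rr = 1) {
  stopifnot(baseline_rate >= 0, rr_prior_vertebral >= 0, rr_osteoporosis >= 0,
            treatment_rr >= 0)
  pmin(1, pmax(0, baseline_rate * rr_prior_vertebral * rr_osteoporosis *
                 treatment_rr))
}

#' Per-cycle death probability
#'
#' Individuals with no hip-fracture history die at the life-table rate
#' `q(age)`. After a hip fracture, lifelong excess mortality applies, but only
#' a fraction of the excess is attributable to the fracture itself:
#' `q' = q * (1 + attributable_fraction * (excess_rr - 1))`, clamped to 1.
#'
#' @param q life-table annual death probability at the current age.
#' @param post_hip logical; any prior hip fracture.
#' @param excess_rr lifelong all-cause mortality relative risk after hip
#'   fracture.
#' @param attributable_fraction fraction of the excess attributable to the
#'   fracture (0.25: comorbidity explains the rest).
#' @return Per-cycle death probability.
#' @export
#' @examples
#' mortality_probability(0.04, TRUE, 2, 0.25)  # 0.05
mortality_probability <- function(q, post_hip, excess_rr = 1,
                                  attributable_fraction = 0.25) {
  stopifnot(q >= 0, q <= 1, excess_rr >= 0,
            attributable_fraction >= 0, attributable_fraction <= 1)
  ifelse(post_hip, pmin(1, q * (1 + attributable_fraction * (excess_rr - 1))), q)
}

# Competing-event draw shared by draw_cycle_event() and the engine: at most
# one fracture per cycle; P(any) = 1 - prod(1 - p_k); conditional on a
# fracture the kind is chosen proportional to p_k. Returns 0L (no event) or
# the kind index.
.competing_event <- function(probs, u_any, u_kind) {
  total <- sum(probs)
  if (total <= 0) return(0L)
  p_any <- 1 - prod(1 - probs)
  if (u_any >= p_any) return(0L)
  cum <- cumsum(probs / total)
  which(u_kind <= cum)[1]
}

#' Draw the (at most one) fracture event for a cycle
#'
#' The probability of any fracture is `1 - prod(1 - p_k)`; conditional on a
#' fracture, the kind is drawn proportional to the per-kind probabilities.
#' Hip is excluded (probability forced to zero) once an individual has had two
#' hip fractures; the remaining kinds are not renormalised upward.
#'
#' @param probs named per-kind fracture probabilities, in [fracture_kinds()]
#'   order.
#' @param hip_blocked logical; individual already has two hip fractures.
#' @param u_any,u_kind uniform(0,1) draws (defaults draw from the session RNG).
#' @return The fracture kind as a string, or `"none"`.
#' @export
draw_cycle_event <- function(probs, hip_blocked = FALSE,
                             u_any = stats::runif(1), u_kind = stats::runif(1)) {
  stopifnot(length(probs) == 4, all(probs >= 0), all(probs <= 1))
  if (hip_blocked) probs[1] <- 0
  k <- .competing_event(probs, u_any, u_kind)
  if (k == 0L) "none" else fracture_kinds()[k]
}

# ---- simulation context ----------------------------------------------------

# Precomputes everything that does not vary across individuals: per-cycle
# baseline fracture probabilities (incidence x risk modifiers), mortality,
# utilities, discount factors, and per-drug schedules (adherence by year,
# community relative risks by on-treatment year, per-year drug/visit/DXA
# charges).
make_sim_context <- function(params, scenario) {
  kinds <- fracture_kinds()
  n_cycles <- scenario$horizon_end_age - scenario$start_age
  ages <- scenario$start_age + seq_len(n_cycles) - 1

  mt <- params$mortality
  q0 <- mt$q[match(ages, mt$age)]
  if (anyNA(q0)) stop("mortality table does not cover the simulated ages", call. = FALSE)

  it <- params$incidence
  rows <- match(ages, it$age)
  if (anyNA(rows)) stop("incidence table does not cover the simulated ages", call. = FALSE)
  mod <- params$risks$rr_prior_vertebral[kinds] * params$risks$rr_osteoporosis[kinds]
  p_base <- sweep(as.matrix(it[rows, kinds]), 2, mod, `*`)
  p_base <- pmin(p_base, 1)

  ub <- params$utilities$baseline
  u_base <- ub$utility[match(ages, ub$age)]
  if (anyNA(u_base)) stop("utility table does not cover the simulated ages", call. = FALSE)

  disc_f <- (1 + scenario$discount_rate)^-(seq_len(n_cycles) - 1)

  make_phase <- function(drug, start_cycle) {
    pl <- params$plans[[drug]]
    a <- as.list(params$adherence[[drug]])
    dur <- pl$duration_years
    adh <- adherence_at(a, seq_len(dur))
    factor <- efficacy_scaling_factor(adh, params$plans$trial_adherence)
    rr_comm <- outer(factor, params$efficacy[[drug]]$rr[kinds],
                     function(f, rr) 1 - f * (1 - rr))
    dxa_years <- if (drug == "teriparatide") 2 else c(5, 10)
    visits <- if (drug == "teriparatide") 2 else 1
    # per fully-persisted on-treatment year: drug (adherence-prorated),
    # physician visits, and DXA in scheduled years
    year_cost <- params$costs$drug_annual[[drug]] * adh +
      visits * params$costs$physician_visit +
      ifelse(seq_len(dur) %in% dxa_years, params$costs$dxa, 0)
    list(drug = drug, start = start_cycle, duration = dur,
         washout = pl$washout_years, schedule = a, rr_comm = rr_comm,
         year_cost = year_cost,
         first_year_charge = 0.25 * params$costs$drug_annual[[drug]])
  }

  phases <- switch(scenario$strategy,
    sequential = list(make_phase("teriparatide", 1),
                      make_phase("alendronate", 3)),
    alendronate_alone = list(make_phase("alendronate", 1)),
    none = list()
  )

  co <- params$costs
  ri <- params$risks
  band <- ifelse(ages < 70, "65-69", ifelse(ages < 75, "70-74", "75-80"))
  productivity <- ifelse(ages <= 80,
                         co$weekly_earnings * co$productivity_weeks *
                           co$labor_participation[band], 0)

  list(kinds = kinds, n_cycles = n_cycles, ages = ages, q0 = q0,
       p_base = p_base, u_base = u_base, disc_f = disc_f, phases = phases,
       frac_cost = co$fracture_treatment[kinds],
       ltc_acute = 6 * co$ltc_monthly * co$ltc_attributable_fraction,
       ltc_posthip_annual = co$ltc_monthly * 12 * co$ltc_stay_fraction *
         co$ltc_attributable_fraction,
       ltc_stay_fraction = co$ltc_stay_fraction,
       productivity = productivity,
       ut_first = params$utilities$first_year[kinds],
       ut_subs = params$utilities$subsequent[kinds],
       excess_mult = 1 + ri$excess_attributable_fraction *
         (ri$hip_excess_mortality_rr - 1),
       scenario = scenario)
}

# Treatment course for one individual: sampled discontinuation months turn
# into a per-cycle treatment relative-risk matrix (minimum across concurrent
# drug effects) and a per-cycle on-treatment charge vector. In the sequential
# strategy the alendronate phase is reached only by teriparatide completers;
# discontinuers never re-initiate.
individual_course <- function(ctx, u1, u2) {
  n <- ctx$n_cycles
  rr <- matrix(1, n, 4)
  cost <- numeric(n)
  if (length(ctx$phases) == 0) return(list(rr = rr, cost = cost))

  apply_phase <- function(ph, u) {
    m <- sample_discontinuation_month(ph$schedule, u)
    yrs <- min(floor(m / 12), ph$duration) # fully persisted years
    if (yrs == 0) {
      # discontinued within the first year: one 3-month fill, no efficacy
      if (ph$start <= n) cost[ph$start] <<- cost[ph$start] + ph$first_year_charge
      return(FALSE)
    }
    on_cycles <- ph$start + seq_len(yrs) - 1
    keep <- on_cycles <= n
    if (any(keep)) {
      cost[on_cycles[keep]] <<- cost[on_cycles[keep]] + ph$year_cost[seq_len(yrs)][keep]
      rr[on_cycles[keep], ] <<- pmin(rr[on_cycles[keep], , drop = FALSE],
                                     ph$rr_comm[seq_len(yrs)[keep], , drop = FALSE])
    }
    rr_stop <- ph$rr_comm[yrs, ]
    w_eff <- effective_washout_years(ph$washout, yrs, ph$duration)
    j <- 1
    repeat {
      t <- ph$start + yrs - 1 + j
      if (t > n) break
      r <- offset_rr_row(rr_stop, j - 0.5, w_eff)
      if (all(r >= 1)) break
      rr[t, ] <<- pmin(rr[t, ], r)
      j <- j + 1
    }
    yrs == ph$duration # completed the full course
  }

  completed1 <- apply_phase(ctx$phases[[1]], u1)
  if (length(ctx$phases) > 1 && completed1) {
    apply_phase(ctx$phases[[2]], u2)
  }
  list(rr = rr, cost = cost)
}

# offset_rr for a vector of per-kind stop values at one time point; cycle j
# after stopping is evaluated at its midpoint (j - 0.5 years since stop).
offset_rr_row <- function(rr_stop, years_since_stop, washout_years) {
  if (washout_years <= 0) return(rep(1, length(rr_stop)))
  frac <- min(1, years_since_stop / washout_years)
  rr_stop + (1 - rr_stop) * frac
}

# Core per-individual walk. Consumes a fixed layout of uniforms (two
# discontinuation draws, then four per cycle: death, any-fracture, kind, LTC)
# so that paired strategies see identical underlying randomness.
sim_one <- function(ctx, seed, keep_trajectory = FALSE) {
  set.seed(seed)
  u_disc <- stats::runif(2)
  n <- ctx$n_cycles
  U <- matrix(stats::runif(4 * n), n, 4)
  course <- individual_course(ctx, u_disc[1], u_disc[2])

  hip_count <- 0L
  post_hip <- FALSE
  in_ltc <- FALSE
  hist <- rep(FALSE, 4)
  cost_hcs <- 0
  cost_nhc <- 0
  qaly <- 0
  frac_counts <- integer(4)
  died <- FALSE
  cycles_lived <- 0L
  rec <- if (keep_trajectory) vector("list", n) else NULL

  for (t in seq_len(n)) {
    q <- if (post_hip) min(1, ctx$q0[t] * ctx$excess_mult) else ctx$q0[t]
    if (U[t, 1] < q) {
      died <- TRUE
      if (keep_trajectory) {
        rec[[t]] <- list(cycle = t - 1L, age = ctx$ages[t], event = "death",
                         cost_treatment = 0, cost_fracture = 0, cost_ltc = 0,
                         cost_productivity = 0, utility = 0)
      }
      break
    }
    p <- ctx$p_base[t, ] * course$rr[t, ]
    if (hip_count >= 2L) p[1] <- 0
    k <- .competing_event(p, U[t, 2], U[t, 3])

    c_treat <- course$cost[t]
    c_frac <- 0
    c_ltc <- if (post_hip) ctx$ltc_posthip_annual else 0
    c_prod <- 0
    if (k > 0L) {
      frac_counts[k] <- frac_counts[k] + 1L
      c_frac <- ctx$frac_cost[[k]]
      if (k == 1L) {
        hip_count <- hip_count + 1L
        if (U[t, 4] < ctx$ltc_stay_fraction) {
          in_ltc <- TRUE
          c_ltc <- c_ltc + ctx$ltc_acute
        }
        c_prod <- ctx$productivity[t]
      }
    }

    mult <- 1
    for (j in 1:4) {
      if (k == j) mult <- mult * ctx$ut_first[[j]]
      else if (hist[j]) mult <- mult * ctx$ut_subs[[j]]
    }
    u_cycle <- ctx$u_base[t] * mult

    d <- ctx$disc_f[t]
    cost_hcs <- cost_hcs + (c_treat + c_frac) * d
    cost_nhc <- cost_nhc + (c_ltc + c_prod) * d
    qaly <- qaly + u_cycle * d

    if (k > 0L) {
      hist[k] <- TRUE
      if (k == 1L) post_hip <- TRUE
    }
    cycles_lived <- t
    if (keep_trajectory) {
      rec[[t]] <- list(cycle = t - 1L, age = ctx$ages[t],
                       event = if (k == 0L) "none" else ctx$kinds[k],
                       cost_treatment = c_treat, cost_fracture = c_frac,
                       cost_ltc = c_ltc, cost_productivity = c_prod,
                       utility = u_cycle)
    }
  }

  out <- list(cost_hcs = cost_hcs, cost_nhc = cost_nhc, qaly = qaly,
              frac_counts = frac_counts, died = died,
              cycles_lived = cycles_lived, in_ltc = in_ltc)
  if (keep_trajectory) {
    out$trajectory <- do.call(rbind, lapply(rec[!vapply(rec, is.null, TRUE)],
                                            as.data.frame))
  }
  out
}

#' Simulate one individual's trajectory
#'
#' Walks a single woman through annual cycles from the scenario start age to
#' death or the horizon age, and returns the per-cycle record: cycle index,
#' age, event (fracture kind, `"none"`, or `"death"`), undiscounted costs by
#' component, and the utility accrued. Totals (discounted at the scenario
#' rate) are attached as attributes. Reproducible given `seed`.
#'
#' @param params an `osteo_params` parameter set.
#' @param scenario an `osteo_scenario` from [make_scenario()].
#' @param seed integer seed for this individual's random stream.
#' @return A data.frame of class `osteo_trajectory` with attributes
#'   `cost_health_care`, `cost_non_health_care`, `qaly` (discounted totals),
#'   `died`, and `fracture_counts`.
#' @export
simulate_individual <- function(params, scenario, seed) {
  ctx <- make_sim_context(params, scenario)
  r <- sim_one(ctx, seed, keep_trajectory = TRUE)
  tr <- r$trajectory
  attr(tr, "cost_health_care") <- r$cost_hcs
  attr(tr, "cost_non_health_care") <- r$cost_nhc
  attr(tr, "qaly") <- r$qaly
  attr(tr, "died") <- r$died
  attr(tr, "fracture_counts") <- setNames(r$frac_counts, ctx$kinds)
  class(tr) <- c("osteo_trajectory", class(tr))
  tr
}

#' Run a Monte-Carlo cohort for one strategy
#'
#' Simulates `n_individuals` women one at a time and summarises discounted
#' costs (by sector) and QALYs with Monte-Carlo standard errors, plus lifetime
#' fracture risks and survival diagnostics. Per-individual seeds derive from
#' the scenario's master seed; with `common_random_numbers` they depend only
#' on the individual index, so cohorts run under different strategies (or
#' perturbed parameters) are paired draw-for-draw.
#'
#' @param params an `osteo_params` parameter set.
#' @param scenario an `osteo_scenario`; `scenario$strategy` selects the
#'   treatment strategy.
#' @return An object of class `osteo_cohort`: strategy, n, `mean_cost`
#'   (named: societal, health_care_sector), `mean_qaly`, standard errors,
#'   lifetime fracture risks, mean life years, and the fraction dead by the
#'   horizon. Per-individual cost/QALY totals are kept in `$totals` and
#'   per-individual fracture counts in `$counts`.
#' @export
run_cohort <- function(params, scenario) {
  ctx <- make_sim_context(params, scenario)
  n <- scenario$n_individuals
  strat_idx <- match(scenario$strategy,
                     c("sequential", "alendronate_alone", "none"))
  totals <- matrix(0, n, 3, dimnames = list(NULL, c("cost_hcs", "cost_nhc", "qaly")))
  fracs <- matrix(0L, n, 4)
  died <- logical(n)
  lived <- integer(n)
  for (i in seq_len(n)) {
    idx <- if (scenario$common_random_numbers) i else i + n * strat_idx
    r <- sim_one(ctx, substream_seed(scenario$master_seed, "individual", idx))
    totals[i, ] <- c(r$cost_hcs, r$cost_nhc, r$qaly)
    fracs[i, ] <- r$frac_counts
    died[i] <- r$died
    lived[i] <- r$cycles_lived
  }
  soc <- totals[, 1] + totals[, 2]
  hcs <- totals[, 1]
  out <- list(
    strategy = scenario$strategy,
    n = n,
    mean_cost = c(societal = mean(soc), health_care_sector = mean(hcs)),
    se_cost = c(societal = stats::sd(soc) / sqrt(n),
                health_care_sector = stats::sd(hcs) / sqrt(n)),
    mean_qaly = mean(totals[, 3]),
    se_qaly = stats::sd(totals[, 3]) / sqrt(n),
    lifetime_risk = setNames(colMeans(fracs > 0), ctx$kinds),
    mean_fractures = setNames(colMeans(fracs), ctx$kinds),
    prop_dead = mean(died),
    mean_life_years = mean(lived),
    totals = totals,
    counts = `colnames<-`(fracs, ctx$kinds),
    scenario = scenario
  )
  class(out) <- "osteo_cohort"
  out
}

#' @export
print.osteo_cohort <- function(x, ...) {
  cat(sprintf("Strategy: %s (n = %s, start age %d)\n", x$strategy,
              format(x$n, big.mark = ","), x$scenario$start_age))
  cat(sprintf("  mean discounted cost: $%s (societal), $%s (health care sector)\n",
              format(round(x$mean_cost[["societal"]]), big.mark = ","),
              format(round(x$mean_cost[["health_care_sector"]]), big.mark = ",")))
  cat(sprintf("  mean discounted QALYs: %.2f (SE %.4f)\n", x$mean_qaly, x$se_qaly))
  cat(sprintf("  dead by age %d: %.1f%%\n", x$scenario$horizon_end_age,
              100 * x$prop_dead))
  invisible(x)
}
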