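# Discounting, per-cycle cost and utility accounting, and incremental
# cost-effectiveness ratios. Costs are tagged by sector: medications,
# physician visits, DXA and fracture treatment belong to the formal health
# care sector; long-term care and unpaid lost productivity are non-health-care
# components, counted only under the societal perspective.

#' Discount a value accrued in a given cycle
#'
#' `value / (1 + rate)^cycle_index`; cycle 0 (the first year) is undiscounted.
#'
#' @param value cost (USD) or utility (QALY) amount.
#' @param cycle_index 0-based cycle index.
#' @param rate annual discount rate (0.03 in the base case).
#' @return Discounted value.
#' @export
#' @examples
#' discount(103, 1, 0.03)  # 100
discount <- function(value, cycle_index, rate) {
  stopifnot(cycle_index >= 0)
  value / (1 + rate)^cycle_index
}

#' Costs accrued in one cycle, by component
#'
#' Components: `treatment` (drug charge plus physician visits plus any
#' scheduled DXA; health care sector), `fracture` (treatment cost of a
#' fracture sustained this cycle; health care sector), `ltc` (long-term care:
#' the attributable 6-month acute cost in a hip-fracture year for those drawn
#' into long-term care, and the population-averaged annual cost while in the
#' post-hip-fracture state; non-health-care sector), and `productivity`
#' (unpaid lost productivity in a hip-fracture year through age 80;
#' non-health-care sector). Under the health-care-sector perspective the
#' non-health-care components are dropped (set to zero).
#'
#' @param params an `osteo_params` parameter set.
#' @param age age during the cycle.
#' @param event fracture kind sustained this cycle, or `"none"`.
#' @param treatment_charge drug + visit + DXA charge for this cycle (from the
#'   treatment course; see [cycle_drug_charge()]).
#' @param post_hip logical; in the post-hip-fracture state (entered in an
#'   earlier cycle).
#' @param entered_ltc logical; this cycle's hip fracture led to long-term-care
#'   placement.
#' @param perspective `"societal"` or `"health_care_sector"`.
#' @return Named numeric: treatment, fracture, ltc, productivity.
#' @export
cycle_costs <- function(params, age, event = "none", treatment_charge = 0,
                        post_hip = FALSE, entered_ltc = FALSE,
                        perspective = c("societal", "health_care_sector")) {
  perspective <- match.arg(perspective)
  co <- params$costs
  kinds <- fracture_kinds()
  out <- c(treatment = treatment_charge, fracture = 0, ltc = 0,
           productivity = 0)
  if (post_hip) {
    out[["ltc"]] <- co$ltc_monthly * 12 * co$ltc_stay_fraction *
      co$ltc_attributable_fraction
  }
  if (event != "none") {
    if (!event %in% kinds) stop(sprintf("unknown fracture kind '%s'", event),
                                call. = FALSE)
    out[["fracture"]] <- co$fracture_treatment[[event]]
    if (event == "hip") {
      if (entered_ltc) {
        out[["ltc"]] <- out[["ltc"]] + 6 * co$ltc_monthly *
          co$ltc_attributable_fraction
      }
      if (age <= 80) {
        band <- if (age < 70) "65-69" else if (age < 75) "70-74" else "75-80"
        out[["productivity"]] <- co$weekly_earnings * co$productivity_weeks *
          co$labor_participation[[band]]
      }
    }
  }
  if (perspective == "health_care_sector") {
    out[["ltc"]] <- 0
    out[["productivity"]] <- 0
  }
  out
}

#' Utility accrued in one cycle
#'
#' Age-specific baseline utility multiplied by the active disutility
#' multipliers: the first-year multiplier of a fracture sustained this cycle,
#' and the subsequent-year multiplier of every previously fractured kind (hip
#' and clinical vertebral carry lifelong disutility; wrist and other carry
#' none beyond the first year). Multipliers from different kinds stack
#' multiplicatively; repeat fractures of one kind do not stack.
#'
#' @param params an `osteo_params` parameter set.
#' @param age age during the cycle.
#' @param event fracture kind sustained this cycle, or `"none"`.
#' @param history character vector of kinds fractured in earlier cycles.
#' @return QALYs accrued this cycle (one year at the adjusted utility).
#' @export
#' @examples
#' p <- default_parameter_set()
#' cycle_utility(p, 70, history = c("hip", "clinical_vertebral"))
cycle_utility <- function(params, age, event = "none", history = character()) {
  ub <- params$utilities$baseline
  base <- ub$utility[match(age, ub$age)]
  if (is.na(base)) stop("age outside the utility table", call. = FALSE)
  mult <- 1
  for (j in fracture_kinds()) {
    if (identical(event, j)) {
      mult <- mult * params$utilities$first_year[[j]]
    } else if (j %in% history) {
      mult <- mult * params$utilities$subsequent[[j]]
    }
  }
  base * mult
}

#' Incremental cost-effectiveness ratio between two strategy results
#'
#' Deltas are intervention minus reference. If the intervention accrues more
#' QALYs at lower cost it dominates (`"dominant"`); fewer QALYs at higher cost
#' and it is dominated (`"dominated"`); zero QALY difference leaves the ICER
#' undefined. Otherwise the ICER is `delta_cost / delta_qaly` in $/QALY.
#'
#' @param reference the comparator [run_cohort()] result (or any list with
#'   `mean_cost` and `mean_qaly`).
#' @param intervention the intervention result.
#' @param perspective which cost perspective to compare.
#' @return An object of class `osteo_icer`: `delta_cost`, `delta_qaly`,
#'   `icer` (NA when dominance or a zero QALY delta makes it undefined), and
#'   `label` in `{"icer", "dominant", "dominated", "undefined"}`.
#' @export
#' @examples
#' a <- list(mean_cost = c(societal = 100), mean_qaly = 1)
#' b <- list(mean_cost = c(societal = 200), mean_qaly = 2)
#' compute_icer(a, b)$icer  # 100
compute_icer <- function(reference, intervention,
                         perspective = c("societal", "health_care_sector")) {
  perspective <- match.arg(perspective)
  cost_of <- function(x) {
    mc <- x$mean_cost
    if (length(mc) > 1 || !is.null(names(mc))) mc[[perspective]] else mc
  }
  dc <- cost_of(intervention) - cost_of(reference)
  dq <- intervention$mean_qaly - reference$mean_qaly
  out <- list(delta_cost = dc, delta_qaly = dq, perspective = perspective)
  if (dq == 0) {
    out$icer <- NA_real_
    out$label <- "undefined"
  } else if (dq > 0 && dc < 0) {
    out$icer <- NA_real_
    out$label <- "dominant"
  } else if (dq < 0 && dc > 0) {
    out$icer <- NA_real_
    out$label <- "dominated"
  } else {
    out$icer <- dc / dq
    out$label <- "icer"
  }
  class(out) <- "osteo_icer"
  out
}

#' @export
print.osteo_icer <- function(x, ...) {
  lab <- switch(x$label,
                icer = sprintf("$%s/QALY",
                               format(round(x$icer / 100) * 100, big.mark = ",")),
                dominant = "dominant (more QALYs, lower cost)",
                dominated = "dominated (fewer QALYs, higher cost)",
                undefined = "undefined (zero QALY difference)")
  cat(sprintf("ICER (%s): %s  [dCost $%s, dQALY %.5f]\n", x$perspective, lab,
              format(round(x$delta_cost), big.mark = ","), x$delta_qaly))
  invisible(x)
}

# ---- base-case comparison ---------------------------------------------------

#' Run the base-case cost-effectiveness comparison
#'
#' Simulates both strategies (alendronate alone as the reference, sequential
#' teriparatide/alendronate as the intervention) under one scenario with
#' paired random streams, and computes ICERs from both the societal and the
#' health-care-sector perspective.
#'
#' @param params an `osteo_params` parameter set.
#' @param scenario an `osteo_scenario`; its `strategy` field is ignored (both
#'   strategies are run).
#' @return An object of class `osteo_cea` with elements `reference`,
#'   `intervention` (both `osteo_cohort`), `icer` (list by perspective), and
#'   `scenario`.
#' @export
#' @examples
#' \donttest{
#' p <- default_parameter_set()
#' cea <- run_cea(p, make_scenario(start_age = 65, n_individuals = 500))
#' print(cea)
#' }
run_cea <- function(params, scenario = make_scenario()) {
  ref_sc <- scenario
  ref_sc$strategy <- "alendronate_alone"
  int_sc <- scenario
  int_sc$strategy <- "sequential"
  reference <- run_cohort(params, ref_sc)
  intervention <- run_cohort(params, int_sc)
  out <- list(
    reference = reference,
    intervention = intervention,
    icer = list(
      societal = compute_icer(reference, intervention, "societal"),
      health_care_sector = compute_icer(reference, intervention,
                                        "health_care_sector")
    ),
    scenario = scenario
  )
  class(out) <- "osteo_cea"
  out
}

#' @export
print.osteo_cea <- function(x, ...) {
  cat(sprintf("Cost-effectiveness, start age %d (n = %s per strategy, 3%% discounting)\n",
              x$scenario$start_age, format(x$reference$n, big.mark = ",")))
  fmt <- function(coh, persp) {
    sprintf("$%s / %.2f QALYs",
            format(round(coh$mean_cost[[persp]]), big.mark = ","), coh$mean_qaly)
  }
  for (persp in c("societal", "health_care_sector")) {
    cat(sprintf("  [%s]\n", gsub("_", " ", persp)))
    cat(sprintf("    alendronate alone:         %s\n", fmt(x$reference, persp)))
    cat(sprintf("    teriparatide/alendronate:  %s\n", fmt(x$intervention, persp)))
    ic <- x$icer[[persp]]
    lab <- if (ic$label == "icer") {
      sprintf("$%s/QALY", format(round(ic$icer / 100) * 100, big.mark = ","))
    } else ic$label
    cat(sprintf("    ICER: %s\n", lab))
  }
  invisible(x)
}

#' @export
summary.osteo_cea <- function(object, ...) {
  rows <- lapply(c("societal", "health_care_sector"), function(persp) {
    data.frame(
      perspective = persp,
      strategy = c("alendronate_alone", "sequential"),
      cost = round(c(object$reference$mean_cost[[persp]],
                     object$intervention$mean_cost[[persp]])),
      qaly = round(c(object$reference$mean_qaly,
                     object$intervention$mean_qaly), 2),
      icer = c(NA, if (object$icer[[persp]]$label == "icer") {
        round(object$icer[[persp]]$icer / 100) * 100
      } else NA),
      label = c("reference", object$icer[[persp]]$label)
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("summary_osteo_cea", "data.frame")
  out
}
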