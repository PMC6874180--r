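# The model's complete input bundle: efficacy, persistence/adherence,
# treatment plans, pricing primitives, costs with sector tags, risk
# modifiers, utilities, mortality, and fracture incidence. Everything the
# simulation consumes is validated here.

#' Default parameter set
#'
#' Builds the base-case parameter bundle. Literature-printed values (trial
#' relative risks, persistence/adherence at 12/24 months, unit prices and
#' price factors, physician visit and DXA fees, fracture treatment costs,
#' long-term-care and productivity assumptions, relative risks for prior
#' vertebral fracture) are carried verbatim in 2018 US dollars. Age-indexed
#' tables with no printed source (fracture incidence, baseline utilities,
#' disutility multipliers, the life table) and the osteoporosis and hip
#' excess-mortality relative risks are synthetic defaults from the
#' `generate_*` family and are flagged as such in `$synthetic_inputs`.
#'
#' Annual drug costs are derived from the pricing primitives at build time:
#' alendronate blends generic ($6.13833/tablet, 52 fills, 27% of AWP) with
#' brand ($38.3525/tablet, 52 fills, 64% of AWP) at 90% generic share;
#' teriparatide blends a 30%-discounted generic/biosimilar with brand
#' ($3426.50 per 28-day fill, 13 fills, 62% of WAC) at 90% generic share.
#'
#' @return An object of class `osteo_params` (a validated named list).
#' @export
#' @examples
#' p <- default_parameter_set()
#' p$efficacy$teriparatide$rr[["hip"]]      # 0.42
#' round(p$costs$drug_annual[["teriparatide"]])  # 20161
default_parameter_set <- function() {
  kinds <- fracture_kinds()

  alen_generic <- annual_drug_cost(6.13833, 52, 0.27)
  alen_brand <- annual_drug_cost(38.3525, 52, 0.64)
  teri_brand <- annual_drug_cost(3426.50, 13, 0.62)

  pricing <- list(
    alendronate = list(generic_unit_price = 6.13833, brand_unit_price = 38.3525,
                       fills_per_year = 52, generic_price_factor = 0.27,
                       brand_price_factor = 0.64, generic_share = 0.90),
    teriparatide = list(brand_unit_price = 3426.50, fills_per_year = 13,
                        brand_price_factor = 0.62, generic_discount = 0.30,
                        generic_share = 0.90)
  )

  ut <- generate_utility_table()
  p <- list(
    efficacy = list(
      teriparatide = list(
        rr = c(hip = 0.42, clinical_vertebral = 0.30, wrist = 0.24,
               other_osteoporotic = 0.50),
        low = c(hip = 0.10, clinical_vertebral = 0.16, wrist = 0.02,
                other_osteoporotic = 0.32),
        high = c(hip = 1.0, clinical_vertebral = 0.55, wrist = 1.0,
                 other_osteoporotic = 0.78),
        dist = c(hip = "triangular", clinical_vertebral = "beta",
                 wrist = "triangular", other_osteoporotic = "beta")
      ),
      alendronate = list(
        rr = c(hip = 0.45, clinical_vertebral = 0.50, wrist = 0.82,
               other_osteoporotic = 0.78),
        low = c(hip = 0.27, clinical_vertebral = 0.33, wrist = 0.25,
                other_osteoporotic = 0.66),
        high = c(hip = 0.68, clinical_vertebral = 0.79, wrist = 1.0,
                 other_osteoporotic = 0.92),
        dist = c(hip = "beta", clinical_vertebral = "beta",
                 wrist = "triangular", other_osteoporotic = "beta")
      )
    ),
    adherence = list(
      teriparatide = c(p12 = 0.634, p24 = 0.408, a12 = 0.544, a24 = 0.398),
      alendronate = c(p12 = 0.387, p24 = 0.237, a12 = 0.313, a24 = 0.228)
    ),
    plans = list(
      teriparatide = list(duration_years = 2, washout_years = 1),
      alendronate = list(duration_years = 10, washout_years = 10),
      trial_adherence = 0.80
    ),
    pricing = pricing,
    costs = list(
      drug_annual = c(
        teriparatide = blended_annual_cost(
          teri_brand, discounted_generic_cost(teri_brand, 0.30), 0.90),
        alendronate = blended_annual_cost(alen_brand, alen_generic, 0.90)
      ),
      physician_visit = 74,
      dxa = 100,
      fracture_treatment = c(hip = 29986, clinical_vertebral = 8325,
                             wrist = 4577, other_osteoporotic = 14144),
      ltc_monthly = 7159,
      ltc_stay_fraction = 0.12,
      ltc_attributable_fraction = 0.25,
      weekly_earnings = 757,
      productivity_weeks = 8,
      labor_participation = c("65-69" = 0.279, "70-74" = 0.166,
                              "75-80" = 0.059)
    ),
    risks = list(
      rr_prior_vertebral = c(hip = 2.3, clinical_vertebral = 4.4,
                             wrist = 1.4, other_osteoporotic = 1.8),
      # synthetic: osteoporosis-vs-general-population multipliers
      rr_osteoporosis = c(hip = 1.8, clinical_vertebral = 1.6,
                          wrist = 1.4, other_osteoporotic = 1.5),
      # synthetic: lifelong relative risk of death after hip fracture, of
      # which only a fraction is attributable to the fracture itself
      hip_excess_mortality_rr = 2.0,
      excess_attributable_fraction = 0.25
    ),
    utilities = list(
      baseline = ut$baseline,
      first_year = ut$first_year,
      subsequent = ut$subsequent
    ),
    mortality = generate_life_table(),
    incidence = generate_incidence_table(),
    synthetic_inputs = c("mortality", "incidence", "utilities",
                         "risks.rr_osteoporosis",
                         "risks.hip_excess_mortality_rr")
  )
  class(p) <- "osteo_params"
  validate_parameter_set(p)
  p
}

#' Validate a parameter set
#'
#' Checks every structural invariant of the model inputs and stops, naming
#' the offending field, on the first violation. Returns the object invisibly
#' so it can be used as an assertion in pipelines.
#'
#' @param p an `osteo_params` list.
#' @return `p`, invisibly.
#' @export
validate_parameter_set <- function(p) {
  kinds <- fracture_kinds()
  need <- c("efficacy", "adherence", "plans", "pricing", "costs", "risks",
            "utilities", "mortality", "incidence")
  for (k in need) {
    if (is.null(p[[k]])) stop_field(k, "missing")
  }

  for (drug in c("teriparatide", "alendronate")) {
    e <- p$efficacy[[drug]]
    if (is.null(e)) stop_field(paste0("efficacy.", drug), "missing")
    for (f in c("rr", "low", "high", "dist")) {
      if (!all(kinds %in% names(e[[f]]))) {
        stop_field(sprintf("efficacy.%s.%s", drug, f),
                   "must be keyed by all four fracture kinds")
      }
    }
    if (any(e$rr <= 0)) stop_field(paste0("efficacy.", drug, ".rr"), "must be > 0")
    if (any(e$low > e$rr | e$rr > e$high)) {
      stop_field(paste0("efficacy.", drug),
                 "requires range_low <= rr <= range_high")
    }
    if (!all(e$dist %in% c("beta", "triangular"))) {
      stop_field(paste0("efficacy.", drug, ".dist"),
                 "must be 'beta' or 'triangular'")
    }

    a <- p$adherence[[drug]]
    if (!all(c("p12", "p24", "a12", "a24") %in% names(a))) {
      stop_field(paste0("adherence.", drug), "needs p12, p24, a12, a24")
    }
    if (any(a < 0 | a > 1)) {
      stop_field(paste0("adherence.", drug), "fractions must lie in [0,1]")
    }
    if (a[["p24"]] > a[["p12"]]) {
      stop_field(paste0("adherence.", drug, ".p24"), "must be <= p12")
    }
    if (a[["a24"]] > a[["a12"]]) {
      stop_field(paste0("adherence.", drug, ".a24"), "must be <= a12")
    }

    pl <- p$plans[[drug]]
    if (is.null(pl$duration_years) || pl$duration_years <= 0) {
      stop_field(paste0("plans.", drug, ".duration_years"), "must be > 0")
    }
    if (is.null(pl$washout_years) || pl$washout_years < 0) {
      stop_field(paste0("plans.", drug, ".washout_years"), "must be >= 0")
    }
  }
  ta <- p$plans$trial_adherence
  if (is.null(ta) || ta <= 0 || ta > 1) {
    stop_field("plans.trial_adherence", "must lie in (0,1]")
  }

  co <- p$costs
  scalar_costs <- c(co$drug_annual, co$physician_visit, co$dxa,
                    co$fracture_treatment, co$ltc_monthly, co$weekly_earnings,
                    co$productivity_weeks)
  if (any(scalar_costs < 0)) stop_field("costs", "all costs must be >= 0")
  if (!all(kinds %in% names(co$fracture_treatment))) {
    stop_field("costs.fracture_treatment", "must be keyed by all four fracture kinds")
  }
  fracs <- c(co$ltc_stay_fraction, co$ltc_attributable_fraction,
             co$labor_participation)
  if (any(fracs < 0 | fracs > 1)) {
    stop_field("costs", "fractions must lie in [0,1]")
  }
  if (!all(c("65-69", "70-74", "75-80") %in% names(co$labor_participation))) {
    stop_field("costs.labor_participation", "needs bands 65-69, 70-74, 75-80")
  }

  ri <- p$risks
  if (!all(kinds %in% names(ri$rr_prior_vertebral)) ||
      !all(kinds %in% names(ri$rr_osteoporosis))) {
    stop_field("risks", "rr tables must be keyed by all four fracture kinds")
  }
  if (any(ri$rr_prior_vertebral < 1)) {
    stop_field("risks.rr_prior_vertebral", "relative risks must be >= 1")
  }
  if (any(ri$rr_osteoporosis < 1)) {
    stop_field("risks.rr_osteoporosis", "relative risks must be >= 1")
  }
  if (ri$hip_excess_mortality_rr < 1) {
    stop_field("risks.hip_excess_mortality_rr", "must be >= 1")
  }
  af <- ri$excess_attributable_fraction
  if (af < 0 || af > 1) {
    stop_field("risks.excess_attributable_fraction", "must lie in [0,1]")
  }

  ub <- p$utilities$baseline
  if (!all(c("age", "utility") %in% names(ub))) {
    stop_field("utilities.baseline", "needs columns age, utility")
  }
  if (any(ub$utility <= 0 | ub$utility > 1)) {
    stop_field("utilities.baseline.utility", "must lie in (0,1]")
  }
  for (f in c("first_year", "subsequent")) {
    m <- p$utilities[[f]]
    if (!all(kinds %in% names(m))) {
      stop_field(paste0("utilities.", f), "must be keyed by all four fracture kinds")
    }
    if (any(m <= 0 | m > 1)) {
      stop_field(paste0("utilities.", f), "multipliers must lie in (0,1]")
    }
  }
  if (any(p$utilities$subsequent[c("wrist", "other_osteoporotic")] != 1)) {
    stop_field("utilities.subsequent",
               "wrist and other fractures carry no disutility after year 1")
  }

  mt <- p$mortality
  if (!all(c("age", "q") %in% names(mt))) {
    stop_field("mortality", "needs columns age, q")
  }
  if (min(mt$age) > 65 || max(mt$age) < 105) {
    stop_field("mortality.age", "must cover ages 65 through 105")
  }
  if (any(mt$q < 0 | mt$q > 1)) stop_field("mortality.q", "must lie in [0,1]")
  if (is.unsorted(mt$q)) {
    stop_field("mortality.q", "must be non-decreasing in age")
  }

  it <- p$incidence
  if (!all(c("age", kinds) %in% names(it))) {
    stop_field("incidence", "needs column age plus all four fracture kinds")
  }
  if (min(it$age) > 65 || max(it$age) < 105) {
    stop_field("incidence.age", "must cover ages 65 through 105")
  }
  rate_mat <- as.matrix(it[kinds])
  if (any(rate_mat < 0)) stop_field("incidence", "rates must be >= 0")
  # after risk modifiers, every per-kind cycle probability must stay below 1
  mod <- ri$rr_prior_vertebral[kinds] * ri$rr_osteoporosis[kinds]
  modified <- sweep(rate_mat, 2, mod, `*`)
  if (any(modified >= 1)) {
    stop_field("incidence",
               "modified per-cycle fracture probability reaches 1 at some age")
  }
  invisible(p)
}

# ---- serialization ---------------------------------------------------------

#' Write a parameter set to a config file plus CSV tables
#'
#' Scalar structure goes to YAML (written at 17 significant digits so doubles
#' round-trip exactly); the age-indexed tables go to `mortality.csv`,
#' `incidence.csv` and `utilities.csv` in `tables_dir`.
#'
#' @param p an `osteo_params` object.
#' @param config_path output YAML path.
#' @param tables_dir output directory for the CSV tables.
#' @return `config_path`, invisibly.
#' @export
write_parameter_set <- function(p, config_path, tables_dir = dirname(config_path)) {
  validate_parameter_set(p)
  if (!dir.exists(tables_dir)) dir.create(tables_dir, recursive = TRUE)
  scal <- unclass(p)
  scal$mortality <- NULL
  scal$incidence <- NULL
  baseline <- p$utilities$baseline
  scal$utilities$baseline <- NULL
  # yaml serialises named atomic vectors as plain sequences; promote them to
  # named lists so keys survive the round trip
  yamlify <- function(x) {
    if (is.list(x)) lapply(x, yamlify)
    else if (!is.null(names(x))) as.list(x)
    else x
  }
  writeLines(yaml::as.yaml(yamlify(scal), precision = 17), config_path)
  write_numeric_csv(p$mortality, file.path(tables_dir, "mortality.csv"))
  write_numeric_csv(p$incidence, file.path(tables_dir, "incidence.csv"))
  write_numeric_csv(baseline, file.path(tables_dir, "utilities.csv"))
  invisible(config_path)
}

#' Load a parameter set from a config file plus CSV tables
#'
#' Inverse of [write_parameter_set()]. Fails with the offending key path on a
#' missing key, and with the offending field on any invariant violation.
#'
#' @param config_path YAML config written by [write_parameter_set()].
#' @param tables_dir directory holding `mortality.csv`, `incidence.csv`,
#'   `utilities.csv`.
#' @return A validated `osteo_params` object.
#' @export
load_parameter_set <- function(config_path, tables_dir = dirname(config_path)) {
  if (!file.exists(config_path)) {
    stop(sprintf("config file not found: %s", config_path), call. = FALSE)
  }
  scal <- yaml::read_yaml(config_path)
  for (f in c("mortality.csv", "incidence.csv", "utilities.csv")) {
    if (!file.exists(file.path(tables_dir, f))) {
      stop(sprintf("parameter table not found: %s", file.path(tables_dir, f)),
           call. = FALSE)
    }
  }
  p <- scal
  # yaml returns named lists for named vectors; restore the numeric vectors
  p$efficacy <- lapply(scal$efficacy, function(e) {
    list(rr = unlist(e$rr), low = unlist(e$low), high = unlist(e$high),
         dist = unlist(e$dist))
  })
  p$adherence <- lapply(scal$adherence, unlist)
  p$costs$drug_annual <- unlist(scal$costs$drug_annual)
  p$costs$fracture_treatment <- unlist(scal$costs$fracture_treatment)
  p$costs$labor_participation <- unlist(scal$costs$labor_participation)
  p$risks$rr_prior_vertebral <- unlist(scal$risks$rr_prior_vertebral)
  p$risks$rr_osteoporosis <- unlist(scal$risks$rr_osteoporosis)
  p$utilities$first_year <- unlist(scal$utilities$first_year)
  p$utilities$subsequent <- unlist(scal$utilities$subsequent)
  p$synthetic_inputs <- unlist(scal$synthetic_inputs)
  p$mortality <- utils::read.csv(file.path(tables_dir, "mortality.csv"))
  p$incidence <- utils::read.csv(file.path(tables_dir, "incidence.csv"))
  p$utilities$baseline <- utils::read.csv(file.path(tables_dir, "utilities.csv"))
  p$utilities <- p$utilities[c("baseline", "first_year", "subsequent")]
  p <- p[c("efficacy", "adherence", "plans", "pricing", "costs", "risks",
           "utilities", "mortality", "incidence", "synthetic_inputs")]
  class(p) <- "osteo_params"
  validate_parameter_set(p)
  p
}

#' @export
print.osteo_params <- function(x, ...) {
  cat("Model parameter set (2018 USD)\n")
  cat(sprintf("  annual drug cost: teriparatide $%s, alendronate $%s\n",
              format(round(x$costs$drug_annual[["teriparatide"]]), big.mark = ","),
              format(round(x$costs$drug_annual[["alendronate"]]), big.mark = ",")))
  cat(sprintf("  teriparatide RR (hip/vert/wrist/other): %s\n",
              paste(x$efficacy$teriparatide$rr, collapse = "/")))
  cat(sprintf("  alendronate RR (hip/vert/wrist/other): %s\n",
              paste(x$efficacy$alendronate$rr, collapse = "/")))
  cat(sprintf("  synthetic inputs: %s\n",
              paste(x$synthetic_inputs, collapse = ", ")))
  invisible(x)
}

# ---- parameter paths (used by DSA/PSA) -------------------------------------

#' Set one scalar in a parameter set by path
#'
#' Paths are dot-separated, e.g. `"costs.drug_annual.teriparatide"`,
#' `"efficacy.teriparatide.rr.hip"`, `"adherence.alendronate.p12"`. The last
#' component may index a named numeric vector.
#'
#' @param p an `osteo_params` object.
#' @param path dot-separated path to one scalar.
#' @param value replacement value.
#' @return The modified parameter set (not re-validated; sensitivity analyses
#'   may deliberately explore values outside base-case bounds).
#' @export
set_parameter <- function(p, path, value) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  rec <- function(node, parts) {
    key <- parts[[1]]
    if (is.list(node)) {
      if (is.null(node[[key]])) {
        stop(sprintf("unknown parameter path component: '%s'", key), call. = FALSE)
      }
      node[[key]] <- if (length(parts) == 1) value else rec(node[[key]], parts[-1])
      node
    } else {
      if (length(parts) != 1 || !key %in% names(node)) {
        stop(sprintf("unknown parameter path component: '%s'", key), call. = FALSE)
      }
      node[[key]] <- value
      node
    }
  }
  out <- rec(unclass(p), parts)
  class(out) <- "osteo_params"
  out
}

#' Get one scalar from a parameter set by path
#' @rdname set_parameter
#' @export
get_parameter <- function(p, path) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  node <- unclass(p)
  for (key in parts) {
    if ((is.list(node) && is.null(node[[key]])) ||
        (!is.list(node) && !key %in% names(node))) {
      stop(sprintf("unknown parameter path component: '%s'", key), call. = FALSE)
    }
    node <- node[[key]]
  }
  node
}

# ---- scenarios -------------------------------------------------------------

#' Define a simulation scenario
#'
#' @param start_age cohort entry age (the study examines 65, 70, 75, 80).
#' @param strategy `"sequential"` (2 years teriparatide then 10 years
#'   alendronate), `"alendronate_alone"` (10 years alendronate), or `"none"`
#'   (no treatment; used for model validation such as lifetime fracture risks).
#' @param horizon_end_age simulation stops at this age (default 105).
#' @param discount_rate annual discount rate for costs and QALYs (default 0.03).
#' @param perspective `"societal"` (includes long-term care and unpaid
#'   productivity) or `"health_care_sector"`.
#' @param wtp_thresholds willingness-to-pay thresholds, $/QALY.
#' @param n_individuals Monte-Carlo sample size per strategy.
#' @param master_seed master seed; all substreams derive from it.
#' @param common_random_numbers pair individual-level random streams across
#'   strategies (variance reduction for incremental quantities).
#' @return An object of class `osteo_scenario`.
#' @export
make_scenario <- function(start_age = 65,
                          strategy = c("sequential", "alendronate_alone", "none"),
                          horizon_end_age = 105,
                          discount_rate = 0.03,
                          perspective = c("societal", "health_care_sector"),
                          wtp_thresholds = c(50000, 100000, 150000),
                          n_individuals = 10000,
                          master_seed = 1L,
                          common_random_numbers = TRUE) {
  strategy <- match.arg(strategy)
  perspective <- match.arg(perspective)
  if (!start_age %in% 65:104) {
    stop("make_scenario: start_age must lie in 65..104", call. = FALSE)
  }
  if (discount_rate < 0 || discount_rate >= 1) {
    stop("make_scenario: discount_rate must lie in [0,1)", call. = FALSE)
  }
  if (start_age >= horizon_end_age) {
    stop("make_scenario: start_age must be below horizon_end_age", call. = FALSE)
  }
  if (n_individuals < 1) {
    stop("make_scenario: n_individuals must be >= 1", call. = FALSE)
  }
  s <- list(start_age = start_age, strategy = strategy,
            horizon_end_age = horizon_end_age, discount_rate = discount_rate,
            perspective = perspective, wtp_thresholds = wtp_thresholds,
            n_individuals = as.integer(n_individuals),
            master_seed = as.integer(master_seed),
            common_random_numbers = isTRUE(common_random_numbers))
  class(s) <- "osteo_scenario"
  s
}
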