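# Synthetic stand-ins for inputs the source study took from a prior technical
# appendix and external vital statistics: an age-indexed female life table,
# age-indexed fracture incidence, age-indexed baseline utilities, and fracture
# disutility multipliers. These are NOT the study's values; they are
# deterministic, parameterised generators producing magnitudes plausible for a
# high-risk osteoporotic cohort, so that every downstream stage is testable.

#' Synthetic female life table (Gompertz)
#'
#' Annual death probability `q(age) = min(1, a * exp(b * (age - 65)))` for
#' ages 65..`max_age`. The default parameters are calibrated so that fewer
#' than 0.1% of a cohort starting at 65 survives past age 105, matching the
#' behaviour expected of a US female life table extrapolated to 105.
#'
#' @param a level: annual death probability at age 65.
#' @param b Gompertz log-slope per year of age.
#' @param max_age last age in the table.
#' @return data.frame with columns `age`, `q`; `q` non-decreasing in age.
#' @export
#' @examples
#' lt <- generate_life_table()
#' head(lt)
generate_life_table <- function(a = 0.013, b = 0.10, max_age = 105) {
  stopifnot(a > 0, b > 0, max_age > 65)
  age <- 65:max_age
  q <- pmin(1, a * exp(b * (age - 65)))
  data.frame(age = age, q = q)
}

#' Synthetic age-indexed fracture incidence table
#'
#' General-population female annual incidence per fracture kind,
#' `rate(age, kind) = base * exp(slope * (age - 65))`, capped at 1. Defaults
#' give an untreated high-risk 65-year-old (prior vertebral fracture and
#' osteoporosis relative risks applied) a lifetime hip-fracture risk in the
#' 40-75% range under the default life table.
#'
#' @param base_rates_at_65 named numeric (one entry per fracture kind):
#'   annual incidence at age 65.
#' @param age_slope named numeric: exponential slope per year of age.
#' @param max_age last age in the table.
#' @return data.frame with column `age` plus one rate column per fracture kind.
#' @export
generate_incidence_table <- function(base_rates_at_65 = c(hip = 0.003,
                                                          clinical_vertebral = 0.0045,
                                                          wrist = 0.006,
                                                          other_osteoporotic = 0.005),
                                     age_slope = c(hip = 0.09,
                                                   clinical_vertebral = 0.055,
                                                   wrist = 0.015,
                                                   other_osteoporotic = 0.045),
                                     max_age = 105) {
  kinds <- fracture_kinds()
  if (!all(kinds %in% names(base_rates_at_65)) ||
      !all(kinds %in% names(age_slope))) {
    stop("generate_incidence_table: rates and slopes must name all four fracture kinds",
         call. = FALSE)
  }
  if (any(base_rates_at_65 < 0)) {
    stop("generate_incidence_table: rates must be non-negative", call. = FALSE)
  }
  age <- 65:max_age
  tab <- data.frame(age = age)
  for (k in kinds) {
    tab[[k]] <- pmin(1, base_rates_at_65[[k]] * exp(age_slope[[k]] * (age - 65)))
  }
  tab
}

#' Synthetic age-indexed baseline utilities and fracture disutility multipliers
#'
#' Baseline utility declines linearly with age from an anchor at 65, floored
#' just above 0. First-year multipliers apply in the fracture year; hip and
#' clinical vertebral fractures carry a lifelong subsequent-year multiplier,
#' while wrist and other fractures have no disutility after the first year
#' (subsequent multiplier fixed at 1).
#'
#' @param anchor_at_65 baseline utility at age 65, in (0,1\].
#' @param annual_decline utility lost per year of age.
#' @param first_year named numeric: first-year multiplier per fracture kind.
#' @param subsequent named numeric: subsequent-year multiplier for hip and
#'   clinical vertebral fracture; wrist/other entries are forced to 1.
#' @param max_age last age in the table.
#' @return list with `baseline` (data.frame age, utility), `first_year`,
#'   `subsequent` (named numerics over the four kinds).
#' @export
generate_utility_table <- function(anchor_at_65 = 0.80,
                                   annual_decline = 0.005,
                                   first_year = c(hip = 0.70,
                                                  clinical_vertebral = 0.80,
                                                  wrist = 0.95,
                                                  other_osteoporotic = 0.91),
                                   subsequent = c(hip = 0.90,
                                                  clinical_vertebral = 0.95,
                                                  wrist = 1.0,
                                                  other_osteoporotic = 1.0),
                                   max_age = 105) {
  stopifnot(anchor_at_65 > 0, anchor_at_65 <= 1, annual_decline >= 0)
  kinds <- fracture_kinds()
  first_year <- first_year[kinds]
  subsequent <- subsequent[kinds]
  subsequent[c("wrist", "other_osteoporotic")] <- 1.0
  if (any(first_year <= 0 | first_year > 1) || any(subsequent <= 0 | subsequent > 1)) {
    stop("generate_utility_table: multipliers must lie in (0,1]", call. = FALSE)
  }
  age <- 65:max_age
  utility <- pmax(anchor_at_65 - annual_decline * (age - 65), 1e-6)
  list(baseline = data.frame(age = age, utility = utility),
       first_year = first_year,
       subsequent = subsequent)
}

#' Write the synthetic input tables as CSV fixtures
#'
#' Emits the CSV formats consumed by [load_parameter_set()]: `mortality.csv`
#' (age, q), `incidence.csv` (age + one column per fracture kind) and
#' `utilities.csv` (age, utility). The files are plain CSV with a header row;
#' their synthetic provenance is carried by the generator documentation and by
#' the `synthetic_inputs` flag of the parameter set that consumes them.
#'
#' @param dir output directory (created if missing).
#' @param life_table,incidence,utilities tables from the generators above;
#'   defaults regenerate them.
#' @return `dir`, invisibly.
#' @export
write_synthetic_tables <- function(dir,
                                   life_table = generate_life_table(),
                                   incidence = generate_incidence_table(),
                                   utilities = generate_utility_table()) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_numeric_csv(life_table, file.path(dir, "mortality.csv"))
  write_numeric_csv(incidence, file.path(dir, "incidence.csv"))
  write_numeric_csv(utilities$baseline, file.path(dir, "utilities.csv"))
  invisible(dir)
}

# Full-precision CSV writer (17 significant digits round-trips doubles).
write_numeric_csv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
}
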