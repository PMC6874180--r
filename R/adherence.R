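# Real-world persistence and adherence, and their effect on efficacy.
#
# Persistence (time from initiation to discontinuation) and adherence
# (fraction of prescribed doses taken while persisting) are observed at 12 and
# 24 months; both decline linearly beyond 2 years up to 5 years and are flat
# thereafter. Trial relative risks are diluted toward 1 in proportion to
# community adherence relative to trial adherence (reference 80%), and fade
# back to 1 linearly after stopping (offset/washout), over a window
# proportional to the completed fraction of the planned course.

#' Persistence (still-on-treatment fraction) at a given month
#'
#' Piecewise-linear survival curve through (0, 1), (12, p12), (24, p24),
#' extrapolated on the 12-24-month slope to month 60, clamped at 0, and
#' constant after month 60 (no further discontinuation hazard beyond 5 years).
#'
#' @param schedule list with elements `p12`, `p24` (12- and 24-month
#'   persistence fractions).
#' @param months time since initiation, in months (vectorised).
#' @return Fraction still on treatment.
#' @export
#' @examples
#' teri <- list(p12 = 0.634, p24 = 0.408)
#' persistence_at(teri, c(0, 12, 18, 24))
persistence_at <- function(schedule, months) {
  p12 <- schedule$p12
  p24 <- schedule$p24
  stopifnot(months >= 0)
  slope2 <- (p24 - p12) / 12 # per month beyond month 12
  p <- ifelse(months <= 12,
              1 + (p12 - 1) * months / 12,
              p12 + slope2 * (pmin(months, 60) - 12))
  pmax(p, 0)
}

#' Adherence in a given treatment year
#'
#' Year 1 uses the 12-month adherence, year 2 the 24-month adherence, years
#' 3-5 continue on the same linear decline (clamped at 0), and years 6+ keep
#' the year-5 value (individuals still on drug from the sixth year onward
#' retain their fifth-year adherence).
#'
#' @param schedule list with elements `a12`, `a24` (12- and 24-month
#'   adherence fractions).
#' @param year_index treatment year, 1-based (vectorised).
#' @return Adherence fraction for that year.
#' @export
#' @examples
#' alen <- list(a12 = 0.313, a24 = 0.228)
#' adherence_at(alen, 1:8)
adherence_at <- function(schedule, year_index) {
  a12 <- schedule$a12
  a24 <- schedule$a24
  stopifnot(year_index >= 1)
  slope <- a24 - a12 # per year beyond year 1
  y <- pmin(year_index, 5)
  pmax(a12 + slope * (y - 1), 0)
}

#' Efficacy dilution factor from community versus trial adherence
#'
#' Relative risk reduction is assumed linear in adherence: at 60% community
#' adherence against an 80% trial reference, 75% of the trial risk reduction
#' is retained. Community adherence above the trial reference cannot amplify
#' efficacy; the factor is capped at 1.
#'
#' @param adherence_community community adherence fraction in (0,1\].
#' @param adherence_trial trial adherence reference in (0,1\] (default 0.80).
#' @return Scaling factor in \[0,1\].
#' @export
#' @examples
#' efficacy_scaling_factor(0.60, 0.80)  # 0.75
efficacy_scaling_factor <- function(adherence_community, adherence_trial = 0.80) {
  if (any(adherence_trial <= 0)) {
    stop("efficacy_scaling_factor: trial adherence must be > 0", call. = FALSE)
  }
  if (any(adherence_community < 0)) {
    stop("efficacy_scaling_factor: community adherence must be >= 0", call. = FALSE)
  }
  pmin(1, adherence_community / adherence_trial)
}

#' Community (effective) relative risk from a trial relative risk
#'
#' `1 - factor * (1 - rr_trial)`: the trial risk reduction scaled by the
#' adherence dilution factor. Equals the trial value at factor 1 and the null
#' value 1 at factor 0.
#'
#' @param rr_trial trial relative risk versus placebo.
#' @param factor scaling factor in \[0,1\] from [efficacy_scaling_factor()].
#' @return Effective relative risk.
#' @export
#' @examples
#' community_rr(0.42, 0.75)  # 0.565
community_rr <- function(rr_trial, factor) {
  stopifnot(rr_trial > 0, factor >= 0, factor <= 1)
  1 - factor * (1 - rr_trial)
}

#' Relative risk during the offset (washout) period after stopping
#'
#' Linear return from the relative risk at stop to 1 over `washout_years`,
#' and exactly 1 thereafter. With `washout_years = 0` the effect vanishes
#' immediately.
#'
#' @param rr_at_stop effective relative risk in the last treated year.
#' @param years_since_stop elapsed time since stopping, in years (vectorised).
#' @param washout_years length of the linear washout window.
#' @return Relative risk, non-decreasing in `years_since_stop` toward 1.
#' @export
#' @examples
#' offset_rr(0.565, c(0, 5, 10), 10)
offset_rr <- function(rr_at_stop, years_since_stop, washout_years) {
  stopifnot(years_since_stop >= 0, washout_years >= 0)
  if (washout_years == 0) {
    return(rep(1, length(years_since_stop)))
  }
  frac <- pmin(1, years_since_stop / washout_years)
  rr_at_stop + (1 - rr_at_stop) * frac
}

#' Washout window for an incomplete treatment course
#'
#' Offset effects are proportional to the length of the treatment period: an
#' individual who completed `years_completed` of a `planned_duration`-year
#' course washes out over `planned_washout * years_completed /
#' planned_duration` years.
#'
#' @param planned_washout full washout window after a completed course, years.
#' @param years_completed years actually on treatment.
#' @param planned_duration planned course length, years.
#' @return Effective washout window in years.
#' @export
#' @examples
#' effective_washout_years(10, 5, 10)  # 5
effective_washout_years <- function(planned_washout, years_completed,
                                    planned_duration) {
  if (planned_duration <= 0) {
    stop("effective_washout_years: planned_duration must be > 0", call. = FALSE)
  }
  stopifnot(planned_washout >= 0, years_completed >= 0,
            years_completed <= planned_duration)
  planned_washout * years_completed / planned_duration
}

#' Sample a discontinuation month from a persistence curve
#'
#' Inverse-CDF draw on the piecewise-linear persistence curve of
#' [persistence_at()], sampled once per individual at treatment start. The
#' curve is flat after month 60, so a uniform draw below the month-60
#' persistence means the individual never discontinues (`Inf`): she completes
#' any planned course.
#'
#' @param schedule list with `p12`, `p24`.
#' @param u uniform(0,1) draw (vectorised).
#' @return Discontinuation month (possibly `Inf`). The month-m survival of the
#'   returned variable equals `persistence_at(schedule, m)`.
#' @export
sample_discontinuation_month <- function(schedule, u) {
  p12 <- schedule$p12
  p24 <- schedule$p24
  slope1 <- (p12 - 1) / 12
  slope2 <- (p24 - p12) / 12
  p60 <- persistence_at(schedule, 60)
  # invert S(m) = u on each linear piece; S is strictly decreasing up to the
  # month where it hits its floor (0 or the month-60 plateau)
  m <- ifelse(u > p12,
              (u - 1) / slope1,
              ifelse(u > p60, 12 + (u - p12) / slope2, Inf))
  m
}
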