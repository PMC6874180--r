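# Medication-cost model: unit price -> annual cost, brand/generic blending,
# adherence-proportional per-cycle charging, and the discount x market-share
# grid used for the teriparatide price-threshold analyses.
#
# Convention: all intermediates are kept at full precision; only figures
# reported to the user are rounded to the nearest dollar. This reproduces
# every printed dollar figure within +/- $1 even though the source mixes
# rounded and unrounded intermediates.

#' Annual drug cost from unit price
#'
#' Converts a per-fill list price into an annual acquisition cost:
#' `unit_price * fills_per_year * price_factor`, where `price_factor` is the
#' fraction of the list price (AWP or WAC) actually paid. For example, generic
#' alendronate at $6.13833/tablet, 52 weekly fills and 27% of AWP gives
#' $86/year; brand teriparatide at $3426.50 per 28-day supply, 13 fills and
#' 62% of WAC gives $27,618/year.
#'
#' @param unit_price list price per fill (USD).
#' @param fills_per_year number of fills per year (52 for a weekly tablet,
#'   13 for a 28-day supply).
#' @param price_factor fraction of the list price actually paid.
#' @return Annual cost in USD/year (unrounded).
#' @export
#' @examples
#' round(annual_drug_cost(6.13833, 52, 0.27))   # 86
#' round(annual_drug_cost(3426.50, 13, 0.62))   # 27618
annual_drug_cost <- function(unit_price, fills_per_year, price_factor) {
  if (any(c(unit_price, fills_per_year, price_factor) < 0)) {
    stop("annual_drug_cost: all inputs must be non-negative", call. = FALSE)
  }
  unit_price * fills_per_year * price_factor
}

#' Generic/biosimilar annual cost at a given discount off brand
#'
#' @param brand_annual brand annual cost (USD/year).
#' @param generic_discount fraction discounted off the brand cost, in
#'   \[0,1\] (0.30 means the generic costs 70% of brand).
#' @return Annual cost of the generic/biosimilar product (USD/year).
#' @export
#' @examples
#' round(discounted_generic_cost(27617.59, 0.30))  # 19332
discounted_generic_cost <- function(brand_annual, generic_discount) {
  if (any(generic_discount < 0 | generic_discount > 1)) {
    stop("discounted_generic_cost: discount must lie in [0,1]", call. = FALSE)
  }
  if (any(brand_annual < 0)) {
    stop("discounted_generic_cost: brand_annual must be non-negative",
         call. = FALSE)
  }
  brand_annual * (1 - generic_discount)
}

#' Market-share-blended annual drug cost
#'
#' Convex combination of the brand and generic/biosimilar annual costs by the
#' fraction of users on the generic/biosimilar product:
#' `generic_annual * share + brand_annual * (1 - share)`.
#'
#' @param brand_annual brand annual cost (USD/year).
#' @param generic_annual generic/biosimilar annual cost (USD/year).
#' @param generic_share fraction of users on the generic/biosimilar, in \[0,1\].
#' @return Blended annual cost (USD/year), always between the two inputs.
#' @export
#' @examples
#' round(blended_annual_cost(1276.37, 86.18, 0.9))  # 205, alendronate
blended_annual_cost <- function(brand_annual, generic_annual, generic_share) {
  if (any(generic_share < 0 | generic_share > 1)) {
    stop("blended_annual_cost: share must lie in [0,1]", call. = FALSE)
  }
  generic_annual * generic_share + brand_annual * (1 - generic_share)
}

#' Blended annual teriparatide cost for a discount/share assumption
#'
#' Convenience composition used throughout the threshold analyses: the
#' generic/biosimilar price is `brand * (1 - discount)` and the population
#' annual cost blends it with the brand price by market share.
#'
#' @param generic_discount fraction off brand for the generic/biosimilar.
#' @param generic_share fraction of users on the generic/biosimilar.
#' @param brand_annual brand annual cost; default is the base-case
#'   $3426.50 x 13 fills x 62% of WAC.
#' @return Annual teriparatide cost (USD/year, unrounded).
#' @export
#' @examples
#' round(teriparatide_annual_cost(0.30, 0.9))  # 20161, base case
#' round(teriparatide_annual_cost(0.85, 0.9))  # 6490
teriparatide_annual_cost <- function(generic_discount, generic_share,
                                     brand_annual = annual_drug_cost(3426.50, 13, 0.62)) {
  blended_annual_cost(brand_annual,
                      discounted_generic_cost(brand_annual, generic_discount),
                      generic_share)
}

#' Teriparatide annual-cost grid over discounts and market shares
#'
#' Tabulates the blended annual cost for every combination of
#' generic/biosimilar price discount and market share, as used in the
#' price-threshold sensitivity analyses (discounts 30%..95% in 5% steps;
#' shares 90%, 75%, 60%).
#'
#' @param discounts vector of generic discounts in \[0,1\].
#' @param shares vector of generic/biosimilar market shares in \[0,1\].
#' @param brand_annual brand annual cost (USD/year).
#' @return Numeric matrix (rows = discounts, columns = shares) of unrounded
#'   annual costs; dimnames carry the discount/share values. Non-increasing
#'   along both margins.
#' @export
#' @examples
#' g <- teriparatide_cost_grid()
#' round(g["0.3", "0.9"])  # 20161
teriparatide_cost_grid <- function(discounts = seq(0.30, 0.95, by = 0.05),
                                   shares = c(0.9, 0.75, 0.6),
                                   brand_annual = annual_drug_cost(3426.50, 13, 0.62)) {
  if (any(discounts < 0 | discounts > 1) || any(shares < 0 | shares > 1)) {
    stop("teriparatide_cost_grid: discounts and shares must lie in [0,1]",
         call. = FALSE)
  }
  g <- outer(discounts, shares, function(d, s) {
    mapply(function(di, si) teriparatide_annual_cost(di, si, brand_annual), d, s)
  })
  dimnames(g) <- list(as.character(discounts), as.character(shares))
  g
}

#' Drug cost charged in one annual cycle
#'
#' Persisting individuals are charged the annual cost prorated by that year's
#' adherence. Individuals who discontinue within the first year of a drug are
#' charged one 3-month supply (a single filled prescription, 25% of the annual
#' cost) once, in the discontinuation year, replacing the adherence-prorated
#' charge. Individuals not on the drug pay nothing.
#'
#' @param annual_cost annual drug cost (USD/year).
#' @param on_treatment logical; persisting on the drug through this cycle.
#' @param adherence fraction of prescribed doses taken this year, in \[0,1\].
#' @param discontinued_within_first_year logical; this is the cycle in which
#'   the individual discontinued, and it is the drug's first year.
#' @return Cost charged this cycle (USD).
#' @export
#' @examples
#' cycle_drug_charge(20161, TRUE, 1.0, FALSE)    # 20161
#' cycle_drug_charge(20161, FALSE, 0, TRUE)      # 5040.25
cycle_drug_charge <- function(annual_cost, on_treatment, adherence,
                              discontinued_within_first_year = FALSE) {
  if (adherence < 0 || adherence > 1) {
    stop("cycle_drug_charge: adherence must lie in [0,1]", call. = FALSE)
  }
  if (on_treatment) {
    annual_cost * adherence
  } else if (discontinued_within_first_year) {
    annual_cost * 0.25
  } else {
    0
  }
}

#' Write the teriparatide pricing grid as CSV
#'
#' @param path output file path.
#' @param ... passed to [teriparatide_cost_grid()].
#' @return The grid, invisibly (values rounded to the nearest dollar in the
#'   file; the returned matrix is unrounded).
#' @export
write_pricing_grid <- function(path, ...) {
  g <- teriparatide_cost_grid(...)
  out <- data.frame(discount = rownames(g), round(g), check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(g)
}
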