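---
title: "Model methods: microsimulation cost-effectiveness of sequential teriparatide/alendronate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model methods: microsimulation cost-effectiveness of sequential teriparatide/alendronate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(osteosim)
```

## The decision problem

Teriparatide is an anabolic osteoporosis drug whose US market exclusivity has
expired, opening the door to generic/biosimilar versions. The question this
package models: for community-dwelling osteoporotic women with a prior
vertebral fracture (a high-risk group), is two years of daily teriparatide
followed by ten years of weekly alendronate (the *sequential* strategy) worth
its extra cost compared with ten years of alendronate alone — and how cheap
would generic/biosimilar teriparatide have to become to change the answer?

The model is an individual-level (microsimulation) Markov model with 1-year
cycles. Each woman is simulated one at a time from her start age (65, 70, 75
or 80) until death or age 105. Costs (2018 US dollars) and quality-adjusted
life years are discounted at 3%/year and summarised as incremental
cost-effectiveness ratios (ICERs, $/QALY), evaluated from a societal
perspective (primary) and a health-care-sector perspective.

## States, events, and trackers

Four health states are distinguished: no new fracture, post-fracture,
post-hip-fracture, and dead. Because an individual-level model carries
memory, the states are supplemented by tracker variables: per-kind fracture
history, hip-fracture count, long-term-care entry, and treatment status.
Within each cycle the order of operations is:

1. **Death draw.** Life-table mortality `q(age)`; after any hip fracture the
   lifelong excess mortality applies as
   `q' = q (1 + 0.25 (RR_excess - 1))` — only 25% of the observed excess is
   attributed to the fracture itself, the rest to comorbidity. Clinical
   vertebral fractures carry no excess mortality. Death first is the
   conservative, standard ordering for annual-cycle models; a woman who dies
   in a cycle accrues nothing that year.
2. **Fracture draw.** At most one fracture per cycle among four kinds (hip,
   clinical vertebral, wrist, other osteoporotic). Per-kind probability =
   baseline incidence × RR(prior vertebral fracture) × RR(osteoporosis) ×
   effective treatment RR, the multiplicative combination. The any-fracture
   probability is `1 - prod(1 - p_k)` and the kind is drawn proportional to
   `p_k`. Hip fractures are capped at two per lifetime; after the second, the
   hip probability is set to zero without renormalising the other kinds
   (renormalisation would transfer hip risk onto other kinds, which has no
   clinical rationale).
3. **Tracker updates.** A hip fracture moves the woman into the absorbing
   post-hip-fracture state; 12% of hip fractures lead to long-term-care
   placement beyond one year (independent Bernoulli per fracture).
4. **Accrual.** Costs by component and sector, and one year of utility,
   discounted by `1/(1.03)^t` with the first year undiscounted. No half-cycle
   correction is applied: persistence logic and charges are defined on whole
   cycles, and nothing in the cost arithmetic implies one.

## Treatment, persistence, adherence, and efficacy

Both drugs are modelled with real-world *persistence* (time from initiation
to discontinuation) and *adherence* (fraction of doses taken while
persisting), anchored at 12 and 24 months (teriparatide 63.4%/40.8%
persistence, 54.4%/39.8% adherence; alendronate 38.7%/23.7% and 31.3%/22.8%).
Both curves decline linearly beyond 2 years up to 5 years and are flat
afterwards; women on alendronate from year 6 onward keep their fifth-year
adherence.

Each woman's discontinuation time is sampled **once**, at treatment start, by
inverse-CDF on the piecewise-linear persistence curve. This gives a
well-defined persistence status per cycle, which matters because efficacy is
granted for a whole cycle if and only if she persists to that cycle's end.
The flat persistence tail beyond month 60 means a woman who reaches 5 years
on drug completes the full course. In the sequential strategy, the
alendronate discontinuation time is drawn afresh when alendronate starts, and
only teriparatide completers start alendronate; discontinuers never
re-initiate (and fractures do not alter persistence).

Trial relative risks are diluted toward 1 in proportion to adherence:
`RR_community = 1 - f (1 - RR_trial)` with `f = min(1, adherence / 0.80)`,
the 80% being the trial adherence reference (applied to both drugs). The cap
at 1 prevents community adherence above the trial level from amplifying
efficacy beyond the trial effect. The year-specific adherence value is used
(not the 12-month value throughout), which follows naturally from charging
and scaling per treatment year.

**Offset (washout).** After stopping, the effective RR returns to 1 linearly
over the washout window: 10 years for a completed alendronate course, 1 year
for completed teriparatide, both scaled proportionally for incomplete courses
(`washout × years_completed / planned_duration`). In an annual-cycle model
the washout must be evaluated at some point within each post-stop cycle; this
package uses the **cycle midpoint** (`j - 0.5` years since stop for the j-th
post-stop cycle). The midpoint convention is the only annualised reading
under which completed teriparatide retains effect through year 2, has partial
effect in year 3, and none afterwards — i.e. risk "returns after 3 years"
with a 1-year linear washout.

When the teriparatide washout overlaps active alendronate (sequential
strategy, year 3), the per-kind treatment RR is the **minimum** of the two
effects rather than their product. Both drugs act on the same skeleton;
multiplying two RRs estimated each against placebo would double-count
protection. The minimum keeps the stronger single effect, which is the
conservative choice for the intervention strategy.

## Drug pricing

Annual acquisition costs are built from list-price primitives: unit price ×
fills/year × the fraction of list price actually paid (64% of AWP for brand,
27% of AWP for generic oral drugs, 62% of WAC for brand teriparatide).
Teriparatide is 13 fills/year (28-day supply), alendronate 52 (weekly
tablet). Generic/biosimilar teriparatide is priced at a discount off the
brand annual cost, and the population-average annual cost blends generic and
brand by market share (base case: 30% discount, 90% generic share, giving
$20,161/year; alendronate: $205/year). All intermediates are kept at full
precision; only reported figures are rounded to the nearest dollar, which
reproduces every published-style figure within ±$1.

Charging follows persistence and adherence: a woman persisting through a
cycle pays the annual cost × that year's adherence (plus physician visits —
two/year on teriparatide, one/year on alendronate — and DXA scans at the end
of teriparatide year 2 and alendronate years 5 and 10). A woman who
discontinues within the first year pays one 3-month supply (25% of the annual
cost) once. Discontinuers in later years pay only for their fully persisted
cycles: persistence governs who is still being charged, adherence prorates
the charge.

## Costs by sector and utilities

Formal health-care-sector components: medications, physician visits, DXA,
and fracture treatment costs (hip $29,986; clinical vertebral $8325; wrist
$4577; other $14,144). Non-health-care components, counted only under the
societal perspective: long-term care after hip fracture (an attributable
6-month nursing-home cost in the fracture year for those placed, and
$7159/month × 12 × 12% placement × 25% attributable ≈ $2577/year averaged
over everyone in the post-hip state until death) and unpaid lost productivity
in the hip-fracture year (8 weeks × $757/week × age-band labor-force
participation: 27.9% at 65–69, 16.6% at 70–74, 5.9% at 75–80, none past 80).
The two long-term-care conventions (charge the acute cost only to the 12%
placed; charge the averaged steady-state cost to all post-hip women) have
identical expectation and mirror how the source figures were constructed.

Utility in a cycle is the age-specific baseline multiplied by disutility
multipliers: the fractured kind's first-year multiplier in the fracture year,
and thereafter the subsequent-year multiplier for hip and clinical vertebral
fractures (lifelong), with wrist and other fractures carrying no disutility
beyond the first year. Multipliers from different kinds stack
multiplicatively — the conservative standard that keeps utility in (0,1] —
and repeat fractures of the same kind do not stack.

## Synthetic stand-in inputs

Four input groups are not printed anywhere in the source literature for this
comparison (they live in a prior technical appendix and external vital
statistics): age-specific fracture incidence, baseline utilities, disutility
multipliers, and the female life table, plus the osteoporosis relative risks
and the hip excess-mortality relative risk. The package ships deterministic,
parameterised synthetic generators for these:

* **Life table**: Gompertz `q(age) = min(1, 0.013 e^{0.10 (age-65)})`,
  calibrated so that under 0.1% of a 65-year-old cohort survives to 105
  (matching the behaviour of an extrapolated US female life table).
* **Incidence**: exponential-in-age rates per kind, with defaults that put an
  untreated high-risk 65-year-old's lifetime hip-fracture risk in the 40–75%
  band after the risk modifiers (RR 2.3 × 1.8 for hip).
* **Utilities**: baseline 0.80 at 65 declining 0.005/year; first-year
  multipliers 0.70 (hip), 0.80 (vertebral), 0.95 (wrist), 0.91 (other);
  subsequent-year multipliers 0.90 (hip) and 0.95 (vertebral).
* **Risk modifiers**: osteoporosis RRs 1.8/1.6/1.4/1.5 across the four kinds;
  hip excess-mortality RR 2.0 with 25% attributable.

These defaults are magnitudes a fracture epidemiologist would call plausible
for this population, chosen once and flagged in
`default_parameter_set()$synthetic_inputs`. **Consequence:** the pricing
arithmetic, adherence scaling and engine mechanics reproduce published-style
figures exactly, but absolute simulation outputs (ICERs, lifetime risks, PSA
probabilities) characterise this model's synthetic configuration, not any
externally tabulated result. Passing tests therefore demonstrate the
correctness of the machinery — against exact enumeration oracles, paired-seed
identities and calibration bands — not numerical fidelity to published ICERs.
What does carry over is the qualitative structure: at the base-case
teriparatide price the sequential strategy's ICER lies far above
$150,000/QALY, and it falls monotonically as the generic discount deepens.

## Sensitivity analyses

* **One-way DSA** (`run_owsa`): rebuilds the parameter set with one scalar
  substituted and reruns both strategies under the same paired seeds, so the
  base-case value reproduces the base-case ICER exactly and parameter effects
  are not confounded with Monte-Carlo noise.
* **Price threshold** (`threshold_discount`): walks the 30%–95% discount grid
  in 5% steps, recomputing the blended annual cost at a given market share,
  and reports the smallest discount whose net monetary benefit at the chosen
  willingness-to-pay is non-negative (equivalent to ICER ≤ WTP for positive
  QALY gains, and robust to dominance).
* **PSA** (`run_psa`): two-level design — an outer loop draws every uncertain
  parameter jointly from its distribution; the inner loop runs the
  microsimulation per strategy. Distribution recipes: triangular with the
  printed range as support and the base value as mode; beta with mean = base
  and sd = range/3.92 (the printed range read as a central 95% interval) on
  the natural [0,1] support; gamma with mean = base, sd = range/3.92;
  log-normal with median = base and the range as central 95% interval;
  ±50% triangulars for persistence/adherence and productivity. Parameters are
  sampled independently (no correlation structure is given); sampled
  24-month persistence/adherence values are clamped to their 12-month
  counterparts to preserve monotonicity. Inner-loop seeds depend only on the
  individual index, so strategies are paired within a simulation, the same
  underlying randomness is reused across simulations (all between-simulation
  variation comes from the parameters), and all-point-mass specs collapse the
  PSA onto the base case exactly.
* **CEAC** (`ceac`): at each willingness-to-pay value, the fraction of
  simulations with non-negative net monetary benefit.

## Random numbers and reproducibility

A single master seed fans out to named substreams through a counter-based
scheme (`individual`, `psa_outer`, ...), so adding an analysis never perturbs
existing streams. Each individual consumes a fixed layout of uniforms — two
discontinuation draws, then four per cycle (death, any-fracture, kind,
long-term care) — drawn after seeding her own substream. Because the layout
is fixed, paired strategies and perturbed parameter sets see identical
underlying randomness, which makes incremental quantities far less noisy and
several identities exact (equal QALYs under null treatment effects, invariant
QALY deltas under pure price changes). `common_random_numbers = FALSE`
switches to strategy-specific streams.

## Numerical choices and problem sizes

Discontinuation months are continuous; efficacy and charging operate on fully
persisted years (`floor(month/12)`). Per-kind cycle probabilities are clamped
to [0,1] and validation rejects any configuration whose modified per-kind
probability reaches 1 at any age. Serialization writes doubles at 17
significant digits, so a written-and-reloaded parameter set is bit-identical.

Default problem sizes in this package's tests and reporting scripts are
chosen for a single CPU: 100,000 individuals for the enumeration-oracle
check on the 3-cycle toy model (where the per-individual cost is tiny),
10,000–50,000 for full-horizon cohorts (the QALY delta between strategies is
≈0.01, so paired seeds matter more than brute force), and a 200 × 2000
PSA for acceptability curves. The study-scale sizes (100,000 base-case
iterations; 1000 × 10,000 PSA) are plain arguments — nothing in the
implementation depends on the defaults.

## Known limitations

* Adverse events, contraindications, treatment switching after fracture, and
  re-initiation after discontinuation are not modelled.
* Patient time costs and future unrelated medical costs are excluded.
* The post-fracture state does not distinguish vertebral from wrist/other
  histories beyond their utility multipliers and risk trackers.
* Synthetic inputs make absolute outputs configuration-specific (see above);
  users with access to real incidence/utility/mortality tables can supply
  them via `load_parameter_set()` and obtain calibrated results with no code
  changes.
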