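---
title: "Modeling least-cost nutritious diets with wild foods and micronutrient powder"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling least-cost nutritious diets with wild foods and micronutrient powder}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietcost)
library(dplyr)
```

## The problem

In arid, food-insecure settings such as Turkana County in northern
Kenya, the question is not only whether a nutritionally adequate diet
exists in local markets, but what the cheapest such diet costs, how
much cheaper it becomes when free-to-collect wild plant foods or a
donated micronutrient powder (MNP) are allowed into it, and whether
households at different wealth levels could afford it at all. This
package implements that analysis as a reusable pipeline: market price
aggregation, composition conversions, intake-frequency constraints,
the least-cost linear program, an intervention scenario ladder, and an
affordability comparison.

## The linear program

One problem instance is an (individual category, season) pair. The six
categories — children 6–8, 9–11 and 12–23 months, and non-pregnant/
non-lactating, pregnant and lactating women — cover the 1,000-day
window where nutrition matters most. The decision variable is the
number of weekly servings $x_f \ge 0$ of each food, continuous, within
frequency bounds $[m_f, M_f]$ that encode cultural eating patterns.

* **Objective.** Weekly food cost
  $\sum_f p_{fs}\, g_{cf}/100 \cdot x_f$ plus a deficit penalty
  $P \sum_k d_k$ (below). Daily cost is weekly cost / 7.
* **Energy** is constrained to a hard band $[1.0, 1.1]$ times the
  weekly requirement. A one-sided floor would let the optimizer pad
  diets with unbounded cheap energy whenever that shaves a
  micronutrient deficit; the 10% ceiling keeps solutions interpretable
  as diets. The band is configurable.
* **Protein and fat** are hard $\ge$ rows.
* **Micronutrients** (absorbed calcium, absorbed iron, zinc, thiamine,
  riboflavin, niacin, magnesium, vitamin C, retinol equivalent,
  folate, B6, B12, D, E, copper, selenium) are *elastic*: each row is
  $\text{supply}_k/R_k + d_k \ge 1$ with $d_k \ge 0$ and penalty
  $P = 10^6 \times$ (most expensive serving) per unit of normalized
  deficit. Because $P$ dwarfs any attainable food cost, the solver
  lexicographically minimizes total shortfall before money. This
  matches how diet-costing tools behave in practice: iron and zinc are
  frequently unreachable from a poor food basket, and the useful
  output is the least-bad diet, its cost, and the size of the gap —
  reported by `adequacy()` as an uncapped percentage of requirement.
* **Servings are continuous.** Whether serving counts should be
  integral is genuinely open; we use the LP relaxation because it is
  convex, reproducible and solver-independent, and provide
  `brute_force_solve()`, an exhaustive integer/grid enumerator, both
  as an independent validation oracle and as an integer mode for small
  instances.

The simplex solve is delegated to `boot::simplex()` (two-phase tableau
simplex, tolerance `1e-10`); the package constructs all rows itself,
drops vacuous rows (a $\ge$ row already satisfied by the forced
minimum servings), detects structurally infeasible bound combinations
before pivoting, and names the violated constraint
(`energy_upper`, `energy_lower`, `protein`, `fat`) in the result. Ties
between equal-cost diets are broken by the deterministic pivoting
order; since costs are reported to 0.1 KES, ties are cosmetic.

## Input conventions and conversions

Composition is per 100 g edible fresh portion (per 1 g sachet for
supplements). Calcium and iron are converted to absorbed amounts with
fixed bioavailability factors 0.48 and 0.05, and β-carotene to retinol
equivalent at 12:1 — the package deliberately models no
phytate/fibre-dependent absorption beyond these fixed factors.
Market prices are aggregated as the simple (unweighted) mean of
per-100 g observation prices within each (food, season); how
multi-village prices were pooled in the field is not documented, so
the simple mean is our stated assumption. Unknown composition cells
(`NA`) contribute zero to every constraint — a conservative choice
that never credits unmeasured nutrients — and adequacy reports flag
the affected nutrients as `composition_incomplete`.

Frequency bounds from the 24-h recall are the 25th and 75th
percentiles of per-household weekly counts. The percentile estimator
is unspecified in the field protocol; we use the linear-interpolation
quantile (R type 7) rounded half-up to an integer, which guarantees
`min <= max`. Where focus-group and recall bounds disagree, the recall
wins (it reflects actual intake). Wild foods carry the focus-group
range 1–3 servings/week and opportunity-cost prices (7.8 KES/100 g
vegetables, 7.7 fruits, both seasons); the MNP enters at zero cost
with 3–4 sachets/week (15/month), or 7–7 in the daily sensitivity
mode.

Requirement profiles embedded in field tools are not published; the
package ships a WHO/FAO-based default table
(`inst/extdata/requirements.csv`, absorbed units for Ca/Fe) and
default portion sizes (150 g market foods, 100 g vegetables/fruits at
the adult-woman base, scaled to 25/30/45% for the three child bands,
1 g sachets), both explicitly user-replaceable; no headline test
depends on their exact values.

## Scenario ladder and affordability

`run_ladder()` solves the baseline for every cell, re-solves with each
intervention's foods added, and reports per-season percentage cost
changes, their across-season average, and a *meaningful* flag: a
reduction of at least 25% in **both** seasons (a cost increase never
qualifies). Reductions are computed per season and then averaged —
not computed on season-averaged costs. MNP scenarios apply to child
categories only. `lacon_daily_cost()` averages the 12 cells,
`annualize()` uses a 365-day year, and `can_afford()` compares the
annual per-person cost to income × food-expenditure share (or total
income), under the stated assumption that every household member
costs the category-average diet regardless of age and sex. KES are
converted to USD at a configurable 103.6 KES/$ (the 2016 rate
consistent with the reference figures). Display conventions: costs to
0.1 KES, percentages to 0.1, adequacy to 1%; internal arithmetic is
unrounded.

## The synthetic data generators

`generate_market()` emulates the survey shape: `n_foods` market foods
cycling through food-group archetypes (staple, legume, oil, vegetable,
milk, meat, fish) with lognormal composition and price variation, 4
traders × 6 villages × 2 seasons of weighed price observations, and
lean prices equal to plenty × `lean_inflation` × noise (exactly ×
inflation when noise is off). `generate_recall()` draws zero-inflated
Poisson weekly counts for 180 households, with counts capped at 21.
A single integer seed governs all draws; a fixed seed reproduces the
outputs byte-identically.

`engineered_gap_instance()` is the sharper tool: an instance whose LP
optima are known in closed form. It uses a proportional requirement
profile (the default adult-woman nutrient density per kcal, scaled by
each category's energy requirement), one energy-dense staple whose
iron/zinc content is set so that the deficit-minimizing optimum sits
at the top of the energy band supplying exactly
$(1-\text{severity})$ of the gap-nutrient requirement, and a synthetic
wild vegetable priced so the all-vegetable diet at the energy floor is
the unique optimum, at exactly `reduction_pct` percent of the baseline
cost — in both seasons and for all six categories simultaneously. A
forced "luxury fruit" variant (minimum one expensive, nutrient-free
serving) raises cost by exactly its price, exercising the
forced-minimum direction. The construction refuses parameter
combinations it cannot realise (reductions smaller in magnitude than
the ~9.1% band width when a gap exists).

What passing these tests shows — and does not. Recovering configured
reductions to 0.1 percentage points demonstrates that the pipeline
(price tables → bounds → LP → scenario arithmetic) is internally
correct, not that any real market resembles the synthetic one. The
generators do not emulate food-item heterogeneity within groups,
correlated price shocks across villages, seasonal availability gaps,
or measurement error in composition tables. Conclusions about a real
setting require that setting's survey data, which the package accepts
through the same CSV interfaces.

## Validation surfaces and problem sizes

The test suite validates the LP against exhaustive enumeration on 200
random instances of up to 5 foods with unit-grid bounds spanning at
most 8 points, using a wide energy ceiling so that rounding a
continuous solution up to the grid stays feasible — that is exactly
the regime in which the grid optimum must lie within one serving's
cost of the LP optimum, which is the asserted bound; tight-band and
infeasible cases are checked by construction instead. Directional
properties (free additions never raise cost, zero-price supplements
never raise cost, forced expensive foods do, uniform price scaling
scales cost exactly, lean inflation raises cost) are tested on the
same instance family with a fixed penalty so objectives are
comparable. Parameter recovery runs the engineered instance at
reductions −30/−45/−70% across 10 seeds (720 LP solves); the whole
suite runs in about a minute on one core.

## Known limitations

* `boot::simplex()` is a dense tableau solver; fine for tens of foods,
  not for thousands. The formulation is solver-agnostic if a faster
  backend is ever wanted.
* The elastic formulation ranks deficits by normalized sum; it has no
  notion of one micronutrient mattering more than another.
* Opportunity-cost pricing of wild foods is a crude stand-in for
  collection labour, seasonality of supply, and sustainability of
  harvest.
* Affordability treats income and food shares as fixed annual scalars;
  no intra-annual smoothing or income response is modeled.
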