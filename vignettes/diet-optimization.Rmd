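---
title: "Least-cost diet optimization for pregnancy: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Least-cost diet optimization for pregnancy: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A pregnant woman on a limited budget needs a daily diet that meets her
trimester's nutrient recommendations, respects customary food-group serving
patterns, and stays palatable — while costing as little as possible. This is
the classical least-cost diet problem, restricted to whole and half
servings so that the answer reads as a menu rather than as fractional grams
of ingredients.

`dietopt` formulates it as an integer linear program over a food database
of candidate items $j = 1, \dots, n$, each with a per-serving price $c_j$
and per-serving nutrient content $a_{ij}$ for the 15 tracked quantities
$i$ (energy, protein, carbohydrate, fat, fibre, vitamins A, C, B1, B2, B3,
sodium, potassium, calcium, iron, phosphorus):

$$\min \; p = \sum_j c_j x_j$$

subject to

$$l_i \le \sum_j a_{ij} x_j \le u_i \quad \text{(nutrients)},$$
$$L_g \le \sum_{j \in g} x_j \le U_g \quad \text{(food groups)},$$
$$0 \le x_j \le \mathrm{cap}_j, \qquad x_j \in \tfrac{1}{2}\mathbb{Z}.$$

The nutrient bounds are the RNI 2017 values per pregnancy trimester
(`rni_bounds()`); vitamin B1, vitamin B2 and potassium carry no upper
recommendation and are unbounded above. The food-group serving bounds are
the MDG 2010 recommendations for the seven food groups, extended by
palatability bounds of 1–4 servings for sugar, salt and oil
(`mdg_group_bounds()`) so the cheapest diets stay culturally acceptable.

### Why half servings

The classic formulation asks for integer servings, yet published group
recommendations themselves use half servings (meat and legumes have lower
bounds of 0.5 servings/day). The package reconciles the two by making the
decision variable an integer count of portions of size `granularity`
(default 0.5 serving): $x_j = g k_j$, $k_j \in \mathbb{Z}_{\ge 0}$. The
granularity is configurable; 0.5 is also exactly representable in binary,
so portion-count arithmetic introduces no rounding.

### Per-item caps

Per-item caps encode the rule that one dish should not repeat through the
day. The packaged default is 2 servings/day per item, with fish capped at 1
serving/day (the "one serving of silver catfish" rule generalized to the
category); both are overridable per category or per item. One serving of
salt is taken as 390 mg sodium (about 1 g of salt); serving sizes of the
other palatability items follow the exchange-list convention (5 g
carbohydrate for sugar, 9 g fat for oil). The salt convention is a package
default — group recommendations bound salt in "servings" without defining
one — and is configurable like every other generator and constraint value.

## Supplements relax lower bounds only

A supplement scenario (`supplement_scenario()`) is a vector of exogenous
daily nutrient amounts. Applying it replaces each dietary lower bound by
$\max(0, l_i - s_i)$ and leaves upper bounds untouched: the upper limits
cap *food* intake, and counting a 100 mg iron tablet against a 29 mg
dietary upper limit would make every supplemented problem infeasible, the
opposite of why supplements are prescribed. Because supplementation only
relaxes constraints, the supplemented optimum can never cost more than the
baseline — the direction the package's scenario comparison
(`compare_scenarios()`) verifies and reports.

The packaged default scenario per trimester is: trimester 1, folic acid
only (folate is outside the tracked panel, so this is a zero vector);
trimesters 2–3, 100 mg/day elemental iron — the national antenatal
recommendation — plus vitamin C 100 mg and a B complex of B1 5 mg, B2 5 mg,
B3 20 mg. The non-iron doses are package defaults chosen to match common
antenatal formulations; published tablet compositions vary, so they are
fully configurable.

## The solver

No part of the optimization is heuristic. `optimize_diet()` runs exact
branch and bound over the LP relaxation:

* **LP relaxation.** A bounded-variable two-phase primal simplex, written
  for this package (compiled core in `src/simplex.cpp`, with a pure-R
  reference implementation kept for cross-checking). Each ranged row
  becomes an equality with a boxed slack; phase 1 minimizes per-row
  artificial variables; Dantzig pricing with a Bland fallback after 80
  non-improving iterations guards against cycling; the basis inverse is
  maintained by product-form updates with refactorization every 60
  iterations. Constraint rows are scaled to unit maximum magnitude, since
  nutrient units span five orders of magnitude (kcal in thousands,
  riboflavin in single mg).
* **Branch and bound.** Best-first on the parent LP bound, breaking ties
  toward the newest node so the search first dives to the LP optimum,
  then prunes the bound-ordered frontier. Branching is on the most
  fractional portion count.
* **Tie-breaking.** Among equal-cost optima the returned serving vector is
  the lexicographically smallest in database item order, obtained by a
  sequential refinement pass (minimize $k_1$ subject to optimal cost, fix
  it, minimize $k_2$, …). This makes results reproducible down to the
  individual foods chosen, at the price of up to one extra small MILP per
  selected item; `lex = FALSE` skips it when only cost and status matter.
* **Tolerances.** Integer feasibility $10^{-6}$ portion units; cost
  comparisons $10^{-9}$ currency units; LP pivot tolerance $10^{-9}$ and
  phase-1 feasibility $10^{-7}$ on the scaled rows. Integer candidates are
  re-verified against the *unscaled* constraints (relative tolerance
  $10^{-7}$) by the same checker the enumeration oracle uses, so solver and
  oracle cannot disagree by construction of their acceptance rule.

`brute_force_diet()` is the independent oracle: exhaustive enumeration of
all portion-count vectors in lexicographic order (guarded at $10^7$
candidates), with the identical feasibility checker and tie-break. The test
suite holds the solver to exact agreement with it — status, cost, and
serving vector — over hundreds of randomized instances.

Unboundedness cannot arise: prices are nonnegative and every variable is
capped, so the feasible region is a finite box.

## Diagnostics

`binding_report()` classifies each nutrient and group at its lower bound,
upper bound, or interior. A constraint counts as binding within a tolerance
of 5% of the bound span (or 5% of the lower bound where no upper exists),
because optimized menus land *near* rather than exactly on the limiting
recommendation for scarce nutrients — e.g. potassium a few mg above its
4700 mg floor. The report also gives both slacks and the relative position
$(v - l)/(u - l)$.

`diagnose_infeasibility()` explains infeasible problems by single-constraint
relaxation: each positive lower bound dropped to zero and each finite upper
bound lifted, one at a time, re-solving a feasibility probe (branch and
bound stopped at the first integer-feasible point). Every relaxation that
restores feasibility is a culprit; if none does, the infeasibility is
flagged irreducible. This is deliberately not an irreducible-infeasible-
subsystem computation: the one-constraint-at-a-time reading matches how a
dietitian asks "which requirement is unmeetable?", and it is transparent to
verify.

## Menu assembly

`assemble_menu()` arranges an optimal serving vector over five meal slots
(breakfast, morning tea, lunch, afternoon tea, dinner). Staple categories
(cereals, meat/poultry, fish, vegetables, legumes, oil, salt) rotate over
the three main meals; fruits, milk and sugar rotate over the tea slots. An
item appears at most once per slot carrying at most `per_slot_max`
(default 2) servings, and the allocations sum exactly to the serving
vector. Slotting is presentation, not optimization: the rule is
deterministic and documented, and no claim is made that it reproduces any
particular published menu, which was assembled by hand.

## Dietary-adequacy statistics

For recall/record data, each subject's days are averaged with equal weight
(`subject_mean_intake()`); "achieving the RNI" means mean intake at or
above the trimester lower bound, inclusive, with a configurable threshold
fraction (default 1.0) since stricter or laxer cut-offs are both in use.
Percentages are rounded half-up to one decimal, matching how such tables
are printed. Energy contributions use the Atwater factors 4/4/9 kcal/g for
carbohydrate/protein/fat, the convention in Malaysian food-composition
practice. Haemoglobin classes are moderate anaemia [8, 10), mild [10, 11),
normal [11, 16] g/dL — printed ranges like "10–10.9" are read as half-open
intervals so the classes tile the scale — and BMI uses the Asian cut-points
(underweight < 18.5, normal [18.5, 23), overweight [23, 27.5), pre-obese
[27.5, 35) kg/m²). Values outside every class are reported as
`out_of_range`, never silently clamped.

## The synthetic generator

No public food-composition database with per-serving market prices
accompanies the study design this package supports, so every test runs on
synthetic data with known ground truth (`generate_food_db()`,
`generate_records()`, `generate_known_optimum_instance()`).

Items are drawn per category with log-normal nutrient densities and prices:
positive, heavy-tailed, and category-structured (fish and meat high in
protein and iron, fruits in vitamin C and potassium, milk in calcium), the
way real food tables look. The serving-defining macro of each category (30 g
carbohydrate for cereals, 14 g protein for meat and fish, …) is drawn
tightly, because serving sizes are defined by it; micronutrients get large
log-sd (0.4–0.7) to produce the occasional liver-like outlier. Energy is
computed from the drawn macros by Atwater factors times a 3% log-normal
analysis noise, keeping items internally consistent. The packaged default
of 200 items over the 10 categories yields a feasible trimester problem for
essentially every seed — chosen once so that the packaged constraint system
and the generator describe the same world, and checked by a seed-sweep in
the test suite.

Recall cohorts draw a habitual basket per subject within customary group
serving ranges, with per-day log-normal variation. An exceedance target
(e.g. 60% of subjects achieving the iron RNI) is met by rescaling each
subject's basket so her mean intake lands on the assigned side of the
bound; the achieving subjects are fixed in count and random in identity, so
the cohort fraction is controlled and the ±5-point check in the tests
measures the estimator, not the generator. A single scale factor cannot
steer several nutrients independently, so only the first target is honoured
and extra targets draw a warning. Covariates come from a three-component
haemoglobin mixture spanning the anaemia classes, a log-normal BMI centred
near 24 kg/m², and a gravidity distribution typical of parity-limited
antenatal cohorts.

Known-optimum instances come in two constructions, because pinned problems
alone test only degenerate geometry: *pinned* (bounds set to exactly what a
drawn serving vector achieves, making it the unique feasible point) and
*oracle* (small random instances certified by exhaustive enumeration).

**What passing tests do not show.** The generator emulates the shape of
food-composition data, not any real national database: real tables have
correlated nutrients within foods (the generator draws them independently
given the category), recipe-level items, measurement error and missingness
patterns, and prices that co-move with nutrient density. Optimal costs on
synthetic data are in abstract currency units and are comparable across
scenarios, not to any published price.

## Problem sizes and runtime choices

The test suite and the acceptance script size their sweeps so the whole
battery runs in minutes on one CPU: enumeration-checked instances use up to
8 items with caps of 4 half-servings (≤ 390,625 candidate vectors);
property sweeps over supplement scenarios use 35-item databases, where a
full solve takes well under a second; full-size 200-item databases are used
where only one or a handful of solves is needed (headline costs, scarcity
diagnosis, feasibility calibration). These sizes are choices about test
economy, not limits of the solver — the 200-item default solves in a few
seconds.

## Known limitations

* Single-day optimization only: no multi-day variety planning, no goal
  programming or weighted-deviation variants.
* No bioavailability modelling — iron absorption enhancers and inhibitors
  (ascorbate, phytates) are a narrative concern, not a computed one.
* Supplement cost is not modelled (the motivating scenario is free
  antenatal supplementation).
* The nutrient panel is fixed at 15; folate, vitamin D and fatty-acid
  detail are out of scope.
* The sequential lexicographic refinement adds up to one small MILP per
  selected item; on large databases with unique optima it is pure overhead
  and can be disabled.
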