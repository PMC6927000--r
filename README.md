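# dietopt

Least-cost diet optimization for pregnancy nutrition.

Designing a daily diet for a pregnant woman that meets her trimester's
Recommended Nutrient Intake (RNI 2017), follows the Malaysian Dietary
Guidelines 2010 food-group serving pattern, stays palatable, and costs as
little as possible is an integer linear program — the classical least-cost
diet problem with servings as the unit of choice:

```
min  p = Σ_j c_j x_j                    (daily food cost)
s.t. l_i ≤ Σ_j a_ij x_j ≤ u_i           (15 nutrient bounds, per trimester)
     L_g ≤ Σ_{j∈g} x_j   ≤ U_g          (10 food-group serving bounds)
     0  ≤ x_j ≤ cap_j,  x_j ∈ ½·Z       (per-item caps, half-serving grid)
```

`dietopt` is for nutrition researchers and dietitians who want this program
solved *exactly* and audited: which constraints bind at the optimum, which
requirement makes a problem infeasible, and how much a free supplement
(e.g. 100 mg/day elemental iron) changes the least cost. It also computes
the standard dietary-assessment statistics for recall/record cohorts
(percentage achieving the RNI, macronutrient energy contributions,
haemoglobin/BMI classification), and ships seeded synthetic generators —
food databases, recall cohorts, and optimization instances with known
optima — so everything is testable without proprietary food-composition
data.

The solver is exact branch and bound over a bounded-variable two-phase
simplex (compiled core under `src/`), with a deterministic lexicographic
tie-break among equal-cost diets and an exhaustive-enumeration oracle
(`brute_force_diet()`) that the test suite holds it to, instance by
instance.

## Worked example

```r
library(dietopt)

db      <- generate_food_db(seed = 42)        # 200-item synthetic database
problem <- build_problem(db, trimester = 2)   # RNI 2017 + MDG 2010 + caps
sol     <- optimize_diet(problem)

print(sol)
#> <diet_solution> optimal
#>   cost 4.4724, 18 items selected, energy 1884.2 kcal

br <- binding_report(sol, problem)
subset(br, side != "none" & type == "nutrient")
#>    constraint       value  lower upper  side
#>   energy_kcal 1884.182938 1880.0  2080 lower
#>       vitC_mg  155.110827   80.0  2000 lower
#>      vitB1_mg    1.424618    1.4   Inf lower
#>      vitB2_mg    1.421640    1.4   Inf lower
#>  potassium_mg 4702.268933 4700.0   Inf lower
#>       iron_mg   20.000995   20.0    29 lower
```

The cheapest trimester-2 diet costs 4.47 currency units/day and sits right
on the lower bounds for energy, potassium and iron — iron is exactly the
nutrient the model has to work hardest to supply. Giving the free antenatal
supplement bundle (iron 100 mg + vitamin C + B complex) relaxes those
dietary requirements and the least cost drops:

```r
compare_scenarios(db, 2, list(default_supplement_scenario(2)))[, 1:3]
#>                      scenario  status     cost
#>                      baseline optimal 4.472380
#>  iron + vitamin C + B complex optimal 4.385606
```

The serving vector arranges into a five-slot day menu:

```r
menu <- assemble_menu(sol, db)
print(menu)
#> DAY MENU
#> BREAKFAST
#>   cereals and grains item 7 (synthetic) (cereals_and_grains_007): 2 servings
#>   ...
#> Food Cost Per Day: 4.47
```

Infeasible problems are findings, not errors: `diagnose_infeasibility()`
relaxes one constraint at a time and names the requirements (e.g. the iron
lower bound on an iron-scarce food supply) whose removal restores
feasibility. Recall/record cohorts flow through `cohort_summary()`:

```r
rc <- generate_records(db, n_subjects = 78, n_days = 3, seed = 1)
cs <- cohort_summary(rc$records, rc$covariates, db, rni_bounds(2))
#> anaemic: 26.9%; mean gravidity 2.88; energy % CHO/protein/fat: 55.3/18.5/26.4
head(cs$intake, 4)
#>     nutrient    mean     sd pct_achieving_rni
#>  energy_kcal 2093.70 276.90              79.5
#>    protein_g   96.65  14.87             100.0
#>       carb_g  289.27  46.07             100.0
#>        fat_g   61.76  14.12              52.6
```

A command-line pipeline (`validate | optimize | scenarios | adequacy |
synth`) wraps the same functions; see `?dietopt_main` and
`inst/cli/dietopt.R`.

## Package layout

| Path | Contents |
| --- | --- |
| `R/food_db.R` | food-database container, CSV I/O, linear nutrient accounting |
| `R/constraints.R` | RNI/MDG bound tables, supplements, problem builder, YAML config |
| `R/simplex.R`, `src/simplex.cpp` | bounded-variable two-phase simplex (R reference + compiled core) |
| `R/optimize.R` | branch and bound, enumeration oracle, binding report, infeasibility diagnosis, scenario comparison |
| `R/menu.R` | five-slot day-menu assembly and rendering |
| `R/adequacy.R` | recall/record summaries, RNI achievement, Hb/BMI classes |
| `R/synthetic.R` | seeded generators: food databases, cohorts, known-optimum instances |
| `R/cli.R`, `inst/cli/dietopt.R` | command-line pipeline |
| `vignettes/diet-optimization.Rmd` | model, solver design, generator design, limitations |
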