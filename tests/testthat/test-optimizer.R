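neutral_bounds <- function(except = list()) {
  nb <- data.frame(nutrient = NUTRIENTS, lower = 0, upper = Inf,
                   stringsAsFactors = FALSE)
  for (nm in names(except)) {
    i <- match(nm, nb$nutrient)
    nb$lower[i] <- except[[nm]][1]
    nb$upper[i] <- except[[nm]][2]
  }
  nb
}

free_groups <- function() {
  stats::setNames(lapply(FOOD_CATEGORIES,
                         function(cat) list(lower = 0, upper = Inf)),
                  FOOD_CATEGORIES)
}

two_item_iron_problem <- function(prices = c(1, 2), cap = 4) {
  db <- food_db(data.frame(
    item_id = c("a", "b"), name = c("A", "B"),
    category = "cereals and grains", price = prices, serving_note = "",
    iron_mg = c(2, 5), stringsAsFactors = FALSE))
  build_problem(db, 1, overrides = list(
    nutrient_bounds = neutral_bounds(list(iron_mg = c(10, Inf))),
    group_bounds = free_groups(),
    item_caps = list(default = cap)))
}

test_that("a unique feasible point is returned at its exact cost", {
  p <- pinned_single_item_problem()
  sol <- optimize_diet(p)
  expect_identical(sol$status, "optimal")
  expect_equal(unname(sol$servings["only"]), 1)
  expect_equal(sol$total_cost, 2.5)
})

test_that("a hand-computed two-item optimum is found", {
  # iron >= 10 mg from A (2 mg, price 1) and B (5 mg, price 2) on a
  # half-serving grid with caps of 4: two servings of B (cost 4) beat any
  # mix that leans on A (e.g. 1.5B + 1.5A costs 4.5)
  p <- two_item_iron_problem()
  sol <- optimize_diet(p)
  bf <- brute_force_diet(p)
  expect_equal(sol$total_cost, 4)
  expect_equal(unname(sol$servings), c(0, 2))
  expect_same_solution(sol, bf)
})

test_that("requirements beyond total attainable supply are infeasible", {
  db <- tiny_db()   # caps 2/1/2 servings, iron 0.8/1.0/0 per serving
  p <- build_problem(db, 1, overrides = list(
    nutrient_bounds = neutral_bounds(list(iron_mg = c(5, Inf))),
    group_bounds = free_groups()))
  # max attainable iron = 2*0.8 + 1*1.0 = 2.6 < 5
  expect_identical(optimize_diet(p)$status, "infeasible")
  expect_identical(brute_force_diet(p)$status, "infeasible")
})

test_that("solver matches the enumeration oracle on random instances", {
  for (s in 1:40) {
    p <- generate_random_instance(s * 7L)
    bf <- brute_force_diet(p)
    op <- optimize_diet(p)
    expect_same_solution(op, bf)
  }
})

test_that("optimal solutions satisfy every bound on independent re-check", {
  for (s in c(2, 9, 23, 31, 44)) {
    p <- generate_random_instance(s)
    sol <- optimize_diet(p)
    if (sol$status != "optimal") next
    ev <- evaluate_servings(sol$servings[sol$servings > 0], p$db)
    expect_equal(as.numeric(ev$profile), as.numeric(sol$achieved))
    expect_equal(ev$cost, sol$total_cost)
    nb <- p$nutrient_bounds
    tolv <- 1e-6 * pmax(1, abs(nb$lower))
    expect_true(all(as.numeric(ev$profile) >= nb$lower - tolv))
    expect_true(all(as.numeric(ev$profile) <=
                      ifelse(is.finite(nb$upper),
                             nb$upper + 1e-6 * pmax(1, nb$upper), Inf)))
    gs <- sol$group_servings[p$group_bounds$category]
    expect_true(all(gs >= p$group_bounds$lower - 1e-9))
    expect_true(all(gs <= p$group_bounds$upper + 1e-9))
    expect_true(all(sol$servings <= p$item_caps + 1e-9))
    # servings on the granularity grid
    expect_true(all(abs(sol$servings / p$granularity -
                          round(sol$servings / p$granularity)) < 1e-9))
  }
})

test_that("relaxing constraints never increases the optimal cost", {
  for (s in c(3, 12, 28)) {
    p <- generate_random_instance(s)
    base <- optimize_diet(p, lex = FALSE)
    if (base$status != "optimal") next
    p_lo <- p; p_lo$nutrient_bounds$lower <- 0.9 * p$nutrient_bounds$lower
    expect_lte(optimize_diet(p_lo, lex = FALSE)$total_cost,
               base$total_cost + 1e-9)
    p_up <- p; p_up$nutrient_bounds$upper <- Inf
    expect_lte(optimize_diet(p_up, lex = FALSE)$total_cost,
               base$total_cost + 1e-9)
    p_cap <- p; p_cap$item_caps <- p$item_caps + p$granularity
    expect_lte(optimize_diet(p_cap, lex = FALSE)$total_cost,
               base$total_cost + 1e-9)
    # a new zero-nutrient item cannot hurt either
    extra <- as.data.frame(p$db)[1, ]
    extra$item_id <- "zzz_extra"
    extra[NUTRIENTS] <- 0
    extra$price <- 99
    p_add <- p
    p_add$db <- food_db(rbind(as.data.frame(p$db), extra))
    p_add$item_caps <- c(p$item_caps, zzz_extra = 2)
    expect_lte(optimize_diet(p_add, lex = FALSE)$total_cost,
               base$total_cost + 1e-9)
  }
})

test_that("scaling all prices scales the cost and keeps the diet", {
  p <- generate_random_instance(17)
  base <- optimize_diet(p)
  expect_identical(base$status, "optimal")
  lam <- 3.25   # exactly representable, so costs scale bit-exactly
  p2 <- p
  p2$db$price <- p$db$price * lam
  scaled <- optimize_diet(p2)
  expect_equal(scaled$total_cost, lam * base$total_cost, tolerance = 1e-12)
  expect_identical(unname(scaled$servings), unname(base$servings))
})

test_that("identical inputs give bit-identical solutions", {
  p <- generate_random_instance(23)
  a <- optimize_diet(p)
  b <- optimize_diet(p)
  expect_identical(a$servings, b$servings)
  expect_identical(a$total_cost, b$total_cost)
})

test_that("equal-cost ties break to the lexicographically smallest vector", {
  # two indistinguishable items: the later one takes the servings, since
  # (0, 2) precedes (2, 0) and any mix in lexicographic order
  db <- food_db(data.frame(
    item_id = c("a", "b"), name = c("A", "B"),
    category = "cereals and grains", price = 1, serving_note = "",
    iron_mg = 5, stringsAsFactors = FALSE))
  p <- build_problem(db, 1, overrides = list(
    nutrient_bounds = neutral_bounds(list(iron_mg = c(10, Inf))),
    group_bounds = free_groups()))
  sol <- optimize_diet(p)
  bf <- brute_force_diet(p)
  expect_equal(unname(sol$servings), c(0, 2))
  expect_same_solution(sol, bf)
})

test_that("binding classification follows the bound-span tolerance", {
  db <- food_db(data.frame(
    item_id = "x", name = "X", category = "vegetables", price = 1,
    serving_note = "", energy_kcal = 1806, potassium_mg = 4703.5,
    fibre_g = 5, stringsAsFactors = FALSE))
  p <- build_problem(db, 1, overrides = list(
    nutrient_bounds = neutral_bounds(list(energy_kcal = c(1680, 1880),
                                          potassium_mg = c(4700, Inf),
                                          fibre_g = c(0, 10))),
    group_bounds = free_groups(),
    item_caps = list(default = 1)))
  sol <- dietopt:::make_solution(2L, p)   # two half-serving units = 1 serving
  br <- binding_report(sol, p)
  # potassium 4703.5 against lower 4700 (no upper): within 5% of the bound
  expect_identical(br$side[br$constraint == "potassium_mg"], "lower")
  # energy 1806 sits well inside [1680, 1880]
  e <- br[br$constraint == "energy_kcal", ]
  expect_identical(e$side, "none")
  expect_equal(e$relative_position, (1806 - 1680) / 200)
  # exactly midway with zero tolerance: no side, equal slacks
  br0 <- binding_report(sol, p, tol_fraction = 0)
  f <- br0[br0$constraint == "fibre_g", ]
  expect_identical(f$side, "none")
  expect_equal(f$slack_lower, f$slack_upper)

  expect_error(binding_report(dietopt:::infeasible_solution(p), p),
               "optimal")
})

test_that("single-constraint relaxation finds infeasibility culprits", {
  # iron demand raised beyond attainable supply: iron is the sole culprit
  db <- tiny_db()
  p <- build_problem(db, 1, overrides = list(
    nutrient_bounds = neutral_bounds(list(iron_mg = c(5, Inf))),
    group_bounds = free_groups()))
  d <- diagnose_infeasibility(p)
  expect_identical(d$culprits, "nutrient:iron_mg lower")
  expect_false(d$irreducible)

  # two independently impossible bounds: no single relaxation suffices
  p2 <- build_problem(db, 1, overrides = list(
    nutrient_bounds = neutral_bounds(list(iron_mg = c(5, Inf),
                                          vitC_mg = c(500, Inf))),
    group_bounds = free_groups()))
  d2 <- diagnose_infeasibility(p2)
  expect_true(d2$irreducible)
  expect_length(d2$culprits, 0)

  # a group lower bound its items cannot reach (every cereal capped at 0)
  p3 <- build_problem(db, 1, overrides = list(
    nutrient_bounds = neutral_bounds(),
    group_bounds = local({
      g <- free_groups()
      g[["cereals and grains"]] <- list(lower = 4, upper = 8)
      g
    }),
    item_caps = list(by_category = list("cereals and grains" = 0))))
  d3 <- diagnose_infeasibility(p3)
  expect_true("group:cereals and grains lower" %in% d3$culprits)

  expect_error(diagnose_infeasibility(pinned_single_item_problem()),
               "infeasible")
})

test_that("scenario comparison preserves order and monotone costs", {
  db <- generate_food_db(small_gen_params(), seed = 4)
  zero <- supplement_scenario("nothing")
  iron <- supplement_scenario("iron 100", iron_mg = 100)
  multi <- default_supplement_scenario(2)
  tab <- compare_scenarios(db, 2, list(zero, iron, multi), lex = FALSE)
  expect_identical(tab$scenario,
                   c("baseline", "nothing", "iron 100", multi$name))
  expect_identical(tab$status, rep("optimal", 4))
  # an all-zero supplement is the baseline
  expect_equal(tab$cost[2], tab$cost[1])
  expect_equal(unlist(tab[2, -1]), unlist(tab[1, -1]))
  # supplementation can only make the diet cheaper
  expect_lte(tab$cost[3], tab$cost[1] + 1e-9)
  expect_lte(tab$cost[4], tab$cost[1] + 1e-9)
  sols <- attr(tab, "solutions")
  expect_length(sols, 4)
  expect_identical(sols[["baseline"]]$status, "optimal")
})

test_that("a failing scenario row does not abort the sweep", {
  db <- generate_food_db(small_gen_params(), seed = 4)
  bad <- structure(list(name = "broken", provided = "not a profile"),
                   class = "supplement_scenario")
  tab <- compare_scenarios(db, 2, list(bad), lex = FALSE)
  expect_identical(tab$status, c("optimal", "error"))
  expect_true(is.na(tab$cost[2]))
})
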