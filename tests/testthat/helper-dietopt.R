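# Shared fixtures, all built in code.

# three hand-written items with easy arithmetic
tiny_db <- function() {
  food_db(data.frame(
    item_id = c("rice_brown", "patin_fish", "palm_oil"),
    name = c("Brown rice", "Silver catfish", "Palm oil"),
    category = c("cereals and grains", "fish", "oil"),
    price = c(0.40, 1.20, 0.15),
    serving_note = c("30 g carbohydrate", "14 g protein", "9 g fat"),
    energy_kcal = c(140, 90, 81),
    protein_g = c(2.5, 14, 0),
    carb_g = c(30, 0, 0),
    fat_g = c(1, 3, 9),
    fibre_g = c(1.8, 0, 0),
    vitA_RE = c(0, 10, 30),
    vitC_mg = c(0, 1, 0),
    vitB1_mg = c(0.1, 0.05, 0),
    vitB2_mg = c(0.05, 0.1, 0),
    vitB3_mg = c(1.5, 3.5, 0),
    sodium_mg = c(5, 80, 0),
    potassium_mg = c(120, 180, 0),
    calcium_mg = c(10, 50, 0),
    iron_mg = c(0.8, 1.0, 0),
    phosphorus_mg = c(60, 150, 0),
    stringsAsFactors = FALSE
  ))
}

# generator presets: a mid-size cohort database and a small one whose diet
# problems solve in well under a second (used for the larger property sweeps)
small_gen_params <- function() {
  list(n_items = c(
    "cereals and grains" = 6, "fruits" = 5, "vegetables" = 6,
    "meat/poultry" = 4, "fish" = 4, "legumes" = 3,
    "milk and dairy products" = 3, "sugar" = 1, "salt" = 1, "oil" = 2))
}

# a one-item problem whose unique feasible point is 1 serving of that item
pinned_single_item_problem <- function() {
  db <- food_db(data.frame(
    item_id = "only", name = "Only food", category = "cereals and grains",
    price = 2.5, serving_note = "",
    energy_kcal = 1800, protein_g = 60, carb_g = 250, fat_g = 55,
    fibre_g = 22, vitA_RE = 900, vitC_mg = 100, vitB1_mg = 1.5,
    vitB2_mg = 1.5, vitB3_mg = 20, sodium_mg = 1600, potassium_mg = 4800,
    calcium_mg = 1100, iron_mg = 21, phosphorus_mg = 800,
    stringsAsFactors = FALSE
  ))
  tot <- evaluate_servings(c(only = 1), db)$profile
  nb <- data.frame(nutrient = NUTRIENTS, lower = as.numeric(tot),
                   upper = as.numeric(tot), stringsAsFactors = FALSE)
  gb <- stats::setNames(lapply(FOOD_CATEGORIES, function(cat) {
    if (cat == "cereals and grains") list(lower = 1, upper = 1)
    else list(lower = 0, upper = Inf)
  }), FOOD_CATEGORIES)
  build_problem(db, 1, overrides = list(nutrient_bounds = nb,
                                        group_bounds = gb))
}

expect_same_solution <- function(a, b) {
  expect_identical(a$status, b$status)
  if (a$status == "optimal") {
    expect_equal(a$total_cost, b$total_cost, tolerance = 1e-12)
    expect_identical(unname(a$servings), unname(b$servings))
  }
}
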