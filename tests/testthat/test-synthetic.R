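test_that("every generator is deterministic under its seed", {
  expect_equal(generate_food_db(seed = 42), generate_food_db(seed = 42))
  db <- generate_food_db(small_gen_params(), seed = 2)
  r1 <- generate_records(db, 6, 3, seed = 5)
  r2 <- generate_records(db, 6, 3, seed = 5)
  expect_equal(r1, r2)
  expect_equal(generate_random_instance(9), generate_random_instance(9))
  k1 <- generate_known_optimum_instance(3, "pinned")
  k2 <- generate_known_optimum_instance(3, "pinned")
  expect_equal(k1$solution$servings, k2$solution$servings)
  # and the caller's RNG stream is left untouched
  set.seed(1); before <- stats::runif(1)
  set.seed(1); invisible(generate_food_db(small_gen_params(), seed = 7))
  expect_identical(stats::runif(1), before)
})

test_that("generated databases validate and honour category counts", {
  db <- generate_food_db(seed = 1)
  expect_s3_class(db, "food_db")
  expect_equal(nrow(db), 200)
  counts <- table(db$category)
  expect_equal(unname(counts["fish"]), 25)
  expect_true(all(db$price > 0))
  expect_true(all(as.matrix(as.data.frame(db)[, NUTRIENTS]) >= 0))
  expect_error(generate_food_db(list(n_items = c(fish = 0)), seed = 1),
               "zero items")
})

test_that("missing palatability categories leave group bounds unmeetable", {
  p <- default_generator_params()
  p$n_items[c("sugar", "salt", "oil")] <- 0
  db <- generate_food_db(list(n_items = p$n_items), seed = 6)
  expect_false(any(db$category %in% c("sugar", "salt", "oil")))
  prob <- build_problem(db, 2)
  expect_identical(optimize_diet(prob, lex = FALSE)$status, "infeasible")
  # no single group relaxation can fix three missing categories at once
  d <- diagnose_infeasibility(prob)
  expect_true(d$irreducible)
})

test_that("iron scarcity scales exactly one column", {
  db <- generate_food_db(small_gen_params(), seed = 3)
  expect_equal(make_iron_scarce(db, 1), db)
  half <- make_iron_scarce(db, 0.5)
  expect_equal(half$iron_mg, db$iron_mg / 2)
  others <- setdiff(names(db), "iron_mg")
  expect_identical(as.data.frame(half)[others], as.data.frame(db)[others])
  expect_error(make_iron_scarce(db, 0), "positive")
})

test_that("records hit the requested exceedance fraction", {
  db <- generate_food_db(small_gen_params(), seed = 8)
  rc <- generate_records(db, n_subjects = 60, n_days = 3,
                         exceedance_targets = c(iron_mg = 0.5), seed = 12)
  subjects <- unique(rc$records$subject_id)
  intakes <- lapply(subjects, function(s) {
    subject_mean_intake(rc$records[rc$records$subject_id == s, ], db)
  })
  pct <- percent_achieving_rni(intakes, rni_bounds(2))
  expect_lt(abs(pct[["iron_mg"]] - 50), 5)
  # covariate mixtures span the intended classes
  expect_true(all(rc$covariates$hb >= 8 & rc$covariates$hb <= 16))
  expect_true(all(rc$covariates$gravidity %in% 1:7))
})

test_that("single-day records equal the subject mean", {
  db <- generate_food_db(small_gen_params(), seed = 8)
  rc <- generate_records(db, n_subjects = 3, n_days = 1, seed = 4)
  s1 <- rc$records[rc$records$subject_id == rc$records$subject_id[1], ]
  m <- subject_mean_intake(s1, db)
  sv <- stats::setNames(s1$servings, s1$item_id)
  expect_equal(as.numeric(m),
               as.numeric(evaluate_servings(sv, db)$profile))
})

test_that("pinned instances are recovered exactly and break under caps", {
  for (s in c(1, 5, 11)) {
    ko <- generate_known_optimum_instance(s, "pinned")
    sol <- optimize_diet(ko$problem)
    expect_identical(sol$status, "optimal")
    expect_equal(sol$servings, ko$solution$servings)
    expect_equal(sol$total_cost, ko$solution$total_cost)
  }
  ko <- generate_known_optimum_instance(2, "pinned")
  j <- which(ko$solution$servings > 0)[1]
  p <- ko$problem
  p$item_caps[j] <- p$item_caps[j] - p$granularity
  expect_identical(optimize_diet(p)$status, "infeasible")
})

test_that("oracle instances match their stored brute-force solutions", {
  for (s in c(2, 8, 21)) {
    ko <- generate_known_optimum_instance(s, "oracle")
    sol <- optimize_diet(ko$problem)
    expect_same_solution(sol, ko$solution)
  }
})

test_that("iron dominates the binding and culprit reports when scarce", {
  # halving iron everywhere makes the iron row the tight one: across seeds,
  # iron should be at its lower bound (feasible) or a culprit (infeasible)
  # more often than any other nutrient
  iron_hits <- 0L
  n_seeds <- 8L
  for (s in seq_len(n_seeds)) {
    db <- make_iron_scarce(generate_food_db(small_gen_params(),
                                            seed = 100 + s), 0.5)
    prob <- build_problem(db, 2)
    sol <- optimize_diet(prob, lex = FALSE)
    hit <- if (sol$status == "optimal") {
      br <- binding_report(sol, prob)
      any(br$constraint == "iron_mg" & br$side == "lower")
    } else {
      "nutrient:iron_mg lower" %in% diagnose_infeasibility(prob)$culprits
    }
    if (hit) iron_hits <- iron_hits + 1L
  }
  expect_gte(iron_hits, 6L)
})
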