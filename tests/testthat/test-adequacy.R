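test_that("subject mean intake averages days with equal weight", {
  db <- tiny_db()
  one_day <- data.frame(subject_id = "s1", day_index = 1,
                        item_id = c("rice_brown", "patin_fish"),
                        servings = c(2, 1), stringsAsFactors = FALSE)
  # identical intake on three days is that day's profile
  rec3 <- do.call(rbind, lapply(1:3, function(d) transform(one_day,
                                                           day_index = d)))
  expect_equal(as.numeric(subject_mean_intake(rec3, db)),
               as.numeric(subject_mean_intake(one_day, db)))

  # days with profiles P and 3P average to 2P
  recP <- rbind(one_day,
                transform(one_day, day_index = 2, servings = servings * 3))
  expect_equal(as.numeric(subject_mean_intake(recP, db)),
               2 * as.numeric(subject_mean_intake(one_day, db)))

  # four-day fixture against hand-computed means: rice servings 1,2,3,4
  rec4 <- data.frame(subject_id = "s1", day_index = 1:4,
                     item_id = "rice_brown", servings = 1:4,
                     stringsAsFactors = FALSE)
  m <- subject_mean_intake(rec4, db)
  expect_equal(m[["carb_g"]], 2.5 * 30)      # mean 2.5 servings x 30 g
  expect_equal(m[["energy_kcal"]], 2.5 * 140)

  expect_error(subject_mean_intake(transform(one_day, item_id = "ghost"), db),
               "ghost")
})

test_that("percent achieving RNI is inclusive at the bound and rounded", {
  rni <- rni_bounds(2)   # iron lower 20
  below <- lapply(1:3, function(i) nutrient_profile(iron_mg = 10))
  expect_equal(unname(percent_achieving_rni(below, rni)["iron_mg"]), 0)
  at <- lapply(1:3, function(i) nutrient_profile(iron_mg = 20))
  expect_equal(unname(percent_achieving_rni(at, rni)["iron_mg"]), 100)
  third <- list(nutrient_profile(iron_mg = 25), nutrient_profile(),
                nutrient_profile(iron_mg = 19.9))
  expect_equal(unname(percent_achieving_rni(third, rni)["iron_mg"]), 33.3)
  # a configurable threshold fraction moves the cut-off
  expect_equal(unname(percent_achieving_rni(third, rni,
                                            threshold = 0.5)["iron_mg"]),
               66.7)
})

test_that("raising an RNI lower bound never raises the percentage", {
  set.seed(31)
  intakes <- lapply(1:40, function(i) {
    nutrient_profile(iron_mg = stats::runif(1, 5, 40))
  })
  rni <- rni_bounds(2)
  pcts <- vapply(seq(5, 45, by = 5), function(cut) {
    r <- rni; r$lower[r$nutrient == "iron_mg"] <- cut
    unname(percent_achieving_rni(intakes, r)["iron_mg"])
  }, numeric(1))
  expect_true(all(diff(pcts) <= 0))
})

test_that("energy contributions use Atwater 4/4/9 and scale invariance", {
  p1 <- nutrient_profile(energy_kcal = 400, carb_g = 100)
  expect_equal(energy_percent(p1), c(cho = 100, protein = 0, fat = 0))
  p2 <- nutrient_profile(energy_kcal = 1840, carb_g = 250, protein_g = 75,
                         fat_g = 60)
  ep <- energy_percent(p2)
  expect_equal(round(unname(ep), 1), c(54.3, 16.3, 29.3))
  expect_equal(energy_percent(p2 * 2), ep)
  expect_error(energy_percent(nutrient_profile(carb_g = 10)), "energy")
})

test_that("haemoglobin and BMI classes use the printed cut-points", {
  expect_identical(classify_hb(10.5), "mild_anaemia")
  expect_identical(classify_hb(11.0), "normal")
  expect_identical(classify_hb(c(8, 9.9, 10, 10.9, 16)),
                   c("moderate_anaemia", "moderate_anaemia", "mild_anaemia",
                     "mild_anaemia", "normal"))
  expect_identical(classify_hb(7.5), "out_of_range")
  expect_identical(classify_bmi(23.0), "overweight")
  expect_identical(classify_bmi(c(18.4, 18.5, 22.9, 27.4, 27.5, 34.9)),
                   c("underweight", "normal", "normal", "overweight",
                     "preobese", "preobese"))
  expect_identical(classify_bmi(36), "out_of_range")
})

table1_covariates <- function() {
  # category counts of a 78-woman antenatal cohort: Hb 55/17/6
  # (normal/mild/moderate), BMI 10/32/22/14, gravidity 17,19,20,10,7,4,1
  hb <- c(rep(11.5, 55), rep(10.5, 17), rep(9.0, 6))
  bmi <- c(rep(17.5, 10), rep(20, 32), rep(24, 22), rep(30, 14))
  gravidity <- rep(1:7, c(17, 19, 20, 10, 7, 4, 1))
  data.frame(subject_id = sprintf("S%02d", 1:78), hb = hb, bmi = bmi,
             gravidity = gravidity, trimester = 2,
             supplement_user = TRUE, stringsAsFactors = FALSE)
}

table1_records <- function() {
  data.frame(subject_id = sprintf("S%02d", 1:78), day_index = 1,
             item_id = "rice_brown", servings = 2, stringsAsFactors = FALSE)
}

test_that("cohort summary reproduces category percentages and means", {
  cs <- cohort_summary(table1_records(), table1_covariates(), tiny_db(),
                       rni_bounds(2))
  expect_equal(cs$n, 78)
  expect_equal(cs$anaemic_pct, 29.5)           # (17 + 6) / 78
  expect_equal(cs$hb$pct[cs$hb$category == "normal"], 70.5)
  expect_equal(cs$hb$pct[cs$hb$category == "mild_anaemia"], 21.8)
  expect_equal(cs$hb$pct[cs$hb$category == "moderate_anaemia"], 7.7)
  expect_equal(cs$bmi$pct[1:4], c(12.8, 41.0, 28.2, 17.9))
  expect_equal(round(cs$mean_gravidity, 2), 2.83)
  expect_equal(cs$gravidity$pct,
               c(21.8, 24.4, 25.6, 12.8, 9.0, 5.1, 1.3))
  # counts tile the cohort; percentages close within rounding
  expect_equal(sum(cs$hb$n), 78)
  expect_equal(sum(cs$bmi$n), 78)
  expect_lt(abs(sum(cs$hb$pct) - 100), 0.2)
  # identical single-item diets: means are exact, SDs zero
  expect_equal(cs$intake$mean[cs$intake$nutrient == "carb_g"], 60)
  expect_equal(cs$intake$sd[cs$intake$nutrient == "carb_g"], 0)
})

test_that("degenerate cohorts are handled explicitly", {
  cs1 <- cohort_summary(table1_records()[1, ], table1_covariates()[1, ],
                        tiny_db(), rni_bounds(2))
  expect_true(all(is.na(cs1$intake$sd)))
  expect_warning(
    cohort_summary(table1_records()[1:2, ], table1_covariates()[1, ],
                   tiny_db(), rni_bounds(2)),
    "covariates")
})

test_that("records and covariates CSVs round-trip through the readers", {
  rc <- generate_records(generate_food_db(small_gen_params(), seed = 2),
                         n_subjects = 5, n_days = 2, seed = 9)
  rp <- withr::local_tempfile(fileext = ".csv")
  cp <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(rc$records, rp, row.names = FALSE)
  utils::write.csv(rc$covariates, cp, row.names = FALSE)
  expect_equal(read_records(rp), rc$records)
  got <- read_covariates(cp)
  expect_equal(got$hb, rc$covariates$hb)
  expect_error(read_records(cp), "missing column")
})
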