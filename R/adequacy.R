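#' Read dietary records and subject covariates
#'
#' Records CSV schema: `subject_id,day_index,item_id,servings` (one row per
#' food per day). Covariates CSV schema:
#' `subject_id,hb,bmi,gravidity,trimester,supplement_user`.
#'
#' @param path CSV path.
#' @return Data frame.
#' @export
read_records <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "day_index", "item_id", "servings")
  missing_cols <- setdiff(need, names(rec))
  if (length(missing_cols)) {
    stop("records CSV missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  rec$subject_id <- as.character(rec$subject_id)
  rec$day_index <- as.integer(rec$day_index)
  rec$servings <- as.numeric(rec$servings)
  if (any(!is.finite(rec$servings)) || any(rec$servings < 0)) {
    stop("servings must be nonnegative numbers", call. = FALSE)
  }
  rec
}

#' @rdname read_records
#' @export
read_covariates <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cov <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "hb", "bmi", "gravidity", "trimester",
            "supplement_user")
  missing_cols <- setdiff(need, names(cov))
  if (length(missing_cols)) {
    stop("covariates CSV missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  cov$subject_id <- as.character(cov$subject_id)
  if (any(cov$hb <= 0) || any(cov$bmi <= 0)) {
    stop("hb and bmi must be positive", call. = FALSE)
  }
  cov
}

#' Mean daily nutrient intake of one subject
#'
#' Each recorded day is converted to a nutrient profile with
#' [evaluate_servings()]; days are averaged with equal weight, matching how
#' multi-day recall data are summarized before comparing against a daily
#' recommendation.
#'
#' @param records Data frame of this subject's records
#'   (`day_index`, `item_id`, `servings`).
#' @param db A [food_db()].
#' @return A [nutrient_profile()] of mean daily intake.
#' @export
subject_mean_intake <- function(records, db) {
  stopifnot(nrow(records) >= 1L)
  days <- unique(records$day_index)
  total <- nutrient_profile()
  for (d in days) {
    rd <- records[records$day_index == d, ]
    sv <- tapply(rd$servings, rd$item_id, sum)
    total <- total + evaluate_servings(
      stats::setNames(as.numeric(sv), names(sv)), db)$profile
  }
  total * (1 / length(days))
}

#' Percentage of a cohort achieving the RNI
#'
#' For each nutrient: `100 * (# subjects with mean intake >= threshold *
#' lower bound) / n`, rounded half-up to one decimal. Achievement is
#' inclusive at the bound.
#'
#' @param intakes List (or data frame rows) of per-subject
#'   [nutrient_profile()]s.
#' @param rni Nutrient bounds from [rni_bounds()] (the lower bounds are the
#'   cut-offs).
#' @param threshold Fraction of the lower bound counted as achievement
#'   (default 1.0).
#' @return Named numeric vector of percentages over [NUTRIENTS].
#' @export
percent_achieving_rni <- function(intakes, rni, threshold = 1) {
  stopifnot(length(intakes) >= 1L)
  mat <- do.call(rbind, lapply(intakes, as.numeric))
  colnames(mat) <- NUTRIENTS
  cut <- rni$lower[match(NUTRIENTS, rni$nutrient)] * threshold
  pct <- 100 * colMeans(sweep(mat, 2L, cut, `>=`))
  round_half_up(stats::setNames(pct, NUTRIENTS), 1)
}

#' Macronutrient contributions to energy
#'
#' Percentage of dietary energy supplied by carbohydrate, protein and fat
#' under the Atwater factors 4, 4 and 9 kcal/g.
#'
#' @param profile A [nutrient_profile()] with positive energy.
#' @return Named vector `c(cho = , protein = , fat = )` in percent.
#' @export
energy_percent <- function(profile) {
  profile <- as_profile(profile)
  energy <- profile[["energy_kcal"]]
  if (!is.finite(energy) || energy <= 0) {
    stop("energy must be positive to compute energy contributions",
         call. = FALSE)
  }
  c(cho = 100 * 4 * profile[["carb_g"]] / energy,
    protein = 100 * 4 * profile[["protein_g"]] / energy,
    fat = 100 * 9 * profile[["fat_g"]] / energy)
}

#' Classify haemoglobin and BMI values
#'
#' Haemoglobin (g/dL): moderate anaemia \[8, 10), mild anaemia \[10, 11),
#' normal \[11, 16\]; anaemia is any value below 11. BMI (kg/m²), Asian
#' cut-points: underweight below 18.5, normal \[18.5, 23), overweight
#' \[23, 27.5), pre-obese \[27.5, 35). Printed ranges such as "10–10.9" are
#' read as half-open intervals so the classes tile the scale; values outside
#' every class return `"out_of_range"` rather than being clamped.
#'
#' @param hb Haemoglobin in g/dL (vectorized).
#' @return Character vector of category codes.
#' @export
classify_hb <- function(hb) {
  stopifnot(all(hb > 0))
  out <- rep("out_of_range", length(hb))
  out[hb >= 8 & hb < 10] <- "moderate_anaemia"
  out[hb >= 10 & hb < 11] <- "mild_anaemia"
  out[hb >= 11 & hb <= 16] <- "normal"
  out
}

#' @rdname classify_hb
#' @param bmi Body-mass index in kg/m² (vectorized).
#' @export
classify_bmi <- function(bmi) {
  stopifnot(all(bmi > 0))
  out <- rep("out_of_range", length(bmi))
  out[bmi < 18.5] <- "underweight"
  out[bmi >= 18.5 & bmi < 23] <- "normal"
  out[bmi >= 23 & bmi < 27.5] <- "overweight"
  out[bmi >= 27.5 & bmi < 35] <- "preobese"
  out
}

HB_LEVELS <- c("normal", "mild_anaemia", "moderate_anaemia", "out_of_range")
BMI_LEVELS <- c("underweight", "normal", "overweight", "preobese",
                "out_of_range")

#' Cohort descriptive and adequacy summary
#'
#' Assembles the cohort-level statistics reported in dietary assessments of
#' pregnant women: per-nutrient mean and sample SD of daily intake, the
#' percentage of subjects achieving each RNI lower bound, macronutrient
#' energy-contribution means, and counts/percentages for haemoglobin
#' category, BMI category and gravidity (with the count-weighted mean
#' gravidity).
#'
#' @param records Records data frame (see [read_records()]).
#' @param covariates Covariates data frame (see [read_covariates()]);
#'   subjects with records but no covariates are kept in the intake
#'   summaries and excluded, with a warning, from the covariate summaries.
#' @param db A [food_db()].
#' @param rni Bounds from [rni_bounds()].
#' @return Object of class `cohort_summary`: `n`, `intake` (data frame
#'   `nutrient`, `mean`, `sd`, `pct_achieving_rni`), `energy_pct` (mean cho/
#'   protein/fat %), `hb` and `bmi` (data frames `category`, `n`, `pct`),
#'   `gravidity` (data frame plus `mean` attribute), `anaemic_pct`,
#'   `mean_gravidity`, `supplement_user_pct`.
#' @export
cohort_summary <- function(records, covariates, db, rni) {
  subjects <- unique(records$subject_id)
  n <- length(subjects)
  if (n == 0L) stop("no subjects in records", call. = FALSE)
  intakes <- lapply(subjects, function(s) {
    subject_mean_intake(records[records$subject_id == s, ], db)
  })
  mat <- do.call(rbind, lapply(intakes, as.numeric))
  colnames(mat) <- NUTRIENTS
  sds <- if (n > 1L) apply(mat, 2L, stats::sd) else rep(NA_real_, ncol(mat))
  intake <- data.frame(
    nutrient = NUTRIENTS,
    mean = colMeans(mat),
    sd = sds,
    pct_achieving_rni = as.numeric(percent_achieving_rni(intakes, rni)),
    stringsAsFactors = FALSE
  )
  ep <- t(vapply(intakes, energy_percent, numeric(3)))
  energy_pct <- colMeans(ep)

  no_cov <- setdiff(subjects, covariates$subject_id)
  if (length(no_cov)) {
    warning(length(no_cov),
            " subject(s) with records but no covariates excluded from ",
            "covariate summaries", call. = FALSE)
  }
  cov <- covariates[covariates$subject_id %in% subjects, ]
  nc <- nrow(cov)
  count_table <- function(x, levels) {
    cnt <- table(factor(x, levels = levels))
    data.frame(category = levels, n = as.integer(cnt),
               pct = round_half_up(100 * as.integer(cnt) / max(nc, 1L), 1),
               stringsAsFactors = FALSE)
  }
  hb_tab <- count_table(classify_hb(cov$hb), HB_LEVELS)
  bmi_tab <- count_table(classify_bmi(cov$bmi), BMI_LEVELS)
  grav_levels <- sort(unique(cov$gravidity))
  grav_tab <- data.frame(
    gravidity = grav_levels,
    n = as.integer(table(factor(cov$gravidity, levels = grav_levels))),
    stringsAsFactors = FALSE
  )
  grav_tab$pct <- round_half_up(100 * grav_tab$n / max(nc, 1L), 1)
  mean_grav <- if (nc) sum(grav_tab$gravidity * grav_tab$n) / nc else NA_real_
  anaemic <- if (nc) {
    round_half_up(100 * mean(cov$hb < 11), 1)
  } else NA_real_

  structure(list(
    n = n, n_with_covariates = nc,
    intake = intake, energy_pct = energy_pct,
    hb = hb_tab, bmi = bmi_tab, gravidity = grav_tab,
    mean_gravidity = mean_grav, anaemic_pct = anaemic,
    supplement_user_pct = if (nc) {
      round_half_up(100 * mean(as.logical(cov$supplement_user)), 1)
    } else NA_real_
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> n = %d subjects (%d with covariates)\n",
              x$n, x$n_with_covariates))
  cat(sprintf("  anaemic: %.1f%%; mean gravidity: %.2f\n",
              x$anaemic_pct, x$mean_gravidity))
  cat(sprintf("  energy from CHO/protein/fat: %.1f / %.1f / %.1f %%\n",
              x$energy_pct[["cho"]], x$energy_pct[["protein"]],
              x$energy_pct[["fat"]]))
  print(x$intake, row.names = FALSE, digits = 4)
  invisible(x)
}
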