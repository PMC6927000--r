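# Seeded synthetic generators: food databases with category-specific
# log-normal nutrient densities and prices, dietary-recall cohorts, and
# optimization instances with known optima. Everything is deterministic
# under its seed and leaves the caller's RNG state untouched.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed) %% .Machine$integer.max, kind = "Mersenne-Twister")
  force(code)
}

# geometric-mean per-serving nutrient densities by category. Serving sizes
# follow exchange-list convention (one cereal serving = 30 g carbohydrate,
# one meat/fish serving = 14 g protein, one legume/milk serving = 7 g
# protein, one sugar serving = 5 g carbohydrate, one oil serving = 9 g fat),
# so the serving-defining macro varies little while micronutrients are
# heavy-tailed across items.
GEN_NUTRIENT_MEANS <- local({
  cols <- setdiff(NUTRIENTS, "energy_kcal")
  m <- matrix(0, length(FOOD_CATEGORIES), length(cols),
              dimnames = list(FOOD_CATEGORIES, cols))
  #                      prot  carb  fat  fibre  vitA vitC   B1    B2    B3    Na    K    Ca   Fe    P
  m["cereals and grains", ] <- c(2.5, 30, 1.0, 2.0, 5, 0.5, 0.12, 0.05, 1.5, 10, 150, 15, 0.9, 70)
  m["fruits", ]            <- c(0.8, 15, 0.3, 2.5, 40, 35, 0.05, 0.04, 0.5, 5, 350, 20, 0.4, 25)
  m["vegetables", ]        <- c(2.0, 5, 0.3, 2.5, 300, 25, 0.07, 0.10, 0.8, 30, 300, 60, 1.3, 45)
  m["meat/poultry", ]      <- c(14, 0.5, 6.0, 0.1, 150, 1, 0.15, 0.25, 4.0, 70, 200, 12, 1.8, 140)
  m["fish", ]              <- c(14, 0.5, 3.0, 0.1, 30, 1, 0.06, 0.12, 3.5, 90, 180, 60, 1.2, 160)
  m["legumes", ]           <- c(7, 12, 2.5, 4.0, 5, 1, 0.20, 0.10, 0.8, 10, 400, 50, 2.2, 130)
  m["milk and dairy products", ] <- c(7, 10, 5.0, 0.2, 80, 1.5, 0.10, 0.40, 0.3, 100, 330, 270, 0.2, 190)
  m["sugar", ]             <- c(0.01, 5, 0.01, 0.05, 0.5, 0.2, 0.001, 0.001, 0.01, 1, 5, 1, 0.02, 1)
  m["salt", ]              <- c(0.001, 0.001, 0.001, 0.001, 0.1, 0.01, 0.001, 0.001, 0.001, 390, 1, 1, 0.01, 0.1)
  m["oil", ]               <- c(0.01, 0.05, 9, 0.02, 30, 0.1, 0.001, 0.001, 0.01, 1, 1, 0.2, 0.02, 0.5)
  m
})

# log-scale spread: serving-defining macros are tight, micronutrients broad
GEN_NUTRIENT_SDLOG <- local({
  cols <- setdiff(NUTRIENTS, "energy_kcal")
  s <- matrix(0.4, length(FOOD_CATEGORIES), length(cols),
              dimnames = list(FOOD_CATEGORIES, cols))
  s[, c("vitA_RE", "vitC_mg", "calcium_mg", "iron_mg")] <- 0.7
  s["cereals and grains", "carb_g"] <- 0.08
  s[c("meat/poultry", "fish"), "protein_g"] <- 0.08
  s[c("legumes", "milk and dairy products"), "protein_g"] <- 0.15
  s["sugar", "carb_g"] <- 0.05
  s["oil", "fat_g"] <- 0.05
  s["salt", ] <- 0.05
  s
})

#' Default synthetic-generator parameters
#'
#' Packaged parameters emulating a several-hundred-item national food
#' database with per-serving market prices: item counts per category,
#' log-normal price distributions (location on the log scale, in abstract
#' currency units per serving) and category-specific log-normal nutrient
#' densities. Energy is derived from the drawn macronutrients via the
#' Atwater factors (4/4/9 kcal/g) times a small log-normal analysis noise,
#' so generated items are internally consistent.
#'
#' @return List with `n_items`, `price_meanlog`, `price_sdlog` (named by
#'   category), `nutrient_means`, `nutrient_sdlog` (category x nutrient
#'   matrices, geometric means / log-sd), `energy_noise_sd`.
#' @export
default_generator_params <- function() {
  list(
    n_items = c("cereals and grains" = 40, "fruits" = 30, "vegetables" = 40,
                "meat/poultry" = 25, "fish" = 25, "legumes" = 15,
                "milk and dairy products" = 15, "sugar" = 4, "salt" = 2,
                "oil" = 4),
    price_meanlog = log(c("cereals and grains" = 0.40, "fruits" = 0.80,
                          "vegetables" = 0.50, "meat/poultry" = 1.50,
                          "fish" = 1.20, "legumes" = 0.50,
                          "milk and dairy products" = 0.80, "sugar" = 0.10,
                          "salt" = 0.02, "oil" = 0.15)),
    price_sdlog = c("cereals and grains" = 0.5, "fruits" = 0.5,
                    "vegetables" = 0.5, "meat/poultry" = 0.5, "fish" = 0.5,
                    "legumes" = 0.5, "milk and dairy products" = 0.5,
                    "sugar" = 0.3, "salt" = 0.3, "oil" = 0.3),
    nutrient_means = GEN_NUTRIENT_MEANS,
    nutrient_sdlog = GEN_NUTRIENT_SDLOG,
    energy_noise_sd = 0.03
  )
}

#' Generate a synthetic food database
#'
#' Draws per-serving nutrient profiles and prices from category-specific
#' log-normal distributions (see [default_generator_params()]). Output is
#' deterministic under `seed` and always passes [food_db()] validation.
#'
#' @param params Generator parameters; any subset of the names of
#'   [default_generator_params()] to override the packaged defaults.
#' @param seed Integer seed.
#' @return A [food_db()].
#' @examples
#' db <- generate_food_db(seed = 1)
#' nrow(db)
#' @export
generate_food_db <- function(params = list(), seed = 1) {
  p <- utils::modifyList(default_generator_params(), params)
  n_items <- p$n_items[p$n_items > 0]
  if (!length(n_items)) stop("zero items in all categories", call. = FALSE)
  bad <- setdiff(names(n_items), FOOD_CATEGORIES)
  if (length(bad)) stop("unknown category: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  cols <- setdiff(NUTRIENTS, "energy_kcal")
  with_seed(seed, {
    rows <- lapply(names(n_items), function(cat) {
      k <- n_items[[cat]]
      mus <- log(p$nutrient_means[cat, cols])
      sds <- p$nutrient_sdlog[cat, cols]
      amounts <- matrix(stats::rlnorm(k * length(cols),
                                      meanlog = rep(mus, each = k),
                                      sdlog = rep(sds, each = k)),
                        nrow = k, dimnames = list(NULL, cols))
      energy <- (4 * (amounts[, "protein_g"] + amounts[, "carb_g"]) +
                   9 * amounts[, "fat_g"]) *
        stats::rlnorm(k, 0, p$energy_noise_sd)
      token <- gsub("[^a-z]+", "_", tolower(cat))
      data.frame(
        item_id = sprintf("%s_%03d", token, seq_len(k)),
        name = sprintf("%s item %d (synthetic)", cat, seq_len(k)),
        category = cat,
        price = stats::rlnorm(k, p$price_meanlog[[cat]], p$price_sdlog[[cat]]),
        serving_note = "",
        energy_kcal = energy,
        amounts,
        check.names = FALSE, stringsAsFactors = FALSE
      )
    })
    food_db(do.call(rbind, rows))
  })
}

#' Scale down the iron content of every item
#'
#' Multiplies each item's per-serving iron by `factor`, leaving every other
#' value untouched — a controlled way to emulate iron-poor food supplies and
#' study when the iron requirement becomes unattainable.
#'
#' @param db A [food_db()].
#' @param factor Positive scale, typically in (0, 1].
#' @return The modified [food_db()].
#' @export
make_iron_scarce <- function(db, factor) {
  stopifnot(inherits(db, "food_db"))
  factor <- as.numeric(factor)[1L]
  if (!is.finite(factor) || factor <= 0) {
    stop("factor must be positive", call. = FALSE)
  }
  db$iron_mg <- db$iron_mg * factor
  db
}

#' Generate a synthetic dietary-recall cohort
#'
#' Per subject, draws a habitual daily basket (servings of a few items per
#' food group, within customary group serving ranges) and per-day log-normal
#' intake variation around it. When an exceedance target is given for a
#' nutrient, each subject's whole basket is rescaled so that her mean daily
#' intake of that nutrient lands above or below the trimester-2 RNI lower
#' bound, with the target fraction of subjects assigned (deterministically
#' in count, randomly in identity) to the "achieving" side. Covariates are
#' drawn from mixtures spanning the anaemia and BMI classes and a gravidity
#' distribution typical of parity-limited antenatal cohorts.
#'
#' @param db A [food_db()].
#' @param n_subjects,n_days Cohort dimensions.
#' @param exceedance_targets Optional named fraction(s) in \[0,1\], e.g.
#'   `c(iron_mg = 0.6)`. Only the first is used to rescale intakes (a single
#'   scale factor cannot steer several nutrients independently); extra
#'   entries draw a warning. A subject whose basket lacks the nutrient
#'   entirely cannot be rescaled and draws a warning with the achieved
#'   fraction.
#' @param seed Integer seed.
#' @param trimester RNI trimester used for the exceedance cut-off.
#' @return List with `records` and `covariates` data frames (schemas as in
#'   [read_records()] / [read_covariates()]).
#' @export
generate_records <- function(db, n_subjects, n_days = 3,
                             exceedance_targets = NULL, seed = 1,
                             trimester = 2) {
  stopifnot(inherits(db, "food_db"), nrow(db) > 0, n_subjects >= 1,
            n_days >= 1)
  gb <- mdg_group_bounds()
  rni <- rni_bounds(trimester)
  target_nutrient <- NULL
  target_frac <- NULL
  if (!is.null(exceedance_targets)) {
    stopifnot(!is.null(names(exceedance_targets)),
              all(names(exceedance_targets) %in% NUTRIENTS),
              all(exceedance_targets >= 0 & exceedance_targets <= 1))
    if (length(exceedance_targets) > 1L) {
      warning("only the first exceedance target is used for rescaling",
              call. = FALSE)
    }
    target_nutrient <- names(exceedance_targets)[1L]
    target_frac <- exceedance_targets[[1L]]
  }
  with_seed(seed, {
    achieve <- if (!is.null(target_nutrient)) {
      sample(rep(c(TRUE, FALSE),
                 c(round(target_frac * n_subjects),
                   n_subjects - round(target_frac * n_subjects))))
    } else rep(NA, n_subjects)
    rec_list <- vector("list", n_subjects)
    n_unscalable <- 0L
    for (s in seq_len(n_subjects)) {
      base <- list()
      for (cat in unique(db$category)) {
        ids <- db$item_id[db$category == cat]
        b <- gb[gb$category == cat, ]
        total <- stats::runif(1, b$lower, b$upper)
        k <- sample(seq_len(min(3L, length(ids))), 1L)
        chosen <- sample(ids, k)
        share <- stats::runif(k); share <- share / sum(share)
        base[chosen] <- as.list(total * share)
      }
      base <- unlist(base)
      day_mult <- matrix(stats::rlnorm(length(base) * n_days, 0, 0.2),
                         n_days, length(base))
      if (!is.null(target_nutrient)) {
        # subject's mean daily intake of the target nutrient
        mean_mult <- colMeans(day_mult)
        per_serving <- db[[target_nutrient]][match(names(base), db$item_id)]
        cur <- sum(per_serving * base * mean_mult)
        bound <- rni$lower[rni$nutrient == target_nutrient]
        want <- if (achieve[s]) bound * stats::runif(1, 1.05, 1.6)
                else bound * stats::runif(1, 0.40, 0.95)
        if (cur <= 0) {
          n_unscalable <- n_unscalable + 1L
        } else {
          day_mult <- day_mult * (want / cur)
        }
      }
      rec_list[[s]] <- do.call(rbind, lapply(seq_len(n_days), function(d) {
        data.frame(subject_id = sprintf("S%04d", s), day_index = d,
                   item_id = names(base),
                   servings = base * day_mult[d, ],
                   stringsAsFactors = FALSE)
      }))
    }
    if (n_unscalable > 0L) {
      warning(sprintf(paste0("%d subject(s) had no %s in their basket and ",
                             "could not be rescaled toward the exceedance ",
                             "target"), n_unscalable, target_nutrient),
              call. = FALSE)
    }
    records <- do.call(rbind, rec_list)
    rownames(records) <- NULL

    rtrunc_norm <- function(n, mean, sd, lo, hi) {
      x <- stats::rnorm(n, mean, sd)
      while (any(bad <- x < lo | x >= hi)) {
        x[bad] <- stats::rnorm(sum(bad), mean, sd)
      }
      x
    }
    grp <- sample(1:3, n_subjects, replace = TRUE,
                  prob = c(0.705, 0.218, 0.077))
    hb <- numeric(n_subjects)
    hb[grp == 1] <- rtrunc_norm(sum(grp == 1), 11.8, 0.6, 11, 16)
    hb[grp == 2] <- rtrunc_norm(sum(grp == 2), 10.5, 0.28, 10, 11)
    hb[grp == 3] <- rtrunc_norm(sum(grp == 3), 9.2, 0.55, 8, 10)
    covariates <- data.frame(
      subject_id = sprintf("S%04d", seq_len(n_subjects)),
      hb = round(hb, 1),
      bmi = round(stats::rlnorm(n_subjects, log(23.8), 0.17), 1),
      gravidity = sample(1:7, n_subjects, replace = TRUE,
                         prob = c(17, 19, 20, 10, 7, 4, 1) / 78),
      trimester = sample(1:3, n_subjects, replace = TRUE,
                         prob = c(0.25, 0.52, 0.23)),
      supplement_user = stats::rbinom(n_subjects, 1, 0.859) == 1,
      stringsAsFactors = FALSE
    )
    list(records = records, covariates = covariates)
  })
}

#' Generate a random small optimization instance
#'
#' Builds a small synthetic food database and a diet problem whose bounds
#' are randomized around an attainable reference diet, yielding a mix of
#' feasible and (occasionally) infeasible instances. Sized for exhaustive
#' enumeration, these instances drive the solver-versus-oracle checks.
#'
#' @param seed Integer seed.
#' @param n_items Number of items (default drawn in 3..8).
#' @param max_units Per-item cap in portion-count units (default 4 half-
#'   servings, i.e. 2 servings).
#' @return A `diet_problem`.
#' @export
generate_random_instance <- function(seed, n_items = NULL, max_units = 4) {
  with_seed(seed, {
    if (is.null(n_items)) n_items <- sample(3:8, 1L)
    cats <- sample(FOOD_CATEGORIES[1:7], n_items, replace = TRUE)
    counts <- table(cats)
    n_by_cat <- stats::setNames(integer(length(FOOD_CATEGORIES)),
                                FOOD_CATEGORIES)
    n_by_cat[names(counts)] <- as.integer(counts)
    db <- generate_food_db(list(n_items = n_by_cat),
                           seed = sample.int(2^30, 1L))
    g <- 0.5
    z <- sample(0:max_units, nrow(db), replace = TRUE) * g
    tot <- evaluate_servings(stats::setNames(z, db$item_id), db)$profile
    n_constrained <- sample(4:8, 1L)
    constrained <- sample(NUTRIENTS, n_constrained)
    nb <- data.frame(nutrient = NUTRIENTS, lower = 0, upper = Inf,
                     stringsAsFactors = FALSE)
    for (nt in constrained) {
      i <- match(nt, nb$nutrient)
      t_i <- tot[[nt]]
      if (t_i <= 0) next
      nb$lower[i] <- t_i * stats::runif(1, 0.5, 1.05)
      if (stats::runif(1) < 0.6) nb$upper[i] <- t_i * stats::runif(1, 1.1, 2)
    }
    # occasionally demand more of one nutrient than plausible, to exercise
    # the infeasible path
    if (stats::runif(1) < 0.25) {
      i <- match(sample(constrained, 1L), nb$nutrient)
      nb$lower[i] <- nb$lower[i] * stats::runif(1, 1.5, 4)
      nb$upper[i] <- max(nb$upper[i], nb$lower[i] * 1.2)
    }
    gbov <- stats::setNames(
      lapply(FOOD_CATEGORIES, function(cat) list(lower = 0, upper = Inf)),
      FOOD_CATEGORIES)
    present <- unique(db$category)
    for (cat in present) {
      if (stats::runif(1) < 0.3) {
        gs <- sum(z[db$category == cat])
        gbov[[cat]] <- list(lower = min(gs, floor(gs * stats::runif(1, 0.3, 1) / g) * g),
                            upper = gs + sample(0:2, 1L) * g)
      }
    }
    build_problem(db, trimester = 2,
                  overrides = list(nutrient_bounds = nb, group_bounds = gbov,
                                   item_caps = list(default = max_units * g),
                                   granularity = g))
  })
}

#' Generate an optimization instance with known optimum
#'
#' Two constructions. `"pinned"`: a serving vector `s*` is drawn, every
#' nutrient bound and group bound is set to exactly the value `s*` achieves
#' (lower = upper) and item caps equal `s*`, making `s*` the unique feasible
#' — hence optimal — point. `"oracle"`: a random small instance is solved by
#' exhaustive enumeration ([brute_force_diet()]) and returned with that
#' certified solution; instances are redrawn until a feasible one appears.
#'
#' @param seed Integer seed.
#' @param construction `"pinned"` or `"oracle"`.
#' @return List with `problem` (a `diet_problem`) and `solution` (its
#'   provably optimal `diet_solution`).
#' @export
generate_known_optimum_instance <- function(seed,
                                            construction = c("pinned",
                                                             "oracle")) {
  construction <- match.arg(construction)
  if (construction == "oracle") {
    for (off in 0:50) {
      problem <- generate_random_instance(seed + off * 1009L)
      sol <- brute_force_diet(problem)
      if (sol$status == "optimal") {
        return(list(problem = problem, solution = sol))
      }
    }
    stop("no feasible oracle instance found near this seed", call. = FALSE)
  }
  with_seed(seed, {
    n_items <- sample(4:8, 1L)
    cats <- sample(FOOD_CATEGORIES[1:7], n_items, replace = TRUE)
    counts <- table(cats)
    n_by_cat <- stats::setNames(integer(length(FOOD_CATEGORIES)),
                                FOOD_CATEGORIES)
    n_by_cat[names(counts)] <- as.integer(counts)
    db <- generate_food_db(list(n_items = n_by_cat),
                           seed = sample.int(2^30, 1L))
    g <- 0.5
    k_star <- sample(0:4, nrow(db), replace = TRUE)
    if (all(k_star == 0)) k_star[1L] <- 1L
    s_star <- stats::setNames(k_star * g, db$item_id)
    tot <- evaluate_servings(s_star, db)$profile
    nb <- data.frame(nutrient = NUTRIENTS, lower = as.numeric(tot),
                     upper = as.numeric(tot), stringsAsFactors = FALSE)
    gbov <- stats::setNames(
      lapply(FOOD_CATEGORIES, function(cat) {
        if (cat %in% db$category) {
          gs <- sum(s_star[db$category == cat])
          list(lower = gs, upper = gs)
        } else list(lower = 0, upper = Inf)
      }), FOOD_CATEGORIES)
    caps <- stats::setNames(as.list(s_star), db$item_id)
    problem <- build_problem(db, trimester = 2,
                             overrides = list(nutrient_bounds = nb,
                                              group_bounds = gbov,
                                              item_caps = list(by_item = caps),
                                              granularity = g))
    list(problem = problem, solution = make_solution(k_star, problem))
  })
}
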