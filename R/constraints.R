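#' Per-trimester nutrient intake bounds (RNI 2017)
#'
#' Returns the packaged lower/upper daily-intake bounds for the 15-nutrient
#' panel for one pregnancy trimester, as used to constrain the diet program.
#' Vitamin B1, vitamin B2 and potassium have no upper recommendation and are
#' unbounded above (`Inf`).
#'
#' @param trimester 1, 2 or 3.
#' @return Data frame with columns `nutrient`, `lower`, `upper` (15 rows, in
#'   [NUTRIENTS] order); `upper` is `Inf` where no upper bound exists.
#' @export
rni_bounds <- function(trimester) {
  trimester <- check_trimester(trimester)
  tab <- utils::read.csv(system.file("extdata", "rni_2017.csv",
                                     package = "dietopt"),
                         stringsAsFactors = FALSE)
  tab <- tab[tab$trimester == trimester, c("nutrient", "lower", "upper")]
  tab$upper[is.na(tab$upper)] <- Inf
  tab <- tab[match(NUTRIENTS, tab$nutrient), ]
  rownames(tab) <- NULL
  tab
}

#' Food-group serving bounds (MDG 2010 + palatability)
#'
#' Daily serving bounds for the seven MDG food groups plus the three
#' palatability items (sugar, salt, oil).
#'
#' @return Data frame with columns `category`, `lower`, `upper` (10 rows, in
#'   [FOOD_CATEGORIES] order).
#' @export
mdg_group_bounds <- function() {
  tab <- utils::read.csv(system.file("extdata", "mdg_2010.csv",
                                     package = "dietopt"),
                         stringsAsFactors = FALSE, check.names = FALSE)
  tab <- tab[match(FOOD_CATEGORIES, tab$category), ]
  rownames(tab) <- NULL
  tab
}

check_trimester <- function(trimester) {
  trimester <- as.integer(trimester)
  if (length(trimester) != 1L || is.na(trimester) || !trimester %in% 1:3) {
    stop("trimester must be 1, 2 or 3", call. = FALSE)
  }
  trimester
}

#' Supplement scenarios
#'
#' A supplement scenario is a named bundle of exogenous daily nutrient
#' amounts. Applying it relaxes the dietary lower bounds (a nutrient already
#' supplied in tablet form need not come from food) while leaving upper
#' bounds on food intake untouched.
#'
#' @param name Scenario label.
#' @param ... Named nutrient amounts (see [nutrient_profile()]), or a single
#'   `nutrient_profile`.
#' @return An object of class `supplement_scenario`.
#' @examples
#' supplement_scenario("iron only", iron_mg = 100)
#' @export
supplement_scenario <- function(name, ...) {
  structure(list(name = as.character(name)[1L],
                 provided = nutrient_profile(...)),
            class = "supplement_scenario")
}

#' @export
print.supplement_scenario <- function(x, ...) {
  cat("<supplement_scenario>", x$name, "\n")
  print(x$provided)
  invisible(x)
}

#' Packaged default supplement scenario per trimester
#'
#' Trimester 1: folic acid only — folate is outside the tracked panel, so
#' the scenario is a zero vector and changes nothing. Trimesters 2 and 3:
#' the antenatal bundle of 100 mg/day elemental iron (the national
#' recommendation for pregnancy) plus vitamin C 100 mg and a B complex
#' (B1 5 mg, B2 5 mg, B3 20 mg); the non-iron doses are configurable
#' defaults, as published tablet compositions vary.
#'
#' @param trimester 1, 2 or 3.
#' @return A [supplement_scenario()].
#' @export
default_supplement_scenario <- function(trimester) {
  trimester <- check_trimester(trimester)
  if (trimester == 1L) {
    supplement_scenario("folic acid only")
  } else {
    supplement_scenario(
      "iron + vitamin C + B complex",
      iron_mg = 100, vitC_mg = 100, vitB1_mg = 5, vitB2_mg = 5, vitB3_mg = 20
    )
  }
}

#' Relax nutrient lower bounds by supplement amounts
#'
#' For each nutrient the new dietary lower bound is
#' `max(0, lower - provided)`; upper bounds are unchanged, since they cap
#' food intake and the supplement is exogenous. The operation is monotone:
#' more supplementation never raises a lower bound.
#'
#' @param nc Nutrient bounds as returned by [rni_bounds()].
#' @param scenario A [supplement_scenario()].
#' @return Adjusted bounds, same shape as `nc`.
#' @export
apply_supplement <- function(nc, scenario) {
  stopifnot(inherits(scenario, "supplement_scenario"),
            inherits(scenario$provided, "nutrient_profile"))
  stopifnot(all(c("nutrient", "lower", "upper") %in% names(nc)))
  nc$lower <- pmax(0, nc$lower - as.numeric(scenario$provided[nc$nutrient]))
  nc
}

#' Build a solvable diet problem
#'
#' Combines a food database with the packaged per-trimester nutrient bounds,
#' food-group serving bounds, per-item serving caps and the portion
#' granularity into one internally consistent problem specification for
#' [optimize_diet()]. Decision variables are integer counts of
#' `granularity`-sized portions, so with the default granularity of 0.5 a
#' food can enter the diet in half-serving steps.
#'
#' Default caps: 2 servings/day per item, except fish items capped at
#' 1 serving/day so that no single fish dish repeats across the day's meals.
#' All caps are overridable per category or per item.
#'
#' @param db A [food_db()].
#' @param trimester 1, 2 or 3.
#' @param overrides Optional named list replacing pieces of the default
#'   configuration: `nutrient_bounds` (data frame or named list of
#'   `list(lower=, upper=)`), `group_bounds` (likewise, keyed by category),
#'   `item_caps` (list with any of `default`, `by_category` (named numeric),
#'   `by_item` (named numeric)), `granularity` (positive number), and
#'   `supplement` (a [supplement_scenario()] applied to the nutrient lower
#'   bounds).
#' @return An object of class `diet_problem` with elements `db`,
#'   `trimester`, `nutrient_bounds`, `group_bounds`, `item_caps` (named
#'   numeric, one per item, servings), `granularity`.
#' @export
build_problem <- function(db, trimester, overrides = list()) {
  stopifnot(inherits(db, "food_db"))
  if (nrow(db) == 0L) stop("food database is empty", call. = FALSE)
  trimester <- check_trimester(trimester)
  stopifnot(is.list(overrides))
  unknown <- setdiff(names(overrides),
                     c("nutrient_bounds", "group_bounds", "item_caps",
                       "granularity", "supplement"))
  if (length(unknown)) {
    stop("unknown override(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }

  nb <- merge_bounds(rni_bounds(trimester), overrides$nutrient_bounds,
                     key = "nutrient", universe = NUTRIENTS)
  gb <- merge_bounds(mdg_group_bounds(), overrides$group_bounds,
                     key = "category", universe = FOOD_CATEGORIES)
  if (!is.null(overrides$supplement)) {
    nb <- apply_supplement(nb, overrides$supplement)
  }

  granularity <- overrides$granularity %||% 0.5
  granularity <- as.numeric(granularity)[1L]
  if (!is.finite(granularity) || granularity <= 0) {
    stop("granularity must be a positive number", call. = FALSE)
  }

  caps <- resolve_item_caps(db, overrides$item_caps, granularity)

  bad <- which(nb$lower > nb$upper)
  if (length(bad)) {
    stop("inconsistent nutrient bound (lower > upper): ",
         paste(nb$nutrient[bad], collapse = ", "), call. = FALSE)
  }
  bad <- which(gb$lower > gb$upper)
  if (length(bad)) {
    stop("inconsistent group bound (lower > upper): ",
         paste(gb$category[bad], collapse = ", "), call. = FALSE)
  }

  structure(list(db = db, trimester = trimester, nutrient_bounds = nb,
                 group_bounds = gb, item_caps = caps,
                 granularity = granularity),
            class = "diet_problem")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

merge_bounds <- function(base, override, key, universe) {
  if (is.null(override)) return(base)
  if (is.data.frame(override)) {
    rows <- seq_len(nrow(override))
    override <- stats::setNames(
      lapply(rows, function(i) list(lower = override$lower[i],
                                    upper = override$upper[i])),
      override[[key]])
  }
  bad <- setdiff(names(override), universe)
  if (length(bad)) {
    stop("unknown ", key, " in override: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  for (nm in names(override)) {
    i <- match(nm, base[[key]])
    ov <- override[[nm]]
    if (!is.null(ov$lower)) base$lower[i] <- as.numeric(ov$lower)
    if (!is.null(ov$upper)) {
      up <- ov$upper
      base$upper[i] <- if (is.null(up) || is.na(up)) Inf else as.numeric(up)
    }
  }
  if (any(base$lower < 0)) stop("bounds must be nonnegative", call. = FALSE)
  base
}

resolve_item_caps <- function(db, item_caps, granularity) {
  default_cap <- 2
  by_category <- c("fish" = 1)
  by_item <- numeric(0)
  if (!is.null(item_caps)) {
    stopifnot(is.list(item_caps))
    if (!is.null(item_caps$default)) default_cap <- item_caps$default
    if (!is.null(item_caps$by_category)) {
      bc <- unlist(item_caps$by_category)
      bad <- setdiff(names(bc), FOOD_CATEGORIES)
      if (length(bad)) {
        stop("unknown category in item_caps: ", paste(bad, collapse = ", "),
             call. = FALSE)
      }
      by_category[names(bc)] <- bc
    }
    if (!is.null(item_caps$by_item)) {
      bi <- unlist(item_caps$by_item)
      bad <- setdiff(names(bi), db$item_id)
      if (length(bad)) {
        stop("unknown item_id in item_caps: ", paste(bad, collapse = ", "),
             call. = FALSE)
      }
      by_item <- bi
    }
  }
  caps <- rep(as.numeric(default_cap), nrow(db))
  hit <- db$category %in% names(by_category)
  caps[hit] <- as.numeric(by_category[db$category[hit]])
  hit <- db$item_id %in% names(by_item)
  caps[hit] <- as.numeric(by_item[db$item_id[hit]])
  if (any(caps < 0)) stop("item caps must be nonnegative", call. = FALSE)
  # caps are realized as integer portion counts; round down to the grid
  caps <- floor(caps / granularity + 1e-9) * granularity
  stats::setNames(caps, db$item_id)
}

#' @export
print.diet_problem <- function(x, ...) {
  cat(sprintf("<diet_problem> trimester %d, %d items, granularity %g serving\n",
              x$trimester, nrow(x$db), x$granularity))
  cat(sprintf("  energy bound [%g, %g] kcal; iron [%g, %g] mg\n",
              x$nutrient_bounds$lower[1], x$nutrient_bounds$upper[1],
              x$nutrient_bounds$lower[14], x$nutrient_bounds$upper[14]))
  invisible(x)
}

#' Read a constraint configuration file
#'
#' Reads a YAML (or JSON) configuration with any of the keys `trimester`,
#' `granularity`, `nutrient_bounds`, `group_bounds`, `item_caps`,
#' `supplement` and returns a list suitable as the `overrides` argument of
#' [build_problem()] plus the trimester, if given. A `supplement` entry is a
#' named mapping of nutrient code to daily amount.
#'
#' @param path Path to a YAML/JSON file.
#' @return List with elements `trimester` (or `NULL`) and `overrides`.
#' @export
read_constraint_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("malformed config file", call. = FALSE)
  overrides <- cfg[intersect(names(cfg),
                             c("nutrient_bounds", "group_bounds",
                               "item_caps", "granularity"))]
  if (!is.null(cfg$supplement)) {
    overrides$supplement <- supplement_scenario(
      cfg$supplement_name %||% "configured supplement",
      nutrient_profile(cfg$supplement))
  }
  list(trimester = cfg$trimester, overrides = overrides)
}
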