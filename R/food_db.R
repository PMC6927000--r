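#' Food databases
#'
#' A food database holds one row per candidate food item: identifier, name,
#' category, price per serving, optional serving note, and the per-serving
#' amounts of the 15 tracked nutrients. Row order is significant — it defines
#' the tie-breaking order used by the optimizer.
#'
#' @param items A data frame with columns `item_id`, `name`, `category`,
#'   `price`, `serving_note` and the 15 nutrient columns named as in
#'   [NUTRIENTS]. Missing nutrient columns are added as zero.
#' @return The validated data frame with class `food_db`.
#' @export
food_db <- function(items) {
  items <- as.data.frame(items, stringsAsFactors = FALSE)
  for (col in c("item_id", "name", "category")) {
    if (is.null(items[[col]])) stop("missing column: ", col, call. = FALSE)
    items[[col]] <- as.character(items[[col]])
  }
  if (is.null(items$price)) stop("missing column: price", call. = FALSE)
  if (is.null(items$serving_note)) items$serving_note <- ""
  for (col in NUTRIENTS) {
    if (is.null(items[[col]])) items[[col]] <- 0
    items[[col]] <- as.numeric(items[[col]])
  }
  items <- items[, c("item_id", "name", "category", "price", "serving_note",
                     NUTRIENTS)]
  validate_food_db(items)
  rownames(items) <- NULL
  class(items) <- c("food_db", "data.frame")
  items
}

validate_food_db <- function(items) {
  dup <- items$item_id[duplicated(items$item_id)]
  if (length(dup)) {
    stop("duplicate item_id: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  bad_cat <- setdiff(unique(items$category), FOOD_CATEGORIES)
  if (length(bad_cat)) {
    stop("unknown category: ", paste(bad_cat, collapse = ", "),
         call. = FALSE)
  }
  for (col in c("price", NUTRIENTS)) {
    v <- items[[col]]
    if (any(!is.finite(v))) {
      stop("non-numeric value in column '", col, "' at row ",
           which(!is.finite(v))[1L], call. = FALSE)
    }
    if (any(v < 0)) {
      stop("negative value in column '", col, "' at row ",
           which(v < 0)[1L], " (item ", items$item_id[which(v < 0)[1L]], ")",
           call. = FALSE)
    }
  }
  invisible(items)
}

#' @export
print.food_db <- function(x, ...) {
  cat(sprintf("<food_db> %d items over %d categories\n",
              nrow(x), length(unique(x$category))))
  print(as.data.frame(table(category = x$category)), row.names = FALSE)
  invisible(x)
}

#' Read a food database from CSV
#'
#' The CSV schema is `item_id,name,category,price,serving_note` followed by
#' the 15 nutrient columns (see [NUTRIENTS]). Blank nutrient cells are read
#' as 0 with a warning, since food-composition tables are routinely sparse;
#' negative amounts, duplicate ids and unknown categories are hard errors.
#'
#' @param path Path to a CSV file.
#' @return A [food_db()] preserving file row order.
#' @export
read_food_db <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  need <- c("item_id", "name", "category", "price", "serving_note", NUTRIENTS)
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stop("food database CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  n_blank <- 0L
  for (col in c("price", NUTRIENTS)) {
    v <- trimws(raw[[col]])
    blank <- v == "" | is.na(v)
    if (any(blank) && col != "price") {
      n_blank <- n_blank + sum(blank)
      v[blank] <- "0"
    }
    num <- suppressWarnings(as.numeric(v))
    if (any(is.na(num))) {
      i <- which(is.na(num))[1L]
      stop("cannot parse column '", col, "' at row ", i,
           " (value '", raw[[col]][i], "')", call. = FALSE)
    }
    raw[[col]] <- num
  }
  if (n_blank > 0L) {
    warning(n_blank, " blank nutrient cell(s) read as 0", call. = FALSE)
  }
  food_db(raw)
}

#' Write a food database to CSV
#'
#' `read_food_db()` applied to the written file reproduces the database
#' exactly (values and row order).
#'
#' @param db A [food_db()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_food_db <- function(db, path) {
  stopifnot(inherits(db, "food_db"))
  utils::write.csv(as.data.frame(db), path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Nutrient totals and cost of a serving vector
#'
#' Linear accounting at the heart of every other computation: totals are
#' `sum_j servings_j * profile_j` and cost is `sum_j servings_j * price_j`.
#' Additive and homogeneous in the serving vector by construction.
#'
#' @param servings Named numeric vector of nonnegative servings, names are
#'   `item_id`s present in `db`. Items omitted count as zero.
#' @param db A [food_db()].
#' @return List with `profile` (a [nutrient_profile()]) and `cost`.
#' @examples
#' db <- food_db(data.frame(
#'   item_id = c("rice", "fish"), name = c("Rice", "Fish"),
#'   category = c("cereals and grains", "fish"), price = c(0.4, 1.2),
#'   energy_kcal = c(140, 90), carb_g = c(30, 0), protein_g = c(2.5, 14)))
#' evaluate_servings(c(rice = 2, fish = 1), db)
#' @export
evaluate_servings <- function(servings, db) {
  stopifnot(inherits(db, "food_db"))
  servings <- servings[servings != 0]
  if (length(servings)) {
    if (is.null(names(servings)) || any(names(servings) == "")) {
      stop("servings must be named by item_id", call. = FALSE)
    }
    unknown <- setdiff(names(servings), db$item_id)
    if (length(unknown)) {
      stop("unknown item_id: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    if (any(servings < 0)) stop("servings must be nonnegative", call. = FALSE)
  }
  x <- stats::setNames(numeric(nrow(db)), db$item_id)
  x[names(servings)] <- servings
  amat <- as.matrix(as.data.frame(db)[, NUTRIENTS, drop = FALSE])
  profile <- nutrient_profile(stats::setNames(as.numeric(crossprod(amat, x)),
                                              NUTRIENTS))
  list(profile = profile, cost = sum(db$price * x))
}

# per-serving nutrient matrix (items x nutrients), used by the solver
nutrient_matrix <- function(db) {
  m <- as.matrix(as.data.frame(db)[, NUTRIENTS, drop = FALSE])
  rownames(m) <- db$item_id
  m
}
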