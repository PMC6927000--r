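#' Meal slots of a day menu
#'
#' The five meal slots used when arranging an optimized serving vector into
#' a day's eating occasions, in day order.
#'
#' @format Character vector of 5 slot codes.
#' @export
MEAL_SLOTS <- c("breakfast", "morning_tea", "lunch", "afternoon_tea", "dinner")

MAIN_SLOTS <- c("breakfast", "lunch", "dinner")
TEA_SLOTS <- c("morning_tea", "afternoon_tea")
STAPLE_CATEGORIES <- c("cereals and grains", "meat/poultry", "fish",
                       "vegetables", "legumes", "oil", "salt")

#' Arrange an optimal serving vector into a day menu
#'
#' Deterministic greedy allocation over the five meal slots: items from the
#' staple categories (cereals, meat/poultry, fish, vegetables, legumes, oil,
#' salt) rotate over the main meals (breakfast, lunch, dinner); fruits, milk
#' and sugar rotate over the remaining tea slots. An item appears at most
#' once per slot, carrying at most `per_slot_max` servings per appearance,
#' so no dish repeats within a meal; the slot allocations sum exactly to the
#' input serving vector.
#'
#' @param solution An optimal `diet_solution`.
#' @param db The [food_db()] it was solved over.
#' @param rules List of slotting rules; currently `per_slot_max` (servings
#'   of one item allowed in one slot, default 2).
#' @return Object of class `day_menu`: `slots` (named list of data frames
#'   `item_id`, `name`, `servings`), `totals` (nutrient profile) and `cost`.
#' @export
assemble_menu <- function(solution, db, rules = list()) {
  stopifnot(inherits(solution, "diet_solution"), inherits(db, "food_db"))
  if (solution$status != "optimal") {
    stop("assemble_menu requires an optimal solution", call. = FALSE)
  }
  per_slot_max <- rules$per_slot_max %||% 2
  slots <- stats::setNames(
    lapply(MEAL_SLOTS, function(s) {
      data.frame(item_id = character(0), name = character(0),
                 servings = numeric(0), stringsAsFactors = FALSE)
    }), MEAL_SLOTS)
  picked <- solution$servings[solution$servings > 0]
  cursor <- c(main = 0L, tea = 0L)
  for (id in names(picked)) {            # db order: picked follows db order
    row <- db[db$item_id == id, ]
    eligible <- if (row$category %in% STAPLE_CATEGORIES) MAIN_SLOTS else TEA_SLOTS
    which_cursor <- if (row$category %in% STAPLE_CATEGORIES) "main" else "tea"
    remaining <- picked[[id]]
    if (remaining > length(eligible) * per_slot_max + 1e-9) {
      stop(sprintf(paste0("item '%s' has %g servings but at most %g fit the ",
                          "day (%d slots x %g per slot); lower its cap or ",
                          "raise per_slot_max"),
                   id, remaining, length(eligible) * per_slot_max,
                   length(eligible), per_slot_max), call. = FALSE)
    }
    while (remaining > 1e-9) {
      slot <- eligible[cursor[[which_cursor]] %% length(eligible) + 1L]
      cursor[[which_cursor]] <- cursor[[which_cursor]] + 1L
      take <- min(remaining, per_slot_max)
      slots[[slot]] <- rbind(slots[[slot]],
                             data.frame(item_id = id, name = row$name,
                                        servings = take,
                                        stringsAsFactors = FALSE))
      remaining <- remaining - take
    }
  }
  structure(list(slots = slots, totals = solution$achieved,
                 cost = solution$total_cost),
            class = "day_menu")
}

#' Render a day menu as text
#'
#' Slot-by-slot listing with servings, the day's nutrient totals and a
#' "Food Cost Per Day" line.
#'
#' @param menu A [assemble_menu()] result.
#' @param format `"text"` (default) or `"markdown"`.
#' @return A character vector of lines, invisibly printable via `cat`.
#' @export
render_menu <- function(menu, format = c("text", "markdown")) {
  stopifnot(inherits(menu, "day_menu"))
  format <- match.arg(format)
  h <- function(x) if (format == "markdown") paste0("## ", x) else toupper(x)
  b <- function(x) if (format == "markdown") paste0("- ", x) else paste0("  ", x)
  lines <- if (format == "markdown") "# Day menu" else "DAY MENU"
  slot_label <- c(breakfast = "Breakfast", morning_tea = "Morning tea",
                  lunch = "Lunch", afternoon_tea = "Afternoon tea",
                  dinner = "Dinner")
  for (s in MEAL_SLOTS) {
    lines <- c(lines, h(slot_label[[s]]))
    tab <- menu$slots[[s]]
    if (nrow(tab) == 0L) {
      lines <- c(lines, b("(empty)"))
    } else {
      lines <- c(lines, b(sprintf("%s (%s): %g serving%s", tab$name,
                                  tab$item_id, tab$servings,
                                  ifelse(tab$servings == 1, "", "s"))))
    }
  }
  lines <- c(lines, h("Daily totals"))
  nz <- menu$totals
  lines <- c(lines, b(sprintf("%s: %s", NUTRIENT_LABELS[NUTRIENTS],
                              formatC(as.numeric(nz), format = "g",
                                      digits = 6))))
  lines <- c(lines, sprintf("Food Cost Per Day: %.2f", menu$cost))
  lines
}

#' @export
print.day_menu <- function(x, ...) {
  cat(render_menu(x), sep = "\n")
  invisible(x)
}
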