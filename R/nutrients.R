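#' The tracked nutrient panel
#'
#' The package accounts for a fixed, closed panel of 15 dietary quantities:
#' energy plus 14 nutrients, each with one canonical unit. Folic acid,
#' vitamin D and individual fatty acids are deliberately outside the panel.
#'
#' @format A character vector of 15 nutrient codes. Each code embeds its
#'   canonical unit (e.g. `"iron_mg"`, `"vitA_RE"`, `"energy_kcal"`).
#' @export
NUTRIENTS <- c(
  "energy_kcal", "protein_g", "carb_g", "fat_g", "fibre_g",
  "vitA_RE", "vitC_mg", "vitB1_mg", "vitB2_mg", "vitB3_mg",
  "sodium_mg", "potassium_mg", "calcium_mg", "iron_mg", "phosphorus_mg"
)

#' Human-readable labels and units for the nutrient panel
#'
#' @format Named character vector mapping nutrient code to display label.
#' @export
NUTRIENT_LABELS <- c(
  energy_kcal = "Energy (kcal)", protein_g = "Protein (g)",
  carb_g = "Carbohydrate (g)", fat_g = "Fat (g)", fibre_g = "Fibre (g)",
  vitA_RE = "Vitamin A (RE)", vitC_mg = "Vitamin C (mg)",
  vitB1_mg = "Vitamin B1 (mg)", vitB2_mg = "Vitamin B2 (mg)",
  vitB3_mg = "Vitamin B3 (mg)", sodium_mg = "Sodium (mg)",
  potassium_mg = "Potassium (mg)", calcium_mg = "Calcium (mg)",
  iron_mg = "Iron (mg)", phosphorus_mg = "Phosphorus (mg)"
)

#' Food categories
#'
#' Ten closed categories: the seven MDG 2010 food groups followed by the
#' three palatability items (sugar, salt, oil) that keep an optimized diet
#' acceptable to eat.
#'
#' @format Character vector of 10 category codes.
#' @export
FOOD_CATEGORIES <- c(
  "cereals and grains", "fruits", "vegetables", "meat/poultry", "fish",
  "legumes", "milk and dairy products", "sugar", "salt", "oil"
)

#' The seven MDG food groups (excludes the palatability items)
#' @format Character vector of 7 category codes.
#' @export
MDG_GROUPS <- FOOD_CATEGORIES[1:7]

#' Construct a nutrient profile
#'
#' A nutrient profile is a named numeric vector over the full [NUTRIENTS]
#' panel; quantities not supplied are zero. Profiles add componentwise and
#' scale by nonnegative scalars, mirroring the linearity of per-serving
#' nutrient accounting.
#'
#' @param ... Named nutrient amounts, e.g. `iron_mg = 100`. Alternatively a
#'   single named numeric vector or list.
#' @return Named numeric vector of length 15, class `nutrient_profile`.
#' @examples
#' nutrient_profile(iron_mg = 100, vitC_mg = 100)
#' @export
nutrient_profile <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.null(names(args)) &&
      (is.numeric(args[[1L]]) || is.list(args[[1L]]))) {
    args <- as.list(args[[1L]])
  }
  amounts <- stats::setNames(numeric(length(NUTRIENTS)), NUTRIENTS)
  if (length(args)) {
    nm <- names(args)
    if (is.null(nm) || any(nm == "")) {
      stop("all nutrient amounts must be named", call. = FALSE)
    }
    bad <- setdiff(nm, NUTRIENTS)
    if (length(bad)) {
      stop("unknown nutrient code(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    vals <- vapply(args, function(v) as.numeric(v)[1L], numeric(1))
    if (any(!is.finite(vals)) || any(vals < 0)) {
      stop("nutrient amounts must be finite and nonnegative", call. = FALSE)
    }
    amounts[nm] <- vals
  }
  structure(amounts, class = "nutrient_profile")
}

#' @export
print.nutrient_profile <- function(x, ...) {
  cat("<nutrient_profile>\n")
  nz <- x[x != 0]
  if (!length(nz)) {
    cat("  (all zero)\n")
  } else {
    for (nm in names(nz)) {
      cat(sprintf("  %-18s %g\n", NUTRIENT_LABELS[[nm]], nz[[nm]]))
    }
  }
  invisible(x)
}

#' @export
Ops.nutrient_profile <- function(e1, e2) {
  out <- NextMethod()
  if (.Generic %in% c("+", "-", "*", "/")) {
    out <- structure(stats::setNames(as.numeric(out), NUTRIENTS),
                     class = "nutrient_profile")
  }
  out
}

as_profile <- function(x) {
  if (inherits(x, "nutrient_profile")) return(x)
  nutrient_profile(x)
}

# round half away from zero (tables use half-up, base round() is banker's)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
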