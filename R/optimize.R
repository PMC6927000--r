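# -- internal ILP machinery ---------------------------------------------------

# Matrix form of a diet_problem in portion-count space: decision variables are
# integer counts k_j with servings x_j = granularity * k_j. Rows are the
# nutrient bounds followed by the food-group serving bounds; rows that are
# vacuous (lower <= 0 and upper infinite) are dropped from the solver but kept
# in the bookkeeping used by diagnostics.
milp_data <- function(problem) {
  db <- problem$db
  g <- problem$granularity
  n <- nrow(db)
  amat <- t(nutrient_matrix(db)) * g              # 15 x n, per portion count
  gmat <- matrix(0, length(FOOD_CATEGORIES), n,
                 dimnames = list(FOOD_CATEGORIES, db$item_id))
  for (i in seq_along(FOOD_CATEGORIES)) {
    gmat[i, db$category == FOOD_CATEGORIES[i]] <- g
  }
  A <- rbind(amat, gmat)
  rl <- c(problem$nutrient_bounds$lower, problem$group_bounds$lower)
  ru <- c(problem$nutrient_bounds$upper, problem$group_bounds$upper)
  rownames(A) <- c(paste0("nutrient:", NUTRIENTS),
                   paste0("group:", FOOD_CATEGORIES))
  keep <- rl > 0 | is.finite(ru)
  # scale kept rows to unit magnitude for the LP's benefit
  A_s <- A[keep, , drop = FALSE]
  sc <- apply(abs(A_s), 1L, max)
  sc[sc == 0 | !is.finite(sc)] <- 1
  list(cost = db$price * g,
       A = A, rl = rl, ru = ru, keep = keep,
       A_s = A_s / sc, rl_s = rl[keep] / sc, ru_s = ru[keep] / sc,
       Kmax = as.integer(round(problem$item_caps / g)),
       granularity = g, item_id = db$item_id)
}

# Shared integer-candidate feasibility check (same path for branch-and-bound
# and the brute-force oracle), in original constraint units.
check_feasible_k <- function(k, md, tol = 1e-7) {
  v <- as.numeric(md$A %*% k)
  tl <- tol * pmax(1, abs(md$rl))
  tu <- tol * pmax(1, abs(md$ru))
  tu[!is.finite(tu)] <- 0
  all(v >= md$rl - tl | !is.finite(md$rl)) &&
    all(v <= md$ru + tu | !is.finite(md$ru))
}

# Exact branch-and-bound over the LP relaxation. `obj` defaults to the cost
# vector; the lexicographic refinement passes unit objectives plus a cost-cap
# row through `extra`. Returns list(status, k, obj).
solve_milp <- function(md, lb = NULL, ub = NULL, obj = md$cost,
                       extra = NULL, incumbent_k = NULL,
                       int_tol = 1e-6, cost_tol = 1e-9, node_limit = 200000L,
                       first_feasible = FALSE) {
  n <- length(md$Kmax)
  if (is.null(lb)) lb <- integer(n)
  if (is.null(ub)) ub <- md$Kmax
  A_s <- md$A_s; rl_s <- md$rl_s; ru_s <- md$ru_s
  if (!is.null(extra)) {
    sc <- max(abs(extra$row), 1e-12)
    A_s <- rbind(A_s, extra$row / sc)
    rl_s <- c(rl_s, -Inf)
    ru_s <- c(ru_s, extra$cap / sc)
  }

  best_obj <- Inf
  best_k <- NULL
  if (!is.null(incumbent_k)) {
    if (all(incumbent_k >= lb & incumbent_k <= ub) &&
        check_feasible_k(incumbent_k, md) &&
        (is.null(extra) || sum(extra$row * incumbent_k) <= extra$cap)) {
      best_obj <- sum(obj * incumbent_k)
      best_k <- incumbent_k
    }
  }

  try_candidate <- function(k) {
    if (!check_feasible_k(k, md)) return(invisible(NULL))
    if (!is.null(extra) && sum(extra$row * k) > extra$cap) return(invisible(NULL))
    o <- sum(obj * k)
    if (o < best_obj - cost_tol) {
      best_obj <<- o
      best_k <<- k
    }
    invisible(NULL)
  }

  # best-first search on the parent LP bound; among equal bounds the newest
  # node wins, so the search dives toward the LP optimum until an incumbent
  # appears and then works the remaining bound-ordered frontier
  nodes <- list(list(lb = lb, ub = ub, bound = -Inf))
  bounds <- -Inf
  n_nodes <- 0L
  while (length(nodes)) {
    if (first_feasible && !is.null(best_k)) break
    cand <- which(bounds <= min(bounds) + 1e-12)
    pick <- cand[length(cand)]
    node <- nodes[[pick]]
    nodes[[pick]] <- NULL
    bounds <- bounds[-pick]
    if (node$bound >= best_obj - cost_tol) next
    n_nodes <- n_nodes + 1L
    if (n_nodes > node_limit) stop("branch-and-bound node limit reached",
                                   call. = FALSE)
    lp <- solve_lp(obj, A_s, rl_s, ru_s, node$lb, node$ub)
    if (lp$status != "optimal") next
    if (lp$obj >= best_obj - cost_tol) next
    x <- lp$x
    frac <- abs(x - round(x))
    if (all(frac <= int_tol)) {
      try_candidate(as.integer(round(x)))
      next
    }
    # rounding heuristic for an early incumbent
    if (is.null(best_k)) {
      try_candidate(as.integer(pmin(node$ub, pmax(node$lb, round(x)))))
    }
    j <- which.max(frac)
    lo <- node; lo$ub[j] <- as.integer(floor(x[j])); lo$bound <- lp$obj
    hi <- node; hi$lb[j] <- as.integer(ceiling(x[j])); hi$bound <- lp$obj
    near_hi <- x[j] - floor(x[j]) > 0.5
    # push the near child last so it is explored first on tied bounds
    nodes <- if (near_hi) c(nodes, list(lo, hi)) else c(nodes, list(hi, lo))
    bounds <- c(bounds, lp$obj, lp$obj)
  }
  if (is.null(best_k)) list(status = "infeasible", k = NULL, obj = NA_real_)
  else list(status = "optimal", k = as.integer(best_k), obj = best_obj)
}

make_solution <- function(k, problem) {
  servings <- stats::setNames(k * problem$granularity, problem$db$item_id)
  ev <- evaluate_servings(servings[servings > 0], problem$db)
  gs <- vapply(FOOD_CATEGORIES, function(cat) {
    sum(servings[problem$db$category == cat])
  }, numeric(1))
  structure(list(status = "optimal", servings = servings,
                 total_cost = ev$cost, achieved = ev$profile,
                 group_servings = gs, granularity = problem$granularity),
            class = "diet_solution")
}

infeasible_solution <- function(problem) {
  structure(list(status = "infeasible",
                 servings = stats::setNames(numeric(nrow(problem$db)),
                                            problem$db$item_id),
                 total_cost = NA_real_, achieved = nutrient_profile(),
                 group_servings = stats::setNames(numeric(length(FOOD_CATEGORIES)),
                                                  FOOD_CATEGORIES),
                 granularity = problem$granularity),
            class = "diet_solution")
}

#' @export
print.diet_solution <- function(x, ...) {
  cat("<diet_solution>", x$status, "\n")
  if (x$status == "optimal") {
    cat(sprintf("  cost %.4f, %d items selected, energy %.1f kcal\n",
                x$total_cost, sum(x$servings > 0),
                x$achieved[["energy_kcal"]]))
  }
  invisible(x)
}

# -- user-facing operations ---------------------------------------------------

#' Solve the least-cost diet program exactly
#'
#' Minimizes total daily food cost over integer counts of
#' `granularity`-sized portions subject to the nutrient bounds, food-group
#' serving bounds and per-item caps in `problem`. The solver is exact branch
#' and bound over the LP relaxation: when any integer-feasible diet exists
#' the returned diet has globally minimal cost. Among equal-cost optima the
#' serving vector that is lexicographically smallest in database item order
#' is returned (sequential refinement), so results are reproducible down to
#' the individual foods chosen.
#'
#' @param problem A [build_problem()] result.
#' @param lex Refine ties lexicographically (default `TRUE`). With random
#'   continuous prices exact cost ties are rare; `lex = FALSE` skips the
#'   refinement pass and returns the first optimum found, still
#'   deterministically.
#' @return A `diet_solution`: `status` (`"optimal"` or `"infeasible"`),
#'   `servings` (named, multiples of the granularity), `total_cost`,
#'   `achieved` nutrient profile and `group_servings`.
#' @seealso [brute_force_diet()] for the enumeration oracle,
#'   [binding_report()], [diagnose_infeasibility()].
#' @export
optimize_diet <- function(problem, lex = TRUE) {
  stopifnot(inherits(problem, "diet_problem"))
  md <- milp_data(problem)
  res <- solve_milp(md)
  if (res$status != "optimal") return(infeasible_solution(problem))
  k <- res$k
  if (lex) {
    cap <- res$obj + 1e-9 * max(1, abs(res$obj))
    fixed_lb <- integer(length(k))
    fixed_ub <- md$Kmax
    for (j in seq_along(k)) {
      if (k[j] == 0L) {                  # zero is already lexicographic-minimal
        fixed_ub[j] <- 0L
        next
      }
      ej <- numeric(length(k)); ej[j] <- 1
      rj <- solve_milp(md, lb = fixed_lb, ub = fixed_ub, obj = ej,
                       extra = list(row = md$cost, cap = cap),
                       incumbent_k = k)
      k <- rj$k
      fixed_lb[j] <- k[j]
      fixed_ub[j] <- k[j]
    }
  }
  make_solution(k, problem)
}

#' Exhaustive-enumeration oracle for the diet program
#'
#' Enumerates every integer portion-count vector within the item caps, in
#' lexicographic order of database items, and returns the minimal-cost
#' feasible diet under the same tie-break as [optimize_diet()]. Identical
#' contract to the branch-and-bound solver; intended as an independent
#' correctness oracle on small instances.
#'
#' @param problem A [build_problem()] result.
#' @param guard Refuse when the search space exceeds this many vectors.
#' @param chunk_size Vectors evaluated per vectorized block.
#' @return A `diet_solution`.
#' @export
brute_force_diet <- function(problem, guard = 1e7, chunk_size = 262144L) {
  stopifnot(inherits(problem, "diet_problem"))
  md <- milp_data(problem)
  n <- length(md$Kmax)
  sizes <- md$Kmax + 1
  space <- prod(sizes)
  if (space > guard) {
    stop(sprintf("search space has %.3g candidate vectors (guard %.3g)",
                 space, guard), call. = FALSE)
  }
  # mixed-radix weights with item 1 as the slowest digit: ascending index
  # order is ascending lexicographic order of (k_1, ..., k_n)
  w <- rev(cumprod(rev(c(sizes[-1L], 1))))
  At <- t(md$A)
  cost_tol <- 1e-9
  best_cost <- Inf
  best_k <- NULL
  tl <- 1e-7 * pmax(1, abs(md$rl)); tl[!is.finite(md$rl)] <- Inf
  tu <- 1e-7 * pmax(1, abs(md$ru)); tu[!is.finite(md$ru)] <- Inf
  lo <- md$rl - tl
  hi <- md$ru + tu
  start <- 0
  while (start < space) {
    idx <- start + seq_len(min(chunk_size, space - start)) - 1
    K <- matrix(0, length(idx), n)
    for (j in seq_len(n)) K[, j] <- (idx %/% w[j]) %% sizes[j]
    V <- K %*% At
    ok <- rep(TRUE, nrow(K))
    for (i in seq_len(ncol(V))) {
      ok <- ok & V[, i] >= lo[i] & V[, i] <= hi[i]
    }
    if (any(ok)) {
      costs <- as.numeric(K[ok, , drop = FALSE] %*% md$cost)
      cmin <- min(costs)
      first <- which(costs <= cmin + cost_tol)[1L]
      if (cmin < best_cost - cost_tol) {
        best_cost <- cmin
        best_k <- K[ok, , drop = FALSE][first, ]
      }
    }
    start <- start + length(idx)
  }
  if (is.null(best_k)) infeasible_solution(problem)
  else make_solution(as.integer(best_k), problem)
}

#' Classify binding constraints of an optimal diet
#'
#' For each nutrient and food group, reports whether the achieved value sits
#' at its lower bound, at its upper bound, or strictly between the two. A
#' constraint counts as binding when it lies within `tol_fraction` of the
#' bound span (`tol_fraction * (upper - lower)` when both bounds are finite,
#' otherwise `tol_fraction * lower`); optimized menus typically land near,
#' not exactly on, the limiting recommendation for scarce nutrients such as
#' iron or potassium.
#'
#' @param solution An optimal `diet_solution`.
#' @param problem The [build_problem()] result it solves.
#' @param tol_fraction Binding tolerance as a fraction of the bound span
#'   (default 0.05).
#' @return Data frame with one row per constraint: `constraint`, `type`
#'   (`"nutrient"`/`"group"`), `value`, `lower`, `upper`, `side` (`"lower"`,
#'   `"upper"` or `"none"`), `slack_lower`, `slack_upper` and
#'   `relative_position` (`(value - lower) / (upper - lower)`, `NA` when a
#'   bound is infinite).
#' @export
binding_report <- function(solution, problem, tol_fraction = 0.05) {
  stopifnot(inherits(solution, "diet_solution"),
            inherits(problem, "diet_problem"))
  if (solution$status != "optimal") {
    stop("binding_report requires an optimal solution", call. = FALSE)
  }
  value <- c(as.numeric(solution$achieved),
             as.numeric(solution$group_servings[FOOD_CATEGORIES]))
  lower <- c(problem$nutrient_bounds$lower, problem$group_bounds$lower)
  upper <- c(problem$nutrient_bounds$upper, problem$group_bounds$upper)
  tol <- ifelse(is.finite(upper), tol_fraction * (upper - lower),
                tol_fraction * lower)
  side <- rep("none", length(value))
  side[value <= lower + tol] <- "lower"
  side[side == "none" & is.finite(upper) & value >= upper - tol] <- "upper"
  span <- upper - lower
  relpos <- ifelse(is.finite(span) & span > 0, (value - lower) / span,
                   NA_real_)
  data.frame(
    constraint = c(NUTRIENTS, FOOD_CATEGORIES),
    type = rep(c("nutrient", "group"),
               c(length(NUTRIENTS), length(FOOD_CATEGORIES))),
    value = value, lower = lower, upper = upper, side = side,
    slack_lower = value - lower, slack_upper = upper - value,
    relative_position = relpos,
    stringsAsFactors = FALSE
  )
}

# fast feasibility probe: branch-and-bound that stops at the first
# integer-feasible point (objective irrelevant)
problem_feasible <- function(problem) {
  md <- milp_data(problem)
  solve_milp(md, obj = numeric(length(md$Kmax)),
             first_feasible = TRUE)$status == "optimal"
}

#' Find single-constraint relaxations that restore feasibility
#'
#' Given an infeasible diet problem, relaxes one constraint at a time — each
#' positive nutrient or group lower bound dropped to 0, each finite upper
#' bound lifted to unbounded — and re-solves. Every relaxation that restores
#' feasibility is listed as a culprit; when no single relaxation helps the
#' infeasibility is flagged irreducible. This mirrors the one-nutrient-at-
#' a-time reading of why a diet fails (e.g. the iron requirement exceeding
#' what any affordable food basket can supply).
#'
#' @param problem An infeasible [build_problem()] result.
#' @return List with `culprits` (character, e.g. `"nutrient:iron_mg lower"`)
#'   and `irreducible` (logical).
#' @export
diagnose_infeasibility <- function(problem) {
  stopifnot(inherits(problem, "diet_problem"))
  if (problem_feasible(problem)) {
    stop("diagnose_infeasibility requires an infeasible problem",
         call. = FALSE)
  }
  culprits <- character(0)
  relaxed_feasible <- problem_feasible   # status is all a relaxation needs
  for (i in seq_along(NUTRIENTS)) {
    nb <- problem$nutrient_bounds
    if (nb$lower[i] > 0) {
      p <- problem; p$nutrient_bounds$lower[i] <- 0
      if (relaxed_feasible(p)) {
        culprits <- c(culprits, paste0("nutrient:", NUTRIENTS[i], " lower"))
      }
    }
    if (is.finite(nb$upper[i])) {
      p <- problem; p$nutrient_bounds$upper[i] <- Inf
      if (relaxed_feasible(p)) {
        culprits <- c(culprits, paste0("nutrient:", NUTRIENTS[i], " upper"))
      }
    }
  }
  for (i in seq_along(FOOD_CATEGORIES)) {
    gb <- problem$group_bounds
    if (gb$lower[i] > 0) {
      p <- problem; p$group_bounds$lower[i] <- 0
      if (relaxed_feasible(p)) {
        culprits <- c(culprits, paste0("group:", FOOD_CATEGORIES[i], " lower"))
      }
    }
    if (is.finite(gb$upper[i])) {
      p <- problem; p$group_bounds$upper[i] <- Inf
      if (relaxed_feasible(p)) {
        culprits <- c(culprits, paste0("group:", FOOD_CATEGORIES[i], " upper"))
      }
    }
  }
  list(culprits = culprits, irreducible = length(culprits) == 0L)
}

#' Compare supplement scenarios on one food database
#'
#' Solves the least-cost diet for a baseline (diet alone) and for each
#' supplement scenario, with the scenario's nutrients relaxing the dietary
#' lower bounds. Because supplementation only relaxes constraints, a
#' scenario's optimal cost is never above the baseline cost — the direction
#' behind cheaper with-supplement menus.
#'
#' @param db A [food_db()].
#' @param trimester 1, 2 or 3.
#' @param scenarios List of [supplement_scenario()] objects.
#' @param overrides Extra [build_problem()] overrides shared by all rows.
#' @param lex Passed to [optimize_diet()].
#' @return Data frame with one row per scenario (baseline first): `scenario`,
#'   `status`, `cost`, `binding_lower` (comma-separated nutrients at their
#'   lower bound) and one `achieved_*` column per nutrient. Full
#'   `diet_solution` objects are attached as attribute `"solutions"`. A row
#'   that errors is reported with status `"error"`; remaining rows still run.
#' @export
compare_scenarios <- function(db, trimester, scenarios, overrides = list(),
                              lex = TRUE) {
  stopifnot(inherits(db, "food_db"), is.list(scenarios))
  entries <- c(list(NULL), scenarios)
  labels <- c("baseline",
              vapply(scenarios, function(s) s$name, character(1)))
  rows <- vector("list", length(entries))
  sols <- vector("list", length(entries))
  for (i in seq_along(entries)) {
    ov <- overrides
    if (!is.null(entries[[i]])) ov$supplement <- entries[[i]]
    row <- tryCatch({
      problem <- build_problem(db, trimester, ov)
      sol <- optimize_diet(problem, lex = lex)
      sols[[i]] <- sol
      if (sol$status == "optimal") {
        br <- binding_report(sol, problem)
        bl <- br$constraint[br$type == "nutrient" & br$side == "lower"]
        c(list(scenario = labels[i], status = "optimal",
               cost = sol$total_cost,
               binding_lower = paste(bl, collapse = ",")),
          stats::setNames(as.list(as.numeric(sol$achieved)),
                          paste0("achieved_", NUTRIENTS)))
      } else {
        c(list(scenario = labels[i], status = "infeasible", cost = NA_real_,
               binding_lower = NA_character_),
          stats::setNames(as.list(rep(NA_real_, length(NUTRIENTS))),
                          paste0("achieved_", NUTRIENTS)))
      }
    }, error = function(e) {
      c(list(scenario = labels[i], status = "error", cost = NA_real_,
             binding_lower = conditionMessage(e)),
        stats::setNames(as.list(rep(NA_real_, length(NUTRIENTS))),
                        paste0("achieved_", NUTRIENTS)))
    })
    rows[[i]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "solutions") <- stats::setNames(sols, labels)
  out
}

#' Write a diet solution to a JSON report
#'
#' @param solution A `diet_solution`.
#' @param path Output path.
#' @param binding Optional [binding_report()] data frame to embed.
#' @return `path`, invisibly.
#' @export
write_solution_json <- function(solution, path, binding = NULL) {
  stopifnot(inherits(solution, "diet_solution"))
  out <- list(
    status = solution$status,
    total_cost = solution$total_cost,
    servings = as.list(solution$servings[solution$servings > 0]),
    achieved = as.list(as.numeric(solution$achieved)) |>
      stats::setNames(NUTRIENTS),
    group_servings = as.list(solution$group_servings)
  )
  if (!is.null(binding)) out$binding <- binding
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
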