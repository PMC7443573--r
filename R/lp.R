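# Least-cost diet LP for one individual category, one season, one food set.
#
# Decision variables are continuous servings per week of each food within
# its frequency bounds. Energy is constrained to a band around the weekly
# requirement (hard, both sides); protein and fat are hard >= rows; each
# micronutrient row is elastic: supply may fall short of the weekly
# requirement at a large per-unit penalty on the normalized deficit, so
# the optimizer first drives shortfalls to the minimum attainable and only
# then minimizes food cost. This mirrors diet-costing practice where some
# micronutrient requirements (typically iron and zinc) are unreachable
# from the local food basket and the tool reports the gap.

#' Assemble a least-cost diet problem
#'
#' @param foods Foods table (see [read_foods()] for the schema); only
#'   foods available in `season` enter the model. Unknown (`NA`)
#'   composition entries contribute zero to all constraints and are
#'   flagged as incomplete in adequacy reports.
#' @param prices Seasonal price table (`food_id`, `season`,
#'   `price_per_100g`), e.g. from [aggregate_prices()]. Supplements may be
#'   omitted; their price is fixed at zero.
#' @param portions Portion table (`category`, `food_id`, `grams`), e.g.
#'   from [default_portions()].
#' @param bounds Weekly frequency bounds (`food_id`, `min_per_week`,
#'   `max_per_week`), e.g. from [bounds_from_recall()].
#' @param requirements Long requirements table (see
#'   [default_requirements()]).
#' @param category Individual category, one of [diet_categories()].
#' @param season `"plenty"` or `"lean"`.
#' @param energy_band Multiplier band on the weekly energy requirement,
#'   default `c(1, 1.1)`: at least 100% and at most 110% of requirement,
#'   preventing unbounded padding with cheap energy.
#' @param penalty Cost per unit of normalized micronutrient deficit
#'   (deficit measured as a fraction of the weekly requirement). Default
#'   `1e6` times the most expensive serving, so deficit reduction
#'   lexicographically dominates food cost.
#' @return A `diet_problem` object.
#' @export
build_diet_problem <- function(foods, prices, portions, bounds,
                               requirements, category, season,
                               energy_band = c(1, 1.1), penalty = NULL) {
  foods <- validate_foods(foods)
  category <- match.arg(category, DIET_CATEGORIES)
  season <- match.arg(season, DIET_SEASONS)
  stopifnot(
    length(energy_band) == 2, energy_band[1] > 0,
    energy_band[1] <= energy_band[2]
  )

  foods <- foods |> filter(food_available(.data$season_availability, season))
  if (nrow(foods) == 0) abort("No food is available in this season.")

  price_season <- prices |> filter(.data$season == !!season)
  joined <- foods |>
    left_join(
      price_season |> select("food_id", "price_per_100g"),
      by = c(id = "food_id")
    ) |>
    left_join(
      portions |>
        filter(.data$category == !!category) |>
        select("food_id", "grams"),
      by = c(id = "food_id")
    ) |>
    left_join(bounds, by = c(id = "food_id"))

  joined$price_per_100g[joined$category == "supplement"] <- 0
  miss <- function(col, what) {
    bad <- joined$id[is.na(joined[[col]])]
    if (length(bad) > 0) {
      abort(paste0(
        "Missing ", what, " for food(s) ", paste(bad, collapse = ", "),
        " (category ", category, ", season ", season, ")."
      ))
    }
  }
  miss("price_per_100g", paste0(season, "-season price"))
  miss("grams", "portion size")
  miss("min_per_week", "frequency bound")
  validate_bounds(
    joined |> select(food_id = "id", "min_per_week", "max_per_week")
  )

  comp <- as.matrix(joined[nutrient_names()])
  rownames(comp) <- joined$id
  na_mask <- is.na(comp)
  comp[na_mask] <- 0
  # per-serving supply: composition is per 100 g, except supplements where
  # it is per sachet (one serving)
  serving_factor <- ifelse(joined$category == "supplement", 1,
    joined$grams / 100
  )
  A <- comp * serving_factor
  cost <- joined$price_per_100g * joined$grams / 100
  cost[joined$category == "supplement"] <- 0

  req_daily <- requirements_for(requirements, category)
  req_weekly <- 7 * req_daily
  elastic <- micro_nutrients()
  elastic <- elastic[!is.na(req_weekly[elastic]) & req_weekly[elastic] > 0]
  hard_macros <- c("protein", "fat")
  hard_macros <- hard_macros[
    !is.na(req_weekly[hard_macros]) & req_weekly[hard_macros] > 0
  ]
  if (is.null(penalty)) penalty <- 1e6 * max(cost, 1e-3)
  if (penalty <= 0) abort("`penalty` must be > 0.")

  structure(
    list(
      category = category, season = season,
      foods = joined |>
        select(
          "id", "name", "category", "grams",
          "price_per_100g", "min_per_week", "max_per_week"
        ),
      A = A, na_mask = na_mask, cost = cost,
      min = joined$min_per_week, max = joined$max_per_week,
      req_daily = req_daily, req_weekly = req_weekly,
      energy_band = energy_band, penalty = penalty,
      elastic = elastic, hard_macros = hard_macros
    ),
    class = "diet_problem"
  )
}

#' @export
print.diet_problem <- function(x, ...) {
  cat(
    "<diet_problem> ", x$category, ", ", x$season, " season: ",
    nrow(x$foods), " foods, ", length(x$elastic),
    " elastic micronutrient rows\n",
    sep = ""
  )
  invisible(x)
}

#' Solve a least-cost diet problem
#'
#' Minimizes weekly food cost plus the deficit penalty over servings
#' within frequency bounds, subject to the energy band and hard
#' protein/fat rows, with elastic micronutrient rows. The solve is
#' deterministic for a fixed problem.
#'
#' @param problem A `diet_problem` from [build_diet_problem()].
#' @param eps Numerical tolerance passed to the simplex pivoting.
#' @return A `diet_solution` with the weekly servings, weekly and daily
#'   food cost (KES; the deficit penalty is excluded from cost but
#'   included in `objective`), per-nutrient adequacy, and `status`:
#'   `"optimal"` (all requirements met), `"optimal_with_deficit"` (some
#'   micronutrient unreachable within bounds) or `"infeasible_bounds"`
#'   (the hard constraints cannot be met; the violated row is named in
#'   `$violated`).
#' @export
solve_diet <- function(problem, eps = 1e-10) {
  stopifnot(inherits(problem, "diet_problem"))
  n <- nrow(problem$A)
  ne <- length(problem$elastic)
  A <- problem$A
  lo <- problem$min
  span <- problem$max - problem$min
  req_w <- problem$req_weekly
  e_row <- A[, "energy"]
  supply_min <- drop(crossprod(A, lo))

  # upper-bound (<=) rows: y_f <= span_f, and the energy ceiling
  ub_energy_rhs <- problem$energy_band[2] * req_w[["energy"]] -
    supply_min[["energy"]]
  if (ub_energy_rhs < -1e-9) {
    return(infeasible_solution(problem, "energy_upper"))
  }
  A1 <- cbind(diag(n), matrix(0, n, ne))
  b1 <- span
  A1 <- rbind(A1, c(e_row, rep(0, ne)))
  b1 <- c(b1, max(ub_energy_rhs, 0))

  # hard >= rows: energy floor, protein, fat
  A2 <- NULL
  b2 <- NULL
  hard_rows <- list(energy = problem$energy_band[1] * req_w[["energy"]])
  for (m in problem$hard_macros) hard_rows[[m]] <- req_w[[m]]
  for (nm in names(hard_rows)) {
    rhs <- hard_rows[[nm]] - supply_min[[nm]]
    if (rhs > 1e-12) {
      if (sum(A[, nm] * span) < rhs - 1e-9) {
        return(infeasible_solution(
          problem, if (nm == "energy") "energy_lower" else nm
        ))
      }
      A2 <- rbind(A2, c(A[, nm], rep(0, ne)))
      b2 <- c(b2, rhs)
    }
  }
  # elastic micronutrient rows, normalized by the weekly requirement:
  # supply/req + deficit >= 1
  for (j in seq_along(problem$elastic)) {
    k <- problem$elastic[j]
    rhs <- 1 - supply_min[[k]] / req_w[[k]]
    if (rhs > 1e-12) {
      dcol <- rep(0, ne)
      dcol[j] <- 1
      A2 <- rbind(A2, c(A[, k] / req_w[[k]], dcol))
      b2 <- c(b2, rhs)
    }
  }

  obj <- c(problem$cost, rep(problem$penalty, ne))
  fit <- boot::simplex(
    a = obj, A1 = A1, b1 = b1, A2 = A2, b2 = b2,
    maxi = FALSE, n.iter = 200 * (n + ne + length(b1) + length(b2)),
    eps = eps
  )
  if (fit$solved == -1) {
    return(infeasible_solution(problem, diagnose_infeasible(problem)))
  }
  if (fit$solved != 1) {
    abort("Simplex did not converge within the iteration limit.")
  }
  x <- pmin(pmax(fit$soln[seq_len(n)] + lo, problem$min), problem$max)
  finish_solution(problem, x, method = "simplex")
}

finish_solution <- function(problem, x, method) {
  supplied <- drop(crossprod(problem$A, x))
  req_w <- problem$req_weekly
  deficits <- vapply(problem$elastic, function(k) {
    max(0, 1 - supplied[[k]] / req_w[[k]])
  }, numeric(1))
  status <- if (all(deficits <= 1e-6)) "optimal" else "optimal_with_deficit"
  weekly_cost <- sum(problem$cost * x)
  servings <- problem$foods |>
    transmute(
      food_id = .data$id, name = .data$name,
      food_category = .data$category,
      servings_per_week = unname(x),
      grams_per_week = unname(x) *
        ifelse(.data$category == "supplement", 1, .data$grams),
      cost_kes = unname(problem$cost * x)
    )
  structure(
    list(
      category = problem$category, season = problem$season,
      servings = servings,
      weekly_cost = weekly_cost, daily_cost = weekly_cost / 7,
      objective = weekly_cost + problem$penalty * sum(deficits),
      supplied = supplied, deficits = deficits,
      status = status, violated = NULL, method = method
    ),
    class = "diet_solution"
  )
}

infeasible_solution <- function(problem, violated) {
  structure(
    list(
      category = problem$category, season = problem$season,
      servings = NULL, weekly_cost = NA_real_, daily_cost = NA_real_,
      objective = NA_real_, supplied = NULL, deficits = NULL,
      status = "infeasible_bounds", violated = violated, method = "simplex"
    ),
    class = "diet_solution"
  )
}

diagnose_infeasible <- function(problem) {
  supply_min <- drop(crossprod(problem$A, problem$min))
  supply_max <- drop(crossprod(problem$A, problem$max))
  req_w <- problem$req_weekly
  if (supply_min[["energy"]] >
    problem$energy_band[2] * req_w[["energy"]] + 1e-9) {
    return("energy_upper")
  }
  if (supply_max[["energy"]] <
    problem$energy_band[1] * req_w[["energy"]] - 1e-9) {
    return("energy_lower")
  }
  for (m in problem$hard_macros) {
    if (supply_max[[m]] < req_w[[m]] - 1e-9) return(m)
  }
  "bounds"
}

#' Nutrient adequacy of a diet solution
#'
#' Adequacy is the percentage of the weekly requirement supplied,
#' uncapped (values above 100 indicate oversupply). Nutrients for which
#' any consumed food has unknown composition are flagged
#' `composition_incomplete`, since unknown entries contribute zero.
#'
#' @param solution A `diet_solution`.
#' @param problem The `diet_problem` it was solved from.
#' @return A tibble `nutrient`, `supplied_weekly`, `required_weekly`,
#'   `adequacy_pct`, `constraint`, `composition_incomplete`.
#' @export
adequacy <- function(solution, problem) {
  stopifnot(inherits(solution, "diet_solution"))
  if (solution$status == "infeasible_bounds") {
    abort("No adequacy profile: the problem was infeasible.")
  }
  x <- solution$servings$servings_per_week
  consumed <- x > 1e-9
  incomplete <- apply(problem$na_mask[consumed, , drop = FALSE], 2, any)
  info <- nutrient_info()
  tibble(
    nutrient = nutrient_names(),
    supplied_weekly = unname(solution$supplied[nutrient_names()]),
    required_weekly = unname(problem$req_weekly[nutrient_names()]),
    adequacy_pct = 100 * .data$supplied_weekly / .data$required_weekly,
    constraint = dplyr::case_when(
      info$class == "energy" ~ "energy_band",
      info$nutrient %in% problem$hard_macros ~ "hard",
      info$nutrient %in% problem$elastic ~ "elastic",
      .default = "none"
    ),
    composition_incomplete = unname(incomplete[nutrient_names()])
  )
}

#' Brute-force grid oracle for small diet problems
#'
#' Exhaustively enumerates servings on a grid within the frequency bounds
#' and returns the feasible (or least-penalized) minimum of the same
#' objective as [solve_diet()]. Intended for validating the LP on small
#' instances; refuses problems larger than `max_foods` foods or
#' `max_points` grid points per food.
#'
#' @param problem A `diet_problem`.
#' @param step Grid step in servings per week.
#' @param max_foods,max_points Size guards.
#' @return A `diet_solution` with `method = "grid"`.
#' @export
brute_force_solve <- function(problem, step = 1, max_foods = 5,
                              max_points = 8) {
  stopifnot(inherits(problem, "diet_problem"))
  n <- nrow(problem$A)
  if (n > max_foods) {
    abort(paste0("Oracle refuses instances with more than ",
      max_foods, " foods."))
  }
  grids <- lapply(seq_len(n), function(i) {
    g <- seq(problem$min[i], problem$max[i], by = step)
    if (g[length(g)] < problem$max[i]) g <- c(g, problem$max[i])
    g
  })
  if (any(lengths(grids) > max_points)) {
    abort(paste0("Oracle refuses grids with more than ",
      max_points, " points per food."))
  }
  X <- as.matrix(expand.grid(grids, KEEP.OUT.ATTRS = FALSE))
  supply <- X %*% problem$A
  req_w <- problem$req_weekly
  feas <- supply[, "energy"] >=
    problem$energy_band[1] * req_w[["energy"]] - 1e-9 &
    supply[, "energy"] <= problem$energy_band[2] * req_w[["energy"]] + 1e-9
  for (m in problem$hard_macros) {
    feas <- feas & supply[, m] >= req_w[[m]] - 1e-9
  }
  if (!any(feas)) {
    sol <- infeasible_solution(problem, diagnose_infeasible(problem))
    sol$method <- "grid"
    return(sol)
  }
  defsum <- rep(0, nrow(X))
  for (k in problem$elastic) {
    defsum <- defsum + pmax(0, 1 - supply[, k] / req_w[[k]])
  }
  obj <- drop(X %*% problem$cost) + problem$penalty * defsum
  obj[!feas] <- Inf
  best <- which.min(obj)
  finish_solution(problem, X[best, ], method = "grid")
}

#' @export
print.diet_solution <- function(x, ...) {
  if (x$status == "infeasible_bounds") {
    cat(
      "<diet_solution> ", x$category, ", ", x$season,
      ": infeasible within bounds (", x$violated, ")\n",
      sep = ""
    )
    return(invisible(x))
  }
  cat(
    "<diet_solution> ", x$category, ", ", x$season, ": ",
    x$status, ", daily cost ", round_half_up(x$daily_cost, 1), " KES\n",
    sep = ""
  )
  invisible(x)
}

#' Tidy a diet solution into its weekly servings
#'
#' @param x A `diet_solution`.
#' @param ... Unused.
#' @return `tidy()`: one row per food with weekly servings, grams and
#'   cost; `glance()`: a one-row summary (status, costs, adequacy range).
#' @export
tidy.diet_solution <- function(x, ...) {
  if (x$status == "infeasible_bounds") {
    return(tibble(
      food_id = character(), name = character(),
      food_category = character(), servings_per_week = numeric(),
      grams_per_week = numeric(), cost_kes = numeric()
    ))
  }
  x$servings
}

#' @rdname tidy.diet_solution
#' @export
glance.diet_solution <- function(x, ...) {
  tibble(
    category = x$category, season = x$season, status = x$status,
    weekly_cost = x$weekly_cost, daily_cost = x$daily_cost,
    n_foods_used = if (is.null(x$servings)) NA_integer_ else
      sum(x$servings$servings_per_week > 1e-9),
    n_deficit_nutrients = if (is.null(x$deficits)) NA_integer_ else
      sum(x$deficits > 1e-6)
  )
}

#' Plot the nutrient-adequacy profile of a diet solution
#'
#' @param object A `diet_solution`.
#' @param problem The `diet_problem` it was solved from.
#' @param ... Unused.
#' @return A ggplot: adequacy (% of weekly requirement, capped at 300 for
#'   display) per nutrient with the 100% reference line.
#' @export
autoplot.diet_solution <- function(object, problem, ...) {
  adq <- adequacy(object, problem) |>
    filter(.data$constraint != "none") |>
    mutate(display_pct = pmin(.data$adequacy_pct, 300))
  ggplot2::ggplot(
    adq,
    ggplot2::aes(
      x = stats::reorder(.data$nutrient, .data$adequacy_pct),
      y = .data$display_pct,
      fill = .data$adequacy_pct >= 100 - 1e-9
    )
  ) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = 100, linetype = 2) +
    ggplot2::coord_flip() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "grey35", `FALSE` = "firebrick")) +
    ggplot2::labs(
      x = NULL, y = "% of weekly requirement supplied (capped at 300)",
      title = paste0(
        object$category, ", ", object$season, " season (", object$status, ")"
      )
    )
}
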