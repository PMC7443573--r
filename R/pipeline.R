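# End-to-end runs and publication-style report tables. All outputs are
# deterministic UTF-8 CSV (or JSON), so regenerating a report from the
# same results is byte-identical.

#' Solve the baseline diet problem for every category and season
#'
#' @param bundle A [diet_bundle()].
#' @param categories,seasons Cells to solve.
#' @param energy_band,penalty Passed to [build_diet_problem()].
#' @param out_dir Optional directory; when given, a `solution.json` per
#'   cell (servings, costs, adequacy, status) and a `costs.csv` summary
#'   are written into it.
#' @return A tibble with one row per cell: `category`, `season`,
#'   `daily_cost`, `weekly_cost`, `status`.
#' @export
run_costing <- function(bundle, categories = diet_categories(),
                        seasons = diet_seasons(),
                        energy_band = c(1, 1.1), penalty = NULL,
                        out_dir = NULL) {
  stopifnot(inherits(bundle, "diet_bundle"))
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  cells <- tidyr::expand_grid(category = categories, season = seasons) |>
    purrr::pmap(function(category, season) {
      prob <- build_diet_problem(
        bundle$foods, bundle$prices, bundle$portions, bundle$bounds,
        bundle$requirements, category, season,
        energy_band = energy_band, penalty = penalty
      )
      sol <- solve_diet(prob)
      if (!is.null(out_dir) && sol$status != "infeasible_bounds") {
        payload <- list(
          category = category, season = season, status = sol$status,
          weekly_cost_kes = sol$weekly_cost,
          daily_cost_kes = sol$daily_cost,
          servings = sol$servings,
          adequacy = adequacy(sol, prob)
        )
        jsonlite::write_json(
          payload,
          file.path(out_dir, paste0(category, "_", season, "_solution.json")),
          auto_unbox = TRUE, digits = NA
        )
      }
      tibble(
        category = category, season = season,
        daily_cost = sol$daily_cost, weekly_cost = sol$weekly_cost,
        status = sol$status
      )
    }) |>
    bind_rows()
  if (!is.null(out_dir)) {
    readr::write_csv(cells, file.path(out_dir, "costs.csv"))
  }
  cells
}

#' Write the scenario ladder as a flat report
#'
#' One row per (category, season, scenario) with baseline and scenario
#' daily cost, the percentage reduction, and the both-season meaningful
#' flag.
#'
#' @param ladder A `scenario_ladder` from [run_ladder()].
#' @param path Optional CSV path.
#' @return The report tibble (invisibly writes `path` when given).
#' @export
report_ladder <- function(ladder, path = NULL) {
  stopifnot(inherits(ladder, "scenario_ladder"))
  out <- ladder$cells |>
    filter(.data$scenario != "baseline") |>
    left_join(
      ladder$summary |> select("category", "scenario", "meaningful"),
      by = c("category", "scenario")
    ) |>
    transmute(
      .data$category, .data$season, .data$scenario,
      baseline_kes = round_half_up(.data$baseline_cost, 1),
      scenario_kes = round_half_up(.data$daily_cost, 1),
      reduction_pct = .data$reduction_pct,
      meaningful = .data$meaningful
    )
  if (!is.null(path)) readr::write_csv(out, path)
  out
}

#' Cost-matrix report (seasonal costs plus scenario reduction columns)
#'
#' Renders the classic summary table: one row per individual category,
#' the two seasonal baseline daily costs, and one season-averaged
#' reduction column per scenario (costs to 0.1 KES, percentages to 0.1).
#'
#' @param ladder A `scenario_ladder`.
#' @param path Optional CSV path.
#' @return A wide tibble.
#' @export
report_cost_matrix <- function(ladder, path = NULL) {
  stopifnot(inherits(ladder, "scenario_ladder"))
  base <- ladder$cells |>
    filter(.data$scenario == "baseline") |>
    select("category", "season", "daily_cost") |>
    mutate(daily_cost = round_half_up(.data$daily_cost, 1)) |>
    tidyr::pivot_wider(
      names_from = "season", values_from = "daily_cost",
      names_prefix = "cost_"
    )
  red <- ladder$summary |>
    select("category", "scenario", "avg_reduction_pct") |>
    tidyr::pivot_wider(
      names_from = "scenario", values_from = "avg_reduction_pct"
    )
  out <- left_join(base, red, by = "category")
  if (!is.null(path)) readr::write_csv(out, path)
  out
}

#' Adequacy report for a set of solved cells
#'
#' @param bundle A [diet_bundle()].
#' @param nutrients Nutrients to report (default the classic gap pair,
#'   absorbed iron and zinc).
#' @param interventions Optional named list of [intervention()]s to
#'   profile alongside baseline.
#' @param categories,seasons Cells to solve.
#' @param path Optional CSV path.
#' @return A tibble `scenario`, `category`, `season`, `nutrient`,
#'   `adequacy_pct` (rounded to 1%).
#' @export
report_adequacy <- function(bundle, nutrients = c("iron_absorbed", "zinc"),
                            interventions = list(),
                            categories = diet_categories(),
                            seasons = diet_seasons(), path = NULL) {
  stopifnot(inherits(bundle, "diet_bundle"))
  profile_one <- function(b, scenario, cats) {
    tidyr::expand_grid(category = cats, season = seasons) |>
      purrr::pmap(function(category, season) {
        prob <- build_diet_problem(
          b$foods, b$prices, b$portions, b$bounds, b$requirements,
          category, season
        )
        sol <- solve_diet(prob)
        adequacy(sol, prob) |>
          filter(.data$nutrient %in% nutrients) |>
          transmute(
            scenario = scenario, category = category, season = season,
            .data$nutrient,
            adequacy_pct = round_half_up(.data$adequacy_pct)
          )
      }) |>
      bind_rows()
  }
  out <- profile_one(bundle, "baseline", categories)
  for (nm in names(interventions)) {
    iv <- interventions[[nm]]
    cats <- intersect(categories, iv$applies_to)
    if (length(cats) > 0) {
      out <- bind_rows(
        out, profile_one(apply_intervention(bundle, iv), iv$name, cats)
      )
    }
  }
  if (!is.null(path)) readr::write_csv(out, path)
  out
}

#' Affordability report
#'
#' @param wealth_groups Wealth-group table (see [can_afford()]).
#' @param annual_cost Annual diet cost per person, KES.
#' @param path Optional CSV path.
#' @return The [affordability_table()] with KES columns rounded to 0.1.
#' @export
report_affordability <- function(wealth_groups, annual_cost, path = NULL) {
  out <- affordability_table(wealth_groups, annual_cost) |>
    mutate(
      budget_kes = round_half_up(.data$budget_kes, 1),
      annual_cost_kes = round_half_up(.data$annual_cost_kes, 1),
      shortfall_kes = round_half_up(.data$shortfall_kes, 1)
    )
  if (!is.null(path)) readr::write_csv(out, path)
  out
}

#' Load a run configuration from YAML
#'
#' The configuration names the five input CSVs (`foods`, `prices`,
#' `recall` or `bounds`, `requirements`, `portions`), the output
#' directory, and optional numeric settings (`energy_band`,
#' `exchange_rate`, `penalty`, `seed`).
#'
#' @param path Path to a YAML file.
#' @return A validated config list.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    abort("Package 'yaml' is required to read YAML configs.")
  }
  cfg <- yaml::read_yaml(path)
  for (key in c("foods", "prices", "requirements")) {
    if (is.null(cfg[[key]])) {
      abort(paste0("Config is missing required entry '", key, "'."))
    }
    if (!file.exists(cfg[[key]])) {
      abort(paste0("Config file not found: ", cfg[[key]]))
    }
  }
  cfg$energy_band <- cfg$energy_band %||% c(1, 1.1)
  cfg$exchange_rate <- cfg$exchange_rate %||% 103.6
  cfg
}

#' Assemble a diet bundle from a run configuration
#'
#' Reads the input CSVs named in the config; bounds come from `bounds` if
#' given, otherwise from the 24-h `recall` counts via
#' [bounds_from_recall()]; portions default to [default_portions()].
#'
#' @param cfg A config list from [read_run_config()].
#' @return A [diet_bundle()].
#' @export
bundle_from_config <- function(cfg) {
  foods <- read_foods(cfg$foods)
  prices <- aggregate_prices(read_prices(cfg$prices), foods = foods)
  bounds <- if (!is.null(cfg$bounds)) {
    read_bounds(cfg$bounds)
  } else if (!is.null(cfg$recall)) {
    bounds_from_recall(read_recall(cfg$recall))
  } else {
    abort("Config needs either 'bounds' or 'recall'.")
  }
  portions <- if (!is.null(cfg$portions)) {
    read_portions(cfg$portions)
  } else {
    default_portions(foods)
  }
  diet_bundle(
    foods, prices, portions, bounds, read_requirements(cfg$requirements)
  )
}
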