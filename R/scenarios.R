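# Intervention scenario ladder: solve the baseline least-cost diet for
# every individual category and season, then re-solve with each
# intervention's foods added, and compare costs.

#' Bundle the model inputs for one study setting
#'
#' @param foods,prices,portions,bounds,requirements The five input tables
#'   (see [build_diet_problem()] for schemas).
#' @return A `diet_bundle` list, the unit the scenario ladder operates on.
#' @export
diet_bundle <- function(foods, prices, portions, bounds, requirements) {
  structure(
    list(
      foods = validate_foods(foods), prices = prices, portions = portions,
      bounds = bounds, requirements = requirements
    ),
    class = "diet_bundle"
  )
}

#' Define an intervention scenario
#'
#' An intervention adds foods (with their own prices and frequency
#' bounds, and optionally portions) to the baseline food list.
#'
#' @param name Scenario label.
#' @param foods Foods table of the added foods (disjoint from baseline).
#' @param prices Seasonal price table for the added foods (supplements may
#'   be omitted: price 0).
#' @param bounds Frequency bounds for the added foods.
#' @param portions Optional portions for the added foods; defaults to
#'   [default_portions()].
#' @param applies_to Individual categories the intervention targets
#'   (default all); e.g. MNP applies to children only.
#' @return An `intervention` object.
#' @export
intervention <- function(name, foods, prices = NULL, bounds,
                         portions = NULL, applies_to = diet_categories()) {
  foods <- validate_foods(foods)
  applies_to <- match.arg(applies_to, DIET_CATEGORIES, several.ok = TRUE)
  if (is.null(portions)) portions <- default_portions(foods)
  structure(
    list(
      name = name, foods = foods, prices = prices, bounds = bounds,
      portions = portions, applies_to = applies_to
    ),
    class = "intervention"
  )
}

apply_intervention <- function(bundle, iv) {
  overlap <- intersect(bundle$foods$id, iv$foods$id)
  if (length(overlap) > 0) {
    abort(paste0(
      "Intervention '", iv$name, "' re-adds baseline food(s): ",
      paste(overlap, collapse = ", ")
    ))
  }
  diet_bundle(
    foods = bind_rows(bundle$foods, iv$foods),
    prices = bind_rows(bundle$prices, iv$prices),
    portions = bind_rows(bundle$portions, iv$portions),
    bounds = bind_rows(bundle$bounds, iv$bounds),
    requirements = bundle$requirements
  )
}

#' The standard wild-food and MNP intervention ladder
#'
#' Builds the canonical scenario list for the Turkana setting: each of the
#' six wild plant foods alone, the three wild fruits together, the three
#' wild vegetables together, all six together, the micronutrient powder
#' (children only), and MNP plus all six (children only). Wild foods enter
#' at their opportunity-cost prices with weekly bounds 1-3; MNP at zero
#' cost with sachet bounds 3-4 (or 7-7 in daily mode).
#'
#' @param mnp_daily Use the one-sachet-per-day MNP sensitivity setting.
#' @return A named list of [intervention()] objects.
#' @export
standard_interventions <- function(mnp_daily = FALSE) {
  wild <- wild_food_items()
  wprices <- wild_food_prices()
  children <- DIET_CATEGORIES[startsWith(DIET_CATEGORIES, "child")]
  wild_iv <- function(ids, name) {
    sub <- wild |> filter(.data$id %in% ids)
    intervention(
      name, sub,
      prices = wprices |> filter(.data$food_id %in% ids),
      bounds = wild_food_bounds(sub)
    )
  }
  mnp <- mnp_food_item()
  ivs <- list(
    wild_iv("grewia_tenax", "grewia_tenax"),
    wild_iv("berchemia_discolor", "berchemia_discolor"),
    wild_iv("sterculia_africana", "sterculia_africana"),
    wild_iv(
      c("grewia_tenax", "berchemia_discolor", "sterculia_africana"),
      "all_wild_fruits"
    ),
    wild_iv("amaranthus_hybridus", "amaranthus_hybridus"),
    wild_iv("celosia_argentea", "celosia_argentea"),
    wild_iv("solanum_americanum", "solanum_americanum"),
    wild_iv(
      c("amaranthus_hybridus", "celosia_argentea", "solanum_americanum"),
      "all_wild_vegetables"
    ),
    wild_iv(wild$id, "all_wild_plant_foods"),
    intervention(
      "mnp", mnp,
      bounds = mnp_bounds(mnp, daily = mnp_daily),
      applies_to = children
    ),
    intervention(
      "mnp_plus_all_wild", bind_rows(mnp, wild),
      prices = wprices,
      bounds = bind_rows(
        mnp_bounds(mnp, daily = mnp_daily), wild_food_bounds(wild)
      ),
      applies_to = children
    )
  )
  rlang::set_names(ivs, vapply(ivs, function(v) v$name, character(1)))
}

#' Percentage cost change of an intervention relative to baseline
#'
#' @param baseline,intervention Daily (or weekly) diet costs in KES.
#' @return `100 * (intervention - baseline) / baseline`, reported to 0.1;
#'   negative means the intervention made the diet cheaper.
#' @export
percent_reduction <- function(baseline, intervention) {
  if (any(baseline <= 0)) abort("Baseline cost must be > 0.")
  round_half_up(100 * (intervention - baseline) / baseline, 1)
}

#' Is a cost reduction meaningful?
#'
#' A scenario is flagged meaningful when it lowers the diet cost by at
#' least `threshold` percent in *both* seasons; a cost increase never
#' qualifies.
#'
#' @param reduction_plenty,reduction_lean Percentage reductions per season
#'   (negative = cheaper).
#' @param threshold Magnitude threshold in percent, default 25.
#' @return Logical.
#' @export
is_meaningful <- function(reduction_plenty, reduction_lean,
                          threshold = 25) {
  reduction_plenty <= -threshold & reduction_lean <= -threshold
}

#' Average a per-season quantity across the two seasons
#'
#' @param plenty,lean Seasonal values (e.g. percentage reductions).
#' @return Their arithmetic mean.
#' @export
season_average <- function(plenty, lean) (plenty + lean) / 2

#' Seasonal cost increase from plenty to lean season
#'
#' @param plenty_cost,lean_cost Daily diet costs per season, KES.
#' @return `100 * (lean - plenty) / plenty`, reported to 0.1.
#' @export
seasonal_increase <- function(plenty_cost, lean_cost) {
  if (any(plenty_cost <= 0)) abort("Plenty-season cost must be > 0.")
  round_half_up(100 * (lean_cost - plenty_cost) / plenty_cost, 1)
}

#' Run the intervention scenario ladder
#'
#' Solves the baseline diet problem for every (category, season) cell and
#' re-solves with each intervention applied, then summarises seasonal
#' reductions, their across-season average, and the meaningful-reduction
#' flag.
#'
#' @param bundle A [diet_bundle()] of baseline inputs.
#' @param interventions A list of [intervention()] objects, e.g.
#'   [standard_interventions()].
#' @param categories,seasons Cells to solve.
#' @param energy_band,penalty Passed to [build_diet_problem()].
#' @return A `scenario_ladder` object with `$cells` (one row per category
#'   x season x scenario, including baseline) and `$summary` (one row per
#'   category x scenario with both-season reductions and the meaningful
#'   flag).
#' @export
run_ladder <- function(bundle, interventions,
                       categories = diet_categories(),
                       seasons = diet_seasons(),
                       energy_band = c(1, 1.1), penalty = NULL) {
  stopifnot(inherits(bundle, "diet_bundle"))
  solve_cell <- function(b, category, season, scenario) {
    prob <- build_diet_problem(
      b$foods, b$prices, b$portions, b$bounds, b$requirements,
      category, season,
      energy_band = energy_band, penalty = penalty
    )
    sol <- solve_diet(prob)
    if (sol$status == "infeasible_bounds") {
      abort(paste0(
        "Scenario '", scenario, "' (", category, ", ", season,
        ") is infeasible within bounds: ", sol$violated
      ))
    }
    tibble(
      category = category, season = season, scenario = scenario,
      daily_cost = sol$daily_cost, status = sol$status
    )
  }
  grid <- tidyr::expand_grid(category = categories, season = seasons)
  base_cells <- purrr::pmap(
    grid,
    function(category, season) solve_cell(bundle, category, season, "baseline")
  ) |> bind_rows()

  iv_cells <- purrr::map(interventions, function(iv) {
    aug <- apply_intervention(bundle, iv)
    cats <- intersect(categories, iv$applies_to)
    if (length(cats) == 0) return(NULL)
    tidyr::expand_grid(category = cats, season = seasons) |>
      purrr::pmap(function(category, season) {
        solve_cell(aug, category, season, iv$name)
      }) |>
      bind_rows()
  }) |> bind_rows()

  cells <- bind_rows(base_cells, iv_cells) |>
    left_join(
      base_cells |> select("category", "season", baseline_cost = "daily_cost"),
      by = c("category", "season")
    ) |>
    mutate(
      reduction_pct = ifelse(
        .data$scenario == "baseline", 0,
        percent_reduction(.data$baseline_cost, .data$daily_cost)
      )
    )

  summary <- cells |>
    filter(.data$scenario != "baseline") |>
    select("category", "season", "scenario", "reduction_pct") |>
    tidyr::pivot_wider(
      names_from = "season", values_from = "reduction_pct",
      names_prefix = "reduction_"
    ) |>
    mutate(
      avg_reduction_pct = round_half_up(
        season_average(.data$reduction_plenty, .data$reduction_lean), 1
      ),
      meaningful = is_meaningful(
        .data$reduction_plenty, .data$reduction_lean
      )
    )

  structure(
    list(cells = cells, summary = summary),
    class = "scenario_ladder"
  )
}

#' @export
print.scenario_ladder <- function(x, ...) {
  cat(
    "<scenario_ladder> ", length(unique(x$cells$scenario)) - 1,
    " scenarios x ", length(unique(x$cells$category)), " categories x ",
    length(unique(x$cells$season)), " seasons\n",
    sep = ""
  )
  print(x$summary)
  invisible(x)
}

#' @rdname tidy.diet_solution
#' @export
tidy.scenario_ladder <- function(x, ...) x$summary

#' @rdname tidy.diet_solution
#' @export
glance.scenario_ladder <- function(x, ...) {
  tibble(
    n_scenarios = length(unique(x$summary$scenario)),
    n_categories = length(unique(x$cells$category)),
    n_meaningful = sum(x$summary$meaningful),
    best_avg_reduction_pct = min(x$summary$avg_reduction_pct)
  )
}

#' Plot the scenario-ladder reduction matrix
#'
#' @param object A `scenario_ladder`.
#' @param ... Unused.
#' @return A ggplot tile map of season-averaged percentage reductions by
#'   category and scenario; meaningful cells are outlined.
#' @export
autoplot.scenario_ladder <- function(object, ...) {
  ggplot2::ggplot(
    object$summary,
    ggplot2::aes(
      x = .data$scenario, y = .data$category,
      fill = .data$avg_reduction_pct
    )
  ) +
    ggplot2::geom_tile() +
    ggplot2::geom_tile(
      data = object$summary |> filter(.data$meaningful),
      fill = NA, colour = "black", linewidth = 0.8
    ) +
    ggplot2::geom_text(
      ggplot2::aes(label = sprintf("%.1f", .data$avg_reduction_pct)),
      size = 3
    ) +
    ggplot2::scale_fill_gradient2(
      low = "darkgreen", mid = "white", high = "firebrick", midpoint = 0,
      name = "avg % change"
    ) +
    ggplot2::theme(
      axis.text.x = ggplot2::element_text(angle = 45, hjust = 1)
    ) +
    ggplot2::labs(x = NULL, y = NULL)
}
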