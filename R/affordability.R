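# Affordability: annualize the average least-cost diet and compare it to
# wealth-group food budgets. Every household member is assumed to need the
# same average diet cost regardless of age and sex, so the per-person
# comparison (annual cost vs annual income per individual) is exact and
# household-level totals cancel.

#' Average daily cost of the least-cost diet across individuals and seasons
#'
#' @param costs Data frame with columns `category`, `season`,
#'   `daily_cost` covering all six individual categories in both seasons
#'   (12 cells).
#' @return The arithmetic mean daily cost in KES.
#' @export
lacon_daily_cost <- function(costs) {
  req <- c("category", "season", "daily_cost")
  missing_cols <- setdiff(req, names(costs))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "`costs` is missing column(s): ", paste(missing_cols, collapse = ", ")
    ))
  }
  full <- tidyr::expand_grid(
    category = DIET_CATEGORIES, season = DIET_SEASONS
  )
  have <- costs |> distinct(.data$category, .data$season)
  absent <- anti_join(full, have, by = c("category", "season"))
  if (nrow(absent) > 0 || anyNA(costs$daily_cost)) {
    abort(paste0(
      "All 12 (category, season) cells are needed; missing: ",
      paste(absent$category, absent$season, sep = "/", collapse = ", ")
    ))
  }
  mean(costs$daily_cost)
}

#' Annualize a daily diet cost
#'
#' @param daily Daily cost in KES.
#' @param days Days per year (365).
#' @return Annual cost in KES.
#' @export
annualize <- function(daily, days = 365) {
  stopifnot(is.numeric(daily), all(daily >= 0, na.rm = TRUE))
  daily * days
}

#' Can each wealth group afford an annual diet cost?
#'
#' The per-person food budget is annual income per individual times the
#' share of income spent on food; with `use_total_income = TRUE` the
#' entire income is assumed available for food.
#'
#' @param wealth_groups Data frame with columns `wealth_group`,
#'   `annual_income_per_individual` and `pct_income_on_food` (e.g.
#'   [turkana_wealth_groups()]).
#' @param annual_cost Annual diet cost per person, KES.
#' @param use_total_income Budget rule: food-expenditure share (default)
#'   or total income.
#' @return The input tibble with `budget_kes`, `affordable` and
#'   `shortfall_kes` (0 when affordable) columns added.
#' @export
can_afford <- function(wealth_groups, annual_cost,
                       use_total_income = FALSE) {
  stopifnot(annual_cost >= 0)
  req <- c("wealth_group", "annual_income_per_individual",
    "pct_income_on_food")
  missing_cols <- setdiff(req, names(wealth_groups))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "`wealth_groups` is missing column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  if (any(wealth_groups$annual_income_per_individual < 0) ||
      any(wealth_groups$pct_income_on_food < 0) ||
      any(wealth_groups$pct_income_on_food > 100)) {
    abort("Incomes must be >= 0 and food shares within [0, 100].")
  }
  wealth_groups |>
    mutate(
      budget_rule = if (use_total_income) "total_income" else "food_share",
      budget_kes = if (use_total_income) {
        .data$annual_income_per_individual
      } else {
        .data$annual_income_per_individual * .data$pct_income_on_food / 100
      },
      annual_cost_kes = annual_cost,
      affordable = .data$budget_kes >= annual_cost,
      shortfall_kes = pmax(0, annual_cost - .data$budget_kes)
    )
}

#' Affordability of a diet under both budget rules
#'
#' Runs [can_afford()] under the food-expenditure-share rule and the
#' total-income rule and stacks the results.
#'
#' @inheritParams can_afford
#' @return An `affordability` tibble (both rules, all groups).
#' @export
affordability_table <- function(wealth_groups, annual_cost) {
  out <- bind_rows(
    can_afford(wealth_groups, annual_cost, use_total_income = FALSE),
    can_afford(wealth_groups, annual_cost, use_total_income = TRUE)
  )
  class(out) <- c("affordability", class(out))
  out
}

#' Plot wealth-group budgets against an annual diet cost
#'
#' @param object An `affordability` tibble from [affordability_table()].
#' @param ... Unused.
#' @return A ggplot of per-person annual budgets by wealth group and
#'   budget rule, with the annual diet cost as a reference line.
#' @export
autoplot.affordability <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(
      x = .data$wealth_group, y = .data$budget_kes,
      fill = .data$budget_rule
    )
  ) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(
      ggplot2::aes(yintercept = .data$annual_cost_kes),
      linetype = 2
    ) +
    ggplot2::labs(
      x = NULL, y = "Annual KES per person",
      fill = "Budget rule",
      title = "Food budgets vs annual least-cost nutritious diet"
    )
}
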