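# Fixtures are built in code: small fully specified foods tables and a
# random-instance generator for LP/oracle property tests.

# A foods table with all nutrient columns zero except those supplied.
make_foods <- function(ids, category = "market", ...) {
  foods <- tibble::tibble(
    id = ids, name = ids, category = category,
    season_availability = "both"
  )
  for (nm in dietcost::nutrient_names()) foods[[nm]] <- 0
  extra <- list(...)
  for (nm in names(extra)) foods[[nm]] <- extra[[nm]]
  foods
}

single_category_requirements <- function(..., category = "woman_NPNL") {
  vals <- c(...)
  tibble::tibble(
    category = category, nutrient = names(vals), daily_amount = unname(vals)
  )
}

# The hand-solvable two-food energy-only LP: A costs 10 KES/serving,
# B costs 5, both 100 kcal/serving, weekly energy requirement 700 kcal
# with band [1, 1.1].
two_food_problem <- function(max_b = 21, max_a = 21) {
  foods <- make_foods(c("A", "B"), energy = c(100, 100))
  prices <- tibble::tibble(
    food_id = c("A", "B"), season = "plenty", price_per_100g = c(10, 5)
  )
  portions <- tibble::tibble(
    category = "woman_NPNL", food_id = c("A", "B"), grams = 100
  )
  bounds <- tibble::tibble(
    food_id = c("A", "B"), min_per_week = 0, max_per_week = c(max_a, max_b)
  )
  reqs <- single_category_requirements(energy = 100)
  build_diet_problem(
    foods, prices, portions, bounds, reqs, "woman_NPNL", "plenty"
  )
}

# Random small instances for LP-vs-oracle comparisons: integer frequency
# bounds spanning at most 7 servings (unit grid), hard energy floor and
# protein/fat rows, elastic iron and zinc, and an energy ceiling wide
# enough never to bind so that rounding an LP solution up to the grid
# stays feasible (that is what makes the grid-resolution bound valid).
random_oracle_instance <- function(penalty = NULL) {
  n <- sample(2:5, 1)
  foods <- make_foods(
    paste0("f", seq_len(n)),
    energy = runif(n, 50, 400),
    protein = runif(n, 0, 20),
    fat = runif(n, 0, 15),
    iron_absorbed = runif(n, 0, 1.2),
    zinc = runif(n, 0, 4)
  )
  prices <- tibble::tibble(
    food_id = foods$id, season = "plenty",
    price_per_100g = runif(n, 2, 40)
  )
  portions <- tibble::tibble(
    category = "woman_NPNL", food_id = foods$id, grams = 100
  )
  mn <- sample(0:2, n, replace = TRUE)
  bounds <- tibble::tibble(
    food_id = foods$id, min_per_week = mn,
    max_per_week = mn + sample(3:7, n, replace = TRUE)
  )
  reqs <- single_category_requirements(
    energy = runif(1, 50, 150), protein = runif(1, 2, 8),
    fat = runif(1, 1, 5), iron_absorbed = runif(1, 0.2, 1.5),
    zinc = runif(1, 1, 5)
  )
  build_diet_problem(
    foods, prices, portions, bounds, reqs, "woman_NPNL", "plenty",
    energy_band = c(1, 1000), penalty = penalty
  )
}

# Rebuild a diet_problem from modified inputs of an existing fixture.
solve_cost <- function(problem) solve_diet(problem)$weekly_cost
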