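test_that("the two-food energy LP has the hand-derived optimum", {
  p <- two_food_problem()
  s <- solve_diet(p)
  expect_equal(s$status, "optimal")
  expect_equal(s$weekly_cost, 35)
  expect_equal(s$daily_cost, 5)
  expect_equal(
    s$servings$servings_per_week[s$servings$food_id == "B"], 7
  )

  # capping the cheap food forces 4 servings of the expensive one
  p2 <- two_food_problem(max_b = 3)
  s2 <- solve_diet(p2)
  expect_equal(s2$weekly_cost, 55)
  expect_equal(sort(s2$servings$servings_per_week), c(3, 4))
})

test_that("unreachable micronutrients yield optimal_with_deficit, not failure", {
  foods <- make_foods("only", energy = 100, iron_absorbed = 0.05)
  prices <- tibble::tibble(
    food_id = "only", season = "plenty", price_per_100g = 10
  )
  portions <- tibble::tibble(
    category = "woman_NPNL", food_id = "only", grams = 100
  )
  bounds <- tibble::tibble(
    food_id = "only", min_per_week = 0, max_per_week = 21
  )
  reqs <- single_category_requirements(energy = 100, iron_absorbed = 1)
  p <- build_diet_problem(
    foods, prices, portions, bounds, reqs, "woman_NPNL", "plenty"
  )
  s <- solve_diet(p)
  expect_equal(s$status, "optimal_with_deficit")
  adq <- adequacy(s, p)
  expect_lt(adq$adequacy_pct[adq$nutrient == "iron_absorbed"], 100)
  # deficit minimization pushes energy to the top of the band
  expect_equal(
    s$supplied[["energy"]], 1.1 * 700,
    tolerance = 1e-8
  )
})

test_that("adequacy is supply over weekly requirement, uncapped", {
  foods <- make_foods("f", energy = 100, zinc = 1, iron_absorbed = 0.3)
  prices <- tibble::tibble(
    food_id = "f", season = "plenty", price_per_100g = 10
  )
  portions <- tibble::tibble(
    category = "woman_NPNL", food_id = "f", grams = 100
  )
  bounds <- tibble::tibble(food_id = "f", min_per_week = 7, max_per_week = 7)
  # 7 servings supply 7 zinc and 2.1 iron weekly
  reqs <- single_category_requirements(
    energy = 100, zinc = 1, iron_absorbed = 0.0625 # weekly: 7 and 0.4375
  )
  p <- build_diet_problem(
    foods, prices, portions, bounds, reqs, "woman_NPNL", "plenty"
  )
  s <- solve_diet(p)
  adq <- adequacy(s, p)
  expect_equal(adq$adequacy_pct[adq$nutrient == "zinc"], 100)
  expect_equal(
    adq$adequacy_pct[adq$nutrient == "iron_absorbed"], 480,
    tolerance = 1e-9
  ) # uncapped oversupply
  expect_equal(adq$adequacy_pct[adq$nutrient == "energy"], 100)

  # a supply of 0.48x requirement reads as 48%
  reqs2 <- single_category_requirements(energy = 100, zinc = 1 / 0.48)
  p2 <- build_diet_problem(
    foods, prices, portions, bounds, reqs2, "woman_NPNL", "plenty"
  )
  s2 <- solve_diet(p2)
  adq2 <- adequacy(s2, p2)
  expect_equal(adq2$adequacy_pct[adq2$nutrient == "zinc"], 48)
})

test_that("infeasible frequency bounds are reported with the violated row", {
  # forced minimums blow through the energy ceiling
  foods <- make_foods(c("A", "B"), energy = c(500, 500))
  prices <- tibble::tibble(
    food_id = c("A", "B"), season = "plenty", price_per_100g = 10
  )
  portions <- tibble::tibble(
    category = "woman_NPNL", food_id = c("A", "B"), grams = 100
  )
  bounds <- tibble::tibble(
    food_id = c("A", "B"), min_per_week = 5, max_per_week = 10
  )
  reqs <- single_category_requirements(energy = 100) # weekly ceiling 770
  p <- build_diet_problem(
    foods, prices, portions, bounds, reqs, "woman_NPNL", "plenty"
  )
  s <- solve_diet(p)
  expect_equal(s$status, "infeasible_bounds")
  expect_equal(s$violated, "energy_upper")
  expect_error(adequacy(s, p), "infeasible")

  # max bounds too small to reach the energy floor
  bounds2 <- tibble::tibble(
    food_id = c("A", "B"), min_per_week = 0, max_per_week = 0.5
  )
  p2 <- build_diet_problem(
    foods, prices, portions, bounds2, reqs, "woman_NPNL", "plenty"
  )
  expect_equal(solve_diet(p2)$status, "infeasible_bounds")
  expect_equal(solve_diet(p2)$violated, "energy_lower")
})

test_that("missing price, portion or bound is a descriptive error", {
  foods <- make_foods("A", energy = 100)
  prices <- tibble::tibble(
    food_id = "A", season = "plenty", price_per_100g = 10
  )
  portions <- tibble::tibble(category = "woman_NPNL", food_id = "A", grams = 100)
  bounds <- tibble::tibble(food_id = "A", min_per_week = 0, max_per_week = 21)
  reqs <- single_category_requirements(energy = 100)
  expect_error(
    build_diet_problem(
      foods, prices[0, ], portions, bounds, reqs, "woman_NPNL", "plenty"
    ),
    "price.*A"
  )
  expect_error(
    build_diet_problem(
      foods, prices, portions[0, ], bounds, reqs, "woman_NPNL", "plenty"
    ),
    "portion"
  )
  expect_error(
    build_diet_problem(
      foods, prices, portions, bounds[0, ], reqs, "woman_NPNL", "plenty"
    ),
    "bound"
  )
})

test_that("uniform price scaling scales cost exactly and keeps the diet", {
  set.seed(21)
  for (i in 1:10) {
    p <- random_oracle_instance()
    s <- solve_diet(p)
    if (s$status == "infeasible_bounds") next
    k <- runif(1, 0.3, 4)
    p_scaled <- p
    p_scaled$cost <- p$cost * k
    p_scaled$penalty <- p$penalty * k
    s_scaled <- solve_diet(p_scaled)
    expect_equal(s_scaled$weekly_cost, k * s$weekly_cost,
      tolerance = 1e-8
    )
    expect_equal(
      s_scaled$servings$servings_per_week, s$servings$servings_per_week,
      tolerance = 1e-6
    )
  }
})

test_that("adding a free-to-skip food never raises the optimum", {
  set.seed(33)
  penalty <- 1e8
  for (i in 1:12) {
    p <- random_oracle_instance(penalty = penalty)
    s <- solve_diet(p)
    if (s$status == "infeasible_bounds") next
    # re-solve with one extra zero-minimum food
    extra <- make_foods("extra",
      energy = runif(1, 50, 400), protein = runif(1, 0, 20),
      iron_absorbed = runif(1, 0, 1.2), zinc = runif(1, 0, 4)
    )
    foods2 <- dplyr::bind_rows(
      make_foods(p$foods$id,
        energy = p$A[, "energy"], protein = p$A[, "protein"],
        fat = p$A[, "fat"], iron_absorbed = p$A[, "iron_absorbed"],
        zinc = p$A[, "zinc"]
      ),
      extra
    )
    prices2 <- tibble::tibble(
      food_id = foods2$id, season = "plenty",
      price_per_100g = c(p$foods$price_per_100g, runif(1, 2, 40))
    )
    portions2 <- tibble::tibble(
      category = "woman_NPNL", food_id = foods2$id, grams = 100
    )
    bounds2 <- tibble::tibble(
      food_id = foods2$id,
      min_per_week = c(p$min, 0), max_per_week = c(p$max, 7)
    )
    reqs <- tibble::tibble(
      category = "woman_NPNL",
      nutrient = names(p$req_daily)[!is.na(p$req_daily)],
      daily_amount = p$req_daily[!is.na(p$req_daily)]
    )
    p2 <- build_diet_problem(
      foods2, prices2, portions2, bounds2, reqs, "woman_NPNL", "plenty",
      energy_band = p$energy_band, penalty = penalty
    )
    s2 <- solve_diet(p2)
    expect_lte(s2$objective, s$objective + 1e-6 * abs(s$objective))
  }
})

test_that("tightening frequency bounds never lowers the optimal objective", {
  set.seed(44)
  penalty <- 1e8
  for (i in 1:10) {
    p <- random_oracle_instance(penalty = penalty)
    s <- solve_diet(p)
    if (s$status == "infeasible_bounds") next
    tight <- p
    j <- sample(nrow(p$foods), 1)
    tight$max <- p$max
    tight$max[j] <- max(p$min[j], p$max[j] - 2)
    s_tight <- solve_diet(tight)
    if (s_tight$status == "infeasible_bounds") next
    expect_gte(s_tight$objective, s$objective - 1e-6 * abs(s$objective))
  }
})

test_that("tidy and glance summarise solutions", {
  p <- two_food_problem()
  s <- solve_diet(p)
  td <- tidy(s)
  expect_named(
    td,
    c("food_id", "name", "food_category", "servings_per_week",
      "grams_per_week", "cost_kes")
  )
  expect_equal(sum(td$cost_kes), s$weekly_cost)
  g <- glance(s)
  expect_equal(g$status, "optimal")
  expect_equal(g$n_foods_used, 1)
  expect_s3_class(autoplot(s, p), "ggplot")
})
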