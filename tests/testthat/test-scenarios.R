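test_that("reduction, meaningfulness and seasonal arithmetic are exact", {
  expect_equal(percent_reduction(100, 75), -25)
  expect_equal(percent_reduction(100, 100), 0)
  expect_equal(percent_reduction(50.0, 14.3), -71.4)
  expect_error(percent_reduction(0, 10), "> 0")

  expect_true(is_meaningful(-30, -27))
  expect_false(is_meaningful(-30, -20))
  expect_true(is_meaningful(-71.4, -71.4))
  expect_true(is_meaningful(-25, -25))
  expect_false(is_meaningful(25, 30)) # a cost increase never qualifies

  expect_equal(season_average(-20, -30), -25)
  expect_equal(season_average(-70.3, -70.3), -70.3)

  expect_equal(seasonal_increase(50.0, 59.4), 18.8)
  expect_equal(seasonal_increase(101.5, 119.0), 17.2)
  expect_equal(seasonal_increase(100, 100), 0)
})

test_that("the engineered vegetable scenario recovers its configured reduction", {
  cfg <- synthetic_config(seed = 3, gap_severity = 0.4)
  inst <- engineered_gap_instance(cfg, reduction_pct = -45)
  ladder <- run_ladder(inst$bundle, list(inst$vegetable))
  expect_equal(nrow(ladder$summary), 6) # one scenario x six categories
  expect_true(all(abs(ladder$summary$avg_reduction_pct + 45) <= 0.1))
  expect_true(all(ladder$summary$meaningful))
  # costs match the closed-form optima
  cells <- ladder$cells |> dplyr::filter(scenario == "baseline")
  truth <- dplyr::left_join(
    cells, inst$truth,
    by = c("category", "season")
  )
  expect_equal(truth$daily_cost, truth$baseline_daily_cost,
    tolerance = 1e-8
  )
})

test_that("zero-price supplement scenarios never increase cost", {
  cfg <- synthetic_config(seed = 9, gap_severity = 0.3)
  inst <- engineered_gap_instance(cfg, reduction_pct = -30)
  mnp <- mnp_food_item()
  iv <- intervention(
    "mnp", mnp,
    bounds = mnp_bounds(mnp),
    applies_to = c("child_6_8m", "child_9_11m", "child_12_23m")
  )
  ladder <- run_ladder(
    inst$bundle, list(iv),
    categories = c("child_6_8m", "child_12_23m")
  )
  expect_true(all(ladder$summary$reduction_plenty <= 1e-9))
  expect_true(all(ladder$summary$reduction_lean <= 1e-9))
})

test_that("a forced expensive food increases cost (positive 'reduction')", {
  cfg <- synthetic_config(seed = 13, gap_severity = 0.35)
  inst <- engineered_gap_instance(
    cfg, reduction_pct = -40, forced_fruit = TRUE, fruit_price = 60
  )
  ladder <- run_ladder(inst$bundle, list(inst$fruit))
  expect_true(all(ladder$summary$reduction_plenty > 0))
  expect_true(all(ladder$summary$reduction_lean > 0))
  expect_false(any(ladder$summary$meaningful))
  # the increase is exactly the forced serving's price
  cells <- ladder$cells |>
    dplyr::filter(scenario == "forced_luxury_fruit") |>
    dplyr::left_join(inst$truth, by = c("category", "season"))
  expect_equal(cells$daily_cost, cells$fruit_daily_cost, tolerance = 1e-8)
})

test_that("the union of free-entry scenarios is at least as cheap as each part", {
  cfg <- synthetic_config(seed = 17, gap_severity = 0.35)
  inst <- engineered_gap_instance(cfg, reduction_pct = -35)
  veg <- inst$vegetable
  # a second, less attractive free-entry vegetable
  veg2 <- veg
  veg2$name <- "veg2"
  veg2$foods$id <- "wild_veg2"
  veg2$foods$name <- "wild_veg2"
  veg2$prices$food_id <- "wild_veg2"
  veg2$prices$price_per_100g <- veg2$prices$price_per_100g * 1.2
  veg2$bounds$food_id <- "wild_veg2"
  veg2$portions$food_id <- "wild_veg2"
  union_iv <- intervention(
    "union", dplyr::bind_rows(veg$foods, veg2$foods),
    prices = dplyr::bind_rows(veg$prices, veg2$prices),
    bounds = dplyr::bind_rows(veg$bounds, veg2$bounds),
    portions = dplyr::bind_rows(veg$portions, veg2$portions)
  )
  ladder <- run_ladder(
    inst$bundle, list(veg, veg2, union_iv),
    categories = "woman_NPNL"
  )
  cost_of <- function(sc, ss) {
    ladder$cells$daily_cost[
      ladder$cells$scenario == sc & ladder$cells$season == ss
    ]
  }
  for (ss in diet_seasons()) {
    expect_lte(
      cost_of("union", ss),
      min(cost_of("synthetic_wild_vegetable", ss), cost_of("veg2", ss)) + 1e-8
    )
  }
})

test_that("MNP plus wild foods equals wild foods alone when MNP changes nothing", {
  cfg <- synthetic_config(seed = 23, gap_severity = 0.35)
  inst <- engineered_gap_instance(cfg, reduction_pct = -40)
  veg <- inst$vegetable
  mnp <- mnp_food_item()
  mnp_iv <- intervention("mnp", mnp, bounds = mnp_bounds(mnp))
  both <- intervention(
    "mnp_plus_veg", dplyr::bind_rows(mnp, veg$foods),
    prices = veg$prices,
    bounds = dplyr::bind_rows(mnp_bounds(mnp), veg$bounds),
    portions = dplyr::bind_rows(
      tibble::tibble(
        category = diet_categories(), food_id = "mnp", grams = 1
      ),
      veg$portions
    )
  )
  # for this category the sachet's absorbed-iron content cannot close the
  # engineered iron gap, so MNP leaves both deficit pressure and cost alone
  ladder <- run_ladder(
    inst$bundle, list(veg, mnp_iv, both),
    categories = "woman_NPNL"
  )
  red <- function(sc) {
    ladder$summary$avg_reduction_pct[ladder$summary$scenario == sc]
  }
  expect_equal(red("mnp"), 0)
  expect_equal(red("mnp_plus_veg"), red("synthetic_wild_vegetable"))
})

test_that("the standard intervention ladder has the published shape", {
  ivs <- standard_interventions()
  expect_length(ivs, 11)
  children <- c("child_6_8m", "child_9_11m", "child_12_23m")
  expect_equal(ivs$mnp$applies_to, children)
  expect_equal(ivs$mnp_plus_all_wild$applies_to, children)
  expect_setequal(
    ivs$all_wild_vegetables$foods$id,
    c("amaranthus_hybridus", "celosia_argentea", "solanum_americanum")
  )
  # wild foods priced at their opportunity costs with bounds 1-3
  expect_true(all(ivs$all_wild_plant_foods$bounds$min_per_week == 1))
  expect_true(all(ivs$all_wild_plant_foods$bounds$max_per_week == 3))
  daily <- standard_interventions(mnp_daily = TRUE)
  expect_equal(daily$mnp$bounds$min_per_week, 7)
})
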