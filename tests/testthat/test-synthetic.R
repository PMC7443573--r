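test_that("market generation is deterministic under a fixed seed", {
  cfg <- synthetic_config(seed = 101)
  m1 <- generate_market(cfg)
  m2 <- generate_market(cfg)
  expect_identical(m1, m2)
  r1 <- generate_recall(cfg, m1$foods)
  r2 <- generate_recall(cfg, m1$foods)
  expect_identical(r1, r2)
  m3 <- generate_market(synthetic_config(seed = 102))
  expect_false(identical(m1$observations$price_kes,
    m3$observations$price_kes))
})

test_that("with noise off every lean price is exactly inflation times plenty", {
  cfg <- synthetic_config(seed = 7, lean_inflation = 1.2, price_noise_sd = 0)
  m <- generate_market(cfg)
  wide <- m$observations |>
    tidyr::pivot_wider(names_from = "season", values_from = "price_kes")
  expect_equal(wide$lean, 1.2 * wide$plenty, tolerance = 1e-12)
})

test_that("lean-season inflation raises the optimal diet cost", {
  cfg <- synthetic_config(seed = 31, lean_inflation = 1.3)
  m <- generate_market(cfg)
  prices <- aggregate_prices(m$observations)
  bounds <- tibble::tibble(
    food_id = m$foods$id, min_per_week = 0, max_per_week = 14
  )
  bundle <- diet_bundle(
    m$foods, prices, default_portions(m$foods), bounds,
    default_requirements()
  )
  for (cat in c("child_12_23m", "woman_NPNL")) {
    costs <- vapply(diet_seasons(), function(ss) {
      p <- build_diet_problem(
        bundle$foods, bundle$prices, bundle$portions, bundle$bounds,
        bundle$requirements, cat, ss,
        penalty = 1e7
      )
      solve_diet(p)$weekly_cost
    }, numeric(1))
    expect_gt(costs[["lean"]], costs[["plenty"]])
  }
})

test_that("recall counts yield valid bounds and exclude nothing structurally", {
  cfg <- synthetic_config(seed = 5, n_households = 60)
  m <- generate_market(cfg)
  recall <- generate_recall(cfg, m$foods)
  expect_equal(nrow(recall), 60 * cfg$n_foods)
  expect_true(all(recall$count_per_week >= 0 & recall$count_per_week <= 21))
  b <- bounds_from_recall(recall)
  expect_true(all(b$min_per_week <= b$max_per_week))

  all_zero <- recall |> dplyr::mutate(count_per_week = 0)
  bz <- bounds_from_recall(all_zero)
  expect_true(all(bz$min_per_week == 0 & bz$max_per_week == 0))
  const <- recall |> dplyr::mutate(count_per_week = 2)
  bc <- bounds_from_recall(const)
  expect_true(all(bc$min_per_week == 2 & bc$max_per_week == 2))
})

test_that("engineered instances carry exact ground truth across severities", {
  # degenerate severity: baseline already adequate, reduction still exact
  cfg0 <- synthetic_config(seed = 19, gap_severity = 0)
  inst0 <- engineered_gap_instance(cfg0, reduction_pct = -20)
  lad0 <- run_ladder(inst0$bundle, list(inst0$vegetable))
  expect_true(all(abs(lad0$summary$avg_reduction_pct + 20) <= 0.1))
  p0 <- build_diet_problem(
    inst0$bundle$foods, inst0$bundle$prices, inst0$bundle$portions,
    inst0$bundle$bounds, inst0$bundle$requirements, "child_6_8m", "plenty"
  )
  s0 <- solve_diet(p0)
  expect_equal(s0$status, "optimal")

  cfg <- synthetic_config(seed = 19, gap_severity = 0.5)
  inst <- engineered_gap_instance(cfg, reduction_pct = -60)
  p <- build_diet_problem(
    inst$bundle$foods, inst$bundle$prices, inst$bundle$portions,
    inst$bundle$bounds, inst$bundle$requirements, "woman_pregnant", "lean"
  )
  s <- solve_diet(p)
  expect_equal(s$status, "optimal_with_deficit")
  adq <- adequacy(s, p)
  gap_adq <- adq$adequacy_pct[adq$nutrient %in% cfg$gap_nutrients]
  expect_equal(gap_adq, c(50, 50), tolerance = 1e-6)

  # construction refuses reductions the energy band cannot realise
  expect_error(
    engineered_gap_instance(cfg, reduction_pct = -5),
    "impossible"
  )
  expect_error(
    engineered_gap_instance(cfg, reduction_pct = 10),
    "impossible"
  )
})
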