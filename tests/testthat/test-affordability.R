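test_that("the average least-cost diet over 12 cells matches hand arithmetic", {
  costs <- turkana_diet_costs() |>
    dplyr::select(category, plenty = cost_plenty, lean = cost_lean) |>
    tidyr::pivot_longer(
      c("plenty", "lean"),
      names_to = "season", values_to = "daily_cost"
    )
  expect_equal(round(lacon_daily_cost(costs), 1), 157.1)
  expect_equal(lacon_daily_cost(costs |> dplyr::mutate(daily_cost = 42)), 42)
  expect_error(lacon_daily_cost(costs[-1, ]), "12")
})

test_that("annualization uses a 365-day year", {
  expect_equal(annualize(0), 0)
  expect_equal(annualize(1), 365)
  expect_equal(round(annualize(85.74)), 31295)
})

test_that("affordability compares budgets with the annual cost", {
  vp <- tibble::tibble(
    wealth_group = "very_poor", household_size = 7,
    annual_income_per_individual = 11786, pct_income_on_food = 68
  )
  out <- can_afford(vp, 31295)
  expect_false(out$affordable)
  expect_equal(out$budget_kes, 8014.48)
  expect_equal(round(out$shortfall_kes), 23281)

  mid <- tibble::tibble(
    wealth_group = "middle", household_size = 8,
    annual_income_per_individual = 21875, pct_income_on_food = 50
  )
  out2 <- can_afford(mid, 31295, use_total_income = TRUE)
  expect_false(out2$affordable)

  rich <- tibble::tibble(
    wealth_group = "g", household_size = 1,
    annual_income_per_individual = 40000, pct_income_on_food = 100
  )
  out3 <- can_afford(rich, 31295)
  expect_true(out3$affordable)
  expect_equal(out3$shortfall_kes, 0)
})

test_that("affordability is monotone in income and share, antitone in cost", {
  base <- tibble::tibble(
    wealth_group = "g", household_size = 5,
    annual_income_per_individual = 20000, pct_income_on_food = 50
  )
  sf <- function(income = 20000, pct = 50, cost = 31295) {
    can_afford(
      base |> dplyr::mutate(
        annual_income_per_individual = income, pct_income_on_food = pct
      ),
      cost
    )$shortfall_kes
  }
  expect_gte(sf(income = 15000), sf(income = 25000))
  expect_gte(sf(pct = 40), sf(pct = 60))
  expect_lte(sf(cost = 20000), sf(cost = 40000))
})

test_that("wealth-group table summarises as published", {
  wg <- turkana_wealth_groups()
  expect_equal(nrow(wg), 4)
  expect_equal(round(mean(wg$annual_income_per_individual)), 17275)
  expect_equal(mean(wg$pct_income_on_food) , 52.75)
})

test_that("affordability_table stacks both budget rules and plots", {
  out <- affordability_table(turkana_wealth_groups(), 31295)
  expect_equal(nrow(out), 8)
  expect_setequal(unique(out$budget_rule), c("food_share", "total_income"))
  expect_s3_class(autoplot(out), "ggplot")
})
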