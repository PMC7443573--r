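# Synthetic data: a two-season, multi-village market survey, 24-h recall
# counts, and an analytically constructed "engineered gap" instance whose
# LP optima are known in closed form. All draws are governed by the single
# integer seed in the config; a fixed seed gives byte-identical outputs.

#' Configuration for the synthetic data generators
#'
#' @param seed Integer seed governing every random draw.
#' @param n_foods Number of market foods.
#' @param n_villages,n_traders Villages surveyed and traders per village.
#' @param lean_inflation Multiplicative lean-season price factor (> 1).
#' @param price_noise_sd Log-scale SD of observation-level price noise;
#'   0 switches noise off.
#' @param n_households Households in the 24-h recall.
#' @param zero_inflation Probability a household never eats a food.
#' @param mean_count Mean weekly consumption count when a food is eaten.
#' @param gap_nutrients Nutrients engineered to be under-supplied at
#'   baseline.
#' @param gap_severity Fraction of the requirement unreachable at baseline
#'   (0 = baseline already adequate), in `[0, 1)`.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1L, n_foods = 12, n_villages = 6,
                             n_traders = 4, lean_inflation = 1.25,
                             price_noise_sd = 0.05, n_households = 180,
                             zero_inflation = 0.3, mean_count = 3,
                             gap_nutrients = c("iron_absorbed", "zinc"),
                             gap_severity = 0.35) {
  stopifnot(
    lean_inflation > 1, n_foods >= 3, n_villages >= 1, n_traders >= 1,
    price_noise_sd >= 0, zero_inflation >= 0, zero_inflation <= 1,
    mean_count > 0, gap_severity >= 0, gap_severity < 1,
    all(gap_nutrients %in% micro_nutrients())
  )
  structure(
    list(
      seed = as.integer(seed), n_foods = n_foods, n_villages = n_villages,
      n_traders = n_traders, lean_inflation = lean_inflation,
      price_noise_sd = price_noise_sd, n_households = n_households,
      zero_inflation = zero_inflation, mean_count = mean_count,
      gap_nutrients = gap_nutrients, gap_severity = gap_severity
    ),
    class = "synthetic_config"
  )
}

# Per-100-g archetype compositions (absorbed units for Ca/Fe) and typical
# unit prices; market foods cycle through these with lognormal variation.
MARKET_ARCHETYPES <- tibble::tribble(
  ~archetype, ~price_100g, ~energy, ~protein, ~fat, ~calcium_absorbed,
  ~iron_absorbed, ~zinc, ~magnesium, ~vitamin_c, ~retinol_equivalent,
  ~folate, ~thiamine, ~riboflavin, ~niacin, ~vitamin_b6, ~vitamin_b12,
  ~vitamin_d, ~vitamin_e, ~copper, ~selenium,
  "staple_grain", 5, 360, 8, 2, 10, 0.15, 1.8, 120, 0, 0,
  25, 0.3, 0.1, 3.5, 0.3, 0, 0, 0.5, 0.3, 10,
  "legume", 9, 340, 22, 2, 50, 0.3, 3.0, 150, 1, 1,
  400, 0.5, 0.2, 2.0, 0.4, 0, 0, 0.8, 0.8, 8,
  "oil", 18, 880, 0, 100, 0, 0, 0, 0, 0, 600,
  0, 0, 0, 0, 0, 0, 0, 14, 0, 0,
  "vegetable", 8, 40, 3, 0.4, 60, 0.2, 0.6, 40, 30, 300,
  60, 0.08, 0.1, 0.7, 0.15, 0, 0, 0.8, 0.1, 1,
  "milk", 10, 65, 3.3, 3.7, 55, 0.003, 0.4, 10, 1, 45,
  5, 0.04, 0.18, 0.1, 0.04, 0.45, 0.1, 0.08, 0.01, 2,
  "meat", 40, 150, 20, 8, 5, 0.5, 4.0, 20, 0, 10,
  5, 0.08, 0.2, 5.0, 0.4, 2.0, 0.2, 0.4, 0.1, 15,
  "fish", 35, 120, 20, 5, 20, 0.25, 1.0, 30, 0, 15,
  10, 0.05, 0.1, 3.0, 0.3, 3.0, 5, 0.6, 0.1, 30
)

#' Generate a synthetic two-season market survey
#'
#' Market foods are drawn around realistic food-group archetypes; each
#' (food, village, trader) has one weighed price observation per season,
#' with the lean-season price equal to the plenty price times
#' `lean_inflation` times observation noise. Iron and zinc contents are
#' scaled down by `gap_severity` so baseline diets carry the configured
#' micronutrient gap pattern.
#'
#' @param config A [synthetic_config()].
#' @return A list with `foods` (foods table) and `observations` (market
#'   price observations for [aggregate_prices()]).
#' @export
generate_market <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  arch <- MARKET_ARCHETYPES[
    rep_len(seq_len(nrow(MARKET_ARCHETYPES)), config$n_foods),
  ]
  noise <- matrix(
    exp(stats::rnorm(config$n_foods * length(nutrient_names()), 0, 0.2)),
    nrow = config$n_foods
  )
  comp <- as.matrix(arch[nutrient_names()]) * noise
  comp[, config$gap_nutrients] <-
    comp[, config$gap_nutrients] * (1 - config$gap_severity)
  foods <- tibble(
    id = sprintf("food%02d", seq_len(config$n_foods)),
    name = paste0(arch$archetype, " ", seq_len(config$n_foods)),
    category = "market",
    season_availability = "both"
  )
  foods <- bind_cols(foods, as_tibble(comp))
  foods <- validate_foods(foods)

  unit_price <- arch$price_100g * exp(stats::rnorm(config$n_foods, 0, 0.3))
  grid <- tidyr::expand_grid(
    food_idx = seq_len(config$n_foods),
    village = sprintf("village%d", seq_len(config$n_villages)),
    trader = seq_len(config$n_traders)
  )
  grid$weight_g <- round(stats::runif(nrow(grid), 80, 500))
  obs_noise <- function() {
    exp(stats::rnorm(nrow(grid), 0, config$price_noise_sd))
  }
  plenty_price <- unit_price[grid$food_idx] * grid$weight_g / 100 *
    obs_noise()
  lean_price <- plenty_price * config$lean_inflation * obs_noise()
  observations <- bind_rows(
    grid |> mutate(season = "plenty", price_kes = plenty_price),
    grid |> mutate(season = "lean", price_kes = lean_price)
  ) |>
    mutate(food_id = foods$id[.data$food_idx]) |>
    select("food_id", "village", "trader", "season", "price_kes", "weight_g")

  list(foods = foods, observations = observations)
}

#' Generate synthetic 24-h recall consumption counts
#'
#' Weekly consumption counts per household and market food from a
#' zero-inflated Poisson; wild foods and fruits do not appear (baseline
#' diets record no wild-food or fruit intake).
#'
#' @param config A [synthetic_config()].
#' @param foods A foods table; only `category == "market"` foods receive
#'   counts.
#' @return A tibble `household_id`, `food_id`, `count_per_week`.
#' @export
generate_recall <- function(config, foods) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed + 1L)
  market <- foods |> filter(.data$category == "market")
  grid <- tidyr::expand_grid(
    household_id = sprintf("hh%03d", seq_len(config$n_households)),
    food_id = market$id
  )
  eats <- stats::runif(nrow(grid)) >= config$zero_inflation
  counts <- ifelse(eats, stats::rpois(nrow(grid), config$mean_count), 0)
  grid |> mutate(count_per_week = pmin(counts, 21))
}

#' Engineered diet instance with analytically known optima
#'
#' Constructs a baseline food set whose least-cost diet provably leaves
#' the gap nutrients at `(1 - gap_severity)` of requirement, plus a cheap
#' nutrient-dense synthetic wild vegetable whose inclusion closes the gap
#' and changes the optimal cost by exactly `reduction_pct` percent in both
#' seasons, for every individual category. The construction uses a
#' proportional requirement profile (nutrient density per kcal taken from
#' the default non-pregnant/non-lactating woman profile, scaled by each
#' category's energy requirement), a single energy-dense staple, and a
#' vegetable priced so the all-vegetable diet at the energy floor is the
#' unique optimum. The closed-form optima of both LPs are returned in
#' `$truth`.
#'
#' @param config A [synthetic_config()]; `gap_severity` and
#'   `lean_inflation` shape the instance.
#' @param reduction_pct Configured percentage cost change of the vegetable
#'   intervention; must be below about -9.1% (the energy-band width) when
#'   `gap_severity > 0`, and at most 0 when `gap_severity == 0`, otherwise
#'   the construction is impossible and an error is raised.
#' @param forced_fruit Also include a "luxury fruit" intervention food
#'   with a forced minimum of one costly serving per week and no nutrient
#'   content, whose addition must *increase* cost.
#' @param fruit_price Price per serving of the forced fruit, KES.
#' @return A list with the baseline `bundle` ([diet_bundle()]), the
#'   `vegetable` and (optionally) `fruit` [intervention()]s, and `truth`
#'   (per category and season: both optimal daily costs, the reduction,
#'   and gap-nutrient adequacy before/after).
#' @export
engineered_gap_instance <- function(config, reduction_pct = -40,
                                    forced_fruit = FALSE,
                                    fruit_price = 50) {
  stopifnot(inherits(config, "synthetic_config"))
  sev <- config$gap_severity
  band <- c(1, 1.1)
  band_factor <- if (sev > 0) band[2] else 1
  if ((1 + reduction_pct / 100) * band_factor > 1 ||
      ((1 + reduction_pct / 100) * band_factor == 1 && sev > 0)) {
    abort(paste0(
      "Construction impossible: reduction_pct = ", reduction_pct,
      " with gap_severity = ", sev,
      " (the vegetable would not be the cheapest energy source)."
    ))
  }
  set.seed(config$seed + 2L)

  defaults <- default_requirements()
  npnl <- requirements_for(defaults, "woman_NPNL")
  density <- npnl / npnl[["energy"]] # per-kcal profile
  energy_daily <- vapply(
    DIET_CATEGORIES,
    function(cc) requirements_for(defaults, cc)[["energy"]],
    numeric(1)
  )
  requirements <- purrr::map(DIET_CATEGORIES, function(cc) {
    tibble(
      category = cc, nutrient = nutrient_names(),
      daily_amount = unname(density[nutrient_names()] * energy_daily[[cc]])
    )
  }) |> bind_rows()

  e_serv <- 1000 # kcal per serving; portion 250 g of a dense staple
  portion_g <- 250
  margin <- stats::runif(1, 1.2, 1.5)
  gap <- config$gap_nutrients
  non_gap <- setdiff(micro_nutrients(), gap)

  per_serving <- function(gap_scale) {
    v <- rlang::set_names(
      numeric(length(nutrient_names())), nutrient_names()
    )
    v[["energy"]] <- e_serv
    v[c("protein", "fat")] <- margin * density[c("protein", "fat")] * e_serv
    v[non_gap] <- margin * density[non_gap] * e_serv
    v[gap] <- gap_scale * density[gap] * e_serv
    v
  }
  staple_gap_scale <- if (sev > 0) (1 - sev) / band[2] else 1.05
  make_food <- function(id, name, category, serving, grams) {
    row <- tibble(
      id = id, name = name, category = category,
      season_availability = "both"
    )
    for (nm in nutrient_names()) row[[nm]] <- serving[[nm]] * 100 / grams
    row
  }
  staple <- make_food(
    "staple", "Engineered staple", "market",
    per_serving(staple_gap_scale), portion_g
  )
  veg <- make_food(
    "wild_veg", "Synthetic wild vegetable", "wild_vegetable",
    per_serving(margin), portion_g
  )

  c0 <- stats::runif(1, 8, 15) # staple KES per serving, plenty season
  cv <- (1 + reduction_pct / 100) * band_factor * c0
  price_tbl <- function(food_id, per_serving_price, grams) {
    tibble(
      food_id = food_id, season = DIET_SEASONS,
      price_per_100g = per_serving_price * 100 / grams *
        c(1, config$lean_inflation)
    )
  }
  prices <- price_tbl("staple", c0, portion_g)
  veg_prices <- price_tbl("wild_veg", cv, portion_g)

  all_foods <- bind_rows(staple, veg)
  portions <- tidyr::expand_grid(
    category = DIET_CATEGORIES,
    food_id = c("staple", "wild_veg")
  ) |> mutate(grams = portion_g)

  bundle <- diet_bundle(
    foods = staple, prices = prices,
    portions = portions |> filter(.data$food_id == "staple"),
    bounds = tibble(food_id = "staple", min_per_week = 0, max_per_week = 21),
    requirements = requirements
  )
  veg_iv <- intervention(
    "synthetic_wild_vegetable", veg,
    prices = veg_prices,
    bounds = tibble(
      food_id = "wild_veg", min_per_week = 0, max_per_week = 21
    ),
    portions = portions |> filter(.data$food_id == "wild_veg")
  )

  fruit_iv <- NULL
  if (forced_fruit) {
    fruit_serving <- rlang::set_names(
      numeric(length(nutrient_names())), nutrient_names()
    )
    fruit <- make_food(
      "luxury_fruit", "Forced luxury fruit", "wild_fruit",
      fruit_serving, 100
    )
    fruit_iv <- intervention(
      "forced_luxury_fruit", fruit,
      prices = price_tbl("luxury_fruit", fruit_price, 100),
      bounds = tibble(
        food_id = "luxury_fruit", min_per_week = 1, max_per_week = 1
      ),
      portions = tibble(
        category = DIET_CATEGORIES, food_id = "luxury_fruit", grams = 100
      )
    )
  }

  truth <- tidyr::expand_grid(
    category = DIET_CATEGORIES, season = DIET_SEASONS
  ) |>
    mutate(
      season_factor = ifelse(.data$season == "lean", config$lean_inflation, 1),
      baseline_weekly_cost = c0 * band_factor *
        7 * unname(energy_daily[.data$category]) / e_serv *
        .data$season_factor,
      vegetable_weekly_cost = (1 + reduction_pct / 100) *
        .data$baseline_weekly_cost,
      baseline_daily_cost = .data$baseline_weekly_cost / 7,
      vegetable_daily_cost = .data$vegetable_weekly_cost / 7,
      reduction_pct = reduction_pct,
      fruit_daily_cost = if (forced_fruit) {
        .data$baseline_daily_cost + fruit_price * .data$season_factor / 7
      } else {
        NA_real_
      },
      gap_adequacy_baseline_pct = (1 - sev) * 100 *
        (if (sev > 0) 1 else 1.05),
      gap_adequacy_vegetable_pct = margin * 100
    ) |>
    select(-"season_factor")

  list(
    bundle = bundle, vegetable = veg_iv, fruit = fruit_iv,
    truth = truth, config = config,
    params = list(
      e_serv = e_serv, c0 = c0, cv = cv, margin = margin,
      band = band, reduction_pct = reduction_pct
    )
  )
}
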