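#' Aggregate market price observations to seasonal prices per 100 g
#'
#' Each observation records the price paid and the edible-portion weight of
#' one weighed sample from one trader. Prices are converted to KES per
#' 100 g and averaged within each (food, season) group — the simple
#' (unweighted) mean over all traders and villages.
#'
#' @param observations Data frame with columns `food_id`, `village`,
#'   `trader`, `season`, `price_kes` (>= 0) and `weight_g` (> 0).
#' @param foods Optional foods table; when given, every (food, season) the
#'   food is available in must have at least one observation, otherwise a
#'   missing-price error names the offending pairs.
#' @return A tibble `food_id`, `season`, `price_per_100g` — the seasonal
#'   price table consumed by [build_diet_problem()].
#' @examples
#' obs <- tibble::tibble(
#'   food_id = "maize", village = "v1", trader = 1,
#'   season = "plenty", price_kes = 20, weight_g = 250
#' )
#' aggregate_prices(obs) # 8 KES per 100 g
#' @export
aggregate_prices <- function(observations, foods = NULL) {
  req <- c("food_id", "season", "price_kes", "weight_g")
  missing_cols <- setdiff(req, names(observations))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "`observations` is missing column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  if (any(observations$price_kes < 0)) abort("Prices must be >= 0.")
  if (any(observations$weight_g <= 0)) abort("Sample weights must be > 0.")
  bad_season <- setdiff(unique(observations$season), DIET_SEASONS)
  if (length(bad_season) > 0) {
    abort(paste0("Unknown season(s): ", paste(bad_season, collapse = ", ")))
  }

  table <- observations |>
    mutate(unit_price = 100 * .data$price_kes / .data$weight_g) |>
    group_by(.data$food_id, .data$season) |>
    summarise(price_per_100g = mean(.data$unit_price), .groups = "drop") |>
    arrange(.data$food_id, .data$season)

  if (!is.null(foods)) {
    needed <- tidyr::expand_grid(
      food_id = foods$id,
      season = DIET_SEASONS
    ) |>
      inner_join(
        foods |> select(food_id = "id", "season_availability"),
        by = "food_id"
      ) |>
      filter(food_available(.data$season_availability, .data$season))
    absent <- anti_join(needed, table, by = c("food_id", "season"))
    if (nrow(absent) > 0) {
      abort(paste0(
        "No price observation for: ",
        paste(absent$food_id, absent$season, sep = "/", collapse = ", ")
      ))
    }
  }
  table
}

food_available <- function(season_availability, season) {
  season_availability == "both" | season_availability == season
}

#' Read and write the package's CSV interchange formats
#'
#' `foods.csv` holds one row per food (`id`, `name`, `category`,
#' `season_availability`, then one unit-suffixed column per nutrient, e.g.
#' `energy_kcal`; empty cells mean content unknown). `prices.csv` holds raw
#' market observations (`food_id`, `village`, `trader`, `season`,
#' `price_kes`, `weight_g`). All files are UTF-8, comma-delimited, with a
#' header row.
#'
#' @param path Path to the CSV file.
#' @param foods,observations Tables as returned by the corresponding reader.
#' @return Readers return tibbles with canonical (unsuffixed) nutrient
#'   column names; writers return `path` invisibly.
#' @export
read_foods <- function(path) {
  spec <- readr::cols(
    id = readr::col_character(),
    name = readr::col_character(),
    category = readr::col_character(),
    season_availability = readr::col_character(),
    .default = readr::col_double()
  )
  raw <- readr::read_csv(path, col_types = spec, progress = FALSE)
  missing_cols <- setdiff(
    c("id", "name", "category", "season_availability", nutrient_csv_cols()),
    names(raw)
  )
  if (length(missing_cols) > 0) {
    abort(paste0(
      basename(path), " is missing column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  out <- raw |>
    select(
      "id", "name", "category", "season_availability",
      all_of(nutrient_csv_cols())
    ) |>
    rlang::set_names(
      c("id", "name", "category", "season_availability", nutrient_names())
    )
  validate_foods(out)
}

#' @rdname read_foods
#' @export
write_foods <- function(foods, path) {
  foods <- validate_foods(foods)
  out <- foods |>
    rlang::set_names(
      c("id", "name", "category", "season_availability", nutrient_csv_cols())
    )
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' @rdname read_foods
#' @export
read_prices <- function(path) {
  spec <- readr::cols(
    food_id = readr::col_character(),
    village = readr::col_character(),
    trader = readr::col_integer(),
    season = readr::col_character(),
    price_kes = readr::col_double(),
    weight_g = readr::col_double()
  )
  readr::read_csv(path, col_types = spec, progress = FALSE)
}

#' @rdname read_foods
#' @export
write_prices <- function(observations, path) {
  readr::write_csv(observations, path, na = "")
  invisible(path)
}

validate_foods <- function(foods) {
  base_cols <- c("id", "name", "category", "season_availability")
  missing_cols <- setdiff(c(base_cols, nutrient_names()), names(foods))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "foods table is missing column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  if (anyDuplicated(foods$id)) {
    abort("Food ids must be unique within a food list.")
  }
  bad_cat <- setdiff(unique(foods$category), FOOD_CATEGORIES)
  if (length(bad_cat) > 0) {
    abort(paste0(
      "Unknown food category: ", paste(bad_cat, collapse = ", ")
    ))
  }
  bad_avail <- setdiff(
    unique(foods$season_availability), c("both", DIET_SEASONS)
  )
  if (length(bad_avail) > 0) {
    abort(paste0(
      "season_availability must be 'both', 'plenty' or 'lean', not: ",
      paste(bad_avail, collapse = ", ")
    ))
  }
  comp <- as.matrix(foods[nutrient_names()])
  if (any(comp < 0, na.rm = TRUE)) {
    abort("Nutrient composition values must be >= 0 (NA = unknown).")
  }
  as_tibble(foods[c(base_cols, nutrient_names())])
}
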