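#' Daily nutrient requirement profiles
#'
#' The package ships a documented default requirements table
#' (`inst/extdata/requirements.csv`) with WHO/FAO-based recommended daily
#' intakes for the six modeled individual categories; calcium and iron
#' requirements are expressed in absorbed units on the same scale as the
#' composition data. These defaults are deliberately user-replaceable:
#' pass any table with the same schema (`category`, `nutrient`,
#' `daily_amount`) to the model builders.
#'
#' @param path Path to a requirements CSV; the default reads the installed
#'   copy.
#' @return `default_requirements()` / `read_requirements()`: a long tibble
#'   `category`, `nutrient`, `daily_amount`; `requirements_for()`: a named
#'   numeric vector of daily amounts over [nutrient_names()] for one
#'   category.
#' @export
default_requirements <- function() {
  read_requirements(
    system.file("extdata", "requirements.csv", package = "dietcost")
  )
}

#' @rdname default_requirements
#' @export
read_requirements <- function(path) {
  spec <- readr::cols(
    category = readr::col_character(),
    nutrient = readr::col_character(),
    daily_amount = readr::col_double()
  )
  out <- readr::read_csv(path, col_types = spec, progress = FALSE)
  bad <- setdiff(unique(out$nutrient), nutrient_names())
  if (length(bad) > 0) {
    abort(paste0("Unknown nutrient(s): ", paste(bad, collapse = ", ")))
  }
  if (any(out$daily_amount <= 0, na.rm = TRUE)) {
    abort("Requirement daily amounts must be > 0 (omit unconstrained rows).")
  }
  out
}

#' @rdname default_requirements
#' @param requirements A long requirements tibble.
#' @param category One of [diet_categories()].
#' @export
requirements_for <- function(requirements, category) {
  rows <- requirements |> filter(.data$category == !!category)
  if (nrow(rows) == 0) {
    abort(paste0("No requirement profile for category '", category, "'."))
  }
  out <- rlang::set_names(
    rep(NA_real_, length(nutrient_names())), nutrient_names()
  )
  out[rows$nutrient] <- rows$daily_amount
  if (is.na(out[["energy"]])) {
    abort(paste0("Category '", category, "' has no energy requirement."))
  }
  out
}

# Default grams per serving by food category (adult-woman base) and
# age-class multiplier; supplements are always one 1-g sachet per serving.
PORTION_BASE_G <- c(
  market = 150, wild_vegetable = 100, wild_fruit = 100, supplement = 1
)
PORTION_MULTIPLIER <- c(
  child_6_8m = 0.25, child_9_11m = 0.3, child_12_23m = 0.45,
  woman_NPNL = 1, woman_pregnant = 1, woman_lactating = 1
)

#' Default recommended portion sizes
#'
#' Grams of edible portion per serving, by individual category and food.
#' Defaults follow the usual diet-modeling convention of a base portion
#' per food group (150 g market foods, 100 g vegetables and fruits, one
#' 1-g sachet for supplements) scaled down for young children (25-45% of
#' the adult portion by age band). Override by supplying your own
#' `portions.csv` (`category`, `food_id`, `grams`).
#'
#' @param foods A foods table.
#' @param categories Individual categories to cover.
#' @return A tibble `category`, `food_id`, `grams`.
#' @export
default_portions <- function(foods, categories = diet_categories()) {
  tidyr::expand_grid(category = categories, food_id = foods$id) |>
    left_join(
      foods |> select(food_id = "id", food_category = "category"),
      by = "food_id"
    ) |>
    mutate(
      grams = ifelse(
        .data$food_category == "supplement",
        PORTION_BASE_G[["supplement"]],
        PORTION_BASE_G[.data$food_category] *
          PORTION_MULTIPLIER[.data$category]
      )
    ) |>
    select("category", "food_id", "grams")
}

#' @rdname read_foods
#' @export
read_portions <- function(path) {
  spec <- readr::cols(
    category = readr::col_character(),
    food_id = readr::col_character(),
    grams = readr::col_double()
  )
  out <- readr::read_csv(path, col_types = spec, progress = FALSE)
  if (any(out$grams <= 0)) abort("Portion sizes must be > 0 grams.")
  out
}
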