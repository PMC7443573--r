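# Reference tables from the 2016 Turkana County (Loima sub-county) field
# surveys: wild-food composition, the national micronutrient-powder
# formulation, household-economy wealth groups, and the modeled daily diet
# costs with scenario reductions. All values are carried exactly as
# compiled; derived quantities are recomputed by the package.

#' Composition of the six selected Turkana wild plant foods
#'
#' Nutrient composition per 100 g edible fresh portion of the three wild
#' vegetables (amaranth, American nightshade, celosia) and three wild
#' fruits (African-star chestnut, wild almond, white crossberry) selected
#' for the intervention models. Calcium and iron are absorbed amounts
#' (bioavailability factors 0.48 and 0.05); vitamin A is retinol
#' equivalent (beta-carotene / 12). `NA` means not available in the
#' composition literature; such cells contribute zero to diet models and
#' are flagged as incomplete in adequacy reports.
#'
#' @param raw If `TRUE`, also include the back-derived raw contents
#'   (`raw_calcium_mg`, `raw_iron_mg`, `beta_carotene_ug`) obtained by
#'   inverting the conversion factors.
#' @return A tibble, one row per species, with canonical nutrient columns.
#' @export
wild_food_composition <- function(raw = FALSE) {
  comp <- tribble(
    ~id,                   ~name,                   ~category,
    ~energy, ~protein, ~fat, ~calcium_absorbed, ~iron_absorbed, ~zinc,
    ~thiamine, ~riboflavin, ~niacin, ~magnesium, ~vitamin_c,
    ~retinol_equivalent,
    "amaranthus_hybridus", "Amaranth",              "wild_vegetable",
    80.31, 6.30, 0.50, 265.44, 0.55, 5.08,
    0.45, 0.70, 0.25, 329.00, 11.16, 436.67,
    "solanum_americanum",  "American nightshade",   "wild_vegetable",
    50.33, 1.61, 2.86, 337.21, 4.90, 1.47,
    NA, NA, NA, 30.01, NA, NA,
    "celosia_argentea",    "Celosia",               "wild_vegetable",
    NA, 4.71, 1.00, 77.92, 0.70, 6.61,
    NA, NA, NA, 36.14, NA, NA,
    "sterculia_africana",  "African-star chestnut", "wild_fruit",
    287.52, 23.83, 6.55, 46.67, 0.63, 5.50,
    NA, NA, NA, 172.77, 4.85, NA,
    "berchemia_discolor",  "Wild almond",           "wild_fruit",
    266.20, 0.99, 2.80, 9.00, 8.75, 0.89,
    NA, NA, NA, 1250.00, 59.43, 33.71,
    "grewia_tenax",        "White crossberry",      "wild_fruit",
    322.68, 4.50, 6.80, 900.00, 6.25, 1.65,
    NA, NA, NA, 1250.00, 161.09, 116.67
  )
  if (raw) {
    comp <- comp |>
      mutate(
        raw_calcium_mg = .data$calcium_absorbed / CALCIUM_ABSORPTION,
        raw_iron_mg = .data$iron_absorbed / IRON_ABSORPTION,
        beta_carotene_ug = .data$retinol_equivalent * BETA_CAROTENE_PER_RE
      )
  }
  comp
}

#' The six wild plant foods as a diet-model food list
#'
#' Expands [wild_food_composition()] into the `foods`-table schema used by
#' [build_diet_problem()] (all canonical nutrient columns, unmeasured
#' nutrients `NA`, available in both seasons).
#'
#' @return A foods tibble with six rows.
#' @export
wild_food_items <- function() {
  comp <- wild_food_composition()
  extra <- setdiff(nutrient_names(), names(comp))
  for (nm in extra) comp[[nm]] <- NA_real_
  comp |>
    mutate(season_availability = "both") |>
    select(
      "id", "name", "category", "season_availability",
      all_of(nutrient_names())
    ) |>
    validate_foods()
}

#' Opportunity-cost prices of the wild plant foods
#'
#' Wild foods have no market price; collection and preparation effort is
#' proxied by averaged market prices of comparable cultivated foods:
#' 7.8 KES per 100 g for the wild vegetables (kales, jute mallow, cowpea
#' leaves) and 7.7 KES per 100 g for the wild fruits (berries, guava,
#' mango), identical across seasons.
#'
#' @return A seasonal price table (`food_id`, `season`, `price_per_100g`).
#' @export
wild_food_prices <- function() {
  foods <- wild_food_items()
  tidyr::expand_grid(food_id = foods$id, season = DIET_SEASONS) |>
    left_join(foods |> select(food_id = "id", "category"), by = "food_id") |>
    mutate(
      price_per_100g = ifelse(.data$category == "wild_vegetable", 7.8, 7.7)
    ) |>
    select("food_id", "season", "price_per_100g")
}

#' Micronutrient powder (MNP) formulation
#'
#' Per-sachet (1 g) micronutrient amounts of the powder distributed to
#' children 6-59 months under the national formulation guidelines. Iron is
#' listed as elemental content; `mnp_food_item()` converts it (and would
#' convert calcium, of which the sachet contains none) to absorbed units
#' with the same bioavailability factors applied to foods.
#'
#' @return `mnp_formulation()`: a tibble `nutrient`, `amount`, `unit` as
#'   formulated; `mnp_food_item()`: a one-row foods table (category
#'   `"supplement"`, composition per sachet, absorbed units).
#' @export
mnp_formulation <- function() {
  tribble(
    ~nutrient,            ~amount, ~unit,
    "retinol_equivalent", 400,     "ug",
    "vitamin_d",          5,       "ug",
    "vitamin_e",          5,       "mg",
    "vitamin_c",          30,      "mg",
    "thiamine",           0.5,     "mg",
    "riboflavin",         0.5,     "mg",
    "niacin",             6,       "mg",
    "vitamin_b6",         0.5,     "mg",
    "vitamin_b12",        0.9,     "ug",
    "folate",             150,     "ug",
    "iron",               10,      "mg",
    "zinc",               4.1,     "mg",
    "copper",             0.56,    "mg",
    "selenium",           17,      "ug"
  )
}

#' @rdname mnp_formulation
#' @export
mnp_food_item <- function() {
  form <- mnp_formulation()
  amounts <- rlang::set_names(form$amount, form$nutrient)
  row <- tibble(
    id = "mnp", name = "Micronutrient powder sachet",
    category = "supplement", season_availability = "both"
  )
  for (nm in nutrient_names()) row[[nm]] <- 0
  for (nm in setdiff(names(amounts), c("iron", "calcium"))) {
    row[[nm]] <- unname(amounts[[nm]])
  }
  row$iron_absorbed <- absorbed_iron(unname(amounts[["iron"]]))
  validate_foods(row)
}

#' Turkana wealth groups from the household economy approach survey
#'
#' Household size, annual income per individual, and the percentage of
#' income spent on food for the four wealth strata identified in Loima
#' sub-county (2015/16).
#'
#' @return A tibble with columns `wealth_group`, `household_size`,
#'   `annual_income_per_individual` (KES) and `pct_income_on_food`.
#' @export
turkana_wealth_groups <- function() {
  tribble(
    ~wealth_group, ~household_size, ~annual_income_per_individual,
    ~pct_income_on_food,
    "very_poor",   7,  11786, 68,
    "poor",        7,  14286, 55,
    "middle",      8,  21875, 50,
    "better_off", 13,  21154, 38
  )
}

#' Modeled daily diet costs and scenario reductions for Turkana
#'
#' Baseline least-cost diet costs (KES per day) in the plenty and lean
#' seasons for the six individual categories, together with the
#' season-averaged percentage cost change when each wild food, food group,
#' or the micronutrient powder is added to the model (negative = cheaper;
#' `NA` where the scenario does not apply — MNP targets children only).
#'
#' @return A tibble, one row per individual category.
#' @export
turkana_diet_costs <- function() {
  tribble(
    ~category, ~cost_plenty, ~cost_lean,
    ~grewia_tenax, ~berchemia_discolor, ~sterculia_africana,
    ~all_wild_fruits,
    ~amaranthus_hybridus, ~celosia_argentea, ~solanum_americanum,
    ~all_wild_vegetables, ~all_wild_plant_foods, ~mnp,
    "child_6_8m",      50.0,  59.4,  -0.3,   0.0,  -0.2, -27.2,
    10.9,  20.2,   3.0, -71.4, -70.3,  0.0,
    "child_9_11m",     65.5,  82.3, -19.0, -12.0, -19.0, -35.2,
    -8.2,  -6.7, -27.7, -66.1, -66.4,  0.0,
    "child_12_23m",   101.5, 119.0, -65.2, -56.4, -33.6, -69.2,
    -62.6, -60.0, -66.0, -67.6, -68.9, -0.6,
    "woman_NPNL",     173.1, 226.3, -26.2, -30.3, -10.5, -16.3,
    -8.7,   3.9, -28.6, -29.8, -22.8, NA,
    "woman_pregnant", 247.8, 304.7, -44.9, -46.0, -12.5, -40.5,
    -21.2, -34.0, -46.7, -45.3, -36.0, NA,
    "woman_lactating", 210.3, 244.9, -31.3, -32.6,  -2.5, -27.1,
    -15.2, -24.8, -33.3, -31.6, -22.6, NA
  )
}
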