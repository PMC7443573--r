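# Canonical nutrient set. Calcium and iron are carried in *absorbed* units
# (after the fixed bioavailability factors); beta-carotene enters as retinol
# equivalent. `class` drives the LP: energy is constrained to a band, macros
# are hard >= rows, micronutrients are elastic rows with a deficit penalty.
NUTRIENT_TABLE <- tibble::tribble(
  ~nutrient,            ~unit,  ~class,
  "energy",             "kcal", "energy",
  "protein",            "g",    "macro",
  "fat",                "g",    "macro",
  "calcium_absorbed",   "mg",   "micro",
  "iron_absorbed",      "mg",   "micro",
  "zinc",               "mg",   "micro",
  "thiamine",           "mg",   "micro",
  "riboflavin",         "mg",   "micro",
  "niacin",             "mg",   "micro",
  "magnesium",          "mg",   "micro",
  "vitamin_c",          "mg",   "micro",
  "retinol_equivalent", "ug",   "micro",
  "folate",             "ug",   "micro",
  "vitamin_b6",         "mg",   "micro",
  "vitamin_b12",        "ug",   "micro",
  "vitamin_d",          "ug",   "micro",
  "vitamin_e",          "mg",   "micro",
  "copper",             "mg",   "micro",
  "selenium",           "ug",   "micro"
)

#' Canonical nutrients tracked by the diet models
#'
#' Composition is stored per 100 g edible fresh portion (per 1 g sachet for
#' supplements). Calcium and iron are absorbed quantities, i.e. raw food
#' content multiplied by the fixed bioavailability factors
#' ([absorbed_calcium()], [absorbed_iron()]); vitamin A activity is retinol
#' equivalent ([beta_carotene_to_re()]).
#'
#' @return `nutrient_info()`: a tibble with columns `nutrient`, `unit` and
#'   `class` (`"energy"`, `"macro"` or `"micro"`); `nutrient_names()`: the
#'   character vector of canonical names; `nutrient_csv_cols()`: the
#'   unit-suffixed column names used in `foods.csv`-style files.
#' @export
nutrient_info <- function() NUTRIENT_TABLE

#' @rdname nutrient_info
#' @export
nutrient_names <- function() NUTRIENT_TABLE$nutrient

#' @rdname nutrient_info
#' @export
nutrient_csv_cols <- function() {
  paste0(NUTRIENT_TABLE$nutrient, "_", NUTRIENT_TABLE$unit)
}

micro_nutrients <- function() {
  NUTRIENT_TABLE$nutrient[NUTRIENT_TABLE$class == "micro"]
}

# Round half away from zero (base round() is banker's rounding); display
# conventions are costs to 0.1 KES and percentages to 0.1.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Convert Kenyan shillings to US dollars
#'
#' @param kes Amount in Kenyan shillings.
#' @param rate Exchange rate in KES per USD; the default reflects the 2016
#'   rate used for the Turkana reference figures.
#' @return Amount in USD.
#' @export
kes_to_usd <- function(kes, rate = 103.6) {
  stopifnot(is.numeric(kes), rate > 0)
  kes / rate
}
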