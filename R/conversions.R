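# Bioavailability conversion factors used when compiling wild-food
# composition per 100 g edible fresh portion.
CALCIUM_ABSORPTION <- 0.48
IRON_ABSORPTION <- 0.05
BETA_CAROTENE_PER_RE <- 12

check_nonnegative <- function(x, what) {
  if (!is.numeric(x)) {
    abort(paste0("`", what, "` must be numeric."))
  }
  if (any(x < 0, na.rm = TRUE)) {
    abort(paste0("`", what, "` must be non-negative."))
  }
  invisible(x)
}

#' Bioavailability and vitamin A activity conversions
#'
#' Raw food content is converted to the quantities the diet models
#' constrain: absorbed calcium (factor 0.48), absorbed iron (factor 0.05)
#' and retinol equivalent (12 ug beta-carotene per 1 ug RE). All three are
#' linear and vectorised; `NA` (content unknown) propagates unchanged.
#'
#' @param raw_mg Raw calcium or iron content, mg per 100 g edible portion.
#' @param beta_carotene_ug Beta-carotene content, ug per 100 g edible
#'   portion.
#' @return The absorbed quantity (mg) or retinol equivalent (ug).
#' @examples
#' absorbed_calcium(553)    # 265.44
#' absorbed_iron(125)       # 6.25
#' beta_carotene_to_re(5240.04) # 436.67
#' @export
absorbed_calcium <- function(raw_mg) {
  check_nonnegative(raw_mg, "raw_mg")
  raw_mg * CALCIUM_ABSORPTION
}

#' @rdname absorbed_calcium
#' @export
absorbed_iron <- function(raw_mg) {
  check_nonnegative(raw_mg, "raw_mg")
  raw_mg * IRON_ABSORPTION
}

#' @rdname absorbed_calcium
#' @export
beta_carotene_to_re <- function(beta_carotene_ug) {
  check_nonnegative(beta_carotene_ug, "beta_carotene_ug")
  beta_carotene_ug / BETA_CAROTENE_PER_RE
}

#' Opportunity-cost price for freely collected wild foods
#'
#' Wild foods carry no market price; the cost of collecting and preparing
#' them is proxied by the mean market price of comparable cultivated foods
#' (e.g. kales, jute mallow and cowpea leaves for wild vegetables).
#'
#' @param proxy_prices Numeric vector of proxy market prices, KES per 100 g
#'   edible portion.
#' @return The arithmetic mean, reported to 0.1 KES.
#' @export
opportunity_cost_price <- function(proxy_prices) {
  if (length(proxy_prices) == 0) {
    abort("`proxy_prices` must contain at least one price.")
  }
  check_nonnegative(proxy_prices, "proxy_prices")
  round_half_up(mean(proxy_prices), 1)
}
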