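#' Weekly intake-frequency bounds from 24-h recall counts
#'
#' For each food, the minimum and maximum weekly servings allowed in the
#' diet models are the 25th and 75th percentiles of the per-household
#' weekly consumption counts (linear-interpolation quantiles, rounded half
#' up to the nearest integer). Quantile monotonicity guarantees
#' `min <= max`.
#'
#' @param recall Data frame with columns `household_id`, `food_id`,
#'   `count_per_week` (counts >= 0), one row per household and food.
#' @return A tibble `food_id`, `min_per_week`, `max_per_week`.
#' @examples
#' recall <- tibble::tibble(
#'   household_id = 1:5, food_id = "maize", count_per_week = 0:4
#' )
#' bounds_from_recall(recall) # min 1, max 3
#' @export
bounds_from_recall <- function(recall) {
  req <- c("household_id", "food_id", "count_per_week")
  missing_cols <- setdiff(req, names(recall))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "`recall` is missing column(s): ", paste(missing_cols, collapse = ", ")
    ))
  }
  if (nrow(recall) == 0) abort("`recall` must contain at least one row.")
  if (any(recall$count_per_week < 0)) abort("Recall counts must be >= 0.")
  recall |>
    group_by(.data$food_id) |>
    summarise(
      min_per_week = round_half_up(
        stats::quantile(.data$count_per_week, 0.25, type = 7, names = FALSE)
      ),
      max_per_week = round_half_up(
        stats::quantile(.data$count_per_week, 0.75, type = 7, names = FALSE)
      ),
      .groups = "drop"
    ) |>
    arrange(.data$food_id)
}

#' Reconcile focus-group and 24-h-recall frequency bounds
#'
#' Focus-group discussions and the 24-h recall can disagree on how often a
#' food is eaten per week; where any bound differs, the recall-derived
#' bound is preferred because it reflects actual household intake.
#'
#' @param fgd_bounds,recall_bounds Bounds tibbles (`food_id`,
#'   `min_per_week`, `max_per_week`). Foods present in only one source keep
#'   that source's bound.
#' @return A bounds tibble covering the union of foods.
#' @export
reconcile_bounds <- function(fgd_bounds, recall_bounds) {
  validate_bounds(fgd_bounds)
  validate_bounds(recall_bounds)
  if (nrow(fgd_bounds) == 1 && nrow(recall_bounds) == 1 &&
      fgd_bounds$food_id != recall_bounds$food_id) {
    abort(paste0(
      "Bound food ids differ: '", fgd_bounds$food_id, "' vs '",
      recall_bounds$food_id, "'."
    ))
  }
  fgd_only <- anti_join(fgd_bounds, recall_bounds, by = "food_id")
  bind_rows(recall_bounds, fgd_only) |> arrange(.data$food_id)
}

#' Weekly frequency bounds for wild foods and the micronutrient powder
#'
#' `wild_food_bounds()` assigns the focus-group-derived weekly intake range
#' of 1-3 servings to every wild vegetable and wild fruit.
#' `mnp_bounds()` assigns the supplementation-program sachet range of 3-4
#' per week (15 sachets per month); `daily = TRUE` switches to the
#' one-sachet-per-day sensitivity setting (7, 7).
#'
#' @param foods A foods table; rows must all be of the appropriate
#'   category (`wild_vegetable`/`wild_fruit`, or `supplement`).
#' @param daily Use the daily-intake sensitivity setting for MNP.
#' @return A bounds tibble (`food_id`, `min_per_week`, `max_per_week`).
#' @export
wild_food_bounds <- function(foods) {
  not_wild <- foods$id[!foods$category %in% c("wild_vegetable", "wild_fruit")]
  if (length(not_wild) > 0) {
    abort(paste0(
      "Wild-food bounds apply only to wild vegetables and fruits; not: ",
      paste(not_wild, collapse = ", ")
    ))
  }
  tibble(food_id = foods$id, min_per_week = 1, max_per_week = 3)
}

#' @rdname wild_food_bounds
#' @export
mnp_bounds <- function(foods, daily = FALSE) {
  not_supp <- foods$id[foods$category != "supplement"]
  if (length(not_supp) > 0) {
    abort(paste0(
      "MNP bounds apply only to supplements; not: ",
      paste(not_supp, collapse = ", ")
    ))
  }
  if (daily) {
    tibble(food_id = foods$id, min_per_week = 7, max_per_week = 7)
  } else {
    tibble(food_id = foods$id, min_per_week = 3, max_per_week = 4)
  }
}

validate_bounds <- function(bounds) {
  req <- c("food_id", "min_per_week", "max_per_week")
  missing_cols <- setdiff(req, names(bounds))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "Bounds table is missing column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  bad <- bounds$min_per_week < 0 |
    bounds$max_per_week < bounds$min_per_week |
    bounds$max_per_week > 21
  if (any(bad)) {
    abort(paste0(
      "Invalid bounds (need 0 <= min <= max <= 21) for: ",
      paste(bounds$food_id[bad], collapse = ", ")
    ))
  }
  invisible(bounds)
}

#' @rdname read_foods
#' @export
read_recall <- function(path) {
  spec <- readr::cols(
    household_id = readr::col_character(),
    food_id = readr::col_character(),
    count_per_week = readr::col_double()
  )
  readr::read_csv(path, col_types = spec, progress = FALSE)
}

#' @rdname read_foods
#' @export
read_bounds <- function(path) {
  spec <- readr::cols(
    food_id = readr::col_character(),
    min_per_week = readr::col_double(),
    max_per_week = readr::col_double()
  )
  out <- readr::read_csv(path, col_types = spec, progress = FALSE)
  validate_bounds(out)
  out
}

#' @rdname read_foods
#' @export
write_bounds <- function(bounds, path) {
  validate_bounds(bounds)
  readr::write_csv(bounds, path, na = "")
  invisible(path)
}
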