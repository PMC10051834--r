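#' Evaluate predictions against known free sugar
#'
#' Cross-dataset validation metrics: sample Pearson correlation between
#' predicted and known free-sugar content and mean absolute error in
#' g/100 g. When the truth is constant the correlation is undefined and
#' reported as `NA` rather than fabricated.
#'
#' @param data Tibble with prediction and truth columns (or anything
#'   coercible); alternatively pass two vectors via `predicted` and `truth`.
#' @param predicted,truth Column names (tidy-select) or numeric vectors.
#' @param name Dataset label for the report.
#' @return One-row tibble: `dataset`, `n`, `pearson_r`, `mae`.
#' @export
evaluate_predictions <- function(data = NULL, predicted = NULL, truth = NULL,
                                 name = "validation") {
  if (is.data.frame(data)) {
    pred <- dplyr::pull(data, {{ predicted }})
    tr <- dplyr::pull(data, {{ truth }})
  } else {
    pred <- predicted
    tr <- truth
  }
  if (length(pred) != length(tr)) {
    abort("predicted and truth have different lengths",
          class = "sugarstep_schema_error")
  }
  if (length(pred) < 3) {
    abort("need at least 3 foods to validate", class = "sugarstep_schema_error")
  }
  r <- if (sd(tr) == 0 || sd(pred) == 0) NA_real_ else stats::cor(pred, tr)
  tibble::tibble(
    dataset = name,
    n = length(pred),
    pearson_r = r,
    mae = mean(abs(pred - tr))
  )
}

#' Menu-level daily error of an annotated table
#'
#' Evaluates how per-food annotation errors combine over realistic daily
#' baskets: for each menu day, daily free-sugar intake (g/day) is computed
#' once from the annotated table and once from the ground truth, and the
#' absolute difference is reported per day together with its mean.
#'
#' @param menu Tibble with `day`, `food_id`, `amount_g` (amounts > 0).
#' @param annotated Tibble with `food_id` and the annotated `free_sugar`
#'   column (g/100 g), e.g. from [annotate_food_table()].
#' @param truth Tibble with `food_id` and `true_free_sugar` (g/100 g).
#' @return A tibble with one row per day (`day`, `intake_annotated`,
#'   `intake_truth`, `abs_error`) carrying the mean daily error in attribute
#'   `"mean_error"`; also printed by `summarize = TRUE` consumers.
#' @export
evaluate_menu <- function(menu, annotated, truth) {
  if (any(menu$amount_g <= 0)) {
    abort("menu amounts must be positive", class = "sugarstep_schema_error")
  }
  missing_ann <- setdiff(menu$food_id, annotated$food_id)
  missing_tru <- setdiff(menu$food_id, truth$food_id)
  offenders <- union(missing_ann, missing_tru)
  if (length(offenders) > 0) {
    abort(paste0("menu food_id(s) not found: ",
                 paste(head(offenders, 10), collapse = ", ")),
          class = "sugarstep_integrity_error")
  }
  joined <- menu |>
    dplyr::left_join(dplyr::select(annotated, "food_id", fs_ann = "free_sugar"),
                     by = "food_id") |>
    dplyr::left_join(dplyr::select(truth, "food_id", fs_tru = "true_free_sugar"),
                     by = "food_id")
  if (anyNA(joined$fs_ann)) {
    abort("menu contains unannotated foods", class = "sugarstep_integrity_error")
  }
  out <- joined |>
    dplyr::group_by(.data$day) |>
    dplyr::summarise(
      intake_annotated = sum(.data$amount_g / 100 * .data$fs_ann),
      intake_truth = sum(.data$amount_g / 100 * .data$fs_tru),
      .groups = "drop"
    ) |>
    dplyr::mutate(abs_error = abs(.data$intake_annotated - .data$intake_truth))
  attr(out, "mean_error") <- mean(out$abs_error)
  out
}
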