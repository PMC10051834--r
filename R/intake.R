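#' Daily free-sugar intake from 24 h recalls
#'
#' Computes per-respondent daily intakes from recall records and an annotated
#' food table. By default only the first recall day per respondent is used
#' (`day_rule = "first"`): single-day recall is the standard basis for
#' population mean intake, at the cost of not capturing usual-intake
#' variance. Free sugar, total sugar and energy are accumulated as
#' `amount/100 * per-100 g value`; percent of energy uses 4 kcal per gram of
#' sugar (Atwater) by default.
#'
#' Unannotated foods contribute 0 g free sugar; the per-respondent count of
#' such records is returned in `n_unannotated` and logged, so affected
#' respondents can be flagged or excluded.
#'
#' @param recalls Tibble `respondent_id`, `day`, `meal`, `food_id`,
#'   `amount_g` (g consumed, > 0).
#' @param annotated Food-table tibble joined with its assignments: needs
#'   `food_id`, `free_sugar`, `total_sugar`, `energy`.
#' @param day_rule `"first"` (default) or `"all"`.
#' @param kcal_per_g Energy density of sugar used for the percent-energy
#'   figure; default 4.
#' @return Tibble with one row per respondent present in the recalls:
#'   `respondent_id`, `fs_g`, `ts_g`, `energy_kcal`, `fs_pct_energy`
#'   (missing when daily energy is 0), `n_unannotated`.
#' @export
compute_daily_intake <- function(recalls, annotated, day_rule = c("first", "all"),
                                 kcal_per_g = 4) {
  day_rule <- match.arg(day_rule)
  if (any(recalls$amount_g <= 0)) {
    abort("recall amounts must be positive", class = "sugarstep_schema_error")
  }
  unknown <- setdiff(recalls$food_id, annotated$food_id)
  if (length(unknown) > 0) {
    abort(paste0("recall food_id(s) not in the annotated table: ",
                 paste(head(unknown, 10), collapse = ", ")),
          class = "sugarstep_integrity_error")
  }
  if (day_rule == "first") {
    recalls <- recalls |>
      dplyr::group_by(.data$respondent_id) |>
      dplyr::filter(.data$day == min(.data$day)) |>
      dplyr::ungroup()
  }
  joined <- recalls |>
    dplyr::left_join(
      dplyr::select(annotated, "food_id", "free_sugar", "total_sugar", "energy"),
      by = "food_id"
    )
  n_un <- sum(is.na(joined$free_sugar))
  if (n_un > 0) {
    message(n_un, " recall record(s) reference unannotated foods; ",
            "they contribute 0 g free sugar")
  }
  n_days <- if (day_rule == "first") 1 else NA  # per-respondent below
  out <- joined |>
    dplyr::group_by(.data$respondent_id) |>
    dplyr::summarise(
      n_days = dplyr::n_distinct(.data$day),
      fs_g = sum(.data$amount_g / 100 * dplyr::coalesce(.data$free_sugar, 0)),
      ts_g = sum(.data$amount_g / 100 * dplyr::coalesce(.data$total_sugar, 0)),
      energy_kcal = sum(.data$amount_g / 100 * dplyr::coalesce(.data$energy, 0)),
      n_unannotated = sum(is.na(.data$free_sugar)),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      dplyr::across(c("fs_g", "ts_g", "energy_kcal"), ~ .x / .data$n_days),
      fs_pct_energy = dplyr::if_else(
        .data$energy_kcal > 0,
        100 * kcal_per_g * .data$fs_g / .data$energy_kcal,
        NA_real_
      )
    ) |>
    dplyr::select(-"n_days")
  out
}

#' Survey-weighted mean and standard error
#'
#' Design-weighted mean with the with-replacement linearization variance
#' estimator: `mean = sum(w * x) / sum(w)` and
#' `SE^2 = n/(n-1) * sum((w * (x - mean))^2) / (sum(w))^2`. With equal
#' weights this reduces to the classical mean and `sqrt(s^2/n)`.
#'
#' @param data Optional tibble; if supplied, `values` and `weights` are
#'   tidy-selected columns, otherwise numeric vectors.
#' @param values,weights Columns or vectors; all weights must be positive.
#' @return One-row tibble `mean`, `se`, `n`.
#' @examples
#' weighted_mean_se(values = c(2, 4), weights = c(1, 3))  # mean 3.5, SE 0.75
#' @export
weighted_mean_se <- function(data = NULL, values = NULL, weights = NULL) {
  if (is.data.frame(data)) {
    x <- dplyr::pull(data, {{ values }})
    w <- dplyr::pull(data, {{ weights }})
  } else {
    x <- values
    w <- weights
  }
  keep <- !is.na(x) & !is.na(w)
  x <- x[keep]
  w <- w[keep]
  n <- length(x)
  if (n < 2) abort("need at least 2 observations", class = "sugarstep_schema_error")
  if (any(w <= 0)) abort("weights must be positive", class = "sugarstep_schema_error")
  if (length(w) != n) abort("values and weights misaligned", class = "sugarstep_schema_error")
  m <- sum(w * x) / sum(w)
  se2 <- n / (n - 1) * sum((w * (x - m))^2) / sum(w)^2
  tibble::tibble(mean = m, se = sqrt(se2), n = n)
}

#' Free sugar by meal type
#'
#' Per-meal-occasion free-sugar grams, summarized unweighted (mean, SE,
#' median, min, max, n occasions) over the six meal types of the recall
#' instrument. Snacks typically dominate: sweetened beverages and sweet
#' bakery items cluster in snack occasions.
#'
#' @param recalls Recall tibble (`respondent_id`, `day`, `meal`, `food_id`,
#'   `amount_g`); `meal` must use the six-level vocabulary `breakfast`,
#'   `am_snack`, `lunch`, `pm_snack`, `supper`, `late_pm_snack`.
#' @param annotated Annotated table with `food_id`, `free_sugar`.
#' @return Tibble with one row per meal type present.
#' @export
meal_type_summary <- function(recalls, annotated) {
  bad <- setdiff(unique(recalls$meal), meal_levels)
  if (length(bad) > 0) {
    abort(paste0("unknown meal label(s): ", paste(bad, collapse = ", ")),
          class = "sugarstep_schema_error")
  }
  recalls |>
    dplyr::left_join(dplyr::select(annotated, "food_id", "free_sugar"),
                     by = "food_id") |>
    dplyr::group_by(.data$respondent_id, .data$day, .data$meal) |>
    dplyr::summarise(
      fs_g = sum(.data$amount_g / 100 * dplyr::coalesce(.data$free_sugar, 0)),
      .groups = "drop"
    ) |>
    dplyr::group_by(meal = factor(.data$meal, levels = meal_levels)) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$fs_g),
      se = sd(.data$fs_g) / sqrt(dplyr::n()),
      median = median(.data$fs_g),
      min = min(.data$fs_g),
      max = max(.data$fs_g),
      .groups = "drop"
    ) |>
    dplyr::mutate(meal = as.character(.data$meal))
}

#' Kruskal-Wallis rank test
#'
#' Nonparametric k-group comparison on ranks with average-rank ties and the
#' standard tie correction; p-value from the chi-squared distribution with
#' k - 1 degrees of freedom.
#'
#' @param data Optional tibble; `values` and `groups` tidy-selected columns,
#'   or vectors.
#' @param values,groups Columns or vectors (groups: factor or character).
#' @return One-row tibble `statistic` (H), `df`, `p.value`.
#' @export
kruskal_wallis <- function(data = NULL, values = NULL, groups = NULL) {
  if (is.data.frame(data)) {
    x <- dplyr::pull(data, {{ values }})
    g <- dplyr::pull(data, {{ groups }})
  } else {
    x <- values
    g <- groups
  }
  g <- factor(g)
  if (nlevels(g) < 2) {
    abort("need at least 2 groups", class = "sugarstep_schema_error")
  }
  kt <- kruskal.test(x, g)
  tibble::tibble(
    statistic = unname(kt$statistic),
    df = unname(kt$parameter),
    p.value = kt$p.value
  )
}

#' Dunn post hoc test with Benjamini-Hochberg correction
#'
#' All pairwise group comparisons after a Kruskal-Wallis test. The z
#' statistic for groups i, j is the difference of mean ranks divided by
#' `sqrt((N(N+1)/12 - sum(t^3 - t)/(12(N-1))) * (1/n_i + 1/n_j))`, where the
#' sum runs over tied groups — the standard tie-correction term. Two-sided
#' normal p-values, BH-adjusted within the pairwise family of this one
#' outcome (not across outcomes).
#'
#' @inheritParams kruskal_wallis
#' @return Tibble with one row per pair: `group1`, `group2`, `z`, `p.value`,
#'   `p.adjusted`.
#' @export
dunn_posthoc_bh <- function(data = NULL, values = NULL, groups = NULL) {
  if (is.data.frame(data)) {
    x <- dplyr::pull(data, {{ values }})
    g <- dplyr::pull(data, {{ groups }})
  } else {
    x <- values
    g <- groups
  }
  keep <- !is.na(x) & !is.na(g)
  x <- x[keep]
  g <- factor(g[keep])
  if (nlevels(g) < 2) {
    abort("need at least 2 groups", class = "sugarstep_schema_error")
  }
  N <- length(x)
  r <- rank(x)  # average ranks for ties
  mean_rank <- tapply(r, g, mean)
  n_g <- tapply(r, g, length)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  v0 <- N * (N + 1) / 12 - tie_term

  lev <- levels(g)
  pairs <- utils::combn(lev, 2)
  z <- numeric(ncol(pairs))
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1, p]
    j <- pairs[2, p]
    denom <- sqrt(v0 * (1 / n_g[[i]] + 1 / n_g[[j]]))
    z[p] <- if (denom == 0) 0 else (mean_rank[[j]] - mean_rank[[i]]) / denom
  }
  praw <- 2 * pnorm(-abs(z))
  tibble::tibble(
    group1 = pairs[1, ], group2 = pairs[2, ],
    z = z, p.value = praw,
    p.adjusted = p.adjust(praw, method = "BH")
  )
}

#' Weighted linear trend over an ordinal variable
#'
#' Weighted least squares of a continuous outcome on an ordinal grouping with
#' indicator (treatment) coding against the lowest category, the standard
#' layout for wealth-gradient tables: the intercept is the reference-level
#' mean and each coefficient is that level's contrast with the reference.
#' Standard errors come from the weighted residual variance on residual
#' degrees of freedom; t statistics and two-sided p-values accordingly.
#'
#' @param data Optional tibble; columns tidy-selected, or vectors.
#' @param values Continuous outcome.
#' @param groups Ordinal grouping; the first factor level (or, for ordered
#'   input, the lowest) is the reference.
#' @param weights Positive survey weights.
#' @return A `sugar_trend` object; `tidy()` gives the coefficient table
#'   (`term`, `estimate`, `std.error`, `statistic`, `p.value`), `glance()`
#'   the fit summary.
#' @export
weighted_trend <- function(data = NULL, values = NULL, groups = NULL,
                           weights = NULL) {
  if (is.data.frame(data)) {
    x <- dplyr::pull(data, {{ values }})
    g <- dplyr::pull(data, {{ groups }})
    w <- dplyr::pull(data, {{ weights }})
  } else {
    x <- values
    g <- groups
    w <- weights
  }
  keep <- !is.na(x) & !is.na(g) & !is.na(w)
  x <- x[keep]
  g <- g[keep]
  if (!is.factor(g)) g <- factor(g)
  # keep declared levels (an empty level is an error, not silently dropped);
  # strip ordered-ness so lm uses indicator, not polynomial, contrasts
  g <- factor(g, levels = levels(g), ordered = FALSE)
  w <- w[keep]
  if (any(tabulate(g, nlevels(g)) == 0)) {
    abort("every group level needs at least one observation",
          class = "sugarstep_schema_error")
  }
  if (any(w <= 0)) abort("weights must be positive", class = "sugarstep_schema_error")
  fit <- lm(x ~ g, weights = w)
  structure(list(fit = fit, levels = levels(g)), class = "sugar_trend")
}

#' @export
print.sugar_trend <- function(x, ...) {
  cat("Weighted linear trend (reference level:", x$levels[1], ")\n")
  print(tidy(x))
  invisible(x)
}

#' @rdname weighted_trend
#' @param x A `sugar_trend` object.
#' @param ... Unused.
#' @export
tidy.sugar_trend <- function(x, ...) {
  # suppress summary.lm's perfect-fit warning: exact fits are legitimate here
  s <- suppressWarnings(summary(x$fit))$coefficients
  terms <- rownames(s)
  terms[1] <- "(Intercept)"
  terms[-1] <- sub("^g", "", terms[-1])
  tibble::tibble(
    term = terms,
    estimate = unname(s[, 1]), std.error = unname(s[, 2]),
    statistic = unname(s[, 3]), p.value = unname(s[, 4])
  )
}

#' @rdname weighted_trend
#' @export
glance.sugar_trend <- function(x, ...) {
  s <- suppressWarnings(summary(x$fit))
  tibble::tibble(
    r.squared = s$r.squared,
    sigma = s$sigma,
    df.residual = x$fit$df.residual,
    nobs = length(x$fit$residuals)
  )
}

#' Sugar-sweetened-beverage servings per day
#'
#' Per-respondent daily SSB servings: total grams of foods whose taxonomy
#' matches one of `ssb_tags` (case-insensitive, any level), divided by the
#' serving size. First recall day only, consistent with
#' [compute_daily_intake()].
#'
#' @param recalls Recall tibble.
#' @param table Food-table tibble (taxonomy columns used for tagging).
#' @param ssb_tags Taxonomy labels identifying sugar-sweetened beverages.
#' @param serving_g Serving size in grams, default 240.
#' @return Tibble `respondent_id`, `ssb_servings` (0 for respondents with no
#'   SSB records).
#' @export
ssb_servings <- function(recalls, table,
                         ssb_tags = c("soft drinks", "sweetened beverages",
                                      "sport drinks", "flavored water"),
                         serving_g = 240) {
  if (serving_g <= 0) abort("serving_g must be positive", class = "sugarstep_schema_error")
  tags <- tolower(ssb_tags)
  is_ssb <- rep(FALSE, nrow(table))
  for (col in c("group_l1", "group_l2", "group_l3")) {
    if (col %in% names(table)) {
      is_ssb <- is_ssb | tolower(trimws(table[[col]])) %in% tags
    }
  }
  ssb_ids <- table$food_id[is_ssb]
  recalls |>
    dplyr::group_by(.data$respondent_id) |>
    dplyr::filter(.data$day == min(.data$day)) |>
    dplyr::summarise(
      ssb_servings = sum(.data$amount_g[.data$food_id %in% ssb_ids]) / serving_g,
      .groups = "drop"
    )
}
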