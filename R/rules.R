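#' Default free-sugar rule table
#'
#' The shipped rule table encodes the two deterministic food-group lists of the
#' annotation cascade. `ZERO` groups are unprocessed or minimally processed
#' foods whose sugars are all intrinsic (spices, herbs, fats and oils, plain
#' cereal grains and flours, eggs, fresh/raw fruit, vegetables, legumes, meat
#' and seafood, non-sweetened beverages, plain milk, nuts, tubers): they get
#' 0 g free sugar. `FULL` groups contain no naturally occurring sugars, so all
#' their total sugar is free (sugars and syrups, confectionery, sweetened
#' beverages, cookies and biscuits, processed meat, coffee/beverage bases with
#' no milk solids, fruit juices, breakfast cereals without fruit or dairy).
#'
#' The table ships as a versioned CSV config
#' (`system.file("extdata", "default_rules.csv", package = "sugarstep")`)
#' rather than hard-coded labels: the lists are policy and users are expected
#' to edit them for their own taxonomy.
#'
#' @return A tibble with columns `level` (`"l1"`, `"l2"`, `"l3"`, `"any"` or
#'   `"food_id"`), `label` (matched case-insensitively, exact) and `action`
#'   (`"ZERO"` or `"FULL"`).
#' @export
default_rule_table <- function() {
  path <- system.file("extdata", "default_rules.csv", package = "sugarstep")
  read_rule_table(path)
}

#' Read a rule table from CSV or YAML
#'
#' CSV rules have columns `level`, `label`, `action`; YAML rules are a list of
#' mappings with the same keys. `level` says where the label is matched:
#' one of the three taxonomy levels, `"any"` level, or an explicit `"food_id"`
#' override (for items such as mixed dishes resolved from ingredient
#' information that no group label can capture).
#'
#' @param path Path to a `.csv`, `.yaml` or `.yml` rule file.
#' @return A validated rule-table tibble.
#' @export
read_rule_table <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("rule file not found: ", path), class = "sugarstep_io_error")
  }
  ext <- tolower(tools::file_ext(path))
  rules <- if (ext %in% c("yaml", "yml")) {
    purrr::map_dfr(yaml::read_yaml(path), tibble::as_tibble)
  } else {
    readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE, show_col_types = FALSE)
  }
  validate_rule_table(rules)
}

#' @rdname read_rule_table
#' @param rules A rule-table tibble.
#' @export
validate_rule_table <- function(rules) {
  need <- c("level", "label", "action")
  miss <- setdiff(need, names(rules))
  if (length(miss) > 0) {
    abort(paste0("rule table lacks column(s): ", paste(miss, collapse = ", ")),
          class = "sugarstep_schema_error")
  }
  rules <- tibble::as_tibble(rules[need])
  rules$level <- tolower(rules$level)
  rules$action <- toupper(rules$action)
  if (!all(rules$level %in% c("l1", "l2", "l3", "any", "food_id"))) {
    abort("rule level must be one of l1, l2, l3, any, food_id",
          class = "sugarstep_schema_error")
  }
  if (!all(rules$action %in% c("ZERO", "FULL"))) {
    abort("rule action must be ZERO or FULL", class = "sugarstep_schema_error")
  }
  # A label must not be claimed by both actions (food_id overrides aside,
  # which shadow group rules by precedence, not by conflict).
  grp <- rules[rules$level != "food_id", ]
  key <- tolower(grp$label)
  both <- intersect(key[grp$action == "ZERO"], key[grp$action == "FULL"])
  if (length(both) > 0) {
    abort(paste0("label(s) mapped to both ZERO and FULL: ",
                 paste(unique(both), collapse = ", ")),
          class = "sugarstep_integrity_error")
  }
  rules
}

# Vectorised rule match over a food table. Returns the action per food:
# "ZERO", "FULL" or NA. Precedence: food_id overrides beat group rules, and
# ZERO beats FULL on conflicting labels (the conservative choice).
match_rules <- function(table, rules) {
  n <- nrow(table)
  action <- rep(NA_character_, n)
  id_rules <- rules[rules$level == "food_id", ]
  grp_rules <- rules[rules$level != "food_id", ]

  hit <- function(rule_subset) {
    if (nrow(rule_subset) == 0) return(rep(FALSE, n))
    out <- rep(FALSE, n)
    for (lev in unique(rule_subset$level)) {
      labels <- tolower(rule_subset$label[rule_subset$level == lev])
      cols <- switch(lev,
        l1 = "group_l1", l2 = "group_l2", l3 = "group_l3",
        any = c("group_l1", "group_l2", "group_l3")
      )
      for (col in cols) {
        if (col %in% names(table)) {
          out <- out | tolower(trimws(table[[col]])) %in% labels
        }
      }
    }
    out
  }

  action[hit(grp_rules[grp_rules$action == "FULL", ])] <- "FULL"
  action[hit(grp_rules[grp_rules$action == "ZERO", ])] <- "ZERO"
  if (nrow(id_rules) > 0) {
    m <- match(table$food_id, id_rules$label)
    action[!is.na(m)] <- id_rules$action[m[!is.na(m)]]
  }
  action
}

#' Assign annotation steps to every food in a table
#'
#' Runs the deterministic part of the free-sugar cascade with strict
#' precedence:
#' \enumerate{
#'   \item foods with 0 g total sugar get 0 g free sugar (step 1);
#'   \item foods in a `ZERO` group get 0 g free sugar (step 2);
#'   \item foods in a `FULL` group get 100% of their total sugar as free sugar
#'     (step 3);
#'   \item every remaining food is routed to the predictive model (step 4,
#'     free sugar pending).
#' }
#' A food with missing total sugar can still receive step 2 (0 g needs no
#' total sugar) but cannot be resolved by steps 1, 3 or 4; it is returned as
#' `"unannotated"` with a warning and is excluded from downstream intake.
#'
#' @param table A food-table tibble.
#' @param rules A rule-table tibble; defaults to [default_rule_table()].
#' @return A tibble with one row per food: `food_id`, `step` (`"1"`..`"4"` or
#'   `"unannotated"`) and `free_sugar` (g/100 g; `NA` for step 4 pending and
#'   unannotated foods).
#' @examples
#' w <- generate_food_table(synthetic_config(n_foods = 100, seed = 7))
#' apply_rules(w$foods) |> dplyr::count(step)
#' @export
apply_rules <- function(table, rules = default_rule_table()) {
  validate_food_table(table)
  rules <- validate_rule_table(rules)
  if (nrow(table) == 0) {
    abort("apply_rules: empty table", class = "sugarstep_schema_error")
  }
  ts <- if ("total_sugar" %in% names(table)) table$total_sugar else rep(NA_real_, nrow(table))
  action <- match_rules(table, rules)

  step <- dplyr::case_when(
    !is.na(ts) & ts == 0          ~ "1",
    !is.na(action) & action == "ZERO" ~ "2",
    is.na(ts)                     ~ "unannotated",
    !is.na(action) & action == "FULL" ~ "3",
    TRUE                          ~ "4"
  )
  free_sugar <- dplyr::case_when(
    step %in% c("1", "2") ~ 0,
    step == "3"           ~ ts,
    TRUE                  ~ NA_real_
  )
  n_un <- sum(step == "unannotated")
  if (n_un > 0) {
    warn(paste0(n_un, " food(s) with missing total sugar could not be ",
                "annotated and are flagged 'unannotated'"))
  }
  tibble::tibble(food_id = table$food_id, step = step, free_sugar = free_sugar)
}

#' Summarize step assignments
#'
#' Counts and percentage shares of the table resolved by each annotation step,
#' optionally broken down by food group for the rule-resolved steps.
#' Percentages are reported to one decimal of the table size.
#'
#' @param assignments Assignment tibble from [apply_rules()] or
#'   [annotate_food_table()].
#' @param table Optional food-table tibble; required for `by_group = TRUE`.
#' @param by_group If `TRUE`, return per-(group, step) counts for steps 1-3
#'   instead of the per-step totals.
#' @return A tibble `step`, `n`, `pct` (per-step totals, all five step labels
#'   always present), or `group_l1`, `step`, `n`, `pct` when `by_group = TRUE`.
#' @export
summarize_steps <- function(assignments, table = NULL, by_group = FALSE) {
  total <- nrow(assignments)
  step_order <- c("1", "2", "3", "4", "unannotated")
  if (by_group) {
    if (is.null(table)) {
      abort("by_group = TRUE needs the food table", class = "sugarstep_schema_error")
    }
    out <- assignments |>
      dplyr::filter(.data$step %in% c("1", "2", "3")) |>
      dplyr::left_join(dplyr::select(table, "food_id", "group_l1"), by = "food_id") |>
      dplyr::count(.data$group_l1, .data$step, name = "n") |>
      dplyr::mutate(pct = round(100 * .data$n / total, 1)) |>
      dplyr::arrange(factor(.data$step, levels = step_order), .data$group_l1)
    return(out)
  }
  assignments |>
    dplyr::count(step = factor(.data$step, levels = step_order),
                 name = "n", .drop = FALSE) |>
    dplyr::mutate(step = as.character(.data$step),
                  pct = round(100 * .data$n / total, 1))
}
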