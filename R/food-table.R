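#' Read a food composition table
#'
#' Loads a delimited text file (UTF-8, comma-delimited, header row) into the
#' canonical food-table tibble: one food per row with an opaque `food_id`, a
#' display `name`, a three-level food-group taxonomy (`group_l1`, `group_l2`,
#' `group_l3`; levels 2-3 may be empty), nutrient amounts per 100 g edible
#' portion (`protein`, `carbohydrate`, `total_sugar`, `fiber`, `total_fat`,
#' `saturated_fat` in g; `sodium` in mg; `energy` in kcal) and, optionally, a
#' `known_free_sugar` column (g/100 g) used for model training and validation.
#'
#' Missing values may be encoded as empty strings or `"NA"`. Any other
#' unparseable numeric cell becomes missing with a warning. Units are fixed by
#' the schema and never guessed.
#'
#' @param path Path to a delimited text file with a header row.
#' @param schema Named character vector mapping canonical column names to the
#'   column names used in the file, e.g. `c(food_id = "code", protein =
#'   "prot_g")`. Canonical names absent from the schema are looked up verbatim.
#' @param delim Field delimiter, default `","`.
#' @param table_name Label attached to the returned table (used by
#'   [coverage_report()]); defaults to the file name.
#' @return A tibble with the canonical columns; absent optional columns are
#'   filled with `NA`. Carries the table label in attribute `"table_name"`.
#' @examples
#' path <- tempfile(fileext = ".csv")
#' writeLines(c(
#'   "food_id,name,group_l1,total_sugar,carbohydrate",
#'   "F1,White rice,Cereals and cereal products,0,28",
#'   "F2,Cola,Misc,10.6,10.6"
#' ), path)
#' read_food_table(path)
#' @export
read_food_table <- function(path, schema = NULL, delim = ",", table_name = NULL) {
  if (!file.exists(path)) {
    abort(paste0("food table file not found: ", path), class = "sugarstep_io_error")
  }
  raw <- readr::read_delim(
    path,
    delim = delim, col_types = readr::cols(.default = readr::col_character()),
    na = character(), progress = FALSE, show_col_types = FALSE
  )
  resolve <- function(canon) {
    if (!is.null(schema) && canon %in% names(schema)) schema[[canon]] else canon
  }
  mandatory <- c("food_id", "name", "group_l1")
  missing_cols <- mandatory[!purrr::map_chr(mandatory, resolve) %in% names(raw)]
  if (length(missing_cols) > 0) {
    abort(
      paste0("mandatory column(s) missing from ", path, ": ",
             paste(missing_cols, collapse = ", ")),
      class = "sugarstep_schema_error"
    )
  }

  out <- tibble::tibble(.rows = nrow(raw))
  character_cols <- c("food_id", "name", "group_l1", "group_l2", "group_l3")
  for (canon in character_cols) {
    src <- resolve(canon)
    out[[canon]] <- if (src %in% names(raw)) {
      v <- raw[[src]]
      dplyr::if_else(is.na(v), "", v)
    } else {
      rep("", nrow(raw))
    }
  }
  numeric_cols <- c(nutrient_columns, "known_free_sugar")
  for (canon in numeric_cols) {
    src <- resolve(canon)
    out[[canon]] <- if (src %in% names(raw)) {
      parse_numeric_cell(raw[[src]], canon, path)
    } else {
      rep(NA_real_, nrow(raw))
    }
  }

  dup <- out$food_id[duplicated(out$food_id)]
  if (length(dup) > 0) {
    abort(
      paste0("duplicate food_id in ", path, ": ",
             paste(unique(dup), collapse = ", ")),
      class = "sugarstep_integrity_error"
    )
  }
  validate_food_table(out)
  attr(out, "table_name") <- table_name %||% basename(path)
  out
}

parse_numeric_cell <- function(x, column, path) {
  blank <- is.na(x) | x == "" | toupper(trimws(x)) == "NA"
  parsed <- suppressWarnings(as.numeric(x))
  bad <- !blank & is.na(parsed)
  if (any(bad)) {
    warn(paste0(
      sum(bad), " unparseable value(s) in column '", column, "' of ", path,
      " set to missing (e.g. \"", x[which(bad)[1]], "\")"
    ))
  }
  parsed[blank] <- NA_real_
  parsed
}

#' Validate a food-table tibble
#'
#' Checks the canonical invariants: unique `food_id`; present nutrient values
#' non-negative; `total_sugar` at most 105% of `carbohydrate` when both are
#' present (5% slack for rounding; a violation is a warning, not an error);
#' `known_free_sugar`, when present, within `[0, total_sugar]`.
#'
#' @param table A food-table tibble.
#' @return The table, invisibly; raises on hard violations.
#' @export
validate_food_table <- function(table) {
  stopifnot(is.data.frame(table))
  need <- c("food_id", "name", "group_l1")
  miss <- setdiff(need, names(table))
  if (length(miss) > 0) {
    abort(paste0("food table lacks column(s): ", paste(miss, collapse = ", ")),
          class = "sugarstep_schema_error")
  }
  if (anyDuplicated(table$food_id) > 0) {
    abort("food table has duplicate food_id values",
          class = "sugarstep_integrity_error")
  }
  for (nut in intersect(c(nutrient_columns, "known_free_sugar"), names(table))) {
    v <- table[[nut]]
    if (any(!is.na(v) & v < 0)) {
      abort(paste0("negative values in nutrient column '", nut, "'"),
            class = "sugarstep_integrity_error")
    }
  }
  if (all(c("total_sugar", "carbohydrate") %in% names(table))) {
    ts <- table$total_sugar
    cho <- table$carbohydrate
    bad <- !is.na(ts) & !is.na(cho) & ts > 1.05 * cho
    if (any(bad)) {
      warn(paste0(sum(bad), " food(s) have total_sugar > 105% of carbohydrate ",
                  "(e.g. ", table$food_id[which(bad)[1]], ")"))
    }
  }
  if (all(c("known_free_sugar", "total_sugar") %in% names(table))) {
    fs <- table$known_free_sugar
    ts <- table$total_sugar
    bad <- !is.na(fs) & (fs < 0 | (!is.na(ts) & fs > ts + 1e-9))
    if (any(bad)) {
      abort(paste0("known_free_sugar outside [0, total_sugar] for: ",
                   paste(head(table$food_id[bad], 5), collapse = ", ")),
            class = "sugarstep_integrity_error")
    }
  }
  invisible(table)
}

#' Write an annotated food table
#'
#' Writes the input table plus two annotation columns: `free_sugar_g_100g`
#' (the assigned free-sugar content) and `imputation_step` (`"1"`, `"2"`,
#' `"3"`, `"4"` or `"unannotated"`). Reading the file back with
#' [read_food_table()] is lossless for the canonical columns.
#'
#' @param table A food-table tibble.
#' @param assignments Step assignments from [apply_rules()] or
#'   [annotate_food_table()]: a tibble with `food_id`, `step`, `free_sugar`.
#' @param path Output file path (comma-delimited, UTF-8).
#' @return `path`, invisibly.
#' @export
write_annotated_table <- function(table, assignments, path) {
  validate_food_table(table)
  unknown <- setdiff(assignments$food_id, table$food_id)
  if (length(unknown) > 0) {
    abort(paste0("assignments reference unknown food_id: ",
                 paste(head(unknown, 5), collapse = ", ")),
          class = "sugarstep_integrity_error")
  }
  if (anyDuplicated(assignments$food_id) > 0) {
    abort("more than one assignment for a food_id",
          class = "sugarstep_integrity_error")
  }
  out <- dplyr::left_join(
    dplyr::select(table, dplyr::any_of(canonical_columns)),
    dplyr::select(assignments, "food_id",
                  free_sugar_g_100g = "free_sugar", imputation_step = "step"),
    by = "food_id"
  ) |>
    dplyr::mutate(
      imputation_step = dplyr::coalesce(as.character(.data$imputation_step),
                                        "unannotated")
    )
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Nutrient coverage report
#'
#' For each table, the percentage of foods with a non-missing value in each of
#' the seven model predictors (protein, carbohydrate, total sugar, fiber,
#' total fat, saturated fat, sodium), reported to one decimal. Coverage of the
#' predictors is what determines how many foods the step-4 model can score.
#'
#' @param tables A single food-table tibble or a (optionally named) list of
#'   them.
#' @return A tibble with one row per table: `table`, `n_foods` and one
#'   percentage column per predictor.
#' @examples
#' w <- generate_food_table(synthetic_config(n_foods = 50, seed = 1))
#' coverage_report(w$foods)
#' @export
coverage_report <- function(tables) {
  if (is.data.frame(tables)) tables <- list(tables)
  if (length(tables) == 0) {
    abort("coverage_report needs at least one table", class = "sugarstep_schema_error")
  }
  labels <- names(tables)
  if (is.null(labels)) labels <- rep("", length(tables))
  purrr::imap_dfr(tables, function(tab, i) {
    if (nrow(tab) == 0) {
      abort("coverage_report: empty table", class = "sugarstep_schema_error")
    }
    label <- if (is.character(i) && nzchar(i)) {
      i
    } else {
      attr(tab, "table_name") %||% paste0("table_", i)
    }
    pct <- purrr::map_dbl(predictor_nutrients, function(nut) {
      v <- if (nut %in% names(tab)) tab[[nut]] else rep(NA_real_, nrow(tab))
      round(100 * sum(!is.na(v)) / nrow(tab), 1)
    })
    tibble::tibble(table = label, n_foods = nrow(tab)) |>
      dplyr::bind_cols(tibble::as_tibble(as.list(setNames(pct, predictor_nutrients))))
  })
}
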