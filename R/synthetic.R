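#' Configuration for the synthetic world
#'
#' Defaults emulate the structure of a national food composition table and
#' recall survey: 1547 foods split across a 12-group taxonomy with roughly
#' 19.5% zero-total-sugar foods, ~43% zero-free-sugar rule groups, ~10%
#' all-free-sugar rule groups and the remaining ~27% mixed recipes that only
#' the predictive model can resolve; multiplicative lognormal analytic noise
#' (sd 0.05) on nutrient totals; an 800-respondent two-day recall survey with
#' a five-level wealth variable (quintile shares echoing a national survey,
#' 0.5% missing) and planted per-quintile free-sugar offsets of
#' (0, 2.5, 5, 6, 9) g/day.
#'
#' All randomness flows from `seed` through a fixed stream-splitting scheme:
#' the food table uses `seed + 1`, the recall survey `seed + 2`, menu plans
#' `seed + 3`, so each artifact can be regenerated independently.
#'
#' @param n_foods Number of foods in the generated table.
#' @param zero_ts_fraction Share of foods constructed with 0 g total sugar.
#' @param rule_zero_fraction Share in zero-free-sugar groups (positive total
#'   sugar, all intrinsic).
#' @param rule_full_fraction Share in 100%-free-sugar groups.
#' @param noise_sd Standard deviation of the multiplicative lognormal noise
#'   applied to nutrient totals; 0 gives exact mixture sums.
#' @param max_ingredients Ingredients per mixed recipe are drawn from
#'   `2:max_ingredients` (capped at 5).
#' @param n_respondents,n_days Survey size and recall days per respondent.
#' @param wealth_probs Probabilities of the five wealth quintiles (normalized).
#' @param missing_wealth_fraction Share of respondents with missing wealth.
#' @param wealth_offsets_g Planted expected extra free-sugar intake (g/day)
#'   per wealth level, lowest first; all zeros plants no gradient.
#' @param seed Master seed.
#' @return A config list, validated.
#' @export
synthetic_config <- function(n_foods = 1547,
                             zero_ts_fraction = 0.195,
                             rule_zero_fraction = 0.43,
                             rule_full_fraction = 0.10,
                             noise_sd = 0.05,
                             max_ingredients = 5,
                             n_respondents = 800,
                             n_days = 2,
                             wealth_probs = c(0.253, 0.242, 0.198, 0.163, 0.139),
                             missing_wealth_fraction = 0.005,
                             wealth_offsets_g = c(0, 2.5, 5, 6, 9),
                             seed = 1L) {
  fractions <- c(zero_ts_fraction, rule_zero_fraction, rule_full_fraction)
  if (any(fractions < 0) || sum(fractions) > 1) {
    abort("step fractions must be non-negative and sum to at most 1",
          class = "sugarstep_schema_error")
  }
  if (n_foods < 1) abort("n_foods must be >= 1", class = "sugarstep_schema_error")
  if (length(wealth_offsets_g) != 5) {
    abort("wealth_offsets_g needs one offset per quintile",
          class = "sugarstep_schema_error")
  }
  list(
    n_foods = as.integer(n_foods),
    zero_ts_fraction = zero_ts_fraction,
    rule_zero_fraction = rule_zero_fraction,
    rule_full_fraction = rule_full_fraction,
    noise_sd = noise_sd,
    max_ingredients = min(as.integer(max_ingredients), 5L),
    n_respondents = as.integer(n_respondents),
    n_days = as.integer(n_days),
    wealth_probs = wealth_probs / sum(wealth_probs),
    missing_wealth_fraction = missing_wealth_fraction,
    wealth_offsets_g = wealth_offsets_g,
    seed = as.integer(seed)
  )
}

# Ingredient archetypes for mixed recipes: per-100 g nutrient densities and
# whether their sugar counts as free (added sugar, honey, syrup, fruit juice
# concentrate) or intrinsic (intact fruit, vegetable, dairy, grain).
recipe_archetypes <- function() {
  tibble::tribble(
    ~name,          ~sugar_type, ~protein, ~carbohydrate, ~sugar, ~fiber, ~total_fat, ~saturated_fat, ~sodium,
    "wheat_flour",  "intrinsic", 10.3,     73.0,          0.5,    2.7,    1.0,        0.2,            2,
    "rice",         "intrinsic", 7.1,      79.0,          0.1,    1.3,    0.7,        0.2,            5,
    "milk",         "intrinsic", 3.4,      4.8,           4.8,    0.0,    3.3,        2.1,            44,
    "fruit_pulp",   "intrinsic", 0.8,      14.0,          10.0,   2.4,    0.3,        0.1,            2,
    "vegetable",    "intrinsic", 2.0,      5.0,           2.5,    2.0,    0.3,        0.1,            20,
    "egg",          "intrinsic", 12.6,     0.7,           0.4,    0.0,    9.5,        3.1,            140,
    "meat",         "intrinsic", 26.0,     0.0,           0.0,    0.0,    10.0,       4.0,            70,
    "coconut",      "intrinsic", 3.3,      15.0,          6.2,    9.0,    33.0,       29.0,           20,
    "butter_oil",   "intrinsic", 0.5,      0.1,           0.1,    0.0,    85.0,       40.0,           10,
    "table_sugar",  "free",      0.0,      99.8,          99.8,   0.0,    0.0,        0.0,            1,
    "honey",        "free",      0.3,      82.0,          75.0,   0.2,    0.0,        0.0,            4,
    "syrup",        "free",      0.0,      76.0,          65.0,   0.0,    0.0,        0.0,            60,
    "juice_conc",   "free",      0.5,      45.0,          42.0,   0.3,    0.1,        0.0,            5
  )
}

# Recipe patterns for model-step foods: which archetypes each food-group
# template draws from, and the Dirichlet concentration of the free-sugar
# ingredients relative to the base.
recipe_patterns <- function() {
  list(
    list(group_l1 = "Cereals and cereal products", group_l2 = "mixed cereal dishes",
         base = c("wheat_flour", "rice", "milk", "butter_oil", "egg"),
         free = c("table_sugar", "syrup", "honey")),
    list(group_l1 = "Milk and milk products", group_l2 = "sweetened dairy",
         base = c("milk", "butter_oil", "coconut"),
         free = c("table_sugar", "syrup")),
    list(group_l1 = "Misc", group_l2 = "mixed dishes",
         base = c("rice", "meat", "vegetable", "butter_oil", "coconut"),
         free = c("table_sugar", "syrup", "honey")),
    list(group_l1 = "Other fruits and veg", group_l2 = "fruit preparations",
         base = c("fruit_pulp", "vegetable"),
         free = c("table_sugar", "juice_conc", "honey")),
    list(group_l1 = "Fish meat and poultry", group_l2 = "mixed meat dishes",
         base = c("meat", "rice", "vegetable", "butter_oil"),
         free = c("table_sugar", "syrup"))
  )
}

# Single-template foods for the deterministic steps. `fs_rule` says what the
# generator expects the cascade to do with them.
simple_templates <- function() {
  U <- function(lo, hi) c(lo, hi)
  list(
    # zero total sugar (intended step 1)
    list(step = "1", l1 = "Fish meat and poultry", l2 = "fresh meat",
         protein = U(15, 30), carbohydrate = U(0, 0), sugar = U(0, 0),
         fiber = U(0, 0), total_fat = U(2, 20), sodium = U(40, 120)),
    list(step = "1", l1 = "Fish meat and poultry", l2 = "fresh fish and meat",
         protein = U(15, 25), carbohydrate = U(0, 0), sugar = U(0, 0),
         fiber = U(0, 0), total_fat = U(1, 12), sodium = U(50, 150)),
    list(step = "1", l1 = "Fish meat and poultry", l2 = "organ meat",
         protein = U(15, 25), carbohydrate = U(0, 4), sugar = U(0, 0),
         fiber = U(0, 0), total_fat = U(3, 10), sodium = U(60, 150)),
    list(step = "1", l1 = "Fats and oils", l2 = "fats and oils",
         protein = U(0, 1), carbohydrate = U(0, 0), sugar = U(0, 0),
         fiber = U(0, 0), total_fat = U(80, 100), sodium = U(0, 600)),
    list(step = "1", l1 = "Misc", l2 = "alcoholic beverages",
         protein = U(0, 1), carbohydrate = U(0, 5), sugar = U(0, 0),
         fiber = U(0, 0), total_fat = U(0, 0), sodium = U(0, 20)),
    # zero-free-sugar groups with positive total sugar (intended step 2)
    list(step = "2", l1 = "Eggs", l2 = "eggs",
         protein = U(10, 14), carbohydrate = U(0.5, 3), sugar = U(0.1, 2.5),
         fiber = U(0, 0), total_fat = U(8, 12), sodium = U(120, 160)),
    list(step = "2", l1 = "Other fruits and veg", l2 = "fruits",
         protein = U(0.3, 1.5), carbohydrate = U(8, 25), sugar = U(2, 15),
         fiber = U(1, 4), total_fat = U(0, 1), sodium = U(0, 10)),
    list(step = "2", l1 = "Green leafy and yellow vegetables", l2 = "vegetables",
         protein = U(1, 4), carbohydrate = U(3, 12), sugar = U(0.5, 8),
         fiber = U(1, 4), total_fat = U(0, 1), sodium = U(5, 80)),
    list(step = "2", l1 = "Dried beans nuts and seeds", l2 = "dried beans nuts and seeds",
         protein = U(15, 25), carbohydrate = U(15, 30), sugar = U(1, 8),
         fiber = U(5, 12), total_fat = U(10, 50), sodium = U(1, 20)),
    list(step = "2", l1 = "Starchy roots and tubers", l2 = "tubers",
         protein = U(1, 3), carbohydrate = U(15, 30), sugar = U(0.5, 5),
         fiber = U(1, 4), total_fat = U(0, 1), sodium = U(5, 60)),
    list(step = "2", l1 = "Cereals and cereal products", l2 = "plain cereals",
         protein = U(6, 13), carbohydrate = U(60, 80), sugar = U(0.1, 2),
         fiber = U(1, 4), total_fat = U(0.5, 3), sodium = U(1, 10)),
    list(step = "2", l1 = "Milk and milk products", l2 = "plain milk",
         protein = U(3, 4), carbohydrate = U(4.5, 5.2), sugar = U(4.4, 5.0),
         fiber = U(0, 0), total_fat = U(1, 4), sodium = U(35, 55)),
    list(step = "2", l1 = "Vitamin C rich foods", l2 = "fresh fruit",
         protein = U(0.5, 1.5), carbohydrate = U(6, 18), sugar = U(3, 12),
         fiber = U(1, 3), total_fat = U(0, 1), sodium = U(0, 10)),
    # 100%-free-sugar groups (intended step 3)
    list(step = "3", l1 = "Sugars and syrups", l2 = "sugars and syrups",
         protein = U(0, 0.5), carbohydrate = U(25, 100), sugar = U(20, 100),
         fiber = U(0, 0), total_fat = U(0, 0.5), sodium = U(0, 60)),
    list(step = "3", l1 = "Misc", l2 = "soft drinks",
         protein = U(0, 0), carbohydrate = U(8, 13), sugar = U(8, 13),
         fiber = U(0, 0), total_fat = U(0, 0), sodium = U(0, 20)),
    list(step = "3", l1 = "Cereals and cereal products", l2 = "cookies",
         protein = U(5, 8), carbohydrate = U(55, 75), sugar = U(15, 35),
         fiber = U(1, 3), total_fat = U(10, 25), sodium = U(100, 400)),
    list(step = "3", l1 = "Fish meat and poultry", l2 = "processed meat",
         protein = U(10, 20), carbohydrate = U(1, 8), sugar = U(0.5, 4),
         fiber = U(0, 0), total_fat = U(10, 30), sodium = U(600, 1200)),
    list(step = "3", l1 = "Misc", l2 = "coffee and beverage base with no milk",
         protein = U(0, 2), carbohydrate = U(35, 80), sugar = U(30, 70),
         fiber = U(0, 1), total_fat = U(0, 2), sodium = U(5, 100)),
    list(step = "3", l1 = "Other fruits and veg", l2 = "fruit juices",
         protein = U(0, 0.5), carbohydrate = U(9, 15), sugar = U(8, 14),
         fiber = U(0, 0.5), total_fat = U(0, 0), sodium = U(0, 10))
  )
}

draw_range <- function(range, n = 1) runif(n, range[1], range[2])

#' Generate a synthetic food composition table with ground truth
#'
#' Builds a food table in which every food's free-sugar content is known by
#' construction. Deterministic-step foods come from single templates (zero
#' total sugar; zero-free-sugar groups whose sugars are all intrinsic;
#' all-free-sugar groups). Model-step foods are Dirichlet-weighted recipes of
#' 2-5 ingredient archetypes: their true free sugar is the sugar contributed
#' by free-type ingredients (added sugar, honey, syrup, juice concentrate),
#' while the table's nutrient totals carry multiplicative lognormal analytic
#' noise. Total sugar is floored at the true free sugar so the defining
#' constraint free sugar <= total sugar survives the noise.
#'
#' @param config A [synthetic_config()].
#' @return A `sugar_world` list: `foods` (canonical food table, with
#'   `known_free_sugar` set to the ground truth), `truth` (`food_id`,
#'   `true_free_sugar`, `true_intrinsic_sugar`), `bookkeeping` (`food_id`,
#'   `intended_step`), `config`.
#' @examples
#' w <- generate_food_table(synthetic_config(n_foods = 200, seed = 42))
#' dplyr::count(w$bookkeeping, intended_step)
#' @export
generate_food_table <- function(config = synthetic_config()) {
  set.seed(config$seed + 1L)
  n <- config$n_foods
  n1 <- round(n * config$zero_ts_fraction)
  n2 <- round(n * config$rule_zero_fraction)
  n3 <- round(n * config$rule_full_fraction)
  n4 <- n - n1 - n2 - n3
  if (n4 < 0) {
    abort("infeasible group mix: fractions leave no room for model foods",
          class = "sugarstep_schema_error")
  }

  templates <- simple_templates()
  tmpl_step <- purrr::map_chr(templates, "step")
  counts <- c("1" = n1, "2" = n2, "3" = n3)
  simple_rows <- purrr::map_dfr(names(counts), function(s) {
    k <- counts[[s]]
    if (k == 0) return(NULL)
    idx <- sample(which(tmpl_step == s), k, replace = TRUE)
    purrr::map_dfr(idx, function(i) {
      t <- templates[[i]]
      sugar <- draw_range(t$sugar)
      carb <- max(draw_range(t$carbohydrate), sugar)
      fat <- draw_range(t$total_fat)
      tibble::tibble(
        group_l1 = t$l1, group_l2 = t$l2, intended_step = s,
        protein = draw_range(t$protein), carbohydrate = carb,
        total_sugar = sugar, fiber = draw_range(t$fiber),
        total_fat = fat, saturated_fat = fat * runif(1, 0.2, 0.5),
        sodium = draw_range(t$sodium),
        true_free_sugar = dplyr::case_when(s == "3" ~ sugar, TRUE ~ 0),
        true_intrinsic_sugar = dplyr::case_when(s == "3" ~ 0, TRUE ~ sugar)
      )
    })
  })

  arch <- recipe_archetypes()
  patterns <- recipe_patterns()
  mixed_rows <- purrr::map_dfr(seq_len(n4), function(i) {
    pat <- patterns[[sample.int(length(patterns), 1)]]
    k <- sample(2:config$max_ingredients, 1)
    n_free <- if (runif(1) < 0.85) sample(1:min(2, k - 1), 1) else 0
    ingredients <- c(
      sample(pat$base, k - n_free, replace = TRUE),
      if (n_free > 0) sample(pat$free, n_free, replace = TRUE)
    )
    w <- rgamma(k, shape = c(rep(3, k - n_free), rep(1, n_free)))
    w <- w / sum(w)
    rows <- arch[match(ingredients, arch$name), ]
    mix <- function(col) sum(w * rows[[col]])
    free_sugar <- sum(w * rows$sugar * (rows$sugar_type == "free"))
    tibble::tibble(
      group_l1 = pat$group_l1, group_l2 = pat$group_l2, intended_step = "4",
      protein = mix("protein"), carbohydrate = mix("carbohydrate"),
      total_sugar = mix("sugar"), fiber = mix("fiber"),
      total_fat = mix("total_fat"), saturated_fat = mix("saturated_fat"),
      sodium = mix("sodium"),
      true_free_sugar = free_sugar,
      true_intrinsic_sugar = mix("sugar") - free_sugar
    )
  })

  foods <- dplyr::bind_rows(simple_rows, mixed_rows)
  foods <- foods[sample.int(nrow(foods)), ]
  foods$food_id <- sprintf("F%04d", seq_len(nrow(foods)))
  foods$name <- paste0(foods$group_l2, " ", seq_len(nrow(foods)))
  foods$group_l3 <- ""

  # Analytic noise on the measured totals; ground-truth free sugar is fixed
  # first, so the model's task carries irreducible noise. Flooring keeps the
  # invariant FS <= TS.
  noisy <- function(v) v * rlnorm(length(v), 0, config$noise_sd)
  for (col in c("protein", "carbohydrate", "fiber", "total_fat",
                "saturated_fat", "sodium")) {
    foods[[col]] <- noisy(foods[[col]])
  }
  foods$total_sugar <- pmax(noisy(foods$total_sugar), foods$true_free_sugar)
  # Step-3 foods are all-free-sugar by construction: their truth tracks the
  # measured total.
  idx3 <- foods$intended_step == "3"
  foods$true_free_sugar[idx3] <- foods$total_sugar[idx3]
  foods$carbohydrate <- pmax(foods$carbohydrate, foods$total_sugar)
  foods$energy <- noisy(4 * (foods$protein + foods$carbohydrate) +
                          9 * foods$total_fat)
  foods$known_free_sugar <- foods$true_free_sugar

  table <- dplyr::select(foods, dplyr::all_of(canonical_columns))
  attr(table, "table_name") <- "synthetic"
  validate_food_table(table)
  structure(
    list(
      foods = table,
      truth = dplyr::select(foods, "food_id", "true_free_sugar",
                            "true_intrinsic_sugar"),
      bookkeeping = dplyr::select(foods, "food_id", "intended_step"),
      config = config
    ),
    class = "sugar_world"
  )
}

#' Generate a weighted 24 h-recall survey over a synthetic world
#'
#' Respondents carry demographics, a positive survey weight (lognormal,
#' independent of wealth so weighted estimators stay unbiased), a five-level
#' wealth variable and an age-appropriate nutritional-status category.
#' Each recall day has the three main meals always and snack occasions with
#' fixed probabilities; snack occasions preferentially draw free-sugar-rich
#' foods, main meals draw staples. The wealth gradient is planted by extra
#' sweetened-beverage consumption whose expected free-sugar contribution per
#' day equals the configured per-quintile offset exactly, so trend models
#' have a known estimand.
#'
#' @param world A `sugar_world` from [generate_food_table()].
#' @param config Defaults to the world's config.
#' @return A list: `recalls` (`respondent_id`, `day`, `meal`, `food_id`,
#'   `amount_g`), `respondents` (`respondent_id`, `age`, `sex`,
#'   `survey_weight`, `wealth`, `bmi_category`, `baz_category`).
#' @export
generate_recall_survey <- function(world, config = world$config) {
  set.seed(config$seed + 2L)
  n <- config$n_respondents
  foods <- world$foods
  truth <- world$truth

  age <- runif(n, 4, 85)
  wealth <- sample(wealth_levels, n, replace = TRUE, prob = config$wealth_probs)
  wealth[runif(n) < config$missing_wealth_fraction] <- NA
  wealth <- factor(wealth, levels = wealth_levels)
  adult <- age >= 19
  respondents <- tibble::tibble(
    respondent_id = sprintf("R%05d", seq_len(n)),
    age = age,
    sex = sample(c("male", "female"), n, replace = TRUE),
    survey_weight = rlnorm(n, 0, 0.5),
    wealth = wealth,
    bmi_category = ifelse(adult,
      sample(c("CED", "normal", "overweight", "obese"), n, replace = TRUE,
             prob = c(0.1, 0.6, 0.22, 0.08)), NA),
    baz_category = ifelse(!adult,
      sample(c("severely_thin", "thin", "normal", "overweight", "obese"), n,
             replace = TRUE, prob = c(0.02, 0.08, 0.78, 0.07, 0.05)), NA)
  )

  fs_conc <- truth$true_free_sugar[match(foods$food_id, truth$food_id)]
  staple_ids <- foods$food_id[fs_conc <= 1]
  sweet_ids <- foods$food_id[fs_conc > 5]
  if (length(sweet_ids) == 0) sweet_ids <- foods$food_id
  ssb_ids <- foods$food_id[tolower(foods$group_l2) == "soft drinks"]
  gradient_id <- if (length(ssb_ids) > 0) ssb_ids[1] else sweet_ids[1]
  gradient_conc <- fs_conc[match(gradient_id, foods$food_id)]

  # Serving sizes scale inversely with free-sugar concentration: sugary
  # concentrates are eaten by the spoonful, beverages and staples by the
  # plate or glass.
  amount_for <- function(ids) {
    conc <- fs_conc[match(ids, foods$food_id)]
    dplyr::case_when(
      conc > 20 ~ runif(length(ids), 5, 40),
      conc > 5  ~ runif(length(ids), 50, 300),
      TRUE      ~ runif(length(ids), 40, 300)
    )
  }

  offsets <- setNames(config$wealth_offsets_g, wealth_levels)
  delta <- ifelse(is.na(wealth), 0, offsets[as.character(wealth)])
  snack_meals <- c(am_snack = 0.5, pm_snack = 0.7, late_pm_snack = 0.1)

  # One row per respondent-day; all occasions drawn vectorised.
  m <- n * config$n_days
  rid_day <- tibble::tibble(
    respondent_id = rep(respondents$respondent_id, each = config$n_days),
    day = rep(seq_len(config$n_days), times = n),
    delta = rep(delta, each = config$n_days)
  )

  parts <- list()
  for (meal in c("breakfast", "lunch", "supper")) {
    k <- sample(1:3, m, replace = TRUE)
    occ <- rep(seq_len(m), k)
    fid <- sample(staple_ids, length(occ), replace = TRUE)
    if (meal == "breakfast") {
      sweet_here <- which(runif(m) < 0.35)
      first_row <- cumsum(k) - k + 1
      fid[first_row[sweet_here]] <- sample(sweet_ids, length(sweet_here),
                                           replace = TRUE)
    }
    parts[[meal]] <- tibble::tibble(
      respondent_id = rid_day$respondent_id[occ], day = rid_day$day[occ],
      meal = meal, food_id = fid, amount_g = amount_for(fid)
    )
  }
  for (meal in names(snack_meals)) {
    present <- which(runif(m) < snack_meals[[meal]])
    sweet_pick <- runif(length(present)) < 0.6
    fid <- character(length(present))
    fid[sweet_pick] <- sample(sweet_ids, sum(sweet_pick), replace = TRUE)
    fid[!sweet_pick] <- sample(staple_ids, sum(!sweet_pick), replace = TRUE)
    parts[[meal]] <- tibble::tibble(
      respondent_id = rid_day$respondent_id[present],
      day = rid_day$day[present],
      meal = meal, food_id = fid, amount_g = amount_for(fid)
    )
  }
  grad <- which(rid_day$delta > 0)
  if (length(grad) > 0 && gradient_conc > 0) {
    parts[["gradient"]] <- tibble::tibble(
      respondent_id = rid_day$respondent_id[grad],
      day = rid_day$day[grad],
      meal = "pm_snack", food_id = gradient_id,
      amount_g = rid_day$delta[grad] / gradient_conc * 100 *
        rgamma(length(grad), shape = 4, rate = 4)
    )
  }
  recalls <- dplyr::bind_rows(parts) |>
    dplyr::arrange(.data$respondent_id, .data$day)
  list(recalls = recalls, respondents = respondents)
}

#' Generate menu plans over a synthetic world
#'
#' Weekly menu plans with realistic daily baskets (5-12 foods per day,
#' 20-300 g each), used to measure how per-food annotation errors combine at
#' the daily-intake level ([evaluate_menu()]). Ground-truth grams per day are
#' computable from the world's truth table.
#'
#' @param world A `sugar_world`.
#' @param n_plans Number of plans (default 2).
#' @param days Days per plan (default 7).
#' @param config Defaults to the world's config.
#' @return Tibble `plan`, `day`, `food_id`, `amount_g`.
#' @export
generate_menu_plans <- function(world, n_plans = 2, days = 7,
                                config = world$config) {
  if (days < 1) abort("days must be >= 1", class = "sugarstep_schema_error")
  set.seed(config$seed + 3L)
  ids <- world$foods$food_id
  purrr::map_dfr(seq_len(n_plans), function(p) {
    purrr::map_dfr(seq_len(days), function(d) {
      k <- sample(5:12, 1)
      tibble::tibble(
        plan = p, day = d,
        food_id = sample(ids, k, replace = FALSE),
        amount_g = runif(k, 20, 300)
      )
    })
  })
}
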