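annotated_two_foods <- tibble::tibble(
  food_id = c("A", "B"),
  free_sugar = c(5, 0), total_sugar = c(6, 1), energy = c(50, 100)
)

test_that("daily intake follows the per-100 g arithmetic", {
  recalls <- tibble::tibble(
    respondent_id = "R1", day = 1, meal = "breakfast",
    food_id = c("A", "B"), amount_g = c(200, 100)
  )
  out <- compute_daily_intake(recalls, annotated_two_foods)
  expect_equal(out$fs_g, 10)
  expect_equal(out$energy_kcal, 200)
  expect_equal(out$fs_pct_energy, 20.0)
})

test_that("only the first recall day contributes under the default rule", {
  recalls <- tibble::tibble(
    respondent_id = "R1", day = c(1, 2), meal = "lunch",
    food_id = "A", amount_g = c(100, 900)
  )
  out <- compute_daily_intake(recalls, annotated_two_foods)
  expect_equal(out$fs_g, 5)
  both <- compute_daily_intake(recalls, annotated_two_foods, day_rule = "all")
  expect_equal(both$fs_g, (5 + 45) / 2)
})

test_that("zero-energy days yield a missing percent of energy", {
  ann <- tibble::tibble(food_id = "Z", free_sugar = 0, total_sugar = 0, energy = 0)
  recalls <- tibble::tibble(respondent_id = "R1", day = 1, meal = "lunch",
                            food_id = "Z", amount_g = 100)
  out <- compute_daily_intake(recalls, ann)
  expect_equal(out$fs_g, 0)
  expect_true(is.na(out$fs_pct_energy))
})

test_that("unannotated foods contribute zero and are counted", {
  ann <- tibble::tibble(food_id = c("A", "U"), free_sugar = c(5, NA),
                        total_sugar = c(6, 3), energy = c(50, 80))
  recalls <- tibble::tibble(respondent_id = "R1", day = 1, meal = "supper",
                            food_id = c("A", "U"), amount_g = c(100, 100))
  expect_message(out <- compute_daily_intake(recalls, ann), "unannotated")
  expect_equal(out$fs_g, 5)
  expect_equal(out$n_unannotated, 1L)
})

test_that("respondents without recalls are absent, unknown foods error", {
  recalls <- tibble::tibble(respondent_id = "R2", day = 1, meal = "lunch",
                            food_id = "A", amount_g = 50)
  out <- compute_daily_intake(recalls, annotated_two_foods)
  expect_equal(out$respondent_id, "R2")
  bad <- dplyr::mutate(recalls, food_id = "GHOST")
  expect_error(compute_daily_intake(bad, annotated_two_foods),
               class = "sugarstep_integrity_error")
})

test_that("weighted mean and SE follow the linearization formulas", {
  out <- weighted_mean_se(values = c(2, 4), weights = c(1, 3))
  expect_equal(out$mean, 3.5)
  expect_equal(out$se, 0.75)

  # equal weights reduce to the classical estimators
  set.seed(18)
  x <- rnorm(30)
  for (c_w in c(1, 2.5)) {
    eq <- weighted_mean_se(values = x, weights = rep(c_w, 30))
    expect_equal(eq$mean, mean(x))
    expect_equal(eq$se, sqrt(var(x) / 30))
  }

  const <- weighted_mean_se(values = rep(7, 10), weights = runif(10, 1, 2))
  expect_equal(const$se, 0)
  expect_error(weighted_mean_se(values = 1, weights = 1),
               class = "sugarstep_schema_error")
})

test_that("meal summaries are unweighted per-occasion statistics", {
  ann <- tibble::tibble(food_id = "S", free_sugar = 10)
  recalls <- tibble::tibble(
    respondent_id = c("R1", "R2", "R3"), day = 1, meal = "pm_snack",
    food_id = "S", amount_g = c(20, 40, 90)  # occasions: 2, 4, 9 g FS
  )
  out <- meal_type_summary(recalls, ann)
  expect_equal(out$mean, 5)
  expect_equal(out$median, 4)
  expect_equal(out$n, 3L)

  expect_error(meal_type_summary(dplyr::mutate(recalls, meal = "brunch"), ann),
               class = "sugarstep_schema_error")
})

test_that("meal summaries match a brute-force group-by oracle", {
  w <- generate_food_table(synthetic_config(n_foods = 200, n_respondents = 80,
                                            seed = 61))
  s <- generate_recall_survey(w)
  ann <- dplyr::rename(w$truth, free_sugar = true_free_sugar)
  out <- meal_type_summary(s$recalls, ann)
  fs_of <- setNames(ann$free_sugar, ann$food_id)
  occ <- aggregate(
    fs ~ respondent_id + day + meal,
    data = transform(as.data.frame(s$recalls),
                     fs = amount_g / 100 * fs_of[food_id]),
    FUN = sum
  )
  for (m in out$meal) {
    v <- occ$fs[occ$meal == m]
    expect_equal(out$mean[out$meal == m], mean(v))
    expect_equal(out$median[out$meal == m], median(v))
  }
})

test_that("Kruskal-Wallis reproduces the hand-ranked example", {
  out <- kruskal_wallis(values = c(1, 2, 3, 4, 5, 6),
                        groups = rep(c("a", "b"), each = 3))
  expect_equal(out$statistic, 3.857, tolerance = 5e-4)
  expect_equal(out$df, 1)

  same <- kruskal_wallis(values = c(1, 2, 3, 1, 2, 3),
                         groups = rep(c("a", "b"), each = 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
  expect_error(kruskal_wallis(values = 1:4, groups = rep("a", 4)),
               class = "sugarstep_schema_error")
})

test_that("Dunn z reproduces the hand computation and BH the step-up", {
  out <- dunn_posthoc_bh(values = c(1, 2, 3, 4, 5, 6),
                         groups = rep(c("a", "b"), each = 3))
  expect_equal(abs(out$z), 1.964, tolerance = 5e-4)

  same <- dunn_posthoc_bh(values = c(1, 2, 3, 1, 2, 3),
                          groups = rep(c("a", "b"), each = 3))
  expect_equal(same$z, 0)
  expect_equal(same$p.adjusted, 1)

  expect_equal(p.adjust(c(0.01, 0.04, 0.03), method = "BH"),
               c(0.03, 0.04, 0.04))
  expect_equal(oracle_bh(c(0.01, 0.04, 0.03)), c(0.03, 0.04, 0.04))
})

test_that("rank statistics are invariant under monotone transforms", {
  set.seed(29)
  x <- rlnorm(40)
  g <- sample(c("a", "b", "c"), 40, replace = TRUE)
  for (f in list(function(v) v^3, function(v) log(v), function(v) 5 * v - 2)) {
    expect_equal(kruskal_wallis(values = f(x), groups = g)$statistic,
                 kruskal_wallis(values = x, groups = g)$statistic)
    expect_equal(dunn_posthoc_bh(values = f(x), groups = g)$z,
                 dunn_posthoc_bh(values = x, groups = g)$z)
  }
})

test_that("for two groups the Dunn z squares to the Kruskal-Wallis H", {
  set.seed(37)
  for (rep in 1:5) {
    x <- sample(1:6, 10, replace = TRUE)  # heavy ties
    g <- rep(c("a", "b"), each = 5)
    h <- kruskal_wallis(values = x, groups = g)$statistic
    z <- dunn_posthoc_bh(values = x, groups = g)$z
    expect_equal(z^2, h, tolerance = 1e-10)
  }
})

test_that("BH adjustment is monotone, bounded and order-preserving", {
  set.seed(43)
  p <- runif(12)
  adj <- p.adjust(p, method = "BH")
  expect_true(all(adj >= p - 1e-12))
  expect_true(all(adj <= 1))
  o <- order(p)
  expect_true(all(diff(adj[o]) >= -1e-12))
  # raising any raw p cannot lower any adjusted p
  p2 <- p
  p2[3] <- min(1, p[3] + 0.2)
  expect_true(all(p.adjust(p2, method = "BH") >= adj - 1e-12))
})

test_that("the weighted trend fits noiseless group means exactly", {
  g <- factor(rep(c("q1", "q2", "q3", "q4", "q5"), each = 4),
              levels = c("q1", "q2", "q3", "q4", "q5"))
  y <- rep(c(10, 12, 14, 16, 18), each = 4)
  fit <- weighted_trend(values = y, groups = g, weights = rep(1, 20))
  td <- tidy(fit)
  expect_equal(td$estimate, c(10, 2, 4, 6, 8))
  expect_equal(glance(fit)$sigma, 0)

  flat <- tidy(weighted_trend(values = rep(3, 20), groups = g,
                              weights = runif(20, 1, 2)))
  expect_equal(flat$estimate[-1], rep(0, 4))
})

test_that("empty levels are rejected by the trend model", {
  g <- factor(c("a", "a", "b"), levels = c("a", "b", "c"))
  expect_error(weighted_trend(values = 1:3, groups = g, weights = rep(1, 3)),
               class = "sugarstep_schema_error")
})

test_that("weighted statistics match brute-force oracles on small instances", {
  set.seed(47)
  for (rep in 1:25) {
    n <- sample(4:8, 1)
    x <- sample(1:5, n, replace = TRUE)  # ties on purpose
    w <- runif(n, 0.5, 3)
    g <- factor(sample(c("a", "b", "c"), n, replace = TRUE))
    while (nlevels(droplevels(g)) < 2) g <- factor(sample(c("a", "b"), n, TRUE))
    g <- droplevels(g)

    o <- oracle_weighted_mean_se(x, w)
    got <- weighted_mean_se(values = x, weights = w)
    expect_equal(got$mean, o$mean)
    expect_equal(got$se, o$se)

    h <- kruskal_wallis(values = x, groups = g)$statistic
    if (stats::var(x) > 0) expect_equal(h, oracle_kruskal_h(x, g))

    p <- runif(sample(2:6, 1))
    expect_equal(p.adjust(p, method = "BH"), oracle_bh(p))

    X <- stats::model.matrix(~g)
    if (qr(X)$rank == ncol(X) && n > ncol(X)) {
      o2 <- oracle_wls(x, X, w)
      td <- tidy(weighted_trend(values = x, groups = g, weights = w))
      expect_equal(td$estimate, o2$beta)
      expect_equal(td$std.error, o2$se)
    }
  }
})

test_that("SSB servings divide grams by the serving size", {
  tab <- make_foods(2, group_l2 = c("soft drinks", "plain cereals"))
  recalls <- tibble::tibble(
    respondent_id = c("R1", "R1", "R2"), day = 1, meal = "pm_snack",
    food_id = c("T001", "T002", "T002"), amount_g = c(480, 100, 100)
  )
  out <- ssb_servings(recalls, tab)
  expect_equal(out$ssb_servings[out$respondent_id == "R1"], 2.0)
  expect_equal(out$ssb_servings[out$respondent_id == "R2"], 0)
})

test_that("SSB servings match a filter-and-sum oracle on survey data", {
  w <- generate_food_table(synthetic_config(n_foods = 150, n_respondents = 60,
                                            seed = 73))
  s <- generate_recall_survey(w)
  out <- ssb_servings(s$recalls, w$foods)
  ssb_ids <- w$foods$food_id[tolower(w$foods$group_l2) %in%
                               c("soft drinks", "sweetened beverages",
                                 "sport drinks", "flavored water")]
  first_day <- s$recalls[s$recalls$day == 1, ]
  for (r in sample(out$respondent_id, 10)) {
    rows <- first_day[first_day$respondent_id == r &
                        first_day$food_id %in% ssb_ids, ]
    expect_equal(out$ssb_servings[out$respondent_id == r],
                 sum(rows$amount_g) / 240)
  }
})

test_that("per-respondent free sugar never exceeds total sugar", {
  w <- generate_food_table(synthetic_config(n_foods = 200, n_respondents = 60,
                                            seed = 83))
  s <- generate_recall_survey(w)
  ann <- dplyr::left_join(
    dplyr::select(w$foods, "food_id", "total_sugar", "energy"),
    dplyr::rename(w$truth, free_sugar = true_free_sugar),
    by = "food_id"
  )
  out <- compute_daily_intake(s$recalls, ann)
  expect_true(all(out$fs_g <= out$ts_g + 1e-9))
})
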