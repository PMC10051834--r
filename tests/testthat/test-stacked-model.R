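test_that("training matrix keeps only complete rows and honors bounds", {
  tab <- make_foods(5, total_sugar = c(2, 3, 4, 5, 6))
  tab$known_free_sugar <- c(1, 1, 2, 2, 3)
  tab$fiber[2] <- NA
  expect_message(m <- build_training_matrix(tab), "dropped")
  expect_equal(nrow(m), 4)

  # two tables concatenate
  m2 <- build_training_matrix(list(tab, tab |>
    dplyr::mutate(food_id = paste0("B", food_id))))
  expect_equal(nrow(m2), 8)

  # all rows missing the response -> error
  tab$known_free_sugar <- NA_real_
  expect_error(suppressMessages(build_training_matrix(tab)),
               class = "sugarstep_schema_error")
})

test_that("the training response equals the generator's ground truth", {
  w <- generate_food_table(synthetic_config(n_foods = 120, seed = 55))
  m <- build_training_matrix(w$foods)
  truth <- w$truth$true_free_sugar[match(m$food_id, w$truth$food_id)]
  expect_equal(m$free_sugar, truth, tolerance = 0)
})

test_that("non-negative stacking solves the closed-form cases", {
  set.seed(12)
  y <- runif(40, 0, 10)
  # an exact predictor plus a biased copy: all weight on the exact one
  w <- fit_stack(cbind(y, y + 5), y)
  expect_equal(w, c(1, 0), tolerance = 1e-8)
  # a single learner equal to y
  expect_equal(fit_stack(cbind(y), y), 1, tolerance = 1e-8)
  # scaled predictor: 1-D least squares gives 0.5
  expect_equal(fit_stack(cbind(2 * y, rep(0, 40)), y)[1], 0.5, tolerance = 1e-8)
  # all-zero predictions cannot be stacked
  expect_error(fit_stack(cbind(rep(0, 40), rep(0, 40)), y),
               class = "sugarstep_integrity_error")
})

test_that("cross-validation selects the first grid point on ties", {
  w <- generate_food_table(synthetic_config(n_foods = 80, seed = 21))
  train <- build_training_matrix(w$foods)
  spec <- list(kind = "gradient_boosted_trees",
               grid = tibble::tibble(nrounds = c(20, 20), eta = 0.1,
                                     max_depth = c(3, 3)))
  fit <- fit_base_learner_cv(train, spec, cv_config(folds = 4, seed = 2))
  expect_equal(fit$cv_mse[1], fit$cv_mse[2])
  expect_equal(fit$best_params$max_depth, 3)
  expect_equal(length(fit$oof), nrow(train))
})

test_that("a constant response is fit exactly by every learner", {
  tab <- make_foods(30, total_sugar = runif(30, 3, 9),
                    carbohydrate = runif(30, 10, 30))
  tab$known_free_sugar <- rep(2, 30)
  tab$protein <- runif(30)
  train <- build_training_matrix(tab)
  for (spec in default_base_learner_specs()) {
    spec$grid <- spec$grid[1, ]
    fit <- fit_base_learner_cv(train, spec, cv_config(folds = 3, seed = 4))
    expect_equal(min(fit$cv_mse), 0)
  }
})

test_that("a response linear in total sugar is learned to near zero error", {
  set.seed(6)
  tab <- make_foods(300, total_sugar = runif(300, 0, 20),
                    carbohydrate = runif(300, 20, 40))
  tab$known_free_sugar <- 0.5 * tab$total_sugar
  train <- build_training_matrix(tab)
  spec <- list(kind = "gradient_boosted_trees",
               grid = tibble::tibble(nrounds = 300, eta = 0.1, max_depth = 6))
  fit <- fit_base_learner_cv(train, spec, cv_config(folds = 5, seed = 6))
  expect_lt(min(fit$cv_mse), 0.05 * stats::var(train$free_sugar))
})

test_that("too few rows for the fold count is an error", {
  tab <- make_foods(5, total_sugar = 1:5)
  tab$known_free_sugar <- rep(0.5, 5)
  train <- build_training_matrix(tab)
  spec <- default_base_learner_specs("random_forest")[[1]]
  expect_error(fit_base_learner_cv(train, spec, cv_config(folds = 10, seed = 1)),
               class = "sugarstep_schema_error")
})

test_that("the stack never does worse than its best base learner", {
  fit <- tiny_model()
  g <- glance(fit)
  expect_lte(g$stack_oof_mse, g$best_single_cv_mse + 1e-9)
  expect_true(all(fit$weights >= 0))
  expect_true(any(fit$weights > 0))
})

test_that("predictions are clipped into [0, total sugar]", {
  fit <- tiny_model()
  w <- generate_food_table(synthetic_config(n_foods = 200, seed = 91))
  pred <- predict(fit, w$foods)
  expect_true(all(pred >= 0))
  expect_true(all(pred <= w$foods$total_sugar + 1e-9))
  raw <- predict(fit, w$foods, clip = FALSE)
  expect_equal(pred, pmin(pmax(raw, 0), w$foods$total_sugar))
})

test_that("foods with missing predictors cannot be scored", {
  fit <- tiny_model()
  tab <- make_foods(2, total_sugar = c(3, 4))
  tab$fiber[1] <- NA
  expect_error(predict(fit, tab), class = "sugarstep_integrity_error")
})

test_that("save/load round-trips predictions and corrupt files error", {
  fit <- tiny_model()
  w <- tiny_world()
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(fit, path)
  back <- load_model(path)
  idx <- sample(nrow(w$foods), 50)
  expect_identical(predict(back, w$foods[idx, ]), predict(fit, w$foods[idx, ]))

  bad <- withr::local_tempfile(fileext = ".rds")
  writeLines("not a model", bad)
  expect_error(load_model(bad), class = "sugarstep_format_error")
  saveRDS(list(format = "something_else"), bad)
  expect_error(load_model(bad), class = "sugarstep_format_error")
})

test_that("training is reproducible from the seed", {
  w <- generate_food_table(synthetic_config(n_foods = 150, seed = 33))
  train <- build_training_matrix(w$foods)
  specs <- default_base_learner_specs(c("random_forest", "gradient_boosted_trees"))
  f1 <- fit_free_sugar_model(train, specs, cv_config(folds = 3, seed = 8))
  f2 <- fit_free_sugar_model(train, specs, cv_config(folds = 3, seed = 8))
  expect_identical(f1$weights, f2$weights)
  expect_identical(predict(f1, w$foods), predict(f2, w$foods))
})

test_that("tidy and glance expose the fitted stack", {
  fit <- tiny_model()
  td <- tidy(fit)
  expect_equal(nrow(td), 4)
  expect_setequal(td$learner,
                  c("support_vector_regression", "random_forest",
                    "gradient_boosted_trees", "rule_fit"))
  expect_equal(td$weight, unname(fit$weights))
  expect_equal(glance(fit)$folds, 3)
})
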