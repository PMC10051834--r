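#' Build the training matrix for the step-4 model
#'
#' Stacks one or more food tables carrying `known_free_sugar` and keeps the
#' rows where the response and all seven predictors (protein, carbohydrate,
#' total sugar, fiber, total fat, saturated fat, sodium) are present. Dropped
#' rows are counted in a message. The predictor order is fixed package-wide.
#'
#' @param tables A food-table tibble or list of them (e.g. several national
#'   databases with added/free-sugar columns).
#' @return A tibble with `food_id`, the seven predictors and `free_sugar`
#'   (the response, g/100 g). Errors if no usable rows remain.
#' @export
build_training_matrix <- function(tables) {
  if (is.data.frame(tables)) tables <- list(tables)
  combined <- purrr::map_dfr(tables, function(tab) {
    validate_food_table(tab)
    dplyr::select(tab, "food_id", dplyr::all_of(predictor_nutrients),
                  free_sugar = "known_free_sugar")
  })
  usable <- complete.cases(
    combined[, c(predictor_nutrients, "free_sugar")]
  )
  dropped <- sum(!usable)
  if (dropped > 0) {
    message(dropped, " row(s) dropped for missing predictor or response")
  }
  out <- combined[usable, , drop = FALSE]
  if (nrow(out) == 0) {
    abort("no usable training rows (missing predictors or known_free_sugar)",
          class = "sugarstep_schema_error")
  }
  bad <- out$free_sugar < 0 | out$free_sugar > out$total_sugar + 1e-9
  if (any(bad)) {
    abort("training response outside [0, total_sugar]",
          class = "sugarstep_integrity_error")
  }
  out
}

#' Base-learner specifications and cross-validation configuration
#'
#' The four base learners of the stack, each with a small documented
#' hyperparameter grid tuned by k-fold cross-validation on mean squared
#' error. Defaults: SVR with RBF kernel, cost in {1, 10}, gamma = 1/p on
#' z-scored predictors; random forest with 500 trees, mtry in {2, 3};
#' gradient boosting with 300 rounds, learning rate 0.1, depth in {3, 6};
#' rule-fit with 50 depth-3 rule-generating trees and an L1 selection path.
#'
#' @param kinds Which learners to include.
#' @return A named list of specs: `kind`, `grid` (tibble, one row per
#'   candidate).
#' @export
default_base_learner_specs <- function(kinds = c("support_vector_regression",
                                                 "random_forest",
                                                 "gradient_boosted_trees",
                                                 "rule_fit")) {
  all_specs <- list(
    support_vector_regression = list(
      kind = "support_vector_regression",
      grid = tibble::tibble(cost = c(1, 10), gamma = 1 / length(predictor_nutrients))
    ),
    random_forest = list(
      kind = "random_forest",
      grid = tibble::tibble(num_trees = 500, mtry = c(2, 3))
    ),
    gradient_boosted_trees = list(
      kind = "gradient_boosted_trees",
      grid = tibble::tibble(nrounds = 300, eta = 0.1, max_depth = c(3, 6))
    ),
    rule_fit = list(
      kind = "rule_fit",
      grid = tibble::tibble(n_trees = 50, max_depth = 3, learning_rate = 0.1)
    )
  )
  kinds <- match.arg(kinds, names(all_specs), several.ok = TRUE)
  all_specs[kinds]
}

#' @rdname default_base_learner_specs
#' @param folds Number of cross-validation folds (default 10).
#' @param seed Integer seed driving fold assignment and every stochastic
#'   learner.
#' @export
cv_config <- function(folds = 10, seed = 1L) {
  if (folds < 2) abort("folds must be >= 2", class = "sugarstep_schema_error")
  list(folds = as.integer(folds), seed = as.integer(seed),
       scoring = "mean_squared_error")
}

# --- internal train/predict dispatch over the four learner kinds ----------

train_learner <- function(kind, x, y, params, seed) {
  if (sd(y) == 0) {
    # degenerate constant response: every learner reduces to the constant
    # (and SVR would have no support vectors at all)
    return(list(kind = kind, constant = y[1]))
  }
  switch(kind,
    support_vector_regression = {
      center <- colMeans(x)
      scale_ <- apply(x, 2, sd)
      scale_[scale_ == 0] <- 1
      z <- scale(x, center = center, scale = scale_)
      fit <- e1071::svm(z, y, type = "eps-regression", kernel = "radial",
                        cost = params$cost, gamma = params$gamma, scale = FALSE)
      list(kind = kind, fit = fit, center = center, scale = scale_)
    },
    random_forest = {
      fit <- ranger::ranger(
        x = x, y = y, num.trees = params$num_trees, mtry = params$mtry,
        seed = seed, num.threads = 1
      )
      list(kind = kind, fit = fit)
    },
    gradient_boosted_trees = {
      set.seed(seed)
      fit <- xgboost::xgb.train(
        params = list(objective = "reg:squarederror",
                      max_depth = params$max_depth, eta = params$eta,
                      nthread = 1),
        data = xgboost::xgb.DMatrix(x, label = y),
        nrounds = params$nrounds, verbose = 0
      )
      list(kind = kind, fit = fit)
    },
    rule_fit = {
      fit <- fit_rulefit(x, y, n_trees = params$n_trees,
                         max_depth = params$max_depth,
                         learning_rate = params$learning_rate, seed = seed)
      list(kind = kind, fit = fit)
    },
    abort(paste0("unknown learner kind: ", kind), class = "sugarstep_schema_error")
  )
}

predict_learner <- function(learner, x) {
  if (!is.null(learner$constant)) return(rep(learner$constant, nrow(x)))
  switch(learner$kind,
    support_vector_regression = {
      z <- scale(x, center = learner$center, scale = learner$scale)
      as.numeric(predict(learner$fit, z))
    },
    random_forest = as.numeric(predict(learner$fit, data = x,
                                       num.threads = 1)$predictions),
    gradient_boosted_trees = as.numeric(predict(learner$fit,
                                                xgboost::xgb.DMatrix(x))),
    rule_fit = predict_rulefit(learner$fit, x)
  )
}

as_predictor_matrix <- function(data) {
  miss <- setdiff(predictor_nutrients, names(data))
  if (length(miss) > 0) {
    abort(paste0("predictor column(s) missing: ", paste(miss, collapse = ", ")),
          class = "sugarstep_schema_error")
  }
  m <- as.matrix(data[, predictor_nutrients])
  storage.mode(m) <- "double"
  m
}

#' Tune one base learner by cross-validation
#'
#' Grid search over the spec's hyperparameter grid: each candidate is scored
#' by k-fold cross-validated mean squared error; the candidate minimizing the
#' mean CV MSE wins, ties resolved by grid order (first wins). The learner is
#' then refit on all rows at the winning point. Out-of-fold predictions from
#' the winning candidate are returned aligned to the training rows; they are
#' the inputs of the stacking step. Fully reproducible given `cv$seed`.
#'
#' @param training Tibble from [build_training_matrix()].
#' @param spec One element of [default_base_learner_specs()].
#' @param cv A [cv_config()].
#' @return A list: `kind`, `learner` (refit on all rows), `best_params`,
#'   `cv_mse` (per grid row), `oof` (out-of-fold predictions).
#' @export
fit_base_learner_cv <- function(training, spec, cv = cv_config()) {
  x <- as_predictor_matrix(training)
  y <- training$free_sugar
  n <- nrow(x)
  if (n < cv$folds) {
    abort(paste0("need at least ", cv$folds, " rows for ", cv$folds,
                 "-fold CV, got ", n), class = "sugarstep_schema_error")
  }
  set.seed(cv$seed)
  fold <- sample(rep(seq_len(cv$folds), length.out = n))

  grid <- spec$grid
  cv_mse <- numeric(nrow(grid))
  oof_by_point <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    params <- as.list(grid[g, ])
    oof <- numeric(n)
    for (k in seq_len(cv$folds)) {
      idx <- fold == k
      fit_k <- train_learner(spec$kind, x[!idx, , drop = FALSE], y[!idx],
                             params, seed = cv$seed + k)
      oof[idx] <- predict_learner(fit_k, x[idx, , drop = FALSE])
    }
    cv_mse[g] <- mean((y - oof)^2)
    oof_by_point[[g]] <- oof
  }
  best <- which.min(cv_mse)  # which.min returns the first minimum: tie contract
  learner <- train_learner(spec$kind, x, y, as.list(grid[best, ]),
                           seed = cv$seed)
  list(kind = spec$kind, learner = learner,
       best_params = as.list(grid[best, ]), cv_mse = cv_mse,
       oof = oof_by_point[[best]])
}

#' Non-negative least-squares stacking weights
#'
#' Combines base learners by the linear combination of their out-of-fold
#' predictions that minimizes squared error under non-negativity, with no
#' intercept: `w = argmin ||y - P w||^2, w >= 0`. Fitting on out-of-fold
#' predictions keeps the meta-learner honest (no learner is evaluated on rows
#' it saw in training).
#'
#' @param oof Matrix of out-of-fold predictions, one column per learner.
#' @param y Response vector aligned with the rows of `oof`.
#' @return Numeric weight vector, one per column of `oof`.
#' @export
fit_stack <- function(oof, y) {
  oof <- as.matrix(oof)
  if (ncol(oof) < 1 || nrow(oof) != length(y)) {
    abort("oof predictions must align with y", class = "sugarstep_schema_error")
  }
  if (all(abs(oof) < 1e-12)) {
    abort("all base-learner predictions are zero; cannot stack",
          class = "sugarstep_integrity_error")
  }
  w <- pracma::lsqnonneg(oof, y)$x
  if (all(w == 0)) {
    # NNLS can zero out everything when all predictions are anti-correlated
    # with y; fall back to the single best learner to keep the invariant
    # "at least one positive weight".
    best <- which.min(colMeans((y - oof)^2))
    w[best] <- sum(y * oof[, best]) / sum(oof[, best]^2)
    w <- pmax(w, 0)
  }
  as.numeric(w)
}

#' Fit the stacked free-sugar model
#'
#' The step-4 predictor: four base regressors (support vector regression,
#' random forest, gradient-boosted trees, rule-fit) each tuned by k-fold
#' cross-validation on mean squared error, then combined by non-negative
#' least squares on their out-of-fold predictions. Predicts free sugar
#' (g/100 g) from the seven nutrients.
#'
#' @param training Tibble from [build_training_matrix()] (or a food table
#'   with `known_free_sugar`, which is passed through it).
#' @param specs Base-learner specs, default [default_base_learner_specs()].
#' @param cv A [cv_config()]; its seed drives all stochastic components.
#' @return A `sugar_stack` object with `learners`, `weights` and `metadata`
#'   (seed, folds, grids, per-learner CV MSE, stack out-of-fold MSE).
#' @examples
#' \donttest{
#' w <- generate_food_table(synthetic_config(n_foods = 400, seed = 3))
#' train <- build_training_matrix(w$foods)
#' fit <- fit_free_sugar_model(train, cv = cv_config(folds = 5, seed = 3))
#' tidy(fit)
#' }
#' @export
fit_free_sugar_model <- function(training, specs = default_base_learner_specs(),
                                 cv = cv_config()) {
  if ("known_free_sugar" %in% names(training)) {
    training <- build_training_matrix(training)
  }
  fits <- purrr::map(specs, fit_base_learner_cv, training = training, cv = cv)
  oof <- do.call(cbind, purrr::map(fits, "oof"))
  colnames(oof) <- purrr::map_chr(fits, "kind")
  y <- training$free_sugar
  weights <- fit_stack(oof, y)
  names(weights) <- colnames(oof)
  structure(
    list(
      learners = purrr::map(fits, "learner"),
      weights = weights,
      metadata = list(
        seed = cv$seed, folds = cv$folds,
        grids = purrr::map(specs, "grid"),
        best_params = purrr::map(fits, "best_params"),
        cv_mse = purrr::map(fits, "cv_mse"),
        stack_oof_mse = mean((y - as.numeric(oof %*% weights))^2),
        n_train = nrow(training)
      )
    ),
    class = "sugar_stack"
  )
}

#' Predict free sugar for foods
#'
#' Raw prediction is the weighted sum of the base learners; the returned
#' value is clipped into `[0, total_sugar]` — free sugar can be neither
#' negative nor exceed the food's total sugar. Clipping is applied once,
#' after stacking, at the contract boundary.
#'
#' @param object A `sugar_stack` model.
#' @param newdata Tibble of foods with the seven predictor columns present
#'   (no missing values; route foods with missing predictors to
#'   `unannotated` instead).
#' @param clip If `FALSE`, return the raw stacked prediction.
#' @param ... Unused.
#' @return Numeric vector of free-sugar predictions, g/100 g.
#' @export
predict.sugar_stack <- function(object, newdata, clip = TRUE, ...) {
  x <- as_predictor_matrix(newdata)
  if (anyNA(x)) {
    abort("missing predictor values; foods with incomplete profiles cannot be scored",
          class = "sugarstep_integrity_error")
  }
  preds <- purrr::map(object$learners, predict_learner, x = x)
  raw <- as.numeric(do.call(cbind, preds) %*% object$weights)
  if (!clip) return(raw)
  pmin(pmax(raw, 0), x[, "total_sugar"])
}

#' @export
print.sugar_stack <- function(x, ...) {
  cat("Stacked free-sugar model (", x$metadata$n_train, " training foods, ",
      x$metadata$folds, "-fold CV, seed ", x$metadata$seed, ")\n", sep = "")
  w <- x$weights
  for (k in names(w)) {
    cat(sprintf("  %-28s w = %.4f  (CV MSE %.3f)\n", k, w[[k]],
                min(x$metadata$cv_mse[[k]])))
  }
  cat(sprintf("  stack out-of-fold MSE: %.3f\n", x$metadata$stack_oof_mse))
  invisible(x)
}

#' Tidy a stacked free-sugar model
#'
#' One row per base learner: stacking weight, minimum cross-validated MSE and
#' the selected hyperparameters (as a compact label).
#'
#' @param x A `sugar_stack` object.
#' @param ... Unused.
#' @return A tibble with columns `learner`, `weight`, `cv_mse`, `params`.
#' @export
tidy.sugar_stack <- function(x, ...) {
  tibble::tibble(
    learner = names(x$weights),
    weight = as.numeric(x$weights),
    cv_mse = purrr::map_dbl(x$metadata$cv_mse[names(x$weights)], min),
    params = purrr::map_chr(x$metadata$best_params[names(x$weights)], function(p) {
      paste(names(p), unlist(p), sep = "=", collapse = ", ")
    })
  )
}

#' @rdname tidy.sugar_stack
#' @return `glance()`: a one-row tibble with `n_train`, `folds`, `seed`,
#'   `stack_oof_mse` and the best single-learner CV MSE.
#' @export
glance.sugar_stack <- function(x, ...) {
  tibble::tibble(
    n_train = x$metadata$n_train,
    folds = x$metadata$folds,
    seed = x$metadata$seed,
    stack_oof_mse = x$metadata$stack_oof_mse,
    best_single_cv_mse = min(purrr::map_dbl(x$metadata$cv_mse, min))
  )
}

model_format_version <- 1L

#' Save / load a fitted model
#'
#' The model file is a versioned R serialization with a metadata header
#' (format tag, version, training seed, grids, stacking weights). Loading a
#' file that is not a model, or has a different format version, raises an
#' explicit format error. `load_model(save_model(m))` is prediction-identical
#' to `m` on any input.
#'
#' @param model A `sugar_stack` object.
#' @param path File path.
#' @return `save_model()`: `path`, invisibly. `load_model()`: the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "sugar_stack"))
  saveRDS(list(format = "sugarstep_model", version = model_format_version,
               metadata = model$metadata, model = model), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e) NULL)
  if (!is.list(obj) || !identical(obj$format, "sugarstep_model")) {
    abort(paste0("not a sugarstep model file: ", path),
          class = "sugarstep_format_error")
  }
  if (!identical(obj$version, model_format_version)) {
    abort(paste0("model format version ", obj$version,
                 " not supported (expected ", model_format_version, ")"),
          class = "sugarstep_format_error")
  }
  obj$model
}

#' Annotate a food table end to end
#'
#' Runs the deterministic cascade ([apply_rules()]) and, when a model is
#' supplied, scores the step-4 foods with it. Step-4 foods with an incomplete
#' predictor profile (or all step-4 foods when `model` is `NULL`) are left
#' `unannotated`.
#'
#' @param table A food-table tibble.
#' @param rules Rule table, default [default_rule_table()].
#' @param model Optional `sugar_stack` model for step 4.
#' @return Assignment tibble (`food_id`, `step`, `free_sugar`) with step-4
#'   free sugar filled in where the model could score.
#' @export
annotate_food_table <- function(table, rules = default_rule_table(),
                                model = NULL) {
  assignments <- apply_rules(table, rules)
  idx4 <- which(assignments$step == "4")
  if (length(idx4) == 0 || is.null(model)) {
    if (length(idx4) > 0) {
      assignments$step[idx4] <- "unannotated"
      warn(paste0(length(idx4), " model-step food(s) left unannotated: ",
                  "no model supplied"))
    }
    return(assignments)
  }
  rows <- table[match(assignments$food_id[idx4], table$food_id), ]
  complete <- complete.cases(rows[, predictor_nutrients])
  if (any(complete)) {
    assignments$free_sugar[idx4[complete]] <-
      predict(model, rows[complete, , drop = FALSE])
  }
  if (any(!complete)) {
    assignments$step[idx4[!complete]] <- "unannotated"
    warn(paste0(sum(!complete), " model-step food(s) have incomplete ",
                "predictor profiles; flagged 'unannotated'"))
  }
  assignments
}
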