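# Independent brute-force oracles, written from the defining formulas with
# plain loops so they share no code path with the implementation.

oracle_weighted_mean_se <- function(x, w) {
  n <- length(x)
  sw <- 0
  swx <- 0
  for (i in seq_len(n)) {
    sw <- sw + w[i]
    swx <- swx + w[i] * x[i]
  }
  m <- swx / sw
  acc <- 0
  for (i in seq_len(n)) acc <- acc + (w[i] * (x[i] - m))^2
  list(mean = m, se = sqrt(n / (n - 1) * acc / sw^2))
}

# Kruskal-Wallis via the rank-sum-of-squares form H = (N-1) * SSB / SST on
# average ranks, algebraically equivalent to the tie-corrected statistic but
# computed by a different route.
oracle_kruskal_h <- function(x, g) {
  r <- rank(x)
  rbar <- mean(r)
  ssb <- 0
  sst <- 0
  for (lev in unique(g)) {
    ri <- r[g == lev]
    ssb <- ssb + length(ri) * (mean(ri) - rbar)^2
  }
  for (i in seq_along(r)) sst <- sst + (r[i] - rbar)^2
  (length(x) - 1) * ssb / sst
}

oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running_min <- Inf
  for (i in rev(seq_len(m))) {
    running_min <- min(running_min, p[o[i]] * m / i)
    adj[o[i]] <- min(running_min, 1)
  }
  adj
}

oracle_wls <- function(y, X, w) {
  W <- diag(w)
  beta <- solve(t(X) %*% W %*% X, t(X) %*% W %*% y)
  e <- y - X %*% beta
  sigma2 <- sum(w * e^2) / (length(y) - ncol(X))
  se <- sqrt(diag(sigma2 * solve(t(X) %*% W %*% X)))
  list(beta = as.numeric(beta), se = as.numeric(se))
}

# Minimal food-table builder for hand-constructed cases.
make_foods <- function(n, group_l1 = "Misc", group_l2 = "", total_sugar = 0,
                       carbohydrate = NULL, ...) {
  extras <- list(...)
  tab <- tibble::tibble(
    food_id = sprintf("T%03d", seq_len(n)),
    name = paste0("food ", seq_len(n)),
    group_l1 = group_l1, group_l2 = group_l2, group_l3 = "",
    protein = 1, carbohydrate = carbohydrate %||%
      pmax(rep_len(total_sugar, n), 1),
    total_sugar = total_sugar,
    fiber = 0.5, total_fat = 1, saturated_fat = 0.3, sodium = 10, energy = 100,
    known_free_sugar = NA_real_
  )
  for (nm in names(extras)) tab[[nm]] <- extras[[nm]]
  tab
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One small fitted stack shared across tests that need a model; trained once
# per test run on a compact world with reduced folds to stay quick.
tiny_model_env <- new.env()
tiny_model <- function() {
  if (is.null(tiny_model_env$model)) {
    w <- generate_food_table(synthetic_config(n_foods = 250, seed = 77))
    train <- build_training_matrix(w$foods)
    tiny_model_env$world <- w
    tiny_model_env$model <- fit_free_sugar_model(
      train, cv = cv_config(folds = 3, seed = 77)
    )
  }
  tiny_model_env$model
}
tiny_world <- function() {
  tiny_model()
  tiny_model_env$world
}
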