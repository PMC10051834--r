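# Rule-fit regression: rules are harvested from a shallow gradient-boosted
# tree ensemble, turned into binary indicator features, concatenated with the
# (winsorized, standardized) linear terms, and selected by an L1 path with
# cross-validated lambda. No installed package provides this learner, so it
# lives here behind the same train/predict interface as the other three.

harvest_rules <- function(booster, feature_names) {
  dt <- as.data.frame(xgboost::xgb.model.dt.tree(model = booster))
  rules <- list()
  for (tr in unique(dt$Tree)) {
    tdt <- dt[dt$Tree == tr, , drop = FALSE]
    row_of <- setNames(seq_len(nrow(tdt)), tdt$ID)
    walk <- function(id, conds) {
      row <- tdt[row_of[[id]], ]
      if (length(conds) > 0) rules[[length(rules) + 1L]] <<- conds
      if (!is.na(row$Feature) && row$Feature != "Leaf") {
        cond_l <- list(feature = row$Feature, op = "<", value = row$Split)
        cond_r <- list(feature = row$Feature, op = ">=", value = row$Split)
        walk(row$Yes, c(conds, list(cond_l)))
        walk(row$No, c(conds, list(cond_r)))
      }
    }
    walk(tdt$ID[tdt$Node == 0], list())
  }
  sig <- purrr::map_chr(rules, function(r) {
    paste(purrr::map_chr(r, ~ paste(.x$feature, .x$op, format(.x$value, digits = 12))),
          collapse = " & ")
  })
  rules[!duplicated(sig)]
}

evaluate_rules <- function(rules, x) {
  if (length(rules) == 0) {
    return(matrix(numeric(0), nrow = nrow(x), ncol = 0))
  }
  out <- matrix(0, nrow = nrow(x), ncol = length(rules))
  for (j in seq_along(rules)) {
    keep <- rep(TRUE, nrow(x))
    for (cond in rules[[j]]) {
      v <- x[, cond$feature]
      keep <- keep & if (cond$op == "<") v < cond$value else v >= cond$value
    }
    out[, j] <- as.numeric(keep)
  }
  out
}

fit_rulefit <- function(x, y, n_trees = 50, max_depth = 3, learning_rate = 0.1,
                        seed = 1L) {
  stopifnot(!is.null(colnames(x)))
  set.seed(seed)
  dm <- xgboost::xgb.DMatrix(x, label = y)
  booster <- xgboost::xgb.train(
    params = list(objective = "reg:squarederror", max_depth = max_depth,
                  eta = learning_rate, subsample = 0.7, nthread = 1),
    data = dm, nrounds = n_trees, verbose = 0
  )
  rules <- harvest_rules(booster, colnames(x))
  rule_x <- evaluate_rules(rules, x)

  # Winsorized linear terms, as in the original formulation, so the linear
  # part is robust to nutrient outliers.
  lims <- apply(x, 2, quantile, probs = c(0.025, 0.975))
  lin_x <- pmin(pmax(x, rep(lims[1, ], each = nrow(x))),
                rep(lims[2, ], each = nrow(x)))
  center <- colMeans(lin_x)
  scale_ <- apply(lin_x, 2, sd)
  scale_[scale_ == 0] <- 1
  lin_z <- scale(lin_x, center = center, scale = scale_)

  design <- cbind(rule_x, lin_z)
  keep <- apply(design, 2, sd) > 0
  if (!any(keep)) {
    # Degenerate design (e.g. constant response): intercept-only model.
    return(structure(list(constant = mean(y)), class = "sugarstep_rulefit"))
  }
  set.seed(seed)
  foldid <- sample(rep(seq_len(5), length.out = nrow(x)))
  cvfit <- glmnet::cv.glmnet(design[, keep, drop = FALSE], y,
                             alpha = 1, foldid = foldid, standardize = FALSE)
  structure(
    list(rules = rules, lims = lims, center = center, scale = scale_,
         keep = keep, cvfit = cvfit, lambda = cvfit$lambda.min),
    class = "sugarstep_rulefit"
  )
}

predict_rulefit <- function(object, x) {
  if (!is.null(object$constant)) {
    return(rep(object$constant, nrow(x)))
  }
  rule_x <- evaluate_rules(object$rules, x)
  lin_x <- pmin(pmax(x, rep(object$lims[1, ], each = nrow(x))),
                rep(object$lims[2, ], each = nrow(x)))
  lin_z <- scale(lin_x, center = object$center, scale = object$scale)
  design <- cbind(rule_x, lin_z)[, object$keep, drop = FALSE]
  as.numeric(predict(object$cvfit, newx = design, s = object$lambda))
}
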