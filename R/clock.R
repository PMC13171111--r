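#' Deterministic stratified train/validation/test split
#'
#' Splits a per-cell feature table into disjoint, exhaustive train,
#' validation and test partitions. Sizes follow a fixed rounding
#' convention: `n_test = floor(test_frac * n)`, then
#' `n_val = ceiling(val_frac * (n - n_test))`, and the remainder trains.
#' Rows are allocated to partitions stratified by the label column
#' (largest-remainder apportionment within strata so the totals are
#' exact), deterministically under `seed`.
#'
#' @param table Data frame with at least 10 rows.
#' @param label Name of the label column used for stratification.
#' @param test_frac,val_frac Fractions (defaults 0.2 and 0.2).
#' @param seed Integer seed.
#' @return List with data frames `train`, `val`, `test` and integer vector
#'   `sizes` (`n_train`, `n_val`, `n_test`).
#' @export
split_data <- function(table, label, test_frac = 0.2, val_frac = 0.2,
                       seed = 1L) {
  stopifnot(is.data.frame(table))
  n <- nrow(table)
  if (n < 10L) stop("need at least 10 rows")
  if (!label %in% names(table)) stop("label column not found: ", label)
  lab <- factor(table[[label]])
  if (any(tabulate(lab) == 0L)) stop("empty class under stratification")
  n_test <- floor(test_frac * n)
  n_val <- ceiling(val_frac * (n - n_test))
  n_train <- n - n_test - n_val

  # largest-remainder apportionment of a total across strata counts
  apportion <- function(counts, total) {
    quota <- counts / sum(counts) * total
    base <- floor(quota)
    short <- total - sum(base)
    if (short > 0) {
      extra <- order(quota - base, decreasing = TRUE)[seq_len(short)]
      base[extra] <- base[extra] + 1
    }
    base
  }

  rng <- local_rng(seed)
  strata <- split(seq_len(n), lab)
  counts <- vapply(strata, length, integer(1))
  test_alloc <- apportion(counts, n_test)
  val_alloc <- apportion(counts, n_val)
  # guard: a stratum cannot supply more rows than it has
  over <- test_alloc + val_alloc > counts
  if (any(over)) {
    val_alloc[over] <- counts[over] - test_alloc[over]
  }
  test_idx <- integer(0); val_idx <- integer(0)
  for (k in seq_along(strata)) {
    ids <- strata[[k]]
    perm <- ids[sample.int(length(ids))]
    test_idx <- c(test_idx, perm[seq_len(test_alloc[k])])
    val_idx <- c(val_idx, perm[test_alloc[k] + seq_len(val_alloc[k])])
  }
  rng()
  train_idx <- setdiff(seq_len(n), c(test_idx, val_idx))
  list(train = table[sort(train_idx), , drop = FALSE],
       val = table[sort(val_idx), , drop = FALSE],
       test = table[sort(test_idx), , drop = FALSE],
       sizes = c(n_train = length(train_idx), n_val = length(val_idx),
                 n_test = n_test))
}

# Feature columns the classifiers consume, in stable order. Factor-like
# columns are integer-coded.
clock_feature_matrix <- function(table, features) {
  miss <- setdiff(features, names(table))
  if (length(miss)) stop("missing feature columns: ",
                         paste(miss, collapse = ", "))
  cols <- lapply(features, function(f) {
    v <- table[[f]]
    if (is.numeric(v)) v else as.numeric(factor(v, levels = sort(unique(as.character(v)))))
  })
  m <- do.call(cbind, cols)
  colnames(m) <- features
  m[is.na(m)] <- -1  # missing intensity for zero-count cells
  m
}

#' Default feature set for the classifiers
#'
#' Counts, counts-per-area, median intensities, mean puncta areas and
#' compartment areas; `mg_association` is included when present.
#' Replicate identity is only used when `use_replicate = TRUE` (off by
#' default to avoid leakage of acquisition structure into the label).
#'
#' @param table Feature table.
#' @param use_replicate Include `replicate_id` as a predictor.
#' @return Character vector of column names.
#' @export
clock_features <- function(table, use_replicate = FALSE) {
  candidates <- c("nuclear_count", "cyto_count", "nuclear_count_per_area",
                  "cyto_count_per_area", "nuclear_median_intensity",
                  "cyto_median_intensity", "nuclear_mean_area_um2",
                  "cyto_mean_area_um2", "nucleus_area_um2",
                  "cytoplasm_area_um2", "mg_association")
  if (use_replicate) candidates <- c(candidates, "replicate_id")
  intersect(candidates, names(table))
}

#' Train an ensemble classifier on per-cell features
#'
#' Fits either a random forest (bagging with random feature selection) or
#' a gradient-boosting machine (sequential trees minimising multinomial
#' log-loss, with early stopping on the validation set) to predict the
#' label (age group or cell class) from image-derived features.
#'
#' @param train,val Data frames from [split_data()]; `val` is used only
#'   for gradient-boosting early stopping.
#' @param label Label column name.
#' @param kind "random_forest" or "gradient_boosting".
#' @param features Feature columns (default [clock_features()]).
#' @param seed Integer seed; training is deterministic given it.
#' @param n_trees Trees for the forest (default 500).
#' @param n_rounds,learning_rate Boosting rounds cap (default 300) and
#'   learning rate (default 0.1); early stopping after 20 stagnant rounds.
#' @return List of class `clock_model` with the fitted model, `kind`,
#'   `features`, `classes`.
#' @export
train_classifier <- function(train, val, label,
                             kind = c("random_forest", "gradient_boosting"),
                             features = NULL, seed = 1L, n_trees = 500L,
                             n_rounds = 300L, learning_rate = 0.1) {
  kind <- match.arg(kind)
  if (is.null(features)) features <- clock_features(train)
  y <- factor(train[[label]])
  if (nlevels(y) < 2L) stop("single-class training data")
  X <- clock_feature_matrix(train, features)
  classes <- levels(y)
  rng <- local_rng(seed)
  if (kind == "random_forest") {
    model <- randomForest::randomForest(x = X, y = y, ntree = n_trees)
  } else {
    dtrain <- xgboost::xgb.DMatrix(X, label = as.integer(y) - 1L,
                                   nthread = 1)
    yv <- factor(val[[label]], levels = classes)
    dval <- xgboost::xgb.DMatrix(clock_feature_matrix(val, features),
                                 label = as.integer(yv) - 1L, nthread = 1)
    model <- xgboost::xgb.train(
      params = xgboost::xgb.params(objective = "multi:softprob",
                                   num_class = length(classes),
                                   eta = learning_rate, max_depth = 6,
                                   nthread = 1, seed = as.integer(seed)),
      data = dtrain, nrounds = n_rounds,
      evals = list(val = dval), early_stopping_rounds = 20L, verbose = 0)
  }
  rng()
  structure(list(model = model, kind = kind, features = features,
                 classes = classes, label = label, seed = seed),
            class = "clock_model")
}

#' Predicted class-membership scores
#'
#' @param object A `clock_model`.
#' @param table Data frame with the feature columns.
#' @return Matrix of scores, one column per class.
#' @export
predict_scores <- function(object, table) {
  stopifnot(inherits(object, "clock_model"))
  X <- clock_feature_matrix(table, object$features)
  if (object$kind == "random_forest") {
    p <- predict(object$model, X, type = "prob")
  } else {
    p <- predict(object$model, xgboost::xgb.DMatrix(X, nthread = 1))
    colnames(p) <- object$classes
  }
  p[, object$classes, drop = FALSE]
}

# Rank-based AUC of scores for a binary indicator (equivalent to the
# Wilcoxon statistic); used for one-vs-rest AUROC.
binary_auc <- function(score, positive) {
  r <- rank(score)
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate a classifier on a held-out test set
#'
#' Computes one-vs-rest AUROC per class from the predicted class scores
#' (via ROC curves), plus the macro average and split sizes.
#'
#' @param model A `clock_model`.
#' @param test Held-out data frame (disjoint from train/val).
#' @param split_sizes Optional named sizes to record in the report.
#' @return List of class `classifier_report`: `model_kind`, `class_auroc`
#'   (named numeric), `macro_auroc`, `feature_importances`, `split_sizes`.
#' @export
evaluate_classifier <- function(model, test, split_sizes = NULL) {
  stopifnot(inherits(model, "clock_model"))
  y <- as.character(test[[model$label]])
  missing_cls <- setdiff(model$classes, unique(y))
  if (length(missing_cls))
    stop("class absent from test set: ", paste(missing_cls, collapse = ", "))
  scores <- predict_scores(model, test)
  auroc <- vapply(model$classes, function(cl) {
    resp <- as.integer(y == cl)
    as.numeric(pROC::auc(pROC::roc(response = resp,
                                   predictor = scores[, cl],
                                   levels = c(0, 1), direction = "<",
                                   quiet = TRUE)))
  }, numeric(1))
  structure(list(model_kind = model$kind,
                 class_auroc = auroc,
                 macro_auroc = mean(auroc),
                 feature_importances = feature_importance(model),
                 split_sizes = split_sizes),
            class = "classifier_report")
}

#' Feature importance of a fitted classifier
#'
#' Total increase in node purity (mean decrease in Gini) for the random
#' forest; total gain (relative influence) for gradient boosting. Scores
#' are nonnegative and normalised to sum to 1, sorted descending.
#'
#' @param model A `clock_model`.
#' @return Named numeric vector over all features (absent-from-trees
#'   features score 0).
#' @export
feature_importance <- function(model) {
  stopifnot(inherits(model, "clock_model"))
  if (model$kind == "random_forest") {
    imp <- randomForest::importance(model$model)[, "MeanDecreaseGini"]
  } else {
    tab <- xgboost::xgb.importance(model = model$model)
    imp <- setNames(rep(0, length(model$features)), model$features)
    imp[tab$Feature] <- tab$Gain
  }
  imp <- pmax(imp, 0)
  tot <- sum(imp)
  if (tot > 0) imp <- imp / tot
  sort(imp, decreasing = TRUE)
}
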