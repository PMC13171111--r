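test_that("split sizes follow the floor/ceil convention at reported sizes", {
  big <- data.frame(label = rep(c("10M", "18M", "24M"), length.out = 28680),
                    x = seq_len(28680))
  sp <- split_data(big, "label", seed = 1)
  expect_equal(unname(sp$sizes["n_test"]), 5736)
  expect_equal(unname(sp$sizes["n_val"]), 4589)
  expect_equal(unname(sp$sizes["n_train"]), 18355)

  small <- data.frame(label = rep(c("1M", "10M", "18M"), length.out = 1232),
                      x = seq_len(1232))
  sp2 <- split_data(small, "label", seed = 1)
  expect_equal(unname(sp2$sizes["n_test"]), 246)
  expect_equal(unname(sp2$sizes["n_val"]), 198)
  expect_equal(unname(sp2$sizes["n_train"]), 788)

  tiny <- data.frame(label = rep(c("A", "B"), 5), x = 1:10)
  expect_equal(unname(split_data(tiny, "label", seed = 1)$sizes["n_test"]), 2)
})

test_that("splits are disjoint, exhaustive, stratified and deterministic", {
  tab <- data.frame(label = rep(c("A", "B", "C"), c(300, 200, 100)),
                    x = seq_len(600))
  s1 <- split_data(tab, "label", seed = 7)
  s2 <- split_data(tab, "label", seed = 7)
  expect_identical(s1, s2)
  ids <- c(s1$train$x, s1$val$x, s1$test$x)
  expect_setequal(ids, tab$x)
  expect_equal(length(ids), length(unique(ids)))
  # stratification: test-set class shares track overall shares
  sh <- table(s1$test$label) / nrow(s1$test)
  expect_equal(as.numeric(sh), c(0.5, 1 / 3, 1 / 6), tolerance = 0.02)
  s3 <- split_data(tab, "label", seed = 8)
  expect_false(identical(s1$test$x, s3$test$x))
  expect_error(split_data(tab[1:5, ], "label"), "at least 10 rows")
})

test_that("training is seeded-deterministic for both model kinds", {
  tab <- simulate_feature_table(n_per_group = 150, seed = 2)$table
  sp <- split_data(tab, "age_group", seed = 2)
  for (kind in c("random_forest", "gradient_boosting")) {
    m1 <- train_classifier(sp$train, sp$val, "age_group", kind = kind,
                           seed = 3, n_trees = 100, n_rounds = 60)
    m2 <- train_classifier(sp$train, sp$val, "age_group", kind = kind,
                           seed = 3, n_trees = 100, n_rounds = 60)
    expect_identical(predict_scores(m1, sp$test), predict_scores(m2, sp$test))
  }
  expect_error(train_classifier(sp$train[sp$train$age_group == "1M", ],
                                sp$val, "age_group"), "single-class")
})

test_that("one-vs-rest AUROC behaves as a rank statistic", {
  # perfect scores
  y <- rep(c("A", "B"), each = 20)
  s <- ifelse(y == "A", 1, 0)
  expect_equal(punctaging:::binary_auc(s, y == "A"), 1)
  # chance-level scores
  set.seed(6)
  s2 <- runif(4000)
  auc2 <- punctaging:::binary_auc(s2, rep(c(TRUE, FALSE), 2000))
  expect_lt(abs(auc2 - 0.5), 0.05)
  # invariance under strictly monotone transforms
  s3 <- runif(200); pos <- rbinom(200, 1, 0.5) == 1
  a0 <- punctaging:::binary_auc(s3, pos)
  expect_equal(punctaging:::binary_auc(log(s3 + 1), pos), a0)
  expect_equal(punctaging:::binary_auc(s3^3, pos), a0)
})

test_that("evaluation reports AUROC per class and normalised importances", {
  tab <- simulate_feature_table(n_per_group = 300, seed = 4)$table
  sp <- split_data(tab, "age_group", seed = 4)
  m <- train_classifier(sp$train, sp$val, "age_group", seed = 4,
                        n_trees = 200)
  rep_ <- evaluate_classifier(m, sp$test, split_sizes = sp$sizes)
  expect_setequal(names(rep_$class_auroc), c("1M", "10M", "18M"))
  expect_true(all(rep_$class_auroc >= 0 & rep_$class_auroc <= 1))
  imp <- rep_$feature_importances
  expect_equal(sum(imp), 1, tolerance = 1e-9)
  expect_true(all(imp >= 0))
  expect_true(all(diff(imp) <= 1e-12))  # sorted descending
  # missing class in test errors
  bad_test <- sp$test[sp$test$age_group != "1M", ]
  expect_error(evaluate_classifier(m, bad_test), "absent")
})

test_that("a planted informative feature dominates the importances", {
  set.seed(12)
  for (s in 1:4) {
    n <- 600
    df <- data.frame(label = rep(c("A", "B"), each = n / 2))
    df$nuclear_count <- ifelse(df$label == "A", 0, 2) + rnorm(n)
    for (f in c("cyto_count", "nucleus_area_um2", "cytoplasm_area_um2",
                "nuclear_median_intensity", "cyto_median_intensity"))
      df[[f]] <- rnorm(n)
    sp <- split_data(df, "label", seed = s)
    m <- train_classifier(sp$train, sp$val, "label", seed = s, n_trees = 150)
    expect_equal(names(feature_importance(m))[1], "nuclear_count")
  }
})

test_that("all-noise features show no spurious dominance", {
  set.seed(13)
  maxratio <- vapply(1:5, function(s) {
    n <- 400
    df <- data.frame(label = rep(c("A", "B"), each = n / 2))
    for (f in c("nuclear_count", "cyto_count", "nucleus_area_um2",
                "cytoplasm_area_um2", "nuclear_median_intensity",
                "cyto_median_intensity")) df[[f]] <- rnorm(n)
    sp <- split_data(df, "label", seed = s)
    m <- train_classifier(sp$train, sp$val, "label", seed = s, n_trees = 150)
    imp <- feature_importance(m)
    max(imp) / mean(imp)
  }, numeric(1))
  expect_true(all(maxratio < 3))
})
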