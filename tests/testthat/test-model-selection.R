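test_that("macro F1 matches hand-computed values", {
  expect_equal(macro_f1(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1.0)
  expect_equal(macro_f1(c(0, 0, 1, 1), c(0, 0, 0, 0)), (2 / 3 + 0) / 2)
  expect_equal(macro_f1(c(0, 0, 0, 1), c(0, 0, 1, 1)), (0.8 + 2 / 3) / 2)
  expect_error(macro_f1(integer(0), integer(0)), "non-empty")
})

test_that("stratified folds balance classes and are deterministic", {
  y <- c(rep(0L, 90), rep(1L, 10))
  f <- stratified_folds(y, k = 10, seed = 4)
  expect_equal(attr(f, "k"), 10L)
  per_fold_ones <- tapply(y, f, sum)
  expect_true(all(per_fold_ones == 1))      # exact stratification
  per_fold_n <- tabulate(f)
  expect_true(max(per_fold_n) - min(per_fold_n) <= 1)
  expect_identical(stratified_folds(y, k = 10, seed = 4), f)
  expect_false(identical(stratified_folds(y, k = 10, seed = 5), f))

  y2 <- c(rep(0L, 95), rep(1L, 5))
  expect_warning(f2 <- stratified_folds(y2, k = 10, seed = 1), "reducing k")
  expect_equal(attr(f2, "k"), 5L)
  expect_error(stratified_folds(rep(1L, 20), k = 5, seed = 1), "single-class")
})

test_that("SMOTE balances classes with convex-combination geometry", {
  set.seed(2)
  X <- rbind(matrix(rnorm(20), 10, 2),
             cbind(seq(0, 1, length.out = 4), 2 * seq(0, 1, length.out = 4)))
  colnames(X) <- c("a", "b")
  y <- c(rep(0L, 10), rep(1L, 4))
  out <- smote_oversample(X, y, k_neighbors = 5, seed = 9)
  expect_equal(as.integer(table(out$y)), c(10L, 10L))
  expect_equal(out$X[1:14, ], X)            # originals preserved
  # minority lies on the line b = 2a: synthetic points must stay on it
  synth <- out$X[15:20, , drop = FALSE]
  expect_lt(max(abs(synth[, "b"] - 2 * synth[, "a"])), 1e-12)
  expect_true(all(synth[, "a"] >= 0 & synth[, "a"] <= 1))
  # determinism
  out2 <- smote_oversample(X, y, k_neighbors = 5, seed = 9)
  expect_identical(out$X, out2$X)
  expect_error(smote_oversample(X[1:11, ], y[1:11], seed = 1), "cannot interpolate")
})

test_that("ANOVA-F selection ranks a label-identical feature first", {
  set.seed(3)
  n <- 60
  y <- rep(c(0L, 1L), n / 2)
  X <- cbind(matrix(rnorm(n * 5), n, 5), perfect = as.numeric(y))
  colnames(X) <- c(paste0("n", 1:5), "perfect")
  expect_true("perfect" %in% select_k_best(X, y, 1))
  expect_equal(select_k_best(X, y, "none"), colnames(X))
  # duplicated columns: deterministic, name-ordered selection
  X2 <- cbind(a2 = X[, "perfect"], a1 = X[, "perfect"], X[, 1:2])
  expect_equal(select_k_best(X2, y, 2), c("a1", "a2"))
  # zero-variance columns never beat informative ones
  X3 <- cbind(X, zv = rep(1, n))
  expect_false("zv" %in% select_k_best(X3, y, 3))
})

test_that("Welch t-test matches the closed form and its symmetries", {
  a <- c(1, 2, 3, 4); b <- c(3, 4, 5, 6)
  got <- welch_t_test(a, b)
  ref <- oracle_welch(a, b)
  expect_equal(got$statistic, ref$statistic, tolerance = 1e-12)
  expect_equal(got$df, ref$df, tolerance = 1e-12)
  expect_equal(got$p_value, ref$p_value, tolerance = 1e-12)
  # swap flips t, keeps p
  rev <- welch_t_test(b, a)
  expect_equal(rev$statistic, -got$statistic, tolerance = 1e-12)
  expect_equal(rev$p_value, got$p_value, tolerance = 1e-12)
  # identical samples -> t = 0, p = 1
  same <- welch_t_test(c(1, 1, 1), c(1, 1, 1))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
})

test_that("the default grid spans the documented configuration space", {
  g <- default_grid()
  expect_gte(length(g), 30L)
  kinds <- unique(vapply(g, `[[`, "", "classifier_kind"))
  expect_setequal(kinds, c("logistic_regression", "knn", "random_forest",
                           "svm", "gradient_boosted_trees"))
  sels <- unique(vapply(g, function(x) as.character(x$selector_k), ""))
  expect_setequal(sels, c("none", "5", "10"))
  expect_setequal(unique(vapply(g, `[[`, "", "sampler")), c("none", "smote"))
  ids <- vapply(g, `[[`, "", "config_id")
  expect_equal(anyDuplicated(ids), 0L)
})

test_that("grid search separates a separable problem and ranks consistently", {
  prob <- separable_features(n = 80, p = 6, shift = 4, seed = 11)
  rg <- run_grid(prob$X, prob$y, grid = base_grid(), k = 5, seed = 21)
  lb <- rg$leaderboard
  expect_gte(lb$macro_f1_mean[1], 0.99)
  # ranking is a permutation of the grid with non-increasing mean macro F1
  expect_equal(sort(lb$config_id), sort(vapply(base_grid(), `[[`, "", "config_id")))
  expect_true(all(diff(lb$macro_f1_mean) <= 1e-12))
  # bit-for-bit reproducible under the master seed
  rg2 <- run_grid(prob$X, prob$y, grid = base_grid(), k = 5, seed = 21)
  expect_identical(rg$leaderboard, rg2$leaderboard)
  # confusion counts cover every observation exactly once
  conf <- rg$details[[1]]$confusion
  expect_equal(sum(conf), length(prob$y))
})

test_that("every classifier kind fits and predicts through the pipeline", {
  prob <- separable_features(n = 60, p = 5, shift = 3, seed = 13)
  for (cfg in base_grid()[vapply(base_grid(), function(g)
    g$selector_k == "none" && g$sampler == "none", TRUE)]) {
    pred <- dyskrep:::fit_pipeline(cfg, prob$X, prob$y, seed = 5)(prob$X)
    expect_true(all(pred %in% c(0L, 1L)), label = cfg$config_id)
    expect_gte(macro_f1(prob$y, pred), 0.9)
  }
})

test_that("chance-level labels cannot exceed chance-level scores by much", {
  prob <- separable_features(n = 120, p = 6, shift = 0, seed = 17)  # pure noise
  rg <- run_grid(prob$X, prob$y, grid = base_grid()[seq(1, 30, by = 3)],
                 k = 5, seed = 23)
  expect_lte(rg$leaderboard$macro_f1_mean[1], 0.75)
})
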