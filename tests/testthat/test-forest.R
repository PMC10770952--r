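test_that("the stratified split keeps prevalence and balances training", {
  cohort <- simulate_cohort(seed = 8)
  sp <- split_cohort(cohort, seed = 2)
  expect_equal(nrow(sp$test), round(491 * 0.2) + round(417 * 0.2))
  expect_equal(length(intersect(sp$train_idx, sp$test_idx)), 0)
  ratio <- sum(sp$train$ci_label) / sum(!sp$train$ci_label)
  expect_true(ratio >= 0.9 && ratio <= 1.1)
  # test fold keeps the cohort prevalence
  expect_equal(mean(sp$test$ci_label), 491 / 908, tolerance = 0.02)
  # identical seeds give identical index sets
  sp2 <- split_cohort(cohort, seed = 2)
  expect_identical(sp$train_idx, sp2$train_idx)
  expect_identical(sp$test_idx, sp2$test_idx)
})

test_that("balance = none leaves an already balanced cohort 1:1", {
  d <- signal_dataset(n = 200, seed = 12)
  d$ci_label <- rep(c(TRUE, FALSE), 100)
  sp <- split_cohort(d, balance = "none", seed = 3)
  expect_equal(sum(sp$train$ci_label), sum(!sp$train$ci_label))
})

test_that("a determining feature is recovered with dominant importance", {
  d <- signal_dataset()
  sp <- split_cohort(d, seed = 1)
  m <- train_forest(sp$train, c("A", "B", "C", "D", "E"),
                    n_trees = 100, seed = 1)
  imp <- tidy(m)
  expect_equal(imp$feature[1], "A")
  expect_gt(imp$importance[1], 0.5)
  ev <- evaluate_forest(m, sp$test)
  expect_gte(ev$auc, 0.95)
  expect_gte(ev$accuracy, 0.95)
})

test_that("forests are deterministic per seed and importances sum to one", {
  d <- signal_dataset(n = 150, seed = 4)
  m1 <- train_forest(d, c("A", "B", "C"), n_trees = 50, seed = 9)
  m2 <- train_forest(d, c("A", "B", "C"), n_trees = 50, seed = 9)
  expect_identical(m1$trees, m2$trees)
  expect_equal(sum(m1$importances), 1, tolerance = 1e-9)
  expect_true(all(m1$importances >= 0))
  m3 <- train_forest(d, c("A", "B", "C"), n_trees = 50, seed = 10)
  expect_false(identical(m1$trees, m3$trees))
})

test_that("each tree trains on a bootstrap multiset of training-set size", {
  d <- signal_dataset(n = 120, seed = 2)
  m <- train_forest(d, c("A", "B", "C"), n_trees = 40, seed = 3)
  expect_equal(dim(m$inbag), c(120, 40))
  expect_true(all(colSums(m$inbag) == 120))
  # with replacement: some rows repeat, some are out of bag
  expect_true(all(apply(m$inbag, 2, max) >= 2))
  expect_true(all(colSums(m$inbag == 0) > 0))
})

test_that("a single unbagged tree equals the exhaustive-search CART oracle", {
  withr::with_seed(6, {
    X <- matrix(round(rnorm(36), 2), 12, 3,
                dimnames = list(NULL, c("A", "B", "C")))
    y <- X[, 1] + 0.3 * X[, 3] > 0
    d <- tibble::as_tibble(as.data.frame(X))
    d$ci_label <- y
    m <- train_forest(d, c("A", "B", "C"), n_trees = 1, mtry = 3,
                      min_leaf = 1, bootstrap = FALSE, seed = 1)
    oracle <- cart_oracle_fit(X, y, min_leaf = 1)
    Xnew <- matrix(round(rnorm(60), 2), 20, 3,
                   dimnames = list(NULL, c("A", "B", "C")))
    dn <- tibble::as_tibble(as.data.frame(Xnew))
    expect_equal(as.numeric(predict_proba(m, dn)$vote_fraction),
                 as.numeric(cart_oracle_predict(oracle, Xnew)))
  })
})

test_that("vote fractions respect record order and tie-to-positive calls", {
  d <- signal_dataset(n = 150, seed = 5)
  m <- train_forest(d, c("A", "B", "C", "D", "E"), n_trees = 20, seed = 2)
  p1 <- predict_proba(m, d)
  p2 <- predict_proba(m, d[150:1, ])
  expect_equal(p1$vote_fraction, rev(p2$vote_fraction))
  expect_equal(p1$predicted, p1$vote_fraction >= 0.5)
  expect_error(predict_proba(m, d[, c("A", "B")]), "missing features")
})

test_that("permuted labels give chance-level AUC", {
  d <- signal_dataset(n = 300, seed = 13)
  aucs <- vapply(1:8, function(s) {
    dperm <- d
    dperm$ci_label <- withr::with_seed(1000 + s, sample(d$ci_label))
    sp <- split_cohort(dperm, seed = s)
    m <- train_forest(sp$train, c("A", "B", "C", "D", "E"),
                      n_trees = 60, seed = s)
    evaluate_forest(m, sp$test)$auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("evaluation reports a coherent confusion matrix and ranking", {
  d <- signal_dataset()
  sp <- split_cohort(d, seed = 4)
  m <- train_forest(sp$train, c("A", "B", "C", "D", "E"),
                    n_trees = 100, seed = 4)
  ev <- evaluate_forest(m, sp$test)
  expect_equal(sum(ev$confusion_matrix), nrow(sp$test))
  expect_equal(unname(rowSums(ev$normalized_confusion)), c(1, 1))
  expect_equal(ev$feature_ranking[1], "A")
  expect_equal(sum(ev$importances), 1, tolerance = 1e-9)
  # near-perfect separation: normalized confusion close to identity
  expect_gt(min(diag(ev$normalized_confusion)), 0.9)
})

test_that("the model comparison carries the documented feature sets", {
  expect_length(model_features("physiological"), 6)
  expect_length(model_features("combined"), 12)
  cohort <- simulate_cohort(seed = 30)
  cmp <- compare_models(cohort, seeds = 1:2, n_trees = 60)
  expect_equal(nrow(cmp$replicates), 2)
  expect_true(all(cmp$replicates$auc_combined > 0.5))
  # importances come per model with the right arity
  sp <- split_cohort(cohort, seed = 1)
  m6 <- train_forest(sp$train, model_features("physiological"),
                     n_trees = 60, seed = 1)
  m12 <- train_forest(sp$train, model_features("combined"),
                      n_trees = 60, seed = 1)
  expect_length(m6$importances, 6)
  expect_length(m12$importances, 12)
  expect_setequal(names(m6$importances), model_features("physiological"))
})

test_that("an added pure-noise feature barely moves the combined AUC", {
  cohort <- simulate_cohort(seed = 44)
  # the noise stream must be independent of every stream the simulator
  # consumed, hence the unrelated seed
  cohort$noise <- withr::with_seed(987654, rnorm(nrow(cohort)))
  base <- numeric(5); plus <- numeric(5)
  for (s in 1:5) {
    sp <- split_cohort(cohort, seed = s)
    base[s] <- evaluate_forest(
      train_forest(sp$train, model_features("combined"),
                   n_trees = 250, seed = s), sp$test)$auc
    plus[s] <- evaluate_forest(
      train_forest(sp$train, c(model_features("combined"), "noise"),
                   n_trees = 250, seed = s), sp$test)$auc
  }
  expect_lt(abs(mean(plus) - mean(base)), 0.03)
})

test_that("forests agree with an established implementation on held-out AUC", {
  skip_if_not_installed("randomForest")
  cohort <- simulate_cohort(seed = 55)
  sp <- split_cohort(cohort, seed = 7)
  ours <- evaluate_forest(
    train_forest(sp$train, model_features("combined"), n_trees = 300,
                 seed = 7), sp$test)$auc
  feats <- model_features("combined")
  rf <- withr::with_seed(7, randomForest::randomForest(
    x = as.data.frame(lapply(sp$train[feats], as.numeric)),
    y = factor(sp$train$ci_label), ntree = 300))
  votes <- predict(rf,
                   as.data.frame(lapply(sp$test[feats], as.numeric)),
                   type = "prob")[, "TRUE"]
  ref <- roc_analysis(votes, sp$test$ci_label)$auc
  expect_equal(ours, ref, tolerance = 0.06)
})

test_that("forest models serialize to plain JSON", {
  d <- signal_dataset(n = 80, seed = 3)
  m <- train_forest(d, c("A", "B", "C"), n_trees = 5, seed = 2)
  path <- file.path(withr::local_tempdir(), "model.json")
  write_forest_json(m, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$params$n_trees, 5)
  expect_equal(length(back$trees$feature), 5)
  expect_equal(sum(unlist(back$importances)), 1, tolerance = 1e-9)
})
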