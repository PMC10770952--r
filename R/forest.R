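#' Model feature sets
#'
#' The two predictor sets of the cognitive-impairment classifier: the six
#' physiological indexes (gender, age, BMI, hypertension, diabetes,
#' hyperlipidemia), the six retinal vascular biomarkers (CRAE, CRVE, AVR,
#' FD, global vein width, global artery width), or their union.
#'
#' @param set `"physiological"`, `"vascular"` or `"combined"`.
#' @return Character vector of column names.
#' @export
model_features <- function(set = c("combined", "physiological", "vascular")) {
  set <- match.arg(set)
  phys <- c("female", "age", "bmi", "hypertension", "diabetes",
            "hyperlipidemia")
  vasc <- c("crae", "crve", "avr", "fd", "global_vein_width",
            "global_artery_width")
  switch(set, physiological = phys, vascular = vasc,
         combined = c(phys, vasc))
}

#' Stratified train/test split with optional training-set balancing
#'
#' Splits a cohort ~4:1 into training and test sets, stratified by class
#' so the test set keeps the cohort prevalence. With
#' `balance = "undersample"` the majority class of the *training* fold is
#' randomly undersampled to a ~1:1 ratio; the test fold is never touched.
#'
#' @param data Cohort tibble.
#' @param label Name of the logical label column (default `"ci_label"`).
#' @param test_frac Test fraction (default 1/5, the "nearly 4:1" split).
#' @param balance `"undersample"` or `"none"`.
#' @param seed Integer seed; identical seeds give identical index sets.
#' @return A list with tibbles `train` and `test` and the integer index
#'   vectors `train_idx`, `test_idx` into `data`.
#' @export
split_cohort <- function(data, label = "ci_label", test_frac = 0.2,
                         balance = c("undersample", "none"), seed = 1L) {
  balance <- match.arg(balance)
  y <- as.logical(data[[label]])
  assert_that(sum(y) >= 5 && sum(!y) >= 5,
              "each class needs at least 5 members")
  withr::with_seed(as.integer(seed), {
    test_idx <- sort(unlist(lapply(c(TRUE, FALSE), function(cl) {
      idx <- which(y == cl)
      sample(idx, round(length(idx) * test_frac))
    })))
    train_idx <- setdiff(seq_len(nrow(data)), test_idx)
    if (balance == "undersample") {
      ytr <- y[train_idx]
      n_min <- min(sum(ytr), sum(!ytr))
      train_idx <- sort(unlist(lapply(c(TRUE, FALSE), function(cl) {
        idx <- train_idx[ytr == cl]
        if (length(idx) > n_min) sample(idx, n_min) else idx
      })))
    }
  })
  list(train = data[train_idx, ], test = data[test_idx, ],
       train_idx = train_idx, test_idx = test_idx)
}

# features -> numeric matrix (logicals and factors become numeric codes)
.feature_matrix <- function(data, features) {
  missing <- setdiff(features, names(data))
  assert_that(length(missing) == 0,
              paste0("missing features: ", paste(missing, collapse = ", ")))
  X <- vapply(features, function(f) as.numeric(data[[f]]),
              numeric(nrow(data)))
  if (!is.matrix(X)) X <- matrix(X, nrow = 1, dimnames = list(NULL, features))
  X
}

#' Train a bagged random forest
#'
#' Random forest built from its defining mechanism: each tree is grown on
#' a bootstrap resample of the training set by exhaustive Gini-impurity
#' split search over a random subset of `mtry` features at every node
#' (thresholds at midpoints between consecutive distinct values; impurity
#' ties broken toward the lower feature index, then the lower threshold);
#' prediction is the class with the most tree votes. Per-feature
#' importances are cumulative weighted impurity decreases, normalized to
#' sum to 1.
#'
#' @param data Training tibble.
#' @param features Predictor column names (see [model_features()]).
#' @param label Logical label column; `TRUE` is the positive class.
#' @param n_trees Number of trees (default 500).
#' @param mtry Features tried per node; default `ceiling(sqrt(p))`.
#' @param min_leaf Minimum samples per leaf (default 5).
#' @param max_depth Maximum tree depth; `Inf` (default) grows to purity.
#' @param bootstrap Draw a bootstrap resample per tree (default `TRUE`;
#'   `FALSE` trains every tree on the full set, which makes a one-tree
#'   forest an exhaustive-search CART).
#' @param seed Integer seed; identical inputs and seed give identical
#'   forests.
#' @return An object of class `rmp_forest`.
#' @export
train_forest <- function(data, features, label = "ci_label",
                         n_trees = 500, mtry = NULL, min_leaf = 5,
                         max_depth = Inf, bootstrap = TRUE, seed = 1L) {
  assert_that(length(features) >= 2, "at least 2 features are required")
  assert_that(!label %in% features, "the label cannot be a feature")
  X <- .feature_matrix(data, features)
  y <- as.integer(as.logical(data[[label]]))
  assert_that(any(y == 1L) && any(y == 0L),
              "both classes must be present in the training set")
  if (is.null(mtry)) mtry <- ceiling(sqrt(length(features)))
  md <- if (is.finite(max_depth)) as.integer(max_depth) else -1L
  fit <- withr::with_seed(as.integer(seed),
                          .cpp_rf_train(X, y, as.integer(n_trees),
                                        as.integer(mtry),
                                        as.integer(min_leaf), md, bootstrap))
  imp <- fit$importance
  total <- sum(imp)
  structure(
    list(trees = fit$trees,
         inbag = fit$inbag,
         importance_raw = setNames(imp, features),
         importances = setNames(if (total > 0) imp / total else
                                  rep(1 / length(imp), length(imp)), features),
         features = features, label = label, n_trees = n_trees,
         mtry = mtry, min_leaf = min_leaf, max_depth = max_depth,
         bootstrap = bootstrap, seed = as.integer(seed)),
    class = "rmp_forest"
  )
}

#' @export
print.rmp_forest <- function(x, ...) {
  top <- sort(x$importances, decreasing = TRUE)
  cat(sprintf("<rmp_forest: %d trees, %d features (mtry %d, min_leaf %d)>\n",
              x$n_trees, length(x$features), x$mtry, x$min_leaf))
  cat("  top importances:",
      paste(sprintf("%s %.3f", names(head(top, 5)), head(top, 5)),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.rmp_forest <- function(x, ...) {
  tibble(feature = names(x$importances),
         importance = unname(x$importances)) |>
    dplyr::arrange(dplyr::desc(.data$importance)) |>
    dplyr::mutate(rank = dplyr::row_number())
}

#' @export
glance.rmp_forest <- function(x, ...) {
  tibble(n_trees = x$n_trees, n_features = length(x$features),
         mtry = x$mtry, min_leaf = x$min_leaf, bootstrap = x$bootstrap)
}

#' Vote-fraction predictions from a forest
#'
#' The fraction of trees voting for the positive class, per record; the
#' hard label is `vote >= 0.5` (a 0.5 tie is called positive).
#'
#' @param model An `rmp_forest`.
#' @param data Records carrying every model feature.
#' @return A tibble: `vote_fraction`, `predicted` (logical).
#' @export
predict_proba <- function(model, data) {
  assert_that(inherits(model, "rmp_forest"), "model must be an rmp_forest")
  X <- .feature_matrix(data, model$features)
  votes <- .cpp_rf_votes(model$trees, X)
  tibble(vote_fraction = votes, predicted = votes >= 0.5)
}

#' @export
predict.rmp_forest <- function(object, newdata, ...) {
  predict_proba(object, newdata)
}

#' Evaluate a forest on a test set
#'
#' Test AUC from [roc_analysis()] on the vote fractions, the confusion
#' matrix at the 0.5 vote threshold (rows = truth, columns = prediction),
#' its row-normalized form, and the normalized Gini importances with
#' their ranking.
#'
#' @param model An `rmp_forest`.
#' @param data Test tibble containing the label column and all features;
#'   both classes must be present.
#' @return An object of class `forest_report`: list with `auc`, `roc`
#'   (the `roc_result`), `confusion_matrix`, `normalized_confusion`,
#'   `importances`, `feature_ranking`, `accuracy`, `n_test`.
#' @export
evaluate_forest <- function(model, data) {
  assert_that(inherits(model, "rmp_forest"), "model must be an rmp_forest")
  truth <- as.logical(data[[model$label]])
  assert_that(any(truth) && any(!truth),
              "both classes must be present in the test set")
  pr <- predict_proba(model, data)
  roc <- roc_analysis(pr$vote_fraction, truth)
  cm <- table(truth = factor(truth, c(TRUE, FALSE)),
              predicted = factor(pr$predicted, c(TRUE, FALSE)))
  cm <- matrix(as.numeric(cm), 2, 2,
               dimnames = list(truth = c("impaired", "healthy"),
                               predicted = c("impaired", "healthy")))
  norm_cm <- cm / rowSums(cm)
  structure(
    list(auc = roc$auc, roc = roc, confusion_matrix = cm,
         normalized_confusion = norm_cm,
         importances = model$importances,
         feature_ranking = names(sort(model$importances, decreasing = TRUE)),
         accuracy = mean(pr$predicted == truth), n_test = nrow(data)),
    class = "forest_report"
  )
}

#' @export
print.forest_report <- function(x, ...) {
  cat(sprintf("<forest_report: AUC = %.4f, accuracy = %.3f on %d records>\n",
              x$auc, x$accuracy, x$n_test))
  cat("  ranking:", paste(head(x$feature_ranking, 5), collapse = " > "), "\n")
  invisible(x)
}

#' @export
tidy.forest_report <- function(x, ...) {
  tibble(feature = names(x$importances),
         importance = unname(x$importances)) |>
    dplyr::arrange(dplyr::desc(.data$importance)) |>
    dplyr::mutate(rank = dplyr::row_number())
}

#' @export
glance.forest_report <- function(x, ...) {
  tibble(auc = x$auc, accuracy = x$accuracy, n_test = x$n_test,
         top_feature = x$feature_ranking[1])
}

#' Compare combined and physiological-only forests
#'
#' For each seed: one stratified balanced split, then a forest on the
#' combined (physiological + vascular) features and a forest on the
#' physiological features alone, trained on the identical training fold
#' and evaluated on the identical test fold. Reports the paired test AUCs.
#'
#' @param data Cohort tibble.
#' @param physiological,vascular Feature sets (defaults from
#'   [model_features()]).
#' @param seeds Integer vector; one replicate per seed.
#' @param label Logical label column.
#' @param balance Training balance passed to [split_cohort()].
#' @param ... Forest hyperparameters passed to [train_forest()].
#' @return An object of class `model_comparison`: list with `replicates`
#'   (tibble of `seed`, `auc_combined`, `auc_physiological`, `difference`),
#'   `mean_difference`, and `frac_combined_wins`.
#' @export
compare_models <- function(data,
                           physiological = model_features("physiological"),
                           vascular = model_features("vascular"),
                           seeds = 1:25, label = "ci_label",
                           balance = "undersample", ...) {
  assert_that(length(physiological) > 0 && length(vascular) > 0,
              "feature lists must be non-empty")
  assert_that(!label %in% c(physiological, vascular),
              "the label cannot appear among the features")
  reps <- purrr::map_dfr(seeds, function(s) {
    sp <- split_cohort(data, label = label, balance = balance, seed = s)
    comb <- train_forest(sp$train, c(physiological, vascular), label = label,
                         seed = s, ...)
    phys <- train_forest(sp$train, physiological, label = label,
                         seed = s, ...)
    tibble(seed = s,
           auc_combined = evaluate_forest(comb, sp$test)$auc,
           auc_physiological = evaluate_forest(phys, sp$test)$auc)
  })
  reps <- dplyr::mutate(reps,
                        difference = .data$auc_combined - .data$auc_physiological)
  structure(
    list(replicates = reps,
         mean_difference = mean(reps$difference),
         frac_combined_wins = mean(reps$difference > 0),
         physiological = physiological, vascular = vascular),
    class = "model_comparison"
  )
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf(paste0("<model_comparison: %d replicates, mean AUC gain of the ",
                     "combined model = %+.4f, combined wins in %.0f%%>\n"),
              nrow(x$replicates), x$mean_difference,
              100 * x$frac_combined_wins))
  invisible(x)
}

#' @export
tidy.model_comparison <- function(x, ...) x$replicates

#' @export
glance.model_comparison <- function(x, ...) {
  tibble(n_replicates = nrow(x$replicates),
         mean_auc_combined = mean(x$replicates$auc_combined),
         mean_auc_physiological = mean(x$replicates$auc_physiological),
         mean_difference = x$mean_difference,
         frac_combined_wins = x$frac_combined_wins)
}

#' @rdname compare_models
#' @param object,x A `model_comparison`.
#' @export
autoplot.model_comparison <- function(object, ...) {
  long <- tidyr::pivot_longer(object$replicates,
                              cols = c("auc_combined", "auc_physiological"),
                              names_to = "model", names_prefix = "auc_",
                              values_to = "auc")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$model, y = .data$auc)) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.4) +
    ggplot2::geom_line(ggplot2::aes(group = .data$seed), alpha = 0.3) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::labs(x = NULL, y = "Test AUC",
                  title = "Combined vs physiological-only forest") +
    ggplot2::theme_minimal()
}

#' Serialize a forest to plain JSON
#'
#' Tree structures are plain nested records (feature index, threshold,
#' child indices, leaf votes), so a saved model is readable without the
#' package.
#'
#' @param model An `rmp_forest`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_forest_json <- function(model, path) {
  assert_that(inherits(model, "rmp_forest"), "model must be an rmp_forest")
  out <- list(features = model$features,
              params = list(n_trees = model$n_trees, mtry = model$mtry,
                            min_leaf = model$min_leaf,
                            bootstrap = model$bootstrap, seed = model$seed),
              importances = as.list(model$importances),
              trees = model$trees)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
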