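test_that("pearson correlation matches hand-computed values", {
  expect_equal(pearson_cor(1:5, seq(2, 10, 2))$pearson_r, 1)
  expect_equal(pearson_cor(1:3, 3:1)$pearson_r, -1)
  expect_equal(pearson_cor(c(1, 2, 3, 4), c(1, 3, 2, 4))$pearson_r, 0.8)
  expect_error(pearson_cor(1:4, rep(2, 4)), "variance")
  expect_error(pearson_cor(1:4, 1:3), "equal length")
})

test_that("pearson is symmetric and invariant under positive affine maps", {
  withr::with_seed(21, {
    x <- rnorm(40); y <- rnorm(40) + 0.5 * x
    expect_equal(pearson_cor(x, y)$pearson_r, pearson_cor(y, x)$pearson_r)
    expect_equal(pearson_cor(3 * x + 2, y)$pearson_r,
                 pearson_cor(x, y)$pearson_r)
  })
})

test_that("group comparison picks the test the variable type demands", {
  withr::with_seed(3, {
    d <- tibble::tibble(ci_label = rep(c(TRUE, FALSE), each = 60),
                        x = rep(rnorm(60), 2),
                        b = rep(c(TRUE, FALSE), 60))
    cg <- compare_groups(d, "x")
    expect_equal(cg$test, "t")
    expect_equal(cg$statistic, 0, tolerance = 1e-12)
    expect_equal(cg$p_value, 1, tolerance = 1e-12)
    # balanced binary variable: proportional table, statistic exactly 0
    cb <- compare_groups(d, "b")
    expect_equal(cb$test, "chi_squared")
    expect_equal(cb$statistic, 0, tolerance = 1e-12)
    # heavy-tailed data fail the normality screen
    d$y <- c(rcauchy(60), rcauchy(60) + 5)
    expect_equal(compare_groups(d, "y")$test, "mann_whitney")
  })
})

test_that("Mann-Whitney U is 0 for fully separated groups", {
  d <- tibble::tibble(ci_label = rep(c(TRUE, FALSE), each = 3),
                      v = c(1, 2, 3, 4, 5, 6))
  cg <- compare_groups(d, "v")
  expect_equal(cg$mw_statistic, 0)
})

test_that("ROC handles separation, ties and the worked 4-point example", {
  sep <- roc_analysis(c(1, 2, 3, 10, 11, 12),
                      c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_equal(sep$auc, 1)
  expect_equal(sep$youden_j, 1)
  tied <- roc_analysis(rep(4, 10), rep(c(TRUE, FALSE), 5))
  expect_equal(tied$auc, 0.5)
  ex <- roc_analysis(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(ex$auc, 1)
  expect_equal(ex$youden_cutoff, 2.5)
  expect_error(roc_analysis(1:4, rep(TRUE, 4)), "both classes")
})

test_that("trapezoid AUC equals the tie-corrected rank statistic", {
  withr::with_seed(77, {
    for (rep in 1:200) {
      n <- sample(6:50, 1)
      scores <- sample(1:8, n, replace = TRUE) + # heavy ties
        ifelse(runif(n) < 0.5, 0, 0.5)
      labels <- c(TRUE, FALSE, runif(n - 2) < 0.5)
      r <- roc_analysis(scores, labels)
      expect_equal(r$auc, r$auc_rank, tolerance = 1e-12)
    }
  })
  # spot-check against the explicit pairwise loop
  withr::with_seed(8, {
    scores <- sample(1:5, 30, replace = TRUE)
    labels <- runif(30) < 0.4
    expect_equal(roc_analysis(scores, labels)$auc,
                 pairwise_auc(scores, labels), tolerance = 1e-12)
  })
})

test_that("ROC agrees with an established implementation on random data", {
  skip_if_not_installed("pROC")
  withr::with_seed(15, {
    scores <- rnorm(120)
    labels <- runif(120) < 0.45
    ours <- roc_analysis(scores, labels)$auc
    ref <- suppressMessages(
      as.numeric(pROC::auc(pROC::roc(labels, scores,
                                     direction = "<", quiet = TRUE))))
    expect_equal(ours, ref, tolerance = 1e-10)
  })
})

test_that("flipping direction complements AUC; with flipped labels J persists", {
  withr::with_seed(9, {
    scores <- rnorm(80)
    labels <- runif(80) < 0.5
    hi <- roc_analysis(scores, labels, "higher_is_positive")
    lo <- roc_analysis(scores, labels, "lower_is_positive")
    expect_equal(hi$auc + lo$auc, 1, tolerance = 1e-12)
    # reversing the direction for the complementary class is the same
    # classification problem, so the optimal J carries over
    lo_flip <- roc_analysis(scores, !labels, "lower_is_positive")
    expect_equal(lo_flip$youden_j, hi$youden_j, tolerance = 1e-12)
    expect_equal(lo_flip$auc, hi$auc, tolerance = 1e-12)
  })
})

test_that("binormal AUC matches its closed form", {
  chk <- binormal_auc_check(0, 1, 1, 1, n = 2000, seed = 3)
  expect_equal(chk$closed_form_auc, pnorm(1 / sqrt(2)))
  expect_lt(chk$abs_diff, 0.02)
  expect_equal(binormal_auc_check(2, 1, 2, 1, seed = 1)$closed_form_auc, 0.5)
  # monotone in the mean separation
  cfs <- vapply(c(0.5, 1, 2),
                function(m) binormal_auc_check(0, 1, m, 1,
                                               seed = 1)$closed_form_auc,
                numeric(1))
  expect_true(all(diff(cfs) > 0))
})

test_that("cohort screens run over the full variable sets", {
  cohort <- simulate_cohort(seed = 5)
  gs <- cohort_stats(cohort)
  expect_equal(nrow(gs), 12)
  expect_true(all(gs$p_value >= 0 & gs$p_value <= 1))
  cs <- correlation_screen(cohort)
  expect_equal(nrow(cs), 12)
  expect_true(all(abs(cs$pearson_r) <= 1))
  # healthy coding: FD higher in healthy -> positive r; flipped coding negates
  fd_r <- cs$pearson_r[cs$variable == "fd"]
  expect_gt(fd_r, 0)
  cs_imp <- correlation_screen(cohort, coding = "impaired")
  expect_equal(cs_imp$pearson_r[cs_imp$variable == "fd"], -fd_r)
})
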