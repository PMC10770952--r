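#' Pearson correlation with a t-based p-value
#'
#' Sample Pearson correlation between two numeric vectors, with the
#' two-sided p-value from the t distribution on n - 2 degrees of freedom.
#' When one vector is a binary indicator this is the point-biserial
#' correlation.
#'
#' @param x,y Numeric vectors of equal length (>= 3), each with non-zero
#'   variance. Logical vectors are coerced to 0/1.
#' @param variable Optional name recorded in the output.
#' @return A one-row tibble: `variable`, `pearson_r`, `p_value`, `n`.
#' @examples
#' pearson_cor(c(1, 2, 3, 4), c(1, 3, 2, 4)) # r = 0.8
#' @export
pearson_cor <- function(x, y, variable = NA_character_) {
  x <- as.numeric(x); y <- as.numeric(y)
  assert_that(length(x) == length(y), "x and y must have equal length")
  assert_that(length(x) >= 3, "at least 3 observations are required")
  assert_that(sd(x) > 0 && sd(y) > 0, "both vectors must have non-zero variance")
  ct <- suppressWarnings(cor.test(x, y, method = "pearson"))
  tibble(variable = variable, pearson_r = unname(ct$estimate),
         p_value = ct$p.value, n = length(x))
}

#' Two-group comparison with the test chosen by variable type
#'
#' Binary variables are compared with the chi-squared test (on the 2 x 2
#' count table, without continuity correction); continuous variables with
#' Student's t-test when both groups pass a Shapiro-Wilk normality screen
#' at alpha = 0.05, and with the Mann-Whitney U test otherwise. Both
#' continuous tests are always computed and reported side by side; `test`,
#' `statistic` and `p_value` carry the one selected by the rule.
#'
#' @param data A data frame (e.g. from [simulate_cohort()]).
#' @param variable Name of the column to compare.
#' @param group Name of a logical/binary grouping column
#'   (default `"ci_label"`).
#' @param shapiro_alpha Significance level of the normality screen.
#' @return A one-row tibble with the selected test, per-group summaries
#'   (means/SDs, or counts and proportions for binary variables), and the
#'   side-by-side t and Mann-Whitney results for continuous variables.
#' @export
compare_groups <- function(data, variable, group = "ci_label",
                           shapiro_alpha = 0.05) {
  assert_that(variable %in% names(data),
              sprintf("unknown variable '%s'", variable))
  assert_that(group %in% names(data), sprintf("unknown group column '%s'", group))
  g <- as.logical(data[[group]])
  x <- data[[variable]]
  assert_that(any(g) && any(!g), "both groups must be non-empty")
  x1 <- x[g]; x0 <- x[!g]

  is_binary <- is.logical(x) || length(unique(x[!is.na(x)])) <= 2
  if (is_binary) {
    tab <- table(factor(as.numeric(g), levels = c(1, 0)),
                 factor(as.numeric(x), levels = sort(unique(as.numeric(x)))))
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    return(tibble(
      variable = variable, type = "binary", test = "chi_squared",
      statistic = unname(ct$statistic), p_value = ct$p.value,
      n_group1 = sum(g), n_group2 = sum(!g),
      prop_group1 = mean(as.numeric(x1)), prop_group2 = mean(as.numeric(x0))
    ))
  }

  x1 <- as.numeric(x1); x0 <- as.numeric(x0)
  # Shapiro-Wilk is defined for 3..5000 observations; screen on the first
  # 5000 values of larger groups
  swp <- function(v) {
    v <- head(v[!is.na(v)], 5000)
    if (length(v) < 3 || sd(v) == 0) return(0)
    shapiro.test(v)$p.value
  }
  normal_both <- swp(x1) > shapiro_alpha && swp(x0) > shapiro_alpha
  tt <- t.test(x1, x0, var.equal = TRUE)
  mw <- suppressWarnings(wilcox.test(x1, x0, exact = FALSE))
  tibble(
    variable = variable, type = "continuous",
    test = if (normal_both) "t" else "mann_whitney",
    statistic = unname(if (normal_both) tt$statistic else mw$statistic),
    p_value = if (normal_both) tt$p.value else mw$p.value,
    n_group1 = length(x1), n_group2 = length(x0),
    mean_group1 = mean(x1), sd_group1 = sd(x1),
    mean_group2 = mean(x0), sd_group2 = sd(x0),
    t_statistic = unname(tt$statistic), t_p_value = tt$p.value,
    mw_statistic = unname(mw$statistic), mw_p_value = mw$p.value
  )
}

#' ROC curve, AUC and Youden-optimal cut-off
#'
#' Builds the full ROC curve over thresholds placed midway between
#' consecutive distinct scores (with -Inf/+Inf sentinels), computes the
#' AUC by the trapezoidal rule over the (FPR, TPR) polyline, cross-checks
#' it against the tie-corrected rank statistic `U / (n1 * n0)`, and
#' locates the cut-off maximizing the Youden index
#' (sensitivity + specificity - 1). Youden ties are broken toward higher
#' sensitivity, then toward the lower threshold.
#'
#' @param scores Numeric marker values.
#' @param labels Logical (or 0/1) class labels; `TRUE` is the positive
#'   (e.g. impaired) class.
#' @param direction `"higher_is_positive"` if large scores indicate the
#'   positive class, `"lower_is_positive"` otherwise.
#' @return An object of class `roc_result`: list with `curve` (tibble of
#'   `threshold`, `sensitivity`, `specificity`, `fpr`, `tpr`, `youden_j`),
#'   `auc` (trapezoid), `auc_rank` (rank-statistic cross-check),
#'   `youden_cutoff`, `youden_j`, `sensitivity_at_cutoff`,
#'   `specificity_at_cutoff`, `direction`, `n_positive`, `n_negative`.
#' @examples
#' r <- roc_analysis(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE))
#' r$auc           # 1
#' r$youden_cutoff # 2.5
#' @export
roc_analysis <- function(scores, labels,
                         direction = c("higher_is_positive",
                                       "lower_is_positive")) {
  direction <- match.arg(direction)
  labels <- as.logical(labels)
  assert_that(length(scores) == length(labels),
              "scores and labels must have equal length")
  assert_that(any(labels) && any(!labels), "both classes must be present")
  sgn <- if (direction == "higher_is_positive") 1 else -1
  s <- sgn * as.numeric(scores)
  n1 <- sum(labels); n0 <- sum(!labels)

  u <- sort(unique(s))
  thr <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
  sens <- vapply(thr, function(t) mean(s[labels] >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(s[!labels] < t), numeric(1))
  curve <- tibble(threshold = sgn * thr, sensitivity = sens,
                  specificity = spec, fpr = 1 - spec, tpr = sens,
                  youden_j = sens + spec - 1)

  # trapezoid over the (FPR, TPR) polyline (thresholds descending ->
  # FPR ascending)
  o <- order(curve$fpr, curve$tpr)
  fx <- curve$fpr[o]; fy <- curve$tpr[o]
  auc <- sum(diff(fx) * (fy[-1] + fy[-length(fy)]) / 2)
  # rank-statistic identity, ties counted 1/2
  r <- rank(s, ties.method = "average")
  auc_rank <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  jmax <- max(curve$youden_j)
  cand <- which(curve$youden_j >= jmax - 1e-12)
  cand <- cand[curve$sensitivity[cand] >= max(curve$sensitivity[cand]) - 1e-12]
  best <- cand[which.min(curve$threshold[cand])]

  structure(
    list(curve = curve, auc = auc, auc_rank = auc_rank,
         youden_cutoff = curve$threshold[best],
         youden_j = curve$youden_j[best],
         sensitivity_at_cutoff = curve$sensitivity[best],
         specificity_at_cutoff = curve$specificity[best],
         direction = direction, n_positive = n1, n_negative = n0),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(paste0("<roc_result: AUC = %.4f, Youden cut-off = %.4g ",
                     "(J = %.3f, sens %.3f, spec %.3f), %d+/%d- >\n"),
              x$auc, x$youden_cutoff, x$youden_j, x$sensitivity_at_cutoff,
              x$specificity_at_cutoff, x$n_positive, x$n_negative))
  invisible(x)
}

#' @export
tidy.roc_result <- function(x, ...) x$curve

#' @export
glance.roc_result <- function(x, ...) {
  tibble(auc = x$auc, auc_rank = x$auc_rank,
         youden_cutoff = x$youden_cutoff, youden_j = x$youden_j,
         sensitivity = x$sensitivity_at_cutoff,
         specificity = x$specificity_at_cutoff,
         n_positive = x$n_positive, n_negative = x$n_negative)
}

#' @rdname roc_analysis
#' @param object,x A `roc_result`.
#' @param ... Unused.
#' @export
autoplot.roc_result <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "red") +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  title = sprintf("ROC curve (AUC = %.3f)", object$auc)) +
    ggplot2::theme_minimal()
}

#' Binormal AUC closed-form check
#'
#' Simulates scores from two Gaussians, computes the empirical AUC with
#' [roc_analysis()], and compares it against the closed form
#' `pnorm(|mu1 - mu0| / sqrt(sd0^2 + sd1^2))`.
#'
#' @param mu0,sd0 Negative-class Gaussian parameters.
#' @param mu1,sd1 Positive-class Gaussian parameters.
#' @param n Total sample size, split evenly between the classes.
#' @param seed Integer seed.
#' @return A one-row tibble: `empirical_auc`, `closed_form_auc`,
#'   `abs_diff`, `n`.
#' @export
binormal_auc_check <- function(mu0 = 0, sd0 = 1, mu1 = 1, sd1 = 1,
                               n = 2000, seed = 1L) {
  assert_that(sd0 > 0 && sd1 > 0, "SDs must be positive")
  withr::with_seed(as.integer(seed), {
    m <- n %/% 2
    scores <- c(rnorm(m, mu0, sd0), rnorm(n - m, mu1, sd1))
    labels <- c(rep(FALSE, m), rep(TRUE, n - m))
    emp <- roc_analysis(scores, labels)$auc
  })
  cf <- pnorm(abs(mu1 - mu0) / sqrt(sd0^2 + sd1^2))
  tibble(empirical_auc = emp, closed_form_auc = cf,
         abs_diff = abs(emp - cf), n = n)
}

#' Cohort-level descriptive and correlation screens
#'
#' `cohort_stats()` runs [compare_groups()] on every requested variable
#' (a group-comparison table in the style of a baseline-characteristics
#' table). `correlation_screen()` runs [pearson_cor()] of every variable
#' against a cognition coding and appends Benjamini-Hochberg adjusted
#' p-values alongside the raw ones.
#'
#' The cognition coding deserves care: `"healthy"` (the default) codes 1
#' for subjects *without* impairment, so variables that are higher in
#' healthy subjects (e.g. FD) get positive correlations; `"impaired"`
#' flips every sign; `"moca"` uses the raw score.
#'
#' @param data A cohort tibble (see [simulate_cohort()]).
#' @param variables Columns to screen; defaults to the model's six
#'   physiological indexes and six retinal parameters.
#' @param group Logical grouping column for `cohort_stats()`.
#' @param coding Cognition coding for `correlation_screen()`.
#' @return A tibble with one row per variable.
#' @export
cohort_stats <- function(data, variables = model_features("combined"),
                         group = "ci_label") {
  purrr::map_dfr(variables, function(v) compare_groups(data, v, group))
}

#' @rdname cohort_stats
#' @export
correlation_screen <- function(data, variables = model_features("combined"),
                               coding = c("healthy", "impaired", "moca")) {
  coding <- match.arg(coding)
  y <- switch(coding,
              healthy = 1 - as.numeric(data$ci_label),
              impaired = as.numeric(data$ci_label),
              moca = as.numeric(data$moca))
  out <- purrr::map_dfr(variables, function(v) {
    pearson_cor(as.numeric(data[[v]]), y, variable = v)
  })
  dplyr::mutate(out, p_adjusted_bh = stats::p.adjust(.data$p_value, "BH"),
                coding = coding)
}
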