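#' Default class-conditional cohort specification
#'
#' The generator's study conditions: class-conditional means/SDs for the
#' continuous variables and prevalences for the binary ones, for a cohort
#' of 491 cognitively impaired (MoCA < 26) and 417 unimpaired subjects.
#' Continuous retinal parameters (AVR, CRAE, CRVE, FD, global artery/vein
#' width) and physiological indexes (age, BMI) are Gaussian within class,
#' truncated at physical bounds; MoCA is an integer 30-point scale.
#'
#' @param n_impaired,n_healthy Class sizes.
#' @param seed Default seed carried by the spec.
#' @return An object of class `cohort_spec` with elements `n_impaired`,
#'   `n_healthy`, `continuous` (tibble: variable, class means/SDs, bounds,
#'   integer flag), `binary` (tibble: variable, class prevalences),
#'   `csvd_probs` (per-class multinomial over scores 0-4) and `seed`.
#' @export
default_cohort_spec <- function(n_impaired = 491, n_healthy = 417, seed = 1L) {
  assert_that(n_impaired > 0 && n_healthy > 0, "class counts must be positive")
  continuous <- tibble(
    variable = c("age", "bmi", "moca", "avr", "crae", "crve", "fd",
                 "global_artery_width", "global_vein_width"),
    mean_impaired = c(59.68, 25.37, 21.78, 0.714, 151.748, 214.560, 1.289,
                      78.711, 133.062),
    sd_impaired = c(10.730, 3.25, 3.148, 0.142, 29.719, 37.510, 0.090,
                    13.701, 33.319),
    mean_healthy = c(50.65, 25.01, 27.66, 0.732, 158.862, 219.977, 1.324,
                     79.777, 121.497),
    sd_healthy = c(11.397, 3.56, 1.318, 0.108, 26.864, 31.034, 0.074,
                   11.633, 21.074),
    lower = c(23, 10, 0, 1e-6, 1e-6, 1e-6, 1e-6, 1e-6, 1e-6),
    upper = c(83, Inf, 30, Inf, Inf, Inf, Inf, Inf, Inf),
    integer_valued = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE,
                       FALSE, FALSE)
  )
  binary <- tibble(
    variable = c("female", "hypertension", "diabetes", "hyperlipidemia",
                 "smoking", "alcohol_nondrinker"),
    p_impaired = c(0.601, 0.540, 0.118, 0.155, 0.265, 0.737),
    p_healthy = c(0.475, 0.403, 0.100, 0.118, 0.218, 0.760),
    model_input = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE)
  )
  csvd_probs <- list(
    impaired = c(101, 146, 126, 65, 52) / sum(c(101, 146, 126, 65, 52)),
    healthy = c(195, 125, 64, 25, 9) / sum(c(195, 125, 64, 25, 9))
  )
  structure(
    list(n_impaired = as.integer(n_impaired),
         n_healthy = as.integer(n_healthy),
         continuous = continuous, binary = binary, csvd_probs = csvd_probs,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

# vectorised truncated-normal draw by rejection, with a bounded retry count
.rtrunc_norm <- function(n, mean, sd, lower, upper, max_rounds = 10000) {
  x <- rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  rounds <- 0
  while (length(bad)) {
    rounds <- rounds + 1
    if (rounds > max_rounds) {
      abort("truncated-normal sampling did not terminate; spec is infeasible",
            class = "retmorph_infeasible_spec")
    }
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lower | x[bad] > upper]
  }
  x
}

# MoCA: integer draw consistent with the class (impaired < 26, else >= 26)
.draw_moca <- function(n, mean, sd, impaired, max_rounds = 10000) {
  ok <- function(v) if (impaired) v < 26 else v >= 26
  x <- pmin(30, pmax(0, round(rnorm(n, mean, sd))))
  bad <- which(!ok(x))
  rounds <- 0
  while (length(bad)) {
    rounds <- rounds + 1
    if (rounds > max_rounds) {
      abort(paste0("MoCA resampling did not terminate: the ",
                   if (impaired) "impaired" else "healthy",
                   "-class MoCA distribution is incompatible with its label"),
            class = "retmorph_infeasible_spec")
    }
    x[bad] <- pmin(30, pmax(0, round(rnorm(length(bad), mean, sd))))
    bad <- bad[!ok(x[bad])]
  }
  as.integer(x)
}

#' Simulate a cohort table
#'
#' Draws one subject row per class member: the class label first (class
#' sizes are fixed by the spec), then the continuous variables from the
#' class-conditional truncated Gaussians and the binary variables from the
#' class prevalences. Variables are independent within class — the spec
#' carries only marginal summaries. The impairment label is re-derived
#' from the MoCA score (< 26), and MoCA draws are resampled until
#' consistent with their class, so `ci_label == (moca < 26)` holds on
#' every row.
#'
#' @param spec A `cohort_spec` from [default_cohort_spec()].
#' @param seed Integer seed (defaults to the spec's); identical
#'   (spec, seed) give identical tables.
#' @param include_extras Also generate the non-model columns (smoking,
#'   alcohol, CSVD score).
#' @return A tibble with one row per subject: `subject_id`, `ci_label`,
#'   `moca`, the physiological indexes, and the six retinal microvascular
#'   parameters.
#' @examples
#' cohort <- simulate_cohort(default_cohort_spec(), seed = 42)
#' nrow(cohort) # 908
#' @export
simulate_cohort <- function(spec = default_cohort_spec(), seed = spec$seed,
                            include_extras = TRUE) {
  assert_that(inherits(spec, "cohort_spec"), "spec must be a cohort_spec")
  withr::with_seed(as.integer(seed), {
    draw_class <- function(n, impaired) {
      out <- tibble(.rows = n)
      for (i in seq_len(nrow(spec$continuous))) {
        v <- spec$continuous[i, ]
        mu <- if (impaired) v$mean_impaired else v$mean_healthy
        sg <- if (impaired) v$sd_impaired else v$sd_healthy
        out[[v$variable]] <- if (v$variable == "moca") {
          .draw_moca(n, mu, sg, impaired)
        } else {
          x <- .rtrunc_norm(n, mu, sg, v$lower, v$upper)
          if (v$integer_valued) round(x) else x
        }
      }
      for (i in seq_len(nrow(spec$binary))) {
        b <- spec$binary[i, ]
        if (!include_extras && !b$model_input) next
        p <- if (impaired) b$p_impaired else b$p_healthy
        out[[b$variable]] <- rbinom(n, 1, p) == 1
      }
      if (include_extras) {
        pr <- if (impaired) spec$csvd_probs$impaired else spec$csvd_probs$healthy
        out$csvd_score <- sample(0:4, n, replace = TRUE, prob = pr)
      }
      out
    }
    cohort <- dplyr::bind_rows(draw_class(spec$n_impaired, TRUE),
                               draw_class(spec$n_healthy, FALSE))
    cohort <- dplyr::mutate(cohort,
                            subject_id = sprintf("S%04d", dplyr::row_number()),
                            ci_label = .data$moca < 26,
                            .before = 1)
    stopifnot(all(cohort$ci_label == (cohort$moca < 26)))
    cohort
  })
}

#' Analytic point-biserial correlation implied by a cohort spec
#'
#' The population Pearson correlation between a continuous variable and
#' the binary impairment indicator under the spec's two-class Gaussian
#' mixture: `r = (mu1 - mu0) * sqrt(p * q) / sd_total`, where `p` is the
#' impaired fraction, `q = 1 - p`, and the total SD combines the
#' within-class variances with the between-class mean gap,
#' `sd_total^2 = p * sd1^2 + q * sd0^2 + p * q * (mu1 - mu0)^2`.
#' Truncation of the Gaussians is ignored (it perturbs the moments only
#' slightly at the default parameters). The impaired class is coded 1.
#'
#' @param spec A `cohort_spec`.
#' @param variable Name of a continuous variable in the spec.
#' @return The analytic correlation (scalar in `[-1, 1]`).
#' @export
point_biserial_check <- function(spec, variable) {
  assert_that(inherits(spec, "cohort_spec"), "spec must be a cohort_spec")
  v <- dplyr::filter(spec$continuous, .data$variable == .env$variable)
  assert_that(nrow(v) == 1,
              sprintf("'%s' is not a continuous variable of the spec", variable))
  p <- spec$n_impaired / (spec$n_impaired + spec$n_healthy)
  q <- 1 - p
  dmu <- v$mean_impaired - v$mean_healthy
  sd_total <- sqrt(p * v$sd_impaired^2 + q * v$sd_healthy^2 + p * q * dmu^2)
  dmu * sqrt(p * q) / sd_total
}
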