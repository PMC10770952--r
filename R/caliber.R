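#' Knudtson-Hubbard pairwise caliber combination
#'
#' The revised branching-coefficient formula combining two vessel widths
#' into one equivalent trunk caliber: `0.88 * sqrt(w1^2 + w2^2)` for
#' arterioles and `0.95 * sqrt(w1^2 + w2^2)` for venules. The coefficients
#' are the canonical revised-formula constants and can be overridden.
#'
#' @param w1,w2 Vessel widths (same units, both positive).
#' @param vessel_class `"artery"` or `"vein"`.
#' @param coefficients Named pair of branching coefficients,
#'   `c(artery = 0.88, vein = 0.95)`.
#' @return The combined caliber, same units as the inputs.
#' @examples
#' knudtson_pair(3, 4, "artery") # 0.88 * 5 = 4.4
#' knudtson_pair(3, 4, "vein")   # 0.95 * 5 = 4.75
#' @export
knudtson_pair <- function(w1, w2, vessel_class = c("artery", "vein"),
                          coefficients = c(artery = 0.88, vein = 0.95)) {
  vessel_class <- match.arg(vessel_class)
  assert_that(all(w1 > 0) && all(w2 > 0), "vessel widths must be positive")
  unname(coefficients[vessel_class]) * sqrt(w1^2 + w2^2)
}

#' Summarize zone-B widths into CRAE or CRVE
#'
#' The iterative Knudtson-Hubbard reduction: take the six largest widths
#' (or all of them with `use_all = TRUE`, or all when fewer than six are
#' available), then repeatedly sort the current list and combine the
#' largest with the smallest via [knudtson_pair()], appending the combined
#' value, until a single number remains. For arteries that number is the
#' central retinal arteriolar equivalent (CRAE); for veins, the venular
#' equivalent (CRVE).
#'
#' @param widths Positive per-vessel mean widths.
#' @param vessel_class `"artery"` or `"vein"`.
#' @param use_all Use every width instead of the six largest.
#' @param n_largest How many of the largest vessels enter the reduction
#'   when `use_all = FALSE` (default 6, the standard "big six").
#' @inheritParams knudtson_pair
#' @return The summary caliber (scalar) with attribute `n_used`; units are
#'   those of `widths`.
#' @examples
#' summarize_caliber(c(18, 15, 14, 12, 11, 10), "artery")
#' @export
summarize_caliber <- function(widths, vessel_class = c("artery", "vein"),
                              use_all = FALSE, n_largest = 6,
                              coefficients = c(artery = 0.88, vein = 0.95)) {
  vessel_class <- match.arg(vessel_class)
  assert_that(length(widths) >= 1, "at least one width is required")
  assert_that(all(widths > 0), "vessel widths must be positive")
  w <- sort(widths, decreasing = TRUE)
  if (!use_all) w <- head(w, n_largest)
  n_used <- length(w)
  w <- sort(w)
  while (length(w) > 1) {
    combined <- knudtson_pair(w[length(w)], w[1], vessel_class,
                              coefficients = coefficients)
    w <- sort(c(w[-c(1, length(w))], combined))
  }
  structure(w, n_used = n_used)
}

#' Arteriole-to-venule ratio
#'
#' AVR = CRAE / CRVE. A degenerate eye with CRAE = 0 yields 0 with a
#' warning; a non-positive CRVE is an error.
#'
#' @param crae,crve Summary calibers from [summarize_caliber()].
#' @return The dimensionless ratio.
#' @export
compute_avr <- function(crae, crve) {
  assert_that(crve > 0, "CRVE must be positive")
  if (crae == 0) {
    warn("CRAE is 0 (degenerate eye); AVR set to 0")
    return(0)
  }
  assert_that(crae > 0, "CRAE must be non-negative")
  crae / crve
}

#' Full caliber summary of one eye
#'
#' Measures zone-B artery and vein segments on a labelled mask and reduces
#' them to CRAE, CRVE and AVR.
#'
#' @param mask A [labeled_vessel_mask()] carrying its [optic_disc()]
#'   geometry (or pass `zone` explicitly).
#' @param zone A `zone_annulus`; defaults to [zone_b()] of the mask's disc.
#' @inheritParams summarize_caliber
#' @inheritParams measure_segments
#' @return A one-row tibble: `crae`, `crve`, `avr`, `n_arteries_used`,
#'   `n_veins_used`.
#' @export
caliber_summary <- function(mask, zone = NULL, use_all = FALSE,
                            n_largest = 6, min_path_length = 10) {
  assert_that(inherits(mask, "labeled_vessel_mask"), "mask must be a labeled_vessel_mask")
  if (is.null(zone)) {
    assert_that(!is.null(mask$disc),
                "mask carries no optic disc geometry; pass `zone` explicitly")
    zone <- zone_b(mask$disc)
  }
  arts <- measure_segments(mask, "artery", zone, min_path_length = min_path_length)
  veins <- measure_segments(mask, "vein", zone, min_path_length = min_path_length)
  assert_that(nrow(arts) > 0 && nrow(veins) > 0,
              "no measurable artery or vein segments in the zone")
  crae_s <- summarize_caliber(arts$mean_width, "artery", use_all = use_all,
                              n_largest = n_largest)
  crve_s <- summarize_caliber(veins$mean_width, "vein", use_all = use_all,
                              n_largest = n_largest)
  tibble(crae = as.numeric(crae_s), crve = as.numeric(crve_s),
         avr = compute_avr(as.numeric(crae_s), as.numeric(crve_s)),
         n_arteries_used = attr(crae_s, "n_used"),
         n_veins_used = attr(crve_s, "n_used"))
}
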