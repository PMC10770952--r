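#' All six retinal microvascular parameters for one eye
#'
#' Runs the full image-side pipeline on a labelled mask: skeleton-based
#' fractal dimension of the vessel network, zone-B Knudtson-Hubbard
#' calibers (CRAE, CRVE, AVR), and global artery/vein width (area over
#' skeleton length).
#'
#' @param mask A [labeled_vessel_mask()] with optic-disc geometry.
#' @inheritParams caliber_summary
#' @param fd_sizes Optional box-size ladder for [vessel_fd()].
#' @return A one-row tibble: `fd`, `fd_r_squared`, `crae`, `crve`, `avr`,
#'   `global_artery_width`, `global_vein_width`, `n_arteries_used`,
#'   `n_veins_used`.
#' @export
eye_morphometry <- function(mask, zone = NULL, use_all = FALSE,
                            n_largest = 6, min_path_length = 10,
                            fd_sizes = NULL) {
  assert_that(inherits(mask, "labeled_vessel_mask"), "mask must be a labeled_vessel_mask")
  if (is.null(zone)) {
    assert_that(!is.null(mask$disc),
                "mask carries no optic disc geometry; pass `zone` explicitly")
    zone <- zone_b(mask$disc)
  }
  # each class is thinned once and the skeleton shared across FD, zone-B
  # segment measurement and global width
  area_a <- sum(mask$grid == 1L)
  area_v <- sum(mask$grid == 2L)
  assert_that(area_a > 0 && area_v > 0,
              "mask must contain both artery and vein pixels")
  skel_a <- skeletonize(mask, "artery")$grid
  skel_v <- skeletonize(mask, "vein")$grid
  fdc <- compute_fd(((skel_a + skel_v) != 0) * 1L, sizes = fd_sizes)
  arts <- measure_segments(mask, "artery", zone,
                           min_path_length = min_path_length,
                           .skeleton = skel_a)
  veins <- measure_segments(mask, "vein", zone,
                            min_path_length = min_path_length,
                            .skeleton = skel_v)
  assert_that(nrow(arts) > 0 && nrow(veins) > 0,
              "no measurable artery or vein segments in the zone")
  crae_s <- summarize_caliber(arts$mean_width, "artery", use_all = use_all,
                              n_largest = n_largest)
  crve_s <- summarize_caliber(veins$mean_width, "vein", use_all = use_all,
                              n_largest = n_largest)
  tibble(fd = fdc$fd, fd_r_squared = fdc$r_squared,
         crae = as.numeric(crae_s), crve = as.numeric(crve_s),
         avr = compute_avr(as.numeric(crae_s), as.numeric(crve_s)),
         global_artery_width = mask$pixel_scale * area_a /
           skeleton_length(skel_a),
         global_vein_width = mask$pixel_scale * area_v /
           skeleton_length(skel_v),
         n_arteries_used = attr(crae_s, "n_used"),
         n_veins_used = attr(crve_s, "n_used"))
}

#' Batch morphometry over a directory of masks
#'
#' Reads every `*.png` mask (with its JSON disc sidecar) in a directory,
#' measures the six retinal microvascular parameters per eye, and
#' (optionally) writes `morphometry.csv` plus a reproducibility manifest.
#' Unreadable masks or eyes where measurement fails are skipped with a
#' logged reason — mirroring quality-control discards — never silently.
#'
#' @param mask_dir Directory containing PNG masks written by
#'   [write_mask_png()].
#' @param out_dir Optional output directory for `morphometry.csv` and
#'   `manifest.json`.
#' @param ... Passed to [eye_morphometry()].
#' @return A tibble with one row per successfully measured eye
#'   (`eye_id` = file stem, then the morphometry columns); skipped eyes
#'   are reported in the `skipped` attribute.
#' @export
run_morphometry <- function(mask_dir, out_dir = NULL, ...) {
  assert_that(dir.exists(mask_dir),
              sprintf("mask directory '%s' does not exist", mask_dir))
  files <- sort(list.files(mask_dir, pattern = "\\.png$", full.names = TRUE))
  skipped <- tibble(eye_id = character(), reason = character())
  rows <- list()
  for (f in files) {
    id <- sub("\\.png$", "", basename(f))
    res <- tryCatch(
      dplyr::bind_cols(tibble(eye_id = id),
                       eye_morphometry(read_mask_png(f), ...)),
      error = function(e) conditionMessage(e))
    if (is.character(res)) {
      message(sprintf("skipping eye '%s': %s", id, res))
      skipped <- dplyr::bind_rows(skipped, tibble(eye_id = id, reason = res))
    } else {
      rows[[length(rows) + 1]] <- res
    }
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else
    dplyr::bind_cols(tibble(eye_id = character()),
                     tibble(fd = numeric(), fd_r_squared = numeric(),
                            crae = numeric(), crve = numeric(),
                            avr = numeric(),
                            global_artery_width = numeric(),
                            global_vein_width = numeric(),
                            n_arteries_used = integer(),
                            n_veins_used = integer()))
  attr(out, "skipped") <- skipped
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(out, file.path(out_dir, "morphometry.csv"), row.names = FALSE)
    manifest <- list(
      stage = "morphometry",
      package_version = as.character(utils::packageVersion("retmorph")),
      n_eyes = nrow(out), n_skipped = nrow(skipped),
      inputs = lapply(files, function(f) {
        list(file = basename(f),
             fnv1a = fnv1a_hash(readBin(f, "raw", file.info(f)$size)))
      }))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

#' Self-contained end-to-end demonstration run
#'
#' Generates a set of synthetic labelled eyes and a simulated cohort,
#' then runs every stage: per-eye morphometry, baseline group
#' comparisons, the Pearson correlation screen, ROC/Youden analyses of FD
#' and global vein width, and the combined-vs-physiological random-forest
#' comparison. All outputs are written as CSV/JSON under `out_dir`
#' together with a manifest that reproduces the run byte-for-byte under
#' the same seed.
#'
#' @param seed Master integer seed for every stage.
#' @param out_dir Output directory (created if needed).
#' @param n_eyes Number of synthetic eyes (default 50).
#' @param cohort_spec Cohort spec (default [default_cohort_spec()],
#'   n = 908).
#' @param forest_seeds Seeds of the forest-comparison replicates.
#' @param n_trees Trees per forest in the comparison.
#' @return Invisibly, a list with the in-memory results (`morphometry`,
#'   `cohort`, `group_comparisons`, `correlations`, `roc_fd`, `roc_gvw`,
#'   `comparison`) and `files`, the written paths.
#' @export
run_full_demo <- function(seed = 1L, out_dir = tempfile("retmorph_demo_"),
                          n_eyes = 50, cohort_spec = default_cohort_spec(),
                          forest_seeds = 1:5, n_trees = 300) {
  seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  mask_dir <- file.path(out_dir, "masks")
  dir.create(mask_dir, showWarnings = FALSE)

  disc <- optic_disc(512, 420, 150)
  for (i in seq_len(n_eyes)) {
    eye_seed <- (seed * 10000L + i) %% 2147483647L
    tree <- generate_vessel_tree(vessel_tree_spec(seed = eye_seed), disc)
    write_mask_png(tree$mask,
                   file.path(mask_dir, sprintf("eye_%03d.png", i)),
                   segments = tree$segments)
  }
  morpho <- run_morphometry(mask_dir, out_dir = out_dir)

  cohort <- simulate_cohort(cohort_spec, seed = seed)
  write.csv(cohort[, setdiff(names(cohort), "centerline")],
            file.path(out_dir, "cohort.csv"), row.names = FALSE)

  groups <- cohort_stats(cohort)
  write.csv(groups, file.path(out_dir, "group_comparisons.csv"),
            row.names = FALSE)
  cors <- correlation_screen(cohort)
  write.csv(cors, file.path(out_dir, "correlations.csv"), row.names = FALSE)

  # impaired eyes have sparser networks (lower FD) but wider veins
  roc_fd <- roc_analysis(cohort$fd, cohort$ci_label,
                         direction = "lower_is_positive")
  roc_gvw <- roc_analysis(cohort$global_vein_width, cohort$ci_label,
                          direction = "higher_is_positive")
  write.csv(tidy(roc_fd), file.path(out_dir, "roc_fd.csv"), row.names = FALSE)
  write.csv(tidy(roc_gvw), file.path(out_dir, "roc_global_vein_width.csv"),
            row.names = FALSE)
  jsonlite::write_json(
    list(fd = as.list(glance(roc_fd)),
         global_vein_width = as.list(glance(roc_gvw))),
    file.path(out_dir, "roc_summary.json"), auto_unbox = TRUE, digits = NA)

  comparison <- compare_models(cohort, seeds = forest_seeds,
                               n_trees = n_trees)
  write.csv(comparison$replicates, file.path(out_dir, "forest_comparison.csv"),
            row.names = FALSE)
  jsonlite::write_json(as.list(glance(comparison)),
                       file.path(out_dir, "forest_summary.json"),
                       auto_unbox = TRUE, digits = NA)

  config <- list(seed = seed, n_eyes = n_eyes,
                 disc = list(center_row = disc$center_row,
                             center_col = disc$center_col,
                             diameter = disc$diameter),
                 cohort = list(n_impaired = cohort_spec$n_impaired,
                               n_healthy = cohort_spec$n_healthy),
                 forest = list(seeds = forest_seeds, n_trees = n_trees))
  manifest <- list(
    config = config,
    config_fnv1a = fnv1a_hash(jsonlite::toJSON(config, auto_unbox = TRUE)),
    package_version = as.character(utils::packageVersion("retmorph")),
    outputs = lapply(sort(list.files(out_dir, pattern = "\\.(csv|json)$")),
                     function(f) {
                       p <- file.path(out_dir, f)
                       list(file = f,
                            fnv1a = fnv1a_hash(readBin(p, "raw",
                                                       file.info(p)$size)))
                     }))
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(
    morphometry = morpho, cohort = cohort, group_comparisons = groups,
    correlations = cors, roc_fd = roc_fd, roc_gvw = roc_gvw,
    comparison = comparison, out_dir = out_dir,
    files = list.files(out_dir, recursive = TRUE, full.names = TRUE)))
}
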