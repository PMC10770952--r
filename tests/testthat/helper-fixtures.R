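# shared fixtures, generated in code (no files)

# horizontal constant-width ribbon of one vessel class in an empty image
make_ribbon_mask <- function(width, length = 200, class_code = 1L,
                             image = c(64, length + 20), row = NULL) {
  g <- matrix(0L, image[1], image[2])
  if (is.null(row)) row <- image[1] %/% 2
  rows <- (row - (width - 1) %/% 2):(row + width %/% 2) # exactly `width` rows
  g[rows, 10:(10 + length - 1)] <- class_code
  labeled_vessel_mask(g)
}

# one small labelled tree, generated once and reused across test files
.fixture_env <- new.env(parent = emptyenv())
cached_tree <- function() {
  if (is.null(.fixture_env$tree)) {
    .fixture_env$tree <- generate_vessel_tree(
      vessel_tree_spec(n_root_pairs = 2, branching_depth = 3, seed = 17,
                       image_size = 640, segment_length_range = c(25, 50),
                       root_width_artery = 12, root_width_vein = 15),
      optic_disc(320, 320, 90))
  }
  .fixture_env$tree
}

# toy cohort where feature A alone determines the label, B..E pure noise
signal_dataset <- function(n = 400, seed = 99) {
  withr::with_seed(seed, {
    d <- tibble::tibble(A = rnorm(n), B = rnorm(n), C = rnorm(n),
                        D = rnorm(n), E = rnorm(n))
    d$ci_label <- d$A > 0
    d
  })
}
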