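test_that("an empty spec yields an all-background mask and no segments", {
  tree <- generate_vessel_tree(vessel_tree_spec(n_root_pairs = 0, seed = 1),
                               optic_disc(512, 420, 150))
  expect_true(all(tree$mask$grid == 0L))
  expect_equal(nrow(tree$segments), 0)
})

test_that("symmetric bifurcation splits an 8 px root into 8/2^(1/3) children", {
  tree <- generate_vessel_tree(
    vessel_tree_spec(n_root_pairs = 1, root_width_artery = 8,
                     root_width_vein = 8, branching_depth = 1,
                     murray_exponent = 3, branch_asymmetry = c(0.5, 0.5),
                     image_size = 512, segment_length_range = c(30, 50),
                     seed = 4),
    optic_disc(256, 256, 80))
  kids <- dplyr::filter(tree$segments, vessel_class == "artery", level == 1)
  expect_equal(nrow(kids), 2)
  expect_equal(kids$true_width, rep(8 / 2^(1 / 3), 2), tolerance = 1e-12)
})

test_that("tree generation is deterministic for a fixed spec and seed", {
  spec <- vessel_tree_spec(n_root_pairs = 2, branching_depth = 2, seed = 11,
                           image_size = 512, segment_length_range = c(25, 45))
  disc <- optic_disc(256, 256, 80)
  t1 <- generate_vessel_tree(spec, disc)
  t2 <- generate_vessel_tree(spec, disc)
  expect_identical(t1$mask$grid, t2$mask$grid)
  expect_equal(t1$segments$true_width, t2$segments$true_width)
})

test_that("every recorded bifurcation satisfies Murray's law to 1e-9", {
  tree <- cached_tree()
  b <- tree$bifurcations
  expect_gt(nrow(b), 0)
  m <- 3
  rel <- abs(b$parent_width^m - b$child1_width^m - b$child2_width^m) /
    b$parent_width^m
  expect_true(all(rel < 1e-9))
})

test_that("mask labels are exclusive and dimensions are consistent", {
  tree <- cached_tree()
  expect_true(all(tree$mask$grid %in% 0:2))
  expect_equal(dim(tree$mask$grid), c(tree$mask$height, tree$mask$width))
})

test_that("in_zone_b flags agree with an independent annulus re-check", {
  tree <- cached_tree()
  zone <- zone_b(optic_disc(320, 320, 90))
  d <- sqrt((tree$segments$mid_row - zone$center_row)^2 +
              (tree$segments$mid_col - zone$center_col)^2)
  expect_equal(tree$segments$in_zone_b,
               d >= zone$inner_radius & d <= zone$outer_radius)
})

test_that("a tree too deep for the image fails loudly, not by truncation", {
  expect_error(
    generate_vessel_tree(
      vessel_tree_spec(branching_depth = 10, image_size = 256,
                       segment_length_range = c(60, 120), seed = 1),
      optic_disc(128, 128, 60)),
    "cannot fit")
})

test_that("fractal fixtures carry their analytic dimensions", {
  expect_equal(attr(generate_fractal_fixture("line", 1, 64), "analytic_fd"), 1)
  expect_equal(attr(generate_fractal_fixture("filled_square", 1, 64),
                    "analytic_fd"), 2)
  expect_equal(attr(generate_fractal_fixture("sierpinski", 4, 16),
                    "analytic_fd"), log(3) / log(2))
  expect_equal(attr(generate_fractal_fixture("koch", 3, 128), "analytic_fd"),
               log(4) / log(3))
  expect_error(generate_fractal_fixture("sierpinski", 6, 32), "2\\^depth")
})

test_that("sierpinski fixture matches the brute-force recursive construction", {
  depth <- 6
  fx <- generate_fractal_fixture("sierpinski", depth, 2^depth)
  brute <- sierpinski_brute(depth)
  expect_equal(sum(fx), sum(brute))
  expect_equal(sum(fx), 3^depth)
  # replicated fixture scales the count by the square of the cell size
  fx729 <- generate_fractal_fixture("sierpinski", depth, 729)
  expect_equal(sum(fx729), 3^depth * (729 %/% 2^depth)^2)
})

test_that("masks round-trip through paletted PNG with their sidecar", {
  tree <- cached_tree()
  path <- file.path(withr::local_tempdir(), "eye.png")
  write_mask_png(tree$mask, path, segments = tree$segments)
  back <- read_mask_png(path)
  expect_identical(back$grid, tree$mask$grid)
  expect_equal(back$disc$diameter, 90)
  expect_equal(back$pixel_scale, 1)
  expect_error(read_mask_png(file.path(dirname(path), "absent.png")),
               "does not exist")
})
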