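test_that("thinning is idempotent on 1-px curves and empties empty masks", {
  line <- matrix(0L, 9, 20)
  line[5, 2:18] <- 1L
  expect_identical(skeletonize(line)$grid, line)
  expect_equal(sum(skeletonize(matrix(0L, 8, 8))$grid), 0)
})

test_that("a filled rectangle thins to its midline", {
  g <- matrix(0L, 9, 25)
  g[3:7, 3:23] <- 1L # 21 x 5 rectangle centred on row 5
  sk <- skeletonize(g)$grid
  idx <- which(sk == 1L, arr.ind = TRUE)
  interior <- idx[idx[, 2] >= 6 & idx[, 2] <= 20, , drop = FALSE]
  expect_true(all(interior[, 1] == 5))
  expect_true(nrow(idx) >= 15 && nrow(idx) <= 21)
})

test_that("skeletons are subsets of their class and strictly 1 px thin", {
  tree <- cached_tree()
  for (cls in c("artery", "vein")) {
    fg <- (tree$mask$grid == ifelse(cls == "artery", 1L, 2L))
    sk <- skeletonize(tree$mask, cls)$grid
    expect_true(all(fg[sk == 1L]))
    two_by_two <- sk[-1, -1] & sk[-nrow(sk), -1] &
      sk[-1, -ncol(sk)] & sk[-nrow(sk), -ncol(sk)]
    expect_equal(sum(two_by_two), 0)
  }
})

test_that("skeleton length weights diagonal steps by sqrt(2)", {
  h <- matrix(0L, 5, 15); h[3, 3:13] <- 1L      # 11 px horizontal run
  expect_equal(skeleton_length(h), 10)
  d <- matrix(0L, 15, 15); diag(d)[3:13] <- 1L  # 11 px diagonal
  expect_equal(skeleton_length(d), 10 * sqrt(2))
  expect_equal(skeleton_length(matrix(0L, 5, 5)), 0)
  iso <- matrix(0L, 5, 5); iso[3, 3] <- 1L
  expect_equal(skeleton_length(iso), 1)
})

test_that("global width recovers the true calibre of ideal ribbons", {
  # thinning retracts ~w/2 from each capped end, so the ribbon must be
  # long relative to its width for area/length to read the true calibre
  for (w in c(3, 5, 9, 15)) {
    m <- make_ribbon_mask(w, length = 600, image = c(64, 620))
    expect_equal(global_width(m, "artery"), w, tolerance = 0.5 / w)
  }
  expect_error(global_width(make_ribbon_mask(5), "vein"),
               class = "retmorph_empty_class")
})

test_that("global width doubles when the mask is scaled 2x", {
  m1 <- make_ribbon_mask(5, length = 150)
  m2 <- make_ribbon_mask(10, length = 300, image = c(128, 330))
  gw1 <- global_width(m1, "artery")
  gw2 <- global_width(m2, "artery")
  expect_equal(gw2 / gw1, 2, tolerance = 0.05)
})

test_that("global width is invariant to translation and 90-degree rotation", {
  g <- make_ribbon_mask(7, length = 150)$grid
  base <- global_width(labeled_vessel_mask(g), "artery")
  shifted <- matrix(0L, nrow(g), ncol(g))
  shifted[11:nrow(g), ] <- g[1:(nrow(g) - 10), ]
  rotated <- t(g[nrow(g):1, ])
  expect_equal(global_width(labeled_vessel_mask(shifted), "artery"), base)
  expect_equal(global_width(labeled_vessel_mask(rotated), "artery"), base)
})

test_that("zone B spans 0.5 to 1.0 disc diameters from the disc margin", {
  z <- zone_b(optic_disc(400, 300, 150))
  expect_equal(z$inner_radius, 150)
  expect_equal(z$outer_radius, 225)
  z2 <- zone_b(optic_disc(10, 10, 2))
  expect_equal(c(z2$inner_radius, z2$outer_radius), c(2, 3))
})

test_that("annulus pixel membership matches the analytic area within 1%", {
  disc <- optic_disc(512, 512, 150)
  z <- zone_b(disc)
  rr <- matrix(seq_len(1024), 1024, 1024)
  cc <- t(rr)
  n_inside <- sum(in_annulus(z, rr, cc))
  analytic <- pi * (z$outer_radius^2 - z$inner_radius^2)
  expect_equal(n_inside, analytic, tolerance = 0.01)
})

test_that("a straight vessel crossing the zone is measured at its true width", {
  # ribbon of width 7 through an annulus around the image centre
  m <- make_ribbon_mask(7, length = 492, image = c(512, 512), row = 256)
  disc <- optic_disc(256, 256, 80)
  segs <- measure_segments(m, "artery", zone_b(disc))
  expect_gt(nrow(segs), 0)
  expect_true(all(abs(segs$mean_width - 7) <= 0.5))
})

test_that("a vessel entirely outside the annulus yields no segments", {
  m <- make_ribbon_mask(5, length = 100, image = c(512, 512), row = 20)
  segs <- measure_segments(m, "artery", zone_b(optic_disc(400, 256, 60)))
  expect_equal(nrow(segs), 0)
})

test_that("zone-B widths of a synthetic tree track ground truth within 10%", {
  tree <- cached_tree()
  zone <- zone_b(optic_disc(320, 320, 90))
  gt <- dplyr::filter(tree$segments, in_zone_b)
  point_seg_dist <- function(p, a, b) {
    v <- b - a; t <- sum((p - a) * v) / sum(v^2)
    t <- min(1, max(0, t))
    sqrt(sum((p - a - t * v)^2))
  }
  n_checked <- 0
  for (cls in c("artery", "vein")) {
    meas <- measure_segments(tree$mask, cls, zone)
    gtc <- dplyr::filter(gt, vessel_class == cls)
    expect_gt(nrow(meas), 0)
    for (i in seq_len(nrow(meas))) {
      # match by the path's middle pixel; skeleton stretches that run far
      # from every true centreline are crossing artefacts, not vessels
      midpx <- meas$centerline[[i]][ceiling(meas$n_points[i] / 2), ]
      d <- vapply(gtc$centerline, function(cl)
        point_seg_dist(midpx, cl[1, ], cl[2, ]), numeric(1))
      if (min(d) > 2) next
      truth <- gtc$true_width[which.min(d)]
      expect_lt(abs(meas$mean_width[i] - truth) / truth, 0.10)
      n_checked <- n_checked + 1
    }
  }
  expect_gte(n_checked, 8)
})

test_that("measured segments come back in a deterministic order", {
  tree <- cached_tree()
  zone <- zone_b(optic_disc(320, 320, 90))
  s1 <- measure_segments(tree$mask, "vein", zone)
  s2 <- measure_segments(tree$mask, "vein", zone)
  expect_identical(s1, s2)
  expect_true(all(diff(s1$mean_width) <= 1e-12))
})
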