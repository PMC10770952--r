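#' Optic disc geometry
#'
#' Location and size of the optic disc in a fundus-style image, in pixel
#' units. The disc diameter is the unit in which the measurement annulus
#' around the disc (zone B) is defined.
#'
#' @param center_row,center_col Disc centre, in pixels (row, col), 1-based.
#' @param diameter Disc diameter in pixels; must be positive.
#' @return An object of class `optic_disc`.
#' @examples
#' optic_disc(512, 420, 150)
#' @export
optic_disc <- function(center_row, center_col, diameter) {
  assert_that(is.numeric(diameter) && length(diameter) == 1 && diameter > 0,
              "disc diameter must be a positive number")
  assert_that(center_row > 0 && center_col > 0,
              "disc centre must have positive coordinates")
  structure(
    list(center_row = as.numeric(center_row),
         center_col = as.numeric(center_col),
         diameter = as.numeric(diameter)),
    class = "optic_disc"
  )
}

#' Specification of a synthetic labelled vessel tree
#'
#' Parameters for the synthetic vascular-mask generator. Artery/vein root
#' pairs sprout from the optic-disc margin and bifurcate outward; at every
#' bifurcation the child widths obey Murray's law,
#' `parent^m = child1^m + child2^m`, with exponent `m = murray_exponent`.
#' Widths are constant within a segment, so every drawn vessel has a known
#' piecewise-constant ground-truth width.
#'
#' @param n_root_pairs Number of artery/vein root pairs (the retina has
#'   four major arcades; default 4).
#' @param root_width_artery,root_width_vein Root calibres in pixels
#'   (veins are wider than arteries in fundus images; defaults 14 and 18).
#' @param branching_depth Number of bifurcation levels below the root.
#' @param branch_angle_spread Total opening angle between sibling branches,
#'   in degrees.
#' @param murray_exponent Exponent of the branching power law (default 3,
#'   Murray's classical value).
#' @param segment_length_range Two-element range of segment lengths, pixels.
#' @param image_size Side of the square output image, pixels.
#' @param branch_asymmetry Two-element range for the fraction of
#'   `parent^m` assigned to the first child; `c(0.5, 0.5)` gives perfectly
#'   symmetric bifurcations.
#' @param seed Integer seed; the generator is deterministic given the spec.
#' @return An object of class `vessel_tree_spec`.
#' @export
vessel_tree_spec <- function(n_root_pairs = 4,
                             root_width_artery = 14,
                             root_width_vein = 18,
                             branching_depth = 4,
                             branch_angle_spread = 60,
                             murray_exponent = 3,
                             segment_length_range = c(30, 60),
                             image_size = 1024,
                             branch_asymmetry = c(0.40, 0.60),
                             seed = 1L) {
  assert_that(n_root_pairs >= 0, "n_root_pairs must be >= 0")
  assert_that(root_width_artery >= 1 && root_width_vein >= 1,
              "root widths must be >= 1 pixel")
  assert_that(branching_depth >= 0, "branching_depth must be >= 0")
  assert_that(murray_exponent > 0, "murray_exponent must be > 0")
  assert_that(length(segment_length_range) == 2 &&
                all(segment_length_range > 0) &&
                diff(segment_length_range) >= 0,
              "segment_length_range must be an increasing positive pair")
  assert_that(all(branch_asymmetry >= 0.05 & branch_asymmetry <= 0.95) &&
                diff(branch_asymmetry) >= 0,
              "branch_asymmetry must be an increasing pair in [0.05, 0.95]")
  structure(
    list(n_root_pairs = as.integer(n_root_pairs),
         root_width_artery = root_width_artery,
         root_width_vein = root_width_vein,
         branching_depth = as.integer(branching_depth),
         branch_angle_spread = branch_angle_spread,
         murray_exponent = murray_exponent,
         segment_length_range = segment_length_range,
         image_size = as.integer(image_size),
         branch_asymmetry = branch_asymmetry,
         seed = as.integer(seed)),
    class = "vessel_tree_spec"
  )
}

#' Labelled vessel mask
#'
#' A raster classifying every pixel as background (0), artery (1) or
#' vein (2) — the image-side input of the morphometry pipeline, standing in
#' for an artery/vein-labelled segmentation of a fundus photograph.
#'
#' @param grid Integer matrix with values in \{0, 1, 2\}.
#' @param pixel_scale Measurement units per pixel (default 1: calibres are
#'   reported in pixels).
#' @param disc Optional [optic_disc()] geometry attached to the mask.
#' @return An object of class `labeled_vessel_mask`.
#' @export
labeled_vessel_mask <- function(grid, pixel_scale = 1, disc = NULL) {
  assert_that(is.matrix(grid), "grid must be a matrix")
  g <- matrix(as.integer(grid), nrow(grid), ncol(grid))
  assert_that(all(g %in% 0:2), "grid labels must be 0 (background), 1 (artery) or 2 (vein)")
  assert_that(pixel_scale > 0, "pixel_scale must be positive")
  structure(
    list(grid = g, height = nrow(g), width = ncol(g),
         pixel_scale = pixel_scale, disc = disc),
    class = "labeled_vessel_mask"
  )
}

#' @export
print.labeled_vessel_mask <- function(x, ...) {
  cat(sprintf("<labeled_vessel_mask %d x %d, %d artery px, %d vein px, pixel_scale = %g>\n",
              x$height, x$width, sum(x$grid == 1L), sum(x$grid == 2L),
              x$pixel_scale))
  invisible(x)
}

# distance from pixel centres to the segment p1->p2, vectorised
.dist_to_segment <- function(r, c, r1, c1, r2, c2) {
  vr <- r2 - r1; vc <- c2 - c1
  len2 <- vr * vr + vc * vc
  if (len2 == 0) return(sqrt((r - r1)^2 + (c - c1)^2))
  t <- pmin(1, pmax(0, ((r - r1) * vr + (c - c1) * vc) / len2))
  sqrt((r - r1 - t * vr)^2 + (c - c1 - t * vc)^2)
}

# stamp one constant-width segment into an integer label matrix;
# binary rule: a pixel is foreground iff its centre is within width/2 of
# the centreline (no anti-aliasing), so widths are analytically checkable
.stamp_segment <- function(grid, r1, c1, r2, c2, width, code) {
  h <- nrow(grid); w <- ncol(grid)
  half <- width / 2
  rr <- max(1L, floor(min(r1, r2) - half)):min(h, ceiling(max(r1, r2) + half))
  cc <- max(1L, floor(min(c1, c2) - half)):min(w, ceiling(max(c1, c2) + half))
  R <- matrix(rr, length(rr), length(cc))
  C <- matrix(cc, length(rr), length(cc), byrow = TRUE)
  d <- .dist_to_segment(as.numeric(R), as.numeric(C), r1, c1, r2, c2)
  hit <- d <= half
  grid[cbind(as.integer(R)[hit], as.integer(C)[hit])] <- code
  grid
}

#' Generate a labelled synthetic vascular tree
#'
#' Rasterizes interleaved artery and vein trees growing outward from the
#' optic-disc margin, and returns both the labelled mask and a ground-truth
#' table of every drawn segment. Child calibres at each bifurcation satisfy
#' Murray's law exactly (to machine precision) with the spec's exponent;
#' branches whose calibre would fall below one pixel stop growing. Veins are
#' drawn after arteries, so at artery/vein crossings the vein label wins
#' (one label per pixel), while the ground truth records both vessels.
#'
#' @param spec A [vessel_tree_spec()].
#' @param disc An [optic_disc()]; the disc must lie inside the image and
#'   leave room for the deepest possible tree, otherwise an error is raised
#'   rather than silently truncating branches.
#' @return A list with elements:
#'   \describe{
#'     \item{mask}{a [labeled_vessel_mask()] (disc geometry attached);}
#'     \item{segments}{tibble of ground truth: `segment_id`, `vessel_class`,
#'       `true_width` (px), `level`, `length`, `mid_row`, `mid_col`,
#'       `in_zone_b`, and a `centerline` list-column of n x 2 point
#'       matrices;}
#'     \item{bifurcations}{tibble of `parent_width`, `child1_width`,
#'       `child2_width` for every bifurcation (for Murray-law checks).}
#'   }
#' @examples
#' tree <- generate_vessel_tree(
#'   vessel_tree_spec(n_root_pairs = 2, branching_depth = 2, seed = 7,
#'                    image_size = 512, segment_length_range = c(25, 45)),
#'   optic_disc(256, 256, 80))
#' tree$mask
#' @export
generate_vessel_tree <- function(spec, disc) {
  assert_that(inherits(spec, "vessel_tree_spec"), "spec must be a vessel_tree_spec")
  assert_that(inherits(disc, "optic_disc"), "disc must be an optic_disc")
  sz <- spec$image_size
  rad <- disc$diameter / 2
  assert_that(disc$center_row - rad >= 1 && disc$center_col - rad >= 1 &&
                disc$center_row + rad <= sz && disc$center_col + rad <= sz,
              "optic disc must lie fully inside the image")
  # worst-case radial extent of a tree: root at the margin plus one segment
  # per level, all at the maximum length and radially aligned
  extent <- rad + (spec$branching_depth + 1) * max(spec$segment_length_range)
  margin <- min(disc$center_row - 1, disc$center_col - 1,
                sz - disc$center_row, sz - disc$center_col)
  assert_that(extent <= margin,
              sprintf(paste0("a tree of depth %d with segments up to %g px ",
                             "cannot fit in a %d px image at this disc ",
                             "position (needs %g px of clearance, has %g)"),
                      spec$branching_depth, max(spec$segment_length_range),
                      sz, extent, margin))

  withr::with_seed(spec$seed, {
    segs <- list(); bifs <- list()
    grow <- function(class, r, c, angle, width, depth_left, level) {
      len <- runif(1, spec$segment_length_range[1], spec$segment_length_range[2])
      r2 <- r + len * sin(angle); c2 <- c + len * cos(angle)
      segs[[length(segs) + 1]] <<- list(
        vessel_class = class, true_width = width, level = level,
        length = len, centerline = rbind(c(r, c), c(r2, c2)))
      if (depth_left > 0) {
        a <- runif(1, spec$branch_asymmetry[1], spec$branch_asymmetry[2])
        m <- spec$murray_exponent
        w1 <- width * a^(1 / m)
        w2 <- width * (1 - a)^(1 / m)
        bifs[[length(bifs) + 1]] <<- list(parent_width = width,
                                          child1_width = w1, child2_width = w2)
        half <- spec$branch_angle_spread / 2 * pi / 180
        jit <- runif(2, 0.6, 1.2)
        if (w1 >= 1) grow(class, r2, c2, angle - half * jit[1], w1, depth_left - 1, level + 1)
        if (w2 >= 1) grow(class, r2, c2, angle + half * jit[2], w2, depth_left - 1, level + 1)
      }
    }
    n <- spec$n_root_pairs
    if (n > 0) {
      base <- seq(0, 2 * pi, length.out = n + 1)[seq_len(n)] + runif(1, 0, 2 * pi)
      for (k in seq_len(n)) {
        for (cls in vessel_classes) {
          ang <- base[k] + (if (cls == "artery") 0 else pi / n) + runif(1, -0.15, 0.15)
          w0 <- if (cls == "artery") spec$root_width_artery else spec$root_width_vein
          grow(cls, disc$center_row + rad * sin(ang),
               disc$center_col + rad * cos(ang), ang, w0,
               spec$branching_depth, 0L)
        }
      }
    }
  })

  grid <- matrix(0L, sz, sz)
  if (length(segs)) {
    ord <- order(vapply(segs, function(s) s$vessel_class, "") == "vein") # arteries first
    for (s in segs[ord]) {
      p <- s$centerline
      grid <- .stamp_segment(grid, p[1, 1], p[1, 2], p[2, 1], p[2, 2],
                             s$true_width, if (s$vessel_class == "artery") 1L else 2L)
    }
  }
  zone <- zone_b(disc)
  seg_tbl <- purrr::map_dfr(seq_along(segs), function(i) {
    s <- segs[[i]]
    mid <- colMeans(s$centerline)
    tibble(segment_id = i, vessel_class = s$vessel_class,
           true_width = s$true_width, level = s$level, length = s$length,
           mid_row = mid[1], mid_col = mid[2],
           in_zone_b = in_annulus(zone, mid[1], mid[2]),
           centerline = list(s$centerline))
  })
  if (nrow(seg_tbl) == 0) {
    seg_tbl <- tibble(segment_id = integer(), vessel_class = character(),
                      true_width = numeric(), level = integer(),
                      length = numeric(), mid_row = numeric(),
                      mid_col = numeric(), in_zone_b = logical(),
                      centerline = list())
  }
  bif_tbl <- if (length(bifs)) purrr::map_dfr(bifs, as_tibble) else
    tibble(parent_width = numeric(), child1_width = numeric(),
           child2_width = numeric())
  list(mask = labeled_vessel_mask(grid, disc = disc),
       segments = seg_tbl, bifurcations = bif_tbl)
}

#' Analytic fractal fixtures
#'
#' Standard constructions with known box-counting dimension, used to
#' calibrate the fractal-dimension estimator: a one-pixel straight line
#' (dimension 1), a filled square (dimension 2), the Sierpinski gasket
#' (log 3 / log 2), and the Koch curve (log 4 / log 3).
#'
#' @param kind One of `"line"`, `"filled_square"`, `"sierpinski"`, `"koch"`.
#' @param depth Recursion depth of the self-similar construction.
#' @param size Image side in pixels; for `"sierpinski"` it must be at least
#'   `2^depth` (the base grid is replicated by an integer factor to fill
#'   `size`).
#' @return A binary `size` x `size` matrix with attribute `analytic_fd`
#'   holding the construction's similarity dimension.
#' @examples
#' f <- generate_fractal_fixture("sierpinski", depth = 5, size = 256)
#' attr(f, "analytic_fd")
#' @export
generate_fractal_fixture <- function(kind = c("line", "filled_square",
                                              "sierpinski", "koch"),
                                     depth = 5, size = 512) {
  kind <- match.arg(kind)
  assert_that(size >= 2, "size must be >= 2")
  m <- switch(kind,
    line = {
      g <- matrix(0L, size, size)
      g[size %/% 2, ] <- 1L
      g
    },
    filled_square = matrix(1L, size, size),
    sierpinski = {
      n <- 2^depth
      assert_that(size >= n, "size must be >= 2^depth for the sierpinski fixture")
      base <- outer(0:(n - 1), 0:(n - 1),
                    function(i, j) as.integer(bitwAnd(i, j) == 0L))
      k <- size %/% n
      g <- matrix(0L, size, size)
      g[seq_len(n * k), seq_len(n * k)] <- kronecker(base, matrix(1L, k, k))
      g
    },
    koch = {
      pts <- .koch_points(depth)
      g <- matrix(0L, size, size)
      # unit segment spans the image width; height of the curve is sqrt(3)/6
      col <- 1 + pts[, 1] * (size - 1)
      row <- size - 2 - pts[, 2] * (size - 1)
      for (i in seq_len(nrow(pts) - 1)) {
        g <- .draw_line_px(g, row[i], col[i], row[i + 1], col[i + 1])
      }
      g
    })
  fd <- switch(kind, line = 1, filled_square = 2,
               sierpinski = log(3) / log(2), koch = log(4) / log(3))
  structure(m, analytic_fd = fd, kind = kind)
}

# vertices of the Koch curve over the unit interval after `depth` iterations
.koch_points <- function(depth) {
  pts <- rbind(c(0, 0), c(1, 0))
  rot60 <- pi / 3
  for (d in seq_len(depth)) {
    out <- matrix(0, nrow = 4 * (nrow(pts) - 1) + 1, ncol = 2)
    k <- 1
    for (i in seq_len(nrow(pts) - 1)) {
      p <- pts[i, ]; q <- pts[i + 1, ]
      v <- (q - p) / 3
      a <- p + v
      b <- p + 2 * v
      tip <- a + c(v[1] * cos(rot60) - v[2] * sin(rot60),
                   v[1] * sin(rot60) + v[2] * cos(rot60))
      out[k, ] <- p; out[k + 1, ] <- a; out[k + 2, ] <- tip; out[k + 3, ] <- b
      k <- k + 4
    }
    out[k, ] <- pts[nrow(pts), ]
    pts <- out
  }
  pts
}

# Bresenham-style rasterization of a 1-px line between real endpoints
.draw_line_px <- function(g, r1, c1, r2, c2) {
  n <- max(2L, ceiling(max(abs(r2 - r1), abs(c2 - c1))) + 1L)
  rr <- round(seq(r1, r2, length.out = n))
  cc <- round(seq(c1, c2, length.out = n))
  keep <- rr >= 1 & rr <= nrow(g) & cc >= 1 & cc <= ncol(g)
  g[cbind(rr[keep], cc[keep])] <- 1L
  g
}

#' Write / read a labelled vessel mask as paletted PNG with a JSON sidecar
#'
#' The PNG stores the raw label codes (0 background, 1 artery, 2 vein) in
#' its 8-bit grey channel; the sidecar (`<path>.json`) stores the optic-disc
#' geometry, the pixel scale, and (optionally) the ground-truth segment
#' list of a synthetic tree.
#'
#' @param mask A [labeled_vessel_mask()].
#' @param path Output PNG path; the sidecar is written next to it.
#' @param segments Optional ground-truth segment tibble from
#'   [generate_vessel_tree()] to embed in the sidecar.
#' @return `path`, invisibly (`write_mask_png`); a [labeled_vessel_mask()]
#'   with a `segments` attribute when the sidecar holds ground truth
#'   (`read_mask_png`).
#' @export
write_mask_png <- function(mask, path, segments = NULL) {
  assert_that(inherits(mask, "labeled_vessel_mask"), "mask must be a labeled_vessel_mask")
  png::writePNG(mask$grid / 255, target = path)
  side <- list(pixel_scale = mask$pixel_scale)
  if (!is.null(mask$disc)) {
    side$disc <- list(center_row = mask$disc$center_row,
                      center_col = mask$disc$center_col,
                      diameter = mask$disc$diameter)
  }
  if (!is.null(segments) && nrow(segments)) {
    side$segments <- lapply(seq_len(nrow(segments)), function(i) {
      list(segment_id = segments$segment_id[i],
           vessel_class = segments$vessel_class[i],
           true_width = segments$true_width[i],
           in_zone_b = segments$in_zone_b[i],
           centerline = unname(segments$centerline[[i]]))
    })
  }
  jsonlite::write_json(side, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mask_png
#' @param path Path of a PNG written by [write_mask_png()].
#' @export
read_mask_png <- function(path) {
  assert_that(file.exists(path), sprintf("mask file '%s' does not exist", path))
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  grid <- matrix(as.integer(round(img * 255)), nrow(img), ncol(img))
  sidecar <- paste0(path, ".json")
  assert_that(file.exists(sidecar),
              sprintf("missing JSON sidecar '%s'", sidecar))
  side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  disc <- if (!is.null(side$disc)) {
    optic_disc(side$disc$center_row, side$disc$center_col, side$disc$diameter)
  }
  m <- labeled_vessel_mask(grid, pixel_scale = side$pixel_scale %||% 1,
                           disc = disc)
  if (!is.null(side$segments)) attr(m, "segments") <- side$segments
  m
}
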