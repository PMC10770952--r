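#' Zone-B measurement annulus around the optic disc
#'
#' The standard caliber-measurement region: an annulus extending from 0.5
#' to 1.0 disc diameters away from the disc *margin*, i.e. inner radius
#' `diameter/2 + 0.5 * diameter` and outer radius `diameter/2 + diameter`
#' from the disc centre. The margin convention is the established one
#' behind CRAE/CRVE protocols; [in_annulus()] is the membership predicate.
#'
#' @param disc An [optic_disc()].
#' @param inner_dd,outer_dd Annulus bounds in disc-diameter units measured
#'   from the disc margin (defaults 0.5 and 1.0).
#' @return An object of class `zone_annulus` with fields `center_row`,
#'   `center_col`, `inner_radius`, `outer_radius` (pixels).
#' @examples
#' zone_b(optic_disc(400, 300, 150)) # inner 150, outer 225
#' @export
zone_b <- function(disc, inner_dd = 0.5, outer_dd = 1.0) {
  assert_that(inherits(disc, "optic_disc"), "disc must be an optic_disc")
  assert_that(inner_dd >= 0 && outer_dd > inner_dd,
              "annulus bounds must satisfy 0 <= inner < outer")
  structure(
    list(center_row = disc$center_row, center_col = disc$center_col,
         inner_radius = disc$diameter / 2 + inner_dd * disc$diameter,
         outer_radius = disc$diameter / 2 + outer_dd * disc$diameter),
    class = "zone_annulus"
  )
}

#' @rdname zone_b
#' @param zone A `zone_annulus`.
#' @param row,col Point coordinates (vectorised).
#' @export
in_annulus <- function(zone, row, col) {
  d <- sqrt((row - zone$center_row)^2 + (col - zone$center_col)^2)
  d >= zone$inner_radius & d <= zone$outer_radius
}

#' Skeletonize one vessel class of a labelled mask
#'
#' Topology-preserving morphological thinning (Zhang-Suen, 8-connected) of
#' the selected class's foreground down to a one-pixel-wide medial curve.
#' An empty foreground yields an empty skeleton.
#'
#' @param mask A [labeled_vessel_mask()], or a plain binary matrix.
#' @param vessel_class `"artery"` or `"vein"` (ignored for a binary matrix).
#' @return An object of class `skeleton_mask`: a list with the binary
#'   `grid` and the `source_class`.
#' @export
skeletonize <- function(mask, vessel_class = c("artery", "vein")) {
  if (inherits(mask, "labeled_vessel_mask")) {
    vessel_class <- match.arg(vessel_class)
    fg <- class_foreground(mask, vessel_class)
  } else {
    assert_that(is.matrix(mask), "mask must be a labeled_vessel_mask or a matrix")
    vessel_class <- if (identical(vessel_class, c("artery", "vein"))) NA_character_ else vessel_class
    fg <- (mask != 0) * 1L
  }
  structure(list(grid = .cpp_thin(fg), source_class = vessel_class),
            class = "skeleton_mask")
}

#' @export
print.skeleton_mask <- function(x, ...) {
  cat(sprintf("<skeleton_mask %d x %d, %d px, class %s>\n",
              nrow(x$grid), ncol(x$grid), sum(x$grid), x$source_class))
  invisible(x)
}

#' Geodesic length of a skeleton
#'
#' Sums the 8-connected adjacencies of skeleton pixels, counting each
#' undirected edge once: 1 for an orthogonal step, `sqrt(2)` for a diagonal
#' step. An isolated pixel contributes 1 (one pixel's worth of curve).
#' Raw pixel counting underestimates oblique curves by up to 29%; the
#' diagonal weighting removes that bias.
#'
#' @param skel A `skeleton_mask` from [skeletonize()], or a binary matrix.
#' @return Length in pixels (scalar).
#' @examples
#' m <- matrix(0L, 5, 12); m[3, 1:11] <- 1L
#' skeleton_length(m) # 10
#' @export
skeleton_length <- function(skel) {
  g <- if (inherits(skel, "skeleton_mask")) skel$grid else (skel != 0) * 1L
  if (sum(g) == 0) return(0)
  h <- nrow(g); w <- ncol(g)
  # each undirected edge counted once: look right, down, down-right, down-left
  right <- sum(g[, -w] & g[, -1])
  down  <- sum(g[-h, ] & g[-1, ])
  dr    <- sum(g[-h, -w] & g[-1, -1])
  dl    <- sum(g[-h, -1] & g[-1, -w])
  # isolated pixels: no neighbour in any of the 8 directions
  nb <- .neighbor_count(g)
  isolated <- sum(g == 1L & nb == 0L)
  right + down + sqrt(2) * (dr + dl) + isolated
}

# maximum over the 3x3 neighbourhood of every pixel
.max3x3 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  p <- matrix(0, h + 2, w + 2)
  p[2:(h + 1), 2:(w + 1)] <- m
  out <- m
  for (dr in -1:1) for (dc in -1:1) {
    out <- pmax(out, p[(2 + dr):(h + 1 + dr), (2 + dc):(w + 1 + dc)])
  }
  out
}

# count of 8-connected foreground neighbours at every pixel
.neighbor_count <- function(g) {
  h <- nrow(g); w <- ncol(g)
  p <- matrix(0L, h + 2, w + 2)
  p[2:(h + 1), 2:(w + 1)] <- g
  nb <- matrix(0L, h, w)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- nb + p[(2 + dr):(h + 1 + dr), (2 + dc):(w + 1 + dc)]
  }
  nb
}

#' Global vessel width: class area divided by skeleton length
#'
#' The whole-image average calibre of one vessel class: total foreground
#' pixel count of that class divided by the geodesic length of its
#' morphological skeleton, scaled by the mask's `pixel_scale`.
#'
#' @param mask A [labeled_vessel_mask()].
#' @param vessel_class `"artery"` or `"vein"`.
#' @return Width in measurement units (pixels when `pixel_scale = 1`).
#' @export
global_width <- function(mask, vessel_class = c("artery", "vein")) {
  assert_that(inherits(mask, "labeled_vessel_mask"), "mask must be a labeled_vessel_mask")
  vessel_class <- match.arg(vessel_class)
  fg <- class_foreground(mask, vessel_class)
  area <- sum(fg)
  if (area == 0) {
    abort(sprintf("global width is undefined: the mask has no %s pixels",
                  vessel_class),
          class = "retmorph_empty_class")
  }
  len <- skeleton_length(skeletonize(mask, vessel_class))
  mask$pixel_scale * area / len
}

#' Measure vessel segments in an annular zone
#'
#' Restricts the class skeleton to the zone, splits it into maximal
#' branch-point-free paths (a branch point is a skeleton pixel with three
#' or more skeleton neighbours), estimates the local calibre at every
#' centreline pixel from the Euclidean distance transform of the class
#' foreground (width = twice the distance to the vessel boundary, read at
#' the transform's ridge around the centreline pixel), and discards paths
#' shorter than `min_path_length` (thinning spurs). Width readings at the
#' path ends that exceed 1.15x the path's median are junction-blob
#' artefacts and are excluded from the width profile.
#'
#' @param mask A [labeled_vessel_mask()].
#' @param vessel_class `"artery"` or `"vein"`.
#' @param zone A `zone_annulus` from [zone_b()]; `NULL` measures the whole
#'   image.
#' @param min_path_length Minimum geodesic path length in pixels
#'   (default 10) below which a path is treated as a spur and dropped.
#' @param .skeleton Optional precomputed skeleton grid of the class (a
#'   performance hook used by [eye_morphometry()] to avoid re-thinning).
#' @return A tibble ordered by descending `mean_width` then centroid
#'   (row, col), with columns `segment_id`, `vessel_class`, `n_points`,
#'   `length`, `mean_width`, `centroid_row`, `centroid_col`, and
#'   list-columns `centerline` (ordered n x 2 point matrix) and
#'   `width_profile`. Widths are in measurement units (`pixel_scale`).
#' @export
measure_segments <- function(mask, vessel_class = c("artery", "vein"),
                             zone = NULL, min_path_length = 10,
                             .skeleton = NULL) {
  assert_that(inherits(mask, "labeled_vessel_mask"), "mask must be a labeled_vessel_mask")
  vessel_class <- match.arg(vessel_class)
  empty <- tibble(segment_id = integer(), vessel_class = character(),
                  n_points = integer(), length = numeric(),
                  mean_width = numeric(), centroid_row = numeric(),
                  centroid_col = numeric(), centerline = list(),
                  width_profile = list())
  fg <- class_foreground(mask, vessel_class)
  if (sum(fg) == 0) return(empty)
  skel <- if (is.null(.skeleton)) skeletonize(mask, vessel_class)$grid else
    .skeleton
  if (!is.null(zone)) {
    assert_that(inherits(zone, "zone_annulus"), "zone must be a zone_annulus")
    idx <- which(skel == 1L, arr.ind = TRUE)
    keep <- in_annulus(zone, idx[, 1], idx[, 2])
    skel[idx[!keep, , drop = FALSE]] <- 0L
  }
  if (sum(skel) == 0) return(empty)

  # width map: 2 * (distance to nearest background pixel - 1/2); the half
  # pixel converts centre-to-centre distance into distance to the boundary,
  # so an ideal ribbon of width w reads exactly w on its midline. The
  # thinned centreline can sit one pixel off the true medial ridge on
  # oblique vessels, so each skeleton pixel reads the maximum transform
  # value over its 3x3 neighbourhood (ridge correction).
  dt <- EBImage::distmap(fg, metric = "euclidean")
  width_map <- 2 * .max3x3(dt) - 1

  nb <- .neighbor_count(skel)
  branch <- skel == 1L & nb >= 3L
  body <- skel
  body[branch] <- 0L
  lab <- .cpp_label8(body)              # 8-connected components
  ncomp <- max(lab)
  if (ncomp == 0) return(empty)

  paths <- vector("list", ncomp)
  for (k in seq_len(ncomp)) {
    pts <- which(lab == k, arr.ind = TRUE)
    path <- .order_path(pts)
    wp <- mask$pixel_scale * width_map[path]
    # adjacent to a junction the transform reads the parent/junction blob,
    # not the vessel; drop inflated runs at the path ends only
    med <- stats::median(wp)
    keep <- rep(TRUE, length(wp))
    j <- 1
    while (j <= length(wp) && wp[j] > 1.15 * med) { keep[j] <- FALSE; j <- j + 1 }
    j <- length(wp)
    while (j >= 1 && wp[j] > 1.15 * med) { keep[j] <- FALSE; j <- j - 1 }
    if (!any(keep)) keep[] <- TRUE
    wp <- wp[keep]
    len <- if (nrow(path) > 1) {
      steps <- sqrt(rowSums((path[-1, , drop = FALSE] -
                             path[-nrow(path), , drop = FALSE])^2))
      sum(steps)
    } else 1
    paths[[k]] <- list(path = path, wp = wp, len = len)
  }
  keep <- vapply(paths, function(p) p$len >= min_path_length, TRUE)
  paths <- paths[keep]
  if (!length(paths)) return(empty)

  out <- purrr::map_dfr(paths, function(p) {
    tibble(vessel_class = vessel_class,
           n_points = nrow(p$path), length = p$len,
           mean_width = mean(p$wp),
           centroid_row = mean(p$path[, 1]), centroid_col = mean(p$path[, 2]),
           centerline = list(unname(p$path)), width_profile = list(p$wp))
  })
  out <- dplyr::arrange(out, dplyr::desc(.data$mean_width),
                        .data$centroid_row, .data$centroid_col)
  dplyr::mutate(out, segment_id = dplyr::row_number(), .before = 1)
}

# order the pixels of a (near-)simple 8-connected path from one endpoint
# to the other by nearest-neighbour tracing
.order_path <- function(pts) {
  n <- nrow(pts)
  if (n <= 2) return(pts)
  # endpoint = pixel with exactly one 8-neighbour within the component
  d2 <- as.matrix(stats::dist(pts))^2
  adj <- d2 > 0 & d2 <= 2
  deg <- rowSums(adj)
  start <- which(deg <= 1)[1]
  if (is.na(start)) start <- 1L # loop: arbitrary start
  visited <- rep(FALSE, n)
  ord <- integer(n)
  cur <- start
  for (i in seq_len(n)) {
    ord[i] <- cur
    visited[cur] <- TRUE
    nxt <- which(adj[cur, ] & !visited)
    if (!length(nxt)) {
      rem <- which(!visited)
      if (!length(rem)) break
      nxt <- rem[which.min(d2[cur, rem])]
    }
    cur <- nxt[1]
  }
  pts[ord[ord > 0], , drop = FALSE]
}
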