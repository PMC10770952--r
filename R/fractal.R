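#' Count occupied boxes at one lattice scale
#'
#' Partitions the image into an axis-aligned lattice of
#' `box_size` x `box_size` squares anchored at the top-left corner
#' (partial boxes at the right/bottom edges count too) and returns the
#' number of squares containing at least one foreground pixel.
#'
#' @param mask Binary matrix (non-zero = foreground).
#' @param box_size Box side in pixels, at least 1.
#' @return Integer count of occupied boxes.
#' @export
box_count <- function(mask, box_size) {
  assert_that(is.matrix(mask), "mask must be a matrix")
  assert_that(box_size >= 1, "box_size must be >= 1")
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0) return(0L)
  br <- (idx[, 1] - 1L) %/% box_size
  bc <- (idx[, 2] - 1L) %/% box_size
  length(unique(br * (((ncol(mask) - 1L) %/% box_size) + 1L) + bc))
}

#' Box-counting fractal dimension
#'
#' Counts occupied boxes over a ladder of box sizes and estimates the
#' fractal dimension as the ordinary least-squares slope of `log(count)`
#' against `log(1 / size)` — the gradient of the logarithms, signed so
#' that denser, more space-filling patterns give larger FD.
#'
#' @param mask Binary matrix with at least 2 foreground pixels.
#' @param sizes Box-size ladder; default: powers of 2 from 2 up to a
#'   quarter of the smaller image dimension (at least 3 sizes required).
#' @return An object of class `boxcount_curve`: a list with `curve`
#'   (tibble of `box_size`, `count`), `fd`, and `r_squared`.
#' @examples
#' fx <- generate_fractal_fixture("sierpinski", depth = 6, size = 512)
#' compute_fd(fx)$fd # close to log(3)/log(2)
#' @export
compute_fd <- function(mask, sizes = NULL) {
  assert_that(is.matrix(mask), "mask must be a matrix")
  assert_that(sum(mask != 0) >= 2,
              "fractal dimension needs at least 2 foreground pixels")
  if (is.null(sizes)) {
    top <- min(dim(mask)) / 4
    sizes <- 2^(1:floor(log2(top)))
  }
  sizes <- sort(unique(as.integer(sizes)))
  assert_that(length(sizes) >= 3, "at least 3 box sizes are required")
  counts <- vapply(sizes, function(s) box_count(mask, s), integer(1))
  fit <- lm(log(counts) ~ log(1 / sizes))
  structure(
    list(curve = tibble(box_size = sizes, count = counts),
         fd = unname(coef(fit)[2]),
         r_squared = suppressWarnings(summary(fit)$r.squared)),
    class = "boxcount_curve"
  )
}

#' @export
print.boxcount_curve <- function(x, ...) {
  cat(sprintf("<boxcount_curve: fd = %.4f, r^2 = %.4f, %d sizes (%d..%d px)>\n",
              x$fd, x$r_squared, nrow(x$curve),
              min(x$curve$box_size), max(x$curve$box_size)))
  invisible(x)
}

#' @export
tidy.boxcount_curve <- function(x, ...) x$curve

#' @export
glance.boxcount_curve <- function(x, ...) {
  tibble(fd = x$fd, r_squared = x$r_squared, n_sizes = nrow(x$curve))
}

#' @rdname compute_fd
#' @param object,x A `boxcount_curve`.
#' @param ... Unused.
#' @export
autoplot.boxcount_curve <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = log(1 / .data$box_size),
                               y = log(.data$count))) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4, colour = "grey40") +
    ggplot2::labs(x = "log(1 / box size)", y = "log(box count)",
                  title = sprintf("Box-counting fit: FD = %.3f (r² = %.3f)",
                                  object$fd, object$r_squared)) +
    ggplot2::theme_minimal()
}

#' Fractal dimension of the vessel centreline network
#'
#' Computes the box-counting dimension of the union of the artery and vein
#' skeletons (the centreline tracings), not of the filled vessel mask:
#' vessel calibre would otherwise leak into the complexity estimate.
#' Arterial and venular trees are not distinguished.
#'
#' @param mask A [labeled_vessel_mask()].
#' @param sizes Optional box-size ladder, as in [compute_fd()].
#' @param on_skeleton Compute on centreline tracings (default). `FALSE`
#'   computes on the filled mask, for sensitivity analysis only.
#' @return The fitted `boxcount_curve`; its `fd` element is the vessel FD.
#' @export
vessel_fd <- function(mask, sizes = NULL, on_skeleton = TRUE) {
  assert_that(inherits(mask, "labeled_vessel_mask"), "mask must be a labeled_vessel_mask")
  assert_that(sum(mask$grid != 0) > 0, "mask has no vessel pixels")
  target <- if (on_skeleton) {
    a <- if (any(mask$grid == 1L)) skeletonize(mask, "artery")$grid else 0L
    v <- if (any(mask$grid == 2L)) skeletonize(mask, "vein")$grid else 0L
    ((a + v) != 0) * 1L
  } else {
    (mask$grid != 0) * 1L
  }
  if (!is.matrix(target)) target <- matrix(target, mask$height, mask$width)
  compute_fd(target, sizes = sizes)
}
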