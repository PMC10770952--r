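# Independent reference implementations used as oracles. Each is written
# from the definition, by a different route than the package code.

# box counting by explicit loop over every lattice cell
naive_box_count <- function(mask, s) {
  h <- nrow(mask); w <- ncol(mask)
  cnt <- 0L
  for (r0 in seq(1, h, by = s)) {
    for (c0 in seq(1, w, by = s)) {
      block <- mask[r0:min(h, r0 + s - 1), c0:min(w, c0 + s - 1)]
      if (any(block != 0)) cnt <- cnt + 1L
    }
  }
  cnt
}

# Knudtson pairing by explicit largest/smallest selection (no sort of the
# whole vector; repeated which.max / which.min)
brute_knudtson <- function(widths, coef, n_largest = 6) {
  w <- widths
  while (length(w) > n_largest) w <- w[-which.min(w)]
  while (length(w) > 1) {
    i_max <- which.max(w)
    big <- w[i_max]; w <- w[-i_max]
    i_min <- which.min(w)
    small <- w[i_min]; w <- w[-i_min]
    w <- c(w, coef * sqrt(big^2 + small^2))
  }
  w
}

# exhaustive-search CART with the same split conventions as the forest:
# Gini impurity, midpoint thresholds, strict improvement, features scanned
# in ascending index order, thresholds ascending
cart_oracle_fit <- function(X, y, min_leaf = 1) {
  gini <- function(yy) {
    p <- mean(yy)
    2 * p * (1 - p)
  }
  grow <- function(rows) {
    yy <- y[rows]
    leaf <- list(leaf = TRUE, pred = as.integer(2 * sum(yy) >= length(yy)))
    if (length(unique(yy)) == 1 || length(rows) < 2 * min_leaf) return(leaf)
    parent <- gini(yy)
    best <- NULL; best_gain <- 0
    for (f in seq_len(ncol(X))) {
      v <- X[rows, f]
      for (thr in sort(unique(v))[-1]) {
        cut <- (sort(unique(v))[which(sort(unique(v)) == thr) - 1] + thr) / 2
        l <- rows[v <= cut]; r <- rows[v > cut]
        if (length(l) < min_leaf || length(r) < min_leaf) next
        gain <- parent - length(l) / length(rows) * gini(y[l]) -
          length(r) / length(rows) * gini(y[r])
        if (gain > best_gain + 1e-12) {
          best_gain <- gain
          best <- list(f = f, cut = cut, l = l, r = r)
        }
      }
    }
    if (is.null(best)) return(leaf)
    list(leaf = FALSE, f = best$f, cut = best$cut,
         left = grow(best$l), right = grow(best$r))
  }
  grow(seq_len(nrow(X)))
}

cart_oracle_predict <- function(tree, X) {
  one <- function(node, x) {
    if (node$leaf) return(node$pred)
    if (x[node$f] <= node$cut) one(node$left, x) else one(node$right, x)
  }
  apply(X, 1, function(x) one(tree, x))
}

# AUC as the tie-corrected pair statistic, by explicit double loop
pairwise_auc <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# Sierpinski gasket by recursive block construction (keep three quadrants)
sierpinski_brute <- function(depth) {
  s <- matrix(1L, 1, 1)
  for (d in seq_len(depth)) {
    n <- nrow(s)
    s <- rbind(cbind(s, s), cbind(s, matrix(0L, n, n)))
  }
  s
}
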