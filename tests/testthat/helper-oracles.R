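# Independent brute-force oracles used to check the package's fast paths.
# These are deliberately naive implementations kept separate from R/.

# Connected-component count by explicit stack-based flood fill.
oracle_component_count <- function(mask, connectivity = 8) {
  nx <- nrow(mask); ny <- ncol(mask)
  seen <- matrix(FALSE, nx, ny)
  if (connectivity == 8) {
    steps <- cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    steps <- cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  }
  count <- 0
  for (i in seq_len(nx)) for (j in seq_len(ny)) {
    if (!mask[i, j] || seen[i, j]) next
    count <- count + 1
    stack <- list(c(i, j)); seen[i, j] <- TRUE
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (k in seq_len(nrow(steps))) {
        q <- p + steps[k, ]
        if (q[1] >= 1 && q[1] <= nx && q[2] >= 1 && q[2] <= ny &&
            mask[q[1], q[2]] && !seen[q[1], q[2]]) {
          seen[q[1], q[2]] <- TRUE
          stack[[length(stack) + 1]] <- q
        }
      }
    }
  }
  count
}

# Greedy intensity-ordered thinning using a full distance matrix.
oracle_dedup <- function(x, y, intensity, min_sep) {
  o <- order(-intensity, x, y)
  x <- x[o]; y <- y[o]
  n <- length(x)
  if (n == 0) return(integer(0))
  D <- as.matrix(dist(cbind(x, y)))
  kept <- integer(0)
  for (i in seq_len(n)) {
    if (length(kept) == 0 || all(D[i, kept] >= min_sep)) kept <- c(kept, i)
  }
  # return kept positions as a sorted coordinate matrix for comparison
  m <- cbind(x[kept], y[kept])
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

# All-pairs nearest-marker distances.
oracle_nearest <- function(cx, cy, mx, my) {
  vapply(seq_along(cx), function(i) {
    if (length(mx) == 0) return(Inf)
    min(sqrt((mx - cx[i])^2 + (my - cy[i])^2))
  }, numeric(1))
}

# Exact point-to-region distance for the surface rule: zero inside a
# positive pixel, otherwise distance to the nearest positive-pixel centre
# minus half a pixel (the boundary offset), floored at zero.
oracle_surface_dist <- function(cx, cy, mask, px) {
  pos <- which(mask, arr.ind = TRUE)
  bx <- (pos[, 1] - 0.5) * px; by <- (pos[, 2] - 0.5) * px
  vapply(seq_along(cx), function(i) {
    ix <- min(max(ceiling(cx[i] / px), 1), nrow(mask))
    iy <- min(max(ceiling(cy[i] / px), 1), ncol(mask))
    if (mask[ix, iy]) return(0)
    max(min(sqrt((bx - cx[i])^2 + (by - cy[i])^2)) - 0.5 * px, 0)
  }, numeric(1))
}

# Exhaustive inner/outer threshold scan over every achievable depth level.
oracle_split_depth <- function(roi, target) {
  depth <- depth_map(roi)
  dv <- depth[roi$mask]
  lev <- sort(unique(dv))
  fr <- vapply(lev, function(d) mean(dv >= d), numeric(1))
  lev[which.min(abs(fr - target))]
}

# Small fully-specified scene used by several tests; any argument of
# scene_config() may be overridden.
tiny_scene <- function(seed = 1, ...) {
  args <- list(image_size_px = c(220L, 220L), pixel_size_um = 2,
               roi_shape = list(type = "disk", radius_um = 180),
               n_particles = 0L, seed = seed)
  args <- utils::modifyList(args, list(...))
  do.call(scene_config, args)
}
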