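# Fixtures are built in code: voxel structures drawn directly on arrays, and
# small graph oracles implemented independently of the package internals.

# label_volume from a set of 0-based voxel coordinates
volume_from_voxels <- function(ijk, dims, spacing = 1) {
  arr <- array(0L, dims)
  arr[ijk + 1L] <- 1L
  label_volume(arr, spacing = rep(spacing, 3))
}

skeleton_from_voxels <- function(ijk, dims, spacing = 1) {
  vol <- volume_from_voxels(ijk, dims, spacing)
  structure(list(voxels = vol$voxels > 0, affine = vol$affine,
                 spacing = vol$spacing, n_foreground = nrow(ijk),
                 kept_largest = FALSE),
            class = "skeleton_mask")
}

# random monotone staircase path: consecutive voxels are 26-adjacent and
# non-consecutive voxels never are (x strictly increases)
random_staircase <- function(n, seed) {
  set.seed(seed)
  steps <- cbind(1L, sample(-1:1, n - 1, replace = TRUE),
                 sample(-1:1, n - 1, replace = TRUE))
  ijk <- rbind(c(0L, 0L, 0L), apply(steps, 2, cumsum))
  sweep(ijk, 2, apply(ijk, 2, min))  # shift non-negative
}

# voxel ring: rasterized circle, closed loop
voxel_ring <- function(radius = 6) {
  th <- seq(0, 2 * pi, length.out = 720)
  ijk <- unique(cbind(round(radius * cos(th)), round(radius * sin(th)), 0))
  sweep(ijk, 2, apply(ijk, 2, min))
}

# Y-shaped skeleton: three straight arms meeting at a junction
y_skeleton_voxels <- function(arms = c(10, 8, 3)) {
  j <- c(12L, 12L, 12L)
  a1 <- t(vapply(seq_len(arms[1]), function(d) j + c(-d, 0L, 0L), integer(3)))
  a2 <- t(vapply(seq_len(arms[2]), function(d) j + c(d, d, 0L), integer(3)))
  a3 <- t(vapply(seq_len(arms[3]), function(d) j + c(d, -d, 0L), integer(3)))
  rbind(matrix(j, 1), a1, a2, a3)
}

# brute-force neighbour count oracle (independent of the compiled kernel)
brute_neighbor_count <- function(ijk, p) {
  sum(apply(ijk, 1, function(q) {
    d <- abs(q - p)
    all(d <= 1) && any(d > 0)
  }))
}

# brute-force enumeration of all simple paths between two voxels on the
# 26-adjacency graph; returns the maximum number of voxels on any path
brute_longest_path <- function(ijk, from, to) {
  n <- nrow(ijk)
  adj <- lapply(seq_len(n), function(i) {
    which(vapply(seq_len(n), function(j) {
      d <- abs(ijk[i, ] - ijk[j, ]); i != j && all(d <= 1)
    }, logical(1)))
  })
  id_from <- which(colSums(abs(t(ijk) - from)) == 0)
  id_to <- which(colSums(abs(t(ijk) - to)) == 0)
  best <- 0
  dfs <- function(v, visited, len) {
    if (v == id_to) { best <<- max(best, len); return(invisible()) }
    for (w in adj[[v]]) if (!visited[w]) {
      visited[w] <- TRUE
      dfs(w, visited, len + 1)
      visited[w] <- FALSE
    }
  }
  visited <- rep(FALSE, n); visited[id_from] <- TRUE
  dfs(id_from, visited, 1)
  best
}

# proper random rotation (det +1) from a seeded QR factorization
random_rotation <- function(seed) {
  set.seed(seed)
  qr_ <- qr(matrix(rnorm(9), 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

apply_rigid <- function(df, R, shift) {
  m <- as.matrix(df[, c("x", "y", "z")]) %*% t(R)
  out <- df
  out$x <- m[, 1] + shift[1]
  out$y <- m[, 2] + shift[2]
  out$z <- m[, 3] + shift[3]
  out
}

pipeline_metrics <- function(points, smoothing = 0, n_samples = 512) {
  sp <- fit_unit_speed_spline(points, smoothing = smoothing)
  prof <- curvature_profile(sp, n_samples)
  list(L = sp$length, aoc = arc_over_chord(sp),
       km = total_curvature(prof), kms = mean_squared_curvature(prof),
       krms = rms_curvature(prof), spline = sp, profile = prof)
}
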