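test_that("binarize isolates a label and rejects absent labels", {
  arr <- array(0L, c(6, 6, 6))
  arr[2:4, 3, 3] <- 1L; arr[5, 5, 5] <- 2L
  vol <- label_volume(arr, spacing = c(1, 1, 1))
  b <- binarize(vol, 1)
  expect_equal(sum(b$voxels), 3)
  expect_true(all(b$voxels[2:4, 3, 3] == 1L))
  expect_error(binarize(vol, 7), class = "tortr_empty_structure")
  # idempotent on binary input
  expect_identical(binarize(b, 1)$voxels, b$voxels)
})

test_that("skeletonization thins a tube to a single thin line", {
  cyl <- voxelize_tube(make_line(c(0, 0, 0), c(25, 0, 0), 20), 2.5,
                       spacing = 1)
  sk <- skeletonize3d(cyl)
  counts <- array(tortr:::neighbor_count_cpp(as.logical(sk$voxels),
                                             dim(sk$voxels)),
                  dim(sk$voxels))
  fg <- counts[!is.na(counts)]
  expect_true(all(fg <= 2))           # one-voxel-wide open line
  expect_equal(sum(fg == 1), 2)       # exactly two ends
  # helix tube: one component, two endpoints after spur pruning
  h <- make_helix(10, 10, turns = 1, n_points = 300)
  tube <- voxelize_tube(h, 1.5, spacing = 0.625)
  skh <- skeletonize3d(tube)
  lab <- tortr:::label_components_cpp(as.logical(skh$voxels),
                                      dim(skh$voxels))
  expect_equal(max(lab), 1)
  expect_equal(nrow(find_endpoints(skh)), 2)
})

test_that("empty and multi-component masks raise typed errors", {
  empty <- label_volume(array(0L, c(5, 5, 5)))
  expect_error(skeletonize3d(empty), class = "tortr_empty_structure")
  arr <- array(0L, c(12, 8, 8))
  arr[2:4, 2:4, 2:4] <- 1L
  arr[8:10, 5:7, 5:7] <- 1L
  two <- label_volume(arr)
  expect_error(skeletonize3d(two), class = "tortr_multi_component")
  expect_warning(skf <- skeletonize3d(two, keep_largest = TRUE),
                 class = "tortr_kept_largest_component")
  expect_true(skf$n_foreground > 0)
})

test_that("endpoint detection matches a brute-force neighbour count", {
  for (seed in 1:15) {
    n <- sample(6:30, 1)
    ijk <- random_staircase(n, seed)
    sk <- skeleton_from_voxels(ijk, apply(ijk, 2, max) + 2L)
    eps <- find_endpoints(sk)
    # oracle: voxels with exactly one 26-neighbour
    truth <- ijk[vapply(seq_len(n), function(i)
      brute_neighbor_count(ijk, ijk[i, ]) == 1, logical(1)), , drop = FALSE]
    truth <- truth[order(truth[, 1], truth[, 2], truth[, 3]), , drop = FALSE]
    expect_equal(nrow(eps), 2)
    expect_equal(unname(eps), unname(truth))
  }
})

test_that("closed rings and isolated voxels are typed errors", {
  ring <- voxel_ring(6)
  sk <- skeleton_from_voxels(ring, apply(ring, 2, max) + 2L)
  expect_error(find_endpoints(sk), class = "tortr_loop_topology")
  solo <- skeleton_from_voxels(matrix(c(2L, 2L, 2L), 1), c(5L, 5L, 5L))
  expect_error(find_endpoints(solo), class = "tortr_degenerate_structure")
})

test_that("order_path returns the ordered walk and is reversal-symmetric", {
  ijk <- cbind(0:4, 0L, 0L)
  sk <- skeleton_from_voxels(ijk, c(7L, 3L, 3L))
  p <- order_path(sk, c(0L, 0L, 0L), c(4L, 0L, 0L))
  expect_equal(p$i, 0:4)
  expect_equal(nrow(p), 5)
  r <- order_path(sk, c(4L, 0L, 0L), c(0L, 0L, 0L))
  expect_equal(r$i, 4:0)
  expect_equal(as.matrix(r[5:1, c("x", "y", "z")]),
               as.matrix(p[, c("x", "y", "z")]), ignore_attr = TRUE)
  # consecutive voxels always 26-adjacent and duplicate-free
  for (seed in 16:20) {
    ijk <- random_staircase(25, seed)
    sk <- skeleton_from_voxels(ijk, apply(ijk, 2, max) + 2L)
    eps <- find_endpoints(sk)
    p <- order_path(sk, eps[1, ], eps[2, ])
    d <- abs(diff(as.matrix(p[, c("i", "j", "k")])))
    expect_true(all(d <= 1) && all(rowSums(d) > 0))
    expect_false(any(duplicated(p[, c("i", "j", "k")])))
    expect_equal(nrow(p), 25)  # clean path covers every voxel
  }
})

test_that("Y-shaped skeletons drop the short spur via the longest pair", {
  ijk <- y_skeleton_voxels(c(10, 8, 3))
  sk <- skeleton_from_voxels(ijk, c(25L, 25L, 25L))
  eps <- find_endpoints(sk)
  expect_equal(nrow(eps), 3)
  # oracle: enumerate simple paths between all endpoint pairs
  best <- 0
  for (a in 1:2) for (b in (a + 1):3)
    best <- max(best, brute_longest_path(ijk, eps[a, ], eps[b, ]))
  expect_equal(best, 19)  # 10-arm + junction + 8-arm
  expect_warning(
    p <- order_path(sk, c(2L, 12L, 12L), c(20L, 20L, 12L)),
    class = "tortr_spur_dropped")
  expect_equal(nrow(p), best)
  expect_true("spur_dropped" %in% attr(p, "warnings"))
})

test_that("order_path errors when endpoints are disconnected", {
  ijk <- rbind(cbind(0:3, 0L, 0L), cbind(8:11, 0L, 0L))
  sk <- skeleton_from_voxels(ijk, c(14L, 3L, 3L))
  expect_error(order_path(sk, c(0L, 0L, 0L), c(11L, 0L, 0L)),
               class = "tortr_disconnection")
})

test_that("extract_centerline recovers phantom tube geometry", {
  h <- make_helix(10, 10, turns = 1, n_points = 300)
  tube <- voxelize_tube(h, 1.5, spacing = 0.625)
  path <- extract_centerline(tube, 1)
  expect_equal(attr(path, "n_endpoints"), 2)
  L <- attr(h, "arc_length")
  expect_lt(abs(nrow(path) - L / 0.625) / (L / 0.625), 0.2)
  expect_error(extract_centerline(tube, 9), class = "tortr_empty_structure")
})

test_that("centerline metrics are invariant under axis permutation + flip", {
  h <- make_helix(6, 15, turns = 1, n_points = 200)
  tube <- voxelize_tube(h, 1.4, spacing = 0.7)
  rec <- function(vol) {
    path <- extract_centerline(vol, 1)
    m <- pipeline_metrics(path, smoothing = 1e-5)
    c(m$L, m$aoc, m$km, m$krms)
  }
  base <- rec(tube)
  # permute axes (z, x, y) and flip x; update the affine to match
  perm <- c(3, 1, 2)
  vox <- aperm(tube$voxels, perm)
  vox <- vox[dim(vox)[1]:1, , ]
  P <- matrix(0, 3, 3); for (a in 1:3) P[a, perm[a]] <- 1
  A <- tube$affine
  A2 <- diag(4)
  A2[1:3, 1:3] <- A[1:3, 1:3] %*% t(P)
  A2[1:3, 4] <- A[1:3, 4]
  # flipping axis 1 of the array: new index i' = (n-1) - i
  n1 <- dim(vox)[1]
  A2[1:3, 4] <- A2[1:3, 4] + A2[1:3, 1] * (n1 - 1)
  A2[1:3, 1] <- -A2[1:3, 1]
  flipped <- label_volume(vox, affine = A2)
  out <- rec(flipped)
  expect_equal(out, base, tolerance = 1e-2)
})
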