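#' Synthetic curves with closed-form ground truth
#'
#' `make_helix()`, `make_arc()` and `make_line()` generate ordered 3D point
#' sets with analytically known curvature, arc length and tortuosity metrics,
#' so every downstream stage (skeletonization, spline fitting, metric
#' computation) can be validated without clinical data. A helix with radius
#' `radius` and pitch `pitch` has constant curvature
#' `radius / (radius^2 + (pitch/2pi)^2)`; a circular arc has curvature
#' `1/radius`; a line has curvature zero.
#'
#' Points are sampled uniformly in the angle parameter, which for a helix is
#' uniform in arc length, matching the unit-speed parametrization assumed by
#' the spline stage.
#'
#' @param radius Helix or arc radius in mm (> 0).
#' @param pitch Axial advance per full turn, in mm (>= 0). `pitch = 0` gives
#'   a circle traversed `turns` times.
#' @param turns Number of revolutions (> 0, need not be an integer).
#' @param n_points Number of samples (>= 4).
#' @param noise_sigma Standard deviation (mm) of isotropic Gaussian noise
#'   added to each coordinate after the ground truth is recorded.
#' @param snr Alternative to `noise_sigma`: signal-to-noise ratio, with the
#'   noise sigma set to `radius / snr` (see [add_noise()]).
#' @param seed Integer seed for the noise generator; required for
#'   reproducible noise.
#' @return A `ground_truth_curve`: a tibble with columns `x`, `y`, `z` (mm)
#'   and `kappa_true` (mm^-1), carrying attributes `arc_length` (mm),
#'   `metrics_true` (closed-form tortuosity metrics) and `amplitude` (the
#'   characteristic scale used for SNR conversion).
#' @examples
#' h <- make_helix(radius = 1, pitch = 2 * pi, turns = 1, n_points = 200)
#' attr(h, "arc_length")          # 2*pi*sqrt(2)
#' unique(h$kappa_true)           # 0.5
#' @export
make_helix <- function(radius, pitch, turns, n_points = 200,
                       noise_sigma = 0, snr = NULL, seed = NULL) {
  if (!is.numeric(radius) || radius <= 0)
    stop_tortr("helix radius must be > 0", "invalid_spec")
  if (!is.numeric(pitch) || pitch < 0)
    stop_tortr("helix pitch must be >= 0", "invalid_spec")
  if (!is.numeric(turns) || turns <= 0)
    stop_tortr("helix turns must be > 0", "invalid_spec")
  if (n_points < 4)
    stop_tortr("n_points must be >= 4 for a cubic spline fit", "invalid_spec")
  if (noise_sigma < 0)
    stop_tortr("noise_sigma must be >= 0", "invalid_spec")
  c0 <- pitch / (2 * pi)
  t <- seq(0, 2 * pi * turns, length.out = n_points)
  pts <- cbind(x = radius * cos(t), y = radius * sin(t), z = c0 * t)
  kappa <- rep(radius / (radius^2 + c0^2), n_points)
  arc_length <- turns * sqrt((2 * pi * radius)^2 + pitch^2)
  curve <- new_ground_truth_curve(pts, kappa, arc_length,
                                  shape = "helix", amplitude = radius)
  if (!is.null(snr)) return(add_noise(curve, snr = snr, seed = seed))
  if (noise_sigma > 0) curve <- perturb_curve(curve, noise_sigma, seed)
  curve
}

#' @rdname make_helix
#' @param start,end 3D endpoints (numeric length-3, mm) of the line.
#' @export
make_line <- function(start, end, n_points = 20) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (length(start) != 3 || length(end) != 3)
    stop_tortr("start and end must be 3D points", "invalid_spec")
  if (n_points < 4)
    stop_tortr("n_points must be >= 4 for a cubic spline fit", "invalid_spec")
  if (sqrt(sum((end - start)^2)) == 0)
    stop_tortr("line endpoints must be distinct", "invalid_spec")
  u <- seq(0, 1, length.out = n_points)
  pts <- cbind(x = start[1] + u * (end[1] - start[1]),
               y = start[2] + u * (end[2] - start[2]),
               z = start[3] + u * (end[3] - start[3]))
  new_ground_truth_curve(pts, rep(0, n_points),
                         arc_length = sqrt(sum((end - start)^2)),
                         shape = "line", amplitude = NULL)
}

#' @rdname make_helix
#' @param angle Subtended angle of the arc in radians (0 < angle <= 2pi).
#' @export
make_arc <- function(radius, angle, n_points = 100) {
  if (!is.numeric(radius) || radius <= 0)
    stop_tortr("arc radius must be > 0", "invalid_spec")
  if (!is.numeric(angle) || angle <= 0 || angle > 2 * pi)
    stop_tortr("arc angle must be in (0, 2*pi]", "invalid_spec")
  if (n_points < 4)
    stop_tortr("n_points must be >= 4 for a cubic spline fit", "invalid_spec")
  t <- seq(0, angle, length.out = n_points)
  pts <- cbind(x = radius * cos(t), y = radius * sin(t), z = rep(0, n_points))
  new_ground_truth_curve(pts, rep(1 / radius, n_points),
                         arc_length = radius * angle,
                         shape = "arc", amplitude = radius)
}

new_ground_truth_curve <- function(pts, kappa_true, arc_length, shape,
                                   amplitude = NULL) {
  out <- tibble::tibble(x = pts[, 1], y = pts[, 2], z = pts[, 3],
                        kappa_true = kappa_true)
  chord <- sqrt(sum((pts[nrow(pts), 1:3] - pts[1, 1:3])^2))
  km <- mean(kappa_true) * arc_length
  kms <- mean(kappa_true^2)
  metrics <- list(
    arc_length = arc_length,
    chord = chord,
    aoc = if (chord > 0) arc_length / chord else Inf,
    total_curvature = km,
    mean_squared_curvature = kms,
    rms_curvature = arc_length * sqrt(kms)
  )
  structure(out,
            class = c("ground_truth_curve", class(out)),
            arc_length = arc_length,
            metrics_true = metrics,
            shape = shape,
            amplitude = amplitude)
}

# evaluate code with a temporary RNG state when seed is given
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

perturb_curve <- function(curve, sigma, seed, snr = NULL) {
  n <- nrow(curve)
  eps <- with_seed(seed, matrix(rnorm(3 * n, 0, sigma), ncol = 3))
  curve$x <- curve$x + eps[, 1]
  curve$y <- curve$y + eps[, 2]
  curve$z <- curve$z + eps[, 3]
  attr(curve, "noise") <- list(sigma = sigma, snr = snr, seed = seed)
  curve
}

#' Add seeded isotropic Gaussian noise at a controlled SNR
#'
#' Perturbs each point of a ground-truth curve with isotropic Gaussian noise
#' whose standard deviation is `amplitude / snr`. The characteristic
#' amplitude is the helix (or arc) radius when the curve has one, and the RMS
#' deviation of the points from their centroid otherwise. All ground-truth
#' fields (true curvature, arc length, closed-form metrics) are preserved
#' from the clean curve, so a noisy phantom still knows its own truth.
#'
#' @param curve A `ground_truth_curve`.
#' @param snr Signal-to-noise ratio (> 0); `Inf` returns the curve unchanged.
#' @param seed Integer seed; the perturbation is bit-reproducible for a fixed
#'   seed.
#' @return The perturbed `ground_truth_curve`.
#' @export
add_noise <- function(curve, snr, seed = NULL) {
  if (!is.numeric(snr) || snr <= 0)
    stop_tortr("snr must be > 0", "invalid_spec")
  if (is.infinite(snr)) return(curve)
  amp <- attr(curve, "amplitude")
  if (is.null(amp)) {
    p <- cbind(curve$x, curve$y, curve$z)
    ctr <- colMeans(p)
    amp <- sqrt(mean(rowSums(sweep(p, 2, ctr)^2)))
  }
  perturb_curve(curve, amp / snr, seed, snr = snr)
}

#' Voxelize a curve into a binary tube mask
#'
#' Builds a binary volume in which a voxel is foreground iff its center lies
#' within `tube_radius` of the polyline through the curve points (the
#' polyline is densified at a quarter of the smallest voxel spacing, so the
#' voxel-center inclusion test is accurate to well below one voxel). The
#' result mimics an upstream artery segmentation: running
#' [extract_centerline()] on it exercises the full skeleton -> spline ->
#' metrics pipeline against the curve's closed-form ground truth.
#'
#' @param curve A `ground_truth_curve` (or any data frame with `x`, `y`, `z`
#'   columns in mm).
#' @param tube_radius Tube radius in mm; should be at least the largest voxel
#'   spacing or the tube may voxelize disconnected.
#' @param spacing Voxel size in mm; scalar (isotropic) or length 3.
#' @param margin Background padding around the tube, in mm.
#' @return A [label_volume()] with foreground label 1 and a diagonal affine.
#' @export
voxelize_tube <- function(curve, tube_radius, spacing = 0.625,
                          margin = NULL) {
  p <- as.matrix(curve[, c("x", "y", "z")])
  if (nrow(p) < 2)
    stop_tortr("cannot voxelize a curve with fewer than 2 points",
               "voxelization")
  if (!is.numeric(tube_radius) || tube_radius <= 0)
    stop_tortr("tube_radius must be > 0", "invalid_spec")
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  if (any(spacing <= 0))
    stop_tortr("spacing must be positive", "invalid_spec")
  if (is.null(margin)) margin <- tube_radius + max(spacing)

  # densify the polyline so union-of-balls ~= tube around segments
  step <- 0.25 * min(spacing)
  dense <- densify_polyline(p, step)

  origin <- apply(dense, 2, min) - margin
  extent <- apply(dense, 2, max) + margin - origin
  dims <- pmax(as.integer(ceiling(extent / spacing)) + 1L, 4L)
  vox <- array(FALSE, dims)
  # per-axis voxel-center coordinates
  ax <- lapply(1:3, function(a) origin[a] + (seq_len(dims[a]) - 1) * spacing[a])
  rad <- ceiling(tube_radius / spacing) + 1L
  r2 <- tube_radius^2
  for (i in seq_len(nrow(dense))) {
    ctr <- dense[i, ]
    ijk <- round((ctr - origin) / spacing)
    lo <- pmax(ijk - rad, 0); hi <- pmin(ijk + rad, dims - 1L)
    ix <- (lo[1]:hi[1]) + 1L; iy <- (lo[2]:hi[2]) + 1L; iz <- (lo[3]:hi[3]) + 1L
    dx2 <- (ax[[1]][ix] - ctr[1])^2
    dy2 <- (ax[[2]][iy] - ctr[2])^2
    dz2 <- (ax[[3]][iz] - ctr[3])^2
    inside <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= r2
    vox[ix, iy, iz] <- vox[ix, iy, iz] | inside
  }
  if (!any(vox))
    stop_tortr("voxelization produced an empty mask", "voxelization")
  lab <- label_components_cpp(as.logical(vox), dim(vox))
  if (max(lab) > 1L)
    stop_tortr(sprintf(
      "tube too thin for the grid: foreground voxelized into %d components",
      max(lab)), "voxelization")
  affine <- diag(c(spacing, 1))
  affine[1:3, 4] <- origin
  label_volume(array(as.integer(vox), dims), affine = affine,
               spacing = spacing)
}

densify_polyline <- function(p, step) {
  segs <- lapply(seq_len(nrow(p) - 1), function(i) {
    a <- p[i, ]; b <- p[i + 1, ]
    len <- sqrt(sum((b - a)^2))
    if (len == 0) return(NULL)
    n <- max(2L, ceiling(len / step) + 1L)
    u <- seq(0, 1, length.out = n)
    if (i < nrow(p) - 1) u <- u[-length(u)]  # avoid duplicating joints
    cbind(a[1] + u * (b[1] - a[1]), a[2] + u * (b[2] - a[2]),
          a[3] + u * (b[3] - a[3]))
  })
  out <- do.call(rbind, segs)
  if (is.null(out))
    stop_tortr("curve has zero length, cannot voxelize", "voxelization")
  out
}
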