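test_that("metrics reproduce closed forms on analytic curves", {
  hel <- pipeline_metrics(make_helix(1, 2 * pi, turns = 1, n_points = 300))
  expect_equal(hel$aoc, sqrt(2), tolerance = 0.005)
  expect_equal(hel$km, pi * sqrt(2), tolerance = 0.01)
  expect_equal(hel$kms, 0.25, tolerance = 0.01)
  expect_equal(hel$krms, 2 * pi * sqrt(2) * 0.5, tolerance = 0.01)

  semi <- pipeline_metrics(make_arc(1, pi, 200))
  expect_equal(semi$aoc, pi / 2, tolerance = 0.005)

  # near-full circle: total curvature approaches 2*pi regardless of radius
  for (R in c(1, 3)) {
    circ <- pipeline_metrics(make_arc(R, 2 * pi - 1e-3, 400))
    expect_equal(circ$km, 2 * pi, tolerance = 0.02)
  }

  ln <- pipeline_metrics(make_line(c(0, 0, 0), c(10, 0, 0), 20))
  expect_equal(ln$aoc, 1, tolerance = 1e-9)
  expect_lt(ln$km, 1e-6)
  expect_lt(ln$kms, 1e-12)
  expect_lt(ln$krms, 1e-6)
})

test_that("multi-turn helices scale total curvature with turns", {
  for (tn in c(1, 2)) {
    m <- pipeline_metrics(make_helix(1, 2 * pi, turns = tn,
                                     n_points = 200 * tn))
    expect_equal(m$km, pi * sqrt(2) * tn, tolerance = 0.02)
  }
})

test_that("AOC, km, krms are scale invariant; kms scales as 1/a^2", {
  base <- pipeline_metrics(make_helix(1, 2 * pi, turns = 1.5,
                                      n_points = 250))
  for (a in c(0.5, 2, 10)) {
    h <- make_helix(1, 2 * pi, turns = 1.5, n_points = 250)
    scaled <- h
    scaled$x <- a * h$x; scaled$y <- a * h$y; scaled$z <- a * h$z
    m <- pipeline_metrics(scaled)
    expect_equal(m$aoc / base$aoc, 1, tolerance = 0.01)
    expect_equal(m$km / base$km, 1, tolerance = 0.01)
    expect_equal(m$krms / base$krms, 1, tolerance = 0.01)
    expect_equal(m$kms / base$kms, 1 / a^2, tolerance = 0.02 / a^2)
  }
})

test_that("curvature metrics fall with pitch and rise with turns", {
  pitch_vals <- c(pi, 2 * pi, 4 * pi, 8 * pi)
  ms <- lapply(pitch_vals, function(p)
    pipeline_metrics(make_helix(1, p, turns = 2, n_points = 250)))
  for (f in c("km", "kms", "krms"))
    expect_true(all(diff(vapply(ms, `[[`, numeric(1), f)) < 0))

  turn_vals <- c(1, 2, 4)
  mt <- lapply(turn_vals, function(tn)
    pipeline_metrics(make_helix(1, 2 * pi, turns = tn,
                                n_points = 150 * tn)))
  for (f in c("km", "krms"))
    expect_true(all(diff(vapply(mt, `[[`, numeric(1), f)) > 0))
})

test_that("AOC is insensitive to wiggle that curvature metrics detect", {
  n <- 400
  x <- seq(0, 100, length.out = n)
  straight <- data.frame(x = x, y = 0, z = 0)
  wiggly <- data.frame(x = x, y = 0.25 * sin(2 * pi * x / 5), z = 0)
  ms <- pipeline_metrics(straight)
  mw <- pipeline_metrics(wiggly)
  expect_lt(mw$aoc / ms$aoc - 1, 0.05)
  expect_gt(mw$km, 1.5 * max(ms$km, 0.1))
  expect_gt(mw$krms, 1.5 * max(ms$krms, 0.1))
})

test_that("tortuosity records carry the full CSV schema and warnings", {
  h <- make_helix(10, 10, turns = 1, n_points = 300)
  tube <- voxelize_tube(h, 1.5, spacing = 0.625)
  path <- extract_centerline(tube, 1)
  sp <- fit_unit_speed_spline(path)
  rec <- compute_tortuosity(sp, path = path, subject_id = "ph", label = 1)
  expect_equal(names(rec), c(
    "subject_id", "label", "n_skeleton_points", "n_endpoints",
    "arc_length_mm", "chord_length_mm", "aoc", "total_curvature",
    "mean_squared_curvature", "rms_curvature", "spline_rmse_mm",
    "combined_quality", "warnings"))
  expect_equal(rec$combined_quality,
               rec$spline_rmse_mm + rec$rms_curvature)
  expect_true(rec$aoc >= 1)
  # optional non-scale-invariant bare RMS column
  rec2 <- compute_tortuosity(sp, path = path, bare_rms = TRUE)
  expect_equal(rec2$rms_curvature_bare,
               sqrt(rec2$mean_squared_curvature), tolerance = 1e-12)

  # reversed path gives the same metrics
  rpath <- path[nrow(path):1, ]
  spr <- fit_unit_speed_spline(rpath, smoothing = sp$smoothing)
  recr <- compute_tortuosity(spr, path = rpath, subject_id = "ph", label = 1)
  for (f in c("arc_length_mm", "aoc", "total_curvature",
              "mean_squared_curvature", "rms_curvature"))
    expect_equal(recr[[f]], rec[[f]], tolerance = 1e-6)
})

test_that("branched structures surface a spur warning in the record", {
  # a main tube with a side branch, drawn by voxel-center-in-tube inclusion
  dims <- c(60, 30, 14)
  spc <- 0.8
  ax <- lapply(1:3, function(a) (seq_len(dims[a]) - 1) * spc - 6)
  pm <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))
  d2seg <- function(p, a, b) {
    ab <- b - a
    tt <- pmin(pmax(((p[, 1] - a[1]) * ab[1] + (p[, 2] - a[2]) * ab[2] +
                       (p[, 3] - a[3]) * ab[3]) / sum(ab^2), 0), 1)
    (p[, 1] - a[1] - tt * ab[1])^2 + (p[, 2] - a[2] - tt * ab[2])^2 +
      (p[, 3] - a[3] - tt * ab[3])^2
  }
  inside <- d2seg(pm, c(0, 0, 0), c(30, 0, 0)) <= 1.6^2 |
    d2seg(pm, c(15, 0, 0), c(22, 7, 0)) <= 1.6^2
  aff <- diag(c(spc, spc, spc, 1)); aff[1:3, 4] <- -6
  vol <- label_volume(array(as.integer(inside), dims), affine = aff)
  path <- suppressWarnings(extract_centerline(vol, 1))
  sp_ <- fit_unit_speed_spline(path)
  rec <- suppressWarnings(
    compute_tortuosity(sp_, path = path, subject_id = "y", label = 1))
  expect_match(rec$warnings, "spur_dropped|multiple_endpoints")
  expect_equal(rec$n_endpoints, 3)
})
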