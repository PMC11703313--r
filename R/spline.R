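#' Fit a unit-speed cubic B-spline to an ordered centerline
#'
#' Two-stage fit. Stage 1 fits a cubic smoothing spline to each coordinate
#' against the chord-length parameter (penalty `lambda` on the integrated
#' squared second derivative; `lambda = 0` interpolates). Stage 2
#' reparametrizes by arc length: the cumulative length of the stage-1 curve
#' is computed by dense quadrature (refined until the total changes by less
#' than 1e-6 relative), the curve is resampled at uniform arc length and
#' refit with interpolating natural cubics, so the parameter of the returned
#' spline *is* distance along the curve and `||r'(s)|| ~ 1`. Curvature can
#' then be read directly from the first and second derivatives.
#'
#' With `smoothing = "auto"` the penalty is selected by 10-fold
#' cross-validation on the stage-1 coordinate fits (interleaved folds,
#' prediction error summed over the three coordinates, minimum over a
#' logarithmic grid). When the least-smoothed candidate already reproduces
#' the points to well below the inter-point spacing the data are treated as
#' noise-free and the interpolating fit is used directly.
#' `smoothing = "combined"` instead picks the grid value minimizing the
#' combined quality score (RMSE + RMS curvature), the score reported per
#' vessel as the fit-quality indicator.
#'
#' @param points A data frame with `x`, `y`, `z` columns in mm (a
#'   `centerline_path`, a `ground_truth_curve`, or any ordered point set).
#'   Consecutive duplicate points are merged.
#' @param smoothing `"auto"`, `"combined"`, or a non-negative smoothing
#'   penalty (0 = interpolation).
#' @param lambda_grid Candidate penalties searched by the automatic modes.
#' @return A `unit_speed_spline` with fields `length` (total arc length L,
#'   mm), `smoothing` (value used) and coordinate spline functions;
#'   evaluate it with [predict()][predict.unit_speed_spline].
#' @examples
#' h <- make_helix(1, 2 * pi, turns = 1, n_points = 200)
#' sp <- fit_unit_speed_spline(h, smoothing = 0)
#' sp$length / (2 * pi * sqrt(2))  # ~ 1
#' @export
fit_unit_speed_spline <- function(points, smoothing = "auto",
                                  lambda_grid = 10^seq(-8, 0, by = 0.5)) {
  mat <- as.matrix(as.data.frame(points)[, c("x", "y", "z")])
  storage.mode(mat) <- "double"
  # merge consecutive duplicates
  if (nrow(mat) > 1) {
    d <- sqrt(rowSums((mat[-1, , drop = FALSE] - mat[-nrow(mat), , drop = FALSE])^2))
    mat <- mat[c(TRUE, d > 0), , drop = FALSE]
  }
  n <- nrow(mat)
  if (n < 4)
    stop_tortr(sprintf(
      "need at least 4 distinct points for a cubic spline fit (got %d)", n),
      "insufficient_points")
  t <- c(0, cumsum(sqrt(rowSums((mat[-1, ] - mat[-n, ])^2))))

  if (identical(smoothing, "auto") || identical(smoothing, "combined")) {
    grid <- sort(lambda_grid[lambda_grid > 0])
    if (length(grid) == 0)
      stop_tortr("lambda_grid must contain positive values", "invalid_spec")
    lam <- if (identical(smoothing, "combined")) {
      score <- vapply(grid, function(l) {
        sp <- try(fit_once(t, mat, l), silent = TRUE)
        if (inherits(sp, "try-error")) return(Inf)
        rmse_quick(sp, mat) +
          rms_curvature(curvature_profile(sp, n_samples = 256))
      }, numeric(1))
      grid[which.min(score)]
    } else {
      sp0 <- fit_once(t, mat, grid[1])
      if (rmse_quick(sp0, mat) <= 1e-3 * mean(diff(t))) 0  # noise-free data
      else grid[which.min(cv_error(t, mat, grid))]
    }
    sp <- fit_once(t, mat, lam)
    sp$smoothing_mode <- if (identical(smoothing, "combined")) "combined"
                         else "auto"
    sp
  } else {
    if (!is.numeric(smoothing) || smoothing < 0)
      stop_tortr(
        "smoothing must be \"auto\", \"combined\" or a non-negative number",
        "invalid_spec")
    fit_once(t, mat, smoothing)
  }
}

# K-fold cross-validated prediction error of the stage-1 coordinate fits,
# interleaved folds, no extrapolation beyond the training range
cv_error <- function(t, mat, grid, K = 10) {
  n <- nrow(mat)
  K <- max(2L, min(K, n %/% 4L))
  folds <- rep_len(seq_len(K), n)
  vapply(grid, function(lam) {
    tot <- 0; m <- 0
    for (f in seq_len(K)) {
      idx <- which(folds != f); out <- which(folds == f)
      out <- out[out > min(idx) & out < max(idx)]
      if (length(out) == 0) next
      for (cc in 1:3) {
        ss <- try(smooth.spline(t[idx], mat[idx, cc], lambda = lam,
                                all.knots = TRUE, keep.data = FALSE),
                  silent = TRUE)
        if (inherits(ss, "try-error")) return(Inf)
        tot <- tot + sum((predict(ss, t[out])$y - mat[out, cc])^2)
      }
      m <- m + length(out)
    }
    if (m == 0) Inf else tot / m
  }, numeric(1))
}

# one full two-stage fit at a fixed penalty
fit_once <- function(t, mat, lambda) {
  f1 <- stage1_fit(t, mat, lambda)
  rp <- arc_length_reparam(f1, max(t), nrow(mat))
  structure(list(fx = rp$fx, fy = rp$fy, fz = rp$fz, length = rp$L,
                 smoothing = lambda, smoothing_mode = "fixed",
                 n_input = nrow(mat), input = mat),
            class = "unit_speed_spline")
}

stage1_fit <- function(t, mat, lambda) {
  fit_coord <- function(y) {
    if (lambda == 0) {
      f <- splinefun(t, y, method = "natural")
      function(u, deriv = 0) f(u, deriv = deriv)
    } else {
      ss <- smooth.spline(t, y, lambda = lambda, all.knots = TRUE,
                          keep.data = FALSE)
      function(u, deriv = 0) predict(ss, u, deriv = deriv)$y
    }
  }
  list(fx = fit_coord(mat[, 1]), fy = fit_coord(mat[, 2]),
       fz = fit_coord(mat[, 3]))
}

# cumulative arc length by dense trapezoidal quadrature with refinement,
# then resampling at uniform arc length and interpolating refit
arc_length_reparam <- function(f1, t_max, n) {
  speed_at <- function(tg) {
    sqrt(f1$fx(tg, 1)^2 + f1$fy(tg, 1)^2 + f1$fz(tg, 1)^2)
  }
  m <- max(20L * n, 2000L)
  repeat {
    tg <- seq(0, t_max, length.out = m + 1L)
    v <- speed_at(tg)
    h <- t_max / m
    s_cum <- c(0, cumsum((v[-1] + v[-length(v)]) * h / 2))
    L <- s_cum[length(s_cum)]
    # Richardson check against half resolution
    L_half <- sum((v[seq(1, m - 1, by = 2)] + v[seq(3, m + 1, by = 2)]) * h)
    if (abs(L - L_half) <= 1e-6 * L || m >= 2e5) break
    m <- 2L * m
  }
  keep <- c(TRUE, diff(s_cum) > 0)
  sinv <- splinefun(s_cum[keep], tg[keep], method = "hyman")
  s_new <- seq(0, L, length.out = max(10L * n, 400L))
  t_new <- pmin(pmax(sinv(s_new), 0), t_max)
  list(fx = splinefun(s_new, f1$fx(t_new), method = "natural"),
       fy = splinefun(s_new, f1$fy(t_new), method = "natural"),
       fz = splinefun(s_new, f1$fz(t_new), method = "natural"),
       L = L)
}

#' Evaluate a unit-speed spline
#'
#' @param object A `unit_speed_spline`.
#' @param s Arc-length positions in `[0, L]` (mm).
#' @param deriv Derivative order 0, 1 or 2.
#' @param ... Unused.
#' @return Numeric matrix with columns `x`, `y`, `z`.
#' @export
predict.unit_speed_spline <- function(object, s, deriv = 0, ...) {
  cbind(x = object$fx(s, deriv = deriv),
        y = object$fy(s, deriv = deriv),
        z = object$fz(s, deriv = deriv))
}

#' @export
print.unit_speed_spline <- function(x, ...) {
  cat("<unit_speed_spline> L = ", signif(x$length, 6), " mm, smoothing = ",
      format(x$smoothing), " (", x$smoothing_mode, "), fit to ", x$n_input,
      " points\n", sep = "")
  invisible(x)
}

#' Sample curvature along arc length
#'
#' Evaluates the curvature `kappa(s) = ||r'(s) x r''(s)|| / ||r'(s)||^3` of
#' a fitted spline at uniformly spaced arc-length positions. The general
#' formula is used (rather than `||r''||`, its unit-speed specialization) so
#' residual parametrization error does not bias the estimate. Samples in the
#' first and last 10% of arc length are flagged as boundary samples:
#' natural-spline end conditions bias curvature there.
#'
#' @param spline A `unit_speed_spline`.
#' @param n_samples Number of samples (>= 2; default 512).
#' @return A `curvature_profile` tibble with columns `s` (mm), `kappa`
#'   (mm^-1) and `boundary` (logical).
#' @export
curvature_profile <- function(spline, n_samples = 512) {
  if (n_samples < 2)
    stop_tortr("n_samples must be >= 2", "invalid_spec")
  L <- spline$length
  s <- seq(0, L, length.out = n_samples)
  d1 <- predict(spline, s, deriv = 1)
  d2 <- predict(spline, s, deriv = 2)
  cr <- cbind(d1[, 2] * d2[, 3] - d1[, 3] * d2[, 2],
              d1[, 3] * d2[, 1] - d1[, 1] * d2[, 3],
              d1[, 1] * d2[, 2] - d1[, 2] * d2[, 1])
  kappa <- sqrt(rowSums(cr^2)) / pmax(sqrt(rowSums(d1^2))^3, .Machine$double.eps)
  out <- tibble::tibble(s = s, kappa = kappa,
                        boundary = s < 0.1 * L | s > 0.9 * L)
  structure(out, class = c("curvature_profile", class(out)),
            arc_length = L)
}

# per-point distance to the curve: nearest of a dense sampling, then
# parabolic refinement of the squared distance through the bracketing triple
spline_residuals <- function(spline, mat, n_dense = 2048) {
  L <- spline$length
  sgrid <- seq(0, L, length.out = n_dense)
  pts <- predict(spline, sgrid)
  h <- L / (n_dense - 1)
  n <- nrow(mat)
  jmin <- integer(n); d2min <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- (pts[, 1] - mat[i, 1])^2 + (pts[, 2] - mat[i, 2])^2 +
      (pts[, 3] - mat[i, 3])^2
    jmin[i] <- which.min(d2)  # ties resolve to the smaller parameter
    d2min[i] <- d2[jmin[i]]
  }
  j <- pmin(pmax(jmin, 2L), n_dense - 1L)
  d2at <- function(s) {
    p <- predict(spline, s)
    (p[, 1] - mat[, 1])^2 + (p[, 2] - mat[, 2])^2 + (p[, 3] - mat[, 3])^2
  }
  f0 <- d2at(sgrid[j]); fm <- d2at(sgrid[j] - h); fp <- d2at(sgrid[j] + h)
  denom <- fm - 2 * f0 + fp
  off <- ifelse(denom > 0, 0.5 * h * (fm - fp) / denom, 0)
  off <- pmin(pmax(off, -h), h)
  s_star <- pmin(pmax(sgrid[j] + off, 0), L)
  sqrt(pmin(d2at(s_star), d2min))
}

rmse_quick <- function(spline, mat, n_dense = 1024) {
  sqrt(mean(spline_residuals(spline, mat, n_dense)^2))
}

#' Fit quality: spline RMSE and combined score
#'
#' The per-point residual is the minimal Euclidean distance from each input
#' point to the fitted curve (dense sampling followed by local parabolic
#' refinement of the squared distance); the RMSE of those residuals measures the
#' spline's fidelity to the data. The combined score adds the
#' arc-length-normalized RMS curvature, penalizing wiggly overfits, and is
#' the quantity minimized by `smoothing = "auto"`.
#'
#' @param spline A `unit_speed_spline`.
#' @param points The points the spline was fit to; defaults to the ones
#'   stored in the spline.
#' @param n_samples Curvature samples used for the RMS-curvature term.
#' @return A `fit_quality` tibble with columns `rmse` (mm),
#'   `rms_curvature` (dimensionless) and `combined = rmse + rms_curvature`.
#' @export
fit_quality <- function(spline, points = NULL, n_samples = 512) {
  mat <- if (is.null(points)) spline$input
         else as.matrix(as.data.frame(points)[, c("x", "y", "z")])
  res <- spline_residuals(spline, mat, n_dense = 2048)
  rmse <- sqrt(mean(res^2))
  rms_c <- rms_curvature(curvature_profile(spline, n_samples))
  out <- tibble::tibble(rmse = rmse, rms_curvature = rms_c,
                        combined = rmse + rms_c)
  structure(out, class = c("fit_quality", class(out)), residuals = res)
}
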