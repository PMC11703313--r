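#' Tidy a fitted unit-speed spline
#'
#' Returns uniformly spaced samples of the fitted curve with curvature, the
#' convenient form for plotting or export.
#'
#' @param x A `unit_speed_spline`.
#' @param n Number of arc-length samples.
#' @param ... Unused.
#' @return A tibble with columns `s`, `x`, `y`, `z`, `kappa`.
#' @export
tidy.unit_speed_spline <- function(x, n = 200, ...) {
  s <- seq(0, x$length, length.out = n)
  p <- predict(x, s)
  prof <- curvature_profile(x, n)
  tibble::tibble(s = s, x = p[, 1], y = p[, 2], z = p[, 3],
                 kappa = prof$kappa)
}

#' One-row summary of a unit-speed spline fit
#'
#' @inheritParams tidy.unit_speed_spline
#' @return A one-row tibble: arc length, smoothing used, point count, RMSE
#'   and combined quality.
#' @export
glance.unit_speed_spline <- function(x, ...) {
  fq <- fit_quality(x)
  tibble::tibble(arc_length_mm = x$length, smoothing = x$smoothing,
                 smoothing_mode = x$smoothing_mode, n_points = x$n_input,
                 rmse = fq$rmse, rms_curvature = fq$rms_curvature,
                 combined = fq$combined)
}

#' Plot a curvature profile
#'
#' Curvature against arc length, with the boundary-flagged first and last
#' 10% of the curve drawn muted (natural-spline end conditions bias those
#' samples).
#'
#' @param object A `curvature_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.curvature_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$s, y = .data$kappa,
                                       alpha = !.data$boundary)) +
    ggplot2::geom_line(show.legend = FALSE) +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.35)) +
    ggplot2::labs(x = "arc length s (mm)",
                  y = expression(kappa(s) ~ (mm^-1))) +
    ggplot2::theme_minimal()
}

#' Plot a fitted spline against its input points
#'
#' Axis-pair projections (xy, xz, yz) of the input points and the fitted
#' curve, the standard visual check that the spline follows the centerline.
#'
#' @param object A `unit_speed_spline`.
#' @param n Curve samples per projection.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.unit_speed_spline <- function(object, n = 400, ...) {
  cur <- tidy(object, n = n)
  inp <- tibble::as_tibble(object$input)
  names(inp) <- c("x", "y", "z")
  proj <- function(df, what) dplyr::bind_rows(
    tibble::tibble(h = df$x, v = df$y, panel = "xy", what = what),
    tibble::tibble(h = df$x, v = df$z, panel = "xz", what = what),
    tibble::tibble(h = df$y, v = df$z, panel = "yz", what = what))
  dat <- dplyr::bind_rows(proj(cur, "spline"), proj(inp, "points"))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$h, y = .data$v)) +
    ggplot2::geom_point(data = dplyr::filter(dat, .data$what == "points"),
                        size = 0.8, colour = "grey40") +
    ggplot2::geom_path(data = dplyr::filter(dat, .data$what == "spline"),
                       colour = "#c0392b") +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
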