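#' Tortuosity metrics from a fitted centerline
#'
#' Four standard metrics of vascular tortuosity, computed from a unit-speed
#' spline and its sampled curvature profile:
#'
#' * **Arc over chord** (AOC, tortuosity index): total arc length L divided
#'   by the straight-line distance between the curve endpoints. >= 1, equal
#'   to 1 only for a straight vessel; insensitive to low-amplitude
#'   high-frequency "wiggle".
#' * **Total curvature** (also called mean curvature in the vascular
#'   literature) `kappa_m = integral of kappa(s) ds`; dimensionless and
#'   scale invariant.
#' * **Mean squared curvature** `kappa_ms = (1/L) integral of kappa(s)^2 ds`
#'   (mm^-2): up-weights sharp bends; *not* scale invariant (scaling every
#'   length by `a` divides it by `a^2`).
#' * **Normalized RMS curvature**
#'   `kappa_rms = L * sqrt((1/L) integral of kappa(s)^2 ds)`: the RMS
#'   curvature rescaled by arc length, which makes it dimensionless and
#'   scale invariant like `kappa_m`. The bare (non-scale-invariant) RMS,
#'   `sqrt((1/L) integral kappa^2 ds)`, is available as an optional column
#'   of [compute_tortuosity()].
#'
#' Integrals use the trapezoidal rule on the profile samples.
#'
#' @param profile A `curvature_profile` from [curvature_profile()].
#' @param spline A `unit_speed_spline`.
#' @return A single numeric value.
#' @examples
#' sp <- fit_unit_speed_spline(make_helix(1, 2 * pi, 1, 200), smoothing = 0)
#' total_curvature(curvature_profile(sp))  # ~ pi * sqrt(2)
#' @name tortuosity-metrics
NULL

#' @rdname tortuosity-metrics
#' @export
arc_over_chord <- function(spline) {
  ends <- predict(spline, c(0, spline$length))
  chord <- sqrt(sum((ends[2, ] - ends[1, ])^2))
  if (chord < 1e-9)
    stop_tortr("chord length is below 1e-9 mm (near-closed curve); arc-over-chord is undefined",
               "degenerate_chord")
  spline$length / chord
}

#' @rdname tortuosity-metrics
#' @export
total_curvature <- function(profile) {
  trapz(profile$s, profile$kappa)
}

#' @rdname tortuosity-metrics
#' @export
mean_squared_curvature <- function(profile) {
  L <- max(profile$s)
  trapz(profile$s, profile$kappa^2) / L
}

#' @rdname tortuosity-metrics
#' @export
rms_curvature <- function(profile) {
  L <- max(profile$s)
  L * sqrt(trapz(profile$s, profile$kappa^2) / L)
}

#' Assemble one per-vessel tortuosity record
#'
#' Computes all four tortuosity metrics plus fit quality and packs them into
#' the one-row tibble written as a CSV line by [run_pipeline()]. As a
#' self-check the curvature integrals are recomputed at twice the sample
#' count; if any metric moves by more than 0.1% an `integration_unstable`
#' warning is recorded.
#'
#' @param spline A `unit_speed_spline`.
#' @param profile Optional `curvature_profile` (recomputed if omitted).
#' @param path Optional `centerline_path`/point set the spline was fit to;
#'   used for the RMSE and for skeleton metadata.
#' @param subject_id,label Identifiers copied into the record.
#' @param warnings Character vector of upstream warnings to record.
#' @param n_samples Curvature samples for the metric integrals.
#' @param bare_rms If `TRUE`, adds the non-scale-invariant bare RMS
#'   curvature (mm^-1) as column `rms_curvature_bare`.
#' @return A `tortuosity_record`: one-row tibble with columns
#'   `subject_id, label, n_skeleton_points, n_endpoints, arc_length_mm,
#'   chord_length_mm, aoc, total_curvature, mean_squared_curvature,
#'   rms_curvature, spline_rmse_mm, combined_quality, warnings`.
#' @export
compute_tortuosity <- function(spline, profile = NULL, path = NULL,
                               subject_id = "", label = NA_integer_,
                               warnings = character(), n_samples = 512,
                               bare_rms = FALSE) {
  if (is.null(profile)) profile <- curvature_profile(spline, n_samples)
  if (!is.null(path)) warnings <- c(warnings, attr(path, "warnings"))
  ends <- predict(spline, c(0, spline$length))
  chord <- sqrt(sum((ends[2, ] - ends[1, ])^2))
  km <- total_curvature(profile)
  kms <- mean_squared_curvature(profile)
  krms <- rms_curvature(profile)
  # integration stability self-check at doubled sampling
  prof2 <- curvature_profile(spline, 2L * nrow(profile))
  rel <- function(a, b) ifelse(pmax(abs(a), abs(b)) < 1e-12, 0,
                               abs(a - b) / pmax(abs(a), abs(b)))
  if (max(rel(km, total_curvature(prof2)),
          rel(kms, mean_squared_curvature(prof2)),
          rel(krms, rms_curvature(prof2))) > 1e-3) {
    warnings <- c(warnings, "integration_unstable")
    warn_tortr("curvature integrals changed by > 0.1% when doubling samples",
               "integration_unstable")
  }
  fq <- fit_quality(spline, points = path, n_samples = nrow(profile))
  out <- tibble::tibble(
    subject_id = subject_id,
    label = as.integer(label),
    n_skeleton_points = if (!is.null(path)) nrow(path) else spline$n_input,
    n_endpoints = if (!is.null(attr(path, "n_endpoints")))
      attr(path, "n_endpoints") else 2L,
    arc_length_mm = spline$length,
    chord_length_mm = chord,
    aoc = arc_over_chord(spline),
    total_curvature = km,
    mean_squared_curvature = kms,
    rms_curvature = krms,
    spline_rmse_mm = fq$rmse,
    combined_quality = fq$combined,
    warnings = paste(unique(warnings), collapse = ";")
  )
  if (bare_rms) out$rms_curvature_bare <- sqrt(kms)
  structure(out, class = c("tortuosity_record", class(out)))
}
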