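#' Run the segmentation-to-CSV tortuosity pipeline
#'
#' Batch driver tying the whole pipeline together: for every input NIfTI
#' labelmap and every requested label, extract the centerline
#' ([extract_centerline()]), fit the unit-speed spline
#' ([fit_unit_speed_spline()]), sample curvature and assemble a
#' [compute_tortuosity()] record. Failures of individual vessels never abort
#' the batch: the affected row carries a stable error code in its `warnings`
#' column (e.g. `label_not_found`, `multi_component`, `loop_topology`) with
#' `NA` metrics, and all other rows are produced normally. The run is
#' deterministic for a fixed configuration.
#'
#' @param input A NIfTI file, a vector of files, or a directory containing
#'   `.nii` / `.nii.gz` files.
#' @param labels Integer vector of target labels (applied to every input).
#' @param smoothing `"auto"` or a fixed non-negative penalty, passed to
#'   [fit_unit_speed_spline()].
#' @param n_samples Curvature samples per vessel.
#' @param keep_largest Keep the largest component of a disconnected mask
#'   (with a warning) instead of failing that vessel.
#' @param out Optional CSV path; written with [readr::write_csv()].
#' @param subject_ids Optional subject ids, one per input file; defaults to
#'   file name stems.
#' @return A tibble with one `tortuosity_record` row per (input, label).
#' @export
run_pipeline <- function(input, labels = 1L, smoothing = "auto",
                         n_samples = 512, keep_largest = FALSE, out = NULL,
                         subject_ids = NULL) {
  files <- input
  if (length(input) == 1 && dir.exists(input))
    files <- sort(list.files(input, pattern = "\\.nii(\\.gz)?$",
                             full.names = TRUE))
  if (length(files) == 0)
    stop_tortr("no NIfTI inputs found", "io")
  missing <- files[!file.exists(files)]
  if (length(missing))
    stop_tortr(paste0("input file not found: ",
                      paste(missing, collapse = ", ")), "io")
  if (length(labels) == 0)
    stop_tortr("label list is empty", "invalid_spec")
  if (is.null(subject_ids))
    subject_ids <- sub("\\.nii(\\.gz)?$", "", basename(files))

  rows <- purrr::map2(files, subject_ids, function(f, sid) {
    vol <- read_labelmap(f)
    purrr::map(labels, function(lab) {
      process_vessel(vol, lab, sid, smoothing = smoothing,
                     n_samples = n_samples, keep_largest = keep_largest)
    })
  })
  res <- dplyr::bind_rows(purrr::flatten(rows))
  if (!is.null(out)) readr::write_csv(res, out)
  res
}

# one vessel; errors become a row with an error code, warnings are collected
process_vessel <- function(vol, label, subject_id, smoothing = "auto",
                           n_samples = 512, keep_largest = FALSE) {
  collected <- character()
  tryCatch(
    withCallingHandlers({
      path <- extract_centerline(vol, label, keep_largest = keep_largest)
      sp <- fit_unit_speed_spline(path, smoothing = smoothing)
      prof <- curvature_profile(sp, n_samples)
      compute_tortuosity(sp, prof, path, subject_id = subject_id,
                         label = label, warnings = collected)
    },
    warning = function(w) {
      collected <<- c(collected, error_code(w))
      invokeRestart("muffleWarning")
    }),
    error = function(e) {
      tibble::tibble(
        subject_id = subject_id, label = as.integer(label),
        n_skeleton_points = NA_integer_, n_endpoints = NA_integer_,
        arc_length_mm = NA_real_, chord_length_mm = NA_real_,
        aoc = NA_real_, total_curvature = NA_real_,
        mean_squared_curvature = NA_real_, rms_curvature = NA_real_,
        spline_rmse_mm = NA_real_, combined_quality = NA_real_,
        warnings = paste(unique(c(collected, error_code(e))), collapse = ";"))
    })
}

# stable short codes derived from the tortr_* condition classes
error_code <- function(cond) {
  cls <- class(cond)
  tcls <- grep("^tortr_", cls, value = TRUE)
  tcls <- setdiff(tcls, c("tortr_error", "tortr_warning"))
  if (length(tcls) == 0) return("internal_error")
  code <- sub("^tortr_", "", tcls[1])
  if (code == "empty_structure" &&
      grepl("label .* not present", conditionMessage(cond)))
    code <- "label_not_found"
  code
}

#' Flag low-quality fits in a metrics CSV
#'
#' Reads a CSV produced by [run_pipeline()] (or the equivalent tibble) and
#' returns the rows whose spline RMSE or combined quality score exceeds the
#' given thresholds, plus rows that failed outright — the vessels a reader
#' should review before trusting the metrics.
#'
#' @param csv Path to a metrics CSV, or the tibble itself.
#' @param rmse_max Maximum acceptable spline RMSE (mm).
#' @param combined_max Maximum acceptable combined quality score.
#' @return A tibble of flagged rows with a `flag_reason` column (empty when
#'   everything passes).
#' @export
validate_report <- function(csv, rmse_max = Inf, combined_max = Inf) {
  df <- if (is.character(csv)) {
    if (!file.exists(csv)) stop_tortr(paste0("CSV not found: ", csv), "io")
    tryCatch(readr::read_csv(csv, show_col_types = FALSE),
             error = function(e) stop_tortr(
               paste0("malformed CSV: ", conditionMessage(e)), "parse"))
  } else tibble::as_tibble(csv)
  needed <- c("subject_id", "label", "spline_rmse_mm", "combined_quality")
  if (nrow(df) == 0 || !all(needed %in% names(df)))
    stop_tortr("CSV is empty or missing pipeline columns", "parse")
  df |>
    dplyr::mutate(flag_reason = dplyr::case_when(
      is.na(.data$spline_rmse_mm) ~ "failed_vessel",
      .data$spline_rmse_mm > rmse_max ~ "rmse_above_threshold",
      .data$combined_quality > combined_max ~ "combined_above_threshold",
      TRUE ~ NA_character_)) |>
    dplyr::filter(!is.na(.data$flag_reason))
}

#' Read a flat key-value configuration file
#'
#' Lines of the form `key = value` (or `key: value`); `#` comments and blank
#' lines ignored. Values given on the command line override the file. Used
#' by the shipped `tortr` CLI; exported so scripted runs can share configs.
#'
#' @param path Path to the config file.
#' @return Named list of character values.
#' @export
read_config <- function(path) {
  if (!file.exists(path))
    stop_tortr(paste0("config file not found: ", path), "io")
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^([^=:]+)[=:](.*)$", lines))
  bad <- lengths(kv) != 3
  if (any(bad))
    stop_tortr(paste0("malformed config line: ", lines[bad][1]), "parse")
  stats::setNames(lapply(kv, function(m) trimws(m[3])),
                  vapply(kv, function(m) trimws(m[2]), character(1)))
}
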