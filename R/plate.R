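#' Compute survival indices from a well table
#'
#' The survival index (SI) of a test well is its fluorescence as a
#' percentage of the plate's control wells after blank subtraction:
#' `si = 100 * (F_test - mean_blank) / (mean_control - mean_blank)`,
#' with the blank and control means taken per plate. Replicate test wells of
#' the same compound, concentration and line/sample are averaged *after* SI
#' computation, so per-well volume differences cancel. SI is not clipped:
#' values above 100 (stimulation) and below 0 are preserved.
#'
#' @param wells Tibble of wells with columns `plate_id`, `role`
#'   (`test`/`control`/`blank`), `compound_id`, `concentration_uM`,
#'   `line_or_sample_id`, `fluorescence`, as produced by
#'   [generate_screen()] or read with [read_plate_csv()].
#' @return Tibble with columns `compound_id`, `concentration_uM`,
#'   `line_or_sample_id`, `si` (percent), `n_wells`.
#' @export
#' @examples
#' scr <- generate_screen(screen_scenario(n_compounds = 10, noise_cv = 0, seed = 1))
#' compute_si(scr$wells)
compute_si <- function(wells) {
  wells <- .check_wells(wells)
  refs <- wells %>%
    dplyr::group_by(.data$plate_id) %>%
    dplyr::summarise(
      mean_blank = mean(.data$fluorescence[.data$role == "blank"]),
      mean_control = mean(.data$fluorescence[.data$role == "control"]),
      .groups = "drop"
    )
  bad <- refs %>% dplyr::filter(.data$mean_control <= .data$mean_blank)
  if (nrow(bad) > 0) {
    abort(paste0(
      "degenerate plate(s): mean control fluorescence does not exceed mean blank: ",
      paste(bad$plate_id, collapse = ", ")
    ))
  }
  wells %>%
    dplyr::filter(.data$role == "test") %>%
    dplyr::left_join(refs, by = "plate_id") %>%
    dplyr::mutate(
      si = 100 * (.data$fluorescence - .data$mean_blank) /
        (.data$mean_control - .data$mean_blank)
    ) %>%
    dplyr::group_by(.data$compound_id, .data$concentration_uM,
                    .data$line_or_sample_id) %>%
    dplyr::summarise(si = mean(.data$si), n_wells = dplyr::n(),
                     .groups = "drop")
}

#' Quality-control a set of plates
#'
#' A plate passes when the coefficient of variation of its control-well
#' fluorescence is below 30% and the control/blank signal ratio exceeds the
#' assay-specific threshold: 10-fold for cell-line plates, 5-fold for
#' primary-culture plates. Both inequalities are strict, so boundary plates
#' fail. Plates with zero mean blank report an infinite ratio and satisfy
#' the ratio criterion. Failing plates are flagged, never dropped.
#'
#' @param wells Well tibble (see [compute_si()]).
#' @param assay_kind `"cell_line"` or `"primary_culture"`; sets the
#'   signal-to-blank threshold (10 or 5).
#' @return Tibble with one row per plate: `plate_id`, `control_cv`,
#'   `signal_to_blank`, `passed`, `reasons` (semicolon-joined failure
#'   reasons, `""` when passed).
#' @export
qc_plates <- function(wells, assay_kind = c("cell_line", "primary_culture")) {
  assay_kind <- match.arg(assay_kind)
  wells <- .check_wells(wells)
  threshold <- if (assay_kind == "cell_line") 10 else 5
  wells %>%
    dplyr::group_by(.data$plate_id) %>%
    dplyr::summarise(
      control_cv = sd(.data$fluorescence[.data$role == "control"]) /
        mean(.data$fluorescence[.data$role == "control"]),
      signal_to_blank = {
        mb <- mean(.data$fluorescence[.data$role == "blank"])
        mc <- mean(.data$fluorescence[.data$role == "control"])
        if (mb == 0) Inf else mc / mb
      },
      .groups = "drop"
    ) %>%
    dplyr::mutate(
      cv_ok = .data$control_cv < 0.30,
      ratio_ok = .data$signal_to_blank > threshold,
      passed = .data$cv_ok & .data$ratio_ok,
      reasons = purrr::map2_chr(.data$cv_ok, .data$ratio_ok, function(cv, ra) {
        r <- c(
          if (!cv) "control CV not below 30%",
          if (!ra) sprintf("control/blank signal ratio not above %g", threshold)
        )
        paste(r, collapse = "; ")
      })
    ) %>%
    dplyr::select("plate_id", "control_cv", "signal_to_blank",
                  "passed", "reasons")
}

.check_wells <- function(wells) {
  wells <- tibble::as_tibble(wells)
  req <- c("plate_id", "role", "compound_id", "concentration_uM",
           "line_or_sample_id", "fluorescence")
  missing <- setdiff(req, names(wells))
  if (length(missing) > 0) {
    abort(paste("well table lacks column(s):", paste(missing, collapse = ", ")))
  }
  if (!all(wells$role %in% c("test", "control", "blank"))) {
    abort("`role` must be one of 'test', 'control', 'blank'.")
  }
  if (any(wells$fluorescence < 0)) abort("fluorescence values must be >= 0.")
  counts <- wells %>%
    dplyr::count(.data$plate_id, .data$role) %>%
    tidyr::pivot_wider(names_from = "role", values_from = "n", values_fill = 0L)
  if (!"control" %in% names(counts)) counts$control <- 0L
  if (!"blank" %in% names(counts)) counts$blank <- 0L
  bad <- counts %>% dplyr::filter(.data$control < 2 | .data$blank < 1)
  if (nrow(bad) > 0) {
    abort(paste0(
      "each plate needs >= 2 control and >= 1 blank wells; offending plate(s): ",
      paste(bad$plate_id, collapse = ", ")
    ))
  }
  wells
}
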