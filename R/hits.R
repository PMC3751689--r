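#' Call differential-cytotoxicity hits between a resistant line and its parent
#'
#' A compound qualifies as a hit when its survival index is *below* the
#' threshold (default 50%) in the resistant line and *above* it in the
#' parental line — both inequalities strict, so SI exactly at the threshold
#' never qualifies. Selectivity is reported as `si_parental - si_resistant`
#' in percentage points and the hit list is sorted by descending
#' selectivity. Compounds scored in only one of the two lines are excluded
#' with a warning, never imputed.
#'
#' @param si_table SI tibble from [compute_si()] (columns `compound_id`,
#'   `line_or_sample_id`, `si`; a `concentration_uM` column, if present with
#'   several values, must be pre-filtered to the screen concentration).
#' @param resistant_line,parental_line Cell-line labels in
#'   `line_or_sample_id`.
#' @param threshold SI threshold in percent (default 50).
#' @return Tibble of class `mdr_hits` with columns `compound_id`,
#'   `si_resistant`, `si_parental`, `selectivity`, `is_hit`, sorted by
#'   descending selectivity. The line labels are stored in attributes
#'   `resistant_line` / `parental_line`.
#' @export
#' @examples
#' scr <- generate_screen(screen_scenario(n_compounds = 100, seed = 1))
#' hits <- compute_si(scr$wells) |>
#'   call_hits("8226/Dox40", "RPMI 8226")
#' dplyr::filter(hits, is_hit)
call_hits <- function(si_table, resistant_line, parental_line, threshold = 50) {
  si_table <- tibble::as_tibble(si_table)
  stopifnot(all(c("compound_id", "line_or_sample_id", "si") %in% names(si_table)))
  if ("concentration_uM" %in% names(si_table) &&
      dplyr::n_distinct(si_table$concentration_uM) > 1) {
    abort("several concentrations present; filter to the screen concentration first.")
  }
  wide <- si_table %>%
    dplyr::filter(.data$line_or_sample_id %in% c(resistant_line, parental_line)) %>%
    dplyr::select("compound_id", "line_or_sample_id", "si") %>%
    tidyr::pivot_wider(names_from = "line_or_sample_id", values_from = "si")
  for (ln in c(resistant_line, parental_line)) {
    if (!ln %in% names(wide)) wide[[ln]] <- NA_real_
  }
  incomplete <- wide %>%
    dplyr::filter(is.na(.data[[resistant_line]]) | is.na(.data[[parental_line]]))
  if (nrow(incomplete) > 0) {
    warn(sprintf(
      "%d compound(s) scored in only one line were excluded (e.g. %s)",
      nrow(incomplete), incomplete$compound_id[1]
    ))
  }
  out <- wide %>%
    dplyr::filter(!is.na(.data[[resistant_line]]) &
                    !is.na(.data[[parental_line]])) %>%
    dplyr::transmute(
      compound_id = .data$compound_id,
      si_resistant = .data[[resistant_line]],
      si_parental = .data[[parental_line]],
      selectivity = .data$si_parental - .data$si_resistant,
      is_hit = .data$si_resistant < threshold & .data$si_parental > threshold
    ) %>%
    dplyr::arrange(dplyr::desc(.data$selectivity))
  attr(out, "resistant_line") <- resistant_line
  attr(out, "parental_line") <- parental_line
  attr(out, "threshold") <- threshold
  class(out) <- c("mdr_hits", class(out))
  out
}

#' Profile a compound against a panel of paired resistance lines
#'
#' Counter-screen summary across a resistance cell-line panel: each
#' resistant line is paired with its declared parental line and the
#' compound's per-pair selectivity (`si_parental - si_resistant`, percentage
#' points) decides a cross-resistance verdict. A pair is
#' `"insensitive"` to its resistance mechanism when the resistant line is at
#' most `tolerance` percentage points less affected than the parent
#' (`si_resistant <= si_parental + tolerance`), else `"cross_resistant"`.
#' Pairs with missing line data are omitted with a warning.
#'
#' @param si_table SI tibble (columns `compound_id`, `line_or_sample_id`,
#'   `si`).
#' @param pairing Tibble with columns `resistant_line`, `parental_line`,
#'   `mechanism`.
#' @param tolerance Cross-resistance tolerance in percentage points
#'   (default 10).
#' @return Tibble with one row per compound x pair: `compound_id`,
#'   `mechanism`, `resistant_line`, `parental_line`, `si_resistant`,
#'   `si_parental`, `selectivity`, `verdict`.
#' @export
panel_profile <- function(si_table, pairing, tolerance = 10) {
  si_table <- tibble::as_tibble(si_table)
  pairing <- tibble::as_tibble(pairing)
  stopifnot(all(c("resistant_line", "parental_line", "mechanism") %in% names(pairing)))
  si_lookup <- si_table %>%
    dplyr::select("compound_id", "line_or_sample_id", "si")
  out <- purrr::pmap_dfr(pairing, function(resistant_line, parental_line, mechanism, ...) {
    res <- si_lookup %>% dplyr::filter(.data$line_or_sample_id == resistant_line)
    par <- si_lookup %>% dplyr::filter(.data$line_or_sample_id == parental_line)
    if (nrow(res) == 0 || nrow(par) == 0) {
      warn(sprintf("pair %s / %s omitted: missing line data", resistant_line, parental_line))
      return(NULL)
    }
    dplyr::inner_join(
      res %>% dplyr::select("compound_id", si_resistant = "si"),
      par %>% dplyr::select("compound_id", si_parental = "si"),
      by = "compound_id"
    ) %>%
      dplyr::mutate(
        mechanism = mechanism,
        resistant_line = resistant_line,
        parental_line = parental_line,
        selectivity = .data$si_parental - .data$si_resistant,
        verdict = ifelse(.data$si_resistant <= .data$si_parental + tolerance,
                         "insensitive", "cross_resistant")
      ) %>%
      dplyr::select("compound_id", "mechanism", "resistant_line",
                    "parental_line", "si_resistant", "si_parental",
                    "selectivity", "verdict")
  })
  out
}
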