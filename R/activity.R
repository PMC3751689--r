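#' Concentration of maximal survival-index dispersion
#'
#' The ex vivo reference concentration for response-rate calculations is
#' the tested concentration at which the standard deviation of SI across
#' tumor samples is largest — where the panel discriminates best between
#' sensitive and resistant samples. Normal (PBMC-like) samples are
#' excluded. Ties, including the all-equal degenerate case, resolve to the
#' lower concentration with a warning.
#'
#' @param panel_si Long panel tibble with columns `sample_id`, `category`,
#'   `concentration_uM`, `si`.
#' @return The selected concentration (uM).
#' @export
select_reference_concentration <- function(panel_si) {
  panel_si <- tibble::as_tibble(panel_si)
  tumor <- panel_si %>% dplyr::filter(.data$category != "normal")
  if (nrow(tumor) == 0) abort("no tumor samples in the panel.")
  grids <- tumor %>%
    dplyr::group_by(.data$sample_id) %>%
    dplyr::summarise(grid = paste(sort(.data$concentration_uM), collapse = ","),
                     .groups = "drop")
  if (dplyr::n_distinct(grids$grid) > 1) {
    ref_grid <- names(sort(table(grids$grid), decreasing = TRUE))[1]
    offenders <- grids$sample_id[grids$grid != ref_grid]
    abort(paste0("samples tested on differing concentration grids: ",
                 paste(offenders, collapse = ", ")))
  }
  sds <- tumor %>%
    dplyr::group_by(.data$concentration_uM) %>%
    dplyr::summarise(sd_si = sd(.data$si), .groups = "drop") %>%
    dplyr::arrange(.data$concentration_uM)
  best <- max(sds$sd_si)
  winners <- sds$concentration_uM[sds$sd_si == best]
  if (length(winners) > 1 || best == 0) {
    warn("tied (or zero) SI dispersion across concentrations; returning the lowest.")
  }
  winners[1]
}

#' Per-diagnosis response rates at a reference concentration
#'
#' The overall median SI is computed over *all tumor samples* (normals
#' excluded) at the reference concentration; a sample responds when its SI
#' is strictly below that median — samples exactly at the median are
#' non-responders. Response rate per diagnosis is the fraction of its
#' samples responding. Diagnoses with zero samples are absent from the
#' output.
#'
#' @param panel_si Long panel tibble (`sample_id`, `diagnosis`, `category`,
#'   `concentration_uM`, `si`).
#' @param reference_concentration Concentration (uM) present on every
#'   sample's grid; see [select_reference_concentration()].
#' @return List of class `response_rates`: `reference_concentration`,
#'   `overall_median_si`, `n_tumor`, and `rates` — a tibble `diagnosis`,
#'   `category`, `n`, `n_responders`, `response_rate`.
#' @export
response_rates <- function(panel_si, reference_concentration) {
  panel_si <- tibble::as_tibble(panel_si)
  at_ref <- panel_si %>%
    dplyr::filter(.data$concentration_uM == reference_concentration)
  if (nrow(at_ref) == 0) abort("reference concentration not on the panel grid.")
  tumor <- at_ref %>% dplyr::filter(.data$category != "normal")
  overall_median <- median(tumor$si)
  rates <- tumor %>%
    dplyr::group_by(.data$diagnosis, .data$category) %>%
    dplyr::summarise(
      n = dplyr::n(),
      n_responders = sum(.data$si < overall_median),
      response_rate = .data$n_responders / .data$n,
      .groups = "drop"
    )
  structure(
    list(
      reference_concentration = reference_concentration,
      overall_median_si = overall_median,
      n_tumor = nrow(tumor),
      rates = rates
    ),
    class = "response_rates"
  )
}

#' @export
print.response_rates <- function(x, ...) {
  cat(sprintf(
    "<response_rates> %d tumor samples at %g uM; overall median SI %.1f\n",
    x$n_tumor, x$reference_concentration, x$overall_median_si
  ))
  print(x$rates)
  invisible(x)
}

#' @rdname response_rates
#' @param x A `response_rates` object.
#' @param ... Unused.
#' @method tidy response_rates
#' @export
tidy.response_rates <- function(x, ...) x$rates

#' Solid-to-hematological activity ratio
#'
#' The S/H ratio compares a drug's pooled response rate in solid-tumor
#' samples to that in hematological samples: responders among solid samples
#' over n solid, divided by the same for hematological — pooled at the
#' sample level, not averaged over diagnoses. A ratio below 1 indicates
#' preferential activity against hematological malignancies. Responder
#' status uses the strictly-below-overall-median rule of
#' [response_rates()]. A zero hematological rate yields `Inf` with a
#' warning.
#'
#' @inheritParams response_rates
#' @return Single numeric ratio.
#' @export
sh_ratio <- function(panel_si, reference_concentration) {
  panel_si <- tibble::as_tibble(panel_si)
  at_ref <- panel_si %>%
    dplyr::filter(.data$concentration_uM == reference_concentration,
                  .data$category != "normal")
  if (!all(c("solid", "hematological") %in% at_ref$category)) {
    abort("both solid and hematological samples are required.")
  }
  overall_median <- median(at_ref$si)
  pooled <- at_ref %>%
    dplyr::group_by(.data$category) %>%
    dplyr::summarise(rate = mean(.data$si < overall_median), .groups = "drop")
  s <- pooled$rate[pooled$category == "solid"]
  h <- pooled$rate[pooled$category == "hematological"]
  if (h == 0) {
    warn("hematological response rate is 0; S/H ratio is infinite.")
    return(Inf)
  }
  s / h
}

#' Normal-vs-tumor specificity ratio of censored median IC50s
#'
#' Ratio of the median IC50 in normal PBMC samples over that in CLL
#' samples; values above 1 indicate preferential activity against the
#' malignant cells. Medians are censored medians ([median_ic50()]). A
#' censored numerator propagates (`"> bound/denominator"`); a censored
#' denominator makes the ratio uninterpretable and is an error.
#'
#' @param ic50_table Tibble with columns `diagnosis`, `ic50`, `censor`
#'   (e.g. from [fit_dose_response()] joined to sample annotation).
#' @param normal_diagnosis,reference_diagnosis Diagnosis labels of the
#'   numerator (normal) and denominator (tumor) groups.
#' @return List with `value`, `censor`, `label` as in [median_ic50()].
#' @export
#' @examples
#' tbl <- tibble::tibble(
#'   diagnosis = c("PBMC", "PBMC", "CLL", "CLL", "CLL"),
#'   ic50 = c(15, 17, 1.5, 2.0, 2.5),
#'   censor = "none"
#' )
#' specificity_ratio(tbl)$value  # 8
specificity_ratio <- function(ic50_table, normal_diagnosis = "PBMC",
                              reference_diagnosis = "CLL") {
  ic50_table <- tibble::as_tibble(ic50_table)
  stopifnot(all(c("diagnosis", "ic50", "censor") %in% names(ic50_table)))
  pick <- function(dx) ic50_table %>% dplyr::filter(.data$diagnosis == dx)
  num_tbl <- pick(normal_diagnosis)
  den_tbl <- pick(reference_diagnosis)
  if (nrow(num_tbl) == 0 || nrow(den_tbl) == 0) {
    abort("both the normal and the reference diagnosis need at least one IC50.")
  }
  num <- median_ic50(num_tbl$ic50, num_tbl$censor)
  den <- median_ic50(den_tbl$ic50, den_tbl$censor)
  if (den$censor != "none") {
    abort("censored denominator median: specificity ratio is uninterpretable.")
  }
  ratio <- num$value / den$value
  list(value = ratio, censor = num$censor,
       label = censored_label(ratio, num$censor))
}

#' Hollow-fiber net growth
#'
#' Percent change in fiber cell density over the in vivo period:
#' `(OD retrieval - OD implantation) / OD implantation * 100`, from optical
#' density read at 570 nm.
#'
#' @param od_implantation,od_retrieval Optical densities; implantation OD
#'   must be positive.
#' @return Net growth in percent (vectorized).
#' @export
#' @examples
#' net_growth(0.4, 0.8)  # 100
net_growth <- function(od_implantation, od_retrieval) {
  if (any(od_implantation <= 0)) abort("implantation OD must be positive.")
  (od_retrieval - od_implantation) / od_implantation * 100
}

#' Compare net growth between two dose groups
#'
#' Two-sample Student's t-test (pooled variance, two-sided) on per-fiber
#' net growth. Groups with fewer than two animals refuse the test (net
#' growth itself is still computable with [net_growth()]).
#'
#' @param records Tibble with columns `dose_group` and either `net_growth`
#'   or both `od_implantation` and `od_retrieval`.
#' @param group_a,group_b Labels in `dose_group`.
#' @return One-row tibble: `group_a`, `group_b`, `mean_a`, `mean_b`,
#'   `difference`, `statistic`, `df`, `p_value`, `n_a`, `n_b`.
#' @export
compare_net_growth <- function(records, group_a, group_b) {
  records <- tibble::as_tibble(records)
  if (!"net_growth" %in% names(records)) {
    stopifnot(all(c("od_implantation", "od_retrieval") %in% names(records)))
    records <- records %>%
      dplyr::mutate(net_growth = net_growth(.data$od_implantation,
                                            .data$od_retrieval))
  }
  a <- records$net_growth[records$dose_group == group_a]
  b <- records$net_growth[records$dose_group == group_b]
  if (length(a) < 2 || length(b) < 2) {
    abort("each group needs at least 2 animals for the t-test.")
  }
  tt <- t.test(a, b, var.equal = TRUE)
  tibble::tibble(
    group_a = group_a, group_b = group_b,
    mean_a = mean(a), mean_b = mean(b),
    difference = mean(a) - mean(b),
    statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p_value = tt$p.value,
    n_a = length(a), n_b = length(b)
  )
}

#' Full ex vivo activity report
#'
#' One-call summary of a drug's ex vivo profile: reference concentration
#' (maximal SI dispersion), overall median SI, per-diagnosis response
#' rates, pooled S/H ratio and — when an IC50 table is supplied — the
#' PBMC/CLL specificity ratio.
#'
#' @inheritParams response_rates
#' @param ic50_table Optional IC50 tibble for [specificity_ratio()].
#' @param reference_concentration Optional; selected automatically when
#'   `NULL`.
#' @return List of class `activity_report`.
#' @export
activity_report <- function(panel_si, ic50_table = NULL,
                            reference_concentration = NULL) {
  if (is.null(reference_concentration)) {
    reference_concentration <- select_reference_concentration(panel_si)
  }
  rr <- response_rates(panel_si, reference_concentration)
  sh <- sh_ratio(panel_si, reference_concentration)
  spec <- if (!is.null(ic50_table) &&
              all(c("PBMC", "CLL") %in% ic50_table$diagnosis)) {
    specificity_ratio(ic50_table)
  } else NULL
  structure(
    list(
      reference_concentration = reference_concentration,
      overall_median_si = rr$overall_median_si,
      response_rates = rr$rates,
      sh_ratio = sh,
      specificity_ratio = spec
    ),
    class = "activity_report"
  )
}

#' @export
print.activity_report <- function(x, ...) {
  cat(sprintf(
    "<activity_report> reference %g uM | overall median SI %.1f | S/H ratio %.3g\n",
    x$reference_concentration, x$overall_median_si, x$sh_ratio
  ))
  if (!is.null(x$specificity_ratio)) {
    cat("  PBMC/CLL specificity ratio:", x$specificity_ratio$label, "\n")
  }
  print(x$response_rates)
  invisible(x)
}

#' @rdname activity_report
#' @param x An `activity_report`.
#' @param ... Unused.
#' @method glance activity_report
#' @export
glance.activity_report <- function(x, ...) {
  tibble::tibble(
    reference_concentration = x$reference_concentration,
    overall_median_si = x$overall_median_si,
    sh_ratio = x$sh_ratio,
    specificity_ratio = if (is.null(x$specificity_ratio)) NA_real_
                        else x$specificity_ratio$value,
    specificity_label = if (is.null(x$specificity_ratio)) NA_character_
                        else x$specificity_ratio$label
  )
}
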