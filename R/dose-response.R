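# Four-parameter logistic survival curve,
#   si(c) = bottom + (top - bottom) / (1 + 10^((log10 c - log10 midpoint) * hill)),
# so a positive hill slope gives survival decreasing with concentration and
# the midpoint is the curve inflection (relative EC50). The primary potency
# readout is the *absolute* IC50: the concentration where the fitted curve
# crosses SI = 50, which coincides with the midpoint only when
# (top + bottom)/2 = 50.

#' Fit a sigmoidal dose-response curve
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt via
#' \pkg{minpack.lm}) of the four-parameter logistic survival model, with
#' multi-start initialization: top/bottom start at the observed extremes,
#' the midpoint at the concentration bracketing the 50% crossing by linear
#' interpolation on log-concentration, hill at 1; additional starts jitter
#' the log-midpoint. Curves with all-identical SI return a degenerate flat
#' fit (`hill = 0` convention, censored IC50, `converged = TRUE`).
#'
#' @param concentration Tested concentrations, uM; at least 4 distinct
#'   strictly positive values.
#' @param si Survival indices (percent), same length.
#' @param constrain If `TRUE`, fix `top = 100` and `bottom = 0` (two-
#'   parameter fit).
#' @param lower,upper Parameter bounds, named `top`, `bottom`, `hill`,
#'   `log10_mid`. Defaults: top in \[50, 150\], bottom in \[-10, 50\], hill
#'   in \[0.1, 10\], log10 midpoint within 2 decades of the tested range.
#' @param n_starts Number of multi-start fits (default 5).
#' @return Object of class `dr_fit`: a list with elements `top`, `bottom`,
#'   `hill`, `midpoint`, `ic50` (numeric bound), `censor` (`"none"`,
#'   `"above_max"`, `"below_min"`), `ic50_label` (e.g. `">40"`),
#'   `residual_sse`, `converged`, `n`, `c_min`, `c_max` and the input
#'   `data`. Use [tidy()] / [glance()] or [ic50_absolute()].
#' @export
#' @examples
#' conc <- c(0.004, 0.04, 0.4, 4, 40)
#' si <- 0 + (100 - 0) / (1 + 10^((log10(conc) - log10(1)) * 1))
#' fit <- fit_sigmoid(conc, si)
#' glance(fit)
fit_sigmoid <- function(concentration, si, constrain = FALSE,
                        lower = NULL, upper = NULL, n_starts = 5) {
  stopifnot(length(concentration) == length(si), all(is.finite(si)))
  if (any(concentration <= 0)) abort("concentrations must be strictly positive.")
  if (dplyr::n_distinct(concentration) < 4) {
    abort("at least 4 distinct concentrations are required.")
  }
  c_min <- min(concentration)
  c_max <- max(concentration)
  n <- length(si)

  if (dplyr::n_distinct(si) == 1) {
    # flat curve: no information about the midpoint
    level <- si[1]
    censor <- if (level >= 50) "above_max" else "below_min"
    return(.new_dr_fit(
      top = level, bottom = level, hill = 0, midpoint = NA_real_,
      censor = censor, residual_sse = 0, converged = TRUE,
      concentration = concentration, si = si, c_min = c_min, c_max = c_max
    ))
  }

  lo <- c(top = 50, bottom = -10, hill = 0.1,
          log10_mid = log10(c_min) - 2)
  hi <- c(top = 150, bottom = 50, hill = 10,
          log10_mid = log10(c_max) + 2)
  if (!is.null(lower)) lo[names(lower)] <- lower
  if (!is.null(upper)) hi[names(upper)] <- upper

  top0 <- min(max(max(si), lo["top"]), hi["top"])
  bot0 <- min(max(min(si), lo["bottom"]), hi["bottom"])
  mid0 <- .interp_crossing(concentration, si)
  mid0 <- min(max(mid0, lo["log10_mid"]), hi["log10_mid"])
  jitters <- seq(-1, 1, length.out = n_starts)

  dat <- data.frame(conc = concentration, si = si)
  best <- NULL
  for (j in jitters) {
    start <- list(top = unname(top0), bottom = unname(bot0),
                  hill = 1, log10_mid = unname(mid0) + j)
    start$log10_mid <- min(max(start$log10_mid, lo["log10_mid"]), hi["log10_mid"])
    fit <- if (constrain) {
      try(suppressWarnings(minpack.lm::nlsLM(
        si ~ 100 / (1 + 10^((log10(conc) - log10_mid) * hill)),
        data = dat, start = start[c("hill", "log10_mid")],
        lower = unname(lo[c("hill", "log10_mid")]),
        upper = unname(hi[c("hill", "log10_mid")]),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      )), silent = TRUE)
    } else {
      try(suppressWarnings(minpack.lm::nlsLM(
        si ~ bottom + (top - bottom) / (1 + 10^((log10(conc) - log10_mid) * hill)),
        data = dat, start = start,
        lower = unname(lo), upper = unname(hi),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      )), silent = TRUE)
    }
    if (inherits(fit, "try-error")) next
    sse <- sum(stats::residuals(fit)^2)
    if (is.null(best) || sse < best$sse - 1e-12) {
      best <- list(fit = fit, sse = sse)
    }
  }

  if (is.null(best)) {
    return(.new_dr_fit(
      top = NA_real_, bottom = NA_real_, hill = NA_real_, midpoint = NA_real_,
      censor = "above_max", residual_sse = NA_real_, converged = FALSE,
      concentration = concentration, si = si, c_min = c_min, c_max = c_max
    ))
  }

  cf <- coef(best$fit)
  top <- if (constrain) 100 else unname(cf["top"])
  bottom <- if (constrain) 0 else unname(cf["bottom"])
  out <- .new_dr_fit(
    top = top, bottom = bottom, hill = unname(cf["hill"]),
    midpoint = 10^unname(cf["log10_mid"]),
    censor = "none", residual_sse = best$sse, converged = TRUE,
    concentration = concentration, si = si, c_min = c_min, c_max = c_max
  )
  ic <- ic50_absolute(out, c_min, c_max)
  out$ic50 <- ic$value
  out$censor <- ic$censor
  out$ic50_label <- ic$label
  out
}

# initial log10 midpoint: linear interpolation of the 50% crossing on
# (log10 c, si); falls back to the mid log-range when the curve never crosses
.interp_crossing <- function(concentration, si) {
  o <- order(concentration)
  lc <- log10(concentration[o])
  s <- si[o]
  cross <- which(diff(sign(s - 50)) != 0)
  if (length(cross) > 0) {
    i <- cross[1]
    if (s[i + 1] == s[i]) return(lc[i])
    lc[i] + (50 - s[i]) * (lc[i + 1] - lc[i]) / (s[i + 1] - s[i])
  } else {
    mean(range(lc))
  }
}

.new_dr_fit <- function(top, bottom, hill, midpoint, censor, residual_sse,
                        converged, concentration, si, c_min, c_max) {
  fit <- structure(
    list(
      top = top, bottom = bottom, hill = hill, midpoint = midpoint,
      ic50 = NA_real_, censor = censor, ic50_label = NA_character_,
      residual_sse = residual_sse, converged = converged,
      n = length(si), c_min = c_min, c_max = c_max,
      data = tibble::tibble(concentration = concentration, si = si)
    ),
    class = "dr_fit"
  )
  fit$ic50 <- if (censor == "above_max") c_max else if (censor == "below_min") c_min else NA_real_
  fit$ic50_label <- censored_label(fit$ic50, censor)
  fit
}

#' Absolute IC50 of a fitted curve, with censoring
#'
#' Solves the fitted four-parameter logistic model for SI = 50 — the
#' *absolute* IC50, not the concentration relative to the asymptotes. When
#' the curve never reaches 50% within the fitted asymptotes or the solution
#' falls outside the tested range `[c_min, c_max]`, the IC50 is censored:
#' `above_max` (reported `"> c_max"`) when survival stays above 50, and
#' `below_min` (`"< c_min"`) when it stays below.
#'
#' @param fit A `dr_fit` from [fit_sigmoid()].
#' @param c_min,c_max Tested concentration range; defaults to the fitted
#'   curve's range.
#' @return List with elements `value` (numeric: the IC50, or the censoring
#'   bound), `censor` (`"none"`, `"above_max"`, `"below_min"`) and `label`
#'   (e.g. `"2.1"`, `">40"`).
#' @export
ic50_absolute <- function(fit, c_min = fit$c_min, c_max = fit$c_max) {
  stopifnot(inherits(fit, "dr_fit"))
  if (!fit$converged) abort("cannot extract an IC50 from a non-converged fit.")
  censored <- function(censor) {
    value <- if (censor == "above_max") c_max else c_min
    list(value = value, censor = censor, label = censored_label(value, censor))
  }
  if (is.na(fit$hill) || fit$hill == 0 || is.na(fit$midpoint)) {
    lvl <- (fit$top + fit$bottom) / 2
    return(censored(if (lvl >= 50) "above_max" else "below_min"))
  }
  if (fit$bottom >= 50) return(censored("above_max"))
  if (fit$top <= 50) return(censored("below_min"))
  log10_ic50 <- log10(fit$midpoint) +
    log10((fit$top - 50) / (50 - fit$bottom)) / fit$hill
  ic50 <- 10^log10_ic50
  if (ic50 > c_max) return(censored("above_max"))
  if (ic50 < c_min) return(censored("below_min"))
  list(value = ic50, censor = "none", label = censored_label(ic50, "none"))
}

#' Format a possibly-censored concentration
#'
#' @param value Numeric value or censoring bound.
#' @param censor `"none"`, `"above_max"` or `"below_min"`.
#' @param digits Significant digits for the printed number (default 3).
#' @return Character: `"2.18"`, `">34"` or `"<0.004"` (comparator + number,
#'   no spaces).
#' @export
censored_label <- function(value, censor, digits = 3) {
  prefix <- c(none = "", above_max = ">", below_min = "<")[censor]
  paste0(prefix, format(signif(value, digits), trim = TRUE, scientific = FALSE))
}

#' Fit dose-response curves over a long SI table
#'
#' Groups a long table of (concentration, SI) points by compound and
#' line/sample, fits each curve with [fit_sigmoid()] and collects the
#' per-curve parameter and IC50 summaries.
#'
#' @param data Tibble with columns `concentration_uM`, `si` and any of
#'   `compound_id`, `sample_id`, `line_or_sample_id` as grouping keys.
#' @param ... Passed to [fit_sigmoid()].
#' @return Tibble with one row per curve: the grouping keys, `top`,
#'   `bottom`, `hill`, `midpoint`, `ic50`, `censor`, `ic50_label`,
#'   `residual_sse`, `converged`, `n`, and a `fit` list-column of `dr_fit`
#'   objects.
#' @export
fit_dose_response <- function(data, ...) {
  data <- tibble::as_tibble(data)
  stopifnot(all(c("concentration_uM", "si") %in% names(data)))
  keys <- intersect(c("compound_id", "sample_id", "line_or_sample_id",
                      "diagnosis", "category"), names(data))
  if (length(keys) == 0) abort("no grouping key column found.")
  data %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) %>%
    dplyr::group_modify(function(d, k) {
      fit <- fit_sigmoid(d$concentration_uM, d$si, ...)
      glance(fit) %>% dplyr::mutate(fit = list(fit))
    }) %>%
    dplyr::ungroup()
}

#' Median of possibly-censored IC50 values
#'
#' Right-censored values (`"> bound"`) rank above every numeric value; the
#' median is taken on this ranking. When a middle rank falls on a censored
#' value the group median itself is censored and reported as `"> bound"`.
#' All censored values in a group must share one bound (mixed bounds are an
#' error); left-censored values are not supported here.
#'
#' @param values Numeric IC50s (for censored entries, the censoring bound).
#' @param censor Character vector, `"none"` or `"above_max"`, recycled if
#'   length 1.
#' @return List with `value`, `censor`, `label` as in [ic50_absolute()].
#' @export
#' @examples
#' median_ic50(c(0.5, 2.0, 34), c("none", "none", "above_max"))   # 2.0
#' median_ic50(c(1.0, 34, 34), c("none", "above_max", "above_max")) # ">34"
median_ic50 <- function(values, censor = "none") {
  stopifnot(length(values) > 0)
  censor <- rep_len(censor, length(values))
  if (any(censor == "below_min")) {
    abort("left-censored values are not supported by `median_ic50()`.")
  }
  if (!all(censor %in% c("none", "above_max"))) abort("invalid censor codes.")
  cens <- censor == "above_max"
  if (any(cens) && dplyr::n_distinct(values[cens]) > 1) {
    abort("mixed censoring bounds within one group.")
  }
  n <- length(values)
  ord <- order(cens, values)  # numeric ascending, censored block last
  sorted_cens <- cens[ord]
  sorted_vals <- values[ord]
  mid <- if (n %% 2 == 1) (n + 1) / 2 else c(n / 2, n / 2 + 1)
  if (any(sorted_cens[mid])) {
    bound <- unique(values[cens])
    list(value = bound, censor = "above_max",
         label = censored_label(bound, "above_max"))
  } else {
    m <- mean(sorted_vals[mid])
    list(value = m, censor = "none", label = censored_label(m, "none"))
  }
}

#' Per-group censored median IC50 table
#'
#' Convenience wrapper producing a diagnosis-level median-IC50 summary
#' table: one row per group with the censored median and sample count.
#'
#' @param fits Tibble from [fit_dose_response()] (needs `ic50`, `censor`).
#' @param by Grouping column name (default `"diagnosis"`).
#' @return Tibble with columns `by`, `median_ic50`, `censor`, `label`, `n`.
#' @export
summarize_panel_ic50 <- function(fits, by = "diagnosis") {
  fits <- tibble::as_tibble(fits)
  stopifnot(all(c(by, "ic50", "censor") %in% names(fits)))
  fits %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) %>%
    dplyr::group_modify(function(d, k) {
      m <- median_ic50(d$ic50, d$censor)
      tibble::tibble(median_ic50 = m$value, censor = m$censor,
                     label = m$label, n = nrow(d))
    }) %>%
    dplyr::ungroup()
}

#' @export
print.dr_fit <- function(x, ...) {
  cat("<dr_fit>", if (x$converged) "converged" else "NOT converged",
      sprintf("| top %.3g bottom %.3g hill %.3g midpoint %.4g | IC50 %s | SSE %.3g\n",
              x$top, x$bottom, x$hill, x$midpoint, x$ic50_label, x$residual_sse))
  invisible(x)
}

#' @rdname fit_sigmoid
#' @param x A `dr_fit` object.
#' @method tidy dr_fit
#' @export
tidy.dr_fit <- function(x, ...) {
  tibble::tibble(
    term = c("top", "bottom", "hill", "midpoint"),
    estimate = c(x$top, x$bottom, x$hill, x$midpoint)
  )
}

#' @rdname fit_sigmoid
#' @method glance dr_fit
#' @export
glance.dr_fit <- function(x, ...) {
  tibble::tibble(
    top = x$top, bottom = x$bottom, hill = x$hill, midpoint = x$midpoint,
    ic50 = x$ic50, censor = x$censor, ic50_label = x$ic50_label,
    residual_sse = x$residual_sse, converged = x$converged, n = x$n
  )
}
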