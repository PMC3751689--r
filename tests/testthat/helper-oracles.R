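# Independent oracles and small fixture builders shared across tests.

library(dplyr)

# Two-tail rank KS statistic via an exhaustive ECDF sweep: walk every
# position x of the ranked universe and take the extreme empirical-CDF gaps
# directly. Deliberately a different route from the package's max over tag
# indices.
ks_oracle <- function(tag_ranks, n) {
  t <- length(tag_ranks)
  a <- -Inf
  b <- -Inf
  for (x in seq_len(n)) {
    le <- sum(tag_ranks <= x)
    lt <- sum(tag_ranks < x)
    a <- max(a, le / t - x / n)
    b <- max(b, x / n - lt / t)
  }
  if (a > b) a else -b
}

# reference 4PL survival curve (positive hill = decreasing survival)
sigmoid_ref <- function(conc, top, bottom, hill, midpoint) {
  bottom + (top - bottom) / (1 + 10^((log10(conc) - log10(midpoint)) * hill))
}

five_point_grid <- c(0.004, 0.04, 0.4, 4, 40)

# hand-built two-plate well table with known control/blank levels
make_plate <- function(plate_id = "P1", test_f, blank = 50, control = 1050,
                       line = "L1", compounds = NULL) {
  if (is.null(compounds)) compounds <- sprintf("C%02d", seq_along(test_f))
  tibble::tibble(
    plate_id = plate_id,
    row = "A",
    col = seq_len(length(test_f) + 5),
    role = c(rep("test", length(test_f)), "control", "control", "control",
             "blank", "blank"),
    compound_id = c(compounds, rep(NA, 5)),
    concentration_uM = c(rep(1, length(test_f)), rep(NA, 5)),
    line_or_sample_id = line,
    fluorescence = c(test_f, rep(control, 3), rep(blank, 2))
  )
}

# small exchangeable panel scenario: solid and hematological share one
# IC50 distribution, so activity indices have no true category signal
exchangeable_panel <- function(seed, n_each = 15, location = 3) {
  dx <- tibble::tribble(
    ~diagnosis, ~category,        ~n,     ~median_ic50,
    "solidA",   "solid",          n_each, location,
    "solidB",   "solid",          n_each, location,
    "hemA",     "hematological",  n_each, location,
    "hemB",     "hematological",  n_each, location
  )
  panel_scenario(diagnoses = dx, seed = seed)
}
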