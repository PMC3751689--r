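#' Describe a two-line differential cytotoxicity screen
#'
#' A screen scenario fixes everything needed to simulate a plate-based
#' fluorometric cytotoxicity screen of a compound library against two (or
#' more) cell lines: the compound universe, per-line susceptibility
#' multipliers, a set of planted selective hits with known true survival,
#' plate-reader signal levels and multiplicative noise. The default mirrors
#' the study design the package validates against: a 3,000-compound library
#' screened at a single concentration against a multidrug-resistant myeloma
#' subline and its parental line, with one planted resistant-line-selective
#' compound.
#'
#' @param n_compounds Number of library compounds.
#' @param lines Character vector of cell-line labels. The first is
#'   conventionally the resistant line, the second its parent, but the
#'   generator itself is agnostic: selectivity lives in `planted_hits`.
#' @param multiplier Named numeric vector (one entry per line) multiplying
#'   each compound's baseline true survival on that line; 1 means no
#'   line-specific resistance effect.
#' @param planted_hits Tibble with columns `compound_id`, `line`,
#'   `true_survival` overriding the baseline survival for selected
#'   compound/line pairs. `NULL` plants the default single hit (survival
#'   0.2 on the first line, 0.9 on the second).
#' @param base_survival_range Range of the uniform distribution from which
#'   each non-hit compound's true survival fraction is drawn (shared across
#'   lines). Most library compounds are inactive, so the default mass sits
#'   near 1.
#' @param control_fluorescence Mean fluorescence of untreated control wells,
#'   arbitrary units, must be positive.
#' @param blank_fluorescence Mean fluorescence of cell-free blank wells,
#'   arbitrary units, non-negative and below `control_fluorescence`.
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   well noise; must lie in \[0, 0.5\].
#' @param screen_concentration Nominal test concentration recorded in the
#'   well table (single-concentration screen).
#' @param seed Integer seed; generation is a pure function of the scenario.
#'
#' @return A list of class `screen_scenario`.
#' @seealso [generate_screen()]
#' @export
#' @examples
#' sc <- screen_scenario(n_compounds = 50, noise_cv = 0, seed = 1)
#' sc$planted_hits
screen_scenario <- function(n_compounds = 3000,
                            lines = c("8226/Dox40", "RPMI 8226"),
                            multiplier = NULL,
                            planted_hits = NULL,
                            base_survival_range = c(0.70, 1.10),
                            control_fluorescence = 5000,
                            blank_fluorescence = 100,
                            noise_cv = 0.1,
                            screen_concentration = 1,
                            seed = 1L) {
  if (n_compounds < 1) abort("`n_compounds` must be at least 1.")
  if (length(lines) < 1) abort("at least one cell line is required.")
  if (anyDuplicated(lines)) abort("cell-line labels must be unique.")
  if (noise_cv < 0 || noise_cv > 0.5) {
    abort("`noise_cv` must lie in [0, 0.5].")
  }
  if (control_fluorescence <= 0) abort("`control_fluorescence` must be > 0.")
  if (blank_fluorescence < 0 || blank_fluorescence >= control_fluorescence) {
    abort("`blank_fluorescence` must satisfy 0 <= blank < control fluorescence.")
  }
  if (is.null(multiplier)) {
    multiplier <- setNames(rep(1, length(lines)), lines)
  }
  if (!setequal(names(multiplier), lines)) {
    abort("`multiplier` must be named by the cell lines.")
  }
  compound_ids <- sprintf("CPD-%04d", seq_len(n_compounds))
  if (is.null(planted_hits)) {
    if (length(lines) >= 2) {
      hit_id <- compound_ids[min(42L, n_compounds)]
      planted_hits <- tibble::tibble(
        compound_id = hit_id,
        line = lines[1:2],
        true_survival = c(0.2, 0.9)
      )
    } else {
      planted_hits <- tibble::tibble(
        compound_id = character(), line = character(),
        true_survival = numeric()
      )
    }
  }
  planted_hits <- tibble::as_tibble(planted_hits)
  stopifnot(all(c("compound_id", "line", "true_survival") %in% names(planted_hits)))
  if (!all(planted_hits$compound_id %in% compound_ids)) {
    abort("planted hit compound ids must belong to the compound universe.")
  }
  if (!all(planted_hits$line %in% lines)) {
    abort("planted hit lines must belong to `lines`.")
  }
  structure(
    list(
      n_compounds = n_compounds,
      compound_ids = compound_ids,
      lines = lines,
      multiplier = multiplier,
      planted_hits = planted_hits,
      base_survival_range = base_survival_range,
      control_fluorescence = control_fluorescence,
      blank_fluorescence = blank_fluorescence,
      noise_cv = noise_cv,
      screen_concentration = screen_concentration,
      seed = as.integer(seed)
    ),
    class = "screen_scenario"
  )
}

#' Describe a diagnosis-annotated ex vivo sensitivity panel
#'
#' Fixes the composition and dose-response structure of a primary patient
#' tumor-cell panel: per-diagnosis sample counts and log-IC50 distributions,
#' the diagnosis-to-category map (solid / hematological / normal), the tested
#' concentration grid and curve-shape parameters. The default emulates a
#' clinically realistic panel structure: five solid-tumor
#' diagnoses with true IC50s far above the highest tested concentration
#' (hence censored ">34" medians), five sensitive hematological diagnoses,
#' and a small normal PBMC arm of intermediate sensitivity, on a 10-fold
#' series ending at 34 uM.
#'
#' @param diagnoses Tibble with columns `diagnosis`, `category` (one of
#'   `"solid"`, `"hematological"`, `"normal"`), `n` (sample count, may be 0)
#'   and `median_ic50` (location of the log10-normal true-IC50 distribution,
#'   uM).
#' @param concentrations Strictly increasing positive tested concentrations
#'   (uM).
#' @param hill_range Range of the uniform distribution of true hill slopes
#'   (positive = survival decreases with concentration).
#' @param top,bottom True upper/lower survival asymptotes (percent).
#' @param log10_ic50_sd Dispersion (sd of log10 IC50) within each diagnosis.
#' @param si_noise_sd Additive Gaussian noise on each survival-index reading
#'   (percentage points).
#' @param seed Integer seed.
#'
#' @return A list of class `panel_scenario`.
#' @seealso [generate_panel()]
#' @export
panel_scenario <- function(diagnoses = default_panel_diagnoses(),
                           concentrations = c(0.0034, 0.034, 0.34, 3.4, 34),
                           hill_range = c(0.8, 1.5),
                           top = 100,
                           bottom = 0,
                           log10_ic50_sd = 0.4,
                           si_noise_sd = 5,
                           seed = 1L) {
  diagnoses <- tibble::as_tibble(diagnoses)
  req <- c("diagnosis", "category", "n", "median_ic50")
  if (!all(req %in% names(diagnoses)) || nrow(diagnoses) == 0) {
    abort("`diagnoses` must be a non-empty tibble with columns diagnosis, category, n, median_ic50.")
  }
  if (anyDuplicated(diagnoses$diagnosis)) {
    abort("each diagnosis must map to exactly one category: duplicated diagnosis labels found.")
  }
  if (!all(diagnoses$category %in% c("solid", "hematological", "normal"))) {
    abort("`category` must be one of 'solid', 'hematological', 'normal'.")
  }
  if (any(concentrations <= 0) || is.unsorted(concentrations, strictly = TRUE)) {
    abort("`concentrations` must be strictly increasing and positive.")
  }
  if (si_noise_sd < 0) abort("`si_noise_sd` must be non-negative.")
  structure(
    list(
      diagnoses = diagnoses,
      concentrations = concentrations,
      hill_range = hill_range,
      top = top,
      bottom = bottom,
      log10_ic50_sd = log10_ic50_sd,
      si_noise_sd = si_noise_sd,
      seed = as.integer(seed)
    ),
    class = "panel_scenario"
  )
}

#' Reference panel composition for the ex vivo generator
#'
#' Sample counts per diagnosis and the location of each diagnosis's true
#' IC50 distribution. Solid tumors are placed at 100 uM — far above the
#' highest tested concentration — so their fitted IC50s come out censored;
#' hematological locations sit in the low micromolar range.
#'
#' @return Tibble with columns `diagnosis`, `category`, `n`, `median_ic50`.
#' @export
default_panel_diagnoses <- function() {
  tibble::tribble(
    ~diagnosis,       ~category,        ~n, ~median_ic50,
    "Breast cancer",  "solid",           8,          100,
    "Colon cancer",   "solid",           5,          100,
    "Lung cancer",    "solid",           6,          100,
    "Renal cancer",   "solid",           8,          100,
    "Ovarian cancer", "solid",          19,          100,
    "AML",            "hematological",   8,         1.56,
    "ALL",            "hematological",  19,         3.21,
    "CML",            "hematological",   2,         0.98,
    "CLL",            "hematological",  11,         2.18,
    "NHL",            "hematological",  13,         0.51,
    "PBMC",           "normal",          4,         16.3
  )
}

#' Describe a mini connectivity database of ranked expression instances
#'
#' Fixes the structure of a small connectivity-map-like resource: a probe
#' universe, a set of mechanism classes each carrying a shared fold-change
#' template, treatment instances (several per compound, several compounds
#' per class) whose probe rankings concentrate their class template's
#' up-regulated genes near rank 1, and a treated/control query expression
#' pair generated from the template of `query_mechanism`.
#'
#' @param n_probes Probe universe size (>= 100).
#' @param n_instances Number of database instances; split evenly over
#'   classes (each class gets at least one).
#' @param n_classes Number of mechanism classes.
#' @param compounds_per_class Distinct compound labels per class; instances
#'   of a class are assigned to its compounds cyclically.
#' @param query_mechanism Class label the query pair is generated from
#'   (default: the first class).
#' @param template_n_up,template_n_down Number of up-/down-regulated
#'   template probes per class.
#' @param log2_fc Magnitude scale of template log2 fold changes.
#' @param class_strength Weight of the class template in each instance's
#'   latent differential-expression score (0 = pure noise).
#' @param rank_noise_sd Sd of the Gaussian noise added to instance latent
#'   scores before ranking; 0 makes same-class instances identical.
#' @param signal_floor Minimum control signal (arbitrary units).
#' @param signal_scale Scale of control signal intensities.
#' @param expr_noise_cv CV of multiplicative lognormal noise on the query
#'   pair's signals.
#' @param present_call_rate Probability a probe is flagged present in a
#'   condition.
#' @param seed Integer seed.
#'
#' @return A list of class `connectivity_scenario`.
#' @seealso [generate_connectivity_db()]
#' @export
connectivity_scenario <- function(n_probes = 500,
                                  n_instances = 60,
                                  n_classes = 6,
                                  compounds_per_class = 2,
                                  query_mechanism = NULL,
                                  template_n_up = 30,
                                  template_n_down = 15,
                                  log2_fc = 2,
                                  class_strength = 1,
                                  rank_noise_sd = 0.3,
                                  signal_floor = 50,
                                  signal_scale = 800,
                                  expr_noise_cv = 0.15,
                                  present_call_rate = 0.98,
                                  seed = 7L) {
  if (n_probes < 100) abort("`n_probes` must be at least 100.")
  if (n_instances < n_classes) {
    abort("each mechanism class needs at least one instance: `n_instances` < `n_classes`.")
  }
  classes <- sprintf("mech_%02d", seq_len(n_classes))
  if (is.null(query_mechanism)) query_mechanism <- classes[1]
  if (!query_mechanism %in% classes) {
    abort("`query_mechanism` must be one of the mechanism classes.")
  }
  if (template_n_up + template_n_down > n_probes) {
    abort("template sizes exceed the probe universe.")
  }
  if (present_call_rate < 0 || present_call_rate > 1) {
    abort("`present_call_rate` must lie in [0, 1].")
  }
  structure(
    list(
      n_probes = n_probes,
      n_instances = n_instances,
      classes = classes,
      compounds_per_class = compounds_per_class,
      query_mechanism = query_mechanism,
      template_n_up = template_n_up,
      template_n_down = template_n_down,
      log2_fc = log2_fc,
      class_strength = class_strength,
      rank_noise_sd = rank_noise_sd,
      signal_floor = signal_floor,
      signal_scale = signal_scale,
      expr_noise_cv = expr_noise_cv,
      present_call_rate = present_call_rate,
      seed = as.integer(seed)
    ),
    class = "connectivity_scenario"
  )
}

#' @export
print.screen_scenario <- function(x, ...) {
  cat("<screen_scenario>", x$n_compounds, "compounds x",
      length(x$lines), "lines;",
      nrow(x$planted_hits %>% dplyr::distinct(.data$compound_id)),
      "planted hit compound(s); noise_cv =", x$noise_cv,
      "; seed =", x$seed, "\n")
  invisible(x)
}

#' @export
print.panel_scenario <- function(x, ...) {
  cat("<panel_scenario>", sum(x$diagnoses$n), "samples,",
      nrow(x$diagnoses), "diagnoses;",
      length(x$concentrations), "concentrations",
      sprintf("(%g-%g uM);", min(x$concentrations), max(x$concentrations)),
      "seed =", x$seed, "\n")
  invisible(x)
}

#' @export
print.connectivity_scenario <- function(x, ...) {
  cat("<connectivity_scenario>", x$n_probes, "probes,",
      x$n_instances, "instances in", length(x$classes), "classes;",
      "query =", x$query_mechanism, "; seed =", x$seed, "\n")
  invisible(x)
}
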