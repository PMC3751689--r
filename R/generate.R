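# Seeded generators. Each is a pure function of its scenario: randomness is
# drawn inside withr::with_seed so the caller's RNG state is untouched and
# identical scenarios give identical output.

# multiplicative lognormal noise with unit mean and coefficient of variation cv
.ln_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate a plate-based differential cytotoxicity screen
#'
#' Produces 384-well plates (16 rows x 24 columns) with the assay's layout
#' convention — two drug-free control columns and one medium-only blank
#' column per plate — for every cell line in the scenario. Each test well's
#' fluorescence is `blank + (control - blank) * true_survival * noise` with
#' multiplicative lognormal noise; control wells carry survival 1 and blank
#' wells cell-free background. True survival per compound/line is emitted in
#' a sidecar table, never in the well table itself.
#'
#' @param scenario A [screen_scenario()].
#' @return A list of class `screen_data` with elements
#'   * `wells`: tibble with columns `plate_id`, `row`, `col`, `role`
#'     (`test`/`control`/`blank`), `compound_id`, `concentration_uM`,
#'     `line_or_sample_id`, `fluorescence`;
#'   * `truth`: tibble `compound_id`, `line`, `true_survival` (ground truth
#'     sidecar);
#'   * `scenario`: the input scenario.
#' @export
#' @examples
#' scr <- generate_screen(screen_scenario(n_compounds = 30, seed = 1))
#' dplyr::count(scr$wells, role)
generate_screen <- function(scenario) {
  stopifnot(inherits(scenario, "screen_scenario"))
  withr::with_seed(scenario$seed, {
    n <- scenario$n_compounds
    base <- runif(n, scenario$base_survival_range[1], scenario$base_survival_range[2])
    truth <- tidyr::expand_grid(
      compound_id = scenario$compound_ids,
      line = scenario$lines
    ) %>%
      dplyr::mutate(
        true_survival = rep(base, each = length(scenario$lines)) *
          unname(scenario$multiplier[.data$line])
      ) %>%
      dplyr::rows_update(scenario$planted_hits, by = c("compound_id", "line"))

    # 16 rows x 24 columns; columns 1-2 control, 24 blank, 3-23 test
    rows <- LETTERS[1:16]
    ctrl_cols <- 1:2
    blank_col <- 24L
    test_cols <- 3:23
    per_plate <- length(rows) * length(test_cols)
    n_plates <- ceiling(n / per_plate)

    wells <- purrr::map_dfr(scenario$lines, function(ln) {
      surv <- truth %>% dplyr::filter(.data$line == ln)
      surv <- setNames(surv$true_survival, surv$compound_id)
      purrr::map_dfr(seq_len(n_plates), function(p) {
        ids <- scenario$compound_ids[
          ((p - 1) * per_plate + 1):min(p * per_plate, n)
        ]
        plate_id <- sprintf("%s_P%02d", gsub("[^A-Za-z0-9]+", "-", ln), p)
        test_grid <- tidyr::expand_grid(col = test_cols, row = rows) %>%
          dplyr::slice(seq_along(ids)) %>%
          dplyr::mutate(
            role = "test",
            compound_id = ids,
            concentration_uM = scenario$screen_concentration
          )
        ctrl_grid <- tidyr::expand_grid(col = ctrl_cols, row = rows) %>%
          dplyr::mutate(role = "control", compound_id = NA_character_,
                        concentration_uM = NA_real_)
        blank_grid <- tidyr::expand_grid(col = blank_col, row = rows) %>%
          dplyr::mutate(role = "blank", compound_id = NA_character_,
                        concentration_uM = NA_real_)
        dplyr::bind_rows(test_grid, ctrl_grid, blank_grid) %>%
          dplyr::mutate(
            plate_id = plate_id,
            line_or_sample_id = ln,
            fluorescence = dplyr::case_when(
              role == "test" ~ scenario$blank_fluorescence +
                (scenario$control_fluorescence - scenario$blank_fluorescence) *
                  surv[compound_id] * .ln_noise(dplyr::n(), scenario$noise_cv),
              role == "control" ~ scenario$blank_fluorescence +
                (scenario$control_fluorescence - scenario$blank_fluorescence) *
                  .ln_noise(dplyr::n(), scenario$noise_cv),
              TRUE ~ scenario$blank_fluorescence * .ln_noise(dplyr::n(), scenario$noise_cv)
            )
          ) %>%
          dplyr::select("plate_id", "row", "col", "role", "compound_id",
                        "concentration_uM", "line_or_sample_id", "fluorescence")
      })
    })
    structure(list(wells = wells, truth = truth, scenario = scenario),
              class = "screen_data")
  })
}

# four-parameter logistic survival curve: positive hill = steeper decline
.sigmoid <- function(conc, top, bottom, hill, midpoint) {
  bottom + (top - bottom) / (1 + 10^((log10(conc) - log10(midpoint)) * hill))
}

#' Simulate an ex vivo patient-cell sensitivity panel
#'
#' Draws each sample's true IC50 from its diagnosis's log10-normal
#' distribution, a hill slope from the scenario range, and evaluates a
#' four-parameter logistic survival curve on the concentration grid with
#' additive Gaussian noise on the survival index. True curve parameters are
#' returned in a sidecar table.
#'
#' @param scenario A [panel_scenario()].
#' @return A list of class `panel_data` with elements
#'   * `si`: long tibble `sample_id`, `diagnosis`, `category`,
#'     `concentration_uM`, `si`;
#'   * `truth`: tibble `sample_id`, `diagnosis`, `category`, `true_ic50`,
#'     `hill`, `top`, `bottom`;
#'   * `scenario`.
#' @export
generate_panel <- function(scenario) {
  stopifnot(inherits(scenario, "panel_scenario"))
  withr::with_seed(scenario$seed, {
    d <- scenario$diagnoses %>% dplyr::filter(.data$n > 0)
    truth <- d %>%
      dplyr::rowwise() %>%
      dplyr::reframe(
        diagnosis = .data$diagnosis,
        category = .data$category,
        sample_idx = seq_len(.data$n),
        true_ic50 = 10^rnorm(.data$n, log10(.data$median_ic50),
                             scenario$log10_ic50_sd),
        hill = runif(.data$n, scenario$hill_range[1], scenario$hill_range[2])
      ) %>%
      dplyr::mutate(
        sample_id = sprintf("S%03d", dplyr::row_number()),
        top = scenario$top,
        bottom = scenario$bottom
      ) %>%
      dplyr::select("sample_id", "diagnosis", "category", "true_ic50",
                    "hill", "top", "bottom")

    si <- truth %>%
      tidyr::expand_grid(concentration_uM = scenario$concentrations) %>%
      dplyr::mutate(
        si = .sigmoid(.data$concentration_uM, .data$top, .data$bottom,
                      .data$hill, .data$true_ic50) +
          rnorm(dplyr::n(), 0, scenario$si_noise_sd)
      ) %>%
      dplyr::select("sample_id", "diagnosis", "category",
                    "concentration_uM", "si")
    structure(list(si = si, truth = truth, scenario = scenario),
              class = "panel_data")
  })
}

#' Simulate a query expression pair and a ranked-instance database
#'
#' Builds (i) a treated/control expression profile pair from the query
#' mechanism's fold-change template, with lognormal control intensities,
#' multiplicative noise and present/absent detection calls, and (ii) a
#' database of instances whose probe rankings are driven by their class
#' template plus Gaussian rank noise, so same-mechanism instances
#' concentrate the template's up-regulated probes near rank 1.
#'
#' @param scenario A [connectivity_scenario()].
#' @return A list of class `connectivity_db` with elements
#'   * `query`: list of two tibbles `treated` and `control`, each with
#'     columns `probe_id`, `signal`, `present`;
#'   * `instances`: long tibble `instance_id`, `compound`, `probe_id`,
#'     `rank` (rank 1 = most up-regulated; a permutation of 1..n_probes per
#'     instance);
#'   * `truth`: tibble `instance_id`, `compound`, `mechanism`;
#'   * `templates`: per-class template tibble `mechanism`, `probe_id`,
#'     `log2_fc`;
#'   * `scenario`.
#' @export
generate_connectivity_db <- function(scenario) {
  stopifnot(inherits(scenario, "connectivity_scenario"))
  withr::with_seed(scenario$seed, {
    probes <- sprintf("probe_%04d", seq_len(scenario$n_probes))
    n_cl <- length(scenario$classes)

    templates <- purrr::map_dfr(scenario$classes, function(cl) {
      picked <- sample(probes, scenario$template_n_up + scenario$template_n_down)
      tibble::tibble(
        mechanism = cl,
        probe_id = picked,
        log2_fc = c(
          scenario$log2_fc * runif(scenario$template_n_up, 0.5, 1.5),
          -scenario$log2_fc * runif(scenario$template_n_down, 0.5, 1.5)
        )
      )
    })

    template_vec <- function(cl) {
      v <- setNames(rep(0, scenario$n_probes), probes)
      tpl <- templates[templates$mechanism == cl, ]
      v[tpl$probe_id] <- tpl$log2_fc
      v
    }

    # query treated/control pair from the query mechanism's template
    ctrl_signal <- scenario$signal_floor +
      rlnorm(scenario$n_probes, log(scenario$signal_scale), 0.6)
    fc <- 2^template_vec(scenario$query_mechanism)
    treat_signal <- ctrl_signal * fc
    query <- list(
      treated = tibble::tibble(
        probe_id = probes,
        signal = treat_signal * .ln_noise(scenario$n_probes, scenario$expr_noise_cv),
        present = rbinom(scenario$n_probes, 1, scenario$present_call_rate) == 1
      ),
      control = tibble::tibble(
        probe_id = probes,
        signal = ctrl_signal * .ln_noise(scenario$n_probes, scenario$expr_noise_cv),
        present = rbinom(scenario$n_probes, 1, scenario$present_call_rate) == 1
      )
    )

    # instances: class template (weighted) + rank noise, ranked descending
    per_class <- diff(round(seq(0, scenario$n_instances, length.out = n_cl + 1)))
    truth <- purrr::map2_dfr(scenario$classes, per_class, function(cl, k) {
      cpds <- sprintf("%s_cpd%s", cl, LETTERS[seq_len(scenario$compounds_per_class)])
      tibble::tibble(
        mechanism = cl,
        compound = rep_len(cpds, k)
      )
    }) %>%
      dplyr::mutate(instance_id = sprintf("inst_%03d", dplyr::row_number())) %>%
      dplyr::select("instance_id", "compound", "mechanism")

    instances <- purrr::pmap_dfr(truth, function(instance_id, compound, mechanism) {
      latent <- scenario$class_strength * template_vec(mechanism) +
        rnorm(scenario$n_probes, 0, scenario$rank_noise_sd)
      # ties (noise-free off-template probes) broken by probe order for determinism
      tibble::tibble(
        instance_id = instance_id,
        compound = compound,
        probe_id = probes,
        rank = rank(-latent, ties.method = "first")
      )
    })

    structure(
      list(query = query, instances = instances, truth = truth,
           templates = templates, scenario = scenario),
      class = "connectivity_db"
    )
  })
}
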