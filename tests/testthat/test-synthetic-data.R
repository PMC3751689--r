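test_that("screen generation is a pure function of the scenario", {
  sc <- screen_scenario(n_compounds = 60, noise_cv = 0.2, seed = 9)
  a <- generate_screen(sc)
  b <- generate_screen(sc)
  expect_identical(a$wells, b$wells)
  expect_identical(a$truth, b$truth)
  # a different seed changes the data
  c <- generate_screen(screen_scenario(n_compounds = 60, noise_cv = 0.2, seed = 10))
  expect_false(identical(a$wells$fluorescence, c$wells$fluorescence))
})

test_that("noise-free screen reproduces planted survival exactly through SI", {
  hits <- tibble::tibble(
    compound_id = "CPD-0042",
    line = c("RES", "PAR"),
    true_survival = c(0.2, 0.9)
  )
  sc <- screen_scenario(n_compounds = 50, lines = c("RES", "PAR"),
                        planted_hits = hits, noise_cv = 0, seed = 1)
  si <- compute_si(generate_screen(sc)$wells)
  got <- si[si$compound_id == "CPD-0042", ]
  expect_equal(got$si[got$line_or_sample_id == "RES"], 20, tolerance = 1e-12)
  expect_equal(got$si[got$line_or_sample_id == "PAR"], 90, tolerance = 1e-12)
})

test_that("screen plates follow the layout convention", {
  scr <- generate_screen(screen_scenario(n_compounds = 400, seed = 2))
  per_plate <- dplyr::count(scr$wells, plate_id, role)
  ctrl <- per_plate[per_plate$role == "control", ]
  blank <- per_plate[per_plate$role == "blank", ]
  expect_true(all(ctrl$n == 32))  # two 16-well columns
  expect_true(all(blank$n == 16)) # one medium-only column
  # every compound appears once per line
  tests <- scr$wells[scr$wells$role == "test", ]
  expect_equal(
    unname(table(table(tests$compound_id))["2"]),
    400
  )
})

test_that("scenario validation rejects out-of-range inputs", {
  expect_error(screen_scenario(noise_cv = 0.7), "noise_cv")
  expect_error(screen_scenario(blank_fluorescence = 6000), "blank")
  expect_error(
    screen_scenario(n_compounds = 10,
                    planted_hits = tibble::tibble(
                      compound_id = "CPD-9999", line = "8226/Dox40",
                      true_survival = 0.2)),
    "universe"
  )
  expect_error(panel_scenario(diagnoses = tibble::tibble()), "non-empty")
  expect_error(panel_scenario(concentrations = c(1, 1, 2)), "strictly increasing")
  expect_error(connectivity_scenario(n_probes = 50), "at least 100")
  expect_error(connectivity_scenario(n_instances = 3, n_classes = 6), "at least one instance")
})

test_that("panel generation honors counts, omits empty diagnoses, and is seeded", {
  dx <- tibble::tribble(
    ~diagnosis, ~category,       ~n, ~median_ic50,
    "A",        "hematological",  5, 1,
    "B",        "solid",          3, 50,
    "C",        "solid",          0, 50
  )
  sc <- panel_scenario(diagnoses = dx, seed = 4)
  pan <- generate_panel(sc)
  expect_setequal(unique(pan$si$diagnosis), c("A", "B"))
  expect_equal(nrow(pan$truth), 8)
  expect_identical(pan$si, generate_panel(sc)$si)
})

test_that("noise-free panel curves round-trip through the fitter", {
  dx <- tibble::tibble(diagnosis = "A", category = "hematological",
                       n = 3, median_ic50 = 1)
  pan <- generate_panel(panel_scenario(diagnoses = dx, si_noise_sd = 0, seed = 8))
  fits <- fit_dose_response(pan$si)
  joined <- dplyr::inner_join(fits, pan$truth, by = "sample_id")
  expect_true(all(joined$censor == "none"))
  expect_lt(max(abs(joined$ic50 - joined$true_ic50) / joined$true_ic50), 1e-4)
})

test_that("solid-resistant panel structure yields mostly censored solid fits", {
  dx <- tibble::tibble(
    diagnosis = c("hem", "sol"), category = c("hematological", "solid"),
    n = c(10, 20), median_ic50 = c(1, 100)
  )
  pan <- generate_panel(panel_scenario(
    diagnoses = dx, concentrations = c(0.004, 0.04, 0.4, 4, 40), seed = 3
  ))
  fits <- fit_dose_response(pan$si)
  solid <- fits[fits$category == "solid", ]
  expect_gt(mean(solid$censor == "above_max"), 0.8)
  expect_true(all(solid$ic50_label[solid$censor == "above_max"] == ">40"))
})

test_that("connectivity db: maximal class sharing with zero noise saturates scores", {
  sc <- connectivity_scenario(rank_noise_sd = 0, expr_noise_cv = 0,
                              present_call_rate = 1, seed = 7)
  cdb <- generate_connectivity_db(sc)
  sig <- build_signature(cdb$query$treated, cdb$query$control,
                         min_signal = 0)
  res <- normalize_scores(connectivity_scores(cdb$instances, sig))
  same <- res$instance_id %in%
    cdb$truth$instance_id[cdb$truth$mechanism == sc$query_mechanism]
  expect_true(all(res$normalized_score[same] == 1))
  # query up tags come from the query template's up-regulated probes
  tpl_up <- cdb$templates$probe_id[
    cdb$templates$mechanism == sc$query_mechanism & cdb$templates$log2_fc > 0
  ]
  expect_true(all(sig$up_tags %in% tpl_up))
})

test_that("full present calls and high signals leave the filter inert", {
  sc <- connectivity_scenario(present_call_rate = 1, expr_noise_cv = 0, seed = 1)
  cdb <- generate_connectivity_db(sc)
  sig <- build_signature(cdb$query$treated, cdb$query$control, min_signal = 0)
  expect_equal(sig$n_filtered, sc$n_probes)
})

test_that("same-class instances sit above other classes in the connectivity ordering", {
  cdb <- generate_connectivity_db(connectivity_scenario(seed = 7))
  sig <- build_signature(cdb$query$treated, cdb$query$control)
  res <- normalize_scores(connectivity_scores(cdb$instances, sig)) %>%
    dplyr::arrange(dplyr::desc(normalized_score)) %>%
    dplyr::mutate(pos = dplyr::row_number()) %>%
    dplyr::left_join(cdb$truth, by = c("instance_id", "compound"))
  same <- res$mechanism == cdb$scenario$query_mechanism
  expect_lt(mean(res$pos[same]), mean(res$pos[!same]))
})

test_that("instance rankings are permutations of the probe universe", {
  cdb <- generate_connectivity_db(connectivity_scenario(seed = 2))
  ranks_ok <- cdb$instances %>%
    dplyr::group_by(instance_id) %>%
    dplyr::summarise(ok = setequal(rank, seq_len(dplyr::n())), .groups = "drop")
  expect_true(all(ranks_ok$ok))
})
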