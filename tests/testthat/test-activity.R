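panel_si_manual <- function(si_by_conc) {
  # si_by_conc: named list conc -> vector of SI (one per sample)
  n <- length(si_by_conc[[1]])
  purrr::imap_dfr(si_by_conc, function(si, conc) {
    tibble::tibble(
      sample_id = sprintf("S%02d", seq_len(n)),
      diagnosis = rep(c("dx1", "dx2"), length.out = n),
      category = rep(c("hematological", "solid"), length.out = n),
      concentration_uM = as.numeric(conc),
      si = si
    )
  })
}

test_that("reference concentration maximizes SI dispersion, ties to the lowest", {
  pan <- panel_si_manual(list(
    `0.4` = c(95, 100, 105, 98),   # sd ~ 4
    `3.4` = c(10, 90, 50, 70),     # sd ~ 34
    `34`  = c(5, 20, 10, 15)       # sd ~ 6
  ))
  expect_equal(select_reference_concentration(pan), 3.4)

  flat <- panel_si_manual(list(`0.4` = rep(50, 4), `3.4` = rep(50, 4)))
  expect_warning(ref <- select_reference_concentration(flat), "tied")
  expect_equal(ref, 0.4)
})

test_that("differing concentration grids are rejected with offenders named", {
  pan <- panel_si_manual(list(`1` = c(50, 60, 70), `10` = c(40, 30, 20)))
  pan <- pan[!(pan$sample_id == "S02" & pan$concentration_uM == 10), ]
  expect_error(select_reference_concentration(pan), "S02")
})

test_that("response rates use the strict below-overall-median rule", {
  pan <- panel_si_manual(list(`1` = c(10, 40, 60, 90)))
  rr <- response_rates(pan, 1)
  expect_equal(rr$overall_median_si, 50)
  # overall: 2 of 4 strictly below the median
  expect_equal(sum(rr$rates$n_responders) / sum(rr$rates$n), 0.5)
  # a diagnosis entirely above the median has rate 0
  pan2 <- tibble::tibble(
    sample_id = sprintf("S%02d", 1:6),
    diagnosis = rep(c("lo", "hi"), each = 3),
    category = "solid",
    concentration_uM = 1,
    si = c(10, 20, 30, 70, 80, 90)
  )
  rr2 <- response_rates(pan2, 1)
  expect_equal(rr2$rates$response_rate[rr2$rates$diagnosis == "hi"], 0)
  expect_equal(rr2$rates$response_rate[rr2$rates$diagnosis == "lo"], 1)
})

test_that("samples exactly at the median are non-responders", {
  pan <- panel_si_manual(list(`1` = c(10, 50, 50, 90, 30)))
  rr <- response_rates(pan, 1)  # median 50
  expect_equal(sum(rr$rates$n_responders), 2)
})

test_that("overall response rate lies in [0.5 - 1/n, 0.5] by construction", {
  for (seed in 1:10) {
    pan <- generate_panel(exchangeable_panel(seed))
    rr <- response_rates(pan$si, 3.4)
    overall <- sum(rr$rates$n_responders) / rr$n_tumor
    expect_lte(overall, 0.5)
    expect_gte(overall, 0.5 - 1 / rr$n_tumor)
  }
})

test_that("normal samples are excluded from tumor statistics", {
  pan <- panel_si_manual(list(`1` = c(10, 90)))
  pbmc <- tibble::tibble(sample_id = "N1", diagnosis = "PBMC",
                         category = "normal", concentration_uM = 1, si = 5)
  rr <- response_rates(dplyr::bind_rows(pan, pbmc), 1)
  expect_equal(rr$n_tumor, 2)
  expect_false("PBMC" %in% rr$rates$diagnosis)
})

test_that("S/H ratio pools at the sample level", {
  # 7 solid (1 responder -> 0.14), 4 hematological (2 responders -> 0.5)
  pan <- tibble::tibble(
    sample_id = sprintf("S%02d", 1:11),
    diagnosis = c(rep(c("sA", "sB"), length.out = 7), rep("h", 4)),
    category = c(rep("solid", 7), rep("hematological", 4)),
    concentration_uM = 1,
    si = c(10, 60, 70, 80, 90, 95, 99, 20, 30, 55, 65)
  )
  # overall median of the 11 SIs is 65; below: 10,60,20,30,55 ->
  # solid responders {10,60}: rate 2/7; hem responders {20,30,55}: 3/4
  sh <- sh_ratio(pan, 1)
  expect_equal(sh, (2 / 7) / (3 / 4))
  # invariant to relabeling diagnoses within a category
  relabeled <- dplyr::mutate(pan, diagnosis = paste0(diagnosis, "_x"))
  expect_equal(sh_ratio(relabeled, 1), sh)
  # invariant to sample order
  expect_equal(sh_ratio(pan[sample(11), ], 1), sh)
})

test_that("zero hematological response rate warns and returns Inf", {
  pan <- tibble::tibble(
    sample_id = sprintf("S%02d", 1:4),
    diagnosis = c("s", "s", "h", "h"),
    category = c("solid", "solid", "hematological", "hematological"),
    concentration_uM = 1,
    si = c(10, 20, 80, 90)
  )
  expect_warning(sh <- sh_ratio(pan, 1), "infinite")
  expect_equal(sh, Inf)
})

test_that("specificity ratio divides censored medians with propagation", {
  tbl <- tibble::tibble(
    diagnosis = c(rep("PBMC", 3), rep("CLL", 3)),
    ic50 = c(10, 16, 20, 1, 2, 3),
    censor = "none"
  )
  expect_equal(specificity_ratio(tbl)$value, 8)

  cens <- tbl
  cens$ic50[1:3] <- 34
  cens$censor[1:3] <- "above_max"
  out <- specificity_ratio(cens)
  expect_equal(out$censor, "above_max")
  expect_equal(out$value, 17)
  expect_equal(out$label, ">17")

  equal <- tbl
  equal$ic50 <- rep(2, 6)
  expect_equal(specificity_ratio(equal)$value, 1)

  bad <- tbl
  bad$ic50[4:6] <- 34
  bad$censor[4:6] <- "above_max"
  expect_error(specificity_ratio(bad), "denominator")
})

test_that("net growth is the percent OD change from implantation", {
  expect_equal(net_growth(0.4, 0.8), 100)
  expect_equal(net_growth(0.4, 0.4), 0)
  expect_equal(net_growth(0.4, 0.2), -50)
  expect_error(net_growth(0, 0.5), "positive")
})

test_that("group comparison runs a pooled-variance two-sided t-test", {
  rec <- tibble::tibble(
    dose_group = rep(c("vehicle", "high"), each = 4),
    od_implantation = rep(0.4, 8),
    od_retrieval = c(0.8, 0.9, 0.85, 0.95, 0.45, 0.5, 0.4, 0.55)
  )
  out <- compare_net_growth(rec, "high", "vehicle")
  ref <- t.test(net_growth(0.4, c(0.45, 0.5, 0.4, 0.55)),
                net_growth(0.4, c(0.8, 0.9, 0.85, 0.95)), var.equal = TRUE)
  expect_equal(out$p_value, ref$p.value)
  expect_equal(out$df, 6)
})

test_that("single-animal groups refuse the test", {
  rec <- tibble::tibble(dose_group = c("a", "b", "b"),
                        net_growth = c(10, 20, 30))
  expect_error(compare_net_growth(rec, "a", "b"), "at least 2")
})

test_that("activity report assembles all indices", {
  pan <- generate_panel(panel_scenario(seed = 17))
  fits <- fit_dose_response(pan$si) %>% dplyr::select(-fit)
  rep <- activity_report(pan$si, fits)
  expect_s3_class(rep, "activity_report")
  gl <- glance(rep)
  expect_true(gl$sh_ratio < 1)  # hematological-preferential by construction
  expect_true(all(rep$response_rates$response_rate >= 0 &
                    rep$response_rates$response_rate <= 1))
  # Table-2-shaped structure: every hematological diagnosis responds more
  # than every solid diagnosis
  hem <- rep$response_rates$response_rate[
    rep$response_rates$category == "hematological"]
  sol <- rep$response_rates$response_rate[rep$response_rates$category == "solid"]
  expect_gt(min(hem), max(sol))
})
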