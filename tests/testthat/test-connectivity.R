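test_that("KS statistic matches the published worked examples", {
  expect_equal(ks_statistic(c(1, 2), 10), 0.8)
  expect_equal(ks_statistic(c(9, 10), 10), -0.9)
})

test_that("tags occupying the top block give the closed form 1 - t/n", {
  for (n in c(10, 50, 200)) {
    for (t in c(1, 3, 7)) {
      expect_equal(ks_statistic(seq_len(t), n), 1 - t / n)
    }
  }
})

test_that("KS statistic agrees with the ECDF-sweep oracle on random cases", {
  set.seed(101)
  for (i in 1:200) {
    n <- sample(5:60, 1)
    t <- sample(seq_len(n - 1), 1)
    tags <- sample(n, t)
    expect_equal(ks_statistic(tags, n), ks_oracle(tags, n))
  }
})

test_that("KS statistic is weakly monotone in single-tag rank improvement", {
  set.seed(55)
  for (i in 1:100) {
    n <- sample(8:40, 1)
    t <- sample(2:(n - 2), 1)
    tags <- sort(sample(n, t))
    # improve one tag's rank toward 1 without colliding with another tag
    movable <- tags[!(tags - 1) %in% c(0, tags)]
    if (length(movable) == 0) next
    pick <- movable[sample.int(length(movable), 1)]
    improved <- sort(c(setdiff(tags, pick), pick - 1))
    expect_gte(ks_statistic(improved, n), ks_statistic(tags, n))
  }
})

test_that("KS statistic rejects degenerate tag sets", {
  expect_error(ks_statistic(integer(0), 10), "1 <= t < n")
  expect_error(ks_statistic(1:10, 10), "1 <= t < n")
  expect_error(ks_statistic(c(1, 1), 10), "distinct")
  expect_error(ks_statistic(c(0, 5), 10), "distinct integers")
})

test_that("connectivity raw score follows the opposite-sign rule", {
  # one instance with known tag placements: up tags at the top, down at the
  # bottom -> strong positive raw score equal to ks_up - ks_down
  n <- 10
  probes <- sprintf("p%02d", 1:n)
  inst <- tibble::tibble(
    instance_id = "i1", compound = "cpd", probe_id = probes, rank = 1:n
  )
  sig <- list(up_tags = c("p01", "p02"), down_tags = c("p09", "p10"))
  res <- connectivity_scores(inst, sig)
  expect_equal(res$ks_up, 0.8)
  expect_equal(res$ks_down, -0.9)
  expect_equal(res$raw_score, 1.7)

  # same-sign tails zero out
  sig2 <- list(up_tags = c("p01", "p02"), down_tags = c("p03", "p04"))
  res2 <- connectivity_scores(inst, sig2)
  expect_gt(res2$ks_up * res2$ks_down, 0)
  expect_equal(res2$raw_score, 0)
})

test_that("raw score is antisymmetric under swapping up and down tags", {
  set.seed(77)
  n <- 100
  probes <- sprintf("p%03d", 1:n)
  for (i in 1:20) {
    inst <- tibble::tibble(instance_id = "i1", compound = "c",
                           probe_id = probes, rank = sample(n))
    tags <- sample(probes, 12)
    sig <- list(up_tags = tags[1:8], down_tags = tags[9:12])
    swapped <- list(up_tags = tags[9:12], down_tags = tags[1:8])
    r1 <- connectivity_scores(inst, sig)$raw_score
    r2 <- connectivity_scores(inst, swapped)$raw_score
    if (r1 != 0 || r2 != 0) expect_equal(r2, -r1)
  }
})

test_that("an instance reversing the query template scores most negative", {
  cdb <- generate_connectivity_db(connectivity_scenario(
    rank_noise_sd = 0, expr_noise_cv = 0, present_call_rate = 1, seed = 7
  ))
  sig <- build_signature(cdb$query$treated, cdb$query$control, min_signal = 0)
  n <- cdb$scenario$n_probes
  reversed <- cdb$instances %>%
    dplyr::filter(instance_id == "inst_001") %>%
    dplyr::mutate(instance_id = "rev", compound = "rev",
                  rank = n + 1L - rank)
  res <- connectivity_scores(dplyr::bind_rows(cdb$instances, reversed), sig)
  expect_equal(res$instance_id[which.min(res$raw_score)], "rev")
})

test_that("normalization maps extremes to +/-1, is idempotent and scale-free", {
  res <- tibble::tibble(instance_id = letters[1:3], compound = letters[1:3],
                        raw_score = c(1.7, 0.85, -0.6))
  norm <- normalize_scores(res)
  expect_equal(norm$normalized_score, c(1, 0.5, -1))
  # idempotent: renormalizing normalized-as-raw changes nothing
  again <- normalize_scores(dplyr::mutate(norm, raw_score = normalized_score))
  expect_equal(again$normalized_score, norm$normalized_score)
  # scale-free
  scaled <- normalize_scores(dplyr::mutate(res, raw_score = raw_score * 7.3))
  expect_equal(scaled$normalized_score, norm$normalized_score)
  # degenerate single positive instance
  one <- normalize_scores(tibble::tibble(raw_score = 0.3))
  expect_equal(one$normalized_score, 1)
  # all-zero raw scores stay zero
  zero <- normalize_scores(tibble::tibble(raw_score = c(0, 0)))
  expect_equal(zero$normalized_score, c(0, 0))
})

test_that("compound ranking aggregates by mean normalized score", {
  res <- tibble::tibble(
    compound = c("a", "a", "b"),
    normalized_score = c(1.0, 0.0, 0.6)
  )
  rk <- rank_compounds(res)
  expect_equal(rk$compound, c("b", "a"))  # 0.6 > 0.5
  expect_equal(rk$n_instances, c(1L, 2L))
})

test_that("signature construction filters on signal, calls and chip membership", {
  probes <- sprintf("p%02d", 1:40)
  treated <- tibble::tibble(probe_id = probes,
                            signal = seq(5000, 400, length.out = 40),
                            present = TRUE)
  control <- tibble::tibble(probe_id = probes, signal = 1000, present = TRUE)
  # a probe with control signal below 300 is excluded even if treated is huge
  control$signal[1] <- 250
  sig <- build_signature(treated, control, n_up = 5, n_down = 5)
  expect_false("p01" %in% sig$up_tags)
  # absent call in either condition excludes
  treated2 <- treated; treated2$present[2] <- FALSE
  sig2 <- build_signature(treated2, control, n_up = 5, n_down = 5)
  expect_false("p02" %in% sig2$up_tags)
  # chip-compatibility list excludes
  sig3 <- build_signature(treated, control, n_up = 5, n_down = 5,
                          allowed_probes = probes[5:40])
  expect_false(any(probes[1:4] %in% c(sig3$up_tags, sig3$down_tags)))
  # with strictly ordered ratios, tags are the extremes of the ordering
  sig4 <- build_signature(treated, control, n_up = 5, n_down = 5,
                          allowed_probes = probes[2:40])
  kept <- setdiff(probes[2:40], probes[1])
  expect_equal(sig4$up_tags, kept[1:5])
  expect_equal(sig4$down_tags, rev(kept)[1:5])
})

test_that("too few surviving probes is an error stating counts", {
  probes <- sprintf("p%02d", 1:10)
  treated <- tibble::tibble(probe_id = probes, signal = 1000, present = TRUE)
  control <- treated
  expect_error(
    build_signature(treated, control, n_up = 8, n_down = 8),
    "survive"
  )
})

test_that("missing signature tags are dropped with a warning, all missing errors", {
  n <- 20
  inst <- tibble::tibble(instance_id = "i", compound = "c",
                         probe_id = sprintf("p%02d", 1:n), rank = 1:n)
  sig <- list(up_tags = c("p01", "NOPE"), down_tags = c("p19", "p20"))
  expect_warning(res <- connectivity_scores(inst, sig), "dropped")
  expect_equal(res$ks_up, ks_statistic(1, n))
  sig_all_missing <- list(up_tags = "X", down_tags = "Y")
  expect_error(
    suppressWarnings(connectivity_scores(inst, sig_all_missing)),
    "none of the signature tags"
  )
})
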