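#' Pipeline configuration
#'
#' Assembles and validates the configuration for [run_pipeline()]: stage
#' toggles, the three synthetic-data scenarios, analysis thresholds and
#' seeds. Unknown keys are rejected so typos cannot silently disable an
#' option.
#'
#' @param stages Named logical vector toggling the stages `simulate`, `qc`,
#'   `si`, `hits`, `fit`, `profile`, `connect`, `gsea`, `report`; omitted
#'   stages default to `TRUE`.
#' @param screen,panel,connectivity Scenario objects ([screen_scenario()],
#'   [panel_scenario()], [connectivity_scenario()]).
#' @param resistant_line,parental_line Lines for hit calling; default the
#'   first two lines of the screen scenario.
#' @param hit_threshold SI threshold for hit calling (percent).
#' @param assay_kind QC assay kind for the screen plates.
#' @param n_up,n_down,min_signal Signature-construction parameters.
#' @param n_perm GSEA permutations.
#' @param gsea_seed Seed for the GSEA permutation draw.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(stages = NULL,
                            screen = screen_scenario(),
                            panel = panel_scenario(),
                            connectivity = connectivity_scenario(),
                            resistant_line = NULL,
                            parental_line = NULL,
                            hit_threshold = 50,
                            assay_kind = "cell_line",
                            n_up = 20, n_down = 10, min_signal = 300,
                            n_perm = 1000, gsea_seed = 1L) {
  stage_names <- c("simulate", "qc", "si", "hits", "fit", "profile",
                   "connect", "gsea", "report")
  on <- setNames(rep(TRUE, length(stage_names)), stage_names)
  if (!is.null(stages)) {
    unknown <- setdiff(names(stages), stage_names)
    if (length(unknown) > 0) {
      abort(paste("unknown stage(s):", paste(unknown, collapse = ", ")))
    }
    on[names(stages)] <- stages
  }
  if (is.null(resistant_line)) resistant_line <- screen$lines[1]
  if (is.null(parental_line)) parental_line <- screen$lines[2]
  structure(
    list(
      stages = on, screen = screen, panel = panel, connectivity = connectivity,
      resistant_line = resistant_line, parental_line = parental_line,
      hit_threshold = hit_threshold, assay_kind = assay_kind,
      n_up = n_up, n_down = n_down, min_signal = min_signal,
      n_perm = n_perm, gsea_seed = as.integer(gsea_seed)
    ),
    class = "pipeline_config"
  )
}

#' Run the screening-to-mechanism pipeline end to end
#'
#' Executes the enabled stages in dependency order — simulate, qc, si,
#' hits, fit, profile, connect, gsea, report — writing each stage's
#' artifacts as plain-text tables into `out_dir` and finishing with a
#' manifest (JSON) that records the configuration hash, seeds, package
#' version and the artifact list. Stages never modify upstream artifacts; a
#' rerun with the same configuration reproduces identical results and an
#' identical configuration hash. A disabled upstream stage whose output a
#' later stage needs is an error naming that stage.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  on <- config$stages
  res <- list()
  artifacts <- character()
  save_csv <- function(x, name) {
    path <- file.path(out_dir, name)
    readr::write_csv(x, path)
    artifacts <<- c(artifacts, name)
  }
  need <- function(x, stage) {
    if (is.null(x)) abort(sprintf("missing upstream artifact: stage '%s' has not run.", stage))
    x
  }

  if (on["simulate"]) {
    res$screen <- generate_screen(config$screen)
    res$panel <- generate_panel(config$panel)
    res$cdb <- generate_connectivity_db(config$connectivity)
    save_csv(res$screen$wells, "screen_wells.csv")
    save_csv(res$screen$truth, "screen_truth.csv")
    save_csv(res$panel$si, "panel_si.csv")
    save_csv(res$panel$truth, "panel_truth.csv")
    save_csv(res$cdb$instances, "connectivity_instances.csv")
  }
  if (on["qc"]) {
    res$qc <- qc_plates(need(res$screen, "simulate")$wells, config$assay_kind)
    save_csv(res$qc, "plate_qc.csv")
  }
  if (on["si"]) {
    res$si <- compute_si(need(res$screen, "simulate")$wells)
    save_csv(res$si, "survival_index.csv")
  }
  if (on["hits"]) {
    res$hits <- call_hits(need(res$si, "si"), config$resistant_line,
                          config$parental_line, config$hit_threshold)
    save_csv(res$hits, "hit_list.csv")
  }
  if (on["fit"]) {
    panel <- need(res$panel, "simulate")
    fits <- fit_dose_response(panel$si)
    res$fits <- fits %>% dplyr::select(-"fit")
    save_csv(res$fits, "dose_response_fits.csv")
    res$ic50_summary <- summarize_panel_ic50(res$fits)
    save_csv(res$ic50_summary, "median_ic50_by_diagnosis.csv")
  }
  if (on["profile"]) {
    panel <- need(res$panel, "simulate")
    ic50_tbl <- need(res$fits, "fit")
    res$activity <- activity_report(panel$si, ic50_tbl)
    save_csv(res$activity$response_rates, "response_rates.csv")
    save_csv(glance(res$activity), "activity_summary.csv")
  }
  if (on["connect"]) {
    cdb <- need(res$cdb, "simulate")
    res$signature <- build_signature(cdb$query$treated, cdb$query$control,
                                     n_up = config$n_up, n_down = config$n_down,
                                     min_signal = config$min_signal)
    res$connectivity <- connectivity_scores(cdb$instances, res$signature) %>%
      normalize_scores()
    res$ranking <- rank_compounds(res$connectivity)
    save_csv(res$connectivity, "connectivity_scores.csv")
    save_csv(res$ranking, "compound_ranking.csv")
  }
  if (on["gsea"]) {
    cdb <- need(res$cdb, "simulate")
    # score genes by query log-ratio; test the query mechanism's up-template
    merged <- dplyr::inner_join(
      cdb$query$treated %>% dplyr::select("probe_id", t = "signal"),
      cdb$query$control %>% dplyr::select("probe_id", c = "signal"),
      by = "probe_id"
    )
    scores <- setNames(log2(merged$t / merged$c), merged$probe_id)
    tpl <- cdb$templates %>%
      dplyr::filter(.data$mechanism == cdb$scenario$query_mechanism,
                    .data$log2_fc > 0)
    res$gsea <- gsea_preranked(scores, tpl$probe_id, n_perm = config$n_perm,
                               seed = config$gsea_seed)
    save_csv(glance(res$gsea), "gsea_query_template.csv")
  }
  if (on["report"]) {
    rep_path <- file.path(out_dir, "report.md")
    .write_report(res, config, rep_path)
    artifacts <- c(artifacts, "report.md")
  }

  manifest <- list(
    package = "mdrscreen",
    version = as.character(utils::packageVersion("mdrscreen")),
    config_hash = rlang::hash(config),
    seeds = list(screen = config$screen$seed, panel = config$panel$seed,
                 connectivity = config$connectivity$seed,
                 gsea = config$gsea_seed),
    stages = as.list(on),
    artifacts = artifacts
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  res$manifest <- manifest
  invisible(res)
}

.write_report <- function(res, config, path) {
  lines <- c("# Pipeline report", "")
  if (!is.null(res$hits)) {
    nh <- sum(res$hits$is_hit)
    lines <- c(lines, sprintf("## Differential screen"),
               sprintf("- %d compounds scored; %d hit(s) (SI < %g in %s, > %g in %s)",
                       nrow(res$hits), nh, config$hit_threshold,
                       config$resistant_line, config$hit_threshold,
                       config$parental_line),
               if (nh > 0) paste0("- hits: ",
                                  paste(res$hits$compound_id[res$hits$is_hit],
                                        collapse = ", ")),
               "")
  }
  if (!is.null(res$qc)) {
    lines <- c(lines, sprintf("- plates passing QC: %d / %d",
                              sum(res$qc$passed), nrow(res$qc)), "")
  }
  if (!is.null(res$ic50_summary)) {
    lines <- c(lines, "## Median IC50 by diagnosis", "",
               "| diagnosis | median IC50 (uM) | n |",
               "|---|---|---|",
               sprintf("| %s | %s | %d |", res$ic50_summary$diagnosis,
                       res$ic50_summary$label, res$ic50_summary$n),
               "")
  }
  if (!is.null(res$activity)) {
    lines <- c(lines, sprintf(
      "- reference concentration %g uM; overall median SI %.1f; S/H ratio %.3g",
      res$activity$reference_concentration, res$activity$overall_median_si,
      res$activity$sh_ratio
    ), "")
  }
  if (!is.null(res$ranking)) {
    topc <- utils::head(res$ranking, 5)
    lines <- c(lines, "## Connectivity ranking (top 5)", "",
               sprintf("- %s (mean score %.3f, %d instances)",
                       topc$compound, topc$mean_score, topc$n_instances),
               "")
  }
  if (!is.null(res$gsea)) {
    lines <- c(lines, sprintf("- GSEA of the query up-template: ES %.3f, nominal p %.4g",
                              res$gsea$es, res$gsea$nominal_p), "")
  }
  readr::write_lines(lines, path)
  invisible(path)
}
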