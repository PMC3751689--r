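#' Build an up/down query signature from a treated/control pair
#'
#' Probes are kept when their signal exceeds `min_signal` in *both*
#' conditions, they carry a present detection call in both, and they belong
#' to the allowed reference-probe list (chip-compatibility filter).
#' Surviving probes are ranked by the treated/control signal ratio, ties
#' broken by probe id for determinism; the top `n_up` become the up tags
#' and the bottom `n_down` the down tags.
#'
#' @param treated,control Tibbles with columns `probe_id`, `signal`,
#'   `present` over an identical probe universe.
#' @param n_up,n_down Tag-list sizes (defaults 20 and 10).
#' @param min_signal Intensity filter in arbitrary units (default 300),
#'   applied to both conditions.
#' @param allowed_probes Character vector of admissible probe ids; default
#'   all probes of the pair.
#' @return List of class `query_signature` with ordered character vectors
#'   `up_tags` (most up-regulated first) and `down_tags` (most
#'   down-regulated first), plus `n_filtered` — the number of probes that
#'   survived filtering.
#' @export
build_signature <- function(treated, control, n_up = 20, n_down = 10,
                            min_signal = 300, allowed_probes = NULL) {
  treated <- tibble::as_tibble(treated)
  control <- tibble::as_tibble(control)
  req <- c("probe_id", "signal", "present")
  stopifnot(all(req %in% names(treated)), all(req %in% names(control)))
  if (!setequal(treated$probe_id, control$probe_id)) {
    abort("treated and control profiles must share an identical probe universe.")
  }
  if (is.null(allowed_probes)) allowed_probes <- treated$probe_id
  if (length(allowed_probes) == 0) abort("`allowed_probes` must be non-empty.")
  merged <- dplyr::inner_join(
    treated %>% dplyr::select("probe_id", t_signal = "signal", t_present = "present"),
    control %>% dplyr::select("probe_id", c_signal = "signal", c_present = "present"),
    by = "probe_id"
  ) %>%
    dplyr::filter(
      .data$t_signal > min_signal, .data$c_signal > min_signal,
      .data$t_present, .data$c_present,
      .data$probe_id %in% allowed_probes
    ) %>%
    dplyr::mutate(ratio = .data$t_signal / .data$c_signal) %>%
    dplyr::arrange(dplyr::desc(.data$ratio), .data$probe_id)
  if (nrow(merged) < n_up + n_down) {
    abort(sprintf(
      "only %d probes survive filtering; %d are needed (%d up + %d down).",
      nrow(merged), n_up + n_down, n_up, n_down
    ))
  }
  structure(
    list(
      up_tags = merged$probe_id[seq_len(n_up)],
      down_tags = rev(merged$probe_id[(nrow(merged) - n_down + 1):nrow(merged)]),
      n_filtered = nrow(merged)
    ),
    class = "query_signature"
  )
}

#' @export
print.query_signature <- function(x, ...) {
  cat("<query_signature>", length(x$up_tags), "up /", length(x$down_tags),
      "down tags from", x$n_filtered, "filtered probes\n")
  invisible(x)
}

#' Two-tail rank Kolmogorov-Smirnov statistic for a tag list
#'
#' Given the ranks of `t` tag probes inside a ranked list of `n` probes
#' (rank 1 = most up-regulated), computes
#' `a = max_j (j/t - V(j)/n)` and `b = max_j (V(j)/n - (j-1)/t)` over the
#' ascending tag ranks `V`, and returns `a` if `a > b`, else `-b`. The
#' statistic lies in (-1, 1): near +1 when the tags crowd the top of the
#' list, near -1 when they crowd the bottom.
#'
#' @param tag_ranks Distinct integer ranks in `1..n`; `1 <= t < n`.
#' @param n Size of the ranked probe universe.
#' @return Numeric statistic in \[-1, 1\].
#' @export
#' @examples
#' ks_statistic(c(1, 2), 10)   #  0.8
#' ks_statistic(c(9, 10), 10)  # -0.9
ks_statistic <- function(tag_ranks, n) {
  t <- length(tag_ranks)
  if (t == 0 || t >= n) abort("need 1 <= t < n tag ranks (tails undefined otherwise).")
  if (anyDuplicated(tag_ranks) || any(tag_ranks < 1) || any(tag_ranks > n) ||
      any(tag_ranks != round(tag_ranks))) {
    abort("tag ranks must be distinct integers within 1..n.")
  }
  v <- sort(tag_ranks)
  j <- seq_len(t)
  a <- max(j / t - v / n)
  b <- max(v / n - (j - 1) / t)
  if (a > b) a else -b
}

#' Score a signature against ranked instances
#'
#' For every instance, the up-tag and down-tag KS statistics are computed
#' on the instance's probe ranking; the raw connectivity score is
#' `ks_up - ks_down` when the two have opposite signs and 0 when they share
#' a sign (a profile cannot both mimic and oppose the query). Signature
#' tags absent from an instance's universe are dropped with a warning and
#' the tag count adjusted; an instance containing none of the tags is an
#' error.
#'
#' @param instances Long tibble with columns `instance_id`, `compound`,
#'   `probe_id`, `rank` (a permutation of `1..n` per instance), as from
#'   [generate_connectivity_db()].
#' @param signature A [build_signature()] result, or any list with
#'   character vectors `up_tags` and `down_tags`.
#' @return Tibble with one row per instance: `instance_id`, `compound`,
#'   `ks_up`, `ks_down`, `raw_score`. Pipe into [normalize_scores()].
#' @export
connectivity_scores <- function(instances, signature) {
  instances <- tibble::as_tibble(instances)
  stopifnot(all(c("instance_id", "compound", "probe_id", "rank") %in% names(instances)))
  up <- signature$up_tags
  down <- signature$down_tags
  if (length(intersect(up, down)) > 0) abort("up and down tags must be disjoint.")
  dropped <- 0L
  out <- instances %>%
    dplyr::group_by(.data$instance_id, .data$compound) %>%
    dplyr::group_modify(function(d, k) {
      r <- d$rank
      if (anyDuplicated(r) || !setequal(r, seq_along(r))) {
        abort(sprintf("instance %s: ranks are not a permutation of 1..n.",
                      k$instance_id))
      }
      n <- nrow(d)
      up_ranks <- d$rank[match(up, d$probe_id)]
      down_ranks <- d$rank[match(down, d$probe_id)]
      n_missing <- sum(is.na(up_ranks)) + sum(is.na(down_ranks))
      if (n_missing == length(up) + length(down)) {
        abort(sprintf("instance %s contains none of the signature tags.",
                      k$instance_id))
      }
      dropped <<- dropped + n_missing
      up_ranks <- up_ranks[!is.na(up_ranks)]
      down_ranks <- down_ranks[!is.na(down_ranks)]
      ks_up <- ks_statistic(up_ranks, n)
      ks_down <- ks_statistic(down_ranks, n)
      raw <- if (ks_up * ks_down > 0) 0 else ks_up - ks_down
      tibble::tibble(ks_up = ks_up, ks_down = ks_down, raw_score = raw)
    }) %>%
    dplyr::ungroup()
  if (dropped > 0) {
    warn(sprintf("%d signature tag occurrence(s) missing from instance universes were dropped.",
                 dropped))
  }
  out
}

#' Normalize raw connectivity scores
#'
#' Positive raw scores are divided by the maximum positive raw score and
#' negative ones by the absolute value of the most negative, so the best
#' mimicking instance scores exactly +1 and the strongest opposing instance
#' exactly -1. All-zero inputs stay 0. Idempotent and invariant to positive
#' rescaling of the raw scores.
#'
#' @param results Tibble from [connectivity_scores()] (needs `raw_score`).
#' @return The input with a `normalized_score` column added (overwritten if
#'   present).
#' @export
normalize_scores <- function(results) {
  results <- tibble::as_tibble(results)
  stopifnot("raw_score" %in% names(results))
  raw <- results$raw_score
  pos_max <- suppressWarnings(max(raw[raw > 0]))
  neg_min <- suppressWarnings(min(raw[raw < 0]))
  results$normalized_score <- dplyr::case_when(
    raw > 0 ~ raw / pos_max,
    raw < 0 ~ raw / abs(neg_min),
    TRUE ~ 0
  )
  results
}

#' Rank compounds by mean normalized connectivity
#'
#' Aggregates instance-level normalized scores to one row per compound
#' (mean over its instances), ordered by descending mean score — the
#' compounds whose expression response most resembles the query signature
#' come first.
#'
#' @param results Tibble with `compound` and `normalized_score` columns
#'   (from [normalize_scores()]).
#' @return Tibble of class `connectivity_ranking`: `compound`,
#'   `mean_score`, `n_instances`, descending.
#' @export
rank_compounds <- function(results) {
  results <- tibble::as_tibble(results)
  stopifnot(all(c("compound", "normalized_score") %in% names(results)))
  out <- results %>%
    dplyr::group_by(.data$compound) %>%
    dplyr::summarise(
      mean_score = mean(.data$normalized_score),
      n_instances = dplyr::n(),
      .groups = "drop"
    ) %>%
    dplyr::arrange(dplyr::desc(.data$mean_score))
  class(out) <- c("connectivity_ranking", class(out))
  out
}
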