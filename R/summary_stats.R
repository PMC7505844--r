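#' Named cell-QC rule presets
#'
#' Three presets covering the droplet and plate filtering schemes:
#'
#' * `droplet_fluid_blood`: remove cells with pct_mito > 10, n_genes < 500
#'   or > 3500, or n_counts (UMIs) > 25,000.
#' * `droplet_tissue`: remove cells with pct_mito > 10, n_genes < 200 or
#'   > 2000, or n_counts > 10,000.
#' * `plate`: remove cells with pct_mito above median + 5 MAD, n_counts
#'   (reads) < 500,000 or > 5,000,000 or above median + 3 MAD, or n_genes
#'   < 1000 or > 6000.
#'
#' All inequalities are strict: a cell sitting exactly on a threshold is
#' kept. The plate mitochondrial rule is robust (MAD-based); an absolute
#' variant (`plate_abs_mito`, cutoff 8.35%) is provided as an alternative
#' reading of the same scheme.
#'
#' @param name Preset name; omit to get the full named list.
#' @return A rules tibble (`metric`, `rule`, `threshold`, `k_mad`) or a
#'   named list of them.
#' @export
qc_rule_presets <- function(name = NULL) {
  rule <- function(metric, rule, threshold = NA_real_, k_mad = NA_real_) {
    tibble(metric = metric, rule = rule, threshold = threshold, k_mad = k_mad)
  }
  presets <- list(
    droplet_fluid_blood = bind_rows(
      rule("pct_mito", "GT", 10),
      rule("n_genes", "LT", 500),
      rule("n_genes", "GT", 3500),
      rule("n_counts", "GT", 25000)
    ),
    droplet_tissue = bind_rows(
      rule("pct_mito", "GT", 10),
      rule("n_genes", "LT", 200),
      rule("n_genes", "GT", 2000),
      rule("n_counts", "GT", 10000)
    ),
    plate = bind_rows(
      rule("pct_mito", "MAD_GT", k_mad = 5),
      rule("n_counts", "LT", 5e5),
      rule("n_counts", "GT", 5e6),
      rule("n_counts", "MAD_GT", k_mad = 3),
      rule("n_genes", "LT", 1000),
      rule("n_genes", "GT", 6000)
    ),
    plate_abs_mito = bind_rows(
      rule("pct_mito", "GT", 8.35),
      rule("n_counts", "LT", 5e5),
      rule("n_counts", "GT", 5e6),
      rule("n_counts", "MAD_GT", k_mad = 3),
      rule("n_genes", "LT", 1000),
      rule("n_genes", "GT", 6000)
    )
  )
  if (is.null(name)) return(presets)
  if (!name %in% names(presets)) {
    abort(sprintf("unknown QC preset '%s' (available: %s)", name,
                  paste(names(presets), collapse = ", ")),
          class = "synovitcr_config_error")
  }
  presets[[name]]
}

#' Robust MAD bounds
#'
#' `median(x) +/- k * MAD` where MAD is the unscaled median absolute
#' deviation `median(|x - median(x)|)`. A degenerate MAD of zero collapses
#' both bounds onto the median.
#'
#' @param values Numeric vector with at least 2 finite values.
#' @param k Number of MADs.
#' @return Named numeric vector `c(lower, upper)`.
#' @export
#' @examples
#' mad_bounds(c(1, 2, 3, 4, 5), k = 1)  # (2, 4)
mad_bounds <- function(values, k) {
  values <- values[is.finite(values)]
  if (length(values) < 2) {
    abort("need at least 2 finite values", class = "synovitcr_usage_error")
  }
  med <- median(values)
  mad_u <- median(abs(values - med))
  c(lower = med - k * mad_u, upper = med + k * mad_u)
}

#' Filter cells on QC metrics
#'
#' A cell is removed iff at least one rule fires; every removed cell lists
#' all rules that fired on it. Rules are strict inequalities: `GT` fires
#' when `value > threshold`, `LT` when `value < threshold`; `MAD_GT` /
#' `MAD_LT` fire above `median + k_mad * MAD` / below `median - k_mad * MAD`
#' of that metric over the input cohort. Filtering the kept set again
#' with absolute rules removes nothing (idempotence); MAD rules are
#' recomputed on whatever cohort they are given.
#'
#' @param metrics Tibble with `barcode` and the metric columns the rules
#'   reference (`n_genes`, `n_counts`, `pct_mito`).
#' @param rules A rules tibble (see [qc_rule_presets()]) or a preset name.
#' @return A list with `kept` (rows of `metrics`) and `removed` (rows plus a
#'   `reasons` character column, comma-separated fired rules).
#' @export
filter_cells <- function(metrics, rules) {
  if (is.character(rules) && length(rules) == 1) rules <- qc_rule_presets(rules)
  metrics <- as_tibble(metrics)
  unknown <- setdiff(unique(rules$metric), names(metrics))
  if (length(unknown) > 0) {
    abort(sprintf("rules reference unknown metric(s): %s",
                  paste(unknown, collapse = ", ")),
          class = "synovitcr_config_error")
  }
  fired <- matrix(FALSE, nrow = nrow(metrics), ncol = nrow(rules))
  labels <- character(nrow(rules))
  for (i in seq_len(nrow(rules))) {
    x <- metrics[[rules$metric[i]]]
    fired[, i] <- switch(
      rules$rule[i],
      GT = x > rules$threshold[i],
      LT = x < rules$threshold[i],
      MAD_GT = x > mad_bounds(x, rules$k_mad[i])[["upper"]],
      MAD_LT = x < mad_bounds(x, rules$k_mad[i])[["lower"]],
      abort(sprintf("unknown rule type '%s'", rules$rule[i]),
            class = "synovitcr_config_error")
    )
    labels[i] <- if (rules$rule[i] %in% c("GT", "LT")) {
      sprintf("%s_%s_%g", rules$metric[i], tolower(rules$rule[i]),
              rules$threshold[i])
    } else {
      sprintf("%s_%s_%gmad", rules$metric[i], tolower(rules$rule[i]),
              rules$k_mad[i])
    }
  }
  fired[is.na(fired)] <- FALSE
  any_fired <- rowSums(fired) > 0
  removed <- metrics[any_fired, , drop = FALSE]
  removed$reasons <- apply(fired[any_fired, , drop = FALSE], 1, function(f) {
    paste(labels[f], collapse = ",")
  })
  list(kept = metrics[!any_fired, , drop = FALSE], removed = as_tibble(removed))
}

#' V-J usage matrix with equal patient weighting
#'
#' Per patient and sample type, computes the frequency of every beta-chain
#' V-J gene pairing over that patient's cells (each patient's matrix sums
#' to 1), then averages the per-patient matrices *with equal weight per
#' patient* within each sample type. Patients with zero cells in a sample
#' type are excluded from that average with a warning.
#'
#' @param cells A tibble with one row per clonotype-bearing cell:
#'   `patient_id`, `sample_type`, `v_gene`, `j_gene` (beta chain calls).
#' @return A `vj_usage` tibble: `sample_type`, `v_gene`, `j_gene`, `weight`
#'   (sums to 1 within each sample type); per-patient matrices are kept in
#'   `attr(x, "per_patient")`.
#' @export
vj_usage <- function(cells) {
  cells <- as_tibble(cells)
  assert_columns(cells, c("patient_id", "sample_type", "v_gene", "j_gene"),
                 what = "cells")
  cells <- filter(cells, !is.na(.data$v_gene), !is.na(.data$j_gene))
  per_patient <- cells |>
    count(.data$sample_type, .data$patient_id, .data$v_gene, .data$j_gene) |>
    group_by(.data$sample_type, .data$patient_id) |>
    mutate(freq = .data$n / sum(.data$n)) |>
    ungroup()
  n_pat <- per_patient |>
    distinct(.data$sample_type, .data$patient_id) |>
    count(.data$sample_type, name = "n_patients")
  out <- per_patient |>
    group_by(.data$sample_type, .data$v_gene, .data$j_gene) |>
    summarise(freq_sum = sum(.data$freq), .groups = "drop") |>
    left_join(n_pat, by = "sample_type") |>
    mutate(weight = .data$freq_sum / .data$n_patients) |>
    select("sample_type", "v_gene", "j_gene", "weight") |>
    arrange(.data$sample_type, dplyr::desc(.data$weight))
  attr(out, "per_patient") <- per_patient
  class(out) <- c("vj_usage", class(out))
  out
}

#' Paired analyte panel test
#'
#' Per analyte, a two-sided paired t test between the two conditions (e.g.
#' plasma vs. synovial fluid), with Bonferroni correction over the number of
#' analytes tested. Subjects missing either side of a pair are dropped
#' pairwise per analyte. Zero variance of the paired differences yields
#' `NaN` p-values with a warning rather than 0 or 1.
#'
#' @param panel Long tibble with columns `subject_id`, `analyte`,
#'   `condition` (exactly two levels; the reported `mean_diff` is the second
#'   level minus the first, in order of first appearance) and `value`.
#' @return A tibble per analyte: `analyte`, `n_pairs`, `mean_diff`,
#'   `t`, `p_raw`, `p_adj`.
#' @export
paired_panel_test <- function(panel) {
  panel <- as_tibble(panel)
  assert_columns(panel, c("subject_id", "analyte", "condition", "value"),
                 what = "panel")
  conds <- unique(panel$condition)  # order of first appearance; diff = 2nd - 1st
  if (length(conds) != 2) {
    abort(sprintf("expected exactly 2 conditions, got %d", length(conds)),
          class = "synovitcr_usage_error")
  }
  wide <- panel |>
    tidyr::pivot_wider(id_cols = c("analyte", "subject_id"),
                       names_from = "condition", values_from = "value") |>
    filter(!is.na(.data[[conds[1]]]), !is.na(.data[[conds[2]]]))
  res <- wide |>
    group_by(.data$analyte) |>
    summarise(
      n_pairs = n(),
      mean_diff = mean(.data[[conds[2]]] - .data[[conds[1]]]),
      sd_diff = sd(.data[[conds[2]]] - .data[[conds[1]]]),
      .groups = "drop"
    )
  if (any(res$n_pairs < 3)) {
    abort(sprintf("analyte '%s' has fewer than 3 complete pairs",
                  res$analyte[res$n_pairs < 3][1]),
          class = "synovitcr_usage_error")
  }
  if (any(res$sd_diff == 0)) {
    warn(sprintf("zero variance of paired differences for: %s",
                 paste(res$analyte[res$sd_diff == 0], collapse = ", ")))
  }
  t_stat <- ifelse(res$sd_diff > 0,
                   res$mean_diff / (res$sd_diff / sqrt(res$n_pairs)), NaN)
  p_raw <- ifelse(is.nan(t_stat), NaN,
                  2 * pt(abs(t_stat), df = res$n_pairs - 1, lower.tail = FALSE))
  m <- nrow(res)
  res |>
    mutate(t = t_stat, p_raw = p_raw, p_adj = pmin(1, p_raw * m)) |>
    select("analyte", "n_pairs", "mean_diff", "t", "p_raw", "p_adj")
}
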