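#' Assign clonotypes from cell partitions
#'
#' A cell's clonotype is defined by the combined alpha- and beta-chain CDR3
#' nucleotide sequences. `OK` cells are keyed by their sorted alpha CDR3-nt
#' tuple plus the beta CDR3-nt, so the key is invariant to alpha-chain order.
#' Because alpha/beta pairing cannot be deduced for partitions with multiple
#' beta chains, those partitions can either be treated as a single clone
#' keyed on the sorted beta CDR3-nt tuple (`include_multiplet_beta = TRUE`,
#' appropriate for pure clonality analysis) or excluded outright
#' (`include_multiplet_beta = FALSE`, appropriate when linking clones to
#' expression data). `ALPHA_ONLY` and `EMPTY` cells never join a clone: a
#' clone requires at least one beta chain.
#'
#' Clonotypes are per-patient entities; supplying partitions from more than
#' one patient is an error.
#'
#' @param partitions A `tcr_partitions` object for a single patient.
#' @param include_multiplet_beta Treat multi-beta partitions as single clones
#'   keyed on their beta set? Default `FALSE`.
#'
#' @return A `tcr_clonotypes` tibble with one row per clone member cell:
#'   `patient_id`, `sample_id`, `barcode`, `clone_id`, `clone_key`,
#'   `clone_size` (cells across all samples). Clone ids are ordered by
#'   descending clone size, ties broken by key.
#' @export
assign_clonotypes <- function(partitions, include_multiplet_beta = FALSE) {
  patients <- unique(partitions$patient_id)
  if (length(patients) > 1) {
    abort(sprintf(
      "clonotypes are per-patient; got partitions for %d patients (%s)",
      length(patients), paste(head(patients, 5), collapse = ", ")
    ), class = "synovitcr_usage_error")
  }
  chains <- partition_chains(partitions)

  key_ok <- chains |>
    filter(.data$status == "OK") |>
    group_by(.data$patient_id, .data$sample_id, .data$barcode) |>
    summarise(clone_key = paste0(
      paste(sort(.data$cdr3_nt[.data$locus == "TRA"]), collapse = "+"),
      "|",
      .data$cdr3_nt[.data$locus == "TRB"][1]
    ), .groups = "drop")

  cells <- key_ok
  if (include_multiplet_beta) {
    key_mb <- chains |>
      filter(.data$status == "MULTIPLET") |>
      group_by(.data$patient_id, .data$sample_id, .data$barcode) |>
      summarise(
        n_beta = sum(.data$locus == "TRB"),
        clone_key = paste0("MB|", paste(sort(.data$cdr3_nt[.data$locus == "TRB"]),
                                        collapse = "+")),
        .groups = "drop"
      ) |>
      filter(.data$n_beta >= 2) |>
      select(-"n_beta")
    cells <- bind_rows(cells, key_mb)
  }

  sizes <- cells |> count(.data$clone_key, name = "clone_size") |>
    arrange(dplyr::desc(.data$clone_size), .data$clone_key) |>
    mutate(clone_id = sprintf("C%04d", row_number()))
  out <- cells |>
    left_join(sizes, by = "clone_key") |>
    select("patient_id", "sample_id", "barcode", "clone_id", "clone_key",
           "clone_size") |>
    arrange(.data$clone_id, .data$sample_id, .data$barcode)
  class(out) <- c("tcr_clonotypes", class(out))
  out
}

#' Two-sided Fisher's exact test for 2x2 tables (vectorised)
#'
#' The two-sided p-value is the sum of hypergeometric probabilities of all
#' tables with the observed margins whose probability does not exceed that of
#' the observed table (within relative tolerance 1e-7). The odds ratio is the
#' unconditional cross-product ratio `a*d / (b*c)`: `Inf` when `b*c == 0`
#' and `a*d > 0`, `NaN` when both products are zero. The table is read
#' row-wise: `matrix(c(a, b, c, d), 2, 2, byrow = TRUE)`.
#'
#' @param a,b,c,d Nonnegative integer vectors of equal length (recycled).
#' @return A tibble with columns `odds_ratio` and `p`.
#' @export
#' @examples
#' fisher_exact_2x2(10, 90, 1, 99)
fisher_exact_2x2 <- function(a, b, c, d) {
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(as.numeric(a), n); b <- rep_len(as.numeric(b), n)
  c <- rep_len(as.numeric(c), n); d <- rep_len(as.numeric(d), n)
  vals <- cbind(a, b, c, d)
  if (any(is.na(vals)) || any(vals < 0) || any(vals != round(vals))) {
    abort("all table entries must be nonnegative integers",
          class = "synovitcr_domain_error")
  }
  or <- ifelse(a * d == 0 & b * c == 0, NaN,
               ifelse(b * c == 0, Inf, (a * d) / (b * c)))
  p <- vapply(seq_len(n), function(i) {
    m <- a[i] + b[i]           # row 1 total
    nn <- c[i] + d[i]          # row 2 total
    k <- a[i] + c[i]           # column 1 total
    support <- max(0, k - nn):min(k, m)
    probs <- dhyper(support, m, nn, k)
    p_obs <- dhyper(a[i], m, nn, k)
    sum(probs[probs <= p_obs * (1 + 1e-7)])
  }, numeric(1))
  tibble(odds_ratio = or, p = pmin(p, 1))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Adjusted values are capped at 1 and returned in input order; a sorted
#' input yields a non-decreasing output.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    abort("p-values must lie in [0, 1]", class = "synovitcr_domain_error")
  }
  p.adjust(p_values, method = "BH")
}

#' Test per-clone enrichment between two samples
#'
#' For every clone observed in either sample of a pair (e.g. synovial fluid
#' vs. blood from the same patient), compares the proportion of cells
#' belonging to that clone between the samples with a two-sided Fisher's
#' exact test, adjusting across all of the patient's clones with
#' Benjamini-Hochberg. A clone is called enriched in the sample where its
#' proportion is higher when the adjusted p-value is at or below
#' `alpha_level`. The per-sample denominator is the number of eligible
#' (clone-assigned) cells in that sample.
#'
#' @param clonotypes A `tcr_clonotypes` tibble from [assign_clonotypes()].
#' @param sample_pair Character vector of two `sample_id` values
#'   `c(A, B)`.
#' @param alpha_level Significance level on the adjusted p-value (inclusive).
#'   Default 0.05.
#'
#' @return A tibble with one row per clone: `clone_id`, `clone_key`,
#'   `a` (clone cells in A), `b` (other cells in A), `c` (clone cells in B),
#'   `d` (other cells in B), `odds_ratio`, `p_raw`, `p_adj`, `enriched_in`
#'   (`NA` when not significant).
#' @export
test_clonal_enrichment <- function(clonotypes, sample_pair, alpha_level = 0.05) {
  if (length(sample_pair) != 2 || anyDuplicated(sample_pair)) {
    abort("`sample_pair` must name two distinct samples",
          class = "synovitcr_usage_error")
  }
  cells <- filter(as_tibble(clonotypes), .data$sample_id %in% sample_pair)
  totals <- table(factor(cells$sample_id, levels = sample_pair))
  if (any(totals == 0)) {
    abort(sprintf("sample '%s' has no eligible cells",
                  sample_pair[which(totals == 0)[1]]),
          class = "synovitcr_usage_error")
  }
  counts <- cells |>
    count(.data$clone_id, .data$clone_key, .data$sample_id) |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "n",
                       values_fill = 0L)
  for (s in sample_pair) if (!s %in% names(counts)) counts[[s]] <- 0L
  a <- counts[[sample_pair[1]]]
  c_ <- counts[[sample_pair[2]]]
  b <- as.integer(totals[1]) - a
  d <- as.integer(totals[2]) - c_
  ft <- fisher_exact_2x2(a, b, c_, d)
  p_adj <- bh_adjust(ft$p)
  prop_a <- a / as.integer(totals[1])
  prop_b <- c_ / as.integer(totals[2])
  enriched_in <- ifelse(
    p_adj <= alpha_level & prop_a != prop_b,
    ifelse(prop_a > prop_b, sample_pair[1], sample_pair[2]),
    NA_character_
  )
  out <- tibble(
    clone_id = counts$clone_id, clone_key = counts$clone_key,
    a = a, b = b, c = c_, d = d,
    odds_ratio = ft$odds_ratio, p_raw = ft$p, p_adj = p_adj,
    enriched_in = enriched_in
  ) |>
    arrange(.data$p_adj, .data$p_raw, .data$clone_id)
  attr(out, "sample_pair") <- sample_pair
  attr(out, "alpha_level") <- alpha_level
  class(out) <- c("tcr_enrichment", class(out))
  out
}

#' Associate enriched cells with phenotype clusters
#'
#' Tests, per phenotype cluster, whether cells belonging to enriched clones
#' are overrepresented in that cluster, using a two-sided Fisher's exact test
#' with Bonferroni correction over the number of clusters tested. Clusters
#' with no cells at all are excluded from testing and do not count toward the
#' Bonferroni multiplier.
#'
#' @param cells A tibble with one row per cell carrying a `cluster_label`
#'   column and a logical `enriched` column.
#' @return A tibble per cluster: `cluster_label`, `a` (enriched cells in
#'   cluster), `b` (enriched elsewhere), `c` (non-enriched in cluster),
#'   `d` (non-enriched elsewhere), `odds_ratio`, `p_raw`, `p_adj`.
#' @export
associate_clusters <- function(cells) {
  assert_columns(cells, c("cluster_label", "enriched"), what = "cells")
  cells <- filter(as_tibble(cells), !is.na(.data$cluster_label))
  if (!any(cells$enriched)) {
    abort("no enriched cells supplied", class = "synovitcr_usage_error")
  }
  labels <- sort(unique(cells$cluster_label))
  if (length(labels) < 2) {
    abort("need at least 2 distinct cluster labels",
          class = "synovitcr_usage_error")
  }
  n_enr <- sum(cells$enriched)
  n_non <- sum(!cells$enriched)
  per <- cells |>
    group_by(.data$cluster_label) |>
    summarise(a = sum(.data$enriched), c = sum(!.data$enriched),
              .groups = "drop") |>
    mutate(b = n_enr - .data$a, d = n_non - .data$c)
  m <- nrow(per)
  ft <- fisher_exact_2x2(per$a, per$b, per$c, per$d)
  per |>
    mutate(odds_ratio = ft$odds_ratio, p_raw = ft$p,
           p_adj = pmin(1, .data$p_raw * m)) |>
    select("cluster_label", "a", "b", "c", "d", "odds_ratio", "p_raw", "p_adj") |>
    arrange(dplyr::desc(.data$odds_ratio))
}

#' Subsample every sample to an equal cell depth
#'
#' Draws a uniform random subset without replacement from each
#' `(patient_id, sample_id)` group so that all groups end up the same size,
#' mirroring equal-depth subsampling before joint analysis.
#'
#' @param cells A tibble with `patient_id` and `sample_id` columns, one row
#'   per cell.
#' @param target Target depth. Defaults to the smallest group size; an
#'   explicit target larger than some group is an error.
#' @param seed Integer seed; the same seed reproduces the same subsets.
#' @return The subsampled tibble.
#' @export
subsample_equal_depth <- function(cells, target = NULL, seed = 1L) {
  cells <- as_tibble(cells)
  assert_columns(cells, c("patient_id", "sample_id"), what = "cells")
  sizes <- count(cells, .data$patient_id, .data$sample_id)
  if (is.null(target)) target <- min(sizes$n)
  if (any(sizes$n < target)) {
    small <- sizes[sizes$n < target, ]
    abort(sprintf("sample %s/%s has %d cells, fewer than target %d",
                  small$patient_id[1], small$sample_id[1], small$n[1], target),
          class = "synovitcr_usage_error")
  }
  with_seed(seed, {
    cells |>
      group_by(.data$patient_id, .data$sample_id) |>
      slice(sort(sample.int(n(), target))) |>
      ungroup()
  })
}
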