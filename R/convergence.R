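#' Prepare beta-chain CDR3 input for convergence grouping
#'
#' Convergence (specificity) grouping operates on single beta-chain CDR3
#' amino-acid sequences only. Per patient, identical (CDR3 aa, V, J) beta
#' chains are aggregated into one sequence entry with a cell count. Because
#' alpha/beta pairing is unknowable for multi-beta partitions, each beta
#' chain of such a partition is emitted as a separate entry whose id carries
#' a `-v<k>` variant suffix. Alpha-only partitions contribute nothing and are
#' counted in `attr(x, "counters")["n_alpha_only_dropped"]`.
#'
#' @param partitions A `tcr_partitions` object (any number of patients).
#' @param reference Character vector of naive-reference CDR3 amino-acid
#'   sequences (must be non-empty; it is attached to the result).
#' @return A `gliph_input` tibble: `seq_id`, `cdr3_aa`, `v_gene`, `j_gene`,
#'   `patient_id`, `source_cells`; the reference is kept in
#'   `attr(x, "reference")`.
#' @export
prepare_gliph_input <- function(partitions, reference) {
  if (length(reference) == 0) {
    abort("naive reference CDR3 set is empty", class = "synovitcr_usage_error")
  }
  chains <- partition_chains(partitions)
  n_alpha_only <- partitions |> as_tibble() |>
    filter(.data$status == "ALPHA_ONLY") |> nrow()

  betas <- chains |> filter(.data$locus == "TRB")
  # Multi-beta partitions: each beta becomes its own variant entry.
  betas <- betas |>
    group_by(.data$patient_id, .data$sample_id, .data$barcode) |>
    mutate(variant = if (n() > 1) paste0("-v", row_number()) else "") |>
    ungroup()

  out <- betas |>
    count(.data$patient_id, .data$cdr3_aa, .data$v_gene, .data$j_gene,
          .data$variant, name = "source_cells") |>
    mutate(seq_id = paste0(.data$patient_id, ":", .data$cdr3_aa, ":",
                           .data$v_gene, ":", .data$j_gene, .data$variant)) |>
    select("seq_id", "cdr3_aa", "v_gene", "j_gene", "patient_id",
           "source_cells") |>
    arrange(.data$seq_id)
  attr(out, "reference") <- as.character(reference)
  attr(out, "counters") <- c(n_alpha_only_dropped = n_alpha_only)
  class(out) <- c("gliph_input", class(out))
  out
}

#' Enumerate interior CDR3 k-mers
#'
#' Counts every contiguous k-mer occurring in the interior of each CDR3
#' (the first and last `flank_trim` residues removed, excluding the
#' germline-templated ends). A motif is counted at most once per sequence
#' (presence semantics). Sequences shorter than `2 * flank_trim + k`
#' contribute nothing for that k.
#'
#' @param cdr3_set Character vector of CDR3 amino-acid sequences.
#' @param k_values Integer k-mer lengths, subset of \{2, 3, 4\}.
#' @param flank_trim Number of residues trimmed from each end (default 3).
#' @return A tibble `motif`, `k`, `n_seqs` (number of sequences containing
#'   the motif).
#' @export
#' @examples
#' enumerate_motifs("CASSNQNTEAFF", k_values = 4)
enumerate_motifs <- function(cdr3_set, k_values = c(2L, 3L, 4L), flank_trim = 3L) {
  if (!all(k_values %in% 2:4)) {
    abort("k_values must be a subset of {2, 3, 4}", class = "synovitcr_domain_error")
  }
  if (flank_trim < 0) abort("flank_trim must be >= 0", class = "synovitcr_domain_error")
  if (length(cdr3_set) == 0) {
    return(tibble(motif = character(), k = integer(), n_seqs = integer()))
  }
  lens <- nchar(cdr3_set)
  interior <- substr(cdr3_set, flank_trim + 1L, lens - flank_trim)
  ilen <- pmax(0L, lens - 2L * flank_trim)
  res <- purrr::map(sort(unique(as.integer(k_values))), function(k) {
    n_kmers <- pmax(0L, ilen - k + 1L)
    if (sum(n_kmers) == 0) {
      return(tibble(motif = character(), k = integer(), n_seqs = integer()))
    }
    seq_idx <- rep(seq_along(interior), n_kmers)
    starts <- sequence(n_kmers)
    kmers <- substr(rep(interior, n_kmers), starts, starts + k - 1L)
    # presence: count each (sequence, motif) pair once
    pairs <- unique(paste0(seq_idx, "\r", kmers))
    motif <- sub("^[0-9]+\r", "", pairs)
    tb <- table(motif)
    tibble(motif = names(tb), k = k, n_seqs = as.integer(tb))
  })
  bind_rows(res) |> arrange(.data$k, .data$motif)
}

#' Motif enrichment against a naive reference repertoire
#'
#' For every interior motif present in the sample, computes the fraction of
#' sample sequences containing it (`observed_freq`), the analogous fraction
#' in the naive reference (`reference_freq`), their ratio (`fold_change`;
#' `Inf` when the motif is absent from the reference), and a resampled
#' p-value: the fraction of `n_subsamples` random reference subsets of the
#' sample's size whose motif frequency reaches the observed frequency,
#' floored at `1 / n_subsamples` (so with the default 1000 subsamples the
#' smallest reportable p is 0.001).
#'
#' @param sample A `gliph_input` object from [prepare_gliph_input()], or any
#'   tibble with a `cdr3_aa` column (then `reference` must be supplied).
#' @param reference Character vector of reference CDR3s; defaults to
#'   `attr(sample, "reference")`. Must be at least as large as the sample.
#' @param k_values,flank_trim Motif enumeration parameters
#'   (see [enumerate_motifs()]).
#' @param n_subsamples Number of reference subsets drawn (default 1000).
#' @param seed Integer seed for the resampling.
#' @return A tibble `motif`, `k`, `n_support` (sample sequences containing
#'   the motif), `observed_freq`, `reference_freq`, `fold_change`,
#'   `p_resampled`.
#' @export
motif_enrichment <- function(sample, reference = NULL,
                             k_values = c(2L, 3L, 4L), flank_trim = 3L,
                             n_subsamples = 1000L, seed = 1L) {
  if (n_subsamples < 1) {
    abort("n_subsamples must be >= 1", class = "synovitcr_domain_error")
  }
  reference <- reference %||% attr(sample, "reference")
  if (is.null(reference) || length(reference) == 0) {
    abort("a non-empty naive reference is required", class = "synovitcr_usage_error")
  }
  seqs <- as_tibble(sample)$cdr3_aa
  n_s <- length(seqs)
  n_r <- length(reference)
  if (n_r < n_s) {
    abort(sprintf("reference (%d) must be at least sample size (%d)", n_r, n_s),
          class = "synovitcr_usage_error")
  }

  obs <- enumerate_motifs(seqs, k_values, flank_trim)
  if (nrow(obs) == 0) {
    return(tibble(motif = character(), k = integer(), n_support = integer(),
                  observed_freq = numeric(), reference_freq = numeric(),
                  fold_change = numeric(), p_resampled = numeric()))
  }
  motif_key <- paste0(obs$k, ":", obs$motif)

  # Sparse reference presence matrix restricted to sample motifs.
  ref_counts <- enumerate_motifs_presence(reference, k_values, flank_trim,
                                          keep = motif_key)
  M <- Matrix::sparseMatrix(
    i = ref_counts$seq_idx, j = ref_counts$motif_idx, x = 1,
    dims = c(n_r, length(motif_key))
  )
  ref_n <- Matrix::colSums(M)

  observed_freq <- obs$n_seqs / n_s
  reference_freq <- as.numeric(ref_n) / n_r
  fold_change <- ifelse(reference_freq > 0, observed_freq / reference_freq,
                        ifelse(observed_freq > 0, Inf, NaN))

  # Subset selection matrix: n_r x n_subsamples indicator of drawn subsets.
  p_resampled <- with_seed(seed, {
    idx <- replicate(n_subsamples, sample.int(n_r, n_s))
    S <- Matrix::sparseMatrix(
      i = as.vector(idx),
      j = rep(seq_len(n_subsamples), each = n_s),
      x = 1, dims = c(n_r, n_subsamples)
    )
    sub_counts <- Matrix::t(S) %*% M   # n_subsamples x n_motifs
    sub_freq <- as.matrix(sub_counts) / n_s
    hits <- colSums(sub_freq >= matrix(observed_freq, nrow = n_subsamples,
                                       ncol = length(observed_freq), byrow = TRUE))
    pmax(hits, 1) / n_subsamples
  })

  tibble(
    motif = obs$motif, k = obs$k, n_support = obs$n_seqs,
    observed_freq = observed_freq, reference_freq = reference_freq,
    fold_change = fold_change, p_resampled = p_resampled
  ) |>
    arrange(dplyr::desc(.data$fold_change), .data$p_resampled, .data$motif)
}

# Presence triplets (sequence index, motif index) for the motifs in `keep`
# (keys "k:motif"). Internal; shares enumeration logic with enumerate_motifs.
enumerate_motifs_presence <- function(seqs, k_values, flank_trim, keep) {
  lens <- nchar(seqs)
  interior <- substr(seqs, flank_trim + 1L, lens - flank_trim)
  ilen <- pmax(0L, lens - 2L * flank_trim)
  out_i <- integer(0); out_j <- integer(0)
  for (k in sort(unique(as.integer(k_values)))) {
    n_kmers <- pmax(0L, ilen - k + 1L)
    if (sum(n_kmers) == 0) next
    seq_idx <- rep(seq_along(interior), n_kmers)
    starts <- sequence(n_kmers)
    kmers <- substr(rep(interior, n_kmers), starts, starts + k - 1L)
    key <- paste0(k, ":", kmers)
    j <- match(key, keep)
    ok <- !is.na(j)
    if (!any(ok)) next
    pair <- unique(cbind(seq_idx[ok], j[ok]))
    out_i <- c(out_i, pair[, 1]); out_j <- c(out_j, pair[, 2])
  }
  list(seq_idx = out_i, motif_idx = out_j)
}

#' Global similarity edges between CDR3 sequences
#'
#' Emits an undirected edge between two sequence entries when their CDR3
#' amino-acid sequences have equal length and Hamming distance at most 1.
#' Sequences of different lengths are never linked regardless of similarity.
#'
#' @param sequences A tibble with `seq_id` and `cdr3_aa` columns.
#' @return A tibble of edges: `from`, `to` (seq_ids, `from < to`).
#' @export
global_edges <- function(sequences) {
  sequences <- as_tibble(sequences)
  assert_columns(sequences, c("seq_id", "cdr3_aa"), what = "sequences")
  edges <- list()
  for (len in unique(nchar(sequences$cdr3_aa))) {
    grp <- sequences[nchar(sequences$cdr3_aa) == len, ]
    if (nrow(grp) < 2) next
    # equal length: Levenshtein distance <= 1 is equivalent to Hamming <= 1
    dd <- adist(grp$cdr3_aa)
    hit <- which(dd <= 1 & upper.tri(dd), arr.ind = TRUE)
    if (nrow(hit) == 0) next
    edges[[length(edges) + 1L]] <- tibble(
      from = pmin(grp$seq_id[hit[, 1]], grp$seq_id[hit[, 2]]),
      to = pmax(grp$seq_id[hit[, 1]], grp$seq_id[hit[, 2]])
    )
  }
  if (length(edges) == 0) return(tibble(from = character(), to = character()))
  bind_rows(edges) |> distinct() |> arrange(.data$from, .data$to)
}

#' Build TCR convergence (specificity) groups
#'
#' Links beta-chain CDR3 sequence entries by (i) *global* edges — equal
#' length, Hamming distance <= 1 (see [global_edges()]) — and (ii) *local*
#' edges — two sequences sharing any motif that is enriched at
#' `fold_change >= fold_min`, `p_resampled <= p_max` and supported by at
#' least `min_depth` sample sequences. Convergence groups are the connected
#' components with at least 2 members of the union graph, ordered by
#' descending member count, ties broken by lexicographically smallest
#' member.
#'
#' @param sequences A `gliph_input` tibble (columns `seq_id`, `cdr3_aa`,
#'   `patient_id`).
#' @param motif_results Output of [motif_enrichment()] on the same
#'   sequences.
#' @param fold_min,p_max,min_depth Local-edge thresholds (defaults 10,
#'   0.001, 3).
#' @param flank_trim Interior trim used when matching motifs; must match the
#'   value used in [motif_enrichment()] (default 3).
#' @return A `tcr_convergence` tibble with one row per group: `crg_id`,
#'   `n_members`, `members` (list of seq_ids), `patients_represented`
#'   (list), `n_patients`, `top_motif`, `top_fold_change`, `top_p`. The edge
#'   list with `edge_type` (`GLOBAL`/`LOCAL`) is in `attr(x, "edges")`.
#' @export
build_convergence_groups <- function(sequences, motif_results,
                                     fold_min = 10, p_max = 0.001,
                                     min_depth = 3L, flank_trim = 3L) {
  sequences <- as_tibble(sequences)
  assert_columns(sequences, c("seq_id", "cdr3_aa", "patient_id"),
                 what = "sequences")
  sig <- motif_results |>
    filter(.data$fold_change >= fold_min,
           .data$p_resampled <= p_max,
           .data$n_support >= min_depth)

  g_edges <- global_edges(sequences) |> mutate(edge_type = "GLOBAL")

  l_edges <- tibble(from = character(), to = character())
  if (nrow(sig) > 0) {
    per_motif <- purrr::pmap(list(sig$motif, sig$k), function(motif, k) {
      hits <- sequences$seq_id[seq_has_motif(sequences$cdr3_aa, motif, k,
                                             flank_trim)]
      if (length(hits) < 2) return(NULL)
      cmb <- utils::combn(sort(hits), 2)
      tibble(from = cmb[1, ], to = cmb[2, ], motif = motif)
    })
    l_edges <- bind_rows(per_motif)
  }
  edge_motifs <- if (nrow(l_edges) > 0 && "motif" %in% names(l_edges)) {
    l_edges |> group_by(.data$from, .data$to) |>
      summarise(motifs = paste(unique(.data$motif), collapse = ","),
                .groups = "drop")
  } else tibble(from = character(), to = character(), motifs = character())
  l_edges <- distinct(select(l_edges, dplyr::any_of(c("from", "to")))) |>
    mutate(edge_type = "LOCAL")

  all_edges <- bind_rows(g_edges, l_edges) |>
    group_by(.data$from, .data$to) |>
    summarise(edge_type = paste(sort(unique(.data$edge_type)), collapse = "+"),
              .groups = "drop")

  if (nrow(all_edges) == 0) {
    out <- tibble(crg_id = character(), n_members = integer(),
                  members = list(), patients_represented = list(),
                  n_patients = integer(), top_motif = character(),
                  top_fold_change = numeric(), top_p = numeric())
    attr(out, "edges") <- all_edges
    class(out) <- c("tcr_convergence", class(out))
    return(out)
  }

  g <- igraph::graph_from_data_frame(all_edges[, c("from", "to")],
                                     directed = FALSE,
                                     vertices = sequences$seq_id)
  comp <- igraph::components(g)
  membership <- tibble(seq_id = names(comp$membership),
                       comp = as.integer(comp$membership))
  groups <- membership |>
    left_join(sequences, by = "seq_id") |>
    group_by(.data$comp) |>
    summarise(
      n_members = n(),
      members = list(sort(.data$seq_id)),
      patients_represented = list(sort(unique(.data$patient_id))),
      n_patients = dplyr::n_distinct(.data$patient_id),
      .groups = "drop"
    ) |>
    filter(.data$n_members >= 2) |>
    mutate(first_member = purrr::map_chr(.data$members, 1)) |>
    arrange(dplyr::desc(.data$n_members), .data$first_member) |>
    mutate(crg_id = sprintf("CRG-%d", row_number()))

  # Supporting motif per group: the enriched motif carried by most members.
  top <- purrr::map(groups$members, function(mem) {
    aa <- sequences$cdr3_aa[match(mem, sequences$seq_id)]
    if (nrow(sig) == 0) return(tibble(top_motif = NA_character_,
                                      top_fold_change = NA_real_,
                                      top_p = NA_real_))
    support <- vapply(seq_len(nrow(sig)), function(i) {
      sum(seq_has_motif(aa, sig$motif[i], sig$k[i], flank_trim))
    }, numeric(1))
    if (all(support < 2)) return(tibble(top_motif = NA_character_,
                                        top_fold_change = NA_real_,
                                        top_p = NA_real_))
    i <- order(-support, -sig$fold_change, sig$p_resampled)[1]
    tibble(top_motif = sig$motif[i], top_fold_change = sig$fold_change[i],
           top_p = sig$p_resampled[i])
  }) |> bind_rows()

  out <- bind_cols(groups, top) |>
    select("crg_id", "n_members", "members", "patients_represented",
           "n_patients", "top_motif", "top_fold_change", "top_p")
  attr(out, "edges") <- left_join(all_edges, edge_motifs, by = c("from", "to"))
  class(out) <- c("tcr_convergence", class(out))
  out
}

# Does each CDR3 contain `motif` in its interior (flank_trim = 3)?
seq_has_motif <- function(cdr3_aa, motif, k, flank_trim = 3L) {
  lens <- nchar(cdr3_aa)
  interior <- substr(cdr3_aa, flank_trim + 1L, lens - flank_trim)
  stringr::str_detect(interior, stringr::fixed(motif))
}
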