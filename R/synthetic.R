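# Synthetic paired-repertoire generator with planted ground truth.
#
# CDR3s are built as a V-anchored amino-acid prefix + random insert +
# J-anchored suffix; nucleotide sequences are drawn codon-wise so that the
# amino-acid translation is consistent and nt length is divisible by 3.
# Inserts are drawn uniformly over the 20 standard residues (codons chosen
# uniformly among synonymous codons): the generator tests statistics, not
# recombination biology.

# Standard genetic code, arranged for vectorised back-translation.
.aa_letters <- c("A","C","D","E","F","G","H","I","K","L",
                 "M","N","P","Q","R","S","T","V","W","Y")
.codon_list <- list(
  A = c("GCT","GCC","GCA","GCG"),
  C = c("TGT","TGC"),
  D = c("GAT","GAC"),
  E = c("GAA","GAG"),
  F = c("TTT","TTC"),
  G = c("GGT","GGC","GGA","GGG"),
  H = c("CAT","CAC"),
  I = c("ATT","ATC","ATA"),
  K = c("AAA","AAG"),
  L = c("TTA","TTG","CTT","CTC","CTA","CTG"),
  M = "ATG",
  N = c("AAT","AAC"),
  P = c("CCT","CCC","CCA","CCG"),
  Q = c("CAA","CAG"),
  R = c("CGT","CGC","CGA","CGG","AGA","AGG"),
  S = c("TCT","TCC","TCA","TCG","AGT","AGC"),
  T = c("ACT","ACC","ACA","ACG"),
  V = c("GTT","GTC","GTA","GTG"),
  W = "TGG",
  Y = c("TAT","TAC")
)
.codon_n <- vapply(.codon_list, length, integer(1))
.codon_mat <- t(vapply(.codon_list, function(x) c(x, rep(NA, 6 - length(x))),
                       character(6)))

# Vectorised random back-translation of amino-acid strings.
back_translate <- function(aa) {
  chars <- strsplit(aa, "", fixed = TRUE)
  lens <- lengths(chars)
  flat <- unlist(chars, use.names = FALSE)
  pick <- floor(runif(length(flat)) * .codon_n[flat]) + 1L
  codons <- .codon_mat[cbind(match(flat, .aa_letters), pick)]
  vapply(split(codons, rep(seq_along(aa), lens)), paste, character(1),
         collapse = "")
}

# Germline-like anchor segments (IMGT-style names; prefixes/suffixes are >= 3
# residues so interior motifs at flank_trim = 3 always fall inside inserts).
tcr_segments <- function() {
  list(
    trbv = tibble(
      gene = c("TRBV28", "TRBV27", "TRBV19", "TRBV9", "TRBV5-1",
               "TRBV12-3", "TRBV4-1", "TRBV20-1"),
      anchor = c("CASS", "CASS", "CASS", "CASS", "CASS",
                 "CASS", "CASS", "CSAR"),
      weight = c(2, 1.5, 1, 1, 1, 1, 1, 0.5)
    ),
    trbj = tibble(
      gene = c("TRBJ1-1", "TRBJ1-2", "TRBJ1-5", "TRBJ2-1", "TRBJ2-3",
               "TRBJ2-7"),
      anchor = c("NTEAFF", "YGYTF", "QPQHF", "NEQFF", "DTQYF", "SYEQYF"),
      weight = c(2, 1, 1, 1, 1, 1)
    ),
    trav = tibble(
      gene = c("TRAV1-2", "TRAV8-2", "TRAV12-1", "TRAV17", "TRAV21",
               "TRAV29DV5"),
      anchor = c("CAV", "CVV", "CVV", "CAT", "CAV", "CAA"),
      weight = c(1, 1, 1, 1, 1, 1)
    ),
    traj = tibble(
      gene = c("TRAJ33", "TRAJ42", "TRAJ49", "TRAJ20", "TRAJ12"),
      anchor = c("SNYQLIW", "GGSQGNLIF", "TGNQFYF", "NDYKLSF", "DSSYKLIF"),
      weight = c(1, 1, 1, 1, 1)
    )
  )
}

#' Configuration for the synthetic paired-repertoire generator
#'
#' Defaults emulate a small paired blood/synovial-fluid CD8 T-cell study:
#' 3 patients with paired PBMC and SFMC samples, a few-large-many-small clone
#' size geometry (truncated power law), a handful of synovial-enriched clones
#' per patient at a 10-fold proportion ratio, one cross-patient convergence
#' group carrying the interior motif `NQNT` on a TRBV28/TRBJ1-1 background,
#' droplet doublet contamination, alpha-chain dropout and occasional second
#' alpha rearrangements, and phenotype cluster labels in which enriched-clone
#' cells are biased toward an activated cluster at a configured odds ratio.
#'
#' @param n_patients Number of patients (paired samples each).
#' @param sample_types Two sample types per patient.
#' @param cells_per_sample Cells per sample.
#' @param n_background_clones Unexpanded/background clones per patient.
#' @param clone_power,clone_max Truncated power-law exponent and maximum for
#'   background clone weights.
#' @param n_planted_enriched Enriched clones planted per patient.
#' @param enrichment_ratio Proportion ratio of planted clones between the
#'   enriched sample and its pair.
#' @param planted_cells Expected cells of a planted clone in the enriched
#'   sample.
#' @param enriched_sample Sample type the planted clones are enriched in.
#' @param planted_crgs List of planted convergence groups, each
#'   `list(motif =, n_clones =, patients = NULL, v_gene =, j_gene =,
#'   cells_per_clone =)`; `n_clones` is per participating patient and
#'   `patients = NULL` means all patients.
#' @param v_usage,j_usage Optional named weight vectors overriding the
#'   default beta V/J segment usage bias.
#' @param doublet_rate Probability that a barcode receives a second cell's
#'   chains.
#' @param alpha_dropout_rate Per-cell probability that each alpha chain
#'   fails to be captured.
#' @param second_alpha_rate Probability that a clone carries two productive
#'   alpha rearrangements.
#' @param cluster_labels Named base probabilities of phenotype clusters.
#' @param cluster_bias `list(cluster =, odds_ratio =)` applied to cells of
#'   planted enriched clones.
#' @param qc_outlier_rate Fraction of cells given failing QC metrics.
#' @param seed Integer seed; the full output is a deterministic function of
#'   the config including the seed.
#' @return A `repertoire_config` list.
#' @export
repertoire_config <- function(n_patients = 3,
                              sample_types = c("PBMC", "SFMC"),
                              cells_per_sample = 2000,
                              n_background_clones = 300,
                              clone_power = 2.5,
                              clone_max = 50,
                              n_planted_enriched = 10,
                              enrichment_ratio = 10,
                              planted_cells = 30,
                              enriched_sample = "SFMC",
                              planted_crgs = list(list(
                                motif = "NQNT", n_clones = 5, patients = NULL,
                                v_gene = "TRBV28", j_gene = "TRBJ1-1",
                                cells_per_clone = 6
                              )),
                              v_usage = NULL, j_usage = NULL,
                              doublet_rate = 0.05,
                              alpha_dropout_rate = 0.15,
                              second_alpha_rate = 0.10,
                              cluster_labels = c(
                                "HLA-DR-low CD8" = 0.30,
                                "Central memory CD8" = 0.25,
                                "Transitional CD8" = 0.15,
                                "HLA-DR-high CD8" = 0.12,
                                "ZNF683+ CD8" = 0.10,
                                "Cycling CD8" = 0.08
                              ),
                              cluster_bias = list(
                                cluster = "HLA-DR-high CD8", odds_ratio = 5
                              ),
                              qc_outlier_rate = 0.05,
                              seed = 20200921) {
  cfg <- list(
    n_patients = n_patients, sample_types = sample_types,
    cells_per_sample = cells_per_sample,
    n_background_clones = n_background_clones,
    clone_power = clone_power, clone_max = clone_max,
    n_planted_enriched = n_planted_enriched,
    enrichment_ratio = enrichment_ratio, planted_cells = planted_cells,
    enriched_sample = enriched_sample, planted_crgs = planted_crgs,
    v_usage = v_usage, j_usage = j_usage,
    doublet_rate = doublet_rate, alpha_dropout_rate = alpha_dropout_rate,
    second_alpha_rate = second_alpha_rate,
    cluster_labels = cluster_labels, cluster_bias = cluster_bias,
    qc_outlier_rate = qc_outlier_rate, seed = seed
  )
  rates <- c(doublet_rate, alpha_dropout_rate, second_alpha_rate,
             qc_outlier_rate)
  if (any(rates < 0 | rates > 1)) {
    abort("all rates must lie in [0, 1]", class = "synovitcr_config_error")
  }
  if (length(sample_types) != 2) {
    abort("exactly two sample types are required",
          class = "synovitcr_config_error")
  }
  if (!enriched_sample %in% sample_types) {
    abort("enriched_sample must be one of sample_types",
          class = "synovitcr_config_error")
  }
  n_crg_cells <- sum(vapply(planted_crgs, function(g) {
    g$n_clones * (g$cells_per_clone %||% 6)
  }, numeric(1)))
  if (n_planted_enriched * planted_cells + n_crg_cells >= cells_per_sample) {
    abort("planted clones exceed the cells available per sample",
          class = "synovitcr_config_error")
  }
  if (abs(sum(cluster_labels) - 1) > 1e-8) {
    abort("cluster_labels probabilities must sum to 1",
          class = "synovitcr_config_error")
  }
  structure(cfg, class = "repertoire_config")
}

# Draw n CDR3 beta (or alpha) chains; optional interior motif in the insert.
draw_cdr3 <- function(n, v_tab, j_tab, v_usage = NULL, j_usage = NULL,
                      motif = NULL, v_gene = NULL, j_gene = NULL,
                      insert_range = 4:8) {
  vw <- if (is.null(v_usage)) setNames(v_tab$weight, v_tab$gene) else v_usage
  jw <- if (is.null(j_usage)) setNames(j_tab$weight, j_tab$gene) else j_usage
  v <- if (is.null(v_gene)) {
    sample(names(vw), n, replace = TRUE, prob = vw)
  } else rep(v_gene, n)
  j <- if (is.null(j_gene)) {
    sample(names(jw), n, replace = TRUE, prob = jw)
  } else rep(j_gene, n)
  ins_len <- sample(insert_range, n, replace = TRUE)
  if (!is.null(motif)) ins_len <- pmax(ins_len, nchar(motif))
  pad <- ins_len - if (is.null(motif)) 0L else nchar(motif)
  rand_aa <- function(len_vec) {
    total <- sum(len_vec)
    flat <- sample(.aa_letters, total, replace = TRUE)
    vapply(split(flat, rep(seq_along(len_vec), len_vec)), paste, character(1),
           collapse = "")
  }
  insert <- if (is.null(motif)) {
    rand_aa(ins_len)
  } else {
    pre_len <- vapply(pad, function(p) sample.int(p + 1L, 1L) - 1L, integer(1))
    pre <- rand_aa(pre_len)
    post <- rand_aa(pad - pre_len)
    paste0(pre, motif, post)
  }
  aa <- paste0(v_tab$anchor[match(v, v_tab$gene)], insert,
               j_tab$anchor[match(j, j_tab$gene)])
  tibble(v_gene = v, j_gene = j, cdr3_aa = aa, cdr3_nt = back_translate(aa))
}

#' Simulate a paired single-cell TCR repertoire with planted truth
#'
#' Generates per-patient clone pools (background clones with truncated
#' power-law weights, planted tissue-enriched clones, planted cross-patient
#' convergence-group clones), allocates cells to the paired samples
#' multinomially (planted clones at the configured proportion ratio),
#' emits per-cell alpha/beta chains with alpha dropout and doublet
#' contamination, assigns phenotype cluster labels with the configured
#' clone-cluster bias, and draws droplet-style QC metrics.
#'
#' @param config A [repertoire_config()] object.
#' @return A list of tibbles:
#' * `contigs` — one row per chain, readable by the analysis pipeline and
#'   writable as a 10x-dialect CSV with [write_contigs_tenx()];
#' * `metadata` — per barcode: `barcode`, `patient_id`, `sample_id`,
#'   `sample_type`, `cluster_label`;
#' * `metrics` — per barcode QC metrics (`n_genes`, `n_counts`, `pct_mito`,
#'   `platform`);
#' * `truth` — per true clone: `patient_id`, `true_clone_id`,
#'   `beta_cdr3_nt`, `beta_cdr3_aa`, `v_gene`, `j_gene`, `enriched_in`
#'   (sample_id or NA), `crg_motif` (or NA), `cluster_bias` (or NA);
#' * `truth_cells` — per barcode: `barcode`, `true_clone_id`, `is_doublet`,
#'   `doublet_partner_clone` (NA when not a doublet).
#' @export
simulate_repertoire <- function(config = repertoire_config()) {
  stopifnot(inherits(config, "repertoire_config"))
  seg <- tcr_segments()
  with_seed(config$seed, {
    patients <- sprintf("PT%02d", seq_len(config$n_patients))
    all <- purrr::map(seq_along(patients), function(pi) {
      simulate_patient(patients[pi], config, seg)
    })
    contigs <- bind_rows(purrr::map(all, "contigs"))
    metadata <- bind_rows(purrr::map(all, "metadata"))
    truth <- bind_rows(purrr::map(all, "truth"))
    truth_cells <- bind_rows(purrr::map(all, "truth_cells"))
    metrics <- simulate_metrics(metadata, config$qc_outlier_rate)
    list(contigs = contigs, metadata = metadata, metrics = metrics,
         truth = truth, truth_cells = truth_cells)
  })
}

simulate_patient <- function(patient, config, seg) {
  n_bg <- config$n_background_clones
  n_enr <- config$n_planted_enriched
  N <- config$cells_per_sample
  s_enr <- config$enriched_sample
  s_other <- setdiff(config$sample_types, s_enr)

  # --- clone pool ------------------------------------------------------
  crg_specs <- purrr::keep(config$planted_crgs, function(g) {
    is.null(g$patients) || patient %in% g$patients
  })
  crg_clones <- purrr::imap(crg_specs, function(g, gi) {
    draw_cdr3(g$n_clones, seg$trbv, seg$trbj,
              config$v_usage, config$j_usage,
              motif = g$motif, v_gene = g$v_gene, j_gene = g$j_gene) |>
      mutate(role = "crg", crg_motif = g$motif,
             cells_per_clone = g$cells_per_clone %||% 6)
  })
  enr_clones <- if (n_enr > 0) {
    draw_cdr3(n_enr, seg$trbv, seg$trbj, config$v_usage, config$j_usage) |>
      mutate(role = "enriched", crg_motif = NA_character_,
             cells_per_clone = config$planted_cells)
  } else NULL
  bg_clones <- draw_cdr3(n_bg, seg$trbv, seg$trbj,
                         config$v_usage, config$j_usage) |>
    mutate(role = "background", crg_motif = NA_character_,
           cells_per_clone = NA_real_)
  clones <- bind_rows(bg_clones, enr_clones, bind_rows(crg_clones)) |>
    mutate(true_clone_id = sprintf("%s-T%04d", patient, row_number()))

  # alpha rearrangements per clone (1 or 2)
  n_clones <- nrow(clones)
  n_alpha <- 1L + rbinom(n_clones, 1L, config$second_alpha_rate)
  alpha1 <- draw_cdr3(n_clones, seg$trav, seg$traj)
  alpha2 <- draw_cdr3(n_clones, seg$trav, seg$traj)

  # --- cell allocation -------------------------------------------------
  # Per-sample clone probabilities; background clones share the remaining
  # mass in proportion to truncated power-law weights.
  pl_sizes <- sample(seq_len(config$clone_max), n_bg, replace = TRUE,
                     prob = seq_len(config$clone_max)^(-config$clone_power))
  p_enr_in <- clones$cells_per_clone / N
  prob <- list()
  for (st in config$sample_types) {
    p <- numeric(n_clones)
    p[clones$role == "crg"] <- p_enr_in[clones$role == "crg"]
    p[clones$role == "enriched"] <- if (st == s_enr) {
      p_enr_in[clones$role == "enriched"]
    } else {
      p_enr_in[clones$role == "enriched"] / config$enrichment_ratio
    }
    rest <- 1 - sum(p)
    p[clones$role == "background"] <- rest * pl_sizes / sum(pl_sizes)
    prob[[st]] <- p
  }

  out_cells <- purrr::map(config$sample_types, function(st) {
    counts <- as.vector(stats::rmultinom(1, N, prob[[st]]))
    tibble(
      clone_idx = rep(seq_len(n_clones), counts),
      sample_type = st,
      sample_id = paste0(patient, "_", st)
    )
  }) |> bind_rows()
  n_cells <- nrow(out_cells)
  out_cells <- out_cells |>
    mutate(
      patient_id = patient,
      barcode = sprintf("%s-%s-%05d-1", patient, .data$sample_type,
                        row_number())
    )

  # --- chains ----------------------------------------------------------
  ci <- out_cells$clone_idx
  keep_a1 <- (runif(n_cells) > config$alpha_dropout_rate)
  keep_a2 <- (n_alpha[ci] == 2L) & (runif(n_cells) > config$alpha_dropout_rate)
  chain_rows <- list(
    tibble(row = seq_len(n_cells), locus = "TRB",
           v_gene = clones$v_gene[ci], j_gene = clones$j_gene[ci],
           cdr3_nt = clones$cdr3_nt[ci], cdr3_aa = clones$cdr3_aa[ci]),
    tibble(row = which(keep_a1), locus = "TRA",
           v_gene = alpha1$v_gene[ci[keep_a1]],
           j_gene = alpha1$j_gene[ci[keep_a1]],
           cdr3_nt = alpha1$cdr3_nt[ci[keep_a1]],
           cdr3_aa = alpha1$cdr3_aa[ci[keep_a1]]),
    tibble(row = which(keep_a2), locus = "TRA",
           v_gene = alpha2$v_gene[ci[keep_a2]],
           j_gene = alpha2$j_gene[ci[keep_a2]],
           cdr3_nt = alpha2$cdr3_nt[ci[keep_a2]],
           cdr3_aa = alpha2$cdr3_aa[ci[keep_a2]])
  )
  chains <- bind_rows(chain_rows)

  # --- doublets: contaminant cells merged into host barcodes -----------
  n_doublet <- rbinom(1, n_cells, config$doublet_rate)
  doublet_host <- sample.int(n_cells, n_doublet)
  partner_clone <- integer(0)
  if (n_doublet > 0) {
    # contaminant drawn from the same sample's clone distribution; a second
    # cell of the host's own clone would be undetectable, so it is excluded
    partner_clone <- vapply(doublet_host, function(h) {
      p <- prob[[out_cells$sample_type[h]]]
      p[out_cells$clone_idx[h]] <- 0
      sample.int(n_clones, 1, prob = p)
    }, integer(1))
    extra_beta <- tibble(
      row = doublet_host, locus = "TRB",
      v_gene = clones$v_gene[partner_clone],
      j_gene = clones$j_gene[partner_clone],
      cdr3_nt = clones$cdr3_nt[partner_clone],
      cdr3_aa = clones$cdr3_aa[partner_clone]
    )
    keep_pa <- runif(n_doublet) > config$alpha_dropout_rate
    extra_alpha <- tibble(
      row = doublet_host[keep_pa], locus = "TRA",
      v_gene = alpha1$v_gene[partner_clone[keep_pa]],
      j_gene = alpha1$j_gene[partner_clone[keep_pa]],
      cdr3_nt = alpha1$cdr3_nt[partner_clone[keep_pa]],
      cdr3_aa = alpha1$cdr3_aa[partner_clone[keep_pa]]
    )
    chains <- bind_rows(chains, extra_beta, extra_alpha)
  }

  contigs <- chains |>
    mutate(
      barcode = out_cells$barcode[.data$row],
      patient_id = patient,
      sample_id = out_cells$sample_id[.data$row],
      d_gene = if_else(.data$locus == "TRB", "TRBD1", ""),
      productive = TRUE,
      umis = stats::rpois(n(), 3) + 1L
    ) |>
    select("barcode", "patient_id", "sample_id", "locus", "v_gene", "d_gene",
           "j_gene", "cdr3_nt", "cdr3_aa", "productive", "umis") |>
    arrange(.data$barcode, .data$locus, .data$cdr3_nt)

  # --- cluster labels --------------------------------------------------
  base_p <- config$cluster_labels
  labels <- names(base_p)
  biased <- clones$role[ci] == "enriched" & !is.null(config$cluster_bias)
  p_mat <- matrix(base_p, nrow = n_cells, ncol = length(base_p), byrow = TRUE)
  if (!is.null(config$cluster_bias) && any(biased)) {
    tgt <- match(config$cluster_bias$cluster, labels)
    or <- config$cluster_bias$odds_ratio
    p_mat[biased, tgt] <- p_mat[biased, tgt] * or
    p_mat <- p_mat / rowSums(p_mat)
  }
  u <- runif(n_cells)
  cum <- t(apply(p_mat, 1, cumsum))
  label_idx <- rowSums(u > cum) + 1L
  metadata <- tibble(
    barcode = out_cells$barcode,
    patient_id = patient,
    sample_id = out_cells$sample_id,
    sample_type = out_cells$sample_type,
    cluster_label = labels[label_idx]
  )

  truth <- clones |>
    mutate(
      patient_id = patient,
      enriched_in = if_else(.data$role == "enriched",
                            paste0(patient, "_", s_enr), NA_character_),
      cluster_bias = if_else(.data$role == "enriched" &
                               !is.null(config$cluster_bias),
                             config$cluster_bias$cluster %||% NA_character_,
                             NA_character_)
    ) |>
    select("patient_id", "true_clone_id", beta_cdr3_nt = "cdr3_nt",
           beta_cdr3_aa = "cdr3_aa", "v_gene", "j_gene", "enriched_in",
           "crg_motif", "cluster_bias")

  truth_cells <- tibble(
    barcode = out_cells$barcode,
    true_clone_id = clones$true_clone_id[ci],
    is_doublet = FALSE,
    doublet_partner_clone = NA_character_
  )
  if (n_doublet > 0) {
    truth_cells$is_doublet[doublet_host] <- TRUE
    truth_cells$doublet_partner_clone[doublet_host] <-
      clones$true_clone_id[partner_clone]
  }

  list(contigs = contigs, metadata = metadata, truth = truth,
       truth_cells = truth_cells)
}

# Droplet-style QC metrics; a configurable fraction of cells gets failing
# values (high mitochondrial load or extreme gene counts).
simulate_metrics <- function(metadata, outlier_rate) {
  n <- nrow(metadata)
  n_genes <- pmax(50L, round(rnorm(n, 1600, 450)))
  n_counts <- pmax(100L, round(n_genes * stats::rlnorm(n, log(4), 0.25)))
  pct_mito <- pmin(100, stats::rgamma(n, shape = 4, scale = 1))
  out <- runif(n) < outlier_rate
  kind <- sample(1:3, n, replace = TRUE)
  pct_mito[out & kind == 1] <- runif(sum(out & kind == 1), 12, 60)
  n_genes[out & kind == 2] <- sample(50:450, sum(out & kind == 2), replace = TRUE)
  n_counts[out & kind == 3] <- round(runif(sum(out & kind == 3), 26000, 80000))
  tibble(
    barcode = metadata$barcode,
    n_genes = as.integer(n_genes),
    n_counts = as.integer(n_counts),
    pct_mito = pct_mito,
    platform = "DROPLET_FLUID_BLOOD"
  )
}

#' Simulate a naive reference CDR3 set
#'
#' Draws beta-chain CDR3 amino-acid sequences from the same V/J-anchored
#' machinery as [simulate_repertoire()] but with no planted motifs beyond
#' the germline anchors, emulating an unselected naive reference repertoire
#' for motif-enrichment testing.
#'
#' @param n Number of sequences (>= 1).
#' @param v_usage,j_usage Optional named weight vectors.
#' @param seed Integer seed.
#' @return Character vector of `n` CDR3 amino-acid sequences.
#' @export
simulate_reference <- function(n, v_usage = NULL, j_usage = NULL, seed = 1L) {
  stopifnot(n >= 1)
  seg <- tcr_segments()
  with_seed(seed, {
    draw_cdr3(n, seg$trbv, seg$trbj, v_usage, j_usage)$cdr3_aa
  })
}

#' Simulate a paired analyte concentration panel
#'
#' Log-normal concentrations for `n_subjects` subjects across two paired
#' conditions, with a per-analyte shift of `effect_sizes` (in units of
#' `noise_sd`, on the log scale) between conditions.
#'
#' @param n_subjects Number of subjects (>= 3).
#' @param analytes Character vector of analyte names.
#' @param effect_sizes Numeric vector (recycled over analytes) of paired
#'   shifts in SD units on the log-concentration scale.
#' @param noise_sd SD of log-concentration noise.
#' @param conditions Two condition names.
#' @param seed Integer seed.
#' @return Long tibble: `subject_id`, `analyte`, `condition`, `value`.
#' @export
simulate_panel <- function(n_subjects = 11,
                           analytes = c("CXCL10", "CXCL9", "MIP1a", "MIP1b"),
                           effect_sizes = c(2, 1.5, 1, 0),
                           noise_sd = 0.5,
                           conditions = c("plasma", "SF"),
                           seed = 1L) {
  if (n_subjects < 3) {
    abort("n_subjects must be >= 3", class = "synovitcr_config_error")
  }
  effect_sizes <- rep_len(effect_sizes, length(analytes))
  with_seed(seed, {
    grid <- tidyr::expand_grid(
      subject_id = sprintf("S%02d", seq_len(n_subjects)),
      analyte = analytes
    )
    base <- rnorm(nrow(grid), mean = log(100), sd = noise_sd)
    shift <- effect_sizes[match(grid$analyte, analytes)] * noise_sd
    bind_rows(
      mutate(grid, condition = conditions[1],
             value = exp(base + rnorm(nrow(grid), 0, noise_sd))),
      mutate(grid, condition = conditions[2],
             value = exp(base + shift + rnorm(nrow(grid), 0, noise_sd)))
    ) |>
      arrange(.data$analyte, .data$subject_id, .data$condition)
  })
}

#' Write contigs as a 10x-dialect contig annotation CSV
#'
#' Columns follow the CellRanger `filtered_contig_annotations.csv`
#' convention (`barcode`, `chain`, `v_gene`, `d_gene`, `j_gene`, `cdr3`,
#' `cdr3_nt`, `productive`, `umis`), plus `patient_id`/`sample_id` carried
#' as extra columns; [read_contig_table()] round-trips the file.
#'
#' @param contigs A contig tibble (e.g. from [simulate_repertoire()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_contigs_tenx <- function(contigs, path) {
  out <- tibble(
    barcode = contigs$barcode,
    chain = contigs$locus,
    v_gene = contigs$v_gene,
    d_gene = contigs$d_gene,
    j_gene = contigs$j_gene,
    cdr3 = contigs$cdr3_aa,
    cdr3_nt = contigs$cdr3_nt,
    productive = ifelse(contigs$productive, "True", "False"),
    umis = contigs$umis,
    patient_id = contigs$patient_id,
    sample_id = contigs$sample_id
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
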