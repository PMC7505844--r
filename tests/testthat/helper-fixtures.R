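# Fixture builders shared across test files. All fixtures are built in code.

# One contig row with sensible defaults.
contig_row <- function(barcode, locus = "TRB", cdr3_aa = "CASSNQNTEAFF",
                       cdr3_nt = NULL, v_gene = NULL, j_gene = NULL,
                       patient_id = "PT01", sample_id = "PT01_SFMC",
                       productive = TRUE, umis = 3L) {
  if (is.null(cdr3_nt)) {
    # deterministic back-translation (first codon of each residue)
    codons <- c(A="GCT",C="TGT",D="GAT",E="GAA",F="TTT",G="GGT",H="CAT",
                I="ATT",K="AAA",L="TTA",M="ATG",N="AAT",P="CCT",Q="CAA",
                R="CGT",S="TCT",T="ACT",V="GTT",W="TGG",Y="TAT")
    cdr3_nt <- paste(codons[strsplit(cdr3_aa, "")[[1]]], collapse = "")
  }
  if (is.null(v_gene)) v_gene <- if (locus == "TRA") "TRAV1-2" else "TRBV28"
  if (is.null(j_gene)) j_gene <- if (locus == "TRA") "TRAJ33" else "TRBJ1-1"
  tibble::tibble(
    barcode = barcode, patient_id = patient_id, sample_id = sample_id,
    locus = locus, v_gene = v_gene,
    d_gene = if (locus == "TRB") "TRBD1" else "",
    j_gene = j_gene, cdr3_nt = cdr3_nt, cdr3_aa = cdr3_aa,
    productive = productive, umis = umis
  )
}

# A cell with the given chain CDR3s (one row per chain).
cell_contigs <- function(barcode, alphas = character(), betas = character(),
                         ...) {
  dots <- list(...)
  arow <- function(aa) {
    do.call(contig_row, c(list(barcode, "TRA", cdr3_aa = aa), dots))
  }
  brow <- function(i) {
    do.call(contig_row, c(list(barcode, "TRB", cdr3_aa = betas[i],
                               v_gene = c("TRBV28", "TRBV19", "TRBV9")[i]),
                          dots))
  }
  dplyr::bind_rows(
    lapply(alphas, arow),
    lapply(seq_along(betas), brow)
  )
}

# Brute-force two-sided Fisher p by exhaustive enumeration of all tables
# with the observed margins, using factorial table probabilities.
fisher_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  table_prob <- function(x) {
    # P(table) under hypergeometric with these margins
    exp(lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k))
  }
  support <- max(0, k - n):min(k, m)
  probs <- vapply(support, table_prob, numeric(1))
  p_obs <- table_prob(a)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Direct step-up BH definition: p_(i) * m / i with cumulative min from the
# largest rank, mapped back to input order.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(1, adj)
  out
}

# Per-patient clonotype + enrichment convenience wrapper.
patient_enrichment <- function(sim, patient, pair_types = c("SFMC", "PBMC"),
                               alpha_level = 0.05,
                               include_multiplet_beta = TRUE) {
  parts <- build_cell_partitions(
    dplyr::filter(sim$contigs, patient_id == patient)
  )
  cl <- assign_clonotypes(parts, include_multiplet_beta = include_multiplet_beta)
  test_clonal_enrichment(cl, paste0(patient, "_", pair_types), alpha_level)
}
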