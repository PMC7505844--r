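# GLIPH-style input preparation, motif enumeration/enrichment, grouping.

test_that("gliph input aggregates betas, suffixes multi-beta variants, drops alpha-only", {
  contigs <- dplyr::bind_rows(
    cell_contigs("BA-1", alphas = "CAVSNYQLIW", betas = "CASSNQNTEAFF"),
    cell_contigs("BB-1", alphas = "CATDSNYQLIW", betas = "CASSNQNTEAFF"),
    cell_contigs("BC-1", betas = c("CASSWGQNTEAFF", "CASSPLGNTEAFF")),
    cell_contigs("BD-1", alphas = "CAVSNYQLIW")
  )
  parts <- build_cell_partitions(contigs)
  gi <- prepare_gliph_input(parts, reference = c("CASSLAPGATNEKLFF"))
  # two identical singlet betas aggregate to one entry with 2 source cells
  agg <- dplyr::filter(gi, cdr3_aa == "CASSNQNTEAFF")
  expect_equal(nrow(agg), 1)
  expect_equal(agg$source_cells, 2L)
  # multi-beta partition emits one suffixed entry per beta
  variants <- dplyr::filter(gi, grepl("-v[12]$", seq_id))
  expect_equal(nrow(variants), 2)
  expect_setequal(variants$cdr3_aa, c("CASSWGQNTEAFF", "CASSPLGNTEAFF"))
  # no alpha-chain sequences; alpha-only partitions counted
  expect_false(any(grepl("^CAV|^CAT", gi$cdr3_aa)))
  expect_equal(unname(attr(gi, "counters")["n_alpha_only_dropped"]), 1)
  expect_error(prepare_gliph_input(parts, character(0)),
               class = "synovitcr_usage_error")
})

test_that("interior motif enumeration matches the worked example and presence semantics", {
  m <- enumerate_motifs("CASSNQNTEAFF", k_values = 4, flank_trim = 3)
  expect_setequal(m$motif, c("SNQN", "NQNT", "QNTE"))
  expect_true(all(m$n_seqs == 1))
  # duplicate motif within one CDR3 counts once
  m2 <- enumerate_motifs("CASANANANAFFF", k_values = 2, flank_trim = 3)
  expect_equal(m2$n_seqs[m2$motif == "NA"], 1L)
  # short sequences contribute nothing; empty set gives empty map
  expect_equal(nrow(enumerate_motifs("CASSF", k_values = 4, flank_trim = 3)), 0)
  expect_equal(nrow(enumerate_motifs(character(0))), 0)
  expect_error(enumerate_motifs("CASSF", k_values = 5),
               class = "synovitcr_domain_error")
})

test_that("motif counting agrees with a brute-force substring oracle", {
  set.seed(31)
  seqs <- replicate(40, paste(sample(c("A", "N", "Q", "T", "S", "E", "F"),
                                     sample(8:16, 1), replace = TRUE),
                              collapse = ""))
  got <- enumerate_motifs(seqs, k_values = c(2, 3, 4), flank_trim = 3)
  for (k in 2:4) {
    counts <- new.env()
    for (s in seqs) {
      interior <- substr(s, 4, nchar(s) - 3)
      if (nchar(interior) < k) next
      kmers <- unique(vapply(seq_len(nchar(interior) - k + 1),
                             function(i) substr(interior, i, i + k - 1),
                             character(1)))
      for (km in kmers) assign(km, (mget(km, counts, ifnotfound = 0)[[1]]) + 1,
                               counts)
    }
    gk <- dplyr::filter(got, k == !!k)
    expect_setequal(gk$motif, ls(counts))
    expect_equal(gk$n_seqs,
                 vapply(gk$motif, function(m) get(m, counts), numeric(1)),
                 ignore_attr = TRUE)
  }
})

test_that("motif enrichment computes fold changes, floors and reproducible p-values", {
  # constructed: motif at frequency 0.10 in a 100-sequence sample vs 0.01 in
  # a 10,000-sequence reference -> fold change 10
  with_m <- paste0("CASS", "NQNT", "WGYEQYF")
  without <- paste0("CASS", "WLDG", "WGYEQYF")
  sample_seqs <- tibble::tibble(
    seq_id = sprintf("s%03d", 1:100),
    cdr3_aa = c(rep(with_m, 10), rep(without, 90)),
    patient_id = "PT01"
  )
  ref <- c(rep(with_m, 100), rep(without, 9900))
  res <- motif_enrichment(sample_seqs, reference = ref, k_values = 4, seed = 3)
  nq <- dplyr::filter(res, motif == "NQNT")
  expect_equal(nq$observed_freq, 0.10)
  expect_equal(nq$reference_freq, 0.01)
  expect_equal(nq$fold_change, 10)
  # motif absent from reference: fold Inf, p at the resampling floor
  ref2 <- rep(without, 200)
  res2 <- motif_enrichment(sample_seqs, reference = ref2, k_values = 4,
                           n_subsamples = 1000, seed = 3)
  nq2 <- dplyr::filter(res2, motif == "NQNT")
  expect_equal(nq2$fold_change, Inf)
  expect_equal(nq2$p_resampled, 0.001)
  expect_true(all(res2$p_resampled >= 0.001))
  # determinism under seed
  res3 <- motif_enrichment(sample_seqs, reference = ref, k_values = 4, seed = 3)
  expect_identical(res, res3)
  expect_error(motif_enrichment(sample_seqs, reference = ref, n_subsamples = 0),
               class = "synovitcr_domain_error")
  expect_error(motif_enrichment(sample_seqs, reference = ref[1:10]),
               class = "synovitcr_usage_error")
})

test_that("global edges require equal length and Hamming distance <= 1", {
  seqs <- tibble::tibble(
    seq_id = c("a", "b", "c", "d", "e"),
    cdr3_aa = c("CASSNQNTEAFF", "CASSNQNTEAYF", "CASSNQNTEAFF",
                "CASSNQNTEAFFX", "CASSWWWWEAFF")
  )
  e <- global_edges(seqs)
  expect_true(nrow(dplyr::filter(e, from == "a", to == "b")) == 1)  # dist 1
  expect_true(nrow(dplyr::filter(e, from == "a", to == "c")) == 1)  # dist 0
  expect_false(any(e$from == "d" | e$to == "d"))  # length mismatch
  expect_false(any((e$from == "a" & e$to == "e") |
                     (e$from == "e" & e$to == "a")))  # dist 4
})

test_that("planted motif groups are recovered and unrelated sequences are inert", {
  planted <- tibble::tibble(
    seq_id = sprintf("p%d", 1:5),
    cdr3_aa = paste0("CASS", c("A", "GL", "WE", "KV", "TY"), "NQNT",
                     c("YEQYF", "TEAFF", "QPQHF", "YGYTF", "NEQFF")),
    patient_id = c("PT01", "PT01", "PT02", "PT02", "PT03")
  )
  set.seed(99)
  bg <- tibble::tibble(
    seq_id = sprintf("b%02d", 1:40),
    # background drawn from the same machinery as the reference, so no
    # motif is systematically enriched in it
    cdr3_aa = simulate_reference(40, seed = 98),
    patient_id = sample(c("PT01", "PT02", "PT03"), 40, replace = TRUE)
  )
  seqs <- dplyr::bind_rows(planted, bg)
  ref <- simulate_reference(5000, seed = 12)
  mo <- motif_enrichment(seqs, reference = ref, seed = 5)
  crg <- build_convergence_groups(seqs, mo)
  hit <- which(vapply(crg$members, function(m) all(planted$seq_id %in% m),
                      logical(1)))
  expect_length(hit, 1)
  expect_gte(crg$n_patients[hit], 2)  # cross-patient convergence
  expect_equal(crg$top_motif[hit], "NQNT")
  # adding an unrelated sequence never changes existing memberships
  extra <- tibble::tibble(seq_id = "zz", cdr3_aa = "CAWWMMHHIIPPRRG",
                          patient_id = "PT01")
  mo2 <- motif_enrichment(dplyr::bind_rows(seqs, extra), reference = ref,
                          seed = 5)
  crg2 <- build_convergence_groups(dplyr::bind_rows(seqs, extra), mo2)
  old <- lapply(crg$members, sort)
  new <- lapply(crg2$members, function(m) sort(setdiff(m, "zz")))
  for (g in old) expect_true(any(vapply(new, identical, logical(1), g)))
  # no shared enriched motif and Hamming >= 2: zero groups
  lone <- tibble::tibble(
    seq_id = c("x1", "x2"),
    cdr3_aa = c("CASSAAAAAATEAFF", "CASSWWWWWWTEAFF"),
    patient_id = "PT01"
  )
  mo3 <- motif_enrichment(lone, reference = ref, seed = 5)
  crg3 <- build_convergence_groups(lone, mo3)
  expect_equal(nrow(crg3), 0)
})

test_that("resampled p-values match exhaustive subset enumeration on a tiny reference", {
  # reference of 12 sequences, sample of 4; all C(12,4) = 495 subsets
  ref <- c(rep("CASSNQNTEAFF", 3), rep("CASSWLDGTEAFF", 9))
  sample_seqs <- tibble::tibble(
    seq_id = sprintf("s%d", 1:4),
    cdr3_aa = c(rep("CASSNQNTEAFF", 2), rep("CASSGGHHTEAFF", 2)),
    patient_id = "PT01"
  )
  res <- motif_enrichment(sample_seqs, reference = ref, k_values = 4,
                          n_subsamples = 2000, seed = 8)
  nq <- dplyr::filter(res, motif == "NQNT")
  # exact p: fraction of 4-subsets with >= 2 of the 3 motif-bearing refs
  combos <- utils::combn(12, 4)
  exact <- mean(colSums(combos <= 3) >= 2)
  mc_sd <- sqrt(exact * (1 - exact) / 2000)
  expect_lt(abs(nq$p_resampled - exact), 3 * mc_sd)
})
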