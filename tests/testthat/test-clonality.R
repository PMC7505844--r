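# Clonotype assignment, Fisher/BH machinery, enrichment and association.

test_that("clonotype keys combine alpha and beta CDR3 nt and ignore alpha order", {
  c1 <- dplyr::bind_rows(
    contig_row("BC1-1", "TRA", cdr3_aa = "CAVSNYQLIW"),
    contig_row("BC1-1", "TRA", cdr3_aa = "CATDSNYQLIW"),
    contig_row("BC1-1", "TRB", cdr3_aa = "CASSNQNTEAFF")
  )
  # same chains, alphas in reverse input order
  c2 <- dplyr::bind_rows(
    contig_row("BC2-1", "TRA", cdr3_aa = "CATDSNYQLIW"),
    contig_row("BC2-1", "TRA", cdr3_aa = "CAVSNYQLIW"),
    contig_row("BC2-1", "TRB", cdr3_aa = "CASSNQNTEAFF")
  )
  cl <- assign_clonotypes(build_cell_partitions(dplyr::bind_rows(c1, c2)))
  expect_equal(dplyr::n_distinct(cl$clone_key), 1)
  expect_equal(nrow(cl), 2)
  expect_equal(cl$clone_size, c(2L, 2L))
})

test_that("multi-beta partitions form a single clone only when requested", {
  mb <- cell_contigs("BCX-1", betas = c("CASSNQNTEAFF", "CASSLGNTEAFF"))
  ok <- cell_contigs("BCY-1", alphas = "CAVSNYQLIW", betas = "CASSNQNTEAFF")
  parts <- build_cell_partitions(dplyr::bind_rows(mb, ok))
  with_mb <- assign_clonotypes(parts, include_multiplet_beta = TRUE)
  expect_equal(nrow(with_mb), 2)
  mb_key <- with_mb$clone_key[with_mb$barcode == "BCX-1"]
  expect_match(mb_key, "^MB\\|")
  # keyed on the sorted beta tuple
  expect_equal(length(strsplit(sub("^MB\\|", "", mb_key), "+", fixed = TRUE)[[1]]), 2)
  without <- assign_clonotypes(parts, include_multiplet_beta = FALSE)
  expect_equal(without$barcode, "BCY-1")
  # alpha-only cells never join a clone
  ao <- cell_contigs("BCZ-1", alphas = "CAVSNYQLIW")
  parts2 <- build_cell_partitions(dplyr::bind_rows(ok, ao))
  expect_false("BCZ-1" %in% assign_clonotypes(parts2, TRUE)$barcode)
})

test_that("clonotype assignment rejects multi-patient input and conserves cells", {
  sim <- simulate_repertoire(repertoire_config(
    n_patients = 2, cells_per_sample = 150, n_background_clones = 40,
    n_planted_enriched = 3, planted_cells = 10,
    planted_crgs = list(), seed = 11
  ))
  parts <- build_cell_partitions(sim$contigs)
  expect_error(assign_clonotypes(parts), "per-patient",
               class = "synovitcr_usage_error")
  p1 <- build_cell_partitions(dplyr::filter(sim$contigs, patient_id == "PT01"))
  cl <- assign_clonotypes(p1, include_multiplet_beta = TRUE)
  eligible <- sum(p1$status == "OK") +
    sum(p1$status == "MULTIPLET" & p1$n_beta >= 2)
  expect_equal(nrow(cl), eligible)
})

test_that("fisher_exact_2x2 matches the spec examples and symmetry", {
  expect_error(fisher_exact_2x2(-1, 2, 3, 4), class = "synovitcr_domain_error")
  r0 <- fisher_exact_2x2(0, 50, 0, 50)
  expect_equal(r0$p, 1)
  expect_true(is.nan(r0$odds_ratio))
  r1 <- fisher_exact_2x2(10, 90, 1, 99)
  expect_equal(r1$odds_ratio, 11)
  expect_equal(r1$p, fisher_oracle(10, 90, 1, 99), tolerance = 1e-10)
  # row swap: identical p, reciprocal odds ratio
  r2 <- fisher_exact_2x2(1, 99, 10, 90)
  expect_equal(r2$p, r1$p, tolerance = 1e-12)
  expect_equal(r2$odds_ratio, 1 / r1$odds_ratio)
  expect_equal(fisher_exact_2x2(3, 0, 0, 5)$odds_ratio, Inf)
})

test_that("fisher_exact_2x2 agrees with enumeration oracle and stats::fisher.test", {
  set.seed(404)
  for (i in 1:200) {
    tab <- as.integer(sample(0:20, 4, replace = TRUE))
    if (sum(tab[1:2]) == 0 || sum(tab[3:4]) == 0) next
    got <- fisher_exact_2x2(tab[1], tab[2], tab[3], tab[4])
    want <- fisher_oracle(tab[1], tab[2], tab[3], tab[4])
    expect_equal(got$p, want, tolerance = 1e-9)
    ft <- stats::fisher.test(matrix(tab, 2, 2, byrow = TRUE))
    expect_equal(got$p, ft$p.value, tolerance = 1e-7)
  }
})

test_that("bh_adjust matches the step-up definition and its invariants", {
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_adjust(c(0.5, 1.2)), class = "synovitcr_domain_error")
  set.seed(7)
  for (i in 1:50) {
    p <- runif(sample(1:100, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(adj >= p))
    expect_true(all(diff(bh_adjust(sort(p))) >= -1e-15))
  }
})

test_that("clonal enrichment flags planted clones and respects symmetry", {
  sim <- simulate_repertoire(repertoire_config(
    n_patients = 1, cells_per_sample = 1500, n_background_clones = 200,
    n_planted_enriched = 5, planted_cells = 30, enrichment_ratio = 10,
    planted_crgs = list(), seed = 2024
  ))
  enr <- patient_enrichment(sim, "PT01")
  hits <- enr$clone_key[!is.na(enr$enriched_in) &
                          enr$enriched_in == "PT01_SFMC"]
  planted <- dplyr::filter(sim$truth, !is.na(enriched_in))
  n_rec <- sum(vapply(planted$beta_cdr3_nt,
                      function(b) any(grepl(b, hits, fixed = TRUE)),
                      logical(1)))
  expect_gte(n_rec, 4)
  # swapping the pair swaps directions, p unchanged
  parts <- build_cell_partitions(sim$contigs)
  cl <- assign_clonotypes(parts, include_multiplet_beta = TRUE)
  fwd <- test_clonal_enrichment(cl, c("PT01_SFMC", "PT01_PBMC"))
  rev <- test_clonal_enrichment(cl, c("PT01_PBMC", "PT01_SFMC"))
  merged <- dplyr::inner_join(tidy(fwd), tidy(rev), by = "clone_id",
                              suffix = c("_f", "_r"))
  expect_equal(merged$p_raw_f, merged$p_raw_r, tolerance = 1e-12)
  flagged <- merged[!is.na(merged$enriched_in_f), ]
  expect_equal(flagged$enriched_in_f, flagged$enriched_in_r)
  # equal proportions are never flagged
  even <- tibble::tibble(
    patient_id = "PT01",
    sample_id = rep(c("PT01_SFMC", "PT01_PBMC"), each = 50),
    barcode = sprintf("B%03d", 1:100),
    clone_id = rep(rep(c("C1", "C2"), each = 25), 2),
    clone_key = rep(rep(c("k1", "k2"), each = 25), 2),
    clone_size = 50L
  )
  expect_true(all(is.na(test_clonal_enrichment(even,
    c("PT01_SFMC", "PT01_PBMC"))$enriched_in)))
  expect_error(test_clonal_enrichment(cl, c("PT01_SFMC", "nope")),
               class = "synovitcr_usage_error")
})

test_that("cluster association recovers a planted odds ratio and excludes empty clusters", {
  # construction: enriched cells all in one cluster dominate the odds ratios
  cells <- tibble::tibble(
    cluster_label = c(rep("X", 20), rep(c("A", "B", "C", "D"), each = 25)),
    enriched = c(rep(TRUE, 20), rep(FALSE, 100))
  )
  res <- associate_clusters(cells)
  expect_equal(res$cluster_label[which.max(res$odds_ratio)], "X")
  expect_equal(res$p_adj, pmin(1, res$p_raw * nrow(res)))
  # planted generative OR of 5: estimate within [3, 8] in >= 90% of replicates
  set.seed(909)
  base_p <- 0.15
  p_enr <- (5 * base_p) / (5 * base_p + (1 - base_p))
  ok <- replicate(200, {
    enriched <- rep(c(TRUE, FALSE), c(200, 1800))
    in_cluster <- ifelse(enriched, runif(2000) < p_enr, runif(2000) < base_p)
    labs <- ifelse(in_cluster, "target",
                   sample(c("o1", "o2", "o3"), 2000, replace = TRUE))
    r <- associate_clusters(tibble::tibble(cluster_label = labs,
                                           enriched = enriched))
    or <- r$odds_ratio[r$cluster_label == "target"]
    or >= 3 && or <= 8
  })
  expect_gte(mean(ok), 0.9)
  # degenerate inputs
  expect_error(associate_clusters(tibble::tibble(
    cluster_label = c("A", "B"), enriched = c(FALSE, FALSE)
  )), class = "synovitcr_usage_error")
  one <- tibble::tibble(cluster_label = "A", enriched = c(TRUE, FALSE))
  expect_error(associate_clusters(one), class = "synovitcr_usage_error")
})

test_that("equal-depth subsampling is exact, reproducible and guarded", {
  cells <- tidyr::expand_grid(
    patient_id = c("P1", "P2", "P3"),
    sample_id = c("A", "B"),
    i = 1:7000
  ) |>
    dplyr::mutate(sample_id = paste(patient_id, sample_id, sep = "_"))
  sub <- subsample_equal_depth(cells, target = 6867, seed = 5)
  expect_equal(nrow(sub), 41202)
  expect_true(all(dplyr::count(sub, patient_id, sample_id)$n == 6867))
  sub2 <- subsample_equal_depth(cells, target = 6867, seed = 5)
  expect_identical(sub, sub2)
  # target equal to the smallest sample returns that sample whole
  small <- dplyr::filter(cells, i <= ifelse(patient_id == "P1", 100, 500))
  whole <- subsample_equal_depth(small, seed = 1)
  expect_equal(sum(whole$patient_id == "P1"), 200)
  expect_error(subsample_equal_depth(small, target = 400),
               class = "synovitcr_usage_error")
})
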