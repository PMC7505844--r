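#' Read a pipeline run configuration from YAML
#'
#' The YAML may contain any subset of the override blocks understood by
#' [run_pipeline()]: `repertoire` (arguments to [repertoire_config()]),
#' `reference_n`, `gliph` (`k_values`, `flank_trim`, `n_subsamples`,
#' `fold_min`, `p_max`, `min_depth`), `qc_preset`, `alpha_level`,
#' `enriched_sample`, `panel` (arguments to [simulate_panel()]), and
#' optionally `contigs`/`metadata`/`metrics` paths pointing at real input
#' files instead of simulation.
#'
#' @param path YAML file path.
#' @return A named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("config file does not exist: %s", path),
          class = "synovitcr_config_error")
  }
  yaml::read_yaml(path) %||% list()
}

#' Run the full analysis pipeline
#'
#' Orchestrates the stages simulate (or load) -> partition -> clonotype ->
#' enrich -> associate -> converge -> qc -> usage -> panel, writing every
#' stage output as a plain-text table under `out_dir` together with a
#' manifest listing each file, its row count and the effective parameters.
#' All randomness flows from `seed` via per-stage derived seeds, so a rerun
#' with identical config and seed reproduces byte-identical outputs.
#'
#' @param out_dir Output directory (created if needed).
#' @param config Named list of overrides (see [read_run_config()]).
#' @param seed Top-level integer seed.
#' @return The manifest tibble, invisibly; also written to
#'   `manifest.tsv`.
#' @export
run_pipeline <- function(out_dir, config = list(), seed = 20200921) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  note <- function(stage, file, rows, params = "") {
    manifest[[length(manifest) + 1L]] <<- tibble(
      stage = stage, file = basename(file), rows = rows, params = params
    )
  }
  fail_stage <- NULL
  res <- tryCatch({
    # --- inputs: simulate or load -------------------------------------
    if (!is.null(config$contigs)) {
      contigs <- read_contig_table(config$contigs,
                                   config$dialect %||% "tenx")
      metadata <- read_cell_metadata(config$metadata)
      metrics <- readr::read_csv(config$metrics, show_col_types = FALSE,
                                 progress = FALSE)
      truth <- NULL
    } else {
      rep_args <- config$repertoire %||% list()
      rep_args$seed <- derive_seed(seed, "simulate")
      rep_cfg <- do.call(repertoire_config, rep_args)
      sim <- simulate_repertoire(rep_cfg)
      contigs <- sim$contigs; metadata <- sim$metadata
      metrics <- sim$metrics; truth <- sim$truth
      f <- file.path(out_dir, "contigs.csv")
      write_contigs_tenx(contigs, f); note("simulate", f, nrow(contigs))
      f <- file.path(out_dir, "metadata.csv")
      readr::write_csv(metadata, f, progress = FALSE)
      note("simulate", f, nrow(metadata))
      f <- file.path(out_dir, "metrics.csv")
      readr::write_csv(metrics, f, progress = FALSE)
      note("simulate", f, nrow(metrics))
      f <- file.path(out_dir, "truth.tsv")
      readr::write_tsv(truth, f, progress = FALSE)
      note("simulate", f, nrow(truth))
    }

    ref_n <- config$reference_n %||% 10000
    reference <- simulate_reference(ref_n, seed = derive_seed(seed, "reference"))
    f <- file.path(out_dir, "reference.txt")
    writeLines(reference, f)
    note("reference", f, length(reference), sprintf("n=%d", ref_n))

    # --- partition ----------------------------------------------------
    partitions <- build_cell_partitions(contigs)
    f <- file.path(out_dir, "partitions.airr.tsv")
    write_airr(partitions, f)
    note("partition", f, nrow(partitions),
         paste(sprintf("%s=%d", names(table(partitions$status)),
                       table(partitions$status)), collapse = " "))

    # --- clonotypes + enrichment per patient --------------------------
    alpha_level <- config$alpha_level %||% 0.05
    sample_types <- unique(metadata$sample_type)
    enriched_sample <- config$enriched_sample %||% "SFMC"
    pair_types <- c(enriched_sample, setdiff(sample_types, enriched_sample)[1])
    per_patient <- purrr::map(unique(partitions$patient_id), function(p) {
      part_p <- partitions[partitions$patient_id == p, ]
      attr(part_p, "chains") <- filter(attr(partitions, "chains"),
                                       .data$patient_id == p)
      class(part_p) <- class(partitions)
      cl <- assign_clonotypes(part_p, include_multiplet_beta = TRUE)
      pair <- paste0(p, "_", pair_types)
      enr <- test_clonal_enrichment(cl, pair, alpha_level) |>
        mutate(patient_id = p, .before = 1)
      list(clonotypes = cl, enrichment = enr)
    })
    clonotypes <- bind_rows(purrr::map(per_patient, "clonotypes"))
    enrichment <- bind_rows(purrr::map(per_patient, "enrichment"))
    f <- file.path(out_dir, "clonotypes.tsv")
    readr::write_tsv(clonotypes, f, progress = FALSE)
    note("clonotype", f, nrow(clonotypes))
    f <- file.path(out_dir, "enrichment.tsv")
    readr::write_tsv(enrichment, f, progress = FALSE)
    note("enrich", f, nrow(enrichment),
         sprintf("pair=%s alpha=%g n_enriched=%d",
                 paste(pair_types, collapse = "/"), alpha_level,
                 sum(!is.na(enrichment$enriched_in))))

    # --- cluster association ------------------------------------------
    enr_keys <- enrichment |>
      filter(!is.na(.data$enriched_in),
             endsWith(.data$enriched_in, enriched_sample))
    assoc_cells <- clonotypes |>
      left_join(select(metadata, "barcode", "cluster_label"), by = "barcode") |>
      mutate(enriched = paste0(.data$patient_id, "|", .data$clone_id) %in%
               paste0(enr_keys$patient_id, "|", enr_keys$clone_id))
    association <- if (any(assoc_cells$enriched)) {
      associate_clusters(assoc_cells)
    } else {
      tibble(cluster_label = character(), a = integer(), b = integer(),
             c = integer(), d = integer(), odds_ratio = numeric(),
             p_raw = numeric(), p_adj = numeric())
    }
    f <- file.path(out_dir, "association.tsv")
    readr::write_tsv(association, f, progress = FALSE)
    note("associate", f, nrow(association))

    # --- convergence (synovial compartment) ---------------------------
    gl <- config$gliph %||% list()
    syn_barcodes <- metadata$barcode[metadata$sample_type == enriched_sample]
    part_syn <- partitions[partitions$barcode %in% syn_barcodes, ]
    attr(part_syn, "chains") <- filter(attr(partitions, "chains"),
                                       .data$barcode %in% syn_barcodes)
    class(part_syn) <- class(partitions)
    gliph_in <- prepare_gliph_input(part_syn, reference)
    motifs <- motif_enrichment(
      gliph_in,
      k_values = gl$k_values %||% c(2L, 3L, 4L),
      flank_trim = gl$flank_trim %||% 3L,
      n_subsamples = gl$n_subsamples %||% 1000L,
      seed = derive_seed(seed, "motif")
    )
    crgs <- build_convergence_groups(
      gliph_in, motifs,
      fold_min = gl$fold_min %||% 10,
      p_max = gl$p_max %||% 0.001,
      min_depth = gl$min_depth %||% 3L,
      flank_trim = gl$flank_trim %||% 3L
    )
    f <- file.path(out_dir, "motifs.tsv")
    readr::write_tsv(motifs, f, progress = FALSE)
    note("converge", f, nrow(motifs))
    f <- file.path(out_dir, "convergence_groups.tsv")
    readr::write_tsv(tidy(crgs), f, progress = FALSE)
    note("converge", f, nrow(crgs),
         sprintf("n_groups=%d", nrow(crgs)))

    # --- qc -----------------------------------------------------------
    qc <- filter_cells(metrics, config$qc_preset %||% "droplet_fluid_blood")
    f <- file.path(out_dir, "qc_kept.csv")
    readr::write_csv(qc$kept, f, progress = FALSE)
    note("qc", f, nrow(qc$kept), config$qc_preset %||% "droplet_fluid_blood")
    f <- file.path(out_dir, "qc_removed.csv")
    readr::write_csv(qc$removed, f, progress = FALSE)
    note("qc", f, nrow(qc$removed))

    # --- V-J usage ----------------------------------------------------
    usage_cells <- partition_chains(partitions) |>
      filter(.data$locus == "TRB", .data$status == "OK") |>
      left_join(select(metadata, "barcode", "sample_type"), by = "barcode")
    usage <- vj_usage(usage_cells)
    f <- file.path(out_dir, "vj_usage.tsv")
    readr::write_tsv(as_tibble(usage), f, progress = FALSE)
    note("usage", f, nrow(usage))

    # --- analyte panel ------------------------------------------------
    panel_args <- config$panel %||% list()
    panel_args$seed <- derive_seed(seed, "panel")
    panel <- do.call(simulate_panel, panel_args)
    stats <- paired_panel_test(panel)
    f <- file.path(out_dir, "panel.tsv")
    readr::write_tsv(panel, f, progress = FALSE)
    note("panel", f, nrow(panel))
    f <- file.path(out_dir, "panel_stats.tsv")
    readr::write_tsv(stats, f, progress = FALSE)
    note("panel", f, nrow(stats))
    TRUE
  }, error = function(e) {
    fail_stage <<- conditionMessage(e)
    e
  })

  man <- bind_rows(manifest)
  if (!is.null(fail_stage)) {
    man <- bind_rows(man, tibble(stage = "FAILED", file = "",
                                 rows = NA_integer_, params = fail_stage))
  }
  readr::write_tsv(man, file.path(out_dir, "manifest.tsv"), progress = FALSE)
  if (inherits(res, "error")) stop(res)
  invisible(man)
}
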