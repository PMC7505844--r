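#' Read a VDJ contig annotation table
#'
#' Reads per-chain TCR contig annotations in either the 10x CellRanger
#' `filtered_contig_annotations.csv` convention (`dialect = "tenx"`) or the
#' AIRR Rearrangement TSV convention (`dialect = "airr"`), returning one row
#' per productive TRA/TRB chain.
#'
#' Row-level filters applied, with counts kept in `attr(x, "counters")`:
#' non-productive chains are dropped (`n_nonproductive`), chains from loci
#' other than TRA/TRB are dropped with a warning (`n_other_locus`), and gene
#' names that do not carry the locus-appropriate prefix (e.g. a `TRB` chain
#' whose V call does not start with `TRBV`) are retained verbatim but counted
#' (`n_bad_gene`) and warned about.
#'
#' @param path Path to the contig file.
#' @param dialect `"tenx"` (comma-separated, CellRanger column names) or
#'   `"airr"` (tab-separated, AIRR Rearrangement minimal columns).
#' @param meta Optional cell metadata data frame (see [read_cell_metadata()])
#'   joined by `barcode` to attach `patient_id` and `sample_id` when the
#'   contig file itself does not carry them.
#'
#' @return A tibble with columns `barcode`, `patient_id`, `sample_id`,
#'   `locus`, `v_gene`, `d_gene`, `j_gene`, `cdr3_nt`, `cdr3_aa`,
#'   `productive`, `umis`, in input row order.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c(
#'   "barcode,chain,v_gene,d_gene,j_gene,cdr3,cdr3_nt,productive,umis",
#'   "AAAC-1,TRB,TRBV28,TRBD1,TRBJ1-1,CASSF,TGCGCCAGCAGCTTC,True,4"
#' ), tf)
#' read_contig_table(tf, "tenx")
read_contig_table <- function(path, dialect = c("tenx", "airr"), meta = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    abort(sprintf("contig file does not exist: %s", path))
  }
  if (file.size(path) == 0) {
    warn("contig file is empty; returning zero records")
    return(empty_contigs())
  }
  raw <- if (dialect == "tenx") {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                    col_types = readr::cols(.default = readr::col_character()))
  } else {
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                    col_types = readr::cols(.default = readr::col_character()))
  }
  if (nrow(raw) == 0 && ncol(raw) <= 1) {
    warn("contig file has no parseable rows; returning zero records")
    return(empty_contigs())
  }

  if (dialect == "tenx") {
    assert_columns(raw, c("barcode", "chain", "v_gene", "d_gene", "j_gene",
                          "cdr3", "cdr3_nt", "productive", "umis"),
                   what = "10x contig table")
    contigs <- tibble(
      barcode    = raw$barcode,
      patient_id = if ("patient_id" %in% names(raw)) raw$patient_id else NA_character_,
      sample_id  = if ("sample_id" %in% names(raw)) raw$sample_id else NA_character_,
      locus      = raw$chain,
      v_gene     = raw$v_gene,
      d_gene     = dplyr::coalesce(raw$d_gene, ""),
      j_gene     = raw$j_gene,
      cdr3_nt    = raw$cdr3_nt,
      cdr3_aa    = raw$cdr3,
      productive = parse_flag(raw$productive),
      umis       = as.integer(raw$umis)
    )
  } else {
    assert_columns(raw, c("cell_id", "locus", "v_call", "j_call",
                          "junction", "junction_aa", "productive"),
                   what = "AIRR rearrangement table")
    contigs <- tibble(
      barcode    = raw$cell_id,
      patient_id = if ("patient_id" %in% names(raw)) raw$patient_id else NA_character_,
      sample_id  = if ("sample_id" %in% names(raw)) raw$sample_id else NA_character_,
      locus      = raw$locus,
      v_gene     = raw$v_call,
      d_gene     = if ("d_call" %in% names(raw)) dplyr::coalesce(raw$d_call, "") else "",
      j_gene     = raw$j_call,
      cdr3_nt    = raw$junction,
      cdr3_aa    = raw$junction_aa,
      productive = parse_flag(raw$productive),
      umis       = if ("duplicate_count" %in% names(raw)) as.integer(raw$duplicate_count) else 0L
    )
  }

  n_nonproductive <- sum(!contigs$productive, na.rm = TRUE) +
    sum(is.na(contigs$productive))
  contigs <- filter(contigs, !is.na(.data$productive), .data$productive)

  other <- !contigs$locus %in% c("TRA", "TRB")
  n_other_locus <- sum(other)
  if (n_other_locus > 0) {
    warn(sprintf("dropped %d chains from loci other than TRA/TRB", n_other_locus))
    contigs <- contigs[!other, ]
  }

  expected_v <- paste0(contigs$locus, "V")
  bad_gene <- !is.na(contigs$v_gene) & !startsWith(contigs$v_gene, expected_v)
  bad_gene <- bad_gene |
    (!is.na(contigs$j_gene) & !startsWith(contigs$j_gene, paste0(contigs$locus, "J")))
  n_bad_gene <- sum(bad_gene)
  if (n_bad_gene > 0) {
    warn(sprintf("%d chains carry gene names without the expected locus prefix (kept verbatim)",
                 n_bad_gene))
  }

  if (!is.null(meta)) {
    assert_columns(meta, c("barcode", "patient_id", "sample_id"), what = "cell metadata")
    contigs <- contigs |>
      select(-"patient_id", -"sample_id") |>
      left_join(distinct(as_tibble(meta), .data$barcode, .data$patient_id, .data$sample_id),
                by = "barcode")
  }
  contigs <- mutate(
    contigs,
    patient_id = dplyr::coalesce(.data$patient_id, "unknown"),
    sample_id  = dplyr::coalesce(.data$sample_id, "unknown")
  )

  attr(contigs, "counters") <- c(
    n_nonproductive = n_nonproductive,
    n_other_locus = n_other_locus,
    n_bad_gene = n_bad_gene
  )
  contigs
}

empty_contigs <- function() {
  tibble(
    barcode = character(), patient_id = character(), sample_id = character(),
    locus = character(), v_gene = character(), d_gene = character(),
    j_gene = character(), cdr3_nt = character(), cdr3_aa = character(),
    productive = logical(), umis = integer()
  )
}

# "True"/"TRUE"/"true"/TRUE -> TRUE; "None"/"" -> NA
parse_flag <- function(x) {
  lx <- tolower(as.character(x))
  out <- rep(NA, length(x))
  out[lx %in% c("true", "t")] <- TRUE
  out[lx %in% c("false", "f")] <- FALSE
  out
}

#' Read a cell metadata table
#'
#' @param path CSV with columns `barcode`, `patient_id`, `sample_id`,
#'   `sample_type` (one of PBMC, SFMC, TISSUE) and `cluster_label`.
#' @return A tibble with those columns.
#' @export
read_cell_metadata <- function(path) {
  meta <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                          col_types = readr::cols(.default = readr::col_character()))
  assert_columns(meta, c("barcode", "patient_id", "sample_id", "sample_type",
                         "cluster_label"), what = "cell metadata")
  bad <- setdiff(unique(meta$sample_type), c("PBMC", "SFMC", "TISSUE"))
  if (length(bad) > 0) {
    warn(sprintf("unrecognised sample_type value(s): %s", paste(bad, collapse = ", ")))
  }
  meta
}

#' Partition chains per cell barcode and classify multiplets
#'
#' Groups productive chains by `(patient_id, sample_id, barcode)`, collapses
#' within-barcode duplicate chains (identical locus + CDR3 nt + V + J; the
#' copy with the highest UMI count is kept, so CellRanger duplicate consensus
#' rows cannot trigger spurious multiplet calls), and classifies every
#' barcode:
#'
#' * `MULTIPLET` - more than 1 beta chain or more than 2 alpha chains;
#' * `ALPHA_ONLY` - no beta chain but at least one alpha chain;
#' * `EMPTY` - no productive chains (only arises for barcodes supplied via
#'   `all_barcodes` with no contigs);
#' * `OK` - otherwise (exactly 1 beta, 0-2 alphas).
#'
#' Classification is a pure function of the per-barcode chain counts.
#'
#' @param contigs A contig tibble from [read_contig_table()] (or with the
#'   same columns).
#' @param all_barcodes Optional tibble (`barcode`, `patient_id`, `sample_id`)
#'   of barcodes that must appear in the output even when they have no
#'   chains; these yield `EMPTY` partitions.
#'
#' @return A `tcr_partitions` tibble with one row per barcode: `patient_id`,
#'   `sample_id`, `barcode`, `n_alpha`, `n_beta`, `status`. The collapsed
#'   chain-level table is kept in `attr(x, "chains")` and is accessible with
#'   [partition_chains()].
#' @export
build_cell_partitions <- function(contigs, all_barcodes = NULL) {
  assert_columns(contigs, c("barcode", "patient_id", "sample_id", "locus",
                            "v_gene", "j_gene", "cdr3_nt", "cdr3_aa", "umis"),
                 what = "contigs")
  chains <- contigs |>
    as_tibble() |>
    group_by(.data$patient_id, .data$sample_id, .data$barcode,
             .data$locus, .data$cdr3_nt, .data$v_gene, .data$j_gene) |>
    arrange(dplyr::desc(.data$umis), .by_group = TRUE) |>
    slice(1) |>
    ungroup()

  parts <- chains |>
    count(.data$patient_id, .data$sample_id, .data$barcode, .data$locus) |>
    tidyr::pivot_wider(names_from = "locus", values_from = "n", values_fill = 0L)
  for (col in c("TRA", "TRB")) {
    if (!col %in% names(parts)) parts[[col]] <- 0L
  }
  parts <- parts |>
    rename(n_alpha = "TRA", n_beta = "TRB") |>
    mutate(status = classify_partition(.data$n_alpha, .data$n_beta))

  if (!is.null(all_barcodes)) {
    extra <- as_tibble(all_barcodes) |>
      distinct(.data$barcode, .data$patient_id, .data$sample_id) |>
      anti_join(parts, by = c("patient_id", "sample_id", "barcode")) |>
      mutate(n_alpha = 0L, n_beta = 0L, status = "EMPTY")
    parts <- bind_rows(parts, extra)
  }
  parts <- arrange(parts, .data$patient_id, .data$sample_id, .data$barcode)
  attr(parts, "chains") <- chains
  class(parts) <- c("tcr_partitions", class(parts))
  parts
}

# Pure multiplet rule: >1 beta or >2 alpha chains.
classify_partition <- function(n_alpha, n_beta) {
  dplyr::case_when(
    n_beta > 1L | n_alpha > 2L ~ "MULTIPLET",
    n_beta == 0L & n_alpha >= 1L ~ "ALPHA_ONLY",
    n_beta == 0L & n_alpha == 0L ~ "EMPTY",
    TRUE ~ "OK"
  )
}

#' Chain-level view of a partition table
#'
#' @param partitions A `tcr_partitions` object from [build_cell_partitions()].
#' @return The collapsed chain tibble with partition `status` joined on.
#' @export
partition_chains <- function(partitions) {
  chains <- attr(partitions, "chains")
  if (is.null(chains)) {
    abort("`partitions` does not carry chain-level data; build it with build_cell_partitions()")
  }
  left_join(chains,
            select(as_tibble(partitions), "patient_id", "sample_id", "barcode", "status"),
            by = c("patient_id", "sample_id", "barcode"))
}

#' @export
print.tcr_partitions <- function(x, ...) {
  cat(sprintf("<tcr_partitions> %d barcodes (%s)\n", nrow(x),
              paste(sprintf("%s: %d", names(table(x$status)), table(x$status)),
                    collapse = ", ")))
  NextMethod()
}

#' Write partitions as an AIRR Rearrangement TSV
#'
#' Emits one rearrangement row per chain of every partition. Multiplet
#' partitions are written in full: multiplet status is an analysis-level
#' classification, not an I/O-level filter. A round trip through
#' [read_contig_table()] with `dialect = "airr"` reproduces the chain
#' records.
#'
#' @param partitions A `tcr_partitions` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_airr <- function(partitions, path) {
  chains <- attr(partitions, "chains")
  if (is.null(chains)) abort("`partitions` must come from build_cell_partitions()")
  out <- tibble(
    cell_id = chains$barcode,
    locus = chains$locus,
    v_call = chains$v_gene,
    d_call = chains$d_gene,
    j_call = chains$j_gene,
    junction = chains$cdr3_nt,
    junction_aa = chains$cdr3_aa,
    productive = "TRUE",
    duplicate_count = chains$umis,
    patient_id = chains$patient_id,
    sample_id = chains$sample_id
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
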