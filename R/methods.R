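# tidy()/glance()/autoplot() methods for result objects.

#' @describeIn test_clonal_enrichment `tidy()` returns the result as a plain
#'   tibble.
#' @param x,object A `tcr_enrichment` object.
#' @param ... Unused.
#' @method tidy tcr_enrichment
#' @export
tidy.tcr_enrichment <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "tcr_enrichment")
  out
}

#' @describeIn test_clonal_enrichment `glance()` summarises a test run:
#'   number of clones tested, number enriched per sample, alpha level.
#' @method glance tcr_enrichment
#' @export
glance.tcr_enrichment <- function(x, ...) {
  pair <- attr(x, "sample_pair")
  tibble(
    n_clones = nrow(x),
    n_cells = x$a[1] + x$b[1] + x$c[1] + x$d[1],
    n_enriched = sum(!is.na(x$enriched_in)),
    n_enriched_a = sum(x$enriched_in == pair[1], na.rm = TRUE),
    n_enriched_b = sum(x$enriched_in == pair[2], na.rm = TRUE),
    alpha_level = attr(x, "alpha_level")
  )
}

#' @describeIn test_clonal_enrichment `autoplot()` draws the per-clone
#'   expansion plot: clone cell counts in the two samples, enriched clones
#'   highlighted.
#' @method autoplot tcr_enrichment
#' @export
autoplot.tcr_enrichment <- function(object, ...) {
  pair <- attr(object, "sample_pair")
  df <- as_tibble(object) |>
    mutate(status = dplyr::case_when(
      is.na(.data$enriched_in) ~ "not enriched",
      .data$enriched_in == pair[1] ~ paste("enriched in", pair[1]),
      TRUE ~ paste("enriched in", pair[2])
    ))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$a, y = .data$c,
                                   colour = .data$status)) +
    ggplot2::geom_jitter(width = 0.15, height = 0.15, alpha = 0.7) +
    ggplot2::scale_x_continuous(trans = "log1p") +
    ggplot2::scale_y_continuous(trans = "log1p") +
    ggplot2::labs(x = paste("cells in", pair[1]),
                  y = paste("cells in", pair[2]),
                  colour = NULL, title = "Per-clone expansion") +
    ggplot2::theme_minimal()
}

#' @describeIn build_convergence_groups `tidy()` flattens groups to one row
#'   per group with `;`-separated member and patient lists.
#' @param x,object A `tcr_convergence` object.
#' @param ... Unused.
#' @method tidy tcr_convergence
#' @export
tidy.tcr_convergence <- function(x, ...) {
  as_tibble(x) |>
    mutate(
      members = purrr::map_chr(.data$members, paste, collapse = ";"),
      patients_represented = purrr::map_chr(.data$patients_represented,
                                            paste, collapse = ";")
    )
}

#' @describeIn build_convergence_groups `glance()` reports group counts and
#'   cross-patient sharing.
#' @method glance tcr_convergence
#' @export
glance.tcr_convergence <- function(x, ...) {
  tibble(
    n_groups = nrow(x),
    n_sequences_grouped = sum(x$n_members),
    n_cross_patient = sum(x$n_patients >= 2),
    largest_group = if (nrow(x) > 0) max(x$n_members) else 0L
  )
}

#' @describeIn build_convergence_groups `autoplot()` draws group sizes
#'   coloured by the number of patients represented.
#' @method autoplot tcr_convergence
#' @export
autoplot.tcr_convergence <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$crg_id, -.data$n_members),
    y = .data$n_members, fill = factor(.data$n_patients)
  )) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "members", fill = "patients",
                  title = "TCR convergence groups") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' @describeIn vj_usage `autoplot()` draws the V-J pairing weights as a tile
#'   map per sample type.
#' @param object A `vj_usage` object.
#' @param ... Unused.
#' @method autoplot vj_usage
#' @export
autoplot.vj_usage <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$j_gene, y = .data$v_gene,
                               fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~sample_type) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "J gene", y = "V gene", fill = "usage",
                  title = "Equal-patient-weight V-J usage") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
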