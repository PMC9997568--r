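# broom-style tidiers for the pipeline's result objects.

#' Tidy a clustering
#'
#' @param x a `paraseek_clustering`.
#' @param ... unused.
#' @return the clusters tibble (one row per cluster).
#' @method tidy paraseek_clustering
#' @export
tidy.paraseek_clustering <- function(x, ...) {
  dplyr::mutate(x$clusters, c = x$c, .before = 1L)
}

#' @rdname tidy.paraseek_clustering
#' @method glance paraseek_clustering
#' @export
glance.paraseek_clustering <- function(x, ...) {
  tibble::tibble(c = x$c, n_clusters = nrow(x$clusters),
                 n_supported = x$n_supported, n_classified = x$n_classified,
                 n_total = x$n_total)
}

#' Tidy a threshold scan
#'
#' @param x a `paraseek_scan`.
#' @param ... unused.
#' @return the per-threshold table (`c`, `n_clusters`, `n_supported`,
#'   `n_classified`) with a `chosen` flag.
#' @method tidy paraseek_scan
#' @export
tidy.paraseek_scan <- function(x, ...) {
  dplyr::mutate(x$grid, chosen = abs(.data$c - x$chosen_c) < 1e-9,
                discarded = .data$c %in% x$discarded_cs)
}

#' @rdname tidy.paraseek_scan
#' @method glance paraseek_scan
#' @export
glance.paraseek_scan <- function(x, ...) {
  tibble::tibble(chosen_c = x$chosen_c,
                 n_supported = x$chosen$n_supported,
                 n_classified = x$chosen$n_classified,
                 n_discarded = length(x$discarded_cs))
}

#' Tidy an annotated gene
#'
#' @param x a `paraseek_gene`.
#' @param ... unused.
#' @return a one-row gene summary tibble.
#' @method tidy paraseek_gene
#' @export
tidy.paraseek_gene <- function(x, ...) {
  gene_summary_row(x)
}

#' Tidy a sample report
#'
#' @param x a `paraseek_report`.
#' @param ... unused.
#' @return the gene summary tibble (one row per reported gene).
#' @method tidy paraseek_report
#' @export
tidy.paraseek_report <- function(x, ...) {
  if (length(x$genes) == 0L) {
    return(tibble::tibble(
      gene_id = character(), length_start_stop = integer(),
      paralog_label = character(), n_cds = integer(), in_frame = logical(),
      partial = logical(), n_repairs = integer(), has_start = logical(),
      has_stop = logical(), all_splice_canonical = logical(),
      n_conserved_cys = integer(), conserved_pro = logical(),
      protein_length = integer(), complete = logical()
    ))
  }
  dplyr::bind_rows(lapply(x$genes, gene_summary_row))
}

#' @rdname tidy.paraseek_report
#' @method glance paraseek_report
#' @export
glance.paraseek_report <- function(x, ...) {
  dplyr::mutate(
    x$counts,
    sample_id = x$sample_id, .before = 1L
  ) |>
    dplyr::mutate(chosen_c = x$chosen_c, n_supported = x$n_supported,
                  n_genes = length(x$genes), n_warnings = length(x$warnings))
}
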