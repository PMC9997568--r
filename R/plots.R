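# ggplot2 views of the pipeline's diagnostic tables.

#' Plot a threshold scan
#'
#' Supported-cluster and classified-amplicon counts across the identity
#' threshold grid, with the chosen threshold marked and discarded thresholds
#' crossed out.
#'
#' @param object a `paraseek_scan`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot paraseek_scan
#' @export
autoplot.paraseek_scan <- function(object, ...) {
  tbl <- tidy(object)
  long <- tidyr::pivot_longer(
    tbl, c("n_supported", "n_classified"),
    names_to = "metric", values_to = "count"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$c, y = .data$count)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(shape = .data$discarded)) +
    ggplot2::geom_vline(xintercept = object$chosen_c, linetype = "dashed") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 4)) +
    ggplot2::labs(x = "identity threshold c", y = NULL, shape = "discarded",
                  title = "Threshold scan",
                  subtitle = paste0("chosen c = ", format(object$chosen_c))) +
    ggplot2::theme_minimal()
}

#' Plot a sample report
#'
#' Filtering funnel (reads in, amplicons extracted, amplicons kept) next to
#' the supported-cluster sizes at the chosen threshold.
#'
#' @param object a `paraseek_report`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot paraseek_report
#' @export
autoplot.paraseek_report <- function(object, ...) {
  funnel <- tibble::tibble(
    stage = factor(
      c("reads in", "reads Q-filtered", "amplicons extracted", "amplicons kept"),
      levels = c("reads in", "reads Q-filtered", "amplicons extracted", "amplicons kept")
    ),
    count = c(object$counts$n_reads_in, object$counts$n_reads_prefiltered,
              object$counts$n_amplicons_extracted, object$counts$n_amplicons_filtered)
  )
  ggplot2::ggplot(funnel, ggplot2::aes(x = .data$stage, y = .data$count)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "count",
                  title = paste0("Sample ", object$sample_id),
                  subtitle = paste0(length(object$genes), " gene(s) at c = ",
                                    format(object$chosen_c))) +
    ggplot2::theme_minimal()
}
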