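# ggplot2 views of the two result types.

#' Plot a metrics report
#'
#' Detection rate (solid) and mean absolute frequency-estimation error
#' (dashed) against designed event frequency, one panel per event kind.
#'
#' @param object A `tepool_metrics` tibble from [metrics_report()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.tepool_metrics <- function(object, ...) {
  df <- filter(object, !is.na(.data$designed_frequency))
  if (nrow(df) == 0) abort("no frequency-stratified rows to plot")
  long <- bind_rows(
    df %>% select("kind", "designed_frequency", value = "sensitivity") %>%
      mutate(measure = "detection rate"),
    df %>% select("kind", "designed_frequency", value = "mean_freq_error") %>%
      mutate(measure = "mean |f̂ - f|")
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$designed_frequency, .data$value,
                                     linetype = .data$measure)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~kind) +
    ggplot2::scale_linetype_manual(values = c("solid", "dashed")) +
    ggplot2::labs(x = "designed population frequency", y = NULL,
                  linetype = NULL) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot called events
#'
#' Estimated population frequency along the genome, coloured by family,
#' shaped by kind.
#'
#' @param object A `tepool_events` tibble.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.tepool_events <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes((.data$start + .data$end) / 2,
                                       .data$frequency,
                                       colour = .data$family,
                                       shape = .data$kind)) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~contig, scales = "free_x") +
    ggplot2::labs(x = "genomic position (bp)",
                  y = "estimated population frequency") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' TSD length distribution
#'
#' Histogram of target-site-duplication lengths among events with
#' both-strand base junction estimates; negative lengths are target-site
#' deletions.
#'
#' @param events A `tepool_events` tibble.
#' @return A ggplot object.
#' @export
plot_tsd_distribution <- function(events) {
  df <- events %>%
    filter(!is.na(.data$junction_plus), !is.na(.data$junction_minus)) %>%
    mutate(tsd = tsd_length(.data$junction_plus, .data$junction_minus))
  ggplot2::ggplot(df, ggplot2::aes(.data$tsd)) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = "TSD length (nt; negative = target-site deletion)",
                  y = "events") +
    ggplot2::theme_minimal()
}
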