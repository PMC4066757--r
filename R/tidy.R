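# broom-style verbs for the result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a metrics report
#'
#' Long format: one row per (kind, designed frequency, measure).
#'
#' @param x A `tepool_metrics` tibble.
#' @param ... Ignored.
#' @return A tibble with `kind`, `designed_frequency`, `measure`, `value`.
#' @export
tidy.tepool_metrics <- function(x, ...) {
  tidyr::pivot_longer(as_tibble(x),
                      cols = c("sensitivity", "precision", "fdr",
                               "mean_freq_error", "junction_found",
                               "junction_correct"),
                      names_to = "measure", values_to = "value")
}

#' One-row summary of a metrics report
#'
#' Overall (frequency-pooled) measures per kind, in wide form.
#'
#' @param x A `tepool_metrics` tibble.
#' @param ... Ignored.
#' @return A tibble with one row per event kind.
#' @export
glance.tepool_metrics <- function(x, ...) {
  filter(as_tibble(x), is.na(.data$designed_frequency)) %>%
    select(-"designed_frequency")
}

#' One-row summary of called events
#'
#' @param x A `tepool_events` tibble.
#' @param ... Ignored.
#' @return Counts and frequency summaries per event kind.
#' @export
glance.tepool_events <- function(x, ...) {
  as_tibble(x) %>%
    group_by(.data$kind) %>%
    summarise(n = dplyr::n(),
              n_base_junction = sum(.data$junction_resolution == "base"),
              mean_frequency = mean(.data$frequency),
              mean_support = mean(.data$T), .groups = "drop")
}
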