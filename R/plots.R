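# ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_hline
#'   geom_col labs theme_minimal facet_wrap
NULL

#' Plot an extracted ion chromatogram
#'
#' @param object EIC from [extract_eic()].
#' @param peaks Optional peak table from [detect_peaks()] to mark apexes.
#' @param ... Unused.
#' @return ggplot object.
#' @export
autoplot.eic <- function(object, peaks = NULL, ...) {
  p <- ggplot(object, aes(x = .data$rt, y = .data$intensity)) +
    geom_line(colour = "steelblue") +
    labs(x = "retention time [min]", y = "intensity [counts]",
         title = sprintf("EIC m/z %.4f (+/- %.1f ppm)",
                         attr(object, "target_mz"), attr(object, "ppm"))) +
    theme_minimal()
  if (!is.null(peaks) && nrow(peaks)) {
    p <- p + geom_point(data = peaks,
                        aes(x = .data$rt_apex, y = .data$intensity_apex),
                        colour = "firebrick", size = 2)
  }
  p
}

#' Plot a recalibration model: raw errors, fitted curve and residuals
#'
#' @param object `recal_model`.
#' @param ... Unused.
#' @return ggplot object.
#' @export
autoplot.recal_model <- function(object, ...) {
  td <- tidy(object)
  long <- tidyr::pivot_longer(td, c("raw_error_ppm", "residual_ppm"),
                              names_to = "stage", values_to = "error_ppm")
  long$stage <- factor(long$stage, c("raw_error_ppm", "residual_ppm"),
                       c("before correction", "after correction"))
  ggplot(long, aes(x = .data$mz, y = .data$error_ppm)) +
    geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    geom_point(alpha = 0.6) +
    geom_line(data = td, aes(x = .data$mz, y = .data$fitted_ppm),
              colour = "firebrick",
              inherit.aes = FALSE) +
    facet_wrap(~stage) +
    labs(x = "m/z [Da]", y = "mass error [ppm]") +
    theme_minimal()
}

#' Plot a cleaned (or annotated) fragment spectrum
#'
#' @param object `clean_spectrum` or any tibble with `mz`/`intensity`.
#' @param ... Unused.
#' @return ggplot object.
#' @export
autoplot.clean_spectrum <- function(object, ...) {
  ggplot(as_tibble(object), aes(x = .data$mz, xend = .data$mz,
                                y = 0, yend = .data$intensity)) +
    ggplot2::geom_segment() +
    labs(x = "m/z [Da]", y = "intensity [counts]") +
    theme_minimal()
}

#' Per-collision-energy pass counts from a prescreen table
#'
#' @param table Flat table from [prescreen_table()].
#' @return ggplot bar chart of pass/fail counts per CE and polarity.
#' @export
plot_qc_summary <- function(table) {
  counts <- table |>
    count(.data$ce, .data$polarity, .data$verdict)
  ggplot(counts, aes(x = factor(.data$ce), y = .data$n, fill = .data$verdict)) +
    geom_col(position = "dodge") +
    facet_wrap(~polarity) +
    labs(x = "collision energy [NCE]", y = "compounds") +
    theme_minimal()
}
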