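#' Plot a k-mer copy-number spectrum
#'
#' @param object a `kmer_histogram`.
#' @param peaks optional `kcn_peaks` row; detected peaks are drawn as
#'   dashed verticals.
#' @param kcn_max right truncation of the x axis.
#' @param ... ignored.
#' @return A ggplot.
#' @export
autoplot.kmer_histogram <- function(object, peaks = NULL, kcn_max = NULL, ...) {
  df <- as_tibble(object)
  if (!is.null(kcn_max)) df <- filter(df, .data$kcn <= kcn_max)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$kcn, y = .data$count)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::labs(x = "k-mer copy number (KCN)", y = "distinct k-mers",
                  title = sprintf("KCN spectrum (k = %s)", attr(object, "k"))) +
    ggplot2::theme_minimal()
  if (!is.null(peaks)) {
    marks <- c(error = peaks$error_minimum, het = peaks$het_peak,
               hom = peaks$hom_peak)
    marks <- marks[!is.na(marks)]
    p <- p + ggplot2::geom_vline(xintercept = marks, linetype = "dashed",
                                 color = "grey40")
  }
  p
}

#' Plot a corrected 4DTv distribution with fitted mixture components
#'
#' Histogram of the corrected 4DTv values with the weighted component
#' densities of a fitted mixture overlaid — the standard figure used to
#' read off WGD waves.
#'
#' @param object a `normal_mixture`.
#' @param values the corrected 4DTv values the model was fitted to.
#' @param bins histogram bin count.
#' @param ... ignored.
#' @return A ggplot.
#' @export
autoplot.normal_mixture <- function(object, values, bins = 60, ...) {
  df <- tibble(value = values)
  grid <- seq(min(values), max(values), length.out = 400)
  comp <- bind_rows(lapply(seq_len(object$k), function(j) {
    tibble(x = grid, component = factor(j),
           density = object$weights[j] * dnorm(grid, object$means[j],
                                               object$sds[j]))
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = bins, fill = "grey85", color = "grey70") +
    ggplot2::geom_line(data = comp,
                       ggplot2::aes(x = .data$x, y = .data$density,
                                    color = .data$component),
                       linewidth = 0.9) +
    ggplot2::labs(x = "corrected 4DTv", y = "density",
                  title = sprintf("Normal mixture, k = %d (BIC %.1f)",
                                  object$k, object$bic)) +
    ggplot2::theme_minimal()
}

#' Heatmap of shared paralogon anchors between chromosomes
#'
#' @param summary result of [paralogon_summary()].
#' @return A ggplot.
#' @export
plot_paralogon_matrix <- function(summary) {
  m <- summary$matrix
  df <- as_tibble(as.table(m), .name_repair = ~c("chrom_a", "chrom_b", "n"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$chrom_a, y = .data$chrom_b,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL, fill = "anchors",
                  title = "Shared paralogon anchor points") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
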