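#' Detect error minimum and het/hom peaks in a KCN histogram
#'
#' Counts are smoothed with a centered moving average, the error cutoff
#' is the first KCN at which the smoothed counts stop decreasing, and
#' modes are the local maxima above that cutoff ranked by height. When
#' the two tallest modes sit at a roughly two-fold KCN ratio (1.7-2.3)
#' the lower one is called the heterozygous peak and the higher the
#' homozygous peak; otherwise the tallest mode is the homozygous peak.
#'
#' @param hist a `kmer_histogram`.
#' @param smoothing_window odd moving-average window width.
#' @return A `kcn_peaks` tibble with one row: `error_minimum`,
#'   `het_peak` (NA when absent), `hom_peak`.
#' @export
detect_kcn_peaks <- function(hist, smoothing_window = 5L) {
  if (smoothing_window %% 2L != 1L) abort("`smoothing_window` must be odd")
  # dense grid so the moving average sees true zeros
  kcn <- seq(min(hist$kcn), max(hist$kcn))
  counts <- numeric(length(kcn))
  counts[match(hist$kcn, kcn)] <- hist$count
  half <- (smoothing_window - 1L) / 2L
  padded <- c(rep(counts[1], half), counts, rep(counts[length(counts)], half))
  sm <- as.numeric(stats::filter(padded, rep(1 / smoothing_window,
                                             smoothing_window), sides = 2))
  sm <- sm[(half + 1L):(half + length(counts))]

  # first local minimum: where the smoothed spectrum stops decreasing
  rising <- which(diff(sm) >= 0)
  if (length(rising) == 0) {
    abort("no local maximum above the error minimum: cannot call peaks")
  }
  min_idx <- rising[1]
  error_minimum <- kcn[min_idx]

  if (min_idx + 1L > length(kcn)) abort("no mode above the error minimum")
  above <- seq(min_idx + 1L, length(kcn))
  is_max <- vapply(above, function(i) {
    left <- if (i == 1L) -Inf else sm[i - 1L]
    right <- if (i == length(sm)) -Inf else sm[i + 1L]
    sm[i] >= left && sm[i] >= right && sm[i] > 0
  }, logical(1))
  modes <- above[is_max]
  if (length(modes) == 0) {
    abort("no local maximum above the error minimum: cannot call peaks")
  }
  # collapse plateaus to their first position
  modes <- modes[c(TRUE, diff(modes) > 1L)]
  modes <- modes[order(-sm[modes])]
  het <- NA_integer_
  hom <- kcn[modes[1]]
  # a genuine heterozygous/homozygous partner must be a substantial mode,
  # not a noise ripple in the sparse tail
  if (length(modes) >= 2L && sm[modes[2]] >= 0.2 * sm[modes[1]]) {
    two <- sort(kcn[modes[1:2]])
    ratio <- two[2] / two[1]
    if (ratio >= 1.7 && ratio <= 2.3) {
      het <- two[1]
      hom <- two[2]
    }
  }
  out <- tibble(error_minimum = as.integer(error_minimum),
                het_peak = as.integer(het), hom_peak = as.integer(hom))
  class(out) <- c("kcn_peaks", class(out))
  out
}

#' Estimate genome size from a KCN histogram (Lander-Waterman)
#'
#' Total k-mer instances are `sum(kcn * count)`; instances at or below
#' the error minimum are treated as sequencing errors and subtracted;
#' the remainder divided by the homozygous k-mer depth (the homozygous
#' peak KCN) gives the genome size. When `read_len` is supplied the
#' implied read-based depth `hom_peak * L / (L - k + 1)` is reported for
#' information.
#'
#' @param hist a `kmer_histogram`.
#' @param peaks a `kcn_peaks` row from [detect_kcn_peaks()].
#' @param read_len optional read length for the informational read-depth
#'   conversion.
#' @return A one-row tibble: `read_depth` (k-mer coverage units),
#'   `read_depth_reads` (NA unless `read_len` given),
#'   `total_kmer_instances`, `error_kmer_instances`, `genome_size`.
#' @export
estimate_genome_size <- function(hist, peaks, read_len = NULL) {
  if (is.na(peaks$hom_peak) || peaks$hom_peak <= 0) {
    abort("homozygous peak absent or zero: cannot estimate genome size")
  }
  total <- sum(as.numeric(hist$kcn) * hist$count)
  err <- sum(as.numeric(hist$kcn[hist$kcn <= peaks$error_minimum]) *
             hist$count[hist$kcn <= peaks$error_minimum])
  rd <- as.numeric(peaks$hom_peak)
  k <- attr(hist, "k")
  rd_reads <- if (!is.null(read_len) && !is.null(k)) {
    rd * read_len / (read_len - k + 1)
  } else NA_real_
  tibble(
    read_depth = rd,
    read_depth_reads = rd_reads,
    total_kmer_instances = total,
    error_kmer_instances = err,
    genome_size = (total - err) / rd
  )
}
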