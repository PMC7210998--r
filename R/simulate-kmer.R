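#' Simulate a diploid k-mer copy-number histogram
#'
#' Emulates the KCN spectrum of a shotgun read set: homozygous single-copy
#' k-mers Poisson-distributed around the k-mer coverage
#' `c = coverage * (read_len - k + 1) / read_len`, a heterozygous
#' component at `c / 2` (each variant haplotype contributes a distinct
#' k-mer at half depth; a k-mer overlaps a heterozygous site with
#' probability `1 - (1 - het)^k`), and an error spike decaying from
#' KCN = 1 whose mass scales with the per-base error rate.
#'
#' @param genome_size haploid genome size in bp (approximated as the
#'   number of distinct single-copy k-mer loci).
#' @param coverage fold read coverage.
#' @param read_len read length in bp.
#' @param k k-mer length (must not exceed `read_len`).
#' @param heterozygosity per-base heterozygosity fraction.
#' @param error_rate per-base sequencing error rate.
#' @param seed optional integer seed.
#' @return A `kmer_histogram` tibble with a `truth` attribute holding
#'   `genome_size` and the k-mer coverage `c`.
#' @export
simulate_kmer_histogram <- function(genome_size, coverage, read_len = 150,
                                    k = 31, heterozygosity = 0,
                                    error_rate = 0, seed = NULL) {
  stopifnot_scalar_number(genome_size, "genome_size", min = 1)
  stopifnot_scalar_number(coverage, "coverage", min = 1e-9)
  if (k > read_len) abort("`k` must not exceed `read_len`")
  with_seed_if(seed, {
    lambda <- coverage * (read_len - k + 1) / read_len
    g <- round(genome_size)
    p_het <- 1 - (1 - heterozygosity)^k
    n_het_loci <- rbinom(1L, g, p_het)
    n_hom <- g - n_het_loci
    depths <- c(
      rpois(n_hom, lambda),
      rpois(2L * n_het_loci, lambda / 2)  # two haplotype variants at c/2
    )
    depths <- depths[depths > 0]
    counts <- tabulate(depths)
    kcn <- seq_along(counts)
    # error k-mers: each base-call error spawns ~k novel low-copy k-mers
    n_err <- round(g * coverage * error_rate * k)
    if (n_err > 0) {
      err_kcn <- 1L + rgeom(n_err, 0.8)
      err_counts <- tabulate(err_kcn, nbins = length(counts))
      if (max(err_kcn) > length(counts)) {
        err_counts <- tabulate(err_kcn)
        counts <- c(counts, numeric(max(err_kcn) - length(counts)))
        kcn <- seq_along(counts)
      }
      counts <- counts + err_counts
    }
    keep <- counts > 0
    hist <- new_kmer_histogram(tibble(kcn = kcn[keep], count = counts[keep]), k = k)
    attr(hist, "truth") <- list(genome_size = g, kmer_coverage = lambda)
    hist
  })
}
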