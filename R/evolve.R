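# Two-parameter (transition/transversion) nucleotide substitution process.
#
# Rates: transitions at alpha = kappa * beta, each of the two transversion
# targets at beta. Time is measured in units where beta = 1, so a pair of
# sequences separated by total time T has expected transversions per site
# 2*T on the corrected scale, and a transversion-difference probability
# Q(T) = (1 - exp(-4*T)) / 2. Inverting -1/2*log(1 - 2*Q) recovers 2*T,
# which is why depths handed to the simulator are on the corrected scale.

# 4x4 transition-probability matrix after time t (beta = 1 units)
k2p_prob_matrix <- function(t, kappa) {
  e1 <- exp(-4 * t)                  # transversion relaxation
  e2 <- exp(-2 * (kappa + 1) * t)    # transition relaxation
  p_same <- 0.25 + 0.25 * e1 + 0.5 * e2
  p_ts   <- 0.25 + 0.25 * e1 - 0.5 * e2
  p_tv   <- 0.25 - 0.25 * e1         # per transversion target
  # base order A, C, G, T; transitions A<->G, C<->T
  m <- matrix(p_tv, 4, 4)
  diag(m) <- p_same
  m[1, 3] <- m[3, 1] <- p_ts
  m[2, 4] <- m[4, 2] <- p_ts
  m
}

# evolve integer-coded bases (1..4) for time t; vectorised by current base
evolve_bases <- function(bases, t, kappa) {
  if (t <= 0 || length(bases) == 0) return(bases)
  P <- k2p_prob_matrix(t, kappa)
  out <- bases
  u <- runif(length(bases))
  for (b in 1:4) {
    idx <- which(bases == b)
    if (length(idx) == 0) next
    cp <- cumsum(P[b, ])
    out[idx] <- findInterval(u[idx], cp) + 1L
  }
  out
}

#' Simulate a pair of four-fold degenerate site columns at a known depth
#'
#' Draws `n_sites` ancestral bases uniformly and evolves two independent
#' lineages under the two-parameter transition/transversion process so
#' that the pair's expected corrected 4DTv equals `depth` (total
#' separation `2 * t` with per-lineage duration `t = depth / 4` in
#' transversion-rate units).
#'
#' @param n_sites number of 4D sites.
#' @param depth expected corrected 4DTv of the pair (must invert to an
#'   uncorrected expectation below the 0.5 saturation bound).
#' @param kappa transition/transversion rate ratio.
#' @param seed optional integer seed.
#' @return A tibble with character columns `base_a`, `base_b`.
#' @export
simulate_divergent_sites <- function(n_sites, depth, kappa = 2, seed = NULL) {
  stopifnot_scalar_number(n_sites, "n_sites", min = 1)
  stopifnot_scalar_number(depth, "depth", min = 0)
  stopifnot_scalar_number(kappa, "kappa", min = 1e-12)
  if ((1 - exp(-2 * depth)) / 2 >= 0.5) {
    abort("depth saturates the uncorrected 4DTv scale")
  }
  with_seed_if(seed, {
    anc <- sample.int(4L, n_sites, replace = TRUE)
    t <- depth / 4
    tibble(
      base_a = .BASES[evolve_bases(anc, t, kappa)],
      base_b = .BASES[evolve_bases(anc, t, kappa)]
    )
  })
}
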