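test_that("retention probability shapes truth family sizes", {
  g1 <- simulate_wgd_genome(wgd_sim_config(
    n_ancestral_genes = 10, wgd_depths = 0.4, retention_prob = 1,
    cds_length_codons = 40, seed = 1))
  expect_true(all(table(g1$truth_families$family_id) == 2L))

  g3 <- simulate_wgd_genome(wgd_sim_config(
    n_ancestral_genes = 10, wgd_depths = c(1.3, 0.8, 0.4), retention_prob = 1,
    cds_length_codons = 40, seed = 1))
  expect_true(all(table(g3$truth_families$family_id) == 8L))

  g0 <- simulate_wgd_genome(wgd_sim_config(
    n_ancestral_genes = 10, wgd_depths = c(1.3, 0.8, 0.4), retention_prob = 0,
    cds_length_codons = 40, seed = 1))
  expect_true(all(table(g0$truth_families$family_id) == 1L))
  expect_equal(nrow(g0$truth_pair_depths), 0L)
})

test_that("truth pair depths follow the event of divergence and cover all pairs", {
  g <- simulate_wgd_genome(wgd_sim_config(
    n_ancestral_genes = 6, wgd_depths = c(1.3, 0.8, 0.4), retention_prob = 1,
    cds_length_codons = 40, seed = 3))
  expect_setequal(unique(g$truth_pair_depths$depth), c(1.3, 0.8, 0.4))
  # every within-family pair appears exactly once
  fam_sizes <- table(g$truth_families$family_id)
  expect_equal(nrow(g$truth_pair_depths), sum(choose(fam_sizes, 2)))
  # every gene is in exactly one family
  expect_equal(sort(g$truth_families$gene_id), sort(g$genes$gene_id))
})

test_that("simulation is bit-reproducible under a fixed seed", {
  cfg <- wgd_sim_config(n_ancestral_genes = 8, wgd_depths = c(0.8, 0.4),
                        retention_prob = 0.7, cds_length_codons = 50,
                        tandem_arrays = list(c(3, 0.9)),
                        intergenic_genes = 3, seed = 42)
  g1 <- simulate_wgd_genome(cfg)
  g2 <- simulate_wgd_genome(cfg)
  expect_identical(g1$genes, g2$genes)
  expect_identical(g1$truth_pair_depths, g2$truth_pair_depths)
})

test_that("config validation rejects saturating or disordered depths", {
  expect_error(wgd_sim_config(wgd_depths = c(0.4, 0.8)), "decreasing")
  expect_error(wgd_sim_config(wgd_depths = c(1.3, -0.1)), "positive")
  expect_error(wgd_sim_config(retention_prob = 1.4), "0, 1")
  expect_error(simulate_divergent_sites(100, depth = -1), ">=")
})

test_that("simulator and 4DTv estimator are mutually calibrated", {
  # pairs at known depth: mean corrected 4DTv within 3 SE of truth
  for (d in c(0.4, 1.3)) {
    vals <- vapply(1:60, function(i) {
      s <- simulate_divergent_sites(1000, d, kappa = 2, seed = 9000 + i)
      fourdtv_statistic(s)$fourdtv_corrected
    }, numeric(1))
    vals <- vals[!is.na(vals)]
    se <- sd(vals) / sqrt(length(vals))
    expect_lt(abs(mean(vals) - d), 3 * se)
  }
})

test_that("k-mer histogram simulator places modes where theory says", {
  # coverage 50, L=150, k=31 -> k-mer coverage c = 50 * 120/150 = 40
  h <- simulate_kmer_histogram(2e5, 50, 150, 31, heterozygosity = 0,
                               error_rate = 0, seed = 1)
  mode_kcn <- h$kcn[which.max(h$count)]
  expect_lt(abs(mode_kcn - 40), 2.5)
  # no error mass below the Poisson body
  expect_equal(sum(h$count[h$kcn <= 5]), 0)

  # heterozygous component at about half the homozygous mode
  h2 <- simulate_kmer_histogram(2e5, 50, 150, 31, heterozygosity = 0.008,
                                error_rate = 0, seed = 1)
  low <- h2$kcn <= 30
  het_mode <- h2$kcn[low][which.max(h2$count[low])]
  expect_lt(abs(het_mode - 20), 2.5)

  expect_error(simulate_kmer_histogram(1e5, 50, read_len = 20, k = 31),
               "read_len")
})

test_that("contig-set simulator truth matches its construction", {
  cs <- simulate_contig_set(20000, n_duplicates = 1, overlap_lengths = 3500,
                            identity_noise = 0, seed = 1, min_overlap = 3000)
  expect_equal(nrow(cs$contigs), 3L)
  expect_true(all(cs$truth$duplicates$remove))
  expect_equal(cs$truth$duplicates$identity, 1)
  expect_true(all(cs$truth$overlaps$merge))
  # merged length bookkeeping: len1 + len2 - overlap covers the genome
  frag_len <- nchar(cs$contigs$sequence[1:2])
  expect_equal(sum(frag_len) - 3500, 20000)

  # 10% noise -> duplicate below the 95% identity bar, marked retained
  cs2 <- simulate_contig_set(20000, n_duplicates = 1, overlap_lengths = integer(0),
                             identity_noise = 0.10, seed = 2)
  expect_false(any(cs2$truth$duplicates$remove))
  expect_lt(cs2$truth$duplicates$identity, 0.95)

  expect_error(simulate_contig_set(9000, overlap_lengths = 9500),
               "infeasible")
})
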