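test_that("global protein alignment matches the exhaustive oracle on tiny cases", {
  # identical sequences: gapless, score = diagonal BLOSUM62 sum
  a <- "MKVW"
  aln <- align_protein_pair(a, a)
  expect_equal(aln$aligned_a, a)
  expect_equal(aln$identity, 1)
  oracle_self <- enumerate_global_alignments(a, a)
  expect_equal(aln$score, oracle_self$score)

  # one-residue deletion
  aln2 <- align_protein_pair("MKV", "MV")
  oracle2 <- enumerate_global_alignments("MKV", "MV")
  expect_equal(aln2$score, oracle2$score)
  expect_equal(nchar(aln2$aligned_a), 3L)
  expect_equal(sum(strsplit(aln2$aligned_b, "")[[1]] == "-"), 1L)

  # terminal extension produces terminal gap columns
  aln3 <- align_protein_pair("MKVW", "MKVWAC")
  expect_equal(substr(aln3$aligned_a, 5, 6), "--")

  expect_error(align_protein_pair("", "MK"), "empty")
})

test_that("back-translation maps residues to codons and validates the CDS", {
  bt <- backtranslate_to_codons("M", "M", "ATG", "ATG")
  expect_equal(bt$codons_a, "ATG")
  expect_equal(bt$codons_b, "ATG")

  bt2 <- backtranslate_to_codons("MK-", "MKV", "ATGAAA", "ATGAAAGTT")
  expect_equal(bt2$codons_a, c("ATG", "AAA", "---"))
  expect_equal(bt2$codons_b, c("ATG", "AAA", "GTT"))

  expect_error(backtranslate_to_codons("MK", "MK", "ATGCCC", "ATGAAA"),
               "codon 2")
})

test_that("4D site extraction requires shared four-fold prefixes", {
  s1 <- extract_4d_sites(c("GGA"), c("GGT"))
  expect_equal(nrow(s1), 1L)
  expect_equal(s1$base_a, "A")
  expect_equal(s1$base_b, "T")
  expect_equal(nrow(extract_4d_sites(c("ATG"), c("ATG"))), 0L)   # Met
  expect_equal(nrow(extract_4d_sites(c("CTA"), c("GTA"))), 0L)   # prefixes differ
  expect_equal(nrow(extract_4d_sites(c("---"), c("GGA"))), 0L)   # gap column
})

test_that("4DTv statistic reproduces the correction closed form and filters", {
  sites <- tibble::tibble(base_a = c(rep("A", 10), rep("G", 30)),
                          base_b = c(rep("C", 10), rep("G", 30)))
  st <- fourdtv_statistic(sites)
  expect_equal(st$n_4d_sites, 40L)
  expect_equal(st$n_transversions, 10L)
  expect_equal(st$fourdtv_raw, 0.25)
  expect_equal(st$fourdtv_corrected, -0.5 * log(0.5), tolerance = 1e-12)

  st0 <- fourdtv_statistic(tibble::tibble(base_a = rep("A", 40),
                                          base_b = rep("G", 40)))
  expect_equal(st0$fourdtv_raw, 0)        # transitions are not transversions
  expect_equal(st0$fourdtv_corrected, 0)

  st29 <- fourdtv_statistic(tibble::tibble(base_a = rep("A", 29),
                                           base_b = rep("A", 29)))
  expect_false(st29$passes_filter)

  sat <- fourdtv_statistic(tibble::tibble(base_a = rep("A", 40),
                                          base_b = rep("C", 40)))
  expect_true(sat$saturated)
  expect_true(is.na(sat$fourdtv_corrected))
  expect_false(sat$passes_filter)

  empty <- fourdtv_statistic(tibble::tibble(base_a = character(),
                                            base_b = character()))
  expect_false(empty$passes_filter)
})

test_that("the correction map is increasing, convex, dominating, symmetric", {
  x <- seq(0, 0.49, by = 0.01)
  cx <- -0.5 * log(1 - 2 * x)
  expect_true(all(diff(cx) > 0))
  expect_true(all(diff(diff(cx)) > 0))
  expect_true(all(cx >= x))
  # swapping the two sequences changes nothing
  s <- simulate_divergent_sites(200, 0.8, seed = 4)
  swapped <- tibble::tibble(base_a = s$base_b, base_b = s$base_a)
  expect_equal(fourdtv_statistic(s)[, -(1:2)],
               fourdtv_statistic(swapped)[, -(1:2)])
})

test_that("transversion counting matches a per-site classification oracle", {
  for (s in 1:5) {
    sites <- withr::with_seed(s, tibble::tibble(
      base_a = sample(c("A", "C", "G", "T"), 200, TRUE),
      base_b = sample(c("A", "C", "G", "T"), 200, TRUE)))
    pur <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)
    oracle <- sum(pur[sites$base_a] != pur[sites$base_b])
    expect_equal(fourdtv_statistic(sites)$n_transversions, oracle)
  }
})

test_that("family-wise 4DTv pipeline scores all pairs and honours modes", {
  sim <- simulate_wgd_genome(wgd_sim_config(
    n_ancestral_genes = 6, wgd_depths = c(0.8, 0.4), retention_prob = 1,
    cds_length_codons = 300, seed = 21))
  recs <- fourdtv_families(sim$truth_families, sim$genes)
  expect_equal(nrow(recs), nrow(sim$truth_pair_depths))
  expect_true(all(recs$passes_filter))
  # measured depths track truth on average
  truth <- dplyr::transmute(sim$truth_pair_depths,
                            lo = pmin(id_a, id_b), hi = pmax(id_a, id_b),
                            depth = depth)
  joined <- dplyr::inner_join(recs, truth,
                              by = c(id_a = "lo", id_b = "hi"))
  expect_equal(nrow(joined), nrow(recs))
  for (d in unique(joined$depth)) {
    v <- joined$fourdtv_corrected[joined$depth == d]
    expect_lt(abs(mean(v) - d), 4 * sd(v) / sqrt(length(v)) + 0.02)
  }
})

test_that("neutral rate arithmetic follows the patristic-distance formula", {
  expect_equal(neutral_rate_from_tree("(a:0.1,b:0.1);", "a", "b", 1e8), 1e-9)
  expect_equal(neutral_rate_from_tree("(a:0.05,b:0.05);", "a", "b", 5e7), 1e-9)
  tr <- ape::read.tree(text = "((a:0.1,b:0.3):0.2,c:0.15);")
  expect_equal(neutral_rate_from_tree(tr, "a", "c", 1e8),
               (0.1 + 0.2 + 0.15) / (2 * 1e8))
  expect_error(neutral_rate_from_tree(tr, "a", "zz", 1e8), "zz")
  expect_error(neutral_rate_from_tree(tr, "a", "b", 0), ">=")
})
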