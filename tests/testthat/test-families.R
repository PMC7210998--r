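test_that("similarity search links identical proteins and ignores random pairs", {
  p <- random_protein(200, 1)
  e <- all_vs_all_similarity(c(a = p, b = p))
  expect_equal(nrow(e), 1L)
  expect_equal(e$percent_identity, 100)
  expect_equal(e$query_cov, 1)

  # independently random proteins never reach E <= 1e-8
  hits <- vapply(1:25, function(s) {
    nrow(all_vs_all_similarity(c(a = random_protein(100, 2 * s),
                                 b = random_protein(100, 2 * s + 1))))
  }, integer(1))
  expect_true(all(hits == 0L))

  expect_error(all_vs_all_similarity(c(a = "MKLV")), "two")
})

test_that("precomputed tabular edges pass through with symmetric collapse", {
  pre <- tibble::tibble(
    query_id = c("a", "b", "c"), subject_id = c("b", "a", "d"),
    percent_identity = c(90, 91, 80), alignment_length = c(100L, 100L, 50L),
    evalue = c(1e-20, 1e-30, 1e-3), bitscore = c(100, 120, 30),
    query_cov = 1, subject_cov = 1
  )
  e <- all_vs_all_similarity(NULL, precomputed = pre)
  # c-d fails the E cutoff; a-b kept once with the better E-value
  expect_equal(nrow(e), 1L)
  expect_equal(e$evalue, 1e-30)
})

test_that("MCL keeps disconnected components apart and isolates singletons", {
  tri <- tibble::tibble(
    query_id = c("a", "a", "b", "d", "d", "e"),
    subject_id = c("b", "c", "c", "e", "f", "f"),
    log10_evalue = rep(-10, 6), evalue = rep(1e-10, 6)
  )
  fam <- mcl_cluster(tri)
  expect_equal(families_to_sets(fam),
               canon_clusters(list(c("a", "b", "c"), c("d", "e", "f"))))

  fam2 <- mcl_cluster(tri, all_ids = c(letters[1:6], "z"))
  expect_true("z" %in% fam2$gene_id)
  expect_equal(sum(fam2$family_id == fam2$family_id[fam2$gene_id == "z"]), 1L)
})

test_that("MCL on the weighted path matches the fixed-point oracle", {
  edges <- tibble::tibble(query_id = c("a", "b"), subject_id = c("b", "c"),
                          log10_evalue = c(-1, -0.01),
                          evalue = 10^c(-1, -0.01))
  got <- families_to_sets(mcl_cluster(edges, inflation = 6))
  oracle <- canon_clusters(mcl_fixed_point_oracle(
    c("a", "b", "c"),
    data.frame(from = c("a", "b"), to = c("b", "c"), weight = c(1, 0.01)),
    inflation = 6))
  expect_equal(got, oracle)
})

test_that("MCL clusters equal connected components on random clique graphs", {
  for (s in 1:10) {
    parts <- withr::with_seed(s, {
      n <- sample(6:12, 1)
      split(paste0("n", seq_len(n)), sort(sample(1:4, n, TRUE)))
    })
    parts <- Filter(function(p) length(p) > 0, parts)
    edges <- dplyr::bind_rows(lapply(parts, function(p) {
      if (length(p) < 2) return(NULL)
      cmb <- utils::combn(p, 2)
      tibble::tibble(query_id = cmb[1, ], subject_id = cmb[2, ],
                     log10_evalue = -10, evalue = 1e-10)
    }))
    all_ids <- unlist(parts, use.names = FALSE)
    got <- families_to_sets(mcl_cluster(edges, all_ids = all_ids))
    want <- if (nrow(edges) > 0) {
      comp <- components_oracle(all_ids,
                                data.frame(from = edges$query_id,
                                           to = edges$subject_id))
      comp
    } else canon_clusters(as.list(all_ids))
    expect_equal(got, want)
  }
})

test_that("MCL is equivariant under node relabelling", {
  edges <- tibble::tibble(query_id = c("a", "a", "b", "c"),
                          subject_id = c("b", "c", "c", "d"),
                          log10_evalue = c(-20, -20, -20, -2),
                          evalue = 10^c(-20, -20, -20, -2))
  base <- families_to_sets(mcl_cluster(edges))
  relabel <- c(a = "w", b = "x", c = "y", d = "z")
  edges2 <- dplyr::mutate(edges, query_id = relabel[query_id],
                          subject_id = relabel[subject_id])
  got <- families_to_sets(mcl_cluster(edges2))
  want <- canon_clusters(lapply(base, function(g) unname(relabel[g])))
  expect_equal(got, want)
})

test_that("family size filtering keeps the two-to-eight band", {
  fam <- tibble::tibble(
    family_id = rep(c("f1", "f2", "f3", "f4"), c(1, 2, 8, 9)),
    gene_id = paste0("g", 1:20)
  )
  kept <- filter_family_sizes(fam)
  expect_setequal(unique(kept$family_id), c("f2", "f3"))
  kept1 <- filter_family_sizes(fam, min_size = 1)
  expect_setequal(unique(kept1$family_id), c("f1", "f2", "f3"))
  expect_equal(nrow(filter_family_sizes(fam[0, ])), 0L)
})

test_that("tandem collapsing picks one representative per local group", {
  genes <- make_genes(rep("fam", 4),
                      proteins = c("MKLVWA", "MKLV", "MKLVW", "MKAC"))
  genes$chromosome <- c("chr1", "chr1", "chr1", "chr2")
  genes$rank <- c(0L, 1L, 9L, 0L)
  fam <- tibble::tibble(family_id = "F", gene_id = genes$gene_id)

  out <- collapse_tandem_members(fam, genes, max_intervening = 5)
  reps <- out$gene_id[out$representative]
  # g1,g2 adjacent -> longer protein g1 wins; g3 beyond the gap bound kept;
  # g4 on another chromosome kept
  expect_setequal(reps, c("g1", "g3", "g4"))

  # chain of three each within reach of the next collapses to one
  genes2 <- make_genes(rep("fam", 3), proteins = c("MKL", "MKLVWA", "MKLV"))
  genes2$rank <- c(0L, 5L, 10L)
  out2 <- collapse_tandem_members(
    tibble::tibble(family_id = "F", gene_id = genes2$gene_id), genes2)
  expect_equal(out2$gene_id[out2$representative], "g2")
})

test_that("families recovered from a clean simulation equal truth", {
  sim <- simulate_wgd_genome(wgd_sim_config(
    n_ancestral_genes = 25, wgd_depths = c(0.8, 0.4), retention_prob = 1,
    cds_length_codons = 120, seed = 11))
  prot <- stats::setNames(sim$genes$protein, sim$genes$gene_id)
  fam <- mcl_cluster(all_vs_all_similarity(prot), all_ids = names(prot))
  expect_equal(families_to_sets(fam),
               families_to_sets(sim$truth_families))
})
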