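rand_seq <- function(n, seed) {
  withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), n, TRUE),
                               collapse = ""))
}

test_that("duplicate removal honours identity and coverage thresholds", {
  S <- rand_seq(4000, 1)
  # identical sequences: lexicographically later id removed
  ct <- tibble::tibble(contig_id = c("X", "Y"), sequence = c(S, S))
  rep1 <- remove_duplicate_contigs(ct)
  expect_equal(rep1$removed$contig_id, "Y")
  expect_equal(rep1$removed$kept_id, "X")
  expect_equal(rep1$surviving$contig_id, "X")

  # a 99%-identity fragment covering only 50% of the smaller is retained
  half <- substr(S, 1, 2000)
  half_mut <- withr::with_seed(2, {
    v <- strsplit(half, "")[[1]]
    pos <- sample(2000, 20)
    v[pos] <- vapply(v[pos], function(b) sample(setdiff(c("A","C","G","T"), b), 1), "")
    paste(v, collapse = "")
  })
  small <- paste0(half_mut, rand_seq(2000, 3))   # only half matches S
  ct2 <- tibble::tibble(contig_id = c("big", "small"),
                        sequence = c(paste0(S, rand_seq(1000, 4)), small))
  rep2 <- remove_duplicate_contigs(ct2)
  expect_equal(nrow(rep2$removed), 0L)

  # 4% point-mutation noise over the whole length is still >= 95% identity
  mut4 <- withr::with_seed(5, {
    v <- strsplit(S, "")[[1]]
    pos <- sample(4000, 160)
    v[pos] <- vapply(v[pos], function(b) sample(setdiff(c("A","C","G","T"), b), 1), "")
    paste(v, collapse = "")
  })
  # equal lengths: the lexicographically later id is the one removed
  ct3 <- tibble::tibble(contig_id = c("aa_orig", "zz_noisy"),
                        sequence = c(S, mut4))
  rep3 <- remove_duplicate_contigs(ct3)
  expect_equal(rep3$removed$contig_id, "zz_noisy")
  expect_gte(rep3$removed$identity, 0.95)

  expect_equal(nrow(remove_duplicate_contigs(
    tibble::tibble(contig_id = character(), sequence = character()))$removed), 0L)
})

test_that("terminal-overlap merging applies length and identity bounds", {
  A <- rand_seq(8000, 10)
  B_tail <- rand_seq(5000, 11)
  B <- paste0(substr(A, 4501, 8000), B_tail)  # 3.5 kb exact suffix/prefix
  ct <- tibble::tibble(contig_id = c("A", "B"), sequence = c(A, B))
  rep1 <- merge_terminal_overlaps(ct, min_overlap = 3000)
  expect_equal(nrow(rep1$merges), 1L)
  expect_equal(rep1$merges$overlap_len, 3500L)
  expect_equal(nchar(rep1$surviving$sequence), 8000 + 8500 - 3500)

  # overlap below the bound: no merge
  rep2 <- merge_terminal_overlaps(ct, min_overlap = 4000)
  expect_equal(nrow(rep2$merges), 0L)

  # 3.5 kb overlap at ~90% identity: no merge at the 95% bar
  ov_mut <- withr::with_seed(12, {
    v <- strsplit(substr(A, 4501, 8000), "")[[1]]
    pos <- sample(3500, 350)
    v[pos] <- vapply(v[pos], function(b) sample(setdiff(c("A","C","G","T"), b), 1), "")
    paste(v, collapse = "")
  })
  B90 <- paste0(ov_mut, B_tail)
  rep3 <- merge_terminal_overlaps(
    tibble::tibble(contig_id = c("A", "B"), sequence = c(A, B90)),
    min_overlap = 3000)
  expect_equal(nrow(rep3$merges), 0L)
})

test_that("reverse-complement terminal overlaps are detected", {
  A <- rand_seq(6000, 20)
  C_tail <- rand_seq(3000, 21)
  # B's END (in its own orientation) overlaps A's end after revcomp
  shared <- substr(A, 2501, 6000)
  B_fwd <- paste0(shared, C_tail)
  B <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(B_fwd)))
  rep1 <- merge_terminal_overlaps(
    tibble::tibble(contig_id = c("A", "B"), sequence = c(A, B)),
    min_overlap = 3000)
  expect_equal(nrow(rep1$merges), 1L)
  expect_equal(nchar(rep1$surviving$sequence), 6000 + 6500 - 3500)
})

test_that("curation operations are idempotent and recover simulated truth", {
  for (noise in c(0, 0.02, 0.10)) {
    cs <- simulate_contig_set(10000, n_duplicates = 2,
                              overlap_lengths = c(3200, 1500),
                              identity_noise = noise, seed = 7 + noise * 100,
                              min_overlap = 3000)
    r1 <- remove_duplicate_contigs(cs$contigs)
    expect_setequal(r1$removed$contig_id,
                    cs$truth$duplicates$contig_id[cs$truth$duplicates$remove])
    expect_setequal(r1$surviving$contig_id, cs$truth$surviving_ids)
    # idempotence
    r1b <- remove_duplicate_contigs(r1$surviving)
    expect_equal(nrow(r1b$removed), 0L)

    r2 <- merge_terminal_overlaps(r1$surviving, min_overlap = 3000)
    expect_equal(nrow(r2$merges), sum(cs$truth$overlaps$merge))
    r2b <- merge_terminal_overlaps(r2$surviving, min_overlap = 3000)
    expect_equal(nrow(r2b$merges), 0L)
    # merging reduces contig count by the number of merges; total length
    # never exceeds the input total
    expect_equal(nrow(r2$surviving), nrow(r1$surviving) - nrow(r2$merges))
    expect_lte(sum(nchar(r2$surviving$sequence)),
               sum(nchar(cs$contigs$sequence)))
  }
})
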