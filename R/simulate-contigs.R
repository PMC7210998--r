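#' Simulate a contig set with known curation truth
#'
#' Cuts a random genome into consecutive fragments whose boundaries share
#' the requested terminal overlaps, then appends near-identical copies of
#' randomly chosen fragments carrying point-mutation noise. The returned
#' truth records which contigs a curation pass should remove (duplicates
#' at or above the identity/coverage thresholds) and which neighbours it
#' should merge (overlaps longer than `min_overlap`).
#'
#' @param genome_length genome length in bp.
#' @param n_duplicates number of duplicated fragments to append.
#' @param overlap_lengths terminal overlap (bp) between each pair of
#'   consecutive fragments; `length(overlap_lengths) + 1` fragments are
#'   produced.
#' @param identity_noise per-base point-mutation rate applied to each
#'   duplicate.
#' @param seed optional integer seed.
#' @param min_identity,min_coverage,min_overlap thresholds used to decide
#'   the truth labels (defaults match the curation defaults).
#' @return A list with `contigs` (tibble `contig_id`, `sequence`) and
#'   `truth`: `duplicates` (tibble `contig_id`, `source_id`, `identity`,
#'   `remove`), `overlaps` (tibble `id_a`, `id_b`, `overlap_len`,
#'   `merge`), and `surviving_ids`, the contig ids expected to survive
#'   duplicate removal (before merging).
#' @export
simulate_contig_set <- function(genome_length, n_duplicates = 1,
                                overlap_lengths = integer(0),
                                identity_noise = 0, seed = NULL,
                                min_identity = 0.95, min_coverage = 0.80,
                                min_overlap = 30000) {
  stopifnot_scalar_number(genome_length, "genome_length", min = 100)
  n_frag <- length(overlap_lengths) + 1L
  with_seed_if(seed, {
    genome <- paste(sample(.BASES, genome_length, replace = TRUE), collapse = "")
    total_span <- genome_length + sum(overlap_lengths)
    base_len <- floor(total_span / n_frag)
    lens <- rep(base_len, n_frag)
    lens[n_frag] <- total_span - base_len * (n_frag - 1L)
    if (any(overlap_lengths >= lens[-n_frag]) ||
        any(overlap_lengths >= lens[-1L])) {
      abort("infeasible overlaps: each must be shorter than the fragments it joins")
    }
    starts <- integer(n_frag)
    starts[1] <- 1L
    for (i in seq_len(n_frag - 1L)) {
      starts[i + 1L] <- starts[i] + lens[i] - overlap_lengths[i]
    }
    ids <- sprintf("frag%02d", seq_len(n_frag))
    seqs <- substring(genome, starts, starts + lens - 1L)
    names(seqs) <- ids

    dup_rows <- NULL
    dup_seqs <- character(0)
    if (n_duplicates > 0) {
      src <- sample(ids, n_duplicates, replace = TRUE)
      dup_ids <- character(n_duplicates)
      identities <- numeric(n_duplicates)
      for (j in seq_len(n_duplicates)) {
        s <- strsplit(seqs[[src[j]]], "")[[1]]
        n_mut <- rbinom(1L, length(s), identity_noise)
        if (n_mut > 0) {
          pos <- sample.int(length(s), n_mut)
          s[pos] <- vapply(s[pos], function(b) sample(setdiff(.BASES, b), 1),
                           character(1))
        }
        dup_ids[j] <- paste0(src[j], "_dup", j)
        identities[j] <- 1 - n_mut / length(s)
        dup_seqs[dup_ids[j]] <- paste(s, collapse = "")
      }
      dup_rows <- tibble(
        contig_id = dup_ids, source_id = src, identity = identities,
        remove = identities >= min_identity & 1 >= min_coverage
      )
    } else {
      dup_rows <- tibble(contig_id = character(), source_id = character(),
                         identity = numeric(), remove = logical())
    }

    overlaps <- tibble(
      id_a = ids[seq_len(n_frag - 1L)],
      id_b = ids[-1L],
      overlap_len = as.integer(overlap_lengths),
      merge = overlap_lengths > min_overlap
    )
    contigs <- tibble(
      contig_id = c(ids, names(dup_seqs)),
      sequence = c(unname(seqs), unname(dup_seqs))
    )
    list(
      contigs = contigs,
      truth = list(
        duplicates = dup_rows,
        overlaps = overlaps,
        surviving_ids = sort(c(ids, dup_rows$contig_id[!dup_rows$remove]))
      )
    )
  })
}
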