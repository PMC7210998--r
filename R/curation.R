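# Contig curation: duplicate (haplotype) contig removal and joining of
# long, high-identity terminal overlaps. Alignment is exact dynamic
# programming (Biostrings) with a k-mer prescreen so clearly unrelated
# pairs are never aligned; identity = matches / aligned columns and
# coverage = aligned span of the smaller contig / its length.

# fraction of the smaller sequence's k-mers present in the larger one,
# plus the span those matches cover on the smaller (an upper hint on the
# achievable alignment coverage)
kmer_match_stats <- function(small, large, k = 11L) {
  if (nchar(small) < k || nchar(large) < k) {
    return(list(fraction = 1, span = 1))
  }
  n <- nchar(small) - k + 1L
  ks <- substring(small, seq_len(n), seq_len(n) + k - 1L)
  m <- nchar(large) - k + 1L
  kl <- unique(substring(large, seq_len(m), seq_len(m) + k - 1L))
  hit <- ks %in% kl
  if (!any(hit)) return(list(fraction = 0, span = 0))
  pos <- which(hit)
  list(fraction = mean(hit),
       span = (pos[length(pos)] - pos[1] + k) / nchar(small))
}

shared_kmer_fraction <- function(small, large, k = 11L) {
  kmer_match_stats(small, large, k)$fraction
}

.dna_submat <- function() {
  Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                           baseOnly = TRUE)
}

# local alignment of smaller vs larger; returns identity/coverage stats
align_contig_pair <- function(small, large) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(small), Biostrings::DNAString(large),
    type = "local", substitutionMatrix = .dna_submat(),
    gapOpening = 4, gapExtension = 2
  )
  cols <- nchar(as.character(Biostrings::pattern(aln)))
  span <- Biostrings::width(Biostrings::pattern(aln))
  list(
    identity = Biostrings::nmatch(aln) / cols,
    coverage = span / nchar(small)
  )
}

#' Remove duplicate (heterozygous) contigs
#'
#' For every pair ordered by size, the smaller contig is removed when an
#' alignment against a larger surviving contig reaches at least
#' `min_identity` over at least `min_coverage` of the smaller contig's
#' length. Removals cascade: a contig already removed cannot cause
#' further removals. Equal-length exact ties remove the lexicographically
#' later id.
#'
#' @param contigs tibble with columns `contig_id`, `sequence`.
#' @param min_identity minimum alignment identity (matches / columns).
#' @param min_coverage minimum fraction of the smaller contig covered.
#' @return A `curation_report`: list with tibbles `removed` (`contig_id`,
#'   `kept_id`, `identity`, `coverage`), `merges` (empty here), and
#'   `surviving` (`contig_id`, `sequence`).
#' @export
remove_duplicate_contigs <- function(contigs, min_identity = 0.95,
                                     min_coverage = 0.80) {
  if (nrow(contigs) == 0) {
    return(new_curation_report(removed = NULL, merges = NULL,
                               surviving = contigs))
  }
  if (anyDuplicated(contigs$contig_id)) abort("contig ids must be unique")
  # larger first; ties broken so the lexicographically later id is "smaller"
  ord <- order(-nchar(contigs$sequence), contigs$contig_id)
  contigs <- contigs[ord, , drop = FALSE]
  n <- nrow(contigs)
  removed_rows <- list()
  alive <- rep(TRUE, n)
  for (i in rev(seq_len(n))) {      # smallest first
    if (i == 1L) break
    for (j in seq_len(i - 1L)) {    # against larger survivors only
      if (!alive[j]) next
      small <- contigs$sequence[i]
      large <- contigs$sequence[j]
      if (grepl(small, large, fixed = TRUE)) {
        # exact containment needs no dynamic program
        st <- list(identity = 1, coverage = 1)
      } else {
        # a removable duplicate (>= min_identity over >= min_coverage of
        # the smaller) must share a large fraction of its 11-mers with the
        # larger (>= ~0.8 * 0.95^11 = 0.46 at the default thresholds) and
        # those matches must span most of the smaller; far below that the
        # exact alignment cannot qualify, so it is skipped
        ks <- kmer_match_stats(small, large)
        if (ks$fraction < 0.35 || ks$span < min_coverage - 0.05) next
        st <- align_contig_pair(small, large)
      }
      if (st$identity >= min_identity && st$coverage >= min_coverage) {
        alive[i] <- FALSE
        removed_rows[[contigs$contig_id[i]]] <- tibble(
          contig_id = contigs$contig_id[i],
          kept_id = contigs$contig_id[j],
          identity = st$identity, coverage = st$coverage
        )
        break
      }
    }
  }
  new_curation_report(
    removed = if (length(removed_rows)) bind_rows(removed_rows) else NULL,
    merges = NULL,
    surviving = arrange(contigs[alive, , drop = FALSE], .data$contig_id)
  )
}

# find the best terminal suffix(A)/prefix(B) overlap, trying B forward and
# reverse-complemented; returns NULL or a stats list
find_terminal_overlap <- function(seq_a, seq_b, min_overlap, min_identity) {
  best <- NULL
  for (orient in c("forward", "revcomp")) {
    b <- if (orient == "forward") seq_b else {
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq_b)))
    }
    # prescreen: a mergeable overlap (> min_overlap at >= min_identity)
    # contains B's entire leading min_overlap window, so both the head
    # and the tail of that window must share most of their 11-mers with
    # A (>= ~0.95^11 = 0.57 at the default identity); far below that the
    # alignment cannot qualify and the dynamic program is skipped
    wlen <- min(nchar(b), min_overlap)
    head_w <- substring(b, 1L, min(wlen, 1000L))
    tail_w <- substring(b, max(1L, wlen - 500L), wlen)
    if (shared_kmer_fraction(head_w, seq_a) < 0.35 ||
        shared_kmer_fraction(tail_w, seq_a) < 0.35) next
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(seq_a), Biostrings::DNAString(b),
      type = "overlap", substitutionMatrix = .dna_submat(),
      gapOpening = 4, gapExtension = 2
    )
    pr <- Biostrings::pattern(aln)
    sr <- Biostrings::subject(aln)
    a_end <- Biostrings::end(pr)
    b_start <- Biostrings::start(sr)
    # must be strictly terminal: reach A's last base, start at B's first
    if (a_end != nchar(seq_a) || b_start != 1L) next
    cols <- nchar(as.character(pr))
    ident <- Biostrings::nmatch(aln) / cols
    olap <- Biostrings::width(pr)
    if (olap > min_overlap && ident >= min_identity) {
      cand <- list(overlap_len = olap, identity = ident, orient = orient,
                   b_used = b, b_end = Biostrings::end(sr))
      if (is.null(best) || cand$overlap_len > best$overlap_len) best <- cand
    }
  }
  best
}

#' Join contigs sharing long, high-identity terminal overlaps
#'
#' When the suffix of one contig aligns to the prefix of another (either
#' orientation) over more than `min_overlap` bases at `min_identity` or
#' better, the two are merged, keeping the first contig's bases across
#' the overlap. Merging is greedy by decreasing overlap length with each
#' contig joining at most once per pass; passes repeat until no further
#' merge applies, so chains collapse fully and the operation is
#' idempotent.
#'
#' @param contigs tibble with columns `contig_id`, `sequence` (run after
#'   duplicate removal).
#' @param min_overlap minimum overlap length in bp (strictly greater
#'   than).
#' @param min_identity minimum overlap alignment identity.
#' @return A `curation_report` with the `merges` table filled
#'   (`id_a`, `id_b`, `overlap_len`, `identity`, `merged_id`).
#' @export
merge_terminal_overlaps <- function(contigs, min_overlap = 30000,
                                    min_identity = 0.95) {
  merges <- list()
  current <- contigs
  repeat {
    n <- nrow(current)
    if (n < 2L) break
    cands <- list()
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j) next
        ov <- find_terminal_overlap(current$sequence[i], current$sequence[j],
                                    min_overlap, min_identity)
        if (!is.null(ov)) {
          cands[[length(cands) + 1L]] <- c(
            list(i = i, j = j, id_a = current$contig_id[i],
                 id_b = current$contig_id[j]), ov)
        }
      }
    }
    if (length(cands) == 0) break
    cands <- cands[order(-vapply(cands, `[[`, numeric(1), "overlap_len"))]
    used <- logical(n)
    merged_any <- FALSE
    for (cd in cands) {
      if (used[cd$i] || used[cd$j]) next
      used[cd$i] <- used[cd$j] <- TRUE
      merged_seq <- paste0(current$sequence[cd$i],
                           substring(cd$b_used, cd$b_end + 1L))
      merged_id <- paste(cd$id_a, cd$id_b, sep = "+")
      merges[[merged_id]] <- tibble(
        id_a = cd$id_a, id_b = cd$id_b,
        overlap_len = cd$overlap_len, identity = cd$identity,
        merged_id = merged_id
      )
      current <- bind_rows(
        current[-c(cd$i, cd$j), , drop = FALSE],
        tibble(contig_id = merged_id, sequence = merged_seq)
      )
      merged_any <- TRUE
      break  # indices shifted; rescan candidates in a fresh pass
    }
    if (!merged_any) break
  }
  if (length(merges) > 0 && nrow(current) > 1L) {
    # detect unmergeable remnants of circular chains quietly: nothing to do,
    # longest-overlap merges were already applied
  }
  new_curation_report(
    removed = NULL,
    merges = if (length(merges)) bind_rows(merges) else NULL,
    surviving = arrange(current, .data$contig_id)
  )
}

new_curation_report <- function(removed, merges, surviving) {
  structure(
    list(
      removed = removed %||% tibble(contig_id = character(),
                                    kept_id = character(),
                                    identity = numeric(),
                                    coverage = numeric()),
      merges = merges %||% tibble(id_a = character(), id_b = character(),
                                  overlap_len = integer(),
                                  identity = numeric(),
                                  merged_id = character()),
      surviving = surviving
    ),
    class = "curation_report"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.curation_report <- function(x, ...) {
  cat(sprintf("Curation report: %d removed, %d merge(s), %d surviving contig(s)\n",
              nrow(x$removed), nrow(x$merges), nrow(x$surviving)))
  invisible(x)
}
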