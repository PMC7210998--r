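#' Build anchor pairs from tandem-collapsed paralog families
#'
#' Tandem members are collapsed to representatives
#' ([collapse_tandem_members()]) and every unordered representative pair
#' of a family becomes an anchor, including intra-chromosomal pairs.
#' Anchors are stored once in canonical order (lexicographic by
#' chromosome then rank).
#'
#' @param families tibble `family_id`, `gene_id` (filtered to the
#'   family-size bound used for synteny).
#' @param genes gene model tibble.
#' @param max_intervening tandem-collapsing gap bound.
#' @return A tibble of anchors: `gene_a`, `gene_b`, `chrom_a`,
#'   `chrom_b`, `rank_a`, `rank_b`, `family_id`.
#' @export
build_anchor_pairs <- function(families, genes, max_intervening = 5L) {
  reps <- collapse_tandem_members(families, genes, max_intervening) %>%
    filter(.data$representative) %>%
    left_join(select(genes, "gene_id", "chromosome", "rank"), by = "gene_id")
  fam_split <- split(seq_len(nrow(reps)), reps$family_id)
  rows <- lapply(fam_split, function(idx) {
    if (length(idx) < 2L) return(NULL)
    cmb <- utils::combn(idx, 2L)
    a <- cmb[1, ]; b <- cmb[2, ]
    # canonical order: (chromosome, rank) lexicographic
    flip <- reps$chromosome[b] < reps$chromosome[a] |
      (reps$chromosome[b] == reps$chromosome[a] & reps$rank[b] < reps$rank[a])
    a2 <- ifelse(flip, b, a); b2 <- ifelse(flip, a, b)
    tibble(
      gene_a = reps$gene_id[a2], gene_b = reps$gene_id[b2],
      chrom_a = reps$chromosome[a2], chrom_b = reps$chromosome[b2],
      rank_a = reps$rank[a2], rank_b = reps$rank[b2],
      family_id = reps$family_id[a2]
    )
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) return(out)
  arrange(out, .data$chrom_a, .data$chrom_b, .data$rank_a, .data$rank_b)
}

# longest strictly-monotone chain (increasing rank_a; rank_b increasing
# for "same" orientation, decreasing for "inverted") with per-step gaps
# bounded on both sides; O(n^2) DP, exact
longest_chain <- function(ra, rb, orientation, max_gap) {
  n <- length(ra)
  ord <- order(ra, if (orientation == "same") rb else -rb)
  ra <- ra[ord]; rb <- rb[ord]
  len <- rep(1L, n)
  prev <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      ok_a <- ra[i] > ra[j] && ra[i] - ra[j] <= max_gap
      ok_b <- if (orientation == "same") {
        rb[i] > rb[j] && rb[i] - rb[j] <= max_gap
      } else {
        rb[i] < rb[j] && rb[j] - rb[i] <= max_gap
      }
      if (ok_a && ok_b && len[j] + 1L > len[i]) {
        len[i] <- len[j] + 1L
        prev[i] <- j
      }
    }
  }
  best <- which.max(len)
  chain <- integer(0)
  while (!is.na(best)) {
    chain <- c(best, chain)
    best <- prev[best]
  }
  ord[chain]
}

#' Chain anchors into collinear blocks
#'
#' Per chromosome pair and orientation, strictly monotone anchor chains
#' with per-step rank gaps of at most `max_gap_genes` on both
#' chromosomes are extracted greedily by decreasing length; each anchor
#' joins at most one block and blocks shorter than `min_anchors` are
#' dropped. Intra-chromosomal anchors participate only when the two
#' sides are separated by at least `max_gap_genes` ranks, preventing
#' self-trivial blocks.
#'
#' @param anchors anchor tibble from [build_anchor_pairs()].
#' @param max_gap_genes per-step rank gap bound.
#' @param min_anchors minimum anchors per block.
#' @return A tibble of blocks: `block_id`, `chrom_a`, `chrom_b`,
#'   `orientation`, `n_anchors`, and an `anchors` list-column of anchor
#'   row tibbles.
#' @export
chain_collinear_blocks <- function(anchors, max_gap_genes = 25L,
                                   min_anchors = 3L) {
  if (nrow(anchors) == 0) {
    return(tibble(block_id = character(), chrom_a = character(),
                  chrom_b = character(), orientation = character(),
                  n_anchors = integer(), anchors = list()))
  }
  anchors <- anchors %>%
    filter(.data$chrom_a != .data$chrom_b |
             abs(.data$rank_a - .data$rank_b) >= max_gap_genes)
  blocks <- list()
  pair_split <- split(anchors, paste(anchors$chrom_a, anchors$chrom_b, sep = "\r"))
  for (pa in pair_split) {
    pool <- pa
    repeat {
      if (nrow(pool) == 0) break
      chains <- lapply(c("same", "inverted"), function(o) {
        list(orientation = o,
             idx = longest_chain(pool$rank_a, pool$rank_b, o, max_gap_genes))
      })
      lens <- vapply(chains, function(c) length(c$idx), integer(1))
      pick <- chains[[which.max(lens)]]
      if (length(pick$idx) < min_anchors) break
      blk <- pool[pick$idx, , drop = FALSE] %>% arrange(.data$rank_a)
      blocks[[length(blocks) + 1L]] <- tibble(
        chrom_a = blk$chrom_a[1], chrom_b = blk$chrom_b[1],
        orientation = pick$orientation,
        n_anchors = nrow(blk),
        anchors = list(blk)
      )
      pool <- pool[-pick$idx, , drop = FALSE]
    }
  }
  if (length(blocks) == 0) {
    return(tibble(block_id = character(), chrom_a = character(),
                  chrom_b = character(), orientation = character(),
                  n_anchors = integer(), anchors = list()))
  }
  out <- bind_rows(blocks) %>%
    arrange(.data$chrom_a, .data$chrom_b, dplyr::desc(.data$n_anchors))
  out$block_id <- sprintf("BLK%03d", seq_len(nrow(out)))
  select(out, "block_id", "chrom_a", "chrom_b", "orientation", "n_anchors",
         "anchors")
}

#' Summarise paralogon blocks per chromosome
#'
#' Anchor totals per chromosome (anchors in retained blocks touching the
#' chromosome) and the symmetric chromosome-pair shared-anchor matrix,
#' the numbers a circos-style paralogon figure displays.
#'
#' @param blocks block tibble from [chain_collinear_blocks()].
#' @param chromosomes optional character vector fixing the chromosome
#'   universe (defaults to chromosomes seen in blocks).
#' @return A list with `totals` (tibble `chromosome`, `n_anchors`) and
#'   `matrix` (symmetric numeric matrix of shared anchor counts;
#'   intra-chromosomal blocks count on the diagonal).
#' @export
paralogon_summary <- function(blocks, chromosomes = NULL) {
  chroms <- sort(unique(c(chromosomes, blocks$chrom_a, blocks$chrom_b)))
  m <- matrix(0, length(chroms), length(chroms),
              dimnames = list(chroms, chroms))
  for (i in seq_len(nrow(blocks))) {
    a <- blocks$chrom_a[i]; b <- blocks$chrom_b[i]
    n <- blocks$n_anchors[i]
    m[a, b] <- m[a, b] + n
    if (a != b) m[b, a] <- m[b, a] + n
  }
  totals <- tibble(
    chromosome = chroms,
    n_anchors = unname(vapply(chroms, function(c) {
      sum(m[c, ])  # row sum includes the intra-chromosomal diagonal
    }, numeric(1)))
  )
  list(totals = totals, matrix = m)
}
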