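#' Detect tandem gene clusters
#'
#' Three rules, applied per chromosome and per gene name: (1) same-name
#' genes are chained while consecutive occurrences are separated by at
#' most `max_intervening` unrelated (different-name) genes; (2) within a
#' chain, a copy is kept only if its global protein identity to at least
#' one other kept copy reaches `min_identity` (single-linkage: survivors
#' are the members of identity-graph components of size two or more);
#' (3) chains with at least `min_size` survivors become clusters.
#' Genes without a name never match any cluster name. Pairs missing a
#' protein sequence skip the identity test with a warning (the member is
#' kept unconfirmed).
#'
#' @param genes gene model tibble (`chromosome`, `rank`, `name`,
#'   `protein`, coordinates).
#' @param max_intervening maximum unrelated genes between consecutive
#'   same-name occurrences.
#' @param min_identity minimum pairwise protein identity.
#' @param min_size minimum surviving copies per cluster.
#' @return A tibble: `cluster_id`, `chromosome`, `name`, `n_genes`,
#'   `span_bp`, and a `members` list-column of gene ids ordered by rank.
#' @export
find_tandem_clusters <- function(genes, max_intervening = 5L,
                                 min_identity = 0.70, min_size = 3L) {
  genes <- arrange(genes, .data$chromosome, .data$rank)
  named <- filter(genes, !is.na(.data$name) & nzchar(.data$name))
  groups <- split(named, list(named$chromosome, named$name), drop = TRUE)
  clusters <- list()
  warned <- FALSE
  # count of same-name occurrences with rank < r, used to turn rank gaps
  # into unrelated-gene counts when occurrences have been dropped
  for (g in groups) {
    if (nrow(g) < min_size) next
    g <- arrange(g, .data$rank)
    n_occ <- nrow(g)
    occ_rank <- g$rank
    # the gap and identity rules interact: dropping an identity-isolated
    # copy can widen a gap past the bound, which can isolate further
    # copies; iterate chaining + filtering to a fixed point
    kept <- rep(TRUE, n_occ)
    repeat {
      idx <- which(kept)
      if (length(idx) == 0) break
      # unrelated genes between consecutive kept occurrences: rank gap
      # minus interleaved same-name occurrences (kept or not)
      gap <- diff(occ_rank[idx]) - 1L
      if (length(idx) > 1L) {
        interleaved <- vapply(seq_len(length(idx) - 1L), function(t) {
          sum(occ_rank > occ_rank[idx[t]] & occ_rank < occ_rank[idx[t + 1L]])
        }, numeric(1))
        gap <- gap - interleaved
      }
      chain_id <- cumsum(c(1L, gap > max_intervening))
      new_kept <- rep(FALSE, n_occ)
      for (ch in split(idx, chain_id)) {
        members <- g[ch, , drop = FALSE]
        survivors <- tandem_identity_survivors(members, min_identity,
                                               warn_missing = !warned)
        if (any(is.na(members$protein))) warned <- TRUE
        new_kept[ch[survivors]] <- TRUE
      }
      if (identical(new_kept, kept)) break
      kept <- new_kept
    }
    idx <- which(kept)
    if (length(idx) == 0) next
    gap <- diff(occ_rank[idx]) - 1L
    if (length(idx) > 1L) {
      interleaved <- vapply(seq_len(length(idx) - 1L), function(t) {
        sum(occ_rank > occ_rank[idx[t]] & occ_rank < occ_rank[idx[t + 1L]])
      }, numeric(1))
      gap <- gap - interleaved
    }
    chain_id <- cumsum(c(1L, gap > max_intervening))
    for (ch in split(idx, chain_id)) {
      kept_g <- g[ch, , drop = FALSE]
      if (nrow(kept_g) < min_size) next
      clusters[[length(clusters) + 1L]] <- tibble(
        chromosome = kept_g$chromosome[1],
        name = kept_g$name[1],
        n_genes = nrow(kept_g),
        span_bp = max(kept_g$end) - min(kept_g$start),
        members = list(kept_g$gene_id)
      )
    }
  }
  if (length(clusters) == 0) {
    return(tibble(cluster_id = character(), chromosome = character(),
                  name = character(), n_genes = integer(),
                  span_bp = numeric(), members = list()))
  }
  out <- bind_rows(clusters) %>%
    arrange(.data$chromosome, dplyr::desc(.data$n_genes), .data$name)
  out$cluster_id <- sprintf("TC%03d", seq_len(nrow(out)))
  select(out, "cluster_id", "chromosome", "name", "n_genes", "span_bp",
         "members")
}

# survivors of the >= min_identity single-linkage rule: members of
# identity-graph components of size >= 2; members without proteins are
# kept unconfirmed
tandem_identity_survivors <- function(members, min_identity, warn_missing = TRUE) {
  n <- nrow(members)
  has_prot <- !is.na(members$protein) & nzchar(members$protein)
  if (any(!has_prot) && warn_missing) {
    warn("protein sequence missing for some tandem candidates; identity test skipped for those pairs")
  }
  adj <- matrix(FALSE, n, n)
  idx <- which(has_prot)
  if (length(idx) >= 2) {
    for (ii in seq_along(idx)[-length(idx)]) {
      for (jj in seq((ii + 1), length(idx))) {
        i <- idx[ii]; j <- idx[jj]
        if (protein_identity(members$protein[i], members$protein[j]) >= min_identity) {
          adj[i, j] <- adj[j, i] <- TRUE
        }
      }
    }
  }
  deg <- rowSums(adj)
  keep <- deg > 0 | !has_prot
  keep
}

#' Confirm tandem clusters against a reference protein set
#'
#' Each member is assigned its best-scoring reference protein (local
#' BLOSUM62 alignment, the same engine as the similarity search); a
#' cluster is flagged confirmed when a strict majority of its members
#' share one best reference. Members without any hit are recorded as
#' unassigned.
#'
#' @param clusters tandem cluster tibble from [find_tandem_clusters()].
#' @param genes gene model tibble supplying member proteins.
#' @param reference_proteins named character vector of reference
#'   proteins (nonempty).
#' @return The cluster tibble with `best_reference` (list-column of
#'   per-member assignments) and logical `confirmed` added.
#' @export
confirm_against_reference <- function(clusters, genes, reference_proteins) {
  if (length(reference_proteins) == 0) abort("reference protein set is empty")
  prot <- setNames(genes$protein, genes$gene_id)
  assign_best <- function(ids) {
    vapply(ids, function(id) {
      p <- prot[[id]]
      if (is.na(p) || !nzchar(p)) return(NA_character_)
      scores <- vapply(reference_proteins, function(r) {
        local_protein_alignment(p, r)$score
      }, numeric(1))
      if (all(scores <= 0)) return(NA_character_)
      names(reference_proteins)[which.max(scores)]
    }, character(1))
  }
  best <- lapply(clusters$members, assign_best)
  confirmed <- vapply(best, function(b) {
    n_members <- length(b)
    b <- b[!is.na(b)]
    if (length(b) == 0) return(FALSE)
    max(table(b)) > n_members / 2  # strict majority of all members
  }, logical(1))
  clusters$best_reference <- best
  clusters$confirmed <- confirmed
  clusters
}
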