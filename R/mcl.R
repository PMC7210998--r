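#' Markov clustering (MCL) of a similarity graph
#'
#' Implements the MCL flow simulation: the weighted adjacency matrix gets
#' per-node self-loops (loop weight = the node's maximum incident edge
#' weight), columns are normalised to a stochastic matrix, and expansion
#' (matrix squaring) alternates with inflation (entrywise power then
#' column renormalisation) with entries below `tol` pruned, until the
#' matrix stops changing. Clusters are read off the attractor support;
#' attractor rows sharing nodes are joined. Disconnected components are
#' clustered independently (they can never merge), which keeps the
#' matrices small. Isolated ids passed via `all_ids` become singletons.
#'
#' @param edges similarity-edge tibble (needs `query_id`, `subject_id`
#'   and either `log10_evalue` or `evalue`, or `bitscore` when
#'   `weight = "bitscore"`).
#' @param inflation inflation exponent (granularity; the pipeline
#'   default follows common practice for paralog families).
#' @param weight edge weight transform: `-log10` E-value capped at 200,
#'   or raw bitscore.
#' @param max_iter iteration cap; non-convergence is an error.
#' @param tol pruning and convergence threshold.
#' @param all_ids optional full id universe so nodes without edges are
#'   reported as singleton families.
#' @return A tibble `family_id`, `gene_id`; families are numbered by
#'   decreasing size then first member, so output is deterministic.
#' @export
mcl_cluster <- function(edges, inflation = 6, weight = c("log_evalue", "bitscore"),
                        max_iter = 200L, tol = 1e-8, all_ids = NULL) {
  weight <- match.arg(weight)
  w <- if (weight == "bitscore") {
    edges$bitscore
  } else if ("log10_evalue" %in% names(edges)) {
    pmin(-edges$log10_evalue, 200)
  } else {
    pmin(-log10(pmax(edges$evalue, 0)), 200)
  }
  if (nrow(edges) > 0 && any(!is.finite(w) | w <= 0)) {
    abort("MCL edge weights must be positive and finite")
  }
  nodes <- sort(unique(c(edges$query_id, edges$subject_id, all_ids)))
  if (length(nodes) == 0) return(tibble(family_id = character(),
                                        gene_id = character()))
  g <- igraph::graph_from_data_frame(
    tibble(from = edges$query_id, to = edges$subject_id, weight = w),
    directed = FALSE, vertices = nodes
  )
  comp <- igraph::components(g)
  clusters <- list()
  for (ci in seq_len(comp$no)) {
    members <- nodes[comp$membership == ci]
    if (length(members) == 1L) {
      clusters[[length(clusters) + 1L]] <- members
      next
    }
    sub <- igraph::induced_subgraph(g, members)
    A <- igraph::as_adjacency_matrix(sub, attr = "weight", sparse = FALSE)
    ids <- igraph::V(sub)$name
    diag(A) <- apply(A, 1, max)          # self-loop = max incident weight
    M <- sweep(A, 2, colSums(A), "/")
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      M2 <- M %*% M                      # expansion
      M2 <- M2^inflation                 # inflation
      M2[M2 < tol] <- 0
      cs <- colSums(M2)
      cs[cs == 0] <- 1
      M2 <- sweep(M2, 2, cs, "/")
      if (max(abs(M2 - M)) < tol) {
        M <- M2
        converged <- TRUE
        break
      }
      M <- M2
    }
    if (!converged) {
      abort(sprintf("MCL did not converge within %d iterations", max_iter))
    }
    # attractors: rows with support; overlapping rows define one cluster
    support <- M > tol
    attractors <- which(rowSums(support) > 0)
    overlap <- support[attractors, , drop = FALSE] %*% t(support[attractors, , drop = FALSE])
    ag <- igraph::graph_from_adjacency_matrix(overlap > 0, mode = "undirected")
    amem <- igraph::components(ag)$membership
    assigned <- rep(NA_integer_, length(ids))
    for (k in seq_along(attractors)) {
      covered <- which(support[attractors[k], ])
      assigned[covered] <- amem[k]
    }
    # nodes with no attractor support (numerically starved) join their
    # strongest column attractor
    for (j in which(is.na(assigned))) {
      k <- which.max(M[attractors, j])
      assigned[j] <- amem[k]
    }
    for (cl in unique(assigned)) {
      clusters[[length(clusters) + 1L]] <- ids[assigned == cl]
    }
  }
  clusters <- lapply(clusters, sort)
  ord <- order(-lengths(clusters),
               vapply(clusters, `[[`, character(1), 1L))
  clusters <- clusters[ord]
  bind_rows(lapply(seq_along(clusters), function(i) {
    tibble(family_id = sprintf("FAM%04d", i), gene_id = clusters[[i]])
  }))
}

#' Filter paralog families by member count
#'
#' @param families tibble `family_id`, `gene_id`.
#' @param min_size,max_size inclusive size bounds (the synteny variant
#'   keeps singletons via `min_size = 1`).
#' @return The filtered family tibble.
#' @export
filter_family_sizes <- function(families, min_size = 2L, max_size = 8L) {
  families %>%
    group_by(.data$family_id) %>%
    filter(n() >= min_size, n() <= max_size) %>%
    ungroup()
}

#' Collapse tandem members of paralog families to one representative
#'
#' Family members on the same chromosome whose rank gap (number of
#' intervening genes) is at most `max_intervening` are grouped
#' transitively; each group keeps its longest-protein member (ties break
#' to the smaller rank). All members are returned with a logical
#' `representative` column.
#'
#' @param families tibble `family_id`, `gene_id`.
#' @param genes gene model tibble supplying `chromosome`, `rank`,
#'   `protein`.
#' @param max_intervening maximum intervening gene count within a tandem
#'   group.
#' @return The family tibble with `representative` added.
#' @export
collapse_tandem_members <- function(families, genes, max_intervening = 5L) {
  info <- families %>%
    left_join(select(genes, "gene_id", "chromosome", "rank", "protein"),
              by = "gene_id") %>%
    mutate(plen = ifelse(is.na(.data$protein), 0L, nchar(.data$protein)))
  info %>%
    group_by(.data$family_id, .data$chromosome) %>%
    arrange(.data$rank, .by_group = TRUE) %>%
    mutate(tgroup = cumsum(c(1L, diff(.data$rank) - 1L > max_intervening))) %>%
    group_by(.data$family_id, .data$chromosome, .data$tgroup) %>%
    mutate(representative = row_number(dplyr::desc(.data$plen * 1e9 - .data$rank)) == 1L) %>%
    ungroup() %>%
    select("family_id", "gene_id", "representative") %>%
    arrange(.data$family_id, .data$gene_id)
}
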