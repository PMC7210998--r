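# Independent oracles used to cross-check the implementation. These are
# deliberately written as brute-force or high-precision routines that do
# not share code with the package internals.

# --- MCL oracle: fixed-point iteration, dense, no pruning ----------------
mcl_fixed_point_oracle <- function(nodes, edge_df, inflation = 6,
                                   self_loop = c("max_incident")) {
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (r in seq_len(nrow(edge_df))) {
    w <- edge_df$weight[r]
    A[edge_df$from[r], edge_df$to[r]] <- w
    A[edge_df$to[r], edge_df$from[r]] <- w
  }
  diag(A) <- apply(A, 1, max)
  M <- sweep(A, 2, colSums(A), "/")
  for (i in 1:1000) {
    M2 <- M %*% M
    M2 <- M2^inflation
    M2 <- sweep(M2, 2, colSums(M2), "/")
    if (max(abs(M2 - M)) < 1e-13) { M <- M2; break }
    M <- M2
  }
  # cluster = support of each attractor row; overlapping rows merged
  support <- M > 1e-9
  attr_rows <- which(rowSums(support) > 0)
  groups <- list()
  for (a in attr_rows) {
    memb <- nodes[support[a, ]]
    hit <- which(vapply(groups, function(g) length(intersect(g, memb)) > 0,
                        logical(1)))
    if (length(hit) == 0) {
      groups[[length(groups) + 1]] <- memb
    } else {
      merged <- unique(c(unlist(groups[hit]), memb))
      groups <- groups[-hit]
      groups[[length(groups) + 1]] <- merged
    }
  }
  covered <- unlist(groups)
  for (x in setdiff(nodes, covered)) groups[[length(groups) + 1]] <- x
  lapply(groups, sort)
}

# canonical form of a clustering for set comparison
canon_clusters <- function(cl) {
  cl <- lapply(cl, sort)
  cl[order(vapply(cl, `[[`, character(1), 1L))]
}

# clusters from a families tibble
families_to_sets <- function(fam) {
  canon_clusters(unname(split(fam$gene_id, fam$family_id)))
}

# --- connected-components oracle -----------------------------------------
components_oracle <- function(nodes, edge_df) {
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  for (r in seq_len(nrow(edge_df))) {
    a <- find(edge_df$from[r]); b <- find(edge_df$to[r])
    if (a != b) parent[[a]] <- b
  }
  roots <- vapply(nodes, find, character(1))
  canon_clusters(unname(split(nodes, roots)))
}

# --- exhaustive global-alignment oracle (tiny sequences) ------------------
# enumerates every global alignment path with affine gaps and returns the
# maximum score; exponential, fine for sequences of length <= 6
enumerate_global_alignments <- function(a, b, gap_open = 10, gap_extend = 0.5) {
  suppressWarnings(utils::data("BLOSUM62", package = "Biostrings",
                               envir = environment()))
  S <- get("BLOSUM62", envir = environment())
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  best <- -Inf
  best_aln <- NULL
  rec <- function(i, j, score, state, al_a, al_b) {
    if (i > length(av) && j > length(bv)) {
      if (score > best) { best <<- score; best_aln <<- list(a = al_a, b = al_b) }
      return(invisible())
    }
    if (i <= length(av) && j <= length(bv)) {
      rec(i + 1, j + 1, score + S[av[i], bv[j]], "m",
          c(al_a, av[i]), c(al_b, bv[j]))
    }
    if (i <= length(av)) {
      pen <- if (state == "ga") gap_extend else gap_open + gap_extend
      rec(i + 1, j, score - pen, "ga", c(al_a, av[i]), c(al_b, "-"))
    }
    if (j <= length(bv)) {
      pen <- if (state == "gb") gap_extend else gap_open + gap_extend
      rec(i, j + 1, score - pen, "gb", c(al_a, "-"), c(al_b, bv[j]))
    }
  }
  rec(1, 1, 0, "none", character(0), character(0))
  list(score = best,
       aligned_a = paste(best_aln$a, collapse = ""),
       aligned_b = paste(best_aln$b, collapse = ""))
}

# --- brute-force tandem-cluster oracle ------------------------------------
# enumerate all same-name subsets satisfying the gap and identity rules,
# report maximal feasible subsets of size >= min_size
tandem_oracle <- function(genes, max_intervening = 5L, min_identity = 0.70,
                          min_size = 3L) {
  out <- list()
  for (chrom in unique(genes$chromosome)) {
    gc <- genes[genes$chromosome == chrom, , drop = FALSE]
    gc <- gc[order(gc$rank), , drop = FALSE]
    for (nm in unique(gc$name[!is.na(gc$name) & nzchar(gc$name)])) {
      occ <- gc[gc$name %in% nm, , drop = FALSE]
      m <- nrow(occ)
      if (m < min_size) next
      # pairwise identity among occurrences
      idm <- matrix(FALSE, m, m)
      for (i in seq_len(m - 1)) for (j in seq(i + 1, m)) {
        idm[i, j] <- idm[j, i] <-
          protein_identity(occ$protein[i], occ$protein[j]) >= min_identity
      }
      # unrelated genes strictly between two occurrences
      unrelated_between <- function(i, j) {
        sum(gc$rank > occ$rank[i] & gc$rank < occ$rank[j] &
              !(gc$name %in% nm))
      }
      feasible <- function(sel) {
        s <- which(sel)
        if (length(s) < min_size) return(FALSE)
        for (t in seq_len(length(s) - 1)) {
          if (unrelated_between(s[t], s[t + 1]) > max_intervening) return(FALSE)
        }
        all(vapply(s, function(i) any(idm[i, setdiff(s, i)]), logical(1)))
      }
      subsets <- Filter(feasible,
                        lapply(seq_len(2^m - 1),
                               function(mask) as.logical(bitwAnd(mask, 2^(seq_len(m) - 1)))))
      # keep maximal subsets only
      keep <- vapply(seq_along(subsets), function(i) {
        !any(vapply(seq_along(subsets), function(j) {
          i != j && all(subsets[[j]] | !subsets[[i]]) && any(subsets[[j]] & !subsets[[i]])
        }, logical(1)))
      }, logical(1))
      for (s in unique(lapply(subsets[keep], which))) {
        out[[length(out) + 1]] <- sort(occ$gene_id[s])
      }
    }
  }
  canon_clusters(unique(out))
}

# random annotation for the tandem oracle tests: names drawn from a pool,
# proteins either exact family copies or heavily degraded ones
random_tandem_annotation <- function(seed, max_genes = 50) {
  withr::with_seed(seed, {
    # per-name copy counts are capped so the subset-enumeration oracle
    # stays cheap (2^m subsets per name)
    pool <- paste0("name", 1:8)
    counts <- pmin(sample(1:7, length(pool), replace = TRUE), 7)
    names <- sample(rep(pool, counts))
    n <- min(length(names), max_genes)
    names <- names[seq_len(n)]
    base <- stats::setNames(vapply(seq_along(pool), function(i)
      random_protein(60, seed * 100 + i), character(1)), pool)
    prots <- vapply(seq_len(n), function(i) {
      if (stats::runif(1) < 0.25) {
        mutate_protein(base[[names[i]]], 0.5, seed = seed * 1000 + i)
      } else base[[names[i]]]
    }, character(1))
    make_genes(names, prots)
  })
}
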