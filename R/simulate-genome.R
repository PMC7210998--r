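#' Configuration for the layered-WGD genome simulator
#'
#' Captures the scenario the simulator emulates: an ancestral gene set hit
#' by 0-3 successive whole-genome duplications at chosen divergence
#' depths (expected corrected 4DTv, oldest first), with independent
#' per-gene retention of each duplicate, neutral evolution of synonymous
#' third positions under a two-parameter transition/transversion process,
#' optional tandem arrays, and single-copy decoy genes.
#'
#' @param n_ancestral_genes number of ancestral (pre-WGD) genes.
#' @param n_chromosomes number of ancestral chromosomes; every WGD
#'   duplicates each chromosome, so the final count is up to
#'   `n_chromosomes * 2^length(wgd_depths)`.
#' @param wgd_depths expected corrected-4DTv divergence of each WGD,
#'   strictly decreasing toward the present.
#' @param retention_prob probability that each new duplicate gene copy is
#'   retained, independently per gene per event.
#' @param kappa transition/transversion rate ratio of the substitution
#'   process.
#' @param cds_length_codons CDS length of every simulated gene, in codons.
#' @param tandem_arrays list of `c(size, identity)` pairs; each inserts an
#'   adjacent same-name array of `size` genes with pairwise protein
#'   identity approximately `identity`.
#' @param intergenic_genes number of unrelated single-copy decoy genes to
#'   intersperse.
#' @param seed integer seed making the simulation bit-reproducible.
#' @return A `wgd_sim_config` list.
#' @export
wgd_sim_config <- function(n_ancestral_genes = 400,
                           n_chromosomes = 2,
                           wgd_depths = c(1.33, 0.85, 0.4),
                           retention_prob = 0.6,
                           kappa = 2,
                           cds_length_codons = 2000,
                           tandem_arrays = list(),
                           intergenic_genes = 0,
                           seed = 1) {
  stopifnot_scalar_number(n_ancestral_genes, "n_ancestral_genes", min = 1)
  stopifnot_scalar_number(n_chromosomes, "n_chromosomes", min = 1)
  stopifnot_scalar_number(retention_prob, "retention_prob", min = 0)
  stopifnot_scalar_number(kappa, "kappa", min = 1e-12)
  stopifnot_scalar_number(cds_length_codons, "cds_length_codons", min = 2)
  if (retention_prob > 1) abort("`retention_prob` must be in [0, 1]")
  if (length(wgd_depths) > 0) {
    if (any(!is.finite(wgd_depths)) || any(wgd_depths <= 0)) {
      abort("`wgd_depths` must be positive and finite")
    }
    if (any(diff(wgd_depths) >= 0)) {
      abort("`wgd_depths` must be strictly decreasing (oldest first)")
    }
    if (any((1 - exp(-2 * wgd_depths)) / 2 >= 0.5)) {
      abort("a WGD depth saturates the uncorrected 4DTv scale")
    }
  }
  structure(
    list(n_ancestral_genes = as.integer(n_ancestral_genes),
         n_chromosomes = as.integer(n_chromosomes),
         wgd_depths = as.numeric(wgd_depths),
         retention_prob = retention_prob,
         kappa = kappa,
         cds_length_codons = as.integer(cds_length_codons),
         tandem_arrays = tandem_arrays,
         intergenic_genes = as.integer(intergenic_genes),
         seed = as.integer(seed)),
    class = "wgd_sim_config"
  )
}

# random CDS of L sense codons (no stops)
random_cds_codons <- function(L, codons = .sense_codons()) {
  sample(codons, L, replace = TRUE)
}

#' Simulate a genome with a known whole-genome duplication history
#'
#' Every ancestral gene starts as a random stop-free CDS. Each WGD event
#' copies every surviving gene onto a duplicated chromosome; each new
#' duplicate survives with `retention_prob`. Between events only the
#' third positions of four-fold degenerate codons evolve (two-parameter
#' process, time scaled so a pair split at depth `d` has expected
#' corrected 4DTv exactly `d`); all other positions are frozen, so
#' proteins stay identical within a family. Tandem arrays are inserted as
#' adjacent same-name copies and decoy singletons interspersed.
#'
#' @param config a [wgd_sim_config()].
#' @return A `simulated_genome` list with elements `genes` (gene model
#'   tibble), `truth_families` (tibble `family_id`, `gene_id`),
#'   `truth_pair_depths` (tibble `id_a`, `id_b`, `depth`),
#'   `truth_tandem_clusters` (list of member-id vectors), and `config`.
#' @export
simulate_wgd_genome <- function(config) {
  if (!inherits(config, "wgd_sim_config")) {
    abort("`config` must be a wgd_sim_config")
  }
  with_seed_if(config$seed, simulate_wgd_genome_impl(config))
}

simulate_wgd_genome_impl <- function(config) {
  L <- config$cds_length_codons
  nG <- config$n_ancestral_genes
  depths <- config$wgd_depths
  n_events <- length(depths)
  event_times <- depths / 4          # per-lineage time before present
  codon_pool <- .sense_codons()
  codon_aa <- as.character(Biostrings::translate(
    Biostrings::DNAStringSet(codon_pool), no.init.codon = TRUE))

  # --- ancestral genes -----------------------------------------------------
  anc_codons <- replicate(nG, random_cds_codons(L, codon_pool), simplify = FALSE)
  anc_prefix <- lapply(anc_codons, function(cd) substr(cd, 1, 2))
  fourd_pos <- lapply(anc_prefix, function(p) which(p %in% .FOURFOLD_PREFIXES))
  anc_chrom <- rep_len(seq_len(config$n_chromosomes), nG)
  anc_order <- stats::ave(seq_len(nG), anc_chrom, FUN = seq_along)

  # --- copies evolving through the event timeline --------------------------
  base_code <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  copies <- tibble(gene = seq_len(nG), lineage = "", suffix = "")
  bases <- lapply(seq_len(nG), function(i) {
    unname(base_code[substr(anc_codons[[i]][fourd_pos[[i]]], 3, 3)])
  })
  now <- if (n_events > 0) event_times[1] else 0
  for (j in seq_len(n_events)) {
    # duplicate at event j
    keep <- runif(nrow(copies)) < config$retention_prob
    dup <- copies[keep, , drop = FALSE]
    if (nrow(dup) > 0) {
      dup$lineage <- paste0(dup$lineage, "d")
      dup$suffix <- paste0(dup$suffix, letters[j])
    }
    copies$lineage <- paste0(copies$lineage, "o")
    dup_bases <- bases[keep]
    copies <- bind_rows(copies, dup)
    bases <- c(bases, dup_bases)
    # evolve everyone to the next event (or to the present)
    t_next <- if (j < n_events) event_times[j + 1] else 0
    dt <- now - t_next
    if (dt > 0) {
      lens <- lengths(bases)
      flat <- evolve_bases(unlist(bases), dt, config$kappa)
      bases <- split(flat, rep.int(seq_along(bases), lens))
      names(bases) <- NULL
    }
    now <- t_next
  }

  # --- rebuild sequences ---------------------------------------------------
  anc_cds_str <- vapply(anc_codons, paste, character(1), collapse = "")
  proteins <- as.character(Biostrings::translate(
    Biostrings::DNAStringSet(anc_cds_str), no.init.codon = TRUE))
  copy_records <- lapply(seq_len(nrow(copies)), function(i) {
    g <- copies$gene[i]
    cd <- anc_codons[[g]]
    pos <- fourd_pos[[g]]
    substr(cd[pos], 3, 3) <- .BASES[bases[[i]]]
    lin <- copies$lineage[i]
    list(
      gene_id = if (nzchar(lin)) paste0("g", g, "_", lin) else paste0("g", g),
      chromosome = paste0("chr", anc_chrom[g], copies$suffix[i]),
      order_key = anc_order[g],
      name = paste0("family protein F", g),
      family_id = paste0("F", g),
      protein = proteins[g],
      cds = paste(cd, collapse = ""),
      lineage = lin
    )
  })

  # --- tandem arrays -------------------------------------------------------
  truth_tandem <- list()
  tandem_records <- list()
  chroms_present <- unique(vapply(copy_records, `[[`, character(1), "chromosome"))
  for (k in seq_along(config$tandem_arrays)) {
    spec <- config$tandem_arrays[[k]]
    size <- as.integer(spec[[1]])
    identity <- as.numeric(spec[[2]])
    base_cd <- random_cds_codons(L, codon_pool)
    m <- round(L * (1 - identity) / 2)
    if (size * m > L) abort("tandem array identity target infeasible at this CDS length")
    mut_pos <- if (m > 0) sample.int(L, size * m) else integer(0)
    chrom <- sample(chroms_present, 1)
    ids <- sprintf("t%d_%d", k, seq_len(size))
    members <- lapply(seq_len(size), function(i) {
      cd <- base_cd
      if (m > 0) {
        for (p in mut_pos[seq((i - 1) * m + 1, i * m)]) {
          alt <- codon_pool[codon_aa != codon_aa[match(cd[p], codon_pool)]]
          cd[p] <- sample(alt, 1)
        }
      }
      list(gene_id = ids[i], chromosome = chrom, order_key = NA_real_,
           name = paste0("tandem protein T", k),
           family_id = paste0("T", k),
           protein = translate_cds(paste(cd, collapse = "")),
           cds = paste(cd, collapse = ""), lineage = NA_character_)
    })
    tandem_records <- c(tandem_records, list(members))
    truth_tandem[[k]] <- ids
  }

  # --- decoy singletons ----------------------------------------------------
  decoy_records <- lapply(seq_len(config$intergenic_genes), function(i) {
    cd <- random_cds_codons(L, codon_pool)
    list(gene_id = paste0("d", i),
         chromosome = sample(chroms_present, 1), order_key = NA_real_,
         name = paste0("decoy protein D", i),
         family_id = paste0("D", i),
         protein = translate_cds(paste(cd, collapse = "")),
         cds = paste(cd, collapse = ""), lineage = NA_character_)
  })

  # --- chromosome layout ---------------------------------------------------
  recs <- c(copy_records, unlist(tandem_records, recursive = FALSE), decoy_records)
  df <- dplyr::bind_rows(lapply(recs, function(r) as_tibble(r[names(r) != "lineage"])))
  gene_len <- 3L * L
  laid <- split(df, df$chromosome)
  laid <- lapply(laid, function(chr_df) {
    # WGD copies keep ancestral order; tandems/decoys drop in at random slots
    n_anchored <- sum(!is.na(chr_df$order_key))
    slot <- chr_df$order_key
    free <- which(is.na(slot))
    if (length(free) > 0) {
      slot[free] <- runif(length(free), 0, n_anchored + 1)
      # keep members of one tandem array adjacent and in id order
      fam <- chr_df$family_id[free]
      for (f in unique(fam[startsWith(fam, "T")])) {
        i <- free[fam == f]
        slot[i] <- slot[i[1]] + seq_along(i) * 1e-6
      }
    }
    chr_df <- chr_df[order(slot), , drop = FALSE]
    chr_df$start <- (seq_len(nrow(chr_df)) - 1L) * (gene_len + 1000L)
    chr_df$end <- chr_df$start + gene_len
    chr_df
  })
  genes <- bind_rows(laid) %>%
    mutate(strand = "+") %>%
    select("gene_id", "chromosome", "start", "end", "strand", "name",
           "protein", "cds", "family_id") %>%
    assign_gene_ranks()

  # --- truth tables --------------------------------------------------------
  truth_families <- genes %>%
    select(family_id = "family_id", gene_id = "gene_id") %>%
    arrange(.data$family_id, .data$gene_id)
  genes <- select(genes, -"family_id")

  split_depth <- function(lin_a, lin_b) {
    a <- strsplit(lin_a, "")[[1]]
    b <- strsplit(lin_b, "")[[1]]
    depths[which(a != b)[1]]
  }
  pair_rows <- list()
  wgd_ids <- vapply(copy_records, `[[`, character(1), "gene_id")
  wgd_gene <- vapply(copy_records, function(r) r$family_id, character(1))
  wgd_lin <- vapply(copy_records, `[[`, character(1), "lineage")
  for (f in unique(wgd_gene)) {
    idx <- which(wgd_gene == f)
    if (length(idx) < 2) next
    cmb <- utils::combn(idx, 2)
    pair_rows[[f]] <- tibble(
      id_a = wgd_ids[cmb[1, ]], id_b = wgd_ids[cmb[2, ]],
      depth = apply(cmb, 2, function(p) split_depth(wgd_lin[p[1]], wgd_lin[p[2]]))
    )
  }
  for (k in seq_along(truth_tandem)) {
    ids <- truth_tandem[[k]]
    if (length(ids) >= 2) {
      cmb <- utils::combn(length(ids), 2)
      pair_rows[[paste0("T", k)]] <- tibble(
        id_a = ids[cmb[1, ]], id_b = ids[cmb[2, ]], depth = 0
      )
    }
  }
  truth_pair_depths <- if (length(pair_rows) > 0) bind_rows(pair_rows) else {
    tibble(id_a = character(), id_b = character(), depth = numeric())
  }

  structure(
    list(genes = genes,
         truth_families = truth_families,
         truth_pair_depths = truth_pair_depths,
         truth_tandem_clusters = truth_tandem,
         config = config),
    class = "simulated_genome"
  )
}

#' @export
print.simulated_genome <- function(x, ...) {
  cat(sprintf(
    "Simulated genome: %d genes on %d chromosomes, %d WGD event(s), %d famil%s\n",
    nrow(x$genes), length(unique(x$genes$chromosome)),
    length(x$config$wgd_depths), length(unique(x$truth_families$family_id)),
    if (length(unique(x$truth_families$family_id)) == 1) "y" else "ies"))
  invisible(x)
}
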