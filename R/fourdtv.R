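#' Back-translate a protein alignment to codon columns
#'
#' Each aligned residue column becomes the source codon of its sequence;
#' residue gaps become `"---"`. The CDSs must translate exactly to the
#' ungapped proteins (standard code); the first discordant codon is
#' reported otherwise.
#'
#' @param aligned_a,aligned_b equal-length gapped protein strings (e.g.
#'   from [align_protein_pair()]).
#' @param cds_a,cds_b the coding sequences (length `3 *` ungapped
#'   protein length).
#' @return A list with `codons_a`, `codons_b`: equal-length character
#'   vectors of codon columns.
#' @export
backtranslate_to_codons <- function(aligned_a, aligned_b, cds_a, cds_b) {
  if (nchar(aligned_a) != nchar(aligned_b)) {
    abort("aligned sequences must have equal length")
  }
  expand_one <- function(aligned, cds, label) {
    prot <- gsub("-", "", aligned)
    if (nchar(cds) != 3L * nchar(prot)) {
      abort(sprintf("CDS of %s has length %d, expected %d",
                    label, nchar(cds), 3L * nchar(prot)))
    }
    codons <- split_codons(cds)
    translated <- strsplit(translate_cds(cds), "")[[1]]
    residues <- strsplit(prot, "")[[1]]
    bad <- which(translated != residues)
    if (length(bad) > 0) {
      abort(sprintf("CDS of %s does not translate to its protein: codon %d (%s) gives %s, expected %s",
                    label, bad[1], codons[bad[1]], translated[bad[1]], residues[bad[1]]))
    }
    expand_codon_columns(aligned, codons)
  }
  list(codons_a = expand_one(aligned_a, cds_a, "sequence a"),
       codons_b = expand_one(aligned_b, cds_b, "sequence b"))
}

# place codons under the non-gap columns of a gapped protein string
expand_codon_columns <- function(aligned, codons) {
  cols <- strsplit(aligned, "")[[1]]
  out <- rep("---", length(cols))
  out[cols != "-"] <- codons
  out
}

#' Extract four-fold degenerate sites from a codon pair alignment
#'
#' A column yields a site when neither codon is a gap, both codons share
#' the same first two bases, and that dinucleotide prefix belongs to one
#' of the eight four-fold families (CTN, GTN, TCN, CCN, ACN, GCN, CGN,
#' GGN). Requiring prefix identity across the pair is conservative: a
#' prefix change could alter the degeneracy class.
#'
#' @param codons_a,codons_b equal-length codon column vectors.
#' @return A tibble of third-position base pairs `base_a`, `base_b`.
#' @export
extract_4d_sites <- function(codons_a, codons_b) {
  if (length(codons_a) != length(codons_b)) {
    abort("codon vectors must have equal length")
  }
  pa <- substr(codons_a, 1, 2)
  pb <- substr(codons_b, 1, 2)
  keep <- codons_a != "---" & codons_b != "---" & pa == pb &
    pa %in% .FOURFOLD_PREFIXES
  tibble(base_a = substr(codons_a[keep], 3, 3),
         base_b = substr(codons_b[keep], 3, 3))
}

#' Compute the corrected 4DTv statistic from 4D site pairs
#'
#' The raw 4DTv is the fraction of 4D sites at which the two bases
#' differ by a transversion (one purine, one pyrimidine). Multiple hits
#' are corrected with `-1/2 * log(1 - 2 * raw)`, defined only below the
#' 0.5 saturation bound; saturated pairs carry `NA` and fail the filter.
#' Pairs with fewer than `min_sites` sites also fail the filter.
#'
#' @param sites tibble of `base_a`, `base_b` character columns.
#' @param min_sites minimum number of 4D sites a pair must have.
#' @param id_a,id_b optional pair identifiers carried through.
#' @return A one-row tibble: `id_a`, `id_b`, `n_4d_sites`,
#'   `n_transversions`, `fourdtv_raw`, `fourdtv_corrected`, `saturated`,
#'   `passes_filter`.
#' @export
fourdtv_statistic <- function(sites, min_sites = 30L,
                              id_a = NA_character_, id_b = NA_character_) {
  n <- nrow(sites)
  tv <- if (n == 0) 0L else sum(.PURINE[sites$base_a] != .PURINE[sites$base_b])
  raw <- if (n == 0) NA_real_ else tv / n
  saturated <- !is.na(raw) && raw >= 0.5
  corrected <- if (!is.na(raw) && !saturated) -0.5 * log(1 - 2 * raw) else NA_real_
  tibble(
    id_a = id_a, id_b = id_b,
    n_4d_sites = as.integer(n), n_transversions = as.integer(tv),
    fourdtv_raw = raw, fourdtv_corrected = corrected,
    saturated = saturated,
    passes_filter = n >= min_sites && !is.na(corrected)
  )
}

#' 4DTv records for every paralog pair of every family
#'
#' For each family all unordered member pairs (or representative pairs
#' after tandem collapsing when `representatives_only`) are aligned at
#' the protein level, back-translated to codons, reduced to 4D sites and
#' scored with [fourdtv_statistic()]. Pairs lacking a protein or CDS are
#' skipped with a warning.
#'
#' @param families tibble `family_id`, `gene_id` (optionally
#'   `representative`).
#' @param genes gene model tibble supplying `protein` and `cds`.
#' @param min_sites minimum 4D site count for the filter.
#' @param representatives_only score only tandem-collapsed
#'   representatives.
#' @return A tibble of 4DTv records with a `family_id` column.
#' @export
fourdtv_families <- function(families, genes, min_sites = 30L,
                             representatives_only = FALSE) {
  if (representatives_only) {
    if (!"representative" %in% names(families)) {
      abort("`families` lacks a representative column; run collapse_tandem_members()")
    }
    families <- filter(families, .data$representative)
  }
  seqs <- setNames(genes$protein, genes$gene_id)
  cdss <- setNames(genes$cds, genes$gene_id)
  # validate every CDS/protein pair once, in bulk (cheaper than per pair)
  usable <- !is.na(seqs) & !is.na(cdss) & nzchar(seqs) & nzchar(cdss)
  check_idx <- which(usable)
  if (length(check_idx) > 0) {
    translated <- as.character(Biostrings::translate(
      Biostrings::DNAStringSet(cdss[check_idx]), no.init.codon = TRUE))
    bad <- translated != seqs[check_idx]
    if (any(bad)) {
      abort(sprintf("CDS of %s does not translate to its protein",
                    names(seqs)[check_idx][bad][1]))
    }
  }
  codon_cache <- lapply(cdss, function(x) if (is.na(x)) NULL else split_codons(x))
  prefix_cache <- lapply(codon_cache, function(cd) {
    if (is.null(cd)) NULL else substr(cd, 1, 2)
  })
  third_cache <- lapply(codon_cache, function(cd) {
    if (is.null(cd)) NULL else substr(cd, 3, 3)
  })
  fam_split <- split(families$gene_id, families$family_id)
  n_skipped <- 0L
  acc <- list()
  for (f in names(fam_split)) {
    ids <- sort(fam_split[[f]])
    if (length(ids) < 2L) next
    cmb <- utils::combn(ids, 2L)
    np <- ncol(cmb)
    n_sites <- integer(np); n_tv <- integer(np); ok <- logical(np)
    for (p in seq_len(np)) {
      a <- cmb[1, p]; b <- cmb[2, p]
      if (!usable[a] || !usable[b]) {
        n_skipped <- n_skipped + 1L
        next
      }
      if (identical(seqs[[a]], seqs[[b]])) {
        # identical proteins align without gaps: codon columns are codons
        pa <- prefix_cache[[a]]; pb <- prefix_cache[[b]]
        ta <- third_cache[[a]]; tb <- third_cache[[b]]
      } else {
        aln <- align_protein_pair(seqs[[a]], seqs[[b]])
        ca <- expand_codon_columns(aln$aligned_a, codon_cache[[a]])
        cb <- expand_codon_columns(aln$aligned_b, codon_cache[[b]])
        gap <- ca == "---" | cb == "---"
        pa <- substr(ca[!gap], 1, 2); pb <- substr(cb[!gap], 1, 2)
        ta <- substr(ca[!gap], 3, 3); tb <- substr(cb[!gap], 3, 3)
      }
      keep <- pa == pb & pa %in% .FOURFOLD_PREFIXES
      n_sites[p] <- sum(keep)
      n_tv[p] <- sum(.PURINE[ta[keep]] != .PURINE[tb[keep]])
      ok[p] <- TRUE
    }
    raw <- ifelse(n_sites > 0, n_tv / n_sites, NA_real_)
    saturated <- !is.na(raw) & raw >= 0.5
    corrected <- rep(NA_real_, np)
    est <- !is.na(raw) & !saturated
    corrected[est] <- -0.5 * log(1 - 2 * raw[est])
    acc[[f]] <- tibble(
      id_a = cmb[1, ], id_b = cmb[2, ],
      n_4d_sites = n_sites, n_transversions = n_tv,
      fourdtv_raw = raw, fourdtv_corrected = corrected,
      saturated = saturated,
      passes_filter = n_sites >= min_sites & !is.na(corrected),
      family_id = f
    )[ok, , drop = FALSE]
  }
  if (n_skipped > 0) {
    warn(sprintf("%d pair(s) skipped for missing protein or CDS", n_skipped))
  }
  bind_rows(acc)
}

#' Neutral substitution rate from a calibrated tree
#'
#' The rate is the patristic path length between two taxa on a neutral
#' (e.g. 4D-site) tree divided by twice their divergence time.
#'
#' @param tree an `ape::phylo`, a newick string, or a path to a newick
#'   file.
#' @param taxon_a,taxon_b leaf names.
#' @param divergence_time divergence time in years.
#' @return Substitutions per site per year.
#' @export
neutral_rate_from_tree <- function(tree, taxon_a, taxon_b, divergence_time) {
  if (is.character(tree)) {
    tree <- if (file.exists(tree)) ape::read.tree(tree) else ape::read.tree(text = tree)
  }
  if (!inherits(tree, "phylo")) abort("`tree` must be a phylo object or newick")
  if (!all(c(taxon_a, taxon_b) %in% tree$tip.label)) {
    missing <- setdiff(c(taxon_a, taxon_b), tree$tip.label)
    abort(sprintf("taxon not in tree: %s", paste(missing, collapse = ", ")))
  }
  stopifnot_scalar_number(divergence_time, "divergence_time", min = 1e-12)
  d <- stats::cophenetic(tree)[taxon_a, taxon_b]
  d / (2 * divergence_time)
}
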