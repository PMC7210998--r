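#' Read a FASTA file into a named character vector
#'
#' Identifiers are the first whitespace-delimited token of each header;
#' sequences are upper-cased and validated against the chosen alphabet
#' (`N`/`X` ambiguity codes tolerated). Record order is preserved and
#' duplicate identifiers are rejected.
#'
#' @param path path to a FASTA file.
#' @param alphabet `"nucleotide"` or `"protein"`.
#' @return Named character vector, one element per record.
#' @export
read_sequences_fasta <- function(path, alphabet = c("nucleotide", "protein")) {
  alphabet <- match.arg(alphabet)
  set <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate FASTA id: %s", ids[duplicated(ids)][1]))
  }
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  allowed <- if (alphabet == "nucleotide") "ACGTN" else "ACDEFGHIKLMNPQRSTVWYXBZU*"
  bad <- grepl(sprintf("[^%s]", allowed), seqs)
  if (any(bad)) {
    abort(sprintf("sequence '%s' contains characters outside the %s alphabet",
                  ids[bad][1], alphabet))
  }
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_sequences_fasta <- function(seqs, path, width = 70L) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Reads `gene` features from a GFF3 file and returns the package's gene
#' model table: one row per gene with 0-based half-open coordinates, a
#' dense per-chromosome `rank` (0-based, ordered by start), a free-text
#' `name` (attribute priority `Name` > `description` > `product`, falling
#' back to the gene id), and optional `protein`/`cds` sequences attached
#' by id from the supplied FASTA mappings.
#'
#' @param path path to a GFF3 file (1-based inclusive coordinates).
#' @param fasta optional named character vector of protein sequences.
#' @param cds_fasta optional named character vector of CDS sequences.
#' @return A tibble with columns `gene_id`, `chromosome`, `start`, `end`,
#'   `strand`, `name`, `rank`, `protein`, `cds`.
#' @export
read_gene_models_gff3 <- function(path, fasta = NULL, cds_fasta = NULL) {
  g <- as.data.frame(rtracklayer::readGFF(path))
  g <- g[g$type == "gene", , drop = FALSE]
  if (any(g$end < g$start)) {
    abort("GFF3 format error: feature with end < start")
  }
  pick_attr <- function(df, key) {
    if (key %in% names(df)) as.character(df[[key]]) else rep(NA_character_, nrow(df))
  }
  id <- pick_attr(g, "ID")
  name <- dplyr::coalesce(pick_attr(g, "Name"), pick_attr(g, "description"),
                          pick_attr(g, "product"), id)
  genes <- tibble(
    gene_id    = id,
    chromosome = as.character(g$seqid),
    start      = as.integer(g$start) - 1L,
    end        = as.integer(g$end),
    strand     = ifelse(as.character(g$strand) %in% c("+", "-"),
                        as.character(g$strand), "+"),
    name       = name
  )
  genes <- assign_gene_ranks(genes)
  genes$protein <- if (is.null(fasta)) NA_character_ else unname(fasta[genes$gene_id])
  genes$cds <- if (is.null(cds_fasta)) NA_character_ else unname(cds_fasta[genes$gene_id])
  if (!is.null(fasta) || !is.null(cds_fasta)) {
    orphan <- is.na(genes$protein) & is.na(genes$cds)
    if (any(orphan)) {
      warn(sprintf("%d gene id(s) absent from both FASTA mappings; sequences left empty",
                   sum(orphan)))
    }
  }
  genes
}

#' Assign dense 0-based gene ranks per chromosome by start coordinate
#'
#' @param genes a gene model tibble (needs `chromosome` and `start`).
#' @return The tibble with a recomputed integer `rank` column.
#' @export
assign_gene_ranks <- function(genes) {
  genes %>%
    group_by(.data$chromosome) %>%
    arrange(.data$start, .by_group = TRUE) %>%
    mutate(rank = row_number() - 1L) %>%
    ungroup() %>%
    arrange(.data$chromosome, .data$rank)
}

#' Write gene models to GFF3
#'
#' Inverse of [read_gene_models_gff3()]: internal 0-based half-open
#' coordinates are converted back to 1-based inclusive. Output is sorted
#' by chromosome and start so writing is deterministic.
#'
#' @param genes gene model tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_models_gff3 <- function(genes, path) {
  genes <- arrange(genes, .data$chromosome, .data$start, .data$gene_id)
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chromosome,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = genes$strand
  )
  gr$type <- "gene"
  gr$source <- "wgdtrace"
  gr$ID <- genes$gene_id
  gr$Name <- genes$name
  rtracklayer::export(gr, path, format = "GFF3")
  invisible(path)
}

#' Read BLAST 12-column tabular similarity hits
#'
#' Expects `outfmt 6` column order (`qseqid sseqid pident length mismatch
#' gapopen qstart qend sstart send evalue bitscore`, 1-based inclusive hit
#' coordinates). Self-hits are dropped and multiple HSPs per ordered pair
#' are collapsed to the single best-bitscore HSP. When sequence lengths
#' are provided, per-side coverages are computed as
#' `(end - start + 1) / length`.
#'
#' @param path path to the tabular file.
#' @param query_lengths,subject_lengths optional named integer vectors of
#'   sequence lengths used to compute coverages.
#' @return A tibble of similarity edges with columns `query_id`,
#'   `subject_id`, `percent_identity`, `alignment_length`, `evalue`,
#'   `bitscore`, `query_cov`, `subject_cov`.
#' @export
read_similarity_tabular <- function(path, query_lengths = NULL,
                                    subject_lengths = NULL) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  hits <- readr::read_tsv(
    path, col_names = cols,
    col_types = readr::cols(
      qseqid = readr::col_character(), sseqid = readr::col_character(),
      .default = readr::col_double()
    ),
    progress = FALSE
  )
  if (anyNA(hits$pident) || anyNA(hits$evalue) || anyNA(hits$bitscore)) {
    abort("similarity table format error: non-numeric field")
  }
  hits <- filter(hits, .data$qseqid != .data$sseqid)
  hits <- hits %>%
    group_by(.data$qseqid, .data$sseqid) %>%
    slice(which.max(.data$bitscore)) %>%
    ungroup()
  cov_of <- function(ids, from, to, lengths, side) {
    if (is.null(lengths)) return(rep(NA_real_, length(ids)))
    if (!all(ids %in% names(lengths))) {
      abort(sprintf("unknown %s id in similarity table", side))
    }
    (abs(to - from) + 1) / unname(lengths[ids])
  }
  tibble(
    query_id         = hits$qseqid,
    subject_id       = hits$sseqid,
    percent_identity = hits$pident,
    alignment_length = as.integer(hits$length),
    evalue           = hits$evalue,
    bitscore         = hits$bitscore,
    query_cov        = cov_of(hits$qseqid, hits$qstart, hits$qend,
                              query_lengths, "query"),
    subject_cov      = cov_of(hits$sseqid, hits$sstart, hits$send,
                              subject_lengths, "subject")
  )
}

#' Read a k-mer copy-number histogram
#'
#' Two whitespace-separated columns per line (jellyfish `histo` dialect):
#' k-mer copy number (KCN) and the count of distinct k-mers at that KCN.
#' Rows are sorted by KCN; zero-count rows are retained.
#'
#' @param path path to the histogram text file.
#' @param k the k-mer length the histogram was computed at.
#' @return A `kmer_histogram` tibble with columns `kcn`, `count` and a
#'   `k` attribute.
#' @export
read_kmer_histogram <- function(path, k) {
  m <- utils::read.table(path, header = FALSE, col.names = c("kcn", "count"))
  if (!is.numeric(m$kcn) || !is.numeric(m$count)) {
    abort("k-mer histogram format error: non-numeric field")
  }
  if (any(m$kcn < 0) || any(m$count < 0)) {
    abort("k-mer histogram format error: negative value")
  }
  new_kmer_histogram(tibble(kcn = as.integer(m$kcn), count = m$count), k = k)
}

#' Construct a k-mer histogram object
#'
#' @param entries tibble with integer `kcn` and numeric `count` columns.
#' @param k k-mer length.
#' @return A `kmer_histogram` tibble sorted by KCN.
#' @export
new_kmer_histogram <- function(entries, k) {
  if (nrow(entries) == 0 || all(entries$count == 0)) {
    abort("k-mer histogram must have at least one nonzero entry")
  }
  if (anyDuplicated(entries$kcn)) abort("duplicate KCN rows in histogram")
  out <- arrange(as_tibble(entries), .data$kcn)
  attr(out, "k") <- as.integer(k)
  class(out) <- c("kmer_histogram", class(out))
  out
}

#' Write a k-mer histogram in jellyfish `histo` format
#'
#' @param hist a `kmer_histogram`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_kmer_histogram <- function(hist, path) {
  writeLines(sprintf("%d %g", hist$kcn, hist$count), path)
  invisible(path)
}
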