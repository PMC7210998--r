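# Shared fixture builders: everything is generated in code at test time.

# minimal gene-model tibble on one chromosome, ranks in listed order
make_genes <- function(names, proteins = NULL, chromosome = "chr1",
                       cds = NULL) {
  n <- length(names)
  tibble::tibble(
    gene_id = paste0("g", seq_len(n)),
    chromosome = chromosome,
    start = (seq_len(n) - 1L) * 1000L,
    end = (seq_len(n) - 1L) * 1000L + 500L,
    strand = "+",
    name = names,
    rank = seq_len(n) - 1L,
    protein = proteins %||% rep(NA_character_, n),
    cds = cds %||% rep(NA_character_, n)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a protein with a chosen fraction of positions replaced (identity control)
mutate_protein <- function(p, frac, seed = 1) {
  withr::with_seed(seed, {
    aa <- strsplit(p, "")[[1]]
    alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    n_mut <- round(length(aa) * frac)
    if (n_mut > 0) {
      pos <- sample(seq_along(aa), n_mut)
      aa[pos] <- vapply(aa[pos], function(b) sample(setdiff(alphabet, b), 1),
                        character(1))
    }
    paste(aa, collapse = "")
  })
}

random_protein <- function(len, seed) {
  withr::with_seed(seed, {
    paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len,
                 replace = TRUE), collapse = "")
  })
}

random_cds <- function(n_codons, seed) {
  codons <- setdiff(as.vector(outer(outer(c("A","C","G","T"), c("A","C","G","T"),
                                          paste0), c("A","C","G","T"), paste0)),
                    c("TAA", "TAG", "TGA"))
  withr::with_seed(seed, paste(sample(codons, n_codons, TRUE), collapse = ""))
}
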