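#' Convert between 1-based inclusive and 0-based half-open coordinates
#'
#' Internally the package stores gene coordinates 0-based half-open; GFF3
#' files are 1-based inclusive. These two helpers are exact inverses.
#'
#' @param start,end numeric vectors of interval bounds.
#' @return A two-column tibble with converted `start` and `end`.
#' @examples
#' coords_to_internal(1, 300)   # -> start 0, end 300
#' coords_to_gff3(0, 300)       # -> start 1, end 300
#' @export
coords_to_internal <- function(start, end) {
  tibble(start = start - 1L, end = end)
}

#' @rdname coords_to_internal
#' @export
coords_to_gff3 <- function(start, end) {
  tibble(start = start + 1L, end = end)
}

# DNA base codes used throughout the simulators: 1=A, 2=C, 3=G, 4=T
.BASES <- c("A", "C", "G", "T")

# purines A,G; a transversion pairs a purine with a pyrimidine
.PURINE <- c(A = TRUE, C = FALSE, G = TRUE, T = FALSE)

# dinucleotide prefixes whose codons are four-fold degenerate
.FOURFOLD_PREFIXES <- c("CT", "GT", "TC", "CC", "AC", "GC", "CG", "GG")

# the 61 sense codons of the standard code
.sense_codons <- function() {
  all <- as.vector(outer(outer(.BASES, .BASES, paste0), .BASES, paste0))
  setdiff(all, c("TAA", "TAG", "TGA"))
}

# run `expr` under a local RNG state seeded with `seed` (NULL = current state)
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# derive a stream of child seeds from one master seed, all < 2^31
derive_seeds <- function(seed, n, stream = 0L) {
  withr::with_seed(as.integer(seed) + 1000L * as.integer(stream), {
    sample.int(.Machine$integer.max - 1L, n)
  })
}

stopifnot_scalar_number <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min) {
    abort(sprintf("`%s` must be a single finite number >= %s", name, min))
  }
}

# split a CDS string into codons (error if length not divisible by 3)
split_codons <- function(cds) {
  n <- nchar(cds)
  if (n %% 3L != 0L) abort("CDS length is not divisible by 3")
  substring(cds, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

# translate a CDS with the standard code; returns an AA string
translate_cds <- function(cds) {
  as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                     no.init.codon = TRUE))
}
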