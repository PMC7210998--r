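#' All-vs-all protein similarity search
#'
#' Either ingests a precomputed BLAST tabular file (primary path for real
#' data, parsed by [read_similarity_tabular()]) or computes exact local
#' alignments itself at synthetic scale. The built-in engine seeds
#' candidate pairs on shared amino-acid words (two-hit style: at least
#' `min_shared_words` shared words of length `word_size`), aligns
#' candidates with BLOSUM62 affine-gap local alignment (11/1), and
#' converts scores to E-values with gapped Karlin-Altschul parameters
#' (lambda = 0.267, K = 0.041) against the total database length.
#' E-values are carried in log10 so deeply similar pairs do not
#' underflow. Symmetric duplicates are collapsed keeping the better
#' E-value; edges worse than `max_evalue` are dropped.
#'
#' @param proteins named character vector of protein sequences (>= 2).
#' @param max_evalue E-value cutoff.
#' @param precomputed optional edge tibble (e.g. from
#'   [read_similarity_tabular()]) used verbatim instead of aligning.
#' @param word_size,min_shared_words seeding parameters of the built-in
#'   engine.
#' @return A similarity-edge tibble: `query_id`, `subject_id`,
#'   `percent_identity`, `alignment_length`, `evalue`, `bitscore`,
#'   `query_cov`, `subject_cov`, `log10_evalue`.
#' @export
all_vs_all_similarity <- function(proteins, max_evalue = 1e-8,
                                  precomputed = NULL,
                                  word_size = 8L, min_shared_words = 2L) {
  if (!is.null(precomputed)) {
    edges <- precomputed %>%
      filter(.data$evalue <= max_evalue, .data$query_id != .data$subject_id)
    if (!"log10_evalue" %in% names(edges)) {
      edges$log10_evalue <- log10(pmax(edges$evalue, 1e-300))
    }
    # collapse symmetric duplicates, keeping the better E-value
    edges <- edges %>%
      mutate(.a = pmin(.data$query_id, .data$subject_id),
             .b = pmax(.data$query_id, .data$subject_id)) %>%
      arrange(.data$.a, .data$.b, .data$log10_evalue) %>%
      distinct(.data$.a, .data$.b, .keep_all = TRUE) %>%
      select(-".a", -".b")
    return(as_tibble(edges))
  }
  if (length(proteins) < 2L) abort("need at least two proteins")
  if (is.null(names(proteins)) || anyDuplicated(names(proteins))) {
    abort("`proteins` must be uniquely named")
  }
  ids <- names(proteins)
  lens <- unname(nchar(proteins))
  db_len <- sum(lens)
  lambda <- 0.267
  K <- 0.041

  # deduplicate exact sequences: align once per distinct-sequence pair and
  # expand the result to every member pair
  group_of <- match(proteins, unique(proteins))
  reps <- which(!duplicated(proteins))
  n_grp <- length(reps)
  members <- split(seq_along(proteins), group_of)

  # word index over distinct sequences only
  word_sets <- lapply(reps, function(i) {
    s <- proteins[[i]]
    n <- nchar(s) - word_size + 1L
    if (n < 1L) return(character(0))
    unique(substring(s, seq_len(n), seq_len(n) + word_size - 1L))
  })
  w <- unlist(word_sets, use.names = FALSE)
  widx <- rep.int(seq_len(n_grp), lengths(word_sets))
  shared_sel <- duplicated(w) | duplicated(w, fromLast = TRUE)
  by_word <- split(widx[shared_sel], w[shared_sel])
  pair_lists <- lapply(by_word, function(m) {
    m <- unique(m)
    if (length(m) < 2L) return(NULL)
    cmb <- utils::combn(m, 2L)
    (cmb[1, ] - 1) + n_grp * (cmb[2, ] - 1)   # encode group pair
  })
  codes <- unlist(pair_lists, use.names = FALSE)
  if (is.null(codes)) codes <- numeric(0)
  shared <- table(codes)
  shared <- shared[shared >= min_shared_words]
  code_vals <- as.numeric(names(shared))
  # candidate group pairs: word-seeded cross-group pairs plus every
  # duplicated group paired with itself
  gp <- tibble(gx = as.integer(code_vals %% n_grp) + 1L,
               gy = as.integer(code_vals %/% n_grp) + 1L)
  gp <- bind_rows(gp, tibble(gx = which(lengths(members) > 1L),
                             gy = which(lengths(members) > 1L)))
  rows <- vector("list", nrow(gp))
  for (p in seq_len(nrow(gp))) {
    gx <- gp$gx[p]; gy <- gp$gy[p]
    st <- local_protein_alignment(proteins[[reps[gx]]], proteins[[reps[gy]]])
    # member pairs this group pair stands for
    if (gx == gy) {
      cmb <- utils::combn(members[[gx]], 2L)
      ii <- cmb[1, ]; jj <- cmb[2, ]
    } else {
      grid <- expand.grid(ii = members[[gx]], jj = members[[gy]])
      ii <- grid$ii; jj <- grid$jj
    }
    log10_e <- log10(K * lens[ii] * db_len) - lambda * st$score / log(10)
    keep <- log10_e <= log10(max_evalue)
    if (!any(keep)) next
    rows[[p]] <- tibble(
      query_id = ids[ii[keep]], subject_id = ids[jj[keep]],
      percent_identity = st$identity,
      alignment_length = as.integer(st$length),
      evalue = 10^log10_e[keep],
      bitscore = (lambda * st$score - log(K)) / log(2),
      query_cov = st$q_span / lens[ii[keep]],
      subject_cov = st$s_span / lens[jj[keep]],
      log10_evalue = log10_e[keep]
    )
  }
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble(query_id = character(), subject_id = character(),
                  percent_identity = numeric(), alignment_length = integer(),
                  evalue = numeric(), bitscore = numeric(),
                  query_cov = numeric(), subject_cov = numeric(),
                  log10_evalue = numeric()))
  }
  arrange(out, .data$query_id, .data$subject_id)
}
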