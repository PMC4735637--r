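# shared in-code fixtures for the test suite

# minimal long-format pooled-counts table from per-sample base-count matrices
make_counts <- function(pos, ref, ..., chrom = "X") {
  samples <- list(...)
  purrr::map_dfr(names(samples), function(s) {
    m <- samples[[s]]
    colnames(m) <- c("A", "T", "C", "G", "N", "del")
    dplyr::bind_cols(
      tibble::tibble(chrom = chrom, pos = pos, ref = ref, sample = s),
      tibble::as_tibble(m)
    )
  })
}

# count matrix row helper: counts for (A, T, C, G, N, del)
cnt <- function(...) matrix(c(...), ncol = 6, byrow = TRUE)

# random small alignment as a character matrix
random_alignment <- function(n_seq, n_site, ids = NULL,
                             bases = c("A", "C", "G", "T")) {
  m <- matrix(sample(bases, n_seq * n_site, replace = TRUE), nrow = n_seq)
  haplo_alignment(m, ids = ids %||% sprintf("s%02d", seq_len(n_seq)))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# brute-force p-distance between two character vectors (pairwise deletion)
brute_pdist <- function(a, b) {
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  sum(a[ok] != b[ok]) / sum(ok)
}

# default balanced-locus alignment reused by several files
balanced_fixture <- function(seed = 3, ...) {
  simulate_balanced_locus(balanced_locus_config(...), seed = seed)
}

group_ids <- function(aln, g) {
  truth <- attr(aln, "group_truth")
  names(truth)[truth == g]
}
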