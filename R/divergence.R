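#' Allele frequencies of sequenced lines relative to the reference
#'
#' For each site and line, the frequency `p` of the allele matching the
#' reference-genome base, computed from pooled nucleotide counts. Sites are
#' dropped for a line when their nucleotide coverage is below `min_coverage`
#' (default 2); only sites passing in every requested line are returned.
#'
#' @param counts Long pooled-counts tibble ([simulate_poolseq()] /
#'   [read_sync()]).
#' @param samples Sample names to extract (default: all).
#' @param min_coverage Minimum per-line nucleotide coverage.
#' @return Wide tibble: `chrom`, `pos`, `ref`, then one `p_<sample>` column
#'   per line.
#' @export
line_frequencies <- function(counts, samples = NULL, min_coverage = 2) {
  samples <- samples %||% unique(counts$sample)
  sub <- counts[counts$sample %in% samples, , drop = FALSE]
  base_mat <- as.matrix(sub[, DNA_BASES])
  cov <- rowSums(base_mat)
  ref_reads <- base_mat[cbind(seq_len(nrow(sub)), match(sub$ref, DNA_BASES))]
  sub$p <- ifelse(cov > 0, ref_reads / cov, NA_real_)
  sub$p[cov < min_coverage] <- NA_real_
  wide <- tidyr::pivot_wider(
    sub[, c("chrom", "pos", "ref", "sample", "p")],
    names_from = "sample", values_from = "p", names_prefix = "p_"
  )
  wide[stats::complete.cases(wide), ]
}

#' Per-SNP between-line Dxy
#'
#' For two lines with reference-allele frequencies `p1`, `p2` (and `q = 1 -
#' p`), the per-SNP divergence is `Dxy = p1 q2 + p2 q1`: the probability that
#' two reads, one from each line, carry different alleles. Symmetric and
#' bounded in `[0, 1]`; equals 1 exactly at a fixed difference.
#'
#' @param p1,p2 Reference-allele frequencies in the two lines, in `[0, 1]`.
#' @return Numeric vector of Dxy values.
#' @examples
#' snp_dxy(1, 0)
#' snp_dxy(0.8, 0.3)
#' @export
snp_dxy <- function(p1, p2) {
  if (any(p1 < 0 | p1 > 1 | p2 < 0 | p2 > 1, na.rm = TRUE)) {
    abort("allele frequencies must lie in [0, 1].")
  }
  p1 * (1 - p2) + p2 * (1 - p1)
}

#' SNP-indexed sliding-window smoothing
#'
#' Smooths a per-SNP statistic over sliding windows of `2 * half_width + 1`
#' SNPs (window defined in SNP index space, not bases). At chromosome ends
#' the window is truncated rather than padded or dropped, so every SNP
#' receives a value; truncated windows are flagged.
#'
#' @param values Per-SNP values, ordered by position.
#' @param half_width Number of SNPs on each side (default 250, i.e. 501-SNP
#'   windows).
#' @return Tibble `index`, `smoothed`, `n_snps`, `truncated`.
#' @export
sliding_mean <- function(values, half_width = 250) {
  if (half_width < 0) abort("`half_width` must be >= 0.")
  n <- length(values)
  if (!n) return(tibble(index = integer(), smoothed = numeric(),
                        n_snps = integer(), truncated = logical()))
  idx <- seq_len(n)
  lo <- pmax(1L, idx - half_width)
  hi <- pmin(n, idx + half_width)
  cs <- c(0, cumsum(ifelse(is.na(values), 0, values)))
  cn <- c(0, cumsum(!is.na(values)))
  tot <- cs[hi + 1] - cs[lo]
  cnt <- cn[hi + 1] - cn[lo]
  tibble(
    index = idx,
    smoothed = ifelse(cnt > 0, tot / cnt, NA_real_),
    n_snps = as.integer(cnt),
    truncated = (hi - lo) < 2L * half_width
  )
}

#' Sliding-window Dxy along a chromosome
#'
#' Computes per-SNP Dxy between two lines from their reference-allele
#' frequencies and smooths it over sliding windows of `2 * half_width + 1`
#' SNPs ([sliding_mean()]).
#'
#' @param freqs Frequency table from [line_frequencies()] (already filtered
#'   for coverage), with columns `p_<line1>` and `p_<line2>`.
#' @param line1,line2 Line names.
#' @param half_width SNPs on each side of the focal SNP (default 250).
#' @return Tibble `chrom`, `pos`, `p1`, `p2`, `dxy`, `smoothed`,
#'   `truncated`.
#' @export
sliding_dxy <- function(freqs, line1, line2, half_width = 250) {
  c1 <- paste0("p_", line1); c2 <- paste0("p_", line2)
  if (!all(c(c1, c2) %in% names(freqs))) {
    abort("frequency columns for both lines are required.")
  }
  freqs <- freqs[order(freqs$chrom, freqs$pos), ]
  d <- snp_dxy(freqs[[c1]], freqs[[c2]])
  sm <- sliding_mean(d, half_width)
  tibble(
    chrom = freqs$chrom, pos = freqs$pos,
    p1 = freqs[[c1]], p2 = freqs[[c2]],
    dxy = d, smoothed = sm$smoothed, truncated = sm$truncated
  )
}

#' Call high-divergence intervals from a smoothed scan
#'
#' Flags SNPs whose smoothed value exceeds `multiplier` times the
#' chromosome-wide median and merges runs of consecutive flagged SNPs into
#' intervals (runs separated by non-flagged SNPs stay distinct).
#'
#' @param scan Tibble with `pos` and `smoothed` columns ([sliding_dxy()]).
#' @param multiplier Threshold multiple of the chromosome median (default 5).
#' @return Tibble `start`, `end`, `n_snps`, `max_smoothed`.
#' @export
peak_interval <- function(scan, multiplier = 5) {
  med <- median(scan$smoothed, na.rm = TRUE)
  thr <- multiplier * med
  hot <- !is.na(scan$smoothed) & scan$smoothed > thr
  if (!any(hot)) {
    return(tibble(start = numeric(), end = numeric(),
                  n_snps = integer(), max_smoothed = numeric()))
  }
  idx <- which(hot)
  run <- cumsum(c(1, diff(idx) != 1))
  purrr::map_dfr(split(idx, run), function(ii) {
    tibble(
      start = scan$pos[ii[1]], end = scan$pos[ii[length(ii)]],
      n_snps = length(ii), max_smoothed = max(scan$smoothed[ii])
    )
  })
}
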