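#' Call diagnostic SNPs from parental pooled counts
#'
#' A SNP is diagnostic for dark-line ancestry when it is diallelic across all
#' sequenced lines, every line reaches a minimum total read count (default
#' 10), and one allele is fixed in the dark parental line while absent from
#' the light parental line.
#'
#' @param counts Long tibble of pooled counts as produced by
#'   [simulate_poolseq()]/[read_sync()] (columns `chrom`, `pos`, `sample`,
#'   `A`, `T`, `C`, `G`, `N`, `del`). All samples present are subject to the
#'   minimum-count filter.
#' @param dark,light Sample names of the dark and light parental lines.
#' @param min_count Minimum total nucleotide count required in every line.
#' @return Tibble of diagnostic SNPs: `chrom`, `pos`, `dark_allele`,
#'   `light_allele`.
#' @examples
#' par <- simulate_parental_genomes(1e4, seed = 1)
#' cnt <- dplyr::bind_rows(
#'   simulate_poolseq(1, par, 30, sample = "dark", seed = 2),
#'   simulate_poolseq(0, par, 30, sample = "light", seed = 3)
#' )
#' diag <- call_diagnostic_snps(cnt, "dark", "light")
#' nrow(diag)
#' @export
call_diagnostic_snps <- function(counts, dark = "dark", light = "light",
                                 min_count = 10) {
  need <- c(dark, light)
  if (!all(need %in% counts$sample)) {
    abort("`dark` and `light` samples must be present in `counts`.")
  }
  base_mat <- as.matrix(counts[, DNA_BASES])
  key <- paste(counts$chrom, counts$pos)
  # coordinates must agree across samples
  tab <- table(key)
  n_samp <- length(unique(counts$sample))
  if (any(tab != n_samp)) {
    abort("samples do not share a common set of site coordinates.")
  }

  # minimum count in every line
  tot <- rowSums(base_mat)
  min_ok_key <- tapply(tot >= min_count, key, all)

  # diallelic across all lines: pooled counts show exactly two alleles
  pooled <- rowsum(base_mat, key)
  n_alleles <- rowSums(pooled > 0)
  dial_ok <- n_alleles == 2

  dk <- counts$sample == dark
  lt <- counts$sample == light
  dark_major <- DNA_BASES[max.col(base_mat[dk, , drop = FALSE], ties.method = "first")]
  dark_fixed <- rowSums(base_mat[dk, , drop = FALSE] > 0) == 1
  names(dark_major) <- names(dark_fixed) <- key[dk]

  light_counts <- base_mat[lt, , drop = FALSE]
  rownames(light_counts) <- key[lt]

  keys <- rownames(pooled)
  dm <- dark_major[keys]
  absent_in_light <- light_counts[cbind(keys, dm)] == 0
  light_major <- DNA_BASES[max.col(light_counts[keys, , drop = FALSE],
                                   ties.method = "first")]

  ok <- dial_ok & as.vector(min_ok_key[keys]) & dark_fixed[keys] & absent_in_light
  res <- counts[dk, c("chrom", "pos")]
  res$dark_allele <- unname(dark_major[key[dk]])
  res$light_allele <- unname(light_major[match(key[dk], keys)])
  res <- res[ok[match(key[dk], keys)], ]
  dplyr::arrange(as_tibble(res), .data$chrom, .data$pos)
}

#' Per-SNP dark-ancestry proportion of a pool
#'
#' At each diagnostic SNP, the proportion of pooled sequencing reads carrying
#' the allele fixed in the dark parental line. Sites with zero pool depth are
#' emitted as missing, never as zero.
#'
#' @param counts Long pooled-counts tibble (see [call_diagnostic_snps()]).
#' @param diagnostic Diagnostic-SNP tibble from [call_diagnostic_snps()].
#' @param sample Name of the pool sample to evaluate.
#' @return Tibble `chrom`, `pos`, `depth`, `ancestry`.
#' @export
snp_ancestry <- function(counts, diagnostic, sample) {
  if (!nrow(diagnostic)) abort("the diagnostic SNP set is empty.")
  sub <- counts[counts$sample == sample, , drop = FALSE]
  sub <- dplyr::inner_join(sub, diagnostic, by = c("chrom", "pos"))
  base_mat <- as.matrix(sub[, DNA_BASES])
  dark_reads <- base_mat[cbind(seq_len(nrow(sub)), match(sub$dark_allele, DNA_BASES))]
  depth <- rowSums(base_mat)
  tibble(
    chrom = sub$chrom, pos = sub$pos, depth = as.integer(depth),
    ancestry = ifelse(depth > 0, dark_reads / depth, NA_real_)
  )
}

#' Average per-SNP values in non-overlapping tiling windows
#'
#' Windows of `width` bases tile the chromosome from coordinate 1 (1-based,
#' inclusive ends). The window mean is the arithmetic mean over the SNPs it
#' contains; windows without SNPs are emitted with a missing mean.
#'
#' @param data Tibble with at least `pos` and `value` columns (see `value`).
#' @param value Name of the value column (default `"ancestry"` falling back
#'   to `"value"`).
#' @param width Window width in bases (> 0).
#' @param chrom_length Optional chromosome length; windows are emitted up to
#'   its end (default: up to the last SNP).
#' @return Tibble `window`, `start`, `end`, `n_snps`, `mean`.
#' @export
window_average <- function(data, value = NULL, width = 1e5,
                           chrom_length = NULL) {
  if (!is.numeric(width) || width <= 0) abort("`width` must be positive.")
  value <- value %||% intersect(c("ancestry", "value"), names(data))[1]
  if (is.na(value) || is.null(value)) abort("no value column found.")
  if (is.unsorted(data$pos)) data <- data[order(data$pos), ]
  chrom_length <- chrom_length %||% max(data$pos, 1)
  n_win <- max(1L, ceiling(chrom_length / width))
  win <- pmin(((data$pos - 1) %/% width) + 1L, n_win)
  f <- factor(win, levels = seq_len(n_win))
  v <- data[[value]]
  means <- tapply(v, f, function(x) mean(x, na.rm = TRUE))
  n_snps <- tapply(!is.na(v), f, sum)
  n_snps[is.na(n_snps)] <- 0L
  means[!is.finite(means)] <- NA_real_
  tibble(
    window = seq_len(n_win),
    start = as.numeric((seq_len(n_win) - 1) * width + 1),
    end = as.numeric(pmin(seq_len(n_win) * width, chrom_length)),
    n_snps = as.integer(n_snps),
    mean = as.numeric(means)
  )
}

#' Identity-by-descent window filter
#'
#' Windows where the parental strains show fewer than one fixed difference
#' per 1,000 sites are flagged as potentially identical-by-descent: ancestry
#' is uninformative there. "Fewer than" is strict, so a window at exactly the
#' threshold is retained.
#'
#' @param n_fixed Fixed parental differences per window.
#' @param n_sites Sites (bases) per window (> 0).
#' @param threshold Minimum fixed-difference density (default 1/1000).
#' @return Logical vector: `TRUE` where the window is excluded.
#' @examples
#' ibd_filter(c(99, 100, 0), 1e5)
#' @export
ibd_filter <- function(n_fixed, n_sites, threshold = 1e-3) {
  if (any(n_sites <= 0)) abort("`n_sites` must be positive.")
  (n_fixed / n_sites) < threshold
}

#' Combine pool window scores and call candidate windows
#'
#' The combined ancestry score of a window is the mean of the heterozygous
#' backcross pool's and the homozygous introgression line's window means. For
#' a dominant causal allele these are expected to be 50% and 100% at the
#' causal locus, so the combined score there should be near 75%. Retained
#' (non-IBD) windows whose combined score falls within `band` of `target`
#' are candidates, ranked by closeness to the target.
#'
#' @param bc_windows,hom_windows Window tables from [window_average()] for
#'   the two pools (identical window grids).
#' @param excluded Logical IBD exclusion flags from [ibd_filter()] (default:
#'   none excluded).
#' @param target Expected combined score at the causal window (default 0.75).
#' @param band Half-width of the acceptance band around `target`.
#' @return Tibble with `window`, `start`, `end`, `bc_mean`, `hom_mean`,
#'   `combined`, `excluded`, `deviation`, `candidate` and `rank` (deviation
#'   rank among candidate windows).
#' @export
candidate_windows <- function(bc_windows, hom_windows, excluded = NULL,
                              target = 0.75, band = 0.05) {
  if (nrow(bc_windows) != nrow(hom_windows) ||
      any(bc_windows$window != hom_windows$window)) {
    abort("window tables must share an identical window grid.")
  }
  excluded <- excluded %||% rep(FALSE, nrow(bc_windows))
  out <- tibble(
    window = bc_windows$window,
    start = bc_windows$start, end = bc_windows$end,
    bc_mean = bc_windows$mean, hom_mean = hom_windows$mean,
    combined = ifelse(excluded, NA_real_,
                      (bc_windows$mean + hom_windows$mean) / 2),
    excluded = excluded
  )
  out$deviation <- abs(out$combined - target)
  out$candidate <- !is.na(out$combined) & out$deviation <= band
  out$rank <- NA_integer_
  if (any(out$candidate)) {
    out$rank[out$candidate] <- rank(out$deviation[out$candidate],
                                    ties.method = "first")
  } else {
    warn("no candidate windows within the acceptance band.")
  }
  out
}

#' Merge candidate windows into ranked candidate intervals
#'
#' Maximal runs of neighbouring candidate windows are merged into intervals,
#' ranked by the smallest deviation from the target score they contain.
#'
#' @param windows Output of [candidate_windows()].
#' @return Tibble `start`, `end`, `n_windows`, `min_deviation`, `rank`.
#' @export
candidate_intervals <- function(windows) {
  cand <- windows[windows$candidate, , drop = FALSE]
  if (!nrow(cand)) {
    return(tibble(start = numeric(), end = numeric(),
                  n_windows = integer(), min_deviation = numeric(),
                  rank = integer()))
  }
  run <- cumsum(c(1, diff(cand$window) != 1))
  out <- dplyr::summarise(
    dplyr::group_by(cand, run = run),
    start = min(.data$start), end = max(.data$end),
    n_windows = dplyr::n(), min_deviation = min(.data$deviation),
    .groups = "drop"
  )
  out <- dplyr::arrange(out[, -1], .data$min_deviation)
  out$rank <- seq_len(nrow(out))
  out
}

#' Goodness-of-fit test of a 1:1 segregation ratio
#'
#' Pearson chi-squared test of two phenotype-class counts against the 1:1
#' ratio expected for a single-locus X-linked trait, with 1 degree of
#' freedom.
#'
#' @param n_class1,n_class2 Observed counts (non-negative, not both zero).
#' @return A list of class `segregation_test` with `statistic`, `df`,
#'   `p.value` and the counts; has [tidy()]/[glance()] methods.
#' @examples
#' segregation_test(680, 645)
#' @export
segregation_test <- function(n_class1, n_class2) {
  if (n_class1 < 0 || n_class2 < 0) abort("counts must be non-negative.")
  if (n_class1 + n_class2 == 0) abort("counts must not both be zero.")
  e <- (n_class1 + n_class2) / 2
  stat <- (n_class1 - e)^2 / e + (n_class2 - e)^2 / e
  structure(
    list(
      statistic = stat, df = 1L, p.value = pchisq(stat, 1, lower.tail = FALSE),
      observed = c(n_class1, n_class2), expected = c(e, e),
      method = "chi-squared goodness of fit against a 1:1 ratio"
    ),
    class = c("segregation_test", "popgen_chisq")
  )
}

#' @export
print.popgen_chisq <- function(x, ...) {
  cat(x$method, "\n", sep = "")
  cat("  X-squared = ", format(x$statistic, digits = 5),
      ", df = ", x$df,
      ", p-value = ", format(x$p.value, digits = 4), "\n", sep = "")
  invisible(x)
}

#' @rdname segregation_test
#' @param x A `popgen_chisq` object.
#' @param ... Unused.
#' @export
tidy.popgen_chisq <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p.value = x$p.value,
         method = x$method)
}

#' @rdname segregation_test
#' @export
glance.popgen_chisq <- function(x, ...) tidy(x)
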