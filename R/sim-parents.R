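#' Simulate two divergent inbred parental X chromosomes
#'
#' Draws a set of biallelic SNPs along one chromosome for a pair of fully
#' inbred parental strains (a "dark" and a "light" line) plus an outgroup
#' genome. A configurable fraction of SNPs are fixed differences between the
#' parents (the diagnostic sites ancestry mapping relies on); at the remaining
#' SNPs both parents carry the same allele and the site can only be divergent
#' to the outgroup. Optional identity-by-descent tracts force the parents to be
#' identical locally, which is what the IBD window filter downstream exists to
#' catch.
#'
#' @param chrom_length Chromosome length in bases (positive integer).
#' @param snp_density Per-base probability that a site is a SNP, in `(0, 1]`
#'   (0 is allowed and yields an empty SNP table).
#' @param fixed_diff_fraction Fraction of SNPs fixed between the two parents.
#' @param outgroup_diff_fraction At SNPs where the parents agree, probability
#'   that the outgroup carries the other allele (an interspecies divergent
#'   site).
#' @param ensure_positions Base positions forced to be parental fixed
#'   differences (e.g. the causal site of a cross design).
#' @param ibd_regions Optional tibble/data frame with `start`, `end` columns;
#'   inside these tracts parental fixed differences are suppressed.
#' @param seed Optional integer seed; the RNG state is restored on exit.
#'
#' @return A tibble of class `parental_genomes` with one row per SNP and
#'   columns `pos`, `ref` (reference-genome allele), `dark_allele`,
#'   `light_allele`, `outgroup_allele`, `alt_allele` (the site's second
#'   segregating allele) and `fixed_diff`. The chromosome length is carried in
#'   `attr(, "chrom_length")`.
#' @examples
#' par <- simulate_parental_genomes(1e5, snp_density = 0.005, seed = 1)
#' mean(par$fixed_diff)
#' @export
simulate_parental_genomes <- function(chrom_length,
                                      snp_density = 0.005,
                                      fixed_diff_fraction = 0.5,
                                      outgroup_diff_fraction = 0.6,
                                      ensure_positions = integer(),
                                      ibd_regions = NULL,
                                      seed = NULL) {
  if (!is.numeric(chrom_length) || length(chrom_length) != 1 ||
      is.na(chrom_length) || chrom_length < 1) {
    abort("`chrom_length` must be a single positive number.")
  }
  chrom_length <- floor(chrom_length)
  if (!is.numeric(snp_density) || snp_density < 0 || snp_density > 1) {
    abort("`snp_density` must lie in [0, 1].")
  }
  for (f in c(fixed_diff_fraction, outgroup_diff_fraction)) {
    if (!is.numeric(f) || f < 0 || f > 1) {
      abort("fractions must lie in [0, 1].")
    }
  }
  if (length(ensure_positions) &&
      (any(ensure_positions < 1) || any(ensure_positions > chrom_length))) {
    abort("`ensure_positions` must fall inside the chromosome.")
  }

  with_seed(seed, {
    n <- rbinom(1, chrom_length, snp_density)
    pos <- sort(unique(c(
      sample.int(chrom_length, n),
      as.integer(ensure_positions)
    )))
    n <- length(pos)
    if (n == 0) {
      out <- tibble(
        pos = integer(), ref = character(), dark_allele = character(),
        light_allele = character(), outgroup_allele = character(),
        alt_allele = character(), fixed_diff = logical()
      )
      return(new_parental_genomes(out, chrom_length))
    }

    a1 <- sample(DNA_BASES, n, replace = TRUE)
    a2 <- vapply(a1, function(b) sample(setdiff(DNA_BASES, b), 1), character(1))
    fixed <- runif(n) < fixed_diff_fraction
    fixed[pos %in% ensure_positions] <- TRUE
    if (!is.null(ibd_regions) && nrow(ibd_regions)) {
      in_ibd <- rep(FALSE, n)
      for (i in seq_len(nrow(ibd_regions))) {
        in_ibd <- in_ibd | (pos >= ibd_regions$start[i] & pos <= ibd_regions$end[i])
      }
      fixed[in_ibd & !(pos %in% ensure_positions)] <- FALSE
    }

    dark <- a1
    light <- ifelse(fixed, a2, a1)
    # reference genome is an independent strain: at fixed differences it
    # matches either parent with equal probability
    ref <- ifelse(fixed & runif(n) < 0.5, a2, a1)
    out_diff <- !fixed & (runif(n) < outgroup_diff_fraction)
    outgroup <- ifelse(out_diff, a2, ifelse(fixed & runif(n) < 0.5, a2, a1))

    out <- tibble(
      pos = as.integer(pos), ref = ref, dark_allele = dark,
      light_allele = light, outgroup_allele = outgroup,
      alt_allele = a2, fixed_diff = fixed
    )
    new_parental_genomes(out, chrom_length)
  })
}

new_parental_genomes <- function(tbl, chrom_length) {
  attr(tbl, "chrom_length") <- as.integer(chrom_length)
  class(tbl) <- c("parental_genomes", class(tbl))
  tbl
}

#' Count parental fixed differences per tiling window
#'
#' Tallies, for each non-overlapping window of `width` bases anchored at
#' coordinate 1, how many SNPs are fixed differences between the parental
#' lines. The per-window density `n_fixed / width` feeds the
#' identity-by-descent filter.
#'
#' @param parents A [simulate_parental_genomes()] table.
#' @param width Window width in bases.
#' @return Tibble with `window`, `start`, `end`, `n_sites`, `n_fixed`.
#' @export
window_fixed_diffs <- function(parents, width = 1e5) {
  if (width <= 0) abort("`width` must be positive.")
  chrom_length <- attr(parents, "chrom_length") %||% max(parents$pos, 1)
  n_win <- max(1L, ceiling(chrom_length / width))
  win <- pmin(((parents$pos - 1) %/% width) + 1L, n_win)
  fixed <- tapply(parents$fixed_diff, factor(win, levels = seq_len(n_win)), sum)
  fixed[is.na(fixed)] <- 0L
  tibble(
    window = seq_len(n_win),
    start = as.integer((seq_len(n_win) - 1L) * width + 1L),
    end = as.integer(pmin(seq_len(n_win) * width, chrom_length)),
    n_sites = as.integer(pmin(seq_len(n_win) * width, chrom_length) -
                           ((seq_len(n_win) - 1L) * width + 1L) + 1L),
    n_fixed = as.integer(fixed)
  )
}
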