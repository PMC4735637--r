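#' Simulate pooled sequencing of an ancestry truth track
#'
#' Emulates pooled whole-genome sequencing of a fly pool: per-site read depth
#' is Poisson with mean `mean_depth`, and the number of reads carrying the
#' dark parental allele is binomial with the pool's true dark-ancestry
#' fraction, perturbed by a symmetric per-read error rate that flips a read to
#' the site's other segregating allele.
#'
#' @param truth A [simulate_backcross()] `pool_truth`, or a tibble with `pos`
#'   and `truth` columns (true dark-allele frequency per site), or a single
#'   number recycled over all parental SNPs.
#' @param parents The [simulate_parental_genomes()] table the truth refers to
#'   (supplies the allele identities written into the counts).
#' @param mean_depth Mean sequencing depth (> 0).
#' @param error_rate Per-read probability of flipping to the alternative
#'   allele, in `[0, 0.5)`.
#' @param sample Sample name recorded in the output.
#' @param chrom Chromosome name recorded in the output.
#' @param seed Optional integer seed.
#' @return A tibble of pooled counts with columns `chrom`, `pos`, `ref`,
#'   `sample`, and per-base read counts `A`, `T`, `C`, `G`, `N`, `del`.
#' @examples
#' par <- simulate_parental_genomes(1e4, seed = 1)
#' cnt <- simulate_poolseq(0.5, par, mean_depth = 50, seed = 2)
#' head(cnt)
#' @export
simulate_poolseq <- function(truth, parents, mean_depth = 50,
                             error_rate = 0, sample = "pool",
                             chrom = "X", seed = NULL) {
  if (!is.numeric(mean_depth) || mean_depth <= 0) {
    abort("`mean_depth` must be > 0.")
  }
  if (!is.numeric(error_rate) || error_rate < 0 || error_rate >= 0.5) {
    abort("`error_rate` must lie in [0, 0.5).")
  }
  if (inherits(truth, "pool_truth")) truth <- truth$snp
  if (is.numeric(truth) && is.null(dim(truth))) {
    truth <- tibble(pos = parents$pos, truth = rep(truth, length.out = nrow(parents)))
  }
  tt <- dplyr::left_join(
    dplyr::select(as_tibble(parents), "pos", "ref",
                  a1 = "dark_allele", a2 = "alt_allele"),
    dplyr::select(as_tibble(truth), "pos", "truth"),
    by = "pos"
  )
  if (anyNA(tt$truth)) abort("`truth` does not cover all parental SNPs.")
  if (any(tt$truth < 0 | tt$truth > 1)) abort("truth fractions must lie in [0, 1].")

  with_seed(seed, {
    n <- nrow(tt)
    depth <- rpois(n, mean_depth)
    f <- tt$truth * (1 - error_rate) + (1 - tt$truth) * error_rate
    n_dark <- rbinom(n, depth, f)
    n_alt <- depth - n_dark

    counts <- matrix(0L, nrow = n, ncol = 6,
                     dimnames = list(NULL, c("A", "T", "C", "G", "N", "del")))
    for (b in DNA_BASES) {
      counts[, b] <- (tt$a1 == b) * n_dark + (tt$a2 == b) * n_alt
    }
    dplyr::bind_cols(
      tibble(chrom = chrom, pos = tt$pos, ref = tt$ref, sample = sample),
      as_tibble(counts)
    )
  })
}

# true dark-allele (a1) frequency of an inbred line or the outgroup genome
line_truth <- function(parents, line = c("dark", "light", "outgroup")) {
  line <- match.arg(line)
  al <- switch(line,
    dark = parents$dark_allele,
    light = parents$light_allele,
    outgroup = parents$outgroup_allele
  )
  tibble(pos = parents$pos, truth = as.numeric(al == parents$dark_allele))
}

#' Simulate a full introgression-mapping experiment
#'
#' Convenience wrapper reproducing the whole sequencing design of an
#' introgression-mapping study on one (scaled-down) X chromosome: two inbred
#' parental lines, a heterozygous backcross carrier pool (BC generation
#' `n_backcross`), a homozygous introgression line, and an outgroup genome,
#' all pool-sequenced to the requested depths. The causal site is always a
#' parental fixed difference.
#'
#' @param chrom_length Chromosome length in bases.
#' @param causal_position Causal-locus coordinate (default: centre of the
#'   window containing the midpoint).
#' @param snp_density,fixed_diff_fraction,outgroup_diff_fraction,ibd_regions
#'   Passed to [simulate_parental_genomes()].
#' @param n_backcross Backcross generations for the heterozygous pool.
#' @param n_backcross_hom Backcross generations behind the homozygous line.
#' @param pool_size Females per sequenced pool.
#' @param recombination_rate Morgans per megabase in female meiosis.
#' @param depths Named mean depths for samples `dark`, `light`, `bc`, `hom`,
#'   `outgroup`.
#' @param error_rate Symmetric per-read error rate.
#' @param chrom Chromosome name used in the counts.
#' @param seed Optional integer seed for the whole experiment.
#' @return A list of class `introgression_experiment`: `parents`, `truth_bc`,
#'   `truth_hom` (`pool_truth` objects), `counts` (one long tibble of pooled
#'   counts for the five samples), `causal_position` and the design objects.
#' @examples
#' \donttest{
#' exp <- simulate_experiment(chrom_length = 5e5, seed = 1)
#' dplyr::count(exp$counts, sample)
#' }
#' @export
simulate_experiment <- function(chrom_length = 2e6,
                                causal_position = NULL,
                                snp_density = 0.005,
                                fixed_diff_fraction = 0.5,
                                outgroup_diff_fraction = 0.6,
                                ibd_regions = NULL,
                                n_backcross = 7,
                                n_backcross_hom = 12,
                                pool_size = 30,
                                recombination_rate = 0.1,
                                depths = c(dark = 30, light = 17, bc = 44,
                                           hom = 80, outgroup = 21),
                                error_rate = 0,
                                chrom = "X",
                                seed = NULL) {
  if (is.null(causal_position)) {
    # centre of the 100-kb tiling window containing the chromosome midpoint
    w <- (chrom_length / 2 - 1) %/% 1e5
    causal_position <- floor(min(w * 1e5 + 5e4, chrom_length / 2))
  }
  with_seed(seed, {
    parents <- simulate_parental_genomes(
      chrom_length, snp_density, fixed_diff_fraction, outgroup_diff_fraction,
      ensure_positions = causal_position, ibd_regions = ibd_regions
    )
    des_bc <- cross_design(causal_position, n_backcross = n_backcross,
                           pool_size = pool_size,
                           recombination_rate = recombination_rate)
    des_hom <- cross_design(causal_position, n_backcross = n_backcross_hom,
                            pool_size = pool_size,
                            recombination_rate = recombination_rate,
                            homozygous = TRUE)
    truth_bc <- simulate_backcross(parents, des_bc)
    truth_hom <- simulate_backcross(parents, des_hom)

    counts <- dplyr::bind_rows(
      simulate_poolseq(line_truth(parents, "dark"), parents,
                       depths[["dark"]], error_rate, "dark", chrom),
      simulate_poolseq(line_truth(parents, "light"), parents,
                       depths[["light"]], error_rate, "light", chrom),
      simulate_poolseq(truth_bc, parents,
                       depths[["bc"]], error_rate, "bc", chrom),
      simulate_poolseq(truth_hom, parents,
                       depths[["hom"]], error_rate, "hom", chrom),
      simulate_poolseq(line_truth(parents, "outgroup"), parents,
                       depths[["outgroup"]], error_rate, "outgroup", chrom)
    )

    structure(
      list(
        parents = parents, truth_bc = truth_bc, truth_hom = truth_hom,
        counts = counts, causal_position = causal_position,
        design_bc = des_bc, design_hom = des_hom
      ),
      class = "introgression_experiment"
    )
  })
}
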