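#' Configuration of a balanced two-haplogroup locus
#'
#' Describes the simulated signature of an ancient balanced polymorphism: two
#' deeply diverged haplogroups (A and B) segregating at a locus, with
#' between-haplogroup divergence concentrated in a core interval and decaying
#' exponentially into the flanks, within-haplogroup diversity from shared
#' polymorphism, and an outgroup genome that is \emph{closer} to haplogroup A
#' than the haplogroups are to each other inside the core — the incomplete
#' lineage sorting signature of a trans-specific polymorphism.
#'
#' All divergence parameters are expected pairwise differences per site
#' (p-distances).
#'
#' @param locus_length Alignment length in bases.
#' @param core_start,core_end Core interval (1-based, inclusive) of the
#'   balanced polymorphism; defaults to a central 500-bp window.
#' @param n_per_group Haplotypes sampled per haplogroup.
#' @param between_divergence Core between-haplogroup divergence.
#' @param within_diversity Within-haplogroup pairwise diversity.
#' @param outgroup_divergence Divergence between haplogroup A and the
#'   outgroup; inside the core this should be below `between_divergence` to
#'   produce the lineage-sorting signature.
#' @param outgroup_divergence_b Divergence between haplogroup B and the
#'   outgroup inside the core (defaults to `between_divergence`).
#' @param flank_decay Distance (bases) over which the between-haplogroup
#'   excess decays to background outside the core.
#' @return A list of class `balanced_locus_config`.
#' @export
balanced_locus_config <- function(locus_length = 3000,
                                  core_start = NULL, core_end = NULL,
                                  n_per_group = 18,
                                  between_divergence = 0.07,
                                  within_diversity = 0.005,
                                  outgroup_divergence = 0.05,
                                  outgroup_divergence_b = between_divergence,
                                  flank_decay = 400) {
  if (locus_length < 10) abort("`locus_length` is too short.")
  if (is.null(core_start)) core_start <- max(1, floor(locus_length / 2) - 249)
  if (is.null(core_end)) core_end <- min(locus_length, core_start + 499)
  if (core_start < 1 || core_end > locus_length || core_start > core_end) {
    abort("core interval must lie inside the locus.")
  }
  if (n_per_group < 2) abort("`n_per_group` must be >= 2.")
  for (d in c(between_divergence, within_diversity, outgroup_divergence,
              outgroup_divergence_b)) {
    if (d < 0 || d > 0.6) abort("divergence parameters must lie in [0, 0.6].")
  }
  if (within_diversity > between_divergence) {
    abort("`within_diversity` cannot exceed `between_divergence`.")
  }
  if (flank_decay <= 0) abort("`flank_decay` must be positive.")
  cfg <- list(
    locus_length = as.integer(locus_length),
    core_start = as.integer(core_start), core_end = as.integer(core_end),
    n_per_group = as.integer(n_per_group),
    between_divergence = between_divergence,
    within_diversity = within_diversity,
    outgroup_divergence = outgroup_divergence,
    outgroup_divergence_b = outgroup_divergence_b,
    flank_decay = flank_decay
  )
  # feasibility of the mutation-class rates (checked at the core, where the
  # haplogroup-private rates are maximal)
  r <- locus_class_rates(cfg)
  if (min(r$rA_core, r$rB_core, r$rO_core) < -1e-12) {
    abort(paste0(
      "infeasible divergence configuration: haplogroup/outgroup rates ",
      "would be negative (require |outgroup_divergence - ",
      "outgroup_divergence_b| <= between_divergence - within_diversity ",
      "and outgroup distances large enough to reach)."
    ))
  }
  structure(cfg, class = "balanced_locus_config")
}

# Solve per-site mutation-class probabilities from the target p-distances.
# Classes: A-private fixed (derived in all of haplogroup A), B-private fixed,
# outgroup-private, and shared ingroup polymorphism (derived allele assigned
# hypergeometrically across the pooled ingroup).
locus_class_rates <- function(cfg) {
  m <- 2L * cfg$n_per_group
  k <- seq_len(m - 1)
  hbar <- mean(2 * k * (m - k) / (m * (m - 1)))  # E[pair diff | shared site]
  pS <- if (hbar > 0) cfg$within_diversity / hbar else 0
  o1 <- cfg$outgroup_divergence - pS / 2
  o2 <- cfg$outgroup_divergence_b - pS / 2
  excess <- cfg$between_divergence - cfg$within_diversity
  rA <- (excess + o1 - o2) / 2
  rB <- (excess + o2 - o1) / 2
  rO <- o1 - rA
  list(pS = pS, hbar = hbar, rA_core = rA, rB_core = rB, rO_core = rO,
       excess = excess, o1 = o1, o2 = o2)
}

#' Simulate a balanced-polymorphism haplotype alignment
#'
#' Places mutations on a fixed four-branch genealogy (haplogroup A crown,
#' haplogroup B crown, outgroup branch, plus shared ingroup polymorphism)
#' under an infinite-sites model, site by site. Inside the core interval the
#' haplogroup-private substitution rates reproduce the configured
#' between-haplogroup divergence; outside, they decay exponentially with
#' distance so the flanks are statistically exchangeable between haplogroups.
#' The outgroup's distance to haplogroup A is held constant along the locus,
#' so within the core the outgroup is closer to A than B is (incomplete
#' lineage sorting) while in the flanks it is the most distant sequence.
#'
#' @param config A [balanced_locus_config()].
#' @param seed Optional integer seed.
#' @param populations Optional population labels recycled across the ingroup
#'   haplotypes (default alternates `"pop1"`/`"pop2"`, mimicking sampling the
#'   same balanced polymorphism in two undifferentiated populations).
#' @return A [haplo_alignment] with ingroup ids `A01...`/`B01...`, an
#'   `outgroup` sequence, the core interval as `subregion`, and the true
#'   haplogroup labels in `attr(, "group_truth")`.
#' @examples
#' aln <- simulate_balanced_locus(balanced_locus_config(), seed = 3)
#' aln
#' @export
simulate_balanced_locus <- function(config = balanced_locus_config(),
                                    seed = NULL, populations = NULL) {
  stopifnot(inherits(config, "balanced_locus_config"))
  L <- config$locus_length
  nG <- config$n_per_group
  m <- 2L * nG
  rates <- locus_class_rates(config)

  pos <- seq_len(L)
  dist_core <- pmax(0, pmax(config$core_start - pos, pos - config$core_end))
  e <- exp(-dist_core / config$flank_decay)
  pA <- rates$rA_core * e
  pB <- rates$rB_core * e
  pO <- rates$o1 - pA          # keeps A-outgroup distance constant
  pS <- rep(rates$pS, L)

  with_seed(seed, {
    anc <- sample(DNA_BASES, L, replace = TRUE)
    der <- vapply(anc, function(b) sample(setdiff(DNA_BASES, b), 1), character(1))

    u <- runif(L)
    clA <- u < pA
    clB <- !clA & u < pA + pB
    clO <- !clA & !clB & u < pA + pB + pO
    clS <- !clA & !clB & !clO & u < pA + pB + pO + pS

    seqs <- matrix(rep(anc, each = m + 1), nrow = m + 1)
    idxA <- seq_len(nG)
    idxB <- nG + seq_len(nG)
    idxO <- m + 1L
    for (j in which(clA)) seqs[idxA, j] <- der[j]
    for (j in which(clB)) seqs[idxB, j] <- der[j]
    for (j in which(clO)) seqs[idxO, j] <- der[j]
    for (j in which(clS)) {
      kj <- sample.int(m - 1L, 1L)
      seqs[sample.int(m, kj), j] <- der[j]
    }

    ids <- c(sprintf("A%02d", seq_len(nG)), sprintf("B%02d", seq_len(nG)),
             "outgroup")
    if (is.null(populations)) populations <- c("pop1", "pop2")
    pops <- c(rep_len(populations, m), NA_character_)
    aln <- haplo_alignment(
      seqs, ids = ids, population = pops, outgroup = "outgroup",
      subregion = c(start = config$core_start, end = config$core_end)
    )
    attr(aln, "group_truth") <- setNames(
      c(rep("A", nG), rep("B", nG)), ids[seq_len(m)]
    )
    attr(aln, "config") <- config
    aln
  })
}
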