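#' Describe a backcross introgression design
#'
#' Parameters of the breeding scheme used to move a dominant "dark" allele
#' into a light genetic background: repeated backcrosses of carrier females to
#' light males with phenotypic selection each generation, on an X chromosome
#' that recombines only in females (males are achiasmatic, as in
#' \emph{Drosophila}, and hemizygous for the X).
#'
#' @param causal_position Base coordinate of the causal locus.
#' @param n_backcross Number of backcross generations (i.e. female meioses the
#'   introgressed chromosome has been through).
#' @param pool_size Number of females pooled for sequencing.
#' @param recombination_rate Expected crossovers per megabase per female
#'   meiosis (Morgans/Mb). The default 0.1 treats the simulated chromosome as
#'   a compressed stand-in for a whole chromosome arm, concentrating a
#'   realistic arm-scale genetic map onto the scaled-down physical length so
#'   that window-scale ancestry decay around the causal locus mirrors the
#'   resolution of a full-size mapping design.
#' @param homozygous If `TRUE`, the design describes an introgression line
#'   made homozygous for the dark causal allele by sibling intercross of
#'   carriers (all pool members then carry two carrier chromosomes); otherwise
#'   a heterozygous backcross pool (one carrier chromosome plus one light
#'   paternal X per female).
#' @param n_founders For a homozygous line, number of discrete founder
#'   haplotypes the pooled copies are drawn from. The default `NULL` draws an
#'   independent carrier haplotype per chromosome copy, approximating a line
#'   whose founder haplotypes have been decorrelated by recombination during
#'   maintenance; set a small integer to model a freshly founded line.
#' @param female_only_recombination Keep crossovers restricted to female
#'   meioses (the X-chromosome design; the only meioses that matter for the
#'   introgressed X are female ones). Provided as a toggle for generality;
#'   with `FALSE` the same Poisson model is used but the design is interpreted
#'   as autosomal-like, which does not change the carrier-lineage simulation.
#' @return A list of class `cross_design`.
#' @export
cross_design <- function(causal_position,
                         n_backcross = 7,
                         pool_size = 30,
                         recombination_rate = 0.1,
                         homozygous = FALSE,
                         n_founders = NULL,
                         female_only_recombination = TRUE) {
  if (!is.numeric(causal_position) || causal_position < 1) {
    abort("`causal_position` must be a positive coordinate.")
  }
  if (n_backcross < 1) abort("`n_backcross` must be >= 1.")
  if (pool_size < 1) abort("`pool_size` must be >= 1.")
  if (recombination_rate < 0) abort("`recombination_rate` must be >= 0.")
  structure(
    list(
      causal_position = as.numeric(causal_position),
      n_backcross = as.integer(n_backcross),
      pool_size = as.integer(pool_size),
      recombination_rate = as.numeric(recombination_rate),
      homozygous = isTRUE(homozygous),
      n_founders = if (is.null(n_founders)) NULL else as.integer(n_founders),
      female_only_recombination = isTRUE(female_only_recombination)
    ),
    class = "cross_design"
  )
}

# A chromosome copy is represented by its dark-ancestry intervals: a numeric
# matrix with columns start,end (1-based, inclusive, non-overlapping, sorted).
# The light parental X is the empty matrix.
empty_track <- function() matrix(numeric(0), ncol = 2,
                                 dimnames = list(NULL, c("start", "end")))
full_track <- function(L) matrix(c(1, L), ncol = 2,
                                 dimnames = list(NULL, c("start", "end")))

# is `pos` inside one of the dark intervals?
track_has <- function(track, pos) {
  if (!nrow(track)) return(FALSE)
  any(pos >= track[, 1] & pos <= track[, 2])
}

# dark indicator of a track at many sorted positions
track_indicator <- function(track, pos) {
  if (!nrow(track)) return(rep(0L, length(pos)))
  # flatten boundaries; odd interval index after findInterval => inside
  bounds <- as.vector(t(cbind(track[, 1], track[, 2] + 1)))
  as.integer(findInterval(pos, bounds) %% 2L == 1L)
}

# intersect a track with [a,b]
track_clip <- function(track, a, b) {
  if (!nrow(track)) return(track)
  s <- pmax(track[, 1], a)
  e <- pmin(track[, 2], b)
  keep <- s <= e
  cbind(start = s[keep], end = e[keep])
}

# one female meiosis between homologs ha/hb (dark-interval tracks) on a
# chromosome of length L: Poisson crossover count, uniform placement, no
# interference; returns the gamete's dark track
meiosis_gamete <- function(ha, hb, L, rate_per_mb) {
  k <- rpois(1, rate_per_mb * L / 1e6)
  cuts <- sort(runif(k, min = 1, max = L))
  bounds <- c(1, cuts, L + 1)
  phase <- (sample.int(2, 1) + seq_len(length(bounds) - 1)) %% 2
  segs <- lapply(seq_len(length(bounds) - 1), function(i) {
    src <- if (phase[i] == 0) ha else hb
    track_clip(src, bounds[i], bounds[i + 1] - 1e-9)
  })
  out <- do.call(rbind, segs)
  if (is.null(out) || !nrow(out)) return(empty_track())
  out <- out[order(out[, 1]), , drop = FALSE]
  # merge touching intervals
  merged <- out[1, , drop = FALSE]
  if (nrow(out) > 1) {
    for (i in 2:nrow(out)) {
      if (out[i, 1] <= merged[nrow(merged), 2] + 1e-6) {
        merged[nrow(merged), 2] <- max(merged[nrow(merged), 2], out[i, 2])
      } else {
        merged <- rbind(merged, out[i, , drop = FALSE])
      }
    }
  }
  merged
}

# simulate one carrier haplotype: n successive backcross meioses, each
# conditioned (by rejection) on transmitting the dark causal allele
carrier_haplotype <- function(L, causal, n_meioses, rate_per_mb,
                              max_tries = 1000) {
  hap <- full_track(L)
  for (g in seq_len(n_meioses)) {
    for (try in seq_len(max_tries)) {
      gam <- meiosis_gamete(hap, empty_track(), L, rate_per_mb)
      if (track_has(gam, causal)) break
      if (try == max_tries) {
        abort(paste0(
          "backcross simulation failed: no carrier gamete obtained in ",
          max_tries, " meioses at generation ", g,
          " (is `causal_position` inside the chromosome?)"
        ))
      }
    }
    hap <- gam
  }
  hap
}

#' Simulate a backcross introgression pool with ancestry truth
#'
#' Runs the carrier-female lineage of a backcross design through `n_backcross`
#' female meioses (Poisson crossovers, uniform placement, selection for the
#' dominant dark allele at the causal position every generation) and assembles
#' a sequencing pool. Heterozygous pools carry one recombinant carrier X and
#' one intact light paternal X per female; homozygous introgression lines
#' carry two carrier chromosomes (independent draws by default, or sampled
#' from a discrete founder set via `n_founders`).
#'
#' @param parents A [simulate_parental_genomes()] table (supplies the SNP
#'   positions and chromosome length).
#' @param design A [cross_design()].
#' @param seed Optional integer seed.
#' @return A list of class `pool_truth` with elements `snp` (tibble `pos`,
#'   `truth` = true dark-ancestry fraction of the pool at each SNP), `tracks`
#'   (tibble `individual`, `copy`, `start`, `end` of dark-ancestry segments)
#'   and the design.
#' @examples
#' par <- simulate_parental_genomes(2e5, seed = 1)
#' des <- cross_design(causal_position = 1e5, n_backcross = 3, pool_size = 5)
#' tr <- simulate_backcross(par, des, seed = 2)
#' tr$snp[which.min(abs(tr$snp$pos - 1e5)), ]
#' @export
simulate_backcross <- function(parents, design, seed = NULL) {
  stopifnot(inherits(design, "cross_design"))
  L <- attr(parents, "chrom_length")
  if (is.null(L)) abort("`parents` must carry a chrom_length attribute.")
  if (design$causal_position > L) {
    abort("`causal_position` lies outside the chromosome.")
  }
  pos <- parents$pos

  with_seed(seed, {
    n_pool <- design$pool_size
    copies <- vector("list", 2L * n_pool)
    if (design$homozygous) {
      if (is.null(design$n_founders)) {
        # copies decorrelated by recombination during line maintenance:
        # independent carrier draw per chromosome copy
        for (j in seq_len(2L * n_pool)) {
          copies[[j]] <- carrier_haplotype(
            L, design$causal_position, design$n_backcross,
            design$recombination_rate
          )
        }
      } else {
        founders <- lapply(seq_len(max(1L, design$n_founders)), function(i) {
          carrier_haplotype(L, design$causal_position, design$n_backcross,
                            design$recombination_rate)
        })
        for (i in seq_len(n_pool)) {
          copies[[2 * i - 1]] <- founders[[sample.int(length(founders), 1)]]
          copies[[2 * i]] <- founders[[sample.int(length(founders), 1)]]
        }
      }
    } else {
      for (i in seq_len(n_pool)) {
        copies[[2 * i - 1]] <- carrier_haplotype(
          L, design$causal_position, design$n_backcross,
          design$recombination_rate
        )
        copies[[2 * i]] <- empty_track() # light paternal X
      }
    }

    dark_counts <- rep(0L, length(pos))
    for (cp in copies) dark_counts <- dark_counts + track_indicator(cp, pos)
    truth <- dark_counts / (2 * n_pool)

    tracks <- purrr::map_dfr(seq_along(copies), function(j) {
      tr <- copies[[j]]
      if (!nrow(tr)) return(tibble())
      tibble(
        individual = as.integer(ceiling(j / 2)),
        copy = as.integer(2 - j %% 2),
        start = tr[, 1], end = tr[, 2]
      )
    })

    structure(
      list(
        snp = tibble(pos = pos, truth = truth),
        tracks = tracks,
        design = design,
        chrom_length = L
      ),
      class = "pool_truth"
    )
  })
}

#' Closed-form backcross ancestry expectation
#'
#' Expected dark-ancestry of the introgressed (carrier) chromosome after `n`
#' backcross meioses with selection on the causal allele, at a marker with
#' recombination fraction `r` from the causal locus: `(1 - r)^n`. With
#' `pool = TRUE` the value is halved, giving the expected pool ancestry
#' fraction of a heterozygous carrier pool (whose second X is always light).
#'
#' @param n Number of backcross meioses.
#' @param r Recombination fraction(s) in `[0, 0.5]`.
#' @param pool Return the heterozygous-pool fraction instead of the
#'   carrier-chromosome expectation.
#' @return Numeric vector of expectations.
#' @examples
#' backcross_expectation(7, 0)            # 1 at the causal site
#' backcross_expectation(7, 0.5)          # (1/2)^7 unlinked, carrier copy
#' backcross_expectation(7, 0, pool = TRUE) # 0.5: pool at the causal site
#' @export
backcross_expectation <- function(n, r, pool = FALSE) {
  if (any(r < 0 | r > 0.5)) abort("`r` must lie in [0, 0.5].")
  e <- (1 - r)^n
  if (pool) e / 2 else e
}

#' Recombination fraction from physical distance
#'
#' Haldane map function for a Poisson crossover process:
#' `r = (1 - exp(-2 d)) / 2` with `d` the map distance in Morgans
#' (`rate_per_mb * distance_bp / 1e6`).
#'
#' @param distance_bp Physical distance in bases.
#' @param rate_per_mb Morgans per megabase.
#' @return Recombination fraction(s).
#' @export
recombination_fraction <- function(distance_bp, rate_per_mb) {
  d <- rate_per_mb * abs(distance_bp) / 1e6
  (1 - exp(-2 * d)) / 2
}
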