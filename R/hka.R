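#' Classify SNPs as polymorphic or divergent
#'
#' Implements the site classification behind the HKA-like scan:
#' \itemize{
#'   \item \emph{polymorphic}: within-species Dxy between the two lines is
#'     greater than 0 (the lines do not share a fixed identical state);
#'   \item \emph{divergent}: Dxy equals 1 between both lines and the outgroup
#'     (both lines fixed for the same allele, outgroup fixed for the other);
#'   \item \emph{other}: everything else, including sites with a missing
#'     outgroup state (which can never be called divergent).
#' }
#'
#' @param p1,p2 Reference-allele frequencies of the two lines.
#' @param p_out Reference-allele frequency of the outgroup (may contain
#'   `NA`).
#' @return Factor with levels `polymorphic`, `divergent`, `other`.
#' @export
classify_sites <- function(p1, p2, p_out) {
  poly <- snp_dxy(p1, p2) > 0
  div <- !poly & !is.na(p_out) &
    snp_dxy(p1, p_out) == 1 & snp_dxy(p2, p_out) == 1
  cls <- rep("other", length(p1))
  cls[poly] <- "polymorphic"
  cls[div] <- "divergent"
  factor(cls, levels = c("polymorphic", "divergent", "other"))
}

#' Sliding-window HKA-like scan
#'
#' Along the classified SNPs (polymorphic and divergent only; `other` sites
#' are dropped before indexing), each SNP's window of `2 * half_width + 1`
#' classified SNPs is compared with the chromosome-wide
#' polymorphic/divergent proportions: expected counts are the window total
#' split by the chromosome-wide class proportions, and the statistic is the
#' Pearson chi-squared over the two classes with 1 degree of freedom. An
#' excess of polymorphism relative to divergence signals balancing
#' selection. Windows are truncated at the ends and flagged.
#'
#' @param classification Factor from [classify_sites()].
#' @param pos Positions parallel to `classification`.
#' @param half_width Classified SNPs on each side (default 50, i.e. 101-SNP
#'   windows).
#' @return Tibble over classified SNPs: `pos`, `n_poly`, `n_div`,
#'   `exp_poly`, `exp_div`, `chi2`, `p`, `truncated`, plus a
#'   Bonferroni-adjusted column `p_bonferroni` provided as a convenience.
#' @export
window_hka <- function(classification, pos, half_width = 50) {
  stopifnot(length(classification) == length(pos))
  keep <- classification %in% c("polymorphic", "divergent")
  cls <- classification[keep]
  pos <- pos[keep]
  n <- length(cls)
  if (!n || length(unique(cls)) < 2) {
    abort("need both polymorphic and divergent SNPs chromosome-wide.")
  }
  prop_poly <- mean(cls == "polymorphic")

  is_poly <- as.integer(cls == "polymorphic")
  idx <- seq_len(n)
  lo <- pmax(1L, idx - half_width)
  hi <- pmin(n, idx + half_width)
  cs <- c(0L, cumsum(is_poly))
  n_poly <- cs[hi + 1] - cs[lo]
  n_tot <- hi - lo + 1L
  n_div <- n_tot - n_poly
  e_poly <- n_tot * prop_poly
  e_div <- n_tot * (1 - prop_poly)
  chi2 <- (n_poly - e_poly)^2 / e_poly + (n_div - e_div)^2 / e_div
  p <- pchisq(chi2, df = 1, lower.tail = FALSE)
  tibble(
    pos = pos, n_poly = as.integer(n_poly), n_div = as.integer(n_div),
    exp_poly = e_poly, exp_div = e_div, chi2 = chi2, p = p,
    p_bonferroni = pmin(1, p * n),
    truncated = (hi - lo) < 2L * half_width
  )
}

#' Locus-level HKA contingency test
#'
#' 2x2 Pearson chi-squared test (1 df, no continuity correction) of the
#' polymorphic/divergent SNP tallies of a focal locus against a reference
#' locus. A significant excess of polymorphism at the focal locus relative to
#' its divergence is the classic signature of balancing selection.
#'
#' @param focal,reference Lists or one-row data frames with `n_polymorphic`
#'   and `n_divergent` counts (a `name` element is carried through if
#'   present).
#' @return A list of class `locus_hka`/`popgen_chisq` with `statistic`,
#'   `df`, `p.value`, the observed table and expected counts; `NA` statistic
#'   with a warning when a margin of the table is zero. Has
#'   [tidy()]/[glance()] methods.
#' @examples
#' locus_hka(list(n_polymorphic = 90, n_divergent = 10),
#'           list(n_polymorphic = 30, n_divergent = 30))
#' @export
locus_hka <- function(focal, reference) {
  obs <- rbind(
    c(focal$n_polymorphic, focal$n_divergent),
    c(reference$n_polymorphic, reference$n_divergent)
  )
  dimnames(obs) <- list(
    locus = c(focal$name %||% "focal", reference$name %||% "reference"),
    class = c("polymorphic", "divergent")
  )
  if (any(obs < 0)) abort("counts must be non-negative.")
  if (all(obs == 0)) abort("at least one count must be positive.")
  res <- list(observed = obs, df = 1L,
              method = "2x2 HKA contingency chi-squared (no continuity correction)")
  if (any(rowSums(obs) == 0) || any(colSums(obs) == 0)) {
    warn("a margin of the contingency table is zero: statistic undefined.")
    res$statistic <- NA_real_
    res$p.value <- NA_real_
    res$expected <- obs * NA_real_
  } else {
    e <- outer(rowSums(obs), colSums(obs)) / sum(obs)
    res$statistic <- sum((obs - e)^2 / e)
    res$p.value <- pchisq(res$statistic, df = 1, lower.tail = FALSE)
    res$expected <- e
  }
  structure(res, class = c("locus_hka", "popgen_chisq"))
}

#' Tally polymorphic and divergent sites per locus
#'
#' Convenience constructor of the per-locus counts consumed by
#' [locus_hka()], from a site classification.
#'
#' @param classification Factor from [classify_sites()].
#' @param name Locus name.
#' @param length Optional locus length in bases.
#' @return A list of class `locus_counts`.
#' @export
locus_counts <- function(classification, name = "locus", length = NULL) {
  structure(
    list(
      name = name,
      n_polymorphic = sum(classification == "polymorphic"),
      n_divergent = sum(classification == "divergent"),
      length = length
    ),
    class = "locus_counts"
  )
}
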