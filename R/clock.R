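#' Jukes–Cantor distance correction
#'
#' Corrects an observed p-distance for multiple hits under the one-parameter
#' substitution model: `d = -(3/4) log(1 - (4/3) p)`. Defined for `p < 0.75`;
#' saturated distances are an error. The corrected distance is never smaller
#' than the observed one.
#'
#' @param p Observed p-distance(s) in `[0, 0.75)`.
#' @return Corrected distance(s).
#' @examples
#' jc_correct(0.1)
#' @export
jc_correct <- function(p) {
  if (any(p < 0, na.rm = TRUE)) abort("p-distances must be >= 0.")
  if (any(p >= 0.75, na.rm = TRUE)) {
    abort("p-distance at or beyond 0.75: saturated under the JC model.")
  }
  -0.75 * log(1 - (4 / 3) * p)
}

#' Define a molecular-clock calibration
#'
#' A calibration anchors the clock at a split of known age: the mean
#' corrected distance between `clade1` and `clade2` is assigned
#' `age` (by default 11 million years, the age commonly used for the most
#' recent common ancestor of the melanogaster species subgroup).
#'
#' @param clade1,clade2 Character vectors of taxon ids on the two sides of
#'   the calibration split.
#' @param age Age of the calibration split (default 11, in millions of
#'   years; the unit propagates to the estimates).
#' @return A list of class `clock_calibration`.
#' @export
clock_calibration <- function(clade1, clade2, age = 11) {
  if (!length(clade1) || !length(clade2)) abort("calibration clades must be non-empty.")
  if (length(intersect(clade1, clade2))) abort("calibration clades must be disjoint.")
  if (!is.numeric(age) || age <= 0) abort("`age` must be positive.")
  structure(list(clade1 = clade1, clade2 = clade2, age = age),
            class = "clock_calibration")
}

# mean corrected between-clade distance from per-pair difference counts
clade_pair_index <- function(ids_a, ids_b) {
  expand.grid(a = ids_a, b = ids_b, stringsAsFactors = FALSE)
}

#' Date a clade split with a calibrated strict clock
#'
#' Distance-based divergence-time estimate: the age of the split between
#' `cladeA` and `cladeB` is the calibration age scaled by the ratio of mean
#' between-clade distances, `age = cal_age * d(A, B) / d(cal1, cal2)`, with
#' distances averaged over all between-clade sequence pairs and corrected
#' with [jc_correct()] (set `correct = FALSE` for raw p-distances).
#' Uncertainty comes from resampling alignment columns with replacement
#' (site bootstrap).
#'
#' @param aln A [haplo_alignment] containing all involved taxa.
#' @param cladeA,cladeB Taxon id sets for the split to date.
#' @param calibration A [clock_calibration()] whose taxa appear in `aln`.
#' @param n_boot Number of site bootstraps (default 1000).
#' @param correct Apply the Jukes–Cantor correction (default `TRUE`).
#' @param conf_level Bootstrap confidence level (default 0.95).
#' @param seed Optional integer seed for the bootstrap.
#' @return A list of class `clock_date`: `age`, `se`, `ci` (bootstrap
#'   percentile interval), `d_split`, `d_calibration`, `n_boot`,
#'   `calibration_age`. Has [tidy()]/[glance()] methods.
#' @export
date_split <- function(aln, cladeA, cladeB, calibration,
                       n_boot = 1000, correct = TRUE,
                       conf_level = 0.95, seed = NULL) {
  stopifnot(inherits(calibration, "clock_calibration"))
  all_ids <- unique(c(cladeA, cladeB, calibration$clade1, calibration$clade2))
  missing_ids <- setdiff(all_ids, aln$ids)
  if (length(missing_ids)) {
    abort(paste0("taxa absent from the alignment: ",
                 paste(missing_ids, collapse = ", ")))
  }
  pairs_split <- clade_pair_index(cladeA, cladeB)
  pairs_cal <- clade_pair_index(calibration$clade1, calibration$clade2)
  pairs <- rbind(pairs_split, pairs_cal)
  which_split <- seq_len(nrow(pairs_split))
  which_cal <- nrow(pairs_split) + seq_len(nrow(pairs_cal))
  dm <- pair_site_diffs(aln, pairs)

  mean_dist <- function(w) {
    nd <- rowSums(dm$diff)
    nc <- rowSums(dm$valid)
    p <- nd / nc
    if (correct) p <- jc_correct(p)
    mean(p[w])
  }
  dist_with_weights <- function(wt, w) {
    nd <- as.vector(dm$diff %*% wt)
    nc <- as.vector(dm$valid %*% wt)
    p <- ifelse(nc > 0, nd / nc, NA_real_)
    p <- pmin(p, 0.749999)
    if (correct) p <- jc_correct(p)
    mean(p[w], na.rm = TRUE)
  }

  d_split <- mean_dist(which_split)
  d_cal <- mean_dist(which_cal)
  if (!is.finite(d_cal) || d_cal <= 0) {
    abort("calibration distance is zero or undefined: cannot scale the clock.")
  }
  age <- calibration$age * d_split / d_cal

  L <- ncol(aln$seqs)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      wt <- tabulate(sample.int(L, L, replace = TRUE), nbins = L)
      dc <- dist_with_weights(wt, which_cal)
      if (!is.finite(dc) || dc <= 0) return(NA_real_)
      calibration$age * dist_with_weights(wt, which_split) / dc
    }, numeric(1))
  })
  boots <- boots[is.finite(boots)]
  alpha <- (1 - conf_level) / 2
  structure(
    list(
      age = age,
      se = if (length(boots) > 1) sd(boots) else NA_real_,
      ci = if (length(boots) > 1) unname(quantile(boots, c(alpha, 1 - alpha)))
           else c(NA_real_, NA_real_),
      d_split = d_split, d_calibration = d_cal,
      n_boot = length(boots), calibration_age = calibration$age,
      conf_level = conf_level
    ),
    class = "clock_date"
  )
}

#' @export
print.clock_date <- function(x, ...) {
  cat("<clock_date> age = ", format(x$age, digits = 4),
      " +/- ", format(x$se, digits = 3),
      "  (", round(100 * x$conf_level), "% CI ",
      format(x$ci[1], digits = 4), "-", format(x$ci[2], digits = 4),
      ", ", x$n_boot, " site bootstraps)\n", sep = "")
  invisible(x)
}

#' @rdname date_split
#' @param x A `clock_date` object.
#' @param ... Unused.
#' @export
tidy.clock_date <- function(x, ...) {
  tibble(
    age = x$age, std.error = x$se,
    conf.low = x$ci[1], conf.high = x$ci[2],
    d_split = x$d_split, d_calibration = x$d_calibration
  )
}

#' @rdname date_split
#' @export
glance.clock_date <- function(x, ...) {
  tibble(age = x$age, std.error = x$se, n_boot = x$n_boot,
         calibration_age = x$calibration_age)
}
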