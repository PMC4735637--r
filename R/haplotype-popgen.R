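#' Pairwise p-distances between aligned haplotypes
#'
#' Uncorrected p-distance (differences / compared sites) with pairwise
#' deletion: for each pair, sites where either sequence carries a gap or an
#' ambiguous character are dropped from both numerator and denominator. A
#' pair with zero comparable sites is an error.
#'
#' @param aln A [haplo_alignment()] (the outgroup, if any, is included in the
#'   matrix; downstream statistics decide whether to use it).
#' @param ids Optional subset of sequence ids.
#' @return A symmetric numeric matrix with zero diagonal.
#' @examples
#' aln <- haplo_alignment(c(a = "ACGT", b = "ACGA", c = "AC-T"))
#' pairwise_distances(aln)
#' @export
pairwise_distances <- function(aln, ids = NULL) {
  stopifnot(inherits(aln, "haplo_alignment"))
  ids <- ids %||% aln$ids
  m <- aln$seqs[ids, , drop = FALSE]
  n <- nrow(m)
  if (n < 2) abort("need at least two sequences.")
  ok <- matrix(is_base(m), nrow = n)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      comp <- ok[i, ] & ok[j, ]
      ns <- sum(comp)
      if (ns == 0) {
        abort(paste0("no comparable sites between '", ids[i], "' and '",
                     ids[j], "'."))
      }
      d[i, j] <- d[j, i] <- sum(m[i, comp] != m[j, comp]) / ns
    }
  }
  d
}

#' Neighbour-joining tree from a distance matrix
#'
#' Standard Saitou–Nei neighbour joining (via \pkg{ape}), with any negative
#' reconstructed branch lengths clamped to zero for interpretability. On an
#' additive distance matrix the generating tree and its branch lengths are
#' recovered exactly.
#'
#' @param d Symmetric distance matrix (>= 3 taxa) or a [haplo_alignment]
#'   (distances computed with [pairwise_distances()]).
#' @return An unrooted `phylo` tree.
#' @export
nj_tree <- function(d) {
  if (inherits(d, "haplo_alignment")) d <- pairwise_distances(d)
  d <- as.matrix(d)
  if (nrow(d) < 3) abort("neighbour joining needs at least 3 taxa.")
  if (any(!is.finite(d))) abort("distance matrix contains non-finite values.")
  tr <- ape::nj(stats::as.dist(d))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

# tips on the child side of edge k of an (unrooted) phylo tree
edge_split_tips <- function(tree, k) {
  child <- tree$edge[k, 2]
  n_tip <- length(tree$tip.label)
  # walk the edge list away from the parent side
  take <- child
  out <- integer(0)
  while (length(take)) {
    node <- take[1]
    take <- take[-1]
    if (node <= n_tip) {
      out <- c(out, node)
    } else {
      kids <- tree$edge[tree$edge[, 1] == node, 2]
      take <- c(take, kids)
    }
  }
  tree$tip.label[out]
}

#' Assign haplotypes to two haplogroups from a tree
#'
#' Splits the ingroup haplotypes into two groups at the longest internal
#' branch of their neighbour-joining tree (the bipartition that, under
#' midpoint logic, separates the two deepest clusters). Ties are broken
#' deterministically towards the earliest internal edge; the group containing
#' the lexicographically smallest id is labelled `"A"`.
#'
#' @param x A [haplo_alignment] (the outgroup is excluded and the tree built
#'   from ingroup p-distances), a `phylo` tree, or a distance matrix.
#' @return A list of class `haplogroup_assignment`: `groups` (named character
#'   vector of `"A"`/`"B"` per id) and `bipartition` (list of the two id
#'   sets).
#' @export
assign_haplogroups <- function(x) {
  if (inherits(x, "haplo_alignment")) {
    tree <- nj_tree(pairwise_distances(x, ids = ingroup_ids(x)))
  } else if (inherits(x, "phylo")) {
    tree <- x
  } else {
    tree <- nj_tree(x)
  }
  n_tip <- length(tree$tip.label)
  internal <- which(tree$edge[, 2] > n_tip)
  if (!length(internal) || max(tree$edge.length[internal]) <= 0) {
    abort("no haplogroup structure: the tree has no positive internal branch.")
  }
  best <- internal[which.max(tree$edge.length[internal])]
  side <- edge_split_tips(tree, best)
  other <- setdiff(tree$tip.label, side)
  sets <- list(side, other)
  has_min <- vapply(sets, function(s) min(s) == min(tree$tip.label), logical(1))
  a <- sets[[which(has_min)[1]]]
  b <- sets[[setdiff(1:2, which(has_min)[1])[1]]]
  groups <- setNames(
    ifelse(tree$tip.label %in% a, "A", "B"), tree$tip.label
  )[order(tree$tip.label)]
  structure(
    list(groups = groups, bipartition = list(A = sort(a), B = sort(b))),
    class = "haplogroup_assignment"
  )
}

#' @export
print.haplogroup_assignment <- function(x, ...) {
  cat("<haplogroup_assignment> A: ", length(x$bipartition$A),
      " sequences, B: ", length(x$bipartition$B), " sequences\n", sep = "")
  invisible(x)
}

# per-site allele frequencies of the two segregating alleles within a group
# of sequences; returns NULL for non-biallelic sites
site_group_freqs <- function(col, idx1, idx2) {
  c1 <- col[idx1]; c2 <- col[idx2]
  c1 <- c1[is_base(c1)]; c2 <- c2[is_base(c2)]
  alleles <- unique(c(c1, c2))
  if (length(alleles) != 2 || length(c1) < 2 || length(c2) < 2) return(NULL)
  list(
    p1 = mean(c1 == alleles[1]), p2 = mean(c2 == alleles[1]),
    n1 = length(c1), n2 = length(c2)
  )
}

#' Per-SNP Hudson FST between two haplogroups
#'
#' Hudson-type estimator `FST = 1 - Hw / Hb`, with `Hw` the mean of the two
#' unbiased within-group heterozygosities `2 p q n / (n - 1)` and
#' `Hb = p1 q2 + p2 q1` the between-group heterozygosity. Estimated at every
#' biallelic site with at least two called sequences per group; sites
#' monomorphic across both groups (Hb = 0) are returned as missing. Values
#' can be slightly negative in finite samples.
#'
#' @param aln A [haplo_alignment].
#' @param assignment A [assign_haplogroups()] result, or a named vector of
#'   `"A"`/`"B"` labels per ingroup id.
#' @return Tibble with `pos` (alignment column) and `fst` for each biallelic
#'   site.
#' @export
per_snp_fst <- function(aln, assignment) {
  groups <- assignment_groups(assignment)
  idx1 <- which(aln$ids %in% names(groups)[groups == "A"])
  idx2 <- which(aln$ids %in% names(groups)[groups == "B"])
  if (!length(idx1) || !length(idx2)) abort("both groups must be non-empty.")
  L <- ncol(aln$seqs)
  fst <- rep(NA_real_, L)
  usable <- logical(L)
  for (s in seq_len(L)) {
    fr <- site_group_freqs(aln$seqs[, s], idx1, idx2)
    if (is.null(fr)) next
    usable[s] <- TRUE
    fst[s] <- hudson_fst(fr$p1, fr$p2, fr$n1, fr$n2)
  }
  tibble(pos = which(usable), fst = fst[usable])
}

#' Hudson FST from group allele frequencies
#'
#' @param p1,p2 Frequency of the same allele in groups 1 and 2.
#' @param n1,n2 Number of sequences sampled per group.
#' @return FST value, or `NA` when the between-group heterozygosity is zero.
#' @export
hudson_fst <- function(p1, p2, n1, n2) {
  hw <- mean(c(
    2 * p1 * (1 - p1) * n1 / (n1 - 1),
    2 * p2 * (1 - p2) * n2 / (n2 - 1)
  ))
  hb <- p1 * (1 - p2) + p2 * (1 - p1)
  if (hb == 0) return(NA_real_)
  1 - hw / hb
}

assignment_groups <- function(assignment) {
  if (inherits(assignment, "haplogroup_assignment")) {
    assignment$groups
  } else {
    stopifnot(!is.null(names(assignment)))
    assignment
  }
}

#' Segregating sites and fixed differences between haplogroups
#'
#' Counts, across the ingroup haplotypes, the segregating sites (>= 2
#' unambiguous alleles) and the fixed differences between the two haplogroups
#' (each group monomorphic, for different alleles; gaps and ambiguities are
#' treated as missing data, never as differences). Every fixed difference is
#' by construction also a segregating site of the pooled ingroup.
#'
#' @param aln A [haplo_alignment].
#' @param assignment A [assign_haplogroups()] result or named label vector.
#' @param subregion Optional `c(start, end)` restricting the counts; defaults
#'   to the full alignment (use `aln$subregion` to restrict to the annotated
#'   interval).
#' @return A list with `n_segregating`, `n_fixed_differences`, and `sites`, a
#'   tibble of `pos`, `segregating`, `fixed` per variable site.
#' @export
site_counts <- function(aln, assignment, subregion = NULL) {
  groups <- assignment_groups(assignment)
  ing <- intersect(aln$ids, names(groups))
  idx1 <- which(aln$ids %in% names(groups)[groups == "A"])
  idx2 <- which(aln$ids %in% names(groups)[groups == "B"])
  cols <- seq_len(ncol(aln$seqs))
  if (!is.null(subregion)) cols <- cols[cols >= subregion[1] & cols <= subregion[2]]
  seg <- logical(length(cols))
  fix <- logical(length(cols))
  for (i in seq_along(cols)) {
    col <- aln$seqs[, cols[i]]
    c1 <- col[idx1][is_base(col[idx1])]
    c2 <- col[idx2][is_base(col[idx2])]
    all_b <- c(c1, c2)
    seg[i] <- length(unique(all_b)) >= 2
    fix[i] <- length(c1) > 0 && length(c2) > 0 &&
      length(unique(c1)) == 1 && length(unique(c2)) == 1 && c1[1] != c2[1]
  }
  keep <- seg | fix
  list(
    n_segregating = sum(seg),
    n_fixed_differences = sum(fix),
    sites = tibble(pos = cols[keep], segregating = seg[keep], fixed = fix[keep])
  )
}

#' Mean between-group divergence (Dxy) from an alignment
#'
#' Mean pairwise p-distance across all between-set sequence pairs.
#'
#' @param aln A [haplo_alignment].
#' @param set1,set2 Character vectors of sequence ids.
#' @return A single numeric value.
#' @export
group_dxy <- function(aln, set1, set2) {
  if (!length(set1) || !length(set2)) abort("both sets must be non-empty.")
  d <- pairwise_distances(aln, ids = unique(c(set1, set2)))
  mean(d[set1, set2, drop = FALSE])
}

#' Scan for incomplete lineage sorting along an alignment
#'
#' Slides a window along the alignment and flags windows where the divergence
#' between the two haplogroups exceeds the smaller of the two
#' haplogroup-to-outgroup divergences — i.e. where the within-species alleles
#' coalesce deeper than the species split. Flagged windows are merged into
#' intervals.
#'
#' @param aln A [haplo_alignment] with an outgroup.
#' @param assignment A [assign_haplogroups()] result or named label vector.
#' @param outgroup_id Outgroup sequence id (defaults to `aln$outgroup`).
#' @param window_bp,step_bp Window and step size in alignment columns. A
#'   window wider than the alignment collapses to one full-length window.
#' @return A tibble of merged intervals (`start`, `end`); the per-window
#'   statistics are attached as `attr(, "windows")`.
#' @export
ils_scan <- function(aln, assignment, outgroup_id = aln$outgroup,
                     window_bp = 500, step_bp = 100) {
  if (is.null(outgroup_id)) abort("an outgroup is required for the ILS scan.")
  groups <- assignment_groups(assignment)
  ids_a <- names(groups)[groups == "A"]
  ids_b <- names(groups)[groups == "B"]
  L <- ncol(aln$seqs)
  if (window_bp >= L) {
    starts <- 1L
    window_bp <- L
  } else {
    starts <- seq(1L, L - window_bp + 1L, by = step_bp)
  }

  pairs_ab <- expand.grid(a = ids_a, b = ids_b, stringsAsFactors = FALSE)
  pairs_ao <- data.frame(a = ids_a, b = outgroup_id)
  pairs_bo <- data.frame(a = ids_b, b = outgroup_id)
  dm <- pair_site_diffs(aln, rbind(pairs_ab, pairs_ao, pairs_bo))
  grp <- rep(c("ab", "ao", "bo"),
             c(nrow(pairs_ab), nrow(pairs_ao), nrow(pairs_bo)))

  win <- purrr::map_dfr(starts, function(s) {
    cols <- s:(min(L, s + window_bp - 1L))
    nd <- rowSums(dm$diff[, cols, drop = FALSE])
    nc <- rowSums(dm$valid[, cols, drop = FALSE])
    dist <- ifelse(nc > 0, nd / nc, NA_real_)
    tibble(
      start = s, end = max(cols),
      d_between = mean(dist[grp == "ab"], na.rm = TRUE),
      d_a_out = mean(dist[grp == "ao"], na.rm = TRUE),
      d_b_out = mean(dist[grp == "bo"], na.rm = TRUE)
    )
  })
  win$ils <- win$d_between > pmin(win$d_a_out, win$d_b_out)

  flagged <- win[which(win$ils), , drop = FALSE]
  intervals <- merge_intervals(flagged$start, flagged$end)
  attr(intervals, "windows") <- win
  intervals
}

# per-pair per-site difference and comparability indicators
pair_site_diffs <- function(aln, pairs) {
  m <- aln$seqs
  ok <- matrix(is_base(m), nrow = nrow(m), dimnames = dimnames(m))
  n_pairs <- nrow(pairs)
  L <- ncol(m)
  diff <- matrix(FALSE, n_pairs, L)
  valid <- matrix(FALSE, n_pairs, L)
  for (i in seq_len(n_pairs)) {
    a <- pairs[i, 1]; b <- pairs[i, 2]
    v <- ok[a, ] & ok[b, ]
    valid[i, ] <- v
    diff[i, v] <- m[a, v] != m[b, v]
  }
  list(diff = diff, valid = valid)
}

# merge possibly-overlapping sorted intervals
merge_intervals <- function(start, end) {
  if (!length(start)) return(tibble(start = integer(), end = integer()))
  o <- order(start)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  out_s <- c(); out_e <- c()
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me + 1) {
      me <- max(me, end[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- start[i]; me <- end[i]
    }
  }
  tibble(start = as.integer(c(out_s, ms)), end = as.integer(c(out_e, me)))
}
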