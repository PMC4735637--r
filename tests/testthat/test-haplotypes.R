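test_that("p-distances use pairwise deletion and match ape's raw distances", {
  aln <- haplo_alignment(c(a = "ACGT", b = "ACGA", c = "AC-T", d = "ACGT"))
  d <- pairwise_distances(aln)
  expect_equal(d["a", "b"], 0.25)
  expect_equal(d["a", "c"], 0)        # gap removed: 3 compared sites
  expect_equal(d["a", "d"], 0)
  expect_true(isSymmetric(d))

  set.seed(41)
  rand <- random_alignment(8, 200)
  d2 <- pairwise_distances(rand)
  oracle <- as.matrix(ape::dist.dna(
    ape::as.DNAbin(apply(rand$seqs, c(1, 2), tolower)),
    model = "raw", pairwise.deletion = TRUE
  ))
  expect_equal(d2, oracle[rownames(d2), colnames(d2)], tolerance = 1e-12)

  gappy <- haplo_alignment(c(x = "A---", y = "-CGT"))
  expect_error(pairwise_distances(gappy), "no comparable sites")
})

test_that("neighbour joining recovers additive trees exactly", {
  set.seed(42)
  for (n_taxa in c(4, 6, 10)) {
    tr <- ape::rtree(n_taxa, br = function(n) runif(n, 0.05, 1))
    tr <- ape::unroot(tr)
    d <- ape::cophenetic.phylo(tr)
    rec <- nj_tree(d)
    expect_equal(ape::dist.topo(tr, rec), setNames(0, "PH85"),
                 ignore_attr = TRUE)
    expect_equal(ape::cophenetic.phylo(rec)[rownames(d), colnames(d)], d,
                 tolerance = 1e-8)
  }
  expect_error(nj_tree(matrix(0, 2, 2)), "at least 3")
})

test_that("haplogroup assignment splits at the longest internal branch", {
  # additive toy: two tight clusters across one long branch
  d <- matrix(0.02, 6, 6,
              dimnames = list(letters[1:6], letters[1:6]))
  d[4:6, 1:3] <- d[1:3, 4:6] <- 0.5
  diag(d) <- 0
  asg <- assign_haplogroups(d)
  expect_setequal(asg$bipartition$A, c("a", "b", "c"))
  expect_setequal(asg$bipartition$B, c("d", "e", "f"))
  expect_identical(unname(asg$groups["a"]), "A")  # smallest id labels A

  # simulated haplogroups recovered up to label swap
  aln <- balanced_fixture(seed = 5)
  truth <- attr(aln, "group_truth")
  asg2 <- assign_haplogroups(aln)
  agree <- mean(asg2$groups[names(truth)] == truth)
  expect_true(agree %in% c(0, 1))

  flat <- haplo_alignment(c(a = "ACGT", b = "ACGT", c = "ACGT", d = "ACGT"))
  expect_error(assign_haplogroups(pairwise_distances(flat) * 0 + 0),
               "no haplogroup structure")
})

test_that("Hudson FST matches hand arithmetic and brackets fixed differences", {
  expect_equal(hudson_fst(1, 0, 10, 10), 1)
  expect_equal(hudson_fst(0.9, 0.1, 10, 10),
               1 - mean(c(2 * .9 * .1 * 10 / 9, 2 * .9 * .1 * 10 / 9)) / 0.82)
  expect_equal(hudson_fst(0.9, 0.1, 10, 10), 0.7561, tolerance = 1e-3)
  expect_true(is.na(hudson_fst(0, 0, 10, 10)))

  # fixed difference between groups scores exactly 1
  aln <- haplo_alignment(c(a1 = "AAAA", a2 = "AAAA", b1 = "TAAA", b2 = "TAAA"))
  groups <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  fst <- per_snp_fst(aln, groups)
  expect_equal(fst$fst[fst$pos == 1], 1)

  # panmictic pseudo-groups: mean FST near zero, may be slightly negative
  set.seed(43)
  vals <- purrr::map_dbl(1:10, function(i) {
    rand <- random_alignment(20, 300, bases = c("A", "T"))
    g <- setNames(rep(c("A", "B"), each = 10), rand$ids)
    mean(per_snp_fst(rand, g)$fst, na.rm = TRUE)
  })
  expect_lt(abs(mean(vals)), 0.03)
})

test_that("site counts enumerate segregating and fixed positions", {
  aln <- haplo_alignment(c(a1 = "AAA", a2 = "AAA", b1 = "TAT", b2 = "TAT"))
  groups <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  sc <- site_counts(aln, groups)
  expect_identical(sc$n_segregating, 2L)
  expect_identical(sc$n_fixed_differences, 2L)
  expect_identical(sc$sites$pos, c(1L, 3L))

  empty <- site_counts(
    haplo_alignment(c(a = "AAAA", b = "AAAA")), c(a = "A", b = "B")
  )
  expect_identical(empty$n_segregating, 0L)
  expect_identical(empty$n_fixed_differences, 0L)

  # gaps are missing data, not differences
  gap <- haplo_alignment(c(a1 = "A-A", a2 = "A-A", b1 = "A-A", b2 = "AAA"))
  sc2 <- site_counts(gap, groups)
  expect_identical(sc2$n_segregating, 0L)
  expect_identical(sc2$n_fixed_differences, 0L)

  # subregion restriction
  sc3 <- site_counts(aln, groups, subregion = c(2, 3))
  expect_identical(sc3$n_segregating, 1L)
})

test_that("planted mutations are recovered by the site counter", {
  aln <- balanced_fixture(seed = 7)
  truth <- attr(aln, "group_truth")
  sc <- site_counts(aln, truth)
  # brute-force recount from the sequences
  ing <- aln$seqs[names(truth), ]
  seg <- sum(apply(ing, 2, function(col) length(unique(col)) >= 2))
  expect_identical(sc$n_segregating, as.integer(seg))
  fixed <- sum(apply(aln$seqs, 2, function(col) {
    a <- unique(col[names(truth)[truth == "A"]])
    b <- unique(col[names(truth)[truth == "B"]])
    length(a) == 1 && length(b) == 1 && a != b
  }))
  expect_identical(sc$n_fixed_differences, as.integer(fixed))
  expect_true(sc$n_fixed_differences <= sc$n_segregating)
})

test_that("the ILS scan flags only the deeply coalescing core", {
  aln <- balanced_fixture(seed = 9)
  cfg <- attr(aln, "config")
  truth <- attr(aln, "group_truth")
  ivs <- ils_scan(aln, truth)
  expect_identical(nrow(ivs), 1L)
  expect_lt(ivs$start, cfg$core_end)
  expect_gt(ivs$end, cfg$core_start)

  # a locus that is all core aggregates into one full-length flagged window
  cfg_core <- balanced_locus_config(locus_length = 600, core_start = 1,
                                    core_end = 600)
  aln_core <- simulate_balanced_locus(cfg_core, seed = 11)
  whole <- ils_scan(aln_core, attr(aln_core, "group_truth"),
                    window_bp = 10 * cfg_core$locus_length)
  expect_identical(nrow(whole), 1L)
  expect_equal(c(whole$start, whole$end), c(1L, 600L))

  # outgroup uniformly farthest: no interval anywhere
  cfg2 <- balanced_locus_config(between_divergence = 0.03,
                                within_diversity = 0.005,
                                outgroup_divergence = 0.15,
                                outgroup_divergence_b = 0.15)
  aln2 <- simulate_balanced_locus(cfg2, seed = 10)
  ivs2 <- ils_scan(aln2, attr(aln2, "group_truth"))
  expect_identical(nrow(ivs2), 0L)
})
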