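test_that("zero within-group diversity collapses each haplogroup to one sequence", {
  aln <- balanced_fixture(seed = 1, within_diversity = 0)
  for (g in c("A", "B")) {
    ids <- group_ids(aln, g)
    d <- pairwise_distances(aln, ids = ids)
    expect_true(all(d == 0))
  }
})

test_that("core divergences recover the configuration within tolerance", {
  cfg <- balanced_locus_config()
  # average over seeds: one 500-site core carries sizeable sampling noise
  stats <- purrr::map_dfr(1:8, function(s) {
    aln <- simulate_balanced_locus(cfg, seed = s)
    ids_a <- group_ids(aln, "A")
    ids_b <- group_ids(aln, "B")
    core <- haplo_alignment(aln$seqs[, cfg$core_start:cfg$core_end],
                            ids = aln$ids)
    tibble::tibble(
      d_ab = group_dxy(core, ids_a, ids_b),
      d_ao = group_dxy(core, ids_a, "outgroup"),
      d_bo = group_dxy(core, ids_b, "outgroup"),
      within = mean(c(pairwise_distances(core, ids_a)[upper.tri(diag(18))],
                      pairwise_distances(core, ids_b)[upper.tri(diag(18))]))
    )
  })
  expect_lt(abs(mean(stats$d_ab) - cfg$between_divergence),
            0.1 * cfg$between_divergence)
  expect_lt(abs(mean(stats$d_ao) - cfg$outgroup_divergence),
            0.1 * cfg$outgroup_divergence)
  expect_lt(abs(mean(stats$d_bo) - cfg$outgroup_divergence_b),
            0.1 * cfg$outgroup_divergence_b)
  expect_lt(abs(mean(stats$within) - cfg$within_diversity),
            0.3 * cfg$within_diversity)
  # the lineage-sorting signature: outgroup closer to A than B is to A
  expect_true(all(stats$d_ao < stats$d_ab))
})

test_that("group Dxy from the module matches direct pairwise counting", {
  aln <- balanced_fixture(seed = 3)
  ids_a <- group_ids(aln, "A")
  ids_b <- group_ids(aln, "B")
  manual <- mean(outer(ids_a, ids_b, Vectorize(function(i, j) {
    brute_pdist(aln$seqs[i, ], aln$seqs[j, ])
  })))
  expect_equal(group_dxy(aln, ids_a, ids_b), manual)
})

test_that("exchangeable haplogroups show no differentiation", {
  cfg <- balanced_locus_config(between_divergence = 0.01,
                               within_diversity = 0.01,
                               outgroup_divergence = 0.05,
                               outgroup_divergence_b = 0.05)
  fsts <- purrr::map_dbl(1:6, function(s) {
    aln <- simulate_balanced_locus(cfg, seed = s)
    truth <- attr(aln, "group_truth")
    mean(per_snp_fst(aln, truth)$fst, na.rm = TRUE)
  })
  expect_lt(abs(mean(fsts)), 0.05)
})

test_that("flanks beyond the decay scale carry no haplogroup structure", {
  cfg <- balanced_locus_config(locus_length = 4000, core_start = 1750,
                               core_end = 2250, flank_decay = 200)
  aln <- simulate_balanced_locus(cfg, seed = 9)
  truth <- attr(aln, "group_truth")
  flank_cols <- c(1:800, 3201:4000)
  flank <- haplo_alignment(aln$seqs[, flank_cols], ids = aln$ids)
  fst <- per_snp_fst(flank, truth)
  expect_lt(mean(fst$fst, na.rm = TRUE), 0.15)
  # outgroup is the most distant sequence out there: no lineage sorting
  ids_a <- group_ids(aln, "A")
  ids_b <- group_ids(aln, "B")
  expect_gt(group_dxy(flank, ids_a, "outgroup"),
            group_dxy(flank, ids_a, ids_b))
})

test_that("misconfigured loci are rejected", {
  expect_error(balanced_locus_config(locus_length = 1000, core_start = 900,
                                     core_end = 1200), "inside the locus")
  expect_error(balanced_locus_config(within_diversity = 0.1,
                                     between_divergence = 0.05), "exceed")
  expect_error(balanced_locus_config(between_divergence = 0.01,
                                     within_diversity = 0.01,
                                     outgroup_divergence = 0.05,
                                     outgroup_divergence_b = 0.2),
               "infeasible")
})
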