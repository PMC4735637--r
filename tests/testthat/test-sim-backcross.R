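test_that("without recombination a heterozygous pool is exactly half dark", {
  par <- simulate_parental_genomes(2e5, snp_density = 0.002, seed = 1)
  des <- cross_design(causal_position = 1e5, n_backcross = 7, pool_size = 10,
                      recombination_rate = 0)
  tr <- simulate_backcross(par, des, seed = 2)
  expect_true(all(tr$snp$truth == 0.5))
})

test_that("selection pins the pool truth at the causal site", {
  par <- simulate_parental_genomes(5e5, snp_density = 0.002,
                                   ensure_positions = 2.5e5, seed = 3)
  des_het <- cross_design(2.5e5, n_backcross = 7, pool_size = 20,
                          recombination_rate = 0.5)
  des_hom <- cross_design(2.5e5, n_backcross = 12, pool_size = 20,
                          recombination_rate = 0.5, homozygous = TRUE)
  tr_het <- simulate_backcross(par, des_het, seed = 4)
  tr_hom <- simulate_backcross(par, des_hom, seed = 5)
  at_causal <- function(tr) tr$snp$truth[tr$snp$pos == 2.5e5]
  expect_identical(at_causal(tr_het), 0.5)
  expect_identical(at_causal(tr_hom), 1.0)
})

test_that("replicate means follow the closed-form carrier expectation", {
  # small chromosome with three marker SNPs: at the causal site, nearby, and
  # at a site made effectively unlinked by a huge map distance
  L <- 1e6
  causal <- 1e3
  near <- 101e3     # 100 kb away
  far <- 999e3
  rate <- 5         # Morgans/Mb so the far SNP is unlinked
  par <- simulate_parental_genomes(L, snp_density = 0,
                                   ensure_positions = c(causal, near, far),
                                   seed = 1)
  des <- cross_design(causal, n_backcross = 7, pool_size = 1,
                      recombination_rate = rate)
  set.seed(42)
  truths <- vapply(seq_len(600), function(i) {
    simulate_backcross(par, des)$snp$truth
  }, numeric(3))
  means <- rowMeans(truths)

  r_near <- recombination_fraction(near - causal, rate)
  exp_causal <- backcross_expectation(7, 0, pool = TRUE)           # 0.5
  exp_near <- backcross_expectation(7, r_near, pool = TRUE)
  exp_far <- backcross_expectation(7, 0.5, pool = TRUE)            # (1/2)^8
  # carrier-chromosome expectation at an unlinked site is (1/2)^7
  expect_equal(backcross_expectation(7, 0.5), 0.5^7)

  expect_identical(means[1], exp_causal)
  mc_se <- apply(truths, 1, stats::sd) / sqrt(ncol(truths))
  expect_lt(abs(means[2] - exp_near), 3 * mc_se[2])
  expect_lt(abs(means[3] - exp_far), 3 * mc_se[3] + 1e-3)
})

test_that("an impossible design fails with a diagnostic", {
  par <- simulate_parental_genomes(1e5, snp_density = 0.001, seed = 1)
  des <- cross_design(5e4, n_backcross = 2, pool_size = 2)
  des$causal_position <- 2e5
  expect_error(simulate_backcross(par, des, seed = 1),
               "outside the chromosome")
})

test_that("pool truth is conserved and tracks partition into [0,1] fractions", {
  par <- simulate_parental_genomes(4e5, snp_density = 0.005, seed = 6)
  des <- cross_design(2e5, n_backcross = 5, pool_size = 8,
                      recombination_rate = 0.3)
  tr <- simulate_backcross(par, des, seed = 7)
  expect_true(all(tr$snp$truth >= 0 & tr$snp$truth <= 1))
  # recompute the truth fraction from the emitted ancestry tracks
  manual <- vapply(tr$snp$pos, function(p) {
    covered <- sum(tr$tracks$start <= p & tr$tracks$end >= p)
    covered / (2 * des$pool_size)
  }, numeric(1))
  expect_equal(tr$snp$truth, manual)
})
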