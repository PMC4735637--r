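test_that("site classes follow the Dxy rules", {
  cls <- classify_sites(
    p1 = c(1, 1, 1, 0.6, 1, 0),
    p2 = c(0, 1, 1, 0.6, 1, 0),
    p_out = c(1, 0, 1, 1, NA, 1)
  )
  expect_equal(as.character(cls),
               c("polymorphic",  # lines differ, outgroup irrelevant
                 "divergent",    # lines fixed same, outgroup opposite
                 "other",        # all three identical
                 "polymorphic",  # segregating in both lines: Dxy > 0
                 "other",        # outgroup missing, lines identical
                 "divergent"))
})

test_that("windowed HKA chi-squared matches the hand-computed contingency", {
  # chromosome-wide 50/50 mix; a window of 101 with 80 polymorphic
  cls <- factor(rep(c("polymorphic", "divergent"), 2000),
                levels = c("polymorphic", "divergent", "other"))
  res <- window_hka(cls, seq_along(cls), half_width = 50)
  i <- 2000
  expect_equal(res$exp_poly[i] + res$exp_div[i], 101)
  expect_equal(res$chi2[i], 0, tolerance = 1e-2)

  # direct evaluation of the statistic the scan should produce
  o <- c(80, 21); e <- c(50.5, 50.5)
  chi2 <- sum((o - e)^2 / e)
  expect_equal(chi2, 34.46535, tolerance = 1e-5)
  expect_equal(pchisq(chi2, 1, lower.tail = FALSE), 4.33e-9, tolerance = 1e-2)

  expect_error(window_hka(factor(rep("polymorphic", 10),
                                 levels = levels(cls)), 1:10),
               "both polymorphic and divergent")
})

test_that("windowed statistics equal brute-force recomputation of the slice", {
  set.seed(31)
  cls <- factor(sample(c("polymorphic", "divergent", "other"), 500,
                       replace = TRUE, prob = c(0.45, 0.35, 0.2)),
                levels = c("polymorphic", "divergent", "other"))
  pos <- sort(sample.int(1e5, 500))
  hw <- 20
  res <- window_hka(cls, pos, half_width = hw)
  keep <- cls %in% c("polymorphic", "divergent")
  cls2 <- cls[keep]
  prop <- mean(cls2 == "polymorphic")
  for (i in sample.int(length(cls2), 25)) {
    sl <- cls2[max(1, i - hw):min(length(cls2), i + hw)]
    o <- c(sum(sl == "polymorphic"), sum(sl == "divergent"))
    e <- length(sl) * c(prop, 1 - prop)
    expect_equal(res$chi2[i], sum((o - e)^2 / e))
    expect_equal(res$n_poly[i] + res$n_div[i], length(sl))
  }
})

test_that("locus-level HKA is a plain 2x2 chi-squared without correction", {
  same <- locus_hka(list(n_polymorphic = 40, n_divergent = 20),
                    list(n_polymorphic = 20, n_divergent = 10))
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)

  res <- locus_hka(list(n_polymorphic = 90, n_divergent = 10),
                   list(n_polymorphic = 30, n_divergent = 30))
  oracle <- suppressWarnings(
    stats::chisq.test(rbind(c(90, 10), c(30, 30)), correct = FALSE)
  )
  expect_equal(res$statistic, unname(oracle$statistic))
  expect_equal(res$statistic, 32)        # frozen from the oracle
  expect_equal(res$p.value, unname(oracle$p.value))

  swapped <- locus_hka(list(n_polymorphic = 30, n_divergent = 30),
                       list(n_polymorphic = 90, n_divergent = 10))
  expect_equal(swapped$statistic, res$statistic)

  expect_warning(
    zero <- locus_hka(list(n_polymorphic = 0, n_divergent = 0),
                      list(n_polymorphic = 5, n_divergent = 5)),
    "margin"
  )
  expect_true(is.na(zero$statistic))
  expect_equal(tidy(res)$p.value, res$p.value)
})

test_that("locus tallies count classified sites", {
  cls <- classify_sites(c(1, 1, 0), c(0, 1, 0), c(1, 0, 1))
  lc <- locus_counts(cls, name = "focal")
  expect_identical(lc$n_polymorphic, 1L)
  expect_identical(lc$n_divergent, 2L)
})
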