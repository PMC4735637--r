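test_that("diagnostic-SNP predicate follows the fixed-difference rules", {
  counts <- make_counts(
    pos = 1:4, ref = c("A", "A", "A", "A"),
    dark = cnt(10, 0, 0, 0, 0, 0,    # fixed A, depth 10
               9, 0, 0, 0, 0, 0,     # fixed A but depth 9 < 10
               10, 2, 0, 0, 0, 0,    # not fixed in dark
               12, 0, 0, 0, 0, 0),
    light = cnt(0, 10, 0, 0, 0, 0,   # fixed T: diagnostic
                0, 20, 0, 0, 0, 0,
                0, 12, 0, 0, 0, 0,
                6, 6, 0, 0, 0, 0)    # dark allele present in light
  )
  diag <- call_diagnostic_snps(counts, "dark", "light", min_count = 10)
  expect_identical(diag$pos, 1L)
  expect_identical(diag$dark_allele, "A")
  expect_identical(diag$light_allele, "T")
})

test_that("the minimum-count filter applies to every line, pools included", {
  counts <- make_counts(
    pos = 1:2, ref = c("A", "A"),
    dark = cnt(20, 0, 0, 0, 0, 0, 20, 0, 0, 0, 0, 0),
    light = cnt(0, 20, 0, 0, 0, 0, 0, 20, 0, 0, 0, 0),
    bc = cnt(5, 5, 0, 0, 0, 0, 2, 3, 0, 0, 0, 0)  # site 2 depth 5 < 10
  )
  diag <- call_diagnostic_snps(counts, "dark", "light", min_count = 10)
  expect_identical(diag$pos, 1L)
})

test_that("ancestry proportions are dark reads over depth, missing at zero depth", {
  diag <- tibble::tibble(chrom = "X", pos = c(1L, 2L, 3L),
                         dark_allele = "A", light_allele = "T")
  counts <- make_counts(
    pos = 1:3, ref = "A",
    bc = cnt(25, 25, 0, 0, 0, 0,
             50, 0, 0, 0, 0, 0,
             0, 0, 0, 0, 0, 0)
  )
  anc <- snp_ancestry(counts, diag, "bc")
  expect_equal(anc$ancestry, c(0.5, 1.0, NA_real_))
  expect_error(snp_ancestry(counts, diag[0, ], "bc"), "empty")
})

test_that("tiling window means equal brute-force grouping", {
  w <- window_average(tibble::tibble(pos = c(10, 20), value = c(0.4, 0.6)),
                      value = "value", width = 100)
  expect_identical(nrow(w), 1L)
  expect_equal(w$mean, 0.5)

  set.seed(11)
  pos <- sort(sample.int(1e6, 501))
  vals <- runif(501)
  win <- window_average(tibble::tibble(pos = pos, value = vals),
                        value = "value", width = 1e5, chrom_length = 1e6)
  manual <- vapply(seq_len(10), function(k) {
    sel <- pos > (k - 1) * 1e5 & pos <= k * 1e5
    if (!any(sel)) NA_real_ else mean(vals[sel])
  }, numeric(1))
  expect_equal(win$mean, manual)
  # empty windows are missing, never zero
  empty <- window_average(tibble::tibble(pos = 250001, value = 1),
                          value = "value", width = 1e5, chrom_length = 4e5)
  expect_true(is.na(empty$mean[1]) && is.na(empty$mean[2]) &&
                is.na(empty$mean[4]))
  expect_error(window_average(tibble::tibble(pos = 1, value = 1),
                              value = "value", width = 0), "positive")
})

test_that("IBD filter is strict below one fixed difference per kilobase", {
  expect_identical(ibd_filter(c(99, 100, 0), 1e5), c(TRUE, FALSE, TRUE))
  expect_error(ibd_filter(1, 0), "positive")
})

test_that("combined window scores and candidate calling follow the 75% rule", {
  mk <- function(means) tibble::tibble(
    window = seq_along(means), start = (seq_along(means) - 1) * 1e5 + 1,
    end = seq_along(means) * 1e5, n_snps = 10L, mean = means
  )
  cand <- candidate_windows(mk(c(0.5, 0.5, 0.5)), mk(c(1.0, 0.5, 1.0)),
                            excluded = c(FALSE, FALSE, TRUE))
  expect_equal(cand$combined, c(0.75, 0.5, NA_real_))
  expect_identical(cand$candidate, c(TRUE, FALSE, FALSE))
  expect_identical(cand$rank[1], 1L)
  # excluded windows carry no combined score even when their means conform
  expect_true(is.na(cand$combined[3]))
  expect_warning(candidate_windows(mk(0.2), mk(0.2)), "no candidate")

  ivs <- candidate_intervals(candidate_windows(
    mk(c(0.52, 0.5, 0.2, 0.5, 0.48)), mk(c(1.0, 0.98, 0.2, 1.0, 1.0))
  ))
  expect_identical(nrow(ivs), 2L)   # run broken by the low window
  expect_identical(ivs$rank, 1:2)
})

test_that("1:1 segregation chi-squared matches the closed form", {
  even <- segregation_test(100, 100)
  expect_equal(even$statistic, 0)
  expect_equal(even$p.value, 1)

  skewed <- segregation_test(150, 50)
  expect_equal(skewed$statistic, 50)
  expect_equal(skewed$p.value, pchisq(50, 1, lower.tail = FALSE))
  expect_lt(skewed$p.value, 2e-12)

  td <- tidy(segregation_test(680, 645))
  expect_equal(td$statistic, (680 - 662.5)^2 / 662.5 * 2)
  expect_error(segregation_test(-1, 5), "non-negative")
  expect_error(segregation_test(0, 0), "zero")
})
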