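test_that("degenerate tracks yield no peaks", {
  expect_equal(nrow(call_peaks(toy_track(rep(3, 50)))), 0)   # all equal
  expect_error(call_peaks(toy_track(rep(1, 10)), percentile = 0), "percentile")
  expect_error(call_peaks(toy_track(rep(1, 10)), percentile = 100),
               "percentile")
})

test_that("the percentile threshold is interpolated over all bins", {
  # 100 bins, three consecutive bins at 100: the 98th percentile of
  # 97 zeros + 3 x 100 is already 100, so nothing exceeds it strictly
  score <- numeric(100)
  score[11:13] <- 100
  tr <- toy_track(score)
  p98 <- call_peaks(tr, percentile = 98)
  expect_equal(attr(p98, "threshold"), oracle_percentile(score, 98))
  expect_equal(attr(p98, "threshold"), 100)
  expect_equal(nrow(p98), 0)
  # at the 90th percentile the threshold interpolates to 0 and the run of
  # three bins becomes one peak spanning bins 10-12 (0-based)
  p90 <- call_peaks(tr, percentile = 90)
  expect_equal(attr(p90, "threshold"), 0)
  expect_equal(nrow(p90), 1)
  expect_equal(p90$start, 10 * 150)
  expect_equal(p90$end, 13 * 150)
  expect_equal(p90$n_bins, 3L)
})

test_that("caller output equals the brute-force oracle on random tracks", {
  set.seed(19)
  for (rep in 1:200) {
    n <- sample(50:400, 1)
    score <- rpois(n, 2) * rbinom(n, 1, 0.7) + rexp(n, 1 / 3) * rbinom(n, 1, 0.05)
    tr <- toy_track(score)
    pct <- sample(c(80, 90, 95, 98), 1)
    got <- call_peaks(tr, percentile = pct)
    want <- oracle_peaks(score, 150L, "chrT", n * 150L, percentile = pct)
    expect_identical(plain_df(got), plain_df(want))
  }
})

test_that("peaks are disjoint, sorted, maximal and above threshold", {
  set.seed(4)
  score <- rexp(2000, 1 / 2) * rbinom(2000, 1, 0.3)
  tr <- toy_track(score)
  pk <- call_peaks(tr, percentile = 90)
  expect_gt(nrow(pk), 0)
  t <- attr(pk, "threshold")
  expect_true(all(pk$start[-1] >= pk$end[-nrow(pk)]))    # sorted, disjoint
  expect_true(all(pk$n_bins >= 2))
  for (i in seq_len(nrow(pk))) {
    k <- (pk$start[i] / 150 + 1):(pk$end[i] / 150)
    expect_true(all(score[k] > t))                       # all bins above
    if (min(k) > 1) expect_lte(score[min(k) - 1], t)     # maximal
    if (max(k) < length(score)) expect_lte(score[max(k) + 1], t)
  }
})

test_that("raising the percentile never increases peak base pairs", {
  set.seed(23)
  for (rep in 1:20) {
    tr <- toy_track(rexp(500, 1 / 2) * rbinom(500, 1, 0.4))
    bp <- vapply(c(80, 90, 95, 98, 99), function(p) {
      pk <- call_peaks(tr, percentile = p)
      sum(pk$end - pk$start)
    }, numeric(1))
    expect_true(all(diff(bp) <= 0))
  }
})

test_that("overlap statistics match the all-pairs oracle", {
  set.seed(31)
  a <- random_intervals(60, 5e5)
  ov <- overlap_peaks(a, a)
  expect_equal(ov$frac_a_overlap, 1)
  expect_equal(ov$frac_b_overlap, 1)

  b <- data.table::copy(a)
  b$start <- b$start + 1e6
  b$end <- b$end + 1e6
  ov <- overlap_peaks(a, b)
  expect_equal(ov$n_a_overlap, 0)
  expect_equal(ov$n_b_overlap, 0)

  for (rep in 1:10) {
    x <- random_intervals(sample(10:80, 1), 2e5)
    y <- random_intervals(sample(10:80, 1), 2e5)
    got <- overlap_peaks(x, y)
    want <- oracle_overlap(x, y)
    expect_equal(got$n_a_overlap, unname(want["n_a_overlap"]))
    expect_equal(got$n_b_overlap, unname(want["n_b_overlap"]))
    expect_equal(got$n_a_only, got$n_a - got$n_a_overlap)
  }
})

test_that("peak density is peaks per megabase per chromosome", {
  sizes <- c(chr1 = 5e6, chr2 = 2e6)
  pk <- data.table::data.table(chrom = rep("chr1", 10),
                               start = seq(0, 9) * 1e5,
                               end = seq(0, 9) * 1e5 + 300)
  d <- peak_density(pk, sizes)
  expect_equal(d$peaks_per_mb, c(2, 0))
  empty <- pk[0, ]
  expect_equal(peak_density(empty, sizes)$peaks_per_mb, c(0, 0))
})
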