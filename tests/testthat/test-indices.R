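test_that("variability is the sample SD with its closed-form cases", {
  expect_equal(variability(rep(0, 10)), 0)
  expect_equal(variability(c(-0.02, 0, 0.02)), 0.02)
  expect_error(variability(0.5), "at least 2")

  set.seed(4)
  x <- rnorm(50)
  for (c_ in c(-3, 0.5, 2)) {
    expect_equal(variability(c_ * x), abs(c_) * variability(x))
  }
  # permutation invariance
  expect_equal(variability(sample(x)), variability(x))
  # robust alternative
  expect_equal(variability(x, estimator = "iqr"), stats::IQR(x))
})

test_that("exact KS statistic matches brute-force sup and stats::ks.test", {
  # two-point sample vs standard normal: D = |0.5 - pnorm(-1)|
  expect_equal(ks_statistic_exact(c(-1, 1)), 0.5 - pnorm(-1))
  expect_equal(round(ks_statistic_exact(c(-1, 1)), 4), 0.3413)

  # mid-quantile samples achieve the minimal sup 0.5/n
  for (n in c(5, 20, 100)) {
    x <- qnorm((seq_len(n) - 0.5) / n)
    expect_equal(ks_statistic_exact(x), 0.5 / n)
  }

  # independent oracle: base R's one-sample KS statistic
  set.seed(10)
  for (k in 1:50) {
    x <- rnorm(sample(10:200, 1), sample(-1:1, 1), runif(1, 0.5, 2))
    expect_equal(ks_statistic_exact(x),
                 unname(stats::ks.test(x, "pnorm")$statistic))
  }
  expect_error(ks_statistic_exact(numeric(0)), "empty")
})

test_that("fast KS estimator honors its 1/grid_size error bound", {
  set.seed(21)
  for (k in 1:100) {
    n <- sample(70:300, 1)
    x <- switch(k %% 3 + 1,
                rnorm(n),
                runif(n, -2, 2),
                c(rnorm(ceiling(n / 2), -1.2, 0.4),
                  rnorm(floor(n / 2), 1.2, 0.4)))
    D <- ks_statistic_exact(x)
    for (g in c(8, 16, 32, 64, 128)) {
      Df <- ks_statistic_fast(x, grid_size = g)
      expect_lte(abs(Df - D), 1 / g)
      expect_lte(Df, D + 1e-12)   # binning can only miss mass of the sup
    }
  }
})

test_that("fast KS works from a CDF alone via numeric inversion", {
  set.seed(2)
  x <- rnorm(150)
  expect_equal(ks_statistic_fast(x, reference_quantile = NULL,
                                 reference_cdf = pnorm, grid_size = 32),
               ks_statistic_fast(x, grid_size = 32), tolerance = 1e-7)
})

test_that("normality behaves as a bounded goodness-of-normality index", {
  expect_equal(normality(rep(0.8, 20)), 0)      # degenerate rule
  expect_error(normality(rnorm(5)), "at least 8")

  set.seed(33)
  meds <- replicate(51, normality(rnorm(150)))
  expect_gte(median(meds), 0.9)

  # strict two-point alternation (bigeminy-like MESC): far from normal
  alt <- rep(c(-0.5, 0.5), 75)
  expect_lte(normality(alt), 0.7)
  expect_equal(1 - ks_statistic_exact(scale(alt)[, 1]), 0.5 + pnorm(-1),
               tolerance = 0.01)

  # affine invariance and permutation invariance
  x <- rnorm(150)
  expect_equal(normality(3.2 * x - 5), normality(x))
  expect_equal(normality(sample(x)), normality(x))
  for (i in 1:20) {
    expect_gte(normality(rnorm(sample(8:60, 1))), 0)
    expect_lte(normality(rnorm(sample(8:60, 1))), 1)
  }
})

test_that("mean index averages the order-0 MESC", {
  expect_equal(mean_index(c(0.8, 0.8, 0.8)), 0.8)
  expect_equal(mean_index(c(0.5, 1.0)), 0.75)
  expect_error(mean_index(numeric(0)), "empty")
})

test_that("compute_indices assembles labeled, ambiguity-free window tables", {
  rec <- single_rhythm_record("AF", n_beats = 450, seed = 9)
  tab <- compute_indices(rec$rr, rec$segments,
                         index_config(window_length = 150, stride = 150))
  expect_equal(nrow(tab), 3L)
  expect_equal(unique(tab$label), "AF")
  expect_named(tab, c("record_id", "window_start_beat", "window_end_beat",
                      "t_start", "t_end", "variability", "normality",
                      "mean_rr", "label"))
  expect_true(all(tab$variability >= 0))
  expect_true(all(tab$normality >= 0 & tab$normality <= 1))
  expect_true(all(tab$mean_rr > 0))

  # a mid-record rhythm switch removes the straddling windows
  rec2 <- gen_record(list(
    list(profile = rhythm_profile("NSR"), n_beats = 600),
    list(profile = rhythm_profile("AF"), n_beats = 600)), seed = 12)
  cfg <- index_config(window_length = 150, stride = 30)
  w_all <- make_windows(rec2$rr, 150, 30)
  w_lab <- label_windows(w_all, rec2$segments)
  tab2 <- compute_indices(rec2$rr, rec2$segments, cfg)
  expect_equal(nrow(tab2), sum(w_lab$label != "ambiguous"))
  expect_gt(sum(w_lab$label == "ambiguous"), 0)
  boundary <- rec2$segments$end[1]
  expect_true(all(tab2$t_start >= boundary - 1e-9 |
                    tab2$t_end <= boundary + 1e-9))
})

test_that("synthetic AF is wide and normal; bigeminy wide but non-normal", {
  af <- single_rhythm_record("AF", n_beats = 3000, seed = 41)
  nsr <- single_rhythm_record("NSR", n_beats = 3000, seed = 42)
  big <- single_rhythm_record("bigeminy", n_beats = 3000, seed = 43)
  t_af <- compute_indices(af$rr, af$segments)
  t_nsr <- compute_indices(nsr$rr, nsr$segments)
  t_big <- compute_indices(big$rr, big$segments)
  expect_gte(median(t_af$normality), 0.9)
  expect_gt(median(t_af$variability), 3 * median(t_nsr$variability))
  expect_lte(median(t_big$normality), 0.7)
  expect_gt(median(t_big$variability), 3 * median(t_nsr$variability))
  expect_lt(median(t_af$mean_rr), median(t_nsr$mean_rr))  # AF tachycardic
})
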