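test_that("the AF generator writes its MESC sd onto the order-1 MESC", {
  v <- gen_segment(rhythm_profile("AF", mesc_sd = 0.08), 2000, seed = 6)
  m1 <- diff(v)
  expect_lt(abs(sd(m1) - 0.08) / 0.08, 0.10)   # within 10% by construction
  expect_true(all(v >= 0.25 & v <= 2.5))       # physiologic clip bounds
})

test_that("zero-jitter bigeminy alternates exactly and fixes the variability", {
  v <- gen_segment(rhythm_profile("bigeminy", jitter_sd = 0), 150, seed = 1)
  expect_equal(unique(v), c(0.5, 1.0))
  m1 <- diff(v)
  expect_true(all(abs(m1) == 0.5))
  expect_true(all(m1[seq(1, length(m1), 2)] == m1[1]))  # strict alternation
  n <- length(m1)
  # closed form for a +/-0.5 alternation (parity decides the imbalance)
  expected <- if (n %% 2 == 0) 0.5 * sqrt(n / (n - 1)) else
    0.5 * sqrt((n + 1) / n)
  expect_equal(variability(m1), expected, tolerance = 1e-12)
  expect_equal(variability(m1), 0.5, tolerance = 0.01)
})

test_that("degenerate sinus rhythm collapses to a constant RR", {
  v <- gen_segment(rhythm_profile("NSR", resp_amplitude = 0, jitter_sd = 0),
                   100, seed = 2)
  expect_equal(v, rep(0.85, 100))
})

test_that("AV block merges dropped beats; PACs couple and compensate", {
  p <- rhythm_profile("av_block", resp_amplitude = 0, jitter_sd = 0,
                      drop_probability = 0.2)
  v <- gen_segment(p, 1000, seed = 3)
  # single, once-merged, and (rare, clipped) twice-merged intervals
  expect_true(all(round(v, 6) %in% c(0.85, 1.7, 2.5)))
  expect_true(all(c(0.85, 1.7) %in% round(v, 6)))
  expect_gt(mean(v > 1), 0.1)

  q <- rhythm_profile("pac", resp_amplitude = 0, jitter_sd = 0,
                      pac_rate = 0.1, coupling_fraction = 0.6)
  w <- gen_segment(q, 1000, seed = 4)
  pac_idx <- which(abs(w - 0.6 * 0.85) < 1e-9)
  expect_gt(length(pac_idx), 20)
  # every premature interval is followed by its compensatory pause
  expect_true(all(abs(w[pac_idx + 1] - (2 - 0.6) * 0.85) < 1e-9))
})

test_that("records are seed-deterministic with seam-exact ground truth", {
  seqs <- list(list(profile = rhythm_profile("NSR"), n_beats = 1000),
               list(profile = rhythm_profile("AF"), n_beats = 500),
               list(profile = rhythm_profile("NSR"), n_beats = 1000))
  r1 <- gen_record(seqs, seed = 31)
  r2 <- gen_record(seqs, seed = 31)
  r3 <- gen_record(seqs, seed = 32)
  expect_identical(r1$rr$intervals, r2$rr$intervals)
  expect_false(identical(r1$rr$intervals, r3$rr$intervals))

  expect_equal(nrow(r1$segments), 3L)
  expect_equal(r1$segments$label, c("N", "AF", "N"))
  # boundaries coincide with the cumulative beat times at the seams
  expect_equal(r1$segments$end[1], sum(r1$rr$intervals[1:1000]))
  expect_equal(r1$segments$end[2], sum(r1$rr$intervals[1:1500]))
  expect_equal(r1$segments$end[3], sum(r1$rr$intervals))
  expect_equal(r1$segments$start[-1], r1$segments$end[-3])  # tiling

  # the annotated AF window fraction is computable exactly from the truth
  tab <- compute_indices(r1$rr, r1$segments)
  w <- label_windows(make_windows(r1$rr, 150, 30), r1$segments)
  expect_equal(mean(tab$label == "AF"),
               sum(w$label == "AF") / sum(w$label != "ambiguous"))
})

test_that("cohorts draw per-patient parameters within the declared ranges", {
  cohort <- gen_cohort(10, af_burden_range = c(0.05, 0.95), seed = 9,
                       beats_per_record = 2000)
  expect_length(cohort, 10L)
  for (rec in cohort) {
    p <- attr(rec, "params")
    expect_gte(p$burden, 0.05); expect_lte(p$burden, 0.95)
    expect_gte(p$af$mean_rr, 0.5); expect_lte(p$af$mean_rr, 0.75)
    expect_gte(p$af$mesc_sd, 0.06); expect_lte(p$af$mesc_sd, 0.09)
    expect_gte(p$nsr$mean_rr, 0.70); expect_lte(p$nsr$mean_rr, 1.0)
    expect_true(all(rec$rr$intervals >= 0.25 & rec$rr$intervals <= 2.5))
    expect_equal(length(rec$rr$intervals), 2000L)
  }
  # ectopy kinds cycle over the patient index: all kinds present
  kinds <- vapply(cohort, function(r) attr(r, "params")$ectopy, character(1))
  expect_setequal(unique(kinds), c("bigeminy", "trigeminy", "none"))

  cohort2 <- gen_cohort(10, seed = 10, beats_per_record = 2000)
  expect_false(identical(cohort[[1]]$rr$intervals,
                         cohort2[[1]]$rr$intervals))
})

test_that("day-scale records generate quickly", {
  t0 <- proc.time()["elapsed"]
  rec <- gen_record(list(list(profile = rhythm_profile("AF"),
                              n_beats = 100000L)), seed = 1)
  expect_equal(length(rec$rr$intervals), 100000L)
  expect_lt(proc.time()["elapsed"] - t0, 5)
})

test_that("invalid profiles are rejected", {
  expect_error(rhythm_profile("AF", mean_rr = 2.5), "mean_rr")
  expect_error(rhythm_profile("NSR", jitter_sd = -0.1), "spread")
  expect_error(rhythm_profile("av_block", drop_probability = 1.4),
               "probabilities")
  expect_error(gen_segment(rhythm_profile("AF"), 1), "n_beats")
})
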