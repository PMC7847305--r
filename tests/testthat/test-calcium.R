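# Calcium response calling: dF% computation, drift QC, threshold
# calibration, responder rules, group summaries and group comparisons.

test_that("dF% recovers a planted percentage signal in closed form", {
  times <- seq(0, 499, by = 1)
  pct <- ifelse(times >= 70 & times <= 300, 20, 0)
  d <- compute_dff(make_trace(pct))
  expect_equal(d$f0, 1000)
  expect_equal(max(d$dff), 20, tolerance = 1e-10)
  expect_equal(d$dff[times < 60], rep(0, sum(times < 60)),
               tolerance = 1e-10)
})

test_that("dF% is invariant to multiplicative gain", {
  times <- seq(0, 499, by = 1)
  f <- 1000 + 50 * sin(times / 40)
  t1 <- roi_trace(times, f, c(60, 150))
  t2 <- roi_trace(times, 7.3 * f, c(60, 150))
  expect_equal(compute_dff(t1)$dff, compute_dff(t2)$dff,
               tolerance = 1e-10)
})

test_that("trace validation enforces baseline and puff invariants", {
  times <- seq(0, 99, by = 1)
  expect_error(roi_trace(times, rep(1, 100), c(5, 50),
                         baseline_frames = 15), "baseline")
  expect_error(roi_trace(times, rep(1, 100), c(60, 150)), "within")
  expect_error(compute_dff(roi_trace(times, rep(-1, 100), c(30, 60),
                                     baseline_frames = 10)), "F0")
})

test_that("drift QC is strict at the limit", {
  times <- seq(0, 499, by = 1)
  # linear ramp: ~5% drift across the recording (F0 averages the first
  # 15 samples of the ramp, so the estimate is slightly below 5)
  f <- 1000 * (1 + 0.05 * times / 499)
  d <- compute_dff(roi_trace(times, f, c(60, 150)))
  expect_equal(d$drift, 5, tolerance = 0.01)
  # the limit is strict: drift == limit fails, just below passes
  d$drift <- 5
  expect_false(qc_drift(d, limit = 5))
  d$drift <- 4.999
  expect_true(qc_drift(d, limit = 5))
  flat <- compute_dff(make_trace(rep(0, 500)))
  expect_true(qc_drift(flat))
})

test_that("the canonical control distribution gives the 5.5% threshold", {
  th <- response_threshold(4.5, 0.5)
  expect_identical(th$threshold, 5.5)
  x <- c(3.9, 4.1, 4.8, 5.2)
  expect_equal(calibrate_threshold(x)$threshold, mean(x) + 2 * sd(x))
  expect_error(calibrate_threshold(4.5), "two")
  expect_error(response_threshold(4.5, -1))
})

test_that("threshold calibration is equivariant under affine shifts", {
  x <- c(3.9, 4.6, 4.2, 5.0, 4.4)
  expect_equal(calibrate_threshold(x + 2)$threshold,
               calibrate_threshold(x)$threshold + 2)
  expect_equal(calibrate_threshold(x * 3)$threshold,
               calibrate_threshold(x)$threshold * 3)
})

test_that("Monte-Carlo calibration from the control distribution is ~5.5%", {
  th <- pulsegen:::with_seed(42, calibrate_threshold(rnorm(1000, 4.5, 0.5)))
  expect_equal(th$threshold, 5.5, tolerance = 0.1 / 5.5)
})

test_that("responders need amplitude above threshold AND post-puff persistence", {
  times <- seq(0, 499, by = 1)
  th <- response_threshold(4.5, 0.5)
  # sustained 35% response outlasting the puff -> responder
  sustained <- ifelse(times >= 70, 35 * exp(-pmax(0, times - 150) / 150), 0)
  call1 <- detect_response(compute_dff(make_trace(sustained)), th)
  expect_true(call1$responder)
  expect_equal(call1$peak_dff, 35, tolerance = 0.01)
  # 6% bump strictly confined to the puff: amplitude passes, duration fails
  bump <- ifelse(times >= 60 & times <= 150,
                 6 * sin(pi * (times - 60) / 90)^2, 0)
  call2 <- detect_response(compute_dff(make_trace(bump)), th)
  expect_true(call2$exceeds_threshold)
  expect_false(call2$outlasts_puff)
  expect_false(call2$responder)
  # 4% sustained change: duration passes, amplitude fails
  small <- ifelse(times >= 70, 4, 0)
  call3 <- detect_response(compute_dff(make_trace(small)), th)
  expect_false(call3$exceeds_threshold)
  expect_false(call3$responder)
  # inhibitory responses count by magnitude, sign is retained
  inhib <- ifelse(times >= 70, -20, 0)
  call4 <- detect_response(compute_dff(make_trace(inhib)), th)
  expect_true(call4$responder)
  expect_lt(call4$peak_dff, 0)
})

test_that("group summaries report exact means, CIs and rectangle AUC", {
  times <- seq(0, 499, by = 1)
  pct <- ifelse(times >= 100 & times < 300, 10, 0)
  dffs <- lapply(1:4, function(i) compute_dff(make_trace(pct, roi_id = i)))
  th <- response_threshold(4.5, 0.5)
  calls <- do.call(rbind, lapply(dffs, detect_response, threshold = th))
  gs <- summarize_group(dffs, calls)
  expect_equal(gs$n_rois, 4)
  # identical traces: zero-width confidence band
  expect_equal(gs$ci_lower, gs$mean_trace, tolerance = 1e-9)
  expect_equal(gs$ci_upper, gs$mean_trace, tolerance = 1e-9)
  # rectangle of height 10 over 200 s (trapezoid smears one sample edge)
  expect_equal(gs$auc, 2000, tolerance = 0.01)
  expect_equal(gs$mean, 10, tolerance = 1e-9)
  expect_equal(gs$responder_fraction, 1)
  # misaligned grids are rejected
  bad <- compute_dff(make_trace(pct, times = times + 0.5))
  expect_error(summarize_group(c(dffs, list(bad)), calls), "aligned")
})

test_that("group comparisons dispatch the right tests and handle ties", {
  a <- c(1, 2, 3, 4, 5)
  b <- c(6, 7, 8, 9, 10)
  un <- compare_groups(a, b, design = "unpaired")
  expect_equal(un$method, "Mann-Whitney")
  expect_lt(un$p_value, 0.05)
  pa <- compare_groups(a, a + 1, design = "paired")
  expect_equal(pa$method, "Wilcoxon signed-rank")
  expect_error(compare_groups(a, b[1:3], design = "paired"), "equal")
  deg <- compare_groups(rep(2, 5), rep(2, 5), design = "unpaired")
  expect_true(deg$degenerate)
  expect_equal(deg$p_value, 1)
  kg <- compare_groups(list(g1 = a, g2 = b, g3 = b + 5), design = "kgroup")
  expect_equal(kg$method, "Kruskal-Wallis")
  expect_s3_class(kg$posthoc, "data.frame")
  expect_equal(nrow(kg$posthoc), 3)
  expect_true(all(kg$posthoc$p_adj >= kg$posthoc$p_unadj - 1e-12))
  fr <- compare_groups(matrix(c(1, 2, 3, 2, 3, 4, 3, 4, 5), nrow = 3),
                       design = "friedman")
  expect_equal(fr$method, "Friedman")
})

test_that("Dunn post hoc agrees with the normal approximation on a known case", {
  g <- list(a = c(1, 2, 3, 4), b = c(5, 6, 7, 8), c = c(9, 10, 11, 12))
  ph <- pulsegen:::dunn_posthoc(g)
  # no ties: sigma = sqrt(N(N+1)/12 * (1/4 + 1/4)), rank means 2.5/6.5/10.5
  sigma <- sqrt(12 * 13 / 12 * 0.5)
  expect_equal(abs(ph$z[ph$comparison == "a - b"]), 4 / sigma,
               tolerance = 1e-9)
  expect_equal(abs(ph$z[ph$comparison == "a - c"]), 8 / sigma,
               tolerance = 1e-9)
})
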