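# Photometry processing, synchronization-event detection, LH pulse
# detection and SE/pulse coincidence.

test_that("scheduled bursts are averaged to one sample per cycle", {
  raw <- data.frame(
    time_s = c(0:4, 20:24, 40:44),
    f = c(rep(10, 5), rep(20, 5), 31:35))
  tr <- process_photometry(raw, schedule = c(on = 5, off = 15))
  expect_length(tr$times, 3)
  expect_equal(tr$times, c(2, 22, 42))
  # burst means 10, 20, 33 against a running 10th-percentile baseline
  expect_equal(tr$dff, 100 * (c(10, 20, 33) - tr$baseline) / tr$baseline)
  expect_error(process_photometry(data.frame(time_s = numeric(0),
                                             f = numeric(0))), "empty")
})

test_that("a constant recording gives an identically zero dF/F", {
  raw <- data.frame(time_s = 0:2000, f = 500)
  raw <- raw[raw$time_s %% 20 < 5, ]
  tr <- process_photometry(raw)
  expect_equal(tr$dff, rep(0, length(tr$dff)))
  expect_equal(tr$baseline, rep(500, length(tr$baseline)))
  # non-positive baselines are rejected rather than divided by
  expect_error(process_photometry(data.frame(time_s = 0:4, f = -1)),
               "baseline")
})

test_that("planted synchronization events are all recovered with timing", {
  sim <- simulate_photometry_lh(photometry_params(seed = 5))
  tr <- process_photometry(sim$photometry)
  se <- detect_synchronization_events(tr)
  expect_equal(nrow(se), length(sim$truth$se_times_s))
  # each detected peak sits within a minute of its planted onset
  err <- abs(se$time - (sim$truth$se_times_s + 10))
  expect_lt(max(err), 60)
})

test_that("the 10%-of-maximum rule excludes sub-threshold bumps", {
  times <- seq(10, 5400, by = 20)
  dff <- numeric(length(times))
  # apexes on the sampling grid so each bump has a unique maximum
  big <- abs(times - 1490) < 60
  small <- abs(times - 3510) < 60
  dff[big] <- 50 * (1 - abs(times[big] - 1490) / 60)
  dff[small] <- 4.5 * (1 - abs(times[small] - 3510) / 60)  # 9% of max
  tr <- structure(list(times = times, dff = dff, baseline = rep(500, length(times)),
                       schedule = c(on = 5, off = 15), max_signal = max(dff)),
                  class = "photometry_trace")
  se <- detect_synchronization_events(tr)
  expect_equal(nrow(se), 1)
  expect_equal(se$time, 1490, tolerance = 1e-9)
})

test_that("slow rises are rejected by the abruptness rule", {
  times <- seq(10, 5400, by = 20)
  # 20-minute linear climb to a plateau: never abrupt
  dff <- pmin(pmax(times - 1000, 0) / 1200, 1) * 40
  tr <- structure(list(times = times, dff = dff, baseline = rep(500, length(times)),
                       schedule = c(on = 5, off = 15), max_signal = max(dff)),
                  class = "photometry_trace")
  expect_equal(nrow(detect_synchronization_events(tr)), 0)
})

test_that("SE detection is invariant to multiplicative gain", {
  sim <- simulate_photometry_lh(photometry_params(seed = 6))
  tr1 <- process_photometry(sim$photometry)
  raw2 <- sim$photometry
  raw2$f <- raw2$f * 4.2
  tr2 <- process_photometry(raw2)
  se1 <- detect_synchronization_events(tr1)
  se2 <- detect_synchronization_events(tr2)
  expect_equal(se1$time, se2$time)
  expect_equal(se1$peak_dff, se2$peak_dff, tolerance = 1e-9)
})

test_that("LH pulses are detected against assay noise with both flanks", {
  t_min <- seq(0, 88, by = 4)
  base <- rep(0.2, length(t_min))
  # one clean pulse rising at 40 min and decaying after
  pulse <- ifelse(t_min >= 40, 1.5 * exp(-(t_min - 40) / 7), 0)
  lh <- data.frame(time_min = t_min, conc = base + pulse)
  pk <- detect_lh_pulses(lh)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$peak_time, 40)
  expect_equal(pk$rise_from_nadir, 1.5, tolerance = 1e-9)
  # a one-sample excursion with no descending flank before a higher rise
  # criterion is not enough on a flat series
  flat <- data.frame(time_min = t_min, conc = base)
  expect_equal(nrow(detect_lh_pulses(flat)), 0)
  # sub-criterion wiggle (< 2 x assay floor above nadir) is ignored
  wig <- base
  wig[10] <- 0.2 + 0.07
  expect_equal(nrow(detect_lh_pulses(
    data.frame(time_min = t_min, conc = wig))), 0)
})

test_that("a pulse peaking at the final sample is still counted", {
  t_min <- seq(0, 40, by = 4)
  conc <- c(rep(0.2, 10), 1.7)
  pk <- detect_lh_pulses(data.frame(time_min = t_min, conc = conc))
  expect_equal(nrow(pk), 1)
  expect_equal(pk$peak_time, 40)
})

test_that("coincidence matching is greedy, one-to-one and windowed", {
  co <- coincidence(c(10, 30, 50), c(12, 32, 52), window_min = 10)
  expect_equal(nrow(co$matched_pairs), 3)
  expect_equal(co$fraction_pulses_preceded_by_se, 1)
  expect_equal(co$fraction_se_followed_by_pulse, 1)
  # a pulse before any SE or beyond the window stays unmatched
  co2 <- coincidence(c(100), c(50, 115), window_min = 10)
  expect_equal(nrow(co2$matched_pairs), 0)
  expect_equal(co2$fraction_pulses_preceded_by_se, 0)
  # one SE cannot explain two pulses
  co3 <- coincidence(c(10), c(12, 14), window_min = 10)
  expect_equal(nrow(co3$matched_pairs), 1)
  expect_equal(co3$fraction_pulses_preceded_by_se, 0.5)
  # no pulses: the pulse-conditional fraction is undefined, not zero
  co4 <- coincidence(c(10, 20), numeric(0))
  expect_true(is.na(co4$fraction_pulses_preceded_by_se))
  expect_equal(co4$fraction_se_followed_by_pulse, 0)
})
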