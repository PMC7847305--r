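# Scheduled-mode photometry processing, synchronization-event detection,
# LH pulse detection, and SE-pulse coincidence scoring.

#' Reduce scheduled raw photometry samples to a dF/F trace
#'
#' Averages each on-period burst to a single sample, estimates a running
#' baseline as a rolling low percentile (10th percentile over 30 min by
#' default; "basal fluorescence" is otherwise undefined for long recordings
#' with slow drift), and computes `dF/F (%) = 100 * (F - baseline) /
#' baseline`. The division by the baseline rather than the instantaneous
#' fluorescence is a documented package convention (see the methods
#' vignette).
#'
#' @param raw Data frame with columns `time_s` and `f` (raw samples taken
#'   during on-periods of the schedule).
#' @param schedule Numeric `c(on, off)` seconds of the acquisition schedule.
#' @param baseline_window_min Rolling-baseline window (minutes).
#' @param baseline_quantile Quantile used as the running baseline.
#' @return Object of class `photometry_trace`: `times` (s, burst centres),
#'   `dff` (%), `baseline`, `schedule`, `max_signal = max(dff)`.
#' @export
process_photometry <- function(raw, schedule = c(on = 5, off = 15),
                               baseline_window_min = 30,
                               baseline_quantile = 0.1) {
  if (is.null(raw) || nrow(raw) == 0) stop("empty photometry input")
  stopifnot(all(c("time_s", "f") %in% names(raw)))
  cycle <- sum(schedule)
  burst <- floor(raw$time_s / cycle)
  f_burst <- tapply(raw$f, burst, mean)
  t_burst <- tapply(raw$time_s, burst, mean)
  ord <- order(t_burst)
  f_burst <- as.numeric(f_burst[ord])
  t_burst <- as.numeric(t_burst[ord])
  w <- max(3L, round(baseline_window_min * 60 / cycle))
  w <- min(w, length(f_burst))
  if (w %% 2 == 0) w <- w - 1L
  base <- zoo::rollapply(zoo::zoo(f_burst), width = w, FUN = quantile,
                         probs = baseline_quantile, names = FALSE,
                         partial = TRUE, align = "center")
  base <- as.numeric(base)
  if (any(base <= 0)) stop("non-positive running baseline; check input scale")
  dff <- 100 * (f_burst - base) / base
  structure(list(times = t_burst, dff = dff, baseline = base,
                 schedule = schedule, max_signal = max(dff)),
            class = "photometry_trace")
}

#' @export
print.photometry_trace <- function(x, ...) {
  cat(sprintf(
    "<photometry_trace> %d samples over %.1f h; max dF/F %.2f%%\n",
    length(x$times), diff(range(x$times)) / 3600, x$max_signal))
  invisible(x)
}

#' Detect synchronization events in a photometry trace
#'
#' SEs are abrupt local maxima whose dF/F exceeds 10% of the recording
#' maximum. "Abrupt" is operationalized as a rise from the preceding
#' trough to the peak within `max_rise_s` (default 2 min); peaks closer
#' than `refractory_s` are merged, keeping the larger. Because the
#' threshold is relative to the recording maximum, detection is invariant
#' to multiplicative scaling of the trace.
#'
#' @param trace A [process_photometry()] result.
#' @param rel_threshold Fraction of the recording maximum a peak must
#'   exceed (default 0.10).
#' @param max_rise_s Maximum trough-to-peak rise time (s).
#' @param refractory_s Minimum separation between events (s).
#' @return Data frame: `time` (s), `peak_dff` (%), `prominence` (%),
#'   `rise_rate` (%/s). Zero rows when nothing qualifies.
#' @export
detect_synchronization_events <- function(trace, rel_threshold = 0.10,
                                          max_rise_s = 120,
                                          refractory_s = 120) {
  stopifnot(inherits(trace, "photometry_trace"))
  empty <- data.frame(time = numeric(0), peak_dff = numeric(0),
                      prominence = numeric(0), rise_rate = numeric(0))
  if (!is.finite(trace$max_signal) || trace$max_signal <= 0) return(empty)
  thr <- rel_threshold * trace$max_signal
  dt <- median(diff(trace$times))
  pk <- pracma::findpeaks(trace$dff, minpeakheight = thr,
                          minpeakdistance = max(1, ceiling(refractory_s / dt)))
  if (is.null(pk)) return(empty)
  pk <- pk[order(pk[, 2]), , drop = FALSE]
  t_peak <- trace$times[pk[, 2]]
  t_begin <- trace$times[pk[, 3]]
  prom <- pk[, 1] - trace$dff[pk[, 3]]
  rise_t <- pmax(t_peak - t_begin, dt)
  keep <- (t_peak - t_begin) <= max_rise_s & pk[, 1] > thr
  data.frame(time = t_peak[keep], peak_dff = pk[keep, 1],
             prominence = prom[keep],
             rise_rate = prom[keep] / rise_t[keep])
}

#' Detect LH pulses against assay noise
#'
#' A local maximum of the LH series is a pulse when its rise from the
#' preceding nadir (the minimum since the last accepted pulse) exceeds
#' `max(rise_mult * assay_cv * nadir, rise_mult * assay_floor)`, and the
#' series subsequently falls by at least `fall_frac` of that criterion
#' before the next candidate -- the descending flank distinguishes a
#' secretory pulse from a one-sample noise excursion. With the default
#' multiplier 2 the rise criterion is twice the assay noise at the nadir,
#' floored at twice the assay sensitivity.
#'
#' @param lh Data frame with `time_min` and `conc` (ng/mL), at least 3
#'   samples.
#' @param assay_floor Assay sensitivity (ng/mL).
#' @param assay_cv Intra-assay coefficient of variation (fraction).
#' @param rise_mult Multiplier on the noise scale for the rise criterion.
#' @param fall_frac Required descending flank, as a fraction of the rise
#'   criterion.
#' @return Data frame: `peak_time` (min), `peak_conc`, `rise_from_nadir`.
#' @export
detect_lh_pulses <- function(lh, assay_floor = 0.04, assay_cv = 0.093,
                             rise_mult = 2, fall_frac = 0.5) {
  stopifnot(all(c("time_min", "conc") %in% names(lh)), nrow(lh) >= 3)
  x <- lh$conc
  n <- length(x)
  # interior local maxima; the final sample also qualifies when it is still
  # rising, so a pulse peaking at the end of the bleed is not lost
  is_max <- c(FALSE, x[2:(n - 1)] > x[1:(n - 2)] &
                x[2:(n - 1)] >= x[3:n], x[n] > x[n - 1])
  out <- data.frame(peak_time = numeric(0), peak_conc = numeric(0),
                    rise_from_nadir = numeric(0))
  last_pulse <- 0L
  for (i in which(is_max)) {
    nadir <- min(x[(last_pulse + 1L):i])
    thr <- max(rise_mult * assay_cv * nadir, rise_mult * assay_floor)
    rise <- x[i] - nadir
    if (rise <= thr) next
    # descending flank before the end or the next qualifying rise; cannot
    # be assessed for a peak at the final sample
    if (i < n) {
      after_min <- min(x[i:n])
      if (x[i] - after_min < fall_frac * thr) next
    }
    out <- rbind(out, data.frame(peak_time = lh$time_min[i],
                                 peak_conc = x[i],
                                 rise_from_nadir = rise))
    last_pulse <- i
  }
  rownames(out) <- NULL
  out
}

#' Score coincidence between synchronization events and LH pulses
#'
#' Greedy one-to-one matching in pulse-time order: each pulse is matched to
#' the nearest preceding unused SE within `window_min`. Reports the
#' fraction of pulses preceded by an SE and the fraction of SEs followed by
#' a pulse; with zero pulses the former is undefined (`NA`).
#'
#' @param se_times_min SE times (minutes).
#' @param pulse_times_min LH pulse times (minutes).
#' @param window_min Matching window (minutes): an SE may explain a pulse
#'   occurring up to this long after it. The default 10 covers the 1-2 min
#'   SE lead plus the 3-5 min blood-sampling granularity.
#' @return Object of class `coincidence_result`: `n_se`, `n_pulses`,
#'   `matched_pairs` (data frame `se_time`, `pulse_time`),
#'   `fraction_pulses_preceded_by_se`, `fraction_se_followed_by_pulse`,
#'   `window`.
#' @export
coincidence <- function(se_times_min, pulse_times_min, window_min = 10) {
  se <- sort(as.numeric(se_times_min))
  pu <- sort(as.numeric(pulse_times_min))
  used <- rep(FALSE, length(se))
  pairs <- data.frame(se_time = numeric(0), pulse_time = numeric(0))
  for (tp in pu) {
    lag <- tp - se
    ok <- which(!used & lag >= 0 & lag <= window_min)
    if (length(ok)) {
      j <- ok[which.min(lag[ok])]
      used[j] <- TRUE
      pairs <- rbind(pairs, data.frame(se_time = se[j], pulse_time = tp))
    }
  }
  structure(list(
    n_se = length(se), n_pulses = length(pu),
    matched_pairs = pairs,
    fraction_pulses_preceded_by_se =
      if (length(pu)) nrow(pairs) / length(pu) else NA_real_,
    fraction_se_followed_by_pulse =
      if (length(se)) nrow(pairs) / length(se) else NA_real_,
    window = window_min), class = "coincidence_result")
}

#' @export
print.coincidence_result <- function(x, ...) {
  cat(sprintf(
    "<coincidence_result> %d SEs, %d pulses, %d matched (window %g min)\n",
    x$n_se, x$n_pulses, nrow(x$matched_pairs), x$window))
  cat(sprintf("  fraction of pulses preceded by an SE: %s\n",
              format(x$fraction_pulses_preceded_by_se)))
  cat(sprintf("  fraction of SEs followed by a pulse: %s\n",
              format(x$fraction_se_followed_by_pulse)))
  invisible(x)
}
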