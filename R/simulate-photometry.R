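# Ground-truthed simulator for paired fiber-photometry / LH-sampling
# sessions: abrupt KNDy synchronization events (SEs) in a scheduled-mode
# photometry trace, and an LH series that either follows every SE with a
# pulse (coupled, wild-type-like) or stays flat at a very low baseline
# (uncoupled, Kiss1-null-like).

#' Parameters for a simulated photometry / LH session
#'
#' Defaults emulate the combined recording protocol: scheduled photometry
#' (5 s on, 15 s off), ~1.5 h sessions, tail-tip LH samples every 3-5 min
#' assayed with a 0.04 ng/mL sensitivity floor and 9.3% coefficient of
#' variation, and SEs preceding each LH pulse by ~2 min in the coupled
#' regime. The uncoupled regime keeps its SEs but holds LH at an invariant
#' very low baseline.
#'
#' @param duration_h Session length (hours).
#' @param se_rate Synchronization events per hour; the planted count is
#'   `round(se_rate * duration_h)`.
#' @param se_amplitude SE amplitude (dF/F %); 0 plants no events.
#' @param se_rise,se_decay SE rise time and decay time constant (s).
#' @param schedule_on,schedule_off Scheduled acquisition (s on, s off).
#' @param raw_rate Raw sampling rate within on-periods (Hz).
#' @param lh_sampling_interval LH sampling interval (min), 3-5.
#' @param lh_baseline Inter-pulse LH level (ng/mL). Defaults to 0.2 when
#'   coupled and 0.075 when uncoupled (the near-floor level of the
#'   kisspeptin-null regime).
#' @param lh_pulse_amplitude LH pulse rise above baseline (ng/mL).
#' @param lh_pulse_decay LH pulse decay time constant (min).
#' @param lh_delay_after_se Delay from SE onset to LH pulse onset (min).
#' @param coupled If `FALSE`, LH stays flat at baseline regardless of SEs.
#' @param assay_floor Assay sensitivity (ng/mL); concentrations are floored
#'   here.
#' @param assay_cv Intra-assay coefficient of variation (fraction),
#'   applied multiplicatively.
#' @param f0 Baseline raw fluorescence (arbitrary units).
#' @param noise_sd Photometry noise SD (dF/F %).
#' @param seed Integer seed.
#' @return List of class `photometry_params`.
#' @export
photometry_params <- function(duration_h = 1.5,
                              se_rate = 4,
                              se_amplitude = 8,
                              se_rise = 10,
                              se_decay = 40,
                              schedule_on = 5,
                              schedule_off = 15,
                              raw_rate = 1,
                              lh_sampling_interval = 4,
                              lh_baseline = if (coupled) 0.2 else 0.075,
                              lh_pulse_amplitude = 1.5,
                              lh_pulse_decay = 7,
                              lh_delay_after_se = 2,
                              coupled = TRUE,
                              assay_floor = 0.04,
                              assay_cv = 0.093,
                              f0 = 500,
                              noise_sd = 0.15,
                              seed = 1L) {
  stopifnot(duration_h > 0, se_rate >= 0, schedule_on > 0,
            schedule_off >= 0, raw_rate > 0,
            lh_sampling_interval >= 3, lh_sampling_interval <= 5,
            lh_baseline > 0, assay_floor >= 0, assay_cv >= 0)
  structure(list(
    duration_h = duration_h, se_rate = se_rate,
    se_amplitude = se_amplitude, se_rise = se_rise, se_decay = se_decay,
    schedule_on = schedule_on, schedule_off = schedule_off,
    raw_rate = raw_rate,
    lh_sampling_interval = lh_sampling_interval,
    lh_baseline = lh_baseline,
    lh_pulse_amplitude = lh_pulse_amplitude,
    lh_pulse_decay = lh_pulse_decay,
    lh_delay_after_se = lh_delay_after_se,
    coupled = isTRUE(coupled),
    assay_floor = assay_floor, assay_cv = assay_cv,
    f0 = f0, noise_sd = noise_sd,
    seed = as.integer(seed)), class = "photometry_params")
}

#' Simulate a paired photometry / LH session with known event times
#'
#' Plants `round(se_rate * duration_h)` abrupt synchronization events at
#' jittered regular intervals (sharp linear rise over `se_rise` s, then
#' exponential decay), samples raw fluorescence on the acquisition schedule,
#' and generates the LH series: in the coupled regime one pulse
#' (instantaneous rise, exponential decay) begins `lh_delay_after_se`
#' minutes after each SE; uncoupled sessions stay at baseline. Assay noise
#' is multiplicative at `assay_cv` and results are floored at
#' `assay_floor`.
#'
#' @param params A [photometry_params()].
#' @return List with `photometry` (data frame `time_s`, `f` of raw
#'   scheduled samples, schedule in attributes), `lh` (data frame
#'   `time_min`, `conc`), and `truth` (list: `se_times_s`,
#'   `pulse_times_min`).
#' @export
simulate_photometry_lh <- function(params) {
  stopifnot(inherits(params, "photometry_params"))
  p <- params
  with_seed(p$seed, {
    dur_s <- p$duration_h * 3600
    cycle <- p$schedule_on + p$schedule_off
    n_se <- if (p$se_amplitude > 0) round(p$se_rate * p$duration_h) else 0L
    se_times <- numeric(0)
    if (n_se > 0) {
      slot <- dur_s / n_se
      se_times <- (seq_len(n_se) - 0.5) * slot +
        runif(n_se, -0.1, 0.1) * slot
    }
    # raw samples on the acquisition schedule
    n_cycles <- floor(dur_s / cycle)
    on_times <- as.vector(outer(seq(0, p$schedule_on - 1e-9, by = 1 / p$raw_rate),
                                (seq_len(n_cycles) - 1) * cycle, "+"))
    on_times <- sort(on_times)
    dff_true <- numeric(length(on_times))
    for (t0 in se_times) {
      dt <- on_times - t0
      shp <- ifelse(dt < 0, 0,
                    pmin(1, dt / p$se_rise) *
                      exp(-pmax(0, dt - p$se_rise) / p$se_decay))
      dff_true <- dff_true + p$se_amplitude * shp
    }
    f <- p$f0 * (1 + dff_true / 100) +
      p$f0 * rnorm(length(on_times), 0, p$noise_sd) / 100
    photometry <- data.frame(time_s = on_times, f = f)
    attr(photometry, "schedule") <- c(on = p$schedule_on,
                                      off = p$schedule_off)
    # LH series
    lh_times <- seq(0, dur_s / 60, by = p$lh_sampling_interval)
    conc <- rep(p$lh_baseline, length(lh_times))
    pulse_times <- numeric(0)
    if (p$coupled && length(se_times)) {
      pulse_times <- se_times / 60 + p$lh_delay_after_se
      pulse_times <- pulse_times[pulse_times <= max(lh_times)]
      for (tp in pulse_times) {
        dt <- lh_times - tp
        conc <- conc + ifelse(dt < 0, 0,
                              p$lh_pulse_amplitude *
                                exp(-dt / p$lh_pulse_decay))
      }
    }
    conc <- conc * (1 + rnorm(length(conc), 0, p$assay_cv))
    conc <- pmax(conc, p$assay_floor)
    lh <- data.frame(time_min = lh_times, conc = conc)
    attr(lh, "assay_floor") <- p$assay_floor
    attr(lh, "assay_cv") <- p$assay_cv
    list(photometry = photometry, lh = lh,
         truth = list(se_times_s = se_times,
                      pulse_times_min = pulse_times))
  })
}
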