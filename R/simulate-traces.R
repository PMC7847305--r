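# Ground-truthed simulator for dendron ROI calcium traces: pre-puff
# baseline, slow puff-confined pressure artifact, optional sustained
# kisspeptin-like response, linear baseline drift, and Gaussian noise.

#' Parameters for simulated dendron ROI traces
#'
#' Defaults follow the recording protocol the response caller targets:
#' 500 s recordings at 0.9 Hz with a 90 s puff, vehicle-puff artifacts of
#' 4.5 +/- 0.5% confined to the puff window, and sustained responses of
#' ~35% that decay over hundreds of seconds.
#'
#' @param n_rois Number of ROIs to simulate.
#' @param frame_rate Frames per second.
#' @param duration Recording length (s); must cover the puff.
#' @param puff_start,puff_duration Puff timing (s).
#' @param artifact_amplitude_mean,artifact_amplitude_sd Distribution (%dF)
#'   of the slow puff artifact, which rises and decays with the puff and is
#'   zero outside it.
#' @param response_amplitude Planted sustained response amplitude (%dF);
#'   0 plants no response anywhere.
#' @param responder_fraction Fraction of ROIs given the response.
#' @param response_onset_delay Response onset after puff start (s).
#' @param response_rise_tau,response_decay_tau Exponential rise (during the
#'   puff) and post-puff decay time constants (s).
#' @param drift_per_recording Linear baseline drift over the recording
#'   (% of F0; positive drifts upward).
#' @param noise_sd Gaussian noise SD (%dF).
#' @param f0 Baseline fluorescence (arbitrary units).
#' @param baseline_frames Pre-puff frames averaged into F0 downstream.
#' @param seed Integer seed; fixes all outputs.
#' @return List of class `trace_params`.
#' @export
trace_params <- function(n_rois = 10, frame_rate = 0.9, duration = 500,
                         puff_start = 60, puff_duration = 90,
                         artifact_amplitude_mean = 4.5,
                         artifact_amplitude_sd = 0.5,
                         response_amplitude = 35,
                         responder_fraction = 1,
                         response_onset_delay = 10,
                         response_rise_tau = 20,
                         response_decay_tau = 150,
                         drift_per_recording = 0,
                         noise_sd = 1,
                         f0 = 1000,
                         baseline_frames = 15,
                         seed = 1L) {
  stopifnot(frame_rate > 0, duration >= puff_start + puff_duration,
            n_rois >= 0, noise_sd >= 0, f0 > 0,
            responder_fraction >= 0, responder_fraction <= 1)
  structure(list(
    n_rois = n_rois, frame_rate = frame_rate, duration = duration,
    puff_start = puff_start, puff_duration = puff_duration,
    artifact_amplitude_mean = artifact_amplitude_mean,
    artifact_amplitude_sd = artifact_amplitude_sd,
    response_amplitude = response_amplitude,
    responder_fraction = responder_fraction,
    response_onset_delay = response_onset_delay,
    response_rise_tau = response_rise_tau,
    response_decay_tau = response_decay_tau,
    drift_per_recording = drift_per_recording,
    noise_sd = noise_sd, f0 = f0,
    baseline_frames = as.integer(baseline_frames),
    seed = as.integer(seed)), class = "trace_params")
}

#' Simulate dendron ROI traces with known responder status
#'
#' Each trace is `F0 * (1 + drift ramp) * (1 + (artifact + response)/100)`
#' plus Gaussian noise. The artifact follows the puff timing (a raised-sine
#' bump confined to the puff window, per-ROI amplitude drawn from the
#' configured normal distribution, negative values allowed). Responder ROIs
#' additionally get a sustained response: exponential rise from
#' `puff_start + response_onset_delay`, exponential decay after puff end.
#'
#' @param params A [trace_params()].
#' @return List with `traces` (list of [roi_trace()]) and `truth` (data
#'   frame: `roi_id`, `responder`, `artifact_amplitude`,
#'   `drift_per_recording`, `qc_should_fail` at the 5% drift rule).
#' @export
simulate_dendron_traces <- function(params) {
  stopifnot(inherits(params, "trace_params"))
  p <- params
  with_seed(p$seed, {
    n_frames <- floor(p$duration * p$frame_rate)
    times <- (seq_len(n_frames) - 1) / p$frame_rate
    puff_end <- p$puff_start + p$puff_duration
    in_puff <- times >= p$puff_start & times <= puff_end
    art_shape <- numeric(n_frames)
    art_shape[in_puff] <-
      sin(pi * (times[in_puff] - p$puff_start) / p$puff_duration)^2
    onset <- p$puff_start + p$response_onset_delay
    resp_shape <- numeric(n_frames)
    after <- times >= onset
    rise <- 1 - exp(-(times[after] - onset) / p$response_rise_tau)
    decay <- exp(-pmax(0, times[after] - puff_end) / p$response_decay_tau)
    resp_shape[after] <- rise * decay
    n_resp <- round(p$responder_fraction * p$n_rois)
    responder <- rep(FALSE, p$n_rois)
    if (n_resp > 0 && p$response_amplitude > 0) {
      responder[sample.int(p$n_rois, n_resp)] <- TRUE
    }
    art_amp <- rnorm(p$n_rois, p$artifact_amplitude_mean,
                     p$artifact_amplitude_sd)
    traces <- lapply(seq_len(p$n_rois), function(i) {
      pct <- art_amp[i] * art_shape +
        if (responder[i]) p$response_amplitude * resp_shape else 0
      ramp <- 1 + (p$drift_per_recording / 100) * times / p$duration
      f <- p$f0 * ramp * (1 + pct / 100) +
        p$f0 * rnorm(n_frames, 0, p$noise_sd) / 100
      roi_trace(times, f, puff_window = c(p$puff_start, puff_end),
                baseline_frames = p$baseline_frames, roi_id = i)
    })
    truth <- data.frame(
      roi_id = seq_len(p$n_rois),
      responder = responder,
      artifact_amplitude = art_amp,
      drift_per_recording = p$drift_per_recording,
      qc_should_fail = abs(p$drift_per_recording) >= 5)
    list(traces = traces, truth = truth)
  })
}
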