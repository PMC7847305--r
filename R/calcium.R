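# Puff-evoked calcium response calling for GnRH dendron ROIs: dF% traces,
# baseline-drift QC, control-calibrated thresholds, responder calls, group
# summaries and rank-based group comparisons.

#' Construct an ROI fluorescence trace
#'
#' @param times Sample times (s), strictly increasing.
#' @param f Raw fluorescence values (arbitrary units).
#' @param puff_window Numeric `c(start, end)` of the drug puff (s); must lie
#'   within the recording, with baseline frames available before the start.
#' @param baseline_frames Number of initial frames averaged into F0
#'   (10-20 frames preceding the puff by convention).
#' @param frame_rate Acquisition rate (Hz); inferred from `times` if `NULL`.
#' @param roi_id Identifier carried through to downstream tables.
#' @return Object of class `roi_trace`.
#' @export
roi_trace <- function(times, f, puff_window, baseline_frames = 15,
                      frame_rate = NULL, roi_id = 1L) {
  stopifnot(length(times) == length(f), all(diff(times) > 0),
            length(puff_window) == 2, puff_window[1] < puff_window[2])
  if (puff_window[1] < times[1] || puff_window[2] > times[length(times)])
    stop("puff_window must lie within the recording")
  if (sum(times < puff_window[1]) < baseline_frames)
    stop("baseline_frames must precede the puff")
  if (is.null(frame_rate)) frame_rate <- 1 / median(diff(times))
  structure(list(roi_id = roi_id, times = times, f = f,
                 frame_rate = frame_rate, puff_window = puff_window,
                 baseline_frames = as.integer(baseline_frames)),
            class = "roi_trace")
}

#' Compute the dF% trace of one ROI
#'
#' F0 is the mean of the first `baseline_frames` samples (all pre-puff);
#' the trace is expressed as `100 * (F - F0) / F0` so the baseline reads 0
#' and reported response amplitudes are percentage increases over baseline.
#' Baseline drift is estimated as the absolute fluorescence change implied
#' by a linear fit to the pre-puff segment, extrapolated across the whole
#' recording, as a percentage of F0.
#'
#' The measure is invariant to multiplicative gain on the raw fluorescence.
#'
#' @param trace A [roi_trace()].
#' @return Object of class `dff_trace` with `times`, `dff` (%), `f0`,
#'   `drift` (% of F0 across the recording) and the puff window.
#' @export
compute_dff <- function(trace) {
  stopifnot(inherits(trace, "roi_trace"))
  nb <- trace$baseline_frames
  f0 <- mean(trace$f[seq_len(nb)])
  if (f0 <= 0) stop("invalid trace: F0 <= 0")
  dff <- 100 * (trace$f - f0) / f0
  pre <- trace$times < trace$puff_window[1]
  drift <- if (sum(pre) >= 2) {
    slope <- coef(lm(trace$f[pre] ~ trace$times[pre]))[2]
    span <- trace$times[length(trace$times)] - trace$times[1]
    100 * abs(slope) * span / f0
  } else NA_real_
  structure(list(roi_id = trace$roi_id, times = trace$times, dff = dff,
                 f0 = f0, drift = unname(drift),
                 puff_window = trace$puff_window),
            class = "dff_trace")
}

#' Baseline-drift quality control
#'
#' A recording passes only when its baseline drift is strictly below the
#' limit (default 5% across the recording); a drift of exactly the limit
#' fails, matching the "<5%" acceptance rule.
#'
#' @param dff A `dff_trace` from [compute_dff()].
#' @param limit Drift limit (% of F0).
#' @return Logical pass flag.
#' @export
qc_drift <- function(dff, limit = 5) {
  stopifnot(inherits(dff, "dff_trace"))
  !is.na(dff$drift) && dff$drift < limit
}

#' Response threshold from control-puff changes
#'
#' The decision threshold for a drug-evoked change is the mean vehicle
#' (aCSF) puff change plus two sample standard deviations: with the
#' canonical control distribution of 4.5 +/- 0.5% this gives the >5.5%
#' rule. `calibrate_threshold()` computes the summary from raw control
#' values; `response_threshold()` builds one directly from a known mean
#' and SD.
#'
#' @param control_changes Numeric vector of control peak changes (%),
#'   at least two values.
#' @return Object of class `response_threshold` with `control_mean`,
#'   `control_sd` and `threshold = control_mean + 2 * control_sd`.
#' @export
calibrate_threshold <- function(control_changes) {
  if (length(control_changes) < 2)
    stop("need at least two control values")
  m <- mean(control_changes)
  s <- sd(control_changes)
  response_threshold(m, s)
}

#' @rdname calibrate_threshold
#' @param control_mean,control_sd Control-change mean and SD (%).
#' @export
response_threshold <- function(control_mean, control_sd) {
  stopifnot(is.finite(control_mean), is.finite(control_sd), control_sd >= 0)
  structure(list(control_mean = control_mean, control_sd = control_sd,
                 threshold = control_mean + 2 * control_sd),
            class = "response_threshold")
}

#' @export
print.response_threshold <- function(x, ...) {
  cat(sprintf(
    "<response_threshold> control %.2f +/- %.2f%% -> respond if |dF%%| > %.2f%%\n",
    x$control_mean, x$control_sd, x$threshold))
  invisible(x)
}

#' Call a responder from a dF% trace
#'
#' A ROI responds when (i) the signed extremum of |dF%| between puff onset
#' and the end of the recording strictly exceeds the calibrated threshold
#' (increases and decreases are both eligible) and (ii) |dF%| remains above
#' the threshold beyond the end of the puff for at least `outlast_frames`
#' frames -- the amplitude-plus-duration rule. Callers should apply
#' [qc_drift()] first; drifting recordings are excluded, not rescued.
#'
#' @param dff A `dff_trace` from [compute_dff()].
#' @param threshold A [response_threshold()].
#' @param outlast_frames Minimum number of supra-threshold frames after the
#'   puff ends.
#' @return One-row data frame: `roi_id`, `peak_dff` (signed, %),
#'   `exceeds_threshold`, `outlasts_puff`, `responder`.
#' @export
detect_response <- function(dff, threshold, outlast_frames = 1) {
  stopifnot(inherits(dff, "dff_trace"),
            inherits(threshold, "response_threshold"))
  th <- threshold$threshold
  win <- dff$times >= dff$puff_window[1]
  peak <- if (any(win)) dff$dff[win][which.max(abs(dff$dff[win]))] else 0
  exceeds <- abs(peak) > th
  post <- dff$times > dff$puff_window[2]
  outlasts <- sum(abs(dff$dff[post]) > th) >= outlast_frames
  data.frame(roi_id = dff$roi_id, peak_dff = peak,
             exceeds_threshold = exceeds, outlasts_puff = outlasts,
             responder = exceeds && outlasts)
}

#' Summarize a group of dF% traces
#'
#' Traces must be time-aligned (same sampling grid relative to puff onset).
#' Produces the per-timepoint mean trace with its pointwise 95% confidence
#' band (t-based across ROIs), scalar mean +/- SEM and median of the peak
#' changes, the trapezoidal area under the mean trace (s.%F), and the
#' responder fraction.
#'
#' @param dffs List of `dff_trace` objects.
#' @param calls Data frame of [detect_response()] rows, one per trace.
#' @param n_mice Optional number of animals contributing.
#' @return Object of class `group_summary`.
#' @export
summarize_group <- function(dffs, calls, n_mice = NA_integer_) {
  if (length(dffs) == 0) stop("empty group")
  times <- dffs[[1]]$times
  if (!all(vapply(dffs, function(d) length(d$times) == length(times) &&
                    max(abs(d$times - times)) < 1e-6, TRUE)))
    stop("traces must be time-aligned on a common grid")
  mat <- do.call(rbind, lapply(dffs, `[[`, "dff"))
  n <- nrow(mat)
  mean_trace <- colMeans(mat)
  if (n > 1) {
    sem_trace <- apply(mat, 2, sd) / sqrt(n)
    tcrit <- qt(0.975, n - 1)
  } else {
    sem_trace <- rep(0, ncol(mat))
    tcrit <- 0
  }
  structure(list(
    n_rois = n, n_mice = n_mice,
    times = times,
    mean_trace = mean_trace,
    ci_lower = mean_trace - tcrit * sem_trace,
    ci_upper = mean_trace + tcrit * sem_trace,
    mean = mean(calls$peak_dff),
    sem = if (n > 1) sd(calls$peak_dff) / sqrt(n) else 0,
    median = median(calls$peak_dff),
    auc = pracma::trapz(times, mean_trace),
    responder_fraction = mean(calls$responder)
  ), class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf(
    "<group_summary> n = %d ROIs; peak dF%% %.1f +/- %.1f (median %.1f); AUC %.0f s.%%F; %.0f%% responders\n",
    x$n_rois, x$mean, x$sem, x$median, x$auc, 100 * x$responder_fraction))
  invisible(x)
}

# Dunn's post hoc z-tests after a Kruskal-Wallis test, with tie correction
# and Bonferroni-adjusted two-sided p-values.
dunn_posthoc <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  x <- unlist(groups, use.names = FALSE)
  g <- rep(names(groups), vapply(groups, length, 0L))
  N <- length(x)
  r <- rank(x)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  rbar <- tapply(r, g, mean)
  ni <- tapply(r, g, length)
  combs <- utils::combn(names(groups), 2)
  res <- apply(combs, 2, function(pair) {
    i <- pair[1]; j <- pair[2]
    sigma <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / ni[i] + 1 / ni[j]))
    z <- (rbar[i] - rbar[j]) / sigma
    c(z = unname(z), p = unname(2 * pnorm(-abs(z))))
  })
  data.frame(comparison = paste(combs[1, ], combs[2, ], sep = " - "),
             z = res["z", ],
             p_unadj = res["p", ],
             p_adj = pmin(1, res["p", ] * ncol(combs)))
}

#' Rank-based group comparisons
#'
#' Dispatches the appropriate non-parametric test: Wilcoxon signed-rank for
#' paired designs, Mann-Whitney (rank-sum) for unpaired two-group designs,
#' and Kruskal-Wallis with Dunn's post hoc z-tests (Bonferroni adjusted) for
#' k-group designs; `friedman` runs a Friedman test on a blocked matrix.
#' Degenerate all-tied inputs are reported as `p = 1` with a flag rather
#' than an error.
#'
#' @param a First sample (numeric), or a list of samples for `"kgroup"`, or
#'   a blocks-by-treatments matrix for `"friedman"`.
#' @param b Second sample for two-group designs.
#' @param design One of `"unpaired"`, `"paired"`, `"kgroup"`, `"friedman"`.
#' @return List with `statistic`, `p_value`, `method`, `degenerate`, and
#'   for k-group designs a `posthoc` data frame.
#' @export
compare_groups <- function(a, b = NULL,
                           design = c("unpaired", "paired", "kgroup",
                                      "friedman")) {
  design <- match.arg(design)
  if (design %in% c("unpaired", "paired")) {
    stopifnot(is.numeric(a), is.numeric(b), length(a) > 0, length(b) > 0)
    if (design == "paired" && length(a) != length(b))
      stop("paired design requires equal lengths")
    degenerate <- if (design == "paired") all(a == b)
                  else length(unique(c(a, b))) == 1
    if (degenerate) {
      return(list(statistic = NA_real_, p_value = 1,
                  method = if (design == "paired")
                    "Wilcoxon signed-rank" else "Mann-Whitney",
                  degenerate = TRUE))
    }
    wt <- suppressWarnings(
      wilcox.test(a, b, paired = design == "paired", exact = FALSE))
    list(statistic = unname(wt$statistic), p_value = wt$p.value,
         method = if (design == "paired") "Wilcoxon signed-rank"
                  else "Mann-Whitney",
         degenerate = FALSE)
  } else if (design == "kgroup") {
    stopifnot(is.list(a), length(a) >= 2)
    if (length(unique(unlist(a))) == 1) {
      return(list(statistic = NA_real_, p_value = 1,
                  method = "Kruskal-Wallis", degenerate = TRUE))
    }
    kt <- kruskal.test(a)
    list(statistic = unname(kt$statistic), p_value = kt$p.value,
         method = "Kruskal-Wallis", degenerate = FALSE,
         posthoc = dunn_posthoc(a))
  } else {
    stopifnot(is.matrix(a))
    if (length(unique(as.vector(a))) == 1) {
      return(list(statistic = NA_real_, p_value = 1,
                  method = "Friedman", degenerate = TRUE))
    }
    ft <- friedman.test(a)
    list(statistic = unname(ft$statistic), p_value = ft$p.value,
         method = "Friedman", degenerate = FALSE)
  }
}
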