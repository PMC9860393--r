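#' EAP detection and measurement configuration
#'
#' @param detect_threshold fixed threshold in pA, or `NULL` for automatic
#'   `auto_k x` MAD of the band-passed trace (thresholds were set per cell
#'   in the original recordings; auto mode is the reproducible default).
#' @param auto_k threshold multiple of the unscaled MAD in auto mode.
#' @param pre_window,post_window event window around the detection peak, s.
#' @param baseline_window interval preceding the event window whose mean is
#'   subtracted before integration, s.
#' @param smooth_window Savitzky-Golay window for inflection analysis, s.
#' @param inflection_min_frac zero-crossings of the second derivative only
#'   count as inflection points when an adjacent excursion reaches this
#'   fraction of the largest second-derivative magnitude; suppresses
#'   noise-induced crossings on the flat baseline.
#' @param clip_limit absolute amplitude (pA) above which segments are
#'   treated as saturated and excluded, or `NULL` to disable.
#' @return list of class `eap_config`.
#' @export
eap_config <- function(detect_threshold = NULL, auto_k = 5,
                       pre_window = 2e-3, post_window = 15e-3,
                       baseline_window = 1e-3, smooth_window = 0.5e-3,
                       inflection_min_frac = 0.05, clip_limit = NULL) {
  stopifnot(pre_window > 0, post_window > 0, baseline_window > 0,
            smooth_window > 0, auto_k > 0,
            inflection_min_frac >= 0, inflection_min_frac < 1)
  if (!is.null(detect_threshold) && detect_threshold <= 0)
    stop("detect_threshold must be > 0")
  structure(list(detect_threshold = detect_threshold, auto_k = auto_k,
                 pre_window = pre_window, post_window = post_window,
                 baseline_window = baseline_window,
                 smooth_window = smooth_window,
                 inflection_min_frac = inflection_min_frac,
                 clip_limit = clip_limit),
            class = "eap_config")
}

#' Detect EAPs on a band-passed current trace
#'
#' Local maxima above threshold, separated by at least one event window.
#' The trace must be band-passed (6-1500 Hz) and stored
#' depolarizing-positive.  Saturated segments (beyond `clip_limit`) are
#' excluded.
#'
#' @param bp a band-passed current [trace()] (pA).
#' @param cfg an [eap_config()].
#' @return data.frame with `time` (s) and `index` per detected event.
#' @export
detect_eaps <- function(bp, cfg = eap_config()) {
  stopifnot(inherits(bp, "trace"), inherits(cfg, "eap_config"))
  v <- bp$samples
  # auto threshold floored at 1.5% of the positive range so filter
  # ringing cannot register as events on noiseless traces
  thr <- cfg$detect_threshold %||%
    max(cfg$auto_k * median(abs(v - median(v))), 0.015 * max(v, 0))
  min_sep <- max(1L, round((cfg$pre_window + cfg$post_window) *
                             bp$sample_rate))
  idx <- local_maxima_above(v, thr, min_sep)
  if (!is.null(cfg$clip_limit)) {
    clipped <- abs(v[idx]) >= cfg$clip_limit
    if (any(clipped))
      warning(sum(clipped), " event(s) at or beyond the clip limit excluded")
    idx <- idx[!clipped]
  }
  data.frame(time = bp$start_time + (idx - 1L) / bp$sample_rate,
             index = idx)
}

#' Peak-aligned mean EAP waveform
#'
#' Events aligned on their detection peak and averaged sample-wise over the
#' event window; the per-sample SD is returned with the mean.  Samples of
#' an event window that overlap the next or previous event are excluded
#' from the average at those samples.
#'
#' @param bp the band-passed current [trace()].
#' @param event_times detection-peak times, s (>= 2 events).
#' @param cfg an [eap_config()].
#' @return list of class `eap_waveform`: `t` (s relative to the peak),
#'   `mean`, `sd` (pA), `n_events`, `sample_rate`.
#' @export
mean_waveform <- function(bp, event_times, cfg = eap_config()) {
  stopifnot(inherits(bp, "trace"))
  if (length(event_times) < 2L)
    stop("mean waveform needs at least 2 events, got ", length(event_times))
  fs <- bp$sample_rate
  pre <- round(cfg$pre_window * fs)
  post <- round(cfg$post_window * fs)
  rel <- (-pre):post
  n <- length(bp$samples)
  ev_idx <- round((sort(event_times) - bp$start_time) * fs) + 1L
  acc <- matrix(NA_real_, nrow = length(event_times), ncol = length(rel))
  for (i in seq_along(ev_idx)) {
    lo <- ev_idx[i] - pre
    hi <- ev_idx[i] + post
    # truncate at neighbouring events
    if (i > 1L) lo <- max(lo, ev_idx[i - 1L] + post + 1L)
    if (i < length(ev_idx)) hi <- min(hi, ev_idx[i + 1L] - pre - 1L)
    lo <- max(lo, 1L); hi <- min(hi, n)
    if (lo > hi) next
    cols <- (lo - (ev_idx[i] - pre) + 1L):(hi - (ev_idx[i] - pre) + 1L)
    acc[i, cols] <- bp$samples[lo:hi]
  }
  structure(list(t = rel / fs,
                 mean = colMeans(acc, na.rm = TRUE),
                 sd = apply(acc, 2, sd, na.rm = TRUE),
                 n_events = length(event_times),
                 sample_rate = fs),
            class = "eap_waveform")
}

#' Running integral of an EAP event
#'
#' Subtracts the baseline (mean of the interval preceding the event
#' window, default 1 ms) and integrates by the cumulative trapezoidal
#' rule; the integral peak is proportional to the peak of the underlying
#' intracellular action potential.
#'
#' @param bp the band-passed current [trace()].
#' @param event_time detection-peak time, s.
#' @param cfg an [eap_config()].
#' @return list with `t` (s), `integral` (pA s, running), and
#'   `integral_peak` (pA s).
#' @export
integrate_eap <- function(bp, event_time, cfg = eap_config()) {
  stopifnot(inherits(bp, "trace"))
  fs <- bp$sample_rate
  n <- length(bp$samples)
  i_ev <- round((event_time - bp$start_time) * fs) + 1L
  w0 <- i_ev - round(cfg$pre_window * fs)
  w1 <- i_ev + round(cfg$post_window * fs)
  if (w0 < 1L || w1 > n)
    stop("event window [", w0, ", ", w1, "] lies outside the trace")
  b0 <- max(1L, w0 - round(cfg$baseline_window * fs))
  baseline <- if (b0 < w0) mean(bp$samples[b0:(w0 - 1L)]) else 0
  tt <- (seq(w0, w1) - 1L) / fs + bp$start_time
  y <- bp$samples[w0:w1] - baseline
  ci <- as.numeric(pracma::cumtrapz(tt, y))
  list(t = tt, integral = ci, integral_peak = max(ci))
}

#' Quantify the secondary depolarizing peak of a mean EAP waveform
#'
#' Differentiates the mean waveform, smooths it (Savitzky-Golay,
#' `smooth_window`), and locates the inflection points of the differential
#' as the zero-crossings of its second derivative.  The third inflection
#' point marks the end of the initial repolarisation phase; the secondary
#' amplitude is the maximum waveform value after it, which accommodates
#' the variable latency of the secondary peak.  The primary amplitude is
#' the waveform maximum up to the third inflection point.
#'
#' @param wf an `eap_waveform` from [mean_waveform()], or any list with
#'   fields `mean` and `sample_rate`.
#' @param cfg an [eap_config()].
#' @return list with `secondary_amp` (pA), `primary_amp` (pA),
#'   `secondary_rel` (fraction), `inflection_times` (s relative to the
#'   aligned peak) and logical `no_secondary_lobe` (fewer than 3
#'   inflection points: `secondary_amp = 0`).
#' @export
secondary_peak <- function(wf, cfg = eap_config()) {
  w <- wf$mean
  fs <- wf$sample_rate
  nw <- odd_window(cfg$smooth_window, fs)
  if (length(w) <= nw)
    stop("waveform too short for the inflection smoothing window")
  d1 <- signal::sgolayfilt(c(0, diff(w)), p = 3, n = nw)
  d2 <- signal::sgolayfilt(c(0, diff(d1)), p = 3, n = nw)
  # Baseline noise crosses zero constantly, so an inflection point is the
  # zero-crossing between two consecutive opposite-signed curvature lobes
  # that each reach inflection_min_frac of the largest curvature.
  cross <- integer(0)
  if (cfg$inflection_min_frac > 0) {
    lim <- cfg$inflection_min_frac * max(abs(d2))
    r <- rle(as.integer(sign(d2) * (abs(d2) >= lim)))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    nz <- which(r$values != 0L)
    if (length(nz) >= 2L) {
      for (k in seq_len(length(nz) - 1L)) {
        a <- nz[k]; b <- nz[k + 1L]
        if (r$values[a] != r$values[b]) {
          seg <- ends[a]:starts[b]
          cross <- c(cross, seg[which.min(abs(d2[seg]))])
        }
      }
    }
  } else {
    sgn <- sign(d2)
    sgn[sgn == 0] <- 1
    cross <- which(diff(sgn) != 0)
  }
  t_rel <- (wf$t %||% ((seq_along(w) - 1L) / fs))
  flagged <- function() list(secondary_amp = 0, primary_amp = max(w),
                             secondary_rel = 0,
                             inflection_times = t_rel[cross],
                             no_secondary_lobe = TRUE)
  if (length(cross) < 3L) return(flagged())
  i3 <- cross[3L]
  if (i3 >= length(w) - 1L) return(flagged())
  # the secondary amplitude must be a genuine local maximum after the
  # third inflection; a monotone decay there is a single-peak EAP
  cand <- local_maxima_above(w[i3:length(w)], -Inf, 1L)
  if (!length(cand)) return(flagged())
  primary <- max(w[seq_len(i3)])
  secondary <- max(w[i3 + cand - 1L])
  list(secondary_amp = secondary, primary_amp = primary,
       secondary_rel = secondary / primary,
       inflection_times = t_rel[cross], no_secondary_lobe = FALSE)
}

#' Shift of the secondary peak between two conditions
#'
#' Compares the secondary-peak amplitude of the mean waveform built from
#' pre-condition events against that from post-condition events (typically
#' the first 50 events before and the last 50 events in a drug);
#' `shift = secondary_amp(pre) - secondary_amp(post)`, so channel block
#' that suppresses the secondary current gives a positive
#' (hyperpolarizing) shift.
#'
#' @param bp_pre,bp_post band-passed current [trace()]s for the two
#'   conditions (may be the same trace).
#' @param pre_events,post_events detection-peak times in each condition
#'   (>= 2 each).
#' @param cfg an [eap_config()].
#' @return list with `shift` (pA), and the two [secondary_peak()] results
#'   as `pre` and `post`.
#' @export
condition_shift <- function(bp_pre, pre_events, bp_post, post_events,
                            cfg = eap_config()) {
  if (length(pre_events) < 2L || length(post_events) < 2L)
    stop("need at least 2 events per condition")
  sp_pre <- secondary_peak(mean_waveform(bp_pre, pre_events, cfg), cfg)
  sp_post <- secondary_peak(mean_waveform(bp_post, post_events, cfg), cfg)
  list(shift = sp_pre$secondary_amp - sp_post$secondary_amp,
       pre = sp_pre, post = sp_post)
}

#' Detect and measure all EAPs in a trace
#'
#' Runs [detect_eaps()], per-event [integrate_eap()] and the population
#' [secondary_peak()] on the mean waveform.
#'
#' @param bp a band-passed current [trace()].
#' @param cfg an [eap_config()].
#' @return list with `events` (data.frame: `time`, `integral_peak`),
#'   `waveform` (the mean waveform, `NULL` for < 2 events) and `secondary`
#'   (the [secondary_peak()] result, `NULL` for < 2 events).
#' @export
analyze_eap_trace <- function(bp, cfg = eap_config()) {
  ev <- detect_eaps(bp, cfg)
  fs <- bp$sample_rate
  margin_lo <- cfg$pre_window + cfg$baseline_window
  ok <- ev$time - margin_lo > bp$start_time &
    ev$time + cfg$post_window < bp$start_time + length(bp$samples) / fs
  ev <- ev[ok, , drop = FALSE]
  ipk <- vapply(ev$time, function(tt)
    integrate_eap(bp, tt, cfg)$integral_peak, 0)
  wf <- NULL; sp <- NULL
  if (nrow(ev) >= 2L) {
    wf <- mean_waveform(bp, ev$time, cfg)
    sp <- secondary_peak(wf, cfg)
  }
  list(events = data.frame(time = ev$time, integral_peak = ipk),
       waveform = wf, secondary = sp)
}
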