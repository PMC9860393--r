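#' Match Ca2+ spikes with EAPs by time
#'
#' Greedy nearest-neighbour matching: each Ca2+ spike is paired with the
#' closest unused EAP within the tolerance (default one imaging frame).
#'
#' @param ca_times Ca2+ spike times, s.
#' @param eap_times EAP times, s.
#' @param tol matching tolerance, s.
#' @param align when `TRUE`, a systematic latency between the two channels
#'   (clock offset, filter/kernel delay) is first estimated as the median
#'   time difference of a coarse match and removed, so `tol` bounds the
#'   jitter only.
#' @return list with `pairs` (data.frame `ca_index`, `eap_index`,
#'   `ca_time`, `eap_time`), `unmatched_ca`, `unmatched_eap` (indices) and
#'   `offset` (the removed latency, s; Ca relative to EAP).
#' @export
match_events <- function(ca_times, eap_times, tol, align = FALSE) {
  offset <- 0
  if (align && length(ca_times) && length(eap_times)) {
    coarse <- match_events(ca_times, eap_times, max(0.25, 10 * tol),
                           align = FALSE)
    if (nrow(coarse$pairs))
      offset <- median(coarse$pairs$ca_time - coarse$pairs$eap_time)
  }
  a <- ca_times - offset
  used <- rep(FALSE, length(eap_times))
  ca_idx <- integer(0); eap_idx <- integer(0)
  for (i in seq_along(a)) {
    if (!length(eap_times)) break
    d <- abs(eap_times - a[i])
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) && d[j] <= tol) {
      used[j] <- TRUE
      ca_idx <- c(ca_idx, i); eap_idx <- c(eap_idx, j)
    }
  }
  list(pairs = data.frame(ca_index = ca_idx, eap_index = eap_idx,
                          ca_time = ca_times[ca_idx],
                          eap_time = eap_times[eap_idx]),
       unmatched_ca = setdiff(seq_along(ca_times), ca_idx),
       unmatched_eap = setdiff(seq_along(eap_times), eap_idx),
       offset = offset)
}

# score detections against ground truth within a +-tol (s) window;
# constant detection latency is not a failure, so matching is aligned
score_detection <- function(detected_times, true_times, tol) {
  m <- match_events(detected_times, true_times, tol, align = TRUE)
  tp <- nrow(m$pairs)
  list(sensitivity = if (length(true_times)) tp / length(true_times) else NA,
       precision = if (length(detected_times)) tp / length(detected_times)
                   else NA,
       matched = m$pairs)
}

write_cell_table <- function(cells, path, seed = NULL) {
  df <- do.call(rbind, lapply(cells, function(cr) {
    data.frame(cell_id = cr$cell_id, rate = cr$rate, isi_cv = cr$isi_cv,
               n_events = cr$n_events, jb_stat = cr$jb_stat,
               jb_crit = cr$jb_crit, multimodal = cr$multimodal,
               mean_snr = cr$mean_snr)
  }))
  if (!is.null(path)) {
    utils::write.csv(df, path, row.names = FALSE)
    jsonlite::write_json(list(seed = seed), paste0(path, ".json"),
                         auto_unbox = TRUE)
  }
  df
}

#' Run the spontaneous-activity scenario
#'
#' Simulates (or loads) per-cell fluorescence recordings, normalizes them
#' to \eqn{\Delta F/F}, detects and measures spikes, and summarizes each
#' cell (rate, ISI CV, JB multimodality, mean SNR) plus population medians
#' and IQRs.
#'
#' @param n_cells number of cells to simulate.
#' @param duration per-cell recording duration, s.
#' @param rate spontaneous rate, Hz.
#' @param params a [spike_class_params()].
#' @param kernel a [kernel_params()].
#' @param cfg a [detection_config()].
#' @param seed integer seed.
#' @param traces optionally, a named list of raw fluorescence [trace()]s
#'   to analyse instead of simulating (names become cell ids).
#' @param out_dir optional output directory for the per-cell CSV.
#' @return list with `cells` (list of [cell_result()]), `table`
#'   (data.frame), `population` (medians ± IQR), `truths` (ground truth
#'   per simulated cell, `NULL` when `traces` given), `seed`.
#' @export
run_spontaneous <- function(n_cells = 32, duration = 300, rate = 0.148,
                            params = spike_class_params(),
                            kernel = kernel_params(),
                            cfg = detection_config(), seed = NULL,
                            traces = NULL, out_dir = NULL) {
  if (is.null(traces)) {
    sims <- lapply(seq_len(n_cells), function(i)
      simulate_spontaneous_cell(rate, duration, params, kernel,
                                seed = derive_seed(seed, i)))
    traces <- lapply(sims, `[[`, "raw")
    names(traces) <- sprintf("cell_%03d", seq_len(n_cells))
    truths <- lapply(sims, `[[`, "truth")
  } else {
    truths <- NULL
    if (is.null(names(traces)))
      names(traces) <- sprintf("cell_%03d", seq_along(traces))
  }
  cells <- vector("list", length(traces))
  for (i in seq_along(traces)) {
    ev <- tryCatch(analyze_ca_trace(dff(traces[[i]]), cfg),
                   error = function(e) {
                     warning("cell ", names(traces)[i], " failed: ",
                             conditionMessage(e))
                     NULL
                   })
    if (is.null(ev)) next
    cells[[i]] <- cell_result(names(traces)[i], ev,
                              trace_duration(traces[[i]]),
                              seed = derive_seed(seed, 1000L + i))
  }
  cells <- Filter(Negate(is.null), cells)
  if (!length(cells))
    return(list(cells = list(), table = NULL, population = NULL,
                truths = truths, seed = seed))
  tab <- write_cell_table(cells,
                          if (!is.null(out_dir))
                            file.path(out_dir, "cells.csv") else NULL,
                          seed = seed)
  pop <- list(
    rate_median = median(tab$rate), rate_iqr = stats::IQR(tab$rate),
    cv_median = median(tab$isi_cv, na.rm = TRUE),
    cv_iqr = stats::IQR(tab$isi_cv, na.rm = TRUE),
    n_multimodal = sum(tab$multimodal, na.rm = TRUE),
    n_cells = nrow(tab))
  list(cells = cells, table = tab, population = pop, truths = truths,
       seed = seed)
}

#' Run the paired Ca2+ / EAP scenario
#'
#' Simulates (or accepts) a simultaneous fluorescence + current recording,
#' detects events on both channels, matches them in time and regresses
#' Ca2+ amplitude on the \eqn{\int}EAP peak.
#'
#' @param rate,duration,params,kernel,template,seed forwarded to
#'   [generate_paired_recording()].
#' @param cfg a [detection_config()].
#' @param eap_cfg an [eap_config()].
#' @param tol matching tolerance, s; default one imaging frame.
#' @param recording optionally a list with `ca` and `eap` traces to
#'   analyse instead of simulating.
#' @return list with `matched` (data.frame `ca_time`, `eap_time`,
#'   `amplitude`, `integral_peak`), `regression` (from
#'   [paired_regression()]), `n_unmatched_ca`, `n_unmatched_eap`, `truth`,
#'   `seed`.
#' @export
run_paired <- function(rate = 0.43, duration = 300,
                       params = spike_class_params(),
                       kernel = kernel_params(),
                       template = eap_template_params(),
                       cfg = detection_config(), eap_cfg = eap_config(),
                       tol = NULL, seed = NULL, recording = NULL) {
  truth <- NULL
  if (is.null(recording)) {
    recording <- generate_paired_recording(rate, duration, params, kernel,
                                           template, seed = seed)
    truth <- recording$truth
    # per-cell threshold, as in the original recordings: the EAP noise
    # floor is far below the primary peak, so half the template primary
    # is a safe cell-specific threshold
    if (is.null(eap_cfg$detect_threshold))
      eap_cfg$detect_threshold <- template$primary_amp / 2
  }
  tol <- tol %||% (1 / recording$ca$sample_rate)
  ca_ev <- analyze_ca_trace(recording$ca, cfg)
  eap_res <- analyze_eap_trace(bandpass(recording$eap), eap_cfg)
  # Ca spikes are matched on their derivative-peak time (stable across
  # amplitudes, unlike the threshold-crossing onset); the constant
  # imaging-vs-ephys latency (kernel rise, filter delay) is removed
  # before the tolerance is applied
  m <- match_events(ca_ev$time, eap_res$events$time, tol, align = TRUE)
  matched <- data.frame(
    ca_time = m$pairs$ca_time, eap_time = m$pairs$eap_time,
    amplitude = ca_ev$amplitude[m$pairs$ca_index],
    integral_peak = eap_res$events$integral_peak[m$pairs$eap_index])
  reg <- if (nrow(matched) >= 3)
    paired_regression(matched$integral_peak, matched$amplitude) else NULL
  list(matched = matched, regression = reg,
       n_unmatched_ca = length(m$unmatched_ca),
       n_unmatched_eap = length(m$unmatched_eap),
       ca_events = ca_ev, eap = eap_res, truth = truth, seed = seed)
}

#' Run a pharmacology scenario
#'
#' Simulates paired pre/post recordings for each cell under a drug
#' condition (`TTx`, `Cd` or `ML218`), analyses both epochs through the
#' full detection chain, and reports the per-cell rate and amplitude
#' comparisons plus the mean-normalized pooled amplitude distributions.
#'
#' @param condition `"TTx"`, `"Cd"` or `"ML218"`.
#' @param n_cells number of cells.
#' @param duration per-epoch duration, s.
#' @param rate spontaneous rate, Hz.
#' @param params,kernel a [spike_class_params()] / [kernel_params()].
#' @param cfg a [detection_config()].
#' @param seed integer seed.
#' @param ... forwarded to [apply_condition()] (e.g. `survival`).
#' @return list with `per_cell` (data.frame of pre/post rates and mean
#'   amplitudes), `rate_test`, `amplitude_test` (paired
#'   [compare_conditions()]), `pooled` (normalized pools),
#'   `distribution_test` (KS on pools), `seed`.
#' @export
run_pharmacology <- function(condition, n_cells = 24, duration = 300,
                             rate = 0.148, params = spike_class_params(),
                             kernel = kernel_params(),
                             cfg = detection_config(), seed = NULL, ...) {
  pre_rate <- post_rate <- pre_amp <- post_amp <- numeric(n_cells)
  cells_amps <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    s_i <- derive_seed(seed, i)
    times <- generate_spike_train(rate, duration,
                                  seed = derive_seed(s_i, 1))
    truth <- assign_amplitudes(times, params, seed = derive_seed(s_i, 2),
                               rate = rate)
    post_truth <- apply_condition(truth, condition, params,
                                  seed = derive_seed(s_i, 3), ...)
    analyze_epoch <- function(tr_truth, stream) {
      d <- render_ca_trace(tr_truth, kernel, duration,
                           seed = derive_seed(s_i, stream))
      analyze_ca_trace(d, cfg)
    }
    ev_pre <- analyze_epoch(truth, 4)
    ev_post <- analyze_epoch(post_truth, 5)
    pre_rate[i] <- nrow(ev_pre) / duration
    post_rate[i] <- nrow(ev_post) / duration
    pre_amp[i] <- if (nrow(ev_pre)) mean(ev_pre$amplitude) else NA
    post_amp[i] <- if (nrow(ev_post)) mean(ev_post$amplitude) else NA
    cells_amps[[i]] <- list(control = ev_pre$amplitude,
                            treated = ev_post$amplitude)
  }
  pooled <- normalize_amplitudes(cells_amps, "control")
  dist_test <- if (length(pooled$treated) >= 5)
    compare_conditions(pooled$control, pooled$treated, "distribution")
  else NULL
  ok <- complete.cases(pre_amp, post_amp)
  list(
    condition = condition,
    per_cell = data.frame(pre_rate = pre_rate, post_rate = post_rate,
                          pre_amp = pre_amp, post_amp = post_amp),
    rate_test = compare_conditions(pre_rate, post_rate, "paired"),
    amplitude_test = if (sum(ok) >= 5)
      compare_conditions(pre_amp[ok], post_amp[ok], "paired") else NULL,
    pooled = pooled, distribution_test = dist_test, seed = seed)
}

#' Benchmark the Ca2+ spike detector against ground truth
#'
#' Sweeps the imaging noise level, scoring sensitivity, precision,
#' amplitude bias and the amplitude-regression R-squared at each point.
#'
#' @param noise_levels \eqn{\Delta F/F} noise SDs to sweep.
#' @param rate,duration Poisson rate (Hz) / duration (s) per point.
#' @param params a [spike_class_params()].
#' @param cfg a [detection_config()].
#' @param frame_rate imaging rate, Hz.
#' @param match_tol_frames match tolerance in frames (default 3).
#' @param seed integer seed.
#' @return data.frame with one row per noise level: `noise_sd`,
#'   `sensitivity`, `precision`, `amplitude_bias`, `mean_snr`,
#'   `r_squared` (true vs measured amplitude over matched events), and
#'   attribute `seed`.
#' @export
run_benchmark <- function(noise_levels = c(0.01, 0.02, 0.04, 0.08),
                          rate = 0.148, duration = 600,
                          params = spike_class_params(),
                          cfg = detection_config(), frame_rate = 60,
                          match_tol_frames = 3, seed = NULL) {
  rows <- lapply(seq_along(noise_levels), function(k) {
    ns <- noise_levels[k]
    kern <- kernel_params(frame_rate = frame_rate, noise_sd = ns)
    sim <- simulate_spontaneous_cell(rate, duration, params, kern,
                                     seed = derive_seed(seed, k))
    ev <- analyze_ca_trace(dff(sim$raw), cfg)
    sc <- score_detection(ev$time, sim$truth$event_times,
                          match_tol_frames / frame_rate)
    est <- ev$amplitude[sc$matched$ca_index]
    tru <- sim$truth$true_amplitudes[sc$matched$eap_index]
    bias <- if (length(tru)) (mean(est) - mean(tru)) / mean(tru) else NA
    r2 <- if (length(tru) >= 3 && var(tru) > 0 && var(est) > 0)
      stats::cor(tru, est)^2 else NA
    fin <- ev$snr[is.finite(ev$snr)]
    data.frame(noise_sd = ns,
               sensitivity = sc$sensitivity, precision = sc$precision,
               amplitude_bias = bias,
               mean_snr = if (length(fin)) mean(fin) else NA,
               r_squared = r2)
  })
  out <- do.call(rbind, rows)
  attr(out, "seed") <- seed
  out
}
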