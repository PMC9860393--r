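#' Parameters of the two-class spike-amplitude mixture
#'
#' Spontaneous Ca2+ spikes come in a small (T-type driven) and a large
#' (HVA-boosted) amplitude class; each class is log-normal on the
#' \eqn{\Delta F/F} scale.  Defaults put the class medians at 0.3 and 1.5
#' \eqn{\Delta F/F}, separated enough that the mixture is bimodal and fails
#' a normality screen.
#'
#' @param p_large probability that an event belongs to the large class.
#' @param small_amp_mu,small_amp_sigma log-scale location / spread of the
#'   small class (`small_amp_mu = log(median)`).
#' @param large_amp_mu,large_amp_sigma same for the large class.
#' @param coupling_slope Ca2+ amplitude (\eqn{\Delta F/F}) per unit EAP
#'   integral peak (pA s), used by [generate_paired_recording()].
#' @param coupling_noise_sd additive Gaussian noise on the coupled Ca2+
#'   amplitude (\eqn{\Delta F/F}).
#' @return list of class `spike_class_params`.
#' @export
spike_class_params <- function(p_large = 0.4,
                               small_amp_mu = log(0.3), small_amp_sigma = 0.25,
                               large_amp_mu = log(1.5), large_amp_sigma = 0.25,
                               coupling_slope = 25, coupling_noise_sd = 0.1) {
  if (p_large < 0 || p_large > 1)
    stop("p_large must be in [0, 1], got ", p_large)
  if (small_amp_sigma < 0 || large_amp_sigma < 0)
    stop("class sigmas must be >= 0")
  if (exp(large_amp_mu) <= exp(small_amp_mu))
    stop("large-class median must exceed small-class median")
  if (coupling_noise_sd < 0) stop("coupling_noise_sd must be >= 0")
  structure(list(p_large = p_large,
                 small_amp_mu = small_amp_mu, small_amp_sigma = small_amp_sigma,
                 large_amp_mu = large_amp_mu, large_amp_sigma = large_amp_sigma,
                 coupling_slope = coupling_slope,
                 coupling_noise_sd = coupling_noise_sd),
            class = "spike_class_params")
}

#' Parameters of the fluorescence transient kernel
#'
#' A GCaMP6f-like unit-peak double-exponential transient,
#' \eqn{\exp(-t/\tau_d) - \exp(-t/\tau_r)} rescaled to peak 1.  The paper's
#' recordings give no kernel, so defaults are literature-typical for
#' GCaMP6f and fully configurable.
#'
#' @param rise_tau,decay_tau rise / decay time constants in seconds
#'   (`0 < rise_tau < decay_tau`).
#' @param frame_rate imaging frame rate in Hz (typically 30-120).
#' @param noise_sd additive i.i.d. Gaussian noise SD in \eqn{\Delta F/F}.
#' @return list of class `kernel_params`.
#' @export
kernel_params <- function(rise_tau = 0.05, decay_tau = 0.4,
                          frame_rate = 60, noise_sd = 0.02) {
  if (!(rise_tau > 0 && rise_tau < decay_tau))
    stop("need 0 < rise_tau < decay_tau, got ", rise_tau, " / ", decay_tau)
  if (frame_rate <= 0) stop("frame_rate must be positive")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(rise_tau = rise_tau, decay_tau = decay_tau,
                 frame_rate = frame_rate, noise_sd = noise_sd),
            class = "kernel_params")
}

#' Parameters of the dual-peak EAP waveform template
#'
#' Phenomenological extracellular action potential: a sum of three Gaussian
#' lobes rendered depolarizing-positive — a primary depolarizing lobe at
#' t = 0, a repolarizing lobe at `secondary_delay / 2` (width
#' `primary_width / 2`), and a secondary depolarizing lobe at
#' `secondary_delay` whose per-event amplitude is `scale * primary_amp`.
#' Widths are full widths at half maximum.  The secondary scale
#' distribution is log-normal with median `secondary_rel_median` and
#' log-spread set so its interquartile width matches `secondary_rel_iqr`.
#'
#' @param sample_rate recording rate in Hz (>= 10 kHz).
#' @param primary_amp primary lobe amplitude, pA.
#' @param primary_width FWHM of the primary lobe, s.
#' @param repol_amp repolarizing lobe depth, pA (rendered negative).
#' @param secondary_delay centre of the secondary lobe relative to the
#'   primary, s.
#' @param secondary_width FWHM of the secondary lobe, s.
#' @param secondary_rel_median median of the per-event secondary scale
#'   (fraction of the primary; default 0.23).
#' @param secondary_rel_iqr interquartile width of that distribution.
#' @param noise_sd additive Gaussian noise, pA.
#' @return list of class `eap_template_params`.
#' @export
eap_template_params <- function(sample_rate = 20000,
                                primary_amp = 25, primary_width = 1e-3,
                                repol_amp = 8,
                                secondary_delay = 3e-3, secondary_width = 2e-3,
                                secondary_rel_median = 0.23,
                                secondary_rel_iqr = 0.26,
                                noise_sd = 0.5) {
  if (sample_rate < 10000)
    stop("sample_rate must be >= 10 kHz, got ", sample_rate)
  if (primary_width <= 0 || secondary_width <= 0 || secondary_delay <= 0)
    stop("widths and delays must be > 0")
  if (secondary_rel_median < 0 || secondary_rel_median > 1.5)
    stop("secondary_rel_median must be in [0, 1.5]")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(sample_rate = sample_rate, primary_amp = primary_amp,
                 primary_width = primary_width, repol_amp = repol_amp,
                 secondary_delay = secondary_delay,
                 secondary_width = secondary_width,
                 secondary_rel_median = secondary_rel_median,
                 secondary_rel_iqr = secondary_rel_iqr,
                 noise_sd = noise_sd),
            class = "eap_template_params")
}

# log-sd such that a log-normal with the given median has the requested
# interquartile width: median * (e^{c s} - e^{-c s}) = iqr, c = qnorm(0.75)
secondary_scale_sdlog <- function(median, iqr) {
  if (median <= 0) return(0)
  asinh(iqr / (2 * median)) / stats::qnorm(0.75)
}

#' Draw per-cell secondary-peak fractions
#'
#' The secondary depolarizing current varies across cells: its per-cell
#' relative amplitude (fraction of the primary, measured on the mean EAP
#' waveform) is log-normal across the population with median
#' `secondary_rel_median` (default 0.23) and log-spread set from
#' `secondary_rel_iqr`.
#'
#' @param n_cells number of cells.
#' @param template an [eap_template_params()].
#' @param seed integer seed.
#' @return numeric vector of per-cell secondary fractions.
#' @export
draw_cell_secondary_rel <- function(n_cells, template = eap_template_params(),
                                    seed = NULL) {
  sdl <- secondary_scale_sdlog(template$secondary_rel_median,
                               template$secondary_rel_iqr)
  with_seed(seed,
            rlnorm(n_cells, log(template$secondary_rel_median), sdl))
}

#' Ground-truth event record for synthetic recordings
#'
#' The oracle for recovery tests: true event times, class labels,
#' amplitudes and per-event secondary scales.
#'
#' @param event_times event times in seconds, strictly increasing.
#' @param class_labels `"small"` / `"large"` per event.
#' @param true_amplitudes true Ca2+ amplitudes (\eqn{\Delta F/F}) per event.
#' @param true_secondary_scales secondary EAP scale per event (fraction).
#' @param rate generating rate in Hz.
#' @param seed seed the record was generated under.
#' @return list of class `ground_truth`.
#' @export
ground_truth <- function(event_times, class_labels = NULL,
                         true_amplitudes = NULL, true_secondary_scales = NULL,
                         rate = NA_real_, seed = NA_integer_) {
  n <- length(event_times)
  if (n > 1 && any(diff(event_times) <= 0))
    stop("event_times must be strictly increasing")
  fill <- function(x, default) if (is.null(x)) rep(default, n) else x
  class_labels <- fill(class_labels, NA_character_)
  true_amplitudes <- fill(true_amplitudes, NA_real_)
  true_secondary_scales <- fill(true_secondary_scales, NA_real_)
  if (length(class_labels) != n || length(true_amplitudes) != n ||
      length(true_secondary_scales) != n)
    stop("one label, amplitude and secondary scale required per event")
  structure(list(event_times = as.numeric(event_times),
                 class_labels = as.character(class_labels),
                 true_amplitudes = as.numeric(true_amplitudes),
                 true_secondary_scales = as.numeric(true_secondary_scales),
                 rate = rate, seed = seed),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d events, rate %.4g Hz, seed %s\n",
              length(x$event_times), x$rate, format(x$seed)))
  invisible(x)
}

#' Generate a homogeneous Poisson spike train
#'
#' Exponential i.i.d. inter-spike intervals at the given rate, truncated to
#' `[0, duration]`.  The default rate is the population median spontaneous
#' rate of CSF-contacting neurons, 0.148 Hz.
#'
#' @param rate mean event rate in Hz (>= 0).
#' @param duration recording duration in seconds (> 0).
#' @param seed integer seed; identical seeds give identical trains.
#' @return numeric vector of event times (seconds), strictly increasing.
#' @examples
#' generate_spike_train(0.148, 600, seed = 1)
#' @export
generate_spike_train <- function(rate = 0.148, duration, seed = NULL) {
  if (rate < 0) stop("rate must be >= 0, got ", rate)
  if (duration <= 0) stop("duration must be > 0, got ", duration)
  if (rate == 0) return(numeric(0))
  with_seed(seed, {
    # draw in blocks until past the end of the window
    times <- numeric(0)
    t_last <- 0
    block <- max(16L, ceiling(rate * duration * 1.25))
    repeat {
      times <- c(times, t_last + cumsum(rexp(block, rate)))
      t_last <- times[length(times)]
      if (t_last > duration) break
    }
    times[times <= duration]
  })
}

#' Assign class labels and amplitudes to events
#'
#' Each event is labelled large with probability `p_large` and its Ca2+
#' amplitude drawn log-normal from its class.  Per-event secondary EAP
#' scales model spike-to-spike variability of the secondary depolarizing
#' current: log-normal with mean equal to the cell's characteristic
#' fraction `cell_secondary_rel` (mean-preserving, so the cell's mean
#' waveform recovers that fraction) and log-spread
#' `secondary_within_sdlog`.
#'
#' @param event_times event times in seconds.
#' @param params a [spike_class_params()].
#' @param seed integer seed.
#' @param template an [eap_template_params()].
#' @param cell_secondary_rel this cell's secondary fraction (defaults to
#'   the template's population median; see [draw_cell_secondary_rel()]).
#' @param secondary_within_sdlog within-cell log-spread of per-event
#'   secondary scales.
#' @param rate generating rate recorded in the result (Hz).
#' @return a [ground_truth()].
#' @export
assign_amplitudes <- function(event_times, params = spike_class_params(),
                              seed = NULL, template = eap_template_params(),
                              cell_secondary_rel = NULL,
                              secondary_within_sdlog = 0.6,
                              rate = NA_real_) {
  stopifnot(inherits(params, "spike_class_params"))
  cell_secondary_rel <- cell_secondary_rel %||% template$secondary_rel_median
  n <- length(event_times)
  with_seed(seed, {
    large <- runif(n) < params$p_large
    amps <- numeric(n)
    amps[large] <- rlnorm(sum(large), params$large_amp_mu,
                          params$large_amp_sigma)
    amps[!large] <- rlnorm(sum(!large), params$small_amp_mu,
                           params$small_amp_sigma)
    scales <- numeric(n)
    if (cell_secondary_rel > 0) {
      # meanlog offset keeps E[scale] = cell_secondary_rel
      scales <- rlnorm(n, log(cell_secondary_rel) -
                         secondary_within_sdlog^2 / 2,
                       secondary_within_sdlog)
    }
    ground_truth(event_times,
                 class_labels = ifelse(large, "large", "small"),
                 true_amplitudes = amps,
                 true_secondary_scales = scales,
                 rate = rate, seed = seed %||% NA_integer_)
  })
}

# unit-peak double-exponential transient evaluated at times t >= 0
ca_kernel <- function(t, rise_tau, decay_tau) {
  t_peak <- log(decay_tau / rise_tau) * rise_tau * decay_tau /
    (decay_tau - rise_tau)
  peak <- exp(-t_peak / decay_tau) - exp(-t_peak / rise_tau)
  ifelse(t < 0, 0, (exp(-t / decay_tau) - exp(-t / rise_tau)) / peak)
}

#' Render a fluorescence trace from ground truth
#'
#' Sum over events of `amplitude *` unit-peak double-exponential transient,
#' sampled at the kernel frame rate, plus i.i.d. Gaussian noise.
#' Overlapping transients add linearly.  Events outside `[0, duration)` are
#' dropped with a warning.
#'
#' @param truth a [ground_truth()].
#' @param kernel a [kernel_params()].
#' @param duration trace duration in seconds.
#' @param seed integer seed (noise only).
#' @return a [trace()] in \eqn{\Delta F/F} units.
#' @export
render_ca_trace <- function(truth, kernel = kernel_params(), duration,
                            seed = NULL) {
  stopifnot(inherits(truth, "ground_truth"), inherits(kernel, "kernel_params"))
  fs <- kernel$frame_rate
  n <- max(2L, round(duration * fs))
  sig <- numeric(n)
  keep <- truth$event_times >= 0 & truth$event_times < duration
  if (any(!keep))
    warning(sum(!keep), " event(s) outside the trace window were dropped")
  # transients are negligible after ~8 decay constants
  klen <- min(n, ceiling(8 * kernel$decay_tau * fs))
  kt <- (seq_len(klen) - 1) / fs
  for (i in which(keep)) {
    i0 <- floor(truth$event_times[i] * fs) + 1L
    frac <- truth$event_times[i] - (i0 - 1L) / fs
    idx <- i0:min(n, i0 + klen - 1L)
    sig[idx] <- sig[idx] +
      truth$true_amplitudes[i] *
      ca_kernel(kt[seq_along(idx)] - frac,
                kernel$rise_tau, kernel$decay_tau)
  }
  if (kernel$noise_sd > 0)
    sig <- sig + with_seed(seed, rnorm(n, 0, kernel$noise_sd))
  trace(sig, fs, units = "dff")
}

# noise-free template waveform at times t (s) relative to the primary peak
eap_waveform <- function(t, template, scale) {
  f2s <- function(w) w / (2 * sqrt(2 * log(2)))
  sp <- f2s(template$primary_width)
  sr <- f2s(template$primary_width / 2)
  ss <- f2s(template$secondary_width)
  template$primary_amp * exp(-t^2 / (2 * sp^2)) -
    template$repol_amp *
      exp(-(t - template$secondary_delay / 2)^2 / (2 * sr^2)) +
    scale * template$primary_amp *
      exp(-(t - template$secondary_delay)^2 / (2 * ss^2))
}

# support of one rendered event, s relative to the primary peak
eap_event_span <- function(template) {
  c(-2 * template$primary_width,
    template$secondary_delay + 3 * template$secondary_width)
}

#' Render an EAP current trace from event times
#'
#' Each event is a stereotyped three-lobe waveform (primary depolarizing,
#' repolarizing, secondary depolarizing scaled per event), rendered
#' depolarizing-positive, plus additive Gaussian noise.
#'
#' @param event_times event times in seconds (primary-peak times).
#' @param template an [eap_template_params()].
#' @param secondary_scales one scale (>= 0) per event.
#' @param duration trace duration in seconds.
#' @param seed integer seed (noise only).
#' @return a [trace()] in pA.
#' @export
render_eap_train <- function(event_times, template = eap_template_params(),
                             secondary_scales, duration, seed = NULL) {
  stopifnot(inherits(template, "eap_template_params"))
  if (length(secondary_scales) != length(event_times))
    stop("need one secondary scale per event: ", length(secondary_scales),
         " scales for ", length(event_times), " events")
  if (any(secondary_scales < 0)) stop("secondary scales must be >= 0")
  fs <- template$sample_rate
  n <- max(2L, round(duration * fs))
  sig <- numeric(n)
  span <- eap_event_span(template)
  for (i in seq_along(event_times)) {
    i0 <- max(1L, floor((event_times[i] + span[1]) * fs) + 1L)
    i1 <- min(n, ceiling((event_times[i] + span[2]) * fs) + 1L)
    if (i0 > i1) next
    tt <- (seq(i0, i1) - 1) / fs - event_times[i]
    sig[i0:i1] <- sig[i0:i1] + eap_waveform(tt, template, secondary_scales[i])
  }
  if (template$noise_sd > 0)
    sig <- sig + with_seed(seed, rnorm(n, 0, template$noise_sd))
  trace(sig, fs, units = "pA")
}

# integral peak (pA s) of a noise-free template event at a given scale
eap_template_integral_peak <- function(template, scale,
                                       window = c(-2e-3, 15e-3)) {
  fs <- template$sample_rate
  tt <- seq(window[1], window[2], by = 1 / fs)
  max(pracma::cumtrapz(tt, eap_waveform(tt, template, scale)))
}

#' Generate a paired Ca2+ / EAP recording with shared ground truth
#'
#' Identical event times drive both channels; each Ca2+ amplitude is
#' `coupling_slope *` (noise-free EAP integral peak) `+ N(0,
#' coupling_noise_sd)`, so every EAP has a matching Ca2+ spike and vice
#' versa.
#'
#' @param rate event rate in Hz.
#' @param duration recording duration in seconds.
#' @param params a [spike_class_params()] (supplies coupling parameters).
#' @param kernel a [kernel_params()].
#' @param template an [eap_template_params()].
#' @param seed integer seed.
#' @return list with `ca` (trace, \eqn{\Delta F/F}), `eap` (trace, pA),
#'   `truth` (a [ground_truth()]) and `integral_peaks` (true noise-free
#'   \eqn{\int}EAP peak per event, pA s).
#' @export
generate_paired_recording <- function(rate = 0.43, duration = 300,
                                      params = spike_class_params(),
                                      kernel = kernel_params(),
                                      template = eap_template_params(),
                                      seed = NULL) {
  times <- generate_spike_train(rate, duration, seed = derive_seed(seed, 1))
  truth <- assign_amplitudes(times, params, seed = derive_seed(seed, 2),
                             template = template, rate = rate)
  ipk <- vapply(truth$true_secondary_scales, function(s)
    eap_template_integral_peak(template, s), 0)
  amps <- params$coupling_slope * ipk
  if (params$coupling_noise_sd > 0)
    amps <- amps + with_seed(derive_seed(seed, 3),
                             rnorm(length(amps), 0, params$coupling_noise_sd))
  truth$true_amplitudes <- pmax(amps, 0)
  ca <- render_ca_trace(truth, kernel, duration, seed = derive_seed(seed, 4))
  eap <- render_eap_train(truth$event_times, template,
                          truth$true_secondary_scales, duration,
                          seed = derive_seed(seed, 5))
  list(ca = ca, eap = eap, truth = truth, integral_peaks = ipk)
}

#' Apply an experimental condition to ground truth
#'
#' Encodes the pharmacology and perturbation scenarios:
#' \describe{
#'   \item{TTx}{identity — Na+ channel block does not affect these Ca2+
#'     spikes.}
#'   \item{Cd}{HVA Ca2+ channel block: all large-class events are
#'     reassigned small-class amplitudes and secondary scales drop to 0.}
#'   \item{ML218}{T-type block: events thinned by a survival probability
#'     (default 0.05).}
#'   \item{electrode}{pipette-contact perturbation: rate multiplied
#'     (default x3) by superposing an independent Poisson train with
#'     freshly assigned amplitudes.}
#'   \item{ACh, ATP}{agonist-evoked trials: trains confined to declared
#'     stimulus windows, large-class-only (ACh) or small-class-only (ATP).}
#' }
#'
#' @param truth a [ground_truth()] (ignored for evoked protocols, which
#'   build their trains inside the stimulus windows).
#' @param condition one of `"TTx"`, `"Cd"`, `"ML218"`, `"electrode"`,
#'   `"ACh"`, `"ATP"`.
#' @param params a [spike_class_params()].
#' @param template an [eap_template_params()].
#' @param seed integer seed.
#' @param survival ML218 survival probability.
#' @param rate_factor electrode rate multiplier.
#' @param stim_windows for evoked protocols, a 2-column matrix of
#'   `[start, end]` stimulus windows in seconds.
#' @param evoked_rate event rate inside stimulus windows, Hz.
#' @return a [ground_truth()] under the condition.
#' @export
apply_condition <- function(truth, condition, params = spike_class_params(),
                            template = eap_template_params(), seed = NULL,
                            survival = 0.05, rate_factor = 3,
                            stim_windows = NULL, evoked_rate = 2) {
  valid <- c("TTx", "Cd", "ML218", "electrode", "ACh", "ATP")
  if (!condition %in% valid)
    stop("unknown condition '", condition, "'; valid conditions: ",
         paste(valid, collapse = ", "))
  stopifnot(inherits(truth, "ground_truth"))
  switch(condition,
    TTx = truth,
    Cd = {
      out <- truth
      large <- out$class_labels == "large"
      out$true_amplitudes[large] <- with_seed(seed,
        rlnorm(sum(large), params$small_amp_mu, params$small_amp_sigma))
      out$class_labels[large] <- "small"
      out$true_secondary_scales[] <- 0
      out
    },
    ML218 = {
      keep <- with_seed(seed,
        runif(length(truth$event_times)) < survival)
      ground_truth(truth$event_times[keep], truth$class_labels[keep],
                   truth$true_amplitudes[keep],
                   truth$true_secondary_scales[keep],
                   rate = truth$rate * survival, seed = seed %||% truth$seed)
    },
    electrode = {
      if (is.na(truth$rate))
        stop("electrode condition needs the ground-truth rate")
      dur <- max(truth$event_times, 0) + 1e-9
      extra_times <- generate_spike_train((rate_factor - 1) * truth$rate,
                                          dur, seed = derive_seed(seed, 11))
      extra <- assign_amplitudes(extra_times, params,
                                 seed = derive_seed(seed, 12),
                                 template = template)
      o <- order(c(truth$event_times, extra$event_times))
      ground_truth(c(truth$event_times, extra$event_times)[o],
                   c(truth$class_labels, extra$class_labels)[o],
                   c(truth$true_amplitudes, extra$true_amplitudes)[o],
                   c(truth$true_secondary_scales,
                     extra$true_secondary_scales)[o],
                   rate = truth$rate * rate_factor,
                   seed = seed %||% truth$seed)
    },
    ACh = ,
    ATP = {
      if (is.null(stim_windows))
        stop(condition, " is an evoked protocol: supply stim_windows")
      stim_windows <- matrix(stim_windows, ncol = 2)
      cls_params <- if (condition == "ACh")
        spike_class_params(p_large = 1,
                           small_amp_mu = params$small_amp_mu,
                           small_amp_sigma = params$small_amp_sigma,
                           large_amp_mu = params$large_amp_mu,
                           large_amp_sigma = params$large_amp_sigma,
                           coupling_slope = params$coupling_slope,
                           coupling_noise_sd = params$coupling_noise_sd)
      else
        spike_class_params(p_large = 0,
                           small_amp_mu = params$small_amp_mu,
                           small_amp_sigma = params$small_amp_sigma,
                           large_amp_mu = params$large_amp_mu,
                           large_amp_sigma = params$large_amp_sigma,
                           coupling_slope = params$coupling_slope,
                           coupling_noise_sd = params$coupling_noise_sd)
      times <- numeric(0)
      for (w in seq_len(nrow(stim_windows))) {
        tw <- generate_spike_train(evoked_rate,
                                   stim_windows[w, 2] - stim_windows[w, 1],
                                   seed = derive_seed(seed, 20 + w))
        times <- c(times, tw + stim_windows[w, 1])
      }
      assign_amplitudes(sort(times), cls_params,
                        seed = derive_seed(seed, 13), template = template,
                        rate = evoked_rate)
    })
}

#' Render a synthetic spontaneous recording as raw fluorescence
#'
#' Convenience wrapper used by the pipeline scenarios: draws a Poisson
#' train, assigns mixture amplitudes, renders the \eqn{\Delta F/F} signal
#' and converts it to raw fluorescence `F = f0 * (1 + dff)` so downstream
#' analysis exercises the baseline normalisation.
#'
#' @param rate,duration Poisson rate (Hz) and duration (s).
#' @param params a [spike_class_params()].
#' @param kernel a [kernel_params()].
#' @param f0 baseline fluorescence in arbitrary units.
#' @param seed integer seed.
#' @return list with `raw` (trace, au) and `truth` (a [ground_truth()]).
#' @export
simulate_spontaneous_cell <- function(rate = 0.148, duration = 300,
                                      params = spike_class_params(),
                                      kernel = kernel_params(),
                                      f0 = 100, seed = NULL) {
  times <- generate_spike_train(rate, duration, seed = derive_seed(seed, 1))
  truth <- assign_amplitudes(times, params, seed = derive_seed(seed, 2),
                             rate = rate)
  dff_tr <- render_ca_trace(truth, kernel, duration,
                            seed = derive_seed(seed, 3))
  raw <- trace(f0 * (1 + dff_tr$samples), kernel$frame_rate, units = "au")
  list(raw = raw, truth = truth)
}
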