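test_that("EAP detection finds template peaks and ignores noise", {
  tmpl <- eap_template_params(noise_sd = 0)
  times <- seq(0.5, 9.5, by = 0.5)
  tr <- render_eap_train(times, tmpl, rep(0.5, length(times)), 10)
  det <- detect_eaps(bandpass(tr))
  expect_identical(nrow(det), length(times))
  expect_lt(max(abs(det$time - times)), 2 / tmpl$sample_rate)

  # pure noise, auto threshold: < 1e-3 false positives per sample
  set.seed(31)
  noise <- trace(rnorm(2e5, 0, 0.5), 20000)
  fp <- nrow(detect_eaps(bandpass(noise)))
  expect_lt(fp / 2e5, 1e-3)
})

test_that("EAP recovery on the noisy synthetic scenario is near-complete", {
  tmpl <- eap_template_params()        # noise_sd 0.5 pA, primary SNR >> 8
  times <- generate_spike_train(0.43, 300, seed = 41)
  truth <- assign_amplitudes(times, seed = 42)
  tr <- render_eap_train(times, tmpl, truth$true_secondary_scales, 300,
                         seed = 43)
  det <- detect_eaps(bandpass(tr),
                     eap_config(detect_threshold = tmpl$primary_amp / 2))
  m <- match_events(det$time, times, 1e-3)
  sens <- nrow(m$pairs) / length(times)
  expect_gte(sens, 0.99)
})

test_that("mean waveform averages aligned events with per-sample SD", {
  tmpl <- eap_template_params(noise_sd = 0)
  times <- seq(0.5, 5, by = 0.5)
  tr <- render_eap_train(times, tmpl, rep(0.23, length(times)), 6)
  bp <- bandpass(tr)
  det <- detect_eaps(bp)
  wf <- mean_waveform(bp, det$time)
  # identical noise-free events: SD zero everywhere (up to the band-pass
  # filter's decaying tails overlapping neighbouring windows)
  expect_lt(max(wf$sd, na.rm = TRUE), 1e-4)

  # i.i.d. noise sd sigma: mean per-sample SD ~ sigma
  sigma <- 0.4
  tmpl_n <- eap_template_params(noise_sd = sigma)
  times2 <- seq(0.5, 50, by = 0.5)
  tr2 <- render_eap_train(times2, tmpl_n, rep(0.23, length(times2)), 51,
                          seed = 51)
  wf2 <- mean_waveform(tr2, times2)   # unfiltered: noise stays white
  n_ev <- length(times2)
  expect_lt(abs(mean(wf2$sd) - sigma), 3 * sigma / sqrt(2 * n_ev))

  expect_error(mean_waveform(bp, det$time[1]), "2 events")
})

test_that("the running EAP integral is a baseline-corrected trapezoid", {
  cfg <- eap_config()
  fs <- 20000
  # zero trace integrates to zero
  z <- trace(rep(0, fs), fs)
  expect_identical(integrate_eap(z, 0.5, cfg)$integral_peak, 0)

  # unit rectangular pulse of width w: integral peak = w
  w <- 5e-3
  pulse <- rep(0, fs)
  i0 <- 10000
  pulse[i0:(i0 + w * fs - 1)] <- 1
  pk <- integrate_eap(trace(pulse, fs), (i0 - 1) / fs + 1e-3, cfg)$integral_peak
  # trapezoid loses half a sample at each pulse edge
  expect_equal(pk, w, tolerance = 0.02)

  # linearity in the signal
  tmpl <- eap_template_params(noise_sd = 0)
  tr <- render_eap_train(0.5, tmpl, 0.3, 1)
  tr3 <- trace(3 * tr$samples, fs)
  expect_equal(integrate_eap(tr3, 0.5, cfg)$integral_peak,
               3 * integrate_eap(tr, 0.5, cfg)$integral_peak,
               tolerance = 1e-9)

  # noise-free events: integral peak strictly monotone in scale
  grid <- c(0.11, 0.23, 0.5, 1.0, 1.5)
  peaks <- vapply(grid, function(s) {
    tr <- render_eap_train(0.5, tmpl, s, 1)
    integrate_eap(tr, 0.5, cfg)$integral_peak
  }, 0)
  expect_equal(cor(peaks, grid, method = "spearman"), 1)
})

test_that("the secondary peak is read after the third inflection point", {
  cfg <- eap_config()
  tmpl <- eap_template_params(noise_sd = 0)
  # noise-free templates over a scale grid: within 2% absolute
  for (s in c(0, 0.11, 0.23, 0.37, 1.0, 1.5)) {
    wf <- template_waveform(tmpl, s)
    sp <- secondary_peak(wf, cfg)
    expect_lt(abs(sp$secondary_rel - s), 0.02)
    expect_true(all(diff(sp$inflection_times) > 0))
    # the third inflection follows the primary peak
    expect_gt(sp$inflection_times[3], 0)
  }

  # single-lobe waveform: flagged, secondary_rel = 0
  fs <- tmpl$sample_rate
  tt <- seq(-2e-3, 15e-3, by = 1 / fs)
  lone <- list(mean = 25 * exp(-tt^2 / (2 * 4.25e-4^2)),
               t = tt, sample_rate = fs)
  sp1 <- secondary_peak(lone, cfg)
  expect_true(sp1$no_secondary_lobe)
  expect_identical(sp1$secondary_rel, 0)
})

test_that("condition shift quantifies secondary-current block", {
  tmpl <- eap_template_params()
  times <- seq(0.5, 60, by = 0.6)
  scales_pre <- rep(0.5, length(times))
  tr_pre <- render_eap_train(times, tmpl, scales_pre, 61, seed = 61)
  tr_post <- render_eap_train(times, tmpl, rep(0, length(times)), 61,
                              seed = 62)
  bp_pre <- bandpass(tr_pre); bp_post <- bandpass(tr_post)

  # identical conditions: zero shift
  same <- condition_shift(bp_pre, times, bp_pre, times)
  expect_equal(same$shift, 0)

  # secondary current abolished: shift equals the pre secondary amplitude
  blocked <- condition_shift(bp_pre, times, bp_post, times)
  expect_lt(abs(blocked$shift - blocked$pre$secondary_amp) /
              blocked$pre$secondary_amp, 0.05)
  expect_gt(blocked$shift, 0)

  expect_error(condition_shift(bp_pre, times[1], bp_post, times), "2 events")
})
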