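test_that("Poisson spike trains match analytic moments", {
  expect_identical(generate_spike_train(0, 100, seed = 1), numeric(0))
  expect_error(generate_spike_train(-1, 10), "rate")
  expect_error(generate_spike_train(1, 0), "duration")

  # long train: count and ISI CV against closed-form Poisson moments
  tr <- generate_spike_train(0.148, 1e6, seed = 101)
  n <- length(tr)
  expect_lt(abs(n - 148000), 3 * sqrt(148000))
  isi <- diff(tr)
  cv <- sd(isi) / mean(isi)
  # CV of n exponential ISIs: sd approx 1/sqrt(n)
  expect_lt(abs(cv - 1), 3 / sqrt(length(isi)))
  expect_true(all(diff(tr) > 0))

  expect_identical(formals(generate_spike_train)$rate, 0.148)
})

test_that("spike trains are reproducible under a seed and leave the RNG alone", {
  a <- generate_spike_train(0.5, 1000, seed = 7)
  b <- generate_spike_train(0.5, 1000, seed = 7)
  expect_identical(a, b)
  set.seed(123); x1 <- rnorm(1)
  set.seed(123); invisible(generate_spike_train(1, 10, seed = 3)); x2 <- rnorm(1)
  expect_identical(x1, x2)
})

test_that("amplitude assignment draws the two-class log-normal mixture", {
  times <- seq(1, 1e4)
  p0 <- spike_class_params(p_large = 0)
  gt0 <- assign_amplitudes(times, p0, seed = 1)
  expect_true(all(gt0$class_labels == "small"))

  p <- spike_class_params(p_large = 0.5, small_amp_mu = log(0.3),
                          large_amp_mu = log(1.5))
  gt <- assign_amplitudes(times, p, seed = 2)
  large_amps <- gt$true_amplitudes[gt$class_labels == "large"]
  # sample median of a log-normal: asymptotic sd = med * sdlog * 1.2533 / sqrt(n)
  se_med <- 1.5 * 0.25 * sqrt(pi / 2) / sqrt(length(large_amps))
  expect_lt(abs(median(large_amps) - 1.5), 3 * se_med)

  # well-separated mixture fails a normality screen
  flag <- multimodality_flag(gt$true_amplitudes[1:500], replicates = 2000,
                             seed = 5)
  expect_true(as.logical(flag))

  expect_error(spike_class_params(p_large = 1.5), "p_large")
  expect_error(spike_class_params(large_amp_mu = log(0.1)), "median")
})

test_that("calcium trace rendering is a linear, unit-peak forward model", {
  kern <- kernel_params(noise_sd = 0)
  # single noise-free event: trace max equals the amplitude (discretization)
  tr <- single_event_trace(amp = 0.8)
  expect_lt(abs(max(tr$samples) - 0.8), 0.8 * 0.01)

  # linearity: two events 200 ms apart equal the sample-wise sum
  t1 <- 2; t2 <- 2.2
  tr1 <- single_event_trace(amp = 0.5, t_event = t1)
  tr2 <- single_event_trace(amp = 1.2, t_event = t2)
  both <- render_ca_trace(
    ground_truth(c(t1, t2), true_amplitudes = c(0.5, 1.2)), kern, 6)
  expect_equal(both$samples, tr1$samples + tr2$samples, tolerance = 1e-12)

  # noise-only trace has the configured SD
  kn <- kernel_params(noise_sd = 0.05)
  noise <- render_ca_trace(ground_truth(numeric(0)), kn, 300, seed = 4)
  expect_gt(length(noise$samples), 1e4)
  expect_lt(abs(sd(noise$samples) - 0.05) / 0.05, 0.10)

  # events outside the window are dropped with a warning
  expect_warning(
    render_ca_trace(ground_truth(c(1, 99), true_amplitudes = c(0.5, 1)),
                    kern, 10),
    "dropped")
})

test_that("EAP rendering scales the secondary lobe per event", {
  tmpl <- eap_template_params(noise_sd = 0)
  expect_error(render_eap_train(c(1, 2), tmpl, 1, 5), "per event")
  cfg <- eap_config()

  ipk <- function(s) {
    tr <- render_eap_train(0.5, tmpl, s, 1)
    integrate_eap(tr, 0.5, cfg)$integral_peak
  }
  # scale 0 reproduces the primary-only template's integral peak
  expect_equal(ipk(0),
               gradespike:::eap_template_integral_peak(tmpl, 0),
               tolerance = 1e-6)
  # scale 1 yields a strictly larger integral peak
  expect_gt(ipk(1), ipk(0))

  # the default across-cell secondary fraction is 23% of the primary
  expect_identical(eap_template_params()$secondary_rel_median, 0.23)
})

test_that("integral peak increases strictly along the secondary-scale grid", {
  tmpl <- eap_template_params(noise_sd = 0)
  grid <- c(0, 0.11, 0.23, 0.37, 0.7, 1.0, 1.5)
  peaks <- vapply(grid, function(s)
    gradespike:::eap_template_integral_peak(tmpl, s), 0)
  expect_true(all(diff(peaks) > 0))
})

test_that("paired recordings couple Ca amplitude to the EAP integral", {
  # exact coupling: R^2 = 1
  p0 <- spike_class_params(coupling_noise_sd = 0)
  rec0 <- generate_paired_recording(0.43, 600, params = p0, seed = 21)
  reg0 <- paired_regression(rec0$integral_peaks,
                            rec0$truth$true_amplitudes)
  expect_equal(reg0$r_squared, 1, tolerance = 1e-9)
  expect_equal(reg0$slope, p0$coupling_slope, tolerance = 1e-6)

  # noise at signal/noise variance ratio 3: E[R^2] = 0.75
  rec_ref <- generate_paired_recording(0.43, 1500,
                                       params = p0, seed = 22)
  sig_sd <- sd(p0$coupling_slope * rec_ref$integral_peaks)
  p3 <- spike_class_params(coupling_noise_sd = sig_sd / sqrt(3))
  rec3 <- generate_paired_recording(0.43, 1500, params = p3, seed = 22)
  n <- length(rec3$integral_peaks)
  expect_gte(n, 200)
  reg3 <- paired_regression(rec3$integral_peaks,
                            rec3$truth$true_amplitudes)
  # Monte-Carlo sd of R^2 ~ 2 R (1 - R^2) / sqrt(n)
  se <- 2 * sqrt(0.75) * 0.25 / sqrt(n)
  expect_lt(abs(reg3$r_squared - 0.75), 3 * se)

  # every event drives both channels
  expect_identical(length(rec0$integral_peaks),
                   length(rec0$truth$event_times))
})

test_that("pharmacology transforms follow the channel-block rules", {
  times <- generate_spike_train(1, 1e4, seed = 31)
  truth <- assign_amplitudes(times, seed = 32, rate = 1)

  # TTx is the identity
  expect_identical(apply_condition(truth, "TTx"), truth)

  # Cd: all labels small, secondary currents abolished
  cd <- apply_condition(truth, "Cd", seed = 33)
  expect_true(all(cd$class_labels == "small"))
  expect_true(all(cd$true_secondary_scales == 0))
  expect_identical(cd$event_times, truth$event_times)
  # reassigned amplitudes come from the small class (all below the
  # large-class floor)
  expect_lt(max(cd$true_amplitudes), exp(log(0.3) + 5 * 0.25))

  # ML218: binomial thinning at the survival probability
  ml <- apply_condition(truth, "ML218", seed = 34, survival = 0.05)
  n0 <- length(truth$event_times)
  expect_lt(abs(length(ml$event_times) - 0.05 * n0),
            3 * sqrt(n0 * 0.05 * 0.95))

  expect_error(apply_condition(truth, "nonsense"), "TTx")
})

test_that("pharmacology transforms preserve ordering and never create events", {
  for (s in 1:5) {
    times <- generate_spike_train(0.5, 2000, seed = 40 + s)
    truth <- assign_amplitudes(times, seed = 50 + s, rate = 0.5)
    for (cond in c("TTx", "Cd", "ML218")) {
      out <- apply_condition(truth, cond, seed = 60 + s)
      expect_true(all(diff(out$event_times) > 0))
      expect_true(all(out$event_times %in% truth$event_times))
    }
  }
})

test_that("electrode and agonist conditions shape rate and amplitude class", {
  times <- generate_spike_train(0.148, 2e4, seed = 71)
  truth <- assign_amplitudes(times, seed = 72, rate = 0.148)
  el <- apply_condition(truth, "electrode", seed = 73, rate_factor = 3)
  n0 <- length(truth$event_times)
  expect_lt(abs(length(el$event_times) - 3 * n0), 3 * sqrt(3 * n0))
  expect_true(all(truth$event_times %in% el$event_times))

  win <- rbind(c(10, 20), c(50, 60))
  ach <- apply_condition(truth, "ACh", seed = 74, stim_windows = win,
                         evoked_rate = 3)
  inside <- (ach$event_times >= 10 & ach$event_times <= 20) |
    (ach$event_times >= 50 & ach$event_times <= 60)
  expect_true(all(inside))
  expect_true(all(ach$class_labels == "large"))

  atp <- apply_condition(truth, "ATP", seed = 75, stim_windows = win)
  expect_true(all(atp$class_labels == "small"))
  expect_error(apply_condition(truth, "ACh"), "stim_windows")
})

test_that("identical config and seed give bit-identical synthetic outputs", {
  a <- simulate_spontaneous_cell(0.148, 120, seed = 5)
  b <- simulate_spontaneous_cell(0.148, 120, seed = 5)
  expect_identical(a$raw$samples, b$raw$samples)
  expect_identical(a$truth, b$truth)
  pa <- generate_paired_recording(0.43, 60, seed = 6)
  pb <- generate_paired_recording(0.43, 60, seed = 6)
  expect_identical(pa$ca$samples, pb$ca$samples)
  expect_identical(pa$eap$samples, pb$eap$samples)
})
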