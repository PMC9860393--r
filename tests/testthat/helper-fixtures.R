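# shared fixtures built in code

# noise-free rendered transient trace with one event of known amplitude
single_event_trace <- function(amp = 1, t_event = 2, duration = 6,
                               kernel = kernel_params(noise_sd = 0)) {
  truth <- ground_truth(t_event, true_amplitudes = amp)
  render_ca_trace(truth, kernel, duration)
}

# noise-free EAP template samples over the standard event window
template_waveform <- function(template = eap_template_params(noise_sd = 0),
                              scale, pre = 2e-3, post = 15e-3) {
  tt <- seq(-pre, post, by = 1 / template$sample_rate)
  list(t = tt,
       mean = gradespike:::eap_waveform(tt, template, scale),
       sample_rate = template$sample_rate)
}

# brute-force Jarque-Bera via explicit central moments (independent oracle)
jb_bruteforce <- function(x) {
  n <- length(x)
  mu <- sum(x) / n
  m2 <- sum((x - mu)^2) / n
  m3 <- sum((x - mu)^3) / n
  m4 <- sum((x - mu)^4) / n
  skew <- m3 / sqrt(m2)^3
  kurt <- m4 / m2^2
  (n / 6) * (skew^2 + (kurt - 3)^2 / 4)
}

expect_identical_tables <- function(a, b) {
  expect_identical(nrow(a), nrow(b))
  for (cl in names(a)) expect_identical(a[[cl]], b[[cl]])
}
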