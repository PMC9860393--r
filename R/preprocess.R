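#' Normalize raw fluorescence to \eqn{\Delta F/F}
#'
#' `(F - F0) / F0`, where the baseline `F0` is the 15th percentile of the
#' full raw trace (linear interpolation between order statistics, the
#' default quantile definition).  A non-positive baseline is rejected as
#' non-physical.
#'
#' @param raw a fluorescence [trace()].
#' @param probs baseline percentile as a probability (default 0.15).
#' @return a [trace()] in \eqn{\Delta F/F}, same length and sample rate.
#' @examples
#' tr <- trace(c(10, 10, 10, 10, 20), 30)
#' dff(tr)$samples  # F0 = 10 -> 0 0 0 0 1
#' @export
dff <- function(raw, probs = 0.15) {
  stopifnot(inherits(raw, "trace"))
  f0 <- unname(quantile(raw$samples, probs, type = 7))
  if (f0 <= 0)
    stop("baseline F0 = ", signif(f0, 4),
         " is not positive; raw fluorescence looks non-physical")
  trace((raw$samples - f0) / f0, raw$sample_rate,
        start_time = raw$start_time, units = "dff")
}

#' Zero-phase band-pass filter
#'
#' Forward-backward application of a 2nd-order Butterworth band-pass
#' (4th-order magnitude overall, zero phase so event times are not
#' skewed).  Edges are handled by reflection padding of one
#' filter-settling length.  Defaults 6-1500 Hz, the band used for EAP
#' detection.
#'
#' @param x a [trace()].
#' @param low,high band edges in Hz, `0 < low < high < sample_rate / 2`.
#' @return the filtered [trace()].
#' @export
bandpass <- function(x, low = 6, high = 1500) {
  stopifnot(inherits(x, "trace"))
  nyq <- x$sample_rate / 2
  if (!(low > 0 && low < high))
    stop("need 0 < low < high, got low = ", low, ", high = ", high)
  if (high >= nyq)
    stop("high cutoff ", high, " Hz must be below the Nyquist frequency ",
         nyq, " Hz")
  bf <- signal::butter(2, c(low, high) / nyq, type = "pass")
  n <- length(x$samples)
  # settle over roughly one period of the low cutoff
  pad <- min(n - 1L, max(16L, ceiling(x$sample_rate / low)))
  # the band-pass has zero DC gain; removing the mean up front avoids a
  # slow settling transient at the pad boundaries
  s <- x$samples - mean(x$samples)
  padded <- c(2 * s[1] - s[(pad + 1):2],        # reflected, anti-symmetric
              s,
              2 * s[n] - s[(n - 1):(n - pad)])
  y <- signal::filtfilt(bf, padded)
  trace(y[(pad + 1):(pad + n)], x$sample_rate,
        start_time = x$start_time, units = x$units)
}
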