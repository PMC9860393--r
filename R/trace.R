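#' Uniformly sampled signal trace
#'
#' The universal currency of the pipeline: a 1-D signal (fluorescence,
#' \eqn{\Delta F/F}, or current in pA) sampled at a fixed rate.
#'
#' @param samples numeric vector of signal values (length >= 2, all finite).
#' @param sample_rate sampling rate in Hz (> 0).
#' @param start_time time of the first sample in seconds.
#' @param units free-text unit label, e.g. `"dff"`, `"au"`, `"pA"`.
#'
#' @return An object of class `trace`: a list with fields `samples`,
#'   `sample_rate`, `start_time` and `units`.
#' @examples
#' tr <- trace(sin(seq(0, 2 * pi, length.out = 100)), sample_rate = 50)
#' trace_duration(tr)
#' @export
trace <- function(samples, sample_rate, start_time = 0, units = "au") {
  samples <- as.numeric(samples)
  if (length(samples) < 2L)
    stop("a trace needs at least 2 samples, got ", length(samples))
  if (!all(is.finite(samples)))
    stop("trace samples must all be finite")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0)
    stop("sample_rate must be a single positive number, got ", sample_rate)
  structure(
    list(samples = samples, sample_rate = as.numeric(sample_rate),
         start_time = as.numeric(start_time), units = as.character(units)),
    class = "trace")
}

#' @export
print.trace <- function(x, ...) {
  cat(sprintf("<trace> %d samples @ %g Hz (%.3f s), units '%s'\n",
              length(x$samples), x$sample_rate,
              trace_duration(x), x$units))
  invisible(x)
}

#' @export
length.trace <- function(x) length(x$samples)

#' Time axis and duration of a trace
#'
#' @param x a [trace()].
#' @return `trace_times()`: vector of sample times in seconds;
#'   `trace_duration()`: duration in seconds (n / sample_rate).
#' @export
trace_times <- function(x) {
  stopifnot(inherits(x, "trace"))
  x$start_time + (seq_along(x$samples) - 1) / x$sample_rate
}

#' @rdname trace_times
#' @export
trace_duration <- function(x) {
  stopifnot(inherits(x, "trace"))
  length(x$samples) / x$sample_rate
}

#' @export
plot.trace <- function(x, ...) {
  plot(trace_times(x), x$samples, type = "l", xlab = "time (s)",
       ylab = x$units, ...)
  invisible(x)
}

#' Write / read traces as delimited text with a JSON sidecar
#'
#' One column per channel with a header row naming channels; the sidecar
#' (`<path>.json`) records sample rate, units, channel names and optional
#' provenance (seed, scenario).  All channels must share one sample rate.
#'
#' @param traces a named list of [trace()] objects (the channels).
#' @param path output path for the delimited text file.
#' @param seed,scenario optional provenance recorded in the sidecar.
#' @return `write_traces()`: `path`, invisibly.  `read_traces()`: a named
#'   list of `trace` objects.
#' @export
write_traces <- function(traces, path, seed = NULL, scenario = NULL) {
  if (inherits(traces, "trace")) traces <- list(signal = traces)
  stopifnot(length(traces) >= 1L, all(vapply(traces, inherits, TRUE, "trace")))
  if (is.null(names(traces)) || any(names(traces) == ""))
    names(traces) <- paste0("ch", seq_along(traces))
  rates <- vapply(traces, `[[`, 0, "sample_rate")
  ns <- vapply(traces, length, 0L)
  if (length(unique(rates)) != 1L || length(unique(ns)) != 1L)
    stop("all channels must share one sample rate and length")
  mat <- do.call(cbind, lapply(traces, `[[`, "samples"))
  colnames(mat) <- names(traces)
  utils::write.table(mat, path, sep = "\t", row.names = FALSE, quote = FALSE)
  sidecar <- list(
    sample_rate_hz = rates[[1]],
    units = as.list(vapply(traces, `[[`, "", "units")),
    channels = names(traces),
    start_time_s = traces[[1]]$start_time)
  if (!is.null(seed)) sidecar$seed <- seed
  if (!is.null(scenario)) sidecar$scenario <- scenario
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  side_path <- paste0(path, ".json")
  if (!file.exists(side_path))
    stop("missing JSON sidecar: ", side_path)
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  if (is.null(side$sample_rate_hz))
    stop("sidecar must declare sample_rate_hz")
  mat <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE)
  out <- lapply(names(mat), function(nm) {
    trace(mat[[nm]], side$sample_rate_hz,
          start_time = side$start_time_s %||% 0,
          units = side$units[[nm]] %||% "au")
  })
  names(out) <- names(mat)
  attr(out, "sidecar") <- side
  out
}

#' Write / read ground truth event tables as CSV
#'
#' Columns: `time_s`, `label`, `amplitude`, `secondary_scale`.
#'
#' @param truth a [ground_truth()] object.
#' @param path CSV path.
#' @return `write_ground_truth()`: `path`, invisibly; `read_ground_truth()`:
#'   a `ground_truth` object (rate and seed restored from attributes row
#'   comments are not used; they are stored in a `.json` sidecar).
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  df <- data.frame(time_s = truth$event_times,
                   label = truth$class_labels,
                   amplitude = truth$true_amplitudes,
                   secondary_scale = truth$true_secondary_scales)
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(list(rate_hz = truth$rate, seed = truth$seed),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  meta <- if (file.exists(paste0(path, ".json")))
    jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  else list()
  ground_truth(event_times = df$time_s, class_labels = df$label,
               true_amplitudes = df$amplitude,
               true_secondary_scales = df$secondary_scale,
               rate = meta$rate_hz %||% NA_real_,
               seed = meta$seed %||% NA_integer_)
}
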