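#' Firing rate and inter-spike-interval coefficient of variation
#'
#' `rate = count / duration`; `isi_cv = SD(ISI) / mean(ISI)` with the
#' sample SD (n - 1 denominator).  The CV is 1 for a homogeneous Poisson
#' process and is reported as `NA` for fewer than 3 events.
#'
#' @param event_times event times in seconds, strictly increasing.
#' @param duration recording duration in seconds (> 0).
#' @return list with `rate` (Hz), `isi_cv`, and `n_events`.
#' @examples
#' rate_and_cv(c(1, 2, 3, 4), 10)  # rate 0.4 Hz, cv 0
#' @export
rate_and_cv <- function(event_times, duration) {
  if (duration <= 0) stop("duration must be > 0, got ", duration)
  if (length(event_times) > 1 && any(diff(event_times) <= 0))
    stop("event_times must be strictly increasing")
  n <- length(event_times)
  cv <- if (n >= 3) {
    isi <- diff(event_times)
    sd(isi) / mean(isi)
  } else NA_real_
  list(rate = n / duration, isi_cv = cv, n_events = n)
}

#' Jarque-Bera statistic
#'
#' The classical statistic `JB = (n/6) (S^2 + (K - 3)^2 / 4)` with skewness
#' `S` and kurtosis `K` computed from biased (population) moment
#' estimators.  Used here, against simulated critical values, to flag
#' multimodal amplitude distributions.
#'
#' @param x numeric sample, `n >= 8`, non-zero variance.
#' @return the JB statistic (>= 0).
#' @export
jarque_bera <- function(x) {
  n <- length(x)
  if (n < 8) stop("Jarque-Bera needs n >= 8, got ", n)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) stop("sample has zero variance")
  s <- mean((x - m)^3) / m2^1.5
  k <- mean((x - m)^4) / m2^2
  n / 6 * (s^2 + (k - 3)^2 / 4)
}

# rows of a matrix -> JB statistics, vectorised for the null simulation
jb_rows <- function(mat) {
  n <- ncol(mat)
  m <- rowMeans(mat)
  c2 <- rowMeans((mat - m)^2)
  c3 <- rowMeans((mat - m)^3)
  c4 <- rowMeans((mat - m)^4)
  s <- c3 / c2^1.5
  k <- c4 / c2^2
  n / 6 * (s^2 + (k - 3)^2 / 4)
}

# package-local cache of simulated critical values
.jb_cache <- new.env(parent = emptyenv())

#' Monte-Carlo critical value for the Jarque-Bera statistic
#'
#' Empirical `1 - alpha` quantile of JB over replicates of `n` i.i.d.
#' standard-normal draws.  At small `n` the JB null is far from its
#' asymptotic chi-squared(2) law, so simulated critical values are used
#' throughout.  Values are cached per `(n, alpha, replicates, seed)`.
#'
#' @param n sample size.
#' @param alpha significance level (default 0.05).
#' @param replicates Monte-Carlo replicates (default 1e5; >= 1e4
#'   recommended).
#' @param seed integer seed; identical arguments give identical values.
#' @return the critical value (a positive scalar).
#' @export
jb_critical_value <- function(n, alpha = 0.05, replicates = 1e5,
                              seed = NULL) {
  stopifnot(n >= 8, alpha > 0, alpha < 1, replicates >= 100)
  key <- paste(n, alpha, replicates, seed %||% "none", sep = "|")
  if (!is.null(.jb_cache[[key]])) return(.jb_cache[[key]])
  stat <- with_seed(seed, {
    # block the replicate matrix to bound memory at large n
    block <- max(1L, min(as.integer(replicates), as.integer(2e6 / n)))
    out <- numeric(0)
    left <- as.integer(replicates)
    while (left > 0L) {
      b <- min(block, left)
      out <- c(out, jb_rows(matrix(rnorm(b * n), nrow = b)))
      left <- left - b
    }
    out
  })
  cv <- unname(quantile(stat, 1 - alpha, type = 7))
  .jb_cache[[key]] <- cv
  cv
}

#' Build a table of JB critical values over sample sizes
#'
#' @param n_values integer sample sizes to tabulate.
#' @param alpha significance level.
#' @param replicates Monte-Carlo replicates per `n`.
#' @param seed integer seed; sub-seeds per `n` are derived from it.
#' @return list of class `null_table` with `crit` (named by `n`), `alpha`,
#'   `replicates`, `seed`.
#' @export
jb_null_table <- function(n_values, alpha = 0.05, replicates = 1e5,
                          seed = NULL) {
  n_values <- sort(unique(as.integer(n_values)))
  crit <- vapply(n_values, function(n)
    jb_critical_value(n, alpha, replicates, seed = derive_seed(seed, n)),
    0)
  names(crit) <- n_values
  structure(list(crit = crit, alpha = alpha, replicates = replicates,
                 seed = seed), class = "null_table")
}

#' Flag a multimodal (non-normal) amplitude distribution
#'
#' `TRUE` iff the sample's JB statistic exceeds the critical value at its
#' sample size.  Samples smaller than 8 are indeterminate (`NA`).
#'
#' @param amplitudes numeric amplitude sample.
#' @param null a `null_table` from [jb_null_table()] covering this sample
#'   size, or `NULL` to simulate the critical value on the fly.
#' @param alpha,replicates,seed forwarded to [jb_critical_value()] when
#'   `null` is `NULL`.
#' @return logical flag (`NA` if indeterminate), with attributes
#'   `jb_stat` and `jb_crit`.
#' @export
multimodality_flag <- function(amplitudes, null = NULL, alpha = 0.05,
                               replicates = 1e4, seed = NULL) {
  n <- length(amplitudes)
  if (n < 8) {
    out <- NA
    attr(out, "jb_stat") <- NA_real_
    attr(out, "jb_crit") <- NA_real_
    return(out)
  }
  crit <- if (!is.null(null)) {
    stopifnot(inherits(null, "null_table"))
    if (!as.character(n) %in% names(null$crit))
      stop("null table does not cover n = ", n)
    null$crit[[as.character(n)]]
  } else {
    jb_critical_value(n, alpha, replicates, seed = seed)
  }
  stat <- jarque_bera(amplitudes)
  out <- stat > crit
  attr(out, "jb_stat") <- stat
  attr(out, "jb_crit") <- crit
  out
}

#' Normalize amplitudes to each cell's control mean
#'
#' Every amplitude (control and treated) of a cell is divided by that
#' cell's mean amplitude in the control condition, removing cell-to-cell
#' amplitude variation before distributions are pooled and compared.
#' Cells without a positive control mean are excluded with a warning.
#'
#' @param cells a list; each element is a cell given as a named list of
#'   numeric amplitude vectors per condition, e.g.
#'   `list(control = ..., Cd = ...)`.
#' @param control_condition name of the control condition.
#' @return named list of pooled normalized amplitude vectors, one per
#'   condition.
#' @export
normalize_amplitudes <- function(cells, control_condition = "control") {
  ok <- vapply(cells, function(cell) {
    !is.null(cell[[control_condition]]) &&
      length(cell[[control_condition]]) > 0 &&
      mean(cell[[control_condition]]) > 0
  }, TRUE)
  if (any(!ok))
    warning(sum(!ok), " cell(s) without a positive control mean excluded")
  cells <- cells[ok]
  conds <- unique(unlist(lapply(cells, names)))
  pooled <- lapply(conds, function(cond) {
    unlist(lapply(cells, function(cell) {
      if (is.null(cell[[cond]])) return(numeric(0))
      cell[[cond]] / mean(cell[[control_condition]])
    }), use.names = FALSE)
  })
  names(pooled) <- conds
  pooled
}

#' Ordinary least-squares regression of Ca2+ amplitude on EAP integral
#'
#' @param integral_peaks \eqn{\int}EAP peaks (pA s), one per matched event.
#' @param ca_amplitudes Ca2+ spike amplitudes (\eqn{\Delta F/F}), matched.
#' @return list with `slope`, `intercept`, `r_squared` (squared Pearson
#'   correlation) and `n`.
#' @export
paired_regression <- function(integral_peaks, ca_amplitudes) {
  if (length(integral_peaks) != length(ca_amplitudes))
    stop("integral_peaks and ca_amplitudes must be matched pairs")
  keep <- complete.cases(integral_peaks, ca_amplitudes)
  x <- integral_peaks[keep]; y <- ca_amplitudes[keep]
  if (length(x) < 3) stop("paired regression needs n >= 3 pairs")
  if (var(x) == 0 || var(y) == 0)
    stop("zero variance in regression input")
  fit <- lm(y ~ x)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = stats::cor(x, y)^2, n = length(x))
}

#' Ca2+ activity index of a recording
#'
#' Default (`"amplitude_sum"`): sum of detected spike amplitudes divided by
#' the recording duration, in \eqn{\Delta F/F\,s^{-1}}.  An alternative
#' `"positive_derivative"` mode (mean positive conditioned derivative per
#' second) is provided because the quantity's definition is a modelling
#' choice; the default matches its units directly.
#'
#' @param x the \eqn{\Delta F/F} [trace()].
#' @param amplitudes detected spike amplitudes on this trace.
#' @param mode `"amplitude_sum"` or `"positive_derivative"`.
#' @param cfg a [detection_config()] (derivative mode only).
#' @return activity index in \eqn{\Delta F/F\,s^{-1}}.
#' @export
activity_index <- function(x, amplitudes, mode = "amplitude_sum",
                           cfg = detection_config()) {
  stopifnot(inherits(x, "trace"))
  mode <- match.arg(mode, c("amplitude_sum", "positive_derivative"))
  dur <- trace_duration(x)
  if (dur <= 0) stop("zero-duration trace")
  if (mode == "amplitude_sum") {
    sum(amplitudes) / dur
  } else {
    d <- condition_derivative(x, cfg)$samples
    sum(pmax(d, 0)) / dur
  }
}

#' Compare per-cell values or pooled distributions between conditions
#'
#' `paired`: Wilcoxon signed-rank on per-cell values; `unpaired`:
#' Mann-Whitney rank-sum; `distribution`: two-sample Kolmogorov-Smirnov on
#' pooled (typically mean-normalized) amplitudes.  P values are two-sided;
#' no multiple-testing correction is applied.
#'
#' @param pre,post numeric vectors: per-cell values (paired/unpaired) or
#'   pooled amplitudes (distribution).
#' @param design `"paired"`, `"unpaired"` or `"distribution"`.
#' @return list with `design`, `statistic`, `p_value`, `n_pre`, `n_post`,
#'   and `summary` (median and IQR per group, formatted).
#' @export
compare_conditions <- function(pre, post, design = "paired") {
  design <- match.arg(design, c("paired", "unpaired", "distribution"))
  if (design == "paired") {
    if (length(pre) != length(post))
      stop("paired design needs matched per-cell vectors")
    if (length(pre) < 5) stop("paired design needs >= 5 cells")
    ht <- if (all(pre == post))
      list(statistic = c(V = 0), p.value = 1)   # no change at all
    else
      suppressWarnings(wilcox.test(pre, post, paired = TRUE,
                                   exact = FALSE))
  } else if (design == "unpaired") {
    if (length(pre) < 5 || length(post) < 5)
      stop("unpaired design needs >= 5 cells per group")
    ht <- suppressWarnings(wilcox.test(pre, post, exact = FALSE))
  } else {
    ht <- suppressWarnings(ks.test(pre, post))
  }
  fmt <- function(v) sprintf("%.3g ±%.3g (median ±IQR)",
                             median(v), stats::IQR(v))
  list(design = design,
       statistic = unname(ht$statistic),
       p_value = ht$p.value,
       n_pre = length(pre), n_post = length(post),
       summary = c(pre = fmt(pre), post = fmt(post)))
}

#' Summarize one cell's detected spikes
#'
#' Bundles rate, ISI CV, amplitudes, JB multimodality flag and mean SNR
#' into the per-cell result row used by the population summaries.
#'
#' @param cell_id cell identifier.
#' @param events spike table from [analyze_ca_trace()].
#' @param duration recording duration, s.
#' @param null optional `null_table` for the multimodality flag.
#' @param seed seed for on-the-fly critical values when `null` is `NULL`.
#' @return list of class `cell_result`.
#' @export
cell_result <- function(cell_id, events, duration, null = NULL,
                        seed = NULL) {
  rc <- rate_and_cv(events$time, duration)
  amps <- events$amplitude
  flag <- multimodality_flag(amps, null = null, seed = seed)
  finite_snr <- events$snr[is.finite(events$snr)]
  structure(list(
    cell_id = cell_id,
    rate = rc$rate, isi_cv = rc$isi_cv, n_events = rc$n_events,
    amplitudes = amps,
    jb_stat = attr(flag, "jb_stat"), jb_crit = attr(flag, "jb_crit"),
    multimodal = as.logical(flag),
    mean_snr = if (length(finite_snr)) mean(finite_snr) else NA_real_),
    class = "cell_result")
}
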