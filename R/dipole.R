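#' Current-dipole time series
#'
#' Container for an aggregate (and optionally layer-resolved) current-dipole
#' waveform with processing metadata.
#'
#' @param times Strictly increasing time grid, ms.
#' @param aggregate Aggregate dipole moment samples.
#' @param L2,L5 Optional per-layer components; when both are present the
#'   aggregate must equal their sum samplewise.
#' @param meta List of processing metadata (units, scaling, smoothing_ms,
#'   n_trials, ...).
#' @return A `DipoleTrace`.
#' @export
dipoleTrace <- function(times, aggregate, L2 = NULL, L5 = NULL,
                        meta = list(units = "nAm", scaling = 1,
                                    smoothing_ms = 0, n_trials = 1)) {
  times <- as.numeric(times); aggregate <- as.numeric(aggregate)
  if (length(times) != length(aggregate))
    stop("'times' and 'aggregate' must have equal length", call. = FALSE)
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("'times' must be strictly increasing", call. = FALSE)
  per_layer <- NULL
  if (!is.null(L2) || !is.null(L5)) {
    if (is.null(L2) || is.null(L5) || length(L2) != length(times) ||
        length(L5) != length(times))
      stop("per-layer components must both be given, same length as 'times'",
           call. = FALSE)
    per_layer <- list(L2 = as.numeric(L2), L5 = as.numeric(L5))
  }
  structure(list(times = times, aggregate = aggregate, per_layer = per_layer,
                 meta = meta), class = "DipoleTrace")
}

#' @export
print.DipoleTrace <- function(x, ...) {
  cat(sprintf(
    "DipoleTrace: %d samples, %.1f-%.1f ms, %s; scaling %g, smoothing %g ms, %d trial(s)\n",
    length(x$times), min(x$times), max(x$times),
    x$meta$units %||% "?", x$meta$scaling %||% 1,
    x$meta$smoothing_ms %||% 0, x$meta$n_trials %||% 1))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

mapTrace <- function(trace, f) {
  trace$aggregate <- f(trace$aggregate)
  if (!is.null(trace$per_layer))
    trace$per_layer <- lapply(trace$per_layer, f)
  trace
}

#' Scale a dipole trace
#'
#' Multiplies every sample (aggregate and per-layer) by a positive factor;
#' the factor represents the number of synchronous pyramidal neurons per
#' modelled neuron contributing to the recorded signal.
#'
#' @param trace A `DipoleTrace`.
#' @param factor Positive scaling factor.
#' @return Scaled `DipoleTrace`; `meta$scaling` is multiplied accordingly.
#' @export
scaleTrace <- function(trace, factor) {
  stopifnot(inherits(trace, "DipoleTrace"))
  if (!is.numeric(factor) || length(factor) != 1 || !is.finite(factor) ||
      factor <= 0)
    stop("'factor' must be a single positive number", call. = FALSE)
  out <- mapTrace(trace, function(x) x * factor)
  out$meta$scaling <- (trace$meta$scaling %||% 1) * factor
  out
}

#' Smooth a dipole trace with a Hamming window
#'
#' Convolves each channel with a unit-area Hamming window of odd length
#' `round(window_ms / sample interval) + 1`, centred, with reflect padding at
#' the edges; the output has the same length as the input.
#'
#' @param trace A `DipoleTrace` on a uniform grid.
#' @param window_ms Window length in ms (default 30); 0 is the identity.
#' @return Smoothed `DipoleTrace`.
#' @export
smoothHamming <- function(trace, window_ms = 30) {
  stopifnot(inherits(trace, "DipoleTrace"))
  if (window_ms < 0) stop("'window_ms' must be >= 0", call. = FALSE)
  if (window_ms == 0) return(trace)
  dt <- trace$times[2] - trace$times[1]
  n <- round(window_ms / dt) + 1
  if (n %% 2 == 0) n <- n + 1
  if (n >= 2 * length(trace$times))
    stop("smoothing window longer than the trace", call. = FALSE)
  if (n < 3) return(trace)
  w <- 0.54 - 0.46 * cos(2 * pi * seq(0, n - 1) / (n - 1))
  w <- w / sum(w)
  half <- (n - 1) / 2
  sm <- function(x) {
    xp <- c(rev(x[2:(half + 1)]), x, rev(x[(length(x) - half):(length(x) - 1)]))
    as.numeric(stats::filter(xp, w, sides = 2))[(half + 1):(half + length(x))]
  }
  out <- mapTrace(trace, sm)
  out$meta$smoothing_ms <- window_ms
  out
}

#' Average dipole traces across trials
#'
#' @param traces List of `DipoleTrace` on identical time grids.
#' @return Samplewise mean `DipoleTrace`; `meta$n_trials` records the count.
#' @export
averageTrials <- function(traces) {
  stopifnot(length(traces) >= 1)
  t0 <- traces[[1]]$times
  for (tr in traces) {
    stopifnot(inherits(tr, "DipoleTrace"))
    if (length(tr$times) != length(t0) || any(tr$times != t0))
      stop("all traces must share the same time grid", call. = FALSE)
  }
  agg <- rowMeans(vapply(traces, function(tr) tr$aggregate,
                         numeric(length(t0))))
  haslay <- !vapply(traces, function(tr) is.null(tr$per_layer), logical(1))
  out <- if (all(haslay)) {
    l2 <- rowMeans(vapply(traces, function(tr) tr$per_layer$L2, numeric(length(t0))))
    l5 <- rowMeans(vapply(traces, function(tr) tr$per_layer$L5, numeric(length(t0))))
    dipoleTrace(t0, agg, l2, l5, meta = traces[[1]]$meta)
  } else dipoleTrace(t0, agg, meta = traces[[1]]$meta)
  out$meta$n_trials <- length(traces)
  out
}

#' Resample a dipole trace by linear interpolation
#'
#' Interpolates onto the uniform grid `k / rate_hz`, k = 0, 1, ... spanning
#' the original support (for 0-250 ms at 600 Hz: 151 samples, both endpoints
#' included).  Downsampling only; extrapolation is an error.
#'
#' @param trace A `DipoleTrace`.
#' @param rate_hz Target rate in Hz (default 600).
#' @return Resampled `DipoleTrace`.
#' @export
resampleTo <- function(trace, rate_hz = 600) {
  stopifnot(inherits(trace, "DipoleTrace"))
  step_ms <- 1000 / rate_hz
  tmin <- trace$times[1]; tmax <- trace$times[length(trace$times)]
  grid <- seq(ceiling(tmin / step_ms), floor(tmax / step_ms + 1e-9)) * step_ms
  if (!length(grid)) stop("target grid does not intersect the trace", call. = FALSE)
  out <- mapTrace(trace, function(x)
    stats::approx(trace$times, x, xout = grid, rule = 1)$y)
  out$times <- grid
  out$meta$rate_hz <- rate_hz
  out
}

#' Write / read waveform TSV files
#'
#' Plain-text tab-separated format with header
#' `time_ms  agg_nAm  L2_nAm  L5_nAm`; the per-layer columns are optional on
#' read.
#'
#' @param trace A `DipoleTrace`.
#' @param path File path.
#' @return `readWaveform` returns a `DipoleTrace`; `writeWaveform` returns
#'   `path` invisibly.
#' @export
writeWaveform <- function(trace, path) {
  stopifnot(inherits(trace, "DipoleTrace"))
  df <- data.frame(time_ms = trace$times, agg_nAm = trace$aggregate)
  if (!is.null(trace$per_layer)) {
    df$L2_nAm <- trace$per_layer$L2
    df$L5_nAm <- trace$per_layer$L5
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeWaveform
#' @export
readWaveform <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  if (!all(c("time_ms", "agg_nAm") %in% names(df)))
    stop("waveform file must have columns time_ms and agg_nAm", call. = FALSE)
  if (all(c("L2_nAm", "L5_nAm") %in% names(df)))
    dipoleTrace(df$time_ms, df$agg_nAm, df$L2_nAm, df$L5_nAm)
  else
    dipoleTrace(df$time_ms, df$agg_nAm)
}
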