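#' N100m amplitude and latency
#'
#' The N100m trough is the absolute signal maximum of the aggregate waveform
#' in the 80-120 ms window (closed interval; ties resolved to the earliest
#' sample).  Amplitude is returned as a magnitude; the signed value and the
#' latency of the extremum are reported alongside.
#'
#' @param wave A `DipoleTrace` covering at least 80-120 ms.
#' @param window Measurement window, ms (default `c(80, 120)`).
#' @return List with `amplitude` (magnitude), `latency` (ms), `value`
#'   (signed sample).
#' @export
measureN100m <- function(wave, window = c(80, 120)) {
  stopifnot(inherits(wave, "DipoleTrace"))
  sel <- which(wave$times >= window[1] & wave$times <= window[2])
  if (!length(sel) || wave$times[1] > window[1] ||
      wave$times[length(wave$times)] < window[2])
    stop(sprintf("waveform does not cover the %g-%g ms window",
                 window[1], window[2]), call. = FALSE)
  v <- wave$aggregate[sel]
  i <- which.max(abs(v))  # which.max takes the first (earliest) maximum
  list(amplitude = abs(v[i]), latency = wave$times[sel[i]], value = v[i])
}

#' Straight-line slope over a time window
#'
#' Ordinary least-squares slope of the aggregate waveform against time over
#' all samples in the closed interval `[t0, t1]`; used for the P50m-N100m
#' (70-90 ms) and N100m-P200m (110-130 ms) slopes.
#'
#' @param wave A `DipoleTrace`.
#' @param t0,t1 Window bounds, ms.
#' @return Slope in signal units per ms.
#' @export
fitWindowSlope <- function(wave, t0, t1) {
  stopifnot(inherits(wave, "DipoleTrace"))
  if (!(t0 < t1)) stop("'t0' must be < 't1'", call. = FALSE)
  sel <- which(wave$times >= t0 & wave$times <= t1)
  if (length(sel) < 2)
    stop("fewer than 2 samples in the window", call. = FALSE)
  x <- wave$times[sel]; y <- wave$aggregate[sel]
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

#' All four component measures of a waveform
#'
#' @param wave A `DipoleTrace`.
#' @param slope_windows List of two c(t0, t1) windows for the ascending and
#'   descending N100m slopes.
#' @return One-row data.frame with n100m_amplitude, n100m_latency,
#'   slope_p50_n100, slope_n100_p200.
#' @export
measureComponents <- function(wave,
                              slope_windows = list(c(70, 90), c(110, 130))) {
  n1 <- measureN100m(wave)
  data.frame(
    n100m_amplitude = n1$amplitude,
    n100m_latency = n1$latency,
    slope_p50_n100 = fitWindowSlope(wave, slope_windows[[1]][1], slope_windows[[1]][2]),
    slope_n100_p200 = fitWindowSlope(wave, slope_windows[[2]][1], slope_windows[[2]][2])
  )
}

#' Root-mean-squared error between two waveforms
#'
#' @param sim,target `DipoleTrace`s on a common time grid (resample first if
#'   needed).
#' @param window Optional c(t0, t1) restriction; default is the full common
#'   epoch.
#' @return RMSE of the aggregate channels, in signal units.
#' @export
rmse <- function(sim, target, window = NULL) {
  stopifnot(inherits(sim, "DipoleTrace"), inherits(target, "DipoleTrace"))
  if (length(sim$times) != length(target$times) ||
      any(abs(sim$times - target$times) > 1e-9))
    stop("waveforms are on different time grids; resample first", call. = FALSE)
  sel <- seq_along(sim$times)
  if (!is.null(window))
    sel <- which(sim$times >= window[1] & sim$times <= window[2])
  sqrt(mean((sim$aggregate[sel] - target$aggregate[sel])^2))
}

#' Population firing rate
#'
#' Mean rate in spikes/s: total spikes of the population divided by
#' (trials x cells x duration).
#'
#' @param raster Spike data.frame with columns population, cell, time (and
#'   optionally trial).
#' @param population Population label.
#' @param duration Epoch length, ms.
#' @param n_trials,n_cells Normalisation counts.
#' @return Rate in spikes/s.
#' @export
firingRates <- function(raster, population, duration, n_trials, n_cells) {
  if (n_trials <= 0 || n_cells <= 0 || duration <= 0)
    stop("'duration', 'n_trials' and 'n_cells' must be positive", call. = FALSE)
  if (!population %in% POPULATIONS)
    stop("unknown population: ", population, call. = FALSE)
  nspk <- sum(raster$population == population)
  nspk / (n_trials * n_cells * duration / 1000)
}

#' Network scale and contributing-cell arithmetic
#'
#' The scaling factor multiplies the reduced network's dipole to stand in for
#' the synchronous population generating the recorded signal: a scaling of S
#' with 200 modelled pyramidal neurons represents `S x 200` cells.
#' Conversely, a signal of magnitude Q with ~0.2 pAm per pyramidal neuron
#' implies `Q / 0.2 pAm` contributing cells.
#'
#' @param scaling Scaling factor (> 0).
#' @param modeled_pyr_total Pyramidal neurons in the reduced model (default
#'   200: 100 per layer).
#' @return `estimateContributingCells`: number of represented cells.
#' @export
estimateContributingCells <- function(scaling, modeled_pyr_total = 200) {
  if (scaling <= 0 || modeled_pyr_total <= 0)
    stop("inputs must be positive", call. = FALSE)
  scaling * modeled_pyr_total
}

#' @rdname estimateContributingCells
#' @param signal_nAm Signal magnitude in nAm.
#' @param per_cell_dipole_pAm Dipole contribution per pyramidal neuron, pAm
#'   (default 0.2).
#' @return `scalingFromSignal`: list with `cells` and `scaling`.
#' @export
scalingFromSignal <- function(signal_nAm, per_cell_dipole_pAm = 0.2,
                              modeled_pyr_total = 200) {
  if (signal_nAm <= 0 || per_cell_dipole_pAm <= 0 || modeled_pyr_total <= 0)
    stop("inputs must be positive", call. = FALSE)
  cells <- signal_nAm * 1000 / per_cell_dipole_pAm  # nAm -> pAm
  list(cells = cells, scaling = cells / modeled_pyr_total)
}

#' Write / read component-measure tables
#'
#' TSV with one row per (subject, hemisphere, presentation) and one column
#' per measure.
#'
#' @param measures Data.frame with columns subject, presentation, hemisphere
#'   and the four measures.
#' @param path File path.
#' @export
writeMeasures <- function(measures, path) {
  utils::write.table(measures, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeMeasures
#' @export
readMeasures <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
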