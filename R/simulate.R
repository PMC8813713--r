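#' Simulation settings
#'
#' @param duration Epoch length in ms (default 250, i.e. 0-250 ms relative to
#'   stimulus onset).
#' @param dt Integration step, ms (default 0.025).
#' @param n_trials Trials per condition (default 10).
#' @param base_seed Integer; trial t uses seed `base_seed + t`.
#' @param record_dt Output resolution, ms (>= dt, multiple of dt).
#' @return A `SimulationConfig`.
#' @export
simulationConfig <- function(duration = 250, dt = 0.025, n_trials = 10,
                             base_seed = 1, record_dt = dt) {
  if (duration <= 0) stop("'duration' must be > 0", call. = FALSE)
  if (dt <= 0) stop("'dt' must be > 0", call. = FALSE)
  if (record_dt < dt) stop("'record_dt' must be >= dt", call. = FALSE)
  if (n_trials < 1) stop("'n_trials' must be >= 1", call. = FALSE)
  structure(list(duration = duration, dt = dt, n_trials = as.integer(n_trials),
                 base_seed = as.integer(base_seed), record_dt = record_dt),
            class = "SimulationConfig")
}

# steady state of the unstimulated network; dt-independent fixed point of the
# implicit scheme, so it is computed with a coarse step and cached
restingState <- function(network, settle_ms = 4000, settle_dt = 0.25) {
  key <- "rest"
  if (!is.null(network$cache[[key]])) return(network$cache[[key]])
  nsteps <- round(settle_ms / settle_dt)
  res <- engine_run(network$engine,
                    matrix(numeric(0), ncol = 4), NULL,
                    settle_dt, nsteps, nsteps, integer(0),
                    matrix(numeric(0), ncol = 4))
  network$cache[[key]] <- res$state
  res$state
}

# expand an EventSchedule into integrator events (step, comp, slot, weight)
scheduleToEvents <- function(schedule, network, dt, nsteps) {
  if (is.null(schedule) || nrow(schedule) == 0)
    return(matrix(numeric(0), ncol = 4))
  p <- network$config$params
  rec_id <- stats::setNames(seq_along(RECEPTORS) - 1L, RECEPTORS)
  eng <- network$engine
  rows <- vector("list", nrow(schedule))
  for (i in seq_len(nrow(schedule))) {
    pp <- schedule$population[i]
    if (!pp %in% names(network$pop_first)) next
    tgt <- p$drive_targets[[schedule$pathway[i]]]
    if (!pp %in% tgt$populations) next
    secs <- tgt$sections[[pp]]
    gcell <- network$pop_first[[pp]] + schedule$cell[i]
    comp0 <- eng$cell_start[gcell + 1L]
    comps <- comp0 + network$templates[[pp]]$sec_index[secs] - 1L
    tev <- schedule$time[i] + tgt$delay[[pp]]
    step <- max(1, round(tev / dt))
    rows[[i]] <- cbind(step, comps, rec_id[[schedule$receptor[i]]],
                       schedule$weight[i])
  }
  ev <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(ev)) matrix(numeric(0), ncol = 4) else ev
}

#' Integrate one trial
#'
#' Runs the network from its resting steady state for the configured duration
#' under the given drive events, and returns the raw (unscaled, unsmoothed)
#' current-dipole trace per layer plus the spike raster.  The dipole is the
#' sum over pyramidal cells and compartments of intracellular axial current
#' times vertical path length, signed positive for current towards the
#' cortical surface; it is reported relative to the resting-network baseline,
#' in fAm.
#'
#' @param network A `Network`.
#' @param schedule An `EventSchedule` (see [sampleDriveSpikes()]).
#' @param sim A `SimulationConfig`.
#' @param trial_seed Recorded in the raster; the integrator itself is
#'   deterministic given the schedule.
#' @param iclamp Optional data.frame (comp, amp_nA, start_ms, stop_ms) of
#'   constant current injections (testing aid).
#' @param record_comps Optional 1-based compartment indices whose membrane
#'   potential and total synaptic current are recorded.
#' @return List with `dipole` (a raw [dipoleTrace()]), `raster`
#'   (trial/population/cell/time data.frame), and if requested `v`, `isyn`.
#' @export
runTrial <- function(network, schedule, sim = simulationConfig(),
                     trial_seed = 0L, iclamp = NULL, record_comps = NULL) {
  stopifnot(inherits(network, "Network"), inherits(sim, "SimulationConfig"))
  if (nrow(schedule) > 0 &&
      (any(schedule$time < 0) || any(schedule$time > sim$duration)))
    stop("drive events must lie within [0, duration]", call. = FALSE)
  nsteps <- round(sim$duration / sim$dt)
  record_every <- max(1L, round(sim$record_dt / sim$dt))
  ev <- scheduleToEvents(schedule, network, sim$dt, nsteps)
  icl <- if (is.null(iclamp)) matrix(numeric(0), ncol = 4) else
    cbind(iclamp$comp - 1L, iclamp$amp,
          round(iclamp$start / sim$dt), round(iclamp$stop / sim$dt))
  rc <- if (is.null(record_comps)) integer(0) else as.integer(record_comps - 1L)
  state0 <- restingState(network)
  res <- engine_run(network$engine, ev, state0, sim$dt, nsteps, record_every,
                    rc, icl)
  q0 <- res$dipole[1, ]
  l2 <- res$dipole[, 1] - q0[1]
  l5 <- res$dipole[, 2] - q0[2]
  trace <- dipoleTrace(res$t, aggregate = l2 + l5, L2 = l2, L5 = l5,
                       meta = list(units = "fAm", scaling = 1,
                                   smoothing_ms = 0, n_trials = 1))
  pop_of <- network$populations
  first <- network$pop_first
  raster <- data.frame(
    trial = rep(as.integer(trial_seed), length(res$spike_cell)),
    population = pop_of[res$spike_cell + 1L],
    cell = res$spike_cell - unname(first[pop_of[res$spike_cell + 1L]]),
    time = res$spike_time,
    stringsAsFactors = FALSE
  )
  out <- list(dipole = trace, raster = raster)
  if (!is.null(record_comps)) {
    out$v <- res$v; out$isyn <- res$isyn; out$t <- res$t
  }
  out
}

#' Simulate a full condition
#'
#' Samples the drive sequence independently for each trial (seed
#' `base_seed + trial`) and integrates the network, returning per-trial raw
#' dipole traces and the pooled spike raster.
#'
#' @param network A `Network`.
#' @param drives List of `DriveSpec`, e.g. from [presetDriveSequence()].
#' @param sim A `SimulationConfig`.
#' @param scaling Scaling factor stored with the result (applied by
#'   [conditionWaveform()]).
#' @param zlists Optional list (one element per trial) of per-drive
#'   standard-normal draw matrices for common-random-numbers evaluation.
#' @return A `SimulationResult` list.
#' @export
simulateCondition <- function(network, drives, sim = simulationConfig(),
                              scaling = 1, zlists = NULL) {
  trials <- vector("list", sim$n_trials)
  rasters <- vector("list", sim$n_trials)
  for (tr in seq_len(sim$n_trials)) {
    sched <- sampleDriveSequence(
      drives, network, sim$duration,
      seed = if (is.null(zlists)) sim$base_seed + tr else NULL,
      zlist = if (is.null(zlists)) NULL else zlists[[tr]])
    res <- runTrial(network, sched, sim, trial_seed = tr)
    trials[[tr]] <- res$dipole
    res$raster$trial <- tr
    rasters[[tr]] <- res$raster
  }
  structure(list(trials = trials, raster = do.call(rbind, rasters),
                 drives = drives, scaling = scaling, sim = sim,
                 network = network),
            class = "SimulationResult")
}

#' Paper-comparable waveform of a simulated condition
#'
#' Applies the fixed post-processing pipeline to a [simulateCondition()]
#' result: average across trials, multiply by the network scaling factor and
#' convert fAm to nAm, smooth with a 30 ms Hamming window, and resample onto
#' the 600 Hz acquisition grid.
#'
#' @param result A `SimulationResult`.
#' @param smoothing_ms Hamming window length, ms.
#' @param rate_hz Output sampling rate, Hz.
#' @param scaling Override for the stored scaling factor.
#' @return A [dipoleTrace()] in nAm.
#' @export
conditionWaveform <- function(result, smoothing_ms = 30, rate_hz = 600,
                              scaling = NULL) {
  stopifnot(inherits(result, "SimulationResult"))
  sc <- if (is.null(scaling)) result$scaling else scaling
  avg <- averageTrials(result$trials)
  sc_nAm <- sc * 1e-6  # fAm -> nAm times network scaling
  out <- scaleTrace(avg, sc_nAm)
  out$meta$units <- "nAm"
  out$meta$scaling <- sc
  out <- smoothHamming(out, smoothing_ms)
  resampleTo(out, rate_hz)
}
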