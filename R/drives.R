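#' Define an exogenous drive
#'
#' A drive is a volley of excitatory input spikes delivered through one of the
#' two canonical pathways: `proximal` (feedforward, via the lemniscal-thalamic
#' relay, onto basal/oblique pyramidal dendrites and both basket populations)
#' or `distal` (feedback, cortico-cortical or non-lemniscal thalamic, onto the
#' distal apical dendrites and layer II/III baskets only).  Per-cell spike
#' times are Gaussian with the given mean and SD.
#'
#' @param name Drive label.
#' @param pathway `"proximal"` or `"distal"`.
#' @param mean_time,sd_time Gaussian spike-time parameters, ms.
#' @param weights Named numeric vector of maximal conductances (uS); names are
#'   `"<population>.<receptor>"`, e.g. `"L5Pyr.ampa"`.
#' @param spikes_per_cell Input spikes per target cell per trial (default 1).
#' @return A `DriveSpec`.
#' @export
driveSpec <- function(name, pathway, mean_time, sd_time, weights,
                      spikes_per_cell = 1) {
  pathway <- match.arg(pathway, c("proximal", "distal"))
  if (sd_time < 0) stop("'sd_time' must be >= 0", call. = FALSE)
  if (any(weights < 0)) stop("drive weights must be >= 0", call. = FALSE)
  if (spikes_per_cell < 1) stop("'spikes_per_cell' must be >= 1", call. = FALSE)
  pops <- sub("\\..*$", "", names(weights))
  recs <- sub("^.*\\.", "", names(weights))
  if (any(!pops %in% POPULATIONS) || any(!recs %in% c("ampa", "nmda")))
    stop("drive weight names must be '<population>.<ampa|nmda>'", call. = FALSE)
  if (pathway == "distal" && any(pops == "L5Basket"))
    stop("distal drives must not target layer V basket cells", call. = FALSE)
  structure(list(name = name, pathway = pathway, mean_time = mean_time,
                 sd_time = sd_time, weights = weights,
                 spikes_per_cell = as.integer(spikes_per_cell)),
            class = "DriveSpec")
}

#' @export
print.DriveSpec <- function(x, ...) {
  cat(sprintf("Drive '%s' (%s): t ~ N(%.3f, %.3f) ms, %d spike(s)/cell\n",
              x$name, x$pathway, x$mean_time, x$sd_time, x$spikes_per_cell))
  invisible(x)
}

# the 28 drive parameters fitted per hemisphere for contralateral tone
# presentation (3 mean times + 3 SDs + 22 synaptic weights), and the
# network scaling factors
DRIVE_TABLE <- list(
  right = list(
    prox1 = list(pathway = "proximal", mean_time = 47.355, sd_time = 2.963,
                 weights = c(L2Pyr.ampa = 0.659, L2Pyr.nmda = 0.535,
                             L2Basket.ampa = 0.997, L2Basket.nmda = 0.987,
                             L5Pyr.ampa = 0.004, L5Pyr.nmda = 0.009,
                             L5Basket.ampa = 0.427, L5Basket.nmda = 0.037)),
    dist1 = list(pathway = "distal", mean_time = 81.091, sd_time = 12.261,
                 weights = c(L2Pyr.ampa = 0.607, L2Pyr.nmda = 0.243,
                             L2Basket.ampa = 0.523, L2Basket.nmda = 0.959,
                             L5Pyr.ampa = 0.964, L5Pyr.nmda = 0.158)),
    prox2 = list(pathway = "proximal", mean_time = 150.826, sd_time = 1.061,
                 weights = c(L2Pyr.ampa = 0.346, L2Pyr.nmda = 0.027,
                             L2Basket.ampa = 0.995, L2Basket.nmda = 0.994,
                             L5Pyr.ampa = 0.005, L5Pyr.nmda = 0.006,
                             L5Basket.ampa = 0.984, L5Basket.nmda = 0.998))
  ),
  left = list(
    prox1 = list(pathway = "proximal", mean_time = 54.898, sd_time = 5.401,
                 weights = c(L2Pyr.ampa = 0.991, L2Pyr.nmda = 1.714,
                             L2Basket.ampa = 0.997, L2Basket.nmda = 0.984,
                             L5Pyr.ampa = 0.004, L5Pyr.nmda = 0.010,
                             L5Basket.ampa = 0.615, L5Basket.nmda = 0.062)),
    dist1 = list(pathway = "distal", mean_time = 82.991, sd_time = 13.208,
                 weights = c(L2Pyr.ampa = 0.607, L2Pyr.nmda = 0.242,
                             L2Basket.ampa = 0.624, L2Basket.nmda = 0.953,
                             L5Pyr.ampa = 0.258, L5Pyr.nmda = 0.157)),
    prox2 = list(pathway = "proximal", mean_time = 161.307, sd_time = 19.844,
                 weights = c(L2Pyr.ampa = 0.854, L2Pyr.nmda = 0.067,
                             L2Basket.ampa = 0.758, L2Basket.nmda = 0.851,
                             L5Pyr.ampa = 0.012, L5Pyr.nmda = 0.004,
                             L5Basket.ampa = 0.980, L5Basket.nmda = 0.902))
  )
)
SCALING_CONTRA <- 1500
SCALING_IPSI <- 1200
IPSI_DELAY_MS <- 5

#' Preset drive sequences for the four modelled conditions
#'
#' Returns the fitted proximal-distal-proximal drive sequence and network
#' scaling factor for one of the four conditions.  The ipsilateral presets are
#' the contralateral drives of the same hemisphere with every mean input time
#' delayed by 5 ms and the scaling factor reduced from 1500 to 1200 (fewer,
#' later-activated neurons for ipsilateral tone presentation).
#'
#' @param condition One of `"right_contra"`, `"left_contra"`, `"right_ipsi"`,
#'   `"left_ipsi"`.
#' @return List with elements `drives` (list of three [driveSpec()] objects)
#'   and `scaling`.
#' @export
presetDriveSequence <- function(condition) {
  ok <- c("right_contra", "left_contra", "right_ipsi", "left_ipsi")
  if (!is.character(condition) || length(condition) != 1 || !condition %in% ok)
    stop("unknown condition; must be one of ", paste(ok, collapse = ", "),
         call. = FALSE)
  hemi <- sub("_.*$", "", condition)
  tab <- DRIVE_TABLE[[hemi]]
  drives <- lapply(names(tab), function(nm) {
    d <- tab[[nm]]
    driveSpec(nm, d$pathway, d$mean_time, d$sd_time, d$weights)
  })
  if (grepl("ipsi$", condition)) {
    drives <- shiftDrives(drives, IPSI_DELAY_MS)
    scaling <- SCALING_IPSI
  } else {
    scaling <- SCALING_CONTRA
  }
  list(drives = drives, scaling = scaling, condition = condition)
}

#' Shift all drive times
#'
#' Adds a common latency to every drive's mean input time, leaving all other
#' parameters untouched (shifts the evoked waveform along the time axis
#' without changing its shape).
#'
#' @param drives List of `DriveSpec`.
#' @param delta Shift in ms.
#' @return Shifted list.
#' @export
shiftDrives <- function(drives, delta) {
  lapply(drives, function(d) { d$mean_time <- d$mean_time + delta; d })
}

#' Sample the input spikes of a drive for one trial
#'
#' Draws one Gaussian spike time per target cell (and per spike of
#' `spikes_per_cell`), independently across cells, and attaches the
#' receptor-specific conductances.  Sampled times are clipped to
#' `[0, duration]`.  Uses R's global RNG: seed it for reproducibility.
#'
#' @param drive A `DriveSpec`.
#' @param network A `Network`.
#' @param duration Simulation duration, ms (clipping window).
#' @param z Optional matrix of standard-normal draws (cells x spikes) to use
#'   instead of fresh draws — used for common-random-numbers optimization,
#'   where spike times must vary smoothly with the drive parameters.
#' @return An `EventSchedule` data.frame with columns drive, pathway,
#'   population, cell, receptor, weight, time.
#' @export
sampleDriveSpikes <- function(drive, network, duration = 250, z = NULL) {
  stopifnot(inherits(drive, "DriveSpec"), inherits(network, "Network"))
  tgt <- network$config$params$drive_targets[[drive$pathway]]
  pops <- sub("\\..*$", "", names(drive$weights))
  recs <- sub("^.*\\.", "", names(drive$weights))
  out <- vector("list", length(drive$weights))
  # one spike time per target cell, shared by that cell's receptors/sections
  cells_by_pop <- list()
  upops <- intersect(unique(pops), names(network$pop_sizes))
  ncell_tot <- sum(vapply(upops, function(pp) network$pop_sizes[[pp]], numeric(1)))
  if (is.null(z)) {
    z <- matrix(stats::rnorm(ncell_tot * drive$spikes_per_cell),
                ncol = drive$spikes_per_cell)
  } else {
    z <- as.matrix(z)
    if (nrow(z) < ncell_tot || ncol(z) < drive$spikes_per_cell)
      stop("'z' must be at least (total target cells) x spikes_per_cell",
           call. = FALSE)
  }
  off <- 0
  for (pp in upops) {
    nc <- network$pop_sizes[[pp]]
    tm <- drive$mean_time + drive$sd_time * z[off + seq_len(nc), , drop = FALSE]
    cells_by_pop[[pp]] <- pmin(pmax(tm, 0), duration)
    off <- off + nc
  }
  k <- 0
  for (j in seq_along(drive$weights)) {
    pp <- pops[j]
    if (!pp %in% upops || drive$weights[j] <= 0) next
    if (!pp %in% tgt$populations) next
    tm <- cells_by_pop[[pp]]
    nc <- nrow(tm); ns <- ncol(tm)
    k <- k + 1
    out[[k]] <- data.frame(
      drive = drive$name, pathway = drive$pathway, population = pp,
      cell = rep(seq_len(nc) - 1L, ns), receptor = recs[j],
      weight = drive$weights[[j]], time = as.vector(tm),
      stringsAsFactors = FALSE
    )
  }
  sched <- if (k > 0) do.call(rbind, out[seq_len(k)]) else
    data.frame(drive = character(0), pathway = character(0),
               population = character(0), cell = integer(0),
               receptor = character(0), weight = numeric(0), time = numeric(0))
  class(sched) <- c("EventSchedule", "data.frame")
  sched
}

#' Sample the full drive sequence of a trial
#'
#' @param drives List of `DriveSpec`.
#' @param network A `Network`.
#' @param duration Simulation duration, ms.
#' @param seed Optional integer seed for the trial.
#' @param zlist Optional list of standard-normal draw matrices (one per
#'   drive), see [sampleDriveSpikes()].
#' @return Combined `EventSchedule`.
#' @export
sampleDriveSequence <- function(drives, network, duration = 250, seed = NULL,
                                zlist = NULL) {
  if (!is.null(seed)) set.seed(seed)
  scheds <- lapply(seq_along(drives), function(i)
    sampleDriveSpikes(drives[[i]], network, duration,
                      z = if (is.null(zlist)) NULL else zlist[[i]]))
  sched <- do.call(rbind, scheds)
  class(sched) <- c("EventSchedule", "data.frame")
  sched
}
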