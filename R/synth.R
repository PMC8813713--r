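#' Specification of a synthetic evoked-field dataset
#'
#' Describes a multi-subject set of auditory-evoked-field-like waveforms with
#' the canonical P50m (+), N100m (-), P200m (+) morphology, configurable
#' laterality effects, between-subject variability and band-limited noise.
#' The default morphology constants are fixture values chosen to resemble
#' source-localised auditory evoked fields qualitatively; they are not fitted
#' to any dataset.
#'
#' @param amplitudes Component peak magnitudes (nAm), named p50/n100/p200
#'   (signs applied internally: the N100m is a trough).
#' @param latencies Component peak latencies, ms.
#' @param widths Gaussian component SDs, ms.
#' @param contra_amp_ratio Contralateral / ipsilateral amplitude ratio
#'   (applied to all components).
#' @param ipsi_latency_shift Added to every component latency for ipsilateral
#'   presentation, ms.
#' @param right_n100_ratio Right / left N100m amplitude ratio.
#' @param amp_sd,lat_sd,width_sd Between-subject SDs of the component
#'   parameters (amplitude per component, nAm; latency ms; width ms).
#' @param noise_sd SD of the additive band-limited noise, nAm.
#' @param noise_bw_hz Low-pass corner of the noise, Hz.
#' @param n_subjects Number of subjects.
#' @param seed Integer seed; generation is fully reproducible from it.
#' @return An `EffectSpec`.
#' @export
effectSpec <- function(amplitudes = c(p50 = 25, n100 = 60, p200 = 30),
                       latencies = c(p50 = 52, n100 = 98, p200 = 185),
                       widths = c(p50 = 8, n100 = 12, p200 = 28),
                       contra_amp_ratio = 1.25,
                       ipsi_latency_shift = 5,
                       right_n100_ratio = 1.3,
                       amp_sd = c(p50 = 5, n100 = 12, p200 = 8),
                       lat_sd = 5, width_sd = 2,
                       noise_sd = 2, noise_bw_hz = 40,
                       n_subjects = 10, seed = 1) {
  if (any(widths <= 0)) stop("'widths' must be > 0", call. = FALSE)
  if (contra_amp_ratio <= 0 || right_n100_ratio <= 0)
    stop("amplitude ratios must be > 0", call. = FALSE)
  if (n_subjects < 1) stop("'n_subjects' must be >= 1", call. = FALSE)
  if (noise_sd < 0) stop("'noise_sd' must be >= 0", call. = FALSE)
  structure(list(amplitudes = amplitudes, latencies = latencies,
                 widths = widths, contra_amp_ratio = contra_amp_ratio,
                 ipsi_latency_shift = ipsi_latency_shift,
                 right_n100_ratio = right_n100_ratio,
                 amp_sd = amp_sd, lat_sd = lat_sd, width_sd = width_sd,
                 noise_sd = noise_sd, noise_bw_hz = noise_bw_hz,
                 n_subjects = as.integer(n_subjects), seed = as.integer(seed)),
            class = "EffectSpec")
}

synthGrid <- function() seq(0, 150) / 600 * 1000  # 600 Hz, 0-250 ms

bandLimitedNoise <- function(n, sd, bw_hz, fs_hz = 600) {
  if (sd <= 0) return(numeric(n))
  x <- stats::rnorm(n + 200)  # pad to suppress filter edge effects
  bf <- signal::butter(4, bw_hz / (fs_hz / 2), type = "low")
  xf <- signal::filtfilt(bf, x)[101:(100 + n)]
  xf / stats::sd(xf) * sd
}

#' Generate a synthetic waveform set
#'
#' Each waveform is the sum of three signed Gaussian components whose
#' subject-level parameters are drawn from the between-subject distributions,
#' with condition effects applied multiplicatively (amplitudes) and additively
#' (latencies), plus band-limited Gaussian noise.  The full 2 x 2
#' (hemisphere x presentation) design is generated for every subject on the
#' 600 Hz, 0-250 ms grid.
#'
#' @param spec An [effectSpec()].
#' @return A `WaveformSet`: list with `design` (subject, hemisphere,
#'   presentation), `traces` (list of [dipoleTrace()]), `spec`.
#' @export
generateWaveforms <- function(spec) {
  stopifnot(inherits(spec, "EffectSpec"))
  set.seed(spec$seed)
  tms <- synthGrid()
  comps <- c("p50", "n100", "p200")
  signs <- c(p50 = 1, n100 = -1, p200 = 1)
  design <- expand.grid(presentation = c("contra", "ipsi"),
                        hemisphere = c("left", "right"),
                        subject = seq_len(spec$n_subjects),
                        stringsAsFactors = FALSE)[, 3:1]
  traces <- vector("list", nrow(design))
  for (s in seq_len(spec$n_subjects)) {
    amp_s <- pmax(spec$amplitudes + stats::rnorm(3, 0, spec$amp_sd), 0.1)
    lat_s <- spec$latencies + stats::rnorm(3, 0, spec$lat_sd)
    wid_s <- pmax(spec$widths + stats::rnorm(3, 0, spec$width_sd), 1)
    names(amp_s) <- names(lat_s) <- names(wid_s) <- comps
    for (h in c("left", "right")) for (p in c("contra", "ipsi")) {
      amp <- amp_s
      if (p == "contra") amp <- amp * spec$contra_amp_ratio
      if (h == "right") amp["n100"] <- amp["n100"] * spec$right_n100_ratio
      lat <- lat_s + if (p == "ipsi") spec$ipsi_latency_shift else 0
      y <- numeric(length(tms))
      for (cc in comps)
        y <- y + signs[[cc]] * amp[[cc]] *
          exp(-(tms - lat[[cc]])^2 / (2 * wid_s[[cc]]^2))
      y <- y + bandLimitedNoise(length(tms), spec$noise_sd, spec$noise_bw_hz)
      i <- which(design$subject == s & design$hemisphere == h &
                   design$presentation == p)
      traces[[i]] <- dipoleTrace(tms, y, meta = list(
        units = "nAm", scaling = 1, smoothing_ms = 0, n_trials = 1))
    }
  }
  structure(list(design = design, traces = traces, spec = spec),
            class = "WaveformSet")
}

#' Null (no-effect) synthetic waveform set
#'
#' [generateWaveforms()] with all condition ratios set to 1 and shifts to 0:
#' the four cells of each subject differ only by noise, so the design is
#' exchangeable.  Used for type-I-error calibration of the ANOVA.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param seed Integer seed.
#' @param ... Further arguments to [effectSpec()].
#' @return A `WaveformSet`.
#' @export
generateNullSet <- function(n_subjects = 10, seed = 1, ...) {
  if (n_subjects < 2)
    stop("'n_subjects' must be >= 2 (the ANOVA needs at least 2 subjects)",
         call. = FALSE)
  generateWaveforms(effectSpec(contra_amp_ratio = 1, ipsi_latency_shift = 0,
                               right_n100_ratio = 1, n_subjects = n_subjects,
                               seed = seed, ...))
}

#' Component measures of every waveform in a set
#'
#' @param ws A `WaveformSet`.
#' @return Data.frame: subject, hemisphere, presentation + the four component
#'   measures, ready for [rmAnova2x2()].
#' @export
measureWaveformSet <- function(ws) {
  stopifnot(inherits(ws, "WaveformSet"))
  meas <- do.call(rbind, lapply(ws$traces, measureComponents))
  cbind(ws$design, meas)
}

#' @export
print.WaveformSet <- function(x, ...) {
  cat(sprintf("WaveformSet: %d subjects x 2 hemispheres x 2 presentations (%d waveforms)\n",
              x$spec$n_subjects, length(x$traces)))
  invisible(x)
}
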