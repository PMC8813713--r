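# Flat key-value parameter files: one `key: value` per line, keys namespaced
# (net.*, sim.*, drive.<name>.*, scaling).  Comments (#) and blank lines are
# ignored.  Round-trip stable at full double precision.

KNOWN_NET_KEYS <- c("n_pyr_per_layer", "n_basket_per_layer", "grid_spacing",
                    "kernel")
KNOWN_SIM_KEYS <- c("duration", "dt", "n_trials", "base_seed", "record_dt")
KNOWN_DRIVE_KEYS <- c("pathway", "mean_time", "sd_time", "spikes_per_cell")

fmtNum <- function(x) formatC(x, digits = 17, format = "g")

#' Write a parameter file
#'
#' Serialises network, simulation and drive parameters (the 28 drive
#' parameters of a condition plus the scaling factor) as a flat key-value
#' text file.
#'
#' @param path Output file.
#' @param drives List of `DriveSpec`.
#' @param scaling Scaling factor.
#' @param net A `NetworkConfig` (only the scalar fields are serialised; the
#'   fixed-parameter registry is code, not file, state).
#' @param sim A `SimulationConfig`.
#' @return `path`, invisibly.
#' @export
writeParams <- function(path, drives, scaling, net = networkConfig(),
                        sim = simulationConfig()) {
  ln <- c(
    sprintf("net.n_pyr_per_layer: %d", net$n_pyr_per_layer),
    sprintf("net.n_basket_per_layer: %d", net$n_basket_per_layer),
    sprintf("net.grid_spacing: %s", fmtNum(net$grid_spacing)),
    sprintf("net.kernel: %d", as.integer(net$kernel)),
    sprintf("sim.duration: %s", fmtNum(sim$duration)),
    sprintf("sim.dt: %s", fmtNum(sim$dt)),
    sprintf("sim.n_trials: %d", sim$n_trials),
    sprintf("sim.base_seed: %d", sim$base_seed),
    sprintf("sim.record_dt: %s", fmtNum(sim$record_dt)),
    sprintf("scaling: %s", fmtNum(scaling))
  )
  for (d in drives) {
    ln <- c(ln,
            sprintf("drive.%s.pathway: %s", d$name, d$pathway),
            sprintf("drive.%s.mean_time: %s", d$name, fmtNum(d$mean_time)),
            sprintf("drive.%s.sd_time: %s", d$name, fmtNum(d$sd_time)),
            sprintf("drive.%s.spikes_per_cell: %d", d$name, d$spikes_per_cell))
    for (w in names(d$weights))
      ln <- c(ln, sprintf("drive.%s.w.%s: %s", d$name, w,
                          fmtNum(d$weights[[w]])))
  }
  writeLines(ln, path)
  invisible(path)
}

#' Read a parameter file
#'
#' Parses the flat key-value dialect written by [writeParams()].  Unknown
#' keys are an error (all offenders listed); malformed lines are reported
#' with their line number.  When `check_condition = TRUE` the file must carry
#' a complete condition: 28 drive parameters (3 mean times, 3 SDs, 22
#' weights) plus the scaling factor.
#'
#' @param path Input file.
#' @param check_condition Enforce condition-file completeness.
#' @return List with `net` (`NetworkConfig`), `drives`, `scaling`, `sim`.
#' @export
readParams <- function(path, check_condition = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- readLines(path)
  kv <- list()
  for (i in seq_along(raw)) {
    s <- trimws(sub("#.*$", "", raw[i]))
    if (!nzchar(s)) next
    m <- regmatches(s, regexec("^([A-Za-z0-9._]+):\\s*(.+)$", s))[[1]]
    if (length(m) != 3)
      stop(sprintf("malformed line %d: '%s'", i, raw[i]), call. = FALSE)
    kv[[m[2]]] <- m[3]
  }
  keys <- names(kv)

  unknown <- character(0)
  for (k in keys) {
    parts <- strsplit(k, ".", fixed = TRUE)[[1]]
    ok <- (parts[1] == "net" && length(parts) == 2 && parts[2] %in% KNOWN_NET_KEYS) ||
      (parts[1] == "sim" && length(parts) == 2 && parts[2] %in% KNOWN_SIM_KEYS) ||
      (k == "scaling") ||
      (parts[1] == "drive" && length(parts) >= 3 &&
         (parts[3] %in% KNOWN_DRIVE_KEYS ||
            (parts[3] == "w" && length(parts) == 5 &&
               parts[4] %in% POPULATIONS && parts[5] %in% c("ampa", "nmda"))))
    if (!ok) unknown <- c(unknown, k)
  }
  if (length(unknown))
    stop("unknown parameter key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)

  num <- function(k, default = NULL) {
    if (!k %in% keys) {
      if (is.null(default)) stop("missing required key: ", k, call. = FALSE)
      return(default)
    }
    as.numeric(kv[[k]])
  }
  net <- networkConfig(
    n_pyr_per_layer = num("net.n_pyr_per_layer", 100),
    n_basket_per_layer = num("net.n_basket_per_layer", 35),
    grid_spacing = num("net.grid_spacing", 1),
    kernel = num("net.kernel", 1) != 0)
  sim <- simulationConfig(
    duration = num("sim.duration", 250), dt = num("sim.dt", 0.025),
    n_trials = num("sim.n_trials", 10), base_seed = num("sim.base_seed", 1),
    record_dt = num("sim.record_dt", num("sim.dt", 0.025)))
  scaling <- num("scaling", if (check_condition) NULL else 1)

  dknames <- unique(vapply(grep("^drive\\.", keys, value = TRUE),
                           function(k) strsplit(k, ".", fixed = TRUE)[[1]][2],
                           character(1)))
  drives <- lapply(dknames, function(dn) {
    pre <- paste0("drive.", dn, ".")
    if (!paste0(pre, "pathway") %in% keys)
      stop("missing required key: ", pre, "pathway", call. = FALSE)
    wkeys <- grep(paste0("^", pre, "w\\."), keys, value = TRUE)
    weights <- stats::setNames(
      vapply(wkeys, function(k) as.numeric(kv[[k]]), numeric(1)),
      sub(paste0("^", pre, "w\\."), "", wkeys))
    driveSpec(dn, kv[[paste0(pre, "pathway")]],
              num(paste0(pre, "mean_time")), num(paste0(pre, "sd_time")),
              weights, num(paste0(pre, "spikes_per_cell"), 1))
  })
  # restore temporal order
  if (length(drives))
    drives <- drives[order(vapply(drives, function(d) d$mean_time, numeric(1)))]

  if (check_condition) {
    missW <- conditionMissingWeights(drives)
    if (length(missW))
      stop("missing drive weight key(s): ", paste(missW, collapse = ", "),
           call. = FALSE)
    npar <- countConditionParams(drives)
    if (npar != 28)
      stop(sprintf("condition file must carry 28 drive parameters (found %d)",
                   npar), call. = FALSE)
  }
  list(net = net, drives = drives, scaling = scaling, sim = sim)
}

#' Count the optimisable drive parameters of a sequence
#'
#' @param drives List of `DriveSpec`.
#' @return Mean times + SDs + weights (28 for a full condition).
#' @export
countConditionParams <- function(drives) {
  sum(vapply(drives, function(d) 2L + length(d$weights), integer(1)))
}

# weight keys a full proximal-distal-proximal condition must carry
conditionMissingWeights <- function(drives) {
  miss <- character(0)
  for (d in drives) {
    pops <- if (d$pathway == "proximal") POPULATIONS else
      c("L2Pyr", "L2Basket", "L5Pyr")
    want <- as.vector(outer(pops, c("ampa", "nmda"), paste, sep = "."))
    miss <- c(miss, paste0("drive.", d$name, ".w.",
                           setdiff(want, names(d$weights)), recycle0 = TRUE))
  }
  miss
}
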