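# shared fixtures: networks and condition simulations are expensive, so they
# are built once per test run and cached here

.fixtures <- new.env(parent = emptyenv())

fullNetwork <- function() {
  if (is.null(.fixtures$net)) .fixtures$net <- buildNetwork(networkConfig())
  .fixtures$net
}

# one pyramidal cell per layer, no baskets (single-cell probes)
pyrOnlyNetwork <- function() {
  if (is.null(.fixtures$pyr1))
    .fixtures$pyr1 <- buildNetwork(networkConfig(n_pyr_per_layer = 1,
                                                 n_basket_per_layer = 0))
  .fixtures$pyr1
}

cachedCondition <- function(condition, n_trials = 10, base_seed = 1) {
  key <- sprintf("%s_%d_%d", condition, n_trials, base_seed)
  if (is.null(.fixtures[[key]])) {
    ps <- presetDriveSequence(condition)
    sim <- simulationConfig(n_trials = n_trials, base_seed = base_seed)
    .fixtures[[key]] <- simulateCondition(fullNetwork(), ps$drives, sim,
                                          scaling = ps$scaling)
  }
  .fixtures[[key]]
}

emptySchedule <- function() {
  structure(data.frame(drive = character(0), pathway = character(0),
                       population = character(0), cell = integer(0),
                       receptor = character(0), weight = numeric(0),
                       time = numeric(0)),
            class = c("EventSchedule", "data.frame"))
}

# synthetic triangular/gaussian test trace on an arbitrary grid
gaussTrace <- function(times = seq(0, 250, length.out = 151), amp = -30,
                       center = 100, width = 10, meta = list(units = "nAm",
                       scaling = 1, smoothing_ms = 0, n_trials = 1)) {
  dipoleTrace(times, amp * exp(-(times - center)^2 / (2 * width^2)),
              meta = meta)
}
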