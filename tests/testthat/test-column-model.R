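test_that("default network has the four populations at the documented sizes", {
  net <- fullNetwork()
  expect_equal(unname(net$pop_sizes[c("L2Pyr", "L5Pyr")]), c(100, 100))
  expect_equal(unname(net$pop_sizes[c("L2Basket", "L5Basket")]), c(35, 35))
  expect_equal(net$templates$L2Pyr$n_comp, 8)
  expect_equal(net$templates$L5Pyr$n_comp, 9)
  expect_equal(net$templates$L2Basket$n_comp, 1)
  # layer V pyramids carry calcium channels, layer II/III do not
  expect_true(any(net$engine$gca[net$populations[net$engine$cell + 1] == "L5Pyr"] > 0))
  expect_true(all(net$engine$gca[net$populations[net$engine$cell + 1] == "L2Pyr"] == 0))
})

test_that("degenerate and invalid configurations are handled", {
  net0 <- buildNetwork(networkConfig(n_pyr_per_layer = 2,
                                     n_basket_per_layer = 0))
  expect_equal(sum(net0$populations %in% c("L2Basket", "L5Basket")), 0)
  expect_error(networkConfig(n_pyr_per_layer = -1), "n_pyr_per_layer")
  expect_error(networkConfig(n_basket_per_layer = -2), "n_basket_per_layer")
  cfg <- networkConfig()
  cfg$params$connectivity$weight[1] <- -1
  expect_error(validateNetworkConfig(cfg), "weight")
})

test_that("override registry scales exactly the advertised parameter classes", {
  cfg <- networkConfig()
  # identity
  same <- applyOverrides(cfg, c(inhibitory_targeting_weights = 1))
  expect_equal(same$params, cfg$params)
  # the five synaptic conductances onto basket cells are scaled, nothing else
  down <- applyOverrides(cfg, c(inhibitory_targeting_weights = 0.1))
  sel <- cfg$params$connectivity$post %in% c("L2Basket", "L5Basket")
  expect_equal(sum(sel), 5)
  expect_equal(down$params$connectivity$weight[sel],
               cfg$params$connectivity$weight[sel] * 0.1)
  expect_equal(down$params$connectivity$weight[!sel],
               cfg$params$connectivity$weight[!sel])
  # calcium density override touches only L5 pyramidal HVA calcium
  ca <- applyOverrides(cfg, c(L5_pyr_calcium_density = 0.06))
  expect_equal(ca$params$cells$L5Pyr$channels$soma[["ca"]],
               cfg$params$cells$L5Pyr$channels$soma[["ca"]] * 0.06)
  expect_equal(ca$params$cells$L5Pyr$channels$dend[["ca"]],
               cfg$params$cells$L5Pyr$channels$dend[["ca"]] * 0.06)
  expect_equal(ca$params$cells$L2Pyr, cfg$params$cells$L2Pyr)
  expect_error(applyOverrides(cfg, c(no_such_class = 1)),
               "inhibitory_targeting_weights")
  expect_error(applyOverrides(cfg, c(L5_pyr_calcium_density = -1)), ">= 0")
})

test_that("undriven network is quiescent and dipole layers are additive", {
  net <- fullNetwork()
  sim <- simulationConfig(n_trials = 1)
  r <- runTrial(net, emptySchedule(), sim)
  expect_equal(nrow(r$raster), 0)
  # resting drift well below one fAm peak-to-peak (evoked deflections are
  # tens of thousands of fAm)
  expect_lt(diff(range(r$dipole$aggregate)), 2)
  expect_equal(r$dipole$aggregate,
               r$dipole$per_layer$L2 + r$dipole$per_layer$L5,
               tolerance = 1e-9)
  # additivity also holds for a driven trial
  res <- cachedCondition("right_contra")
  tr <- res$trials[[1]]
  expect_equal(tr$aggregate, tr$per_layer$L2 + tr$per_layer$L5,
               tolerance = 1e-9)
})

test_that("identical configuration and seed reproduce rasters and dipoles exactly", {
  net <- fullNetwork()
  ps <- presetDriveSequence("right_contra")
  sim <- simulationConfig(n_trials = 2, base_seed = 42)
  a <- simulateCondition(net, ps$drives, sim, scaling = ps$scaling)
  b <- simulateCondition(net, ps$drives, sim, scaling = ps$scaling)
  expect_identical(a$raster, b$raster)
  expect_equal(a$trials[[1]]$aggregate, b$trials[[1]]$aggregate,
               tolerance = 0)
  expect_equal(a$trials[[2]]$aggregate, b$trials[[2]]$aggregate,
               tolerance = 0)
})

test_that("a passive compartment follows the closed-form RC charging curve", {
  p <- defaultNetworkParams()
  p$cells$L2Basket$channels$soma <- c(leak = 1e-4)
  net <- buildNetwork(networkConfig(n_pyr_per_layer = 0,
                                    n_basket_per_layer = 1, params = p))
  geom <- p$cells$L2Basket$sections
  area <- pi * geom$diam * geom$L
  gl <- 1e-4 * area * 1e-2           # uS
  cm <- p$cells$L2Basket$cm * area * 1e-5  # nF
  tau <- cm / gl                      # ms
  amp <- 0.05                         # nA
  sim <- simulationConfig(duration = ceiling(5 * tau) + 10, n_trials = 1)
  soma <- net$engine$soma[net$populations == "L2Basket"][1] + 1
  r <- runTrial(net, emptySchedule(), sim,
                iclamp = data.frame(comp = soma, amp = amp, start = 0,
                                    stop = sim$duration),
                record_comps = soma)
  v0 <- -65; vinf <- v0 + amp / gl
  sel <- r$t <= 5 * tau
  vexact <- vinf + (v0 - vinf) * exp(-r$t[sel] / tau)
  expect_lt(max(abs(r$v[sel, 1] - vexact)), 0.01 * abs(vinf - v0))
})

test_that("halving the time step barely changes a driven subthreshold trace", {
  net <- pyrOnlyNetwork()
  soma <- net$engine$soma[net$populations == "L2Pyr"][1] + 1
  sch <- data.frame(drive = "p", pathway = "proximal", population = "L2Pyr",
                    cell = 0L, receptor = "ampa", weight = 5e-4, time = 50)
  v <- lapply(c(0.025, 0.0125), function(dt) {
    sim <- simulationConfig(duration = 100, dt = dt, record_dt = 0.025,
                            n_trials = 1)
    runTrial(net, sch, sim, record_comps = soma)$v[, 1]
  })
  expect_gt(diff(range(v[[1]])), 0.5)        # the input actually did something
  expect_lt(max(v[[1]]), -50)                # and stayed subthreshold
  expect_lt(max(abs(v[[1]] - v[[2]])), 0.2)  # mV; self-convergence
})

test_that("shifting every drive event shifts the raw dipole along time", {
  net <- fullNetwork()
  ps <- presetDriveSequence("right_contra")
  sim <- simulationConfig(n_trials = 1, base_seed = 7)
  delta <- 10; steps <- round(delta / sim$record_dt)
  s1 <- sampleDriveSequence(ps$drives, net, sim$duration, seed = 7)
  s2 <- s1; s2$time <- s2$time + delta
  r1 <- runTrial(net, s1, sim)$dipole$aggregate
  r2 <- runTrial(net, s2, sim)$dipole$aggregate
  n <- length(r1)
  expect_gt(diff(range(r1)), 1e4)  # strongly driven
  expect_lt(max(abs(r1[1:(n - steps)] - r2[(steps + 1):n])),
            1e-4 * diff(range(r1)))
})

test_that("proximal and distal drives deflect the dipole with opposite polarity", {
  net <- fullNetwork()
  sim <- simulationConfig(n_trials = 1, duration = 150)
  prox <- data.frame(drive = "p", pathway = "proximal",
                     population = rep(c("L2Pyr", "L2Basket"), each = 100)[1:135],
                     cell = c(0:99, 0:34), receptor = "ampa",
                     weight = c(rep(0.659, 100), rep(0.997, 35)), time = 47)
  rp <- runTrial(net, prox, sim)
  # layer II/III spiking shortly after the input, initial positive deflection
  l2spk <- rp$raster$time[rp$raster$population %in% c("L2Pyr", "L2Basket")]
  expect_gt(length(l2spk), 10)
  expect_true(min(l2spk) > 47 && min(l2spk) < 60)
  early <- rp$dipole$times >= 47 & rp$dipole$times <= 70
  expect_gt(max(rp$dipole$aggregate[early]), 0)
  expect_gt(max(rp$dipole$aggregate[early]), -min(rp$dipole$aggregate[early]))
  # distal drive pushes current down the apical dendrites: net negative
  dist <- data.frame(drive = "d", pathway = "distal",
                     population = rep(c("L2Pyr", "L5Pyr"), each = 100),
                     cell = rep(0:99, 2), receptor = "ampa",
                     weight = rep(c(0.607, 0.964), each = 100), time = 81)
  rd <- runTrial(net, dist, sim)
  late <- rd$dipole$times >= 85 & rd$dipole$times <= 120
  expect_lt(min(rd$dipole$aggregate[late]), 0)
  expect_gt(-min(rd$dipole$aggregate[late]), max(rd$dipole$aggregate[late]))
})

test_that("simulation parameters are validated", {
  expect_error(simulationConfig(dt = 0), "dt")
  expect_error(simulationConfig(duration = -5), "duration")
  expect_error(simulationConfig(n_trials = 0), "n_trials")
  net <- pyrOnlyNetwork()
  sch <- data.frame(drive = "p", pathway = "proximal", population = "L2Pyr",
                    cell = 0L, receptor = "ampa", weight = 0.1, time = 500)
  expect_error(runTrial(net, sch, simulationConfig(n_trials = 1)),
               "within")
})
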