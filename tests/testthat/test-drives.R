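test_that("condition presets carry the fitted drive parameters", {
  rc <- presetDriveSequence("right_contra")
  expect_equal(vapply(rc$drives, function(d) d$mean_time, numeric(1)),
               c(47.355, 81.091, 150.826))
  expect_equal(vapply(rc$drives, function(d) d$sd_time, numeric(1)),
               c(2.963, 12.261, 1.061))
  expect_equal(rc$scaling, 1500)
  lc <- presetDriveSequence("left_contra")
  expect_equal(vapply(lc$drives, function(d) d$mean_time, numeric(1)),
               c(54.898, 82.991, 161.307))
  # the single parameter distinguishing the hemispheres' N100m mechanism
  expect_equal(lc$drives[[2]]$weights[["L5Pyr.ampa"]], 0.258)
  expect_equal(rc$drives[[2]]$weights[["L5Pyr.ampa"]], 0.964)
  # ipsilateral: +5 ms on every input, scaling 1500 -> 1200
  ri <- presetDriveSequence("right_ipsi")
  expect_equal(vapply(ri$drives, function(d) d$mean_time, numeric(1)),
               c(47.355, 81.091, 150.826) + 5)
  expect_equal(ri$scaling, 1200)
  expect_equal(ri$drives[[2]]$weights, rc$drives[[2]]$weights)
  # a full condition exposes exactly the 28 fitted drive parameters
  for (cond in c("right_contra", "left_contra", "right_ipsi", "left_ipsi"))
    expect_equal(countConditionParams(presetDriveSequence(cond)$drives), 28)
  expect_error(presetDriveSequence("middle_contra"), "unknown condition")
})

test_that("drive validation enforces pathway targeting rules", {
  expect_error(driveSpec("d", "distal", 80, 10, c(L5Basket.ampa = 1)),
               "layer V basket")
  expect_error(driveSpec("d", "proximal", 50, -1, c(L2Pyr.ampa = 1)),
               "sd_time")
  expect_error(driveSpec("d", "proximal", 50, 1, c(L2Pyr.ampa = -1)),
               ">= 0")
})

test_that("shifting drives is additive and touches nothing else", {
  rc <- presetDriveSequence("right_contra")$drives
  expect_equal(shiftDrives(rc, 0), rc)
  s5 <- shiftDrives(rc, 5)
  expect_equal(vapply(s5, function(d) d$mean_time, numeric(1)),
               c(52.355, 86.091, 155.826))
  expect_equal(s5[[1]]$weights, rc[[1]]$weights)
  expect_equal(shiftDrives(shiftDrives(rc, 3), 4), shiftDrives(rc, 7))
})

test_that("spike sampling matches its Gaussian law and is reproducible", {
  net <- fullNetwork()
  d <- driveSpec("d", "proximal", 47.355, 2.963, c(L2Pyr.ampa = 0.5),
                 spikes_per_cell = 100)  # 100 x 100 cells = 10,000 draws
  set.seed(11)
  sch <- sampleDriveSpikes(d, net, duration = 250)
  expect_equal(nrow(sch), 10000)
  se_mean <- 2.963 / sqrt(10000)
  se_sd <- 2.963 / sqrt(2 * 10000)
  expect_lt(abs(mean(sch$time) - 47.355), 3 * se_mean)
  expect_lt(abs(sd(sch$time) - 2.963), 3 * se_sd)
  # reproducibility under an identical RNG state
  set.seed(99); a <- sampleDriveSpikes(d, net, 250)
  set.seed(99); b <- sampleDriveSpikes(d, net, 250)
  expect_identical(a, b)
})

test_that("degenerate drives sample sensibly", {
  net <- fullNetwork()
  d0 <- driveSpec("d", "proximal", 60, 0, c(L2Basket.ampa = 0.1))
  sch <- sampleDriveSpikes(d0, net, 250)
  expect_true(all(sch$time == 60))
  dempty <- driveSpec("d", "distal", 60, 1, c(L2Pyr.ampa = 0)[0])
  expect_equal(nrow(sampleDriveSpikes(dempty, net, 250)), 0)
  # sampled times are clipped to the simulation window
  dneg <- driveSpec("d", "proximal", 1, 30, c(L2Basket.ampa = 0.1))
  set.seed(2)
  schn <- sampleDriveSpikes(dneg, net, 250)
  expect_true(all(schn$time >= 0 & schn$time <= 250))
})

test_that("generated schedules never target layer V baskets distally", {
  net <- fullNetwork()
  for (cond in c("right_contra", "left_contra")) {
    sch <- sampleDriveSequence(presetDriveSequence(cond)$drives, net, 250,
                               seed = 5)
    expect_false(any(sch$pathway == "distal" & sch$population == "L5Basket"))
  }
})

test_that("doubling a drive conductance doubles the peak synaptic current", {
  net <- pyrOnlyNetwork()
  tuft <- net$engine$cell_start[which(net$populations == "L5Pyr")] +
    net$templates$L5Pyr$sec_index[["apical_tuft"]]
  sim <- simulationConfig(duration = 80, n_trials = 1)
  peak <- vapply(c(1e-4, 2e-4), function(w) {
    sch <- data.frame(drive = "d", pathway = "distal", population = "L5Pyr",
                      cell = 0L, receptor = "ampa", weight = w, time = 40)
    r <- runTrial(net, sch, sim, record_comps = tuft)
    max(abs(r$isyn[, 1]))
  }, numeric(1))
  expect_gt(peak[1], 0)
  expect_equal(peak[2] / peak[1], 2, tolerance = 0.02)
})
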