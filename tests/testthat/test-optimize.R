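# small shared setup: optimisation against a self-generated target with
# common random numbers (search trials identical to the target's)
optSetup <- function() {
  if (is.null(.fixtures$opt)) {
    net <- fullNetwork()
    drives <- presetDriveSequence("right_contra")$drives
    sim <- simulationConfig(n_trials = 3, base_seed = 1)
    set.seed(501)
    zl <- lapply(1:3, function(tr) lapply(drives, function(d)
      matrix(rnorm(aefsim:::totalTargetCells(d, net)), ncol = 1)))
    res <- simulateCondition(net, drives, sim, scaling = 1500, zlists = zl)
    target <- conditionWaveform(res)
    .fixtures$opt <- list(net = net, drives = drives, sim = sim,
                          target = target)
  }
  .fixtures$opt
}

test_that("a budget of one evaluation returns the initial point", {
  s <- optSetup()
  init <- paramVector(s$drives, free = "times")
  r <- optimizeDriveParameters(init, s$target, s$net, s$drives, sim = s$sim,
                               scaling = 1500, budget = 1, seed = 501)
  expect_equal(r$n_evaluations, 1)
  expect_equal(r$best$value, init$value)
  expect_equal(nrow(r$trajectory), 1)
})

test_that("starting at the truth is a fixed point of the search", {
  s <- optSetup()
  init <- paramVector(s$drives, free = "times")
  r <- optimizeDriveParameters(init, s$target, s$net, s$drives, sim = s$sim,
                               scaling = 1500, budget = 8, seed = 501)
  # the target was generated with the same common random numbers, so the
  # initial RMSE is (numerically) zero and no candidate can improve on it
  expect_lt(r$trajectory$rmse[1], 1e-9)
  expect_lt(r$best_rmse, 1e-9)
  expect_equal(r$best$value, init$value, tolerance = 1e-9)
})

test_that("the running minimum of the trajectory never increases", {
  s <- optSetup()
  init <- paramVector(s$drives, free = "times")
  init$value[init$name == "prox1.mean_time"] <- 47.355 + 6
  r <- optimizeDriveParameters(init, s$target, s$net, s$drives, sim = s$sim,
                               scaling = 1500, budget = 12, seed = 501)
  runmin <- cummin(r$trajectory$rmse)
  expect_true(all(diff(runmin) <= 0))
  expect_lte(r$best_rmse, r$trajectory$rmse[1])
  expect_lte(r$n_evaluations, 12)
})

test_that("the search is deterministic under a fixed seed policy", {
  s <- optSetup()
  init <- paramVector(s$drives, free = "times")
  init$value[init$name == "dist1.mean_time"] <- 81.091 - 4
  r1 <- optimizeDriveParameters(init, s$target, s$net, s$drives, sim = s$sim,
                                scaling = 1500, budget = 10, seed = 501)
  r2 <- optimizeDriveParameters(init, s$target, s$net, s$drives, sim = s$sim,
                                scaling = 1500, budget = 10, seed = 501)
  expect_equal(r1$trajectory, r2$trajectory)
  expect_equal(r1$best$value, r2$best$value)
})

test_that("parameter vectors validate and round-trip to drives", {
  drives <- presetDriveSequence("right_contra")$drives
  pv <- paramVector(drives, scaling = 1500, free = character(0))
  expect_error(optimizeDriveParameters(pv, gaussTrace(), fullNetwork(),
                                       drives, budget = 5), "frozen")
  expect_equal(nrow(pv), 29)  # 28 drive parameters + scaling
  pv2 <- paramVector(drives, free = "times")
  pv2$value[pv2$name == "prox1.mean_time"] <- 50
  back <- paramsToDrives(pv2, drives)
  expect_equal(back$drives[[1]]$mean_time, 50)
  expect_equal(back$drives[[2]]$weights, drives[[2]]$weights)
  expect_null(back$scaling)
})
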