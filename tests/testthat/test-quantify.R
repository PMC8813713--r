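test_that("the N100m is the absolute extremum inside 80-120 ms", {
  x <- gaussTrace(amp = -30, center = 100)
  m <- measureN100m(x)
  expect_equal(m$amplitude, 30, tolerance = 1e-6)
  expect_equal(m$latency, 100, tolerance = 1)
  expect_equal(sign(m$value), -1)
  # monotone ramp: extremum sits at a window edge
  t <- seq(0, 250, length.out = 151)
  ramp <- dipoleTrace(t, t)
  expect_equal(measureN100m(ramp)$latency, max(t[t <= 120]))
  # a deeper trough outside the window is ignored
  y <- -30 * exp(-(t - 100)^2 / 200) - 80 * exp(-(t - 130)^2 / 20)
  m2 <- measureN100m(dipoleTrace(t, y))
  expect_lte(m2$latency, 120)
  expect_lt(abs(m2$amplitude - 30), 3)
  # a P200m-like bump outside the window does not move the measurement
  y3 <- x$aggregate + 50 * exp(-(t - 185)^2 / (2 * 20^2))
  m3 <- measureN100m(dipoleTrace(t, y3))
  expect_equal(m3$latency, m$latency)
  expect_equal(m3$amplitude, m$amplitude, tolerance = 1e-3)
  expect_error(measureN100m(dipoleTrace(0:50, rnorm(51))), "window")
})

test_that("window slopes are ordinary least squares on the closed interval", {
  t <- seq(0, 250, length.out = 151)
  expect_equal(fitWindowSlope(dipoleTrace(t, 2 * t + 1), 70, 90), 2)
  expect_equal(fitWindowSlope(dipoleTrace(t, rep(4, 151)), 110, 130), 0)
  # line + zero-mean noise: slope within 3 analytic standard errors
  set.seed(17)
  sel <- t >= 70 & t <= 90
  expect_equal(sum(sel), 13)
  sigma <- 1.5; beta <- -0.8
  y <- beta * t + rnorm(151, 0, sigma)
  se <- sigma / sqrt(sum((t[sel] - mean(t[sel]))^2))
  est <- fitWindowSlope(dipoleTrace(t, y), 70, 90)
  expect_lt(abs(est - beta), 3 * se)
  # matches lm() exactly
  expect_equal(est, unname(coef(lm(y[sel] ~ t[sel]))[2]), tolerance = 1e-12)
  expect_error(fitWindowSlope(dipoleTrace(t, y), 90, 70), "t0")
  expect_error(fitWindowSlope(dipoleTrace(t, y), 70.2, 70.4), "2 samples")
})

test_that("rmse equals its definition and is a metric on waveforms", {
  t <- seq(0, 250, length.out = 151)
  set.seed(23)
  a <- dipoleTrace(t, rnorm(151)); b <- dipoleTrace(t, rnorm(151))
  expect_equal(rmse(a, a), 0)
  cst <- dipoleTrace(t, a$aggregate + 3.25)
  expect_equal(rmse(a, cst), 3.25)
  expect_equal(rmse(a, b), sqrt(mean((a$aggregate - b$aggregate)^2)),
               tolerance = 1e-12)
  expect_equal(rmse(a, b), rmse(b, a))
  expect_gt(rmse(a, b), 0)
  expect_error(rmse(a, dipoleTrace(t + 1, b$aggregate)), "grids")
})

test_that("firing rates normalise by trials, cells and duration", {
  empty <- data.frame(population = character(0), cell = integer(0),
                      time = numeric(0))
  expect_equal(firingRates(empty, "L2Pyr", 250, 10, 100), 0)
  r5 <- data.frame(population = "L5Pyr", cell = 0, time = seq(10, 210, 50))
  expect_equal(firingRates(r5, "L5Pyr", 250, 1, 1), 20)
  expect_equal(firingRates(r5, "L5Pyr", 500, 1, 1), 10)  # inverse in duration
  shuf <- r5; shuf$cell <- sample(0:4, 5, replace = TRUE)
  expect_equal(firingRates(shuf, "L5Pyr", 250, 1, 1),
               firingRates(r5, "L5Pyr", 250, 1, 1))
  expect_error(firingRates(r5, "L4Spiny", 250, 1, 1), "unknown population")
  expect_error(firingRates(r5, "L5Pyr", 250, 0, 1), "positive")
})

test_that("network scale converts to contributing-cell counts", {
  expect_equal(estimateContributingCells(1, 200), 200)
  s <- scalingFromSignal(10)
  expect_equal(s$cells, 50000)
  expect_equal(s$scaling, 250)
  expect_error(estimateContributingCells(0), "positive")
  expect_error(scalingFromSignal(-1), "positive")
})
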