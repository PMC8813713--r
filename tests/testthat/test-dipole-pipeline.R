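test_that("scaling is multiplicative, composes, and validates its factor", {
  x <- gaussTrace()
  expect_equal(scaleTrace(x, 1)$aggregate, x$aggregate)
  u <- dipoleTrace(x$times, rep(1, length(x$times)))
  expect_equal(scaleTrace(u, 1500)$aggregate, rep(1500, length(x$times)))
  expect_equal(scaleTrace(scaleTrace(x, 3), 5)$aggregate,
               scaleTrace(x, 15)$aggregate)
  expect_equal(scaleTrace(scaleTrace(x, 3), 5)$meta$scaling, 15)
  expect_error(scaleTrace(x, 0), "positive")
  expect_error(scaleTrace(x, -2), "positive")
})

test_that("Hamming smoothing has unit area and reproduces its kernel", {
  times <- seq(0, 250, by = 1)
  const <- dipoleTrace(times, rep(3.5, length(times)))
  expect_equal(smoothHamming(const, 30)$aggregate, const$aggregate)
  # unit impulse maps to the normalised kernel itself
  y <- rep(0, length(times)); y[126] <- 1
  imp <- dipoleTrace(times, y)
  sm <- smoothHamming(imp, 30)$aggregate
  n <- 31  # round(30 / 1) + 1
  w <- 0.54 - 0.46 * cos(2 * pi * seq(0, n - 1) / (n - 1))
  w <- w / sum(w)
  expect_equal(sm[126 + seq(-15, 15)], w)
  expect_equal(sum(sm), 1)  # far from edges: mass preserved
  expect_equal(smoothHamming(imp, 0)$aggregate, y)
  expect_error(smoothHamming(dipoleTrace(0:10, rnorm(11)), 1000), "longer")
})

test_that("trial averaging is the samplewise mean with the expected variance", {
  x <- gaussTrace()
  expect_equal(averageTrials(rep(list(x), 10))$aggregate, x$aggregate)
  expect_equal(averageTrials(rep(list(x), 10))$meta$n_trials, 10)
  neg <- x; neg$aggregate <- -neg$aggregate
  expect_equal(averageTrials(list(x, neg))$aggregate,
               rep(0, length(x$times)))
  # variance of a mean of n iid noise traces ~ sigma^2 / n
  set.seed(31)
  n <- 100; sigma <- 2
  traces <- lapply(seq_len(n), function(i)
    dipoleTrace(x$times, rnorm(length(x$times), 0, sigma)))
  v <- var(averageTrials(traces)$aggregate)
  expect_equal(v, sigma^2 / n, tolerance = 0.35)
  bad <- dipoleTrace(x$times + 0.5, x$aggregate)
  expect_error(averageTrials(list(x, bad)), "time grid")
})

test_that("resampling hits the acquisition grid and is exact on lines", {
  x <- gaussTrace(times = seq(0, 250, by = 0.025))
  r <- resampleTo(x, 600)
  expect_equal(length(r$times), 151)
  expect_equal(r$times[1], 0)
  expect_equal(r$times[151], 150 / 600 * 1000)
  ramp <- dipoleTrace(seq(0, 250, by = 0.025),
                      2 * seq(0, 250, by = 0.025) + 1)
  rr <- resampleTo(ramp, 600)
  expect_equal(rr$aggregate, 2 * rr$times + 1)
  # resampling onto (essentially) its own grid is the identity
  y600 <- gaussTrace()
  expect_equal(resampleTo(y600, 600)$aggregate, y600$aggregate,
               tolerance = 1e-12)
})

test_that("the pipeline is linear: smoothing, scaling and averaging commute", {
  set.seed(8)
  times <- seq(0, 250, by = 0.5)
  xs <- lapply(1:4, function(i) dipoleTrace(times, rnorm(length(times))))
  k <- 7.5
  a <- smoothHamming(scaleTrace(xs[[1]], k), 30)$aggregate
  b <- scaleTrace(smoothHamming(xs[[1]], 30), k)$aggregate
  expect_equal(a, b, tolerance = 1e-12)
  p1 <- smoothHamming(scaleTrace(averageTrials(xs), k), 30)$aggregate
  p2 <- smoothHamming(averageTrials(lapply(xs, scaleTrace, factor = k)),
                      30)$aggregate
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("waveform TSV files round-trip and tolerate missing layer columns", {
  res <- cachedCondition("right_contra")
  wave <- conditionWaveform(res)
  f <- tempfile(fileext = ".tsv")
  writeWaveform(wave, f)
  back <- readWaveform(f)
  expect_equal(back$times, wave$times)
  expect_equal(back$aggregate, wave$aggregate, tolerance = 1e-10)
  expect_equal(back$per_layer$L5, wave$per_layer$L5, tolerance = 1e-10)
  # aggregate-only file
  writeWaveform(dipoleTrace(wave$times, wave$aggregate), f)
  agg <- readWaveform(f)
  expect_null(agg$per_layer)
  expect_equal(agg$aggregate, wave$aggregate, tolerance = 1e-10)
  unlink(f)
})
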