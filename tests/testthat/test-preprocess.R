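test_that("within-region averaging equals the brute-force vertex mean", {
  expect_equal(
    unname(average_within_regions(matrix(c(1, 3), 1, 2), c("A", "A"))[1, 1]),
    2)
  v <- matrix(5, 4, 3)
  expect_equal(average_within_regions(v, rep("A", 3)),
               matrix(5, 4, 1, dimnames = list(NULL, "A")))
  set.seed(1)
  vv <- matrix(rnorm(6 * 10), 10, 6)
  map <- c("A", "B", "A", "B", "B", "A")
  got <- average_within_regions(vv, map, region_order = c("A", "B"))
  manual <- matrix(NA_real_, 10, 2, dimnames = list(NULL, c("A", "B")))
  for (t in 1:10) for (r in c("A", "B"))
    manual[t, r] <- mean(vv[t, map == r])
  expect_equal(got, manual)
  expect_error(average_within_regions(vv, c(map[-6], NA)), "unmapped")
  expect_error(average_within_regions(vv, map, region_order = c("A", "B", "C")),
               "no vertices")
})

test_that("linear detrending removes lines and preserves 0.1-Hz amplitude", {
  n <- 688  # 550.4 s at TR 0.8
  ramp <- cbind(3 * seq_len(n) + 7, rep(4, n))
  out <- detrend_linear(ramp)
  expect_lt(max(abs(out)), 1e-8 * max(abs(ramp)))
  tt <- (seq_len(n) - 1) * 0.8
  y <- sin(2 * pi * 0.1 * tt)
  yd <- detrend_linear(cbind(y, y))[, 1]
  fit <- lm(yd ~ sin(2 * pi * 0.1 * tt) + cos(2 * pi * 0.1 * tt))
  amp <- sqrt(sum(coef(fit)[2:3]^2))
  expect_lt(abs(amp - 1), 0.01)
  expect_error(detrend_linear(matrix(1, 2, 1)), "3 samples")
})

test_that("the activation band passes 0.1 Hz and rejects DC", {
  n <- 696; TR <- 0.8
  tt <- (seq_len(n) - 1) * TR
  y <- sin(2 * pi * 0.1 * tt)
  f <- bandpass(cbind(y), activation_band(), TR = TR)[, 1]
  fit <- lm(f ~ sin(2 * pi * 0.1 * tt) + cos(2 * pi * 0.1 * tt))
  amp <- sqrt(sum(coef(fit)[2:3]^2))
  expect_gt(amp, 0.9); expect_lt(amp, 1.1)
  for (band in list(activation_band(), fc_band())) {
    dc <- bandpass(cbind(rep(2, n)), band, TR = TR)[, 1]
    expect_lt(max(abs(dc[100:600])), 0.2)  # < 10% of the DC input
  }
  expect_error(bandpass_spec(0.08, 0.008), "low < high")
  expect_error(bandpass(cbind(y), bandpass_spec(0.05, 0.7), TR = TR),
               "Nyquist")
})

test_that("filtering and detrending are linear operators", {
  set.seed(4)
  n <- 400
  x <- matrix(rnorm(n), n, 1); y <- matrix(rnorm(n), n, 1)
  for (op in list(function(m) detrend_linear(m),
                  function(m) bandpass(m, activation_band(), TR = 0.8))) {
    lhs <- op(2.5 * x - 1.2 * y)
    rhs <- 2.5 * op(x) - 1.2 * op(y)
    expect_equal(lhs, rhs, tolerance = 1e-8)
  }
})

test_that("zero-phase filtering leaves a band-centred sinusoid unshifted", {
  n <- 696; TR <- 0.8
  tt <- (seq_len(n) - 1) * TR
  y <- sin(2 * pi * 0.1 * tt)
  f <- bandpass(cbind(y), activation_band(), TR = TR)[, 1]
  cc <- ccf(f, y, lag.max = 5, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("cycle averaging is the sample-wise segment mean", {
  d <- build_task_design("object_location")
  acq <- acquisition_params()
  b <- cycle_sample_bounds(d, acq)
  one <- sin(seq_len(225) / 9)
  vals <- matrix(0, acq$n_samples, 2)
  for (cyc in 1:3) vals[b[cyc, 1]:b[cyc, 2], ] <- cbind(one, 2 * one)
  run <- timeseries_run(vals, 0.8, c("A", "B"), design = d)
  avg <- average_cycles(run)
  expect_equal(nrow(avg$values), 225L)
  expect_equal(avg$values[, 1], one)
  expect_equal(avg$meta$n_cycles, 3L)
  # elementwise arithmetic: cycles valued 1 and 3 average to 2
  vals2 <- matrix(0, acq$n_samples, 1)
  vals2[b[1, 1]:b[1, 2], ] <- 1
  vals2[b[2, 1]:b[2, 2], ] <- 3
  vals2[b[3, 1]:b[3, 2], ] <- 2
  avg2 <- average_cycles(timeseries_run(vals2, 0.8, "A", design = d))
  expect_equal(avg2$values[, 1], rep(2, 225))
})

test_that("cycle averaging reduces independent noise variance about 3-fold", {
  d <- build_task_design("object_location")
  acq <- acquisition_params()
  set.seed(11)
  ratios <- replicate(40, {
    vals <- matrix(rnorm(acq$n_samples), acq$n_samples, 1)
    avg <- average_cycles(timeseries_run(vals, 0.8, "A", design = d))
    var(vals) / var(avg$values)
  })
  expect_lt(abs(mean(ratios) - 3) / 3, 0.2)
})
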