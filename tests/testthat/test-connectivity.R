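test_that("FC matches the direct correlation formula and its contracts", {
  set.seed(3)
  x <- matrix(rnorm(50 * 3), 50, 3, dimnames = list(NULL, c("a", "b", "c")))
  fc <- functional_connectivity(x, band = NULL)
  # brute-force covariance / (sd * sd)
  for (i in 1:3) for (j in 1:3) {
    num <- mean((x[, i] - mean(x[, i])) * (x[, j] - mean(x[, j])))
    den <- sqrt(mean((x[, i] - mean(x[, i]))^2) *
                  mean((x[, j] - mean(x[, j]))^2))
    expect_equal(fc$values[i, j], num / den, tolerance = 1e-10)
  }
  expect_equal(fc$values, t(fc$values))
  expect_equal(diag(fc$values), c(a = 1, b = 1, c = 1))
  dup <- cbind(x, d = x[, 1], e = -x[, 1])
  fcd <- functional_connectivity(dup, band = NULL)
  expect_equal(fcd$values["a", "d"], 1, tolerance = 1e-10)
  expect_equal(fcd$values["a", "e"], -1, tolerance = 1e-10)
  bad <- cbind(x, flat = rep(1, 50))
  expect_error(functional_connectivity(bad, band = NULL), "flat")
})

test_that("lagged FC equals the shifted-correlation loop", {
  set.seed(8)
  x <- matrix(rnorm(60 * 2), 60, 2, dimnames = list(NULL, c("a", "b")))
  lf <- lagged_fc(x, 4)
  for (i in 1:2) for (j in 1:2)
    expect_equal(lf$values[i, j], cor(x[1:56, i], x[5:60, j]),
                 tolerance = 1e-12)
  # zero shift through the general path reproduces plain FC
  expect_equal(lagged_fc(x, 0)$values,
               functional_connectivity(x, band = NULL)$values,
               tolerance = 1e-12)
  # exact lag-k copy correlates 1 at lag k
  y <- rnorm(60)
  z <- cbind(a = y, b = c(rep(0, 3), y[1:57]))
  expect_equal(lagged_fc(z, 3)$values["a", "b"], 1, tolerance = 1e-10)
  expect_error(lagged_fc(x, 60), "out of range")
})

test_that("Fisher-z averaging matches the closed form", {
  expect_equal(fisher_z_mean(list(matrix(0, 2, 2), matrix(0, 2, 2))),
               matrix(0, 2, 2))
  set.seed(9)
  m1 <- cor(matrix(rnorm(80), 20, 4))
  m2 <- cor(matrix(rnorm(80), 20, 4))
  got <- fisher_z_mean(list(m1, m2))
  manual <- tanh((atanh(m1) + atanh(m2)) / 2)
  off <- row(m1) != col(m1)
  expect_equal(got[off], manual[off], tolerance = 1e-12)
  expect_equal(diag(got), rep(1, 4))
})

test_that("directionality reversal is a transposing involution", {
  set.seed(10)
  ec <- list(values = matrix(runif(25, 0, 0.2), 5, 5), reversed = FALSE)
  ec$values[2, 4] <- 0.19
  r1 <- reverse_directionality(ec)
  expect_true(r1$reversed)
  expect_equal(r1$values[4, 2], 0.19)
  expect_equal(r1$values, t(ec$values))
  r2 <- reverse_directionality(r1)
  expect_identical(r2$values, ec$values)
  expect_false(r2$reversed)
  sym <- list(values = (ec$values + t(ec$values)) / 2, reversed = FALSE)
  rs <- reverse_directionality(sym)
  expect_equal(rs$values, sym$values)
  expect_true(rs$reversed)
})

test_that("directional difference is antisymmetric", {
  m <- matrix(0, 2, 2); m[1, 2] <- 0.1; m[2, 1] <- 0.04
  D <- directional_difference(m)
  expect_equal(D[1, 2], 0.06)
  expect_equal(D[2, 1], -0.06)
  set.seed(12)
  M <- matrix(runif(36, 0, 0.2), 6, 6)
  DD <- directional_difference(list(values = M))
  expect_equal(DD + t(DD), matrix(0, 6, 6))
})

test_that("group GEC of identical participants equals the single fit", {
  set.seed(13)
  x <- simulate_hopf(make_ground_truth_network(5, 0.4, seed = 2),
                     acq = acquisition_params(0.8, 300), seed = 3)
  colnames(x) <- letters[1:5]
  fc <- functional_connectivity(x, band = NULL)
  lf <- lagged_fc(x, 3)
  cfg <- gec_config(max_iter = 4, sim_length_samples = 300,
                    reverse_for_fmri = FALSE, seed = 21)
  single <- fit_gec(fc, lf, config = cfg)
  grp <- group_gec(list(fc, fc, fc), list(lf, lf, lf), config = cfg)
  expect_equal(coef(grp), coef(single), tolerance = 1e-12)
})

test_that("mismatched labels are rejected", {
  set.seed(14)
  x <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("a", "b", "z")))
  fcx <- functional_connectivity(x, band = NULL)
  lfy <- lagged_fc(y, 3)
  expect_error(fit_gec(fcx, lfy, config = gec_config(max_iter = 2)),
               "labels")
  fcy <- functional_connectivity(y, band = NULL)
  expect_error(group_gec(list(fcx, fcy), list(lagged_fc(x, 3), lfy)),
               "labels")
})
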