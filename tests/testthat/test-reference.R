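test_that("region reference values and self-consistency after referencing", {
  d <- c(8, 8, 8)
  vals <- array(0, d)
  m <- array(FALSE, d); m[2:4, 2:4, 2:4] <- TRUE
  vals[m] <- 0.05
  vol <- susceptibility_volume(vals)
  expect_equal(region_reference_value(vol, m), 0.05)
  m3 <- array(FALSE, d); m3[1:3, 1, 1] <- TRUE
  vals2 <- array(0, d); vals2[m3] <- c(1, 2, 100)
  expect_equal(region_reference_value(susceptibility_volume(vals2), m3,
                                      stat = "median"), 2)
  v3 <- array(rnorm(prod(d)), d)
  vol3 <- susceptibility_volume(v3)
  ref <- region_reference_value(vol3, m)
  shifted <- apply_reference(vol3, ref)
  expect_equal(region_reference_value(shifted, m), 0, tolerance = 1e-12)
  expect_error(region_reference_value(vol, array(FALSE, d)), "empty")
})

test_that("whole-brain referencing is a mean shift and ~none on inversions", {
  d <- c(8, 8, 8)
  brain <- array(TRUE, d)
  v <- array(rnorm(prod(d)), d)
  vol <- susceptibility_volume(v - mean(v), brain_mask = brain)
  expect_equal(whole_brain_reference(vol), 0, tolerance = 1e-14)
  volc <- susceptibility_volume(v - mean(v) + 0.3, brain_mask = brain)
  expect_equal(whole_brain_reference(volc), 0.3, tolerance = 1e-12)
  # direct inversions de-mean the lattice, so whole-brain referencing of a
  # reconstruction barely moves it
  fx <- fixture_recons()
  wb <- whole_brain_reference(fx$recons$tkd)
  expect_lt(abs(wb), 5e-3)
})

test_that("relative variance map matches hand-computed ratios", {
  d <- c(4, 4, 4)
  a <- array(2, d)
  expect_true(all(relative_variance_map(list(a, a, a))$values == 0))
  v1 <- array(1, d); v2 <- array(3, d)
  rv <- relative_variance_map(list(v1, v2))
  # sample variance (n-1) of {1,3} is 2, mean is 2 -> ratio 1
  expect_true(all(rv$values == 1))
  expect_equal(rv$n_inputs, 2L)
  expect_error(relative_variance_map(list(v1)), "at least 2")
  expect_error(relative_variance_map(list(v1, array(1, c(5, 4, 4)))),
               "lattice")
})

test_that("low-percentile mask follows the interpolated-percentile convention", {
  d <- c(10, 10, 10)
  ramp <- array(1:1000, d)          # in-brain |values| are 1..1000
  brain <- array(TRUE, d)
  m3 <- low_percentile_mask(ramp, brain, 3)
  # brute-force oracle: linear-interpolation 3rd percentile of 1..1000 is
  # 1 + 0.03 * 999 = 30.97, so voxels 1..30 survive
  expect_equal(sum(m3), 30)
  expect_true(all(ramp[m3] <= 30.97))
  expect_equal(sum(low_percentile_mask(ramp, brain, 100)), 1000)
  # monotone in the percentile
  prev <- low_percentile_mask(ramp, brain, 1)
  for (p in c(2, 5, 20, 60, 100)) {
    cur <- low_percentile_mask(ramp, brain, p)
    expect_true(all(cur[prev]))
    prev <- cur
  }
  # near-zero across-input mean gives a huge |ratio|: never selected
  vols <- list(array(c(-1, rep(1, 999)), d), array(c(1.001, rep(3, 999)), d))
  rv <- relative_variance_map(vols)
  expect_false(low_percentile_mask(rv, brain, 3)[1])
  expect_error(low_percentile_mask(ramp, array(FALSE, d), 3), "empty")
})

test_that("ARLO recovers mono-exponential decay and agrees with log-linear fit", {
  te <- seq(5, 40, by = 5)
  d <- c(5, 5, 5)
  set.seed(1)
  r2_true <- array(runif(prod(d), 2, 80), d)
  m0 <- array(runif(prod(d), 50, 150), d)
  es <- simulate_echoes(m0, r2_true, te, noise_sd = 0)
  arlo <- fit_r2s(es)
  # noiseless decay at 0.020 / ms is 20 Hz, recovered within 1 %
  es20 <- simulate_echoes(array(100, d), array(20, d), te)
  expect_equal(fit_r2s(es20)$values[1, 1, 1], 20, tolerance = 0.01)
  # constant signal -> 0 Hz
  esc <- simulate_echoes(array(100, d), array(0, d), te)
  expect_true(all(fit_r2s(esc)$values == 0))
  # dual-estimator cross-check on noiseless fixtures (within 2 %)
  loglin <- fit_r2s_loglin(es)
  expect_equal(arlo$values, loglin$values, tolerance = 0.02)
  expect_equal(arlo$values, r2_true, tolerance = 0.02)
  # scale invariance
  es_scaled <- echo_series(es$magnitudes * 3.7, te)
  expect_equal(fit_r2s(es_scaled)$values, arlo$values, tolerance = 1e-10)
  expect_error(echo_series(es$magnitudes[, , , 1:2, drop = FALSE], te[1:2]),
               "3 echoes")
  expect_error(echo_series(es$magnitudes, c(5, 10, 20, 25, 30, 35, 40, 50)),
               "equally spaced")
})

test_that("R2* threshold isolates the fluid compartment of the phantom", {
  fx <- fixture_echoes()
  brain <- fx$phantom$chi$brain_mask
  r2s <- fit_r2s(fx$echoes)
  m <- r2s_reference_mask(r2s, brain, 4)
  csf <- roi_mask(fx$phantom$labels, "csf")
  expect_identical(m, csf & brain)
  # everything >= 10 Hz under a 4 Hz threshold is an error
  hot <- array(10, dim(brain))
  expect_error(r2s_reference_mask(hot, brain, 4), "raise threshold")
  expect_error(r2s_reference_mask(r2s, brain, -4), "positive")
})

test_that("referencing is a pure scalar shift", {
  x <- rnorm(100)
  expect_identical(apply_reference(x, 0), x)
  expect_equal(var(apply_reference(x, 1.3)), var(x), tolerance = 1e-12)
  d <- c(8, 8, 8)
  vol <- susceptibility_volume(array(rnorm(prod(d)), d),
                               brain_mask = array(TRUE, d))
  refd <- apply_reference(vol, whole_brain_reference(vol))
  expect_equal(whole_brain_reference(refd), 0, tolerance = 1e-14)
  expect_error(apply_reference(x, NaN), "finite")
})
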