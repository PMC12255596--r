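test_that("phantom construction is piecewise-constant with the nine study ROIs", {
  fx <- fixture_phantom()
  ph <- fx$phantom
  expect_setequal(unname(ph$labels$legend),
                  c("csf", "corpus_callosum", "internal_capsule", "amygdala",
                    "caudate", "pallidum", "putamen", "thalamus",
                    "hippocampus"))
  # every ROI mean equals its specified chi exactly (piecewise constant)
  spec <- default_roi_spec()
  for (e in spec) {
    m <- roi_mask(ph$labels, e$name)
    expect_gt(sum(m), 0)
    expect_identical(unique(as.vector(ph$chi$values[m])), e$chi)
  }
  # zero phantom: chi identically 0, labels still populated
  spec0 <- lapply(spec, function(e) {e$chi <- 0; e})
  ph0 <- build_phantom(roi_spec = spec0)
  expect_true(all(ph0$chi$values == 0))
  expect_identical(sort(unique(as.vector(ph0$labels$labels))), 0:9)
})

test_that("overlapping or out-of-lattice geometries are rejected", {
  bad <- list(
    list(name = "a", type = "sphere", center = c(16, 16, 16), radius = 4,
         chi = 0.1, r2s = 20),
    list(name = "b", type = "sphere", center = c(18, 16, 16), radius = 4,
         chi = 0.2, r2s = 20))
  expect_error(build_phantom(c(32, 32, 32), bad), "overlaps")
  out <- list(list(name = "c", type = "sphere", center = c(2, 16, 16),
                   radius = 4, chi = 0.1, r2s = 20))
  expect_error(build_phantom(c(32, 32, 32), out), "outside")
})

test_that("dipole kernel attains its analytic values and bounds", {
  k <- dipole_kernel(c(16, 16, 16))
  D <- k$values
  expect_identical(D[1, 1, 1], 0)          # zero frequency
  expect_equal(D[1, 1, 2], -2 / 3)         # frequency purely along B0
  expect_equal(D[2, 1, 1], 1 / 3)          # orthogonal to B0
  expect_equal(D[1, 2, 1], 1 / 3)
  expect_true(all(D >= -2 / 3 - 1e-12 & D <= 1 / 3 + 1e-12))
  # configurable B0 axis
  k1 <- dipole_kernel(c(16, 16, 16), b0_axis = 1)
  expect_equal(k1$values[2, 1, 1], -2 / 3)
  expect_error(dipole_kernel(c(16, 16, 1)), "degenerate")
})

test_that("forward field annihilates DC, is linear, and has zero mean", {
  d <- c(16, 16, 16)
  k <- dipole_kernel(d)
  unif <- susceptibility_volume(array(0.3, d))
  f <- forward_field(unif, k)
  expect_lt(max(abs(f$values)), 1e-12)
  set.seed(42)
  a1 <- array(rnorm(prod(d)), d); a2 <- array(rnorm(prod(d)), d)
  f1 <- forward_field(susceptibility_volume(a1), k)$values
  f2 <- forward_field(susceptibility_volume(a2), k)$values
  f12 <- forward_field(susceptibility_volume(2 * a1 - 3 * a2), k)$values
  expect_equal(f12, 2 * f1 - 3 * f2, tolerance = 1e-10)
  expect_lt(abs(mean(f1)) / diff(range(f1)), 1e-10)
  expect_error(forward_field(unif, dipole_kernel(c(8, 8, 8))), "shapes")
})

test_that("forward field of a sphere matches the analytic dipole pattern", {
  d <- c(64, 64, 64); a <- 4; chi0 <- 0.1; ctr <- c(33, 33, 33)
  ix <- slice.index(array(0, d), 1); iy <- slice.index(array(0, d), 2)
  iz <- slice.index(array(0, d), 3)
  r2 <- (ix - ctr[1])^2 + (iy - ctr[2])^2 + (iz - ctr[3])^2
  chi <- array(0, d); chi[r2 <= a^2] <- chi0
  f <- forward_field(susceptibility_volume(chi), dipole_kernel(d))
  # closed-form external dipole field with the voxelized effective radius
  aeff <- (3 * sum(r2 <= a^2) / (4 * pi))^(1 / 3)
  r <- sqrt(r2); cosq <- (iz - ctr[3])^2 / pmax(r2, 1)
  analytic <- chi0 * aeff^3 * (3 * cosq - 1) / (3 * pmax(r, 1)^3)
  sel <- r >= 2 * a & r <= 16
  expect_gt(cor(f$values[sel], analytic[sel]), 0.999)
  expect_lt(max(abs(f$values[sel] - analytic[sel])),
            0.1 * max(abs(analytic[sel])))
})

test_that("dipole inversions recover the demeaned phantom", {
  fx <- fixture_recons()
  gt <- fx$phantom$chi$values
  gt_dm <- gt - mean(gt)
  expect_gt(cor(as.vector(fx$recons$tkd$values), as.vector(gt_dm)), 0.9)
  # ROI means are biased method-specifically but correlated with truth
  expect_gt(cor(as.vector(fx$recons$tikhonov$values), as.vector(gt_dm)), 0.85)
  # zero field -> zero map; strong regularization -> map shrinks to 0
  zf <- field_volume(array(0, c(8, 8, 8)))
  k8 <- dipole_kernel(c(8, 8, 8))
  expect_true(all(reconstruct(zf, k8, "tkd")$values == 0))
  expect_true(all(reconstruct(zf, k8, "tikhonov")$values == 0))
  big <- reconstruct(fx$field, fx$kernel, "tikhonov", lambda = 1e6)
  expect_lt(max(abs(big$values)), 1e-4)
  expect_error(reconstruct(fx$field, fx$kernel, "tkd", delta = 0),
               "undefined")
  expect_error(reconstruct(fx$field, fx$kernel, "tikhonov", lambda = 0),
               "undefined")
})

test_that("reconstruct-of-forward is invariant to a constant offset (DC ambiguity)", {
  fx <- fixture_recons()
  chi_shift <- susceptibility_volume(fx$phantom$chi$values + 0.7,
                                     brain_mask = fx$phantom$chi$brain_mask)
  f2 <- forward_field(chi_shift, fx$kernel)
  for (method in c("tkd", "tikhonov")) {
    r2 <- reconstruct(f2, fx$kernel, method)
    r1 <- if (method == "tkd") fx$recons$tkd else fx$recons$tikhonov
    expect_equal(r2$values, r1$values, tolerance = 1e-10)
  }
})

test_that("echo simulation follows the decay model and is seed-reproducible", {
  d <- c(4, 4, 4)
  m0 <- array(runif(prod(d), 50, 150), d)
  te0 <- c(0, 5, 10, 15)
  es <- simulate_echoes(m0, array(30, d), te0, noise_sd = 0)
  expect_equal(es$magnitudes[, , , 1], m0)          # TE = 0 echo is m0
  es0 <- simulate_echoes(m0, array(0, d), te0, noise_sd = 0)
  for (e in 1:4) expect_equal(es0$magnitudes[, , , e], m0)  # R2* = 0
  a <- simulate_echoes(m0, array(20, d), te0, noise_sd = 5, seed = 7)
  b <- simulate_echoes(m0, array(20, d), te0, noise_sd = 5, seed = 7)
  expect_identical(a$magnitudes, b$magnitudes)
  expect_true(all(a$magnitudes >= 0))
  expect_error(simulate_echoes(m0, array(20, d), te0, noise_sd = -1),
               "nonnegative")
  expect_error(simulate_echoes(m0, array(-1, d), te0), "nonnegative")
})
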