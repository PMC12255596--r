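# Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

fixture_phantom <- function() {
  if (is.null(.fixtures$phantom)) {
    .fixtures$phantom <- build_phantom()
    .fixtures$kernel <- dipole_kernel(dim(.fixtures$phantom$chi$values))
  }
  list(phantom = .fixtures$phantom, kernel = .fixtures$kernel)
}

# forward-simulate the phantom and invert with both emulators
fixture_recons <- function() {
  if (is.null(.fixtures$recons)) {
    fx <- fixture_phantom()
    fld <- forward_field(fx$phantom$chi, fx$kernel)
    brain <- fx$phantom$chi$brain_mask
    .fixtures$field <- fld
    .fixtures$recons <- list(
      tkd = reconstruct(fld, fx$kernel, "tkd", delta = 0.2,
                        brain_mask = brain),
      tikhonov = reconstruct(fld, fx$kernel, "tikhonov", lambda = 0.05,
                             brain_mask = brain))
  }
  list(phantom = .fixtures$phantom, kernel = .fixtures$kernel,
       field = .fixtures$field, recons = .fixtures$recons)
}

# noiseless multi-echo series over the phantom relaxation map
fixture_echoes <- function() {
  if (is.null(.fixtures$echoes)) {
    fx <- fixture_phantom()
    brain <- fx$phantom$chi$brain_mask
    r2s <- phantom_r2s(fx$phantom$labels, default_roi_spec(), brain)
    m0 <- array(0, dim(brain)); m0[brain] <- 100
    .fixtures$r2s_true <- r2s
    .fixtures$echoes <- simulate_echoes(m0, r2s, seq(5, 40, by = 5))
  }
  list(phantom = .fixtures$phantom, r2s_true = .fixtures$r2s_true,
       echoes = .fixtures$echoes)
}

# small two-ROI null design used by the statistical calibration tests
null_design <- function(rois = c("thalamus", "csf"), reference_roi = "csf",
                        ...) {
  mu <- matrix(0, 3, length(rois),
               dimnames = list(c("HC", "LTLE", "RTLE"), rois))
  cohort_design(roi_means = mu, reference_roi = reference_roi,
                reference_rois = reference_roi, ...)
}
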