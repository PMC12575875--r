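test_that("MAD rule keeps inliers and drops gross outliers", {
  set.seed(1)
  x <- c(rnorm(12, 100, 0.5), 150)
  keep <- reject_outliers_mad(x, 3)
  expect_false(keep[13])
  expect_true(all(keep[1:12]))
})

test_that("defocus round trip recovers the simulated C1", {
  px <- 0.26
  sys <- optical_system(300, c1_nm = -2000, c3_mm = 2.7, focal_spread_nm = 8.5,
                        illum_semiangle_mrad = 0.02)
  ph <- make_phantom("ice", c(512, 512), px,
                     list(k_lo = 0.1, k_hi = 1.8, rms_phase = 0.2), seed = 11)
  img <- image_from_exit_wave(multislice_exit_wave(ph, beam_tilt(sys, 0), sys),
                              sys, px)
  grid_step <- 25
  est <- estimate_defocus(img, sys, seq(-2400, -1600, by = grid_step), px,
                          patches = c(4, 4))
  expect_lt(abs(est$c1 - (-2000)), grid_step)
  expect_gte(est$se, 0)
  expect_gte(est$n_used, 2)
  expect_false(est$sign_ambiguous)    # C3 = 2.7 mm breaks the C1 sign symmetry
  expect_false(est$low_confidence)
})

test_that("whole-image defocus fit is accurate on a noiseless micrograph", {
  px <- 0.26
  sys <- optical_system(300, c1_nm = -2000, c3_mm = 2.7, focal_spread_nm = 8.5,
                        illum_semiangle_mrad = 0.02)
  ph <- make_phantom("ice", c(512, 512), px,
                     list(k_lo = 0.1, k_hi = 1.8, rms_phase = 0.2), seed = 21)
  img <- image_from_exit_wave(multislice_exit_wave(ph, beam_tilt(sys, 0), sys),
                              sys, px)
  est <- estimate_defocus(img, sys, seq(-2400, -1600, by = 25), px, patches = NULL)
  expect_lt(abs(est$c1 - (-2000)), 25)
})

test_that("pure-defocus spectra are flagged sign-ambiguous", {
  px <- 0.26
  sys <- optical_system(300, c1_nm = -500, c3_mm = 0, focal_spread_nm = 5)
  ph <- make_phantom("ice", c(256, 256), px,
                     list(k_lo = 0.1, k_hi = 1.8, rms_phase = 0.2), seed = 2)
  img <- image_from_exit_wave(multislice_exit_wave(ph, beam_tilt(sys, 0), sys),
                              sys, px)
  est <- estimate_defocus(img, sys, seq(-700, -300, by = 25), px, patches = NULL)
  expect_true(est$sign_ambiguous)
})

test_that("a corrupted patch is excluded by the 3xMAD rule", {
  px <- 0.26
  sys <- optical_system(300, c1_nm = -2000, c3_mm = 2.7, focal_spread_nm = 8.5,
                        illum_semiangle_mrad = 0.02)
  ph <- make_phantom("ice", c(512, 512), px,
                     list(k_lo = 0.1, k_hi = 1.8, rms_phase = 0.2), seed = 11)
  img <- image_from_exit_wave(multislice_exit_wave(ph, beam_tilt(sys, 0), sys),
                              sys, px)
  # corrupt one patch with a strong CTF imprint at a very different defocus
  sys_bad <- optical_system(300, c1_nm = -1000, c3_mm = 2.7, focal_spread_nm = 8.5,
                            illum_semiangle_mrad = 0.02)
  ph_bad <- make_phantom("ice", c(128, 128), px,
                         list(k_lo = 0.1, k_hi = 1.8, rms_phase = 0.2), seed = 99)
  img[1:128, 1:128] <- image_from_exit_wave(
    multislice_exit_wave(ph_bad, beam_tilt(sys_bad, 0), sys_bad), sys_bad, px)
  est <- estimate_defocus(img, sys, seq(-2400, -1600, by = 25), px, patches = c(4, 4))
  expect_lt(est$n_used, length(est$estimates))
  expect_lt(abs(est$c1 - (-2000)), 25)
})

test_that("phase correlation is exact for integer circular shifts", {
  a <- make_phantom("ice", c(128, 128), 0.1, list(rms_phase = 0.3), seed = 5)$phase[[1]]
  expect_equal(register_images(list(a, a))[2, ], c(0, 0))
  b <- a[c(122:128, 1:121), c(4:128, 1:3)]   # roll by (+7, -3)
  expect_equal(register_images(list(a, b))[2, ], c(7, -3))
  # inverse consistency
  expect_equal(register_images(list(b, a))[2, ], c(-7, 3))
  expect_error(register_images(list(a, matrix(1, 128, 128))), "variance")
})

test_that("subpixel shifts are recovered within a tenth of a pixel", {
  a <- make_phantom("ice", c(128, 128), 0.1, list(rms_phase = 0.3), seed = 5)$phase[[1]]
  for (s in list(c(0.3, 0), c(-0.25, 0.4), c(0.3, -0.3))) {
    got <- register_images(list(a, fourier_shift(a, s)))[2, ]
    expect_lt(max(abs(got - s)), 0.10)
  }
})

test_that("tilt-shift compensation removes the aberration-induced displacement", {
  px <- 0.1
  sys <- optical_system(300, c1_nm = -2000, c3_mm = 2.7)
  base <- make_phantom("ice", c(128, 128), px, list(rms_phase = 0.3), seed = 5)$phase[[1]]
  tilts <- list(beam_tilt(sys, 0), beam_tilt(sys, 0.0019, 0),
                beam_tilt(sys, 0.0019, pi / 2))
  # forward-displace each image by exactly the predicted aberration shift
  stack <- lapply(tilts, function(tl) {
    fourier_shift(base, tilt_induced_shift(sys, tl) / px)
  })
  shifts <- register_images(stack)
  out <- compensate_tilt_shift(stack, shifts, sys, tilts, px)
  resid <- register_images(c(list(base), out$stack))
  expect_lt(max(abs(resid[-1, ])), 0.5)
  # report bookkeeping: applied drift = measured - predicted
  expect_equal(out$report$applied_shift,
               out$report$measured_shift - out$report$predicted_shift)
})

test_that("zero tilts and zero drift leave the stack unchanged", {
  px <- 0.1
  sys <- optical_system(300, c1_nm = -2000, c3_mm = 2.7)
  base <- make_phantom("ice", c(64, 64), px, list(rms_phase = 0.3), seed = 5)$phase[[1]]
  tilts <- list(beam_tilt(sys, 0), beam_tilt(sys, 0))
  out <- compensate_tilt_shift(list(base, base), matrix(0, 2, 2), sys, tilts, px)
  expect_equal(out$stack[[2]], base, tolerance = 1e-10)
})

test_that("effective defocus converts to axial by removing 2 C3 tau^2", {
  sys <- optical_system(300, c1_nm = -2000, c3_mm = 2.7)
  tau <- 0.0019
  c1_eff <- -2000 + 2 * sys$c3 * tau^2
  expect_equal(axial_from_effective_defocus(c1_eff, sys, tau), -2000)
})
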