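test_that("phantom generation is deterministic and kind-correct", {
  p1 <- make_phantom("ice", c(64, 64), 0.1, list(rms_phase = 0.05), seed = 3)
  p2 <- make_phantom("ice", c(64, 64), 0.1, list(rms_phase = 0.05), seed = 3)
  expect_identical(p1$phase, p2$phase)
  # ice is a pure phase object
  expect_true(all(p1$amplitude[[1]] == 1))
  expect_lt(abs(mean(p1$phase[[1]])), 1e-10)
  expect_error(make_phantom("ice", c(32, 32), 0.1), "at least 64")
  expect_warning(make_phantom("ice", c(64, 64), 0.1, list(rms_phase = 2), seed = 1),
                 "pi/2")
})

test_that("lattice phantom has spectral peaks at the lattice frequency", {
  d <- 0.235
  p <- make_phantom("lattice", c(256, 256), 0.04, list(spacing = d, peak_phase = 0.05))
  g <- frequency_grid(c(256, 256), 0.04)
  pow <- Mod(fft2(p$phase[[1]] - mean(p$phase[[1]])))^2
  ring <- g$kr > 0.5 / d & g$kr < 1.5 / d
  peak_k <- g$kr[ring][which.max(pow[ring])]
  expect_equal(peak_k, 1 / d, tolerance = 0.05)
})

test_that("multislice exit wave reduces to the thin-object product", {
  sys <- roundtrip_system()
  ph <- roundtrip_phantom(64)
  tl <- beam_tilt(sys, 0.008, 1.2)
  psi <- multislice_exit_wave(ph, tl, sys)
  x <- (seq_len(64) - 1) * ph$pixel_size
  plane <- exp(2i * pi * (outer(tl$k_tau[1] * x, rep(1, 64)) +
                          outer(rep(1, 64), tl$k_tau[2] * x)))
  expect_equal(psi, phantom_transmission(ph) * plane, tolerance = 1e-14)
})

test_that("empty phantom passes the tilted plane wave through unchanged", {
  sys <- roundtrip_system()
  ph <- make_phantom("ice", c(64, 64), 0.1, list(rms_phase = 0.05), seed = 1)
  ph$phase[[1]][] <- 0
  psi <- multislice_exit_wave(ph, beam_tilt(sys, 0.01, 0.5), sys)
  expect_equal(Mod(psi), matrix(1, 64, 64), tolerance = 1e-12)
})

test_that("phase-only multislice conserves intensity through propagation", {
  sys <- roundtrip_system()
  ph <- make_phantom("ice", c(64, 64), 0.1, list(rms_phase = 0.2), seed = 9,
                     n_slices = 5, slice_thickness = 2)
  psi <- multislice_exit_wave(ph, beam_tilt(sys, 0.005, 0), sys)
  expect_lt(abs(sum(Mod(psi)^2) - 64 * 64) / (64 * 64), 1e-10)
})

test_that("identity transfer returns the exit-wave intensity", {
  sys <- optical_system(300)    # no aberrations, no envelopes: w = 1
  ph <- roundtrip_phantom(64)
  psi <- multislice_exit_wave(ph, beam_tilt(sys, 0), sys)
  expect_equal(image_from_exit_wave(psi, sys, ph$pixel_size), Mod(psi)^2,
               tolerance = 1e-12)
})

test_that("weak-phase image contrast follows 2 sin(chi) times the phase spectrum", {
  sys <- optical_system(300, c1_nm = -50)   # no envelopes
  ph <- make_phantom("ice", c(128, 128), 0.05,
                     list(k_lo = 0.5, k_hi = 4, rms_phase = 0.002), seed = 5)
  psi <- multislice_exit_wave(ph, beam_tilt(sys, 0), sys)
  img <- image_from_exit_wave(psi, sys, ph$pixel_size)
  g <- frequency_grid(c(128, 128), 0.05)
  chi <- aberration_phase(sys, g$kx, g$ky)
  pred <- 2 * sin(chi) * fft2(ph$phase[[1]])
  got <- fft2(img - mean(img))
  band <- g$kr > 0.5 & g$kr < 4
  rel <- sqrt(sum(Mod(got - pred)[band]^2) / sum(Mod(pred)[band]^2))
  expect_lt(rel, 0.01)
})

test_that("tilted illumination puts the unscattered peak at k_tau", {
  sys <- roundtrip_system()
  ph <- roundtrip_phantom(128)
  tl <- efptycho:::snap_tilt_to_grid(beam_tilt(sys, 0.010, 0), sys,
                                     c(128L, 128L), ph$pixel_size)
  psi <- multislice_exit_wave(ph, tl, sys)
  spec <- Mod(fft2(psi))
  peak <- which(spec == max(spec), arr.ind = TRUE)
  g <- frequency_grid(c(128, 128), ph$pixel_size)
  expect_equal(c(g$kx[peak], g$ky[peak]), tl$k_tau, tolerance = 1e-9)
})

test_that("detector returns the exact scaled image in the infinite-fluence mode", {
  img <- matrix(runif(64 * 64, 0.5, 1.5), 64, 64)
  img <- img / mean(img)
  det <- detector_model(mtf_sigma = Inf)
  out <- apply_detector(img, 100, 0.1, det, noise = FALSE)
  expect_equal(out, 100 * 0.01 * img, tolerance = 1e-12)
  expect_error(apply_detector(img - 2, 100, 0.1, det), "negative")
})

test_that("unit-sum MTF kernel leaves the expected total count unchanged", {
  img <- matrix(runif(64 * 64, 0.5, 1.5), 64, 64)
  det <- detector_model(mtf_sigma = 0.35)
  out <- apply_detector(img, 200, 0.1, det, noise = FALSE)
  expect_equal(sum(out), sum(200 * 0.01 * img), tolerance = 1e-9)
})

test_that("Poisson draws have the right mean", {
  det <- detector_model(mtf_sigma = Inf)
  img <- matrix(1, 100, 100)
  out <- apply_detector(img, 500, 0.1, det, noise = TRUE, seed = 42)
  lambda <- 500 * 0.01
  se <- sqrt(lambda / length(img))
  expect_lt(abs(mean(out) - lambda), 3 * se)
})

test_that("tilt-series protocols produce the documented geometries", {
  sys <- roundtrip_system()
  ph <- roundtrip_phantom(64)
  det <- detector_model(mtf_sigma = Inf)
  # robust-sample protocol: one axial + six tilts, azimuths 60 deg apart
  s7 <- simulate_tilt_series(ph, tilt_protocol(0.010, 6, TRUE), sys, det,
                             700, seed = 1, noise = FALSE)
  expect_length(s7$images, 7)
  mags <- vapply(s7$tilts, function(t) t$magnitude, numeric(1))
  expect_equal(mags[1], 0)
  az <- vapply(s7$tilts[-1], function(t) t$azimuth, numeric(1))
  expect_equal(sort(diff(sort(az))), rep(pi / 3, 5), tolerance = 0.05)
  # low-fluence protocol: four tilts, no axial image
  s4 <- simulate_tilt_series(ph, tilt_protocol(0.005, 4, FALSE), sys, det,
                             400, seed = 1, noise = FALSE)
  expect_length(s4$images, 4)
  expect_true(all(vapply(s4$tilts, function(t) t$magnitude, numeric(1)) > 0))
  # fluence budget split equally
  expect_equal(s7$fluence_per_image * 7, 700)
  expect_equal(s4$fluence_per_image * 4, 400)
})

test_that("identical seeds give bit-identical series", {
  sys <- roundtrip_system()
  ph <- roundtrip_phantom(64)
  det <- detector_model()
  a <- simulate_tilt_series(ph, tilt_protocol(0.01, 3, TRUE), sys, det, 1e4, seed = 5)
  b <- simulate_tilt_series(ph, tilt_protocol(0.01, 3, TRUE), sys, det, 1e4, seed = 5)
  expect_identical(a$images, b$images)
})
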