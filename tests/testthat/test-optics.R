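test_that("electron wavelength matches the relativistic closed form", {
  # hc / sqrt(E (E + 2 m0 c^2)) with E in keV, evaluated independently
  lam <- function(kv) 1.23984193 / sqrt(kv * (kv + 2 * 510.99895))
  expect_equal(electron_wavelength(300), lam(300), tolerance = 1e-12)
  expect_equal(electron_wavelength(300), 1.9687e-3, tolerance = 1e-4)
  expect_equal(electron_wavelength(100), 3.7014e-3, tolerance = 1e-4)
  expect_error(electron_wavelength(0), "positive")
  expect_error(electron_wavelength(-10), "positive")
})

test_that("optical system validates inputs and keeps wavelength consistent", {
  sys <- optical_system(300, c1_nm = -2000, c3_mm = 2.7, focal_spread_nm = 8.5,
                        illum_semiangle_mrad = 0.02)
  expect_equal(sys$wavelength, electron_wavelength(300))
  expect_equal(sys$c3, 2.7e6)              # mm converted to nm
  expect_equal(sys$illum_semiangle, 2e-5)  # mrad converted to rad
  expect_error(optical_system(300, focal_spread_nm = -1), ">= 0")
  expect_error(optical_system(300, transfer_threshold = 0), "\\(0, 1\\]")
  expect_error(optical_system(-300), "positive")
})

test_that("beam tilt wavevector has magnitude tau/lambda", {
  sys <- optical_system(300)
  for (tau in c(0, 0.0019, 0.005, 0.0123, 0.015)) {
    for (az in c(0, 1.1, pi, 5.0)) {
      tl <- beam_tilt(sys, tau, az)
      expect_equal(sqrt(sum(tl$k_tau^2)), tau / sys$wavelength, tolerance = 1e-12)
    }
  }
  expect_error(beam_tilt(sys, -0.001), ">= 0")
})

test_that("aberration phase follows the C1/C3 Saxton form", {
  sys0 <- optical_system(300)
  expect_equal(aberration_phase(sys0, 3, 4), 0)
  sys <- optical_system(300, c1_nm = 2.5)
  expect_equal(aberration_phase(sys, 5, 0), 0.3866, tolerance = 1e-3)
  # overfocus-positive convention: positive C1 gives positive phase
  expect_gt(aberration_phase(sys, 1, 0), 0)
  # C3 term scales as |k|^4
  sysc3 <- optical_system(300, c3_mm = 1)
  expect_equal(aberration_phase(sysc3, 2, 0) / aberration_phase(sysc3, 1, 0), 16,
               tolerance = 1e-10)
})

test_that("effective WTF reduces to the axial WTF at zero tilt", {
  sys <- optical_system(300, c1_nm = -50, c3_mm = 0.5, focal_spread_nm = 4.3,
                        illum_semiangle_mrad = 0.02, aperture_kmax_invnm = 6)
  g <- frequency_grid(c(64, 64), 0.1)
  expect_equal(effective_wtf(g, sys, beam_tilt(sys, 0)), axial_wtf(g, sys),
               tolerance = 1e-14)
})

test_that("effective WTF is unit-bounded and peaks on the achromatic circle", {
  sys <- optical_system(300, c1_nm = -100, c3_mm = 1, focal_spread_nm = 6,
                        illum_semiangle_mrad = 0.02)
  g <- frequency_grid(c(128, 128), 0.05)
  tl <- beam_tilt(sys, 0.010, 0.7)
  w <- effective_wtf(g, sys, tl)
  expect_lte(max(Mod(w)), 1 + 1e-12)
  # the temporal envelope alone attains 1 where |q + k_tau| = |k_tau|
  sys_t <- optical_system(300, focal_spread_nm = 6)   # chi = 0, beta = 0
  wt <- effective_wtf(g, sys_t, beam_tilt(sys_t, 0.010, 0.7))
  kt <- beam_tilt(sys_t, 0.010, 0.7)$k_tau
  on_circle <- abs(sqrt((g$kx + kt[1])^2 + (g$ky + kt[2])^2) - sqrt(sum(kt^2))) < 0.05
  expect_gt(min(Mod(wt)[on_circle]), 0.999)
})

test_that("central transfer loss matches the envelope at the passband centre", {
  # oracle: 1 - |effective_wtf| at the grid point nearest q = -k_tau, with
  # aperture absent and the spatial envelope disabled (beta = 0)
  sys <- optical_system(300, c1_nm = -300, focal_spread_nm = 4.3)
  g <- frequency_grid(c(128, 128), 0.05)
  dk <- 1 / (128 * 0.05)
  # choose a tilt whose wavevector lies exactly on the grid
  ktau <- 32 * dk
  tau <- ktau * sys$wavelength
  w <- effective_wtf(g, sys, beam_tilt(sys, tau, 0))
  at_centre <- 1 - Mod(w)[128 - 32 + 1, 1]    # q = (-ktau, 0) in FFT layout
  expect_equal(central_transfer_loss(sys, tau), at_centre, tolerance = 1e-10)
})

test_that("central transfer loss is monotone in tilt and zero without focal spread", {
  sys <- optical_system(300, focal_spread_nm = 4.3)
  taus <- seq(0, 0.02, by = 0.002)
  losses <- vapply(taus, central_transfer_loss, numeric(1), system = sys)
  expect_true(all(diff(losses) > 0))
  expect_equal(losses[1], 0)
  sys0 <- optical_system(300, focal_spread_nm = 0)
  expect_equal(central_transfer_loss(sys0, 0.015), 0)
})

test_that("optimal coupling tilt and its preconditions", {
  expect_equal(optimal_tilt(-2000, 2.7) * 1e3, 27.2, tolerance = 1e-2)
  expect_equal(optimal_tilt(0, 2.7), 0)
  expect_error(optimal_tilt(2000, 2.7), "opposite signs")
  expect_error(optimal_tilt(-2000, 0), "nonzero")
})

test_that("tilt-induced defocus change follows 2 C3 tau^2", {
  sys <- optical_system(300, c1_nm = -2000, c3_mm = 2.7)
  off <- tilt_defocus_offset(sys, 0.005)
  expect_equal(off$delta_c1, 135)
  expect_equal(off$relative, 0.0675, tolerance = 1e-10)
  expect_equal(tilt_defocus_offset(sys, 0)$delta_c1, 0)
  sys_g <- optical_system(300, c1_nm = 11.5, c3_mm = 0.0015)
  expect_equal(tilt_defocus_offset(sys_g, 0.0123)$delta_c1, 0.454, tolerance = 1e-3)
})

test_that("tilt-induced shift equals the aberration-phase gradient at k_tau", {
  sys <- optical_system(300, c1_nm = -2000, c3_mm = 2.7)
  tl <- beam_tilt(sys, 0.0019, 0)
  s <- tilt_induced_shift(sys, tl)
  expect_equal(sqrt(sum(s^2)), 3.7815, tolerance = 1e-4)
  # numerical gradient of chi at k_tau, central differences
  h <- 1e-5
  kt <- tl$k_tau
  gx <- (aberration_phase(sys, kt[1] + h, kt[2]) -
         aberration_phase(sys, kt[1] - h, kt[2])) / (2 * h)
  gy <- (aberration_phase(sys, kt[1], kt[2] + h) -
         aberration_phase(sys, kt[1], kt[2] - h)) / (2 * h)
  num <- sqrt(gx^2 + gy^2) / (2 * pi)
  expect_lt(abs(sqrt(sum(s^2)) - num) / num, 1e-6)
  # gold parameters, and the zero-tilt case
  sys_g <- optical_system(300, c1_nm = 11.5, c3_mm = 0.0015)
  expect_equal(sqrt(sum(tilt_induced_shift(sys_g, beam_tilt(sys_g, 0.0123, 1))^2)),
               0.1442, tolerance = 1e-3)
  expect_equal(tilt_induced_shift(sys, beam_tilt(sys, 0)), c(0, 0))
})

test_that("frequency grid spans Nyquist with step 1/extent", {
  g <- frequency_grid(c(64, 96), 0.2)
  expect_equal(max(g$kx), 1 / (2 * 0.2) - 1 / (64 * 0.2))
  expect_equal(min(g$kx), -1 / (2 * 0.2))
  expect_equal(sort(unique(as.vector(g$ky)))[2] - sort(unique(as.vector(g$ky)))[1],
               1 / (96 * 0.2), tolerance = 1e-12)
  expect_equal(g$kx[1, 1], 0)
  expect_equal(g$ky[1, 1], 0)
})
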