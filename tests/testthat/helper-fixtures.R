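# Shared fixtures for the test suite. Everything is generated in code, with
# fixed seeds; expensive objects are memoized per session.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Benign mid-defocus system used for round-trip reconstructions: modest
# underfocus, mild focal spread, tiny source size (Table-like values scaled
# to a 12.8 nm field of view at 0.05 nm pixels).
roundtrip_system <- function() {
  optical_system(300, c1_nm = -20, c3_mm = 0, focal_spread_nm = 2,
                 illum_semiangle_mrad = 0.02)
}

# Strictly band-limited pure-phase phantom (ice kind) so the thin-object
# spectrum stays inside every shifted passband.
roundtrip_phantom <- function(n = 128L) {
  make_phantom("ice", c(n, n), 0.05,
               list(k_lo = 0.3, k_hi = 4.5, rms_phase = 0.05), seed = 7)
}

roundtrip_series <- function(n = 128L) {
  memo(paste0("series_", n), {
    simulate_tilt_series(roundtrip_phantom(n), tilt_protocol(0.010, 6, TRUE),
                         roundtrip_system(), detector_model(mtf_sigma = Inf),
                         total_fluence = 7e5, seed = 1, noise = FALSE)
  })
}

# Cryo-like system of the low-fluence protocol (strong underfocus, large
# focal spread), with the defocus scaled to stay well sampled on the
# reduced test grids.
cryo_system <- function(c1 = -50) {
  optical_system(300, c1_nm = c1, c3_mm = 0, focal_spread_nm = 8.5,
                 illum_semiangle_mrad = 0.02)
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
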