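# File formats and pipeline plumbing: a minimal MRC (mode 2) stack
# reader/writer, JSON sidecar metadata, YAML run configuration, and the
# simulate -> preprocess -> reconstruct -> analyze pipeline.

#' Write an image stack as an MRC file (mode 2)
#'
#' Minimal MRC2014 writer: 32-bit IEEE float voxels, little-endian, one
#' section per image, pixel size recorded in the cell dimensions.
#'
#' @param stack A matrix or a list of matrices of identical shape.
#' @param path Output path.
#' @param pixel_size Pixel size in nm (stored in Angstrom in the header).
#' @return `path`, invisibly.
#' @export
write_mrc <- function(stack, path, pixel_size) {
  if (is.matrix(stack)) stack <- list(stack)
  d <- dim(stack[[1]])
  nz <- length(stack)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  all_v <- unlist(lapply(stack, as.vector))
  wi(c(d[1], d[2], nz))            # nx ny nz (rows as fast axis)
  wi(2L)                           # mode 2: float32
  wi(c(0L, 0L, 0L))                # nxstart nystart nzstart
  wi(c(d[1], d[2], nz))            # mx my mz
  wf(c(d[1], d[2], max(nz, 1)) * pixel_size * 10)  # cella, Angstrom
  wf(c(90, 90, 90))                # cellb
  wi(c(1L, 2L, 3L))                # mapc mapr maps
  wf(c(min(all_v), max(all_v), mean(all_v)))       # dmin dmax dmean
  wi(c(0L, 0L))                    # ispg nsymbt
  wi(rep(0L, 25L))                 # extra
  wf(c(0, 0, 0))                   # origin
  writeChar("MAP ", con, nchars = 4L, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wf(stats::sd(all_v))             # rms
  wi(0L)                           # nlabl
  writeBin(raw(800L), con)         # empty labels
  for (img in stack) wf(as.vector(img))
  invisible(path)
}

#' Read an MRC file written in mode 2
#'
#' @param path Path to an MRC file.
#' @return List with `stack` (list of matrices), `pixel_size` (nm).
#' @export
read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n, size = 4L, endian = "little")
  rf <- function(n) readBin(con, "numeric", n, size = 4L, endian = "little")
  nxyz <- ri(3L)
  mode <- ri(1L)
  if (mode != 2L) stop("only MRC mode 2 (float32) is supported", call. = FALSE)
  ri(3L)                           # nxstart..
  ri(3L)                           # mx my mz
  cella <- rf(3L)
  if (any(cella[1:2] <= 0)) stop("negative or zero pixel size in MRC header", call. = FALSE)
  seek(con, 1024L)
  px <- cella[1] / nxyz[1] / 10    # Angstrom -> nm
  stack <- vector("list", nxyz[3])
  for (s in seq_len(nxyz[3])) {
    stack[[s]] <- matrix(rf(nxyz[1] * nxyz[2]), nxyz[1], nxyz[2])
  }
  list(stack = stack, pixel_size = px)
}

optics_to_config <- function(system) {
  list(voltage_kv = system$voltage_kv, c1_nm = system$c1,
       c3_mm = system$c3 / 1e6, focal_spread_nm = system$focal_spread,
       illum_semiangle_mrad = system$illum_semiangle * 1e3,
       aperture_kmax_invnm = system$aperture_kmax,
       transfer_threshold = system$transfer_threshold)
}

#' Build an optical system from an `optics` config block
#'
#' Accepts the keys `voltage_kv`, `c1_nm`, `c3_mm`, `focal_spread_nm`,
#' `illum_semiangle_mrad`, `aperture_kmax_invnm` (optional) and
#' `transfer_threshold`; unknown keys are rejected by name. Aberration
#' coefficients beyond C1/C3 are not supported and refuse to load.
#'
#' @param block Named list (parsed from YAML/JSON).
#' @return An [optical_system()].
#' @export
optics_from_config <- function(block) {
  allowed <- c("voltage_kv", "c1_nm", "c3_mm", "focal_spread_nm",
               "illum_semiangle_mrad", "aperture_kmax_invnm", "transfer_threshold")
  higher <- grep("^c[5-9]", names(block), value = TRUE)
  if (length(higher)) {
    stop("aberrations beyond C3 are not supported: ", paste(higher, collapse = ", "),
         call. = FALSE)
  }
  unknown <- setdiff(names(block), allowed)
  if (length(unknown)) {
    stop("unknown optics key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  optical_system(
    voltage_kv = block$voltage_kv,
    c1_nm = block$c1_nm %||% 0,
    c3_mm = block$c3_mm %||% 0,
    focal_spread_nm = block$focal_spread_nm %||% 0,
    illum_semiangle_mrad = block$illum_semiangle_mrad %||% 0,
    aperture_kmax_invnm = block$aperture_kmax_invnm,
    transfer_threshold = block$transfer_threshold %||% 0.10
  )
}

#' Write / read a tilt series as MRC + JSON sidecar
#'
#' The images go into an MRC stack (mode 2), one section per illumination;
#' tilt magnitudes (mrad), azimuths (deg), the per-image fluence, the optics
#' block and the seed go into a JSON sidecar with the same basename and a
#' `.json` extension. Writing then reading reproduces the images bit-exactly
#' and the metadata exactly.
#'
#' @param series A `tilt_series`.
#' @param path Output `.mrc` path.
#' @return `path`, invisibly.
#' @export
write_tilt_series <- function(series, path) {
  stopifnot(inherits(series, "tilt_series"))
  write_mrc(series$images, path, series$pixel_size)
  meta <- list(
    pixel_size_nm = series$pixel_size,
    fluence_per_image = series$fluence_per_image,
    tilt_magnitude_mrad = vapply(series$tilts, function(t) t$magnitude * 1e3, numeric(1)),
    tilt_azimuth_deg = vapply(series$tilts, function(t) t$azimuth * 180 / pi, numeric(1)),
    optics = optics_to_config(series$optics),
    provenance = series$provenance
  )
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' @rdname write_tilt_series
#' @param warn_tol Relative pixel-size mismatch between MRC header and
#'   sidecar above which a warning is raised (default 0.001).
#' @return For `read_tilt_series`, a `tilt_series`.
#' @export
read_tilt_series <- function(path, warn_tol = 0.001) {
  side <- sidecar_path(path)
  if (!file.exists(side)) stop("missing JSON sidecar: ", side, call. = FALSE)
  mrc <- read_mrc(path)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  n <- length(mrc$stack)
  if (length(meta$tilt_magnitude_mrad) != n) {
    stop(sprintf("sidecar lists %d tilts for a %d-section stack",
                 length(meta$tilt_magnitude_mrad), n), call. = FALSE)
  }
  if (abs(mrc$pixel_size - meta$pixel_size_nm) > warn_tol * meta$pixel_size_nm) {
    warning(sprintf("MRC header pixel size (%.6g nm) differs from sidecar (%.6g nm)",
                    mrc$pixel_size, meta$pixel_size_nm))
  }
  system <- optics_from_config(as.list(meta$optics))
  tilts <- lapply(seq_len(n), function(j) {
    beam_tilt(system, meta$tilt_magnitude_mrad[j] * 1e-3,
              meta$tilt_azimuth_deg[j] * pi / 180)
  })
  structure(list(
    images = mrc$stack, tilts = tilts,
    fluence_per_image = meta$fluence_per_image,
    optics = system, pixel_size = meta$pixel_size_nm,
    provenance = meta$provenance
  ), class = "tilt_series")
}

#' Read and validate a run configuration
#'
#' Parses a YAML run configuration with blocks `optics`, `simulate`,
#' `preprocess`, `reconstruct`, `analyze` plus `seed`, `out_dir` and
#' `log_level`. Unknown keys at the top level or inside a block are
#' rejected with a message naming the offending key. Per-stage seeds are
#' derived deterministically from the global seed and the stage name.
#'
#' @param path Path to a YAML file, or a named list already parsed.
#' @return Validated configuration list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  top_allowed <- c("optics", "simulate", "preprocess", "reconstruct",
                   "analyze", "seed", "out_dir", "log_level")
  unknown <- setdiff(names(cfg), top_allowed)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  block_allowed <- list(
    simulate = c("phantom", "shape", "pixel_size_nm", "tilt_magnitude_mrad",
                 "n_azimuths", "axial", "total_fluence", "noise",
                 "mtf_sigma", "phantom_params", "n_slices", "slice_thickness_nm"),
    preprocess = c("c1_grid_nm", "patches", "reference_index", "skip_defocus"),
    reconstruct = c("iterations", "step0", "decay_factor", "decay_every",
                    "upsample", "epsilon", "order"),
    analyze = c("threshold", "min_redundancy", "mode")
  )
  for (b in names(block_allowed)) {
    if (!is.null(cfg[[b]])) {
      bad <- setdiff(names(cfg[[b]]), block_allowed[[b]])
      if (length(bad)) {
        stop(sprintf("unknown key(s) in `%s` block: %s", b,
                     paste(bad, collapse = ", ")), call. = FALSE)
      }
    }
  }
  if (is.null(cfg$optics)) stop("config needs an `optics` block", call. = FALSE)
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  structure(cfg, class = "run_config")
}

# Deterministic per-stage seed below 2^31, derived from the global seed and
# the stage name.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

#' Run the eFP pipeline
#'
#' Executes simulate -> preprocess -> reconstruct -> analyze from a
#' validated configuration, writing each stage's outputs (MRC stacks, JSON
#' reports) and a `manifest.json` recording the config hash, input file
#' hashes, seeds and package version under the output directory. All
#' randomness derives from the config seed, so identical configurations
#' yield identical outputs.
#'
#' @param config A [read_run_config()] result (or a path to the YAML file).
#' @param out_dir Output directory (defaults to `config$out_dir`).
#' @return Named list of artifact paths, invisibly.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  out_dir <- out_dir %||% config$out_dir %||% "."
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  system <- optics_from_config(config$optics)
  paths <- list()
  log_msg <- function(...) message("[efp] ", sprintf(...))

  # --- simulate -------------------------------------------------------
  sim <- config$simulate
  if (is.null(sim)) stop("pipeline stage `simulate` failed: no simulate block", call. = FALSE)
  phantom <- make_phantom(
    kind = sim$phantom %||% "composite",
    shape = rep(sim$shape %||% 128L, length.out = 2L),
    pixel_size = sim$pixel_size_nm,
    params = sim$phantom_params %||% list(),
    seed = stage_seed(config$seed, "phantom"),
    n_slices = sim$n_slices %||% 1L,
    slice_thickness = sim$slice_thickness_nm %||% 0
  )
  protocol <- tilt_protocol(
    tilt_magnitude = (sim$tilt_magnitude_mrad %||% 10) * 1e-3,
    n_azimuths = sim$n_azimuths %||% 6L,
    axial = sim$axial %||% TRUE
  )
  detector <- detector_model(mtf_sigma = sim$mtf_sigma %||% 0.35)
  series <- simulate_tilt_series(phantom, protocol, system, detector,
                                 total_fluence = sim$total_fluence %||% 1e4,
                                 seed = stage_seed(config$seed, "simulate"),
                                 noise = sim$noise %||% TRUE)
  paths$series <- file.path(out_dir, "series.mrc")
  write_tilt_series(series, paths$series)
  paths$phantom <- file.path(out_dir, "phantom_phase.mrc")
  write_mrc(Reduce(`+`, phantom$phase), paths$phantom, phantom$pixel_size)
  log_msg("simulate: %d images written to %s", length(series$images), paths$series)

  # --- preprocess -----------------------------------------------------
  pre <- config$preprocess %||% list()
  shifts <- register_images(series, reference_index = pre$reference_index %||% 1L)
  comp <- compensate_tilt_shift(series, shifts, system, series$tilts,
                                series$pixel_size)
  series_corr <- comp$stack
  report <- list(shifts = comp$report[c("measured_shift", "predicted_shift",
                                        "applied_shift")])
  if (!isTRUE(pre$skip_defocus) && !is.null(pre$c1_grid_nm)) {
    def <- estimate_defocus(series$images[[1]], system, pre$c1_grid_nm,
                            series$pixel_size,
                            patches = pre$patches %||% NULL)
    report$defocus <- unclass(def)
  }
  paths$series_corr <- file.path(out_dir, "series_corr.mrc")
  write_tilt_series(series_corr, paths$series_corr)
  paths$preprocess_report <- file.path(out_dir, "preprocess_report.json")
  jsonlite::write_json(report, paths$preprocess_report, auto_unbox = TRUE,
                       digits = NA, matrix = "rowmajor")
  log_msg("preprocess: corrected stack written to %s", paths$series_corr)

  # --- reconstruct ----------------------------------------------------
  rec <- config$reconstruct %||% list()
  rcfg <- recon_config(
    iterations = rec$iterations %||% 50L,
    step0 = rec$step0 %||% 0.1,
    decay_factor = rec$decay_factor %||% 0.5,
    decay_every = rec$decay_every %||% 10L,
    upsample = rec$upsample %||% 2L,
    epsilon = rec$epsilon %||% 1e-3,
    order = rec$order %||% "fixed",
    seed = stage_seed(config$seed, "reconstruct")
  )
  est <- pie_reconstruct(series_corr, system, rcfg)
  wave <- exit_wave(est, "canvas")
  paths$exitwave <- file.path(out_dir, "exitwave.mrc")
  write_mrc(list(Arg(wave), Mod(wave)), paths$exitwave, est$canvas_pixel_size)
  paths$recon_report <- file.path(out_dir, "recon_report.json")
  jsonlite::write_json(list(config = unclass(rcfg), data_error = est$history),
                       paths$recon_report, auto_unbox = TRUE, digits = NA)
  log_msg("reconstruct: exit wave written to %s", paths$exitwave)

  # --- analyze --------------------------------------------------------
  ana <- config$analyze %||% list()
  shape <- dim(series$images[[1]])
  grid <- frequency_grid(shape, series$pixel_size)
  map <- redundancy_map(system, series$tilts, grid,
                        threshold = ana$threshold %||% system$transfer_threshold)
  mask <- redundancy_mask(map, ana$min_redundancy %||% 2L)
  truth_phase <- Reduce(`+`, phantom$phase)
  rec_phase <- Arg(exit_wave(est, "measurement"))
  p <- psnr(mask_filter(rec_phase, mask), mask_filter(truth_phase, mask))
  kmax_mask <- if (any(mask)) max(grid$kr[mask]) else 0
  analysis <- list(
    psnr_db = p,
    final_data_error = data_error(est, series_corr, system),
    redundancy_max = max(map$counts),
    aperture_kmax_invnm = kmax_mask,
    aperture_resolution_nm = if (kmax_mask > 0) 1 / kmax_mask else NA
  )
  paths$analysis_report <- file.path(out_dir, "analysis_report.json")
  jsonlite::write_json(analysis, paths$analysis_report, auto_unbox = TRUE, digits = NA)
  log_msg("analyze: report written to %s", paths$analysis_report)

  # --- manifest -------------------------------------------------------
  manifest <- list(
    config = unclass(config),
    config_hash = unname(digest_obj(unclass(config))),
    seeds = list(global = config$seed,
                 phantom = stage_seed(config$seed, "phantom"),
                 simulate = stage_seed(config$seed, "simulate"),
                 reconstruct = stage_seed(config$seed, "reconstruct")),
    file_hashes = as.list(tools::md5sum(unlist(paths))),
    version = as.character(utils::packageVersion("efptycho"))
  )
  paths$manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

# md5 of a serialized R object via a temp file (tools::md5sum is file-based)
digest_obj <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  con <- file(tf, "wb")
  serialize(x, con, version = 2L)
  close(con)
  tools::md5sum(tf)
}
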