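# Configuration handling, I/O round trips, and the end-to-end pipeline
# driver: phantom -> sampling -> acquisition -> motion estimation/binning ->
# reconstruction -> water/fat -> dictionary matching -> maps + statistics.

#' Interior (eroded) region mask
#'
#' Voxels whose full 6-neighbourhood carries the same non-zero label;
#' boundary (partial-volume) voxels are excluded from accuracy statistics.
#'
#' @param labels Integer 3D label volume.
#' @return Logical volume.
#' @export
interior_mask <- function(labels) {
  d <- dim(labels)
  ok <- labels > 0
  shift_eq <- function(ax, by) {
    idx <- rep(list(quote(expr = )), 3)
    n <- d[ax]
    src <- pmin(pmax(seq_len(n) + by, 1L), n)
    idx[[ax]] <- src
    nb <- do.call(`[`, c(list(labels), idx, list(drop = FALSE)))
    nb == labels
  }
  for (ax in 1:3) for (by in c(-1L, 1L)) ok <- ok & shift_eq(ax, by)
  ok
}

default_vial_tissues <- function() {
  data.frame(
    t1    = c(300, 600, 900, 1095, 1245, 1395, 1500, 1800, 2200),
    t1rho = c(35, 44, 50, 56, 65, 80, 100, 120, 150),
    t2    = c(23, 29, 35, 44, 50, 62, 80, 110, 140))
}

#' Default pipeline configuration
#'
#' The desk-scale study conditions: a 64 x 64 x 16 volume of 2 mm isotropic
#' voxels with 9 water vials spanning the myocardial parameter range (all
#' values on the dictionary grid), 6 coils, 6-fold per-contrast
#' undersampling, 4 respiratory bins of sinusoidal breathing with 8 mm
#' foot-head excursion, 70 dB object SNR, and the full HD-PROST
#' reconstruction chain.
#'
#' @return Nested configuration list.
#' @export
default_config <- function() {
  vt <- default_vial_tissues()
  list(
    seed = 1L,
    output_dir = NULL,
    phantom = list(type = "vials", shape = c(64L, 64L, 16L), voxel_size = 2,
                   n_vials = 9L, t1 = vt$t1, t1rho = vt$t1rho, t2 = vt$t2,
                   m0 = rep(1, 9), fat_vials = integer(),
                   fat_fraction = numeric()),
    coils = list(n_coils = 6L),
    acquisition = list(rr_interval = 1000, ti = 250, tsl = 40, sla = 400,
                       t2prep_dur = 40, tr = 6.71, te1 = 2.38, te2 = 4.76,
                       flip_angle = 8, segments_per_hb = 16L,
                       trigger_delay = NA, n_prep_cycles = 3L,
                       centric_fraction = 0.30, idle_fifth = FALSE),
    sampling = list(accel = 6, golden_step_deg = 137.508, vd_exponent = 1.2),
    motion = list(enabled = TRUE, fh_amplitude = 8, period = 4.3, drift = 0,
                  jitter_sd = 0.5, n_bins = 4L, inav_downsample = 2L,
                  max_shift = 20, soft_weight = 0,
                  registration = list(grid_spacing = 16, n_levels = 2L,
                                      lambda_smooth = 0.01, max_iter = 150L)),
    noise = list(snr_db = 70),
    fat = list(offres_hz = -220),
    recon = list(method = "hdprost", lam = 0.04, mu = 0.1, outer_iters = 5L,
                 sense_iters = 5L, search_window = 20L, patch_size = 5L,
                 n_similar = 20L, patch_offset = 4L),
    mapping = list(ranges = NULL, mask_frac = 0.05)
  )
}

merge_config <- function(base, user, path = "") {
  for (nm in names(user)) {
    key <- if (path == "") nm else paste0(path, "$", nm)
    if (!nm %in% names(base))
      stop("unknown configuration key: ", key)
    if (is.list(base[[nm]]) && !is.null(names(base[[nm]])) && is.list(user[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], user[[nm]], key)
    else base[[nm]] <- user[[nm]]
  }
  base
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML file (or takes a list), overlays it on [default_config()],
#' and rejects unknown keys.
#'
#' @param x Path to a YAML file, a list of overrides, or `NULL` for the
#'   defaults.
#' @return Validated configuration list.
#' @export
qcmr_config <- function(x = NULL) {
  user <- if (is.null(x)) list()
          else if (is.character(x)) yaml::read_yaml(x)
          else if (is.list(x)) x
          else stop("config must be a YAML path or a list")
  merge_config(default_config(), user)
}

# Tiny polynomial content hash of the serialized configuration (manifest id).
config_hash <- function(cfg) {
  bytes <- as.numeric(serialize(cfg, NULL, ascii = TRUE))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Write / read volumes with geometry round-trip
#'
#' Real volumes go to NIfTI-1 (voxel size carried in the header); complex
#' arrays and composite objects go to RDS bundles. The function writes,
#' reads back, and returns what was read.
#'
#' @param volume Numeric array (NIfTI) or any R object (RDS).
#' @param path Destination; extension `.nii`/`.nii.gz` selects NIfTI,
#'   anything else RDS.
#' @param voxel_size Voxel size in mm for NIfTI output.
#' @return The re-read object.
#' @export
io_roundtrip <- function(volume, path, voxel_size = 2) {
  if (grepl("\\.nii(\\.gz)?$", path)) {
    if (is.complex(volume)) stop("complex volumes go to RDS, not NIfTI: ", path)
    img <- RNifti::asNifti(volume)
    RNifti::pixdim(img) <- rep(voxel_size, length(dim(volume)))
    RNifti::writeNifti(img, path)
    out <- RNifti::readNifti(path)
    array(as.numeric(out), dim(volume))
  } else {
    saveRDS(volume, path)
    readRDS(path)
  }
}

write_map_nifti <- function(vol, path, voxel_size) {
  vol[is.na(vol)] <- 0
  img <- RNifti::asNifti(vol)
  RNifti::pixdim(img) <- rep(voxel_size, 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Run the full simulation + reconstruction + mapping pipeline
#'
#' Executes every stage of the toolkit under one configuration and seed:
#' phantom and coil construction, trajectory generation, Bloch-weighted
#' k-space simulation with motion and noise, navigator motion estimation
#' and respiratory binning, translational k-space correction, per-bin SENSE
#' and free-form-deformation registration, motion-compensated
#' reconstruction (HD-PROST, plain iterative SENSE, or the zero-filled
#' adjoint), two-point Dixon water/fat separation, polarity restoration and
#' dictionary matching, and per-vial statistics. Identical configuration
#' and seed give identical outputs.
#'
#' @param config A configuration from [qcmr_config()] (or a list of
#'   overrides, or a YAML path).
#' @param dictionary Optional pre-built `qcmr_dictionary` (saves rebuild
#'   time when running several pipelines with one acquisition spec).
#' @param verbose Log stage timings to stderr.
#' @return Invisibly, a list with all intermediates: `phantom`, `sens`,
#'   `pattern`, `motion`, `acquisition`, `shifts_est`, `bins`, `recon`,
#'   `waterfat`, `signals`, `dictionary`, `maps`, `stats`, `manifest`.
#' @export
run_pipeline <- function(config = qcmr_config(), dictionary = NULL,
                         verbose = FALSE) {
  if (!is.list(config) || is.null(config$phantom)) config <- qcmr_config(config)
  cfg <- config
  t_start <- Sys.time()
  stage <- function(name, code) {
    t0 <- Sys.time()
    r <- tryCatch(force(code), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    if (verbose) message(sprintf("[qcmr] %-12s %6.1fs", name,
                                 as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    r
  }
  seed <- cfg$seed

  acq <- stage("acquire-spec", {
    aargs <- cfg$acquisition[setdiff(names(cfg$acquisition), "idle_fifth")]
    if (!is.null(aargs$trigger_delay) && is.na(aargs$trigger_delay))
      aargs$trigger_delay <- NULL
    do.call(acq_spec, aargs)
  })
  idle_fifth <- isTRUE(cfg$acquisition$idle_fifth)

  phant <- stage("phantom", {
    if (cfg$phantom$type == "heart") make_heart_phantom(cfg$phantom$shape,
                                                        cfg$phantom$voxel_size)
    else {
      p <- make_vial_phantom(cfg$phantom$n_vials,
                             tissue_params(cfg$phantom$t1, cfg$phantom$t1rho,
                                           cfg$phantom$t2, cfg$phantom$m0),
                             fat_vials = cfg$phantom$fat_vials,
                             shape = cfg$phantom$shape,
                             voxel_size = cfg$phantom$voxel_size)
      if (length(cfg$phantom$fat_fraction))
        for (v in seq_along(cfg$phantom$fat_fraction))
          p$fat_fraction[p$labels == v] <- cfg$phantom$fat_fraction[v]
      p
    }
  })

  sens <- stage("coils", make_coil_sensitivities(cfg$coils$n_coils,
                                                 phant$shape,
                                                 substream_seed(seed, "sens")))

  pattern <- stage("sampling", generate_caspr_pattern(
    phant$shape[2:3], accel = cfg$sampling$accel,
    segments_per_hb = acq$segments_per_hb,
    golden_step_deg = cfg$sampling$golden_step_deg,
    vd_exponent = cfg$sampling$vd_exponent,
    seed = substream_seed(seed, "sampling")))

  motion_on <- isTRUE(cfg$motion$enabled)
  trace <- if (motion_on)
    simulate_motion_trace(pattern$n_heartbeats, cfg$motion$fh_amplitude,
                          cfg$motion$period, cfg$motion$drift,
                          cfg$motion$jitter_sd,
                          seed = substream_seed(seed, "motion"))
  else NULL

  sigma <- if (!is.null(cfg$noise$snr_db))
    noise_sigma_for_snr(phant, cfg$noise$snr_db) else 0

  sim <- stage("simulate", simulate_acquisition(
    phant, acq, pattern, sens, motion = trace, noise_sigma = sigma,
    seed = seed, fat_offres_hz = cfg$fat$offres_hz,
    inav_downsample = cfg$motion$inav_downsample, idle_fifth = idle_fifth))

  n_hb <- pattern$n_heartbeats
  n_bins <- if (motion_on) cfg$motion$n_bins else 1L

  est <- stage("motion-est", {
    if (!motion_on) {
      list(shifts = matrix(0, n_hb, 2),
           bins = list(bin = rep(1L, n_hb), centers = 0, reference = 1L))
    } else {
      ref_inav <- sim$inavs[, , 1]
      attr(ref_inav, "pixel_size") <- attr(sim$inavs, "pixel_size")
      shifts <- t(vapply(seq_len(n_hb), function(hb) {
        nav <- sim$inavs[, , hb]
        attr(nav, "pixel_size") <- attr(sim$inavs, "pixel_size")
        estimate_translation_ncc(nav, ref_inav, max_shift = cfg$motion$max_shift)
      }, numeric(2)))
      bins <- assign_bins(shifts[, 2], n_bins)
      list(shifts = shifts, bins = bins)
    }
  })

  kcorr <- stage("k-correct", {
    if (motion_on)
      correct_translation_kspace(sim$kspace, est$shifts, est$bins$bin)
    else sim$kspace
  })

  bmasks <- stage("bin-masks", bin_sampling_masks(pattern, est$bins$bin, n_bins))

  fields <- stage("register", {
    if (n_bins == 1L) vector("list", 1L)
    else {
      bimg <- reconstruct_bin_images(kcorr, bmasks, sens,
                                     soft_weight = cfg$motion$soft_weight)
      refb <- est$bins$reference
      regc <- cfg$motion$registration
      # per-bin (rl, fh) centres; the known inter-bin translation seeds the
      # free-form registration
      ctr <- t(vapply(seq_len(n_bins), function(b) {
        sel <- est$bins$bin == b
        if (!any(sel)) return(c(0, 0))
        c(median(est$shifts[sel, 1]), median(est$shifts[sel, 2]))
      }, numeric(2)))
      f <- vector("list", n_bins)
      for (b in seq_len(n_bins)) {
        if (b == refb) next
        dtr <- ctr[b, ] - ctr[refb, ]
        f[[b]] <- register_ffd(Mod(bimg$images[[refb]]), Mod(bimg$images[[b]]),
                               grid_spacing = regc$grid_spacing,
                               n_levels = regc$n_levels,
                               voxel_size = phant$voxel_size,
                               lambda_smooth = regc$lambda_smooth,
                               max_iter = regc$max_iter,
                               init_translation = c(-dtr[1], -dtr[2], 0))
      }
      f
    }
  })

  E <- stage("operator", compose_encoding_operator(bmasks, sens, fields,
                                                   phant$voxel_size))

  rcfg <- hdprost_config(cfg$recon$lam, cfg$recon$mu, cfg$recon$outer_iters,
                         cfg$recon$sense_iters, cfg$recon$search_window,
                         cfg$recon$patch_size, cfg$recon$n_similar,
                         cfg$recon$patch_offset)
  recon <- stage("recon", {
    if (cfg$recon$method == "hdprost") hd_prost_reconstruct(kcorr$data, E, rcfg)
    else if (cfg$recon$method == "sense") {
      X <- data_consistency_step(E, kcorr$data, config = rcfg)
      structure(list(X = X, residual_history = NA_real_, config = rcfg),
                class = "qcmr_recon")
    } else if (cfg$recon$method == "adjoint") {
      shape <- phant$shape
      X <- array(complex(real = 0), c(shape, 2L, pattern$n_contrasts))
      for (cc in seq_len(pattern$n_contrasts)) for (e in 1:2)
        X[, , , e, cc] <- encode_adjoint(
          E, array(kcorr$data[, , , , e, cc], c(shape, dim(kcorr$data)[4])), cc)
      structure(list(X = X, residual_history = NA_real_, config = rcfg),
                class = "qcmr_recon")
    } else stop("unknown recon method: ", cfg$recon$method)
  })

  wf <- stage("waterfat", separate_waterfat(recon$X, acq, cfg$fat$offres_hz))

  pol <- stage("polarity", restore_polarity(wf$water,
                                            array(recon$X[, , , 2, 4],
                                                  phant$shape)))

  dict <- stage("dictionary", {
    if (!is.null(dictionary)) dictionary
    else build_dictionary(acq, cfg$mapping$ranges %||% default_dictionary_ranges(),
                          idle_fifth = idle_fifth)
  })

  maps <- stage("matching", match_dictionary(pol$signals, dict,
                                             mask_frac = cfg$mapping$mask_frac))
  stats <- stage("stats", region_stats(maps, phant$labels, phant))

  manifest <- list(package = "qcmr",
                   version = as.character(utils::packageVersion("qcmr")),
                   seed = seed, config_hash = config_hash(cfg),
                   n_heartbeats = n_hb, n_bins = n_bins,
                   noise_sigma = sigma,
                   elapsed_s = as.numeric(difftime(Sys.time(), t_start,
                                                   units = "secs")))

  out <- list(phantom = phant, sens = sens, pattern = pattern, motion = trace,
              acquisition = sim, shifts_est = est$shifts, bins = est$bins,
              kspace = kcorr, fields = fields, operator = E, recon = recon,
              waterfat = wf, signals = pol$signals, dictionary = dict,
              maps = maps, stats = stats, manifest = manifest, config = cfg)

  if (!is.null(cfg$output_dir)) stage("write", {
    dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
    vs <- phant$voxel_size
    for (nm in c("t1", "t1rho", "t2", "match_score"))
      write_map_nifti(maps[[nm]], file.path(cfg$output_dir,
                                            paste0(nm, ".nii.gz")), vs)
    if (!is.null(wf$fat_fraction_est))
      write_map_nifti(wf$fat_fraction_est,
                      file.path(cfg$output_dir, "fat_fraction.nii.gz"), vs)
    saveRDS(kcorr, file.path(cfg$output_dir, "kspace.rds"))
    saveRDS(recon, file.path(cfg$output_dir, "recon.rds"))
    write.csv(stats, file.path(cfg$output_dir, "region_stats.csv"),
              row.names = FALSE)
    jsonlite::write_json(manifest, file.path(cfg$output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  })

  invisible(out)
}
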