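# Synthetic digital phantoms and the forward acquisition model:
# piecewise-constant tissue-parameter volumes, smooth complex coil
# sensitivities, per-heartbeat respiratory translations, and simulation of
# motion-corrupted, undersampled two-echo Dixon k-space plus 2D image
# navigators.
#
# Axis convention used throughout: dim 1 = x = right-left (readout, fully
# sampled), dim 2 = y = foot-head (phase encode 1), dim 3 = z = anterior-
# posterior (phase encode 2, the thin slab). Respiratory motion is a rigid
# in-plane (RL, FH) translation per heartbeat; image navigators are coronal
# (x-y) projections along z.

new_tpm <- function(shape, voxel_size, t1, t1rho, t2, m0, fat_fraction, labels) {
  structure(list(shape = as.integer(shape), voxel_size = voxel_size,
                 t1 = t1, t1rho = t1rho, t2 = t2, m0 = m0,
                 fat_fraction = fat_fraction, labels = labels),
            class = "qcmr_tpm")
}

#' Cylindrical vial phantom
#'
#' Builds a piecewise-constant 3D tissue-parameter volume with `n_vials`
#' cylindrical vials (long axis along z) arranged on a ring, on a zero-signal
#' background, mimicking relaxometry calibration phantoms with vials of
#' graded agar/NiCl2 concentration.
#'
#' @param n_vials Number of vials.
#' @param params A [tissue_params()] of length `n_vials` (or a data frame
#'   with columns t1, t1rho, t2 and optionally m0).
#' @param fat_vials Integer indices of vials whose fat fraction is 1
#'   (default none; all others are water, fat fraction 0).
#' @param shape Volume dimensions in voxels, default `c(64, 64, 16)`.
#' @param voxel_size Isotropic voxel size in mm, default 2.
#' @param vial_radius Vial radius in voxels; default scales with the matrix.
#' @param ring_radius Radius of the ring of vial centres in voxels.
#' @return A `qcmr_tpm`: parameter volumes `t1`, `t1rho`, `t2`, `m0`,
#'   `fat_fraction` and an integer `labels` volume (0 = background,
#'   1..n_vials = vial id).
#' @export
make_vial_phantom <- function(n_vials, params = NULL, fat_vials = integer(),
                              shape = c(64, 64, 16), voxel_size = 2,
                              vial_radius = NULL, ring_radius = NULL) {
  shape <- as.integer(shape)
  if (is.data.frame(params))
    params <- tissue_params(params$t1, params$t1rho, params$t2,
                            if (is.null(params$m0)) 1 else params$m0)
  if (n_vials > 0 && (is.null(params) || length(params$t1) != n_vials))
    stop("params must supply one tissue per vial")
  if (is.null(vial_radius)) vial_radius <- max(2, floor(min(shape[1:2]) * 0.09))
  if (is.null(ring_radius)) ring_radius <- floor(min(shape[1:2]) * 0.30)
  zero <- array(0, shape)
  labels <- array(0L, shape)
  t1 <- t1rho <- t2 <- m0 <- ff <- zero
  if (n_vials > 0) {
    cx <- shape[1] / 2 + 0.5; cy <- shape[2] / 2 + 0.5
    ang <- 2 * pi * (seq_len(n_vials) - 1) / n_vials
    vx <- cx + ring_radius * cos(ang)
    vy <- cy + ring_radius * sin(ang)
    if (n_vials > 1) {
      dmin <- min(dist(cbind(vx, vy)))
      if (dmin < 2 * vial_radius + 1)
        stop("overlapping vials: reduce vial_radius or n_vials, or enlarge ring_radius")
    }
    if (any(vx - vial_radius < 1 | vx + vial_radius > shape[1] |
            vy - vial_radius < 1 | vy + vial_radius > shape[2]))
      stop("vials do not fit inside the volume")
    xg <- matrix(seq_len(shape[1]), shape[1], shape[2])
    yg <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
    zslab <- seq(max(1L, 2L), min(shape[3], shape[3] - 1L))
    for (v in seq_len(n_vials)) {
      inside2d <- (xg - vx[v])^2 + (yg - vy[v])^2 <= vial_radius^2
      for (z in zslab) {
        sl <- labels[, , z]
        sl[inside2d] <- v
        labels[, , z] <- sl
      }
      vol <- labels == v
      t1[vol] <- params$t1[v]; t1rho[vol] <- params$t1rho[v]
      t2[vol] <- params$t2[v]; m0[vol] <- params$m0[v]
      if (v %in% fat_vials) ff[vol] <- 1
    }
  }
  new_tpm(shape, voxel_size, t1, t1rho, t2, m0, ff, labels)
}

#' Two-compartment "heart" phantom
#'
#' A simple thick-walled ellipsoidal annulus (myocardium) around a blood
#' pool, with an optional epicardial fat rim, for exercising the pipeline on
#' a contiguous object rather than isolated vials.
#'
#' @param shape,voxel_size As in [make_vial_phantom()].
#' @param myo,blood,fat [tissue_params()] for the three compartments.
#' @return A `qcmr_tpm` with labels 1 = myocardium, 2 = blood pool,
#'   3 = fat rim (if enabled).
#' @export
make_heart_phantom <- function(shape = c(64, 64, 16), voxel_size = 2,
                               myo = tissue_params(1100, 56, 44),
                               blood = tissue_params(1700, 150, 150),
                               fat = tissue_params(300, 120, 100)) {
  shape <- as.integer(shape)
  cx <- shape[1] / 2 + 0.5; cy <- shape[2] / 2 + 0.5; cz <- shape[3] / 2 + 0.5
  rx <- shape[1] * 0.28; ry <- shape[2] * 0.28; rz <- max(shape[3] * 0.35, 2)
  g <- expand.grid(x = seq_len(shape[1]), y = seq_len(shape[2]), z = seq_len(shape[3]))
  r2 <- ((g$x - cx) / rx)^2 + ((g$y - cy) / ry)^2 + ((g$z - cz) / rz)^2
  labels <- array(0L, shape)
  labels[r2 <= 1] <- 1L          # myocardium shell
  labels[r2 <= 0.45] <- 2L       # blood pool
  labels[r2 > 1 & r2 <= 1.35] <- 3L  # fat rim
  zero <- array(0, shape)
  t1 <- t1rho <- t2 <- m0 <- ff <- zero
  comp <- list(myo, blood, fat)
  for (v in 1:3) {
    vol <- labels == v
    t1[vol] <- comp[[v]]$t1[1]; t1rho[vol] <- comp[[v]]$t1rho[1]
    t2[vol] <- comp[[v]]$t2[1]; m0[vol] <- comp[[v]]$m0[1]
  }
  ff[labels == 3L] <- 1
  new_tpm(shape, voxel_size, t1, t1rho, t2, m0, ff, labels)
}

#' Smooth complex coil sensitivity maps
#'
#' Gaussian-lobe magnitude profiles centred around the field of view with
#' smooth low-order polynomial phase, normalized so that
#' `sum_c |S_c|^2 = 1` at every voxel.
#'
#' @param n_coils Number of coils (>= 1).
#' @param shape Volume dimensions.
#' @param seed Integer seed (maps are deterministic given the seed).
#' @return Complex array `[shape x n_coils]`.
#' @export
make_coil_sensitivities <- function(n_coils, shape = c(64, 64, 16), seed = 1) {
  if (n_coils < 1) stop("n_coils must be >= 1")
  shape <- as.integer(shape)
  sens <- array(complex(real = 0), c(shape, n_coils))
  g <- expand.grid(x = seq_len(shape[1]), y = seq_len(shape[2]), z = seq_len(shape[3]))
  with_seed(seed, {
    ang <- 2 * pi * (seq_len(n_coils) - 1) / n_coils + runif(1, 0, 2 * pi)
    rad <- 0.65 * min(shape[1:2]) / 2 * 2  # lobe centres just outside the FOV ring
    cx <- shape[1] / 2 + rad * cos(ang)
    cy <- shape[2] / 2 + rad * sin(ang)
    cz <- shape[3] / 2 + runif(n_coils, -shape[3] / 4, shape[3] / 4)
    width <- 0.9 * max(shape[1:2])
    for (cc in seq_len(n_coils)) {
      mag <- exp(-(((g$x - cx[cc])^2 + (g$y - cy[cc])^2) / (2 * width^2) +
                     (g$z - cz[cc])^2 / (2 * (width / 2)^2)))
      ph <- 2 * pi * (runif(1, -0.2, 0.2) * g$x / shape[1] +
                        runif(1, -0.2, 0.2) * g$y / shape[2] +
                        runif(1, -0.2, 0.2) * g$z / shape[3]) + runif(1, 0, 2 * pi)
      if (n_coils == 1L) ph <- 0
      sens[, , , cc] <- array(complex(modulus = mag, argument = ph), shape)
    }
  })
  ssq <- sqrt(apply(abs(sens)^2, 1:3, sum))
  sens / as.vector(ssq)  # recycles over the coil dimension
}

#' Per-heartbeat respiratory motion trace
#'
#' Foot-head displacement modelled as a rectified-sine breathing profile with
#' optional linear drift and seeded Gaussian jitter; right-left displacement
#' is a fixed fraction of foot-head (the dominant component).
#'
#' @param n_heartbeats Number of heartbeats.
#' @param fh_amplitude Peak foot-head excursion (mm). Default 8.
#' @param period Breathing period in heartbeats. Default 4.3 (a ~4 s breath
#'   at 60 bpm, incommensurate with the 5-heartbeat sequence cycle).
#' @param drift Linear drift in mm per heartbeat.
#' @param jitter_sd SD of per-beat Gaussian jitter (mm).
#' @param rl_fraction RL amplitude as a fraction of FH. Default 0.3.
#' @param seed Integer seed.
#' @return A `qcmr_motion_trace`: list with `fh`, `rl` (mm, length
#'   `n_heartbeats`), `n_heartbeats`, `seed`.
#' @export
simulate_motion_trace <- function(n_heartbeats, fh_amplitude = 8, period = 4.3,
                                  drift = 0, jitter_sd = 0.5,
                                  rl_fraction = 0.3, seed = 1) {
  if (fh_amplitude < 0) stop("fh_amplitude must be >= 0")
  t <- seq_len(n_heartbeats) - 1
  fh <- fh_amplitude * sin(pi * t / period)^2 + drift * t
  if (jitter_sd > 0)
    fh <- fh + with_seed(seed, rnorm(n_heartbeats, sd = jitter_sd))
  rl <- rl_fraction * fh
  structure(list(n_heartbeats = as.integer(n_heartbeats), fh = fh, rl = rl,
                 seed = seed),
            class = "qcmr_motion_trace")
}

# Object-referenced complex noise level for a target SNR in dB:
# sigma per real/imaginary component such that
# 20*log10(mean |object signal| / sigma) = snr_db.
noise_sigma_for_snr <- function(map, snr_db) {
  msig <- mean(map$m0[map$m0 > 0])
  msig / 10^(snr_db / 20)
}

# Signed contrast weights per labelled region: [n_labels x 5] from the Bloch
# shot train, using each region's own relaxation parameters.
region_contrast_weights <- function(map, acq, idle_fifth = FALSE) {
  labs <- sort(unique(as.vector(map$labels)))
  labs <- labs[labs != 0]
  if (length(labs) == 0L) return(list(labels = integer(), w = matrix(0, 0, 5)))
  idx <- match(labs, as.vector(map$labels))
  tis <- tissue_params(map$t1[idx], map$t1rho[idx], map$t2[idx], m0 = 1)
  w <- simulate_shot_train(tis, acq, idle_fifth = idle_fifth)
  if (is.null(dim(w))) w <- matrix(w, 1L)
  list(labels = labs, w = w)
}

#' Forward simulation of the motion-corrupted two-echo Dixon acquisition
#'
#' Builds, for every contrast and echo, the complex object image
#' `m0 * w_c * ((1-ff) + ff * exp(i*theta_e))` (single-peak fat model with
#' chemical shift `fat_offres_hz`), multiplies by the coil sensitivities,
#' Fourier-transforms, and samples the trajectory's phase-encode cells
#' heartbeat by heartbeat with the rigid (RL, FH) translation of that
#' heartbeat applied as a k-space phase ramp. Complex Gaussian noise of SD
#' `noise_sigma` (per real/imaginary component) is added to the sampled data.
#' A low-resolution coronal image navigator at the true shift is produced for
#' every heartbeat.
#'
#' @param map A `qcmr_tpm` phantom.
#' @param acq An [acq_spec()].
#' @param pattern A [generate_caspr_pattern()] sampling pattern.
#' @param sens Coil sensitivities `[shape x n_coils]`.
#' @param motion A [simulate_motion_trace()] covering the pattern's
#'   heartbeats, or `NULL` for a static object.
#' @param noise_sigma Per-component noise SD in k-space (unitary transform
#'   convention). Default 0.
#' @param seed Integer seed for the noise stream.
#' @param fat_offres_hz Single-peak fat chemical shift (Hz). Default -220
#'   (1.5 T), making TE1 approximately out-of-phase and TE2 in-phase.
#' @param inav_downsample Navigator downsampling factor (Fourier crop).
#' @param idle_fifth Passed to the signal model.
#' @return A list with `kspace` (a `qcmr_kspace`), `inavs`
#'   (`[nx/f x ny/f x n_heartbeats]` real array) and `images` (clean
#'   coil-free complex contrast images `[shape x 2 echoes x 5 contrasts]`).
#' @export
simulate_acquisition <- function(map, acq, pattern, sens, motion = NULL,
                                 noise_sigma = 0, seed = 1,
                                 fat_offres_hz = -220, inav_downsample = 2,
                                 idle_fifth = FALSE) {
  shape <- map$shape
  if (!all(dim(sens)[1:3] == shape)) stop("shape mismatch between map and sens")
  if (!all(pattern$matrix == shape[2:3]))
    stop("shape mismatch between map and sampling pattern")
  nc <- pattern$n_contrasts
  ncoil <- dim(sens)[4]
  n_hb <- pattern$n_heartbeats
  if (is.null(motion)) {
    motion <- list(fh = rep(0, n_hb), rl = rep(0, n_hb), n_heartbeats = n_hb)
  }
  if (length(motion$fh) < n_hb) stop("motion trace shorter than the acquisition")

  rw <- region_contrast_weights(map, acq, idle_fifth = idle_fifth)
  theta <- 2 * pi * fat_offres_hz * c(acq$te1, acq$te2) / 1000

  images <- array(complex(real = 0), c(shape, 2L, nc))
  for (cc in seq_len(nc)) {
    wmap <- array(0, shape)
    for (j in seq_along(rw$labels))
      wmap[map$labels == rw$labels[j]] <- rw$w[j, cc]
    base <- map$m0 * wmap
    for (e in 1:2)
      images[, , , e, cc] <- base * ((1 - map$fat_fraction) +
                                       map$fat_fraction * exp(1i * theta[e]))
  }

  # static multi-coil k-space per contrast/echo
  kstat <- array(complex(real = 0), c(shape, ncoil, 2L, nc))
  for (cc in seq_len(nc)) for (e in 1:2) for (co in seq_len(ncoil))
    kstat[, , , co, e, cc] <- fftc(sens[, , , co] * images[, , , e, cc])

  kx <- kfreq(shape[1]) / map$voxel_size   # cycles / mm
  ky <- kfreq(shape[2]) / map$voxel_size

  data <- array(complex(real = 0), c(shape, ncoil, 2L, nc))
  masks <- array(0L, c(shape[2], shape[3], nc))
  hb_index <- array(0L, c(shape[2], shape[3], nc))

  for (cc in seq_len(nc)) {
    for (s in seq_len(pattern$n_cycles)) {
      hb <- (s - 1L) * nc + cc
      shot <- pattern$shots[[cc]][[s]]
      dx <- motion$rl[hb]; dy <- motion$fh[hb]
      rampx <- exp(-2i * pi * kx * dx)
      for (q in seq_len(nrow(shot))) {
        iy <- shot[q, 1]; iz <- shot[q, 2]
        if (masks[iy, iz, cc] == 1L) next  # keep first acquisition of a cell
        # ph recycles down the fully-sampled readout (first) dimension
        ph <- rampx * exp(-2i * pi * ky[iy] * dy)
        data[, iy, iz, , , cc] <- kstat[, iy, iz, , , cc] * ph
        masks[iy, iz, cc] <- 1L
        hb_index[iy, iz, cc] <- hb
      }
    }
  }

  if (noise_sigma > 0) {
    nsampled <- sum(masks) * shape[1] * ncoil * 2L
    noise <- with_seed(substream_seed(seed, "noise"),
                       complex(real = rnorm(nsampled, sd = noise_sigma),
                               imaginary = rnorm(nsampled, sd = noise_sigma)))
    ni <- 1L
    for (cc in seq_len(nc)) {
      sel <- which(masks[, , cc] == 1L, arr.ind = TRUE)
      if (nrow(sel) == 0L) next
      nblock <- nrow(sel) * shape[1] * ncoil * 2L
      blk <- array(noise[ni:(ni + nblock - 1L)],
                   c(shape[1], nrow(sel), ncoil, 2L))
      for (q in seq_len(nrow(sel)))
        data[, sel[q, 1], sel[q, 2], , , cc] <-
          data[, sel[q, 1], sel[q, 2], , , cc] + blk[, q, , ]
      ni <- ni + nblock
    }
  }

  kspace <- structure(list(data = data, masks = masks, hb_index = hb_index,
                           noise_sigma = noise_sigma, acq = acq,
                           voxel_size = map$voxel_size, shape = shape),
                      class = "qcmr_kspace")

  inavs <- simulate_inavs(map, motion, n_hb, inav_downsample)
  list(kspace = kspace, inavs = inavs, images = images)
}

# Coronal projection navigators: project m0 along z, shift by the heartbeat's
# true (RL, FH) translation via a Fourier phase ramp, low-pass by cropping
# the central k-space block, and return magnitude images.
simulate_inavs <- function(map, motion, n_hb, factor = 2) {
  proj <- apply(map$m0, 1:2, sum)
  nx <- nrow(proj); ny <- ncol(proj)
  kxm <- matrix(kfreq(nx) / map$voxel_size, nx, ny)
  kym <- matrix(kfreq(ny) / map$voxel_size, nx, ny, byrow = TRUE)
  kp <- fftc(proj)
  nxo <- nx %/% factor; nyo <- ny %/% factor
  x0 <- floor(nx / 2) + 1L - nxo %/% 2L
  y0 <- floor(ny / 2) + 1L - nyo %/% 2L
  out <- array(0, c(nxo, nyo, n_hb))
  for (hb in seq_len(n_hb)) {
    ksh <- kp * exp(-2i * pi * (kxm * motion$rl[hb] + kym * motion$fh[hb]))
    crop <- ksh[x0:(x0 + nxo - 1L), y0:(y0 + nyo - 1L)]
    out[, , hb] <- Mod(ifftc(crop))
  }
  attr(out, "pixel_size") <- map$voxel_size * factor
  out
}
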