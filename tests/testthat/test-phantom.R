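# Digital phantoms, coil sensitivities, motion traces, and the forward
# acquisition model.

test_that("vial phantom is piecewise constant with the requested tissues", {
  p0 <- make_vial_phantom(0, shape = c(16, 16, 4))
  expect_true(all(p0$m0 == 0))
  expect_identical(sort(unique(as.vector(p0$labels))), 0L)

  vt <- data.frame(t1 = seq(400, 2000, length.out = 9),
                   t1rho = seq(30, 150, length.out = 9),
                   t2 = seq(25, 120, length.out = 9))
  p <- make_vial_phantom(9, vt, shape = c(64, 64, 16))
  expect_identical(length(unique(as.vector(p$labels))), 10L)
  for (v in 1:9) {
    sel <- p$labels == v
    expect_gt(sum(sel), 0)
    expect_equal(unique(p$t1[sel]), vt$t1[v])
    expect_equal(unique(p$t1rho[sel]), vt$t1rho[v])
    expect_equal(unique(p$t2[sel]), vt$t2[v])
  }
  expect_error(make_vial_phantom(9, vt, shape = c(64, 64, 16),
                                 vial_radius = 12), "overlap")
})

test_that("coil sensitivities are normalized, smooth and deterministic", {
  s1 <- make_coil_sensitivities(1, c(16, 16, 4), seed = 5)
  expect_equal(max(abs(Mod(s1) - 1)), 0, tolerance = 1e-9)
  s <- make_coil_sensitivities(6, c(16, 16, 4), seed = 5)
  ssq <- apply(abs(s)^2, 1:3, sum)
  expect_equal(max(abs(ssq - 1)), 0, tolerance = 1e-9)
  s2 <- make_coil_sensitivities(6, c(16, 16, 4), seed = 5)
  expect_identical(s, s2)
  s3 <- make_coil_sensitivities(6, c(16, 16, 4), seed = 6)
  expect_false(identical(s, s3))
})

test_that("motion trace amplitude, determinism and quantile balance", {
  tr0 <- simulate_motion_trace(20, fh_amplitude = 0, drift = 0, jitter_sd = 0)
  expect_true(all(tr0$fh == 0) && all(tr0$rl == 0))
  n <- 60
  tr <- simulate_motion_trace(n, fh_amplitude = 8, drift = 0.05,
                              jitter_sd = 0.4, seed = 7)
  expect_true(max(abs(tr$fh)) <= 8 + 0.05 * n + 3 * 0.4 + 8 * .Machine$double.eps)
  expect_identical(simulate_motion_trace(n, 8, drift = 0.05, jitter_sd = 0.4,
                                         seed = 7)$fh, tr$fh)
  expect_equal(tr$rl, 0.3 * tr$fh)
  # quantile binning of the trace is balanced to +-1 heartbeat per bin
  b <- assign_bins(tr$fh, 4)
  counts <- tabulate(b$bin, 4)
  expect_true(max(counts) - min(counts) <= 1)
})

test_that("noise-free static fully-sampled acquisition is an identity pipeline", {
  p <- small_phantom()
  acq <- acq_spec()
  pat <- generate_caspr_pattern(p$shape[2:3], accel = 1, seed = 3)
  sens <- make_coil_sensitivities(4, p$shape, seed = 2)
  sim <- simulate_acquisition(p, acq, pat, sens)
  # coil-combined inverse transform of contrast 2, echo 2 equals the clean image
  img <- array(0i, p$shape)
  for (co in 1:4)
    img <- img + Conj(sens[, , , co]) * ifftc(array(sim$kspace$data[, , , co, 2, 2],
                                                    p$shape))
  truth <- sim$images[, , , 2, 2]
  expect_lt(relerr(img, truth), 1e-6)
  # Parseval under the unitary transform convention
  ksum <- sum(abs(sim$kspace$data[, , , , 2, 2])^2)
  isum <- sum(abs(truth)^2)  # sum_c |S_c|^2 = 1
  expect_equal(ksum, isum, tolerance = 1e-9)
})

test_that("fat phase model: out-of-phase echo flips pure-fat voxels", {
  p <- small_phantom()
  p$fat_fraction[p$labels == 2] <- 1   # one pure-fat vial
  acq <- acq_spec()
  pat <- generate_caspr_pattern(p$shape[2:3], accel = 1, seed = 3)
  sens <- make_coil_sensitivities(1, p$shape, seed = 2)
  # exact out-of-phase at echo 1: theta_1 = pi  <->  f = -0.5/te1 kHz
  f_op <- -500 / acq$te1
  sim <- simulate_acquisition(p, acq, pat, sens, fat_offres_hz = f_op)
  fatvox <- which(p$fat_fraction == 1)
  e1 <- sim$images[, , , 1, 2][fatvox]
  e2 <- sim$images[, , , 2, 2][fatvox]
  # theta_2 = 2 theta_1 = -2 pi: fat back in phase at echo 2, so e1 = -e2
  expect_lt(max(Mod(e1 + e2)), 1e-9)
  # water-only phantom: echo magnitudes agree voxelwise
  p2 <- small_phantom()
  sim2 <- simulate_acquisition(p2, acq, pat, sens, fat_offres_hz = -220)
  expect_equal(Mod(sim2$images[, , , 1, 3]), Mod(sim2$images[, , , 2, 3]),
               tolerance = 1e-9)
})

test_that("k-space shift theorem and acquisition determinism", {
  p <- small_phantom()
  acq <- acq_spec()
  pat <- generate_caspr_pattern(p$shape[2:3], accel = 2, seed = 4)
  sens <- make_coil_sensitivities(2, p$shape, seed = 2)
  mot <- simulate_motion_trace(pat$n_heartbeats, fh_amplitude = 6, seed = 9)
  simA <- simulate_acquisition(p, acq, pat, sens, motion = mot,
                               noise_sigma = 1e-5, seed = 11)
  simB <- simulate_acquisition(p, acq, pat, sens, motion = mot,
                               noise_sigma = 1e-5, seed = 11)
  expect_identical(simA$kspace$data, simB$kspace$data)
  simC <- simulate_acquisition(p, acq, pat, sens, motion = mot,
                               noise_sigma = 1e-5, seed = 12)
  expect_false(identical(simA$kspace$data, simC$kspace$data))

  # integer-voxel shift multiplies k-space by the analytic phase ramp
  mot1 <- simulate_motion_trace(pat$n_heartbeats, fh_amplitude = 0,
                                jitter_sd = 0)
  mot1$fh <- rep(2 * p$voxel_size, pat$n_heartbeats)  # +2 voxels FH
  mot1$rl <- rep(0, pat$n_heartbeats)
  sim0 <- simulate_acquisition(p, acq, pat, sens)
  sim1 <- simulate_acquisition(p, acq, pat, sens, motion = mot1)
  sel <- which(sim0$kspace$masks[, , 1] == 1L, arr.ind = TRUE)
  ky <- (seq_len(p$shape[2]) - 1 - floor(p$shape[2] / 2)) / p$shape[2]
  for (q in head(seq_len(nrow(sel)), 20)) {
    iy <- sel[q, 1]; iz <- sel[q, 2]
    ramp <- exp(-2i * pi * ky[iy] * 2)
    expect_equal(sim1$kspace$data[, iy, iz, 1, 1, 1],
                 sim0$kspace$data[, iy, iz, 1, 1, 1] * ramp,
                 tolerance = 1e-9)
  }
  expect_error(simulate_acquisition(p, acq, pat,
                                    make_coil_sensitivities(2, c(8, 8, 4)),
                                    motion = NULL), "mismatch")
})

test_that("navigators track the true in-plane shift", {
  p <- small_phantom()
  acq <- acq_spec()
  pat <- generate_caspr_pattern(p$shape[2:3], accel = 2, seed = 4)
  sens <- make_coil_sensitivities(1, p$shape, seed = 2)
  mot <- simulate_motion_trace(pat$n_heartbeats, fh_amplitude = 0, jitter_sd = 0)
  mot$fh <- c(0, rep(6, pat$n_heartbeats - 1))
  mot$rl <- c(0, rep(-3, pat$n_heartbeats - 1))
  sim <- simulate_acquisition(p, acq, pat, sens, motion = mot,
                              inav_downsample = 2)
  ref <- sim$inavs[, , 1]; nav <- sim$inavs[, , 2]
  ps <- attr(sim$inavs, "pixel_size")
  est <- estimate_translation_ncc(nav, ref, max_shift = 12, pixel_size = ps)
  expect_lt(abs(est["fh"] - 6), 0.25 * ps)
  expect_lt(abs(est["rl"] + 3), 0.25 * ps)
})
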