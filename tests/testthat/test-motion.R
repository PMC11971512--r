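# Navigator shift estimation, binning, k-space correction, bin
# reconstruction, FFD registration, and the encoding operator.

make_test_image <- function(n = 40, cx = 18, cy = 21, w = 4) {
  g <- expand.grid(x = seq_len(n), y = seq_len(n))
  matrix(exp(-((g$x - cx)^2 + (g$y - cy)^2) / (2 * w^2)), n, n)
}

test_that("NCC estimates known integer and fractional shifts", {
  img <- make_test_image()
  expect_equal(unname(estimate_translation_ncc(img, img, max_shift = 10)),
               c(0, 0))
  shifted <- make_test_image(cx = 18 + 3, cy = 21 - 2)
  est <- estimate_translation_ncc(shifted, img, max_shift = 10, pixel_size = 1)
  expect_lt(abs(est["rl"] - 3), 0.25)
  expect_lt(abs(est["fh"] + 2), 0.25)
  # antisymmetry
  rev <- estimate_translation_ncc(img, shifted, max_shift = 10, pixel_size = 1)
  expect_lt(max(abs(est + rev)), 0.25)
  # subpixel: a 1.4-pixel shift of a smooth blob
  sub <- make_test_image(cx = 18 + 1.4)
  est2 <- estimate_translation_ncc(sub, img, max_shift = 10, pixel_size = 1)
  expect_lt(abs(est2["rl"] - 1.4), 0.25)
  # pixel size scales the output
  est3 <- estimate_translation_ncc(shifted, img, max_shift = 40, pixel_size = 4)
  expect_lt(abs(est3["rl"] - 12), 1)
  expect_error(estimate_translation_ncc(matrix(1, 8, 8), matrix(1, 8, 8)),
               "flat image")
})

test_that("quantile binning balances counts and flags end-expiration", {
  expect_identical(assign_bins(rep(3.3, 7))$bin, rep(1L, 7))
  b <- assign_bins(c(5, 1, 7, 3, 8, 2, 6, 4), 4)
  expect_identical(tabulate(b$bin, 4), rep(2L, 4))
  # recompute medians by hand
  for (bb in 1:4)
    expect_equal(b$centers[bb],
                 median(c(5, 1, 7, 3, 8, 2, 6, 4)[b$bin == bb]))
  expect_identical(b$reference, which.min(abs(b$centers)))
  # trace with negative baseline: reference is the minimal |median| bin
  b2 <- assign_bins(c(-9, -8, 0.5, 1, 6, 7, 12, 13), 4)
  expect_identical(b2$reference, 2L)
})

test_that("translational k-space correction is unitary and inverts the shift", {
  p <- small_phantom()
  acq <- acq_spec()
  pat <- generate_caspr_pattern(p$shape[2:3], accel = 1, seed = 3)
  sens <- make_coil_sensitivities(2, p$shape, seed = 2)
  n_hb <- pat$n_heartbeats
  mot <- simulate_motion_trace(n_hb, fh_amplitude = 0, jitter_sd = 0)
  mot$fh <- rep(4, n_hb); mot$rl <- rep(-2, n_hb)
  sim <- simulate_acquisition(p, acq, pat, sens, motion = mot)
  sim0 <- simulate_acquisition(p, acq, pat, sens)
  shifts <- cbind(mot$rl, mot$fh)
  corr <- correct_translation_kspace(sim$kspace, shifts)
  # magnitudes unchanged (unit-modulus phase)
  expect_equal(Mod(corr$data), Mod(sim$kspace$data), tolerance = 1e-12)
  # corrected k-space equals the static acquisition
  expect_lt(relerr(corr$data, sim0$kspace$data), 1e-9)
  # shifts equal to bin centres: data untouched
  bins <- rep(1L, n_hb)
  centers <- matrix(c(-2, 4), 1)
  corr2 <- correct_translation_kspace(sim$kspace, shifts, bins, centers)
  expect_equal(corr2$data, sim$kspace$data, tolerance = 1e-12)
  # missing heartbeat tag
  broken <- sim$kspace
  sel <- which(broken$masks[, , 1] == 1L, arr.ind = TRUE)
  broken$hb_index[sel[1, 1], sel[1, 2], 1] <- 0L
  expect_error(correct_translation_kspace(broken, shifts), "heartbeat tag")
})

test_that("simulated-trace correction re-aligns the shot images", {
  p <- small_phantom()
  acq <- acq_spec()
  pat <- generate_caspr_pattern(p$shape[2:3], accel = 1, seed = 7)
  sens <- make_coil_sensitivities(2, p$shape, seed = 2)
  mot <- simulate_motion_trace(pat$n_heartbeats, fh_amplitude = 6,
                               jitter_sd = 0.3, seed = 5)
  sim <- simulate_acquisition(p, acq, pat, sens, motion = mot)
  corr <- correct_translation_kspace(sim$kspace, cbind(mot$rl, mot$fh))
  img <- array(0i, p$shape)
  for (co in 1:2)
    img <- img + Conj(sens[, , , co]) * ifftc(array(corr$data[, , , co, 2, 2],
                                                    p$shape))
  ref <- sim$images[, , , 2, 2]
  proj_e <- apply(Mod(img), 1:2, sum)
  proj_r <- apply(Mod(ref), 1:2, sum)
  res <- estimate_translation_ncc(proj_e, proj_r, max_shift = 10,
                                  pixel_size = 1)
  expect_lt(max(abs(res)), 0.25)
})

test_that("CG-SENSE bin reconstruction: exactness at full sampling, descent", {
  p <- small_phantom()
  acq <- acq_spec()
  pat <- generate_caspr_pattern(p$shape[2:3], accel = 1, seed = 3)
  sens <- make_coil_sensitivities(3, p$shape, seed = 2)
  sim <- simulate_acquisition(p, acq, pat, sens)
  bm <- bin_sampling_masks(pat, rep(1L, pat$n_heartbeats), n_bins = 1)
  rec <- reconstruct_bin_images(sim$kspace, bm, sens)
  truth <- sim$images[, , , 2, 4]
  expect_lt(relerr(rec$images[[1]], truth), 1e-5)
  expect_false(is.unsorted(rev(rec$resid[[1]])))  # non-increasing residual
  # empty bin errors with the bin named
  bm2 <- bin_sampling_masks(pat, rep(2L, pat$n_heartbeats), n_bins = 2)
  expect_error(reconstruct_bin_images(sim$kspace, bm2, sens), "empty bin 1")
})

test_that("4-bin reconstruction localizes the known per-bin displacement", {
  p <- small_phantom()
  acq <- acq_spec()
  pat <- generate_caspr_pattern(p$shape[2:3], accel = 1, seed = 3)
  sens <- make_coil_sensitivities(3, p$shape, seed = 2)
  n_hb <- pat$n_heartbeats
  mot <- simulate_motion_trace(n_hb, 0, jitter_sd = 0)
  # two well-separated respiratory positions
  mot$fh <- rep(c(0, 8), length.out = n_hb)
  mot$rl <- 0 * mot$fh
  sim <- simulate_acquisition(p, acq, pat, sens, motion = mot)
  bins <- assign_bins(mot$fh, 2)
  corr <- correct_translation_kspace(sim$kspace, cbind(mot$rl, mot$fh),
                                     bins$bin)
  bm <- bin_sampling_masks(pat, bins$bin, 2)
  rec <- reconstruct_bin_images(corr, bm, sens, n_iter = 20)
  # the two bin images are displaced by the known inter-bin shift; measured
  # by cross-correlation of their coronal projections (robust to the
  # residual aliasing of the per-bin undersampled reconstructions)
  pr <- lapply(rec$images, function(im) apply(Mod(im), 1:2, sum))
  est <- estimate_translation_ncc(pr[[2]], pr[[1]], max_shift = 10,
                                  pixel_size = 1)
  shift_vox <- 8 / p$voxel_size
  expect_lt(abs(est["fh"] - shift_vox), 0.5)
  expect_lt(abs(est["rl"]), 0.5)
  # centroid moves in the same direction
  cen <- vapply(rec$images, function(im) {
    m <- apply(Mod(im), 2, sum)
    sum(seq_along(m) * m) / sum(m)
  }, numeric(1))
  expect_gt(cen[2] - cen[1], 0.5)
})

test_that("FFD registration: identity, rigid shift, smooth bump", {
  vol <- array(0, c(32, 32, 8)); vol[10:22, 10:22, 3:6] <- 1
  vol <- gauss_smooth(vol, 1.5)
  d0 <- register_ffd(vol, vol, voxel_size = 2)
  expect_lt(max(abs(d0)) / 2, 0.1)  # < 0.1 voxel
  # known 2-voxel shift: moving(x+u) = reference(x) needs u = +2 voxels
  mv <- array(0, c(32, 32, 8)); mv[(10:22) + 2, 10:22, 3:6] <- 1
  mv <- gauss_smooth(mv, 1.5)
  d1 <- register_ffd(mv, vol, voxel_size = 2)
  obj <- abs(vol) > 0.2
  expect_lt(abs(median(d1[, , , 1][obj]) / 2 - 2), 0.5)
  # smooth synthetic bump: recovered field halves the MSE
  g <- expand.grid(x = 1:32, y = 1:32, z = 1:8)
  bump <- 2.5 * exp(-((g$x - 16)^2 + (g$y - 16)^2) / 50)
  px <- array(g$x + bump, c(32, 32, 8))
  warped <- array(qcmr:::interp3(vol, as.vector(px), g$y, g$z), c(32, 32, 8))
  d2 <- register_ffd(warped, vol, voxel_size = 2)
  W <- qcmr:::warp_matrix(d2, 2)
  back <- array(as.vector(W %*% as.vector(warped)), c(32, 32, 8))
  mse0 <- mean((warped - vol)^2)
  mse1 <- mean((back - vol)^2)
  expect_lt(mse1, 0.5 * mse0)
})

test_that("encoding operator passes adjoint, linearity and projection checks", {
  shape <- c(16, 16, 8)
  sens <- make_coil_sensitivities(3, shape, seed = 4)
  pat <- generate_caspr_pattern(shape[2:3], accel = 2, seed = 6,
                                segments_per_hb = 8)
  tr <- simulate_motion_trace(pat$n_heartbeats, 6, seed = 3)
  bins <- assign_bins(tr$fh, 2)
  masks <- bin_sampling_masks(pat, bins$bin, 2)
  # one non-trivial deformation field
  withr_seed <- 9
  f <- array(0, c(shape, 3))
  f[, , , 1] <- 1.5
  fields <- list(NULL, structure(f, class = "qcmr_deformation"))
  op <- compose_encoding_operator(masks, sens, fields, voxel_size = 2)
  set.seed(withr_seed)
  for (rep in 1:5) {
    x <- array(complex(real = rnorm(prod(shape)), imaginary = rnorm(prod(shape))),
               shape)
    y <- array(complex(real = rnorm(prod(shape) * 3),
                       imaginary = rnorm(prod(shape) * 3)), c(shape, 3))
    cc <- sample(1:5, 1)
    Ex <- encode_forward(op, x, cc)
    Ehy <- encode_adjoint(op, y, cc)
    lhs <- sum(Conj(y) * Ex)
    rhs <- sum(Conj(Ehy) * x)
    expect_lt(Mod(lhs - rhs) / Mod(lhs), 1e-6)
    # linearity
    x2 <- array(complex(real = rnorm(prod(shape)),
                        imaginary = rnorm(prod(shape))), shape)
    E12 <- encode_forward(op, 2 * x - 3i * x2, cc)
    expect_lt(relerr(E12, 2 * Ex - 3i * encode_forward(op, x2, cc)), 1e-9)
    # masked energy never exceeds the unmasked chain, summed over bins
    full <- 0
    for (b in 1:2) {
      xb <- qcmr:::apply_warp(op$warps[[b]], x)
      for (co in 1:3) full <- full + sum(Mod(fftc(sens[, , , co] * xb))^2)
    }
    expect_lte(sum(Mod(Ex)^2), full + 1e-9)
  }
  # B = 1, identity field, full mask: E reduces to F S
  m1 <- array(1L, c(shape[2], shape[3], 1, 5))
  op1 <- compose_encoding_operator(m1, sens, list(NULL), voxel_size = 2)
  x <- array(complex(real = rnorm(prod(shape))), shape)
  y1 <- encode_forward(op1, x, 1)
  for (co in 1:3)
    expect_lt(relerr(y1[, , , co], fftc(sens[, , , co] * x)), 1e-9)
})
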