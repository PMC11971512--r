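# HD-PROST: patch selection, HOSVD denoising, CG data consistency, and the
# full ADMM loop.

small_config <- function(...) hdprost_config(search_window = 8, patch_size = 3,
                                             n_similar = 6, patch_offset = 2,
                                             ...)

test_that("patch selection matches the exhaustive-search oracle", {
  cfg <- small_config()
  set.seed(42)
  vol <- array(rnorm(16^3), c(16, 16, 16))
  for (v in list(c(1, 1, 1), c(5, 7, 3), c(13, 13, 13), c(7, 11, 9))) {
    got <- patch_select(vol, v, cfg)
    want <- oracle_patch_search(vol, v, cfg)
    expect_identical(as.integer(got$corners), as.integer(want))
    # the reference patch itself always selected at distance zero
    lin_v <- v[1] + (v[2] - 1) * 16 + (v[3] - 1) * 256
    expect_true(lin_v %in% got$corners)
    expect_equal(min(got$dist), 0)
  }
  # constant image: all distances zero, ties resolved by scan order
  cvol <- array(1, c(12, 12, 12))
  sel <- patch_select(cvol, c(5, 5, 5), cfg)
  expect_true(all(sel$dist == 0))
  expect_true(all(apply(sel$tensor, 2, function(p) all(p == sel$tensor[, 1, ]))))
})

test_that("HOSVD denoising: identity cases and noise reduction", {
  set.seed(7)
  # rank-(1,1,1) tensor is reproduced
  a <- complex(real = rnorm(27), imaginary = rnorm(27))
  b <- complex(real = rnorm(6), imaginary = rnorm(6))
  cc <- complex(real = rnorm(4), imaginary = rnorm(4))
  T1 <- outer(outer(a, b), cc)
  expect_lt(relerr(hosvd_denoise(T1, 0.2), T1), 1e-9)
  # lam = 0 is the identity on any tensor
  Tr <- array(complex(real = rnorm(27 * 6 * 4), imaginary = rnorm(27 * 6 * 4)),
              c(27, 6, 4))
  expect_lt(relerr(hosvd_denoise(Tr, 0), Tr), 1e-9)
  # noisy low-rank tensor: error to the clean tensor drops by >= 30%
  U1 <- matrix(complex(real = rnorm(27 * 2), imaginary = rnorm(27 * 2)), 27)
  U2 <- matrix(complex(real = rnorm(6 * 2), imaginary = rnorm(6 * 2)), 6)
  U3 <- matrix(complex(real = rnorm(4 * 2), imaginary = rnorm(4 * 2)), 4)
  core <- array(complex(real = rnorm(8), imaginary = rnorm(8)), c(2, 2, 2))
  clean <- qcmr:::ttm(qcmr:::ttm(qcmr:::ttm(core, U1, 1), U2, 2), U3, 3)
  noise <- 0.05 * max(Mod(clean)) *
    array(complex(real = rnorm(27 * 6 * 4), imaginary = rnorm(27 * 6 * 4)),
          c(27, 6, 4))
  den <- hosvd_denoise(clean + noise, 0.1)
  expect_lt(relerr(den, clean), 0.7 * relerr(clean + noise, clean))
})

test_that("overlap aggregation with lam = 0 reproduces the image (partition)", {
  cfg <- small_config()
  shape <- c(12, 12, 8)
  set.seed(3)
  X10 <- matrix(complex(real = rnorm(prod(shape) * 2),
                        imaginary = rnorm(prod(shape) * 2)), prod(shape), 2)
  plan <- qcmr:::build_patch_plan(X10, shape, cfg)
  PX <- qcmr:::patches_extract(X10, plan)
  Z <- qcmr:::patches_aggregate(PX, plan, prod(shape))
  expect_true(all(plan$counts > 0))
  expect_lt(relerr(Z / plan$counts, X10), 1e-9)
})

test_that("data consistency: mu = 0 identity case and dense-solve oracle", {
  # full sampling, identity motion, mu = 0: coil-combined inverse transform
  shape <- c(8, 8, 4)
  sens <- make_coil_sensitivities(3, shape, seed = 5)
  m1 <- array(1L, c(shape[2], shape[3], 1, 1))
  op <- compose_encoding_operator(m1, sens, list(NULL))
  set.seed(8)
  img <- array(complex(real = rnorm(prod(shape)),
                       imaginary = rnorm(prod(shape))), shape)
  K <- array(0i, c(shape, 3, 1, 1))
  for (co in 1:3) K[, , , co, 1, 1] <- fftc(sens[, , , co] * img)
  cfg <- hdprost_config(sense_iters = 10)
  X <- data_consistency_step(op, K, config = cfg)
  expect_lt(relerr(array(X[, , , 1, 1], shape), img), 1e-5)
  # CG objective is non-increasing
  r <- attr(X, "resid")[[1]]
  expect_false(is.unsorted(rev(r)))

  # undersampled 8x8x1 toy: CG equals the explicit dense least-squares solve
  shape1 <- c(8, 8, 1)
  sens1 <- make_coil_sensitivities(2, shape1, seed = 9)
  mask <- array(0L, c(8, 1, 1, 1))
  mask[c(1, 2, 4, 5, 8), 1, 1, 1] <- 1L
  op1 <- compose_encoding_operator(mask, sens1, list(NULL))
  x_true <- array(complex(real = rnorm(64), imaginary = rnorm(64)), shape1)
  K1 <- array(0i, c(shape1, 2, 1, 1))
  for (co in 1:2) K1[, , , co, 1, 1] <-
    qcmr:::expand_mask(matrix(mask[, , 1, 1], 8, 1), 8) *
    fftc(array(sens1[, , , co], shape1) * x_true)
  # dense forward matrix, built column by column
  n <- 64
  A <- matrix(0i, 2 * n, n)
  for (j in 1:n) {
    ej <- array(0i, shape1); ej[j] <- 1
    A[, j] <- as.vector(encode_forward(op1, ej, 1))
  }
  rhsv <- as.vector(K1[, , , , 1, 1])
  x_dense <- solve(Conj(t(A)) %*% A + 1e-12 * diag(n), Conj(t(A)) %*% rhsv)
  cfg2 <- hdprost_config(sense_iters = 200)
  X1 <- data_consistency_step(op1, K1, config = cfg2, tol = 1e-12)
  expect_lt(relerr(as.vector(X1[, , , 1, 1]), as.vector(x_dense)), 1e-6)
})

test_that("HD-PROST recovers fully sampled data and improves undersampled", {
  p <- small_phantom(shape = c(24, 24, 8))
  acq <- acq_spec()
  sens <- make_coil_sensitivities(3, p$shape, seed = 2)
  cfg <- small_config(outer_iters = 3, sense_iters = 8)

  # fully sampled, no noise: X within 1e-3 of the true contrast images
  pat1 <- generate_caspr_pattern(p$shape[2:3], accel = 1, seed = 4,
                                 segments_per_hb = 12)
  sim1 <- simulate_acquisition(p, acq, pat1, sens)
  m1 <- bin_sampling_masks(pat1, rep(1L, pat1$n_heartbeats), 1)
  op1 <- compose_encoding_operator(m1, sens, list(NULL))
  rec1 <- hd_prost_reconstruct(sim1$kspace$data, op1, cfg)
  for (cc in 1:5) for (e in 1:2)
    expect_lt(relerr(array(rec1$X[, , , e, cc], p$shape),
                     sim1$images[, , , e, cc]), 1e-3)

  # 6x undersampled, noisy: NRMSE reduced by >= 40% vs zero-filled adjoint,
  # and the data-consistency residual does not grow over outer iterations
  p6 <- make_vial_phantom(3, tissue_params(c(600, 1095, 1500), c(44, 56, 80),
                                           c(29, 44, 62)),
                          shape = c(32, 32, 8), vial_radius = 5,
                          ring_radius = 9)
  sens6 <- make_coil_sensitivities(6, p6$shape, seed = 2)
  pat6 <- generate_caspr_pattern(p6$shape[2:3], accel = 6, seed = 4)
  sim6 <- simulate_acquisition(p6, acq, pat6, sens6, noise_sigma = 3e-4,
                               seed = 13)
  m6 <- bin_sampling_masks(pat6, rep(1L, pat6$n_heartbeats), 1)
  op6 <- compose_encoding_operator(m6, sens6, list(NULL))
  cfg6 <- hdprost_config(search_window = 10, patch_size = 5, n_similar = 10,
                         patch_offset = 3, outer_iters = 5, sense_iters = 5)
  rec6 <- hd_prost_reconstruct(sim6$kspace$data, op6, cfg6)
  err_rec <- err_adj <- 0
  for (cc in 1:5) for (e in 1:2) {
    truth <- sim6$images[, , , e, cc]
    adj <- encode_adjoint(op6, array(sim6$kspace$data[, , , , e, cc],
                                     c(p6$shape, 6)), cc)
    err_rec <- err_rec + relerr(array(rec6$X[, , , e, cc], p6$shape), truth)
    err_adj <- err_adj + relerr(adj, truth)
  }
  expect_lt(err_rec, 0.6 * err_adj)
  # monitored descent: after the dual-variable transient peaks, the
  # data-consistency residual decreases monotonically and ends well below
  # the peak
  h <- rec6$residual_history[-1]   # drop the SENSE pilot
  pk <- which.max(h)
  expect_lt(pk, length(h))
  expect_false(is.unsorted(rev(h[pk:length(h)])))
  expect_lt(h[length(h)], 0.9 * h[pk])

  # determinism: no RNG inside the reconstruction
  rec6b <- hd_prost_reconstruct(sim6$kspace$data, op6, cfg6)
  expect_identical(rec6$X, rec6b$X)

  # global-phase equivariance
  recp <- hd_prost_reconstruct(sim6$kspace$data * exp(0.7i), op6, cfg6)
  expect_lt(relerr(recp$X, rec6$X * exp(0.7i)), 1e-6)
})
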