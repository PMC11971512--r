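# Patch-based higher-order low-rank reconstruction (HD-PROST):
# ADMM on  ||EX - K||_F^2 + lambda sum_v ||T_v||_* + (mu/2) sum_v
# ||T_v - P_v(X) - Y_v/mu||_F^2,
# alternating (i) CG data consistency, (ii) patch-tensor HOSVD denoising with
# hard core thresholding, (iii) dual update. P_v extracts, for each voxel v
# of a stride grid, the n_similar most similar 3D patches (L2 distance on
# the contrast-averaged magnitude) across all contrast-echo images, giving a
# 3rd-order tensor [patch voxels x similar patches x contrasts].

#' HD-PROST reconstruction settings
#'
#' @param lam Nuclear-norm regularization weight; the HOSVD core is
#'   hard-thresholded at `lam * max|core|`. Default 0.04.
#' @param mu ADMM coupling parameter. Default 0.1.
#' @param outer_iters Outer ADMM iterations. Default 5.
#' @param sense_iters CG iterations of the data-consistency solve. Default 5.
#' @param search_window Similar-patch search window (voxels per side).
#'   Default 20.
#' @param patch_size Patch side length (voxels). Default 5.
#' @param n_similar Number of similar patches per tensor. Default 20.
#' @param patch_offset Stride of the patch grid. Default 4.
#' @return A `qcmr_hdprost_config`.
#' @export
hdprost_config <- function(lam = 0.04, mu = 0.1, outer_iters = 5L,
                           sense_iters = 5L, search_window = 20L,
                           patch_size = 5L, n_similar = 20L,
                           patch_offset = 4L) {
  vals <- c(lam = lam, mu = mu, outer_iters = outer_iters,
            sense_iters = sense_iters, search_window = search_window,
            patch_size = patch_size, n_similar = n_similar,
            patch_offset = patch_offset)
  if (any(!is.finite(vals)) || any(vals[-1] <= 0) || lam < 0)
    stop("invalid HD-PROST configuration: all parameters must be positive")
  if (patch_size > search_window)
    stop("patch_size must not exceed search_window")
  structure(as.list(vals), class = "qcmr_hdprost_config")
}

# Stride grid of patch corners along one dimension (always includes the last
# valid corner so patches cover the whole extent).
corner_grid <- function(n, ps, off) {
  last <- n - ps + 1L
  if (last < 1L) stop("patch larger than volume")
  g <- seq(1L, last, by = off)
  if (g[length(g)] != last) g <- c(g, last)
  as.integer(g)
}

# Precomputed geometry for batched patch selection on a volume `shape`.
patch_geometry <- function(shape, config) {
  ps <- config$patch_size
  hw <- (config$search_window - ps) %/% 2L
  grids <- lapply(shape, corner_grid, ps = ps, off = config$patch_offset)
  corners <- as.matrix(expand.grid(x = grids[[1]], y = grids[[2]],
                                   z = grids[[3]]))
  po <- expand.grid(dx = 0:(ps - 1), dy = 0:(ps - 1), dz = 0:(ps - 1))
  poff <- po$dx + po$dy * shape[1] + po$dz * shape[1] * shape[2]
  cand_range <- function(v, n) {
    lo <- max(1L, v - hw)
    hi <- min(n - ps + 1L, v + hw)
    lo:hi
  }
  list(shape = shape, ps = ps, hw = hw, corners = corners, poff = poff,
       cand_range = cand_range,
       lin = function(xyz) xyz[, 1] + (xyz[, 2] - 1L) * shape[1] +
         (xyz[, 3] - 1L) * shape[1] * shape[2])
}

# Select the n_similar most similar patch corners for one reference corner.
# `simvol` is the contrast-averaged magnitude volume. Ties are broken by
# window scan order (column-major over the candidate window).
select_similar <- function(simvol, geom, v, n_similar) {
  shape <- geom$shape
  cx <- geom$cand_range(v[1], shape[1])
  cy <- geom$cand_range(v[2], shape[2])
  cz <- geom$cand_range(v[3], shape[3])
  cand <- as.matrix(expand.grid(x = cx, y = cy, z = cz))
  clin <- geom$lin(cand)
  idx <- outer(geom$poff, clin, "+")
  ref <- simvol[geom$poff + geom$lin(matrix(v, 1))]
  d <- colSums((matrix(simvol[idx], nrow = length(geom$poff)) - ref)^2)
  sel <- order(d, method = "radix")[seq_len(min(n_similar, length(d)))]
  list(corners = clin[sel], dist = d[sel])
}

#' Extract the similar-patch tensor for one stride-grid voxel
#'
#' Finds the `n_similar` patches most similar to the patch anchored at `v`
#' (smallest L2 distance on the contrast-averaged magnitude within the
#' search window, the reference patch itself always included at distance 0)
#' and stacks them over all contrast images into a 3rd-order tensor.
#'
#' @param X Complex array `[nx x ny x nz x C]` (or a 3D volume, C = 1).
#' @param v Patch corner (3 integers on the stride grid).
#' @param config An [hdprost_config()].
#' @return List with `tensor` (`[patch_voxels x n_similar x C]`), `corners`
#'   (linear corner indices) and `dist` (squared L2 distances).
#' @export
patch_select <- function(X, v, config = hdprost_config()) {
  if (length(dim(X)) == 3L) dim(X) <- c(dim(X), 1L)
  shape <- dim(X)[1:3]; C <- dim(X)[4]
  geom <- patch_geometry(shape, config)
  simvol <- array(0, shape)
  for (cc in seq_len(C)) simvol <- simvol + Mod(X[, , , cc])
  simvol <- simvol / C
  sel <- select_similar(simvol, geom, as.integer(v), config$n_similar)
  nv <- prod(shape)
  Xm <- matrix(X, nv, C)
  idx <- outer(geom$poff, sel$corners, "+")
  tensor <- array(Xm[as.vector(idx), ], c(length(geom$poff), length(sel$corners), C))
  list(tensor = tensor, corners = sel$corners, dist = sel$dist)
}

# ---- HOSVD ------------------------------------------------------------------

unfold <- function(Tn, mode) {
  d <- dim(Tn)
  perm <- c(mode, setdiff(1:3, mode))
  matrix(aperm(Tn, perm), d[mode])
}

ttm <- function(Tn, M, mode) {  # tensor x_mode M (complex-safe)
  d <- dim(Tn)
  perm <- c(mode, setdiff(1:3, mode))
  a <- matrix(aperm(Tn, perm), d[mode])
  out <- M %*% a
  dn <- c(nrow(M), d[perm[2]], d[perm[3]])
  aperm(array(out, dn), order(perm))
}

# Mode singular vectors via the Hermitian eigendecomposition of the small
# Gram matrix of the unfolding (equivalent to the left factor of its SVD,
# several times cheaper for wide unfoldings).
mode_basis <- function(M) {
  H <- M %*% Conj(t(M))
  eigen(H, symmetric = TRUE)$vectors
}

#' Higher-order SVD denoising of a patch tensor
#'
#' Computes the HOSVD (mode-wise singular bases of the three unfoldings),
#' hard-thresholds core coefficients with magnitude below
#' `lam * max|core|`, and reconstructs the tensor. `lam = 0` is the
#' identity.
#'
#' @param tensor 3rd-order (complex) tensor.
#' @param lam Relative hard-threshold level.
#' @return The denoised tensor.
#' @export
hosvd_denoise <- function(tensor, lam) {
  U <- lapply(1:3, function(m) mode_basis(unfold(tensor, m)))
  core <- ttm(ttm(ttm(tensor, Conj(t(U[[1]])), 1L), Conj(t(U[[2]])), 2L),
              Conj(t(U[[3]])), 3L)
  if (lam > 0) {
    thr <- lam * max(Mod(core))
    core[Mod(core) < thr] <- 0
  }
  ttm(ttm(ttm(core, U[[1]], 1L), U[[2]], 2L), U[[3]], 3L)
}

# ---- batched patch machinery for the ADMM loop ------------------------------

# Fix the patch selection (corners per stride-grid voxel + coverage counts)
# from a pilot image; selection is then held fixed across ADMM iterations so
# the dual variable stays consistent with one P_v.
build_patch_plan <- function(X10, shape, config) {
  C <- ncol(X10)
  geom <- patch_geometry(shape, config)
  simvol <- array(rowMeans(Mod(X10)), shape)
  ncent <- nrow(geom$corners)
  nsim <- config$n_similar
  corners <- matrix(0L, nsim, ncent)
  for (ci in seq_len(ncent)) {
    sel <- select_similar(simvol, geom, geom$corners[ci, ], nsim)
    corners[, ci] <- sel$corners
  }
  counts <- numeric(prod(shape))
  for (ci in seq_len(ncent)) for (j in seq_len(nsim)) {
    lin <- geom$poff + corners[j, ci]
    counts[lin] <- counts[lin] + 1
  }
  list(geom = geom, corners = corners, counts = counts,
       ncent = ncent, nsim = nsim, C = C, pvox = length(geom$poff))
}

# P(X): extract all patch tensors -> [pvox, nsim, C, ncenters]
patches_extract <- function(X10, plan) {
  out <- array(complex(real = 0), c(plan$pvox, plan$nsim, plan$C, plan$ncent))
  for (ci in seq_len(plan$ncent)) {
    idx <- outer(plan$geom$poff, plan$corners[, ci], "+")
    out[, , , ci] <- array(X10[as.vector(idx), ], c(plan$pvox, plan$nsim, plan$C))
  }
  out
}

# P^T(T): scatter-add all patch tensors back -> [nvox x C] (unnormalized)
patches_aggregate <- function(Tn, plan, nvox) {
  Z <- matrix(complex(real = 0), nvox, plan$C)
  for (ci in seq_len(plan$ncent)) for (j in seq_len(plan$nsim)) {
    lin <- plan$geom$poff + plan$corners[j, ci]
    Z[lin, ] <- Z[lin, ] + Tn[, j, , ci]
  }
  Z
}

#' CG data-consistency update of the ADMM
#'
#' Approximately solves
#' `argmin_X ||EX - K||^2 + (mu/2) sum_v ||T_v - P_v(X) - Y_v/mu||^2`
#' by conjugate gradient on the normal equations, one contrast-echo image at
#' a time, warm-started at `X_init`. With `T = NULL` the patch term is
#' dropped (plain iterative SENSE).
#'
#' @param E A `qcmr_encop`.
#' @param K Multi-coil k-space `[nx x ny x nz x ncoil x 2 x n_contrasts]`.
#' @param T_patch,Y Patch tensors and dual `[pvox x nsim x C x ncent]`, or
#'   `NULL`.
#' @param config An [hdprost_config()].
#' @param X_init Warm start `[nx x ny x nz x 2 x n_contrasts]` or `NULL`.
#' @param plan Patch plan (internal; required when `T_patch` is given).
#' @param tol CG relative-residual tolerance. Default 1e-6.
#' @return Updated `X` with attribute `resid` (per-image CG histories).
#' @export
data_consistency_step <- function(E, K, T_patch = NULL, Y = NULL, config,
                                  X_init = NULL, plan = NULL, tol = 1e-6) {
  shape <- E$shape
  necho <- dim(K)[5]; nc <- dim(K)[6]
  X <- if (is.null(X_init)) array(complex(real = 0), c(shape, necho, nc)) else X_init
  mu <- if (is.null(T_patch)) 0 else config$mu
  nvox <- prod(shape)
  Z <- NULL; counts <- NULL
  if (mu > 0) {
    if (is.null(plan)) stop("patch plan required when T is supplied")
    Z <- patches_aggregate(T_patch - Y / mu, plan, nvox)
    counts <- plan$counts
  }
  resid <- vector("list", necho * nc)
  for (cc in seq_len(nc)) for (e in seq_len(necho)) {
    ce <- (cc - 1L) * necho + e
    Kce <- array(K[, , , , e, cc], c(shape, dim(K)[4]))
    rhs <- encode_adjoint(E, Kce, cc)
    if (mu > 0) rhs <- rhs + (mu / 2) * array(Z[, ce], shape)
    normal_op <- function(x) {
      out <- encode_adjoint(E, encode_forward(E, x, cc), cc)
      if (mu > 0) out <- out + (mu / 2) * array(counts, shape) * x
      out
    }
    x0 <- array(X[, , , e, cc], shape)
    sol <- cg_solve(normal_op, rhs, x0 = x0, n_iter = config$sense_iters,
                    tol = tol)
    if (length(sol$resid) > 1 &&
        sol$resid[length(sol$resid)] > 10 * sol$resid[1])
      stop("data-consistency CG diverged (residual grew more than 10x)")
    X[, , , e, cc] <- sol$x
    resid[[ce]] <- sol$resid
  }
  attr(X, "resid") <- resid
  X
}

#' HD-PROST reconstruction of the multi-contrast volumes
#'
#' Runs the full ADMM: iterative-SENSE initialization, then `outer_iters`
#' rounds of (i) CG data consistency, (ii) HOSVD denoising of all
#' stride-grid patch tensors with overlap-averaged reaggregation implied by
#' the coupling term, and (iii) dual update `Y <- Y + mu (P(X) - T)`. The
#' patch selection is computed once from the SENSE pilot and held fixed.
#'
#' @param K Multi-coil k-space `[nx x ny x nz x ncoil x 2 x n_contrasts]`
#'   (zero where unsampled).
#' @param E A `qcmr_encop`.
#' @param config An [hdprost_config()].
#' @param verbose Print per-iteration residuals.
#' @return A `qcmr_recon`: list with `X` (`[nx x ny x nz x 2 x n_contrasts]`
#'   complex images) and `residual_history` (data-consistency residual
#'   `||EX - K||_F` after initialization and after each outer iteration).
#' @export
hd_prost_reconstruct <- function(K, E, config = hdprost_config(),
                                 verbose = FALSE) {
  shape <- E$shape
  necho <- dim(K)[5]; nc <- dim(K)[6]
  nvox <- prod(shape)
  C <- necho * nc

  dc_resid <- function(X) {
    s <- 0
    for (cc in seq_len(nc)) for (e in seq_len(necho)) {
      d <- encode_forward(E, array(X[, , , e, cc], shape), cc) -
        array(K[, , , , e, cc], c(shape, dim(K)[4]))
      s <- s + sum(Mod(d)^2)
    }
    sqrt(s)
  }

  # iterative-SENSE pilot
  X <- data_consistency_step(E, K, config = config, X_init = NULL)
  history <- dc_resid(X)
  if (verbose) message(sprintf("pilot: ||EX-K|| = %.4g", history))

  X10 <- matrix(X, nvox, C)
  plan <- build_patch_plan(X10, shape, config)
  T_patch <- patches_extract(X10, plan)
  for (ci in seq_len(plan$ncent))
    T_patch[, , , ci] <- hosvd_denoise(array(T_patch[, , , ci],
                                             dim(T_patch)[1:3]), config$lam)
  Y <- array(complex(real = 0), dim(T_patch))

  for (it in seq_len(config$outer_iters)) {
    X <- data_consistency_step(E, K, T_patch, Y, config, X_init = X, plan = plan)
    PX <- patches_extract(matrix(X, nvox, C), plan)
    G <- PX + Y / config$mu
    for (ci in seq_len(plan$ncent))
      T_patch[, , , ci] <- hosvd_denoise(array(G[, , , ci],
                                               dim(G)[1:3]), config$lam)
    Y <- Y + config$mu * (PX - T_patch)
    history <- c(history, dc_resid(X))
    if (verbose) message(sprintf("iter %d: ||EX-K|| = %.4g", it,
                                 history[length(history)]))
  }
  structure(list(X = X, residual_history = history, config = config),
            class = "qcmr_recon")
}

#' @export
print.qcmr_recon <- function(x, ...) {
  d <- dim(x$X)
  cat(sprintf("qcmr reconstruction: %dx%dx%d, %d echoes x %d contrasts\n",
              d[1], d[2], d[3], d[4], d[5]))
  cat("  ||EX-K|| history:", paste(signif(x$residual_history, 4),
                                   collapse = " -> "), "\n")
  invisible(x)
}
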