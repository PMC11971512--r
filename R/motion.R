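# Navigator-based translational motion estimation, respiratory binning,
# k-space translational correction, per-bin SENSE reconstruction, B-spline
# free-form-deformation registration, and assembly of the motion-compensated
# encoding operator  E(c) = sum_b A_b(c) F S U_b.

#' Estimate the in-plane translation between two navigator images
#'
#' Maximizes the normalized cross-correlation over integer shifts within
#' `max_shift`, then refines each axis to sub-pixel precision with a 3-point
#' parabolic fit. The returned shift is the displacement of `inav` relative
#' to `reference` (positive = object moved towards larger indices); exact
#' ties are broken towards the smaller |shift|.
#'
#' @param inav,reference 2D real images of identical shape (dim 1 = RL,
#'   dim 2 = FH).
#' @param max_shift Search range in mm (each axis, both signs).
#' @param pixel_size Pixel size in mm; defaults to the `pixel_size`
#'   attribute of `inav`, else 1.
#' @return Named numeric `c(rl=, fh=)` in mm.
#' @export
estimate_translation_ncc <- function(inav, reference, max_shift = 20,
                                     pixel_size = NULL) {
  if (!all(dim(inav) == dim(reference))) stop("images must have the same shape")
  if (is.null(pixel_size))
    pixel_size <- attr(inav, "pixel_size") %||% 1
  if (sd(inav) == 0 || sd(reference) == 0)
    stop("flat image: cannot estimate translation")
  nx <- nrow(inav); ny <- ncol(inav)
  m <- max(1L, min(floor(max_shift / pixel_size), nx - 2L, ny - 2L))
  shifts <- expand.grid(a = -m:m, b = -m:m)
  shifts <- shifts[order(shifts$a^2 + shifts$b^2, abs(shifts$a), abs(shifts$b)), ]
  ncc_at <- function(a, b) {
    i1 <- max(1L, 1L + a); i2 <- min(nx, nx + a)
    j1 <- max(1L, 1L + b); j2 <- min(ny, ny + b)
    if (i2 < i1 || j2 < j1) return(-Inf)
    u <- inav[i1:i2, j1:j2]
    v <- reference[(i1 - a):(i2 - a), (j1 - b):(j2 - b)]
    su <- sd(u); sv <- sd(v)
    if (su == 0 || sv == 0) return(-Inf)
    mean((u - mean(u)) * (v - mean(v))) / (su * sv)
  }
  ncc <- matrix(-Inf, 2L * m + 1L, 2L * m + 1L)  # [a + m + 1, b + m + 1]
  best <- c(0L, 0L); bestv <- -Inf
  for (q in seq_len(nrow(shifts))) {
    a <- shifts$a[q]; b <- shifts$b[q]
    v <- ncc_at(a, b)
    ncc[a + m + 1L, b + m + 1L] <- v
    if (v > bestv) { bestv <- v; best <- c(a, b) }
  }
  refine <- function(cm1, c0, cp1) {
    den <- cm1 - 2 * c0 + cp1
    if (!is.finite(den) || den >= 0) return(0)
    d <- 0.5 * (cm1 - cp1) / den
    max(-0.5, min(0.5, d))
  }
  da <- db <- 0
  ia <- best[1] + m + 1L; ib <- best[2] + m + 1L
  if (ia > 1L && ia < 2L * m + 1L)
    da <- refine(ncc[ia - 1L, ib], ncc[ia, ib], ncc[ia + 1L, ib])
  if (ib > 1L && ib < 2L * m + 1L)
    db <- refine(ncc[ia, ib - 1L], ncc[ia, ib], ncc[ia, ib + 1L])
  c(rl = (best[1] + da) * pixel_size, fh = (best[2] + db) * pixel_size)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assign heartbeats to respiratory bins
#'
#' Equal-count (quantile) binning of the foot-head displacement trace. The
#' reference bin is the end-expiration bin, taken as the bin whose median
#' FH displacement is smallest in magnitude.
#'
#' @param fh_trace Numeric FH displacement per heartbeat (mm).
#' @param n_bins Number of bins. Default 4.
#' @return List with `bin` (integer per heartbeat), `centers` (median FH per
#'   bin, mm; `NA` for empty bins) and `reference` (index of the reference
#'   bin).
#' @export
assign_bins <- function(fh_trace, n_bins = 4L) {
  n <- length(fh_trace)
  if (n == 0L) stop("empty trace")
  if (diff(range(fh_trace)) == 0) {
    bin <- rep(1L, n)
  } else {
    bin <- as.integer(ceiling(rank(fh_trace, ties.method = "first") * n_bins / n))
  }
  centers <- vapply(seq_len(n_bins),
                    function(b) if (any(bin == b)) median(fh_trace[bin == b]) else NA_real_,
                    numeric(1))
  reference <- which.min(abs(centers))
  list(bin = bin, centers = centers, reference = reference)
}

#' Correct the k-space data of each heartbeat to its bin centre position
#'
#' Removes each sample's acquired translation down to the residual of its
#' respiratory bin centre: sample data acquired at heartbeat shift `d` in a
#' bin centred at `d_c` are multiplied by the linear phase that displaces
#' the underlying image by `-(d - d_c)` (RL and FH components), so all data
#' within a bin correspond to the common bin-centre position. The phase has
#' unit magnitude, so k-space magnitudes are unchanged.
#'
#' @param kspace A `qcmr_kspace`.
#' @param shifts `[n_heartbeats x 2]` matrix of (rl, fh) shifts in mm (e.g.
#'   navigator estimates).
#' @param bins Integer bin per heartbeat, or `NULL` to correct everything to
#'   position zero.
#' @param bin_centers `[n_bins x 2]` (rl, fh) bin centres in mm; default the
#'   per-bin medians of `shifts`.
#' @return The corrected `qcmr_kspace`.
#' @export
correct_translation_kspace <- function(kspace, shifts, bins = NULL,
                                       bin_centers = NULL) {
  shifts <- as.matrix(shifts)
  nhb <- nrow(shifts)
  if (is.null(bins)) {
    bins <- rep(1L, nhb)
    bin_centers <- matrix(0, 1, 2)
  } else if (is.null(bin_centers)) {
    nb <- max(bins)
    bin_centers <- t(vapply(seq_len(nb), function(b) {
      if (!any(bins == b)) return(c(0, 0))
      c(median(shifts[bins == b, 1]), median(shifts[bins == b, 2]))
    }, numeric(2)))
  }
  shape <- kspace$shape
  kx <- kfreq(shape[1]) / kspace$voxel_size
  ky <- kfreq(shape[2]) / kspace$voxel_size
  nc <- dim(kspace$data)[6]
  ncoil <- dim(kspace$data)[4]
  for (cc in seq_len(nc)) {
    sel <- which(kspace$masks[, , cc] == 1L, arr.ind = TRUE)
    for (q in seq_len(nrow(sel))) {
      iy <- sel[q, 1]; iz <- sel[q, 2]
      hb <- kspace$hb_index[iy, iz, cc]
      if (hb == 0L) stop("missing heartbeat tag for sampled cell")
      if (hb > nhb) stop("heartbeat tag outside the shift table")
      d <- shifts[hb, ] - bin_centers[bins[hb], ]
      ph <- exp(2i * pi * (kx * d[1] + ky[iy] * d[2]))
      kspace$data[, iy, iz, , , cc] <- kspace$data[, iy, iz, , , cc] * ph
    }
  }
  attr(kspace, "translation_corrected") <- TRUE
  kspace
}

# ---- conjugate gradient on the normal equations -----------------------------

# CG for a Hermitian positive (semi)definite operator `apply_A`. Returns the
# solution and the residual-norm history.
cg_solve <- function(apply_A, b, x0 = NULL, n_iter = 10L, tol = 1e-6) {
  x <- if (is.null(x0)) array(complex(real = 0), dim(b) %||% length(b)) else x0
  r <- b - apply_A(x)
  p <- r
  rs <- sum(Mod(r)^2)
  b0 <- sqrt(sum(Mod(b)^2))
  hist <- sqrt(rs)
  for (it in seq_len(n_iter)) {
    if (sqrt(rs) <= tol * max(b0, .Machine$double.eps)) break
    Ap <- apply_A(p)
    alpha <- rs / Re(sum(Conj(p) * Ap))
    if (!is.finite(alpha)) break
    x <- x + alpha * p
    r <- r - alpha * Ap
    rs_new <- sum(Mod(r)^2)
    hist <- c(hist, sqrt(rs_new))
    p <- r + (rs_new / rs) * p
    rs <- rs_new
  }
  list(x = x, resid = hist)
}

expand_mask <- function(mask, nx) array(rep(as.numeric(mask), each = nx),
                                        c(nx, dim(mask)))

#' Iterative SENSE reconstruction of the per-bin images
#'
#' Conjugate-gradient SENSE on one contrast/echo of the binned,
#' translation-corrected k-space, solved independently per respiratory bin.
#' With `soft_weight > 0`, samples of neighbouring bins are included at that
#' weight (soft binning).
#'
#' @param kspace A (translation-corrected) `qcmr_kspace`.
#' @param bin_masks `[ny x nz x n_bins x n_contrasts]` from
#'   [bin_sampling_masks()].
#' @param sens Coil sensitivities.
#' @param contrast,echo Which contrast/echo drives the bin images (default
#'   contrast 4, the T2-prepared bright-blood volume, echo 2, in-phase).
#' @param n_iter,tol CG iteration budget and relative residual tolerance.
#' @param soft_weight Weight in (0,1) for neighbouring-bin samples; 0 = hard
#'   binning.
#' @return List with `images` (list of complex volumes per bin) and
#'   `resid` (list of CG residual histories).
#' @export
reconstruct_bin_images <- function(kspace, bin_masks, sens, contrast = 4L,
                                   echo = 2L, n_iter = 15L, tol = 1e-6,
                                   soft_weight = 0) {
  shape <- kspace$shape
  nx <- shape[1]
  n_bins <- dim(bin_masks)[3]
  K <- kspace$data[, , , , echo, contrast, drop = FALSE]
  dim(K) <- c(shape, dim(kspace$data)[4])
  ncoil <- dim(K)[4]
  images <- vector("list", n_bins)
  resid <- vector("list", n_bins)
  for (b in seq_len(n_bins)) {
    own <- matrix(bin_masks[, , b, contrast], dim(bin_masks)[1],
                  dim(bin_masks)[2])
    if (sum(own) == 0L) stop("empty bin ", b, ": no samples to reconstruct")
    w <- own
    if (soft_weight > 0) {
      for (nb in c(b - 1L, b + 1L)) {
        if (nb >= 1L && nb <= n_bins)
          w <- w + soft_weight * bin_masks[, , nb, contrast]
      }
      w <- pmin(w, 1)
    }
    wex <- expand_mask(w, nx)
    sl <- lapply(seq_len(ncoil), function(co) array(sens[, , , co], shape))
    normal_op <- function(x) {
      out <- array(complex(real = 0), shape)
      for (co in seq_len(ncoil)) {
        k <- fftc(sl[[co]] * x) * wex
        out <- out + Conj(sl[[co]]) * ifftc(k)
      }
      out
    }
    rhs <- array(complex(real = 0), shape)
    for (co in seq_len(ncoil))
      rhs <- rhs + Conj(sl[[co]]) * ifftc(wex * array(K[, , , co], shape))
    sol <- cg_solve(normal_op, rhs, n_iter = n_iter, tol = tol)
    images[[b]] <- sol$x
    resid[[b]] <- sol$resid
  }
  list(images = images, resid = resid)
}

# ---- B-spline free-form deformation registration ----------------------------

bspline3 <- function(t) {
  a <- abs(t)
  ifelse(a < 1, (4 - 6 * a^2 + 3 * a^3) / 6,
         ifelse(a < 2, (2 - a)^3 / 6, 0))
}

# Dense [n_points x n_controls] cubic B-spline basis for points `x` (mm) on
# a uniform control lattice of spacing `s` (mm) starting at `x0`.
bspline_basis <- function(x, s, x0, nc) {
  B <- matrix(0, length(x), nc)
  for (i in seq_len(nc)) B[, i] <- bspline3((x - (x0 + (i - 1) * s)) / s)
  B
}

# Multiply a 3D array by a matrix along one dimension.
tmult <- function(arr, M, dim) {
  d <- dim(arr)
  perm <- c(dim, setdiff(1:3, dim))
  a <- aperm(arr, perm)
  dim(a) <- c(d[dim], prod(d[-dim]))
  out <- M %*% a
  dim(out) <- c(nrow(M), d[perm[2]], d[perm[3]])
  aperm(out, order(perm))
}

# Trilinear interpolation of `img` at voxel coordinates (px, py, pz),
# clamped to the volume. Returns a vector in voxel scan order.
interp3 <- function(img, px, py, pz) {
  d <- dim(img)
  px <- pmin(pmax(px, 1), d[1]); py <- pmin(pmax(py, 1), d[2])
  pz <- pmin(pmax(pz, 1), d[3])
  x0 <- pmin(floor(px), d[1] - 1L); y0 <- pmin(floor(py), d[2] - 1L)
  z0 <- pmin(floor(pz), d[3] - 1L)
  if (d[1] == 1L) x0 <- rep(1, length(px))
  if (d[3] == 1L) z0 <- rep(1, length(pz))
  fx <- px - x0; fy <- py - y0; fz <- pz - z0
  idx <- function(a, b, c) ((c - 1) * d[2] + (b - 1)) * d[1] + a
  v <- img[idx(x0, y0, z0)] * (1 - fx) * (1 - fy) * (1 - fz)
  x1 <- pmin(x0 + 1, d[1]); y1 <- pmin(y0 + 1, d[2]); z1 <- pmin(z0 + 1, d[3])
  v <- v + img[idx(x1, y0, z0)] * fx * (1 - fy) * (1 - fz)
  v <- v + img[idx(x0, y1, z0)] * (1 - fx) * fy * (1 - fz)
  v <- v + img[idx(x1, y1, z0)] * fx * fy * (1 - fz)
  v <- v + img[idx(x0, y0, z1)] * (1 - fx) * (1 - fy) * fz
  v <- v + img[idx(x1, y0, z1)] * fx * (1 - fy) * fz
  v <- v + img[idx(x0, y1, z1)] * (1 - fx) * fy * fz
  v <- v + img[idx(x1, y1, z1)] * fx * fy * fz
  v
}

# Second-difference (discrete bending) operator along each dimension.
second_diff_energy_grad <- function(d3) {
  g <- array(0, dim(d3)); e <- 0
  for (dm in 1:3) {
    n <- dim(d3)[dm]
    if (n < 3) next
    perm <- c(dm, setdiff(1:3, dm))
    a <- aperm(d3, perm)
    dd <- a[2:(n - 1), , , drop = FALSE] * (-2) +
      a[1:(n - 2), , , drop = FALSE] + a[3:n, , , drop = FALSE]
    e <- e + sum(dd^2)
    ga <- array(0, dim(a))
    ga[2:(n - 1), , ] <- ga[2:(n - 1), , , drop = FALSE] - 4 * dd
    ga[1:(n - 2), , ] <- ga[1:(n - 2), , , drop = FALSE] + 2 * dd
    ga[3:n, , ] <- ga[3:n, , , drop = FALSE] + 2 * dd
    g <- g + aperm(ga, order(perm))
  }
  list(e = e, g = g)
}

block_downsample <- function(img, fac) {
  if (fac == 1L) return(img)
  d <- dim(img)
  dn <- pmax(d %/% fac, 1L)
  out <- array(0, dn)
  for (i in seq_len(dn[1])) for (j in seq_len(dn[2])) for (k in seq_len(dn[3])) {
    out[i, j, k] <- mean(img[((i - 1) * fac + 1):min(i * fac, d[1]),
                             ((j - 1) * fac + 1):min(j * fac, d[2]),
                             ((k - 1) * fac + 1):min(k * fac, d[3])])
  }
  out
}

#' Non-rigid registration by multi-resolution B-spline free-form deformation
#'
#' Minimizes the mean squared intensity difference between the warped moving
#' image and the reference, with a discrete bending-energy penalty on the
#' B-spline control lattice, by L-BFGS over `n_levels` resolution levels
#' (coarse to fine; the control lattice is fixed in mm across levels).
#'
#' @param moving,reference Real 3D magnitude images of identical shape.
#' @param grid_spacing B-spline control-point spacing in mm. Default 16.
#' @param n_levels Resolution levels. Default 2.
#' @param voxel_size Voxel size in mm. Default 2.
#' @param lambda_smooth Bending-energy weight. Default 0.01.
#' @param max_iter L-BFGS iterations per level. Default 150.
#' @param init_translation Optional rigid initialization `c(dx, dy, dz)` in
#'   mm (e.g. the known inter-bin translation); the control lattice starts
#'   from this uniform displacement instead of zero.
#' @return A `qcmr_deformation`: dense displacement field, dims
#'   `c(shape, 3)`, in mm; `moving(x + u(x)) ~ reference(x)`.
#' @export
register_ffd <- function(moving, reference, grid_spacing = 16, n_levels = 2L,
                         voxel_size = 2, lambda_smooth = 0.01, max_iter = 150L,
                         init_translation = NULL) {
  if (!all(dim(moving) == dim(reference))) stop("images must have the same shape")
  shape <- dim(moving)
  sc <- max(abs(reference))
  if (sc == 0) sc <- 1
  moving <- moving / sc; reference <- reference / sc
  extent <- shape * voxel_size
  s <- grid_spacing
  x0 <- -s  # lattice starts one spacing before the volume
  nc <- pmax(ceiling(extent / s) + 4L, 4L)
  dpar <- array(0, c(nc, 3L))  # control displacements (mm)
  if (!is.null(init_translation))
    for (comp in 1:3) dpar[, , , comp] <- init_translation[comp]
  converged <- TRUE

  for (lev in rev(seq_len(n_levels))) {
    fac <- 2L^(lev - 1L)
    mv <- block_downsample(moving, fac)
    rf <- block_downsample(reference, fac)
    dl <- dim(mv)
    vs <- voxel_size * fac
    coords <- lapply(1:3, function(dd) ((seq_len(dl[dd])) - 0.5) * vs)
    Bs <- lapply(1:3, function(dd) bspline_basis(coords[[dd]], s, x0, nc[dd]))
    base <- as.matrix(expand.grid(x = seq_len(dl[1]), y = seq_len(dl[2]),
                                  z = seq_len(dl[3])))
    # finite-difference gradients of the moving image (voxel units)
    gimg <- lapply(1:3, function(dd) {
      n <- dl[dd]
      perm <- c(dd, setdiff(1:3, dd))
      a <- aperm(mv, perm)
      g <- a
      if (n >= 2) {
        g[2:(n - 1), , ] <- (a[3:n, , , drop = FALSE] - a[1:(n - 2), , , drop = FALSE]) / 2
        g[1, , ] <- a[2, , ] - a[1, , ]
        g[n, , ] <- a[n, , ] - a[n - 1, , ]
      } else g[] <- 0
      aperm(g, order(perm))
    })
    nvox <- prod(dl)
    unpack <- function(par) array(par, c(nc, 3L))
    disp_at_vox <- function(d3c) {  # control array -> voxel displacement (mm)
      tmult(tmult(tmult(d3c, Bs[[1]], 1L), Bs[[2]], 2L), Bs[[3]], 3L)
    }
    ctrl <- function(dp, comp) array(dp[, , , comp], nc)
    fn <- function(par) {
      dp <- unpack(par)
      px <- base[, 1] + as.vector(disp_at_vox(ctrl(dp, 1))) / vs
      py <- base[, 2] + as.vector(disp_at_vox(ctrl(dp, 2))) / vs
      pz <- base[, 3] + as.vector(disp_at_vox(ctrl(dp, 3))) / vs
      r <- interp3(mv, px, py, pz) - as.vector(rf)
      pen <- 0
      for (comp in 1:3) pen <- pen + second_diff_energy_grad(ctrl(dp, comp))$e
      mean(r^2) + lambda_smooth * pen
    }
    gr <- function(par) {
      dp <- unpack(par)
      px <- base[, 1] + as.vector(disp_at_vox(ctrl(dp, 1))) / vs
      py <- base[, 2] + as.vector(disp_at_vox(ctrl(dp, 2))) / vs
      pz <- base[, 3] + as.vector(disp_at_vox(ctrl(dp, 3))) / vs
      r <- interp3(mv, px, py, pz) - as.vector(rf)
      out <- array(0, c(nc, 3L))
      for (comp in 1:3) {
        gw <- interp3(gimg[[comp]], px, py, pz)  # dI/dvoxel at warped pos
        rv <- array(2 * r * gw / (nvox * vs), dl)  # chain rule to mm
        gcomp <- tmult(tmult(tmult(rv, t(Bs[[1]]), 1L), t(Bs[[2]]), 2L),
                       t(Bs[[3]]), 3L)
        sm <- second_diff_energy_grad(ctrl(dp, comp))
        out[, , , comp] <- gcomp + lambda_smooth * sm$g
      }
      as.vector(out)
    }
    opt <- optim(as.vector(dpar), fn, gr, method = "L-BFGS-B",
                 control = list(maxit = max_iter))
    if (opt$convergence != 0 && opt$convergence != 1) converged <- FALSE
    dpar <- unpack(opt$par)
  }
  if (!converged)
    warning("registration did not converge; returning best-so-far field")

  coords <- lapply(1:3, function(dd) ((seq_len(shape[dd])) - 0.5) * voxel_size)
  Bs <- lapply(1:3, function(dd) bspline_basis(coords[[dd]], s, x0, nc[dd]))
  disp <- array(0, c(shape, 3L))
  for (comp in 1:3)
    disp[, , , comp] <- tmult(tmult(tmult(array(dpar[, , , comp], nc),
                                          Bs[[1]], 1L), Bs[[2]], 2L), Bs[[3]], 3L)
  structure(disp, class = "qcmr_deformation", voxel_size = voxel_size)
}

# Sparse trilinear warp matrix for a dense displacement field (mm):
# (Wx)[v] = x interpolated at voxel position v + u(v)/voxel_size. The
# adjoint of the warp is the matrix transpose (interpolation transpose, not
# the inverse warp).
warp_matrix <- function(disp, voxel_size, shape = dim(disp)[1:3]) {
  nvox <- prod(shape)
  base <- as.matrix(expand.grid(x = seq_len(shape[1]), y = seq_len(shape[2]),
                                z = seq_len(shape[3])))
  px <- pmin(pmax(base[, 1] + as.vector(disp[, , , 1]) / voxel_size, 1), shape[1])
  py <- pmin(pmax(base[, 2] + as.vector(disp[, , , 2]) / voxel_size, 1), shape[2])
  pz <- pmin(pmax(base[, 3] + as.vector(disp[, , , 3]) / voxel_size, 1), shape[3])
  x0 <- pmin(floor(px), max(shape[1] - 1L, 1L)); fx <- px - x0
  y0 <- pmin(floor(py), max(shape[2] - 1L, 1L)); fy <- py - y0
  z0 <- pmin(floor(pz), max(shape[3] - 1L, 1L)); fz <- pz - z0
  x1 <- pmin(x0 + 1L, shape[1]); y1 <- pmin(y0 + 1L, shape[2])
  z1 <- pmin(z0 + 1L, shape[3])
  lin <- function(a, b, c) ((c - 1) * shape[2] + (b - 1)) * shape[1] + a
  rows <- rep(seq_len(nvox), 8L)
  cols <- c(lin(x0, y0, z0), lin(x1, y0, z0), lin(x0, y1, z0), lin(x1, y1, z0),
            lin(x0, y0, z1), lin(x1, y0, z1), lin(x0, y1, z1), lin(x1, y1, z1))
  vals <- c((1 - fx) * (1 - fy) * (1 - fz), fx * (1 - fy) * (1 - fz),
            (1 - fx) * fy * (1 - fz), fx * fy * (1 - fz),
            (1 - fx) * (1 - fy) * fz, fx * (1 - fy) * fz,
            (1 - fx) * fy * fz, fx * fy * fz)
  Matrix::sparseMatrix(i = rows, j = cols, x = vals, dims = c(nvox, nvox))
}

apply_warp <- function(W, x) {
  if (is.null(W)) return(x)
  d <- dim(x)
  out <- as.vector(W %*% Re(x)) + 1i * as.vector(W %*% Im(x))
  array(out, d)
}

apply_warp_adjoint <- function(W, x) {
  if (is.null(W)) return(x)
  d <- dim(x)
  out <- as.vector(Matrix::crossprod(W, Re(x))) +
    1i * as.vector(Matrix::crossprod(W, Im(x)))
  array(out, d)
}

#' Compose the motion-compensated encoding operator
#'
#' Builds `E(c) = sum_b A_b(c) F S U_b`: per respiratory bin, warp the image
#' with the bin's deformation field, multiply by the coil sensitivities,
#' Fourier transform, and keep the bin's sampled phase-encode cells. The
#' adjoint applies the conjugate-transpose chain, with the warp adjoint
#' implemented as the transpose of the trilinear interpolation.
#'
#' @param masks `[ny x nz x n_bins x n_contrasts]` binned sampling masks.
#' @param sens Coil sensitivities `[shape x n_coils]`.
#' @param fields List (length `n_bins`) of `qcmr_deformation` fields or
#'   `NULL` entries (identity).
#' @param voxel_size Voxel size in mm.
#' @return A `qcmr_encop` with `forward(x, contrast)` semantics via
#'   [encode_forward()] / [encode_adjoint()].
#' @export
compose_encoding_operator <- function(masks, sens, fields = NULL,
                                      voxel_size = 2) {
  shape <- dim(sens)[1:3]
  if (!all(dim(masks)[1:2] == shape[2:3])) stop("mask/sens shape mismatch")
  n_bins <- dim(masks)[3]; n_contrasts <- dim(masks)[4]
  if (is.null(fields)) fields <- vector("list", n_bins)
  if (length(fields) != n_bins) stop("one deformation field per bin required")
  warps <- lapply(fields, function(f) {
    if (is.null(f)) return(NULL)
    if (!all(dim(f)[1:3] == shape)) stop("field/sens shape mismatch")
    warp_matrix(f, voxel_size)
  })
  # pre-expanded masks and per-coil volumes (hot path of the CG loop;
  # explicit dims also guard against dropped singleton dimensions)
  mex <- lapply(seq_len(n_bins), function(b)
    lapply(seq_len(n_contrasts), function(cc)
      expand_mask(matrix(masks[, , b, cc], dim(masks)[1], dim(masks)[2]),
                  shape[1])))
  ncoil <- dim(sens)[4]
  sl <- lapply(seq_len(ncoil), function(co) array(sens[, , , co], shape))
  slc <- lapply(sl, Conj)
  structure(list(shape = shape, ncoil = ncoil, n_bins = n_bins,
                 n_contrasts = n_contrasts, masks = masks, sens = sens,
                 sl = sl, slc = slc, warps = warps, mex = mex,
                 voxel_size = voxel_size),
            class = "qcmr_encop")
}

#' Apply the encoding operator or its adjoint for one contrast
#'
#' @param op A `qcmr_encop`.
#' @param x Complex image volume (forward) or multi-coil k-space
#'   `[shape x n_coils]` (adjoint).
#' @param contrast Contrast index.
#' @return Multi-coil k-space (forward) or image volume (adjoint).
#' @export
encode_forward <- function(op, x, contrast) {
  shape <- op$shape
  y <- array(complex(real = 0), c(shape, op$ncoil))
  for (b in seq_len(op$n_bins)) {
    if (sum(op$masks[, , b, contrast]) == 0L) next
    mex <- op$mex[[b]][[contrast]]
    xb <- apply_warp(op$warps[[b]], x)
    for (co in seq_len(op$ncoil))
      y[, , , co] <- array(y[, , , co], shape) +
        mex * fftc(op$sl[[co]] * xb)
  }
  y
}

#' @rdname encode_forward
#' @export
encode_adjoint <- function(op, x, contrast) {
  shape <- op$shape
  out <- array(complex(real = 0), shape)
  for (b in seq_len(op$n_bins)) {
    if (sum(op$masks[, , b, contrast]) == 0L) next
    mex <- op$mex[[b]][[contrast]]
    acc <- array(complex(real = 0), shape)
    for (co in seq_len(op$ncoil))
      acc <- acc + op$slc[[co]] * ifftc(mex * array(x[, , , co], shape))
    out <- out + apply_warp_adjoint(op$warps[[b]], acc)
  }
  out
}
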