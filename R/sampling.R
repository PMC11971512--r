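# Variable-density Cartesian trajectory with spiral profile order in the
# (ky, kz) phase-encode plane: each shot (one heartbeat of one contrast) is
# an approximate spiral interleaf snapped to the Cartesian grid, rotated by
# the golden angle between successive shots of a contrast and offset by a
# fraction of the golden angle across contrasts, with centric (centre-out)
# sample ordering within every shot.
#
# Index convention: DC cell at (floor(ny/2)+1, floor(nz/2)+1), 1-based.

dc_index <- function(n) floor(n / 2) + 1L

#' Centric reordering of one shot
#'
#' Sorts the samples of a shot by ascending distance from the k-space
#' centre; ties are broken by ascending angle, then by ky index.
#'
#' @param shot Integer matrix `[n x 2]` of (ky, kz) indices (1-based).
#' @param matrix_size `(ny, nz)` of the phase-encode plane.
#' @return The reordered `[n x 2]` matrix.
#' @export
order_centric <- function(shot, matrix_size) {
  if (is.null(dim(shot)) || nrow(shot) == 0L) stop("shot must be non-empty")
  cy <- dc_index(matrix_size[1]); cz <- dc_index(matrix_size[2])
  dy <- shot[, 1] - cy; dz <- shot[, 2] - cz
  r <- sqrt(dy^2 + dz^2)
  ang <- atan2(dz, dy) %% (2 * pi)
  shot[order(r, ang, shot[, 1], method = "radix"), , drop = FALSE]
}

# One spiral interleaf: nseg samples from the centre to the edge of the
# phase-encode plane at base angle `ang0`, radial positions following a
# variable-density law (sample k at normalized radius (k/(nseg-1))^q with
# q = 1/(2 - vd_exponent)), snapped to the grid. `extent(theta)` reaches the
# rectangle boundary so full sampling can cover corner cells.
spiral_shot <- function(matrix_size, nseg, ang0, vd_exponent, turns = 0.5) {
  ny <- matrix_size[1]; nz <- matrix_size[2]
  cy <- dc_index(ny); cz <- dc_index(nz)
  q <- 1 / (2 - vd_exponent)
  t <- (seq_len(nseg) - 1) / (nseg - 1)
  rnorm_ <- t^q
  theta <- ang0 + 2 * pi * turns * t
  ry <- (ny - 1) / 2; rz <- (nz - 1) / 2
  # per-angle radius to the rectangle boundary (in normalized units)
  bound <- 1 / pmax(abs(cos(theta)), 1e-9)
  boundz <- 1 / pmax(abs(sin(theta)), 1e-9)
  rect <- pmin(bound, boundz * 1)  # normalized so r=1 touches the ellipse
  rmax <- pmin(rect, sqrt(2))      # cap at the rectangle diagonal
  iy <- round(cy + rnorm_ * rmax * ry * cos(theta))
  iz <- round(cz + rnorm_ * rmax * rz * sin(theta))
  cbind(pmin(pmax(iy, 1L), ny), pmin(pmax(iz, 1L), nz))
}

# Nearest cell to (iy, iz) for which `free[cell]` is TRUE, searching outward
# over square rings; deterministic tie-break by distance then (ky, kz).
nearest_free_cell <- function(iy, iz, free) {
  ny <- nrow(free); nz <- ncol(free)
  for (rad in 0:(max(ny, nz))) {
    yy <- (iy - rad):(iy + rad)
    zz <- (iz - rad):(iz + rad)
    ring <- if (rad == 0L) cbind(iy, iz) else
      rbind(cbind(yy, iz - rad), cbind(yy, iz + rad),
            cbind(iy - rad, zz), cbind(iy + rad, zz))
    ring <- ring[ring[, 1] >= 1 & ring[, 1] <= ny &
                   ring[, 2] >= 1 & ring[, 2] <= nz, , drop = FALSE]
    ring <- unique(ring)
    if (nrow(ring) == 0L) next
    ok <- free[cbind(ring[, 1], ring[, 2])]
    if (!any(ok)) next
    pool <- ring[ok, , drop = FALSE]
    d2 <- (pool[, 1] - iy)^2 + (pool[, 2] - iz)^2
    return(pool[order(d2, pool[, 1], pool[, 2], method = "radix")[1], ])
  }
  NULL
}

# Snap one shot onto the grid without duplicates. The first sample is always
# the exact k-space centre (re-acquired every shot, as centric profile
# ordering prescribes). Every other sample that collides -- with this shot or
# with a cell this contrast has already sampled -- is re-drawn at the nearest
# cell not yet sampled by the contrast, keeping the interleaf's variable
# density approximately intact while making each shot's remaining samples
# fresh. When the plane is exhausted, the nearest cell outside this shot is
# used instead (duplicates across shots are then unavoidable).
dedup_shot <- function(shot, matrix_size, union_mask) {
  ny <- matrix_size[1]; nz <- matrix_size[2]
  taken <- matrix(FALSE, ny, nz)   # cells used by this shot
  out <- shot
  cy <- dc_index(ny); cz <- dc_index(nz)
  out[1, ] <- c(cy, cz)
  taken[cy, cz] <- TRUE
  for (q in seq(2L, length.out = nrow(shot) - 1L)) {
    iy <- shot[q, 1]; iz <- shot[q, 2]
    pick <- nearest_free_cell(iy, iz, !taken & !union_mask)
    if (is.null(pick)) pick <- nearest_free_cell(iy, iz, !taken)
    if (is.null(pick)) stop("could not place sample: phase-encode plane exhausted")
    taken[pick[1], pick[2]] <- TRUE
    out[q, ] <- pick
  }
  out
}

#' Generate the variable-density spiral-profile Cartesian sampling pattern
#'
#' @param matrix_size `(ny, nz)` phase-encode matrix.
#' @param accel Per-contrast acceleration (undersampling) factor, >= 1.
#' @param n_contrasts Number of interleaved contrasts. Default 5.
#' @param n_heartbeats Total heartbeats to schedule; default chosen from
#'   `accel` so the per-contrast sampled fraction is within 10% of
#'   `1/accel`.
#' @param segments_per_hb Samples per shot. Default 16.
#' @param golden_step_deg Rotation increment between successive shots of a
#'   contrast (default 137.508); contrast `c` adds an extra offset of
#'   `golden_step_deg * (c-1) / n_contrasts`.
#' @param vd_exponent Variable-density exponent: radial sample density
#'   proportional to `r^-vd_exponent`. Default 1.2.
#' @param seed Integer seed (pattern generation is deterministic; the seed
#'   only rotates the global starting angle).
#' @return A `qcmr_pattern`: list with `matrix`, `shots` (per contrast, a
#'   list over heartbeats of ordered `[segments x 2]` index matrices),
#'   `n_cycles`, `n_contrasts`, `n_heartbeats`, `accel`, `golden_step_deg`,
#'   `vd_exponent`, `seed`, and `masks` (`[ny x nz x n_contrasts]` union
#'   masks).
#' @export
generate_caspr_pattern <- function(matrix_size, accel, n_contrasts = 5L,
                                   n_heartbeats = NULL, segments_per_hb = 16L,
                                   golden_step_deg = 137.508,
                                   vd_exponent = 1.2, seed = 1) {
  if (accel < 1) stop("unsatisfiable accel: must be >= 1")
  ny <- matrix_size[1]; nz <- matrix_size[2]
  ncell <- ny * nz
  target <- ncell / accel
  g <- golden_step_deg * pi / 180
  ang_seed <- with_seed(seed, runif(1, 0, 2 * pi))

  # Each shot contributes the centre plus segments_per_hb - 1 fresh cells
  # (until the plane fills), so the cycle count follows in closed form.
  if (segments_per_hb < 2L) stop("segments_per_hb must be >= 2")
  n_cycles <- if (!is.null(n_heartbeats)) n_heartbeats %/% n_contrasts
              else max(1L, 1L + ceiling((target - segments_per_hb) /
                                          (segments_per_hb - 1L)))
  if (n_cycles < 1L) stop("unsatisfiable accel: not enough heartbeats")

  gen_contrast <- function(cc) {
    shots <- vector("list", n_cycles)
    union_mask <- matrix(FALSE, ny, nz)
    for (s in seq_len(n_cycles)) {
      ang0 <- ang_seed + (s - 1) * g + (cc - 1) * g / n_contrasts
      sh <- spiral_shot(c(ny, nz), segments_per_hb, ang0, vd_exponent)
      sh <- dedup_shot(sh, c(ny, nz), union_mask)
      sh <- order_centric(sh, c(ny, nz))
      union_mask[sh] <- TRUE
      shots[[s]] <- sh
    }
    list(shots = shots, union = union_mask)
  }
  per_contrast <- lapply(seq_len(n_contrasts), gen_contrast)

  masks <- array(0L, c(ny, nz, n_contrasts))
  for (cc in seq_len(n_contrasts)) masks[, , cc] <- per_contrast[[cc]]$union * 1L

  structure(list(matrix = c(ny, nz),
                 shots = lapply(per_contrast, `[[`, "shots"),
                 n_cycles = n_cycles, n_contrasts = as.integer(n_contrasts),
                 n_heartbeats = as.integer(n_cycles * n_contrasts),
                 segments_per_hb = as.integer(segments_per_hb),
                 accel = accel, golden_step_deg = golden_step_deg,
                 vd_exponent = vd_exponent, seed = seed, masks = masks),
            class = "qcmr_pattern")
}

#' @export
print.qcmr_pattern <- function(x, ...) {
  frac <- apply(x$masks, 3, mean)
  cat(sprintf("qcmr sampling pattern %dx%d, %d contrasts x %d shots x %d samples\n",
              x$matrix[1], x$matrix[2], x$n_contrasts, x$n_cycles, x$segments_per_hb))
  cat(sprintf("  per-contrast sampled fraction %.3f-%.3f (accel %.1f requested)\n",
              min(frac), max(frac), x$accel))
  invisible(x)
}

# First-acquisition heartbeat per (ky, kz, contrast): schedule order is
# cycle-major (cycle s, heartbeat (s-1)*n_contrasts + c), samples in centric
# order within a shot. Duplicate cells across shots keep their first
# acquisition, so the per-cell heartbeat tag is unique.
first_acquisition_hb <- function(pattern) {
  ny <- pattern$matrix[1]; nz <- pattern$matrix[2]
  nc <- pattern$n_contrasts
  hb_index <- array(0L, c(ny, nz, nc))
  for (cc in seq_len(nc)) for (s in seq_len(pattern$n_cycles)) {
    hb <- (s - 1L) * nc + cc
    sh <- pattern$shots[[cc]][[s]]
    for (q in seq_len(nrow(sh)))
      if (hb_index[sh[q, 1], sh[q, 2], cc] == 0L)
        hb_index[sh[q, 1], sh[q, 2], cc] <- hb
  }
  hb_index
}

#' Per-bin sampling masks
#'
#' Splits each contrast's sampling mask by the respiratory bin of the
#' heartbeat in which each cell was (first) acquired. The per-bin masks of a
#' contrast are an exact partition of its union mask.
#'
#' @param pattern A `qcmr_pattern`.
#' @param bin_of_heartbeat Integer vector of bin labels (1..`n_bins`) per
#'   heartbeat.
#' @param n_bins Number of respiratory bins. Default 4.
#' @return Integer array `[ny x nz x n_bins x n_contrasts]`.
#' @export
bin_sampling_masks <- function(pattern, bin_of_heartbeat, n_bins = 4L) {
  if (any(bin_of_heartbeat < 1L | bin_of_heartbeat > n_bins))
    stop("bin label out of range 1..n_bins")
  if (length(bin_of_heartbeat) < pattern$n_heartbeats)
    stop("bin_of_heartbeat shorter than the pattern's heartbeats")
  hb_index <- first_acquisition_hb(pattern)
  ny <- pattern$matrix[1]; nz <- pattern$matrix[2]
  nc <- pattern$n_contrasts
  masks <- array(0L, c(ny, nz, n_bins, nc))
  for (cc in seq_len(nc)) {
    hmap <- hb_index[, , cc]
    sel <- which(hmap > 0L)
    b <- bin_of_heartbeat[hmap[sel]]
    for (bb in seq_len(n_bins)) {
      m <- matrix(0L, ny, nz)
      m[sel[b == bb]] <- 1L
      masks[, , bb, cc] <- m
    }
  }
  masks
}
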