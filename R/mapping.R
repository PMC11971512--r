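# Polarity restoration, dictionary matching, and the 2D spin-echo reference
# fitting models (inversion-recovery spin echo and mono-exponential decay)
# used as accuracy references.

#' Restore the signed polarity of the multi-contrast water signals
#'
#' Removes the background phase voxelwise using the 4th-contrast in-phase
#' image as the phase reference: each contrast value is multiplied by
#' `exp(-i arg(reference))` and the real part is taken. The
#' inversion-recovery contrast may legitimately come out negative.
#'
#' @param water_contrasts Complex array `[nx x ny x nz x n_contrasts]`.
#' @param reference Complex volume, conventionally the 4th-contrast in-phase
#'   echo image.
#' @return List with `signals` (real array, same shape) and `qc_mask`
#'   (logical volume, `TRUE` where the reference voxel is zero and the
#'   polarity is therefore undefined).
#' @export
restore_polarity <- function(water_contrasts, reference) {
  d <- dim(water_contrasts)
  if (!all(dim(reference) == d[1:3])) stop("reference/water shape mismatch")
  qc <- Mod(reference) == 0
  ph <- exp(-1i * Arg(reference))
  out <- array(0, d)
  for (cc in seq_len(d[4])) out[, , , cc] <- Re(water_contrasts[, , , cc] * ph)
  list(signals = out, qc_mask = qc)
}

#' Voxelwise dictionary matching
#'
#' Normalizes each voxel's signed multi-contrast signal vector to unit L2
#' norm and selects the dictionary atom with the maximum (signed) inner
#' product; ties break to the lowest atom index. Voxels whose signal norm is
#' below `mask_frac` of the volume's 95th-percentile norm are masked out.
#'
#' @param signals Real array `[nx x ny x nz x n_points]` of polarity-
#'   restored signals (or an `[n_vox x n_points]` matrix).
#' @param dict A `qcmr_dictionary`.
#' @param mask Optional logical volume restricting the matched voxels; by
#'   default derived from the signal norms.
#' @param mask_frac Masking threshold as a fraction of the 95th-percentile
#'   signal norm. Default 0.05.
#' @param chunk Number of voxels matched per block (default 256; together
#'   with the internal 4096-atom blocking this keeps every inner-product
#'   block inside the CPU cache).
#' @return A `qcmr_maps`: list of `t1`, `t1rho`, `t2` volumes (ms;
#'   `NA` outside the mask), `match_score`, `mask`, and `index` (matched
#'   atom index).
#' @export
match_dictionary <- function(signals, dict, mask = NULL, mask_frac = 0.05,
                             chunk = NULL) {
  if (nrow(dict$atoms) == 0L) stop("empty dictionary")
  if (is.null(chunk)) chunk <- 256L
  d <- dim(signals)
  as_matrix <- length(d) == 2L
  shape <- if (as_matrix) c(d[1], 1L, 1L) else d[1:3]
  npts <- if (as_matrix) d[2] else d[4]
  if (npts != ncol(dict$atoms)) stop("signal length does not match dictionary atoms")
  S <- matrix(signals, prod(shape), npts)
  nrm <- sqrt(rowSums(S^2))
  if (is.null(mask)) {
    thr <- mask_frac * quantile(nrm, 0.95, names = FALSE)
    mask <- nrm > max(thr, 0)
  } else {
    mask <- as.vector(mask) & nrm > 0
  }
  vox <- which(mask)
  idx <- integer(length(vox))
  score <- numeric(length(vox))
  A <- dict$atoms
  n_atoms <- nrow(A)
  achunk <- 4096L  # block both dimensions so each Gram block stays in cache
  for (st in seq(1L, length(vox), by = chunk)) {
    en <- min(st + chunk - 1L, length(vox))
    blk <- vox[st:en]
    nb <- length(blk)
    Sb <- t(S[blk, , drop = FALSE] / nrm[blk])            # [n_pts x n_blk]
    best <- rep(-Inf, nb); bidx <- integer(nb)
    for (ast in seq(1L, n_atoms, by = achunk)) {
      aen <- min(ast + achunk - 1L, n_atoms)
      G <- A[ast:aen, , drop = FALSE] %*% Sb              # [achunk x n_blk]
      na <- aen - ast + 1L
      for (j in seq_len(nb)) {
        w <- which.max(G[, j])
        v <- G[w, j]
        if (v > best[j]) { best[j] <- v; bidx[j] <- w + ast - 1L }
      }
    }
    idx[st:en] <- bidx
    score[st:en] <- best
  }
  mk_vol <- function(vals) {
    v <- rep(NA_real_, prod(shape))
    v[vox] <- vals
    array(v, shape)
  }
  structure(list(t1 = mk_vol(dict$grid$t1[idx]),
                 t1rho = mk_vol(dict$grid$t1rho[idx]),
                 t2 = mk_vol(dict$grid$t2[idx]),
                 match_score = mk_vol(score),
                 mask = array(mask, shape),
                 index = mk_vol(idx)),
            class = "qcmr_maps")
}

#' Self-consistency of a dictionary under its own matcher
#'
#' Checks, for every atom, that matching the atom against the full
#' dictionary returns its own parameters with inner-product score 1. Because
#' the atoms are unit vectors, an atom can only fail if some other atom has
#' an inner product with it of at least its self-score (i.e. the two atoms
#' coincide to floating-point precision, `||a_i - a_j||` below ~1e-7). The
#' check therefore reduces, exactly, to finding all near-coincident atom
#' pairs -- done with a sorted sliding window on the most-spread coordinate
#' -- and resolving only those candidates by direct argmax matching. A
#' random subsample is additionally verified against the general
#' [match_dictionary()] path.
#'
#' @param dict A `qcmr_dictionary`.
#' @param n_direct Size of the random subsample matched brute-force through
#'   [match_dictionary()] as a cross-check. Default 2000.
#' @param seed Seed for the subsample.
#' @return List with `fraction` (fraction of atoms that self-match with
#'   score 1), `n_atoms`, `n_candidate_pairs` (near-coincident pairs
#'   examined), and `direct_fraction` (agreement of the brute-force
#'   subsample).
#' @export
dictionary_self_match <- function(dict, n_direct = 2000L, seed = 1L) {
  A <- dict$atoms
  n <- nrow(A)
  # window threshold: ip >= 1 - 1e-12 requires ||a_i - a_j|| <= ~1.5e-6
  thr <- 1.5e-6
  spread <- apply(A, 2, function(x) diff(range(x)))
  k <- which.max(spread)
  ord <- order(A[, k], method = "radix")
  As <- A[ord, , drop = FALSE]
  cand_i <- integer(0); cand_j <- integer(0)
  off <- 1L
  repeat {
    if (off >= n) break
    gap <- As[(1L + off):n, k] - As[1:(n - off), k]
    close_k <- which(gap <= thr)
    if (length(close_k) == 0L) break
    d2 <- rowSums((As[close_k + off, , drop = FALSE] -
                     As[close_k, , drop = FALSE])^2)
    hit <- close_k[d2 <= thr^2]
    cand_i <- c(cand_i, ord[hit]); cand_j <- c(cand_j, ord[hit + off])
    off <- off + 1L
  }
  fails <- logical(n)
  if (length(cand_i)) {
    sus <- unique(c(cand_i, cand_j))
    for (v in sus) {
      ip <- as.vector(A %*% A[v, ])
      self <- ip[v]
      best <- which(ip >= self)[1]  # ties break to the lowest index
      pars <- dict$grid[best, ]
      fails[v] <- !(isTRUE(all.equal(ip[best], 1, tolerance = 1e-9)) &&
                      pars$t1 == dict$grid$t1[v] &&
                      pars$t1rho == dict$grid$t1rho[v] &&
                      pars$t2 == dict$grid$t2[v])
    }
  }
  direct <- NA_real_
  if (n_direct > 0L) {
    sub <- with_seed(seed, sample.int(n, min(n_direct, n)))
    mm <- match_dictionary(A[sub, , drop = FALSE], dict,
                           mask = rep(TRUE, length(sub)))
    direct <- mean(mm$index[, 1, 1] == sub &
                     abs(mm$match_score[, 1, 1] - 1) < 1e-9)
  }
  list(fraction = mean(!fails), n_atoms = n,
       n_candidate_pairs = length(cand_i), direct_fraction = direct)
}

#' Reference spin-echo fitting protocol
#'
#' The inversion-time, spin-lock-time and echo-time lists of the 2D
#' spin-echo reference protocols used for accuracy validation.
#'
#' @param ti_list Inversion times (ms) of the IR spin-echo series.
#' @param tr Repetition time (ms) of the IR spin-echo.
#' @param tsl_list Spin-lock durations (ms) of the T1rho-prepared series.
#' @param te_list Echo times (ms) of the T2 series.
#' @return A `qcmr_reffit` list.
#' @export
reference_fit_spec <- function(ti_list = c(50, 350, 650, 950, 1250, 1550,
                                           1850, 2150, 2450),
                               tr = 10000,
                               tsl_list = c(2, 14, 26, 38, 50, 62, 74, 86),
                               te_list = c(12, 27, 42, 57, 72, 87, 102, 117)) {
  for (l in list(ti_list, tsl_list, te_list))
    if (is.unsorted(l, strictly = TRUE)) stop("time lists must be strictly increasing")
  structure(list(ti_list = ti_list, tr = tr, tsl_list = tsl_list,
                 te_list = te_list), class = "qcmr_reffit")
}

#' Inversion-recovery spin-echo T1 fit
#'
#' Two-parameter (T1, M0) Levenberg-Marquardt fit of the signed IR
#' spin-echo model `S = M0 (1 - 2 exp(-TI/T1) + exp(-TR/T1))`.
#'
#' @param signal Signed real signal at each inversion time.
#' @param spec A [reference_fit_spec()] (uses `ti_list`, `tr`).
#' @param init Optional `c(t1, m0)` start; default `t1 = 800`,
#'   `m0 = max |signal|`.
#' @return Named vector `c(t1=, m0=)`.
#' @export
fit_ir_se <- function(signal, spec = reference_fit_spec(), init = NULL) {
  ti <- spec$ti_list
  if (length(signal) != length(ti)) stop("signal length must match ti_list")
  if (length(signal) < 3L) stop("need at least 3 points for the 2-parameter fit")
  start <- if (is.null(init)) c(t1 = 800, m0 = max(abs(signal)))
           else c(t1 = init[1], m0 = init[2])
  df <- data.frame(s = signal, ti = ti, tr = spec$tr)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      s ~ m0 * (1 - 2 * exp(-ti / t1) + exp(-tr / t1)),
      data = df, start = as.list(start),
      lower = c(t1 = 1, m0 = -Inf), upper = c(t1 = 5000, m0 = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("IR-SE fit did not converge: ", conditionMessage(e),
                             "; residual sum at start = ",
                             signif(sum((df$s - start["m0"] *
                                           (1 - 2 * exp(-ti / start["t1"]) +
                                              exp(-spec$tr / start["t1"])))^2), 4)))
  co <- coef(fit)
  c(t1 = unname(co["t1"]), m0 = unname(co["m0"]))
}

#' Mono-exponential decay fit (T1rho or T2)
#'
#' Ordinary least squares of `log(signal)` on the preparation times:
#' `S = M0 exp(-t/tau)`.
#'
#' @param signal Positive real signal values.
#' @param times Preparation durations (ms): spin-lock times for T1rho, echo
#'   times for T2.
#' @return Named vector `c(tau=, m0=)`.
#' @export
fit_monoexp <- function(signal, times) {
  if (length(signal) != length(times)) stop("signal/times length mismatch")
  if (any(signal <= 0)) stop("non-positive signal: mono-exponential log fit undefined")
  fit <- lm(log(signal) ~ times)
  slope <- coef(fit)[2]
  c(tau = unname(-1 / slope), m0 = unname(exp(coef(fit)[1])))
}

#' Per-region summary statistics of quantitative maps
#'
#' @param maps A `qcmr_maps`.
#' @param labels Integer label volume (0 = background).
#' @param truth Optional `qcmr_tpm` supplying ground-truth values.
#' @return Data frame with one row per label: mean/SD of each parameter and
#'   (if truth given) the truth values and median absolute percentage errors.
#' @export
region_stats <- function(maps, labels, truth = NULL) {
  labs <- sort(unique(as.vector(labels)))
  labs <- labs[labs != 0]
  rows <- lapply(labs, function(lb) {
    sel <- labels == lb & maps$mask & !is.na(maps$t1)
    r <- data.frame(label = lb, n_voxels = sum(sel),
                    t1_mean = mean(maps$t1[sel]), t1_sd = sd(maps$t1[sel]),
                    t1rho_mean = mean(maps$t1rho[sel]), t1rho_sd = sd(maps$t1rho[sel]),
                    t2_mean = mean(maps$t2[sel]), t2_sd = sd(maps$t2[sel]))
    if (!is.null(truth)) {
      tsel <- labels == lb
      r$t1_true <- median(truth$t1[tsel])
      r$t1rho_true <- median(truth$t1rho[tsel])
      r$t2_true <- median(truth$t2[tsel])
      r$t1_medape <- median(abs(maps$t1[sel] - r$t1_true)) / r$t1_true * 100
      r$t1rho_medape <- median(abs(maps$t1rho[sel] - r$t1rho_true)) / r$t1rho_true * 100
      r$t2_medape <- median(abs(maps$t2[sel] - r$t2_true)) / r$t2_true * 100
    }
    r
  })
  do.call(rbind, rows)
}
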