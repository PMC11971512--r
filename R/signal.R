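# Bloch simulation of the longitudinal magnetization for the 5-heartbeat
# magnetization-prepared spoiled-GRE sequence, and dictionary generation.
#
# Model: 1D longitudinal-only Bloch simulation assuming perfect spoiling.
# Preparations are instantaneous apart from their stated exponential decay
# (IR: sign flip; spin-lock: exp(-TSL/T1rho); T2-prep: exp(-dur/T2)); T1
# recovery during the preparations themselves is neglected. All functions are
# vectorized over tissues so a whole dictionary grid is simulated in one pass.

# T1 relaxation of mz towards m0 over t ms (vectorized).
relax_t1 <- function(mz, t, t1, m0) m0 + (mz - m0) * exp(-t / t1)

#' Apply a magnetization preparation to the longitudinal magnetization
#'
#' @param mz Longitudinal magnetization entering the preparation (vectorized).
#' @param prep One of `"IR"` (adiabatic inversion, perfect sign flip),
#'   `"NONE"`, `"T1RHO"` (spin-lock, factor `exp(-tsl/t1rho)`) or `"T2PREP"`
#'   (factor `exp(-t2prep_dur/t2)`).
#' @param tissue A [tissue_params()].
#' @param acq An [acq_spec()] supplying `tsl` and `t2prep_dur`.
#' @return Magnetization after the preparation.
#' @export
apply_preparation <- function(mz, prep = c("IR", "NONE", "T1RHO", "T2PREP"),
                              tissue, acq) {
  prep <- match.arg(prep)
  switch(prep,
         IR = -mz,
         NONE = mz,
         T1RHO = mz * exp(-acq$tsl / tissue$t1rho),
         T2PREP = mz * exp(-acq$t2prep_dur / tissue$t2))
}

#' Simulate one segmented spoiled-GRE readout
#'
#' Per excitation k: the acquired signal is `mz_k * sin(FA)`, the remaining
#' longitudinal magnetization is `mz_k * cos(FA)` (perfect spoiling of the
#' transverse component), and between excitations mz relaxes towards m0 with
#' time constant T1 over one TR.
#'
#' @param mz_in Longitudinal magnetization at the first excitation
#'   (vectorized over tissues).
#' @param tissue A [tissue_params()].
#' @param acq An [acq_spec()].
#' @return A list with `signal` (`[n_tissue x segments_per_hb]` matrix, or a
#'   plain vector for a single tissue) and `mz_out`, the magnetization at the
#'   end of the last TR interval.
#' @export
simulate_readout <- function(mz_in, tissue, acq) {
  nseg <- acq$segments_per_hb
  if (nseg < 1L) stop("invalid parameter: segments_per_hb must be >= 1")
  fa <- acq$flip_angle * pi / 180
  n <- length(tissue$t1)
  mz <- rep_len(mz_in, n)
  e1 <- exp(-acq$tr / tissue$t1)
  sig <- matrix(0, n, nseg)
  for (k in seq_len(nseg)) {
    sig[, k] <- mz * sin(fa)
    mz <- mz * cos(fa)
    mz <- tissue$m0 + (mz - tissue$m0) * e1
  }
  if (n == 1L) sig <- drop(sig)
  list(signal = sig, mz_out = mz)
}

# The per-heartbeat preparation schedule of the sequence.
hb_schedule <- c("IR", "NONE", "T1RHO", "T2PREP", "NONE")

#' Simulate the 5-heartbeat shot train and return the 5 dictionary points
#'
#' Runs `n_prep_cycles` repetitions of the 5-heartbeat schedule (IR with
#' inversion time TI before the readout; no preparation; spin-lock
#' preparation; T2 preparation; and a final no-preparation heartbeat) and
#' returns, for the last repetition, the mean over the first
#' `round(centric_fraction * segments_per_hb)` readout signals of each
#' heartbeat -- the k-space-centre signal under centric reordering. Values
#' are signed: the inversion-recovery contrast may be negative.
#'
#' @param tissue A [tissue_params()] (vectorized).
#' @param acq An [acq_spec()].
#' @param idle_fifth If `TRUE`, heartbeat 5 acquires no readout (pure
#'   recovery beat) and the 5th dictionary point is copied from heartbeat 2.
#'   Default `FALSE`: heartbeat 5 acquires the 5th (no-preparation) contrast.
#' @return A numeric vector of length 5 (single tissue) or an
#'   `[n_tissue x 5]` matrix of signed contrast-point signals.
#' @export
simulate_shot_train <- function(tissue, acq, idle_fifth = FALSE) {
  n <- length(tissue$t1)
  nseg <- acq$segments_per_hb
  ncentre <- max(1L, round(acq$centric_fraction * nseg))
  td <- acq$trigger_delay
  window <- nseg * acq$tr
  rest <- acq$rr_interval - td - window
  mz <- tissue$m0  # start from equilibrium
  out <- matrix(0, n, 5L)
  for (cyc in seq_len(acq$n_prep_cycles)) {
    for (hb in 1:5) {
      prep <- hb_schedule[hb]
      if (hb == 5L && idle_fifth) {
        mz <- relax_t1(mz, acq$rr_interval, tissue$t1, tissue$m0)
        next
      }
      if (prep == "IR") {
        mz <- relax_t1(mz, td - acq$ti, tissue$t1, tissue$m0)
        mz <- -mz
        mz <- relax_t1(mz, acq$ti, tissue$t1, tissue$m0)
      } else {
        mz <- relax_t1(mz, td, tissue$t1, tissue$m0)
        mz <- apply_preparation(mz, prep, tissue, acq)
      }
      ro <- simulate_readout(mz, tissue, acq)
      mz <- ro$mz_out
      if (cyc == acq$n_prep_cycles) {
        sig <- ro$signal
        if (is.null(dim(sig))) sig <- matrix(sig, 1L)
        out[, hb] <- rowMeans(sig[, seq_len(ncentre), drop = FALSE])
      }
      mz <- relax_t1(mz, rest, tissue$t1, tissue$m0)
    }
  }
  if (idle_fifth) out[, 5L] <- out[, 2L]
  if (n == 1L) drop(out) else out
}

# ---- dictionary -------------------------------------------------------------

#' Parse `[start, step, stop]` range triplets into a deduplicated value list
#'
#' @param spec Either a numeric vector of values, or a list of numeric
#'   triplets `c(start, step, stop)` (inclusive of `stop`).
#' @return Strictly increasing, deduplicated numeric vector.
#' @export
parse_ranges <- function(spec) {
  vals <- if (is.list(spec)) {
    unlist(lapply(spec, function(tr) {
      if (length(tr) != 3L) stop("range triplet must be c(start, step, stop)")
      seq(tr[1], tr[3], by = tr[2])
    }))
  } else as.numeric(spec)
  vals <- sort(unique(vals))
  if (length(vals) == 0L || any(!is.finite(vals)))
    stop("range specification produced no finite values")
  vals
}

#' Default dictionary parameter ranges
#'
#' The T1 / T1rho / T2 grids used for dictionary generation, as
#' `[start, step, stop]` triplets (ms). T1 spans 50-3000 ms with fine 15 ms
#' steps through the myocardial range; T1rho and T2 share one grid spanning
#' 5-600 ms with fine 1.5 ms steps through 20-80 ms.
#'
#' @return Named list of triplet lists for `t1`, `t1rho`, `t2`.
#' @export
default_dictionary_ranges <- function() {
  rho <- list(c(5, 5, 20), c(20, 1.5, 80), c(80, 4, 100),
              c(100, 10, 300), c(300, 100, 600))
  list(t1 = list(c(50, 50, 600), c(600, 15, 1800),
                 c(1800, 50, 2200), c(2200, 100, 3000)),
       t1rho = rho, t2 = rho)
}

#' Build the matching dictionary for the 5-heartbeat sequence
#'
#' Simulates the sequence for the Cartesian product of the T1/T1rho/T2 value
#' lists, keeping only combinations with `t2 <= t1rho <= t1`, and stores the
#' unit-L2-normalized signed 5-point signal of each combination as one
#' dictionary atom.
#'
#' @param acq An [acq_spec()].
#' @param grid_spec Named list with elements `t1`, `t1rho`, `t2`, each a
#'   numeric vector or list of `[start, step, stop]` triplets (see
#'   [parse_ranges()]). Default [default_dictionary_ranges()].
#' @param idle_fifth Passed to [simulate_shot_train()].
#' @return An object of class `qcmr_dictionary`: list with `grid` (data frame
#'   of t1, t1rho, t2), `atoms` (`[n_entries x 5]`, unit-norm rows, signed)
#'   and `acq`.
#' @export
build_dictionary <- function(acq, grid_spec = default_dictionary_ranges(),
                             idle_fifth = FALSE) {
  t1v <- parse_ranges(grid_spec$t1)
  rhov <- parse_ranges(grid_spec$t1rho)
  t2v <- parse_ranges(grid_spec$t2)
  grid <- expand.grid(t2 = t2v, t1rho = rhov, t1 = t1v,
                      KEEP.OUT.ATTRS = FALSE)[, c("t1", "t1rho", "t2")]
  keep <- grid$t2 <= grid$t1rho & grid$t1rho <= grid$t1
  grid <- grid[keep, , drop = FALSE]
  if (nrow(grid) == 0L) stop("empty dictionary grid after t2 <= t1rho <= t1 constraint")
  rownames(grid) <- NULL
  tissue <- tissue_params(grid$t1, grid$t1rho, grid$t2, m0 = 1)
  atoms <- simulate_shot_train(tissue, acq, idle_fifth = idle_fifth)
  if (is.null(dim(atoms))) atoms <- matrix(atoms, 1L)
  nrm <- sqrt(rowSums(atoms^2))
  if (any(nrm == 0)) stop("dictionary atom with zero signal; check acquisition spec")
  atoms <- atoms / nrm
  structure(list(grid = grid, atoms = atoms, acq = acq),
            class = "qcmr_dictionary")
}

#' @export
print.qcmr_dictionary <- function(x, ...) {
  cat(sprintf("qcmr dictionary: %d atoms x %d points\n", nrow(x$atoms), ncol(x$atoms)))
  cat(sprintf("  T1 %g-%g ms | T1rho %g-%g ms | T2 %g-%g ms (t2 <= t1rho <= t1)\n",
              min(x$grid$t1), max(x$grid$t1), min(x$grid$t1rho), max(x$grid$t1rho),
              min(x$grid$t2), max(x$grid$t2)))
  invisible(x)
}

#' Save / load a dictionary
#'
#' Dictionaries are persisted as a single RDS bundle holding the parameter
#' grid, the atom matrix and the acquisition spec used for generation.
#'
#' @param dict A `qcmr_dictionary`.
#' @param path File path.
#' @return `load_dictionary` returns the `qcmr_dictionary`.
#' @export
save_dictionary <- function(dict, path) {
  stopifnot(inherits(dict, "qcmr_dictionary"))
  saveRDS(dict, path)
  invisible(path)
}

#' @rdname save_dictionary
#' @export
load_dictionary <- function(path) {
  x <- readRDS(path)
  if (!inherits(x, "qcmr_dictionary")) stop("not a qcmr dictionary: ", path)
  x
}
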