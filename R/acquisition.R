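#' Tissue relaxation parameters
#'
#' Container for the voxel-level relaxation parameters used throughout the
#' simulator: longitudinal relaxation T1, rotating-frame relaxation under
#' spin-lock T1rho, transverse relaxation T2 (all ms) and equilibrium
#' magnetization M0 (arbitrary units). All arguments are recycled to a common
#' length, so the same constructor serves a single tissue or a whole
#' dictionary grid.
#'
#' @param t1,t1rho,t2 Relaxation times in ms; must be finite and positive.
#' @param m0 Equilibrium magnetization, non-negative. Default 1.
#' @param check_order If `TRUE`, require `t2 <= t1rho <= t1` (the physical
#'   ordering imposed on dictionary atoms).
#' @return An object of class `qcmr_tissue`: a list of numeric vectors
#'   `t1`, `t1rho`, `t2`, `m0` of equal length.
#' @export
tissue_params <- function(t1, t1rho, t2, m0 = 1, check_order = FALSE) {
  n <- max(length(t1), length(t1rho), length(t2), length(m0))
  t1 <- rep_len(as.numeric(t1), n); t1rho <- rep_len(as.numeric(t1rho), n)
  t2 <- rep_len(as.numeric(t2), n); m0 <- rep_len(as.numeric(m0), n)
  stopifnot_positive(t1, "t1"); stopifnot_positive(t1rho, "t1rho")
  stopifnot_positive(t2, "t2")
  if (!all(is.finite(m0)) || any(m0 < 0))
    stop("invalid parameter: m0 must be finite and non-negative")
  if (check_order && !all(t2 <= t1rho & t1rho <= t1))
    stop("tissue parameters must satisfy t2 <= t1rho <= t1")
  structure(list(t1 = t1, t1rho = t1rho, t2 = t2, m0 = m0),
            class = "qcmr_tissue")
}

#' Acquisition specification for the 5-heartbeat interleaved sequence
#'
#' All sequence timing for the magnetization-prepared Dixon GRE acquisition:
#' one preparation per heartbeat over a repeating 5-heartbeat schedule
#' (inversion recovery, none, spin-lock, T2-preparation, none), with a
#' segmented spoiled gradient-echo readout of `segments_per_hb` excitations
#' per heartbeat.
#'
#' @param rr_interval Heartbeat duration (ms). Default 1000 (60 bpm).
#' @param ti Inversion time, from the inversion pulse to the first readout
#'   excitation (centric ordering puts the k-space centre first), ms.
#' @param tsl Spin-lock duration (ms).
#' @param sla Spin-lock amplitude (Hz); carried as metadata (no dispersion
#'   model).
#' @param t2prep_dur T2-preparation duration (ms).
#' @param tr Repetition time of the readout (ms).
#' @param te1,te2 First/second (out-of-phase / in-phase) echo times (ms).
#' @param flip_angle Readout excitation flip angle (degrees).
#' @param segments_per_hb Number of readout excitations per heartbeat.
#' @param trigger_delay Delay from the start of the heartbeat to the first
#'   readout excitation (ms). Default `rr_interval - 300`, raised to `ti` and
#'   capped so the readout window fits inside the heartbeat.
#' @param n_prep_cycles Number of 5-heartbeat sets simulated; the first
#'   `n_prep_cycles - 1` establish the steady state.
#' @param centric_fraction Fraction of the readout (from the start, i.e. the
#'   k-space centre under centric reordering) averaged into each dictionary
#'   point.
#' @return An object of class `qcmr_acq` (named list of the above).
#' @export
acq_spec <- function(rr_interval = 1000, ti = 250, tsl = 40, sla = 400,
                     t2prep_dur = 40, tr = 6.71, te1 = 2.38, te2 = 4.76,
                     flip_angle = 8, segments_per_hb = 16L,
                     trigger_delay = NULL, n_prep_cycles = 3L,
                     centric_fraction = 0.30) {
  segments_per_hb <- as.integer(segments_per_hb)
  if (segments_per_hb < 1L) stop("invalid parameter: segments_per_hb must be >= 1")
  for (v in c(rr_interval, tsl, sla, t2prep_dur, tr, te1, te2, flip_angle))
    if (!is_scalar_number(v) || v <= 0) stop("invalid parameter: timings must be positive")
  if (!is_scalar_number(ti) || ti < 0) stop("invalid parameter: ti must be >= 0")
  if (!is_scalar_number(centric_fraction) || centric_fraction <= 0 || centric_fraction > 1)
    stop("invalid parameter: centric_fraction must be in (0, 1]")
  window <- segments_per_hb * tr
  if (is.null(trigger_delay)) {
    trigger_delay <- min(rr_interval - 300, rr_interval - window)
    trigger_delay <- max(trigger_delay, ti)
  }
  if (trigger_delay < ti)
    stop("invalid parameter: trigger_delay must be >= ti (inversion inside the heartbeat)")
  if (window > rr_interval - trigger_delay)
    stop("invalid parameter: segments_per_hb * tr must fit in rr_interval - trigger_delay")
  structure(list(rr_interval = rr_interval, ti = ti, tsl = tsl, sla = sla,
                 t2prep_dur = t2prep_dur, tr = tr, te1 = te1, te2 = te2,
                 flip_angle = flip_angle, segments_per_hb = segments_per_hb,
                 trigger_delay = trigger_delay,
                 n_prep_cycles = as.integer(n_prep_cycles),
                 centric_fraction = centric_fraction),
            class = "qcmr_acq")
}

#' @export
print.qcmr_acq <- function(x, ...) {
  cat("5-heartbeat joint T1/T1rho/T2 acquisition\n")
  cat(sprintf("  RR %g ms | TI %g ms | TSL %g ms @ %g Hz | T2prep %g ms\n",
              x$rr_interval, x$ti, x$tsl, x$sla, x$t2prep_dur))
  cat(sprintf("  readout: %d x TR %g ms (window %g ms), FA %g deg, TE %g/%g ms\n",
              x$segments_per_hb, x$tr, x$segments_per_hb * x$tr,
              x$flip_angle, x$te1, x$te2))
  cat(sprintf("  trigger delay %g ms | %d prep cycles | centric fraction %g\n",
              x$trigger_delay, x$n_prep_cycles, x$centric_fraction))
  invisible(x)
}

#' Duration of the per-heartbeat acquisition window
#'
#' @param acq An [acq_spec()].
#' @return `segments_per_hb * tr` in ms.
#' @export
acquisition_window_ms <- function(acq) acq$segments_per_hb * acq$tr
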