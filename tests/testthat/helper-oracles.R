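# Shared fixtures and independent oracle implementations used across the
# test files. Oracles are deliberately written as straightforward scalar /
# brute-force code, structured differently from the package's vectorized
# implementations.

# Event-driven scalar simulation of the 5-heartbeat sequence: builds an
# explicit event timeline (relax / invert / scale / excite) and interprets
# it step by step.
oracle_shot_train <- function(t1, t1rho, t2, m0, acq, idle_fifth = FALSE) {
  events <- list()
  push <- function(ev) events[[length(events) + 1L]] <<- ev
  nseg <- acq$segments_per_hb
  td <- acq$trigger_delay
  rest <- acq$rr_interval - td - nseg * acq$tr
  for (cyc in seq_len(acq$n_prep_cycles)) {
    for (hb in 1:5) {
      last <- cyc == acq$n_prep_cycles
      if (hb == 5L && idle_fifth) { push(list("relax", acq$rr_interval)); next }
      if (hb == 1L) {
        push(list("relax", td - acq$ti)); push(list("invert"))
        push(list("relax", acq$ti))
      } else {
        push(list("relax", td))
        if (hb == 3L) push(list("scale", exp(-acq$tsl / t1rho)))
        if (hb == 4L) push(list("scale", exp(-acq$t2prep_dur / t2)))
      }
      for (k in seq_len(nseg)) {
        push(list("excite", if (last) hb else 0L))
        push(list("relax", acq$tr))
      }
      push(list("relax", rest))
    }
  }
  mz <- m0
  fa <- acq$flip_angle * pi / 180
  rec <- vector("list", 5L)
  for (ev in events) {
    if (ev[[1]] == "relax") mz <- m0 + (mz - m0) * exp(-ev[[2]] / t1)
    else if (ev[[1]] == "invert") mz <- -mz
    else if (ev[[1]] == "scale") mz <- mz * ev[[2]]
    else { # excite
      if (ev[[2]] > 0L) rec[[ev[[2]]]] <- c(rec[[ev[[2]]]], mz * sin(fa))
      mz <- mz * cos(fa)
    }
  }
  ncentre <- max(1L, round(acq$centric_fraction * nseg))
  out <- vapply(rec, function(s) if (is.null(s)) NA_real_
                else mean(s[seq_len(ncentre)]), numeric(1))
  if (idle_fifth) out[5] <- out[2]
  out
}

# Brute-force count of dictionary entries from value lists under the
# physical ordering constraint (nested loops, no expand.grid).
oracle_dictionary_count <- function(t1v, rhov, t2v) {
  n <- 0L
  for (t1 in t1v) {
    for (rho in rhov) {
      if (rho > t1) next
      n <- n + sum(t2v <= rho)
    }
  }
  n
}

# Exhaustive similar-patch search on a (single-contrast) volume: all patch
# corners in the clamped window, squared L2 distances on the magnitude
# volume (the similarity contract), stable order.
oracle_patch_search <- function(vol, v, config) {
  vol <- abs(vol)
  ps <- config$patch_size
  hw <- (config$search_window - ps) %/% 2
  d <- dim(vol)
  rng <- function(x, n) max(1, x - hw):min(n - ps + 1, x + hw)
  ref <- vol[v[1]:(v[1] + ps - 1), v[2]:(v[2] + ps - 1), v[3]:(v[3] + ps - 1)]
  cand <- expand.grid(x = rng(v[1], d[1]), y = rng(v[2], d[2]),
                      z = rng(v[3], d[3]))
  dist <- numeric(nrow(cand))
  for (q in seq_len(nrow(cand))) {
    p <- vol[cand$x[q]:(cand$x[q] + ps - 1), cand$y[q]:(cand$y[q] + ps - 1),
             cand$z[q]:(cand$z[q] + ps - 1)]
    dist[q] <- sum((p - ref)^2)
  }
  ord <- order(dist, method = "radix")[seq_len(config$n_similar)]
  lin <- cand$x + (cand$y - 1) * d[1] + (cand$z - 1) * d[1] * d[2]
  lin[ord]
}

# Small acquisition spec shared by several tests.
small_acq <- function(...) acq_spec(...)

# A small 3-vial phantom on the dictionary grid.
small_phantom <- function(shape = c(32, 32, 8)) {
  make_vial_phantom(3, tissue_params(c(600, 1095, 1500), c(44, 56, 80),
                                     c(29, 44, 62)),
                    shape = shape, vial_radius = 3,
                    ring_radius = floor(min(shape[1:2]) * 0.28))
}

# Reduced dictionary ranges covering the small phantom (keeps module tests
# fast; the acceptance tests use the full grids).
small_ranges <- function() {
  list(t1 = list(c(300, 50, 600), c(600, 15, 1800)),
       t1rho = list(c(20, 1.5, 80), c(80, 4, 100)),
       t2 = list(c(20, 1.5, 80)))
}
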