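#' @importFrom stats fft rnorm runif median quantile coef lm optim sd
#' @importFrom utils write.csv
NULL

# ---- centred unitary FFT helpers -------------------------------------------
# Convention: DC sits at index floor(n/2)+1 (1-based) in both image and k-space.
# Transforms are unitary so Parseval holds exactly.

circshift1 <- function(x, shift, dim) {
  n <- dim(x)[dim]
  if (n == 1L || shift %% n == 0L) return(x)
  idx <- ((seq_len(n) - 1L - shift) %% n) + 1L
  args <- rep(list(quote(expr = )), length(dim(x)))
  args[[dim]] <- idx
  do.call(`[`, c(list(x), args, list(drop = FALSE)))
}

fftshift <- function(x, dims = seq_along(dim(x))) {
  for (d in dims) x <- circshift1(x, floor(dim(x)[d] / 2), d)
  x
}

ifftshift <- function(x, dims = seq_along(dim(x))) {
  for (d in dims) x <- circshift1(x, -floor(dim(x)[d] / 2), d)
  x
}

.chk_cache <- new.env(parent = emptyenv())

# (-1)^(i1+i2+...) checkerboard; for even dims, conjugating the FFT with it
# equals the centred (fftshift) transform, at a fraction of the indexing
# cost. Cached per shape.
checkerboard <- function(d) {
  key <- paste(d, collapse = "x")
  ch <- .chk_cache[[key]]
  if (is.null(ch)) {
    idx <- lapply(d, function(n) seq_len(n) - 1)
    g <- Reduce(function(a, b) outer(a, b, "+"), idx)
    ch <- array((-1)^as.vector(g), d)
    .chk_cache[[key]] <- ch
  }
  ch
}

#' Centred unitary FFT / inverse FFT
#'
#' Forward and inverse discrete Fourier transforms over all array dimensions,
#' with the DC component at index `floor(n/2)+1` along each axis and a
#' `1/sqrt(N)` scaling so that the transform is unitary (Parseval-exact).
#' For all-even shapes the centring is applied as a checkerboard modulation
#' (identical result, much cheaper than index shuffling).
#'
#' @param x Numeric or complex array.
#' @return Complex array of the same shape.
#' @export
fftc <- function(x) {
  d <- dim(x)
  if (is.null(d)) d <- length(x)
  if (all(d %% 2 == 0)) {
    ch <- checkerboard(d)
    return(ch * array(fft(ch * x), d) / sqrt(prod(d)))
  }
  fftshift(array(fft(ifftshift(x)), d)) / sqrt(prod(d))
}

#' @rdname fftc
#' @export
ifftc <- function(x) {
  d <- dim(x)
  if (is.null(d)) d <- length(x)
  if (all(d %% 2 == 0)) {
    ch <- checkerboard(d)
    return(ch * array(fft(ch * x, inverse = TRUE), d) / sqrt(prod(d)))
  }
  fftshift(array(fft(ifftshift(x), inverse = TRUE), d)) / sqrt(prod(d))
}

# Index-space spatial frequencies (cycles per sample) matching fftc layout.
kfreq <- function(n) (seq_len(n) - 1L - floor(n / 2)) / n

# ---- seeded RNG scoping -----------------------------------------------------
# Evaluate code under a given seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic named sub-seeds fanned out from one pipeline seed, so stages
# can be re-run in isolation. Kept below 2^31.
substream_seed <- function(seed, name) {
  offs <- c(phantom = 1L, sens = 2L, motion = 3L, noise = 4L,
            sampling = 5L, recon = 6L, misc = 7L)
  if (!name %in% names(offs)) stop("unknown substream: ", name)
  as.integer((as.numeric(seed) + offs[[name]] * 1009) %% 2147483647)
}

# ---- small numeric helpers --------------------------------------------------

l2norm <- function(x) sqrt(sum(abs(x)^2))

relerr <- function(a, b) l2norm(a - b) / max(l2norm(b), .Machine$double.eps)

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

stopifnot_positive <- function(x, what) {
  if (!all(is.finite(x)) || any(x <= 0))
    stop("invalid parameter: ", what, " must be finite and positive")
}

# Separable Gaussian smoothing of a real or complex array (reflected borders).
gauss_smooth <- function(x, sigma) {
  if (sigma <= 0) return(x)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-0.5 * ((-r:r) / sigma)^2)
  k <- k / sum(k)
  d <- dim(x)
  for (axis in seq_along(d)) {
    n <- d[axis]
    # reflect-padded 1D convolution applied along `axis`
    idx <- c(rev(seq_len(min(r, n - 1)) + 1L), seq_len(n),
             n - seq_len(min(r, n - 1)))
    if (length(idx) < n + 2 * r) { # very small axis: clamp
      idx <- pmin(pmax(c(seq_len(r) * 0 + 1L, seq_len(n), rep(n, r)), 1L), n)
    }
    perm <- c(axis, seq_along(d)[-axis])
    xp <- aperm(x, perm)
    dim(xp) <- c(n, prod(d[-axis]))
    xpad <- xp[idx, , drop = FALSE]
    out <- matrix(0, n, ncol(xp))
    if (is.complex(x)) out <- matrix(complex(real = 0), n, ncol(xp))
    for (j in seq_along(k)) out <- out + k[j] * xpad[(j - 1L) + seq_len(n), , drop = FALSE]
    dim(out) <- d[perm]
    x <- aperm(out, order(perm))
  }
  x
}
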