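# Internal numerical helpers: centred FFT conventions, seeded RNG, small stats.
#
# Throughout the package the DC element of a length-n axis sits at 0-based
# index floor(n/2), matching the centred-FFT convention used for images,
# k-space grids and the kz axis alike.

#' @importFrom stats fft mvfft rnorm prcomp sd
NULL

# circular shift of the first dimension index vector
.shift_idx <- function(n, s) ((seq_len(n) - 1L + s) %% n) + 1L

.fftshift_idx <- function(n) .shift_idx(n, -(n %/% 2L))   # index map applying fftshift
.ifftshift_idx <- function(n) .shift_idx(n, n %/% 2L)

fftshift2 <- function(x) x[.fftshift_idx(nrow(x)), .fftshift_idx(ncol(x)), drop = FALSE]
ifftshift2 <- function(x) x[.ifftshift_idx(nrow(x)), .ifftshift_idx(ncol(x)), drop = FALSE]

# Centred unnormalised 2D DFT: X[j] = sum_x x[x] exp(-2*pi*1i*(j-c)(x-c)/n)
cfft2 <- function(x) fftshift2(stats::fft(ifftshift2(x)))
# Its exact adjoint (centred unnormalised inverse DFT, no 1/N factor)
cfft2_adj <- function(x) fftshift2(stats::fft(ifftshift2(x), inverse = TRUE))

# central crop of a matrix from (nosx, nosy) to (nx, ny), centres aligned
crop_center2 <- function(x, nx, ny) {
  sx <- nrow(x) %/% 2L - nx %/% 2L
  sy <- ncol(x) %/% 2L - ny %/% 2L
  x[sx + seq_len(nx), sy + seq_len(ny), drop = FALSE]
}

# central zero-pad of a matrix to (nosx, nosy)
pad_center2 <- function(x, nosx, nosy) {
  out <- matrix(0 + 0i, nosx, nosy)
  sx <- nosx %/% 2L - nrow(x) %/% 2L
  sy <- nosy %/% 2L - ncol(x) %/% 2L
  out[sx + seq_len(nrow(x)), sy + seq_len(ncol(x))] <- x
  out
}

# Evaluate an expression with a private RNG stream; the global .Random.seed
# is left untouched so library code never perturbs user-level randomness.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# sample skewness (biased form; only its sign is ever used)
skewness <- function(x) {
  x <- x - mean(x)
  s <- sqrt(mean(x^2))
  if (s == 0) return(0)
  mean(x^3) / s^3
}

# Real inner product between complex arrays, Re<a, b> = sum Re(conj(a) * b)
re_inner <- function(a, b) sum(Re(Conj(a) * b))

# Fraction of one-sided spectral power (DC excluded) inside [band[1], band[2]] Hz
# for a series sampled at fs Hz. Returns 0 for a constant series.
band_power_fraction <- function(x, fs, band) {
  n <- length(x)
  x <- x - mean(x)
  if (all(x == 0)) return(0)
  p <- Mod(stats::fft(x))^2
  f <- (seq_len(n) - 1L) * fs / n
  half <- f > 0 & f <= fs / 2
  inband <- half & f >= band[1] & f <= band[2]
  sum(p[inband]) / sum(p[half])
}

stopifnot_scalar <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || (positive && x <= 0))
    stop(sprintf("'%s' must be a finite positive scalar", name), call. = FALSE)
  invisible(x)
}

# operation counter used to assert how work scales with the number of bins
.op_counter <- new.env(parent = emptyenv())
.op_counter$nufft <- 0L

#' Reset or read the non-uniform transform call counter
#'
#' Every application of a type-1 or type-2 non-uniform transform (fast
#' gridding or exact DFT) to a single 2D image or sample set increments an
#' internal counter; coil stacks count one call per coil. The counter makes
#' work-scaling properties (e.g. linearity in the number of respiratory
#' bins) assertable as operation counts rather than wall time.
#'
#' @return `nufft_call_count()` returns the current count (integer).
#' @export
nufft_call_count <- function() .op_counter$nufft

#' @rdname nufft_call_count
#' @export
nufft_call_reset <- function() {
  .op_counter$nufft <- 0L
  invisible(0L)
}

.count_nufft <- function(k = 1L) {
  .op_counter$nufft <- .op_counter$nufft + as.integer(k)
  invisible(NULL)
}
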