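# Volume comparison (SSIM) and the Amdahl's-law timing predictors.

# separable Gaussian "valid" filtering matrix: rows index valid positions
.ssim_filter <- function(n, window, sigma) {
  t <- seq_len(window) - (window + 1) / 2
  g <- exp(-t^2 / (2 * sigma^2))
  g <- g / sum(g)
  nv <- n - window + 1L
  if (nv < 1) stop("window larger than image", call. = FALSE)
  W <- matrix(0, nv, n)
  for (i in seq_len(nv)) W[i, i + seq_len(window) - 1L] <- g
  W
}

# SSIM between two real 2D images over the valid filtering region
.ssim2d <- function(x, y, L, window, sigma, k1, k2) {
  Wr <- .ssim_filter(nrow(x), window, sigma)
  Wc <- .ssim_filter(ncol(x), window, sigma)
  f <- function(z) Wr %*% z %*% t(Wc)
  mx <- f(x); my <- f(y)
  vx <- f(x^2) - mx^2
  vy <- f(y^2) - my^2
  cxy <- f(x * y) - mx * my
  c1 <- (k1 * L)^2; c2 <- (k2 * L)^2
  mean(((2 * mx * my + c1) * (2 * cxy + c2)) /
         ((mx^2 + my^2 + c1) * (vx + vy + c2)))
}

#' Structural similarity between two 4D volumes
#'
#' Standard SSIM with a Gaussian window, computed on magnitude images per
#' (slice, bin) over the valid filtering region and averaged. The dynamic
#' range is the maximum magnitude of `a` (the reference volume); identical
#' volumes score exactly 1.
#'
#' @param a,b `volume4d` objects or complex/numeric 4D arrays
#'   `{nx, ny, nz, n_bins}` of identical shape.
#' @param window Gaussian window size (default 11).
#' @param sigma Gaussian window standard deviation (default 1.5).
#' @param k1,k2 SSIM stabilisation constants (defaults 0.01, 0.03).
#' @return List with `mean` (scalar), `per_bin` (length `n_bins`) and
#'   `per_slice_bin` (`{nz, n_bins}` matrix).
#' @export
ssim_4d <- function(a, b, window = 11L, sigma = 1.5, k1 = 0.01, k2 = 0.03) {
  A <- if (inherits(a, "volume4d")) a$image else a
  B <- if (inherits(b, "volume4d")) b$image else b
  if (!identical(dim(A), dim(B)))
    stop("volumes must have identical shape", call. = FALSE)
  A <- Mod(A); B <- Mod(B)
  L <- max(A)
  d <- dim(A)
  scores <- matrix(0, d[3], d[4])
  for (z in seq_len(d[3])) for (bb in seq_len(d[4]))
    scores[z, bb] <- .ssim2d(A[, , z, bb], B[, , z, bb], L,
                             window, sigma, k1, k2)
  list(mean = mean(scores), per_bin = colMeans(scores),
       per_slice_bin = scores)
}

#' Timing breakdown of a slice-parallel reconstruction
#'
#' Holds the serial stage times (data preparation, thread start-up, NUFFT
#' planning, host-device transfers) and the per-slice solve times used by
#' the Amdahl's-law predictors.
#'
#' @param t_preparation,t_threading,t_plan,t_transfers stage times in
#'   seconds (>= 0).
#' @param t_slice numeric vector of per-slice reconstruction seconds.
#' @return An object of class `timing_breakdown`.
#' @export
timing_breakdown <- function(t_preparation = 0, t_threading = 0,
                             t_plan = 0, t_transfers = 0, t_slice = 0) {
  vals <- c(t_preparation, t_threading, t_plan, t_transfers, t_slice)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("all timing components must be finite and >= 0", call. = FALSE)
  structure(list(t_preparation = t_preparation, t_threading = t_threading,
                 t_plan = t_plan, t_transfers = t_transfers,
                 t_slice = t_slice),
            class = "timing_breakdown")
}

#' Amdahl's-law reconstruction-time predictors
#'
#' With at least one worker per slice, the parallel reconstruction time is
#' bounded below by the serial stages plus the slowest slice:
#' `amdahl_cpu()` returns
#' `t_preparation + t_threading + t_plan + max(t_slice)`; `amdahl_gpu()`
#' returns `t_preparation + t_transfers + max(t_slice)` (planning masked
#' by the transfers), with the idealisation `max(t_slice) -> 0` under
#' infinite parallelism available as a flag.
#'
#' @param t a [timing_breakdown()].
#' @param infinite_parallelism drop the slice term (GPU idealisation).
#' @return Predicted seconds (scalar).
#' @export
amdahl_cpu <- function(t) {
  stopifnot(inherits(t, "timing_breakdown"))
  t$t_preparation + t$t_threading + t$t_plan + max(t$t_slice)
}

#' @rdname amdahl_cpu
#' @export
amdahl_gpu <- function(t, infinite_parallelism = FALSE) {
  stopifnot(inherits(t, "timing_breakdown"))
  slice <- if (infinite_parallelism) 0 else max(t$t_slice)
  t$t_preparation + t$t_transfers + slice
}
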