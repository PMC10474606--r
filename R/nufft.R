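# Non-uniform Fourier transforms between a Cartesian image grid and radial
# k-space samples.
#
# Two engines share one planning interface:
#   * nufft_plan()  - fast gridding NUFFT: min-max (least-squares optimal)
#     interpolation on an oversampled FFT grid with an alternately optimised
#     separable scaling (deapodization), realised as a sparse spreading
#     matrix so that type-1 is the exact adjoint of type-2 by construction.
#   * nudft_plan()  - exact direct-summation non-uniform DFT, O(M*N), used
#     as the accuracy oracle and as the simulation/reference engine.
#
# Conventions: image DC voxel and k-space DC sample at 0-based index
# floor(n/2); coordinates in normalised radians within [-pi, pi); type-2
# evaluates s_m = sum_x f[x] exp(-1i * k_m . (x - c)).

#' NUFFT accuracy configuration
#'
#' The gridding NUFFT interpolates an FFT computed on a grid oversampled by
#' factor `oversampling` using an interpolator of width `kernel_width` grid
#' cells. For a relative accuracy of 1e-3 the standard width is 4 at
#' oversampling 2.0 and 5 at oversampling 1.25; those defaults are filled
#' in automatically. The interpolation weights are least-squares optimal
#' for the configured support width, and the plan guarantees `tolerance` by
#' rounding the fine grid up by a few cells when the aliasing floor of the
#' configured width demands it (the width itself - the per-sample cost -
#' is never changed; at oversampling 2.0 the grid is exactly 2n). The
#' documented complexity is O(M * mu^2 + J^2 N log(J^2 N)) with M k-space
#' samples, N image pixels, J = `oversampling` and mu = `kernel_width`.
#'
#' @param oversampling grid oversampling factor R (1.25 and 2.0 are the
#'   standard working points).
#' @param tolerance target relative L2 accuracy in (0, 1), default `1e-3`.
#' @param kernel_width interpolation support width in grid cells (an
#'   integer of at least 2); defaults to 4 when `oversampling >= 2`, 5
#'   otherwise.
#' @return An object of class `nufft_config`.
#' @export
nufft_config <- function(oversampling = 2, tolerance = 1e-3,
                         kernel_width = NULL) {
  if (!is.numeric(oversampling) || oversampling <= 1)
    stop("'oversampling' must exceed 1", call. = FALSE)
  if (!is.numeric(tolerance) || tolerance <= 0 || tolerance >= 1)
    stop("'tolerance' must lie in (0, 1)", call. = FALSE)
  if (is.null(kernel_width))
    kernel_width <- if (oversampling >= 2) 4L else 5L
  if (kernel_width < 2) stop("'kernel_width' must be >= 2", call. = FALSE)
  structure(list(oversampling = oversampling, tolerance = tolerance,
                 kernel_width = as.integer(kernel_width)),
            class = "nufft_config")
}

# Kaiser-Bessel kernel on [-w/2, w/2] (used to seed the scaling
# optimisation); beta from Beatty's formula for per-axis oversampling sigma.
.kb_beta <- function(w, sigma) pi * sqrt((w / sigma)^2 * (sigma - 0.5)^2 - 0.8)

.kb_eval <- function(u, w, beta) {
  t <- 1 - (2 * u / w)^2
  out <- numeric(length(u))
  ok <- t > 0
  out[ok] <- besselI(beta * sqrt(t[ok]), 0) / besselI(beta, 0)
  out
}

# kernel support offsets relative to the base grid index (floor for even
# widths, round for odd) so that all support points lie within w/2 cells
.kb_base_offsets <- function(w) {
  if (w %% 2L == 0L) seq.int(-w %/% 2L + 1L, w %/% 2L) else
    seq.int(-(w %/% 2L), w %/% 2L)
}

.grid_base <- function(g, w) if (w %% 2L == 0L) floor(g) else floor(g + 0.5)

# Conservative aliasing-floor model for a width-w interpolator at per-axis
# oversampling sigma (2D relative L2); used to pick the fine-grid size.
.nufft_err_model <- function(sigma, w) 2 * sqrt(2) * exp(-pi * w * sqrt(1 - 1 / sigma))

# smallest even fine-grid size >= sigma*n whose aliasing floor meets tol
.fine_grid_size <- function(n, sigma, w, tol) {
  nos <- 2L * as.integer(ceiling(sigma * n / 2))
  while (.nufft_err_model(nos / n, w) > tol && nos < 4L * n) nos <- nos + 2L
  nos
}

# continuous-FT deapodization of the Kaiser-Bessel kernel by quadrature;
# seeds the alternating scaling optimisation
.kb_quad_deapod <- function(n, nos, w, beta) {
  du <- 1 / 32
  u <- seq(-w / 2 + du / 2, w / 2 - du / 2, by = du)
  phi <- .kb_eval(u, w, beta)
  xs <- (seq_len(n) - 1 - n %/% 2) / nos
  ft <- vapply(xs, function(xi) sum(phi * cos(2 * pi * u * xi)) * du, 0)
  1 / ft
}

# Per-axis min-max machinery. For a scaling d[x], the LS-optimal width-w
# interpolation weights at frequency k solve A u = psi(k), where
#   A[o,p]   = sum_x d^2 exp(+2i pi (o-p)(x-c)/nos)        (w x w, fixed)
#   psi_o(k) = sum_x d   exp(-i (k - 2 pi (j_o-c_os)/nos)(x-c))
# The scaling itself is refined by alternating LS on a fine frequency grid
# (Fessler-style optimised scaling factors). Memoised per geometry.
.axis_cache <- new.env(parent = emptyenv())

.axis_scaling <- function(n, nos, w, iters = 8L, per_cell = 6L) {
  key <- paste(n, nos, w, sep = "|")
  hit <- .axis_cache[[key]]
  if (!is.null(hit)) return(hit)
  c_os <- nos %/% 2L
  xs <- seq_len(n) - 1 - n %/% 2L
  d <- .kb_quad_deapod(n, nos, w, .kb_beta(w, nos / n))
  ks <- seq(-pi, pi, length.out = nos * per_cell + 1)[-(nos * per_cell + 1)]
  g <- ks * nos / (2 * pi) + c_os
  base <- .grid_base(g, w)
  offs <- .kb_base_offsets(w)
  J <- outer(base, offs, `+`)
  E <- exp(-1i * outer(ks, xs))
  for (it in seq_len(iters)) {
    A <- .axis_gram(d, xs, nos, offs)
    rhs <- matrix(0i, length(ks), w)
    for (o in seq_len(w))
      rhs[, o] <- (exp(2i * pi * outer(J[, o] - c_os, xs) / nos) * E) %*% d
    U <- t(solve(A, t(rhs)))
    Tm <- matrix(0i, length(ks), n)
    for (o in seq_len(w))
      Tm <- Tm + U[, o] * exp(-2i * pi * outer(J[, o] - c_os, xs) / nos)
    d <- Re(colSums(Conj(Tm) * E) / colSums(Mod(Tm)^2))
  }
  .axis_cache[[key]] <- d
  d
}

.axis_gram <- function(d, xs, nos, offs) {
  ts <- outer(offs, offs, `-`)
  vals <- vapply(as.vector(ts),
                 function(t) sum(d^2 * exp(2i * pi * t * xs / nos)),
                 complex(1))
  matrix(vals, length(offs), length(offs))
}

# per-sample LS-optimal axis weights for coordinates k given scaling d
.axis_weights <- function(k, n, nos, w, d) {
  c_os <- nos %/% 2L
  xs <- seq_len(n) - 1 - n %/% 2L
  g <- k * nos / (2 * pi) + c_os
  base <- .grid_base(g, w)
  offs <- .kb_base_offsets(w)
  J <- outer(base, offs, `+`)
  A <- .axis_gram(d, xs, nos, offs)
  delta <- k - 2 * pi * (J - c_os) / nos
  Psi <- matrix(exp(-1i * outer(as.vector(delta), xs)) %*% d, length(k), w)
  list(idx = J %% nos, wt = t(solve(A, t(Psi))))
}

#' Plan a gridding NUFFT for fixed sample locations
#'
#' Precomputes the sparse spreading matrix (min-max interpolation weights)
#' and scaling factors for a fixed set of non-uniform sample locations and
#' grid size. Planning is the expensive step; the returned plan is reused
#' for every subsequent transform with the same geometry (once per type and
#' per worker in the parallel solver).
#'
#' @param kx,ky sample coordinates in normalised radians, each in
#'   `[-pi, pi)`; vectors (or matrices, flattened) of equal length M.
#' @param nx,ny image grid size.
#' @param config a [nufft_config()].
#' @return An object of class `nufft_plan`.
#' @export
nufft_plan <- function(kx, ky, nx, ny, config = nufft_config()) {
  kx <- as.vector(kx); ky <- as.vector(ky)
  if (length(kx) != length(ky)) stop("kx/ky length mismatch", call. = FALSE)
  if (any(kx < -pi | kx >= pi | ky < -pi | ky >= pi))
    stop("sample coordinates must lie in [-pi, pi)", call. = FALSE)
  w <- config$kernel_width
  nosx <- .fine_grid_size(nx, config$oversampling, w, config$tolerance)
  nosy <- .fine_grid_size(ny, config$oversampling, w, config$tolerance)
  dx <- .axis_scaling(nx, nosx, w)
  dy <- .axis_scaling(ny, nosy, w)
  axx <- .axis_weights(kx, nx, nosx, w, dx)
  axy <- .axis_weights(ky, ny, nosy, w, dy)
  M <- length(kx)
  rows <- rep(seq_len(M), times = w * w)
  cols <- integer(M * w * w)
  vals <- complex(M * w * w)
  p <- 0L
  for (ox in seq_len(w)) for (oy in seq_len(w)) {
    ii <- p * M + seq_len(M)
    cols[ii] <- axx$idx[, ox] + axy$idx[, oy] * nosx + 1L
    vals[ii] <- axx$wt[, ox] * axy$wt[, oy]
    p <- p + 1L
  }
  Sre <- Matrix::sparseMatrix(i = rows, j = cols, x = Re(vals),
                              dims = c(M, nosx * nosy))
  Sim <- Matrix::sparseMatrix(i = rows, j = cols, x = Im(vals),
                              dims = c(M, nosx * nosy))
  structure(list(Sre = Sre, Sim = Sim,
                 Sre_t = Matrix::t(Sre), Sim_t = Matrix::t(Sim),
                 deapod = outer(dx, dy),
                 nx = as.integer(nx), ny = as.integer(ny),
                 nosx = nosx, nosy = nosy, M = M, config = config),
            class = "nufft_plan")
}

# complex sparse pair (Sre + 1i*Sim) times complex matrix
.sp_cmul <- function(Sre, Sim, z) {
  z <- as.matrix(z)
  zr <- Re(z); zi <- Im(z)
  (as.matrix(Sre %*% zr) - as.matrix(Sim %*% zi)) +
    1i * (as.matrix(Sre %*% zi) + as.matrix(Sim %*% zr))
}

# conjugate-transposed pair (Sre_t - 1i*Sim_t) times complex matrix
.sp_cmul_h <- function(Sre_t, Sim_t, z) {
  z <- as.matrix(z)
  zr <- Re(z); zi <- Im(z)
  (as.matrix(Sre_t %*% zr) + as.matrix(Sim_t %*% zi)) +
    1i * (as.matrix(Sre_t %*% zi) - as.matrix(Sim_t %*% zr))
}

#' Apply a planned non-uniform transform
#'
#' `ksp_forward()` is the type-2 transform (uniform image to non-uniform
#' samples); `ksp_adjoint()` is the type-1 transform (samples to image),
#' implemented as the exact adjoint of the forward plan. Both accept a
#' single image/sample set or a stack with one slice/column per coil.
#'
#' @param plan a `nufft_plan` or `nudft_plan`.
#' @param x for `ksp_forward` an `{nx, ny}` complex matrix or
#'   `{nx, ny, n}` array; for `ksp_adjoint` a length-M complex vector or
#'   `{M, n}` matrix.
#' @return Samples (`M` vector or `{M, n}` matrix) or images (`{nx, ny}`
#'   matrix or `{nx, ny, n}` array) correspondingly.
#' @export
ksp_forward <- function(plan, x) UseMethod("ksp_forward")

#' @rdname ksp_forward
#' @export
ksp_adjoint <- function(plan, x) UseMethod("ksp_adjoint")

#' @export
ksp_forward.nufft_plan <- function(plan, x) {
  single <- length(dim(x)) < 3L
  if (single) x <- array(x, c(plan$nx, plan$ny, 1L))
  n <- dim(x)[3]
  .count_nufft(n)
  out <- matrix(0 + 0i, plan$M, n)
  for (j in seq_len(n)) {
    g <- pad_center2(x[, , j] * plan$deapod, plan$nosx, plan$nosy)
    G <- cfft2(g)
    out[, j] <- .sp_cmul(plan$Sre, plan$Sim, as.vector(G))
  }
  if (single) out[, 1] else out
}

#' @export
ksp_adjoint.nufft_plan <- function(plan, x) {
  x <- if (is.null(dim(x))) matrix(x, ncol = 1L) else x
  n <- ncol(x)
  .count_nufft(n)
  out <- array(0 + 0i, c(plan$nx, plan$ny, n))
  for (j in seq_len(n)) {
    G <- matrix(.sp_cmul_h(plan$Sre_t, plan$Sim_t, x[, j]),
                plan$nosx, plan$nosy)
    img <- crop_center2(cfft2_adj(G), plan$nx, plan$ny)
    out[, , j] <- img * Conj(plan$deapod)
  }
  if (n == 1L) out[, , 1] else out
}

#' Plan an exact non-uniform DFT (oracle engine)
#'
#' Precomputes the separable complex exponential factors for direct
#' summation over all image voxels. Exact to floating point, with cost
#' O(M * N); a guard refuses problems beyond desk scale (about 1e8
#' products) for which the gridding NUFFT should be used instead.
#'
#' @inheritParams nufft_plan
#' @param max_products resource guard on `M * nx * ny`.
#' @return An object of class `nudft_plan`.
#' @export
nudft_plan <- function(kx, ky, nx, ny, max_products = 1e8) {
  kx <- as.vector(kx); ky <- as.vector(ky)
  if (length(kx) != length(ky)) stop("kx/ky length mismatch", call. = FALSE)
  if (length(kx) * nx * ny > max_products)
    stop("exact NUDFT size guard exceeded; use the gridding NUFFT",
         call. = FALSE)
  xs <- seq_len(nx) - 1 - nx %/% 2
  ys <- seq_len(ny) - 1 - ny %/% 2
  structure(list(Ex = exp(-1i * outer(kx, xs)),  # M x nx
                 Ey = exp(-1i * outer(ky, ys)),  # M x ny
                 nx = as.integer(nx), ny = as.integer(ny), M = length(kx)),
            class = "nudft_plan")
}

#' @export
ksp_forward.nudft_plan <- function(plan, x) {
  single <- length(dim(x)) < 3L
  if (single) x <- array(x, c(plan$nx, plan$ny, 1L))
  n <- dim(x)[3]
  .count_nufft(n)
  B <- plan$Ex %*% matrix(x, plan$nx, plan$ny * n)   # M x (ny*n), one zgemm
  out <- matrix(0 + 0i, plan$M, n)
  for (j in seq_len(n))
    out[, j] <- rowSums(B[, (j - 1L) * plan$ny + seq_len(plan$ny),
                          drop = FALSE] * plan$Ey)
  if (single) out[, 1] else out
}

#' @export
ksp_adjoint.nudft_plan <- function(plan, x) {
  x <- if (is.null(dim(x))) matrix(x, ncol = 1L) else x
  n <- ncol(x)
  .count_nufft(n)
  out <- array(0 + 0i, c(plan$nx, plan$ny, n))
  Eyc <- Conj(plan$Ey)
  for (j in seq_len(n)) {
    B <- Eyc * x[, j]                       # M x ny, column recycling
    out[, , j] <- crossprod(Conj(plan$Ex), B)
  }
  if (n == 1L) out[, , 1] else out
}

#' Exact non-uniform DFT without explicit planning
#'
#' Convenience wrapper around [nudft_plan()] for one-off oracle
#' evaluations: `direction = "forward"` maps an image to samples (type-2
#' analogue), `"adjoint"` maps samples to an image (type-1 analogue).
#'
#' @param x image matrix (forward) or sample vector (adjoint).
#' @param kx,ky sample coordinates in normalised radians.
#' @param direction `"forward"` or `"adjoint"`.
#' @param grid for the adjoint, the target image size `c(nx, ny)`.
#' @param max_products resource guard on `M * nx * ny`.
#' @return Complex samples or image.
#' @export
exact_nudft <- function(x, kx, ky, direction = c("forward", "adjoint"),
                        grid = NULL, max_products = 1e8) {
  direction <- match.arg(direction)
  if (direction == "forward") {
    p <- nudft_plan(kx, ky, nrow(x), ncol(x), max_products)
    ksp_forward(p, x)
  } else {
    if (is.null(grid)) stop("'grid' required for the adjoint", call. = FALSE)
    p <- nudft_plan(kx, ky, grid[1], grid[2], max_products)
    ksp_adjoint(p, x)
  }
}

#' Type-2 (image to k-space) and type-1 (k-space to image) gridding NUFFT
#'
#' One-shot wrappers that plan and apply a gridding transform. For repeated
#' transforms with fixed geometry build a [nufft_plan()] once and use
#' [ksp_forward()] / [ksp_adjoint()].
#'
#' @param image complex `{nx, ny}` matrix.
#' @param samples complex vector of length M.
#' @param kx,ky coordinates in normalised radians in `[-pi, pi)`.
#' @param grid target image size `c(nx, ny)` for type-1.
#' @param config a [nufft_config()].
#' @return Complex samples (type-2) or image (type-1); relative L2 error
#'   versus the exact non-uniform DFT bounded by `config$tolerance`.
#' @export
nufft_type2 <- function(image, kx, ky, config = nufft_config()) {
  ksp_forward(nufft_plan(kx, ky, nrow(image), ncol(image), config), image)
}

#' @rdname nufft_type2
#' @export
nufft_type1 <- function(samples, kx, ky, grid, config = nufft_config()) {
  ksp_adjoint(nufft_plan(kx, ky, grid[1], grid[2], config), samples)
}
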