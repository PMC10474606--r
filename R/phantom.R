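# Synthetic respiratory-moving phantoms and exact stack-of-stars k-space.
#
# The simulator stands in for patient acquisitions: a quasi-periodic
# breathing trace drives an ellipse phantom whose geometry is affine in the
# respiratory amplitude; multi-coil k-space is evaluated by EXACT
# non-uniform DFT per kz plane (never by the gridding NUFFT, so simulated
# data are free of the approximation being tested) with ground truth
# retained for recovery tests.

#' Generate a quasi-periodic respiratory trace sampled per spoke
#'
#' The surrogate is `sin(2 pi f t) + drift * t + noise` rescaled to
#' `[0, 1]`; one sample per spoke at interval `spoke_interval_s`. The
#' default cadence mirrors a clinical abdominal protocol acquiring 831
#' spokes in 287 s (about 0.345 s per spoke). Amplitude 1 is taken as
#' end-inspiration.
#'
#' @param duration_s total duration in seconds (> 0).
#' @param spoke_interval_s time between spokes in seconds (> 0).
#' @param frequency_hz breathing frequency in Hz (> 0; typical 0.2-0.3).
#' @param drift slow baseline drift per second (dimensionless, applied
#'   before rescaling). The default keeps the accumulated drift over a
#'   clinical 287 s scan well below the breathing peak-to-peak amplitude,
#'   as observed physiologically.
#' @param noise_sd standard deviation of additive Gaussian noise.
#' @param seed RNG seed; the trace is reproduced bitwise for equal seeds.
#' @return An object of class `respiratory_trace`: list with `times`,
#'   `amplitude` (both length `round(duration_s / spoke_interval_s)`) and
#'   `params`.
#' @export
make_respiratory_trace <- function(duration_s, spoke_interval_s,
                                   frequency_hz = 0.25, drift = 0.003,
                                   noise_sd = 0.05, seed = 1L) {
  stopifnot_scalar(duration_s, "duration_s")
  stopifnot_scalar(spoke_interval_s, "spoke_interval_s")
  if (!is.numeric(frequency_hz) || frequency_hz <= 0)
    stop("'frequency_hz' must be positive", call. = FALSE)
  n <- as.integer(round(duration_s / spoke_interval_s))
  times <- (seq_len(n) - 1) * spoke_interval_s
  raw <- sin(2 * pi * frequency_hz * times) + drift * times +
    with_seed(seed, rnorm(n, 0, noise_sd))
  rng <- range(raw)
  amp <- if (diff(rng) > 0) (raw - rng[1]) / diff(rng) else rep(0.5, n)
  structure(list(times = times, amplitude = amp,
                 params = list(frequency_hz = frequency_hz, drift = drift,
                               noise_sd = noise_sd, seed = seed,
                               spoke_interval_s = spoke_interval_s)),
            class = "respiratory_trace")
}

#' Deformable ellipse phantom
#'
#' A motion phantom is a list of ellipses whose centre, semi-axes and
#' rotation are affine functions of the respiratory amplitude `a` in
#' `[0, 1]`: parameter(a) = value + a * delta. Coordinates live in the unit
#' field of view `[-0.5, 0.5)` in x, y and (nominal) z; every ellipse must
#' stay inside the FOV over the whole amplitude range.
#'
#' @param ellipses list of ellipse descriptions; each a list with fields
#'   `centre` (x, y), `axes` (semi-axes), `rot` (degrees), `intensity`
#'   (complex), `z` (c(zmin, zmax) slab in nominal-FOV units) and optional
#'   motion deltas `d_centre`, `d_axes`, `d_rot` (defaults 0).
#' @return An object of class `motion_phantom`.
#' @export
motion_phantom <- function(ellipses) {
  ell <- lapply(ellipses, function(e) {
    e$d_centre <- if (is.null(e$d_centre)) c(0, 0) else e$d_centre
    e$d_axes <- if (is.null(e$d_axes)) c(0, 0) else e$d_axes
    e$d_rot <- if (is.null(e$d_rot)) 0 else e$d_rot
    for (a in c(0, 1)) {
      ctr <- e$centre + a * e$d_centre
      ax <- e$axes + a * e$d_axes
      if (any(abs(ctr) + ax > 0.5))
        stop("ellipse leaves the unit field of view over a in [0, 1]",
             call. = FALSE)
    }
    e
  })
  structure(list(ellipses = ell), class = "motion_phantom")
}

#' Default abdominal-like motion phantom
#'
#' Three structures inside a static oval "body": a large superior-inferior
#' translating "organ" (the respiratory mover, default excursion
#' `excursion` FOV units along y), a small co-moving lesion, and a static
#' posterior disc. Intended as a standard fixture for self-gating and
#' reconstruction tests; the mover's excursion in voxels is
#' `excursion * ny`.
#'
#' @param excursion peak-to-peak motion amplitude in FOV units.
#' @return A [motion_phantom()].
#' @export
default_motion_phantom <- function(excursion = 0.12) {
  motion_phantom(list(
    list(centre = c(0, 0), axes = c(0.44, 0.40), rot = 0,
         intensity = 0.6 + 0i, z = c(-0.5, 0.5)),
    list(centre = c(-0.05, -0.10), axes = c(0.16, 0.13), rot = 15,
         intensity = 0.9 + 0.15i, z = c(-0.35, 0.35),
         d_centre = c(0, excursion)),
    list(centre = c(-0.02, -0.06), axes = c(0.045, 0.04), rot = 0,
         intensity = 1.4 + 0i, z = c(-0.15, 0.2),
         d_centre = c(0, excursion)),
    list(centre = c(0.22, 0.18), axes = c(0.09, 0.07), rot = -20,
         intensity = 1.1 - 0.1i, z = c(-0.3, 0.1))
  ))
}

#' Render a motion phantom at a fixed respiratory amplitude
#'
#' Voxel value = sum of the intensities of all ellipses containing the
#' voxel centre at amplitude `a`. Voxel centres sit at
#' `(i - floor(n/2)) / n` in FOV units per in-plane axis. Along z the grid
#' has `grid[3]` planes; `z_fov` sets how many of those planes span the
#' nominal unit FOV (defaults to all of them), so an oversampled kz axis
#' renders the phantom into the central `z_fov` planes with empty margins.
#'
#' @param phantom a [motion_phantom()].
#' @param a respiratory amplitude in `[0, 1]`.
#' @param grid integer `c(nx, ny, nz)`.
#' @param z_fov number of z planes spanning the nominal FOV.
#' @return Complex array `{nx, ny, nz}`.
#' @export
render_phantom <- function(phantom, a, grid, z_fov = grid[3]) {
  stopifnot(inherits(phantom, "motion_phantom"))
  if (a < 0 || a > 1) stop("'a' must lie in [0, 1]", call. = FALSE)
  nx <- grid[1]; ny <- grid[2]; nz <- grid[3]
  xs <- (seq_len(nx) - 1 - nx %/% 2) / nx
  ys <- (seq_len(ny) - 1 - ny %/% 2) / ny
  zs <- (seq_len(nz) - 1 - nz %/% 2) / z_fov
  X <- matrix(xs, nx, ny)
  Y <- matrix(ys, nx, ny, byrow = TRUE)
  out <- array(0 + 0i, c(nx, ny, nz))
  for (e in phantom$ellipses) {
    ctr <- e$centre + a * e$d_centre
    ax <- e$axes + a * e$d_axes
    th <- (e$rot + a * e$d_rot) * pi / 180
    U <- (X - ctr[1]) * cos(th) + (Y - ctr[2]) * sin(th)
    V <- -(X - ctr[1]) * sin(th) + (Y - ctr[2]) * cos(th)
    inside <- (U / ax[1])^2 + (V / ax[2])^2 <= 1
    zsel <- which(zs >= e$z[1] & zs <= e$z[2] & zs >= -0.5 & zs < 0.5)
    add <- matrix(0 + 0i, nx, ny)
    add[inside] <- e$intensity
    for (k in zsel) out[, , k] <- out[, , k] + add
  }
  out
}

#' Smooth synthetic coil-sensitivity maps
#'
#' Complex Gaussian-bump sensitivities with smooth linear phase ramps,
#' emulating an anterior/posterior surface-coil array: coil centres
#' alternate around the FOV perimeter, magnitudes are broad Gaussians
#' (everywhere positive, so the root-sum-of-squares never vanishes) and
#' each coil carries a mild low-order phase.
#'
#' @param grid integer `c(nx, ny, nz)`.
#' @param n_coils number of coils (default 8: four anterior, four
#'   posterior).
#' @param seed RNG seed for the phase-ramp draws.
#' @return An object of class `coil_model`: list with complex `maps`
#'   `{nx, ny, nz, n_coils}`.
#' @export
make_coil_maps <- function(grid, n_coils = 8L, seed = 1L) {
  nx <- grid[1]; ny <- grid[2]; nz <- grid[3]
  xs <- (seq_len(nx) - 1 - nx %/% 2) / nx
  ys <- (seq_len(ny) - 1 - ny %/% 2) / ny
  zs <- if (nz > 1) (seq_len(nz) - 1 - nz %/% 2) / nz else 0
  ang <- 2 * pi * (seq_len(n_coils) - 1) / n_coils + pi / n_coils
  ph <- with_seed(seed, matrix(rnorm(3 * n_coils, 0, 1.5), 3, n_coils))
  maps <- array(0 + 0i, c(nx, ny, nz, n_coils))
  X <- matrix(xs, nx, ny)
  Y <- matrix(ys, nx, ny, byrow = TRUE)
  for (cix in seq_len(n_coils)) {
    cx <- 0.55 * cos(ang[cix]); cy <- 0.55 * sin(ang[cix])
    mag2d <- exp(-((X - cx)^2 + (Y - cy)^2) / (2 * 0.35^2))
    pha2d <- ph[1, cix] * X + ph[2, cix] * Y
    for (k in seq_len(nz)) {
      zmod <- exp(-(zs[k])^2 / (2 * 0.6^2))
      maps[, , k, cix] <- (0.05 + mag2d * zmod) *
        exp(1i * (pha2d + ph[3, cix] * zs[k]))
    }
  }
  structure(list(maps = maps), class = "coil_model")
}

#' Simulate a golden-angle stack-of-stars acquisition of a moving phantom
#'
#' For each spoke the phantom is rendered at the trace amplitude of that
#' spoke's timestamp, multiplied by every coil map, transformed along z by
#' a centred orthonormal FFT, and each kz plane is evaluated at the spoke's
#' in-plane sample locations by exact non-uniform DFT. All kz encodes of a
#' spoke share the spoke's timestamp (the kz loop is fast relative to
#' breathing). The kz axis is oversampled by `kz_oversampling` relative to
#' the `nz` nominal slices, mirroring clinical protocols; the surplus
#' encodes are cropped after the kz FFT during reconstruction.
#'
#' @param phantom a [motion_phantom()].
#' @param coils a [make_coil_maps()] result; its z extent must equal the
#'   oversampled kz count `round(kz_oversampling * nz)`.
#' @param spec a [trajectory_spec()]; one spoke per trace sample.
#' @param trace a [make_respiratory_trace()]; `length == n_spokes`.
#' @param nz nominal slice count.
#' @param kz_oversampling oversampling factor along kz (default 1.61).
#' @param n_bins_truth number of respiratory bins at which ground-truth
#'   images are rendered (amplitude bins of the trace; bin 1 =
#'   end-inspiration).
#' @return An object of class `simulated_acquisition`: list with
#'   `acquisition` (a [radial_acquisition()]), `trace`, `coils` (maps on
#'   the oversampled z grid), `coils_nominal` (central `nz` planes),
#'   `truth_images` `{nx, ny, nz, n_bins_truth}` and `truth_amplitudes`.
#' @export
simulate_kspace <- function(phantom, coils, spec, trace, nz,
                            kz_oversampling = 1.61, n_bins_truth = 4L) {
  stopifnot(inherits(coils, "coil_model"), inherits(spec, "trajectory_spec"),
            inherits(trace, "respiratory_trace"))
  if (length(trace$amplitude) != spec$n_spokes)
    stop("trace length must equal n_spokes", call. = FALSE)
  dm <- dim(coils$maps)
  nx <- dm[1]; ny <- dm[2]; n_kz <- dm[3]; nc <- dm[4]
  if (n_kz != round(kz_oversampling * nz))
    stop("coil map z extent must equal round(kz_oversampling * nz)",
         call. = FALSE)
  traj <- golden_angle_trajectory(spec)
  n_read <- spec$n_read
  xs <- seq_len(nx) - 1 - nx %/% 2
  ys <- seq_len(ny) - 1 - ny %/% 2
  data <- array(0 + 0i, c(n_read, spec$n_spokes, n_kz, nc))
  zord <- .ifftshift_idx(n_kz)
  for (j in seq_len(spec$n_spokes)) {
    img <- render_phantom(phantom, trace$amplitude[j], c(nx, ny, n_kz),
                          z_fov = nz)
    obj <- array(as.vector(img) * as.vector(coils$maps),
                 c(nx, ny, n_kz, nc))     # img recycles over coils
    # centred orthonormal FFT along z
    m <- matrix(aperm(obj, c(3, 1, 2, 4)), n_kz)
    m <- stats::mvfft(m[zord, , drop = FALSE]) / sqrt(n_kz)
    obj <- aperm(array(m[.fftshift_idx(n_kz), , drop = FALSE],
                       c(n_kz, nx, ny, nc)), c(2, 3, 1, 4))
    # exact NUDFT of every kz plane and coil at this spoke's samples
    Ex <- exp(-1i * outer(traj$kx[, j], xs))
    Ey <- exp(-1i * outer(traj$ky[, j], ys))
    B <- Ex %*% matrix(obj, nx)                    # n_read x (ny*n_kz*nc)
    BB <- array(B, c(n_read, ny, n_kz * nc)) *
      as.vector(Ey)                                 # recycles over planes
    for (l in seq_len(n_kz * nc))
      data[, j, (l - 1L) %% n_kz + 1L, (l - 1L) %/% n_kz + 1L] <-
        rowSums(BB[, , l])
  }
  acq <- radial_acquisition(data, traj$angles, trace$times, traj,
                            kz_nominal = as.integer(nz))
  # ground truth at bin-centre amplitudes (amplitude bins of the trace)
  ord <- order(-trace$amplitude, trace$times)
  sizes <- .balanced_sizes(length(ord), n_bins_truth)
  idx_split <- split(ord, rep(seq_len(n_bins_truth), sizes))
  amps <- vapply(idx_split, function(ix) mean(trace$amplitude[ix]), 0)
  truth <- array(0 + 0i, c(nx, ny, nz, n_bins_truth))
  for (b in seq_len(n_bins_truth))
    truth[, , , b] <- render_phantom(phantom, amps[b], c(nx, ny, nz))
  crop <- n_kz %/% 2 - nz %/% 2 + seq_len(nz)
  structure(list(acquisition = acq, trace = trace, coils = coils,
                 coils_nominal = coils$maps[, , crop, , drop = FALSE],
                 truth_images = truth, truth_amplitudes = amps,
                 kz_oversampling = kz_oversampling),
            class = "simulated_acquisition")
}
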