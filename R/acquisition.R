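# Golden-angle radial stack-of-stars geometry: trajectory specification,
# in-plane sample coordinates and radial density-compensation weights.

#' Golden-angle increment in degrees
#'
#' The golden angle 180 * (sqrt(5) - 1) / 2 (about 111.246 degrees) yields
#' near-uniform angular coverage of the half-circle for any contiguous run
#' of spokes, which is what makes retrospective respiratory binning of a
#' continuously acquired radial scan possible.
#' @export
golden_angle <- function() 180 * (sqrt(5) - 1) / 2

#' Radial trajectory specification
#'
#' Describes the in-plane geometry of a radial stack-of-stars acquisition:
#' `n_read` samples per spoke spanning `[-k_extent, +k_extent)` with the DC
#' sample at 0-based index `floor(n_read/2)`, and `n_spokes` spokes whose
#' angle progresses by `angle_increment` degrees (golden angle by default),
#' taken modulo 180 so each full spoke is represented once.
#'
#' @param n_read samples per spoke (integer >= 2).
#' @param n_spokes number of spokes (integer >= 1).
#' @param angle_increment spoke-to-spoke rotation in degrees.
#' @param start_angle angle of the first spoke in degrees.
#' @param k_extent maximum spatial frequency in normalised radians, in (0, pi].
#' @return An object of class `trajectory_spec`.
#' @export
trajectory_spec <- function(n_read, n_spokes,
                            angle_increment = golden_angle(),
                            start_angle = 0, k_extent = pi) {
  if (!is.numeric(n_read) || length(n_read) != 1L || n_read < 2 ||
      n_read != round(n_read))
    stop("'n_read' must be an integer >= 2", call. = FALSE)
  if (!is.numeric(n_spokes) || length(n_spokes) != 1L || n_spokes < 1 ||
      n_spokes != round(n_spokes))
    stop("'n_spokes' must be an integer >= 1", call. = FALSE)
  if (!is.numeric(k_extent) || k_extent <= 0 || k_extent > pi)
    stop("'k_extent' must lie in (0, pi]", call. = FALSE)
  structure(list(n_read = as.integer(n_read), n_spokes = as.integer(n_spokes),
                 angle_increment = angle_increment,
                 start_angle = start_angle, k_extent = k_extent),
            class = "trajectory_spec")
}

#' Spoke angles of a trajectory specification
#'
#' @param spec a [trajectory_spec()].
#' @return Numeric vector of spoke angles in degrees, in `[0, 180)`.
#' @export
spoke_angles <- function(spec) {
  j <- seq_len(spec$n_spokes) - 1
  (spec$start_angle + j * spec$angle_increment) %% 180
}

#' Generate in-plane radial sample coordinates
#'
#' Sample radii are uniform over `[-k_extent, +k_extent)` with DC at index
#' `floor(n_read/2)` (0-based); spoke `j` lies at angle
#' `(start_angle + j * angle_increment) mod 180` degrees. Coordinates are
#' returned in normalised radians, suitable for the non-uniform transforms.
#'
#' @param spec a [trajectory_spec()].
#' @return An object of class `trajectory2d`: list with `kx`, `ky` matrices
#'   of shape `{n_read, n_spokes}`, `angles` (degrees) and `spec`.
#' @export
golden_angle_trajectory <- function(spec) {
  stopifnot(inherits(spec, "trajectory_spec"))
  ang_deg <- spoke_angles(spec)
  th <- ang_deg * pi / 180
  r <- (seq_len(spec$n_read) - 1 - spec$n_read %/% 2) *
    (2 * spec$k_extent / spec$n_read)
  kx <- outer(r, cos(th))
  ky <- outer(r, sin(th))
  structure(list(kx = kx, ky = ky, angles = ang_deg, spec = spec),
            class = "trajectory2d")
}

#' Radial (Ram-Lak) density-compensation weights
#'
#' Radial sampling oversamples the k-space centre; the standard ramp
#' compensation weights each sample proportionally to its distance from DC,
#' with the DC sample itself given half the weight of the first nonzero
#' radius (Ram-Lak centre convention). Weights are normalised to a maximum
#' of 1 and are used (as their square root) to precondition the
#' data-fidelity term of the reconstruction.
#'
#' @param traj a `trajectory2d`.
#' @return An object of class `density_weights`: list with matrix `w` of the
#'   same shape as `traj$kx`, all weights in `[0, 1]`.
#' @export
radial_density_weights <- function(traj) {
  stopifnot(inherits(traj, "trajectory2d"))
  r <- sqrt(traj$kx^2 + traj$ky^2)
  w <- r
  pos <- r[r > 0]
  if (length(pos)) w[r == 0] <- min(pos) / 2
  w <- w / max(w)
  structure(list(w = w), class = "density_weights")
}

#' Raw radial stack-of-stars acquisition
#'
#' Container for the pre-sorted multi-coil raw data: complex k-space indexed
#' by readout sample, spoke, Cartesian kz encode and coil, together with the
#' per-spoke angles, timestamps and the in-plane trajectory. `kz_nominal`
#' records how many image slices the prescribed field of view contains; when
#' the kz axis is oversampled, `n_kz > kz_nominal` encodes are acquired and
#' the surplus is cropped after the kz FFT.
#'
#' @param data complex array `{n_read, n_spokes, n_kz, n_coils}`.
#' @param angles spoke angles in degrees, length `n_spokes`.
#' @param timestamps acquisition times in seconds, strictly increasing.
#' @param traj a `trajectory2d` for the in-plane sampling.
#' @param kz_nominal integer number of slices within the prescribed FOV.
#' @return An object of class `radial_acquisition`.
#' @export
radial_acquisition <- function(data, angles, timestamps, traj, kz_nominal) {
  d <- dim(data)
  if (length(d) != 4L) stop("'data' must be a 4D array", call. = FALSE)
  if (length(angles) != d[2] || length(timestamps) != d[2])
    stop("angles/timestamps must have one entry per spoke", call. = FALSE)
  if (any(diff(timestamps) <= 0))
    stop("'timestamps' must be strictly increasing", call. = FALSE)
  if (!identical(dim(traj$kx), d[1:2]))
    stop("trajectory shape does not match data", call. = FALSE)
  if (kz_nominal > d[3])
    stop("'kz_nominal' cannot exceed the number of kz encodes", call. = FALSE)
  structure(list(data = data, angles = as.numeric(angles),
                 timestamps = as.numeric(timestamps), traj = traj,
                 kz_nominal = as.integer(kz_nominal)),
            class = "radial_acquisition")
}

#' @export
print.radial_acquisition <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "radial_acquisition: %d read x %d spokes x %d kz x %d coils (kz_nominal %d)\n",
    d[1], d[2], d[3], d[4], x$kz_nominal))
  invisible(x)
}
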