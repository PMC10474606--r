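# Raw-data container, NIfTI export and configuration files.
#
# The package's native dataset container is a single self-describing file:
# a one-line magic string, a JSON header declaring named arrays (shape,
# element type, byte length) and scalar attributes, then the raw
# little-endian payloads in declared order (complex arrays stored as
# interleaved re/im doubles). The layout mirrors the acquisition model:
# /kspace {n_read, n_spokes, n_kz, n_coils}, /angles, /timestamps,
# optional /coilmaps and ground-truth arrays, with attributes kz_nominal,
# kz_oversampling, k_extent, kz_partial_fourier, tr_s, seed,
# format_version.

.SGDC_MAGIC <- "SGDC1"
.SGDC_VERSION <- "1.0"

.write_array_bin <- function(con, x) {
  if (is.complex(x)) {
    buf <- numeric(2 * length(x))
    buf[c(TRUE, FALSE)] <- Re(x)
    buf[c(FALSE, TRUE)] <- Im(x)
    writeBin(buf, con, size = 8, endian = "little")
  } else {
    writeBin(as.numeric(x), con, size = 8, endian = "little")
  }
}

.read_array_bin <- function(con, dims, type) {
  n <- prod(dims)
  if (type == "complex") {
    buf <- readBin(con, "numeric", 2 * n, size = 8, endian = "little")
    x <- complex(real = buf[c(TRUE, FALSE)], imaginary = buf[c(FALSE, TRUE)])
  } else {
    x <- readBin(con, "numeric", n, size = 8, endian = "little")
  }
  if (length(dims) > 1) array(x, dims) else x
}

#' Write a dataset container
#'
#' Serialises a [radial_acquisition()] or [simulate_kspace()] result into
#' the package's raw-data container. Writing is deterministic: equal
#' inputs produce byte-identical files.
#'
#' @param x a `radial_acquisition` or `simulated_acquisition`.
#' @param path output file path.
#' @param coilmaps optional complex coil maps to embed.
#' @param attrs named list of extra scalar attributes (e.g. `seed`,
#'   `kz_partial_fourier`, `tr_s`).
#' @return `path`, invisibly.
#' @export
write_dataset <- function(x, path, coilmaps = NULL, attrs = list()) {
  if (inherits(x, "simulated_acquisition")) {
    if (is.null(coilmaps)) coilmaps <- x$coils$maps
    attrs$kz_oversampling <- attrs$kz_oversampling %||% x$kz_oversampling
    arrays <- list(kspace = x$acquisition$data,
                   angles = x$acquisition$angles,
                   timestamps = x$acquisition$timestamps,
                   coilmaps = coilmaps,
                   truth_trace = x$trace$amplitude,
                   truth_images = x$truth_images)
    acq <- x$acquisition
  } else if (inherits(x, "radial_acquisition")) {
    arrays <- list(kspace = x$data, angles = x$angles,
                   timestamps = x$timestamps)
    if (!is.null(coilmaps)) arrays$coilmaps <- coilmaps
    acq <- x
  } else stop("unsupported object", call. = FALSE)
  attrs$kz_nominal <- attrs$kz_nominal %||% acq$kz_nominal
  attrs$k_extent <- attrs$k_extent %||% acq$traj$spec$k_extent
  attrs$angle_increment <- attrs$angle_increment %||%
    acq$traj$spec$angle_increment
  attrs$start_angle <- attrs$start_angle %||% acq$traj$spec$start_angle
  attrs$format_version <- .SGDC_VERSION
  header <- list(
    format_version = .SGDC_VERSION,
    attrs = attrs,
    arrays = lapply(names(arrays), function(nm) {
      a <- arrays[[nm]]
      list(name = nm, dims = if (is.null(dim(a))) length(a) else dim(a),
           type = if (is.complex(a)) "complex" else "double")
    }))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(.SGDC_MAGIC,
               jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA)),
             con)
  for (a in arrays) .write_array_bin(con, a)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a dataset container
#'
#' Reads the package container back into a [radial_acquisition()] plus any
#' embedded coil maps and ground truth. Two acquisition-side gaps are
#' repaired on read: a partial-Fourier kz axis (attribute
#' `kz_partial_fourier < 1`, data stored with the acquired leading planes
#' only) is zero-filled to the full kz extent and the filled plane count
#' reported; missing timestamps are synthesised from the repetition-time
#' attribute `tr_s` with a warning.
#'
#' @param path container file path.
#' @return List with `acquisition`, optional `coilmaps`, `truth_trace`,
#'   `truth_images`, the header `attrs` and `zero_filled_planes`.
#' @export
read_dataset <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (!identical(readLines(con, 1), .SGDC_MAGIC))
    stop("not a dataset container", call. = FALSE)
  header <- jsonlite::fromJSON(readLines(con, 1), simplifyVector = TRUE)
  ver <- header$format_version
  if (is.null(ver) || strsplit(ver, ".", fixed = TRUE)[[1]][1] !=
      strsplit(.SGDC_VERSION, ".", fixed = TRUE)[[1]][1])
    stop("unsupported container format version: ", ver, call. = FALSE)
  arrays <- list()
  for (i in seq_len(nrow(header$arrays))) {
    nm <- header$arrays$name[i]
    dims <- header$arrays$dims[[i]]
    arrays[[nm]] <- .read_array_bin(con, dims, header$arrays$type[i])
  }
  at <- header$attrs
  ksp <- arrays$kspace
  d <- dim(ksp)
  zero_filled <- 0L
  pf <- at$kz_partial_fourier %||% 1
  if (pf < 1) {
    n_full <- as.integer(round(d[3] / pf))
    zero_filled <- n_full - d[3]
    full <- array(0 + 0i, c(d[1], d[2], n_full, d[4]))
    full[, , seq_len(d[3]), ] <- ksp
    ksp <- full
    d <- dim(ksp)
  }
  ts <- arrays$timestamps
  if (is.null(ts) || length(ts) == 0) {
    tr <- at$tr_s
    if (is.null(tr)) stop("no timestamps and no tr_s attribute", call. = FALSE)
    warning("timestamps missing; synthesised from tr_s", call. = FALSE)
    ts <- (seq_len(d[2]) - 1) * tr
  }
  spec <- trajectory_spec(d[1], d[2],
                          angle_increment = at$angle_increment %||% golden_angle(),
                          start_angle = at$start_angle %||% 0,
                          k_extent = at$k_extent %||% pi)
  traj <- golden_angle_trajectory(spec)
  if (!is.null(arrays$angles) && length(arrays$angles))
    traj$angles <- arrays$angles
  acq <- radial_acquisition(ksp, traj$angles, ts, traj,
                            kz_nominal = at$kz_nominal %||% d[3])
  list(acquisition = acq, coilmaps = arrays$coilmaps,
       truth_trace = arrays$truth_trace, truth_images = arrays$truth_images,
       attrs = at, zero_filled_planes = zero_filled)
}

#' Write a reconstructed 4D volume as NIfTI
#'
#' Writes the magnitude of a [reconstruct_4d()] result as a 4D NIfTI-1
#' image with the respiratory-bin axis on the 4th dimension (stated in the
#' header description) and the given voxel size; optionally stores the
#' complex data alongside in the package container format.
#'
#' @param vol a `volume4d` (or complex 4D array).
#' @param path output path (`.nii` or `.nii.gz`).
#' @param voxel_size numeric length-3 voxel size in mm.
#' @param complex_path optional path for a complex-valued sidecar.
#' @return `path`, invisibly.
#' @export
write_volume4d <- function(vol, path, voxel_size = c(1.5, 1.5, 3),
                           complex_path = NULL) {
  img <- if (inherits(vol, "volume4d")) vol$image else vol
  mag <- Mod(img)
  nif <- RNifti::asNifti(mag,
                         list(pixdim = c(-1, voxel_size, 1, 0, 0, 0),
                              descrip = "dim4 = respiratory bin (1 = end-inspiration)"),
                         datatype = "float")
  RNifti::writeNifti(nif, path)
  if (!is.null(complex_path)) {
    con <- file(complex_path, "wb")
    writeLines(c(.SGDC_MAGIC, jsonlite::toJSON(
      list(format_version = .SGDC_VERSION,
           attrs = list(format_version = .SGDC_VERSION),
           arrays = list(list(name = "volume", dims = dim(img),
                              type = "complex"))),
      auto_unbox = TRUE, digits = NA)), con)
    .write_array_bin(con, img)
    close(con)
  }
  invisible(path)
}

#' Read a 4D NIfTI volume
#'
#' @param path NIfTI file path.
#' @return Numeric 4D array.
#' @export
read_volume4d <- function(path) {
  img <- RNifti::readNifti(path)
  array(as.numeric(img), dim(img))
}
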