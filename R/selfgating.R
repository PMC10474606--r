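# Respiratory self-gating from the k-space centre.
#
# The DC readout sample of every spoke tracks the total transverse
# magnetisation, which respiration modulates. Two surrogate extraction
# methods are provided: the baseline (PCA over the magnitude of the DC
# navigator across kz and coils, respiratory-band component selection) and
# ADERS (angle-dependent background subtraction followed by coil-quality
# rejection before the PCA).

#' Extract the DC navigator from an acquisition
#'
#' Returns the central (kx = ky = 0) readout sample of every spoke, kz
#' encode and coil — readout index `floor(n_read/2)` — together with spoke
#' angles and timestamps. The acquisition is not modified.
#'
#' @param acq a [radial_acquisition()].
#' @return An object of class `dc_navigator`: list with complex `values`
#'   `{n_spokes, n_kz, n_coils}`, `angles`, `times`.
#' @export
extract_dc_navigator <- function(acq) {
  stopifnot(inherits(acq, "radial_acquisition"))
  d <- dim(acq$data)
  if (d[1] < 2) stop("need at least 2 readout samples", call. = FALSE)
  dc <- d[1] %/% 2 + 1L
  structure(list(values = acq$data[dc, , , , drop = TRUE],
                 angles = acq$angles, times = acq$timestamps),
            class = "dc_navigator")
}

# navigator values as a 3D array even when n_kz or n_coils is 1
.nav_array <- function(nav) {
  v <- nav$values
  if (length(dim(v)) == 3L) return(v)
  n_sp <- length(nav$angles)
  if (is.null(dim(v))) return(array(v, c(n_sp, 1L, 1L)))
  array(v, c(dim(v)[1], dim(v)[2], 1L))
}

# spoke sampling rate from timestamps
.nav_fs <- function(times) 1 / stats::median(diff(times))

# standardize + deterministic sign: non-negative skewness (an end-exhale
# plateau makes the distribution of a breathing surrogate skewed, so this
# fixes the orientation reproducibly)
.standardize_signal <- function(x) {
  x <- x - mean(x)
  x <- x / sqrt(mean(x^2))                     # population variance 1
  if (skewness(x) < 0) x <- -x
  x
}

# PCA over feature columns; returns the standardized score of the component
# with the highest respiratory-band power fraction
.pca_band_component <- function(X, fs, band) {
  X <- sweep(X, 2, colMeans(X))
  keep <- apply(X, 2, function(col) stats::sd(col) > 0)
  if (!any(keep)) stop("navigator has no varying features", call. = FALSE)
  X <- X[, keep, drop = FALSE]
  if (nrow(X) < ncol(X))
    warning("fewer spokes than navigator features; PCA is rank-deficient",
            call. = FALSE)
  pc <- stats::prcomp(X, center = FALSE, scale. = FALSE)
  nc <- ncol(pc$x)
  frac <- vapply(seq_len(nc),
                 function(i) band_power_fraction(pc$x[, i], fs, band), 0)
  pick <- which.max(frac)
  list(score = .standardize_signal(pc$x[, pick]), pc_index = pick,
       band_fraction = frac[pick])
}

#' Baseline PCA self-gating
#'
#' Features are the magnitudes of the DC navigator flattened over
#' (kz, coil), mean-centred per feature; principal component analysis is
#' performed over spokes and the component with the largest spectral-power
#' fraction inside the respiratory band is selected, standardized to zero
#' mean and unit variance, and oriented so its skewness is non-negative.
#'
#' @param nav a [extract_dc_navigator()] result.
#' @param band_hz respiratory frequency band in Hz, default `c(0.1, 0.5)`.
#' @return An object of class `respiratory_signal`: list with `value`
#'   (standardized, one per spoke), `method`, `retained_coils`, `pc_index`,
#'   `times`.
#' @export
baseline_selfgating <- function(nav, band_hz = c(0.1, 0.5)) {
  stopifnot(inherits(nav, "dc_navigator"))
  v <- .nav_array(nav)
  if (dim(v)[1] < 8) stop("need at least 8 spokes", call. = FALSE)
  X <- Mod(matrix(v, dim(v)[1]))
  sel <- .pca_band_component(X, .nav_fs(nav$times), band_hz)
  structure(list(value = sel$score, method = "baseline",
                 retained_coils = seq_len(dim(v)[3]),
                 pc_index = sel$pc_index, times = nav$times),
            class = "respiratory_signal")
}

#' Angle-dependent background subtraction of the DC navigator
#'
#' For every (kz, coil) feature the navigator magnitudes are ordered by
#' spoke angle and a centred moving average over `window` angle-neighbours
#' is subtracted (shrinking symmetrically at the ends of the angle range).
#' This removes the angle-dependent baseline that golden-angle sampling
#' imprints on the DC signal while preserving angle-independent (temporal,
#' i.e. respiratory) modulation. The result, returned in original spoke
#' order, is the real-valued magnitude residual.
#'
#' @param nav a [extract_dc_navigator()] result.
#' @param window odd integer >= 3, number of angle-neighbours averaged.
#' @return A `dc_navigator` whose `values` are real residuals.
#' @export
aders_correct <- function(nav, window = 11L) {
  stopifnot(inherits(nav, "dc_navigator"))
  if (window %% 2 == 0 || window < 3)
    stop("'window' must be odd and >= 3", call. = FALSE)
  v <- .nav_array(nav)
  n_sp <- dim(v)[1]
  if (window >= n_sp)
    stop("'window' must be smaller than the number of spokes", call. = FALSE)
  ord <- order(nav$angles)
  half <- window %/% 2
  out <- array(0, dim(v))
  for (k in seq_len(dim(v)[2])) for (cix in seq_len(dim(v)[3])) {
    m <- Mod(v[, k, cix])[ord]
    cs <- cumsum(c(0, m))
    lo <- pmax(seq_len(n_sp) - half, 1L)
    hi <- pmin(seq_len(n_sp) + half, n_sp)
    ma <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
    res <- m - ma
    out[ord, k, cix] <- res
  }
  structure(list(values = out, angles = nav$angles, times = nav$times),
            class = "dc_navigator")
}

#' Coil-quality scores from per-coil candidate signals
#'
#' Scores each coil's candidate respiratory signal by the fraction of its
#' one-sided spectral power (DC excluded) that falls inside the
#' respiratory band; a coil whose DC navigator is dominated by breathing
#' scores near 1, white noise scores near the band's bandwidth fraction,
#' and a constant coil scores 0.
#'
#' @param signals_per_coil numeric matrix `{n_spokes, n_coils}` of
#'   candidate signals (e.g. each coil's leading PCA component).
#' @param fs sampling rate in Hz (spokes per second).
#' @param band_hz respiratory band in Hz.
#' @return An object of class `coil_quality`: list with `score` per coil.
#' @export
coil_quality <- function(signals_per_coil, fs, band_hz = c(0.1, 0.5)) {
  s <- as.matrix(signals_per_coil)
  score <- apply(s, 2, function(x) band_power_fraction(x, fs, band_hz))
  structure(list(score = score), class = "coil_quality")
}

#' ADERS self-gating with coil rejection
#'
#' Pipeline: [aders_correct()] removes the angle-dependent baseline; each
#' coil's corrected features (over kz) are reduced to a leading principal
#' component and scored by [coil_quality()]; the `floor(n_coils/2)`
#' lowest-scoring coils are rejected; PCA across the remaining coils'
#' features selects the respiratory-band component as in
#' [baseline_selfgating()].
#'
#' @inheritParams baseline_selfgating
#' @param window angle-neighbour window passed to [aders_correct()].
#' @return A `respiratory_signal` with `method = "aders"` and the retained
#'   coil indices.
#' @export
aders_selfgating <- function(nav, window = 11L, band_hz = c(0.1, 0.5)) {
  stopifnot(inherits(nav, "dc_navigator"))
  v <- .nav_array(nav)
  n_coils <- dim(v)[3]
  if (n_coils < 2) stop("need at least 2 coils", call. = FALSE)
  corrected <- aders_correct(nav, window)
  cv <- .nav_array(corrected)
  fs <- .nav_fs(nav$times)
  # leading PC per coil as that coil's candidate signal
  cand <- vapply(seq_len(n_coils), function(cix) {
    X <- matrix(cv[, , cix], dim(cv)[1])
    X <- sweep(X, 2, colMeans(X))
    if (all(X == 0)) return(rep(0, dim(cv)[1]))
    stats::prcomp(X, center = FALSE)$x[, 1]
  }, numeric(dim(cv)[1]))
  quality <- coil_quality(cand, fs, band_hz)
  n_drop <- n_coils %/% 2L
  retained <- sort(order(quality$score, decreasing = TRUE)[
    seq_len(n_coils - n_drop)])
  X <- matrix(cv[, , retained], dim(cv)[1])
  sel <- .pca_band_component(X, fs, band_hz)
  structure(list(value = sel$score, method = "aders",
                 retained_coils = retained, pc_index = sel$pc_index,
                 coil_scores = quality$score, times = nav$times),
            class = "respiratory_signal")
}
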