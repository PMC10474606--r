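# Respiratory binning: amplitude (equal-count) bins, overlapping
# respiratory bins (ORB), and sorting of raw data into the per-bin layout
# consumed by the solver.

# group sizes differing by at most 1, larger groups first
.balanced_sizes <- function(n, k) {
  base <- n %/% k
  rem <- n %% k
  c(rep(base + 1L, rem), rep(base, k - rem))
}

.new_bin_assignment <- function(per_bin, n_spokes, overlapping) {
  membership <- vector("list", n_spokes)
  for (b in seq_along(per_bin))
    for (s in per_bin[[b]]) membership[[s]] <- c(membership[[s]], b)
  structure(list(n_bins = length(per_bin), membership = membership,
                 per_bin_spokes = per_bin, overlapping = overlapping),
            class = "bin_assignment")
}

#' Non-overlapping amplitude bins
#'
#' Spokes are sorted by decreasing signal value (stable; ties broken by
#' acquisition time) and partitioned into `n_bins` contiguous equal-count
#' groups whose sizes differ by at most one, with the larger groups at the
#' end-inspiration side. Bin 1 holds the largest signal values
#' (end-inspiration), bin `n_bins` the smallest (end-expiration); every
#' spoke belongs to exactly one bin. Within each bin, spokes are listed in
#' acquisition order.
#'
#' @param signal a `respiratory_signal` (or numeric vector, with order as
#'   acquisition order).
#' @param n_bins number of respiratory bins (>= 2).
#' @return An object of class `bin_assignment`: list with `n_bins`,
#'   `membership` (per spoke, vector of bin indices), `per_bin_spokes`
#'   (per bin, acquisition-ordered spoke indices) and `overlapping`.
#' @export
amplitude_bins <- function(signal, n_bins) {
  v <- if (inherits(signal, "respiratory_signal")) signal$value else signal
  n <- length(v)
  if (n_bins < 2 || n_bins != round(n_bins))
    stop("'n_bins' must be an integer >= 2", call. = FALSE)
  if (n_bins > n)
    stop("more bins than spokes", call. = FALSE)
  ord <- order(-v, seq_len(n))
  sizes <- .balanced_sizes(n, n_bins)
  groups <- unname(split(ord, rep(seq_len(n_bins), sizes)))
  per_bin <- lapply(groups, sort)
  .new_bin_assignment(per_bin, n, overlapping = FALSE)
}

#' Overlapping respiratory bins (ORB)
#'
#' Spokes are sorted by decreasing signal value and partitioned into
#' `2 * n_bins` equal-count half-groups H1..H(2n); bin `i` is the union of
#' half-groups `{2i-2, 2i-1, 2i, 2i+1}` intersected with `[1, 2n]`. Every
#' interior spoke therefore contributes to exactly two adjacent bins, while
#' spokes in the extreme half-groups (maximum inhalation H1 and maximum
#' exhalation H(2n)) belong to a single bin. When `2*n_bins` divides the
#' spoke count, interior bins hold `2 n / n_bins` spokes and the two
#' extremum bins 3/4 of that.
#'
#' @inheritParams amplitude_bins
#' @return A `bin_assignment` with `overlapping = TRUE`.
#' @export
overlapping_bins <- function(signal, n_bins) {
  v <- if (inherits(signal, "respiratory_signal")) signal$value else signal
  n <- length(v)
  if (n_bins < 2 || n_bins != round(n_bins))
    stop("'n_bins' must be an integer >= 2", call. = FALSE)
  if (n < 2 * n_bins)
    stop("need at least 2*n_bins spokes", call. = FALSE)
  ord <- order(-v, seq_len(n))
  nh <- 2L * n_bins
  sizes <- .balanced_sizes(n, nh)
  halves <- unname(split(ord, rep(seq_len(nh), sizes)))
  per_bin <- lapply(seq_len(n_bins), function(i) {
    hs <- intersect(c(2 * i - 2, 2 * i - 1, 2 * i, 2 * i + 1), seq_len(nh))
    sort(unlist(halves[hs], use.names = FALSE))
  })
  .new_bin_assignment(per_bin, n, overlapping = TRUE)
}

#' Sort raw data into per-bin k-space
#'
#' Gathers the data, trajectory columns and density weights of every bin's
#' member spokes into the pre-solver layout
#' `data{n_read, n_lines_b, n_kz, n_bins, n_coils}` (ragged: `n_lines_b`
#' varies over bins). Data are only re-indexed, never modified; a spoke
#' contributing to two overlapping bins appears in both.
#'
#' @param acq a [radial_acquisition()].
#' @param assignment a `bin_assignment` for the same spokes.
#' @param weights optional `density_weights` matching the trajectory;
#'   computed with [radial_density_weights()] when omitted.
#' @return An object of class `binned_kspace`: list with per-bin lists
#'   `data` `{n_read, n_lines_b, n_kz, n_coils}`, `kx`, `ky`, `w`
#'   (matrices `{n_read, n_lines_b}`), plus `spokes` (member indices),
#'   `n_bins`, `overlapping`.
#' @export
sort_into_bins <- function(acq, assignment, weights = NULL) {
  stopifnot(inherits(acq, "radial_acquisition"),
            inherits(assignment, "bin_assignment"))
  d <- dim(acq$data)
  if (length(assignment$membership) != d[2])
    stop("assignment does not match the acquisition spoke count",
         call. = FALSE)
  if (is.null(weights)) weights <- radial_density_weights(acq$traj)
  bins <- lapply(assignment$per_bin_spokes, function(sp) {
    if (any(sp < 1 | sp > d[2])) stop("spoke index out of range", call. = FALSE)
    list(data = acq$data[, sp, , , drop = FALSE],
         kx = acq$traj$kx[, sp, drop = FALSE],
         ky = acq$traj$ky[, sp, drop = FALSE],
         w = weights$w[, sp, drop = FALSE],
         spokes = sp)
  })
  structure(list(bins = bins, n_bins = assignment$n_bins,
                 overlapping = assignment$overlapping,
                 n_read = d[1], n_kz = d[3], n_coils = d[4]),
            class = "binned_kspace")
}
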