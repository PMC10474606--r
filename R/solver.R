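# kz decoupling, per-slice nonlinear conjugate-gradient solver and the
# slice-parallel 4D reconstruction driver.
#
# A stack-of-stars acquisition is Cartesian along kz, so after a 1D FFT
# along that axis the 3D problem separates into independent 2D problems —
# one per slice — that are solved in parallel with no communication. The
# solver is Fletcher-Reeves nonlinear CG with Armijo backtracking; the
# fidelity term is quadratic along any search direction, so each line
# search costs a single forward transform regardless of backtrack count.

#' Reconstruction configuration
#'
#' Defaults follow the standard XD-GRASP protocol: 8 respiratory bins,
#' 8 CG iterations, regularisation weight `lambda = 0.02` (scaled by the
#' maximum magnitude of the initial image when `lambda_scale = "auto"`,
#' making it dimensionless), density-compensated fidelity, and a
#' backtracking line search (initial step 1, shrink 0.6, sufficient
#' decrease 0.01, at most 150 backtracks).
#'
#' @param n_bins number of respiratory bins.
#' @param n_iter CG iterations per slice.
#' @param lambda total-variation regularisation weight.
#' @param lambda_scale `"auto"` (multiply by `max |d0|` of each slice's
#'   initial image) or `"absolute"`.
#' @param l1_smooth smoothing epsilon of the L1 relaxation.
#' @param nufft a [nufft_config()].
#' @param engine `"nufft"` or `"nudft"` (exact reference path).
#' @param density_compensation apply sqrt-ramp density weighting inside
#'   the fidelity term.
#' @param early_stop_tol relative objective-decrease threshold below which
#'   iteration stops early; 0 disables (the default: a fixed iteration
#'   budget).
#' @param step_init,step_shrink,step_c1,max_backtracks line-search
#'   parameters.
#' @param workers parallel workers for the slice loop.
#' @param assignment `"contiguous"` (adjacent slice blocks per worker) or
#'   `"dynamic"` (round-robin queue emulation).
#' @param gating_window ADERS angle-neighbour window.
#' @param band_hz respiratory band in Hz for self-gating.
#' @return An object of class `recon_config`.
#' @export
recon_config <- function(n_bins = 8L, n_iter = 8L, lambda = 0.02,
                         lambda_scale = c("auto", "absolute"),
                         l1_smooth = 1e-15, nufft = nufft_config(),
                         engine = c("nufft", "nudft"),
                         density_compensation = TRUE,
                         early_stop_tol = 0,
                         step_init = 1, step_shrink = 0.6, step_c1 = 0.01,
                         max_backtracks = 150L, workers = 1L,
                         assignment = c("contiguous", "dynamic"),
                         gating_window = 11L, band_hz = c(0.1, 0.5)) {
  if (n_iter < 1) stop("'n_iter' must be >= 1", call. = FALSE)
  if (lambda < 0) stop("'lambda' must be >= 0", call. = FALSE)
  structure(list(n_bins = as.integer(n_bins), n_iter = as.integer(n_iter),
                 lambda = lambda, lambda_scale = match.arg(lambda_scale),
                 l1_smooth = l1_smooth, nufft = nufft,
                 engine = match.arg(engine),
                 density_compensation = isTRUE(density_compensation),
                 early_stop_tol = early_stop_tol, step_init = step_init,
                 step_shrink = step_shrink, step_c1 = step_c1,
                 max_backtracks = as.integer(max_backtracks),
                 workers = as.integer(workers),
                 assignment = match.arg(assignment),
                 gating_window = as.integer(gating_window),
                 band_hz = band_hz),
            class = "recon_config")
}

#' Decouple binned k-space into independent per-slice problems
#'
#' Applies a centred orthonormal inverse FFT along the kz axis of every
#' bin's data, crops the oversampled kz extent centrally to `kz_nominal`
#' slices, and packages one self-contained problem per retained slice
#' (per-bin 2D radial data for every coil, the matching coil-map slice,
#' and the shared per-bin trajectories and weights).
#'
#' @param binned a [sort_into_bins()] result.
#' @param maps complex coil maps `{nx, ny, kz_nominal, n_coils}` (or more
#'   kz planes, centrally cropped).
#' @param kz_nominal number of image slices to retain.
#' @return List of `slice_problem` objects (length `kz_nominal`).
#' @export
kz_decouple <- function(binned, maps, kz_nominal) {
  stopifnot(inherits(binned, "binned_kspace"))
  n_kz <- binned$n_kz
  if (kz_nominal > n_kz)
    stop("'kz_nominal' cannot exceed the kz encode count", call. = FALSE)
  dmap <- dim(maps)
  if (dmap[3] > kz_nominal) {
    crop <- dmap[3] %/% 2 - kz_nominal %/% 2 + seq_len(kz_nominal)
    maps <- maps[, , crop, , drop = FALSE]
  } else if (dmap[3] != kz_nominal)
    stop("coil maps must cover kz_nominal slices", call. = FALSE)
  crop <- n_kz %/% 2 - kz_nominal %/% 2 + seq_len(kz_nominal)
  zord <- .ifftshift_idx(n_kz)
  slabs <- lapply(binned$bins, function(bin) {
    d <- dim(bin$data)                     # {n_read, n_lines, n_kz, n_coils}
    m <- matrix(aperm(bin$data, c(3, 1, 2, 4)), n_kz)
    m <- stats::mvfft(m[zord, , drop = FALSE], inverse = TRUE) / sqrt(n_kz)
    m <- m[.fftshift_idx(n_kz), , drop = FALSE][crop, , drop = FALSE]
    aperm(array(m, c(kz_nominal, d[1], d[2], d[4])), c(2, 3, 1, 4))
  })
  lapply(seq_len(kz_nominal), function(z) {
    data <- lapply(slabs, function(sl) {
      d <- dim(sl)
      matrix(sl[, , z, ], d[1] * d[2], d[4])
    })
    structure(list(z = z, data = data,
                   maps = array(maps[, , z, ], c(dmap[1], dmap[2], dmap[4])),
                   traj_bins = lapply(binned$bins, function(b)
                     list(kx = b$kx, ky = b$ky)),
                   weight_bins = lapply(binned$bins, function(b) b$w)),
              class = "slice_problem")
  })
}

#' Solve the reconstruction of one slice
#'
#' Fletcher-Reeves nonlinear conjugate gradient on the smoothed XD-GRASP
#' objective, initialised with the adjoint image `d0 = A^H (W m)`. The
#' Armijo backtracking line search exploits that the fidelity term is an
#' exact quadratic along the search direction, so every line search costs
#' one forward transform. Runs `n_iter` iterations unless the relative
#' objective decrease falls below `early_stop_tol` or the line search
#' fails; the objective trace is non-increasing by construction.
#'
#' @param problem a `slice_problem` from [kz_decouple()].
#' @param config a [recon_config()].
#' @param encoding optional pre-built [slice_encoding()] sharing plans
#'   across slices.
#' @return List with complex `images` `{nx, ny, n_bins}`, numeric `trace`
#'   (objective after initialisation and each accepted step),
#'   `lambda_effective`, `iterations`, and `status` (`"ok"`,
#'   `"early_stop"` or `"line_search_failure"`).
#' @export
solve_slice <- function(problem, config = recon_config(), encoding = NULL) {
  stopifnot(inherits(problem, "slice_problem"))
  if (is.null(encoding)) {
    wb <- if (config$density_compensation) problem$weight_bins
      else lapply(problem$weight_bins, function(w) array(1, dim(w)))
    encoding <- slice_encoding(problem$traj_bins, wb, problem$maps,
                               config$nufft, config$engine)
  }
  m <- problem$data
  eps <- config$l1_smooth
  y <- lapply(seq_along(m), function(b)
    encoding$sqrtw[[b]] * as.matrix(m[[b]]))
  # d0 = A^H y: the density-compensated (filtered) backprojection, which
  # lands on the image scale thanks to the encoding normalisation
  d <- encode_adjoint(y, encoding)
  lam <- if (config$lambda_scale == "auto")
    config$lambda * max(Mod(d)) else config$lambda
  if (!is.finite(lam) || max(Mod(d)) == 0) lam <- 0
  r <- encode_forward(d, encoding)
  for (b in seq_along(r)) r[[b]] <- r[[b]] - y[[b]]
  fid <- sum(vapply(r, function(x) sum(Mod(x)^2), 0))
  obj_tv <- function(dd) if (lam > 0) tv_norm_smooth(dd, eps) else 0
  f <- fid + lam * obj_tv(d)
  trace <- f
  grad_at <- function(rr, dd) {
    g <- 2 * encode_adjoint(rr, encoding)
    if (lam > 0 && dim(dd)[3] > 1) {
      p <- tv_bins(dd)
      g <- g + lam * tv_bins_adjoint(p / sqrt(Mod(p)^2 + eps),
                                     dim(dd)[3])
    }
    g
  }
  g <- grad_at(r, d)
  p <- -g
  g2 <- re_inner(g, g)
  status <- "ok"
  iters <- 0L
  for (it in seq_len(config$n_iter)) {
    gp <- re_inner(g, p)
    if (gp >= 0) { p <- -g; gp <- -g2 }     # restart on non-descent
    q <- encode_forward(p, encoding)
    a1 <- 2 * sum(vapply(seq_along(q), function(b)
      re_inner(q[[b]], r[[b]]), 0))
    a2 <- sum(vapply(q, function(x) sum(Mod(x)^2), 0))
    alpha <- config$step_init
    ok <- FALSE
    for (bt in seq_len(config$max_backtracks)) {
      fc <- (fid + alpha * a1 + alpha^2 * a2) + lam * obj_tv(d + alpha * p)
      if (fc <= f + config$step_c1 * alpha * gp) { ok <- TRUE; break }
      alpha <- alpha * config$step_shrink
    }
    if (!ok) {
      status <- "line_search_failure"
      if (it == 1L)
        warning("line search failed at the first iteration; returning the adjoint image",
                call. = FALSE)
      break
    }
    d <- d + alpha * p
    for (b in seq_along(r)) r[[b]] <- r[[b]] + alpha * q[[b]]
    fid <- fid + alpha * a1 + alpha^2 * a2
    f_new <- fid + lam * obj_tv(d)
    iters <- it
    trace <- c(trace, f_new)
    rel_dec <- (f - f_new) / max(f, .Machine$double.eps)
    f <- f_new
    g_new <- grad_at(r, d)
    g2_new <- re_inner(g_new, g_new)
    beta <- g2_new / max(g2, .Machine$double.eps)
    p <- -g_new + beta * p
    g <- g_new; g2 <- g2_new
    if (config$early_stop_tol > 0 && rel_dec < config$early_stop_tol) {
      status <- "early_stop"
      break
    }
  }
  list(images = d, trace = trace, lambda_effective = lam,
       iterations = iters, status = status, z = problem$z)
}

#' Assign slices to parallel workers
#'
#' `"contiguous"` gives every worker a block of adjacent slices (block
#' sizes differ by at most one, larger blocks first), which preserves
#' memory locality; `"dynamic"` emulates a work-stealing queue by
#' round-robin interleaving. Results are always deposited by slice index,
#' so the reconstruction is identical for any worker count and assignment
#' mode.
#'
#' @param n_slices number of slices.
#' @param workers number of workers (>= 1).
#' @param assignment `"contiguous"` or `"dynamic"`.
#' @return List (one element per worker) of slice-index vectors.
#' @export
schedule <- function(n_slices, workers, assignment = c("contiguous", "dynamic")) {
  assignment <- match.arg(assignment)
  workers <- max(1L, min(as.integer(workers), n_slices))
  if (assignment == "contiguous") {
    sizes <- .balanced_sizes(n_slices, workers)
    plan <- split(seq_len(n_slices), rep(seq_len(workers), sizes))
  } else {
    plan <- split(seq_len(n_slices), rep_len(seq_len(workers), n_slices))
  }
  lapply(unname(plan), unname)
}

#' Respiratory-resolved 4D reconstruction
#'
#' Full XD-GRASP pipeline: self-gating, respiratory binning, per-bin data
#' sorting, kz FFT decoupling and slice-parallel CG reconstruction. The
#' four data-preparation strategies combine the two gating methods with
#' the two binning methods: `"baseline"` (PCA gating, non-overlapping
#' bins), `"aders"` (ADERS gating, non-overlapping), `"orb"` (PCA gating,
#' overlapping bins) and `"combined"` (ADERS gating, overlapping bins).
#'
#' @param acq a [radial_acquisition()].
#' @param maps coil-sensitivity maps `{nx, ny, kz_nominal, n_coils}` (the
#'   oversampled z extent is also accepted and cropped centrally).
#' @param strategy data-preparation strategy (see Details).
#' @param config a [recon_config()].
#' @param signal optional precomputed `respiratory_signal`, overriding the
#'   gating step.
#' @return An object of class `volume4d`: list with complex `image`
#'   `{nx, ny, nz, n_bins}` and `provenance` (strategy, signal metadata,
#'   per-slice objective traces and timings, configuration).
#' @export
reconstruct_4d <- function(acq, maps,
                           strategy = c("baseline", "aders", "orb", "combined"),
                           config = recon_config(), signal = NULL) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(acq, "radial_acquisition"))
  t_prep0 <- proc.time()[["elapsed"]]
  if (is.null(signal)) {
    nav <- extract_dc_navigator(acq)
    signal <- if (strategy %in% c("aders", "combined"))
      aders_selfgating(nav, config$gating_window, config$band_hz)
    else baseline_selfgating(nav, config$band_hz)
  }
  assignment <- if (strategy %in% c("orb", "combined"))
    overlapping_bins(signal, config$n_bins)
  else amplitude_bins(signal, config$n_bins)
  binned <- sort_into_bins(acq, assignment)
  problems <- kz_decouple(binned, maps, acq$kz_nominal)
  nz <- length(problems)
  # one plan per bin and type, shared across slices and workers
  dmap <- dim(maps)
  plans <- lapply(binned$bins, function(b)
    if (config$engine == "nufft")
      nufft_plan(b$kx, b$ky, dmap[1], dmap[2], config$nufft)
    else nudft_plan(b$kx, b$ky, dmap[1], dmap[2]))
  wb <- if (config$density_compensation)
    lapply(binned$bins, function(b) b$w)
  else lapply(binned$bins, function(b) array(1, dim(b$w)))
  t_prep <- proc.time()[["elapsed"]] - t_prep0
  solve_one <- function(pr) {
    enc <- slice_encoding(pr$traj_bins, wb, pr$maps, config$nufft,
                          config$engine, plans = plans)
    t0 <- proc.time()[["elapsed"]]
    res <- solve_slice(pr, config, encoding = enc)
    res$seconds <- proc.time()[["elapsed"]] - t0
    res
  }
  plan <- schedule(nz, config$workers, config$assignment)
  if (config$workers > 1L && length(plan) > 1L &&
      .Platform$OS.type == "unix") {
    chunks <- parallel::mclapply(plan, function(ix)
      lapply(problems[ix], solve_one), mc.cores = length(plan))
  } else {
    chunks <- lapply(plan, function(ix) lapply(problems[ix], solve_one))
  }
  results <- vector("list", nz)
  for (ch in chunks) for (res in ch) results[[res$z]] <- res
  nb <- config$n_bins
  vol <- array(0 + 0i, c(dmap[1], dmap[2], nz, nb))
  for (z in seq_len(nz)) vol[, , z, ] <- results[[z]]$images
  structure(list(
    image = vol,
    provenance = list(strategy = strategy, config = config,
                      signal_method = signal$method,
                      retained_coils = signal$retained_coils,
                      bin_sizes = vapply(assignment$per_bin_spokes, length, 0L),
                      traces = lapply(results, `[[`, "trace"),
                      slice_seconds = vapply(results, `[[`, 0, "seconds"),
                      status = vapply(results, `[[`, "", "status"),
                      t_preparation = t_prep)),
    class = "volume4d")
}

#' @export
print.volume4d <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("volume4d: %d x %d x %d slices x %d bins (%s strategy)\n",
              d[1], d[2], d[3], d[4], x$provenance$strategy))
  invisible(x)
}
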