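test_that("kz decoupling is orthonormal and maps encodes to slices", {
  sim <- sim_small()
  acq <- sim$acquisition
  sig <- baseline_selfgating(extract_dc_navigator(acq))
  binned <- sort_into_bins(acq, amplitude_bins(sig, 3))

  # Parseval without cropping: decoupling to the full kz extent preserves
  # energy exactly
  full <- kz_decouple(binned, sim$coils$maps, binned$n_kz)
  e_in <- sum(vapply(binned$bins, function(b) sum(Mod(b$data)^2), 0))
  e_out <- sum(vapply(full, function(pr)
    sum(vapply(pr$data, function(m) sum(Mod(m)^2), 0)), 0))
  expect_equal(e_out / e_in, 1, tolerance = 1e-10)

  # single kz encode passes through unscaled
  acq1 <- sim$acquisition
  acq1$data <- acq1$data[, , 2, , drop = FALSE]
  acq1$kz_nominal <- 1L
  b1 <- sort_into_bins(acq1, amplitude_bins(sig, 3))
  p1 <- kz_decouple(b1, sim$coils_nominal[, , 1, , drop = FALSE], 1)
  expect_length(p1, 1L)
  expect_equal(p1[[1]]$data[[2]][, 1],
               as.vector(b1$bins[[2]]$data[, , 1, 1]), tolerance = 1e-12)
})

test_that("a single-slice phantom concentrates energy in its slice", {
  # phantom occupying only the central slice of five
  ph <- motion_phantom(list(list(centre = c(0, 0), axes = c(0.3, 0.25),
                                 rot = 0, intensity = 1 + 0i,
                                 z = c(-0.05, 0.05))))
  tr <- make_respiratory_trace(30 * 0.3, 0.3, noise_sd = 0)
  sim <- simulate_kspace(ph, uniform_coils(c(16, 16, 5)),
                         trajectory_spec(16, 30), tr, 5, kz_oversampling = 1)
  binned <- sort_into_bins(sim$acquisition, amplitude_bins(rep(0:1, 15), 2))
  probs <- kz_decouple(binned, sim$coils$maps, 5)
  energy <- vapply(probs, function(pr)
    sum(vapply(pr$data, function(m) sum(Mod(m)^2), 0)), 0)
  expect_gt(energy[3] / sum(energy), 0.99)
})

test_that("CG recovers the truth on an exactly invertible system", {
  n <- 16
  set.seed(12)
  ct <- cartesian_trajectory(n)
  truth <- matrix(0i, n, n)
  truth[5:12, 4:13] <- 1
  truth[8:9, 8:9] <- 2 + 1i
  m <- matrix(exact_nudft(truth, ct$kx, ct$ky, "forward"), ncol = 1)
  problem <- structure(list(
    z = 1L, data = list(m),
    maps = array(1 + 0i, c(n, n, 1)),
    traj_bins = list(list(kx = ct$kx, ky = ct$ky)),
    weight_bins = list(matrix(1, n, n))), class = "slice_problem")
  res <- solve_slice(problem, recon_config(n_bins = 1, n_iter = 8, lambda = 0,
                                           engine = "nudft"))
  expect_lt(rel_l2(res$images[, , 1], truth), 0.01)
  expect_true(all(diff(res$trace) <= 1e-9 * res$trace[1]))
})

test_that("an overwhelming TV weight collapses the bins together", {
  sim <- sim_small()
  acq <- sim$acquisition
  sig <- baseline_selfgating(extract_dc_navigator(acq))
  binned <- sort_into_bins(acq, amplitude_bins(sig, 4))
  probs <- kz_decouple(binned, sim$coils_nominal, 2)
  # lambda at 1e6 x the image scale; a smooth relaxation (l1_smooth on the
  # image scale) keeps the TV term quadratic near the collapsed minimizer
  # so CG can actually reach the limit instead of creeping along the
  # nonsmooth corner
  res <- solve_slice(probs[[2]],
                     recon_config(n_bins = 4, n_iter = 30, lambda = 1e6,
                                  lambda_scale = "auto", l1_smooth = 0.1))
  img <- res$images
  ref <- sqrt(sum(Mod(img[, , 1])^2))
  for (b in 2:4)
    expect_lt(sqrt(sum(Mod(img[, , b] - img[, , 1])^2)) / ref, 0.01)
})

test_that("objective traces never increase across fixtures", {
  vol <- recon_small()
  for (tr in vol$provenance$traces) {
    expect_gte(length(tr), 2L)
    expect_true(all(diff(tr) <= 1e-9 * tr[1]))
  }
})

test_that("the volume is invariant to worker count and assignment mode", {
  sim <- sim_small()
  base <- recon_small()
  for (cfg in list(recon_config(n_bins = 4, workers = 3),
                   recon_config(n_bins = 4, workers = 2,
                                assignment = "dynamic"))) {
    v <- reconstruct_4d(sim$acquisition, sim$coils_nominal, "baseline", cfg)
    expect_identical(v$image, base$image)
  }
})

test_that("reconstruction is deterministic end to end", {
  sim <- sim_small()
  v2 <- reconstruct_4d(sim$acquisition, sim$coils_nominal, "baseline",
                       recon_config(n_bins = 4))
  expect_identical(v2$image, recon_small()$image)
})

test_that("schedule partitions slices as specified", {
  s <- schedule(7, 3)
  expect_identical(vapply(s, length, 0L), c(3L, 2L, 2L))
  expect_identical(s[[1]], 1:3)
  s64 <- schedule(64, 8)
  for (k in 1:8) expect_identical(s64[[k]], ((k - 1L) * 8L + 1L):(k * 8L))
  sd <- schedule(7, 3, "dynamic")
  expect_identical(sd[[1]], c(1L, 4L, 7L))
  expect_identical(sort(unlist(schedule(11, 4, "dynamic"))), 1:11)
})

test_that("transform work scales linearly with the number of bins", {
  # duplicate one bin's data so the per-bin work is identical: the total
  # transform count must then be exactly proportional to n_bins
  sim <- sim_small()
  acq <- sim$acquisition
  binned <- sort_into_bins(acq, amplitude_bins(rep(0, 160), 2))
  probs <- kz_decouple(binned, sim$coils_nominal, 1)
  base <- probs[[1]]
  counts <- vapply(c(1L, 2L, 4L), function(nb) {
    pr <- base
    pr$data <- rep(base$data[1], nb)
    pr$traj_bins <- rep(base$traj_bins[1], nb)
    pr$weight_bins <- rep(base$weight_bins[1], nb)
    nufft_call_reset()
    solve_slice(pr, recon_config(n_bins = nb, n_iter = 4))
    nufft_call_count()
  }, 0L)
  expect_identical(counts[2], 2L * counts[1])
  expect_identical(counts[3], 4L * counts[1])
})

test_that("a single bin reduces to the unregularised reconstruction", {
  sim <- sim_small()
  binned <- sort_into_bins(sim$acquisition, amplitude_bins(rep(0, 160), 2))
  pr <- kz_decouple(binned, sim$coils_nominal, 1)[[1]]
  pr$data <- pr$data[1]; pr$traj_bins <- pr$traj_bins[1]
  pr$weight_bins <- pr$weight_bins[1]
  r_auto <- solve_slice(pr, recon_config(n_bins = 1, n_iter = 5))
  r_l0 <- solve_slice(pr, recon_config(n_bins = 1, n_iter = 5, lambda = 0))
  expect_equal(r_auto$images, r_l0$images, tolerance = 1e-12)
})

test_that("reconstructed bin-to-bin displacement matches the ground truth", {
  sim <- sim_small()
  vol <- recon_small()
  # y-centroid shift between end-inspiration and end-expiration, slice 2
  # (inside the mover's z-extent), magnitude images
  centroid_y <- function(img) {
    m <- Mod(img)
    sum(col(m) * m) / sum(m)
  }
  # the self-gated sign convention cannot know which extreme is
  # inspiration, so compare displacement magnitudes
  rec_shift <- centroid_y(vol$image[, , 2, 1]) - centroid_y(vol$image[, , 2, 4])
  tru_shift <- centroid_y(sim$truth_images[, , 2, 1]) -
    centroid_y(sim$truth_images[, , 2, 4])
  expect_gt(abs(tru_shift), 0.3)      # the fixture genuinely moves
  expect_lt(abs(abs(rec_shift) - abs(tru_shift)), 1)
})

test_that("early stopping and line-search failure paths terminate cleanly", {
  sim <- sim_small()
  binned <- sort_into_bins(sim$acquisition,
                           amplitude_bins(baseline_selfgating(
                             extract_dc_navigator(sim$acquisition)), 2))
  pr <- kz_decouple(binned, sim$coils_nominal, 1)[[1]]
  res <- solve_slice(pr, recon_config(n_bins = 2, n_iter = 20,
                                      early_stop_tol = 0.5))
  expect_identical(res$status, "early_stop")
  expect_lt(res$iterations, 20L)
  # an unsatisfiable line search returns the initial image with a warning
  expect_warning(
    res2 <- solve_slice(pr, recon_config(n_bins = 2, n_iter = 3,
                                         max_backtracks = 1L,
                                         step_init = 1e30)),
    "line search")
  expect_identical(res2$status, "line_search_failure")
  expect_identical(res2$iterations, 0L)
})
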