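test_that("gridding NUFFT meets its accuracy contract against the exact NUDFT", {
  set.seed(31)
  for (cfgpair in list(c(2, 4), c(1.25, 5))) {
    cfg <- nufft_config(cfgpair[1], 1e-3)
    expect_identical(cfg$kernel_width, as.integer(cfgpair[2]))
    # random image on the spec'd small size and on a working size
    for (n in c(16, 48)) {
      tr <- golden_angle_trajectory(trajectory_spec(n, max(3, n %/% 3)))
      img <- matrix(complex(real = rnorm(n * n), imaginary = rnorm(n * n)),
                    n, n)
      s_ex <- exact_nudft(img, tr$kx, tr$ky, "forward")
      expect_lt(rel_l2(nufft_type2(img, tr$kx, tr$ky, cfg), s_ex),
                cfg$tolerance)
      a_ex <- exact_nudft(s_ex, tr$kx, tr$ky, "adjoint", grid = c(n, n))
      expect_lt(rel_l2(nufft_type1(s_ex, tr$kx, tr$ky, c(n, n), cfg), a_ex),
                cfg$tolerance)
    }
  }
})

test_that("NUFFT degenerate cases and errors behave", {
  n <- 32
  tr <- golden_angle_trajectory(trajectory_spec(n, 7))
  # unit impulse at the FFT-centre voxel transforms to unit-magnitude samples
  imp <- matrix(0 + 0i, n, n); imp[n %/% 2 + 1, n %/% 2 + 1] <- 1
  expect_equal(Mod(nufft_type2(imp, tr$kx, tr$ky)), rep(1, n * 7),
               tolerance = 2e-3)
  # zero image / zero samples map to zero
  expect_true(all(nufft_type2(matrix(0i, n, n), tr$kx, tr$ky) == 0))
  expect_true(all(nufft_type1(complex(n * 7), tr$kx, tr$ky, c(n, n)) == 0))
  expect_error(nufft_plan(c(0, 4), c(0, 0), n, n), "pi")
  expect_error(nufft_config(oversampling = 0.9), "oversampling")
  expect_error(nufft_config(tolerance = 2), "tolerance")
})

test_that("exact NUDFT agrees with closed forms and the FFT limit", {
  # 1x1 image: every sample equals the voxel value
  v <- matrix(3 - 2i, 1, 1)
  s <- exact_nudft(v, c(-1, 0.3, 2), c(0.5, -0.2, 1), "forward")
  expect_equal(s, rep(3 - 2i, 3))

  # samples exactly on Cartesian grid frequencies reproduce the centred FFT
  n <- 8
  set.seed(5)
  img <- matrix(complex(real = rnorm(n^2), imaginary = rnorm(n^2)), n, n)
  ct <- cartesian_trajectory(n)
  s <- exact_nudft(img, ct$kx, ct$ky, "forward")
  ref <- stargrasp:::cfft2(img)
  expect_lt(rel_l2(matrix(s, n, n), ref), 1e-12)

  # round-trip energy is positive for nonzero input
  expect_gt(Re(sum(Conj(s) * s)), 0)
  expect_error(nudft_plan(1:10, 1:10, 1e4, 1e4), "guard")
})

test_that("all linear operator pairs pass randomized adjoint tests", {
  set.seed(77)
  n <- 24
  tr <- golden_angle_trajectory(trajectory_spec(n, 9))
  tol10 <- 10 * 1e-3
  for (engine in c("nufft", "nudft")) {
    plan <- if (engine == "nufft") nufft_plan(tr$kx, tr$ky, n, n)
      else nudft_plan(tr$kx, tr$ky, n, n)
    for (rep in 1:3) {
      x <- matrix(complex(real = rnorm(n^2), imaginary = rnorm(n^2)), n, n)
      y <- complex(real = rnorm(plan$M), imaginary = rnorm(plan$M))
      gap <- abs(re_inner(ksp_forward(plan, x), y) -
                   re_inner(x, ksp_adjoint(plan, y))) /
        (sqrt(sum(Mod(x)^2)) * sqrt(sum(Mod(y)^2)))
      expect_lt(gap, tol10)
    }
  }

  # full coil encoding (2 bins, 3 coils, ramp weights)
  maps <- array(complex(real = rnorm(n * n * 3), imaginary = rnorm(n * n * 3)),
                c(n, n, 3))
  w <- radial_density_weights(tr)$w
  tb <- list(list(kx = tr$kx[, 1:5], ky = tr$ky[, 1:5]),
             list(kx = tr$kx[, 6:9], ky = tr$ky[, 6:9]))
  wb <- list(w[, 1:5], w[, 6:9])
  enc <- slice_encoding(tb, wb, maps)
  d <- array(complex(real = rnorm(n * n * 2), imaginary = rnorm(n * n * 2)),
             c(n, n, 2))
  y <- lapply(c(5, 4), function(k)
    matrix(complex(real = rnorm(n * k * 3), imaginary = rnorm(n * k * 3)),
           n * k, 3))
  lhs <- sum(vapply(1:2, function(b)
    re_inner(encode_forward(d, enc)[[b]], y[[b]]), 0))
  rhs <- re_inner(d, encode_adjoint(y, enc))
  expect_lt(abs(lhs - rhs) / (sqrt(sum(Mod(d)^2)) *
                                sqrt(sum(vapply(y, function(z) sum(Mod(z)^2), 0)))),
            tol10)

  # TV pair
  p <- array(complex(real = rnorm(n * n), imaginary = rnorm(n * n)), c(n, n, 1))
  d2 <- array(complex(real = rnorm(2 * n * n), imaginary = rnorm(2 * n * n)),
              c(n, n, 2))
  expect_lt(abs(re_inner(tv_bins(d2), p) - re_inner(d2, tv_bins_adjoint(p))) /
              (sqrt(sum(Mod(d2)^2)) * sqrt(sum(Mod(p)^2))), 1e-12)
})

test_that("encoding reduces to a plain NUFFT in the degenerate case", {
  n <- 16
  tr <- golden_angle_trajectory(trajectory_spec(n, 5))
  maps <- array(1 + 0i, c(n, n, 1))
  enc <- slice_encoding(list(list(kx = tr$kx, ky = tr$ky)),
                        list(matrix(1, n, n * 5 / 5)[, rep(1, 5)] * 0 + 1),
                        maps, normalize = FALSE)
  # weights identically 1, S identically 1, single bin: forward == type-2
  set.seed(3)
  img <- matrix(complex(real = rnorm(n^2), imaginary = rnorm(n^2)), n, n)
  d <- array(img, c(n, n, 1))
  expect_equal(encode_forward(d, enc)[[1]][, 1],
               nufft_type2(img, tr$kx, tr$ky), tolerance = 1e-12)
  # zero image maps to zero data and back
  expect_true(all(encode_forward(d * 0, enc)[[1]] == 0))
  expect_true(all(encode_adjoint(list(matrix(0i, n * 5, 1)), enc) == 0))
})

test_that("TV along bins has the stated structure", {
  d <- array(1 + 2i, c(3, 3, 4))
  expect_true(all(tv_bins(d) == 0))
  expect_equal(tv_norm_smooth(d, 1e-15), 3 * 3 * 3 * sqrt(1e-15))
  # a single differing voxel produces a single difference
  d2 <- array(0i, c(3, 3, 2)); d2[2, 2, 2] <- 4 + 0i
  p <- tv_bins(d2)
  expect_equal(p[2, 2, 1], 4 + 0i)
  expect_equal(sum(Mod(p) > 0), 1)
  # one bin: empty difference stack
  expect_identical(dim(tv_bins(array(1i, c(2, 2, 1)))), c(2L, 2L, 0L))
})

test_that("objective matches plug-in values and an oracle re-evaluation", {
  set.seed(9)
  n <- 16
  tr <- golden_angle_trajectory(trajectory_spec(n, 6))
  w <- radial_density_weights(tr)$w
  maps <- array(complex(real = rnorm(n * n * 2), imaginary = rnorm(n * n * 2)),
                c(n, n, 2))
  tb <- list(list(kx = tr$kx[, 1:3], ky = tr$ky[, 1:3]),
             list(kx = tr$kx[, 4:6], ky = tr$ky[, 4:6]))
  wb <- list(w[, 1:3], w[, 4:6])
  m <- lapply(1:2, function(b)
    matrix(complex(real = rnorm(n * 3 * 2), imaginary = rnorm(n * 3 * 2)),
           n * 3, 2))
  enc <- slice_encoding(tb, wb, maps)

  # d = 0: fidelity is the weighted data energy, tv the eps floor
  ob0 <- objective(array(0i, c(n, n, 2)), m, enc, lambda_eff = 0.5, eps = 1e-15)
  wm2 <- sum(vapply(1:2, function(b)
    sum(Mod(enc$sqrtw[[b]] * m[[b]])^2), 0))
  expect_equal(ob0$fidelity, wm2, tolerance = 1e-12)
  expect_equal(ob0$tv, n * n * sqrt(1e-15), tolerance = 1e-10)
  expect_equal(ob0$total, ob0$fidelity + 0.5 * ob0$tv)

  # lambda = 0 and consistent data: objective vanishes within NUFFT accuracy
  d <- array(complex(real = rnorm(2 * n^2), imaginary = rnorm(2 * n^2)),
             c(n, n, 2))
  fwd <- encode_forward(d, enc)
  m_consistent <- lapply(1:2, function(b) fwd[[b]] / enc$sqrtw[[b]])
  obc <- objective(d, m_consistent, enc, 0)
  expect_lt(obc$total / ob0$fidelity, 1e-20)

  # oracle: literal re-evaluation with the exact NUDFT engine
  enc_ex <- slice_encoding(tb, wb, maps, engine = "nudft")
  ob <- objective(d, m, enc, 0.3)
  ob_ex <- objective(d, m, enc_ex, 0.3)
  expect_equal(ob$total, ob_ex$total, tolerance = 1e-3)

  # invariance under a global phase rotation of image and consistent data
  phi <- exp(1i * 0.7)
  ob1 <- objective(d, lapply(m, function(x) x * phi), enc, 0.3)
  ob2 <- objective(d * phi, lapply(m, function(x) x * phi), enc, 0.3)
  expect_equal(ob2$tv, ob$tv, tolerance = 1e-10)
  expect_equal(ob2$fidelity, ob$fidelity, tolerance = 1e-8)
  expect_false(isTRUE(all.equal(ob1$fidelity, ob$fidelity)))
})

test_that("gradient matches central finite differences", {
  set.seed(21)
  n <- 12
  tr <- golden_angle_trajectory(trajectory_spec(n, 4))
  w <- radial_density_weights(tr)$w
  maps <- array(complex(real = rnorm(n * n * 2), imaginary = rnorm(n * n * 2)),
                c(n, n, 2))
  tb <- list(list(kx = tr$kx[, 1:2], ky = tr$ky[, 1:2]),
             list(kx = tr$kx[, 3:4], ky = tr$ky[, 3:4]))
  wb <- list(w[, 1:2], w[, 3:4])
  enc <- slice_encoding(tb, wb, maps, engine = "nudft")
  m <- lapply(1:2, function(b)
    matrix(complex(real = rnorm(n * 2 * 2), imaginary = rnorm(n * 2 * 2)),
           n * 2, 2))
  d <- array(complex(real = rnorm(2 * n^2), imaginary = rnorm(2 * n^2)),
             c(n, n, 2))
  lam <- 0.4; eps <- 1e-8
  g <- gradient(d, m, enc, lam, eps)
  for (rep in 1:3) {
    v <- array(complex(real = rnorm(2 * n^2), imaginary = rnorm(2 * n^2)),
               c(n, n, 2))
    h <- 1e-5
    fp <- objective(d + h * v, m, enc, lam, eps)$total
    fm <- objective(d - h * v, m, enc, lam, eps)$total
    expect_equal(re_inner(g, v), (fp - fm) / (2 * h),
                 tolerance = 1e-4)
  }
  # zero data, zero image: zero gradient
  z <- array(0i, c(n, n, 2))
  mz <- lapply(c(2, 2), function(k) matrix(0i, n * k, 2))
  expect_equal(max(Mod(gradient(z, mz, enc, lam, eps))), 0, tolerance = 1e-12)
})

test_that("the gradient vanishes at an exactly solvable minimizer", {
  # fully determined system: Cartesian-complete trajectory, S = 1, w = 1
  n <- 8
  set.seed(2)
  ct <- cartesian_trajectory(n)
  maps <- array(1 + 0i, c(n, n, 1))
  tb <- list(list(kx = ct$kx, ky = ct$ky))
  wb <- list(matrix(1, n, n))
  enc <- slice_encoding(tb, wb, maps, engine = "nudft", normalize = FALSE)
  truth <- matrix(complex(real = rnorm(n^2), imaginary = rnorm(n^2)), n, n)
  m <- list(matrix(exact_nudft(truth, ct$kx, ct$ky, "forward"), ncol = 1))
  g <- gradient(array(truth, c(n, n, 1)), m, enc, 0)
  expect_lt(max(Mod(g)), 1e-6 * sqrt(sum(Mod(m[[1]])^2)))
})
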