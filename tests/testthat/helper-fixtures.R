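# Shared fixtures, memoised so expensive simulations run once per session.

.fixtures <- new.env(parent = emptyenv())

fx <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

rel_l2 <- function(a, b) sqrt(sum(Mod(a - b)^2) / sum(Mod(b)^2))

uniform_coils <- function(grid, n_coils = 1L) {
  structure(list(maps = array(1 + 0i, c(grid, n_coils))),
            class = "coil_model")
}

# small moving-phantom acquisition: 32^2 in-plane, 2 nominal slices,
# 3 kz encodes, 4 coils, 160 spokes
sim_small <- function() fx("sim_small", function() {
  trace <- make_respiratory_trace(160 * 0.345, 0.345, seed = 7)
  simulate_kspace(default_motion_phantom(),
                  make_coil_maps(c(32, 32, 3), 4, seed = 2),
                  trajectory_spec(32, 160), trace, nz = 2,
                  kz_oversampling = 1.5)
})

# gating-scale acquisition: full clinical cadence (831 spokes / 287 s),
# 8 coils, 32^2 in-plane, 2 nominal slices
sim_gating <- function() fx("sim_gating", function() {
  trace <- make_respiratory_trace(287, 287 / 831, seed = 42)
  simulate_kspace(default_motion_phantom(),
                  make_coil_maps(c(32, 32, 3), 8, seed = 11),
                  trajectory_spec(32, 831), trace, nz = 2,
                  kz_oversampling = 1.5)
})

# baseline 4-bin reconstruction of sim_small (fast NUFFT engine)
recon_small <- function() fx("recon_small", function() {
  sim <- sim_small()
  reconstruct_4d(sim$acquisition, sim$coils_nominal, "baseline",
                 recon_config(n_bins = 4))
})

# a trajectory whose samples enumerate the full Cartesian frequency grid,
# making the single-coil unweighted system exactly invertible
cartesian_trajectory <- function(n) {
  f <- 2 * pi * (seq_len(n) - 1 - n %/% 2) / n
  list(kx = matrix(rep(f, times = n), n, n),
       ky = matrix(rep(f, each = n), n, n))
}

# bind {n_read, n_lines, n_kz, n_coils} arrays along the spoke dimension
abind_spokes <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]])
  total <- sum(vapply(parts, function(p) dim(p)[2], 0L))
  out <- array(0i, c(d[1], total, d[3], d[4]))
  at <- 0L
  for (p in parts) {
    out[, at + seq_len(dim(p)[2]), , ] <- p
    at <- at + dim(p)[2]
  }
  out
}

# hand-built DC navigator object for synthetic gating tests
make_navigator <- function(values, angles, times) {
  structure(list(values = values, angles = angles, times = times),
            class = "dc_navigator")
}
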