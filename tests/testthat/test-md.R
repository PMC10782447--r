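test_that("velocity initialization is Maxwell-Boltzmann with zero net momentum", {
  set.seed(1)
  n <- 10000
  sys <- particle_system(matrix(runif(3 * n, 0, 20), ncol = 3),
                         rep(c("Na", "Cl"), n / 2), c(20, 20, 20))
  v <- init_velocities(sys, 300, seed = 2)
  expect_equal(instantaneous_temperature(sys, v), 300, tolerance = 0.02)
  p <- colSums(v * sys$mass)
  expect_lt(max(abs(p)), 1e-9)
  # frozen particles stay at rest
  sys$mobile[1:5] <- FALSE
  v2 <- init_velocities(sys, 300, seed = 2)
  expect_equal(v2[1:5, ], matrix(0, 5, 3))
})

test_that("temperature conventions: 3N-3 dof, single-particle edge case", {
  sys1 <- particle_system(matrix(1, 1, 3), "Na", c(4, 4, 4))
  v <- matrix(c(0.3, 0, 0), 1, 3)
  kB <- unit_constants()$k_B
  m <- sys1$mass[1]
  expect_equal(instantaneous_temperature(sys1, v),
               m * 0.09 / (3 * kB))  # N_dof = 3 for a single mobile particle
  expect_equal(instantaneous_temperature(sys1, 0 * v), 0)
  sys4 <- particle_system(matrix(runif(12), 4, 3), rep("Na", 4), c(4, 4, 4))
  v4 <- matrix(rnorm(12), 4, 3)
  ke <- 0.5 * sum(sys4$mass * rowSums(v4^2))
  expect_equal(instantaneous_temperature(sys4, v4), 2 * ke / (kB * 9))
  expect_equal(instantaneous_temperature(sys4, v4, ndof_offset = 0),
               2 * ke / (kB * 12))
})

test_that("langevin_step with gamma -> 0 reproduces the velocity-Verlet recursion", {
  # harmonic oscillator, closed-form Verlet recursion as the oracle
  k <- 5; m <- 2; dt <- 0.01
  ff <- function(p) -k * p
  cfg <- md_config(n_steps = 1, dt = dt, thermostat = FALSE)
  st <- list(positions = matrix(c(1, 0, 0), 1), velocities = matrix(0, 1, 3),
             masses = m)
  xs <- numeric(200); vs <- numeric(200)
  for (i in 1:200) {
    st <- langevin_step(st, ff, cfg)
    xs[i] <- st$positions[1, 1]
  }
  x0 <- 1; v0 <- 0; xr <- numeric(200)
  f0 <- -k * x0
  for (i in 1:200) {
    x1 <- x0 + v0 * dt + 0.5 * f0 / m * dt^2
    f1 <- -k * x1
    v0 <- v0 + 0.5 * (f0 + f1) / m * dt
    x0 <- x1; f0 <- f1
    xr[i] <- x1
  }
  expect_equal(xs, xr, tolerance = 1e-12)
})

test_that("the OU step samples the correct stationary velocity variance", {
  set.seed(4)
  cfg <- md_config(n_steps = 1, dt = 0.002, temperature = 300, tau = 0.1)
  n <- 3000
  st <- list(positions = matrix(0, n, 3), velocities = matrix(0, n, 3),
             masses = rep(10, n))
  ff <- function(p) matrix(0, nrow(p), 3)
  for (i in 1:400) st <- langevin_step(st, ff, cfg)
  vvar <- mean(st$velocities^2)
  expect_equal(vvar, unit_constants()$k_B * 300 / 10, tolerance = 0.02)
})

test_that("frozen particles never move and keep zero velocity", {
  sys <- make_ionic_box(fixture_spec(n_each = 8, box = 3, seed = 3))
  sys$mobile[1:4] <- FALSE
  tr <- run_md(sys, md_config(n_steps = 500, save_stride = 0.1, seed = 5))
  for (f in seq_len(n_frames(tr)))
    expect_identical(traj_frame(tr, f)[1:4, ], wrap_positions(sys)$positions[1:4, ])
})

test_that("zero-step runs return exactly the initial frame with prior forces", {
  sys <- make_ionic_box(fixture_spec(n_each = 8, box = 3, seed = 4))
  oc <- ssip_oracle_nacl()
  tr <- run_md(sys, md_config(n_steps = 0, save_forces = TRUE, seed = 1,
                              tabulate = FALSE), extra = oc)
  expect_equal(n_frames(tr), 1L)
  expect_equal(traj_frame(tr, 1), wrap_positions(sys)$positions,
               tolerance = 1e-15)
  # dual-route force check: MD pair-list path vs brute-force evaluators
  fmd <- t(tr$forces[, , 1])
  fref <- evaluate_prior(sys)$forces + oracle_extra_forces(sys, oc)$forces
  expect_equal(fmd, fref, tolerance = 1e-12)
  # tabulated kernels agree with the analytic ones to interpolation error
  trt <- run_md(sys, md_config(n_steps = 0, save_forces = TRUE, seed = 1),
                extra = oc)
  expect_lt(max(abs(t(trt$forces[, , 1]) - fref)) / max(abs(fref)), 1e-6)
})

test_that("MD is reproducible for a fixed seed", {
  sys <- make_ionic_box(fixture_spec(n_each = 8, box = 3, seed = 6))
  t1 <- run_md(sys, md_config(n_steps = 400, save_stride = 0.1, seed = 11))
  t2 <- run_md(sys, md_config(n_steps = 400, save_stride = 0.1, seed = 11))
  expect_identical(t1$pos, t2$pos)
  t3 <- run_md(sys, md_config(n_steps = 400, save_stride = 0.1, seed = 12))
  expect_false(identical(t3$pos, t2$pos))
})

test_that("NVE conserves energy and momentum over a short run", {
  sys <- make_ionic_box(fixture_spec(n_each = 16, box = 3.2, seed = 7))
  v0 <- init_velocities(sys, 300, seed = 8)
  tr <- run_md(sys, md_config(n_steps = 2000, thermostat = FALSE,
                              save_stride = 0.2, log_stride = 0.02,
                              save_velocities = TRUE, seed = 1),
               velocities = v0)
  E <- tr$log$epot + tr$log$ekin
  expect_lt(max(abs(E - E[1])) / abs(E[1]), 1e-4)
  pfin <- colSums(t(tr$vel[, , n_frames(tr)]) * sys$mass)
  expect_lt(max(abs(pfin)), 1e-8)
  expect_error(run_md(sys, md_config(n_steps = 10, thermostat = FALSE)),
               "requires explicit initial velocities")
})

test_that("trajectory image counters unwrap continuous paths", {
  sys <- make_ionic_box(fixture_spec(n_each = 6, box = 3, seed = 9))
  tr <- run_md(sys, md_config(n_steps = 5000, save_stride = 0.05, seed = 13))
  up <- unwrap_positions(tr)
  # unwrapped displacement between consecutive frames is always small
  steps <- abs(up[, , -1] - up[, , -dim(up)[3]])
  expect_lt(max(steps), 1.0)
  # wrapped positions remain in the box
  expect_true(all(tr$pos >= 0 & tr$pos < max(sys$box)))
})
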