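test_that("RDF of an ideal gas is one and matches a brute-force histogram", {
  set.seed(41)
  n <- 60; nf <- 120; L <- 4
  pos <- array(runif(3 * n * nf, 0, L), c(3, n, nf))
  traj <- make_test_traj(pos, c(L, L, L), rep(c("Na", "Cl"), n / 2))
  rdf <- radial_distribution(traj, "Na", "Cl", bin_width = 0.05)
  # per-bin Poisson bound: |g - 1| < 5 sigma with sigma = 1/sqrt(ideal count)
  edges <- 0.05 * (0:length(rdf$r))
  shell <- 4 / 3 * pi * diff(edges^3)
  ideal <- nf * 30 * 30 * shell / L^3
  expect_true(all(abs(rdf$g - 1) < 5 / sqrt(ideal) + 0.02))
  expect_lt(mean(abs(rdf$g[rdf$r > 0.3] - 1)), 0.03)
  expect_true(all(rdf$g >= 0))
  # brute-force R oracle on a couple of frames, exact equality of counts
  sel_a <- which(traj$species == "Na"); sel_b <- which(traj$species == "Cl")
  ref <- numeric(length(rdf$r))
  for (f in 1:3) for (i in sel_a) for (j in sel_b) {
    d <- sqrt(sum(minimum_image_displacement(pos[, i, f], pos[, j, f],
                                             traj$box)^2))
    k <- floor(d / 0.05) + 1
    if (k <= length(ref)) ref[k] <- ref[k] + 1
  }
  rdf3 <- radial_distribution(traj, "Na", "Cl", bin_width = 0.05, frames = 1:3)
  expect_identical(unname(rdf3$counts), unname(ref))
})

test_that("two fixed particles give a single RDF bin; relabeling invariance", {
  pos <- array(0, c(3, 2, 1))
  pos[, 2, 1] <- c(0.573, 0, 0)
  traj <- make_test_traj(pos, c(3, 3, 3), c("Na", "Cl"))
  rdf <- radial_distribution(traj, "Na", "Cl", bin_width = 0.01)
  expect_equal(sum(rdf$counts > 0), 1L)
  expect_equal(rdf$r[which(rdf$counts > 0)], 0.575)
  set.seed(5)
  n <- 20; nf <- 4
  p2 <- array(runif(3 * n * nf, 0, 3), c(3, n, nf))
  t1 <- make_test_traj(p2, c(3, 3, 3), rep("Na", n))
  perm <- sample(n)
  t2 <- make_test_traj(p2[, perm, , drop = FALSE], c(3, 3, 3), rep("Na", n))
  r1 <- radial_distribution(t1, "Na", "Na")
  r2 <- radial_distribution(t2, "Na", "Na")
  expect_identical(r1$counts, r2$counts)
  expect_error(radial_distribution(t1, "Na", "Qq"), "empty species")
})

test_that("coordination numbers integrate the RDF correctly", {
  rdf <- structure(list(r = seq(0.005, 1.5, by = 0.01),
                        g = rep(1, 150), rho_b = 0.8), class = "rdf_result")
  n <- coordination_number(rdf)
  expect_equal(n$n, 4 / 3 * pi * 0.8 * n$r^3, tolerance = 2e-4)
  expect_true(all(diff(n$n) >= 0))
  rdf$g <- rep(0, 150)
  expect_equal(coordination_number(rdf)$n, rep(0, 150))
  # random profile vs independent quadrature (integrate() on a spline)
  set.seed(9)
  rdf$g <- runif(150, 0, 2)
  n2 <- coordination_number(rdf)
  fs <- splinefun(rdf$r, 4 * pi * 0.8 * rdf$g * rdf$r^2, method = "natural")
  ref <- integrate(fs, 0, rdf$r[80], subdivisions = 500)$value
  expect_equal(n2$n[80], ref, tolerance = 0.02)
})

test_that("cylindrical NDP normalizes a uniform system to one", {
  set.seed(12)
  n <- 80; nf <- 150; L <- c(5, 5, 3)
  pos <- array(runif(3 * n * nf) * L, c(3, n, nf))
  traj <- make_test_traj(pos, L, rep("Na", n), times = (seq_len(nf) - 1) * 10)
  ndp <- cylindrical_ndp(traj, "Na", bin_width = 0.25, block_ps = 300)
  well_sampled <- ndp$r > 0.5   # innermost shells hold too few counts
  expect_true(all(abs(ndp$density[well_sampled] - 1) < 0.15))
  expect_true(all(ndp$sd >= 0))
  expect_gte(ndp$n_blocks, 2)
  # all ions at one radius in a single frame: a single occupied bin
  p1 <- array(0, c(3, 4, 1))
  ang <- c(0, pi / 2, pi, 3 * pi / 2)
  p1[1, , 1] <- 2.5 + 1.1 * cos(ang); p1[2, , 1] <- 2.5 + 1.1 * sin(ang)
  p1[3, , 1] <- 1.5
  t1 <- make_test_traj(p1, L, rep("Na", 4))
  n1 <- cylindrical_ndp(t1, "Na", bin_width = 0.2, block_ps = 1)
  expect_equal(sum(n1$density > 0), 1L)
  # constant profile across blocks: zero block std
  pc <- array(rep(p1, 6), c(3, 4, 6))
  tc <- make_test_traj(pc, L, rep("Na", 4), times = 0:5)
  nc <- cylindrical_ndp(tc, "Na", bin_width = 0.2, block_ps = 2)
  expect_equal(max(nc$sd), 0)
})

test_that("occupancy grids are normalized probability fields", {
  L <- c(2, 2, 2)
  p <- array(0, c(3, 1, 1)); p[, 1, 1] <- c(0.52, 0.11, 1.93)
  t1 <- make_test_traj(p, L, "Na")
  g1 <- occupancy_grid_3d(t1, "Na", spacing = 0.05)
  expect_equal(sum(g1$p), 1)
  expect_equal(sum(g1$p == 1), 1L)
  # two frames, two voxels, half each
  p2 <- array(0, c(3, 1, 2)); p2[, 1, 1] <- 0.1; p2[, 1, 2] <- 1.4
  g2 <- occupancy_grid_3d(make_test_traj(p2, L, "Na"), "Na", spacing = 0.05)
  expect_equal(sort(g2$p[g2$p > 0]), c(0.5, 0.5))
  set.seed(31)
  pr <- array(runif(3 * 7 * 9) * 2, c(3, 7, 9))
  gr <- occupancy_grid_3d(make_test_traj(pr, L, rep("Na", 7)), "Na")
  expect_equal(sum(gr$p), 1, tolerance = 1e-12)
  expect_true(all(gr$p >= 0))
  expect_error(occupancy_grid_3d(t1, "Na", spacing = 0), "spacing")
})

test_that("dwell events close gaps at the tolerance boundary", {
  # occupied [0,10] ps, vacant (10,11), occupied [11,20] at 0.5 ps stride
  times <- seq(0, 20, by = 0.5)
  occ <- !(times > 10 & times < 11)
  ev1 <- ionsolv:::dwell_events(occ, times, tol = 1)   # gap == tol: closed
  expect_equal(ev1, 20)
  ev2 <- ionsolv:::dwell_events(occ, times, tol = 0.5)
  expect_equal(ev2, c(10, 9))
  expect_equal(ionsolv:::dwell_events(rep(FALSE, 10), 1:10, 1), numeric(0))
})

test_that("shell occupancy and residence match a hand-computed toy trajectory", {
  # one site at the origin; 3 ions stepping in and out of a 0.5 nm shell
  L <- c(4, 4, 4); nf <- 9
  pos <- array(2, c(3, 4, nf))
  pos[, 1, ] <- 0.1                      # the site (particle 1)
  r_in <- c(0.2, 0.2, 0.9, 0.2, 0.2, 0.2, 0.9, 0.9, 0.9)  # ion A pattern
  pos[1, 2, ] <- 0.1 + r_in              # ion A: in when r_in small
  pos[1, 3, ] <- 0.1 + 0.2               # ion B: always in
  pos[1, 4, ] <- 0.1 + 1.5               # ion C: never in
  pos[2, 2:4, ] <- 0.1; pos[3, 2:4, ] <- 0.1
  traj <- make_test_traj(pos, L, c("PH", "Na", "Na", "Na"),
                         times = 0:(nf - 1))
  res <- shell_occupancy_residence(traj, list(site = 1), cutoffs = 0.5,
                                   species = "Na", gap_tol = 1)
  # occupancy per frame: A in at frames 1,2,4,5,6 (+gap closes frame 3), B always
  occA <- c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  expect_equal(res$occupancy_mean, mean(occA + 1))
  # events: A one merged event 0..5 ps (gap of 2 ps at tol 1 stays open?)
  # gap at frame 3 spans 2 ps between occupied t=1 and t=3 -> gap 2 > tol 1
  expect_equal(res$n_events, 3L)  # A: [0,1], [3,5]; B: [0,8]
  expect_equal(sort(ionsolv:::dwell_events(occA, 0:8, 1)), c(1, 2))
  expect_equal(res$residence_mean, mean(c(1, 2, 8)))
  expect_error(shell_occupancy_residence(traj, list(site = 1), cutoffs = 3),
               "below half")
})

test_that("Einstein diffusion recovers a known Brownian coefficient", {
  set.seed(77)
  D0 <- 0.02; dtf <- 0.5; n <- 120; nf <- 400
  steps <- array(rnorm(3 * n * (nf - 1), sd = sqrt(2 * D0 * dtf)),
                 c(3, n, nf - 1))
  pos <- array(0, c(3, n, nf))
  for (f in 2:nf) pos[, , f] <- pos[, , f - 1] + steps[, , f - 1]
  traj <- make_test_traj(pos + 50, c(100, 100, 100), rep("Na", n),
                         times = (seq_len(nf) - 1) * dtf,
                         img = array(0L, c(3, n, nf)))
  est <- self_diffusion_einstein(traj, "Na")
  expect_equal(est$D_nm2_ps, D0, tolerance = 0.05)
  expect_true(est$diffusive)
  expect_equal(est$D_m2_s, est$D_nm2_ps * 1e-6)
  # static particles: D = 0
  ps <- array(1, c(3, 5, 50))
  ts <- make_test_traj(ps, c(10, 10, 10), rep("Na", 5), times = 0:49,
                       img = array(0L, c(3, 5, 50)))
  expect_equal(self_diffusion_einstein(ts, "Na")$D_nm2_ps, 0)
  # ballistic input is flagged as non-diffusive
  pb <- array(0, c(3, 5, 60))
  for (f in 1:60) pb[1, , f] <- 0.3 * (f - 1)
  tb <- make_test_traj(pb + 20, c(60, 60, 60), rep("Na", 5), times = 0:59,
                       img = array(0L, c(3, 5, 60)))
  eb <- self_diffusion_einstein(tb, "Na")
  expect_false(eb$diffusive)
  expect_gt(eb$msd_exponent, 1.8)
  # wrapped-only trajectories are rejected
  tw <- make_test_traj(ps, c(10, 10, 10), rep("Na", 5))
  expect_error(self_diffusion_einstein(tw, "Na"), "image counters")
})

test_that("block averages discard the remainder and obey CLT scaling", {
  expect_equal(block_average(rep(3.3, 10), 2),
               list(mean = 3.3, sd = 0, n_blocks = 5,
                    block_means = rep(3.3, 5)))
  ba <- block_average(c(1, 1, 2, 2), 2)
  expect_equal(ba$mean, 1.5)
  expect_equal(ba$sd, sd(c(1, 2)))
  expect_error(block_average(1:3, 2), "fewer than 2")
  # remainder is discarded
  expect_equal(block_average(c(1, 1, 2, 2, 99), 2)$mean, 1.5)
  set.seed(8)
  x <- rnorm(20000)
  ba2 <- block_average(x, 100)
  expect_equal(ba2$sd, 1 / sqrt(100), tolerance = 0.1)
})
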