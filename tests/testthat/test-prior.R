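p_default <- default_species_params()

two_body <- function(r, s1 = "Na", s2 = "Na", L = 6) {
  particle_system(rbind(c(1, 1, 1), c(1 + r, 1, 1)), c(s1, s2), c(L, L, L),
                  params = p_default)
}

test_that("neighbor list satisfies the superset guarantee and matches brute force", {
  s <- two_body(0.5)
  expect_equal(nrow(build_neighbor_list(s, 0.9, 0)$pairs), 1L)
  s2 <- two_body(1.5)
  expect_equal(nrow(build_neighbor_list(s2, 0.9, skin = 0.2)$pairs), 0L)
  set.seed(7)
  sys <- particle_system(matrix(runif(300, 0, 3), ncol = 3),
                         sample(c("Na", "Cl"), 100, TRUE), c(3, 3, 3))
  nl <- build_neighbor_list(sys, 1.0, skin = 0)
  # O(N^2) R-side oracle
  ref <- list()
  for (i in 1:99) for (j in (i + 1):100) {
    d <- minimum_image_displacement(sys$positions[i, ], sys$positions[j, ],
                                    sys$box)
    if (sum(d^2) < 1) ref[[length(ref) + 1]] <- c(i, j)
  }
  ref <- do.call(rbind, ref)
  expect_equal(nl$pairs[order(nl$pairs[, 1], nl$pairs[, 2]), , drop = FALSE],
               ref[order(ref[, 1], ref[, 2]), , drop = FALSE],
               ignore_attr = TRUE)
  expect_error(build_neighbor_list(sys, 2.0), "exceeds half")
})

test_that("LJ energy pins the sigma zero and the minimum", {
  cfg <- prior_config(lj_shift = FALSE)
  sig <- p_default$table$sigma[p_default$table$species == "Na"]
  eps <- p_default$table$epsilon[p_default$table$species == "Na"]
  expect_equal(lj_energy_forces(two_body(sig), p_default, cfg)$energy, 0,
               tolerance = 1e-12)
  at_min <- lj_energy_forces(two_body(2^(1 / 6) * sig), p_default, cfg)
  expect_equal(at_min$energy, -eps, tolerance = 1e-12)
  expect_lt(max(abs(at_min$forces)), 1e-10)
  # energy shift moves energies, not forces
  shifted <- lj_energy_forces(two_body(2^(1 / 6) * sig), p_default,
                              prior_config(lj_shift = TRUE))
  expect_equal(shifted$forces, at_min$forces)
  expect_false(isTRUE(all.equal(shifted$energy, at_min$energy)))
})

test_that("DSF Wolf pair energy and force vanish at the Coulomb cutoff", {
  cfg <- prior_config()
  s <- two_body(cfg$r_cut_coul, "Na", "Cl")
  w <- wolf_energy_forces(s, p_default, cfg)
  self <- -unit_constants()$k_e / cfg$eps_r *
    (pracma_free_erfc(cfg$alpha * cfg$r_cut_coul) / (2 * cfg$r_cut_coul) +
       cfg$alpha / sqrt(pi)) * 2
  expect_equal(w$energy, self, tolerance = 1e-12)
  expect_lt(max(abs(w$forces)), 1e-12)
  # just inside the cutoff both are continuous (no impulse)
  eps_in <- wolf_energy_forces(two_body(cfg$r_cut_coul - 1e-6, "Na", "Cl"),
                               p_default, cfg)
  expect_lt(abs(eps_in$energy - self), 1e-9)
  expect_lt(max(abs(eps_in$forces)), 1e-5)
})

test_that("prior forces are exact analytic gradients and obey Newton's third law", {
  set.seed(11)
  cfg <- prior_config()
  sys <- make_ionic_box(fixture_spec(n_each = 10, box = 3, seed = 3))
  ef <- evaluate_prior(sys, p_default, cfg)
  expect_equal(ef$energy, ef$e_lj + ef$e_coul)
  expect_lt(max(abs(colSums(ef$forces))), 1e-10)
  err <- fd_force_error(sys, function(s) evaluate_prior(s, p_default, cfg)$energy,
                        ef$forces, idx = c(1, 7, 15))
  expect_lt(err, 1e-6)
  # neutral particles: prior equals the LJ term alone
  sysn <- sys; sysn$charge <- rep(0, n_particles(sys))
  expect_equal(evaluate_prior(sysn, p_default, cfg)$energy,
               lj_energy_forces(sysn, p_default, cfg)$energy)
  # two-particle system decomposes into independently computed terms
  s2 <- two_body(0.4, "Na", "Cl")
  expect_equal(evaluate_prior(s2, p_default, cfg)$energy,
               lj_energy_forces(s2, p_default, cfg)$energy +
                 wolf_energy_forces(s2, p_default, cfg)$energy)
})

test_that("prior energy is invariant under translation and identical-particle permutation", {
  sys <- make_ionic_box(fixture_spec(n_each = 8, box = 3, seed = 5))
  e0 <- evaluate_prior(sys)$energy
  tr <- sys; tr$positions <- sweep(tr$positions, 2, c(0.37, -1.2, 5.1), "+")
  expect_equal(evaluate_prior(tr)$energy, e0, tolerance = 1e-10)
  nas <- which(sys$species == "Na")
  pm <- sys; pm$positions[nas, ] <- sys$positions[rev(nas), ]
  expect_equal(evaluate_prior(pm)$energy, e0, tolerance = 1e-10)
})

test_that("overlapping particles raise an overlap error", {
  s <- particle_system(rbind(c(1, 1, 1), c(1 + 5e-5, 1, 1)), c("Na", "Cl"),
                       c(6, 6, 6))
  expect_error(evaluate_prior(s), "overlap")
})

test_that("Wolf energy approaches the Madelung limit on a rock-salt lattice", {
  mad <- madelung_check(d = 0.28, n_cells = 6)
  expect_lt(mad$rel_err, 0.01)
  # independent oracle: neutralized-shell (Evjen) direct lattice sum
  K <- 8
  idx <- expand.grid(i = -K:K, j = -K:K, k = -K:K)
  w <- function(v) ifelse(abs(v) == K, 0.5, 1)
  terms <- with(idx, {
    r <- sqrt(i^2 + j^2 + k^2)
    s <- (-1)^(i + j + k + 1)
    ok <- r > 0
    (s * w(i) * w(j) * w(k) / r)[ok]
  })
  evjen_madelung <- sum(terms)
  expect_equal(evjen_madelung, 1.7475646, tolerance = 2e-4)
  expect_equal(mad$e_pair, -evjen_madelung * unit_constants()$k_e / 0.28,
               tolerance = 0.01)
})
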