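small_desc <- descriptor_config(n_radial = 6, r_min = 0.1)

test_that("descriptor of an isolated particle is the zero vector", {
  sys <- particle_system(rbind(c(1, 1, 1), c(3.5, 3.5, 3.5)), c("Na", "Cl"),
                         c(7, 7, 7))
  mod <- correction_model(c("Na", "Cl"), small_desc)
  expect_equal(environment_descriptor(sys, 1, mod),
               rep(0, length(environment_descriptor(sys, 1, mod))))
  expect_error(environment_descriptor(sys, 5, mod), "out of range")
})

test_that("descriptors are invariant under rotation, reflection and permutation", {
  set.seed(21)
  pos <- matrix(runif(15, 1, 3), 5, 3)
  sys <- particle_system(pos, c("Na", "Cl", "Na", "Cl", "Na"), c(40, 40, 40))
  mod <- correction_model(c("Na", "Cl"), small_desc)
  d0 <- environment_descriptor(sys, 1, mod)
  # mirror image (reflection through x-plane about the central atom)
  refl <- sys
  refl$positions[, 1] <- 2 * pos[1, 1] - pos[, 1]
  expect_equal(environment_descriptor(refl, 1, mod), d0, tolerance = 1e-12)
  th <- 1.1
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  rot <- sys
  rot$positions <- sweep((sweep(pos, 2, pos[1, ], "-") %*% t(R)), 2,
                         pos[1, ] + 5, "+")
  expect_equal(environment_descriptor(rot, 1, mod), d0, tolerance = 1e-10)
  # permuting the two identical Na neighbors (rows 3 and 5)
  perm <- sys; perm$positions[c(3, 5), ] <- pos[c(5, 3), ]
  expect_equal(environment_descriptor(perm, 1, mod), d0, tolerance = 1e-12)
})

test_that("features vary continuously as a neighbor crosses the cutoff", {
  mod <- correction_model(c("Na"), small_desc)
  rc <- small_desc$r_cut
  vals <- vapply(seq(rc - 0.01, rc + 0.01, by = 0.001), function(r) {
    sys <- particle_system(rbind(c(2, 2, 2), c(2 + r, 2, 2)), c("Na", "Na"),
                           c(8, 8, 8))
    sum(abs(environment_descriptor(sys, 1, mod)))
  }, 1.0)
  expect_true(all(diff(vals) <= 0))          # smooth decay to ...
  expect_equal(vals[length(vals)], 0)        # ... exactly zero outside
  expect_lt(max(abs(diff(vals))), 0.02)      # no jump at the cutoff
})

test_that("ml-invisible particles are absent from descriptors and get zero force", {
  set.seed(3)
  pos <- matrix(runif(18, 1, 2.2), 6, 3)
  base <- particle_system(pos, rep(c("Na", "Cl"), 3), c(5, 5, 5))
  hidden <- particle_system(rbind(pos, c(1.5, 1.5, 1.5)),
                            c(rep(c("Na", "Cl"), 3), "OP"), c(5, 5, 5),
                            ml_visible = c(rep(TRUE, 6), FALSE))
  mod <- correction_model(c("Na", "Cl"), small_desc, init = "random", seed = 5)
  expect_equal(environment_descriptor(hidden, 1, mod),
               environment_descriptor(base, 1, mod))
  F <- model_forces(hidden, mod)
  expect_equal(F[7, ], c(0, 0, 0))
  expect_error(environment_descriptor(hidden, 7, mod), "not ML-visible")
})

test_that("zero parameters give zero energy and forces; unknown species error", {
  sys <- make_ionic_box(fixture_spec(n_each = 6, box = 3, seed = 9))
  mod <- correction_model(c("Na", "Cl"), small_desc)  # zero-initialized
  expect_equal(model_energy(sys, mod), 0)
  expect_equal(max(abs(model_forces(sys, mod))), 0)
  modna <- correction_model("Na", small_desc)
  expect_error(model_energy(sys, modna), "vocabulary")
})

test_that("model energy is rotation invariant and forces are exact gradients", {
  set.seed(31)
  sys <- make_ionic_box(fixture_spec(n_each = 8, box = 3, seed = 31))
  for (hid in c(0L, 4L)) {
    mod <- correction_model(c("Na", "Cl"), small_desc, hidden = hid,
                            init = "random", seed = 8)
    e0 <- model_energy(sys, mod)
    big <- sys; big$box <- c(50, 50, 50)
    e1 <- model_energy(big, mod)
    th <- 0.8
    R <- rbind(c(1, 0, 0), c(0, cos(th), -sin(th)), c(0, sin(th), cos(th)))
    rot <- big; rot$positions <- big$positions %*% t(R) + 7
    expect_equal(model_energy(rot, mod), e1, tolerance = 1e-10)
    F <- model_forces(sys, mod)
    expect_lt(max(abs(colSums(F))), 1e-8)
    err <- fd_force_error(sys, function(s) model_energy(s, mod), F,
                          idx = c(1, 5, 12), h = 1e-6)
    expect_lt(err, 1e-5)
    # determinism
    expect_identical(model_forces(sys, mod), F)
  }
})

test_that("a 3-particle toy model matches a hand-composed descriptor evaluation", {
  # linear single-species head: E = sum_i w . d_i, recomposed in R
  dc <- descriptor_config(n_radial = 4, r_min = 0.2, include_angular = FALSE)
  mod <- correction_model("Na", dc, init = "random", seed = 17)
  pos <- rbind(c(1, 1, 1), c(1.45, 1, 1), c(1, 1.52, 1))
  sys <- particle_system(pos, rep("Na", 3), c(6, 6, 6))
  w <- mod$heads$Na$w / mod$scale
  fc <- function(r, rc) ifelse(r < rc, 0.5 * (cos(pi * r / rc) + 1), 0)
  dvec <- function(i) {
    out <- numeric(length(dc$centers))
    for (j in setdiff(1:3, i)) {
      r <- sqrt(sum((pos[j, ] - pos[i, ])^2))
      if (r < dc$r_cut) {
        # Gaussian basis with 6-sigma support, shifted to zero at its edge
        gs <- exp(-(r - dc$centers)^2 / (2 * dc$sigma_basis^2)) - exp(-18)
        gs[abs(r - dc$centers) > 6 * dc$sigma_basis] <- 0
        out <- out + gs * fc(r, dc$r_cut)
      }
    }
    out
  }
  e_hand <- sum(vapply(1:3, function(i) sum(w * dvec(i)), 1.0))
  expect_equal(model_energy(sys, mod), e_hand, tolerance = 1e-12)
})

test_that("atomic energies are strictly local (perturbation beyond the cutoff)", {
  pos <- rbind(c(1, 1, 1), c(1.4, 1, 1), c(4.5, 4.5, 4.5))
  sys <- particle_system(pos, c("Na", "Cl", "Na"), c(9, 9, 9))
  mod <- correction_model(c("Na", "Cl"), small_desc, init = "random", seed = 2)
  a0 <- model_forces(sys, mod, atomic = TRUE)$atomic_energies
  moved <- sys; moved$positions[3, ] <- c(5.3, 5.1, 4.9)
  a1 <- model_forces(moved, mod, atomic = TRUE)$atomic_energies
  expect_identical(a1[1:2], a0[1:2])
})

test_that("model serialization round-trips bit-exactly", {
  for (hid in c(0L, 3L)) {
    mod <- correction_model(c("Na", "Cl"), small_desc, hidden = hid,
                            init = "random", seed = 4)
    mod$scale <- runif(length(mod$scale), 0.5, 2)
    f <- withr::local_tempfile(fileext = ".json")
    save_correction_model(mod, f)
    back <- load_correction_model(f)
    expect_identical(back$scale, mod$scale)
    expect_identical(flatten_params_test(back), flatten_params_test(mod))
    expect_identical(back$descriptor$centers, mod$descriptor$centers)
    sys <- make_ionic_box(fixture_spec(n_each = 5, box = 3, seed = 1))
    expect_identical(model_forces(sys, back), model_forces(sys, mod))
  }
  expect_error(load_correction_model(withr::local_tempfile(lines = "{}")),
               "not an ionsolv")
})
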