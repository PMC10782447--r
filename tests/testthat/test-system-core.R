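test_that("minimum-image displacement follows the half-open convention", {
  expect_equal(minimum_image_displacement(c(0, 0, 0), c(0.9, 0, 0), c(1, 1, 1)),
               c(-0.1, 0, 0))
  expect_equal(minimum_image_displacement(c(0.3, 0.2, 0.9), c(0.3, 0.2, 0.9),
                                          c(2, 2, 2)), c(0, 0, 0))
  # exactly L/2 maps to -L/2 (half-open interval)
  expect_equal(minimum_image_displacement(c(0, 0, 0), c(0.5, 0, 0), c(1, 1, 1)),
               c(-0.5, 0, 0))
  expect_error(minimum_image_displacement(c(0, 0, 0), c(1, 0, 0), c(0, 1, 1)),
               "invalid box")
})

test_that("minimum-image displacement is antisymmetric", {
  set.seed(1)
  for (k in 1:20) {
    a <- runif(3, -3, 3); b <- runif(3, -3, 3); L <- runif(3, 0.5, 2)
    expect_identical(minimum_image_displacement(a, b, L),
                     -minimum_image_displacement(b, a, L))
  }
})

test_that("wrap_positions wraps into [0, L), is idempotent and preserves distances", {
  set.seed(2)
  pos <- matrix(runif(30, -5, 5), ncol = 3)
  sys <- particle_system(pos, rep("Na", 10), c(1.7, 2.3, 3.1),
                         charge = rep(0, 10))
  w1 <- wrap_positions(sys)
  expect_true(all(w1$positions >= 0))
  expect_true(all(sweep(w1$positions, 2, sys$box, "/") < 1))
  expect_equal(wrap_positions(w1)$positions, w1$positions)
  dmat <- function(s) {
    n <- n_particles(s)
    out <- matrix(0, n, n)
    for (i in 1:n) for (j in 1:n)
      out[i, j] <- sqrt(sum(minimum_image_displacement(
        s$positions[i, ], s$positions[j, ], s$box)^2))
    out
  }
  expect_equal(dmat(w1), dmat(sys), tolerance = 1e-12)
  # single-coordinate examples
  s2 <- particle_system(rbind(c(1.2, 0.1, 0.1), c(-0.3, 0.1, 0.1)),
                        c("Na", "Na"), c(1, 1, 1), charge = c(0, 0))
  w2 <- wrap_positions(s2)
  expect_equal(w2$positions[, 1], c(0.2, 0.7), tolerance = 1e-12)
})

test_that("ionic concentration matches closed-form expectations and scales with volume", {
  pos <- matrix(runif(64 * 3, 0, 4.2), ncol = 3)
  sys <- particle_system(pos, rep("Na", 64), c(4.2, 4.2, 4.2))
  expect_equal(ionic_concentration(sys, "Na"),
               64 / (6.02214076e23 * 4.2^3 * 1e-24), tolerance = 1e-12)
  expect_equal(ionic_concentration(sys, "Na"), 1.4344, tolerance = 1e-4)
  one <- particle_system(matrix(0.5, 1, 3), "Na", rep(1.66054^(1 / 3) * 1, 3))
  expect_equal(ionic_concentration(one, "Na"), 1.0, tolerance = 1e-4)
  expect_error(ionic_concentration(sys, "Xx"), "not present")
  big <- sys; big$box <- sys$box * 2^(1 / 3)
  expect_equal(ionic_concentration(big, "Na"),
               ionic_concentration(sys, "Na") / 2, tolerance = 1e-12)
})

test_that("species tables mix by Lorentz-Berthelot with pair overrides", {
  p <- default_species_params()
  tt <- p$table
  tabs <- lj_tables(p, c("Na", "Cl"))
  expect_equal(tabs$sigma["Na", "Cl"],
               (tt$sigma[tt$species == "Na"] + tt$sigma[tt$species == "Cl"]) / 2)
  expect_equal(tabs$epsilon["Na", "Cl"],
               sqrt(tt$epsilon[tt$species == "Na"] *
                      tt$epsilon[tt$species == "Cl"]))
  ov <- data.frame(s1 = "Na", s2 = "Cl", sigma = 0.3, epsilon = 0.7)
  tabs2 <- lj_tables(p, c("Na", "Cl"), ov)
  expect_equal(tabs2$sigma["Cl", "Na"], 0.3)
  expect_equal(tabs2$epsilon["Na", "Cl"], 0.7)
  expect_equal(tabs2$sigma["Na", "Na"], tabs$sigma["Na", "Na"])
  expect_error(lj_tables(p, c("Na", "Qq")), "unknown species")
})

test_that("particle_system enforces its invariants", {
  pos <- matrix(runif(6), 2, 3)
  expect_error(particle_system(pos, c("Na", "Cl"), c(1, -1, 1)), "invalid box")
  expect_error(particle_system(pos, c("Na", "Cl"), c(1, 1, 1),
                               charge = c(1, -1),
                               ml_visible = c(TRUE, FALSE)),
               "zero charge")
  sys <- particle_system(pos, c("Na", "OP"), c(2, 2, 2),
                         ml_visible = c(TRUE, FALSE))
  expect_equal(sys$charge, c(1, 0))
})
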