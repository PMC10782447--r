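test_that("delta targets are reference minus prior forces", {
  sys <- make_ionic_box(fixture_spec(n_each = 6, box = 3, seed = 12))
  pr <- evaluate_prior(sys)
  # reference identical to the prior: all deltas zero
  dd0 <- make_delta_dataset(list(labeled_configuration(sys, pr$forces)))
  expect_equal(max(abs(dd0$items[[1]]$delta)), 0)
  # hand-set references subtract elementwise
  fref <- pr$forces + 1.5
  dd1 <- make_delta_dataset(list(labeled_configuration(sys, fref)))
  expect_equal(dd1$items[[1]]$delta, fref - pr$forces)
  # oracle-generated configurations: delta equals the oracle's extra term
  oc <- ssip_oracle_nacl()
  lab <- generate_labeled_dataset(
    fixture_spec(n_each = 8, box = 3, seed = 13, n_configs = 4,
                 equilibration_ps = 2), oc)
  dd <- make_delta_dataset(lab)
  for (k in seq_along(lab)) {
    # closed form: delta = the oracle's extra-term forces, up to the MD
    # engine's tabulated-kernel accuracy
    ex <- oracle_extra_forces(lab[[k]]$system, oc)
    expect_lt(max(abs(dd$items[[k]]$delta - ex$forces)), 1e-3)
  }
})

test_that("dataset splitting is reproducible, disjoint and exhaustive", {
  sys <- make_ionic_box(fixture_spec(n_each = 4, box = 3, seed = 1))
  f <- evaluate_prior(sys)$forces
  dd <- make_delta_dataset(replicate(10, labeled_configuration(sys, f),
                                     simplify = FALSE))
  sp <- split_dataset(dd, 0.8, seed = 42)
  expect_length(sp$split$train, 8)
  expect_length(sp$split$val, 2)
  expect_length(intersect(sp$split$train, sp$split$val), 0)
  expect_setequal(c(sp$split$train, sp$split$val), 1:10)
  sp2 <- split_dataset(dd, 0.8, seed = 42)
  expect_identical(sp2$split, sp$split)
  expect_error(split_dataset(dd, 1.2), "fraction")
  # empirical membership frequency over repeated 5-item splits
  dd5 <- make_delta_dataset(replicate(5, labeled_configuration(sys, f),
                                      simplify = FALSE))
  hits <- numeric(5)
  ndraw <- 4000
  for (s in seq_len(ndraw))
    hits[split_dataset(dd5, 0.8, seed = s)$split$val] <-
      hits[split_dataset(dd5, 0.8, seed = s)$split$val] + 1
  expect_true(all(abs(hits / ndraw - 0.2) < 0.02))
})

test_that("force-matching loss equals the brute-force triple-loop mean", {
  a <- array(rnorm(2 * 3 * 3), c(2, 3, 3))
  b <- array(rnorm(2 * 3 * 3), c(2, 3, 3))
  expect_equal(force_matching_loss(a, a), 0)
  expect_equal(force_matching_loss(a, a + 2), 4)
  s <- 0; n <- 0
  for (i in 1:2) for (j in 1:3) for (k in 1:3) {
    s <- s + (a[i, j, k] - b[i, j, k])^2; n <- n + 1
  }
  expect_equal(force_matching_loss(a, b), s / n)
  expect_equal(force_matching_loss(a, b, reduction = "sum"), s)
  expect_error(force_matching_loss(a, b[, , 1:2]), "shape mismatch")
})

test_that("training on all-zero targets from zero init leaves parameters at zero", {
  sys <- make_ionic_box(fixture_spec(n_each = 6, box = 3, seed = 2))
  pr <- evaluate_prior(sys)
  dd <- split_dataset(make_delta_dataset(
    replicate(6, labeled_configuration(sys, pr$forces), simplify = FALSE)),
    seed = 1)
  mod <- correction_model(c("Na", "Cl"),
                          descriptor_config(n_radial = 4, r_min = 0.2))
  fit <- train_model(mod, dd, epochs = 3, seed = 1)
  expect_equal(max(abs(flatten_params_test(fit$model))), 0)
  expect_equal(fit$history$train, rep(0, 4))
})

test_that("linear mode recovers generating coefficients (closed-form LS oracle)", {
  set.seed(55)
  dc <- descriptor_config(n_radial = 5, r_min = 0.2, include_angular = FALSE)
  gen <- correction_model("Na", dc, init = "random", seed = 99)
  theta_star <- flatten_params_test(gen)
  make_cfg <- function(seed) {
    spec <- fixture_spec(n_each = 5, box = 3, seed = seed)
    sys <- make_ionic_box(spec)
    sys$charge <- rep(0, n_particles(sys))
    sys$species <- rep("Na", n_particles(sys))
    labeled_configuration(sys, model_forces(sys, gen))
  }
  configs <- lapply(1:40, make_cfg)
  # a prior with no charges and tiny LJ so the delta is the model force
  pz <- species_params(data.frame(species = "Na", sigma = 0.05, epsilon = 0,
                                  charge = 0, mass = 23))
  dd <- split_dataset(make_delta_dataset(configs, params = pz), seed = 3)
  mod0 <- correction_model("Na", dc)
  fit <- train_model(mod0, dd, epochs = 600, lr = 0.01, batch_size = 8,
                     weight_decay = 0, patience = 600, seed = 4)
  # rescale: trained weights live on standardized features
  theta_hat <- flatten_params_test(fit$model) / fit$model$scale
  expect_lt(sqrt(sum((theta_hat - theta_star)^2) / sum(theta_star^2)), 1e-3)
  # closed-form least squares through the model as a black box:
  # build the design by evaluating forces at unit parameter vectors
  items <- dd$items[dd$split$train]
  rows <- function(model) as.vector(t(do.call(rbind, lapply(items, function(it)
    model_forces(it$system, model)))))
  M <- length(theta_star)
  X <- vapply(seq_len(M), function(m) {
    unit <- ionsolv:::unflatten_params(mod0, replace(numeric(M), m, 1))
    rows(unit)
  }, numeric(length(rows(gen))))
  y <- as.vector(t(do.call(rbind, lapply(items, function(it) it$delta))))
  theta_ls <- qr.solve(X, y)
  expect_equal(theta_ls, theta_star, tolerance = 1e-8, ignore_attr = TRUE)
  expect_lt(sqrt(sum((theta_hat - theta_ls)^2) / sum(theta_ls^2)), 1e-3)
})

test_that("returned model never has worse validation loss than the start", {
  oc <- ssip_oracle_nacl()
  lab <- generate_labeled_dataset(
    fixture_spec(n_each = 10, box = 3, seed = 77, n_configs = 30,
                 equilibration_ps = 2), oc)
  dd <- split_dataset(make_delta_dataset(lab), seed = 5)
  mod <- correction_model(c("Na", "Cl"),
                          descriptor_config(n_radial = 8, r_min = 0.2))
  fit <- train_model(mod, dd, epochs = 15, seed = 6)
  expect_lte(fit$best_val, fit$history$val[1])
  expect_equal(fit$history$epoch[1], 0)
  # end-to-end reproducibility for a fixed seed
  fit2 <- train_model(mod, dd, epochs = 15, seed = 6)
  expect_identical(flatten_params_test(fit$model),
                   flatten_params_test(fit2$model))
  # force RMSE helper consistency: baseline is the RMS of the targets
  base <- force_rmse(dd, NULL)
  manual <- sqrt(mean(unlist(lapply(dd$items[dd$split$val], function(it)
    it$delta[it$has_target, ]^2))))
  expect_equal(base, manual)
})
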