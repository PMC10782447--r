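# Shared fixtures. Heavyweight study objects (oracle dataset, trained model,
# closure MD runs) are built lazily and cached for the whole test session.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_env)) assign(key, builder(), envir = .fixture_env)
  get(key, envir = .fixture_env)
}

# small random ionic system (no overlaps), cubic box
random_ion_system <- function(n = 16, L = 3, seed = 1) {
  make_ionic_box(fixture_spec(n_each = n %/% 2, box = L, seed = seed))
}

# trajectory object from a raw 3 x N x F position array (analysis tests)
make_test_traj <- function(pos, box, species, times = NULL, img = NULL,
                           charge = NULL, mobile = NULL, mlvis = NULL) {
  n <- dim(pos)[2]; nf <- dim(pos)[3]
  if (is.null(times)) times <- seq_len(nf) - 1
  structure(list(
    pos = pos, img = img, vel = NULL, forces = NULL, times = times,
    box = box, species = species,
    charge = if (is.null(charge)) rep(0, n) else charge,
    mass = rep(1, n),
    mobile = if (is.null(mobile)) rep(TRUE, n) else mobile,
    ml_visible = if (is.null(mlvis)) rep(TRUE, n) else mlvis,
    log = NULL, dt = if (nf > 1) diff(times)[1] else 1,
    stride_ps = if (nf > 1) diff(times)[1] else 1), class = "trajectory")
}

# central finite-difference force check; returns max relative error over
# sampled coordinates (relative to the max force magnitude)
fd_force_error <- function(sys, energy_fn, forces, idx = NULL, h = 1e-6) {
  if (is.null(idx)) idx <- seq_len(min(3, nrow(sys$positions)))
  fref <- max(abs(forces), 1e-10)
  err <- 0
  for (i in idx) for (k in 1:3) {
    pp <- sys; pp$positions[i, k] <- pp$positions[i, k] + h
    pm <- sys; pm$positions[i, k] <- pm$positions[i, k] - h
    fd <- -(energy_fn(pp) - energy_fn(pm)) / (2 * h)
    err <- max(err, abs(fd - forces[i, k]) / fref)
  }
  err
}

# ---- the NaCl oracle study (shared by training/closure/transfer tests) -----

study_descriptor <- function() {
  descriptor_config(r_cut = 0.9, n_radial = 66, r_min = 0.25,
                    width_factor = 1.5)
}

study_dataset <- function() memo("study_dataset", function() {
  oc <- ssip_oracle_nacl()
  lab <- generate_labeled_dataset(
    fixture_spec(n_each = 32, box = 3.76, seed = 101, n_configs = 1900,
                 equilibration_ps = 10), oc)
  split_dataset(make_delta_dataset(lab), fraction = 0.8, seed = 102)
})

study_fit <- function() memo("study_fit", function() {
  mod <- correction_model(c("Na", "Cl"), study_descriptor())
  train_model(mod, study_dataset(), epochs = 120, lr = 0.02,
              batch_size = 32, patience = 30, seed = 103)
})

closure_rdfs <- function() memo("closure_rdfs", function() {
  oc <- ssip_oracle_nacl()
  sys <- make_ionic_box(fixture_spec(n_each = 32, box = 3.76, seed = 104))
  cfg <- function(seed) md_config(n_steps = 4e6, save_stride = 0.5,
                                  log_stride = 10, seed = seed)
  tro <- run_md(sys, cfg(105), extra = oc)
  trd <- run_md(sys, cfg(106), model = study_fit()$model)
  fr <- seq(41, n_frames(tro))  # discard 20 ps equilibration
  list(oracle = radial_distribution(tro, "Na", "Cl", frames = fr),
       dis = radial_distribution(trd, "Na", "Cl", frames = fr))
})

# complementary error function via the normal CDF (base R)
pracma_free_erfc <- function(x) 2 * pnorm(-sqrt(2) * x)

flatten_params_test <- function(model) ionsolv:::flatten_params(model)

cpp_min_pair_distance_test <- function(sys)
  ionsolv:::cpp_min_pair_distance(sys$positions, sys$box)
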