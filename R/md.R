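#' MD run configuration
#'
#' Defaults mirror the implicit-solvent protocol this toolkit targets: 1 fs
#' velocity-Verlet timestep, 300 K, Langevin coupling time 0.1 ps (friction
#' gamma = 1/tau), frames saved every 1 ps.
#'
#' @param n_steps number of integration steps.
#' @param dt timestep (ps), default 0.001 (1 fs).
#' @param temperature target temperature (K), default 300.
#' @param tau Langevin coupling time (ps), default 0.1.
#' @param thermostat logical; FALSE gives NVE velocity Verlet (initial
#'   velocities must then be supplied to [run_md()]).
#' @param save_stride frame-saving interval (ps), default 1.
#' @param log_stride scalar-log interval (ps), default `save_stride`.
#' @param seed RNG seed for thermostat noise and velocity initialization.
#' @param skin neighbor-list skin (nm), default 0.2.
#' @param tabulate use cubic-Hermite pair tables for the LJ/Wolf/oracle and
#'   linear-model radial kernels (default TRUE; the standard engine
#'   technique, accurate to interpolation error ~1e-8). Set FALSE to force
#'   fully analytic kernels.
#' @param save_velocities,save_forces store per-frame velocities/forces.
#' @return Object of class `md_config`.
#' @export
md_config <- function(n_steps, dt = 0.001, temperature = 300, tau = 0.1,
                      thermostat = TRUE, save_stride = 1,
                      log_stride = save_stride, seed = 1, skin = 0.2,
                      tabulate = TRUE,
                      save_velocities = FALSE, save_forces = FALSE) {
  stopifnot(dt > 0, tau > 0, n_steps >= 0, save_stride > 0, temperature > 0)
  structure(list(n_steps = as.integer(n_steps), dt = dt,
                 temperature = temperature, tau = tau,
                 thermostat = isTRUE(thermostat),
                 save_stride = save_stride, log_stride = log_stride,
                 seed = seed, skin = skin, tabulate = isTRUE(tabulate),
                 save_velocities = isTRUE(save_velocities),
                 save_forces = isTRUE(save_forces)),
            class = "md_config")
}

#' Maxwell-Boltzmann velocity initialization
#'
#' Draws velocities at temperature `T` for mobile particles, zeroes frozen
#' particles, and removes the net momentum of the mobile set.
#'
#' @param sys a [particle_system].
#' @param temperature temperature (K).
#' @param seed RNG seed.
#' @return N x 3 velocity matrix (nm/ps).
#' @export
init_velocities <- function(sys, temperature = 300, seed = 1) {
  stopifnot(inherits(sys, "particle_system"), temperature > 0)
  if (any(sys$mass[sys$mobile] <= 0)) stop("mobile particles need mass > 0")
  set.seed(seed)
  n <- n_particles(sys)
  kB <- unit_constants()$k_B
  sdv <- sqrt(kB * temperature / sys$mass)
  v <- matrix(rnorm(3 * n), n, 3) * sdv
  v[!sys$mobile, ] <- 0
  mob <- sys$mobile
  if (sum(mob) > 0) {
    ptot <- colSums(v[mob, , drop = FALSE] * sys$mass[mob])
    v[mob, ] <- sweep(v[mob, , drop = FALSE], 2,
                      ptot / sum(sys$mass[mob]), "-")
  }
  v
}

#' Instantaneous kinetic temperature
#'
#' `T = 2 KE / (k_B N_dof)` over mobile particles with
#' `N_dof = max(3 N_mobile - 3, 3)` (three degrees of freedom are removed
#' for the zeroed net momentum; a single mobile particle keeps its full 3).
#'
#' @param sys a [particle_system].
#' @param velocities N x 3 velocity matrix (nm/ps).
#' @param ndof_offset degrees of freedom removed (default 3; use 0 under a
#'   Langevin thermostat, which does not conserve momentum).
#' @return Temperature (K).
#' @export
instantaneous_temperature <- function(sys, velocities, ndof_offset = 3) {
  mob <- sys$mobile
  nmob <- sum(mob)
  if (nmob < 1) stop("no mobile particles")
  ke <- 0.5 * sum(sys$mass[mob] * rowSums(velocities[mob, , drop = FALSE]^2))
  ndof <- max(3 * nmob - ndof_offset, 3)
  2 * ke / (unit_constants()$k_B * ndof)
}

#' One BAOAB Langevin step with an arbitrary force function
#'
#' Reference (pure-R) implementation of the integrator used by [run_md()]:
#' half-kick, half-drift, Ornstein-Uhlenbeck velocity update with
#' `exp(-gamma dt)` decay and exact thermal noise variance, half-drift,
#' half-kick with recomputed forces. With `thermostat = FALSE` (or gamma = 0)
#' this reduces exactly to velocity Verlet. Frozen particles never move.
#'
#' @param state list with `positions`, `velocities`, `masses`, optional
#'   `mobile` mask and cached `forces`.
#' @param force_fn function(positions) -> N x 3 forces.
#' @param cfg an [md_config] (uses dt, temperature, tau, thermostat).
#' @return Updated state (positions, velocities, forces).
#' @export
langevin_step <- function(state, force_fn, cfg) {
  p <- as.matrix(state$positions); v <- as.matrix(state$velocities)
  m <- state$masses
  mob <- if (is.null(state$mobile)) rep(TRUE, nrow(p)) else state$mobile
  F <- if (is.null(state$forces)) force_fn(p) else state$forces
  if (any(!is.finite(F))) stop("non-finite forces entering langevin_step")
  dt <- cfg$dt
  gamma <- if (cfg$thermostat) 1 / cfg$tau else 0
  v[mob, ] <- v[mob, ] + 0.5 * dt * F[mob, , drop = FALSE] / m[mob]
  p[mob, ] <- p[mob, ] + 0.5 * dt * v[mob, , drop = FALSE]
  if (gamma > 0) {
    c1 <- exp(-gamma * dt)
    c2 <- sqrt(unit_constants()$k_B * cfg$temperature / m[mob] * (1 - c1^2))
    nm <- sum(mob)
    v[mob, ] <- c1 * v[mob, , drop = FALSE] + matrix(rnorm(3 * nm), nm, 3) * c2
  }
  p[mob, ] <- p[mob, ] + 0.5 * dt * v[mob, , drop = FALSE]
  F <- force_fn(p)
  v[mob, ] <- v[mob, ] + 0.5 * dt * F[mob, , drop = FALSE] / m[mob]
  list(positions = p, velocities = v, masses = m, mobile = mob, forces = F)
}

#' Run implicit-solvent MD
#'
#' BAOAB Langevin (or NVE velocity-Verlet) dynamics under the physics prior,
#' optionally plus an oracle force field's extra terms and/or a trained
#' correction model. Positions are wrapped with per-particle image counters
#' so trajectories can be unwrapped exactly for diffusion analysis.
#'
#' @param sys a [particle_system].
#' @param cfg an [md_config].
#' @param params a [species_params] table.
#' @param prior_cfg a [prior_config].
#' @param model optional [correction_model] (adds correction forces).
#' @param extra optional [oracle_force_field] extra terms (adds the oracle's
#'   pair/3-body corrections; used to generate reference dynamics).
#' @param velocities optional N x 3 initial velocities; drawn from
#'   Maxwell-Boltzmann at `cfg$temperature` when omitted (requires
#'   thermostat) .
#' @return Object of class `trajectory`.
#' @export
run_md <- function(sys, cfg, params = default_species_params(),
                   prior_cfg = prior_config(), model = NULL, extra = NULL,
                   velocities = NULL) {
  stopifnot(inherits(sys, "particle_system"), inherits(cfg, "md_config"))
  sys <- wrap_positions(sys)
  a <- prior_cpp_args(sys, params, prior_cfg)
  check_cutoff_box(max(prior_cfg$r_cut_lj, prior_cfg$r_cut_coul) + cfg$skin,
                   sys$box)
  set.seed(cfg$seed)
  if (is.null(velocities)) {
    if (!cfg$thermostat)
      stop("NVE run requires explicit initial velocities")
    velocities <- init_velocities(sys, cfg$temperature,
                                  seed = cfg$seed + 1L)
  }
  chid <- if (!is.null(model)) model_chid(model, sys) else
    integer(n_particles(sys))
  extra_cpp <- if (!is.null(extra)) oracle_extra_cpp(extra, a$vocab) else NULL
  model_cpp_l <- if (!is.null(model)) model_cpp(model) else NULL
  stride <- max(1L, as.integer(round(cfg$save_stride / cfg$dt)))
  lstride <- max(1L, as.integer(round(cfg$log_stride / cfg$dt)))
  gamma <- if (cfg$thermostat) 1 / cfg$tau else 0
  img0 <- matrix(0L, n_particles(sys), 3)
  res <- cpp_md_run(sys$positions, as.matrix(velocities), img0,
                    a$spid, chid, sys$charge, sys$mass, sys$box,
                    sys$mobile, sys$ml_visible, a$prior,
                    extra_cpp, model_cpp_l,
                    cfg$dt, cfg$n_steps, stride, lstride,
                    gamma, cfg$temperature, cfg$skin,
                    cfg$save_velocities, cfg$save_forces,
                    isTRUE(cfg$tabulate))
  structure(list(
    pos = res$pos, img = res$img,
    vel = if (cfg$save_velocities) res$vel else NULL,
    forces = if (cfg$save_forces) res$forces else NULL,
    times = res$times, box = sys$box,
    species = sys$species, charge = sys$charge, mass = sys$mass,
    mobile = sys$mobile, ml_visible = sys$ml_visible,
    log = as.data.frame(res$log), final_vel = res$final_vel,
    dt = cfg$dt, stride_ps = stride * cfg$dt
  ), class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d frames x %d particles, %.4g ps span, stride %.4g ps\n",
              n_frames(x), dim(x$pos)[2], max(x$times), x$stride_ps))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `trajectory`.
#' @export
n_frames <- function(traj) length(traj$times)

#' Positions of one frame as an N x 3 matrix
#' @param traj a `trajectory`.
#' @param frame frame index (1-based).
#' @param unwrap undo periodic wrapping using the stored image counters.
#' @export
traj_frame <- function(traj, frame, unwrap = FALSE) {
  p <- t(traj$pos[, , frame, drop = FALSE][, , 1])
  if (unwrap)
    p <- p + sweep(t(traj$img[, , frame, drop = FALSE][, , 1]), 2, traj$box, "*")
  p
}

#' Reconstruct the particle system of a trajectory frame
#' @param traj a `trajectory`.
#' @param frame frame index.
#' @export
traj_system <- function(traj, frame = 1) {
  particle_system(traj_frame(traj, frame), traj$species, traj$box,
                  charge = traj$charge, mass = traj$mass,
                  mobile = traj$mobile, ml_visible = traj$ml_visible)
}

#' Unwrapped positions array (3 x N x F)
#'
#' Uses the per-particle image counters maintained by the MD engine; errors
#' if the trajectory carries no image information.
#' @param traj a `trajectory`.
#' @export
unwrap_positions <- function(traj) {
  if (is.null(traj$img)) stop("trajectory has no image counters; cannot unwrap")
  traj$pos + traj$img * array(traj$box, dim = dim(traj$pos))
}
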