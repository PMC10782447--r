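#' Configuration of the physics prior
#'
#' The prior is a 12-6 Lennard-Jones potential plus Wolf-summation Coulomb
#' electrostatics screened by a dielectric continuum (relative permittivity
#' `eps_r`, default 95, the measured dielectric constant of a common
#' three-site water model). The default Wolf variant is damped shifted force
#' (DSF): pair energy and force both go continuously to zero at the Coulomb
#' cutoff, so MD never sees an impulse at the cutoff. The damping parameter
#' `alpha` is an engineering default; both it and the variant are
#' configuration, not physics the toolkit pins down.
#'
#' @param r_cut_lj LJ cutoff (nm), default 0.9.
#' @param r_cut_coul Coulomb cutoff (nm), default 1.2; must be >= `r_cut_lj`.
#' @param eps_r relative dielectric constant, >= 1; default 95.
#' @param alpha Wolf damping (1/nm), default 2.0.
#' @param wolf_variant `"dsf"` (damped shifted force, default) or
#'   `"energy_shift"`.
#' @param lj_shift logical; shift the LJ energy to zero at the cutoff
#'   (default TRUE; forces are unaffected).
#' @param pair_overrides optional data.frame of LJ pair overrides
#'   (see [lj_tables()]).
#' @return Object of class `prior_config`.
#' @export
prior_config <- function(r_cut_lj = 0.9, r_cut_coul = 1.2, eps_r = 95,
                         alpha = 2.0, wolf_variant = c("dsf", "energy_shift"),
                         lj_shift = TRUE, pair_overrides = NULL) {
  wolf_variant <- match.arg(wolf_variant)
  if (!(r_cut_lj > 0 && r_cut_lj <= r_cut_coul))
    stop("require 0 < r_cut_lj <= r_cut_coul")
  if (eps_r < 1) stop("eps_r must be >= 1")
  if (alpha <= 0) stop("alpha must be > 0")
  structure(list(r_cut_lj = r_cut_lj, r_cut_coul = r_cut_coul, eps_r = eps_r,
                 alpha = alpha, wolf_variant = wolf_variant,
                 lj_shift = lj_shift, pair_overrides = pair_overrides),
            class = "prior_config")
}

check_cutoff_box <- function(rc, box) {
  if (rc > min(box) / 2 + 1e-12)
    stop(sprintf("cutoff %.4g nm exceeds half the smallest box edge (%.4g nm)",
                 rc, min(box) / 2))
}

# Assemble the C++-side prior parameter list for a system.
prior_cpp_args <- function(sys, params, cfg) {
  vocab <- sort(unique(sys$species))
  tabs <- lj_tables(params, vocab, cfg$pair_overrides)
  list(vocab = vocab,
       spid = species_ids(sys$species, vocab),
       prior = list(sig = tabs$sigma, eps = tabs$epsilon,
                    rc_lj = cfg$r_cut_lj, rc_coul = cfg$r_cut_coul,
                    alpha = cfg$alpha, eps_r = cfg$eps_r,
                    lj_shift = isTRUE(cfg$lj_shift),
                    wolf_variant = if (cfg$wolf_variant == "dsf") 0L else 1L,
                    do_lj = TRUE, do_coul = TRUE))
}

#' Build a Verlet neighbor list
#'
#' Lists every unordered pair with minimum-image distance below
#' `cutoff + skin`; the superset guarantee holds until any particle has moved
#' more than `skin/2` since construction.
#'
#' @param sys a [particle_system].
#' @param cutoff interaction cutoff (nm).
#' @param skin buffer distance (nm), default 0.2.
#' @return Object of class `neighbor_list` with a 2-column `pairs` matrix
#'   (1-based indices, i < j).
#' @export
build_neighbor_list <- function(sys, cutoff, skin = 0.2) {
  stopifnot(inherits(sys, "particle_system"))
  check_cutoff_box(cutoff + skin, sys$box)
  pairs <- cpp_pairs_within(sys$positions, sys$box, cutoff + skin)
  structure(list(pairs = pairs, cutoff = cutoff, skin = skin),
            class = "neighbor_list")
}

prior_terms <- function(sys, params, cfg, do_lj, do_coul) {
  stopifnot(inherits(sys, "particle_system"), inherits(cfg, "prior_config"))
  check_cutoff_box(if (do_coul) cfg$r_cut_coul else cfg$r_cut_lj, sys$box)
  a <- prior_cpp_args(sys, params, cfg)
  cpp_prior_ef(sys$positions, a$spid, sys$charge, sys$box,
               a$prior$sig, a$prior$eps, cfg$r_cut_lj, cfg$r_cut_coul,
               cfg$alpha, cfg$eps_r, isTRUE(cfg$lj_shift),
               a$prior$wolf_variant, do_lj, do_coul, sys$mobile)
}

#' Lennard-Jones energy and forces
#'
#' @param sys a [particle_system].
#' @param params a [species_params] object.
#' @param cfg a [prior_config].
#' @return list(`energy`, `forces`) with forces as an N x 3 matrix
#'   (kJ/mol/nm). Forces are exact analytic gradients and sum to zero.
#' @export
lj_energy_forces <- function(sys, params = default_species_params(),
                             cfg = prior_config()) {
  r <- prior_terms(sys, params, cfg, do_lj = TRUE, do_coul = FALSE)
  list(energy = r$e_lj, forces = r$forces)
}

#' Wolf-summation Coulomb energy and forces
#'
#' Damped, cutoff-based electrostatics with a self-term correction; in the
#' default DSF variant both pair energy and pair force vanish continuously at
#' the cutoff.
#'
#' @inheritParams lj_energy_forces
#' @return list(`energy`, `forces`); the energy includes the Wolf self term.
#' @export
wolf_energy_forces <- function(sys, params = default_species_params(),
                               cfg = prior_config()) {
  r <- prior_terms(sys, params, cfg, do_lj = FALSE, do_coul = TRUE)
  list(energy = r$e_coul, forces = r$forces)
}

#' Total prior energy and forces (LJ + Wolf)
#'
#' Auxiliary oxygens contribute only through LJ (their charge is zero by
#' construction); frozen particles receive forces from mobile particles but
#' are never moved. Pairs in which both particles are frozen are excluded
#' (rigid-scaffold internal energy is a constant and is not part of the
#' potential of mean force the toolkit models).
#'
#' @inheritParams lj_energy_forces
#' @return list(`energy`, `e_lj`, `e_coul`, `forces`).
#' @export
evaluate_prior <- function(sys, params = default_species_params(),
                           cfg = prior_config()) {
  r <- prior_terms(sys, params, cfg, do_lj = TRUE, do_coul = TRUE)
  list(energy = r$e_lj + r$e_coul, e_lj = r$e_lj, e_coul = r$e_coul,
       forces = r$forces)
}
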