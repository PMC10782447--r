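#' Analytic oracle force field
#'
#' The oracle stands in for an expensive explicit-solvent reference: it is
#' the physics prior plus analytically known extra terms, so delta-learning
#' targets are known in closed form and training becomes a controlled
#' recovery experiment. Extra terms are (a) per-species-pair sums of
#' Gaussians `A exp(-(r - r0)^2 / (2 w^2))` under a smooth cosine cutoff
#' envelope and (b) an optional three-body angular term
#' `lambda * sum_(j<k) (cos(theta) + 1/3)^2 fc(rij) fc(rik)` among particles
#' of one species.
#'
#' @param pair_terms data.frame with columns `s1`, `s2` (species labels),
#'   `A` (kJ/mol), `r0` (nm), `w` (nm); one row per Gaussian.
#' @param r_cut cutoff of the extra pair terms (nm), default 0.9.
#' @param triple optional list(`lambda` (kJ/mol), `species`, `r_cut`).
#' @param params species table used when the oracle's "true" LJ parameters
#'   should differ from the model prior's (default: identical).
#' @param prior_cfg the prior configuration the oracle shares.
#' @return Object of class `oracle_force_field`.
#' @export
oracle_force_field <- function(pair_terms, r_cut = 0.9, triple = NULL,
                               params = default_species_params(),
                               prior_cfg = prior_config()) {
  stopifnot(is.data.frame(pair_terms),
            all(c("s1", "s2", "A", "r0", "w") %in% names(pair_terms)))
  if (!is.null(triple))
    stopifnot(all(c("lambda", "species", "r_cut") %in% names(triple)))
  structure(list(pair_terms = pair_terms, r_cut = r_cut, triple = triple,
                 params = params, prior_cfg = prior_cfg),
            class = "oracle_force_field")
}

#' The shipped NaCl SSIP oracle preset
#'
#' Gaussian wells in the Na-Cl channel at 0.46 and 0.50 nm create a
#' solvent-separated ion-pair (SSIP) double feature in the pair potential of
#' mean force, plus a contact well at 0.33 nm and a barrier at 0.40 nm;
#' shallow wells structure the like-ion channels, and a weak three-body term
#' among Na within the ML cutoff supplies a genuine many-body component.
#' Well widths (0.015 nm for the SSIP pair) keep the two minima resolvable
#' at the default 0.01 nm RDF bin.
#'
#' @param with_triple include the three-body Na term (default TRUE).
#' @return An [oracle_force_field].
#' @export
ssip_oracle_nacl <- function(with_triple = TRUE) {
  pair_terms <- data.frame(
    s1 = c("Na", "Na", "Na", "Na", "Na", "Cl"),
    s2 = c("Cl", "Cl", "Cl", "Cl", "Na", "Cl"),
    A  = c(-3.0, 1.2, -2.0, -1.8, -1.0, -0.8),
    r0 = c(0.33, 0.40, 0.46, 0.50, 0.43, 0.55),
    w  = c(0.020, 0.020, 0.015, 0.015, 0.025, 0.030),
    stringsAsFactors = FALSE
  )
  oracle_force_field(pair_terms, r_cut = 0.9,
                     triple = if (with_triple)
                       list(lambda = 0.5, species = "Na", r_cut = 0.9)
                     else NULL)
}

# C++ representation of the oracle's extra terms against a species vocab.
oracle_extra_cpp <- function(oracle, vocab) {
  pt <- oracle$pair_terms
  keys <- unique(pt[, c("s1", "s2")])
  pairs <- lapply(seq_len(nrow(keys)), function(k) {
    sel <- pt$s1 == keys$s1[k] & pt$s2 == keys$s2[k]
    i1 <- match(keys$s1[k], vocab); i2 <- match(keys$s2[k], vocab)
    if (is.na(i1) || is.na(i2)) return(NULL)
    list(s1 = i1 - 1L, s2 = i2 - 1L,
         A = pt$A[sel], r0 = pt$r0[sel], w = pt$w[sel])
  })
  pairs <- Filter(Negate(is.null), pairs)
  tr <- NULL
  if (!is.null(oracle$triple)) {
    is <- match(oracle$triple$species, vocab)
    if (!is.na(is))
      tr <- list(lambda = oracle$triple$lambda, rc = oracle$triple$r_cut,
                 species = is - 1L)
  }
  list(rc = oracle$r_cut, pairs = pairs, triple = tr)
}

#' Oracle extra-term energy and forces on a configuration
#'
#' The part of the oracle beyond the prior, evaluated in closed form; by the
#' oracle decomposition identity, `F_oracle = F_prior + F_extra` exactly.
#'
#' @param sys a [particle_system].
#' @param oracle an [oracle_force_field].
#' @return list(`energy`, `forces`).
#' @export
oracle_extra_forces <- function(sys, oracle) {
  vocab <- sort(unique(sys$species))
  cpp_extra_ef(sys$positions, species_ids(sys$species, vocab), sys$box,
               oracle_extra_cpp(oracle, vocab), length(vocab), sys$mobile)
}

#' Full oracle energy and forces (prior + extra terms)
#'
#' @inheritParams oracle_extra_forces
#' @return list(`energy`, `forces`).
#' @export
oracle_forces <- function(sys, oracle) {
  pr <- evaluate_prior(sys, oracle$params, oracle$prior_cfg)
  ex <- oracle_extra_forces(sys, oracle)
  list(energy = pr$energy + ex$energy, forces = pr$forces + ex$forces)
}

#' One-dimensional scan of an oracle species-pair potential
#'
#' Evaluates the oracle's pair interaction (prior pair terms + extra
#' Gaussians) for an isolated pair at distances `r` — the pair potential of
#' mean force the oracle encodes. Used to verify e.g. the SSIP double
#' minimum of the shipped preset.
#'
#' @param oracle an [oracle_force_field].
#' @param s1,s2 species labels.
#' @param r distances (nm).
#' @param include_prior include LJ + screened Coulomb (default TRUE).
#' @return data.frame(r, energy).
#' @export
oracle_pair_potential <- function(oracle, s1, s2,
                                  r = seq(0.2, 0.89, by = 0.002),
                                  include_prior = TRUE) {
  L <- max(3, 2 * oracle$prior_cfg$r_cut_coul + 0.5)
  e <- vapply(r, function(ri) {
    sys <- particle_system(rbind(c(L / 2, L / 2, L / 2),
                                 c(L / 2 + ri, L / 2, L / 2)),
                           c(s1, s2), c(L, L, L), params = oracle$params)
    ep <- if (include_prior)
      evaluate_prior(sys, oracle$params, oracle$prior_cfg)$energy else 0
    ep + oracle_extra_forces(sys, oracle)$energy
  }, numeric(1))
  data.frame(r = r, energy = e)
}

#' Fixture specification for synthetic ionic boxes
#'
#' @param concentration target NaCl concentration (mol/L); ignored when
#'   `n_each` is given.
#' @param box length-3 box edges (nm) or a scalar cubic edge.
#' @param n_each explicit number of Na (= Cl) ion pairs, overriding
#'   `concentration`.
#' @param seed RNG seed.
#' @param n_configs number of labeled configurations to generate.
#' @param stride_ps sampling stride (ps), default 1.
#' @param equilibration_ps discarded initial span (ps), default 10.
#' @param min_dist minimum initial pair distance (nm), default 0.25.
#' @return Object of class `fixture_spec`.
#' @export
fixture_spec <- function(concentration = 1.0, box = 3.76, n_each = NULL,
                         seed = 1, n_configs = 2000, stride_ps = 1,
                         equilibration_ps = 10, min_dist = 0.25) {
  if (length(box) == 1) box <- rep(box, 3)
  stopifnot(all(box > 0))
  structure(list(concentration = concentration, box = box, n_each = n_each,
                 seed = seed, n_configs = n_configs, stride_ps = stride_ps,
                 equilibration_ps = equilibration_ps, min_dist = min_dist),
            class = "fixture_spec")
}

#' Build a random non-overlapping NaCl box
#'
#' Equal Na and Cl counts from the requested concentration (nearest integer
#' to `c * N_A * V`), plus Na counterions neutralizing any scaffold charge.
#' Packing is seeded rejection sampling with a minimum-distance constraint.
#'
#' @param spec a [fixture_spec].
#' @param scaffold optional frozen [particle_system] (e.g. a CG polyion) to
#'   embed; its sites are kept and neutralized with extra Na.
#' @param params species table for charges/masses.
#' @return A [particle_system].
#' @export
make_ionic_box <- function(spec, scaffold = NULL,
                           params = default_species_params()) {
  stopifnot(inherits(spec, "fixture_spec"))
  v_l <- prod(spec$box) * 1e-24
  n_each <- if (!is.null(spec$n_each)) spec$n_each else
    as.integer(round(spec$concentration * unit_constants()$N_A * v_l))
  set.seed(spec$seed)
  pos0 <- NULL; sp0 <- character(0)
  extra_na <- 0L
  if (!is.null(scaffold)) {
    stopifnot(inherits(scaffold, "particle_system"))
    pos0 <- scaffold$positions; sp0 <- scaffold$species
    qnet <- sum(scaffold$charge)
    if (abs(qnet - round(qnet)) > 1e-9)
      stop("scaffold net charge must be integer for neutralization")
    extra_na <- as.integer(round(-qnet))
    if (extra_na < 0) stop("positively charged scaffolds are not supported")
  }
  n_na <- n_each + extra_na
  n_cl <- n_each
  n_new <- n_na + n_cl
  placed <- matrix(NA_real_, n_new, 3)
  occupied <- pos0
  md2 <- spec$min_dist^2
  for (k in seq_len(n_new)) {
    ok <- FALSE
    for (att in 1:2000) {
      cand <- runif(3) * spec$box
      ok <- TRUE
      if (!is.null(occupied) && nrow(occupied) > 0) {
        d <- sweep(occupied, 2, cand, "-")
        for (c3 in 1:3) d[, c3] <- d[, c3] - spec$box[c3] *
            floor(d[, c3] / spec$box[c3] + 0.5)
        if (min(rowSums(d^2)) < md2) ok <- FALSE
      }
      if (ok) break
    }
    if (!ok) stop("packing failure: could not place particle ", k,
                  " after 2000 attempts (density too high for min_dist)")
    placed[k, ] <- cand
    occupied <- rbind(occupied, cand)
  }
  pos <- rbind(pos0, placed)
  species <- c(sp0, rep("Na", n_na), rep("Cl", n_cl))
  mobile <- c(if (!is.null(scaffold)) scaffold$mobile, rep(TRUE, n_new))
  mlvis <- c(if (!is.null(scaffold)) scaffold$ml_visible, rep(TRUE, n_new))
  charge <- c(if (!is.null(scaffold)) scaffold$charge,
              rep(c(1, -1), c(n_na, n_cl)))
  particle_system(pos, species, spec$box, charge = charge,
                  mobile = mobile, ml_visible = mlvis, params = params)
}

#' Generate a labeled dataset by sampling oracle MD
#'
#' Runs Langevin MD under the full oracle (prior + extra terms), discards an
#' equilibration span, then stores configurations with the oracle's forces
#' on the mobile ML-visible particles at the sampling stride.
#'
#' @param spec a [fixture_spec].
#' @param oracle an [oracle_force_field].
#' @param scaffold optional frozen scaffold passed to [make_ionic_box()].
#' @param temperature temperature (K), default 300.
#' @return list of [labeled_configuration] objects (length
#'   `spec$n_configs`).
#' @export
generate_labeled_dataset <- function(spec, oracle, scaffold = NULL,
                                     temperature = 300) {
  stopifnot(inherits(spec, "fixture_spec"),
            inherits(oracle, "oracle_force_field"))
  if (spec$n_configs == 0) return(list())
  sys <- make_ionic_box(spec, scaffold, oracle$params)
  total_ps <- spec$equilibration_ps + spec$n_configs * spec$stride_ps
  cfg <- md_config(n_steps = round(total_ps / 0.001), dt = 0.001,
                   temperature = temperature, save_stride = spec$stride_ps,
                   log_stride = max(1, spec$stride_ps * 50),
                   seed = spec$seed, save_forces = TRUE)
  traj <- run_md(sys, cfg, params = oracle$params,
                 prior_cfg = oracle$prior_cfg, extra = oracle)
  nskip <- ceiling(spec$equilibration_ps / spec$stride_ps)
  frames <- seq(nskip + 1, n_frames(traj))
  frames <- tail(frames, spec$n_configs)
  conc <- ionic_concentration(sys, "Cl")
  lapply(seq_along(frames), function(k) {
    f <- frames[k]
    labeled_configuration(traj_system(traj, f),
                          t(traj$forces[, , f]),
                          index = k,
                          meta = list(concentration = conc, time = traj$times[f],
                                      source = "oracle-md"))
  })
}

#' Frozen double-helical polyion scaffold
#'
#' A minimal stand-in for periodic CG DNA: two antiparallel helical strands
#' of charge -1 sites ("PH"), z-periodic with the box.
#'
#' @param n_per_strand phosphate sites per strand.
#' @param pitch helix pitch (nm), default 3.4; must not exceed the box
#'   z-edge.
#' @param radius helix radius (nm), default 0.94.
#' @param box length-3 box (nm); the helix axis passes through the box
#'   center in x/y.
#' @param params species table ("PH" parameters).
#' @return A frozen, ML-visible [particle_system] with net charge
#'   `-2 * n_per_strand`.
#' @export
make_helical_polyion <- function(n_per_strand, pitch = 3.4, radius = 0.94,
                                 box = c(8.5, 8.5, 3.4),
                                 params = default_species_params()) {
  if (length(box) == 1) box <- rep(box, 3)
  if (pitch > box[3] + 1e-9) stop("pitch exceeds box z-edge")
  if (2 * radius >= min(box[1:2])) stop("helix diameter exceeds box x/y")
  z <- (seq_len(n_per_strand) - 1) / n_per_strand * pitch
  phi <- 2 * pi * z / pitch
  mk <- function(phase) cbind(box[1] / 2 + radius * cos(phi + phase),
                              box[2] / 2 + radius * sin(phi + phase),
                              z)
  pos <- rbind(mk(0), mk(2.1))  # ~120 degree phase offset between strands
  particle_system(pos, rep("PH", 2 * n_per_strand), box,
                  charge = rep(-1, 2 * n_per_strand),
                  mobile = rep(FALSE, 2 * n_per_strand),
                  ml_visible = rep(TRUE, 2 * n_per_strand), params = params)
}
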