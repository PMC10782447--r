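#' Descriptor configuration for the local correction potential
#'
#' Atomic environments are encoded with rotation/translation/permutation
#' invariant atom-centered symmetry functions: a radial Gaussian basis per
#' neighbor-species channel, optionally augmented with Behler-style angular
#' (3-body) invariants per unordered species pair. A C1 cosine envelope sends
#' every feature and its gradient smoothly to zero at the cutoff, so the
#' correction never injects force discontinuities into MD.
#'
#' @param r_cut ML cutoff (nm), default 0.9.
#' @param n_radial number of radial Gaussian centers per species channel
#'   (default 8), placed uniformly on `[r_min, r_cut]`.
#' @param r_min first radial center (nm), default 0.
#' @param width_factor basis width as a multiple of the center spacing
#'   (default 1).
#' @param include_angular include 3-body invariants (default TRUE).
#' @param ang_zeta,ang_lambda,ang_eta angular function parameters; defaults
#'   `zeta = c(1,1,2,2)`, `lambda = c(1,-1,1,-1)`, `eta = 0`, spanning
#'   polynomials in cos(theta) up to degree 2.
#' @return Object of class `descriptor_config`.
#' @export
descriptor_config <- function(r_cut = 0.9, n_radial = 8, r_min = 0,
                              width_factor = 1, include_angular = TRUE,
                              ang_zeta = c(1, 1, 2, 2),
                              ang_lambda = c(1, -1, 1, -1),
                              ang_eta = rep(0, 4)) {
  stopifnot(r_cut > 0, n_radial >= 2, r_min >= 0, r_min < r_cut,
            width_factor > 0,
            length(ang_zeta) == length(ang_lambda),
            length(ang_zeta) == length(ang_eta))
  centers <- seq(r_min, r_cut, length.out = n_radial)
  structure(list(r_cut = r_cut, centers = centers,
                 sigma_basis = width_factor * diff(centers[1:2]),
                 include_angular = isTRUE(include_angular),
                 ang_zeta = as.numeric(ang_zeta),
                 ang_lambda = as.numeric(ang_lambda),
                 ang_eta = as.numeric(ang_eta)),
            class = "descriptor_config")
}

desc_cpp <- function(dcfg, n_species) {
  c(unclass(dcfg), list(n_species = as.integer(n_species)))
}

n_features <- function(dcfg, n_species) {
  S <- n_species
  S * length(dcfg$centers) +
    (if (dcfg$include_angular) S * (S + 1) / 2 * length(dcfg$ang_zeta) else 0)
}

#' Trainable local many-body correction potential
#'
#' The correction energy is a sum of atomic energies over ML-visible
#' particles; each atomic energy is a parametric function (linear readout by
#' default, or a one-hidden-layer tanh network with `hidden > 0`) of that
#' particle's environment descriptor. Forces are exact analytic gradients.
#'
#' @param species character vector: the species vocabulary the model covers.
#' @param descriptor a [descriptor_config].
#' @param hidden hidden-layer width; 0 (default) for a linear readout.
#' @param init `"zero"` (default for linear) or `"random"`; hidden layers are
#'   always randomly initialized (symmetry breaking).
#' @param seed RNG seed for random initialization.
#' @return Object of class `correction_model`.
#' @export
correction_model <- function(species, descriptor = descriptor_config(),
                             hidden = 0, init = NULL, seed = 1) {
  stopifnot(length(species) >= 1, hidden >= 0)
  M <- n_features(descriptor, length(species))
  if (is.null(init)) init <- if (hidden == 0) "zero" else "random"
  set.seed(seed)
  heads <- lapply(species, function(s) {
    if (hidden == 0) {
      w <- if (init == "zero") numeric(M) else rnorm(M, sd = 0.01)
      list(w = w)
    } else {
      list(W1 = matrix(rnorm(hidden * M, sd = 1 / sqrt(M)), hidden, M),
           b1 = numeric(hidden),
           w2 = rnorm(hidden, sd = 0.01))
    }
  })
  names(heads) <- species
  structure(list(species = as.character(species), descriptor = descriptor,
                 hidden = as.integer(hidden), heads = heads,
                 scale = rep(1, M), meta = list(seed = seed)),
            class = "correction_model")
}

#' @export
print.correction_model <- function(x, ...) {
  cat(sprintf("<correction_model> species: %s; features: %d; head: %s\n",
              paste(x$species, collapse = ","),
              n_features(x$descriptor, length(x$species)),
              if (x$hidden == 0) "linear" else sprintf("tanh(%d)", x$hidden)))
  invisible(x)
}

model_cpp <- function(model) {
  list(descriptor = desc_cpp(model$descriptor, length(model$species)),
       heads = unname(model$heads), scale = model$scale)
}

# channel/head ids for a system against the model vocabulary; ml-invisible
# particles get a dummy id (never dereferenced).
model_chid <- function(model, sys) {
  chid <- match(sys$species, model$species) - 1L
  bad <- is.na(chid) & sys$ml_visible
  if (any(bad))
    stop("ML-visible species outside model vocabulary: ",
         paste(unique(sys$species[bad]), collapse = ", "))
  chid[is.na(chid)] <- 0L
  chid
}

#' Environment descriptor of one particle
#'
#' Features depend only on minimum-image relative positions and species of
#' ML-visible neighbors within the cutoff; invariant under rotation,
#' translation and same-species permutation, and C1-smooth in all
#' coordinates.
#'
#' @param sys a [particle_system].
#' @param i particle index (1-based); must be ML-visible.
#' @param model a [correction_model] (supplies descriptor config and species
#'   vocabulary).
#' @return Numeric feature vector.
#' @export
environment_descriptor <- function(sys, i, model) {
  stopifnot(inherits(sys, "particle_system"))
  if (i < 1 || i > n_particles(sys)) stop("particle index out of range")
  if (!sys$ml_visible[i]) stop("particle ", i, " is not ML-visible")
  cpp_descriptor(sys$positions, model_chid(model, sys), sys$ml_visible,
                 sys$box, i - 1L, desc_cpp(model$descriptor,
                                           length(model$species)))
}

#' Correction-potential energy
#'
#' @param sys a [particle_system].
#' @param model a [correction_model].
#' @return Scalar energy (kJ/mol).
#' @export
model_energy <- function(sys, model) {
  r <- cpp_model_ef(sys$positions, model_chid(model, sys), sys$ml_visible,
                    sys$box, model_cpp(model), FALSE)
  r$energy
}

#' Correction-potential forces
#'
#' Analytic gradient of [model_energy()]; ML-invisible particles receive
#' exactly zero correction force, and forces sum to zero (translation
#' invariance).
#'
#' @inheritParams model_energy
#' @param atomic also return per-particle atomic energies.
#' @return N x 3 force matrix, or a list if `atomic = TRUE`.
#' @export
model_forces <- function(sys, model, atomic = FALSE) {
  r <- cpp_model_ef(sys$positions, model_chid(model, sys), sys$ml_visible,
                    sys$box, model_cpp(model), TRUE)
  if (atomic) list(forces = r$forces, energy = r$energy,
                   atomic_energies = r$atomic_energies)
  else r$forces
}

# ---- flat parameter vector helpers (optimizer side) ------------------------
flatten_params <- function(model) {
  unlist(lapply(model$heads, function(h) {
    if (!is.null(h[["w"]])) h[["w"]] else c(as.numeric(h$W1), h$b1, h$w2)
  }), use.names = FALSE)
}

unflatten_params <- function(model, theta) {
  pos <- 0L
  M <- n_features(model$descriptor, length(model$species))
  for (s in seq_along(model$heads)) {
    h <- model$heads[[s]]
    if (!is.null(h[["w"]])) {
      model$heads[[s]]$w <- theta[pos + seq_len(M)]
      pos <- pos + M
    } else {
      H <- nrow(h$W1)
      model$heads[[s]]$W1 <- matrix(theta[pos + seq_len(H * M)], H, M)
      pos <- pos + H * M
      model$heads[[s]]$b1 <- theta[pos + seq_len(H)]
      pos <- pos + H
      model$heads[[s]]$w2 <- theta[pos + seq_len(H)]
      pos <- pos + H
    }
  }
  model
}

# doubles as 17-significant-digit strings: sprintf("%.17g") -> as.numeric is
# an exact round trip, which plain JSON number formatting is not
num_out <- function(x) sprintf("%.17g", as.numeric(x))
num_in <- function(x) as.numeric(x)

#' Serialize a correction model to a portable JSON file
#'
#' Numeric payloads are stored as 17-significant-digit decimal strings, so
#' the round trip through [load_correction_model()] is bit-exact.
#'
#' @param model a [correction_model].
#' @param path output file path.
#' @export
save_correction_model <- function(model, path) {
  dc <- unclass(model$descriptor)
  for (nm in c("r_cut", "centers", "sigma_basis", "ang_zeta", "ang_lambda",
               "ang_eta"))
    dc[[nm]] <- num_out(dc[[nm]])
  heads <- lapply(model$heads, function(h) {
    if (!is.null(h[["w"]])) list(w = num_out(h[["w"]]))
    else list(W1 = num_out(h$W1), b1 = num_out(h$b1), w2 = num_out(h$w2))
  })
  obj <- list(format = "ionsolv-correction-model", version = 1L,
              species = model$species, descriptor = dc,
              hidden = model$hidden, heads = heads,
              scale = num_out(model$scale), meta = model$meta)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE), path)
  invisible(path)
}

#' Load a serialized correction model
#'
#' @param path file written by [save_correction_model()].
#' @return A [correction_model].
#' @export
load_correction_model <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(obj$format, "ionsolv-correction-model"))
    stop("not an ionsolv correction model file: ", path)
  dcfg <- obj$descriptor
  for (nm in c("r_cut", "centers", "sigma_basis", "ang_zeta", "ang_lambda",
               "ang_eta"))
    dcfg[[nm]] <- num_in(dcfg[[nm]])
  dcfg$include_angular <- isTRUE(dcfg$include_angular)
  class(dcfg) <- "descriptor_config"
  hidden <- as.integer(obj$hidden)
  heads <- lapply(seq_along(obj$species), function(s) {
    h <- if (is.data.frame(obj$heads)) as.list(obj$heads[s, ]) else obj$heads[[s]]
    if (!is.null(h[["w"]])) list(w = num_in(h[["w"]]))
    else list(W1 = matrix(num_in(h$W1), nrow = hidden),
              b1 = num_in(h$b1), w2 = num_in(h$w2))
  })
  names(heads) <- obj$species
  structure(list(species = obj$species, descriptor = dcfg,
                 hidden = hidden, heads = heads,
                 scale = num_in(obj$scale), meta = obj$meta),
            class = "correction_model")
}
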