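#' Particle system with an orthorhombic periodic box
#'
#' The shared container for ions, CG scaffold sites and auxiliary particles.
#' Frozen particles (`mobile = FALSE`) never move during MD; particles with
#' `ml_visible = FALSE` (the auxiliary phosphate oxygens) are invisible to the
#' correction potential and must carry exactly zero charge.
#'
#' @param positions N x 3 matrix of coordinates (nm).
#' @param species character vector of species labels, length N.
#' @param box length-3 vector of box edge lengths (nm), all > 0.
#' @param charge charges (e); defaults from `params` by species.
#' @param mass masses (g/mol); defaults from `params` by species.
#' @param mobile logical, FALSE for frozen scaffold sites.
#' @param ml_visible logical, FALSE for particles hidden from the correction
#'   potential.
#' @param params a [species_params] object supplying defaults.
#' @return Object of class `particle_system`.
#' @export
particle_system <- function(positions, species, box,
                            charge = NULL, mass = NULL,
                            mobile = NULL, ml_visible = NULL,
                            params = default_species_params()) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3) stop("positions must be an N x 3 matrix")
  n <- nrow(positions)
  species <- as.character(species)
  if (length(species) != n) stop("species length must match positions")
  if (length(box) != 3 || any(!is.finite(box)) || any(box <= 0))
    stop("invalid box: need 3 positive finite edge lengths")
  tab <- params$table
  idx <- match(species, tab$species)
  if (is.null(charge)) {
    if (anyNA(idx)) stop("unknown species (no default charge): ",
                         paste(unique(species[is.na(idx)]), collapse = ", "))
    charge <- tab$charge[idx]
  }
  if (is.null(mass)) {
    if (anyNA(idx)) stop("unknown species (no default mass)")
    mass <- tab$mass[idx]
  }
  if (is.null(mobile)) mobile <- rep(TRUE, n)
  if (is.null(ml_visible)) ml_visible <- rep(TRUE, n)
  stopifnot(length(charge) == n, length(mass) == n,
            length(mobile) == n, length(ml_visible) == n)
  if (any(!ml_visible & charge != 0))
    stop("auxiliary (ml-invisible) particles must have zero charge")
  sys <- structure(list(
    positions = unname(positions), species = species,
    charge = as.numeric(charge), mass = as.numeric(mass),
    box = as.numeric(box), periodic = TRUE,
    mobile = as.logical(mobile), ml_visible = as.logical(ml_visible)
  ), class = "particle_system")
  sys
}

#' @export
print.particle_system <- function(x, ...) {
  cat(sprintf("<particle_system> %d particles, box %.4g x %.4g x %.4g nm\n",
              nrow(x$positions), x$box[1], x$box[2], x$box[3]))
  cat("  species:", paste(sprintf("%s(%d)", names(table(x$species)),
                                  as.integer(table(x$species))), collapse = " "), "\n")
  cat(sprintf("  mobile: %d, ml-visible: %d, net charge: %+g e\n",
              sum(x$mobile), sum(x$ml_visible), sum(x$charge)))
  invisible(x)
}

#' Number of particles in a system
#' @param sys a [particle_system].
#' @export
n_particles <- function(sys) nrow(sys$positions)

#' Minimum-image displacement between two positions
#'
#' Returns `r_j - r_i` mapped into the half-open interval `[-L/2, L/2)` per
#' axis, so the displacement is antisymmetric: `d(i,j) = -d(j,i)` exactly.
#'
#' @param r_i,r_j length-3 position vectors (nm).
#' @param box length-3 box edge vector (nm).
#' @return Length-3 displacement (nm).
#' @examples
#' minimum_image_displacement(c(0, 0, 0), c(0.9, 0, 0), c(1, 1, 1))  # -0.1
#' @export
minimum_image_displacement <- function(r_i, r_j, box) {
  if (any(box <= 0)) stop("invalid box: edges must be > 0")
  d <- as.numeric(r_j) - as.numeric(r_i)
  d - box * floor(d / box + 0.5)
}

#' Wrap all coordinates into the primary box [0, L)
#'
#' Idempotent; pairwise minimum-image distances are unchanged.
#'
#' @param sys a [particle_system].
#' @return The system with wrapped coordinates.
#' @export
wrap_positions <- function(sys) {
  stopifnot(inherits(sys, "particle_system"))
  p <- sys$positions
  for (k in 1:3) p[, k] <- p[, k] - sys$box[k] * floor(p[, k] / sys$box[k])
  sys$positions <- p
  sys
}

#' Molar concentration of one species in the box
#'
#' @param sys a [particle_system].
#' @param species species label to count.
#' @return Concentration in mol/L.
#' @examples
#' # 64 Na in a (4.2 nm)^3 box is about 1.435 mol/L
#' @export
ionic_concentration <- function(sys, species) {
  stopifnot(inherits(sys, "particle_system"))
  if (!species %in% sys$species) stop("species not present: ", species)
  v_l <- prod(sys$box) * 1e-24  # nm^3 -> L
  sum(sys$species == species) / (unit_constants()$N_A * v_l)
}

# Map species labels to 0-based ids against a vocabulary (stop on miss).
species_ids <- function(species, vocab) {
  id <- match(species, vocab) - 1L
  if (anyNA(id)) stop("species not in vocabulary: ",
                      paste(unique(species[is.na(id)]), collapse = ", "))
  id
}
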