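#' Per-species force-field parameters
#'
#' A species table holds the Lennard-Jones parameters, default charge and
#' mass per species label. The shipped defaults for Na/Cl are placeholder
#' values in the spirit of common monovalent-ion parameter sets (the
#' empirically optimized pair table this toolkit's prior would ideally use is
#' not reproduced here); override them freely, per species or per pair.
#'
#' @param df data.frame with columns `species`, `sigma` (nm), `epsilon`
#'   (kJ/mol), `charge` (e), `mass` (g/mol).
#' @return Object of class `species_params`.
#' @seealso [lj_tables()] for the mixed per-pair tables.
#' @export
species_params <- function(df) {
  stopifnot(is.data.frame(df),
            all(c("species", "sigma", "epsilon", "charge", "mass") %in% names(df)))
  if (anyDuplicated(df$species)) stop("duplicate species labels")
  if (any(df$sigma <= 0)) stop("sigma must be > 0")
  if (any(df$epsilon < 0)) stop("epsilon must be >= 0")
  if (any(df$mass <= 0)) stop("mass must be > 0")
  df$species <- as.character(df$species)
  structure(list(table = df), class = "species_params")
}

#' Default species table (ions, CG DNA sites, auxiliary oxygens)
#'
#' Placeholder monovalent-ion LJ parameters plus generic CG-site parameters.
#' CG DNA site kinds: `PH` (phosphate, charge -1), `S5`/`S3` (sugar halves),
#' `B1`/`B2`/`B3` (base groups), `OP` (auxiliary phosphate oxygen, LJ only).
#'
#' @return A [species_params] object.
#' @export
default_species_params <- function() {
  species_params(data.frame(
    species = c("Na", "Cl", "PH", "S5", "S3", "B1", "B2", "B3", "OP"),
    sigma   = c(0.2160, 0.4478, 0.40, 0.45, 0.45, 0.45, 0.45, 0.45, 0.296),
    epsilon = c(1.4754, 0.0535, 0.50, 0.40, 0.40, 0.40, 0.40, 0.40, 0.650),
    charge  = c(1, -1, -1, 0, 0, 0, 0, 0, 0),
    mass    = c(22.98977, 35.453, 94.97, 57.05, 60.06, 40, 40, 40, 15.999),
    stringsAsFactors = FALSE
  ))
}

#' Mixed Lennard-Jones pair tables
#'
#' Applies Lorentz-Berthelot mixing (arithmetic sigma, geometric epsilon)
#' over the species present, then applies any explicit pair overrides.
#'
#' @param params a [species_params] object.
#' @param species character vector of species labels defining the table order.
#' @param pair_overrides optional data.frame with columns `s1`, `s2`, `sigma`,
#'   `epsilon` overriding individual (unordered) pairs.
#' @return list with `species`, `sigma` and `epsilon` (S x S matrices).
#' @export
lj_tables <- function(params, species, pair_overrides = NULL) {
  stopifnot(inherits(params, "species_params"))
  tab <- params$table
  missing <- setdiff(species, tab$species)
  if (length(missing))
    stop("unknown species in table: ", paste(missing, collapse = ", "))
  idx <- match(species, tab$species)
  sig <- outer(tab$sigma[idx], tab$sigma[idx], function(a, b) (a + b) / 2)
  eps <- outer(tab$epsilon[idx], tab$epsilon[idx], function(a, b) sqrt(a * b))
  if (!is.null(pair_overrides)) {
    stopifnot(all(c("s1", "s2", "sigma", "epsilon") %in% names(pair_overrides)))
    for (k in seq_len(nrow(pair_overrides))) {
      i <- match(pair_overrides$s1[k], species)
      j <- match(pair_overrides$s2[k], species)
      if (is.na(i) || is.na(j)) next
      sig[i, j] <- sig[j, i] <- pair_overrides$sigma[k]
      eps[i, j] <- eps[j, i] <- pair_overrides$epsilon[k]
    }
  }
  dimnames(sig) <- dimnames(eps) <- list(species, species)
  list(species = species, sigma = sig, epsilon = eps)
}
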