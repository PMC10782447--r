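#' Load the nucleotide CG templates
#'
#' The shipped template table partitions every atom of the four internal
#' (phosphorylated) deoxynucleotides into six CG groups: phosphate (group 1,
#' site kind `PH`), two sugar halves (`S5`, `S3`) and three base groups
#' (`B1`-`B3`); the non-bridging phosphate oxygens O1P/O2P are additionally
#' flagged as auxiliary. The partition is a reconstruction in the spirit of
#' published six-site ("sugar"-type) CG DNA models and ships as editable
#' data, not code. Atom counts per residue follow standard internal
#' nucleic-residue compositions (DA 32, DC 30, DG 33, DT 32 atoms).
#'
#' @param path template TSV (columns residue, atom, element, mass, group,
#'   aux); defaults to the shipped file.
#' @return data.frame of class `nucleotide_templates`.
#' @export
load_nucleotide_templates <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "dna_cg_templates.tsv", package = "ionsolv")
  tt <- read.table(path, header = TRUE, sep = "\t", quote = "",
                   comment.char = "", stringsAsFactors = FALSE)
  need <- c("residue", "atom", "element", "mass", "group", "aux")
  if (!all(need %in% names(tt))) stop("template file missing columns")
  if (!all(tt$group %in% 1:6)) stop("template groups must be 1..6")
  class(tt) <- c("nucleotide_templates", "data.frame")
  tt
}

cg_site_kinds <- c("PH", "S5", "S3", "B1", "B2", "B3")

base_complement <- c(A = "T", T = "A", G = "C", C = "G")

#' Reverse complement of a DNA sequence string
#' @param sequence string over A/C/G/T.
#' @return Reverse-complement string.
#' @export
reverse_complement <- function(sequence) {
  b <- strsplit(toupper(sequence), "")[[1]]
  if (!all(b %in% names(base_complement))) stop("invalid base characters")
  paste(rev(unname(base_complement[b])), collapse = "")
}

# deterministic pseudo-atomic layout: group centers in a residue-local
# cylindrical frame (radius from helix axis, azimuth offset, z offset),
# atoms on a small ring around their group center.
cg_group_geometry <- data.frame(
  group = 1:6,
  radius = c(0.94, 0.78, 0.70, 0.52, 0.38, 0.24),
  dphi   = c(0.55, 0.30, 0.10, 0.00, -0.05, -0.10),  # rad
  dz     = c(0.10, 0.05, -0.03, 0.00, 0.02, -0.02)
)

#' Build an idealized B-form DNA duplex
#'
#' Generates an all-atom duplex with standard B-DNA rise (0.34 nm) and twist
#' (36 degrees): atoms are named and counted per the shipped templates and
#' placed by a deterministic idealized helical layout (synthetic geometry;
#' group placements approximate B-form radial ordering, they are not fitted
#' crystallographic coordinates). The complementary strand is generated
#' automatically and runs antiparallel. With `periodic = TRUE` all residues
#' are internal/phosphorylated and the duplex tiles its own pitch in z.
#'
#' @param sequence strand-1 sequence over A/C/G/T (5'->3').
#' @param periodic logical; TRUE (default) builds a z-periodic duplex. Only
#'   the periodic form is supported: the shipped templates cover internal
#'   residues only, so `periodic = FALSE` is rejected.
#' @param rise rise per base pair (nm), default 0.34.
#' @param twist twist per base pair (degrees), default 36.
#' @param box optional box; default `c(8.5, 8.5, n_bp * rise)`.
#' @param templates a [load_nucleotide_templates()] table.
#' @return Object of class `aa_structure` (data.frame of atoms with strand,
#'   resid, resname, atom, element, mass, x, y, z) with box and sequence
#'   attributes.
#' @export
build_ideal_bdna <- function(sequence, periodic = TRUE, rise = 0.34,
                             twist = 36, box = NULL,
                             templates = load_nucleotide_templates()) {
  b <- strsplit(toupper(sequence), "")[[1]]
  if (!all(b %in% names(base_complement)))
    stop("invalid base characters in sequence")
  if (!periodic)
    stop("unsupported terminus: templates cover internal (phosphorylated) ",
         "residues only; build periodic duplexes")
  n <- length(b)
  if (is.null(box)) box <- c(8.5, 8.5, n * rise)
  comp <- strsplit(reverse_complement(sequence), "")[[1]]
  axis <- box[1:2] / 2
  place_strand <- function(bases, strand, phase0, handed) {
    out <- vector("list", n)
    for (i in seq_len(n)) {
      rn <- paste0("D", bases[i])
      tt <- templates[templates$residue == rn, ]
      phi0 <- phase0 + handed * 2 * pi * (twist / 360) * (i - 1)
      z0 <- (i - 1) * rise
      gg <- cg_group_geometry
      xyz <- matrix(NA_real_, nrow(tt), 3)
      for (g in 1:6) {
        rows <- which(tt$group == g)
        cen <- c(axis[1] + gg$radius[g] * cos(phi0 + handed * gg$dphi[g]),
                 axis[2] + gg$radius[g] * sin(phi0 + handed * gg$dphi[g]),
                 z0 + gg$dz[g])
        m <- length(rows)
        ang <- 2 * pi * (seq_len(m) - 1) / max(m, 1)
        # small deterministic ring around the group center, tilted per group
        xyz[rows, 1] <- cen[1] + 0.06 * cos(ang)
        xyz[rows, 2] <- cen[2] + 0.06 * sin(ang) * cos(0.5 * g)
        xyz[rows, 3] <- cen[3] + 0.06 * sin(ang) * sin(0.5 * g)
      }
      out[[i]] <- data.frame(strand = strand, resid = i, resname = rn,
                             atom = tt$atom, element = tt$element,
                             mass = tt$mass, group = tt$group, aux = tt$aux,
                             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                             stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  }
  s1 <- place_strand(b, 1L, phase0 = 0, handed = 1)
  s2 <- place_strand(comp, 2L, phase0 = 2.4, handed = 1)
  df <- rbind(s1, s2)
  if (periodic) df$z <- df$z %% box[3]
  structure(df, class = c("aa_structure", "data.frame"),
            box = box, periodic = periodic, sequence = toupper(sequence))
}

#' Total atom count of an all-atom structure
#'
#' @param struct an `aa_structure` (or any atom data.frame).
#' @return Integer count including hydrogens.
#' @export
count_atoms <- function(struct) {
  if (is.null(struct) || NROW(struct) == 0) return(0L)
  nrow(struct)
}

#' Map an all-atom DNA structure to the six-site CG representation
#'
#' Each CG site is placed at the center of mass of its template atom group;
#' an N-nucleotide structure yields exactly 6 N ML-visible sites (kinds
#' `PH`, `S5`, `S3`, `B1`, `B2`, `B3`). Sites are frozen; the phosphate site
#' carries charge -1 e, all others 0 (configurable via the species table).
#'
#' @param struct an `aa_structure` from [build_ideal_bdna()] or
#'   [read_pdb_structure()].
#' @param templates a [load_nucleotide_templates()] table.
#' @param box box for the scaffold; defaults to the structure's box.
#' @param params species table supplying CG-site charges and masses.
#' @return A frozen, ML-visible [particle_system] (the CG scaffold).
#' @export
map_to_cg <- function(struct, templates = load_nucleotide_templates(),
                      box = NULL, params = default_species_params()) {
  stopifnot(inherits(struct, "data.frame"))
  if (is.null(box)) box <- attr(struct, "box")
  if (is.null(box)) stop("no box given and structure carries none")
  keys <- unique(struct[, c("strand", "resid", "resname")])
  sites <- vector("list", nrow(keys))
  for (k in seq_len(nrow(keys))) {
    rn <- keys$resname[k]
    tt <- templates[templates$residue == rn, ]
    if (nrow(tt) == 0) stop("unknown residue in mapping: ", rn)
    at <- struct[struct$strand == keys$strand[k] &
                   struct$resid == keys$resid[k], ]
    miss <- setdiff(tt$atom, at$atom)
    if (length(miss))
      stop(sprintf("mapping error: residue %s %d/%d missing atom(s) %s",
                   rn, keys$strand[k], keys$resid[k],
                   paste(miss, collapse = ", ")))
    pos <- matrix(NA_real_, 6, 3)
    for (g in 1:6) {
      an <- tt$atom[tt$group == g]
      rows <- at[match(an, at$atom), ]
      w <- rows$mass / sum(rows$mass)
      # minimum-image COM relative to the group's first atom, so groups
      # straddling a periodic boundary are handled correctly
      ref <- c(rows$x[1], rows$y[1], rows$z[1])
      d <- cbind(rows$x, rows$y, rows$z)
      d <- sweep(d, 2, ref, "-")
      for (c3 in 1:3) d[, c3] <- d[, c3] - box[c3] *
          floor(d[, c3] / box[c3] + 0.5)
      com <- ref + colSums(w * d)
      pos[g, ] <- com - box * floor(com / box)
    }
    sites[[k]] <- data.frame(kind = cg_site_kinds, x = pos[, 1], y = pos[, 2],
                             z = pos[, 3], strand = keys$strand[k],
                             resid = keys$resid[k], stringsAsFactors = FALSE)
  }
  sdf <- do.call(rbind, sites)
  n <- nrow(sdf)
  sys <- particle_system(as.matrix(sdf[, c("x", "y", "z")]), sdf$kind, box,
                         mobile = rep(FALSE, n), ml_visible = rep(TRUE, n),
                         params = params)
  attr(sys, "site_table") <- sdf
  sys
}

#' Append auxiliary phosphate oxygens to a CG scaffold
#'
#' Adds the non-bridging oxygen positions bonded to each phosphate as
#' LJ-only sites (`OP`): charge exactly 0 and invisible to the correction
#' potential, two per phosphate by template construction.
#'
#' @param scaffold the CG [particle_system] from [map_to_cg()].
#' @param struct the all-atom structure the scaffold was mapped from.
#' @param templates a [load_nucleotide_templates()] table.
#' @param params species table ("OP" parameters).
#' @return The scaffold with auxiliary oxygens appended.
#' @export
add_auxiliary_oxygens <- function(scaffold, struct,
                                  templates = load_nucleotide_templates(),
                                  params = default_species_params()) {
  stopifnot(inherits(scaffold, "particle_system"))
  nph <- sum(scaffold$species == "PH")
  if (nph == 0) return(scaffold)
  auxnames <- unique(templates$atom[templates$aux])
  aux <- struct[struct$atom %in% auxnames, ]
  if (nrow(aux) == 0) stop("no resolvable auxiliary oxygens in structure")
  keys <- unique(struct[, c("strand", "resid")])
  per <- merge(keys, aggregate(list(n = aux$atom),
                               by = aux[, c("strand", "resid")], FUN = length),
               all.x = TRUE)
  if (any(is.na(per$n)) || any(per$n < 1))
    stop("phosphate without resolvable bonded oxygens")
  n_new <- nrow(aux)
  tab <- params$table
  op <- tab[tab$species == "OP", ]
  site_tab <- attr(scaffold, "site_table")
  out <- particle_system(
    rbind(scaffold$positions, as.matrix(aux[, c("x", "y", "z")])),
    c(scaffold$species, rep("OP", n_new)), scaffold$box,
    charge = c(scaffold$charge, rep(0, n_new)),
    mass = c(scaffold$mass, rep(op$mass, n_new)),
    mobile = c(scaffold$mobile, rep(FALSE, n_new)),
    ml_visible = c(scaffold$ml_visible, rep(FALSE, n_new)),
    params = params)
  attr(out, "site_table") <- site_tab
  out
}
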