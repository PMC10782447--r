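#' Write configurations or a trajectory in extended-XYZ format
#'
#' One block per frame: atom count, a comment line with
#' `Lattice="..." Properties=... Time=...`, then per-atom rows. Species,
#' positions and (when present) charges, mobility/ML-visibility flags and
#' forces are written at full double precision, so read/write round-trips
#' are numerically lossless. Units are the package's internal units (nm,
#' kJ/mol/nm, ps), recorded in the header.
#'
#' @param data a [particle_system], a list of [labeled_configuration]s, or a
#'   `trajectory`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_configurations <- function(data, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  fmt <- function(x) sprintf("%.17g", x)
  write_frame <- function(pos, species, box, time = NULL, charge = NULL,
                          mobile = NULL, mlvis = NULL, forces = NULL) {
    n <- nrow(pos)
    props <- "species:S:1:pos:R:3"
    cols <- list(species, fmt(pos[, 1]), fmt(pos[, 2]), fmt(pos[, 3]))
    if (!is.null(charge)) { props <- paste0(props, ":charge:R:1")
      cols <- c(cols, list(fmt(charge))) }
    if (!is.null(mobile)) { props <- paste0(props, ":mobile:I:1")
      cols <- c(cols, list(as.integer(mobile))) }
    if (!is.null(mlvis)) { props <- paste0(props, ":ml_visible:I:1")
      cols <- c(cols, list(as.integer(mlvis))) }
    if (!is.null(forces)) { props <- paste0(props, ":forces:R:3")
      cols <- c(cols, list(fmt(forces[, 1]), fmt(forces[, 2]), fmt(forces[, 3]))) }
    lat <- sprintf('Lattice="%s 0 0 0 %s 0 0 0 %s"', fmt(box[1]), fmt(box[2]),
                   fmt(box[3]))
    hdr <- sprintf('%s Properties=%s units=nm,kJ/mol/nm,ps%s', lat, props,
                   if (!is.null(time)) sprintf(" Time=%s", fmt(time)) else "")
    writeLines(as.character(n), con)
    writeLines(hdr, con)
    if (n > 0) writeLines(do.call(paste, cols), con)
  }
  if (inherits(data, "particle_system")) {
    write_frame(data$positions, data$species, data$box, charge = data$charge,
                mobile = data$mobile, mlvis = data$ml_visible)
  } else if (inherits(data, "trajectory")) {
    for (f in seq_len(n_frames(data)))
      write_frame(traj_frame(data, f), data$species, data$box,
                  time = data$times[f], charge = data$charge,
                  mobile = data$mobile, mlvis = data$ml_visible,
                  forces = if (!is.null(data$forces)) t(data$forces[, , f]))
  } else if (is.list(data)) {
    for (lc in data) {
      stopifnot(inherits(lc, "labeled_configuration"))
      s <- lc$system
      fz <- lc$forces
      fz[is.na(fz)] <- 0
      write_frame(s$positions, s$species, s$box,
                  time = if (!is.null(lc$meta$time)) lc$meta$time,
                  charge = s$charge, mobile = s$mobile,
                  mlvis = s$ml_visible, forces = fz)
    }
  } else stop("unsupported data type for write_configurations")
  invisible(path)
}

parse_xyz_header <- function(line, lineno) {
  get <- function(key) {
    m <- regmatches(line, regexpr(sprintf('%s="[^"]*"', key), line))
    if (length(m)) return(gsub(sprintf('%s="|"$', key), "", m))
    m <- regmatches(line, regexpr(sprintf("%s=[^ ]+", key), line))
    if (length(m)) return(sub(sprintf("%s=", key), "", m))
    NULL
  }
  lat <- get("Lattice")
  if (is.null(lat)) stop("parse error at line ", lineno, ": missing Lattice")
  lv <- as.numeric(strsplit(trimws(lat), "[ \t]+")[[1]])
  if (length(lv) != 9 || any(!is.finite(lv)))
    stop("parse error at line ", lineno, ": bad Lattice")
  props <- get("Properties")
  if (is.null(props)) stop("parse error at line ", lineno, ": missing Properties")
  pp <- strsplit(props, ":")[[1]]
  if (length(pp) %% 3 != 0) stop("parse error at line ", lineno, ": bad Properties")
  spec <- data.frame(name = pp[seq(1, length(pp), 3)],
                     type = pp[seq(2, length(pp), 3)],
                     n = as.integer(pp[seq(3, length(pp), 3)]))
  tm <- get("Time")
  list(box = lv[c(1, 5, 9)], props = spec,
       time = if (!is.null(tm)) as.numeric(tm) else NA_real_)
}

#' Read configurations from an extended-XYZ file
#'
#' Inverse of [write_configurations()] for the supported fields. Frames with
#' force columns come back as [labeled_configuration]s, frames without as
#' bare [particle_system]s.
#'
#' @param path input file.
#' @param params species table for defaults when charge columns are absent.
#' @return list of [labeled_configuration] or [particle_system] objects.
#' @export
read_configurations <- function(path, params = default_species_params()) {
  lines <- readLines(path)
  out <- list()
  i <- 1; frame <- 0
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1; next }
    frame <- frame + 1
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop("parse error at line ", i, ": expected atom count")
    if (i + 1 > length(lines))
      stop("truncated frame ", frame, " at line ", i, ": missing header")
    hdr <- parse_xyz_header(lines[i + 1], i + 1)
    if (i + 1 + n > length(lines))
      stop("truncated frame ", frame, ": expected ", n, " atom rows")
    rows <- lines[i + 1 + seq_len(n)]
    tok <- strsplit(trimws(rows), "[ \t]+")
    ncol_expect <- sum(hdr$props$n)
    if (n > 0 && any(vapply(tok, length, 1L) != ncol_expect))
      stop("parse error in frame ", frame, ": wrong column count")
    cols <- list(); off <- 0
    for (k in seq_len(nrow(hdr$props))) {
      nm <- hdr$props$name[k]; nc <- hdr$props$n[k]
      v <- lapply(seq_len(nc), function(c3)
        vapply(tok, `[[`, "", off + c3))
      cols[[nm]] <- if (hdr$props$type[k] == "S") v[[1]] else
        do.call(cbind, lapply(v, as.numeric))
      off <- off + nc
    }
    if (is.null(cols$species) || is.null(cols$pos))
      stop("frame ", frame, " lacks species/pos columns")
    sys <- particle_system(
      cols$pos, cols$species, hdr$box,
      charge = if (!is.null(cols$charge)) as.numeric(cols$charge),
      mobile = if (!is.null(cols$mobile)) as.numeric(cols$mobile) > 0,
      ml_visible = if (!is.null(cols$ml_visible))
        as.numeric(cols$ml_visible) > 0,
      params = params)
    out[[frame]] <- if (!is.null(cols$forces))
      labeled_configuration(sys, cols$forces, index = frame,
                            meta = list(time = hdr$time))
    else sys
    i <- i + 2 + n
  }
  out
}

#' Labeled access to configurations read from file
#'
#' @param configs result of [read_configurations()].
#' @return The list, verified to consist of [labeled_configuration]s.
#' @export
require_labeled <- function(configs) {
  ok <- vapply(configs, inherits, TRUE, "labeled_configuration")
  if (!all(ok))
    stop("configurations lack force columns (unlabeled): frames ",
         paste(which(!ok), collapse = ", "))
  configs
}

#' Write a trajectory in a LAMMPS-dump-compatible dialect
#'
#' `ITEM: TIMESTEP / NUMBER OF ATOMS / BOX BOUNDS pp pp pp / ATOMS id type
#' x y z [fx fy fz]`, coordinates in nm.
#'
#' @param traj a `trajectory`.
#' @param path output file.
#' @export
write_lammps_dump <- function(traj, path) {
  con <- file(path, "wt"); on.exit(close(con))
  types <- as.integer(factor(traj$species, levels = sort(unique(traj$species))))
  hasf <- !is.null(traj$forces)
  for (f in seq_len(n_frames(traj))) {
    p <- traj_frame(traj, f)
    writeLines(c("ITEM: TIMESTEP",
                 sprintf("%d", as.integer(round(traj$times[f] / traj$dt))),
                 "ITEM: NUMBER OF ATOMS", sprintf("%d", nrow(p)),
                 "ITEM: BOX BOUNDS pp pp pp",
                 sprintf("0 %.17g", traj$box[1]),
                 sprintf("0 %.17g", traj$box[2]),
                 sprintf("0 %.17g", traj$box[3]),
                 paste("ITEM: ATOMS id type x y z",
                       if (hasf) "fx fy fz" else "")), con)
    for (i in seq_len(nrow(p))) {
      row <- sprintf("%d %d %.17g %.17g %.17g", i, types[i],
                     p[i, 1], p[i, 2], p[i, 3])
      if (hasf) row <- paste(row, sprintf("%.17g %.17g %.17g",
                                          traj$forces[1, i, f],
                                          traj$forces[2, i, f],
                                          traj$forces[3, i, f]))
      writeLines(row, con)
    }
  }
  invisible(path)
}

#' Read a LAMMPS dump file (subset: id/type/x/y/z[/fx/fy/fz])
#'
#' @param path dump file.
#' @param species_map character vector mapping numeric types to species
#'   labels.
#' @param params species table.
#' @return list of [particle_system] / [labeled_configuration] objects.
#' @export
read_lammps_dump <- function(path, species_map, params = default_species_params()) {
  lines <- readLines(path)
  out <- list(); i <- 1; frame <- 0
  while (i <= length(lines)) {
    if (!startsWith(lines[i], "ITEM: TIMESTEP"))
      stop("parse error at line ", i, ": expected ITEM: TIMESTEP")
    n <- as.integer(lines[i + 3])
    box <- vapply(lines[i + 5:7], function(l)
      diff(as.numeric(strsplit(trimws(l), "[ \t]+")[[1]][1:2])), 1.0)
    cols <- strsplit(sub("ITEM: ATOMS ", "", lines[i + 8]), "[ \t]+")[[1]]
    frame <- frame + 1
    if (i + 8 + n > length(lines)) stop("truncated frame ", frame)
    tok <- strsplit(trimws(lines[i + 8 + seq_len(n)]), "[ \t]+")
    m <- do.call(rbind, lapply(tok, as.numeric))
    colnames(m) <- cols[seq_len(ncol(m))]
    ord <- order(m[, "id"])
    m <- m[ord, , drop = FALSE]
    sp <- species_map[m[, "type"]]
    sys <- particle_system(m[, c("x", "y", "z")], sp, box, params = params)
    out[[frame]] <- if (all(c("fx", "fy", "fz") %in% cols))
      labeled_configuration(sys, m[, c("fx", "fy", "fz")], index = frame)
    else sys
    i <- i + 9 + n
  }
  out
}

#' Write an all-atom structure as PDB
#'
#' Coordinates are converted from nm to Angstrom.
#'
#' @param struct an `aa_structure`.
#' @param path output file.
#' @export
write_pdb_structure <- function(struct, path) {
  con <- file(path, "wt"); on.exit(close(con))
  box <- attr(struct, "box")
  if (!is.null(box))
    writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f  90.00  90.00  90.00 P 1           1",
                       box[1] * 10, box[2] * 10, box[3] * 10), con)
  chains <- c("A", "B")
  for (i in seq_len(nrow(struct))) {
    writeLines(sprintf("ATOM  %5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
                       i, substr(struct$atom[i], 1, 4), struct$resname[i],
                       chains[struct$strand[i]], struct$resid[i],
                       struct$x[i] * 10, struct$y[i] * 10, struct$z[i] * 10,
                       struct$element[i]), con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read an all-atom nucleic structure from PDB
#'
#' Uses bio3d when available; residue and atom names must follow the shipped
#' template (AMBER-style) conventions. Coordinates are converted to nm.
#'
#' @param path PDB file.
#' @param templates template table supplying masses.
#' @return An `aa_structure`.
#' @export
read_pdb_structure <- function(path, templates = load_nucleotide_templates()) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("reading PDB requires the bio3d package")
  pdb <- bio3d::read.pdb(path)
  a <- pdb$atom
  strand <- as.integer(factor(a$chain, levels = unique(a$chain)))
  key <- paste(a$resid, a$elety)
  tkey <- paste(templates$residue, templates$atom)
  mi <- match(key, tkey)
  if (anyNA(mi))
    stop("atoms not covered by templates: ",
         paste(head(unique(key[is.na(mi)]), 5), collapse = "; "))
  df <- data.frame(strand = strand, resid = a$resno, resname = a$resid,
                   atom = a$elety, element = templates$element[mi],
                   mass = templates$mass[mi], group = templates$group[mi],
                   aux = templates$aux[mi],
                   x = a$x / 10, y = a$y / 10, z = a$z / 10,
                   stringsAsFactors = FALSE)
  box <- NULL
  lines <- readLines(path, n = 50)
  cr <- grep("^CRYST1", lines, value = TRUE)
  if (length(cr))
    box <- as.numeric(c(substr(cr[1], 7, 15), substr(cr[1], 16, 24),
                        substr(cr[1], 25, 33))) / 10
  structure(df, class = c("aa_structure", "data.frame"), box = box,
            periodic = TRUE)
}

#' Write an occupancy grid as a text volumetric file
#'
#' Simple header (origin, spacing, dims) followed by values in x-fastest
#' order; readable by common volumetric tools after trivial conversion.
#'
#' @param grid an `occupancy_grid`.
#' @param path output file.
#' @export
write_grid <- function(grid, path) {
  con <- file(path, "wt"); on.exit(close(con))
  writeLines(c("# ionsolv occupancy grid v1",
               sprintf("origin %.17g %.17g %.17g", grid$origin[1],
                       grid$origin[2], grid$origin[3]),
               sprintf("spacing %.17g", grid$spacing),
               sprintf("dims %d %d %d", grid$dims[1], grid$dims[2],
                       grid$dims[3])), con)
  writeLines(sprintf("%.10g", as.vector(grid$p)), con)
  invisible(path)
}

#' Write an analysis result as a TSV table
#'
#' @param x an `rdf_result`, `ndp_result`, coordination data.frame, MD log,
#'   or any data.frame.
#' @param path output file.
#' @export
write_result_table <- function(x, path) {
  df <- if (inherits(x, "rdf_result"))
    data.frame(r = x$r, g = x$g, counts = x$counts)
  else if (inherits(x, "ndp_result"))
    data.frame(r = x$r, density = x$density, sd = x$sd)
  else as.data.frame(x)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- run configuration ------------------------------------------------------

default_run_config <- function() {
  list(
    system = list(species_params = NULL, pair_overrides = NULL),
    prior = list(r_cut_lj = 0.9, r_cut_coul = 1.2, eps_r = 95, alpha = 2.0,
                 wolf_variant = "dsf", lj_shift = TRUE),
    descriptor = list(r_cut = 0.9, n_radial = 8, r_min = 0,
                      width_factor = 1, include_angular = TRUE),
    model = list(hidden = 0, seed = 1),
    training = list(epochs = 200, lr = 0.02, batch_size = 32, patience = 30,
                    fraction = 0.8, seed = 1),
    md = list(n_steps = 1000, dt = 0.001, temperature = 300, tau = 0.1,
              thermostat = TRUE, save_stride = 1, seed = 1, skin = 0.2),
    fixtures = list(concentration = 1.0, box = 3.76, n_configs = 2000,
                    stride_ps = 1, equilibration_ps = 10, seed = 1),
    analysis = list(rdf_bin = 0.01, ndp_bin = 0.02, grid_spacing = 0.05,
                    gap_tol = 1, block_ps = 1000)
  )
}

merge_config <- function(base, override, path = "") {
  for (nm in names(override)) {
    if (!nm %in% names(base))
      stop("unknown config key: ", paste0(path, nm))
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]],
                                 paste0(path, nm, "."))
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Read a YAML run configuration
#'
#' Unknown keys are rejected; all defaults are materialized so the resolved
#' configuration is fully self-describing (it is persisted with every CLI
#' run).
#'
#' @param path YAML file, or NULL for pure defaults.
#' @return Nested configuration list.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    over <- yaml::read_yaml(path)
    if (!is.null(over)) cfg <- merge_config(cfg, over)
  }
  cfg
}
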