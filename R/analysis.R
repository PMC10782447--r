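#' Radial distribution function between two species
#'
#' Standard minimum-image pair-histogram estimator with shell-volume
#' normalization `4 pi r^2 dr rho_B`; for identical selections every
#' unordered pair is counted once and the normalization uses `(N_A - 1)/2`
#' partners, so an ideal gas gives g = 1 in every bin.
#'
#' @param traj a `trajectory`.
#' @param species_a,species_b species labels.
#' @param bin_width bin width (nm), default 0.01.
#' @param r_max maximum distance (nm); default `min(box)/2 - bin_width`.
#' @param frames frame indices to include (default all).
#' @return Object of class `rdf_result`: data.frame-like list with `r`
#'   (bin centers), `g`, plus counts and normalization metadata.
#' @export
radial_distribution <- function(traj, species_a, species_b, bin_width = 0.01,
                                r_max = NULL, frames = NULL) {
  if (is.null(r_max)) r_max <- min(traj$box) / 2 - bin_width
  stopifnot(r_max <= min(traj$box) / 2 + 1e-9, bin_width > 0)
  sel_a <- which(traj$species == species_a)
  sel_b <- which(traj$species == species_b)
  if (!length(sel_a) || !length(sel_b))
    stop("empty species selection: ", species_a, "/", species_b)
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  nbins <- as.integer(floor(r_max / bin_width))
  same <- identical(species_a, species_b)
  pos <- traj$pos[, , frames, drop = FALSE]
  counts <- cpp_rdf_counts(pos, traj$box, sel_a - 1L, sel_b - 1L,
                           bin_width, nbins, same)
  nf <- length(frames)
  vol <- prod(traj$box)
  edges <- bin_width * (0:nbins)
  shell <- 4 / 3 * pi * (edges[-1]^3 - edges[-(nbins + 1)]^3)
  npairs <- if (same) length(sel_a) * (length(sel_a) - 1) / 2 else
    length(sel_a) * length(sel_b)
  ideal <- nf * npairs * shell / vol
  g <- ifelse(ideal > 0, counts / ideal, 0)
  structure(list(r = (edges[-1] + edges[-(nbins + 1)]) / 2, g = g,
                 counts = counts, bin_width = bin_width,
                 n_frames = nf, n_a = length(sel_a), n_b = length(sel_b),
                 rho_b = length(sel_b) / vol,
                 species = c(species_a, species_b)),
            class = "rdf_result")
}

#' Coordination number profile from an RDF
#'
#' `n(r) = 4 pi rho_B int_0^r g(s) s^2 ds`, integrated with the trapezoid
#' rule on the RDF bins; monotone non-decreasing.
#'
#' @param rdf an `rdf_result` (bins contiguous from 0).
#' @param rho_b partner number density (1/nm^3); defaults to the density
#'   stored in the RDF.
#' @return data.frame(r, n).
#' @export
coordination_number <- function(rdf, rho_b = NULL) {
  if (is.null(rho_b)) rho_b <- rdf$rho_b
  f <- 4 * pi * rho_b * rdf$g * rdf$r^2
  r <- rdf$r
  # trapezoid from 0: first bin integrates from 0 assuming f(0) = 0
  n <- cumsum(c(f[1] * r[1] / 2,
                (f[-1] + f[-length(f)]) / 2 * diff(r)))
  data.frame(r = r, n = n)
}

#' Cylindrical normalized density profile around an axis
#'
#' Counts species occurrences in cylindrical shells around a z-aligned axis
#' and normalizes by the species' box-mean number density, so the profile
#' approaches 1 in bulk (box-mean convention; with a scaffold present the
#' plateau sits slightly above 1 because the scaffold excludes volume).
#' Uncertainty is estimated by block averaging over time blocks.
#'
#' @param traj a `trajectory`.
#' @param species species label.
#' @param axis_xy axis position in x/y (nm); default box center.
#' @param bin_width radial bin width (nm), default 0.02.
#' @param r_max maximum radius (nm); default `min(box_x, box_y)/2`.
#' @param block_ps block length for the error estimate (ps), default 1000.
#' @return Object of class `ndp_result` with `r`, `density` (normalized),
#'   `sd` (over block means), `n_blocks`.
#' @export
cylindrical_ndp <- function(traj, species, axis_xy = NULL, bin_width = 0.02,
                            r_max = NULL, block_ps = 1000) {
  sel <- which(traj$species == species)
  if (!length(sel)) stop("no particles of species ", species)
  if (is.null(axis_xy)) axis_xy <- traj$box[1:2] / 2
  if (is.null(r_max)) r_max <- min(traj$box[1:2]) / 2
  nbins <- as.integer(floor(r_max / bin_width))
  nf <- n_frames(traj)
  span <- traj$times[nf] - traj$times[1]
  nblocks <- max(1L, min(nf, as.integer(floor(span / block_ps))))
  block_of <- pmin(nblocks,
                   1L + as.integer(floor((traj$times - traj$times[1]) /
                                           (span / nblocks + 1e-12))))
  rho_mean <- length(sel) / prod(traj$box)
  edges <- bin_width * (0:nbins)
  shell_vol <- pi * (edges[-1]^2 - edges[-(nbins + 1)]^2) * traj$box[3]
  block_counts <- matrix(0, nbins, nblocks)
  block_frames <- tabulate(block_of, nblocks)
  for (f in seq_len(nf)) {
    dx <- traj$pos[1, sel, f] - axis_xy[1]
    dy <- traj$pos[2, sel, f] - axis_xy[2]
    dx <- dx - traj$box[1] * floor(dx / traj$box[1] + 0.5)
    dy <- dy - traj$box[2] * floor(dy / traj$box[2] + 0.5)
    r <- sqrt(dx^2 + dy^2)
    k <- floor(r / bin_width) + 1
    k <- k[k >= 1 & k <= nbins]
    if (length(k))
      block_counts[, block_of[f]] <- block_counts[, block_of[f]] +
        tabulate(k, nbins)
  }
  dens_block <- sweep(block_counts, 2, pmax(block_frames, 1), "/") /
    (shell_vol * rho_mean)
  keep <- block_frames > 0
  dens <- rowMeans(dens_block[, keep, drop = FALSE])
  sdv <- if (sum(keep) >= 2) apply(dens_block[, keep, drop = FALSE], 1, sd)
  else rep(NA_real_, nbins)
  structure(list(r = (edges[-1] + edges[-(nbins + 1)]) / 2, density = dens,
                 sd = sdv, n_blocks = sum(keep), species = species,
                 block_ps = block_ps),
            class = "ndp_result")
}

#' 3D occupancy grid of a species over a trajectory
#'
#' Voxel value = occurrences / (n_frames * n_particles of the species), so
#' the grid sums to exactly 1 over the whole box.
#'
#' @param traj a `trajectory`.
#' @param species species label.
#' @param spacing voxel edge (nm), default 0.05 (0.5 Angstrom).
#' @return Object of class `occupancy_grid`: `origin`, `spacing`, `dims`,
#'   and the probability array `p`.
#' @export
occupancy_grid_3d <- function(traj, species, spacing = 0.05) {
  stopifnot(spacing > 0)
  sel <- which(traj$species == species)
  if (!length(sel)) stop("no particles of species ", species)
  dims <- pmax(1L, as.integer(ceiling(traj$box / spacing - 1e-9)))
  p <- array(0, dims)
  nf <- n_frames(traj)
  for (f in seq_len(nf)) {
    ix <- pmin(dims[1], pmax(1L, 1L + floor(traj$pos[1, sel, f] %% traj$box[1] / spacing)))
    iy <- pmin(dims[2], pmax(1L, 1L + floor(traj$pos[2, sel, f] %% traj$box[2] / spacing)))
    iz <- pmin(dims[3], pmax(1L, 1L + floor(traj$pos[3, sel, f] %% traj$box[3] / spacing)))
    idx <- cbind(ix, iy, iz)
    for (k in seq_len(nrow(idx))) p[idx[k, 1], idx[k, 2], idx[k, 3]] <-
        p[idx[k, 1], idx[k, 2], idx[k, 3]] + 1
  }
  p <- p / (nf * length(sel))
  structure(list(origin = c(0, 0, 0), spacing = spacing, dims = dims, p = p,
                 species = species, n_frames = nf),
            class = "occupancy_grid")
}

# dwell events of a logical occupancy series with gap closure.
# Gaps of duration <= tol (equality closes) are bridged; event duration is
# t_last - t_first (a single-frame visit has zero duration).
dwell_events <- function(occ, times, tol) {
  if (!any(occ)) return(numeric(0))
  idx <- which(occ)
  starts <- idx[1]; ends <- integer(0); last <- idx[1]
  if (length(idx) > 1) {
    for (k in idx[-1]) {
      gap <- times[k] - times[last]
      if (gap > tol + 1e-12) { ends <- c(ends, last); starts <- c(starts, k) }
      last <- k
    }
  }
  ends <- c(ends, last)
  times[ends] - times[starts]
}

#' First-shell occupancy and residence times around site groups
#'
#' For each site group, each ion's occupancy series is "within `cutoff` of
#' any site of the group" (minimum image). Dwell events are maximal occupied
#' intervals after closing vacancies of duration <= `gap_tol` (fast
#' fluctuations are omitted); residence time is the mean event duration.
#' Occupancy is the time-mean number of ions in the shell.
#'
#' @param traj a `trajectory`.
#' @param site_groups named list of particle index vectors (the sites).
#' @param cutoffs shell cutoff per group (nm), recycled.
#' @param species ion species monitored, default "Na".
#' @param gap_tol gap tolerance (ps), default 1; must be >= the frame
#'   stride.
#' @return data.frame per group: mean/sd occupancy, mean/sd residence time,
#'   event count.
#' @export
shell_occupancy_residence <- function(traj, site_groups, cutoffs,
                                      species = "Na", gap_tol = 1) {
  stopifnot(length(site_groups) >= 1)
  cutoffs <- rep_len(cutoffs, length(site_groups))
  if (any(cutoffs >= min(traj$box) / 2))
    stop("shell cutoff must be below half the smallest box edge")
  if (gap_tol < traj$stride_ps - 1e-9)
    stop("gap tolerance below the frame stride")
  ions <- which(traj$species == species)
  if (!length(ions)) stop("no ions of species ", species)
  nf <- n_frames(traj)
  out <- lapply(seq_along(site_groups), function(gi) {
    sites <- site_groups[[gi]]
    cut2 <- cutoffs[gi]^2
    occ <- matrix(FALSE, nf, length(ions))
    for (f in seq_len(nf)) {
      sp <- traj$pos[, sites, f, drop = FALSE]
      ip <- traj$pos[, ions, f, drop = FALSE]
      for (a in seq_along(ions)) {
        d <- sp - as.vector(ip[, a, 1])
        for (c3 in 1:3) d[c3, , 1] <- d[c3, , 1] - traj$box[c3] *
            floor(d[c3, , 1] / traj$box[c3] + 0.5)
        occ[f, a] <- any(colSums(d[, , 1, drop = FALSE]^2) < cut2)
      }
    }
    counts <- rowSums(occ)
    ev <- unlist(lapply(seq_along(ions), function(a)
      dwell_events(occ[, a], traj$times, gap_tol)))
    data.frame(group = names(site_groups)[gi],
               occupancy_mean = mean(counts), occupancy_sd = sd(counts),
               residence_mean = if (length(ev)) mean(ev) else NA_real_,
               residence_sd = if (length(ev) > 1) sd(ev) else NA_real_,
               n_events = length(ev),
               cutoff = cutoffs[gi])
  })
  res <- do.call(rbind, out)
  attr(res, "gap_tol") <- gap_tol
  res
}

#' Self-diffusion coefficient via the Einstein relation
#'
#' MSD averaged over ions and multiple time origins on unwrapped
#' coordinates; `D = slope/6` from a least-squares fit on the stated window.
#' Reports a linearity diagnostic (R^2 of the fit); strongly ballistic or
#' poorly averaged input shows up as a poor fit / curvature.
#'
#' @param traj a `trajectory` (must carry image counters).
#' @param species species label.
#' @param fit_window fraction of the MSD span to fit, default c(0.1, 0.5).
#' @param origin_stride use every k-th frame as a time origin (default:
#'   ~100 origins).
#' @return list with `D_nm2_ps`, `D_m2_s`, `msd` (data.frame t, msd),
#'   `fit_window` (ps), `r_squared`.
#' @export
self_diffusion_einstein <- function(traj, species, fit_window = c(0.1, 0.5),
                                    origin_stride = NULL) {
  if (is.null(traj$img)) stop("trajectory lacks image counters (unwrapped coordinates unavailable)")
  sel <- which(traj$species == species)
  if (!length(sel)) stop("no particles of species ", species)
  up <- unwrap_positions(traj)[, sel, , drop = FALSE]
  nf <- dim(up)[3]
  if (nf < 4) stop("too few frames for a diffusion estimate")
  maxlag <- nf - 1
  if (is.null(origin_stride)) origin_stride <- max(1L, nf %/% 100)
  origins <- seq(1, nf - 1, by = origin_stride)
  msd <- numeric(maxlag)
  cnt <- numeric(maxlag)
  for (o in origins) {
    lags <- seq_len(nf - o)
    for (l in lags) {
      d <- up[, , o + l] - up[, , o]
      msd[l] <- msd[l] + mean(colSums(d^2))
      cnt[l] <- cnt[l] + 1
    }
  }
  msd <- msd / pmax(cnt, 1)
  tlag <- traj$stride_ps * seq_len(maxlag)
  lo <- fit_window[1] * tlag[maxlag]; hi <- fit_window[2] * tlag[maxlag]
  w <- which(tlag >= lo & tlag <= hi)
  if (length(w) < 2) stop("fit window too narrow for the trajectory")
  fit <- lm(msd[w] ~ tlag[w])
  D <- coef(fit)[[2]] / 6
  r2 <- summary(fit)$r.squared
  # log-log slope over the window: ~1 for diffusive, ~2 for ballistic input
  pos_w <- w[msd[w] > 0]
  expo <- if (length(pos_w) >= 2)
    coef(lm(log(msd[pos_w]) ~ log(tlag[pos_w])))[[2]] else NA_real_
  list(D_nm2_ps = D, D_m2_s = D * 1e-6,
       msd = data.frame(t = tlag, msd = msd),
       fit_window = c(lo, hi), r_squared = r2,
       msd_exponent = expo,
       diffusive = is.finite(expo) && expo < 1.5)
}

#' Block average of a scalar series
#'
#' Partitions into complete blocks of `block_len` samples (remainder
#' discarded), returning the mean of block means and their standard
#' deviation.
#'
#' @param series numeric vector.
#' @param block_len samples per block (>= 1); at least 2 complete blocks
#'   required.
#' @return list(`mean`, `sd`, `n_blocks`, `block_means`).
#' @export
block_average <- function(series, block_len) {
  stopifnot(block_len >= 1)
  nb <- length(series) %/% block_len
  if (nb < 2) stop("fewer than 2 complete blocks")
  x <- series[seq_len(nb * block_len)]
  bm <- colMeans(matrix(x, nrow = block_len))
  list(mean = mean(bm), sd = sd(bm), n_blocks = nb, block_means = bm)
}
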