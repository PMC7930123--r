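# Bilayer structural properties: density profiles, thickness, 2D maps,
# areas per lipid (general and grid-tessellation per species).

# headgroup centroid z (and x/y) per lipid molecule per frame
headgroup_positions <- function(traj, species = NULL) {
  mols <- lipid_particles_by_molecule(traj$topology, species = species %||%
    setdiff(unique(traj$topology$species), "protein"), role = "headgroup")
  nf <- n_frames(traj)
  nm <- length(mols)
  pos <- array(0, dim = c(nf, nm, 3))
  for (m in seq_len(nm)) {
    idx <- mols[[m]]
    if (length(idx) == 1L) {
      pos[, m, ] <- traj$coords[, idx, ]
    } else {
      for (k in 1:3) pos[, m, k] <- rowMeans(traj$coords[, idx, k, drop = FALSE])
    }
  }
  topo <- traj$topology
  mol_species <- vapply(mols, function(idx) topo$species[idx[1]], character(1))
  list(pos = pos, molecule_id = as.integer(names(mols)),
       species = mol_species)
}

# per-frame bilayer midplane: mean z of all lipid headgroup particles
midplane_z <- function(traj) {
  idx <- particle_ids(traj$topology, role = "headgroup")
  if (length(idx) == 0)
    stopf("lc_config_error", "no headgroup particles in topology")
  rowMeans(traj$coords[, idx, 3, drop = FALSE])
}

#' Density profile along the membrane normal
#'
#' Time-averaged number density of particle groups along z, measured
#' relative to the per-frame bilayer midplane (mean headgroup z), in
#' counts/A^3. Integrating a group's profile over z and multiplying by the
#' box x-y area recovers its mean particle count.
#'
#' @inheritParams n_frames
#' @param groups named list of particle-id vectors, or `NULL` to use every
#'   (lipid species x role) combination present.
#' @param bin_width z bin width in Angstrom.
#' @param window optional [analysis_window()].
#' @return An `lc_density_profile` tibble: `z_A` (bin centers), `group`,
#'   `density` (counts/A^3), with the box area and bin width as attributes.
#' @export
density_profile <- function(traj, groups = NULL, bin_width = 1,
                            window = NULL) {
  if (!is.null(window)) traj <- slice_window(traj, window)
  topo <- traj$topology
  if (is.null(groups)) {
    combos <- dplyr::distinct(
      dplyr::filter(topo, .data$species != "protein"),
      .data$species, .data$role)
    groups <- setNames(
      purrr::map2(combos$species, combos$role,
                  ~ particle_ids(topo, species = .x, role = .y)),
      paste(combos$species, combos$role, sep = "."))
  }
  if (any(lengths(groups) == 0))
    stopf("lc_config_error", "empty group(s): %s",
          paste(names(groups)[lengths(groups) == 0], collapse = ", "))
  mid <- midplane_z(traj)
  area <- mean(traj$box[, 1] * traj$box[, 2])
  zrel <- traj$coords[, , 3, drop = FALSE]
  dim(zrel) <- dim(traj$coords)[1:2]
  zrel <- zrel - mid
  half <- ceiling(max(abs(zrel)) / bin_width) * bin_width + bin_width
  edges <- seq(-half, half, by = bin_width)
  nf <- n_frames(traj)
  prof <- purrr::imap_dfr(groups, function(idx, nm) {
    z <- as.vector(zrel[, idx])
    h <- hist(z, breaks = edges, plot = FALSE)
    tibble(z_A = h$mids, group = nm,
           density = h$counts / (nf * area * bin_width))
  })
  structure(prof, bin_width = bin_width, box_area = area,
            n_frames = nf,
            class = c("lc_density_profile", class(prof)))
}

# 3-point parabolic refinement of a histogram peak position
refine_peak <- function(z, y, i) {
  if (i == 1 || i == length(y)) return(z[i])
  den <- y[i - 1] - 2 * y[i] + y[i + 1]
  if (den == 0) return(z[i])
  z[i] + 0.5 * (y[i - 1] - y[i + 1]) / den * (z[2] - z[1])
}

#' Bilayer thickness from a headgroup density profile
#'
#' Thickness is the distance between the two leaflet peaks of a headgroup
#' density profile (conventionally the phosphatidylcholine headgroups), with
#' 3-point parabolic interpolation around each maximum so the answer is not
#' quantized to the bin width.
#'
#' @param profile an [density_profile()] result.
#' @param group profile group holding the reference headgroups.
#' @return Thickness in Angstrom.
#' @export
bilayer_thickness <- function(profile, group = "POPC.headgroup") {
  tb <- dplyr::filter(as_tibble(profile), .data$group == !!group)
  if (nrow(tb) == 0)
    stopf("lc_config_error", "profile has no group '%s' (available: %s)",
          group, paste(unique(profile$group), collapse = ", "))
  lower <- dplyr::filter(tb, .data$z_A < 0)
  upper <- dplyr::filter(tb, .data$z_A >= 0)
  if (nrow(lower) == 0 || nrow(upper) == 0 ||
      max(lower$density) == 0 || max(upper$density) == 0)
    stopf("lc_analysis_error",
          "headgroup profile is unimodal; cannot separate leaflet peaks")
  p1 <- refine_peak(lower$z_A, lower$density, which.max(lower$density))
  p2 <- refine_peak(upper$z_A, upper$density, which.max(upper$density))
  p2 - p1
}

#' 2D number-density map in the membrane plane
#'
#' x-y histogram of the selected particles averaged over the analysis
#' window, in counts/A^2. Grid dimensions are the nearest integer cell
#' counts giving the requested spacing for the (mean) box.
#'
#' @inheritParams density_profile
#' @param species lipid species to map (or `"protein"`).
#' @param role optional role filter.
#' @param spacing target grid spacing in Angstrom.
#' @return An `lc_density_map`: list with `grid` (nx x ny matrix), `x_A`,
#'   `y_A` (cell centers) and `spacing`.
#' @export
density_map_2d <- function(traj, species, role = NULL, spacing = 1,
                           window = NULL) {
  if (!is.null(window)) traj <- slice_window(traj, window)
  idx <- particle_ids(traj$topology, species = species, role = role)
  if (length(idx) == 0)
    stopf("lc_config_error", "empty selection for species %s", species)
  Lx <- mean(traj$box[, 1]); Ly <- mean(traj$box[, 2])
  nx <- max(1L, round(Lx / spacing)); ny <- max(1L, round(Ly / spacing))
  x <- wrap_box(as.vector(traj$coords[, idx, 1]), Lx)
  y <- wrap_box(as.vector(traj$coords[, idx, 2]), Ly)
  ix <- pmin(nx, floor(x / Lx * nx) + 1L)
  iy <- pmin(ny, floor(y / Ly * ny) + 1L)
  counts <- matrix(0, nx, ny)
  tab <- table(factor(ix, levels = seq_len(nx)), factor(iy, levels = seq_len(ny)))
  counts[] <- as.numeric(tab)
  cell_area <- (Lx / nx) * (Ly / ny)
  structure(list(grid = counts / (n_frames(traj) * cell_area),
                 x_A = (seq_len(nx) - 0.5) * Lx / nx,
                 y_A = (seq_len(ny) - 0.5) * Ly / ny,
                 spacing = c(Lx / nx, Ly / ny), species = species),
            class = "lc_density_map")
}

#' Assign lipids to leaflets
#'
#' A lipid is `upper` when its headgroup centroid sits more than `delta`
#' above the per-frame midplane, `lower` when more than `delta` below, and
#' `transition` in between. The midplane is the mean headgroup z over all
#' lipids, so slowly drifting membranes are handled.
#'
#' @inheritParams density_profile
#' @param species lipid species to label (default: all lipid species).
#' @param delta half-width of the transition band in Angstrom.
#' @return An `lc_leaflets` object: integer label matrix
#'   `[frame x molecule]` with values +1 (upper), 0 (transition), -1
#'   (lower), plus molecule ids, species and frame times.
#' @export
assign_leaflets <- function(traj, species = NULL, delta = 5) {
  hp <- headgroup_positions(traj, species)
  mid <- midplane_z(traj)
  z <- hp$pos[, , 3, drop = FALSE]
  dim(z) <- dim(hp$pos)[1:2]
  z <- z - mid
  labels <- matrix(0L, nrow(z), ncol(z))
  labels[z > delta] <- 1L
  labels[z < -delta] <- -1L
  structure(list(labels = labels, molecule_id = hp$molecule_id,
                 species = hp$species, times = traj$times, delta = delta),
            class = "lc_leaflets")
}

#' General area per lipid
#'
#' Mean over frames of box x-y area divided by the number of lipids per
#' leaflet (the mean of the two leaflet populations at each frame).
#'
#' @inheritParams assign_leaflets
#' @param window optional [analysis_window()].
#' @return Area per lipid in A^2.
#' @export
area_general <- function(traj, species = NULL, window = NULL) {
  if (!is.null(window)) traj <- slice_window(traj, window)
  lf <- assign_leaflets(traj, species)
  n_up <- rowSums(lf$labels == 1L)
  n_lo <- rowSums(lf$labels == -1L)
  n_per_leaflet <- (n_up + n_lo) / 2
  if (any(n_per_leaflet == 0))
    stopf("lc_analysis_error", "no lipids assigned to leaflets")
  mean(traj$box[, 1] * traj$box[, 2] / n_per_leaflet)
}

#' Per-species area per lipid by grid tessellation
#'
#' Every cell of a regular x-y grid is assigned to the nearest lipid
#' reference particle (periodic minimum image, ties to the lowest molecule
#' id), per leaflet and frame; a lipid's area is its cell count times the
#' cell area, and the species value is the mean over lipids and frames.
#' The grid partitions the leaflet completely, so per-leaflet areas sum to
#' the box x-y area exactly.
#'
#' @inheritParams area_general
#' @param reference_roles named list mapping species to the roles of their
#'   reference particles (defaults: phosphate/glycerol beads for POPC,
#'   amide headgroup beads for CER6, headgroup otherwise).
#' @param spacing target grid spacing in Angstrom (cell counts are the
#'   nearest integers per box edge).
#' @param frames frame indices to analyse (default: all frames in window).
#' @return An `lc_area_report`: `$sa_general` (A^2), `$sa_species` tibble,
#'   `$per_lipid` tibble (frame, leaflet, molecule_id, species, area_A2),
#'   `$grid` (nx, ny, spacing).
#' @export
area_per_species <- function(traj, reference_roles = NULL, spacing = 1,
                             window = NULL, frames = NULL) {
  if (!is.null(window)) traj <- slice_window(traj, window)
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  if (spacing > min(traj$box[, 1:2]) / 10)
    stopf("lc_config_error",
          "grid spacing %g A exceeds a tenth of the box edge", spacing)
  lf <- assign_leaflets(traj)
  topo <- traj$topology
  species_present <- unique(lf$species)
  if (is.null(reference_roles)) {
    reference_roles <- lapply(setNames(nm = species_present), function(sp)
      switch(sp, POPC = c("headgroup", "linker"), "headgroup"))
  }
  # reference particles per molecule, ordered by molecule_id
  refs_by_mol <- lapply(seq_along(lf$molecule_id), function(m) {
    sp <- lf$species[m]
    particle_ids(topo, species = sp,
                 role = reference_roles[[sp]] %||% "headgroup",
                 molecule_id = lf$molecule_id[m])
  })
  per <- list()
  for (f in frames) {
    Lx <- traj$box[f, 1]; Ly <- traj$box[f, 2]
    nx <- max(1L, round(Lx / spacing)); ny <- max(1L, round(Ly / spacing))
    cell_area <- (Lx / nx) * (Ly / ny)
    for (side in c(1L, -1L)) {
      mols <- which(lf$labels[f, ] == side)
      if (length(mols) == 0) next
      ref_idx <- unlist(refs_by_mol[mols])
      ref_mol <- rep(mols, lengths(refs_by_mol[mols]))
      xy <- cbind(wrap_box(traj$coords[f, ref_idx, 1], Lx),
                  wrap_box(traj$coords[f, ref_idx, 2], Ly))
      assign <- cpp_grid_nearest(nx, ny, Lx, Ly, xy)
      ncells <- tabulate(assign, nbins = length(ref_idx))
      area_by_mol <- tapply(ncells * cell_area, ref_mol, sum)
      per[[length(per) + 1L]] <- tibble(
        frame = f, leaflet = if (side == 1L) "upper" else "lower",
        molecule_id = lf$molecule_id[as.integer(names(area_by_mol))],
        species = lf$species[as.integer(names(area_by_mol))],
        area_A2 = as.numeric(area_by_mol),
        box_area_A2 = Lx * Ly)
    }
  }
  per_lipid <- dplyr::bind_rows(per)
  sa_species <- dplyr::summarise(
    dplyr::group_by(per_lipid, .data$species),
    area_A2 = mean(.data$area_A2), sd_A2 = sd(.data$area_A2),
    n = dplyr::n(), .groups = "drop")
  structure(list(
    sa_general = area_general(traj),
    sa_species = sa_species,
    per_lipid = per_lipid,
    grid = list(spacing = spacing)
  ), class = "lc_area_report")
}

#' @export
print.lc_area_report <- function(x, ...) {
  cat(sprintf("<lc_area_report> general SA/lipid %.2f A^2\n", x$sa_general))
  print(x$sa_species)
  invisible(x)
}
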