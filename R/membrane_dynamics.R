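# Lateral diffusion, flip-flop detection, headgroup clustering, and
# geometric hydrogen bonds.

#' Lateral mean-square displacement of lipid headgroups
#'
#' Tracks each lipid's headgroup centroid, removes periodic boundary jumps
#' by accumulating minimum-image displacements between consecutive frames,
#' and averages the squared x-y displacement over all molecules and all
#' valid time origins (the standard overlapping-origin estimator):
#' `MSD(tau) = < |r(t0 + tau) - r(t0)|^2 >`.
#'
#' @inheritParams assign_leaflets
#' @param species lipid species to track.
#' @param window optional [analysis_window()].
#' @return An `lc_msd` tibble: `lag_ns`, `msd_A2`, `n_pairs`; species and
#'   molecule count as attributes. `MSD(0) = 0` by construction.
#' @export
msd_lateral <- function(traj, species, window = NULL) {
  if (!is.null(window)) traj <- slice_window(traj, window)
  if (n_frames(traj) < 2)
    stopf("lc_analysis_error", "MSD needs at least 2 frames")
  hp <- headgroup_positions(traj, species)
  nf <- dim(hp$pos)[1]; nm <- dim(hp$pos)[2]
  # unwrap x and y by accumulating minimum-image steps
  X <- hp$pos[, , 1, drop = TRUE]; Y <- hp$pos[, , 2, drop = TRUE]
  if (nm == 1) { X <- matrix(X, nf, 1); Y <- matrix(Y, nf, 1) }
  for (f in 2:nf) {
    X[f, ] <- X[f - 1, ] + min_image(X[f, ] - X[f - 1, ], traj$box[f, 1])
    Y[f, ] <- Y[f - 1, ] + min_image(Y[f, ] - Y[f - 1, ], traj$box[f, 2])
  }
  dt <- frame_dt(traj)
  lags <- 0:(nf - 1)
  msd <- numeric(nf); npairs <- integer(nf)
  msd[1] <- 0; npairs[1] <- nf * nm
  for (k in seq_len(nf - 1)) {
    dX <- X[(1 + k):nf, , drop = FALSE] - X[1:(nf - k), , drop = FALSE]
    dY <- Y[(1 + k):nf, , drop = FALSE] - Y[1:(nf - k), , drop = FALSE]
    msd[k + 1] <- mean(dX^2 + dY^2)
    npairs[k + 1] <- length(dX)
  }
  out <- tibble(lag_ns = lags * dt, msd_A2 = msd, n_pairs = npairs)
  structure(out, species = species, n_molecules = nm,
            class = c("lc_msd", class(out)))
}

#' Fit a lateral diffusion coefficient to an MSD curve
#'
#' Ordinary least squares of `MSD = 4 D tau + c` over lags between 10% and
#' 90% of the maximum lag (the central, well-averaged part of the curve).
#' `D` is returned in 10^-7 cm^2/s; numerically this equals `D` in A^2/ns
#' since 1 A^2/ns = 10^-7 cm^2/s exactly.
#'
#' @param msd an [msd_lateral()] curve.
#' @param fit_window fractions of the maximum lag bounding the fit.
#' @return An `lc_diffusion_fit`: `$D` (10^-7 cm^2/s), `$D_A2_ns`,
#'   `$intercept`, `$n_points`, `$fit_window_ns`. A negative fitted slope is
#'   reported as-is with a warning.
#' @export
fit_diffusion <- function(msd, fit_window = c(0.1, 0.9)) {
  tb <- as_tibble(msd)
  lo <- fit_window[1] * max(tb$lag_ns); hi <- fit_window[2] * max(tb$lag_ns)
  use <- tb$lag_ns >= lo & tb$lag_ns <= hi
  if (sum(use) < 3)
    stopf("lc_analysis_error", "fewer than 3 MSD points in the fit window")
  fit <- stats::lm(msd_A2 ~ lag_ns, data = tb[use, ])
  slope <- unname(coef(fit)[2])
  if (slope < 0) warn("negative MSD slope; D reported as fitted")
  D_A2_ns <- slope / 4
  structure(list(D = D_A2_ns, D_A2_ns = D_A2_ns,
                 intercept = unname(coef(fit)[1]),
                 n_points = sum(use), fit_window_ns = c(lo, hi),
                 species = attr(msd, "species", exact = TRUE)),
            class = "lc_diffusion_fit")
}

#' @export
print.lc_diffusion_fit <- function(x, ...) {
  cat(sprintf("<lc_diffusion_fit> %s: D = %.3g x 10^-7 cm^2/s (%d points)\n",
              x$species %||% "?", x$D, x$n_points))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.lc_diffusion_fit <- function(x, ...) {
  tibble(term = c("D", "intercept"),
         estimate = c(x$D, x$intercept),
         unit = c("1e-7 cm^2/s", "A^2"))
}

#' @exportS3Method generics::glance
glance.lc_diffusion_fit <- function(x, ...) {
  tibble(D = x$D, intercept = x$intercept, n_points = x$n_points,
         fit_lo_ns = x$fit_window_ns[1], fit_hi_ns = x$fit_window_ns[2])
}

#' Detect lipid flip-flop events
#'
#' An event is a change of stable leaflet: the lipid leaves a leaflet where
#' it resided at least `dwell_ns` and subsequently resides at least
#' `dwell_ns` in the opposite leaflet. Excursions into the transition band
#' that return to the same leaflet do not count. The rate is events per
#' microsecond of trajectory, with an SD over equal time blocks.
#'
#' @param leaflets an [assign_leaflets()] result.
#' @param dwell_ns minimum stable residence (default 50 ns).
#' @param n_blocks number of equal time blocks for the rate SD.
#' @return An `lc_flipflops`: `$events` tibble (molecule_id, species,
#'   time_ns, from, to), `$per_molecule` counts, `$n_events`,
#'   `$n_molecules`, `$rate_per_us`, `$rate_sd`.
#' @export
detect_flipflops <- function(leaflets, dwell_ns = 50, n_blocks = 5) {
  stopifnot(inherits(leaflets, "lc_leaflets"))
  times <- leaflets$times
  dt <- times[2] - times[1]
  duration <- (length(times)) * dt  # span covered by the sampled frames
  dwell_frames <- max(1L, round(dwell_ns / dt))
  if (nrow(leaflets$labels) < 2 * dwell_frames)
    stopf("lc_analysis_error",
          "trajectory shorter than twice the dwell criterion")
  ev <- purrr::map_dfr(seq_along(leaflets$molecule_id), function(m) {
    v <- leaflets$labels[, m]
    rl <- rle(v)
    ends <- cumsum(rl$lengths); starts <- ends - rl$lengths + 1L
    stable <- which(rl$values != 0L & rl$lengths >= dwell_frames)
    if (length(stable) < 2) return(NULL)
    flips <- which(diff(rl$values[stable]) != 0L)
    if (length(flips) == 0) return(NULL)
    prev <- stable[flips]; nxt <- stable[flips + 1L]
    tibble(molecule_id = leaflets$molecule_id[m],
           species = leaflets$species[m],
           time_ns = (times[ends[prev]] + times[starts[nxt]]) / 2,
           from = ifelse(rl$values[prev] == 1L, "upper", "lower"),
           to = ifelse(rl$values[nxt] == 1L, "upper", "lower"))
  })
  n_events <- nrow(ev)
  per_mol <- if (n_events > 0)
    dplyr::count(ev, .data$molecule_id, name = "n_events")
  else tibble(molecule_id = integer(), n_events = integer())
  dur_us <- duration / 1000
  rate <- n_events / dur_us
  # SD of the rate across equal time blocks
  edges <- seq(times[1] - dt / 2, times[1] - dt / 2 + duration,
               length.out = n_blocks + 1)
  block_counts <- if (n_events > 0)
    tabulate(findInterval(ev$time_ns, edges, rightmost.closed = TRUE),
             nbins = n_blocks)
  else rep(0L, n_blocks)
  rate_sd <- sd(block_counts / (dur_us / n_blocks))
  structure(list(events = ev, per_molecule = per_mol,
                 n_events = n_events, n_molecules = nrow(per_mol),
                 rate_per_us = rate, rate_sd = rate_sd,
                 dwell_ns = dwell_frames * dt, duration_us = dur_us),
            class = "lc_flipflops")
}

#' @export
print.lc_flipflops <- function(x, ...) {
  cat(sprintf(
    "<lc_flipflops> %d events from %d molecules over %.3g us (%.2f +/- %.2f events/us)\n",
    x$n_events, x$n_molecules, x$duration_us, x$rate_per_us, x$rate_sd))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.lc_flipflops <- function(x, ...) {
  tibble(n_events = x$n_events, n_molecules = x$n_molecules,
         rate_per_us = x$rate_per_us, rate_sd = x$rate_sd,
         dwell_ns = x$dwell_ns, duration_us = x$duration_us)
}

#' Detect lipid headgroup clusters
#'
#' Single-linkage clustering of headgroup centroids under the periodic x-y
#' distance: a cluster is a maximal connected set of two or more lipids
#' whose headgroups lie within `radius` of a neighbour.
#'
#' @inheritParams msd_lateral
#' @param radius linkage radius in Angstrom (default 5).
#' @return An `lc_clusters`: `$per_frame` tibble (frame, time_ns,
#'   n_clusters, largest), `$fraction_frames_clustered`,
#'   `$size_distribution` tibble.
#' @export
detect_clusters <- function(traj, species, radius = 5, window = NULL) {
  if (!is.null(window)) traj <- slice_window(traj, window)
  hp <- headgroup_positions(traj, species)
  nf <- dim(hp$pos)[1]; nm <- dim(hp$pos)[2]
  sizes_all <- integer()
  per_frame <- vector("list", nf)
  for (f in seq_len(nf)) {
    x <- hp$pos[f, , 1]; y <- hp$pos[f, , 2]
    dx <- min_image(outer(x, x, "-"), traj$box[f, 1])
    dy <- min_image(outer(y, y, "-"), traj$box[f, 2])
    adj <- dx^2 + dy^2 <= radius^2
    diag(adj) <- FALSE
    pairs <- which(adj & upper.tri(adj), arr.ind = TRUE)
    if (nrow(pairs) == 0) {
      per_frame[[f]] <- tibble(frame = f, time_ns = traj$times[f],
                               n_clusters = 0L, largest = 0L)
      next
    }
    g <- igraph::graph_from_edgelist(pairs, directed = FALSE)
    comp <- igraph::components(g)
    sizes <- comp$csize[comp$csize >= 2]
    sizes_all <- c(sizes_all, sizes)
    per_frame[[f]] <- tibble(frame = f, time_ns = traj$times[f],
                             n_clusters = length(sizes),
                             largest = if (length(sizes)) max(sizes) else 0L)
  }
  pf <- dplyr::bind_rows(per_frame)
  structure(list(
    per_frame = pf,
    fraction_frames_clustered = mean(pf$n_clusters > 0),
    size_distribution = dplyr::count(tibble(size = sizes_all), .data$size),
    radius = radius, species = species
  ), class = "lc_clusters")
}

#' @export
print.lc_clusters <- function(x, ...) {
  cat(sprintf(
    "<lc_clusters> %s: clusters in %.1f%% of frames (radius %g A)\n",
    x$species, 100 * x$fraction_frames_clustered, x$radius))
  invisible(x)
}

#' Geometric hydrogen bonds
#'
#' A bond is present in a frame when the donor-acceptor minimum-image
#' distance is at most `dist_cutoff` and the hydrogen-donor-acceptor angle
#' is at most `angle_cutoff`. Intended for atomistic trajectories whose
#' topology distinguishes hydrogens.
#'
#' @inheritParams msd_lateral
#' @param donors,hydrogens paired integer particle ids (`hydrogens[i]` is
#'   bonded to `donors[i]`).
#' @param acceptors integer particle ids of acceptor atoms.
#' @param dist_cutoff donor-acceptor distance cutoff in Angstrom.
#' @param angle_cutoff H-D-A angle cutoff in degrees.
#' @return An `lc_hbonds`: `$occupancy` tibble (donor, hydrogen, acceptor,
#'   occupancy in `[0, 1]`) for pairs observed at least once, `$n_frames`.
#' @export
hydrogen_bonds <- function(traj, donors, hydrogens, acceptors,
                           dist_cutoff = 3.5, angle_cutoff = 30,
                           window = NULL) {
  if (!is.null(window)) traj <- slice_window(traj, window)
  if (length(hydrogens) == 0)
    stopf("lc_config_error", "no hydrogens supplied; hydrogen-bond analysis needs explicit hydrogens")
  stopifnot(length(donors) == length(hydrogens))
  nf <- n_frames(traj)
  keys <- list()
  counts <- new.env(parent = emptyenv())
  for (f in seq_len(nf)) {
    box <- traj$box[f, ]
    D <- traj$coords[f, donors, , drop = FALSE]; dim(D) <- c(length(donors), 3)
    H <- traj$coords[f, hydrogens, , drop = FALSE]; dim(H) <- c(length(hydrogens), 3)
    A <- traj$coords[f, acceptors, , drop = FALSE]; dim(A) <- c(length(acceptors), 3)
    for (i in seq_along(donors)) {
      da <- sweep(A, 2, D[i, ], "-")
      for (k in 1:3) da[, k] <- min_image(da[, k], box[k])
      d2 <- rowSums(da^2)
      cand <- which(d2 <= dist_cutoff^2 & acceptors != donors[i])
      if (length(cand) == 0) next
      dh <- min_image(H[i, ] - D[i, ], box)
      for (j in cand) {
        cosang <- sum(dh * da[j, ]) / sqrt(sum(dh^2) * d2[j])
        ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
        if (ang <= angle_cutoff) {
          key <- paste(donors[i], hydrogens[i], acceptors[j], sep = "|")
          counts[[key]] <- (counts[[key]] %||% 0L) + 1L
        }
      }
    }
  }
  ks <- ls(counts)
  occ <- if (length(ks) > 0) {
    parts <- do.call(rbind, strsplit(ks, "|", fixed = TRUE))
    tibble(donor = as.integer(parts[, 1]), hydrogen = as.integer(parts[, 2]),
           acceptor = as.integer(parts[, 3]),
           occupancy = unname(vapply(ks, function(k) counts[[k]],
                                     integer(1))) / nf)
  } else {
    tibble(donor = integer(), hydrogen = integer(), acceptor = integer(),
           occupancy = numeric())
  }
  structure(list(occupancy = dplyr::arrange(occ, .data$donor, .data$acceptor),
                 n_frames = nf, dist_cutoff = dist_cutoff,
                 angle_cutoff = angle_cutoff),
            class = "lc_hbonds")
}
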