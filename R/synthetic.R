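# Synthetic data generators with exact ground truth: kinematic membrane
# patches, a tetrameric channel contact system, and ephys recordings.
# Lipids are stubs (no forces, no excluded volume beyond an optional
# minimum-separation rule): the analyses only consume coordinates, so the
# generators reproduce the statistical structure the analyses assume and
# record the truth they must recover.

# run code under a seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", globalenv())
  on.exit(if (had) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

#' Specify a synthetic bicomponent membrane patch
#'
#' Defaults emulate the coarse-grained POPC:CER6 8:2 patch: 400 + 100
#' lipids in a 125 x 125 A box, headgroup planes at +/-19.5 A (a 39 A
#' bilayer), species diffusion constants of 6.6 and 13.8 A^2/ns
#' (= 6.6 and 13.8 x 10^-7 cm^2/s), 5 us of dynamics at 10 ns frames.
#' Scheduled flip-flops are deterministic smooth crossings completing
#' within `crossing_ns`, stable on both sides -- exact ground truth for
#' event counting. A minimum ceramide headgroup separation (move
#' rejection) keeps default patches cluster-free; set `min_sep = 0` for
#' independent walkers.
#'
#' @param n_popc,n_cer lipid counts (split evenly between leaflets).
#' @param box_xy,box_z box lengths (A).
#' @param leaflet_z headgroup plane offset from the midplane (A).
#' @param d_popc,d_cer lateral diffusion constants (A^2/ns).
#' @param z_sigma headgroup z noise SD (A).
#' @param n_single_flips,n_double_flips ceramides scheduled to cross the
#'   midplane once / twice (times drawn from the seed), or supply
#'   `flip_schedule` directly.
#' @param flip_schedule optional tibble (`cer_index`, `time_ns`) of
#'   crossings; overrides the counts above.
#' @param crossing_ns duration of a scheduled crossing.
#' @param dwell_ns stable-residence scale used to validate schedule spacing.
#' @param duration_ns,dt_ns trajectory length and frame interval.
#' @param min_sep minimum ceramide headgroup x-y separation (A); 0 disables.
#' @param seed integer seed fixing the full output.
#' @return An `lc_membrane_spec` list.
#' @export
membrane_spec <- function(n_popc = 400, n_cer = 100, box_xy = 125,
                          box_z = 80, leaflet_z = 19.5,
                          d_popc = 6.6, d_cer = 13.8, z_sigma = 1.5,
                          n_single_flips = 0, n_double_flips = 0,
                          flip_schedule = NULL, crossing_ns = 20,
                          dwell_ns = 50, duration_ns = 5000, dt_ns = 10,
                          min_sep = 6, seed = 1) {
  if (n_popc < 0 || n_cer < 0 || n_popc + n_cer < 2)
    stopf("lc_spec_error", "need at least 2 lipids")
  if (n_single_flips + n_double_flips > n_cer)
    stopf("lc_spec_error", "more scheduled crossers than ceramides")
  spec <- structure(as.list(environment()), class = "lc_membrane_spec")
  spec
}

# draw well-spaced crossing times for the scheduled flip-floppers
draw_flip_schedule <- function(spec) {
  if (!is.null(spec$flip_schedule)) {
    sch <- as_tibble(spec$flip_schedule)
    stopifnot(all(c("cer_index", "time_ns") %in% names(sch)))
  } else {
    n1 <- spec$n_single_flips; n2 <- spec$n_double_flips
    if (n1 + n2 == 0)
      return(tibble(cer_index = integer(), time_ns = numeric()))
    crossers <- sample.int(spec$n_cer, n1 + n2)
    lo <- 4 * spec$dwell_ns
    hi <- spec$duration_ns - 4 * spec$dwell_ns
    if (hi <= lo + (n2 > 0) * (4 * spec$dwell_ns + 2 * spec$crossing_ns))
      stopf("lc_spec_error",
            "trajectory too short to schedule stable crossings (need > %g ns)",
            8 * spec$dwell_ns)
    singles <- tibble(cer_index = crossers[seq_len(n1)],
                      time_ns = stats::runif(n1, lo, hi))
    gap <- 4 * spec$dwell_ns + 2 * spec$crossing_ns
    d_first <- stats::runif(n2, lo, hi - gap)
    doubles <- tibble(
      cer_index = rep(crossers[n1 + seq_len(n2)], each = 2),
      time_ns = as.vector(rbind(d_first,
                                d_first + gap + stats::runif(n2, 0, spec$dwell_ns))))
    sch <- dplyr::bind_rows(singles, doubles)
  }
  if (any(sch$cer_index < 1 | sch$cer_index > spec$n_cer))
    stopf("lc_spec_error", "flip schedule references unknown ceramide index")
  sp <- dplyr::summarise(dplyr::group_by(sch, .data$cer_index),
                         min_gap = if (dplyr::n() > 1) min(diff(sort(.data$time_ns))) else Inf,
                         .groups = "drop")
  if (any(sp$min_gap < 2 * spec$dwell_ns))
    stopf("lc_spec_error",
          "crossings of one molecule closer than twice the dwell time")
  dplyr::arrange(sch, .data$cer_index, .data$time_ns)
}

#' Generate a synthetic membrane trajectory
#'
#' Lipids are 3-bead stubs (headgroup / linker / tail) performing 2D
#' Brownian motion at the specified diffusion constants with periodic
#' wrapping; bead z tracks the leaflet plane with Gaussian noise, scaled
#' toward the midplane for linker and tail. Scheduled flip-flops follow a
#' smooth cosine z path. The manifest records the planted diffusion
#' constants, every scheduled crossing, and the leaflet composition.
#'
#' @param spec an [membrane_spec()].
#' @return A list: `$trajectory` ([trajectory()]), `$manifest` (list with
#'   `true_d`, `true_events`, `n_events`, `n_molecules`, `composition`).
#' @export
gen_membrane <- function(spec = membrane_spec()) {
  stopifnot(inherits(spec, "lc_membrane_spec"))
  with_seed(spec$seed, {
    sch <- draw_flip_schedule(spec)
    nf <- round(spec$duration_ns / spec$dt_ns)
    times <- (seq_len(nf) - 1) * spec$dt_ns
    nm <- spec$n_popc + spec$n_cer
    species <- rep(c("POPC", "CER6"), c(spec$n_popc, spec$n_cer))
    # leaflets: first half of each species upper (+1), second half lower (-1)
    side0 <- integer(nm)
    side0[species == "POPC"] <- rep(c(1L, -1L), each = ceiling(spec$n_popc / 2))[seq_len(spec$n_popc)]
    side0[species == "CER6"] <- rep(c(1L, -1L), each = ceiling(spec$n_cer / 2))[seq_len(spec$n_cer)]
    d_mol <- ifelse(species == "POPC", spec$d_popc, spec$d_cer)
    cer_ids <- which(species == "CER6")

    # initial x-y: jittered lattice; ceramides draw from one lattice shared
    # across leaflets so the x-y separation rule holds from the first frame
    X <- matrix(0, nf, nm); Y <- matrix(0, nf, nm)
    ngrid <- max(2L, ceiling(sqrt(max(sum(side0 == 1L), sum(side0 == -1L)))))
    place <- function(mols, sites) {
      gx <- ((sites - 1) %% ngrid + 0.5) * spec$box_xy / ngrid
      gy <- ((sites - 1) %/% ngrid + 0.5) * spec$box_xy / ngrid
      X[1, mols] <<- gx + stats::runif(length(mols), -0.5, 0.5)
      Y[1, mols] <<- gy + stats::runif(length(mols), -0.5, 0.5)
      sites
    }
    cer_sites <- place(cer_ids, sample(ngrid^2, length(cer_ids)))
    for (s in c(1L, -1L)) {
      pop <- which(side0 == s & species == "POPC")
      taken <- cer_sites[side0[cer_ids] == s]
      free <- setdiff(seq_len(ngrid^2), taken)
      place(pop, sample(free, length(pop)))
    }
    step_sd <- sqrt(2 * d_mol * spec$dt_ns)
    check_sep <- spec$min_sep > 0 && length(cer_ids) > 1
    for (f in 2:nf) {
      X[f, ] <- X[f - 1, ] + stats::rnorm(nm, 0, step_sd)
      Y[f, ] <- Y[f - 1, ] + stats::rnorm(nm, 0, step_sd)
      if (check_sep) {
        for (iter in 1:100) {
          dx <- min_image(outer(X[f, cer_ids], X[f, cer_ids], "-"), spec$box_xy)
          dy <- min_image(outer(Y[f, cer_ids], Y[f, cer_ids], "-"), spec$box_xy)
          bad <- dx^2 + dy^2 < spec$min_sep^2
          diag(bad) <- FALSE
          viol <- cer_ids[rowSums(bad) > 0]
          if (length(viol) == 0) break
          X[f, viol] <- X[f - 1, viol]
          Y[f, viol] <- Y[f - 1, viol]
        }
      }
    }
    X <- wrap_box(X, spec$box_xy); Y <- wrap_box(Y, spec$box_xy)

    # leaflet occupancy s(t) in [-1, 1], with scheduled smooth crossings
    S <- matrix(rep(side0, each = nf), nf, nm)
    for (ci in unique(sch$cer_index)) {
      m <- cer_ids[ci]
      tc <- sort(sch$time_ns[sch$cer_index == ci])
      prof <- rep(NA_real_, nf)
      cur <- side0[m]
      for (k in seq_along(tc)) {
        in_cross <- times >= tc[k] - spec$crossing_ns / 2 &
          times <= tc[k] + spec$crossing_ns / 2
        u <- (times[in_cross] - (tc[k] - spec$crossing_ns / 2)) / spec$crossing_ns
        prof[in_cross] <- cur * cos(pi * u)
        cur <- -cur
      }
      # piecewise-constant sides between crossings
      side_t <- side0[m] * (-1)^findInterval(times, tc)
      S[, m] <- ifelse(is.na(prof), side_t, prof)
    }

    np <- nm * 3L
    coords <- array(0, dim = c(nf, np, 3))
    head_idx <- seq(1L, np, by = 3L)
    z0 <- spec$box_z / 2
    zs <- c(spec$leaflet_z, spec$leaflet_z - 6.5, spec$leaflet_z - 13)
    for (b in 1:3) {
      idx <- head_idx + (b - 1L)
      coords[, idx, 1] <- X
      coords[, idx, 2] <- Y
      sig <- if (b == 1) spec$z_sigma else spec$z_sigma / 2
      coords[, idx, 3] <- z0 + zs[b] * S +
        matrix(stats::rnorm(nf * nm, 0, sig), nf, nm)
    }
    topo <- topology_table(
      particle_id = seq_len(np),
      molecule_id = rep(seq_len(nm), each = 3L),
      species = rep(species, each = 3L),
      role = rep(c("headgroup", "linker", "tail"), nm))
    traj <- trajectory(coords, times = times,
                       box = c(spec$box_xy, spec$box_xy, spec$box_z),
                       topology = topo, wrapped = TRUE)
    per_mol <- if (nrow(sch) > 0) table(sch$cer_index) else integer()
    manifest <- list(
      spec = unclass(spec)[setdiff(names(spec), "flip_schedule")],
      true_d = tibble(species = c("POPC", "CER6"),
                      d_A2_ns = c(spec$d_popc, spec$d_cer)),
      true_events = tibble(molecule_id = spec$n_popc + sch$cer_index,
                           time_ns = sch$time_ns),
      n_events = nrow(sch),
      n_molecules = length(unique(sch$cer_index)),
      composition = tibble(species = c("POPC", "CER6"),
                           n = c(spec$n_popc, spec$n_cer)))
    list(trajectory = traj, manifest = manifest)
  })
}

#' Specify a synthetic tetrameric channel system
#'
#' A static tetramer whose residues sit on a cylindrical lattice with more
#' than 10 A between neighbours, so a lipid parked 4 A outside its target
#' residue is within the 6 A contact cutoff of that residue only: the
#' generator's schedule is an exact frame-level ground truth for the
#' contact metrics. Planted binders dwell continuously at their residue
#' (on every chain) for `planted_dwell_ns`; background lipids alternate
#' bulk excursions with brief Poisson-like visits to random residues.
#'
#' @param n_residues residues per chain (4 chains, identical numbering).
#' @param planted_residues residue numbers receiving a long-dwell lipid.
#' @param planted_dwell_ns planted dwell (default 5 us, i.e. a long-lasting
#'   binding event against a <= 1 us background).
#' @param n_background background lipid count.
#' @param background_species species tags recycled over background lipids.
#' @param contact_ns fixed background visit duration (ns), bounded by
#'   `contact_cap_fraction` of the window. A fixed duration keeps the
#'   background maximum-occupancy distribution hard-bounded, so boxplot
#'   outlier selection separates planted long-dwell binders from background
#'   by construction rather than by a statistical margin.
#' @param mean_gap_ns mean bulk sojourn between visits (ns, geometric).
#' @param contact_cap_fraction visit-length cap as a fraction of the
#'   analysis window.
#' @param duration_ns,dt_ns trajectory length and frame interval.
#' @param window [analysis_window()] the manifest truth refers to.
#' @param radius cylinder radius (A).
#' @param box_xy,box_z box lengths (A).
#' @param noise_sd positional noise on lipid beads (A).
#' @param seed integer seed.
#' @return An `lc_channel_spec` list.
#' @export
channel_spec <- function(n_residues = 60, planted_residues = integer(),
                         planted_dwell_ns = 5000, n_background = 60,
                         background_species = "CER6",
                         contact_ns = 80, mean_gap_ns = 800,
                         contact_cap_fraction = 0.02,
                         duration_ns = 10000, dt_ns = 10,
                         window = analysis_window(0.2, 1.0),
                         radius = 40, box_xy = 220, box_z = 150,
                         noise_sd = 0.3, seed = 1) {
  planted_residues <- as.integer(planted_residues)
  if (anyDuplicated(planted_residues))
    stopf("lc_spec_error", "planted residues must be distinct")
  if (length(planted_residues) > 0 &&
      any(planted_residues < 1 | planted_residues > n_residues))
    stopf("lc_spec_error", "planted residues outside 1..%d", n_residues)
  if (planted_dwell_ns > duration_ns)
    stopf("lc_spec_error", "planted dwell exceeds trajectory duration")
  structure(as.list(environment()), class = "lc_channel_spec")
}

#' Generate a synthetic channel-membrane contact system
#'
#' @param spec an [channel_spec()].
#' @return A list: `$trajectory`, `$manifest`. The manifest holds
#'   `per_chain` and `aggregated` tibbles of true contact-duration and
#'   maximum-occupancy (ns, over the spec's analysis window), the planted
#'   residue set, and the window.
#' @export
gen_channel_system <- function(spec = channel_spec()) {
  stopifnot(inherits(spec, "lc_channel_spec"))
  with_seed(spec$seed, {
    nf <- round(spec$duration_ns / spec$dt_ns)
    times <- (seq_len(nf) - 1) * spec$dt_ns
    wf1 <- floor(spec$window$start_fraction * nf) + 1L
    wf2 <- floor(spec$window$end_fraction * nf)
    chains <- c("A", "B", "C", "D")
    n_res <- spec$n_residues
    n_z <- ceiling(n_res / 6)
    cx <- spec$box_xy / 2; cz <- spec$box_z / 2

    # residue lattice: 24 angular columns (6 per chain) x n_z levels
    res_tab <- tidyr::expand_grid(chain = chains, residue_number = seq_len(n_res))
    col_within <- (res_tab$residue_number - 1L) %% 6L
    level <- (res_tab$residue_number - 1L) %/% 6L
    ang <- 2 * pi * (match(res_tab$chain, chains) - 1L) / 4 +
      2 * pi * col_within / 24
    res_tab$x <- cx + spec$radius * cos(ang)
    res_tab$y <- cx + spec$radius * sin(ang)
    res_tab$z <- cz + (level - (n_z - 1) / 2) * 11
    res_tab$angle <- ang

    # lipid roster: one planted lipid per (planted residue x chain), then bg
    planted <- tidyr::expand_grid(residue_number = spec$planted_residues,
                                  chain = chains)
    n_pl <- nrow(planted)
    n_lip <- n_pl + spec$n_background
    lip_species <- c(rep("CER6", n_pl),
                     rep_len(spec$background_species,
                             max(spec$n_background, 1))[seq_len(spec$n_background)])

    dwell_f <- max(1L, round(spec$planted_dwell_ns / spec$dt_ns))
    cap_f <- max(1L, floor(spec$contact_cap_fraction * (wf2 - wf1 + 1L)))
    contact_f <- min(cap_f, max(1L, round(spec$contact_ns / spec$dt_ns)))
    mean_gap_f <- max(1, spec$mean_gap_ns / spec$dt_ns)

    # schedule: one row per visit (lipid, residue, chain, f1, f2)
    visits <- list()
    for (l in seq_len(n_pl)) {
      f1 <- wf1 + sample.int(max(1L, wf2 - wf1 + 1L - dwell_f), 1L) - 1L
      visits[[length(visits) + 1L]] <- tibble(
        lipid = l, residue_number = planted$residue_number[l],
        chain = planted$chain[l], f1 = f1, f2 = f1 + dwell_f - 1L)
    }
    for (l in seq_len(spec$n_background)) {
      f <- 1L + stats::rgeom(1, 1 / mean_gap_f)
      while (f <= nf) {
        len <- contact_f
        if (f + len - 1L > nf) break
        tgt <- sample.int(4L * n_res, 1L)
        visits[[length(visits) + 1L]] <- tibble(
          lipid = n_pl + l,
          residue_number = ((tgt - 1L) %% n_res) + 1L,
          chain = chains[((tgt - 1L) %/% n_res) + 1L],
          f1 = f, f2 = f + len - 1L)
        f <- f + len + 1L + stats::rgeom(1, 1 / mean_gap_f)
      }
    }
    visits <- if (length(visits) > 0) dplyr::bind_rows(visits) else
      tibble(lipid = integer(), residue_number = integer(),
             chain = character(), f1 = integer(), f2 = integer())

    # coordinates: static protein + lipids teleporting bulk <-> visit site
    np_prot <- nrow(res_tab)
    np <- np_prot + n_lip * 3L
    coords <- array(0, dim = c(nf, np, 3))
    for (f in seq_len(nf)) {
      coords[f, seq_len(np_prot), 1] <- res_tab$x
      coords[f, seq_len(np_prot), 2] <- res_tab$y
      coords[f, seq_len(np_prot), 3] <- res_tab$z
    }
    bead_r <- c(4, 7, 10)  # radial offsets: head, linker, tail
    for (l in seq_len(n_lip)) {
      base <- np_prot + (l - 1L) * 3L
      # bulk defaults
      ang_b <- stats::runif(nf, 0, 2 * pi)
      rad_b <- stats::runif(nf, spec$radius + 30, spec$radius + 60)
      z_b <- cz + stats::runif(nf, -(n_z - 1) * 11 / 2, (n_z - 1) * 11 / 2)
      for (b in 1:3) {
        coords[, base + b, 1] <- cx + (rad_b + bead_r[b] - 4) * cos(ang_b)
        coords[, base + b, 2] <- cx + (rad_b + bead_r[b] - 4) * sin(ang_b)
        coords[, base + b, 3] <- z_b
      }
      vs <- visits[visits$lipid == l, ]
      for (v in seq_len(nrow(vs))) {
        ri <- which(res_tab$residue_number == vs$residue_number[v] &
                      res_tab$chain == vs$chain[v])
        fr <- vs$f1[v]:vs$f2[v]
        for (b in 1:3) {
          coords[fr, base + b, 1] <- cx + (spec$radius + bead_r[b]) *
            cos(res_tab$angle[ri])
          coords[fr, base + b, 2] <- cx + (spec$radius + bead_r[b]) *
            sin(res_tab$angle[ri])
          coords[fr, base + b, 3] <- res_tab$z[ri]
        }
      }
    }
    if (n_lip > 0) {
      lip_sel <- seq(np_prot + 1L, np)
      coords[, lip_sel, ] <- coords[, lip_sel, ] +
        stats::rnorm(length(coords[, lip_sel, ]), 0, spec$noise_sd)
    }

    topo <- topology_table(
      particle_id = seq_len(np),
      molecule_id = c(match(res_tab$chain, chains),
                      4L + rep(seq_len(n_lip), each = 3L)),
      species = c(rep("protein", np_prot), rep(lip_species, each = 3L)),
      role = c(rep("backbone", np_prot),
               rep(c("headgroup", "linker", "tail"), n_lip)),
      residue_number = c(res_tab$residue_number, rep(NA_integer_, n_lip * 3L)),
      residue_name = c(rep("RES", np_prot), rep(lip_species, each = 3L)),
      chain = c(res_tab$chain, rep(NA_character_, n_lip * 3L)))
    traj <- trajectory(coords, times = times,
                       box = c(spec$box_xy, spec$box_xy, spec$box_z),
                       topology = topo, wrapped = TRUE)

    manifest <- channel_truth(visits, lip_species, n_res, chains,
                              wf1, wf2, spec$dt_ns, spec)
    list(trajectory = traj, manifest = manifest)
  })
}

# frame-exact contact truth over the analysis window, from the schedule
channel_truth <- function(visits, lip_species, n_res, chains, wf1, wf2,
                          dt, spec) {
  nw <- wf2 - wf1 + 1L
  per <- tidyr::expand_grid(residue_number = seq_len(n_res), chain = chains)
  per$contact_duration_ns <- 0
  per$max_occupancy_ns <- 0
  # clip visits to the window
  v <- visits
  v$f1 <- pmax(v$f1, wf1); v$f2 <- pmin(v$f2, wf2)
  v <- v[v$f1 <= v$f2, , drop = FALSE]
  if (nrow(v) > 0) {
    key <- paste(v$residue_number, v$chain)
    for (k in unique(key)) {
      rows <- v[key == k, ]
      u <- logical(nw)
      for (i in seq_len(nrow(rows)))
        u[(rows$f1[i]:rows$f2[i]) - wf1 + 1L] <- TRUE
      j <- which(per$residue_number == rows$residue_number[1] &
                   per$chain == rows$chain[1])
      per$contact_duration_ns[j] <- sum(u) * dt
      per$max_occupancy_ns[j] <- max(rows$f2 - rows$f1 + 1L) * dt
    }
  }
  agg <- dplyr::summarise(
    dplyr::group_by(per, .data$residue_number),
    contact_duration_ns = mean(.data$contact_duration_ns),
    max_occupancy_ns = mean(.data$max_occupancy_ns), .groups = "drop")
  list(per_chain = per, aggregated = agg,
       planted_residues = sort(spec$planted_residues),
       visits = visits, window = spec$window,
       window_frames = c(wf1, wf2), window_ns = nw * dt,
       species = unique(lip_species))
}

#' Specify and generate synthetic electrophysiology datasets
#'
#' Activation (Boltzmann), deactivation (mono-exponential) and
#' dose-response (plateau-anchored Hill) tables from the stated closed
#' forms plus Gaussian noise; the manifest carries the generating
#' parameters. Defaults mirror the wild-type channel: `V1/2 = -20` mV,
#' `k = 8` mV, `tau = 100` ms, and the WT C6-ceramide dose-response row.
#'
#' @param v_half,k Boltzmann parameters (mV).
#' @param v_grid voltages sampled (mV).
#' @param tau_ms,A,C deactivation parameters.
#' @param t_grid_ms deactivation time base (ms).
#' @param ic50_uM,hill,stable dose-response parameters.
#' @param conc_uM concentrations sampled (uM).
#' @param sigma Gaussian noise SD applied to every dataset.
#' @param seed integer seed.
#' @return `ephys_spec()`: an `lc_ephys_spec`. `gen_ephys()`: a list of
#'   tibbles `$activation` (v_mV, i_norm), `$deactivation` (t_ms, current),
#'   `$dose` (conc_uM, residual) and `$manifest`; with `out_dir` set, the
#'   three CSVs and a JSON manifest are also written.
#' @export
ephys_spec <- function(v_half = -20, k = 8, v_grid = seq(-100, 40, by = 10),
                       tau_ms = 100, A = 1, C = 0,
                       t_grid_ms = seq(0, 800, by = 2),
                       ic50_uM = 22, hill = 0.8, stable = 0.3,
                       conc_uM = c(2, 20, 100, 500),
                       sigma = 0, seed = 1) {
  if (sigma < 0) stopf("lc_spec_error", "noise sigma must be >= 0")
  if (length(v_grid) < 4 || length(conc_uM) < 3 || length(t_grid_ms) < 4)
    stopf("lc_spec_error", "degenerate sampling grid")
  structure(as.list(environment()), class = "lc_ephys_spec")
}

#' @rdname ephys_spec
#' @param spec an `lc_ephys_spec`.
#' @param out_dir optional directory for CSV + manifest output.
#' @export
gen_ephys <- function(spec = ephys_spec(), out_dir = NULL) {
  stopifnot(inherits(spec, "lc_ephys_spec"))
  with_seed(spec$seed, {
    act <- tibble(
      v_mV = spec$v_grid,
      i_norm = boltzmann_activation(spec$v_grid, spec$v_half, spec$k) +
        stats::rnorm(length(spec$v_grid), 0, spec$sigma))
    deact <- tibble(
      t_ms = spec$t_grid_ms,
      current = spec$A * exp(-spec$t_grid_ms / spec$tau_ms) + spec$C +
        stats::rnorm(length(spec$t_grid_ms), 0, spec$sigma))
    dose <- tibble(
      conc_uM = spec$conc_uM,
      residual = hill_residual(spec$conc_uM, spec$ic50_uM, spec$hill,
                               spec$stable) +
        stats::rnorm(length(spec$conc_uM), 0, spec$sigma))
    out <- list(activation = act, deactivation = deact, dose = dose,
                manifest = unclass(spec))
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      readr::write_csv(act, file.path(out_dir, "activation.csv"), progress = FALSE)
      readr::write_csv(deact, file.path(out_dir, "deactivation.csv"), progress = FALSE)
      readr::write_csv(dose, file.path(out_dir, "dose_response.csv"), progress = FALSE)
      jsonlite::write_json(unclass(spec), file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    out
  })
}
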