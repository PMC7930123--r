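#' Per-frame residue-lipid contact series
#'
#' A protein residue and a lipid molecule are in contact in a frame when any
#' particle of the residue lies within `cutoff` (minimum-image distance) of
#' any particle of that lipid. The 6 A default is the customary bead-contact
#' cutoff for coarse-grained systems; it applies unchanged to atomistic input.
#'
#' @inheritParams n_frames
#' @param lipid_species species tag of the lipid of interest (e.g. `"CER6"`).
#' @param cutoff contact cutoff in Angstrom.
#' @param lipid_role optionally restrict the lipid particle set to given
#'   roles (e.g. `"headgroup"` for headgroup-specific contacts).
#' @return An `lc_contact_series` object holding a logical
#'   `[residue x lipid x frame]` array plus residue/lipid bookkeeping and the
#'   frame interval `dt` (ns). `as_tibble()` converts it to the sparse pair
#'   representation (pairs with at least one contact frame).
#' @export
contact_series <- function(traj, lipid_species, cutoff = 6,
                           lipid_role = NULL) {
  stopifnot(inherits(traj, "lc_trajectory"), cutoff > 0)
  check_species(traj, c("protein", lipid_species))
  res <- protein_particles_by_residue(traj$topology)
  lip <- lipid_particles_by_molecule(traj$topology, lipid_species,
                                     role = lipid_role)
  flags <- cpp_contact_flags(traj$coords, traj$box,
                             unname(res$groups), unname(lip), cutoff)
  structure(
    list(flags = flags,
         residue_number = res$residue_number,
         chain = res$chain,
         lipid_molecule_id = as.integer(names(lip)),
         dt = frame_dt(traj),
         n_frames = n_frames(traj),
         species = lipid_species, cutoff = cutoff),
    class = "lc_contact_series"
  )
}

#' @export
print.lc_contact_series <- function(x, ...) {
  cat(sprintf(
    "<lc_contact_series> %d residues x %d %s lipids x %d frames (cutoff %g A)\n",
    length(x$residue_number), length(x$lipid_molecule_id), x$species,
    x$n_frames, x$cutoff))
  invisible(x)
}

#' @exportS3Method tibble::as_tibble
as_tibble.lc_contact_series <- function(x, ...) {
  hit <- which(apply(x$flags, c(1, 2), any), arr.ind = TRUE)
  tibble(residue_number = x$residue_number[hit[, 1]],
         chain = x$chain[hit[, 1]],
         lipid_molecule_id = x$lipid_molecule_id[hit[, 2]],
         n_contact_frames = vapply(seq_len(nrow(hit)), function(i)
           sum(x$flags[hit[i, 1], hit[i, 2], ]), integer(1)))
}

# union over lipid molecules: [residue x frame] logical matrix
union_flags <- function(cs) {
  d <- dim(cs$flags)
  u <- matrix(FALSE, d[1], d[3])
  for (l in seq_len(d[2])) u <- u | cs$flags[, l, ]
  u
}

#' Contact-duration and maximum-occupancy metrics
#'
#' `contact_duration()` is the total time (ns) a residue spends within the
#' cutoff of *any* lipid of the species (union over molecules).
#' `max_occupancy()` is the longest uninterrupted contact (ns) between the
#' residue and an *individual* lipid molecule: a run ends when that molecule
#' leaves the cutoff for at least one frame. `continuity = "union"` instead
#' measures the longest run of the union series (any molecule present).
#'
#' @param cs an [contact_series()] object.
#' @param continuity run continuity convention for `max_occupancy()`.
#' @param gap_tolerance_frames number of consecutive off frames bridged
#'   inside a run (default 0: a single absent frame breaks the run).
#' @return A tibble with one row per (residue_number, chain) and the metric
#'   in ns. For every residue `max_occupancy <= contact_duration` and both
#'   are bounded by the window length.
#' @export
contact_duration <- function(cs) {
  stopifnot(inherits(cs, "lc_contact_series"))
  u <- union_flags(cs)
  tibble(residue_number = cs$residue_number, chain = cs$chain,
         contact_duration_ns = rowSums(u) * cs$dt)
}

#' @rdname contact_duration
#' @export
max_occupancy <- function(cs, continuity = c("molecule", "union"),
                          gap_tolerance_frames = 0) {
  stopifnot(inherits(cs, "lc_contact_series"))
  continuity <- match.arg(continuity)
  if (continuity == "molecule") {
    flags <- cs$flags
    if (gap_tolerance_frames > 0) flags <- bridge_gaps(flags, gap_tolerance_frames)
    runs <- cpp_longest_run(flags)
    longest <- apply(runs, 1, max)
  } else {
    u <- union_flags(cs)
    a <- array(u, dim = c(nrow(u), 1, ncol(u)))
    if (gap_tolerance_frames > 0) a <- bridge_gaps(a, gap_tolerance_frames)
    longest <- as.vector(cpp_longest_run(a))
  }
  tibble(residue_number = cs$residue_number, chain = cs$chain,
         max_occupancy_ns = longest * cs$dt)
}

# fill FALSE gaps of length <= g that are flanked by TRUE, per (res, lipid)
bridge_gaps <- function(flags, g) {
  d <- dim(flags)
  for (r in seq_len(d[1])) for (l in seq_len(d[2])) {
    v <- flags[r, l, ]
    rl <- rle(v)
    inner <- !rl$values & rl$lengths <= g &
      seq_along(rl$values) > 1 & seq_along(rl$values) < length(rl$values)
    rl$values[inner] <- TRUE
    flags[r, l, ] <- inverse.rle(rl)
  }
  flags
}

#' Both contact metrics for one replica
#'
#' Convenience wrapper: windows the trajectory, computes the contact series,
#' and returns contact-duration and maximum-occupancy per (residue, chain).
#'
#' @inheritParams contact_series
#' @inheritParams max_occupancy
#' @param window an [analysis_window()] applied before analysis; `NULL` uses
#'   all frames.
#' @param replica replica label stored in the output.
#' @return A tibble (residue_number, chain, replica, contact_duration_ns,
#'   max_occupancy_ns) covering every protein residue (zeros when a residue
#'   never touches the species).
#' @export
contact_metrics <- function(traj, lipid_species, cutoff = 6,
                            window = analysis_window(), replica = 1L,
                            continuity = c("molecule", "union"),
                            gap_tolerance_frames = 0) {
  if (!is.null(window)) traj <- slice_window(traj, window)
  cs <- contact_series(traj, lipid_species, cutoff = cutoff)
  dplyr::mutate(
    dplyr::inner_join(contact_duration(cs),
                      max_occupancy(cs, continuity = match.arg(continuity),
                                    gap_tolerance_frames = gap_tolerance_frames),
                      by = c("residue_number", "chain")),
    replica = replica, .after = "chain")
}

#' Aggregate contact metrics over tetramer subunits and replicas
#'
#' A homotetramer yields four metric values per residue and replica; the
#' reported per-residue value is the arithmetic mean over `4 x n_replicas`
#' values. Chains lacking contact contribute zeros (they are present in
#' [contact_metrics()] output); a replica missing a chain outright is a data
#' error.
#'
#' @param replica_tables a list of [contact_metrics()] tibbles (or one tibble
#'   with a `replica` column).
#' @return An `lc_contact_metrics` tibble: per residue_number, `n_values`,
#'   mean `contact_duration_ns` and `max_occupancy_ns`; the raw per-chain,
#'   per-replica values are kept in `attr(, "raw")`.
#' @export
aggregate_tetramer <- function(replica_tables) {
  raw <- if (is.data.frame(replica_tables)) as_tibble(replica_tables)
         else dplyr::bind_rows(replica_tables)
  need <- c("residue_number", "chain", "replica",
            "contact_duration_ns", "max_occupancy_ns")
  stopifnot(all(need %in% names(raw)))
  resnums <- sort(unique(raw$residue_number))
  for (rep in unique(raw$replica)) {
    chains <- sort(unique(raw$chain[raw$replica == rep]))
    if (length(chains) != 4)
      stopf("lc_data_error",
            "replica %s has %d chains (%s); a tetramer needs 4",
            rep, length(chains), paste(chains, collapse = ", "))
    for (ch in chains) {
      have <- sort(unique(raw$residue_number[raw$replica == rep & raw$chain == ch]))
      if (!identical(have, resnums))
        stopf("lc_data_error",
              "replica %s chain %s does not cover the shared residue numbering",
              rep, ch)
    }
  }
  agg <- dplyr::summarise(
    dplyr::group_by(raw, .data$residue_number),
    n_values = dplyr::n(),
    contact_duration_ns = mean(.data$contact_duration_ns),
    max_occupancy_ns = mean(.data$max_occupancy_ns),
    .groups = "drop")
  structure(agg, raw = raw,
            class = c("lc_contact_metrics", class(agg)))
}

#' Select contact hot spots with boxplot statistics
#'
#' Applies the two-tier selection to aggregated per-residue metrics:
#' residues in the upper quartile of the contact-duration distribution
#' (`> Q3`), and maximum-occupancy outliers (`> Q3 + 1.5 * IQR`, with
#' `IQR = Q3 - Q1`). Quartiles use linear interpolation of order statistics
#' (R type 7) by default; Tukey hinges are available because outlier
#' membership can differ near the threshold.
#'
#' @param aggregated an [aggregate_tetramer()] result (or any tibble with
#'   `residue_number`, `contact_duration_ns`, `max_occupancy_ns`).
#' @param quartile_type `"type7"` (default) or `"hinges"`.
#' @return An `lc_hotspots` object: `$table` with logical flags, per-metric
#'   `$thresholds`, and the residue sets `$outliers` (maximum-occupancy,
#'   the "red" class when also upper-quartile), `$upper_quartile`, and
#'   `$upper_quartile_only` (the "yellow" class).
#' @export
select_hotspots <- function(aggregated, quartile_type = c("type7", "hinges")) {
  quartile_type <- match.arg(quartile_type)
  tb <- as_tibble(aggregated)
  stopifnot(all(c("residue_number", "contact_duration_ns",
                  "max_occupancy_ns") %in% names(tb)))
  if (sum(tb$contact_duration_ns > 0) < 4)
    warn("fewer than 4 residues with nonzero contact metrics; selection may be meaningless")
  if (all(tb$max_occupancy_ns == 0) && all(tb$contact_duration_ns == 0)) {
    warn("all contact metrics are zero; no hot spots selected")
    tb$in_upper_quartile <- FALSE
    tb$is_outlier <- FALSE
    thr <- tibble(metric = c("contact_duration", "max_occupancy"),
                  q1 = 0, q3 = 0, iqr = 0, threshold = c(0, 0))
  } else {
    qd <- lc_quartiles(tb$contact_duration_ns, quartile_type)
    qo <- lc_quartiles(tb$max_occupancy_ns, quartile_type)
    tb$in_upper_quartile <- tb$contact_duration_ns > qd$q3
    tb$is_outlier <- tb$max_occupancy_ns > qo$q3 + 1.5 * qo$iqr
    thr <- tibble(
      metric = c("contact_duration", "max_occupancy"),
      q1 = c(qd$q1, qo$q1), q3 = c(qd$q3, qo$q3), iqr = c(qd$iqr, qo$iqr),
      threshold = c(qd$q3, qo$q3 + 1.5 * qo$iqr))
  }
  structure(list(
    table = tb,
    thresholds = thr,
    quartile_type = quartile_type,
    outliers = tb$residue_number[tb$is_outlier],
    upper_quartile = tb$residue_number[tb$in_upper_quartile],
    upper_quartile_only =
      setdiff(tb$residue_number[tb$in_upper_quartile],
              tb$residue_number[tb$is_outlier])
  ), class = "lc_hotspots")
}

#' @export
print.lc_hotspots <- function(x, ...) {
  cat(sprintf("<lc_hotspots> %d residues: %d upper-quartile, %d outliers (%s quartiles)\n",
              nrow(x$table), length(x$upper_quartile), length(x$outliers),
              x$quartile_type))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.lc_hotspots <- function(x, ...) x$table

#' @exportS3Method generics::glance
glance.lc_hotspots <- function(x, ...) {
  tibble(n_residues = nrow(x$table),
         n_upper_quartile = length(x$upper_quartile),
         n_outliers = length(x$outliers),
         duration_q3 = x$thresholds$threshold[1],
         occupancy_outlier_threshold = x$thresholds$threshold[2])
}

#' Headgroup contact specificity between two lipid species
#'
#' Recomputes contact-duration with the lipid particle set restricted to
#' headgroup particles, for two species side by side, to ask whether a
#' residue is targeted by one headgroup chemistry and not the other.
#'
#' @inheritParams contact_series
#' @param species_a,species_b the two lipid species to compare.
#' @param residues optional residue numbers to keep (default all).
#' @param window analysis window (`NULL` for all frames).
#' @return A tibble per (residue_number, chain): `duration_a_ns`,
#'   `duration_b_ns` and their ratio (`Inf` when only A binds, `NA` when
#'   neither does).
#' @export
lipid_specificity <- function(traj, species_a, species_b, residues = NULL,
                              cutoff = 6, window = analysis_window()) {
  if (!is.null(window)) traj <- slice_window(traj, window)
  check_species(traj, c(species_a, species_b))
  one <- function(sp, nm) {
    cs <- contact_series(traj, sp, cutoff = cutoff, lipid_role = "headgroup")
    setNames(contact_duration(cs), c("residue_number", "chain", nm))
  }
  out <- dplyr::inner_join(one(species_a, "duration_a_ns"),
                           one(species_b, "duration_b_ns"),
                           by = c("residue_number", "chain"))
  if (!is.null(residues))
    out <- dplyr::filter(out, .data$residue_number %in% residues)
  dplyr::mutate(out, ratio = dplyr::case_when(
    .data$duration_b_ns > 0 ~ .data$duration_a_ns / .data$duration_b_ns,
    .data$duration_a_ns > 0 ~ Inf,
    TRUE ~ NA_real_))
}

# whole-protein contact flags per lipid molecule: [lipid x frame]
protein_lipid_flags <- function(traj, species, cutoff) {
  check_species(traj, c("protein", species))
  prot <- list(particle_ids(traj$topology, species = "protein"))
  lip <- lipid_particles_by_molecule(traj$topology, species)
  flags <- cpp_contact_flags(traj$coords, traj$box, prot, unname(lip), cutoff)
  list(mat = matrix(flags, dim(flags)[2], dim(flags)[3]),
       molecule_id = as.integer(names(lip)))
}

#' Number of lipids in contact with the protein over time
#'
#' Counts, per frame, the lipid molecules of a species with at least one
#' particle within the cutoff of any protein particle.
#'
#' @inheritParams lipid_specificity
#' @param species lipid species tag.
#' @return A list: `$series` tibble (frame, time_ns, n_in_contact), plus
#'   `$mean` and `$sd` over frames.
#' @export
lipids_in_contact <- function(traj, species, cutoff = 6, window = NULL) {
  if (!is.null(window)) traj <- slice_window(traj, window)
  pf <- protein_lipid_flags(traj, species, cutoff)
  counts <- colSums(pf$mat)
  list(series = tibble(frame = seq_along(counts), time_ns = traj$times,
                       n_in_contact = counts),
       mean = mean(counts), sd = sd(counts))
}

#' Per-lipid binding events against the whole protein
#'
#' Maximal consecutive runs of whole-protein contact of each lipid molecule
#' become binding events. The event-duration histogram uses 0.5 us bins, and
#' the fraction of events (and of molecules whose every event) does not
#' exceed a threshold is reported -- the headline statistic separating a
#' background of brief encounters from rare long-dwelling binders.
#'
#' @inheritParams lipids_in_contact
#' @param gap_tolerance_frames off frames bridged inside an event (default 0).
#' @param threshold_us duration threshold for the reported fractions.
#' @return A list: `$events` tibble (molecule_id, start_ns, end_ns,
#'   duration_ns), `$histogram` tibble (bin_lo_us, bin_hi_us, n),
#'   `$fraction_events_leq`, `$fraction_molecules_leq`, `$threshold_us`.
#' @export
binding_events <- function(traj, species, cutoff = 6,
                           gap_tolerance_frames = 0, threshold_us = 1,
                           window = NULL) {
  if (!is.null(window)) traj <- slice_window(traj, window)
  pf <- protein_lipid_flags(traj, species, cutoff)
  dt <- frame_dt(traj)
  t0 <- traj$times[1]
  ev <- purrr::map_dfr(seq_len(nrow(pf$mat)), function(l) {
    v <- pf$mat[l, ]
    if (gap_tolerance_frames > 0) {
      rl <- rle(v)
      inner <- !rl$values & rl$lengths <= gap_tolerance_frames &
        seq_along(rl$values) > 1 & seq_along(rl$values) < length(rl$values)
      rl$values[inner] <- TRUE
      v <- inverse.rle(rl)
    }
    rl <- rle(v)
    if (!any(rl$values)) return(NULL)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    keep <- rl$values
    tibble(molecule_id = pf$molecule_id[l],
           start_ns = t0 + (starts[keep] - 1L) * dt,
           end_ns = t0 + (ends[keep] - 1L) * dt,
           duration_ns = rl$lengths[keep] * dt)
  })
  if (nrow(ev) > 0) {
    dur_us <- ev$duration_ns / 1000
    edges <- seq(0, ceiling(max(dur_us) / 0.5) * 0.5 + 0.5, by = 0.5)
    h <- hist(dur_us, breaks = edges, plot = FALSE)
    histogram <- tibble(bin_lo_us = head(edges, -1), bin_hi_us = edges[-1],
                        n = h$counts)
    frac_ev <- mean(dur_us <= threshold_us)
    by_mol <- tapply(dur_us, ev$molecule_id, function(d) all(d <= threshold_us))
    frac_mol <- mean(by_mol)
  } else {
    histogram <- tibble(bin_lo_us = numeric(), bin_hi_us = numeric(),
                        n = integer())
    frac_ev <- NA_real_; frac_mol <- NA_real_
  }
  list(events = ev, histogram = histogram,
       fraction_events_leq = frac_ev, fraction_molecules_leq = frac_mol,
       threshold_us = threshold_us)
}

#' Sidechain distance to an internal cavity
#'
#' For each chain, the per-frame distance between the centroid of a residue's
#' sidechain particles and the centroid of a cavity-defining selection, with
#' a pooled fixed-width histogram. Useful for detecting two-state sidechain
#' dynamics (e.g. lipid-facing vs cavity-facing aromatic rings), reported as
#' the two highest local maxima of the histogram.
#'
#' @inheritParams lipid_specificity
#' @param residue_number residue whose sidechain is tracked.
#' @param cavity_particles integer particle ids defining the cavity center.
#' @param bin_width histogram bin width in Angstrom.
#' @return A list: `$series` tibble (frame, time_ns, chain, distance_A),
#'   `$histogram` tibble (bin_mid_A, count), `$modes` (up to two distances).
#' @export
sidechain_cavity_distance <- function(traj, residue_number, cavity_particles,
                                      bin_width = 0.5, window = NULL) {
  if (!is.null(window)) traj <- slice_window(traj, window)
  topo <- traj$topology
  cav <- as.integer(cavity_particles)
  if (length(cav) == 0 || any(!cav %in% topo$particle_id))
    stopf("lc_config_error", "empty or invalid cavity selection")
  chains <- sort(unique(topo$chain[topo$species == "protein"]))
  series <- purrr::map_dfr(chains, function(ch) {
    sc <- particle_ids(topo, species = "protein", role = "sidechain",
                       chain = ch, residue_number = residue_number)
    if (length(sc) == 0)
      stopf("lc_config_error",
            "residue %d chain %s has no sidechain particles",
            residue_number, ch)
    d <- vapply(seq_len(n_frames(traj)), function(f) {
      p <- frame_centroid(traj$coords, f, sc)
      q <- frame_centroid(traj$coords, f, cav)
      sqrt(sum((p - q)^2))
    }, numeric(1))
    tibble(frame = seq_len(n_frames(traj)), time_ns = traj$times,
           chain = ch, distance_A = d)
  })
  edges <- seq(0, ceiling(max(series$distance_A) / bin_width) * bin_width +
                 bin_width, by = bin_width)
  h <- hist(series$distance_A, breaks = edges, plot = FALSE)
  histogram <- tibble(bin_mid_A = h$mids, count = h$counts)
  cnt <- h$counts
  loc <- which(cnt > c(-Inf, head(cnt, -1)) & cnt >= c(tail(cnt, -1), -Inf))
  modes <- h$mids[loc[order(cnt[loc], decreasing = TRUE)]][seq_len(min(2, length(loc)))]
  list(series = series, histogram = histogram, modes = modes)
}
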