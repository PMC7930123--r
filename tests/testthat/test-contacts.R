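# per-residue contact metrics, hot-spot selection, binding events

test_that("contact cutoff behaves at the threshold and across the boundary", {
  near <- make_contact_frame(matrix(c(5.9, 0, 0), 1))
  far <- make_contact_frame(matrix(c(6.1, 0, 0), 1))
  expect_equal(sum(contact_series(near, "CER6")$flags), 1)
  expect_equal(sum(contact_series(far, "CER6")$flags), 0)
  # periodic: residue at 0, lipid at box - 0.5 -> distance 0.5
  pbc <- make_contact_frame(matrix(c(49.5, 0, 0), 1), box = c(50, 50, 50))
  expect_equal(sum(contact_series(pbc, "CER6")$flags), 1)
})

test_that("contact sets match an all-pairs brute-force check", {
  set.seed(101)
  for (case in 1:100) {
    box <- c(runif(1, 15, 25), runif(1, 15, 25), runif(1, 15, 25))
    n_res <- sample(2:4, 1); n_lip <- sample(2:4, 1)
    res_particles <- sample(1:2, n_res, replace = TRUE)
    lip_particles <- sample(1:3, n_lip, replace = TRUE)
    np <- sum(res_particles) + sum(lip_particles)
    xyz <- matrix(runif(np * 3, 0, max(box)), np, 3)
    species <- c(rep("protein", sum(res_particles)), rep("CER6", sum(lip_particles)))
    role <- c(rep("backbone", sum(res_particles)),
              unlist(lapply(lip_particles, function(k)
                c("headgroup", rep("tail", k - 1)))))
    mol <- c(rep(seq_len(n_res), res_particles),
             n_res + rep(seq_len(n_lip), lip_particles))
    resnum <- c(rep(seq_len(n_res), res_particles), rep(NA_integer_, sum(lip_particles)))
    chain <- c(rep("A", sum(res_particles)), rep(NA_character_, sum(lip_particles)))
    tr <- make_traj(xyz, box = box, species = species, role = role,
                    molecule_id = mol, residue_number = resnum, chain = chain)
    cs <- contact_series(tr, "CER6", cutoff = 6)
    res_idx <- split(seq_len(sum(res_particles)), rep(seq_len(n_res), res_particles))
    lip_idx <- split(sum(res_particles) + seq_len(sum(lip_particles)),
                     rep(seq_len(n_lip), lip_particles))
    for (r in seq_len(n_res)) for (l in seq_len(n_lip)) {
      ri <- which(cs$residue_number == r)
      expect_identical(cs$flags[ri, l, 1],
                       oracle_contact(xyz, box, res_idx[[r]], lip_idx[[l]], 6))
    }
  }
})

test_that("duration counts the union of molecules; occupancy the longest run", {
  # one lipid [1,1,0,1] -> occupancy 2, duration 3
  p <- array(FALSE, dim = c(1, 1, 4)); p[1, 1, c(1, 2, 4)] <- TRUE
  tr <- make_pattern_traj(p)
  cs <- contact_series(tr, "CER6")
  expect_equal(contact_duration(cs)$contact_duration_ns, 3)
  expect_equal(max_occupancy(cs)$max_occupancy_ns, 2)
  # A [1,0,1,0], B [0,1,1,1]: union duration 4, per-molecule max run 3
  p2 <- array(FALSE, dim = c(1, 2, 4))
  p2[1, 1, c(1, 3)] <- TRUE; p2[1, 2, 2:4] <- TRUE
  tr2 <- make_pattern_traj(p2)
  cs2 <- contact_series(tr2, "CER6")
  expect_equal(contact_duration(cs2)$contact_duration_ns, 4)
  expect_equal(max_occupancy(cs2)$max_occupancy_ns, 3)
  expect_equal(max_occupancy(cs2, continuity = "union")$max_occupancy_ns, 4)
  # alternating lipids covering every frame -> duration = window length
  p3 <- array(FALSE, dim = c(1, 2, 6))
  p3[1, 1, c(1, 3, 5)] <- TRUE; p3[1, 2, c(2, 4, 6)] <- TRUE
  cs3 <- contact_series(make_pattern_traj(p3), "CER6")
  expect_equal(contact_duration(cs3)$contact_duration_ns, 6)
})

test_that("metrics match run/union enumeration on random patterns", {
  set.seed(202)
  for (case in 1:60) {
    n_res <- sample(2:4, 1); n_lip <- sample(1:3, 1); nf <- sample(5:12, 1)
    p <- array(FALSE, dim = c(n_res, n_lip, nf))
    for (l in seq_len(n_lip)) for (f in seq_len(nf)) {
      r <- sample(0:n_res, 1)
      if (r > 0) p[r, l, f] <- TRUE
    }
    cs <- contact_series(make_pattern_traj(p), "CER6")
    dur <- contact_duration(cs); occ <- max_occupancy(cs)
    for (r in seq_len(n_res)) {
      union_count <- sum(apply(p[r, , , drop = FALSE], 3, any))
      runs <- vapply(seq_len(n_lip), function(l)
        oracle_longest_run(p[r, l, ]), integer(1))
      expect_equal(dur$contact_duration_ns[dur$residue_number == r], union_count)
      expect_equal(occ$max_occupancy_ns[occ$residue_number == r], max(runs))
      # invariants: occupancy <= duration <= window; union bound
      expect_lte(max(runs), union_count)
      expect_lte(union_count, nf)
      expect_lte(union_count, sum(p[r, , ]))
    }
  }
})

test_that("metrics are invariant under rigid translation plus wrapping", {
  g <- gen_channel_system(channel_spec(
    n_residues = 8, planted_residues = 2, planted_dwell_ns = 300,
    n_background = 8, duration_ns = 600, dt_ns = 20, seed = 5))
  tr <- g$trajectory
  cm0 <- contact_metrics(tr, "CER6", window = NULL)
  shifted <- tr
  shifted$coords <- tr$coords + rep(c(93.7, -41.2, 17.9), each = prod(dim(tr$coords)[1:2]))
  for (k in 1:3)
    shifted$coords[, , k] <- shifted$coords[, , k] %% tr$box[1, k]
  cm1 <- contact_metrics(shifted, "CER6", window = NULL)
  expect_equal(cm1, cm0)
})

test_that("increasing the cutoff never decreases either metric", {
  g <- gen_channel_system(channel_spec(
    n_residues = 8, planted_residues = 3, planted_dwell_ns = 300,
    n_background = 10, duration_ns = 600, dt_ns = 20, seed = 6))
  cm_small <- contact_metrics(g$trajectory, "CER6", cutoff = 5, window = NULL)
  cm_large <- contact_metrics(g$trajectory, "CER6", cutoff = 8, window = NULL)
  expect_true(all(cm_large$contact_duration_ns >= cm_small$contact_duration_ns))
  expect_true(all(cm_large$max_occupancy_ns >= cm_small$max_occupancy_ns))
})

test_that("tetramer aggregation averages 4 x n_replicas values exactly", {
  base <- tidyr::expand_grid(residue_number = 1:3, chain = LETTERS[1:4])
  reps <- lapply(1:4, function(i)
    dplyr::mutate(base, replica = i,
                  contact_duration_ns = rep(c(1, 2, 3, 4), 3),
                  max_occupancy_ns = rep(c(1, 2, 3, 4), 3) / 2))
  agg <- aggregate_tetramer(reps)
  expect_equal(agg$n_values, rep(16L, 3))
  expect_equal(agg$contact_duration_ns, rep(2.5, 3))
  expect_equal(agg$max_occupancy_ns, rep(1.25, 3))
  # single replica with identical chains: mean equals the common value
  one <- dplyr::mutate(base, replica = 1, contact_duration_ns = 7,
                       max_occupancy_ns = 3)
  expect_equal(aggregate_tetramer(one)$contact_duration_ns, rep(7, 3))
  # random values against an independent mean
  set.seed(7)
  rnd <- dplyr::mutate(dplyr::bind_rows(reps),
                       contact_duration_ns = runif(48),
                       max_occupancy_ns = 0)
  agg2 <- aggregate_tetramer(rnd)
  for (r in 1:3)
    expect_equal(agg2$contact_duration_ns[agg2$residue_number == r],
                 mean(rnd$contact_duration_ns[rnd$residue_number == r]))
  # missing chain is a data error naming the replica
  expect_error(aggregate_tetramer(dplyr::filter(one, chain != "C")),
               class = "lc_data_error")
})

test_that("hot-spot selection reproduces hand-computed quartile thresholds", {
  mk <- function(v) tibble::tibble(residue_number = seq_along(v),
                                   contact_duration_ns = v,
                                   max_occupancy_ns = v)
  # values 1..8, 100: Q1 = 3, Q3 = 7, IQR = 4, outlier threshold 13
  hs <- select_hotspots(mk(c(1:8, 100)))
  thr <- hs$thresholds[hs$thresholds$metric == "max_occupancy", ]
  expect_equal(thr$q1, 3); expect_equal(thr$q3, 7)
  expect_equal(thr$threshold, 13)
  expect_equal(hs$outliers, 9L)  # the residue holding 100
  # values 1..8: Q3 = 6.25 -> upper quartile {7, 8}
  hs2 <- select_hotspots(mk(1:8))
  expect_equal(sort(hs2$upper_quartile), c(7L, 8L))
  # all equal: IQR = 0, no outliers
  hs3 <- select_hotspots(mk(rep(5, 8)))
  expect_length(hs3$outliers, 0)
  # all zero: empty selection with a warning
  expect_warning(expect_warning(hs4 <- select_hotspots(mk(rep(0, 8)))))
  expect_length(hs4$outliers, 0)
})

test_that("headgroup specificity separates planted species", {
  # species A headgroups visit residue 2; species B never does
  g <- gen_channel_system(channel_spec(
    n_residues = 8, planted_residues = 2, planted_dwell_ns = 500,
    n_background = 0, duration_ns = 1000, dt_ns = 20, seed = 9))
  tr <- g$trajectory
  # rebrand half the planted lipids... instead: add POPC background never binding
  spec2 <- lipid_specificity(tr, "CER6", "CER6", window = NULL)
  expect_equal(spec2$duration_a_ns, spec2$duration_b_ns)  # identity case
  g2 <- gen_channel_system(channel_spec(
    n_residues = 8, planted_residues = 2, planted_dwell_ns = 500,
    n_background = 4, background_species = "POPC",
    mean_gap_ns = 1e9,  # background never visits
    duration_ns = 1000, dt_ns = 20, seed = 9))
  sp <- lipid_specificity(g2$trajectory, "CER6", "POPC", window = NULL)
  r2 <- sp[sp$residue_number == 2, ]
  expect_true(all(r2$duration_a_ns > 0))
  expect_true(all(r2$duration_b_ns == 0))
  expect_true(all(is.infinite(r2$ratio)))
})

test_that("lipid counts in contact match brute force and planted counts", {
  tr <- make_contact_frame(rbind(c(3, 0, 0), c(0, 4, 0), c(0, 0, 5.5),
                                 c(20, 20, 20)))
  lic <- lipids_in_contact(tr, "CER6")
  expect_equal(lic$series$n_in_contact, 3)
  none <- make_contact_frame(matrix(c(20, 20, 20), 1))
  expect_equal(lipids_in_contact(none, "CER6")$series$n_in_contact, 0)
  set.seed(33)
  for (case in 1:20) {
    box <- c(30, 30, 30)
    n_lip <- 8
    xyz <- matrix(runif((n_lip + 1) * 3, 0, 30), n_lip + 1, 3)
    tr <- make_contact_frame(xyz[-1, , drop = FALSE], residue_xyz = xyz[1, ],
                             box = box)
    expected <- sum(vapply(2:(n_lip + 1), function(i)
      oracle_dist(xyz[1, ], xyz[i, ], box) <= 6, logical(1)))
    expect_equal(lipids_in_contact(tr, "CER6")$series$n_in_contact, expected)
  }
})

test_that("binding events are maximal whole-protein contact runs", {
  # lipid in contact frames 10..19 of a dt = 10 ns trajectory -> 100 ns event
  p <- array(FALSE, dim = c(1, 1, 30)); p[1, 1, 10:19] <- TRUE
  tr <- make_pattern_traj(p, dt = 10)
  be <- binding_events(tr, "CER6")
  expect_equal(nrow(be$events), 1)
  expect_equal(be$events$duration_ns, 100)
  expect_equal(be$events$start_ns, 90)
  # random patterns vs run enumeration
  set.seed(44)
  for (case in 1:40) {
    nf <- sample(8:20, 1); n_lip <- sample(1:3, 1)
    p <- array(FALSE, dim = c(2, n_lip, nf))
    for (l in seq_len(n_lip)) p[1, l, ] <- runif(nf) < 0.4
    tr <- make_pattern_traj(p)
    be <- binding_events(tr, "CER6")
    for (l in seq_len(n_lip)) {
      v <- apply(p[, l, , drop = FALSE], 3, any)
      rl <- rle(as.vector(v))
      exp_durs <- rl$lengths[rl$values]
      got <- be$events$duration_ns[be$events$molecule_id ==
                                     sort(unique(tr$topology$molecule_id[tr$topology$species == "CER6"]))[l]]
      expect_equal(sort(got), sort(exp_durs))
    }
  }
})

test_that("a planted 5 us binder yields one event in the 4-6 us range", {
  g <- gen_channel_system(channel_spec(
    n_residues = 8, planted_residues = 4, planted_dwell_ns = 5000,
    n_background = 0, duration_ns = 10000, dt_ns = 10, seed = 12))
  be <- binding_events(g$trajectory, "CER6", window = analysis_window(0.2, 1))
  expect_equal(nrow(be$events), 4)  # one lipid per chain
  expect_true(all(be$events$duration_ns >= 4000 & be$events$duration_ns <= 6000))
  hist_hits <- be$histogram$n[be$histogram$bin_lo_us >= 4 &
                                be$histogram$bin_hi_us <= 6]
  expect_equal(sum(hist_hits), 4)
})

test_that("sidechain-cavity distances equal direct centroid arithmetic", {
  # constant geometry: sidechain 5 A from the cavity center
  np <- 3
  xyz <- rbind(c(10, 10, 10),     # backbone
               c(15, 10, 10),     # sidechain
               c(10, 10, 10))     # cavity particle
  tr <- make_traj(list(xyz, xyz), box = c(40, 40, 40),
                  species = c("protein", "protein", "protein"),
                  role = c("backbone", "sidechain", "backbone"),
                  molecule_id = c(1, 1, 1),
                  residue_number = c(1L, 1L, 2L),
                  chain = c("A", "A", "A"))
  out <- sidechain_cavity_distance(tr, 1, cavity_particles = 3)
  expect_equal(out$series$distance_A, c(5, 5))
  # two-state series -> two histogram modes at the planted distances
  frames <- c(replicate(10, rbind(c(10, 10, 10), c(17, 10, 10), c(10, 10, 10)),
                        simplify = FALSE),
              replicate(10, rbind(c(10, 10, 10), c(23, 10, 10), c(10, 10, 10)),
                        simplify = FALSE))
  tr2 <- make_traj(frames, box = c(40, 40, 40),
                   species = rep("protein", 3),
                   role = c("backbone", "sidechain", "backbone"),
                   molecule_id = c(1, 1, 1), residue_number = c(1L, 1L, 2L),
                   chain = rep("A", 3))
  out2 <- sidechain_cavity_distance(tr2, 1, cavity_particles = 3)
  expect_equal(sort(out2$modes), c(7.25, 13.25), tolerance = 0.3)
  expect_error(sidechain_cavity_distance(tr2, 2, cavity_particles = 3),
               class = "lc_config_error")
})
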