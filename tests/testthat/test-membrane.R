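# bilayer structure and dynamics: densities, thickness, areas, MSD,
# leaflets, flip-flops, clusters, hydrogen bonds

make_bilayer <- function(z_upper, z_lower, n_per_leaflet = 12,
                         box = c(40, 40, 60), nf = 1, jitter = 0) {
  n <- 2 * n_per_leaflet
  frames <- lapply(seq_len(nf), function(f) {
    cbind(runif(n, 0, box[1]), runif(n, 0, box[2]),
          box[3] / 2 + rep(c(z_upper, z_lower), each = n_per_leaflet) +
            rnorm(n, 0, jitter))
  })
  make_traj(frames, box = box, species = rep("POPC", n),
            role = rep("headgroup", n), molecule_id = seq_len(n))
}

test_that("density profiles match a direct histogram and integrate to counts", {
  set.seed(1)
  tr <- make_bilayer(19.5, -19.5, n_per_leaflet = 20, nf = 5, jitter = 2)
  prof <- density_profile(tr)
  # integral x box area = mean particle count of the group
  area <- mean(tr$box[, 1] * tr$box[, 2])
  integral <- sum(prof$density) * attr(prof, "bin_width")
  expect_equal(integral * area, 40)
  # symmetric construction -> symmetric profile about 0 within binning
  up <- sum(prof$density[prof$z_A > 0])
  lo <- sum(prof$density[prof$z_A < 0])
  expect_equal(up, lo, tolerance = 0.15)
  # all particles at the midplane -> single occupied bin at z = 0
  tr0 <- make_bilayer(0, 0, n_per_leaflet = 10)
  p0 <- density_profile(tr0)
  expect_lte(abs(p0$z_A[p0$density > 0]), 0.5)
  expect_equal(sum(p0$density > 0), 1)
})

test_that("bilayer thickness recovers the leaflet peak separation", {
  set.seed(2)
  expect_equal(bilayer_thickness(density_profile(make_bilayer(19.5, -19.5,
    n_per_leaflet = 200))), 39, tolerance = 0.02)
  expect_equal(bilayer_thickness(density_profile(make_bilayer(20, -20,
    n_per_leaflet = 200))), 40, tolerance = 0.02)
  # noisy Gaussian leaflets recovered within one bin
  trn <- make_bilayer(18, -18, n_per_leaflet = 400, nf = 10, jitter = 1.5)
  expect_equal(bilayer_thickness(density_profile(trn)), 36, tolerance = 1)
  # unimodal profile is an analysis error
  expect_error(bilayer_thickness(density_profile(make_bilayer(0, 0))),
               class = "lc_analysis_error")
})

test_that("2D density maps localize static and planted particles", {
  tr <- make_traj(matrix(c(12.3, 31.7, 10), 1), box = c(40, 40, 20))
  map <- density_map_2d(tr, "POPC")
  expect_equal(sum(map$grid > 0), 1)
  hit <- which(map$grid > 0, arr.ind = TRUE)
  expect_equal(map$x_A[hit[1]], 12.3, tolerance = 0.5)
  expect_equal(map$y_A[hit[2]], 31.7, tolerance = 0.5)
  # planted stationary lipid among diffusers -> global maximum at its site
  set.seed(3)
  n <- 30; nf <- 40
  frames <- lapply(seq_len(nf), function(f)
    cbind(c(20, runif(n - 1, 0, 40)), c(20, runif(n - 1, 0, 40)), 10))
  trp <- make_traj(frames, box = c(40, 40, 20))
  mp <- density_map_2d(trp, "POPC", spacing = 2)
  peak <- which(mp$grid == max(mp$grid), arr.ind = TRUE)
  expect_equal(mp$x_A[peak[1]], 20, tolerance = 1.1)
  expect_equal(mp$y_A[peak[2]], 20, tolerance = 1.1)
})

test_that("general area per lipid is box area over leaflet population", {
  set.seed(4)
  tr <- make_bilayer(19.5, -19.5, n_per_leaflet = 50,
                     box = c(100, 100, 60))
  expect_equal(area_general(tr), 200)
})

test_that("tessellation areas partition the leaflet and match brute force", {
  # two lipids at symmetric positions split a 10 x 10 box evenly
  tr <- make_traj(rbind(c(2.5, 5, 55), c(7.5, 5, 55),
                        c(2.5, 5, 5), c(7.5, 5, 5)),
                  box = c(10, 10, 60), molecule_id = 1:4)
  rep1 <- area_per_species(tr, spacing = 0.5)
  expect_equal(rep1$per_lipid$area_A2, rep(50, 4))
  # single lipid owns the whole leaflet
  tr1 <- make_traj(rbind(c(3, 3, 55), c(5, 5, 5)), box = c(10, 10, 60),
                   molecule_id = 1:2)
  rep2 <- area_per_species(tr1, spacing = 0.5)
  expect_equal(rep2$per_lipid$area_A2, c(100, 100))
  # conservation to machine precision + brute-force per-lipid equality
  set.seed(5)
  for (case in 1:6) {
    n <- sample(4:8, 1)
    box <- c(24, 18, 60)
    xyz <- cbind(runif(2 * n, 0, box[1]), runif(2 * n, 0, box[2]),
                 rep(c(55, 5), each = n))
    tr <- make_traj(xyz, box = box, molecule_id = seq_len(2 * n))
    rp <- area_per_species(tr, spacing = 1)
    sums <- tapply(rp$per_lipid$area_A2, rp$per_lipid$leaflet, sum)
    expect_equal(as.vector(sums), rep(box[1] * box[2], 2))
    upper <- rp$per_lipid[rp$per_lipid$leaflet == "upper", ]
    expected <- oracle_grid_areas(24, 18, box[1], box[2],
                                  xyz[seq_len(n), 1:2, drop = FALSE])
    expect_equal(upper$area_A2[order(upper$molecule_id)], expected)
  }
  expect_error(area_per_species(tr1, spacing = 3), class = "lc_config_error")
})

test_that("species-weighted tessellation area equals the general area", {
  m <- gen_membrane(membrane_spec(n_popc = 40, n_cer = 10, box_xy = 60,
                                  duration_ns = 50, dt_ns = 10, seed = 6))
  rp <- area_per_species(m$trajectory, spacing = 1, frames = 1:3)
  w <- rp$sa_species$n / sum(rp$sa_species$n)
  # 50 lipids over two leaflets in a 60 x 60 box -> 144 A^2 per lipid
  expect_equal(sum(w * rp$sa_species$area_A2), 60 * 60 / 25, tolerance = 1e-9)
  expect_equal(rp$sa_general, 60 * 60 / 25)
})

test_that("MSD handles immobile, ballistic and Brownian motion", {
  # immobile -> MSD identically zero
  tr <- make_traj(replicate(10, matrix(c(5, 5, 5), 1), simplify = FALSE))
  expect_equal(tibble::as_tibble(msd_lateral(tr, "POPC"))$msd_A2, rep(0, 10))
  # ballistic x = v t -> MSD = v^2 tau^2 (with wrapping over a small box)
  v <- 0.8
  frames <- lapply(0:19, function(f) matrix(c((v * f) %% 30, 5, 5), 1))
  trb <- make_traj(frames, box = c(30, 30, 30))
  msd <- tibble::as_tibble(msd_lateral(trb, "POPC"))
  expect_equal(msd$msd_A2, (v * msd$lag_ns)^2, tolerance = 1e-10)
  # random walks vs explicit per-origin enumeration
  set.seed(7)
  nf <- 12; nm <- 3
  X <- apply(matrix(rnorm(nf * nm), nf, nm), 2, cumsum)
  Y <- apply(matrix(rnorm(nf * nm), nf, nm), 2, cumsum)
  frames <- lapply(seq_len(nf), function(f)
    cbind(X[f, ] %% 50, Y[f, ] %% 50, 5))
  trw <- make_traj(frames, box = c(50, 50, 50), molecule_id = 1:3)
  got <- tibble::as_tibble(msd_lateral(trw, "POPC"))$msd_A2
  expect_equal(got, oracle_msd(X, Y), tolerance = 1e-9)
})

test_that("MSD is translation invariant and unaffected by wrapping", {
  set.seed(8)
  m <- gen_membrane(membrane_spec(n_popc = 20, n_cer = 0, duration_ns = 100,
                                  dt_ns = 5, min_sep = 0, seed = 8))
  tr <- m$trajectory
  msd1 <- tibble::as_tibble(msd_lateral(tr, "POPC"))$msd_A2
  shifted <- tr
  shifted$coords[, , 1] <- (tr$coords[, , 1] + 61.3) %% tr$box[1, 1]
  shifted$coords[, , 2] <- (tr$coords[, , 2] - 17.9) %% tr$box[1, 2]
  expect_equal(tibble::as_tibble(msd_lateral(shifted, "POPC"))$msd_A2, msd1,
               tolerance = 1e-9)
})

test_that("diffusion fits recover exact lines and planted walkers", {
  # exact line MSD = 4 tau: D = 1 A^2/ns = 1e-7 cm^2/s
  msd <- structure(tibble::tibble(lag_ns = 0:100, msd_A2 = 4 * (0:100),
                                  n_pairs = 101:1),
                   species = "POPC", class = c("lc_msd", "tbl_df", "tbl", "data.frame"))
  fit <- fit_diffusion(msd)
  expect_equal(fit$D, 1, tolerance = 1e-12)
  # constant offset leaves D unchanged
  msd2 <- msd; msd2$msd_A2 <- msd2$msd_A2 + 7
  expect_equal(fit_diffusion(msd2)$D, 1, tolerance = 1e-12)
  expect_equal(fit_diffusion(msd2)$intercept, 7, tolerance = 1e-9)
  # planted D = 0.9e-7 cm^2/s walkers (atomistic-scale dynamics)
  m <- gen_membrane(membrane_spec(n_popc = 400, n_cer = 0, d_popc = 0.9,
                                  duration_ns = 250, dt_ns = 1, min_sep = 0,
                                  seed = 31))
  D <- fit_diffusion(msd_lateral(m$trajectory, "POPC"))$D
  expect_equal(D, 0.9, tolerance = 0.12)
})

test_that("leaflet labels follow the headgroup z against the midplane", {
  tr <- make_bilayer(10, -2, n_per_leaflet = 1, box = c(20, 20, 60))
  lf <- assign_leaflets(tr, delta = 5)
  # midplane = mean(10, -2) + box/2 -> offsets +6 / -6... both beyond delta
  expect_equal(as.vector(lf$labels), c(1L, -1L))
  lf2 <- assign_leaflets(tr, delta = 7)
  expect_equal(as.vector(lf2$labels), c(0L, 0L))
  # synthetic bilayer: labels match construction away from transitions
  m <- gen_membrane(membrane_spec(n_popc = 30, n_cer = 10, duration_ns = 100,
                                  dt_ns = 10, seed = 9))
  lf3 <- assign_leaflets(m$trajectory)
  expect_true(all(lf3$labels != 0))
  expect_equal(sum(lf3$labels[1, ] == 1L), 20)  # half of each species up
})

test_that("flip-flop detection counts stable crossings only", {
  mk_labels <- function(v) {
    structure(list(labels = matrix(v, ncol = 1), molecule_id = 1L,
                   species = "CER6", times = (seq_along(v) - 1) * 10,
                   delta = 5), class = "lc_leaflets")
  }
  # clean crossing with long dwell on both sides -> one event
  ff1 <- detect_flipflops(mk_labels(c(rep(1L, 10), 0L, rep(-1L, 10))),
                          dwell_ns = 50)
  expect_equal(ff1$n_events, 1)
  expect_equal(ff1$events$from, "upper")
  # excursion into the transition zone and back -> no event
  ff2 <- detect_flipflops(mk_labels(c(rep(1L, 8), 0L, 0L, rep(1L, 8))),
                          dwell_ns = 50)
  expect_equal(ff2$n_events, 0)
  # brief dip into the other leaflet below the dwell -> still no event
  ff3 <- detect_flipflops(mk_labels(c(rep(1L, 8), -1L, -1L, rep(1L, 8))),
                          dwell_ns = 50)
  expect_equal(ff3$n_events, 0)
  expect_error(detect_flipflops(mk_labels(c(1L, 1L)), dwell_ns = 50),
               class = "lc_analysis_error")
})

test_that("scheduled membrane crossings are recovered exactly", {
  m <- gen_membrane(membrane_spec(n_single_flips = 10, n_double_flips = 4,
                                  seed = 21))
  ff <- detect_flipflops(assign_leaflets(m$trajectory))
  expect_equal(ff$n_events, 18)
  expect_equal(ff$n_molecules, 14)
  expect_equal(ff$rate_per_us, 3.6)
  expect_equal(ff$n_events, sum(ff$per_molecule$n_events))
  expect_equal(ff$rate_per_us * ff$duration_us, ff$n_events)
  expect_setequal(ff$per_molecule$molecule_id,
                  unique(m$manifest$true_events$molecule_id))
  # detected crossing times sit near the scheduled times
  j <- dplyr::inner_join(ff$events, m$manifest$true_events,
                         by = "molecule_id", relationship = "many-to-many")
  expect_true(all(tapply(abs(j$time_ns.x - j$time_ns.y),
                         paste(j$molecule_id, j$time_ns.x),
                         min) < 100))
})

test_that("cluster detection matches connected components under periodicity", {
  # 4 A apart -> one cluster of two; 6 A apart -> none
  tr_close <- make_traj(rbind(c(10, 10, 10), c(14, 10, 10)),
                        box = c(30, 30, 30), species = rep("CER6", 2),
                        molecule_id = 1:2)
  cl <- detect_clusters(tr_close, "CER6")
  expect_equal(cl$per_frame$n_clusters, 1L)
  expect_equal(cl$size_distribution$size, 2L)
  tr_far <- make_traj(rbind(c(10, 10, 10), c(16, 10, 10)),
                      box = c(30, 30, 30), species = rep("CER6", 2),
                      molecule_id = 1:2)
  expect_equal(detect_clusters(tr_far, "CER6")$per_frame$n_clusters, 0L)
  # random sparse configurations vs BFS components
  set.seed(10)
  for (case in 1:30) {
    n <- sample(5:12, 1); box <- c(25, 25, 20)
    xyz <- cbind(runif(n, 0, 25), runif(n, 0, 25), 10)
    tr <- make_traj(xyz, box = box, species = rep("CER6", n),
                    molecule_id = seq_len(n))
    cl <- detect_clusters(tr, "CER6")
    comps <- oracle_components(xyz[, 1], xyz[, 2], box, 5)
    sizes <- sort(lengths(comps)[lengths(comps) >= 2])
    expect_equal(cl$per_frame$n_clusters, length(sizes))
    if (length(sizes) > 0)
      expect_equal(sort(rep(cl$size_distribution$size,
                            cl$size_distribution$n)), sizes)
  }
})

test_that("hydrogen bonds obey the distance and angle cutoffs", {
  mk <- function(dpos, hpos, apos) {
    make_traj(rbind(dpos, hpos, apos), box = c(30, 30, 30),
              species = rep("protein", 3), role = c("backbone", "backbone", "backbone"),
              molecule_id = c(1, 1, 2), residue_number = c(1L, 1L, 2L),
              chain = rep("A", 3))
  }
  # D-A 3.4 A, angle 0 -> bond
  hb1 <- hydrogen_bonds(mk(c(5, 5, 5), c(6, 5, 5), c(8.4, 5, 5)),
                        donors = 1, hydrogens = 2, acceptors = 3)
  expect_equal(nrow(hb1$occupancy), 1)
  expect_equal(hb1$occupancy$occupancy, 1)
  # D-A 3.6 A, angle 0 -> no bond
  hb2 <- hydrogen_bonds(mk(c(5, 5, 5), c(6, 5, 5), c(8.6, 5, 5)),
                        donors = 1, hydrogens = 2, acceptors = 3)
  expect_equal(nrow(hb2$occupancy), 0)
  # D-A 3.4 A, angle 40 -> no bond
  ang <- 40 * pi / 180
  hb3 <- hydrogen_bonds(mk(c(5, 5, 5), c(5 + cos(ang), 5 + sin(ang), 5),
                           c(8.4, 5, 5)),
                        donors = 1, hydrogens = 2, acceptors = 3)
  expect_equal(nrow(hb3$occupancy), 0)
  expect_error(hydrogen_bonds(mk(c(5, 5, 5), c(6, 5, 5), c(8, 5, 5)),
                              donors = integer(), hydrogens = integer(),
                              acceptors = 3),
               class = "lc_config_error")
  # random geometries vs direct recomputation
  set.seed(11)
  for (case in 1:60) {
    box <- c(12, 12, 12)
    d <- runif(3, 0, 12); h <- d + rnorm(3, 0, 0.7); a <- runif(3, 0, 12)
    hb <- hydrogen_bonds(mk(d, h, a), donors = 1, hydrogens = 2,
                         acceptors = 3)
    expect_equal(nrow(hb$occupancy) == 1,
                 oracle_hbond(d, h, a, box, 3.5, 30))
  }
})
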