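# Small in-code fixtures shared across test files.

`%||%` <- function(a, b) if (is.null(a)) b else a

# evaluate under a seed, restoring the caller's RNG state afterwards
with_seed_local <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", globalenv())
  on.exit(if (had) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# bare trajectory from explicit coordinates: `coords` is a list of
# n_particles x 3 matrices (one per frame) or a single matrix
make_traj <- function(coords, box = c(50, 50, 50), species = NULL,
                      role = NULL, molecule_id = NULL, residue_number = NULL,
                      chain = NULL, dt = 1) {
  if (is.matrix(coords)) coords <- list(coords)
  np <- nrow(coords[[1]])
  arr <- array(0, dim = c(length(coords), np, 3))
  for (f in seq_along(coords)) arr[f, , ] <- coords[[f]]
  topo <- topology_table(
    particle_id = seq_len(np),
    molecule_id = molecule_id %||% seq_len(np),
    species = species %||% rep("POPC", np),
    role = role %||% rep("headgroup", np),
    residue_number = residue_number %||% NA_integer_,
    residue_name = NA_character_,
    chain = chain %||% NA_character_)
  trajectory(arr, times = (seq_along(coords) - 1) * dt, box = box,
             topology = topo)
}

# one protein residue (1 bead) + n lipids (1 bead each) at given positions
make_contact_frame <- function(lipid_xyz, residue_xyz = c(0, 0, 0),
                               box = c(50, 50, 50)) {
  n <- nrow(lipid_xyz)
  make_traj(rbind(residue_xyz, lipid_xyz), box = box,
            species = c("protein", rep("CER6", n)),
            role = c("backbone", rep("headgroup", n)),
            molecule_id = seq_len(n + 1),
            residue_number = c(1L, rep(NA_integer_, n)),
            chain = c("A", rep(NA_character_, n)))
}

# trajectory realizing a prescribed residue x lipid x frame contact pattern:
# residue beads on a line, far apart; lipids teleport to their residue when
# in contact, far away otherwise
make_pattern_traj <- function(pattern, dt = 1) {
  d <- dim(pattern)  # n_res x n_lip x n_frames
  box <- c(40 * d[1] + 200, 400, 100)
  res_x <- (seq_len(d[1]) - 1) * 40 + 20
  frames <- lapply(seq_len(d[3]), function(f) {
    lip <- t(vapply(seq_len(d[2]), function(l) {
      r <- which(pattern[, l, f])
      if (length(r) >= 1) c(res_x[r[1]], 53, 50) else c(10 + 30 * l, 300, 50)
    }, numeric(3)))
    rbind(cbind(res_x, 50, 50), lip)
  })
  make_traj(frames, box = box,
            species = c(rep("protein", d[1]), rep("CER6", d[2])),
            role = c(rep("backbone", d[1]), rep("headgroup", d[2])),
            molecule_id = seq_len(d[1] + d[2]),
            residue_number = c(seq_len(d[1]), rep(NA_integer_, d[2])),
            chain = c(rep("A", d[1]), rep(NA_character_, d[2])),
            dt = dt)
}
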