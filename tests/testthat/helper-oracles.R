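# Independent brute-force oracles: deliberately naive reimplementations
# (plain loops, no shared code with the package internals) used to validate
# the optimized kernels on small random instances.

oracle_mic <- function(d, L) d - L * round(d / L)

oracle_dist <- function(p, q, box) {
  sqrt(sum(oracle_mic(p - q, box)^2))
}

# per-frame group-vs-group contact: any pair within cutoff
oracle_contact <- function(frame_coords, box, idx_a, idx_b, cutoff) {
  for (a in idx_a) for (b in idx_b) {
    if (oracle_dist(frame_coords[a, ], frame_coords[b, ], box) <= cutoff)
      return(TRUE)
  }
  FALSE
}

oracle_longest_run <- function(v) {
  best <- 0L; cur <- 0L
  for (x in v) {
    if (isTRUE(x)) { cur <- cur + 1L; best <- max(best, cur) } else cur <- 0L
  }
  best
}

# connected components (BFS) of points under periodic x-y linkage
oracle_components <- function(x, y, box, radius) {
  n <- length(x)
  seen <- rep(FALSE, n)
  comps <- list()
  for (s in seq_len(n)) {
    if (seen[s]) next
    queue <- s; seen[s] <- TRUE; comp <- integer()
    while (length(queue) > 0) {
      i <- queue[1]; queue <- queue[-1]; comp <- c(comp, i)
      for (j in seq_len(n)) {
        if (!seen[j]) {
          dx <- oracle_mic(x[i] - x[j], box[1])
          dy <- oracle_mic(y[i] - y[j], box[2])
          if (dx^2 + dy^2 <= radius^2) { seen[j] <- TRUE; queue <- c(queue, j) }
        }
      }
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps
}

# MSD by explicit loops over origins and lags (x-y, already unwrapped)
oracle_msd <- function(X, Y) {
  nf <- nrow(X); nm <- ncol(X)
  msd <- numeric(nf)
  for (k in 0:(nf - 1)) {
    tot <- 0; cnt <- 0
    for (t0 in 1:(nf - k)) for (m in 1:nm) {
      tot <- tot + (X[t0 + k, m] - X[t0, m])^2 + (Y[t0 + k, m] - Y[t0, m])^2
      cnt <- cnt + 1
    }
    msd[k + 1] <- tot / cnt
  }
  msd
}

# per-reference grid-cell counts by explicit nearest-point loops
oracle_grid_areas <- function(nx, ny, Lx, Ly, refs) {
  counts <- integer(nrow(refs))
  for (j in seq_len(ny)) for (i in seq_len(nx)) {
    cx <- (i - 0.5) * Lx / nx; cy <- (j - 0.5) * Ly / ny
    best <- Inf; who <- 0L
    for (k in seq_len(nrow(refs))) {
      d2 <- oracle_mic(cx - refs[k, 1], Lx)^2 + oracle_mic(cy - refs[k, 2], Ly)^2
      if (d2 < best) { best <- d2; who <- k }
    }
    counts[who] <- counts[who] + 1L
  }
  counts * (Lx / nx) * (Ly / ny)
}

oracle_hbond <- function(d, h, a, box, dist_cut, ang_cut) {
  if (oracle_dist(d, a, box) > dist_cut) return(FALSE)
  u <- oracle_mic(h - d, box); v <- oracle_mic(a - d, box)
  ang <- acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
  ang <= ang_cut
}
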