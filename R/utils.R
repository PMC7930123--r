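# internal helpers shared across modules

# minimum-image convention for orthorhombic boxes: fold displacement
# components into (-L/2, L/2]. `dx` is a matrix (or vector) of displacement
# components, `box` the matching box lengths (recycled).
min_image <- function(dx, box) {
  dx - box * round(dx / box)
}

# squared minimum-image distance between one point and a matrix of points
min_image_dist2 <- function(p, pts, box) {
  d <- sweep(pts, 2, p)
  for (k in seq_along(box)) d[, k] <- min_image(d[, k], box[k])
  rowSums(d^2)
}

# wrap absolute coordinates into [0, L)
wrap_box <- function(x, box) {
  x - box * floor(x / box)
}

# centroid of a particle selection in one frame of a [frame x particle x 3] array
frame_centroid <- function(coords, f, idx) {
  m <- coords[f, idx, , drop = FALSE]
  dim(m) <- c(length(idx), 3L)
  colMeans(m)
}

stopf <- function(class, fmt, ...) {
  abort(sprintf(fmt, ...), class = c(class, "lipocontact_error"))
}

is_count <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) &&
  x >= 1 && x == round(x)

# deterministic child seeds below 2^31 derived from one user seed
derive_seed <- function(seed, index) {
  (as.integer(seed) * 7919L + as.integer(index) * 104729L) %% 2147483647L
}

# type-7 quantiles (linear interpolation of order statistics), the package's
# single quartile convention unless a caller opts into Tukey hinges
lc_quartiles <- function(x, type = c("type7", "hinges")) {
  type <- match.arg(type)
  if (type == "type7") {
    q <- quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
  } else {
    f <- stats::fivenum(x)
    q <- f[c(2, 4)]
  }
  list(q1 = q[1], q3 = q[2], iqr = q[2] - q[1])
}
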