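#' Build a trajectory object
#'
#' The central in-memory container for coordinate series: a dense
#' `[frame, particle, xyz]` array in Angstrom, per-frame orthorhombic box
#' lengths, frame times in nanoseconds, and a topology table describing every
#' particle. All analysis functions in the package consume this object.
#'
#' @param coords numeric array of dimension `n_frames x n_particles x 3`
#'   (Angstrom). A single frame may be given as an `n_particles x 3` matrix.
#' @param times numeric vector of frame times in ns, strictly increasing and
#'   (within tolerance) uniformly spaced.
#' @param box per-frame box lengths in Angstrom: an `n_frames x 3` matrix, or
#'   a length-3 vector recycled to all frames. Orthorhombic boxes only.
#' @param topology a topology table, see [topology_table()].
#' @param wrapped logical, whether coordinates are wrapped into the primary
#'   box. Stored as metadata; analyses that need wrapped or unwrapped input
#'   handle the conversion themselves.
#'
#' @return An object of class `lc_trajectory`.
#' @seealso [topology_table()], [slice_window()], [load_trajectory()]
#' @export
trajectory <- function(coords, times, box, topology, wrapped = TRUE) {
  if (is.matrix(coords)) coords <- array(coords, dim = c(1L, dim(coords)))
  if (!is.array(coords) || length(dim(coords)) != 3L || dim(coords)[3] != 3L)
    stopf("lc_format_error", "coords must be an n_frames x n_particles x 3 array")
  n_frames <- dim(coords)[1]
  n_particles <- dim(coords)[2]
  if (!all(is.finite(coords)))
    stopf("lc_format_error", "coords contain non-finite values")
  if (length(times) != n_frames)
    stopf("lc_format_error", "times length (%d) != n_frames (%d)",
          length(times), n_frames)
  if (n_frames > 1) {
    dts <- diff(times)
    if (any(dts <= 0))
      stopf("lc_format_error", "frame times must be strictly increasing")
    if (max(dts) - min(dts) > 1e-3 * stats::median(dts))
      stopf("lc_format_error", "frame times are not uniformly spaced")
  }
  if (is.null(dim(box))) box <- matrix(box, n_frames, 3, byrow = TRUE)
  box <- as.matrix(box)
  if (ncol(box) != 3L)
    stopf("lc_format_error",
          "box must have 3 columns (orthorhombic boxes only; triclinic input is unsupported)")
  if (nrow(box) == 1L && n_frames > 1L)
    box <- box[rep(1L, n_frames), , drop = FALSE]
  if (nrow(box) != n_frames)
    stopf("lc_format_error", "box must have one row per frame")
  if (any(box <= 0)) stopf("lc_format_error", "box lengths must be positive")
  topology <- validate_topology(topology)
  if (nrow(topology) != n_particles)
    stopf("lc_format_error",
          "topology has %d particles but coordinates have %d",
          nrow(topology), n_particles)
  structure(
    list(coords = coords, times = as.numeric(times), box = box,
         topology = topology, wrapped = isTRUE(wrapped)),
    class = "lc_trajectory"
  )
}

#' @export
print.lc_trajectory <- function(x, ...) {
  cat(sprintf(
    "<lc_trajectory> %d frames x %d particles, %.4g ns (dt = %.4g ns)\n",
    n_frames(x), n_particles(x), diff(range(x$times)), frame_dt(x)))
  sp <- dplyr::count(x$topology, .data$species)
  cat("  species:",
      paste(sprintf("%s (%d particles)", sp$species, sp$n), collapse = ", "),
      "\n")
  invisible(x)
}

#' Trajectory accessors
#'
#' Small helpers reading off basic dimensions of an [trajectory()] object:
#' frame count, particle count, and the frame interval dt (ns) derived from
#' the first two time stamps. Duration metrics throughout the package are
#' `run length x dt`, so they inherit the time resolution of the input.
#'
#' @param traj an `lc_trajectory`.
#' @return A scalar.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' @rdname n_frames
#' @export
n_particles <- function(traj) dim(traj$coords)[2]

#' @rdname n_frames
#' @export
frame_dt <- function(traj) {
  if (n_frames(traj) < 2) return(NA_real_)
  traj$times[2] - traj$times[1]
}

#' Define an analysis window as trajectory fractions
#'
#' Long simulations are commonly analysed over their final stretch only, after
#' discarding an equilibration transient; the default keeps the last 80% of
#' frames (e.g. the last 8 us of a 10 us replica).
#'
#' @param start_fraction,end_fraction fractions of the trajectory, with
#'   `0 <= start < end <= 1`.
#' @return An `lc_window` object.
#' @export
analysis_window <- function(start_fraction = 0.2, end_fraction = 1.0) {
  if (!is.numeric(start_fraction) || !is.numeric(end_fraction) ||
      start_fraction < 0 || end_fraction > 1 ||
      start_fraction >= end_fraction)
    stopf("lc_config_error",
          "need 0 <= start_fraction < end_fraction <= 1 (got %s, %s)",
          format(start_fraction), format(end_fraction))
  structure(list(start_fraction = start_fraction,
                 end_fraction = end_fraction), class = "lc_window")
}

#' Restrict a trajectory to an analysis window
#'
#' Keeps frames with zero-based index in `[floor(start * n), floor(end * n))`;
#' times and per-frame boxes are preserved. Composing two windows equals the
#' single equivalent window.
#'
#' @inheritParams n_frames
#' @param window an [analysis_window()], or a numeric pair
#'   `c(start_fraction, end_fraction)`.
#' @return A new `lc_trajectory` holding the selected frames.
#' @export
slice_window <- function(traj, window = analysis_window()) {
  if (is.numeric(window) && length(window) == 2)
    window <- analysis_window(window[1], window[2])
  stopifnot(inherits(window, "lc_window"))
  n <- n_frames(traj)
  idx <- seq.int(floor(window$start_fraction * n) + 1L,
                 length.out = floor(window$end_fraction * n) -
                   floor(window$start_fraction * n))
  if (length(idx) < 1)
    stopf("lc_config_error", "analysis window selects no frames (n = %d)", n)
  out <- traj
  out$coords <- traj$coords[idx, , , drop = FALSE]
  out$times <- traj$times[idx]
  out$box <- traj$box[idx, , drop = FALSE]
  out
}

# particle indices matching topology filters; NULL filters match everything
particle_ids <- function(topology, species = NULL, role = NULL, chain = NULL,
                         residue_number = NULL, molecule_id = NULL) {
  keep <- rep(TRUE, nrow(topology))
  if (!is.null(species)) keep <- keep & topology$species %in% species
  if (!is.null(role)) keep <- keep & topology$role %in% role
  if (!is.null(chain)) keep <- keep & topology$chain %in% chain
  if (!is.null(residue_number))
    keep <- keep & topology$residue_number %in% residue_number
  if (!is.null(molecule_id)) keep <- keep & topology$molecule_id %in% molecule_id
  which(keep)
}

# species present in a trajectory, with a helpful error when one is missing
check_species <- function(traj, species) {
  present <- unique(traj$topology$species)
  missing <- setdiff(species, present)
  if (length(missing) > 0)
    stopf("lc_config_error",
          "species not present in topology: %s (available: %s)",
          paste(missing, collapse = ", "), paste(present, collapse = ", "))
  invisible(species)
}
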