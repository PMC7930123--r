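#' Read a structure plus coordinate series into a trajectory
#'
#' Structures may be GRO or PDB; coordinate series may be a multi-frame GRO
#' file or a DCD binary (read through bio3d). XTC/TRR input is not supported
#' and raises an explicit error. The particle count of the structure and the
#' series must agree. Species and role assignment is driven by
#' `topology_spec` (see [read_topology_spec()]).
#'
#' @param structure_path path to a `.gro` or `.pdb` structure file.
#' @param trajectory_path path to a multi-frame `.gro` or a `.dcd` file;
#'   `NULL` analyses the structure as a single frame.
#' @param topology_spec a topology specification list mapping residue names
#'   to species/roles, or a path to its YAML form.
#' @param dt_ns frame interval in ns for formats that carry no time stamps
#'   (DCD); ignored when the series provides times.
#' @return An [trajectory()] object. Coordinates are stored as found in the
#'   file; `$wrapped` is set to `TRUE` (both supported writers emit wrapped
#'   coordinates).
#' @export
load_trajectory <- function(structure_path, trajectory_path = NULL,
                            topology_spec = NULL, dt_ns = 1) {
  ext <- function(p) tolower(tools::file_ext(p))
  if (!file.exists(structure_path))
    stopf("lc_io_error", "structure file not found: %s", structure_path)
  stru <- switch(ext(structure_path),
    gro = read_gro_frames(structure_path),
    pdb = read_pdb_structure(structure_path),
    stopf("lc_format_error", "unsupported structure format: .%s",
          ext(structure_path)))
  topo <- build_topology(stru$atoms, topology_spec)
  n <- nrow(stru$atoms)
  if (is.null(trajectory_path)) {
    coords <- stru$coords
    times <- stru$times %||% 0
    box <- stru$box
  } else {
    e <- ext(trajectory_path)
    if (e %in% c("xtc", "trr"))
      stopf("lc_format_error",
            "XTC/TRR input is not supported; convert to DCD or multi-frame GRO")
    tr <- switch(e,
      gro = read_gro_frames(trajectory_path),
      dcd = read_dcd_frames(trajectory_path, dt_ns = dt_ns),
      stopf("lc_format_error", "unsupported trajectory format: .%s", e))
    if (dim(tr$coords)[2] != n)
      stopf("lc_format_error",
            "particle count mismatch: structure has %d, trajectory has %d",
            n, dim(tr$coords)[2])
    coords <- tr$coords
    times <- tr$times %||% (seq_len(dim(tr$coords)[1]) - 1) * dt_ns
    box <- tr$box
  }
  trajectory(coords, times = times, box = box, topology = topo,
             wrapped = TRUE)
}

# ---- GRO (fixed-width text, lengths in nm, times in ps) ----------------

read_gro_frames <- function(path) {
  lines <- readLines(path)
  frames <- list(); times <- numeric(); boxes <- list()
  atoms <- NULL
  i <- 1L
  while (i <= length(lines)) {
    title <- lines[i]
    natoms <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(natoms))
      stopf("lc_format_error", "malformed GRO: bad atom count at line %d", i + 1L)
    if (i + 1L + natoms + 1L > length(lines))
      stopf("lc_format_error", "malformed GRO: truncated frame at line %d", i)
    body <- lines[(i + 2L):(i + 1L + natoms)]
    xyz <- cbind(as.numeric(substr(body, 21, 28)),
                 as.numeric(substr(body, 29, 36)),
                 as.numeric(substr(body, 37, 44))) * 10  # nm -> Angstrom
    if (anyNA(xyz))
      stopf("lc_format_error", "malformed GRO coordinates near line %d", i + 2L)
    if (is.null(atoms)) {
      atoms <- tibble(
        resid = as.integer(substr(body, 1, 5)),
        resname = trimws(substr(body, 6, 10)),
        atom = trimws(substr(body, 11, 15)),
        chain = NA_character_
      )
    } else if (natoms != nrow(atoms)) {
      stopf("lc_format_error",
            "particle count changes between GRO frames (%d vs %d)",
            nrow(atoms), natoms)
    }
    boxline <- as.numeric(strsplit(trimws(lines[i + 2L + natoms]), "\\s+")[[1]])
    if (length(boxline) > 3 && any(boxline[-(1:3)] != 0))
      stopf("lc_format_error",
            "triclinic box in GRO input; orthorhombic boxes only")
    boxes[[length(boxes) + 1L]] <- boxline[1:3] * 10
    tm <- regmatches(title, regexpr("t=\\s*[-0-9.eE+]+", title))
    times <- c(times, if (length(tm) == 1)
      as.numeric(sub("t=\\s*", "", tm)) / 1000 else NA_real_)  # ps -> ns
    frames[[length(frames) + 1L]] <- xyz
    i <- i + natoms + 3L
  }
  coords <- array(0, dim = c(length(frames), nrow(atoms), 3))
  for (f in seq_along(frames)) coords[f, , ] <- frames[[f]]
  if (anyNA(times)) times <- NULL
  list(coords = coords, times = times,
       box = do.call(rbind, boxes), atoms = atoms)
}

#' Write a trajectory as a multi-frame GRO file
#'
#' Text output (lengths in nm, frame times in ps on the title line), readable
#' by [load_trajectory()] and by standard visualization tools. Coordinates
#' are written wrapped into the primary box at 3 decimals of nm (0.01 A).
#'
#' @inheritParams n_frames
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gro <- function(traj, path) {
  topo <- traj$topology
  prot <- topo$species == "protein"
  resname <- substr(ifelse(is.na(topo$residue_name) | topo$residue_name == "",
                           topo$species, topo$residue_name), 1, 5)
  # chain survives the format round trip via segment-style residue names
  resname[prot] <- paste0("PRO", topo$chain[prot])
  resid <- ifelse(prot, topo$residue_number, topo$molecule_id) %% 100000L
  rolemap <- c(headgroup = "HGR", linker = "LNK", tail = "TAIL",
               backbone = "BB", sidechain = "SC")
  atomname <- ifelse(topo$role %in% names(rolemap), rolemap[topo$role],
                     substr(topo$role, 1, 5))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (f in seq_len(n_frames(traj))) {
    box <- traj$box[f, ]
    xyz <- wrap_box(traj$coords[f, , , drop = TRUE], rep(box, each = n_particles(traj)))
    writeLines(sprintf("lipocontact frame %d t= %.4f", f, traj$times[f] * 1000), con)
    writeLines(sprintf("%5d", n_particles(traj)), con)
    writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       resid, resname, atomname,
                       topo$particle_id %% 100000L,
                       xyz[, 1] / 10, xyz[, 2] / 10, xyz[, 3] / 10), con)
    writeLines(sprintf("%10.5f%10.5f%10.5f", box[1] / 10, box[2] / 10, box[3] / 10), con)
  }
  invisible(path)
}

# ---- PDB / DCD via bio3d ----------------------------------------------

read_pdb_structure <- function(path) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  atoms <- tibble(resid = as.integer(at$resno), resname = trimws(at$resid),
                  atom = trimws(at$elety), chain = as.character(at$chain))
  coords <- array(0, dim = c(1L, nrow(atoms), 3))
  coords[1, , ] <- cbind(at$x, at$y, at$z)
  cry <- pdb$cryst1
  box <- if (!is.null(cry) && length(cry$abc) == 3) {
    if (!is.null(cry$abg) && any(abs(cry$abg - 90) > 1e-6))
      stopf("lc_format_error", "triclinic PDB cell; orthorhombic boxes only")
    matrix(cry$abc, 1, 3)
  } else {
    matrix(apply(coords[1, , , drop = TRUE], 2, function(v) diff(range(v)) + 20), 1, 3)
  }
  list(coords = coords, times = NULL, box = box, atoms = atoms)
}

read_dcd_frames <- function(path, dt_ns = 1) {
  m <- bio3d::read.dcd(path, verbose = FALSE, cell = FALSE)
  nf <- nrow(m); np <- ncol(m) / 3
  coords <- array(0, dim = c(nf, np, 3))
  coords[, , 1] <- m[, seq(1, by = 3, length.out = np)]
  coords[, , 2] <- m[, seq(2, by = 3, length.out = np)]
  coords[, , 3] <- m[, seq(3, by = 3, length.out = np)]
  box <- matrix(apply(coords, 3, max) - apply(coords, 3, min) + 20, 1, 3)
  list(coords = coords, times = (seq_len(nf) - 1) * dt_ns, box = box,
       atoms = NULL)
}

# ---- topology specification -------------------------------------------

#' Read or validate a topology specification
#'
#' The specification maps residue names found in structure files to species
#' and per-atom roles, e.g. (YAML form):
#' ```yaml
#' residues:
#'   POPC: {species: POPC, roles: {PO4: headgroup, GL1: linker, GL2: linker},
#'          default_role: tail}
#'   CER6: {species: CER6, roles: {AM1: headgroup, AM2: headgroup},
#'          default_role: tail}
#'   __protein__: {species: protein, roles: {BB: backbone},
#'                 default_role: sidechain}
#' ```
#' The key `__protein__` applies to any residue name not otherwise listed
#' that looks like an amino acid (fallback for protein residues).
#'
#' @param spec a path to a YAML file or an already-built list.
#' @return The validated specification list.
#' @export
read_topology_spec <- function(spec) {
  if (is.character(spec) && length(spec) == 1) spec <- yaml::read_yaml(spec)
  if (!is.list(spec) || is.null(spec$residues))
    stopf("lc_config_error", "topology_spec must contain a 'residues' map")
  spec
}

build_topology <- function(atoms, topology_spec) {
  if (is.null(topology_spec)) topology_spec <- default_topology_spec()
  spec <- read_topology_spec(topology_spec)$residues
  resmap <- names(spec)
  known <- atoms$resname %in% resmap
  fallback <- "__protein__" %in% resmap
  if (any(!known) && !fallback) {
    bad <- unique(atoms$resname[!known])
    stopf("lc_config_error", "unknown species in topology_spec: %s",
          paste(bad, collapse = ", "))
  }
  entry_of <- function(rn) if (rn %in% resmap) spec[[rn]] else spec[["__protein__"]]
  species <- character(nrow(atoms)); role <- character(nrow(atoms))
  for (rn in unique(atoms$resname)) {
    e <- entry_of(rn)
    sel <- atoms$resname == rn
    species[sel] <- e$species
    roles <- unlist(e$roles)
    role[sel] <- ifelse(atoms$atom[sel] %in% names(roles),
                        roles[atoms$atom[sel]],
                        e$default_role %||% "tail")
  }
  prot <- species == "protein"
  # molecules: protein chains are one molecule each; lipids break on resid change
  chain <- atoms$chain
  for (rn in unique(atoms$resname)) {
    e <- entry_of(rn)
    if (!is.null(e$chain)) chain[atoms$resname == rn] <- e$chain
  }
  if (any(prot) && all(is.na(chain[prot]))) chain[prot] <- "A"
  # lipid molecule breaks: new molecule when resid or resname changes
  lipid_break <- c(TRUE, atoms$resid[-1] != atoms$resid[-nrow(atoms)] |
                     atoms$resname[-1] != atoms$resname[-nrow(atoms)])
  mol_key <- ifelse(prot, paste0("P", chain), paste0("L", cumsum(lipid_break)))
  topology_table(
    particle_id = seq_len(nrow(atoms)),
    molecule_id = as.integer(factor(mol_key, levels = unique(mol_key))),
    species = species,
    role = role,
    residue_number = ifelse(prot, atoms$resid, NA_integer_),
    residue_name = atoms$resname,
    chain = ifelse(prot, chain, NA_character_)
  )
}

default_topology_spec <- function() {
  lipid_roles <- list(PO4 = "headgroup", NC3 = "headgroup", HGR = "headgroup",
                      GL1 = "linker", GL2 = "linker", LNK = "linker")
  cer_roles <- list(AM1 = "headgroup", AM2 = "headgroup", OH = "headgroup",
                    HGR = "headgroup", LNK = "linker")
  prot_roles <- list(BB = "backbone", CA = "backbone", N = "backbone",
                     C = "backbone", O = "backbone")
  prot_entry <- function(ch) list(species = "protein", roles = prot_roles,
                                  default_role = "sidechain", chain = ch)
  list(residues = list(
    POPC = list(species = "POPC", roles = lipid_roles, default_role = "tail"),
    CER6 = list(species = "CER6", roles = cer_roles, default_role = "tail"),
    DPCE = list(species = "CER6", roles = cer_roles, default_role = "tail"),
    PROA = prot_entry("A"), PROB = prot_entry("B"),
    PROC = prot_entry("C"), PROD = prot_entry("D"),
    `__protein__` = list(species = "protein", roles = prot_roles,
                         default_role = "sidechain")
  ))
}

# ---- tables and manifests ---------------------------------------------

#' Write an analysis table as CSV
#'
#' Numeric columns are rounded to 6 significant digits; rows are ordered
#' deterministically by residue number, chain and replica when those columns
#' are present, so repeated runs produce byte-identical files.
#'
#' @param table a data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metric_table <- function(table, path) {
  tb <- as_tibble(table)
  keys <- intersect(c("residue_number", "chain", "replica"), names(tb))
  if (length(keys) > 0)
    tb <- dplyr::arrange(tb, dplyr::across(dplyr::all_of(keys)))
  tb <- dplyr::mutate(tb, dplyr::across(dplyr::where(is.numeric),
                                        ~ signif(.x, 6)))
  tryCatch(readr::write_csv(tb, path, progress = FALSE),
           error = function(e) stopf("lc_io_error",
                                     "cannot write table to %s: %s",
                                     path, conditionMessage(e)))
  invisible(path)
}

#' @rdname write_metric_table
#' @export
read_metric_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Write a JSON run manifest
#'
#' Records parameters, seed, analysis window and md5 hashes of input files
#' alongside every pipeline result so that a finished run can be audited and
#' reproduced.
#'
#' @param path output JSON path.
#' @param parameters named list of analysis parameters.
#' @param seed integer seed used for any stochastic stage (or `NULL`).
#' @param window an [analysis_window()] or `NULL`.
#' @param files character vector of input paths to hash.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, parameters = list(), seed = NULL,
                               window = NULL, files = character()) {
  hashes <- if (length(files) > 0) as.list(tools::md5sum(files)) else NULL
  manifest <- list(
    package = "lipocontact",
    version = as.character(utils::packageVersion("lipocontact")),
    parameters = parameters,
    seed = seed,
    window = if (!is.null(window)) unclass(window),
    file_hashes = hashes
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
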