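#' Build a topology table
#'
#' One row per particle (bead in coarse-grained systems, atom in atomistic
#' ones) mapping it to a molecule, a species (e.g. `POPC`, `CER6`,
#' `protein`), a structural role, and -- for protein particles -- a residue
#' number, residue name and chain. Roles are free-form but the analyses rely
#' on the conventions `headgroup` / `linker` / `tail` for lipids and
#' `backbone` / `sidechain` for proteins.
#'
#' @param particle_id integer ids, `1..n` in coordinate order.
#' @param molecule_id integer molecule ids; every particle belongs to exactly
#'   one molecule.
#' @param species character species tag per particle.
#' @param role character role tag per particle.
#' @param residue_number,residue_name,chain protein annotation; `NA` for
#'   lipid/solvent particles. Tetramers use chains `A`-`D` with identical
#'   residue numbering.
#' @return A tibble with class-checked columns.
#' @export
topology_table <- function(particle_id, molecule_id, species, role,
                           residue_number = NA_integer_,
                           residue_name = NA_character_,
                           chain = NA_character_) {
  tb <- tibble(
    particle_id = as.integer(particle_id),
    molecule_id = as.integer(molecule_id),
    species = as.character(species),
    role = as.character(role),
    residue_number = as.integer(residue_number),
    residue_name = as.character(residue_name),
    chain = as.character(chain)
  )
  validate_topology(tb)
}

validate_topology <- function(topology) {
  need <- c("particle_id", "molecule_id", "species", "role",
            "residue_number", "residue_name", "chain")
  missing <- setdiff(need, names(topology))
  if (length(missing) > 0)
    stopf("lc_format_error", "topology lacks columns: %s",
          paste(missing, collapse = ", "))
  topology <- as_tibble(topology)
  if (anyNA(topology$molecule_id))
    stopf("lc_format_error", "every particle must belong to a molecule")
  prot <- topology$species == "protein"
  if (any(prot) &&
      (anyNA(topology$residue_number[prot]) || anyNA(topology$chain[prot])))
    stopf("lc_format_error",
          "every protein particle needs a residue_number and chain")
  lip <- topology[!prot & topology$role %in% c("headgroup", "linker", "tail"), ]
  if (nrow(lip) > 0) {
    by_mol <- dplyr::summarise(
      dplyr::group_by(lip, .data$molecule_id),
      has_head = any(.data$role == "headgroup"), .groups = "drop")
    if (!all(by_mol$has_head))
      stopf("lc_format_error",
            "lipid molecules without a headgroup particle: %s",
            paste(head(by_mol$molecule_id[!by_mol$has_head], 5), collapse = ", "))
  }
  topology
}

# check tetramer structure: exactly 4 chains sharing one residue numbering
check_tetramer <- function(topology) {
  prot <- dplyr::filter(topology, .data$species == "protein")
  if (nrow(prot) == 0) stopf("lc_config_error", "no protein in topology")
  chains <- sort(unique(prot$chain))
  if (length(chains) != 4)
    stopf("lc_format_error", "expected 4 protein chains, found %d (%s)",
          length(chains), paste(chains, collapse = ", "))
  resnums <- lapply(chains, function(ch)
    sort(unique(prot$residue_number[prot$chain == ch])))
  if (!all(vapply(resnums[-1], identical, logical(1), resnums[[1]])))
    stopf("lc_format_error", "chains do not share identical residue numbering")
  chains
}

# lipid molecules of a species: list mapping molecule_id -> particle indices
lipid_particles_by_molecule <- function(topology, species, role = NULL) {
  idx <- particle_ids(topology, species = species, role = role)
  if (length(idx) == 0)
    stopf("lc_config_error", "no particles for species %s%s", species,
          if (is.null(role)) "" else paste0(" with role ", paste(role, collapse = "/")))
  split(idx, topology$molecule_id[idx])
}

# protein particles grouped by (residue_number, chain)
protein_particles_by_residue <- function(topology) {
  idx <- which(topology$species == "protein")
  key <- paste(topology$residue_number[idx], topology$chain[idx], sep = "|")
  groups <- split(idx, key)
  info <- do.call(rbind, strsplit(names(groups), "|", fixed = TRUE))
  list(groups = groups,
       residue_number = as.integer(info[, 1]),
       chain = info[, 2])
}
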