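# Literature-derived reference values for the hERG1-ceramide system.
# These drive the synthetic generators' default conditions and serve as
# comparison points in examples and tests.

#' Reference dose-response parameters for hERG1 variants
#'
#' Half-maximal inhibitory concentration, Hill coefficient and plateau
#' (stable residual current at saturating inhibitor) reported for
#' C6-ceramide block of hERG1 variants, plus the C8-ceramide value for the
#' wild type. These parameter sets are the ground truth the synthetic
#' dose-response generator samples from; the F656C plateau is an estimated
#' value (no clear asymptote up to 500 uM).
#'
#' @return A tibble: `ligand`, `variant`, `ic50_uM`, `hill`, `stable_level`.
#' @export
reference_dose_params <- function() {
  tibble(
    ligand = c(rep("CER6", 6), "CER8"),
    variant = c("WT", "B", "Y652A", "F656C", "M651T", "F557L", "WT"),
    ic50_uM = c(22, 8, 17, 385, 46, 33, 98),
    hill = c(0.8, 1.1, 1.0, 0.5, 0.9, 1.9, 1.0),
    stable_level = c(0.3, 0.1, 0.1, 0.0, 0.4, 0.4, 0.3)
  )
}

#' Reference membrane properties of the POPC:CER6 (8:2) patch
#'
#' Surface areas per lipid (general and per species), lateral diffusion
#' coefficients, bilayer thickness and flip-flop statistics reported for
#' coarse-grained (CG) and atomistic (AA) simulations of the bicomponent
#' patch. The synthetic membrane generator uses the CG values as its
#' default dynamics.
#'
#' @return A tibble: `property`, `resolution` (`"CG"` / `"AA"`), `value`,
#'   `sd`, `unit`.
#' @export
reference_membrane_properties <- function() {
  tibble(
    property = c("sa_lipid", "sa_popc", "sa_cer6", "d_popc", "d_cer6",
                 "thickness", "flipflop_events", "flipflop_molecules",
                 "flipflop_rate",
                 "sa_lipid", "sa_popc", "sa_cer6", "d_popc", "d_cer6",
                 "thickness"),
    resolution = c(rep("CG", 9), rep("AA", 6)),
    value = c(60.0, 62.5, 52.1, 6.6, 13.8, 39, 18, 14, 3.6,
              59.7, 62.3, 51.5, 0.9, 1.0, 40),
    sd = c(0.6, 0.6, 2.2, 0.3, 0.1, NA, NA, NA, 1.4,
           0.7, 0.8, 1.6, 0.2, 0.3, NA),
    unit = c("A^2", "A^2", "A^2", "1e-7 cm^2/s", "1e-7 cm^2/s", "A",
             "events", "molecules", "events/us",
             "A^2", "A^2", "A^2", "1e-7 cm^2/s", "1e-7 cm^2/s", "A")
  )
}

#' Reference ceramide binding free energies
#'
#' Alchemical (free energy perturbation) binding free energies of C6-ceramide
#' at the VSD-PD interface for the closed- and open-pore states of the
#' wild-type channel, consumed by [ddg_compare()].
#'
#' @return A tibble: `state`, `dg_kcal_mol`, `sd_kcal_mol`.
#' @export
reference_binding_energies <- function() {
  tibble(state = c("closed", "open"),
         dg_kcal_mol = c(-8.7, -4.0),
         sd_kcal_mol = c(1.6, 1.1))
}
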