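---
title: "Methods: contact mapping, membrane analytics and ephys fits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contact mapping, membrane analytics and ephys fits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipocontact)
```

This vignette is the package's own account of its methods: the models and
conventions implemented, the tunable parameters and their defaults, what the
synthetic generators do and do not emulate, and the numerical choices made
where the design was genuinely open.

## The scientific setting

Amphipathic lipids such as short-chain ceramides partition into membranes
and can modulate ion channels from the lipid phase rather than through the
aqueous pore. For a homotetrameric channel like hERG1, whose non-swapped
topology packs each voltage-sensor domain against the pore domain of the
neighbouring subunit, the four VSD–PD interfaces form lipid-accessible
crevices. Three kinds of evidence meet in such a study: per-residue contact
statistics from coarse-grained simulations, the biophysical health of the
membrane models those simulations use, and patch-clamp dose-response and
gating measurements on channel variants. The package implements the
analysis layer for all three.

## Contact metrics

A trajectory is a dense `[frame × particle × xyz]` array (Å) with per-frame
orthorhombic box lengths and a topology table assigning every particle to a
molecule, species, role and — for protein — residue and chain. A residue
and a lipid molecule are *in contact* in a frame when any particle of the
residue is within the cutoff (default 6 Å, the customary bead-contact
criterion in coarse-grained work) of any particle of that lipid, under the
minimum-image convention. All particles of both partners participate; a
headgroup-only restriction is available for species-specificity questions.

Two per-residue metrics summarise the contact series:

* **contact-duration** — `dt ×` the number of frames in which the *union*
  over lipid molecules of the species is in contact;
* **maximum-occupancy** — the longest consecutive run of frames in contact
  with an *individual* lipid molecule, `× dt`. Continuity is per molecule: a
  single frame out of range ends that molecule's run. A union-continuity
  variant and a configurable `gap_tolerance_frames` (default 0) exist for
  sensitivity analysis, never as silent defaults.

Durations are `run length × dt`, so they inherit the time resolution of the
input; the frame interval is read from the file, not assumed.

For a homotetramer every replica yields four values per residue; selection
operates on the arithmetic mean over `4 × n_replicas` values, with chains
lacking contact contributing zeros. Hot spots are selected per metric:

* contact-duration upper quartile: `x > Q3`;
* maximum-occupancy outliers: `x > Q3 + 1.5·IQR`, `IQR = Q3 − Q1`.

Quartiles use linear interpolation of order statistics (R type 7). Tukey
hinges are offered as an option because membership near the threshold can
differ between conventions; the convention used is recorded in the result.
The intersection structure (occupancy outliers versus duration-only
residues) is reported explicitly, mirroring the red/yellow classes of
contact-map figures.

The default analysis window keeps the last 80 % of frames
(`analysis_window(0.2, 1)`), the usual practice of discarding an
equilibration transient; window arithmetic is frame-index based
(`[floor(start·n), floor(end·n))`) so that composing windows is exact.

## Membrane analytics

* **Density profiles** are time-averaged histograms (default 1 Å bins)
  along z measured from the per-frame midplane, defined as the mean
  headgroup z of all lipids — robust to membrane drift, unlike the box
  centre. Count densities are per Å³, so integrating a profile over z and
  multiplying by the box x–y area recovers the group's mean particle count
  (a tested invariant).
* **Thickness** is the distance between the two leaflet peaks of a
  headgroup profile, each refined by a 3-point parabola. Without the
  refinement 1 Å bins would quantize the answer; with it, planted 39/40 Å
  constructions are recovered to well under a bin.
* **Areas per lipid.** The general value is box x–y area divided by lipids
  per leaflet (mean of the two leaflet populations). Per-species values use
  grid tessellation: each cell of a regular grid (cell counts are the
  nearest integers giving ~1 Å spacing for the actual box — spacing, not
  cell count, is the physical parameter) is assigned to the nearest lipid
  reference particle in periodic x–y, ties to the lowest molecule id.
  Reference particles default to phosphate+glycerol beads for POPC and the
  amide headgroup beads for ceramide. Per-leaflet areas sum to the box area
  to machine precision, every frame — the tessellation identity the test
  suite checks alongside a brute-force nearest-cell oracle.
* **Lateral diffusion.** Headgroup tracks are unwrapped by accumulating
  minimum-image displacements between consecutive frames; `MSD(τ)` averages
  the squared x–y displacement over all molecules and all overlapping time
  origins. `MSD = 4Dτ + c` is fitted by ordinary least squares over lags
  between 10 % and 90 % of the maximum lag. Units: D is reported in
  10⁻⁷ cm²/s, numerically equal to Å²/ns (1 Å²/ns = 10⁻⁷ cm²/s exactly).
  At the test suite's problem size (400 walkers, 250 ns at 1 ns frames) a
  single realization of this estimator has a relative scatter of several
  percent, dominated by the long-lag part of the curve where few
  independent segments exist; recovery checks therefore average replicate
  fits rather than trusting one realization.
* **Leaflets and flip-flop.** A lipid is upper/lower when its headgroup is
  more than δ = 5 Å above/below the midplane, otherwise in the transition
  band. A flip-flop is a change of *stable* leaflet: residence of at least
  `dwell_ns` (default 50 ns) on both sides; excursions into the band that
  return do not count. The dwell and band half-width are configurable and
  recorded — the cited characterization does not fix them numerically, so
  the synthetic planted-event tests define correctness. The event rate is
  `n_events / trajectory length` with an SD over 5 equal time blocks;
  molecule-level counts (single versus double crossers) are retained.
* **Clustering** is single-linkage over headgroup centroids with a 5 Å
  periodic x–y radius; a cluster needs at least two lipids. **Hydrogen
  bonds** use the geometric 3.5 Å donor–acceptor / 30° H–D–A criterion on
  explicit-hydrogen input.

## Electrophysiology fits

All fits are Levenberg–Marquardt least squares with physically-motivated
parameterizations:

* **Activation**: `I/Imax = 1/(1 + exp[(V½ − Vm)/k])`; starts at the
  voltage whose response is nearest 0.5 and `k = 8 mV`. Shift-equivariance
  in voltage is a tested property. Non-convergence or a non-positive slope
  factor yields a flagged failure object, not an error.
* **Deactivation**: `I(t) = A·exp(−t/τ) + C` from the current peak onward,
  with `log τ` as the free parameter so τ stays positive. A bi-exponential
  option reports the amplitude-weighted τ and is never chosen silently.
* **Dose-response**: `I/Icon(C) = s + (1 − s)/(1 + (C/IC50)^h)` with
  `log IC50` free. The plateau-anchored form was chosen because the
  response at `C = IC50` is then `(1 + s)/2` — halfway between full current
  and the residual plateau — which reproduces the internal consistency
  between the wild-type reference parameters (IC50 22 µM, h 0.8, s 0.3)
  and a ~35 % tail-current reduction near 20 µM. Whether a published IC50
  means this midpoint or the absolute-half point is generally not stated;
  the midpoint convention is flagged to users. Concentration
  scale-equivariance is a tested property.

  With four concentrations a *free* plateau is not identifiable for
  low-affinity curves whose IC50 approaches the top of the sampled range;
  the noisy-recovery tests therefore fix the plateau at its known value
  (for the F656C-like row the published plateau is itself an extrapolated
  estimate, not a fitted asymptote). Noiseless refits keep all three
  parameters free.
* **Deltas and energies.** Gating deltas are control − treated per matched
  variant; pIC50 is computed in molar units. Binding free-energy pairs are
  compared as `ΔΔG = ΔG_closed − ΔG_open` with quadrature SD.

## Synthetic generators: what they emulate, and what they do not

The generators produce the statistical structure the analyses consume, with
exact ground truth, and nothing more. Lipids are kinematic stubs — no
forces, no excluded volume — because every analysis here is a function of
coordinates only.

**Membrane patches** default to the bicomponent 8:2 composition: 400 POPC +
100 ceramides in a 125 × 125 Å box, headgroup planes at ±19.5 Å (39 Å
bilayer), species diffusion constants 6.6 and 13.8 Å²/ns (the
coarse-grained values in 10⁻⁷ cm²/s), 5 µs at 10 ns frames. Scheduled
flip-flops are deterministic cosine crossings completing within 20 ns,
validated to be at least two dwell times apart — exact truth for event
counting, unlike rare-event sampling. A minimum ceramide headgroup
separation (6 Å, via move rejection; initial positions drawn from one
lattice shared across leaflets so the rule holds from frame 1) keeps
default patches free of 5 Å clusters, matching the no-cluster outcome of
the dispersed composition; diffusion studies disable it to get independent
walkers.

**Channel systems** place four chains of residues on a cylindrical lattice
with >10 Å between neighbours, so a lipid parked 4 Å outside its target
residue is inside the 6 Å cutoff of that residue only — the generator's
schedule is therefore frame-exact truth for both metrics, which the test
suite verifies to equality. Planted binders dwell 5 µs (about 60 % of the
8 µs analysis window) at their residue on every chain. Background lipids
alternate bulk sojourns (geometric, mean 800 ns) with visits of *fixed*
duration (80 ns = 1 % of the window, bounded by a 2 % cap) to uniformly
random residues. The fixed duration is deliberate: it hard-bounds the
background maximum-occupancy distribution, and because most residues
saturate the bound, Q3 equals it and the `Q3 + 1.5·IQR` threshold cannot be
crossed by background — planted-binder recovery with zero false positives
holds by construction. With any spread-out visit-length distribution the
boxplot rule would flag a fraction of a percent of background residues as a
matter of arithmetic, which is worth remembering when interpreting outlier
counts on real data.

**Ephys datasets** are the closed forms above plus Gaussian noise, seeded.

What the generators do *not* emulate: molecular packing and excluded
volume, realistic rotational/conformational dynamics, correlated lipid
motion, force-field energetics, curvature, undulations, or electrostatics.
Passing tests therefore demonstrate the correctness of the *analysis*
implementations under known truth — not that the analyses would extract
truth from data whose physics violates their assumptions (e.g. strongly
correlated diffusion would break the independent-walker error model of the
MSD fit).

## Numerical choices and degenerate inputs

* Orthorhombic boxes only; triclinic input is an explicit unsupported-format
  error. Molecules are wrapped whole (by their first particle) so
  intra-molecular distances never cross the boundary.
* Coordinates are Å, times ns internally; GRO I/O converts nm/ps at the
  boundary, writing at 0.001 nm precision. Chains survive the GRO round
  trip via segment-style residue names (`PROA`…`PROD`); bead roles via
  reserved atom names.
* Quartile-based selection warns and selects nothing on all-zero metrics;
  fits return flagged failure objects on non-decaying traces, monotonically
  increasing dose data, or non-positive slope factors at the optimum.
* Optimizer tolerances are 10⁻¹⁰; tighter settings make the wrap-up `nls`
  call fail on exact-fit (zero-residual) synthetic data.
* Tie-breaks: tessellation cells go to the lowest molecule id; histogram
  peak refinement falls back to the bin centre when the parabola
  degenerates.

## Problem sizes used by the test suite

The suite is sized for a single CPU: channel systems of 60 residues × 4
chains with ~60–110 lipids over 1000 frames (planted-binder sweeps across
k = 4…12 over 20 seeds), membrane patches of 500 lipids over 500 frames,
diffusion recoveries of 400 walkers × 250 frames averaged over 12 replicate
seeds per planted value, 100-case randomized oracle-equivalence loops per
kernel, and 200-replicate noise studies for the dose-response and
deactivation fitters.

## Known limitations

* XTC/TRR cannot be read (no installed reader); convert to DCD or
  multi-frame GRO/PDB first.
* Hydrogen-bond analysis expects explicit hydrogen/donor/acceptor indices
  rather than inferring them from element typing.
* The flip-flop dwell criterion is a convention; systems with genuinely
  fast interleaflet exchange near the dwell scale will be sensitive to it.
* Boxplot outlier selection on aggregated metrics is a screening rule, not
  a significance test; on real (heterogeneous) backgrounds some flagged
  residues are expected by arithmetic alone.
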