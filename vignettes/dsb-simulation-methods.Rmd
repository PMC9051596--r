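---
title: "Simulating early DSB induction from Lu-177 in planar cell cultures: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating early DSB induction from Lu-177 in planar cell cultures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(lutadsb)
```

## The problem

Targeted radionuclide therapy with Lu-177-DOTATATE irradiates cell cultures
from two pools of activity: radiopharmaceutical bound to the cells
(internalized into an organelle, or attached to the membrane) and unbound
activity in the culture medium. The biologically decisive quantity is not the
average absorbed dose to the dish but the energy that individual electron
tracks deposit inside individual nuclei, because that is what sets the yield
of DNA double-strand breaks (DSBs). `lutadsb` implements a two-step,
desk-scale Monte Carlo chain for this problem:

1. **Irradiation.** Electrons from Lu-177 decays (continuous beta spectrum
   plus discrete internal-conversion lines) are transported through a planar
   50-cell population sitting in a water cylinder; every particle crossing
   into the nucleus of the central cell is recorded in a phase space.
2. **Damage.** Phase-space particles are replayed through the nucleus;
   in-nucleus energy deposits are converted into strand breaks by a
   calibrated surrogate and clustered into DSBs by the opposite-strand
   < 10 bp rule, then normalized per source particle (SP), per Gbp and per
   Gy.

A combination formula links the two scales: with cumulated decays $n_M$
(medium) and $n_C$ (cells), reach probabilities $p_{M\to N}$, $p_{C\to N}$,
and per-SP yields per emission type,

$$N_{DSBs} = \big[(n_M\,p_{M\to N} + n_C\,p_{C\to N})\cdot N_{DSBs}/SP\big]_\beta
 + 0.15\,\big[(n_M\,p_{M\to N} + n_C\,p_{C\to N})\cdot N_{DSBs}/SP\big]_{IC},$$

with 1 beta and 0.15 conversion electrons per decay.

## Geometry model and its surrogates

Each cell has four nested water compartments (density 1 g/cm^3): membrane,
cytoplasm, Golgi, nucleus. The three measured morphologies
(`table1_morphology(1:3)`) carry printed compartment volumes, cytoplasm
bounding boxes, and nucleus half-dimensions; nuclei are exact parametric
solids (cell 1 an ellipsoid with half-axes 12, 8.5, 1.9 um; cells 2 and 3
elliptic cylinders), so their volumes are closed-form (811.79, 714.71,
1105.84 um^3).

The imaged polygonal meshes for cytoplasm and Golgi are not distributed, so
surrogates are used:

* **Cytoplasm**: an elliptic-cylinder solid with the bounding-box height and
  footprint aspect, scaled so that solid volume = cytoplasm + Golgi +
  nucleus. The cytoplasm *compartment* (solid minus the organelles, which is
  what activity sampling uses) then matches the measured volume exactly. A
  centered superellipsoid matched to both the printed bounding box and
  volume cannot contain the cell-2 nucleus (the measured cytoplasm fills
  only 17% of its box while the nucleus spans 71% of the box height), so the
  surrogate keeps the height and the volume and gives up the x/y box extent;
  lobed shapes can be supplied as ASCII OBJ/PLY meshes via
  `read_mesh_region()` instead.
* **Golgi**: a volume-matched ellipsoid of aspect 2:1:0.6 placed adjacent to
  the nucleus along +x with a configurable clearance (`golgi_gap`, default
  0.2 um). The imagery shows only that the Golgi hugs the nucleus; the gap
  is deliberately a free parameter.
* **Membrane**: a 7.5 nm radial shell over the cytoplasm surface. Its
  sampling and containment use the ray from the cell center (a constant-
  thickness shell to first order); at 7.5 nm against ~30 um cell dimensions
  the distinction from a true offset surface is immaterial.

Constructors verify the nesting invariants numerically and refuse degenerate
geometry. Populations are placed on a jittered rectangular grid whose pitch
is solved analytically so footprint coverage of the substrate equals the
confluence target (50% by default, always within the +/-5-point band);
jitter stays inside each grid tile, so placements are irregular yet provably
non-overlapping. The dish plane is z = 0, cells sit on it, and the medium is
a water cylinder of diameter = height = 1.76 mm (the maximum beta range)
centered on the scored cell.

## Source term

`lu177_default_scheme()` ships three beta branches (endpoints 177.0, 385.3,
498.3 keV) and six conversion-electron lines summing to ~0.147 per decay;
the table is a plain-text file and explicitly replaceable — transcribe your
preferred compilation if fidelity beyond a few percent matters. Beta
energies are drawn from the allowed-transition Fermi shape
$N(E) \propto F(Z{=}72, E)\, p\, E_{tot}\, (Q-E)^2$ with a point-charge
relativistic Fermi function and no screening; the sampled mean
(~139 keV) sits ~4% above the reference mean beta energy, adequate for every
contract here, and a fully tabulated spectrum can be supplied instead.
Photons and Auger electrons are excluded by design. Emission directions are
isotropic. Uptake is instant and permanent: 73% of in-cell decays in the
internalization compartment (Golgi or cytoplasm hypothesis), 27% on the
membrane, uniform within each compartment, sampled across all 50 cells
simultaneously.

Cumulated decays follow $n = A_0 (1 - e^{-\lambda t})/\lambda$ per pool over
the 4 h exposure. The split of 2.5 MBq/mL added activity between medium and
cell-bound pools comes from unpublished uptake assays, so
`uptake_per_cell` (default 0.04 Bq per cell per MBq/mL) and
`medium_fraction` (default 1) are labelled synthetic scenario inputs; every
downstream equation takes $n_M$, $n_C$ explicitly so nothing else depends on
them.

## Electron transport

Transport is class-II condensed history in water, written in C++ for speed
(`src/transport.cpp`), and deliberately simpler than track structure:

* continuous energy loss by inversion of the CSDA range built from an
  embedded ~29-point collision stopping-power table (log-log interpolated,
  refined 60x for the range integral). The table reproduces the printed
  anchors: 1.76 mm range at the 497.8 keV endpoint, ~236 um at the mean beta
  energy;
* explicit delta rays above 1.75 keV (the 0.2 um range cut in water) from a
  1/T^2 Moller tail, sharing the primary's event identifier;
* Gaussian restricted energy-loss straggling and Highland small-angle
  multiple scattering per step;
* steps capped at `min(10 um, 10% of residual range)` and refined to
  0.35 um near the scored nucleus so boundary crossings and in-nucleus
  deposit positions are resolved at sub-micron scale;
* tracking cutoff 100 eV; residual energy deposits locally; electrons
  leaving the medium cylinder escape.

Energy is conserved exactly per history (initial = deposits + escaped, to
1e-6 keV), and with scattering, straggling and deltas disabled the stepping
reduces to its own range integral — both are tested contracts. Every
outside-to-inside crossing of the central nucleus appends a phase-space
record (position on the boundary to 1e-3 um, direction, energy, particle
type, origin compartment, event id); re-entries create new records with the
same id. Phase spaces read/write as delimited text, losslessly to 6
significant digits.

Absolute agreement with condensed-history-free track-structure codes is
*not* claimed: the published headline numbers that depend on
cross-section-level physics (absolute reach probabilities of order printed
in the source study, mean specific energies per particle) are outside this
package's quantitative surface. What is preserved — and tested — is the
geometric and microdosimetric structure: ordering of sources, linearity,
conservation, and the calibrated damage scale described next.

## Microdosimetry

Per event (primary and its secondaries together), the specific energy is
$z = \varepsilon / m$ with $\varepsilon$ the in-nucleus energy imparted and
$m$ the water mass of the analytic nucleus volume. `z` distributions,
$\bar z$, and the identity mean dose $= \sum_i z_i$ are computed by
`specific_energy_distribution()` / `mean_absorbed_dose()`; reach
probabilities use distinct event ids over primaries with Wilson 95%
intervals. Summaries report $\bar z$ in both Gy and mGy: the printed
mean-specific-energy table in the source study is of order 1 "Gy" per
entering particle, which for an ~8e-13 kg nucleus would require several MeV
per electron — physically impossible for sub-500 keV electrons, so those
printed values are treated as mGy and excluded from quantitative acceptance.
This package's cell-source campaigns give $\bar z$ of ~0.6-0.9 mGy per
entering particle, and lower for medium sources, reproducing the reported
ordering (medium spectra shifted to lower energy deposits).

## DNA damage surrogate

The full physical/physicochemical/chemical simulation chain is collapsed
into a per-deposit stochastic model on a 6 Gbp genome spread uniformly over
the nucleus (G0/G1; no eu/heterochromatin split):

* every in-nucleus deposit of energy $E$ spawns damage sites with
  expectation `sb_per_keV * E / (1 + site_extra_mean)`, spread uniformly
  over the genomic span of the deposit's step (0.34 nm/bp packing);
* each site carries `1 + Poisson(site_extra_mean)` breaks within +/-3 bp,
  strands independent by default (`strand_corr = 0.5`);
* breaks are labelled direct (gated by the 17.5 eV direct-damage threshold
  on the parent deposit) or indirect (probability `indirect_fraction`,
  default 0.6, standing in for the 2.5 ns radical chemistry);
* DSBs are maximal clusters under the transitive closure of "opposite
  strands, separation strictly < 10 bp"; exactly 2 breaks = simple, >= 3 =
  complex. The clustering equals a brute-force pair-graph oracle on hundreds
  of random break sets, and the strict boundary (9 clusters, 10 does not) is
  pinned by test.

`sb_per_keV` is the one calibrated constant. `scripts/calibrate_sb_per_kev.R`
runs the full chain once at a probe value and scales it so the end-to-end
yield equals 2.65 DSB/(Gy Gbp), the centre of the 2.3-3.0 band reported for
this and comparable low-LET settings; the recorded value (0.0402) is the
package default, and a fresh-seed run must land inside the band — the
calibration is part of the stated model, not a tuning knob. `site_extra_mean`
defaults to 0.2 so the simple-DSB fraction sits in the 80-92% range expected
for low-LET radiation (~85% observed in the default chain). With these
choices the surrogate's DSB yield is linear in dose by construction
(per-event damage is independent), mirroring the exact linearity of the
published dose-DSB correlation; its SSB-to-DSB ratio is *not* calibrated and
should not be interpreted quantitatively.

## What the defaults produce

The shipped default scenario (cell-1 morphology, 50 cells at 50% confluence,
2.5 MBq/mL for 4 h, Golgi internalization, synthetic uptake defaults) gives,
at seed 3: beta and IC cell-source yields of 2.7 and 3.0 DSB/(Gy Gbp),
~13.6 DSBs per cell, and a dose-response slope of 0.0156 DSBs per cell per
mGy with $R^2 = 1$ — inside the published 7-24 DSBs/cell range and between
the published 0.014 and 0.017 slopes. The DSBs-per-cell figure inherits the
synthetic uptake conversion, so treat its agreement as consistency of
scales, not validation of the uptake model. The slope identity
(slope = per-Gy yield x 6/1000) is exact by construction and tested.

## Numerical choices and degenerate inputs

* Boundary convention: points on a surface belong to the inner compartment;
  containment, sampling and crossing tests share this convention.
* Rejection sampling raises an error below 1e-4 acceptance instead of
  spinning.
* Clustering is defined via transitive closure, so no order-dependent ties
  exist; permutation and translation invariance are property-tested.
* Empty distributions (no in-nucleus events) report `NA` means and are
  flagged, never silently zeroed; zero dose with nonzero DSBs flags the
  per-Gy yield as undefined.
* All randomness flows through R's RNG (including the C++ stepper via
  `unif_rand`), so a single `set.seed`/`seed =` argument reproduces any
  stage bit-for-bit; campaigns rerun under the same seed write
  byte-identical phase-space files.
* Integer bp coordinates are stored as doubles (6e9 exceeds 32-bit range).

## Known limitations

* Condensed-history physics: no interaction-by-interaction track structure,
  no sub-keV shell effects beyond the stopping-power table's approximate
  sub-keV rows; absolute reach probabilities and per-particle specific
  energies are structural, not reference-grade.
* The cytoplasm surrogate underfills the measured bounding box (no lobes);
  user meshes can replace it.
* No photons, no Auger electrons, no time-resolved uptake or dose-rate
  effects, no repair kinetics, no cell-cycle radiosensitivity distribution,
  no base damage or non-DSB clustered lesions — matching the stated scope of
  the modeled experiment; several of these are the natural next extensions.
* The medium-source reach probability at this geometry is ~1e-5 per decay,
  so medium campaigns need ~1e6 primaries for a resolved estimate; the
  acceptance script does exactly that.
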