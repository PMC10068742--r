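---
title: "Methods: from bilayer ensembles to partition coefficients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from bilayer ensembles to partition coefficients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scpart)
```

## The problem and the model

Solute partitioning between water and the stratum-corneum (SC) lipid
matrix is summarized by the coefficient K_lip.  In the simulation route
this package supports, an equilibrated lipid bilayer ensemble is reduced
to slice-wise structural inputs for a continuum-solvation engine, which
returns a free-energy profile ΔG(z) of the solute along the membrane
normal, referenced to bulk water.  `scpart` covers the two flanks of that
workflow — compiling the structural inputs, and turning ΔG(z) into
partition coefficients and benchmark statistics.  It does **not** run
molecular dynamics and does **not** compute ΔG(z): the profile is always
an input.

The z axis is divided into n equal slices of thickness h = box_z / n and
volume δV = h·A (A the lateral box area).  n is chosen so h is as close
as possible to a 0.1 nm target — thin enough that each slice can be
treated as homogeneous, the same "ca. 1 Å" convention used by continuum
membrane models.  Given the water occupancy fractions
x_w(z_i) = n_w(z_i)/n_w,tot and the profile ΔG(z_i), the extensive
mol/mol coefficient is the Boltzmann integral

K = Σ_i V(z_i) e^(−ΔG(z_i)/RT) / Σ_i V(z_i) x_w(z_i) e^(−ΔG(z_i)/RT),

which uses the *full* profile (not just the minimum) and therefore stays
finite and positive even for strongly hydrophilic solutes whose
free-energy minimum lies in the water phase.  With uniform slice volumes
the δV cancels in K, and the intensive form follows by normalizing the
amount in the whole system per mass of lipid against the amount per
volume of water:

K_lip [L/kg] = K · δV[L] / m_lip[kg],  m_lip = n_lip · M_lip / N_A,

with δV converted at 1 nm³ = 10⁻²⁴ L and M_lip the count-weighted mean
lipid molecular weight, so n_lip·M_lip is the exact total lipid mass.
Both equal-volume requirements are enforced: the grid constructor only
produces uniform slices, and the profile reader rejects non-uniform z
spacing (tolerance: 1 % of the mean spacing).

## Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| target slice thickness | 0.1 | nm | "ca. 1 Å" slicing convention; n = round(box_z/0.1) |
| temperature | 303.15 | K | skin-relevant simulation temperature; R = 8.314462618×10⁻³ kJ/(mol·K) |
| SASA probe radius | 0.14 | nm | conventional water-probe radius (the `gmx sasa` default) |
| SASA lattice points | 960 | – | <1 % discretization error on 10-atom clusters (tested); 3840 used for analytic validation |
| log K_ow exclusion | > 5.0 strict | log units | measured K_lip of extremely lipophilic solutes depends on sample lipid content |
| reduced-set cut | < 1.0 strict | log units | retained set is log K_ow ≥ 1; isolates the hydrophilic underprediction regime |

Logarithms are base 10 throughout; ΔG is kJ/mol.

## Numerical conventions

* **Binning** is half-open [z_lo, z_hi) on fractional coordinates after
  periodic wrapping into [0, box_z); an atom exactly at box_z lands in
  slice 1.  Fluctuating NPT boxes are handled by binning each frame in
  fractional z on the fixed n-slice grid; δV uses the time-averaged box.
  The grid refuses an ensemble whose mean box_z disagrees by more than
  1 %.
* **Water location** is the oxygen position (first O atom of the
  molecule), not the centre of mass — cheap, stable, and the common
  density-tool convention.
* **Bilayer centre** is the mass-density-weighted *circular* mean of z,
  so leaflets split across the periodic boundary are handled correctly.
* **Symmetrization** shifts by whole slices only (no sub-slice
  interpolation, so normalization is conserved exactly, not just
  approximately), then averages slice i with slice n+1−i.  For even n the
  reflection point is the box midplane between the two central slices;
  for odd n the middle slice is its own mirror.  Symmetrizing an
  already-centred profile is a fixed point.
* **Boltzmann sums** factor out the maximum exponent before
  exponentiating; profiles anywhere in [−500, +500] kJ/mol neither
  overflow nor underflow (tested), and agreement with the naive unshifted
  sum is at 10⁻¹² relative for moderate profiles.
* **SASA** uses a deterministic Fibonacci spiral lattice rather than
  random points, so results are exactly reproducible without a seed.  A
  lattice point is buried when strictly inside another inflated sphere;
  coincident centres therefore bury the smaller sphere completely rather
  than erroring.  Occlusion context is the whole frame *excluding* water:
  SASA measures accessibility to the solvent, so the solvent must not
  occlude.  Periodic images are not considered (fixture molecules are
  kept away from the boundary; see limitations).
* **Conformer selection** is argmin |SASA − mean| with ties broken by the
  earliest (frame, molecule) pair in iteration order; exported
  coordinates are translated to the conformer centroid.
* **Through-origin fit**: β = Σxy/Σx² with x = log K_ow, y = log K_lip.
  The fit has no intercept because the relationship is reported in the
  field as a bare proportionality.  The Pearson R is computed on (x, y)
  directly — deliberately fit-independent, so it measures the linear
  association, not the quality of the constrained fit.  The fit RMSE is
  the root mean squared through-origin residual; whether published fit
  RMSEs are exactly this variant or an orthogonal one is not always
  stated, which is a known comparison caveat.
* **Quadrant analysis** assigns pairs with either residual exactly zero
  to no quadrant (reported as `on_axis`) so the sign-agreement fraction
  is well defined.

## What the synthetic generators emulate — and what they do not

`generate_bilayer_fixture` builds bead-chain lipids (one heavier polar
head bead, 5–14 tail beads of 60 u at 0.22 nm spacing) with per-type
molecular weights matched to the real SC lipids (CER2 650.0, CER3 652.0,
LIGN 368.6, CHOL 386.7 g/mol) so that composition bookkeeping and the
L/kg conversion operate on realistic masses.  Three geometries are
generated:

* `single_bilayer` — head planes at centre ± 2.2 nm, tails inward, two
  outer water slabs; the HPm2/HPm3 presets carry 150 lipids (1:1:1) and
  4500 waters (fully hydrated, 30 per lipid);
* `stacked_trilayer` — three stacked bilayers with water only outside the
  stack (anhydrous inner leaflets), the HPm2t preset;
* `amorphous` — randomly oriented chains in a lipid slab joined to a
  water slab (biphasic), the Amor preset with 9346 waters.

The long-periodicity-phase geometry is *not* generated: it originates
from an imported literature structure, and the stacked fixture already
exercises the multi-leaflet code path.  Frames differ by iid Gaussian
positional noise (default σ = 0.03 nm, a small fraction of a slice, so
leaflet structure survives time averaging while densities still spread
over neighbouring slices).  Default boxes (e.g. 7.2 × 7.2 × 10 nm for a
single bilayer) are chosen so the lipids fit at ≥ 0.55 nm lateral spacing
and the water slabs have realistic room; the generator errors rather than
squeezing molecules into an undersized box.

What a green test on these fixtures establishes: binning, normalization,
symmetrization, composition bookkeeping, SASA occlusion logic, format
round-trips, and the integration arithmetic are correct.  What it does
**not** establish: any claim about real CHARMM-grade physics — chain
packing, hydrogen bonding, realistic density amplitudes, or the accuracy
of any particular ΔG(z).  Likewise `generate_solute_table` plants a known
slope (default β = 0.74), noise (σ = 0.46 log units), and strata (2
records above log K_ow = 5, 16 below 1, in a 64-record table) so the
dataset filters and fits can be verified by parameter recovery — those
defaults describe the statistical structure of the compiled experimental
SC database, but the synthetic records are not those measurements, and no
test asserts the experimental fit itself.

## Design choices made where the design was open

* **Layer-table dialect.**  The downstream engine's proprietary layer
  file layout is not published, so the package defines an open,
  self-describing TSV dialect (header with grid, temperature, frame count
  and molecule catalog; one row per slice) and claims no byte
  compatibility.  Densities are stored *per atom slot* — finer than
  per-type aggregation, which is recoverable as a sum.
* **Water profile from the layer table.**  The water type's first atom
  slot carries a normalized density, which is exactly x_w; file-based
  prediction therefore needs no second input.
* **Element handling at the format boundary.**  GRO carries no element
  field; elements are inferred from atom names, masses and Bondi radii
  from a built-in element table, both overridable per molecule type via a
  reference ensemble or a radii file (vdW radii for SASA are a known
  convention choice, so they are user-adjustable).
* **Bead "elements".**  Generated beads are labelled O (heads, water) and
  C (tails) with explicit masses/radii; readers reattach those via the
  `reference` argument since text formats cannot carry them.

## Limitations

* No binary trajectory formats (XTC/TRR/DCD) and no topology parsing;
  ensembles come from (concatenated) GRO or multi-model PDB text.
* SASA ignores periodic images; molecules crossing the box boundary would
  see an artificial interface.  Fixture geometries avoid this; real
  whole-bilayer SASA should be run on whole molecules.
* The Lee–Richards slicing algorithm and per-residue decompositions are
  out of scope; only Shrake–Rupley totals and per-atom areas are
  provided.
* The mol/mol → L/kg conversion presumes uniform slice volumes; grids
  with varying δV are rejected rather than approximated.
* Experimental reference data (solute tables with measured log K_lip and
  log K_ow) must be supplied by the user; the package ships none.
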