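---
title: "Scoring protein surface electrostatic changes: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring protein surface electrostatic changes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A missense variant swaps one amino acid for another. When the swapped residue
is charged, or repacks its neighbourhood, the electrostatic character of the
protein *surface* can change in ways that matter for binding partners,
substrates, and membranes — yet are invisible to sequence-level scores.
`surfdelta` quantifies such changes: it builds a molecular surface for the
wild-type and the variant structure, attaches an electrostatic potential to
every surface vertex, restricts attention to the surface patch around the
mutated site, and asks whether the two per-vertex potential distributions
differ, reporting a median potential shift in units of $k_BT/e_c$ together
with resampling-based p-values.

The comparison runs at two spatial scopes (whole surface vs. local patch) and
two levels of structural detail (a single static structure vs. a pooled
conformational ensemble, e.g. frames from a molecular-dynamics trajectory).

## The statistical model

Let $\Phi_{WT}$ and $\Phi_{V}$ be the multisets of per-vertex surface
potentials for wild-type and variant over the same nominal region. Each
resampling iteration draws $n_{points}$ values (default 100) from each side
and computes three two-sample tests:

* **Welch's t** — sensitive to mean differences only;
* **Kolmogorov–Smirnov (KS)** — the maximum difference between empirical
  cumulative distributions;
* **two-sample Anderson–Darling (AD)** — a tail-weighted ECDF discrepancy
  (the Scholz–Stephens $A^2_{akN}$ k-sample statistic in its midrank form,
  standardized as $T = (A^2 - (k-1))/\sigma_N$).

The procedure repeats for $n_{iter}$ iterations (default 1000) and aggregates
per-iteration p-values by their **median** (default). Fixing the per-draw
size is the point of the resampling design: a finer surface mesh or more
trajectory frames yields more vertices, and without subsampling any
difference could be made arbitrarily "significant" simply by measuring the
same surface at more points. The median of per-iteration p-values is
calibrated under the null (in fact conservative, since iterations reuse the
same underlying samples) and stable in $n_{iter}$.

A **Fisher combination** aggregation ($-2\sum\log p_i$ against
$\chi^2_{2n_{iter}}$) is available because single extreme p-values cannot be
reached by a median; it is reported with an explicit caveat that resampling
iterations are not independent, making the combination anti-conservative.
Reports always state which rule produced the headline p-value.

The effect size is `median_shift` = median(variant) − median(WT), computed on
the **full** samples, never on resamples. Significance uses a strict
`p < alpha` threshold with `alpha = 0.01` by default. No multiple-testing
correction is applied across variants; reports carry a note saying so.

The AD test's p-value comes from the published asymptotic interpolation of
the standardized statistic (five levels from 0.25 to 0.01, adjusted for
$m = k - 1$), interpolated monotonically on the logit scale. Outside the
tabulated range the logit/log-linear tangent is extrapolated and the result
flagged `extrapolated` — never floored or capped, because silent clipping
would mask exactly the strongest surface changes the method is after. On a
10-point pooled sample the extrapolated p agrees with the exhaustive
252-reassignment permutation p to within 0.03–0.05, and the standardized
statistic matches an independent implementation to nine decimal places (see
the test suite).

## The molecular surface

The solvent-excluded surface (SES) is the boundary of the set of points
farther than the probe radius from solvent: equivalently, the inward offset,
by the probe radius $p$, of the solvent-accessible surface (SAS, the boundary
of the union of atom spheres inflated by $p$). `compute_ses()` realises this
on a regular grid:

1. sample the exact signed SAS field $\min_i(|x - a_i| - r_i - p)$ at every
   grid node — its zero set is exactly the SAS;
2. extract the SAS by **marching tetrahedra** on the Freudenthal/Kuhn 6-tet
   decomposition of each cube (translation-invariant, hence watertight, with
   no ambiguous cases and no case tables);
3. form the erosion field $\phi(x) = p - d(x, \text{SAS})$, with the distance
   evaluated against the extracted SAS vertex cloud by local splatting;
4. extract the SES as the zero level set of $\phi$, again by marching
   tetrahedra, welding vertices on shared grid edges so that closedness and
   Euler-characteristic checks are exact integer properties of the mesh.

Using surface *samples* for the erosion distance, rather than a binary
voxel-image distance transform, removes the $O(h)$ bias of voxel erosion:
contact patches are recovered to $O(h^2)$ and the single-atom SES area is
within 1.3% of the analytic sphere at the default-comparable 0.3 Å spacing
(4% at 0.6 Å, converging under refinement). Interior cavities appear as
separate closed components and are retained in whole-surface ("global")
scores — the conservative choice, since a cavity surface is still protein
surface.

Each vertex is assigned to the residue of its nearest atom, with "nearest"
measured as centre distance minus atom radius (so the atom that generated
that patch of surface owns it) and ties broken by the lower atom serial for
determinism.

**Parameters.** `grid_spacing` defaults to 0.5 Å — comparable to common
molecular-surface grid tools and fine enough that region vertex counts are
stable; 0.3 Å is used where sub-percent area accuracy matters.
`probe_radius` defaults to 1.4 Å (a water-sized probe); 0 gives the van der
Waals surface. A configurable `voxel_budget` (default $10^8$ nodes) turns
runaway grids into an actionable error suggesting coarser spacing.

## The electrostatic potential

Two sources, selected by `electrostatics_config()`:

* **Screened Coulomb (Debye–Hückel)**, the built-in model:
  $$\phi(r) = \frac{C(T)}{\varepsilon_r}\sum_i \frac{q_i\,e^{-\kappa |r - r_i|}}{|r - r_i|},
  \qquad C(T) = \frac{e_c^2}{4\pi\varepsilon_0 k_B T} \approx 557.0\ \text{Å}
  \ \text{at } 300\,\text{K},$$
  in $k_BT/e_c$ per elementary charge, with the Debye parameter
  $\kappa = \sqrt{2 e_c^2 N_A \cdot 10^3 I/(\varepsilon_0\varepsilon_r k_B T)}$
  from the ionic strength $I$ (mol/L). Defaults: $\varepsilon_r = 78.5$,
  $I = 0.150$ M (Debye length ≈ 7.9 Å), $T = 300$ K — conventional aqueous
  values, echoed in every report. This model deliberately has **no
  low-dielectric solute cavity**: it keeps the package self-contained and
  exactly testable against closed forms and brute-force sums.
* **Imported OpenDX grids** (`read_dx_grid()` + `map_grid_to_mesh()`), for
  users who want full Poisson–Boltzmann physics from APBS: per-vertex values
  come from trilinear interpolation of the 8 surrounding nodes (exact on
  affine fields; self-consistent with the direct model to < 0.1% median
  relative error at 0.25 Å spacing). Grid values are assumed to be in
  $k_BT/e_c$, APBS's default output unit.

## The local region

The region of interest is the set of residues whose minimum pairwise
atom-centre distance to any atom of the mutated residue is ≤ 4 Å (inclusive
boundary), plus the site itself. Design choices where the procedure was
genuinely open:

* **Distances between atom centres**, not surface-to-surface — the simplest
  reading of "minimum pairwise distance". Hydrogens count when present
  (excludable by flag), since their presence is a property of the input
  preparation, not of the method.
* **WT ∪ mutant union** (`consensus_region()`): the residue set is the union
  of the WT-derived and mutant-derived neighbourhoods, so both potential
  samples describe the same nominal patch even when a mutant side chain
  reaches farther, or the site is deleted entirely.
* **Cross-chain neighbours included** by default: surfaces are physical
  objects; a residue across a dimer interface is part of the local surface
  regardless of chain bookkeeping.
* **For ensembles, the region is fixed from frame 1** of the wild-type
  ensemble, keeping the region's identity stable over the dynamics; per-frame
  recomputation is available behind a flag for users who want the region to
  track conformational change.

A fully buried region (no surface vertices) is an explicit error rather than
an empty result — burial is a real, reportable biological outcome, not a
degenerate case to silently skip.

## Ensembles

Multi-model PDB files become `ensemble` objects; per-atom charges and radii
are joined from a companion PQR by (chain, residue number, atom name) and
held fixed across frames — standard fixed-charge force-field semantics
(conformations change geometry, not charge). Frames are superposed onto a
reference (Cα atoms by default) with a Kabsch fit whose rotation is always
proper (determinant +1, reflection case handled by sign correction), and the
production tail of a trajectory is selected as the final quarter
(`ceiling(0.25 N)` frames) by default. Per-frame region potentials are pooled
across conformers, tagged by source frame; per-frame vertex counts are *not*
equalized before pooling, because the resampler's fixed per-draw size already
prevents frame-count inflation. A single-frame ensemble reproduces the static
pipeline bit for bit — the static mode *is* the 1-frame special case. How
many frames to extract from the production tail has no principled default;
the frame stride is a configuration knob.

## What the synthetic generator emulates — and what it does not

`make_toy_protein()` lays 10–60 residues (3 atoms each) along a helical curve
or a Fibonacci sphere with per-residue charges; `make_mutant()` perturbs only
the site residue (charge, radius, sub-Å jitter); `make_wobble_ensemble()`
adds seeded Gaussian displacements around frame 1; `sample_potential_pair()`
draws potential-like value pairs with controlled location shifts and shape
changes (normal, heavy-tailed, bimodal). Everything is deterministic under
its seed.

These fixtures exercise every pipeline contract — surface closedness, region
geometry, charge bookkeeping, pooling, statistical calibration and power — at
desk scale (seconds per case). They are **not** physically realistic
proteins: no backbone chemistry, no force field, no solvent structure, no
correlated conformational modes. Passing tests therefore demonstrate that the
machinery measures what it claims to measure on inputs with known ground
truth; they do not validate biological conclusions about any particular
protein. For real systems the quality of the answer inherits the quality of
the input structures, their protonation/charge assignment, and (for dynamic
mode) the sampling of the trajectory. The bimodal fixture applies its shape
change as a mean- and median-preserving mode-separation change rather than a
mode-weight change: a weight change moves the mean and would hand the t-test
the very signal the fixture exists to deny it.

## Numerical choices and degenerate inputs

* Grid fields with exact zeros are nudged by $10^{-9}h$ so the iso-surface
  never passes through grid nodes (no degenerate faces).
* Two identical constant samples give p = 1 for every test by convention; a
  zero-variance pair with different means gives t = ±∞, p = 0.
* p-values below $10^{-300}$ are serialized as the string `"<1e-300"`, never
  the float 0.
* Aggregated p-values under index resampling are positionally seeded: the
  median shift negates exactly under argument swap, while aggregated
  p-values agree up to resampling noise (per-iteration draws differ between
  orders). The underlying tests themselves are exactly exchange-symmetric.
* Evaluation points closer than $10^{-6}$ Å to an atom centre are an error
  naming the point.
* PQR parsing accepts both whitespace-delimited (the APBS convention) and
  fixed-column dialects, detected per line, because real PQR files are
  inconsistent; parse failures cite the line number.
* All residue identifiers in reports are author-assigned numbers (the
  numbering used in variant names like D306Y), never sequential indices.

## Problem sizes used by the tests and the acceptance script

Calibration uses 500 seeded runs of the full resampling procedure (1000
iterations each) on 5000-point null samples; power uses 100 seeded runs per
shift (1.0 and 0.41 $k_BT/e_c$, the latter being the scale of subtle local
static effects the method is designed to resolve); the robustness contrast
uses 100 runs of 400-point bimodal pairs. Geometry and electrostatics oracles
run on single atoms and 3–40-residue toys at 0.25–0.6 Å spacing; the
end-to-end pipeline checks use a 14-residue toy with a −2e charge-flip
mutant. These sizes make the whole suite reproducible on one CPU in a few
minutes while leaving every statistical conclusion comfortably clear of its
threshold.

## Known limitations

* The built-in electrostatics is a screened-Coulomb model with a single
  solvent dielectric; systems where the low-dielectric protein interior or
  membrane slabs dominate the surface potential should import APBS grids.
* The marching-tetrahedra surface slightly over-triangulates compared to
  classic marching cubes (more, smaller triangles for the same grid); area
  and topology are unaffected.
* Aggregated median-p values cannot go below the per-iteration floor of the
  AD interpolation's extrapolation; genuinely astronomical significance
  (p ≈ 10⁻³⁰⁰) is only reachable through the Fisher aggregation, with the
  stated caveat.
* Shape-based (non-electrostatic) surface descriptors are out of scope.
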