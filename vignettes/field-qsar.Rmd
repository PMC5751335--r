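---
title: "Molecular-field QSAR with qsar3d: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Molecular-field QSAR with qsar3d}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qsar3d)
```

## The model

qsar3d implements the classical grid-based 3D-QSAR workflow for series of
rigid, superposable analogues. Its assumptions are those of the method
itself: the compounds act through a common binding mode, a rigid-core
superposition is a meaningful proxy for that mode, and the biological
response varies smoothly with the molecular property fields sampled around
the aligned set. Structures are consumed as prepared 3D conformers —
conformational search and force-field minimisation are deliberately out of
scope.

Activity enters as the elongation `E` (mm) of a growth bioassay,
transformed to `pE = log10(100 * E / Emax)` with `Emax` the dataset
maximum, so the most active compound sits at exactly pE = 2 and differences
between compounds are independent of the `Emax` choice.

Two field families are sampled on a shared cubic lattice enclosing all
aligned molecules:

* **CoMFA.** Steric: Lennard-Jones 6–12 probe energy with
  Lorentz–Berthelot-style combination over the shipped per-element table
  (minimum-energy distance = atom radius + probe radius, well depth =
  geometric mean). Electrostatic: Coulomb energy
  `332.17 q q_probe / (eps(r) r)` in kcal/mol with the distance-dependent
  dielectric `eps(r) = r` by default. Both are truncated at ±30 kcal/mol;
  at lattice points where the steric term reaches the cutoff (probe inside
  the molecule) the electrostatic value is treated as missing and replaced
  by the column mean across molecules.
* **CoMSIA.** Gaussian similarity indices
  `-sum_i w_probe w_i exp(-alpha r_i^2)` with atomic weights: van der Waals
  radius cubed (steric), partial charge (electrostatic), atomic
  hydrophobicity (hydrophobic) and 0/1 donor/acceptor flags. The Gaussian
  decay removes the need for cutoffs and makes the fields smooth
  everywhere.

Partial charges come from an in-package Gasteiger PEOE implementation
(iterative partial equalisation of orbital electronegativities, six damped
iterations); the electronegativity parameters and all per-element atom
parameters are shipped as documented plain-text tables so field values are
bit-reproducible and the tables are swappable.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| grid spacing | 2.0 | Å | lattice resolution; the conventional setting of the motivating study |
| grid margin | 4.0 | Å | box padding around the union bounding box |
| probe charge / radius | +1 / 1.52 | e / Å | sp³-carbon-like probe |
| energy cutoff | 30 | kcal/mol | CoMFA truncation |
| column filter | 2.0 | kcal/mol | drop CoMFA columns with max−min variation below this |
| CoMSIA column filter | 0 | – | similarity indices live on another scale; only constant columns are dropped |
| attenuation `alpha` | 0.3 | Å⁻² | CoMSIA Gaussian width |
| max components | 20 | – | cap on the LOO component search |
| split ratio | 8:2 | – | random train/test split when no explicit test ids are given |

`run_pipeline()` refuses configs that drift from the canonical field
settings unless `allow_nonstandard = TRUE`, so a run cannot silently use a
non-standard grid.

## PLS, cross-validation and model search

The regression core is NIPALS PLS1 on mean-centred data. Columns are not
autoscaled (the field-QSAR convention: within a block, the energy scale is
meaningful); instead each field block is divided by the standard deviation
of its centred entries ("block scaling") so that blocks of different
physical units contribute comparably. Fit statistics follow the standard
conventions: `SEE = sqrt(RSS/(n−N−1))` and
`F = (r²/N)/((1−r²)/(n−N−1))`.

Leave-one-out cross-validation defines
`q² = 1 − PRESS/Σ(y−ȳ)²` and `SEP = sqrt(PRESS/(n−N−1))`. Two routes are
provided: a naive refit loop, and a fast covariance-based path that runs
PLS entirely in sample (Gram-matrix) space, deflating the held-out
cross-kernel row alongside. The two are algebraically identical; the test
suite enforces agreement to 1e-8 on random problems, and the naive path is
retained as the oracle. The number of components is the `N ≤ 20`
maximising q², with exact ties resolved toward the smaller N.

`enumerate_field_models()` fits one model per non-empty subset of the
available fields (3 CoMFA, 31 CoMSIA combinations) and tabulates q², N,
SEP, SEE, r²ncv, F and per-field contributions, where the contribution of
a field is the sum over its columns of |coefficient| × column standard
deviation, normalised across fields.

## External validation

`predictive_r2()` implements `r²pred = (SD − PRESS)/SD` with SD measured
against the training-set mean. `tropsha_battery()` computes the squared
Pearson correlation r², the through-origin slopes in both orientations
(`k`: predicted on observed; `k'`: observed on predicted), the
corresponding through-origin determination coefficients `r0²` and `r0'²`,
and `rm² = r²(1 − sqrt(r² − r0'²))`.

Two conventions required a decision:

* The literature formula for rm² is sometimes printed with the square root
  typographically collapsed; the standard form above is implemented — it
  reproduces the published rm² values from the packaged prediction tables,
  confirming the reading.
* Which orientation the primed quantities denote is under-documented in
  the field. The package fixes "primed = observed regressed on predicted
  through the origin", the orientation that reproduces the published k′
  and r′0² columns, and always reports both orientations so nothing is
  hidden by the convention.

Criteria flags follow the usual thresholds (q² > 0.5, r² > 0.6,
(r² − r0²)/r² < 0.1 in at least one orientation, 0.85 ≤ k ≤ 1.15 in at
least one orientation, rm² > 0.5).

## Contour maps

For a fitted model, the importance of grid point j in field b is
`beta_j × s_j` (pE units) mapped back onto the lattice, with filtered
columns contributing zero. The published "% contribution" contouring
convention is not fully specified anywhere, so the package fixes and
documents a cumulative-mass rule: the favourable level is the threshold
such that cells at or above it carry `(100 − favored_pct)%` of the total
positive importance mass (top 20% of mass at the default
`favored_pct = 80`), mirrored on the negative side with `disfavored_pct`.
The percentages are free parameters; recovery of planted causal sites —
not visual matching of published figures — is the accepted evidence that
the rule behaves sensibly. Grids export as Gaussian cube or OpenDX text
files plus a JSON manifest.

## The synthetic generator

Real brassinosteroid 3D structures are not deposited, so the generator
stands in for them. It emulates exactly what the method consumes: a set of
rigidly alignable analogues sharing a point-atom scaffold (12 carbon-like
atoms), differing at three well-separated decoration sites whose
substituent fragments vary in charge, bulk, hydrophobicity and H-bond
character, with activity

```
pE = base + sum_s w_s * prop_s + N(0, noise_sd)
```

Defaults: 30 molecules, one causal electrostatic site with weight −1 pE
per unit charge (electron-rich substituents raise activity — the direction
seen for polyhydroxylated steroid growth promoters), `noise_sd = 0.05` pE,
baseline 1.3 pE (mid-range of the motivating datasets). Atom parameters
are hand-assigned, bypassing charge perception, so field/PLS tests do not
depend on the charge scheme; a second, fully bonded demo mode
(`demo_polyol_set()`) exercises the Gasteiger path.

What the toys deliberately do **not** emulate: conformational flexibility,
realistic intramolecular charge distributions, correlated substituent
effects, or assay error structure. Passing recovery tests therefore shows
that the pipeline's machinery is correct and sensitive at realistic signal
levels — not that the method would succeed on any particular real series.

## Numerical choices and degenerate inputs

* Distances below 1e-6 Å are clamped before LJ/Coulomb evaluation; the
  truncation bound then applies.
* Columns are stored in a fixed raster order (x fastest, then y, then z)
  so column indices are portable across runs.
* Superposition uses the SVD (Kabsch) solution with det = +1 enforced —
  reflections are forbidden because the target molecules are chiral; cores
  with fewer than 3 atoms or collinear geometry are rejected.
* Zero-variance responses, rank-exceeding component counts, empty
  molecule sets and unparameterised elements raise immediate errors rather
  than propagating NaN.
* Component-selection ties go to the smaller N (first maximum).
* All-NA electrostatic columns (every molecule excluded at that point)
  become 0 and are then removed as constant by filtering.

## Problem sizes

The test suite and recovery studies run on deliberately compact problems:
30-molecule synthetic sets on lattices of roughly 500 points (about 2,400
CoMSIA columns), LOO at up to 6 components, 25-seed recovery batteries and
50-seed component-selection simulations. These sizes were chosen as the
smallest at which the statistical claims under test are stable; real
studies simply scale the same code to denser grids and larger series.

## Known limitations

* Gasteiger PEOE here covers the common organic elements and sigma
  charges only; pi-system refinement is not implemented, and charges for
  exotic elements require extending the shipped table.
* The rigid-core alignment cannot rescue series without a genuinely
  common scaffold; no field-based or flexible alignment is provided.
* LOO is the only built-in cross-validation scheme, matching the
  motivating protocol; k-fold schemes would need to be added by the user.
* Printed model-search statistics of the motivating study (its Tables of
  q²/SEP/SEE/F per field combination) are not numerically reproducible
  without the original structures, charges and alignment; the package's
  property-based battery substitutes for them by construction.
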