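---
title: "Methods: a rigid-body ligament-strain model of the canine sacroiliac joint"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a rigid-body ligament-strain model of the canine sacroiliac joint}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sijstrain)
```

## Scope and design

`sijstrain` re-expresses a CT-derived finite-element workflow for canine
sacroiliac joint (SIJ) ligament strain as a self-contained, desk-scale
simulator. The original workflow segmented a patient CT volume, meshed the
bones, inserted nonlinear springs for the ligaments, and solved a
deformable finite-element problem; the patient data are confidential and
the GUI toolchain is not reproducible in code. This package keeps the
mechanical content — the constitutive laws, the spring topologies, the
load battery, the strain averaging and the repeatability statistics — and
replaces the patient-specific stages with parametric synthetic geometry
and, for the segmentation-like stage, a voxel phantom.

Two deliberate simplifications define the model class:

* **Rigid bones.** Bone Young's modulus (17 GPa) exceeds the ligament
  stiffness scale (~10^2 N/mm over ~10 mm elements) by many orders of
  magnitude, so ligament strain is dominated by rigid-body motion of the
  sacrum and first caudal vertebra (C1). Bones are therefore rigid; the
  isotropic bone elasticity (with its derived bulk and shear moduli) is
  retained in the `materials` layer as part of the material contract but
  enters no force balance. A consequence: fixing the hemipelves at the
  acetabula fixes them everywhere, so the hemipelves are a fixed
  environment.
* **Static, muscle-free loading.** Only dead in-plane forces at a sacral
  load point are applied, matching the eight-scenario battery; muscles,
  gravity and dynamics are out of scope.

## Geometry

The canonical landmark set is a synthetic, exactly mirror-symmetric
configuration loosely sized to a 25 kg Labrador retriever. Coordinates are
in mm with the origin midway between the acetabula; x is lateral (right
positive), y dorsal, z cranial (right-handed). These axes are a documented
package convention — the source workflow never fixes its axes — and the
scenario forces map x to lateral and y to dorsal. All dimensions scale as
`scale * (body_mass / 25)^(1/3)`. The specific default distances
(inter-acetabular span 60 mm, sacral attachment sheets spanning z = 15–45 mm,
ischiatic tuberosities at (±28, −5, −55), sacrocaudal interface of 180 mm²
at 3 mm thickness) are synthetic defaults, not measured values; no
published coordinates exist for any attachment point, so placement is
synthetic by necessity.

Each sheet ligament (dorsal and ventral sacroiliac) uses 4 sacral and 4
ilial points joined by 10 springs: the 4 parallels plus the 6 one-step
diagonals. This is the unique crisscross reading consistent with a count
of ten; a full bipartite connection would give 16. The SIJ itself is 10
parallel springs per side across the joint gap, and the sacrotuberous
ligament is 2 springs per side in a "Y" sharing the tuberosity insertion
(origins on S3 and C1). Total: 64 springs, with rest lengths taken from
the reference geometry so the reference configuration is exactly
stress-free.

## Constitutive laws

**Ligaments.** Tensile stiffness is piecewise constant in strain
(39/55/103/100 N/mm with breakpoints at 2.5%, 5% and 10%) and zero in
compression. Two details are package decisions: bands are half-open and
closed on the left (a strain of exactly 0.10 maps to 100 N/mm), making the
lookup total and deterministic; and the published non-monotonicity
(103 then 100) is kept as printed. Stiffness has units of force per unit
*elongation* indexed by strain, so force is the closed-form integral of
stiffness over elongation — continuous, piecewise linear — and energy is
the corresponding C^1 piecewise quadratic. The tests verify force against
numeric quadrature of the stiffness and energy derivatives against the
force by finite differences.

**Sacrocaudal joint.** The tangent modulus is `E(ε) = 20.71 ε + 234 ε²`
MPa in compression and zero in tension, with stress the exact
antiderivative `σ(ε) = 10.355 ε² + 78 ε³`. As printed (for ε < 0) the
modulus would be negative at small compression, contradicting the stated
increasing-stiffness behaviour, so ε is interpreted throughout as the
*compressive strain magnitude*; the printed coefficients are preserved
exactly. The joint element is a single compression-only nonlinear bar:
force = σ(ε)·area along the line between the two interface points, with
ε = (rest thickness − gap)/rest thickness. Area and thickness are
synthetic configuration values (the source joint volume was drawn
manually and its dimensions are unstated).

**Mooney–Rivlin fit.** The three-parameter incompressible model
`W = c10 (I1 − 3) + c01 (I2 − 3) + c11 (I1 − 3)(I2 − 3)` is linear in its
coefficients, so the fit to the joint stress curve is a closed-form
weighted linear least-squares problem (weights 1/σ, i.e. relative
residuals) — deterministic by construction. The stress measure and strain
mapping for the fit were genuinely open choices; we measured the
achievable accuracy of each standard convention over compressive strain
magnitudes [0.01, 0.30] (60 uniform samples):

| convention | best achievable max rel. error |
|---|---|
| engineering strain (λ = 1 − ε), nominal stress | ~6% (even minimax) |
| engineering strain, true stress | ~5% |
| logarithmic strain (λ = exp(−ε)), true stress | **1.3% (plain weighted LS)** |

The logarithmic-strain / true-stress convention is therefore the package
default for `fit_mooney_rivlin()`; `mr_uniaxial_stress()` exposes both the
nominal and true measures. The recorded `max_rel_error` is checked against
the 2% residual bound in the tests. The equilibrium solver uses the
polynomial joint law directly; the fit is reported alongside it as the
hyperelastic formulation equivalent.

## Equilibrium solver

Static equilibrium of the two free bodies is posed as minimization of
total potential energy over a 12-vector pose (translation in mm and
rotation vector in radians per body): spring energies + SIJ compression
penalty + joint energy + grounding regularization − load work. Energy
minimization was preferred over force Newton iteration because the
piecewise laws make the energy C^1 but the forces only piecewise smooth;
a quasi-Newton search is robust to stiffness-band crossings. The
implementation runs BFGS with the analytic gradient (exact rotation
derivatives via the Rodrigues map), then polishes with damped Newton steps
on a finite-difference Hessian of that gradient until the gradient 2-norm
is at or below the tolerance (default 1e-6 N), typically reaching ~1e-9.
An independent force-summation oracle (not the gradient code path)
verifies per-body force and moment balance below 1e-6 N (N·mm) in the
tests.

Numerical choices worth noting:

* **SIJ compression penalty** (default on, 1e3 N/mm): the SIJ springs are
  tension-only, but in the source model bone contact resists compression;
  a linear compression-only penalty across each SIJ spring pair prevents
  interpenetration. This is a disclosed deviation from a pure spring
  reading.
* **Grounding regularization**: a tiny isotropic spring (1e-6 N/mm
  translational, 1e-4 N·mm/rad rotational) on each free body removes the
  rigid-body indeterminacy that arises when all tension-only elements go
  slack (C1 is otherwise held only by two tension springs and a
  compression-only joint). A warning is emitted if the regularization
  stores more than 1e-6 of the elastic energy at convergence.
* **Guards**: rotations beyond 0.5 rad or translations beyond 50 mm abort
  with a mechanism error — displacements under the N-scale loads against
  N/mm-scale stiffness should stay in the small-rotation regime, so such
  drift indicates an unconstrained mechanism, not a valid solution.
* Loads are dead (direction-fixed) forces; the source does not state
  follower vs dead loading.

## Scenario battery and strain grid

The battery is the fixed table of eight in-plane loads: (0, ±200),
(±200, 0) and the four diagonals at ±141.4 N per component. 141.4 is
stored exactly as printed (200·cos 45° rounded to one decimal), keeping
the table bit-exact. Per-spring strains from each equilibrium are averaged
(plain arithmetic mean) within each ligament group and side. The grid
keeps the three named ligament groups — dorsal sacroiliac, sacrotuberous,
ventral sacroiliac (10, 2 and 10 springs per cell) — because those are the
groups the repeatability analysis reports; SIJ spring strains are computed
and exported but excluded by default (`include_sij = TRUE` restores them
as a fourth, exploratory group).

## Repeatability study

Each trial emulates one manual model-building session: every spring
attachment landmark is displaced by i.i.d. zero-mean Gaussian noise
(default sd 0.25 mm per axis — a plausible hand-placement scatter for
~0.6 mm CT voxels; configurable), the model is rebuilt with rest lengths
from the trial's own geometry, and the full battery is solved. With five
trials, each of the 48 cells is regressed on trial index by closed-form
OLS (slope, t-based 95% CI, two-sided p with n − 2 df), and the
repeatable fraction is the share of cells failing to reject the zero-slope
null at α = 0.05. No multiple-testing correction is applied, matching the
exploratory design. Two degenerate cases never arise in noisy data but do
in a deterministic reimplementation and get explicit conventions: a
constant series (zero variance) has an undefined t statistic and is
declared repeatable; an exact nonzero-slope line (zero residual variance)
is treated as p = 0, not repeatable. Both are flagged in the output. The
published 47/48 outcome depends on unreleased per-trial data and is not a
reproduction target; the package instead reports the stochastic
repeatable fraction under its own seeded noise model (45/48 at sd 0.25 mm,
seed 42, in the README example).

## Lesion-count statistics

Cohorts are one row per dog with work status (Breeder/Detection/Other),
sex, neuter status, age group, and counts for seven CT lesion categories
per joint side. The synthetic generator draws independent Poisson counts
(small non-negative integers; per-side mean = half the per-dog total mean)
with defaults equal to the published group summary means, and assigns
covariates by the cohort's defining conventions (Breeders are intact
females). The one-way ANOVA is the textbook between/within decomposition
(the all-equal-means edge case returns F = 0, p = 1); Fisher's protected
LSD runs pooled-variance pairwise t-tests only when the omnibus p-value
passes the protection threshold, default 0.10 — the threshold under which
the source treated an omnibus result as evidence in its exploratory
setting — and reports two-sided p-values (the source's halved "/2"
notation is not emulated). The factorial analysis uses Type III sums of
squares via full-vs-reduced model comparisons under sum-to-zero contrasts
(approximating the common GUI-statistics workflow; Type II is available),
drops single-level factors as inestimable, and reports aliased columns
from empty design cells instead of failing — with Breeders all female,
the work-status × sex interaction is structurally aliased in realistic
cohorts.

## Synthetic CT phantom

The phantom exercises a segmentation-like stage without DICOM data: one
simple box solid per bone (sacrum, both hemipelves, C1) sized from that
bone's landmarks, voxelized on a 226-slice grid (default spacing
0.8 × 0.8 × 0.625 mm), plus a unique-intensity fiducial voxel per landmark
in place of manual tracing. Box faces are snapped inward to voxel
boundaries, which keeps neighbouring bones separated by at least one
background voxel (the sacrum–ilium corridor is only 4 mm wide) and makes
each solid's analytic volume exactly representable on the grid — the
threshold-segmentation round trip (6-connected components, labels mapped
to bones through the solid centers) then recovers the analytic volumes
exactly and every landmark to within one voxel. Volumes and label maps
export to NIfTI; bone surfaces export to binary STL as voxel-boundary
iso-surfaces. The phantom emulates slice count, spacing, thresholding and
fiducial recovery; it does not emulate attenuation physics, noise, partial
volume effects or realistic bone shapes, so passing round-trip tests says
nothing about segmenting real CT data.

## What the synthetic conditions do and do not show

Passing tests demonstrate internal correctness: constitutive laws as
published, equilibria that balance forces and moments, exact symmetry
properties, calibrated statistics. They do not validate the model against
real canine tissue (the source itself borrowed human tissue properties
and performed no cadaveric validation), nor do they reproduce numbers
that depend on the confidential per-dog and per-trial data (the specific
slope/CI/p table, the 47/48 fraction, the cohort p-values).

## Problem sizes and determinism

The default study sizes are the source's own: 8 scenarios, 5 trials, 48
regressions, a 22-dog cohort (6/10/6). Statistical calibration checks use
2,000-replicate simulations. Every stochastic step (operator noise, trial
seeds, cohorts) is driven by explicit integer seeds, and equilibrium
solves are deterministic, so whole studies reproduce bitwise from a
configuration and its seeds.
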