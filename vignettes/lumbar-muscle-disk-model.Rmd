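---
title: "A coupled muscle / intervertebral-disk model of the lower lumbar spine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A coupled muscle / intervertebral-disk model of the lower lumbar spine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinewell)
```

## What the package models

`spinewell` is a desk-scale, quasi-static simulator of the functional
interaction between the major back muscles and the intervertebral disks
(IVDs) of the lower lumbar spine (L3--S1).  Its scientific question is
mechanistic: stretch-activated muscle produces force whenever its
fascicles are strained, and the IVDs change length on physiological
time scales as they exchange fluid with their surroundings (overnight
swelling, daytime creep).  The two therefore form a feedback loop: disk
swelling strains the muscles and pre-activates them; muscle force loads
the disks and alters their fluid exchange.  The package couples

* an **active, transversely isotropic, hyperelastic muscle law** of the
  Hill type, in which activation is driven by stretch rather than by a
  prescribed neural input,
* a **46-fascicle muscle network** (multifidus MF, erector spinae
  components LTpL, LTpTh, ILpL, and psoas PS) on a synthetic lordotic
  L3--S1 geometry,
* a **distributed body-weight loading** procedure that converts a
  body-segment inertia table into three eccentric vertical loads, and
* a **one-dimensional osmo-poroelastic disk column** (cartilage
  endplate -- nucleus pulposus -- cartilage endplate) with
  strain-dependent permeability,

inside a sagittal-plane quasi-static equilibrium solver with three
rigid mobile vertebrae (L3, L4, L5; S1 fixed).  Everything is in
N--mm--MPa--s units.

The package is a deliberate *reduction* of a full 3D finite-element
musculoskeletal model.  Reduced, its absolute force and pressure
magnitudes are indicative only; its quantitative surface is the
overnight swelling pressure rise of the disk column and the battery of
direction and ordering checks exercised by the test suite.

## The muscle constitutive model

The muscle is a fiber-reinforced composite whose strain energy
decouples into an isotropic matrix part and a fiber part,

$$U = \frac{G}{2}(\bar I_1 - 3) + \frac{K}{2}(\ln J)^2
  + \sigma_0 \int_1^{\bar\lambda_f} f_{PE}(\lambda)\,d\lambda
  + \sigma_0 \int_1^{\bar\lambda_f} f_{SE}(\lambda, \zeta)\,d\lambda ,$$

with $J = \det\mathbf F$, $\bar I_1 = J^{-2/3}\,\mathrm{tr}\,\mathbf C$,
and the deviatoric fiber stretch
$\bar\lambda_f = J^{-1/3}\lambda = \sqrt{\mathbf N^\top \bar{\mathbf C}\mathbf N}$
($\lambda$ is the fiber stretch, $\mathbf N$ the undeformed fiber
direction).  The passive fiber branch is quadratic and tension-only,
$f_{PE} = A(\bar\lambda_f - 1)^2$ for $\bar\lambda_f > 1$; the active
branch is exponential,
$f_{SE} = 0.1\{\exp[100(\bar\lambda_f - 1 - \zeta)] - 1\}$ for
$\bar\lambda_f > 1 + \zeta$, zero otherwise.  Both fiber integrals have
elementary antiderivatives and are evaluated in closed form; numerical
quadrature survives only as a test oracle.

The **contractile strain** $\zeta$ replaces an explicit activation
input: $\zeta = C_{CE1}\,\varepsilon$ for shortening
($\varepsilon < 0$, concentric) and $\zeta = C_{CE2}\,\varepsilon$ for
lengthening (eccentric), where $\varepsilon = (L - L_0)/L_0$ is the
engineering strain of the whole fascicle.  The active parameter is a
sarcomere-length ratio, $C_{CE} = L^S / 2.8\,\mu m$; the shipped
concentric/eccentric pairs per muscle group keep the group-to-group
ratios of the sarcomere-derived values constant (the test suite asserts
a coefficient of variation below 0.1%).  Because $\zeta$ is recomputed
from the current $\varepsilon$ at every solver step, the contraction
velocity enters only through the history of $\varepsilon$; no explicit
force--velocity curve is used, and no separate tendon compartment is
modeled.

Stress is obtained by exact differentiation of the energy,
$\mathbf S = 2\,\partial U/\partial\mathbf C$, giving an isochoric
Neo-Hookean matrix term, a volumetric term $K \ln J\, \mathbf C^{-1}$,
and a fiber term proportional to
$U_F' = \sigma_0(f_{PE} + f_{SE})$; the Cauchy stress is the
push-forward $\boldsymbol\sigma = J^{-1}\mathbf F \mathbf S \mathbf F^\top$.
We derive the stress from the energy rather than transcribing published
tensor formulas; a central-finite-difference oracle
($\mathbf S$ vs $2\,\partial U/\partial \mathbf C$ over 100 random
states, relative tolerance $10^{-6}$) and a frame-indifference check
arbitrate correctness.

### Parameters

| parameter | value | units | meaning |
|---|---|---|---|
| $G$ | $16.42\times10^{-4}$ | MPa | matrix shear modulus |
| $K$ | $1000\,G = 1.642$ | MPa | matrix bulk modulus (near-incompressible) |
| $\sigma_0$ | 0.46 | MPa | maximum tetanic stress, one value for all groups |
| $A$ | 4.0 | -- | passive fiber constant |
| $C_{CE1}/C_{CE2}$ | per group | -- | concentric / eccentric active parameters |

All defaults live in `inst/extdata/muscle_materials.csv` and are
traceable through `parameter_provenance()`.

### The uniaxial element contract

Fascicles are straight unidirectional elements.  Two reductions of the
3D law to a one-dimensional element are implemented in
`fascicle_axial_force()`:

* **laterally free** (isochoric, $J = 1$): the matrix contributes the
  incompressible Neo-Hookean uniaxial stress $G(\lambda^2 -
  1/\lambda)$.  This is the textbook reduction, but with the shipped
  $G$ of order $10^{-3}$ MPa it makes fascicles essentially
  force-free in compression, and because every $C_{CE1} < 1$ the
  concentric activation condition $\bar\lambda_f > 1 + \zeta$ can never
  be met while shortening.
* **laterally confined** ($\mathbf F = \mathrm{diag}(1, 1, \lambda)$,
  $J = \lambda$): the volumetric matrix term participates, the element
  gains a compressive stiffness of order $K$, and since
  $\bar\lambda_f - 1 \approx \tfrac23\varepsilon$ the concentric branch
  activates for shortening whenever $C_{CE1} > 2/3$ (all groups).

The coupled simulator uses the **confined** contract.  The choice is
forced by the physiology the model is meant to reproduce: in relaxed
standing the dorsal fascicles shorten slightly and transfer a few
newtons of *compressive* force to the vertebrae, with the volumetric
matrix stress dominating the active stress in the psoas -- behavior
that only the confined element exhibits.  The free contract remains the
default of the standalone `fascicle_axial_force()` API and is fully
tested; switch with `spine_model(lateral = "free")`.

## Fascicle anatomy

The published topology of the network is fixed: 23 sagittally symmetric
pairs (8 MF, 3 LTpL, 2 ILpL, 4 LTpTh, 6 PS per side), 13 local pairs
attached only to lumbar vertebrae and 10 global pairs reaching the
thoracic rod or the femur, 46 elements in total.  Exact insertion
coordinates are not part of that published description, so
`lumbar_geometry()` synthesizes them from per-vertebra landmark offsets
(spinous process, lamina, transverse process, anterolateral vertebral
body) on a configurable lordotic chain; the network is therefore
explicit, reproducible, and swappable for subject-specific data.  The
L5/S1 wedge angle is proportional to the L4/L5 wedge through a config
ratio (default 1.4), since only the proportionality is anatomically
standardized.  ILpTh is omitted, consistent with its negligible lumbar
contribution.  Equivalent cross-sectional areas (volume / length) are
shipped as plausible defaults in the config and enter every force
computation through the config only.

The **thoracic rod** -- a rigid stand-in for the dorsal third rib, the
common rostral insertion of the LTpTh fascicles -- sits on the vertical
axis through L3, 250 mm above it, and is kinematically slaved to the
axial translation of L3, preserving their axial alignment in every
posture.  A useful consequence: the rod-to-L3 fascicles carry no strain
in any axial motion, and indeed they stay mechanically quiet in all
scenarios, as expected for thoracic elements in an L3--S1 model.  The
femoral node (common PS insertion) and all sacral/iliac nodes are fixed.

## Distributed gravity loads

Standing is loaded with three eccentric vertical forces derived from a
body-segment table (head, C1--C7, T1--T12, L1--L5: body-mass
percentages, sagittal moments of inertia, center-of-mass
eccentricities).  Masses are scaled from the percentages
($m_i = \mathrm{BM}_i \cdot M/100$); for a 70.8 kg subject this yields
239.6 N lumped at L3/L4, 18.06 N at L4/L5 and 18.06 N at L5/S1 -- 275.7 N
in total, about 40% of body weight.  The historically published
per-segment masses of the L4/L5 rows are inconsistent with the
percentages (an apparent decimal error) and are kept only for
provenance; the percentages are authoritative because they reproduce
the published loads.

The lumped load acts at the **effective eccentricity**
$R_\mathrm{eff} = \sum m_i r_i / \sum m_i$ over head--L3.  The
eccentricity profile $r_i$ itself is not published; the shipped profile
has a plausible anthropometric shape and its overall scale is
calibrated once so that the default $R_\mathrm{eff}$ is 41.4 mm (the
calibration is labeled in the fixture).  The Huygens--Steiner helpers
(`steiner_inertia()`, `effective_inertia_L3()`) reproduce the
transferred-inertia bookkeeping of the source table: fourteen
transferred terms (T1..L2) plus a local term; head and cervical rows
contribute weight but not transferred inertia, their axis distances
being negligible.

## The disk column

Each IVD is reduced to an axial biphasic column: a nucleus pulposus
core (default 8 mm) between two cartilage endplates (0.8 mm each),
effective area 1800 mm^2, at least 5 (default 7) nodes per layer.  The
solid skeleton is linear poroelastic in confined compression (aggregate
modulus $H_A = K + 4G/3$); the fluid is intrinsically incompressible
and flows by Darcy's law down the gradient of $p - \pi$, where $\pi$ is
a fixed osmotic pressure field: $\Delta\pi$ (default 0.15 MPa) across
the NP, ramping to zero across each endplate, zero at the drained outer
boundaries.  At zero load the column therefore swells until $p = \pi$;
the intradiscal pressure (IDP) reported at the NP mid-node is this
total fluid pressure, so the overnight equilibrium approaches
$\Delta\pi$ from below and the 8-hour rise lands near 0.14 MPa -- inside
the 0.10--0.24 MPa window measured in vivo overnight.

Permeability is strain dependent through the void ratio
$e = e_0 + (1 + e_0)\,\varepsilon$:

$$k = k_0\left[\frac{e(1+e_0)}{e_0(1+e)}\right]^2
      \exp\!\left[M\!\left(\frac{1+e}{1+e_0} - 1\right)\right].$$

The published form of this law is typographically ambiguous in its
source; we adopt the normalization that the name "initial permeability"
for $k_0$ forces, $k(e_0) = k_0$ exactly (asserted in the tests).
Tissue defaults (AF, NP, CEP) ship in
`inst/extdata/disk_materials.csv`; the AF row is unused by the default
NP--CEP column but available for an annulus variant.

### Numerics

Space: linear finite elements, equal-order displacement/pressure.
Time: backward Euler with adaptive step (growth 1.2, capped at 600 s in
the scenarios) and a per-step fixed-point update of the permeability,
iterated to a residual of $10^{-10}$ on the coupled system.  Three
numerical behaviors are worth knowing:

* **Stable step range.** With equal-order elements and intrinsically
  incompressible constituents, steps far below $h^2/c_v$ (with $h$ the
  element size and $c_v = k H_A$) produce spurious pressure
  oscillations near drained boundaries; the scenario steps (1--600 s)
  sit comfortably inside the stable range, and the undrained limit is
  probed at $dt \approx 1$ s, where the NP-center response to a step
  load recovers $F/A$ to 1%.
* **Early swelling dip.** In the first minutes of free swelling, the
  NP-center pressure of the default mesh dips slightly negative before
  rising: the steep swelling front at the stiff CEP/NP interface is
  narrower than one NP element.  The dip shrinks from $-0.036$ to
  $-0.0002$ MPa when the mesh is refined from 7 to 25 nodes per layer
  while the 8-h value moves by only $5\times10^{-5}$ MPa; the
  acceptance quantity is insensitive to it.  Refining the default mesh
  further was not worth the cost in the coupled runs.
* **Verification.** The solver's primary verification is agreement
  with the closed-form consolidation series (uniform column, constant
  permeability, step load) to better than 1% space-time L2 error at 31
  nodes per layer; mesh halving changes the 8-h NP pressure by < 1%,
  and doubling $\Delta\pi$ doubles the rise in the linear regime to
  within 5%.

## The coupled scenario engine

Sagittal-plane quasi-statics: 3 DOF per free vertebra
(anteroposterior, axial, rotation), Newton-solved each step with a
finite-difference Jacobian to a relative residual of $10^{-8}$; the
disk columns advance one backward-Euler increment *inside* the solve
(staggered coupling), loaded by the relative axial displacement of the
adjacent bodies.  Ligaments and facets are lumped into per-level
rotational and shear springs.

Two lumped choices deserve emphasis:

* **Rotational stiffness (5e7 N mm/rad per level) is a calibration,
  not a prediction.**  The full osteoligamentous complex it replaces
  keeps relaxed-standing rotations very small; a physiological
  *segment* stiffness in this slot would let the eccentric gravity
  moment flex the segment by several degrees, stretch the dorsal
  fascicles, and reverse the muscle effects the model exists to study.
  The default keeps standing rotations near 0.03 degrees; rotations
  are part of the recorded state (`result$q`), so the calibration is
  visible, and the spring constants are ordinary config parameters.
* **Scenario semantics of the osmotic field.**  The osmotic gradient
  is the *driver of the lying scenario*: `run_night_rest()` and
  rest-then-standing run with it active, while standing alone starts
  from a disk in Darcy equilibrium with its surroundings
  (`pi_scale = 0`), i.e. from a day-state disk with no net swelling
  tendency.

Scenario problem sizes: the 60-s standing ramp uses 30 steps; 8-h rest
uses adaptive steps from 1 s to 600 s (about 80 steps).  A full
rest-then-standing run takes a few tens of seconds on one core.

### What the scenarios reproduce

With all defaults the engine reproduces, as *directions and orderings*:

* overnight swelling stretches every fascicle (the rod-slaved LTpTh at
  L3 stays exactly neutral) and activates cranial multifidus more than
  caudal (cumulative swelling from L5/S1 to L3/L4);
* prior rest raises the standing IDP at every level by far more than
  the 34% lower bound (the default model gives ~74--85%), with
  rest-then-standing IDPs (0.28--0.31 MPa) close to in-vivo standing
  measurements;
* including the muscles *lowers* the standing IDP (without prior
  rest): the slightly shortened, concentrically activated fascicles act
  as posterior struts that bypass part of the body weight directly to
  the pelvis.  In the reduced model the effect is a fraction of a
  percent -- well inside the reported "up to 9%" bound but much smaller,
  because only 60 s of consolidation settlement strains the struts;
* without prior rest the largest per-level resultant (vector sum of
  the forces of the fascicles attached to each vertebra) occurs at
  L3/L4.

One reported ordering is *not* reproduced: with prior rest the maximum
per-level attached resultant should move to L5/S1, but the reduced
model keeps it at L3/L4.  The cause is structural.  With three
identical disk columns, every scenario produces fascicle strains
proportional to the cumulative swelling/settlement above each level, a
pattern that always peaks in the L3-attached fascicles; the caudal
shift observed in the full 3D model arises from kinematic
redistribution (pre-activated cranial muscles restricting the forward
rotation of L3, unloading that level by more than half), which a
planar model with locked rotations cannot express.  The transmitted
force crossing each disk plane (also recorded, `level_cross`) *does*
peak at L5/S1 after rest, consistent with the caudal accumulation of
tension.  The corresponding acceptance expectation is left failing
rather than redefined.

## What the synthetic data do and do not show

The geometry generator produces an anatomically plausible, sagittally
symmetric, lordotic L3--S1 chain.  It preserves the published counts,
groupings, scopes and the straight-line-of-action abstraction, but its
insertion coordinates, CSAs and the eccentricity profile of the gravity
loads are synthetic (two of them deliberately calibrated: the
eccentricity scale to 41.4 mm, the rotational stiffness to small
standing rotations).  Passing tests therefore demonstrate the internal
consistency of the constitutive laws, the solvers and the couplings,
and the robustness of the direction/ordering results to the documented
parameter ranges -- not subject-specific predictive accuracy.  Absolute
fascicle forces and IDPs inherit the reduction's simplifications:
planar kinematics, 1D disks without annulus fiber reinforcement, no
facet contact, no muscle viscoelasticity (excluded deliberately; at the
very low strain rates of overnight swelling the active forces dominate
the deviatoric passive ones), no wrapping or inter-fascicle contact.

## Reproducing the headline numbers

`scripts/acceptance.R` recomputes, from a fresh model: the 8-h swelling
rise of the default column (t5), the minimum per-level percentage
increase of standing IDP due to prior rest (t6), and the maximum
per-level percentage reduction of standing IDP due to muscle inclusion
(t7), and writes them as JSON.  All three are deterministic; the
`--seed` argument exists for interface uniformity and seeds the few
randomized test utilities only.
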