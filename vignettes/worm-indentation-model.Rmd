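---
title: "A three-compartment finite-element model of nematode indentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A three-compartment finite-element model of nematode indentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(nemaindent)
```

## The model

`nemaindent` simulates the indentation of an adult *C. elegans* by a
spherical AFM probe and inverts those simulations to assign Young's moduli
to three tissue compartments. The body is idealized as a straight cylinder
of concentric compartments: a pseudocoelom core (diameter 26.3 µm), a
muscle annulus (width 1.0 µm) and an outer annulus merging hypodermis
(0.1 µm) and cuticle (0.6 µm), which are too thin to parameterize
separately. The interface radii are therefore 13.15, 14.15 and 14.85 µm.
Each compartment carries one isotropic, nearly incompressible neo-Hookean
material,

$$W = C_{10}\,(\bar I_1 - 3) + \tfrac{1}{D_1}(J-1)^2,
\qquad C_{10} = \mu/2,\quad D_1 = 2/\kappa,$$

the decoupled form that is the default of the large commercial solvers, so
that engineering constants map one-to-one onto $(C_{10}, D_1)$ via
$\mu = E/(2(1+\nu))$ and $\kappa = E/(3(1-2\nu))$. Tissue
incompressibility is imposed in the *near*-incompressible sense with
$\nu = 0.49$ by default (configurable to 0.499): exact incompressibility
with displacement elements locks, and the chosen element technology
handles 0.49–0.499 robustly (verified by the test that the indentation
force moves by under 5% between the two values).

The probe is the 10 µm glass bead of the AFM cantilever, modelled as an
analytic rigid sphere (radius 5 µm) descending onto the top generator of
the cylinder at mid-length; the animal rests on a rigid frictionless plane
(the agarose bed). Contact on both surfaces is node-to-analytic-surface
penalty contact. Loading is displacement-controlled sphere descent; the
indenter force is read from the contact reactions, and a run terminates
when the reaction reaches the 450 nN AFM set force (the terminal point is
interpolated to the set force exactly) or at a prescribed depth.
Indentation depth is defined as sphere descent after first touch — the
quantity the instrument reports after its own processing — and the
cantilever-compliance correction belongs to the data-processing pipeline,
not to the simulator.

## Discretization and solver

The mesh is a structured all-hex O-grid: a square core, radial transition
layers graded so the thinnest layer sits under the contact, then one
structured ring per annular compartment, extruded axially with grading
towards the contact plane. Two mirror symmetries (the axial-vertical plane
through the contact point and the transverse-vertical plane at mid-length)
reduce the model to a quarter at identical solution. Circumferential
spacing clusters at the top (contact) and bottom (support) generators.
At the default refinement (level 1) the minimum element edge in the
contact zone is below 0.4 µm, the resolution at which the indenter force
at fixed depth changes by less than 2% under further refinement (the
convergence test compares levels 1 and 2 at 300 nm). Level 0 is a coarse
variant used inside calibration searches; level 2 exists for convergence
checks.

Elements are 8-node trilinear hexahedra with 2×2×2 Gauss quadrature for
the deviatoric term and one-point (centroid) integration of the
volumetric term — selective reduced integration, the mean-dilatation
remedy for volumetric locking of linear hexes. The formulation is total
Lagrangian with the exact consistent tangent of the element internal
force (finite-difference verified to 10⁻⁵ relative). Equilibrium is found
by full Newton iteration with load-step cutback on failure; the default
convergence criterion is a residual norm below 10⁻⁸ relative to the
larger of the external force scale and the step's initial out-of-balance.
The solver contains no randomness: repeated runs are bit-identical.

Newton systems are solved by sparse supernodal Cholesky. Because the
default contact linearization keeps only the normal-direction dyad
$k\,\mathbf n\mathbf n^\top$ (positive semidefinite), the assembled
tangent is almost always definite; the surface-curvature term of the
exact linearization — a percent-level perturbation at the shallow
penetrations the penalty permits, but indefinite — is available via
`contact_contribution(curvature = TRUE)` and is finite-difference
verified in the tests. When a factorization is still indefinite the
solver falls back to a simplicial LDLᵀ and, as a last resort, to a
Tikhonov-damped direction.

The penalty is pressure-like, `penalty_factor × max(E) / h_contact`,
converted to a nodal stiffness through each surface node's tributary
area. The default factor of 50 was fixed by the penalty-convergence
property: doubling it moves the force at a fixed 300 nm indentation by
well under 1%, while penetrations stay in the low-nanometre range.

## Choices where the design was open

* **Cylinder length.** 90 µm (about three outer diameters), so end
  effects at the central contact are negligible.
* **Support.** A rigid frictionless plane under the full length. A
  clamped bottom line is a plausible alternative; the plane was chosen as
  the closer analogue of an animal resting on agarose.
* **Load stepping.** Descent increments of 50 nm by default with
  automatic cutback and regrowth; hyperelastic statics are
  path-independent, and halving the step changes the terminal force by
  under 0.1%.
* **Contact-point rule.** Processing detects contact as the first sample
  exceeding 5 baseline standard deviations for 10 consecutive samples,
  then refines by scanning candidate contact positions with a
  one-parameter 3/2-power fit; the refinement removes the late bias of
  pure thresholding at realistic noise.
* **Hertz fitting.** $F = \tfrac43 \frac{E}{1-\nu^2}\sqrt R\,
  \delta^{3/2}$ is linear in $E$, so the least-squares fit is closed
  form. The assumed $\nu$ is 0.5, consistent with the incompressibility
  assumption; the fit range defaults to the entire processed curve.
* **Misfit and optimizer.** Calibration minimizes the RMS force error on
  the target's displacement grid (monotone-spline interpolation of the
  simulated curve keeps load-step sampling out of the misfit), using
  Nelder–Mead in log₁₀-modulus space through a logistic bound transform,
  default bounds 10–10⁴ kPa per compartment and a budget of 150 forward
  evaluations. This replaces a manual trial-and-error search with a
  reproducible one.

## Interpreting the Hertz benchmark

The Hertz law describes the *local* contact between a rigid sphere and an
elastic half space. Two real features of the modelled geometry make the
simulated force at equal sphere *descent* fall below it: the substrate
curvature (a sphere on a 14.85 µm cylinder has a smaller effective
contact radius than on a flat, roughly a −7% force effect) and the
compression of the whole body between indenter and support (the axis
centerline under the probe translates downward by a few percent of the
descent). Neither is an error of the mechanics; both vanish as the body
grows. The analytic benchmark therefore runs the homogeneous model on a
thick cylinder (120 µm diameter, large against the ~1 µm contact radius,
with the standard thin surface layers retained so the contact-scale
strain field stays resolved) and compares the force against the closed
form at the *local* indentation — descent minus the centerline
displacement at the contact cross-section — where the two agree within a
few percent. The worm-sized geometry's deviation at equal descent is the
expected geometric effect, and it is why an effective "overall modulus"
from a Hertz fit of a worm curve sits below the true tissue moduli.

## What the synthetic fixtures emulate — and what they do not

`make_raw_curve()` builds raw AFM records with the acquisition features
that the processing chain must undo: a flat pre-contact baseline with
Gaussian force noise, an optional constant offset and linear drift, a
contact point, a post-contact rise from either the closed-form Hertz law
or an FE forward solve, and cantilever compliance coupling piezo position
to tip–sample displacement (`piezo = δ + F/k`, default k = 7.5 N/m,
sampled at 1 nm). Every fixture carries machine-readable ground truth, so
tests assert recovery exactly, and identical seeds give bit-identical
curves. Real AFM records additionally contain adhesion on retraction,
viscoelastic rate dependence, piezo hysteresis and non-Gaussian noise;
none of these are modelled, so passing tests demonstrate correctness of
the processing and inversion logic, not robustness to every artefact of
real data.

Scenario presets carry the calibrated per-condition modulus triples
(BDM mean 150/1200/840; BDM salt-control 105/390/880; high salt
90/650/76; aldicarb 140/950/94 kPa) with the 450 nN set force.

## Identifiability

The indenter force is far more sensitive to the pseudocoelom modulus than
to the muscle modulus (a +10% perturbation of each, compared at the
working depth, differs by about a factor two in force response), which
matches the physical picture: with all compartments nearly
incompressible, surface deformation is transmitted to the core, and the
thin muscle annulus contributes comparatively little. In consequence the
muscle modulus is weakly identified — compensating combinations of
(cuticle, muscle, pseudocoelom) fit a noisy curve essentially equally
well — and the recovery test bounds only the cuticle and pseudocoelom
moduli (10% at 2% multiplicative noise on a densely sampled target) while
reporting the muscle error. Sparse targets (a dozen points) make the
degeneracy markedly worse; `calibration_sensitivity()` quantifies it at
any fitted point.

## Problem sizes used by the tests

The test-suite forward solves run on the level-0 mesh (about 1 200
elements); the analytic-contact benchmark and the convergence check use
levels 1–2 (about 4 200 and 13 000 elements), and the acceptance script
reports all headline quantities from the level-1 mesh. The calibration
recovery experiment searches on level 0 with an 80-evaluation budget,
about the point where the optimizer's best-so-far trace flattens.

## Known limitations

* One observed discrepancy with the source experiments is documented in
  the test suite: softening the muscle and stiffening the pseudocoelom
  (150/900/1400 kPa) produces a curve that our model makes marginally
  stiffer, not softer, at shallow depth (it is markedly stiffer at depth,
  and fits the reference curve strictly worse, as expected). The shallow
  branch plausibly depends on support and end-constraint details for
  which no published values exist.
* The idealized cylinder uses the anatomical compartment widths; the
  resulting outer diameter (~29.7 µm) is below typical measured adult
  widths (~54–56 µm). The discrepancy is inherited from the compartment
  parameterization, not resolved here.
* The cuticle and muscle are isotropic; anisotropy, pseudocoelomic fluid
  transport and active muscle tone are out of scope.
* The pseudocoelom is a solid nearly incompressible compartment; internal
  pressure is represented only through its effective stiffness, not as an
  explicit fluid cavity load.

## Reproducing the headline numbers

`scripts/acceptance.R --seed 1 --out results/acceptance.json` rebuilds
the level-1 model and recomputes, from scratch, the four per-condition
indentation depths at 450 nN and the averaged overall modulus from
Hertz/Sneddon fits of the simulated BDM envelope curves.
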