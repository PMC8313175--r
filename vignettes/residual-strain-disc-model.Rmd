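---
title: "Modeling residual strain in the intervertebral disc: osmotic swelling and multigenerational annulus fibers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling residual strain in the intervertebral disc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(resdisc)
```

## The problem

The unloaded intervertebral disc is not stress-free. Two mechanisms store
residual strain in the annulus fibrosus (AF): the osmotic swelling pressure
generated by the proteoglycan fixed charge of the tissue, and an inherent
pre-strain of the angle-ply collagen fibers acquired during growth. When a
disc is removed from the vertebrae and cut radially, the AF springs open,
and the opening gap is a direct organ-scale readout of that residual
strain. Tissue-level material testing, however, is performed on excised
samples whose residual strain has been released, so a finite element model
built from tissue-test constants starts from a stress-free reference and
must re-establish the residual state before it can mimic a physiological
disc.

`resdisc` implements a quasi-static continuum model of the disc that builds
the residual state in two modes:

* **swelling-only** — both fiber families are present from time zero and
  all residual strain is swelling-induced;
* **multigen** — the disc swells fiber-free, then the two fiber families
  are deposited in *different reference configurations*, recorded at
  opposite torsional twist states, so the neutral disc also carries fiber
  pre-strain.

## Constitutive model

All tissue regions (outer/inner AF, transitional layers, nucleus pulposus
(NP), cartilage endplate (CEP)) share one constitutive structure with
region-specific constants. Units are mm–N–MPa–s throughout; concentrations
are mM (numerically identical to mol/m^3 and, for osmolarity, to mOsm/L).

**Extrafibrillar matrix** — the Holmes–Mow exponentially stiffening
hyperelastic solid,

$$W = \frac{\lambda + 2\mu}{4\beta_m}\left(e^{Q} - 1\right),\qquad
Q = \frac{\beta_m}{\lambda + 2\mu}\Big[(2\mu-\lambda)(I_1-3)
  + \lambda(I_2-3) - (\lambda+2\mu)\ln J^2\Big],$$

with the Lamé parameters obtained from the region's Young's modulus and
Poisson ratio. The Cauchy stress is evaluated analytically and is verified
in the test suite against central finite differences of the energy at
random admissible deformations.

**Donnan swelling** — the osmotic pressure of the matrix fixed charge
against a mobile-ion bath,

$$\pi = RT\Phi\left(\sqrt{c_F^2 + \bar c^{*2}} - \bar c^*\right),\qquad
c_F(J) = \frac{\varphi_0^w}{J - 1 + \varphi_0^w}\,c_{0F},$$

entering the total stress as $-\pi I$. The fixed charge density dilutes as
the tissue swells. The swelling state of a simulation is controlled by an
activation level $\alpha \in [0,1]$ scaling every region's $c_{0F}$; the
swelling protocol ramps $\alpha$ from 0 to 1 through a sequence of
equilibria.

**Fibers** — each AF element carries two fiber families at $\pm\theta$
from the circumferential direction in the circumferential–axial plane.
With $I_n = \lambda_n^2$ and $I_0 = \lambda_0^2$, the energy is zero for
slack fibers ($I_n < 1$), follows the toe-region power law

$$\Psi_n = \frac{E_f}{4\beta_f(\beta_f-1)}\,(I_0-1)^{2-\beta_f}(I_n-1)^{\beta_f},
\qquad 1 \le I_n \le I_0,$$

and is linear with modulus $E_f$ above the transition stretch $\lambda_0$,
offset so that both the energy and the stress are continuous at both branch
points. Printed forms of the toe-region fiber *stress* circulating in the
disc literature sometimes omit the $(I_0-1)^{2-\beta_f}$ normalization and
are then not derivable from the energy; this package defines the fiber
stress strictly as $\sigma_n = d\Psi_n/d\lambda_n$ (the standard
toe-power-law / linear fiber family) and enforces that consistency in the
test suite by finite differences.

**Strain-dependent permeability** — the transport law

$$k(J) = k_0\left(\frac{J-\varphi_0}{1-\varphi_0}\right)^2
e^{M(J^2-1)/2}$$

does not affect drained equilibria; it is exercised by the one-dimensional
transient consolidation engine (below).

### Parameters

The packaged per-region constants (`default_material_table()`) are
tissue-test values: matrix modulus 0.018–0.305 MPa, Poisson ratio
0.16–0.24, stiffening coefficient 0.29–3.4, permeability
0.00056–0.0047 mm^4/(N s) with strain exponent 2.71–5.75, fixed charge
density 44–379 mM, fiber modulus 3.0–15.6 MPa, transition stretch
1.020–1.028, ply angle 31.0°–44.5° (outer AF to NP transition), toe
exponent 4. Three quantities the sources leave open are set here as
package defaults, all configurable:

* **osmotic coefficient and temperature** — $\Phi = 1$, $T = 310$ K: the
  ideal Donnan assumption at body temperature;
* **reference water fractions** — 0.80 for NP and its transitional layer,
  0.70 for the AF regions, 0.60 for CEP: typical reported disc tissue
  water contents. These set both the pore-collapse bound of the
  permeability law and the dilution rate of the fixed charge;
* **bovine cylinder dimensions** — outer diameter 20 mm, height 7 mm, NP
  radius fraction 0.5: the source defers the experimental disc size to a
  citation without printing it, so a representative caudal disc size is
  fixed once in the geometry default.

The human cross-section is an ellipse whose plan-view lengths
($L_{rl} = 38.6$ mm, $L_{ap} = 27.8$ mm) are chosen so that the published
preload formula $0.2\,\mathrm{MPa}\cdot(0.84\,L_{rl}L_{ap})\cdot 1.5$
returns the published 270 N dynamic preload; disc height is 11 mm.

## Meshes

Cross-sections are meshed with an O-grid: a square core block (NP)
surrounded by concentric rings carrying the radial sequence NP →
NPtrans → IAF → AFtrans → OAF, the two transitional bands exactly one
element thick. Element edges run circumferentially/radially/axially, so
the per-element material triad (circumferential $e_1$, axial $e_2$,
radial $e_3$) follows from the element corner positions by the same
$a = n_2-n_1$, $d = n_5-n_1$ construction used for the fiber plies. The
human disc is the same topology scaled anisotropically to the ellipse.

A radial cut plane at one lateral sector is built into every mesh as
duplicated, tied node pairs spanning the full AF thickness (the NP core
stays intact, matching the intact-nucleus incision experiment) and the
full height; `release_cut()` switches the minus-side elements to the
duplicate nodes.

The default resolution (16 sectors, 8 radial stations, 4 axial layers;
576 elements, about 2 400 nodes) keeps every protocol on a desk scale:
the full bovine incision pipeline runs in about a minute and the human
preload-plus-torsion pipeline in under half a minute on one CPU. All
builders accept finer specs (`geometry_spec()`) for refinement studies.

## Protocols

All organ-scale stages are **drained equilibria**: the 12-hour preload
holds and the slow quasi-static tests are represented by the
Donnan-equilibrated elastic solution, and the nominally rate-controlled
test cases are executed as sequences of drained equilibria with the rate
label mapping control values onto pseudo-time (the mode is recorded in
each curve's metadata). The full three-dimensional transient biphasic
problem is out of scope; the transport law is exercised by the 1D
consolidation engine instead.

* **Swelling** (`swell_to_equilibrium`): both end surfaces gripped
  (inferior fixed, superior kinematically driven), $\alpha: 0 \to 1$ in
  10 substeps; the multigen human protocol simultaneously ramps the
  height from 11 to 11.5 mm ($\Delta H = 0.5$ mm).
* **Deposition** (`run_multigen_deposition`): twist the superior surface
  to $-\Omega$, record generation 1 ($+\theta$): the per-element
  deformation gradient snapshot and the push-forward
  $F(x,u)\,v_f/\lVert F(x,u)\,v_f\rVert$ of the time-zero ply direction;
  return to neutral (the matrix is hyperelastic, so the neutral state is
  recovered exactly); twist to $+\Omega$, record generation 2
  ($-\theta$); return; then ramp the fiber modulus from exactly zero
  ("negligible" is implemented as zero) to full value in 10 equilibrium
  substeps with the boundary held fixed. Fiber stretches are always
  evaluated through the relative gradient
  $F(x,t)\,F(x,u)^{-1}$ against the deposition-time direction, never
  re-derived from deformed geometry.
* **Preload** (`apply_preload`): axial force control of the superior
  surface (a one-dimensional bordered unknown in the Newton system), all
  other platen degrees of freedom fixed.
* **Test cases** (`run_test_case`): axial load ramps, displacement-
  controlled stress relaxation, and rotation ramps about the axial,
  sagittal or coronal axes, reporting the conjugate reaction
  (displacement or moment).
* **Incision** (`release_platens` + `simulate_incision`): the end grips
  are first replaced by a statically determinate 3-2-1 support with the
  former grip reactions ramped to zero — mirroring the experimental
  removal of the disc from the vertebrae, and necessary for the cylinder
  to open at all — then the cut-plane ties are released. The opening gap
  is the distance between the cut-face centroids at the outer AF edge at
  mid-height (the measurement locus is an explicit option; the
  experimental definition is not published).

## Numerics

* Trilinear hexahedra with full 2×2×2 quadrature in a total-Lagrangian
  formulation. The Table-1 Poisson ratios are all ≤ 0.24, far from
  incompressibility, so no special volumetric treatment is needed (the
  osmotic pressure is an explicit stress term, not a constraint).
* Element internal forces are exact; element tangents are forward finite
  differences of the force vector (step 1e-6 mm). Converged states
  therefore satisfy the exact residual; only the iteration path depends
  on the FD step.
* Newton with backtracking line search, at most 40 iterations, and a few
  non-monotone escape steps to cross fiber-engagement kinks; adaptive
  substep halving (and re-growth) in every protocol stage. Convergence:
  residual norm ≤ 1e-8 (absolute) + 1e-8 × the larger of the external
  force magnitude and the gross internal-force level of the stressed
  body.
* Linear solves use a cached supernodal sparse Cholesky factorization of
  the symmetrized tangent (the exact tangent is symmetric; FD asymmetry
  is ~1e-6 relative), with an unsymmetric LU fallback if the
  factorization fails. Force control adds one bordered unknown handled
  by a Schur complement.
* The freshly cut swollen cylinder has a nearly zero-stiffness opening
  mode (millimetres of motion per millinewton of released traction),
  which stalls plain continuation. `simulate_incision` therefore ramps
  an artificial tie stiffness across the cut pairs down geometrically
  (1 → 1e-5 N/mm) and finishes with the stiffness at exactly zero, so
  the reported opened state is a true unstabilized equilibrium.
* Ties at branch points of the piecewise fiber law go to the toe branch
  (closed-interval membership).
* The simulation path contains no randomness: identical configurations
  reproduce bit-identical results. The only seeded component of the
  package is the synthetic fixture-curve noise.

## One-dimensional consolidation

`transient_confined_consolidation` integrates the coupled
displacement–pressure system of a confined Holmes–Mow column with the
strain-dependent permeability: linear elements, backward Euler, analytic
Jacobian, a mesh graded toward the free-draining surface. In the
small-strain, constant-permeability limit it reproduces the classical
single-drainage consolidation series (checked to within 1% of the final
settlement at 20 time factors in the test suite), and for finite loads it
converges to the nonlinear drained solution. This engine is the
time-accurate counterpart of the drained organ-scale solves and the only
place the permeability law is load-bearing.

## Synthetic experimental fixtures

The organ-scale validation curves of the source studies are not
redistributable, so `generate_fixture_curve()` provides deterministic
stand-ins: saturating exponentials for creep and relaxation, power-law
plus linear shapes for ramps and rotations, each with a symmetric
confidence band and optional seeded noise. They have the right
qualitative shape and support exact NMSE identity tests (model ≡ mean →
0; model ≡ CI bound → 1), but they carry no information about real disc
stiffness. Consequently, passing the NMSE machinery tests says nothing
about agreement with real experiments — the quantitative validation
surface of this package is the bovine incision experiment, whose
experimental gap statistics are published numbers.

## What the model does and does not show

The package reproduces, from tissue-level constants and with no
organ-scale fitting, the qualitative structure of disc residual strain:
swelling-only residual strain concentrates fiber engagement at the NP/AF
transition, while multigenerational deposition produces markedly more
uniform fiber strain across the AF (the test suite checks the
coefficient-of-variation ordering at the 270 N preload); torsional
stiffness at 3° grows with the deposition twist angle; and the incision
gap of the multigeneration model is far smaller than that of the
swelling-only model for every twist angle, with the swelling-only gap
close to the published simulation value. The multigeneration gap on the
default scaled-down cylinder comes out above the published value: after
the fiber-modulus ramp the activated fiber ring compresses the swollen
cylinder and much of the deposited pre-strain relaxes, so less fiber
residual stress survives to close the cut than in the original
organ-scale model, whose cylinder diameter was also matched to an
unpublished experimental bovine size. The acceptance suite asserts the
published experimental range and reports this honestly.

Known limitations: no cartilage endplates in the default meshes; rigid
platens only (the Neo-Hookean bone law is available but unused by
default); drained-equilibrium representation of all rate-controlled
tests; no regional (anterior/posterior) property variation; the human
cross-section is a parameterized ellipse, not an image-derived mean
shape; and the axial stiffness of the default coarse meshes under
multi-hundred-newton loads is lower than that of a physiological disc,
so the loading protocols are best used for trend and ordering studies at
moderate loads rather than absolute load-displacement prediction.
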