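---
title: "Modelling GAG Donnan swelling and arterial residual stress with gagring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling GAG Donnan swelling and arterial residual stress with gagring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

A radially cut arterial ring springs open; the opening angle is the standard
surrogate for the circumferential residual stress locked into the intact
vessel. Sulfated glycosaminoglycans (sGAG) carry fixed negative charges that
attract counter-ions and water, generating a Donnan osmotic pressure inside
the wall. Because sGAG are concentrated toward the lumen, the inner wall
swells more than the outer wall, and the differential swelling bends the ring
open. `gagring` models this mechanism end to end for porcine thoracic aortic
rings (ascending, arch, and descending regions): it converts mural sGAG
profiles to fixed charge densities (FCD), embeds them in a charged porous
solid matrix, and solves for the swollen equilibrium shape of a cut ring to
predict the opening angle contributed by GAG alone.

# Mixture model

The total Cauchy stress is the sum of a fluid pressure and the elastic
stress of the drained solid skeleton,

$$\sigma = -\pi I + \sigma^e,$$

where at equilibrium against an unpressurized bath $\pi$ is the Donnan
osmotic pressure

$$\pi = R\,T\,\Phi\left(\sqrt{(c^F)^2 + (\bar c^*)^2} - \bar c^*\right),$$

with $c^F$ the FCD per fluid volume in the current configuration, $\bar c^*$
the bath osmolarity (300 mol m$^{-3}$, physiological), and $\Phi = 1$ for an
ideal solution. Volume change dilutes the charges:

$$c^F = \frac{\varphi_0^\omega}{J - 1 + \varphi_0^\omega}\,c_0^F,$$

with reference fluid fraction $\varphi_0^\omega = 0.7$ (70% tissue water)
and $J = \det F$. Because $\pi$ depends on $F$ only through $J$, the swelling
term derives from a scalar potential and the whole model remains
hyperelastic — the finite-element tangent is symmetric, which the solver
exploits.

The solid skeleton uses the Holmes–Mow law common in hydrated soft-tissue
mechanics,

$$W = \tfrac12 c\,(e^Q - 1),\qquad c = \frac{\lambda + 2\mu}{2\beta},$$
$$Q = \frac{\beta}{\lambda+2\mu}\left[(2\mu-\lambda)(I_1-3) +
\lambda(I_2-3) - (\lambda+2\mu)\ln J^2\right].$$

All ring simulations set $\lambda = 0$, which gives the drained skeleton a
zero Poisson ratio — the appropriate choice when the volumetric response is
carried by fluid exchange rather than the solid. With $\lambda = 0$ the
Cauchy stress has the closed form $\sigma^e = (\mu/J)\,e^Q(B - I)$, which the
compiled element kernel uses directly; the general-$\lambda$ energy and
stress are implemented in R (`hm_energy()`, `hm_cauchy_stress()`) and are
verified against finite differences of the energy in the test suite.

## FCD from sGAG

Each chondroitin-sulfate disaccharide (molecular weight 513 g/mol) carries
two negative charges, so a concentration $c$ in g per litre of tissue water
maps to $c^F = (2/513)\,c$ eq/L. Mural profiles measured in thin slices are
interpolated piecewise-linearly in normalized depth and averaged over eight
equal-width domains (one per radial element); bin-averaging was chosen over
pointwise sampling because it is conservative and order-independent, and
both options are exposed (`interpolate_to_domains(method = )`). Published
per-domain FCD values for the three regions ship as `porcine_fcd()`;
magnitudes decrease from the intima toward the adventitia (the descending
region has a small non-monotonic bump around mid-wall, which is preserved
as printed).

# Biaxial constitutive fitting

Planar biaxial tests report second Piola–Kirchhoff membrane tensions
(N/m) against Green strains. Under the short-time incompressibility of a
fluid-saturated tissue ($J = 1$), $E_{33}$ is eliminated and the reduced
membrane energy gives

$$T_{11} = \mu\Big[1 - \tfrac{1}{\Delta(2E_{11}+1)}\Big]e^{Q},\qquad
Q = 2\beta\big(E_{11}+E_{22}+\tfrac12[1/\Delta - 1]\big),$$

with $\Delta = (2E_{11}+1)(2E_{22}+1)$, $T_{22}$ by symmetry and
$T_{12} = 0$ (shear is negligible in these tests). Fitting minimizes the sum
over all points of $|T_{11}$-error$| + |T_{22}$-error$| + |T_{12}$-error$|$
— read as a plain L1 aggregate; an RMS variant is exposed via
`aggregate = "rms"`. Because the objective is non-smooth at the optimum, a
derivative-free Nelder–Mead simplex is used, multi-started from a
deterministic log-space lattice (nine starts for two parameters), with
positivity enforced by log-parameterization and ties broken on lowest
objective then lowest $\beta$. Goodness of fit is reported as squared
Pearson correlations pooled per loading direction (fiber / cross-fiber).

Confidence intervals use a seeded nonparametric residual bootstrap (1000
resamples by default): residuals are resampled per tension component, added
back to the fitted curves, and the model refitted from the incumbent. This
was chosen because asymptotic covariances are awkward for L1 objectives.

## Two-layer wall and the stiffness ratio r

The wall may be split into intima-media ($M$) and adventitia ($A$) sharing
the in-plane strain, with additive layer tensions and thicknesses
$H = H_M + H_A$. Because the layers cannot be identified independently from
total-tension data, the adventitial modulus is tied to the medial one by a
ratio $r = \mu_A/\mu_M$, swept over $\{0.1, 0.2, 0.5, 1, 2, 5, 10\}$.

The ratio is applied to the *membrane* moduli (N/m): $\mu_A = r\,\mu_M$,
and each layer is then converted to a volumetric modulus with its own
undeformed thickness ($\hat\mu_M = \mu_M/H_M$, $\hat\mu_A = \mu_A/H_A$) for
the 3D simulations. This choice is empirical: with the published two-layer
parameters it reproduces the published two-layer opening angles almost
exactly (the acceptance suite checks the 35/21/16-degree anchor cases),
whereas tying the volumetric moduli systematically underpredicts them. The
volumetric alternative remains available (`r_scale = "volumetric"`). Layer thickness
fractions use the element split of the ring model (7/8, 6/8, 5/8 of the
wall for ascending/arch/descending).

A fitted $\beta_A$ printed as 0.00 denotes the near-linear limit of the
exponential law; simulations represent it as $10^{-3}$ (the stress effect of
this choice is below 0.5%).

The nine protocol strain ratios of the original rig are not published; the
synthetic generator defaults to
$\{1{:}1, 1{:}0.75, 0.75{:}1, 1{:}0.5, 0.5{:}1, 1{:}0.25, 0.25{:}1, 1{:}0,
0{:}1\}$ with the dominant arm reaching a Green strain of 0.5 in steps of
0.025, and 5% multiplicative Gaussian noise as the default noise model —
package stand-ins representative of biaxial rigs, not measured values.
Parameter recovery from such data (exact on noiseless input, <10% at 5%
noise) is the validation route for the fitting machinery, since the raw
tension curves behind the published parameter tables are not available.

# Quarter-ring finite-element model

Symmetry reduces the cut ring to a quarter model: half the circumference
(mirror plane A through the cut diameter) and half the height (mid-height
plane B). The mesh uses 20-node serendipity hexahedra with mid-edge nodes
placed on the exact cylindrical surfaces, at a reference resolution of 8
radial x 20 circumferential x 8 axial elements; the radial count equals the
number of FCD domains so each element carries one domain value. Plane A is
fixed in $y$, plane B in $z$, and the single inner node on both planes in
all directions, leaving the cut face traction-free. A total-Lagrangian
Newton solver with an analytic symmetric tangent ramps the FCD linearly from
zero in 10 increments, halving the increment (up to six times, with
recovery) if an increment diverges; each linear solve uses supernodal sparse
Cholesky with simplicial-LDL and sparse-LU fallbacks. Element quadrature is
3x3x3 Gauss. The solve is fully deterministic.

The opening angle follows the classical opened-sector convention: mirror
the deformed quarter across plane A, take the mid-height inner-arc midpoint
M and the two inner cut-edge points, and measure the angle they subtend at
M — 0 degrees for a closed ring, 180 for a straightened strip, negative if
the ring curls past closed (which the descending region does at small r).

## Reduced-height mode and problem sizes

Because the swelling field is nearly uniform along the ring axis, the angle
is insensitive to the axial element count; the package therefore provides a
reduced mode with a single quadratic element over the half height
(8 x 20 x 1), which the routine tests and the acceptance script use. The
mesh-convergence test doubles all three directions (8x10x1 against 16x20x2,
keeping the radial count a multiple of the eight FCD domains) and requires
the angle to move by less than 2 degrees. The published-resolution
8 x 20 x 8 model (about 19,000 degrees of freedom) runs through the same
code path and is available via `resolution = c(8, 20, 8)`.

## Opened-sector oracle

An independent reduced model guards the FE solver: assume the swollen ring
deforms as an axisymmetric opened sector, $r = r(\rho)$,
$\varphi = k\theta$, uniform $\lambda_z$, and integrate radial equilibrium
through the wall (fixed-grid RK4 per FCD domain, so integration never
crosses a property jump). With both surface tractions zero, the net
circumferential force $\int\sigma_{\theta\theta}\,dr = [r\,\sigma_{rr}]$
vanishes identically — it cannot select $k$. The conditions that close the
problem are zero net axial force and zero net bending moment of
$\sigma_{\theta\theta}$ on the cut (reference-point independent precisely
because the net force is identically zero); releasing the bending moment is
what lets the sector open. The oracle and the FE solver agree within 15% on
the reference rings, which is the expected fidelity of a one-dimensional
ansatz against a full model with end effects.

# Evaluation metrics

Simulated angles are scored against the experimentally measured *decrease*
in opening angle after enzymatic GAG depletion ("delta": 29/20/13 degrees
by region), since that is the quantity a swelling-only model should
recover, and additionally reported as a fraction of the control angles
(114/61/31 degrees). Percentages round half-up to integers (27.59 becomes
28), matching the published tables. Configurations whose biaxial fits were
not published as acceptable, and negative simulated angles (never observed
experimentally), are excluded from evaluation and reported as missing. An
arithmetic-only report mode decouples this bookkeeping from the FE solver
so the error tables are exactly checkable on their own.

# Parameters at a glance

| Parameter | Default | Units | Notes |
|---|---|---|---|
| Bath osmolarity $\bar c^*$ | 300 | mol/m$^3$ | physiological saline |
| Osmotic coefficient $\Phi$ | 1 | – | ideal solution |
| Fluid fraction $\varphi_0^\omega$ | 0.7 | – | 70% tissue water |
| Temperature $T$ | 298.15 | K | not stated for the original runs; $\pi$ scales linearly in $T$, so 310 K would raise pressures by 4% |
| sGAG charge/mass | 2 / 513 | eq/mol, g/mol | chondroitin sulfate disaccharide |
| $\lambda$ | 0 | Pa | zero Poisson ratio skeleton |
| Ramp steps | 10 | – | linear FCD scaling |
| Newton tolerance | 1e-8 | relative | per increment |

# Known limitations

* Only the Donnan swelling of sulfated GAG is modelled: no fiber
  architecture (an exponential-fiber anisotropic law is out of scope), no
  hyaluronic acid, no viscoelasticity, and no transient fluid flow (the
  swelling equilibrium is treated as quasi-instantaneous). Accordingly the
  model recovers the GAG *contribution* to the opening angle, about a third
  of the total.
* Rings are perfect cylinders; real cross-sections are not.
* The published one- and two-layer parameter tables cannot be re-derived
  here because the underlying raw biaxial curves are unpublished; they are
  treated as inputs, and the fitting code is validated by synthetic-data
  recovery instead.
* The synthetic biaxial generator emulates strain-driven protocols with
  i.i.d. noise; it does not reproduce rig artefacts (marker loss,
  preconditioning drift, shear coupling), so passing recovery tests shows
  correctness of the estimator, not robustness to every experimental
  pathology.

```{r example}
library(gagring)

# one-layer ascending ring, reduced-height mesh
sol <- simulate_opening_angle("ascending", layers = 1, reduced = TRUE)
sol$opening_angle

# score all published configurations without rerunning the solver
build_report(mode = "arithmetic")
```
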