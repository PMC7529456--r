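---
title: "Modeling umbilical artery closure: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling umbilical artery closure: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cordclose)
```

## The mechanical problem

At birth the umbilical artery must occlude within minutes while the vein
stays patent. The arterial wall is bilayered: an inner tunica media rich in
hydrated glycosaminoglycans (aggrecan, versican) surrounded by an outer,
contraction-primed smooth-muscle layer. `cordclose` models this wall as a
thick-walled, incompressible, bilayered cylinder held at a fixed axial
stretch and loaded by luminal pressure, smooth-muscle active stress in the
outer layer, and a prescribed degree of swelling of the inner layer. Three
questions drive the analysis:

1. How does the loaded inner radius depend on active stress and inner-layer
   volume (closure curves)?
2. At which active stress does the cylindrical state become unstable to
   inward circumferential folding, and with how many folds?
3. Can the passive constitutive parameters be recovered from biaxial
   pressure-diameter and axial-force tests?

## Kinematics and constitutive model

In cylindrical coordinates a tube with unloaded radii $A \le R \le C$
(interface at $B$) deforms axisymmetrically with axial stretch
$\lambda_z$. The inner layer is swollen to a normalized volume $v$
(current/reference; $v>1$ swelling, $v<1$ fluid exudation), treated
quasi-statically as a pointwise constraint $\det \mathbf F = v$; the outer
layer is incompressible ($\det \mathbf F = 1$). The radius map is then
closed-form:

$$r^2 = a^2 + v\,\frac{R^2-A^2}{\lambda_z}\ (A\le R\le B), \qquad
  r^2 = b^2 + \frac{R^2-B^2}{\lambda_z}\ (B\le R\le C),$$

with circumferential stretch $\lambda_\theta = r/R$ and radial stretch
$\lambda_r = vR/(\lambda_z r)$ (inner) or $R/(\lambda_z r)$ (outer).

Each layer carries the strain energy

$$W = \frac{\mu}{2}\left(\lambda_r^2+\lambda_\theta^2+\lambda_z^2-3\right)
 + \sum_k \frac{c_1^k}{4c_2^k}\left[e^{c_2^k (\lambda_k^2-1)^2}-1\right],$$

the four-fiber-family form standard for murine vessels: an axial family
($\eta=0$), a circumferential family ($\eta=90^\circ$) and two symmetric
diagonal families ($\pm\eta$), with fiber stretch
$\lambda_k^2=\lambda_z^2\cos^2\eta+\lambda_\theta^2\sin^2\eta$. Fibers
carry load in extension only. The inner layer is neo-Hookean
(`mu = 3.0` kPa, the GAG-rich matrix); the outer layer combines a soft
matrix (`mu = 0.1` kPa) with the four fiber families and is the only
contractile layer. Extra Cauchy stresses are
$\hat\sigma_i = \lambda_i \partial W/\partial\lambda_i$; the strain energy
is measured per unit current volume, so the same expressions apply in the
swollen layer and equilibrium, axial force and the stability analysis all
derive from one potential. Smooth muscle adds a circumferential Cauchy
stress with a parabolic length-tension law,

$$\sigma_{act} = T_{act}\,\lambda_\theta
 \left[1-\left(\frac{\lambda_m-\lambda_\theta}{\lambda_m-\lambda_0}\right)^2\right]_+ ,$$

zero at the minimum contractile stretch $\lambda_0 = 0.2$ and with peak
force density at $\lambda_m = 2.5$. The positive-part clamp makes the law
continuous everywhere; in all contraction simulations
$\lambda_\theta < \lambda_m$, so the clamp only matters below $\lambda_0$.

The packaged parameter set (`umbilical_artery_model()`) is the murine
umbilical-artery table used for every simulation here: $A,B,C$ =
161.77, 206.86, 236.92 um, $\lambda_z = 1.28$, and the layer parameters
above. Pressures are quoted in mmHg (1 mmHg = 0.133322 kPa).

## Equilibrium and closure curves

Radial equilibrium reduces to one scalar equation per loading,

$$P = \int_a^{c} \left(\sigma_{\theta\theta}-\sigma_{rr}\right)\frac{dr}{r},$$

evaluated by composite Gauss-Legendre quadrature (200 nodes per layer by
default; the quadrature is exact to machine precision well below that).
`solve_inner_radius()` scans the pressure-radius relation over
$a \in [10^{-3}A,\,3A]$ and refines every root by bracketed
root-finding (tolerance $10^{-6}$ um). With strong active stress the
relation is non-monotone — several equilibria coexist — which is exactly
the origin of the sharp patent-to-narrow transition in the closure curves.
Sweeps therefore follow the quasi-static branch by continuation (the
stable root, $dP/da > 0$, nearest the previous solution) and jump to the
remaining branch when the patent one folds. If no root exists above
$10^{-3}A$ the state is reported occluded rather than extrapolated.

Closure curves normalize the inner radius by its passive value at the same
$(P, v)$; the model does not state a normalization, and this choice makes
every curve start at 1 and isolates the effect of contraction. The axial
stretch is held at 1.28 throughout and the transducer axial force
$f = \pi\int (2\hat\sigma_{zz}-\hat\sigma_{\theta\theta}-\hat\sigma_{rr})\,r\,dr$
is an output, not a constraint.

Two robustness choices matter numerically: the scan grid is refined
logarithmically near closure, where the pressure-radius relation is steep;
and `swelling_crossover()` first brackets the curve crossing on a grid and
then solves the exact difference $a(T;v_{low})-a(T;v_{high})$ by
root-finding, so the reported crossover does not depend on the scan step
(verified to within 1 kPa under grid refinement).

At 25 mmHg with the packaged parameters the crossover sits near 50 kPa:
below it, a shrunken inner layer ($v=0.5$) leaves a *larger* lumen than a
volume-conserving one; above it, volume loss aids narrowing. The curves
plateau at high active stress — contraction alone does not occlude the
vessel.

## Buckling analysis

Perturbations are plane strain in $(r,\theta)$ at fixed $\lambda_z$:
observed folds are longitudinal ridges, so the eigenproblem is
one-dimensional in $r$. A stream function $\phi = f(r)\sin n\theta$
($u_r = n f/r\,\cos n\theta$, $u_\theta = -f'\sin n\theta$) satisfies
incremental incompressibility identically. The second variation of the
total potential is assembled from the plane-strain instantaneous
(small-on-large) moduli at the deformed state plus the base
Lagrange-multiplier field recovered from radial equilibrium, with the
luminal pressure contributing its exact second-order area term (follower
load). The Euler-Lagrange equations of this functional form a canonical
first-order system integrated by fixed-step RK4 from the lumen through
both layers (displacement and traction continuity at the interface); a
sign change of the outer boundary-condition determinant in $T_{act}$
locates the critical active stress, refined by bisection to 0.1 kPa.

The machinery is verified four independent ways:

* a thin neo-Hookean ring under hydrostatic suction collapses at
  $(n^2-1)\,\mu h^3/(3R^3)$, reproduced to a few tenths of a percent for
  $n = 2..5$ — this exercises the prestress coupling *and* the follower
  pressure term, whose $(n^2-1)$ structure is diagnostic;
* the $n=1$ rigid translation is neutral (determinant at machine zero)
  with and without pressure and prestress;
* the second-order lumen-area formula matches a direct polygon-area
  computation;
* determinant zeros agree with an independent finite-difference
  eigenvalue discretization of the same quadratic form (the test suite
  brackets the 7-fold critical stress with it).

Three ingredients of the incremental problem are not derivable from the
equilibrium model and are exposed as switches on `mode_determinant()`,
`critical_active_stress()` and `fold_sweep()`:

* **`outer_support`** (default `"embedded"`): the outer surface is held
  radially and circumferentially, representing the perivascular support of
  the surrounding cord tissue (Wharton's jelly). This is also what the
  tissue shows: the outer wall stays round while the inner layer folds.
  With a traction-free outer surface (`"free"`) the soft outer layer
  admits a global ovalisation ($n=2$) as the lowest mode, and the critical
  stress then *increases* with fold number — inconsistent with the
  many-folded morphology this model exists to explain.
* **`active_stiffness`** (default `FALSE`): the activation level is
  treated as constant over the fast perturbation, so the derivative of
  the tone law with respect to $\lambda_\theta$ is excluded from the
  moduli. The rotational terms from *carrying* the base active stress are
  always retained — the moduli-stress identities require them. Including
  the constitutive stiffening (`TRUE`) raises and flattens the
  fold-number curve so that it plateaus by $n \approx 4$.
* **`pressure_increment`** (default `"follower"`): pressure stays normal
  to the deforming surface. The `"dead"` alternative (traction frozen on
  the unperturbed surface) renders the second variation asymptotically
  marginal over a wide range of active stress and is numerically
  degenerate here; it is retained for comparison only.

With the defaults, at $v = 0.5$ and 25 mmHg the critical active stress
decreases monotonically from 120.6 kPa ($n=2$) to 55.9 kPa ($n=7$) and
then flattens; the 5%-relative-drop criterion selects a plateau at
**7 folds**, a few kPa above the ~50 kPa closure transition — the vessel
first narrows sharply, then buckles and closes. A useful interpretation:
the large-$n$ limit of the critical load coincides with the luminal
surface of the compressed inner layer reaching the classical plane-strain
surface-instability ratio $\lambda_\theta/\lambda_r \approx 0.295$, while
the outer support penalizes long-wavelength modes, whose influence decays
like $(a/c)^n$; the competition sets the plateau onset.

Two caveats. First, the analysis is linear: it locates the bifurcation but
does not predict fold amplitude or post-buckling contact, so "closure via
buckling" is reported as a flag (critical stress inside the sweep range on
a still-narrowing branch), not as a computed closed shape. Second, the
dependence of the critical stress on the swelling level is dominated by
*when* each swelling level's own closure path reaches critical inner-layer
compression; this path effect makes the computed critical stress increase
with $v$ at fixed fold number, even though at matched active stress a more
swollen inner layer does carry more compressive hoop stress. Readers
comparing against contraction experiments at different hydration states
should mind this distinction; it is the one qualitative behavior of the
biological narrative that this implementation does not reproduce, and the
corresponding property test documents the discrepancy rather than hiding
it.

## Parameter estimation

`fit_passive()` recovers the outer-layer parameters
$\{\mu_2, c_1^1, c_2^1, c_1^2, c_2^2, c_1^{3,4}, c_2^{3,4}, \eta\}$ by
bounded multi-start Levenberg-Marquardt in log-parameter space (bounds:
moduli $[10^{-4}, 10^3]$ kPa, exponents $[10^{-3}, 50]$, $\eta \in
(0^\circ, 90^\circ)$; starts sampled from a seeded uniform design). The
inner modulus $\mu_1$ is held fixed: a passive pressure-diameter test
cannot separate the swollen core's stiffness from the outer wall's.

The residual convention matters. The biaxial rig *controls* pressure and
axial stretch and *measures* diameter and force, and the synthetic-data
generator accordingly perturbs only diameter and force. Regressing
predicted pressure at the measured (noisy) diameter is an
errors-in-variables setup and shows a clear bias at 2% diameter noise
(20-40% on the stiff fiber parameters in our experiments, persisting when
the optimizer is started at the truth). The default `residual =
"response"` therefore solves the model at the exact controlled pressure
(a vectorized bracketed-bisection + Newton inversion across all protocol
points simultaneously) and residualizes diameter and force, each weighted
by its per-protocol standard deviation. The classical pressure-residual
objective remains available as `residual = "pressure"`.

With the default protocols (pressure sweeps 2.5-25 mmHg at axial
stretches 0.95/1.00/1.05 times in vivo; force-length sweeps at 5/15/25
mmHg — the standard murine design, since the exact protocol set of the
source experiments is not published) recovery from noise-free data is
exact to well below 1%, and at 2% multiplicative noise with four vessels
the median errors of the load-bearing parameters are a few percent. The
0.1 kPa outer matrix modulus is the exception: its stress contribution
sits an order of magnitude below the fiber stresses and it is not
identifiable at that noise level (median error around 50%); this is the
same identifiability reason for fixing $\mu_1$.

`fit_active_tone()` closes the loop with the contraction experiments: it
solves for the $T_{act}$ that reproduces an observed outer-diameter
reduction at fixed pressure (the murine artery constricts 30-50% at
25 mmHg under KCl), by bisection along the quasi-static branch.

## Synthetic data

`generate_biaxial()` and `generate_contraction()` forward-simulate the
protocols with a ground-truth model and apply multiplicative Gaussian
noise to the measured responses only (defaults 1% diameter, 3% force —
conservative figures for video-tracked diameter and transducer force,
since the source rig's noise is unreported; geometry is treated as
measured exactly). Four vessels per dataset mirror the murine study size.
Outputs are byte-reproducible from the spec and seed, and the generator
restores the caller's RNG state.

What the generator does *not* emulate: preconditioning hysteresis,
time-dependent KCl response, vessel-to-vessel parameter heterogeneity, or
measurement error in the unloaded geometry. Passing recovery tests on
these data therefore demonstrate correctness of the estimation machinery
under the stated noise model, not robustness to every failure mode of real
biaxial data.

## Numerical choices at a glance

| Quantity | Default | Why |
|---|---|---|
| Quadrature nodes per layer | 200 (60 in fitting) | pressure integral converged to ~1e-10 (1e-8) relative |
| Radius root tolerance | 1e-6 um | far below measurement scale |
| Stability integration steps per layer | 200 | determinant invariant to 0.1% under doubling |
| Critical-stress bisection | 0.1 kPa | matches reporting precision |
| Plateau criterion | 5% relative drop | smallest n whose drop to n+1 falls below it |
| Fit starts | 10 (CLI default) | landscape is benign; 1-2 suffice in practice |
| Fit bounds | moduli 1e-4..1e3 kPa, exponents 1e-3..50, eta 1..89 deg | generous physical ranges |

Degenerate inputs are handled explicitly: occlusion is reported (not
extrapolated) when no patent equilibrium exists; buckling search reports
"closure without buckling" when the base state occludes first; determinant
magnitudes below 1e-14 are treated as sign-indeterminate (the shooting
space degenerates in nearly collapsed states); infeasible synthetic
protocol points are dropped with a count.

## Worked example

```{r example, eval = FALSE}
model <- umbilical_artery_model()

## closure curves and the swelling crossover at 25 mmHg
cross <- swelling_crossover(model, P = 25, v_low = 0.5, v_high = 1,
                            T_act = seq(0, 150, by = 2))
cross$T_cross          # ~49.8 kPa

## fold-number dependence of the buckling threshold at v = 0.5
folds <- fold_sweep(model, n = 2:12, v = 0.5, P = 25)
attr(folds, "n_star")  # plateau at n = 7

## synthetic biaxial data and parameter recovery
spec <- synthetic_spec(model = model, seed = 17)
d <- generate_biaxial(spec)
fit <- fit_passive(d, model$geometry, mu1 = 3.0, n_starts = 4, seed = 17)
fit
```

The same pipeline, end to end with stage outputs on disk, is
`run_full(list(seed = 17))`. Simulation sizes used throughout the package
defaults (201-point active-stress grids, modes 2-12, 50-replicate
recovery studies) run on a single CPU in minutes.

## Known limitations

* Quasi-equilibrated swelling: the degree of swelling is prescribed per
  simulation; no poroelastic or mixture dynamics, permeabilities or
  fixed-charge densities are modeled.
* No viscoelasticity, growth/remodeling, axial-mode perturbations,
  post-buckling fold growth or luminal contact.
* The stability defaults (embedded outer surface, activation constant
  during perturbation) are modeling commitments made to reproduce the
  observed fold selection; both alternatives are computed and exposed as
  switches, and the swelling-dependence caveat above stands.
* A comparison wall made of the soft outer material throughout (uniform
  matrix + smooth muscle, no GAG core) keeps a tensile mean inner hoop
  stress only at modest tone (about +2.7 kPa at `T_act = 20`); under
  stronger contraction it collapses nearly axisymmetrically at 25 mmHg
  and the eigenvalue oracle confirms an accompanying instability around
  17-30 kPa. In this implementation such a wall is simply too soft to
  remain patent, so statements about buckling resistance of a uniform
  wall only hold on its patent range; the corresponding property test
  records this honestly.
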