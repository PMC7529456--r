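# cordclose

Biomechanics of umbilical artery closure at birth.

The umbilical artery occludes within minutes of delivery; the vein stays
patent. The artery's wall is built for this: an inner tunica media swollen
with glycosaminoglycans (aggrecan/versican) sits inside a
contraction-primed smooth-muscle outer layer. `cordclose` implements a
continuum-mechanical model of that wall — a thick-walled, bilayered,
incompressible cylinder under luminal pressure, fixed axial stretch,
inner-layer swelling and smooth-muscle active stress — and the analyses
built on it:

* **Equilibrium closure curves.** Radial equilibrium
  `P = ∫ (σ_θθ − σ_rr)/r dr` solved for the loaded inner radius over
  grids of active stress `T_act` and normalized inner-layer volume `v`,
  with quasi-static branch continuation through the sharp
  patent-to-narrow transition.
* **Buckling stability.** Plane-strain incremental (small-on-large)
  analysis of inward circumferential folding: critical active stress per
  fold number `n`, via a stream-function shooting determinant verified
  against classical ring-collapse theory and an independent
  finite-difference eigenvalue oracle.
* **Parameter estimation.** Bounded multi-start nonlinear regression of
  passive biaxial pressure–diameter and axial-force data for the
  four-fiber-family wall model, plus calibration of the active-tone
  magnitude from observed KCl contraction.
* **Synthetic data.** A generator emulating murine ex vivo biaxial
  sessions (n = 4 vessels, pressures to 25 mmHg, response-only
  multiplicative noise), so every analysis is testable end to end.

The wall model: per layer, strain energy
`W = μ/2 (λ_r² + λ_θ² + λ_z² − 3) + Σ_k c1k/(4 c2k) [exp(c2k (λ_k² − 1)²) − 1]`
with tension-only fibers at angles η from the axis
(`λ_k² = λ_z² cos²η + λ_θ² sin²η`), and circumferential active stress
`T_act λ_θ [1 − ((λ_m − λ_θ)/(λ_m − λ_0))²]₊` in the outer layer. The
inner layer is neo-Hookean and swollen (`det F = v`). The packaged
murine umbilical-artery parameter set is returned by
`umbilical_artery_model()`.

## Worked example

```r
library(cordclose)
model <- umbilical_artery_model()
model
#> Bilayered vessel model
#>   unloaded radii A, B, C: 161.77, 206.86, 236.92 um; lambda_z = 1.280
#>   inner layer: mu = 3 kPa, 0 fiber families
#>   outer layer: mu = 0.1 kPa, 4 fiber families, contractile
#>   tone window: lambda_0 = 0.20, lambda_m = 2.50

## passive loaded state at 25 mmHg
solve_inner_radius(model, P = 25)
#> Loaded bilayered-tube state
#>   P = 25.00 mmHg, T_act = 0.00 kPa, v = 1.000, lambda_z = 1.280
#>   a = 270.323 um, b = 292.531 um, c = 313.243 um
#>   axial force 0.6491 mN; mean stt inner 3.17 kPa, outer 47.7 kPa

## the swelling-contraction crossover: below ~50 kPa a shrunken inner
## layer (v = 0.5) leaves a wider lumen, above it volume loss aids closure
cross <- swelling_crossover(model, P = 25, v_low = 0.5, v_high = 1,
                            T_act = seq(0, 150, by = 2))
cross$T_cross
#> [1] 49.77631

## critical buckling stress vs number of folds at v = 0.5
folds <- fold_sweep(model, n = 2:12, v = 0.5, P = 25)
head(folds[, 1:4], 7)
#>   n   v P_mmHg T_act_crit_kPa
#> 1 2 0.5     25      120.57031
#> 2 3 0.5     25       91.03906
#> 3 4 0.5     25       76.27344
#> 4 5 0.5     25       65.25781
#> 5 6 0.5     25       59.24219
#> 6 7 0.5     25       55.88281
#> 7 8 0.5     25       53.77344
attr(folds, "n_star")
#>     v n_star
#> 1 0.5      7
```

Reading: at 25 mmHg the passive artery inflates to an inner radius of
270 um. Sweeping smooth-muscle active stress for two inner-layer volumes,
the radius curves cross at 49.8 kPa — the active stress above which
losing inner-layer volume helps rather than hinders narrowing. The
critical active stress for inward folding falls with fold number and
flattens at seven folds (55.9 kPa), just above the closure transition:
the vessel narrows sharply near 50 kPa, then buckles with ~7 folds and
proceeds to closure. Many-folded buckling of the inner layer is the
mechanism that lets contraction finish the job it cannot do
axisymmetrically.

`run_full(list(seed = 17))` executes the full pipeline
(simulate → fit → closure sweep → buckling sweep) into a run directory
with tidy CSVs and a `summary.json`. A thin command-line wrapper with the
same verbs is installed at `inst/cli/cordclose`.

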