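# sanstools

Contrast matching and form-factor model fitting for small-angle neutron
scattering (SANS) of biomolecules and their insoluble partners.

SANS measures the intensity *I(q)* versus momentum transfer *q*
(= 4π sin θ / λ, in Å⁻¹) and probes structure from nanometres to
micrometres. When a soluble protein binds a large insoluble scaffold —
the motivating application is a multidomain protein coating chitin
nanofibers — two things make the analysis specific enough to deserve a
package:

1. **Contrast variation.** Hydrogen and deuterium have coherent
   scattering lengths of opposite sign, so an H₂O/D₂O mixture can be
   tuned to the *match point* where a component's scattering-length
   density (SLD) equals the solvent's and that component disappears from
   the signal. `sanstools` computes SLDs from elemental composition
   (with labile-H exchange and perdeuteration bookkeeping), solves the
   match point in closed form, and implements the integrated-intensity
   estimator for locating a match point from a measured contrast series
   (trapezoid integration over a q-window, quadratic fit, minimum).

2. **Models for fibers and hierarchical aggregates.**
   * flexible cylinder: wormlike chain with excluded-volume corrections
     (Pedersen–Schurtenberger method 3) times a circular cross-section
     factor, plus a power law *α₂ q⁻ᴰ* for scattering from large sharp
     interfaces:
     *I(q) = α₁ P_flex(q; R, L_C, b_Kuhn) + α₂ q⁻ᴰ + c*
   * the Beaucage unified model with N structural levels,
     *I(q) = c + Σᵢ [Gᵢ exp(−q²Rgᵢ²/3) + Bᵢ exp(−q²Rg₍ᵢ₊₁₎²/3)(1/qᵢ\*)^Dᵢ]*
     with *qᵢ\* = q [erf(qRgᵢ/√6)]⁻³*
   * a random-walk chain of ellipsoids (decoupling approximation) for
     elongated multidomain proteins
   * Gaussian resolution smearing for a relative wavelength spread.

   Fitting is weighted Levenberg–Marquardt with the constraints fiber
   work needs: fixed contour length, every Rg bounded by π/q_min, a
   two-stage protocol for the two-level unified model, seeded
   multi-start, 1σ uncertainties and reduced χ².

A reader/writer for columnar reduced SAS data (SASBDB-style `.dat`), a
synthetic-data generator (instrument-like grids, counting-statistics
noise, full contrast series) and a small CLI complete the pipeline.

## Worked example

Theoretical match point of β-chitin (anhydro-GlcNAc repeat unit C8H13NO5,
three exchangeable hydrogens, density 1.5 g/mL), then a full fiber fit on
a synthetic pinhole-SANS curve:

```r
library(sanstools)

chitin <- molecular_composition("C8H13NO5", labile_h = 3, density = 1.5)
match_point(chitin)
#> Contrast match point: 44.6% D2O  (closed_form)
#>   SLD at match : 2.528 x 1e-6 A^-2

truth <- flexcyl_params(alpha1 = 5, radius = 16, kuhn = 318, contour = 5000,
                        alpha2 = 1e-9, decay = 4, background = 0.01)
curve <- generate_curve("flexible_cylinder_powerlaw", truth,
                        instrument_d11(120), noise_spec(0.02, seed = 1))
fit_chitin_reference(curve, config = fit_config(seed = 1))
#> Model 'flexible_cylinder_powerlaw' fit: 120 points, 6 free parameters
#>   reduced chi-square: 0.8062   (converged: TRUE)
#>               estimate uncertainty  note
#> alpha1     5.02916e+00    2.79e-02
#> radius     1.60684e+01    9.80e-02
#> kuhn       3.22821e+02    1.19e+01
#> contour    5.00000e+03          NA fixed
#> alpha2     1.00689e-09    9.15e-11
#> decay      3.99938e+00    1.45e-02
#> background 1.00315e-02    4.64e-05
```

Read: the match point says 44.6% D₂O renders chitin invisible (full
exchange, 1.5 g/mL). The fit recovers the generating fiber: cross-section
radius 16.07 ± 0.10 Å, Kuhn length 323 ± 12 Å (a very rigid chain — the
Kuhn length is twice the persistence length), Porod exponent 4.00
(sharp interfaces), with the contour length held at 5000 Å because fibers
longer than the measurement window cannot be sized. Reduced χ² near 1
means the model describes the data within the quoted uncertainties.

The same protocols run on deposited reduced data: download a `.dat` file
from SASBDB and pass it to `read_sas_ascii()` +
`fit_chitin_reference()` (fiber curves, e.g. accession SASDW42) or
`fit_beaucage_two_stage()` (protein–fiber complexes, e.g. SASDWA2,
SASDWC2).

## Command line

```sh
Rscript inst/scripts/sanscli.R matchpoint --config inst/examples/matchpoint.yml
Rscript inst/scripts/sanscli.R fit        --data chitin.dat --model chitin_reference --seed 1
Rscript inst/scripts/sanscli.R simulate   --config inst/examples/simulate.yml
```
(after installation the script and configs live under
`system.file("scripts", ...)` / `system.file("examples", ...)`)

Subcommands `matchpoint`, `fit`, `simulate`; YAML configs with flag
overrides; JSON run reports with config snapshots and input digests.
Exit codes: 0 ok, 2 usage error, 3 fit did not converge.

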