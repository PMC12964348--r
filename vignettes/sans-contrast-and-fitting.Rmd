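---
title: "Contrast matching and hierarchical model fitting for bio-SANS"
author: "sanstools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contrast matching and hierarchical model fitting for bio-SANS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sanstools)
```

## Scope and assumptions

`sanstools` supports small-angle neutron scattering (SANS) studies of
systems in which a soluble biomolecule interacts with a large, insoluble
partner — the motivating case is a multidomain protein decorating
polysaccharide (chitin) nanofibers. Three pieces of analysis recur in such
studies and are implemented here:

1. **Contrast matching.** Neutron scattering contrast is the difference
   between a component's scattering-length density (SLD) and the
   solvent's. Because H and D have coherent scattering lengths of opposite
   sign, an H2O/D2O mixture can be tuned until a chosen component becomes
   invisible. The package computes SLDs, closed-form match points, and the
   integrated-intensity estimator used to locate a match point from a
   measured contrast series.
2. **Form-factor models.** Semiflexible nanofibers are described by a
   wormlike-chain ("flexible cylinder") model with excluded-volume
   corrections and a circular cross-section, plus a low-q power law for
   scattering from large, sharply bounded clusters. Hierarchical
   protein–fiber aggregates, which have no tractable geometric model, are
   described by the empirical unified model of Beaucage with two
   structural levels. Elongated multidomain proteins are described by a
   chain of ellipsoids on a random walk.
3. **Constrained weighted fitting** of those models, with the constraints
   that fiber data require (fixed contour length, a hard upper bound on
   every radius of gyration at $\pi/q_{\min}$) and a two-stage protocol
   for the multi-level unified model.

Throughout, $q$ is in $\mathrm{\AA}^{-1}$, lengths in $\mathrm{\AA}$,
intensities in $\mathrm{cm}^{-1}$, and SLDs in
$10^{-6}\,\mathrm{\AA}^{-2}$.

## Scattering-length densities and match points

For a molecule (or polymer repeat unit) with element counts $n_e$, mass
density $\rho$ and molar mass $M$, the SLD is $\sum_e n_e b_e / V$ with
$V = M/(\rho N_A)$ and $b_e$ the tabulated bound coherent scattering
lengths (Sears 1992), embedded as constants. Three kinds of hydrogen are
distinguished:

* non-labile H, a fraction `deuteration` of which is D (biosynthetic
  perdeuteration);
* labile (N–H/O–H) hydrogens, a fraction
  `exchange_fraction` $\times f_{\mathrm{D_2O}}$ of which carry $b_D$;
* solvent hydrogens, handled by a linear solvent line between the SLDs of
  pure H2O ($-0.56$) and pure D2O ($+6.36$), computed from the measured
  densities 0.997 and 1.105 g/mL.

Both the composition SLD and the solvent SLD are affine in
$f_{\mathrm{D_2O}}$, so the match point is solved in closed form; values
outside $[0,1]$ are reported as-is and flagged unreachable. Defaults:
`exchange_fraction = 1` (full labile exchange). This is configurable
because real materials — crystalline polysaccharides especially — exchange
incompletely, have density heterogeneity between crystalline and amorphous
regions, and carry residual impurities, so closed-form predictions are
estimates to be confirmed experimentally. The molecular volume is taken
from the mass density alone (no partial-specific-volume tables), and the
volume is treated as independent of deuteration; for the chitin repeat
unit (C8H13NO5, three exchangeable H, $\rho = 1.5$ g/mL) the closed form
gives:

```{r matchpoint}
chitin <- molecular_composition("C8H13NO5", labile_h = 3, density = 1.5)
match_point(chitin)
```

The **series estimator** (`match_point_from_series()`) mirrors the
experimental procedure: each curve of a contrast series is integrated over
a q-window (default 0.03–0.4 $\mathrm{\AA}^{-1}$) with the trapezoid rule
on its native grid — no interpolation assumptions — and the integrated
intensity is regressed on $f_{\mathrm{D_2O}}$ with a second-degree
polynomial whose minimum is the estimate. Since scattered intensity is
proportional to contrast squared, which is an exact quadratic in
$f_{\mathrm{D_2O}}$, this estimator is unbiased for an ideal series; a
downward-opening or degenerate parabola is rejected as having no interior
minimum.

## The flexible-cylinder model

Fiber curves are fit with

$$ I(q) = \alpha_1\, P_{\mathrm{flex}}(q; R, L_C, b) + \alpha_2 q^{-D} + c $$

where $P_{\mathrm{flex}}$ is the wormlike-chain scattering function times
the circular cross-section factor $[2 J_1(qR)/(qR)]^2$, normalized to 1 at
$q = 0$. The chain function follows the "method 3" parameterization of
Pedersen & Schurtenberger (1996) with excluded-volume corrections, the
form implemented in the community-standard flexible-cylinder models:

* $R_g^2 = \alpha^2(n)\, L b/6$ with
  $\alpha^2(x) = [1 + (x/3.12)^2 + (x/8.67)^3]^{0.176/3}$ and $n = L/b$
  Kuhn segments (Benoit–Doty finite-length factor for short chains);
* at low q, a crossover
  $w(qR_g) = \tfrac12[1 + \tanh((qR_g - 1.523)/0.1477)]$ blends the Debye
  coil function into the excluded-volume expansion
  $C_1 x^{-1/\nu} + C_2 x^{-2/\nu} + C_3 x^{-3/\nu}$
  ($\nu = 0.585$, $C_1 = 1.22$, $C_2 = 0.4288$, $C_3 = -1.651$), plus the
  local-stiffness correction term with weight $3.06\,n^{-0.44}$ for
  $n > 10$;
* at $qb > 3.1$ a two-term power law $a_1 (qb)^{-4.12} + a_2 (qb)^{-4.42}$
  plus the rod term $\pi/(qL)$ takes over, with $a_1, a_2$ determined by
  continuity of value and slope at the crossover.

Two numerical choices are worth recording. First, the tanh crossover
weight tends to a small positive constant as $qR_g \to 0$ while the
$C_3 x^{-3/\nu}$ term diverges, so the weight is clamped to zero below
$qR_g = 1$; the discontinuity this introduces is $O(10^{-6})$. Second, the
$C_1..C_3$ interpolant is mildly non-monotone around $qR_g \approx 2$ — a
known artifact of the parameterization — and is replaced by its running
minimum in $q$, evaluated on a dense internal grid so the envelope does
not depend on the caller's q-grid; the envelope is continuous and
identical to the raw interpolant wherever it is already decreasing.

Chains with fewer than four Kuhn segments are nearly rigid. There the
package blends the *exact* orientation-averaged rod form factor with a
Debye/power-law construct ($p_1 = 5.36$, $p_2 = 5.62$), with weight
$(4 - n)/3$ clamped to $[0,1]$, so the rigid-rod limit is reached exactly
for $b \ge L$. The model is therefore discontinuous in its parameters at
$n = 4$; fits of semiflexible fibers are kept away from that boundary (see
below). An independent Python implementation of the same equations ships
in `inst/oracle/` and is used by the test suite as a coding cross-check.

The power-law term with free decay exponent $D$ captures Porod scattering
from interfaces below the fiber signal; $D \approx 4$ indicates sharp,
solvent-impenetrable interfaces. $\alpha_1$ is treated as a free scale in
$\mathrm{cm}^{-1}$ (it absorbs contrast squared, number density and
volume), so fits do not require absolute-scale bookkeeping.

## The unified (Beaucage) model

Aggregate curves are fit with the $N$-level unified model

$$ I(q) = c + \sum_{i=1}^{N}\Big[ G_i e^{-q^2 R_{g,i}^2/3}
 + B_i e^{-q^2 R_{g,i+1}^2/3}\, (1/q_i^*)^{D_i} \Big], \qquad
 q_i^* = \frac{q}{[\operatorname{erf}(q R_{g,i}/\sqrt 6)]^{3}} $$

with levels ordered largest first and $R_{g,N+1} = 0$ (the last level's
power law has no high-q cutoff — the standard convention when the smallest
level has no sub-structure). The power term is evaluated as
$[\operatorname{erf}(qR_g/\sqrt6)]^{3D} q^{-D}$, which vanishes like
$q^{2D}$ as $q \to 0$ instead of dividing by a vanishing error function.
$G$ and $B$ are independent fit parameters; the Beaucage-consistent value
of $B$ given $(G, R_g, D)$ is available (`beaucage_consistent_B()`) and is
used for starting values and for constructing self-consistent synthetic
levels.

## Fitting

`fit_curve()` minimizes $\sum_k [(I_k - I_{\mathrm{model}}(q_k))/\sigma_k]^2$
with Levenberg–Marquardt least squares under box constraints
(`minpack.lm`). Design choices, several of which settle questions the
model family leaves open:

* **Weighting** defaults to $1/\sigma^2$ with the reported one-standard-
  deviation uncertainties; uniform weighting is available.
* **Log-scale optimization** for strictly positive shape parameters
  ($R_g$, radius, Kuhn and contour length) for conditioning across
  decades; scale parameters stay linear so they can collapse to exactly
  zero (a spurious level's $G$ or $B$ should be allowed to vanish).
* **Uncertainties** are $1\sigma$, from
  $(J^TJ)^{-1}\chi^2_{\mathrm{red}}$ at the optimum with column-scaled
  inversion; a singular information matrix yields `NA` markers rather than
  numbers. $\chi^2$ is reported *reduced* (per degree of freedom) and
  labelled as such.
* **Multi-start** (seeded, perturbations of 0.4 in the transformed space)
  mitigates the multimodality of unified models; the unperturbed start is
  always included, so the final result can never be worse than its
  starting point.
* **Non-convergence is data**, reported in the result status, never
  thrown.
* **Resolution:** if the curve records a relative q-resolution, the model
  is smeared with a Gaussian of width $\sigma_q = (\Delta q/q)\,q$ by
  Gauss–Legendre quadrature during fitting, matching how the synthetic
  curves are generated.

`fit_beaucage_two_stage()` implements the two-level protocol: each level
is first fit alone — level 1 on the low-q side, level 2 on the high-q side
of a split at the geometric mean of the q-range (the natural midpoint on a
log grid; configurable) — and the combined nine-parameter fit starts from
those estimates. Both $R_g$ are bounded by $\pi/q_{\min}$ so no reported
size lies outside the measured window; estimates pinned at that bound are
flagged in the constraint log. If a stage-1 sub-fit fails, heuristic
Guinier/power-law starts are substituted and a warning is recorded.

`fit_chitin_reference()` is the fiber protocol: contour length fixed
(default 5000 $\mathrm{\AA}$, about $2\pi/q_{\min}$ for a typical pinhole
q-range — fibers much longer than the window cannot be sized, so the
parameter is pinned just above it) and a kuhn upper bound at
`contour/4.2` to keep the fit in the semiflexible regime, away from the
$n = 4$ branch boundary. Because the Kuhn direction is strongly coupled to
the low-q power law, a cold joint start regularly falls into a spurious
basin; the protocol therefore first fits everything except the Kuhn
length, then releases it (multi-start) from the phase-1 optimum.

## Synthetic data

`generate_curve()` evaluates any package model on an instrument-like grid
(log-spaced by default), applies Gaussian resolution smearing, and adds
seeded Gaussian noise with $\sigma = \max(\mathrm{rel}\cdot I,
\mathrm{floor})$. Gaussian multiplicative noise — not Poisson counts — is
the right statistical structure for *reduced* SAS data, whose error bars
are Gaussian-propagated one-standard-deviation estimates. Two presets
bracket the use cases: a pinhole-SANS grid (0.0013–0.4102
$\mathrm{\AA}^{-1}$, 9% wavelength spread) and a USANS grid
($5\times10^{-5}$–$10^{-3}$ $\mathrm{\AA}^{-1}$).

`generate_contrast_series()` simulates the match-point experiment: one
fixed normalized shape (a rigid nanofiber by default: $R = 16$,
$b = 318$, $L = 5000\ \mathrm{\AA}$) scaled by squared contrast at each
D2O fraction, with the six-fraction default series 0, 20, 42, 66, 80,
100%. H/D-exchange-induced shape changes and the different incoherent
backgrounds of H2O and D2O buffers are *not* modelled beyond a flat
background term — the assumptions the integrated-intensity estimator
itself makes.

What passing the recovery tests does and does not show: the generator
draws from the same model families the fits assume, so recovery tests
demonstrate the estimation machinery (identifiability, constraints,
calibration of $\chi^2$ and uncertainties) under the stated noise — they
do not probe model misspecification on real fibers (polydispersity,
elliptical cross-sections, structure factor from fiber–fiber
correlations, H/D-dependent incoherent backgrounds), which real data
contain.

## Problem sizes and known limitations

The shipped tests and examples use 120–150 point grids, 2–3% relative
noise, single fits per protocol and a 50-replicate $\chi^2$ calibration
study with a three-parameter model — sizes chosen so the whole suite runs
in well under a minute while leaving every estimate's uncertainty far
below the tolerances being asserted.

* The largest structural level of a two-level aggregate typically has its
  Guinier region at or beyond the low-q edge of the window
  ($q_{\min} R_{g,1} \gtrsim 2$); its $R_g$ is then weakly identified,
  with 10–20% scatter across noise realizations and occasionally larger —
  which is why the $\pi/q_{\min}$ bound and the at-bound flag exist. The
  second level's $R_g$ and both decay exponents are robust.
* USANS slit smearing and desmearing are not implemented; only the grid
  preset is provided.
* The solvent line idealizes mixing as linear between the endpoint SLDs;
  a solute identical to water reproduces the line exactly at $f = 0$ and
  to ~0.3% at $f = 1$ (excess-volume effects are ignored).
* The wormlike-chain parameterization is an interpolation formula;
  outside $qb \in [10^{-3}, 10]$ or for exotic parameter ratios its
  accuracy is inherited from the published fits to simulation data.
* Experimental match points from real series (incomplete exchange,
  density heterogeneity, impurities) can differ from the closed form by
  several percent D2O; the closed form is a planning tool, not a
  substitute for the measurement.
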