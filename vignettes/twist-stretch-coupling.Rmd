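---
title: "Harmonic twist-stretch coupling of DNA and RNA duplexes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Harmonic twist-stretch coupling of DNA and RNA duplexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

Double-stranded DNA lengthens when it is overtwisted; double-stranded RNA
shortens. Both behaviours are captured by a single off-diagonal element of
a 2x2 stiffness matrix over two global coordinates of a duplex segment:
its total helical twist $\omega$ (the sum of the step twists, in degrees)
and its length $l$ (the sum of the helical rises, in Angstrom). This
package implements that harmonic model end to end: a calibrated Gaussian
generator of helical-coordinate ensembles, three independent estimators of
the coupling coefficient, and a rigid base-pair geometry engine that shows
*why* the two helical topologies couple twist and stretch with opposite
signs.

## The model

The deformation energy of a segment is assumed quadratic,
$$E = \tfrac12\, \Delta w^\top K\, \Delta w, \qquad
\Delta w = (\omega - \omega_0,\; l - l_0),$$
with $K$ symmetric positive definite. Completing the square shows that at
fixed twist deviation $\Delta\omega$ the energy-minimizing elongation is
$\Delta l = -(k_{12}/k_{22})\,\Delta\omega$: the stiffness-matrix form of
the twist-stretch coupling. In the canonical ensemble $K$ is tied to the
coordinate covariance $C$ by the fluctuation relation $K = k_B T C^{-1}$,
which turns the coupling into pure covariance ratios:
$$\left.\frac{\Delta l}{\Delta\omega}\right|_{\rm constr} =
\frac{c_{12}}{c_{11}} \quad\text{(A/deg)}, \qquad
\left.\frac{\Delta \omega}{\Delta l}\right|_{\rm constr} =
\frac{c_{12}}{c_{22}} \quad\text{(deg/A)}.$$
`twist_stretch_fit()` estimates $C$ from a snapshot series (unbiased
$n-1$ covariance), inverts it at $k_B = 0.0019872$ kcal/mol/K, and
reports both coefficients; `deformation_energy()`,
`constrained_minimum()`, `stiffness_from_cov()` expose the pieces.
Degrees and Angstrom are kept throughout, so the coupling comes out in
the conventional A/deg without unit gymnastics.

```{r}
library(twistretch)
spec <- plant_coupling(duplex_preset("dna", seed = 1), 0.032)
series <- sample_ensemble(spec, n_snapshots = 20000)
fit <- twist_stretch_fit(series, n_boot = 200, seed = 2)
fit
```

## What the generator emulates, and what it does not

`duplex_preset()` encodes the stationary fluctuation statistics of 16-bp
duplex simulations: per-step means and SDs (DNA: mean twist 32.0&deg;,
twist SD 1.1&deg;, rise SD 0.11 A; RNA: 31.5&deg;, 0.9&deg;, 0.15 A, with
the A-form geometry x-disp $-4.4$ A, inclination 17.5&deg;, rise 2.67 A),
a 6x6 intra-step correlation block, and a nearest-neighbour twist
anti-correlation of $-0.3$. The *signs* of the intra-step couplings are
the physically established ones (DNA: twist-rise $+$, twist-inclination
$-$; RNA: twist-rise $-$, twist-inclination $+$; both: twist up pulls
x-displacement toward the axis). Their default magnitude $|r| = 0.3$ is a
calibration, not a measurement: full cross-correlation matrices of such
simulations are not published, so downstream analyses must not treat the
preset magnitudes as data. When an exact coupling is needed,
`plant_coupling()` adjusts the twist-rise correlation so that
$c_{12}/c_{11}$ over a 10-step window equals a chosen value -- the
package's ground-truth mechanism, used with $\pm$ the experimental-scale
magnitudes $+0.032$ and $-0.037$ A/deg throughout the tests.

Snapshots are drawn i.i.d. from the assembled $6 n_{bp}$-dimensional
Gaussian. Real trajectory frames are autocorrelated and mildly
anharmonic; neither feature is modelled, because every analysis here
consumes stationary moments only. Consequently, standard errors from this
generator are smaller than those of a dynamical trajectory at equal
length, and passing tests demonstrate the correctness of the estimators,
not the accuracy of any force field. The `snapshot_spacing` field is
carried as pure metadata.

Defaults chosen once and kept: 16 bp with the central 10 steps analyzed
(`inner_window()`), mirroring the standard exclusion of frayed termini;
$10^5$ snapshots as the canonical ensemble size; a single integer seed
drives one central generator so that every result is bit-reproducible.

## Three routes to the coupling

1. **Covariance route.** `covariance2()` on `global_coords()`;
   uncertainty by plain snapshot bootstrap (`bootstrap_coupling()`),
   appropriate because snapshots are exchangeable.
2. **Binned regression.** `bin_xy()` buckets per-snapshot window means of
   twist into 0.2&deg; intervals anchored at multiples of the width and
   records the within-bin means of *both* coordinates with their SEMs
   (both axes are interval averages, so both carry error bars);
   `fit_slope()` runs weighted least squares (weights $1/\mathrm{SEM}^2$,
   an unweighted option is provided) over the bins within
   $\pm 1.5$&deg; of the global mean twist, regressing the y means on the
   x means rather than on bin centers -- using centers would add a small
   discretization bias that the mean-x abscissa removes exactly for
   linear data. Bins under 50 points are dropped; anchoring and the
   minimum count are this package's choices, the 0.2&deg; width and
   $\pm1.5$&deg; window the conventional ones.
3. **Torque scan.** `torque_scan()` adds a quadratic restraint
   $\tfrac12 k(\omega_R - \omega_{\rm ref})^2$ on the total twist of a
   restrained window (default force constant 0.015 kcal/mol/deg$^2$,
   setpoints every 2.5&deg;) to the implicit Gaussian energy and tracks
   the equilibrium helical parameters -- the in-silico analogue of a
   torque-tweezer setpoint scan. For a Gaussian the tilt is exact
   (rank-one covariance downdate, mean shift along $\Sigma a$), so the
   analytic mode needs no sampling; the Monte-Carlo mode draws from the
   tilted Gaussian and reports errors from five contiguous blocks.

For a harmonic model the scan's rise-vs-twist slope equals the
unrestrained $c_{12}/c_{11}$ *of the restrained coordinate*, for any
restraint strength -- a theorem the tests assert to $10^{-10}$. One
subtlety is worth stating plainly: the conventional protocol restrains 12
central steps but analyzes the inner 10. When neighbouring step twists
are correlated, the slope measured over a strict sub-window is close to,
but not exactly, the sub-window's own $c_{12}/c_{11}$ (the restraint
reaches the analysis window partly through the neighbour terms). The scan
therefore reports both the analysis-window slope (the quantity usually
plotted) and the restrained-window slope (the quantity the theorem pins);
with the package defaults they differ by a few percent.

A fourth, purely visual route is the occupancy free-energy surface
`pmf_surface()`, $-k_BT\ln(\rho/\rho_{\max})$ over (mean twist, mean
rise) cells, capped at 35 kcal/mol and masked below 10 counts per cell.
It is a population analogue of an energy histogram, not a force-field
energy; only the orientation of its low-energy valley (positive tilt for
DNA-like, negative for RNA-like coupling) is asserted anywhere.

## The geometric mechanism

`build_duplex()` stacks rigid base-pair frames along a global +z axis:
cumulative phase and height from the step twists and rises, orientation
$R_z(\varphi)R_x(\eta)R_y(\tau)$ (z-x-y Euler order), origin displaced by
(x-disp, y-disp) in the rotated frame. The first base pair anchors the
model at phase 0, height 0, and its own step parameters are defined as
zero -- this makes `extract_params()` an exact inverse (round-trip
residuals $<10^{-8}$ over randomized parameter sets) without ever
fitting local helical axes; extraction from curved duplexes is
deliberately out of scope. Inclination or tip at $\pm90$&deg; is
rejected (Euler degeneracy) rather than wrapped. Step twists are
reported in $(-180, 180]$; the cumulative phase is kept unwrapped.

`stack_to_rise()` captures the core mechanism: hold the stacking
distance between neighbouring pairs fixed (the component of the
inter-origin vector along the mean base normal, root-found to
$10^{-10}$ A against the builder itself) and ask what helical rise
results. For an inclined, displaced helix the in-plane chord set by
twist and x-displacement eats into the stack, so rise must respond --
and the direction of the response depends on the helical topology.
Families of structures built this way reproduce both behaviours as pure
geometry, with no energetics at all: B-DNA-like trends (twist up,
inclination down, displacement toward the axis) give strictly increasing
extension, A-RNA-like trends (twist up, inclination up, displacement
inward from $-4.8$ to $-4.0$ A) give strictly decreasing extension and a
sharply closing major groove.

Groove widths are measured between backbone proxy points fixed in each
base-pair frame at $(-3.0, \pm 8.8, 0)$ A, minus the standard 5.8 A
phosphate-radius correction, floored at zero. The proxies are a
calibration chosen so that the canonical B build (36&deg;/3.4 A) yields
the textbook 5.8 / 11.8 A minor/major pair with the narrow groove in the
negative register direction; that assignment is then fixed. For each
interior pair the metric takes the minimal cross-strand proxy distance
over register offsets $2 \ldots \mathrm{round}(360^\circ/\bar\Omega)-2$
on either side -- almost a full turn rather than the nominal half turn,
because a half-turn cutoff makes the candidate set jump discontinuously
whenever the twist crosses an integer half-turn register, which would put
spurious steps into groove-vs-twist trends. Models must span about two
turns. Note that groove conventions differ between analysis tools; this
proxy metric tracks the axis-measured trend (the A-form major groove
closes on overtwisting) and is not expected to reproduce curvilinear
groove definitions, under which the major-groove trend can even change
sign.

## Analytic fluctuation estimates

`fluctuation_estimates()` converts macroscopic moduli into per-step
thermal fluctuation scales: bend $\theta = \sqrt{2h/P}$, twist
$\tau = \sqrt{h/(2\pi^2 C)}$, rise $z = \sqrt{k_BT\,h/S}$ ($P$, $C$
persistence lengths in nm, $S$ the stretch modulus in pN, $h$ the rise
in nm, $k_BT$ in pN nm). The formulas are implemented verbatim. With the
commonly quoted moduli ($P=50$ nm, $C=109$ nm, $S=1000$ pN, $h=0.34$ nm)
they give $\theta = 6.7$&deg;, $\tau = 0.72$&deg;, $z = 0.37$ A at 300 K.
Literature summaries sometimes quote slightly different numbers for the
same formulas (notably a rise fluctuation near 0.14 A); those values are
not recoverable from these expressions with these inputs, and the
package makes no attempt to tune inputs to reproduce them.

## Numerical choices and edge cases

* Positive definiteness of the assembled $6 n_{bp}$ covariance is
  enforced by Cholesky at spec construction; `plant_coupling()` reports
  the feasible coupling interval (found by bisection against the same
  test) when a target is unreachable.
* The sample covariance container tolerates the singular boundary
  (perfectly correlated coordinates) so that degenerate data can be
  represented; inversion into a stiffness fails there, with a clear
  error.
* `block_errors()` splits contiguously, remainder to the last block, and
  reports the SD across block means -- with five blocks this is the
  usual trajectory error bar.
* Windows are 1-based contiguous index ranges everywhere in the R API;
  series files label snapshots and base pairs 0-based.
* Bootstrap and sampling determinism: every stochastic function takes a
  seed and restores the caller's RNG state.

## Problem sizes

The test suite runs the full-scale analyses at $10^5$ snapshots (the
canonical ensemble size for this model class) for the oracle-equivalence
and recovery checks, $2\times10^4$--$5\times10^4$ for sign and variance
checks, and a thousand randomized parameter sets for the geometric
round trip; the complete suite finishes in about a minute on one core.
`scripts/acceptance.R` re-derives the headline numbers (couplings by all
three routes for both presets, the variance ratio, fluctuation
estimates, groove widths) from scratch at the same sizes.

## Known limitations

* No sequence dependence: steps are statistically identical; labels are
  carried but never used.
* No bending degrees of freedom and no 6x6 step stiffness -- only the
  two-coordinate global model.
* The generator's Gaussianity means anharmonic effects (e.g. twist-state
  bimodality) are out of reach by construction.
* Groove widths use proxy phosphates on rigid frames; they are
  calibrated for trend work, not for absolute comparison with
  curvilinear groove analyses.
* No all-atom reconstruction or energy minimization; `write_pdb()`
  emits pseudo-atom markers for visual inspection only.
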