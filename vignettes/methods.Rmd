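---
title: "Models and numerical methods in PumpProbeTools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical methods in PumpProbeTools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PumpProbeTools)
```

PumpProbeTools implements the two quantitative procedures at the heart of
pump-probe studies of reversibly switchable fluorescent proteins (RSFPs):
global lifetime analysis of transient UV-visible absorption data, and the
difference-structure-factor analysis of time-resolved crystallography
(q-weighted difference maps, extrapolated structure factors, and the
alpha-scan occupancy estimator). Both are exercised end to end on
synthetic data with known ground truth. This vignette explains the models,
the tunable parameters, the numerical choices, and what passing tests do
and do not demonstrate.

## Global lifetime analysis

### Model

The transient difference absorbance on a wavelength-by-delay grid is
modelled as a weighted sum of exponential ground-state relaxations sharing
time constants across all wavelengths:

$$\Delta A(\lambda, t) \;=\; \sum_{i=1}^{k} \mathrm{DAS}_i(\lambda)\,
e^{-t/\tau_i},$$

where the per-wavelength weights $\mathrm{DAS}_i(\lambda)$ are the
decay-associated spectra. A negative DAS amplitude at a wavelength means
the band *grows* with that time constant (each component relaxes toward
zero). The least-squares objective is unweighted across cells: no
per-point statistical weights are applied, since the measurement model
supplies none.

### Variable projection

`fitGlobal()` exploits the separability of the model. For trial time
constants the DAS are the exact solution of a linear least-squares
subproblem (one shared normal-equation solve for all wavelengths); only
the $k$ time constants are nonlinear parameters. They are refined with
the Levenberg-Marquardt minimizer (`minpack.lm::nls.lm`) on the projected
residual, in $\log\tau$ coordinates so positivity is structural and the
step scale is relative. Convergence uses a relative chi-square tolerance
of `ftol = 1e-10` with a 500-iteration cap; non-convergence is flagged on
the result object, never silent.

Initialisation matters for multi-exponential fits. By default eight
starts are drawn from log-spaced $\tau$ grids spanning the delay range,
shifted by a factor of $10^{0.2}$ between starts, and the best final
chi-square is kept. Supplying `initTaus` suppresses the multi-start
(used, for example, by the bootstrap refits, which start from the best
fit). Adjacent optimal time constants closer than a ratio of 1.05 are
reported as degenerate, since separate exponentials are then barely
identifiable.

Standard errors of the time constants come from the curvature matrix of
the projected functional at the optimum (the Jacobian is that of the
reduced problem, so the elimination of the DAS is accounted for), scaled
by the residual variance with the linear DAS parameters counted in the
degrees of freedom, and mapped from $\log\tau$ by the delta method.

### Residual-shuffling bootstrap

Curvature-matrix errors assume the fitted parameters are the truth, so
`bootstrapFit()` estimates parameter spread by refitting replicate
datasets: each replicate is the best-fit reconstruction plus the residual
matrix with a uniformly chosen 25% of its entries permuted among
themselves (values conserved). The shuffled-subset reading keeps the
marginal residual distribution exactly; resampling with replacement is
available as an option (`resample = TRUE`). Replicates whose refit fails
to converge are excluded and counted. With `shuffleFraction = 0` every
replicate equals the original data and the spreads collapse to exactly
zero, a useful degeneracy check.

### Isotope comparison

`isotopeRatios()` matches components of two fits by ascending-$\tau$ rank
and reports $\tau_D/\tau_H$, which equals the kinetic isotope effect
$k_H/k_D$ because $k = 1/\tau$. Rank matching is the natural pairing when
the same three-step relaxation is measured in both solvents; ratios near
2-2.5 flag proton-transfer steps, ratios near 1 flag steps without
proton motion.

### The synthetic spectra

`buildReferenceScheme()` fixes the ground truth for four measured
conditions (H2O, D2O, microcrystal suspension, ammonium-sulfate buffer)
using the published condition-specific time constants. The DAS shapes are
*not* tabulated anywhere, so the package fixes them once as signed sums
of Gaussian bands reproducing the qualitative band structure of the
photocycle: component 1 grows the 460-nm band while 390 nm decays,
component 2 carries the 460-to-480-nm band shift and the negative band
near 410-420 nm, component 3 carries the final 390-nm decay and 480-nm
growth. Absolute delta-A scales are conventional (order 0.1-1). An
optional static offset for a residual fraction of molecules left in the
on-state is available and disabled by default.

The acquisition grid reproduces the instrument's three delay windows
(10 ns to 5 us at 500 ps/point, 5 us to 100 us at 10 ns/point, 100 us to
10 ms at 1 us/point); `thin` subsamples each window while preserving its
endpoints and structure. Tests and the acceptance analyses run on
thinned grids (50-100x, i.e. 300-600 delay points), which keeps fits
well-conditioned — the thinned grid still samples each decade of the
relaxation — at problem sizes a laptop handles in seconds; these sizes
are the package's chosen study conditions for its own verification.
Additive Gaussian noise with `sigma = 0.01` delta-A units (about 1% of
the band amplitudes) stands in for a realistic flash-photolysis noise
floor.

What the generator does *not* emulate: instrument response convolution,
pump-energy fluctuation, wavelength-dependent noise, detector
nonlinearity, or any branched/target kinetic scheme. Parameter-recovery
results on these synthetics therefore demonstrate the correctness of the
estimator, not the information content of any particular real
measurement.

### The picosecond window

The early-time analysis (tens of ps to 2 ns, one ~87 ps component plus a
stimulated-emission band) needs no separate code path: a 1-component
`fitGlobal()` over a grid restricted to that window covers it.

## Crystallographic difference analysis

### Structure factors and maps

Toy models are a handful of C/N/O atoms in a P1 cell (default
20 x 20 x 20 Angstrom), small enough that direct-summation oracles are
affordable. Kinematic structure factors use tabulated 4-Gaussian form
factors, isotropic Debye-Waller damping, and occupancies; one unique
hemisphere is stored with Friedel mates implied. Map synthesis places
each coefficient and its Friedel conjugate on the FFT grid, so maps are
real by construction; grids are chosen with spacing at most `dmin`/3 and
FFT-friendly sizes. Maps are stored in sigma units (grid rms), matching
how difference maps are contoured and integrated in practice.

### q-weighting

The q-weighting procedure down-weights difference amplitudes whose
uncertainty is large compared with the difference signal. The exact
published formula of the cited scheme is not reproduced in the source
text, so the package adopts a binned Bayesian shrinkage estimator
documented as an approximation of it: in equal-count resolution bins
(default 10), the signal variance is
$V_s = \max(0, \langle \Delta F^2\rangle - \langle\sigma^2_{\Delta
F}\rangle)$ and each reflection gets
$q_h = V_s/(V_s + \sigma^2_{\Delta F,h})$, floored at 0.01. Noiseless
data give $q \equiv 1$; pure-noise differences collapse to the floor.

### Extrapolated structure factors

Extrapolation operates on amplitudes, as printed:

$$F_{ext} = \alpha\,\frac{q}{\langle q \rangle}\,(F_{on} - F_{off}) +
F_{off}, \qquad \alpha = 1/\mathrm{occupancy} \ge 1 .$$

Negative extrapolated amplitudes are unphysical; they are clamped to
zero and counted, and the clamp count is monotone non-decreasing in
$\alpha$. Amplitude-space extrapolation is a first-order approximation
to the underlying complex mixture
$F_{on} = (1-f)F_{off} + f F_{int}$; it is accurate when the
conformational change perturbs a modest share of the total scattering.
The toy generator therefore displaces 2 of 10 atoms by 1-2 Angstrom by
default — the smallest displaced share consistent with a non-trivial
difference map — and the tests verify that at a noiseless 50% mixture
the $\alpha = 2$ extrapolation reproduces the pure-intermediate
amplitudes to a few percent (median; about 4% at 2.5 Angstrom
resolution, degrading to ~6% at 1.5 Angstrom, where 1-2 Angstrom
displacements decorrelate the two states' contributions).

### The alpha-scan and why it needs an imperfect model

`alphaScan()` scans $\alpha$, synthesizes the
$F_{ext} - F_{calc}$ map for each value (phases and calculated
amplitudes from the supplied off-state model), integrates
absolute density at or beyond 3 sigma within 2 Angstrom of the given
sites, and divides by the same integral of the q-weighted observed
difference map, which does not depend on $\alpha$. The occupancy
estimate is $1/\alpha^{*}$ at the curve's argmax (ties broken toward
smaller $\alpha$, and an essentially flat curve — max/min below 1.01 —
is flagged indeterminate rather than trusted).

The shape of this curve deserves an honest account, because the package's
synthetic world exposes a condition that real experiments satisfy
implicitly. The rising branch of the ratio curve is produced by the
static, $\alpha$-independent background that the imperfect phase model
contributes to the $F_{ext} - F_{calc}$ map (in $\sigma$ units, the
light-induced features grow with $\alpha$ *relative to* that fixed
background). The falling branch is produced by the degradation of the
extrapolated data once $\alpha$ exceeds the physical $1/f$: amplitudes
systematically cross zero and are truncated, which injects
model-density-shaped artefacts and inflates the map rms. The maximum
therefore sits near $1/f$ — but only if a model-error background exists.
With a mathematically exact calculated model (available only in a
synthetic world) the rising branch vanishes and the argmax degenerates
toward the grid origin. For this reason `buildToyPair()` returns,
alongside the ground-truth models, a `refined` replica of the off state
with a 0.15 Angstrom rms coordinate error — the typical accuracy of a
model refined at ~1.5 Angstrom resolution — and the scan is run against
that replica, exactly as a real analysis runs against a refined model
rather than the truth. The 0.15 Angstrom figure was fixed once, from
refinement-accuracy realism, not adjusted afterwards.

Two practical notes follow. First, the curve's maximum is broad: between
roughly $0.8/f$ and $1.3/f$ the ratio varies by well under one percent,
so the per-run argmax scatters by a few tenths in $\alpha$ even at 2%
amplitude noise, and estimates should be read as medians over replicate
syntheses (the pipeline reports per-run curves so this is visible). On
these toys the median estimate carries a residual upward bias of roughly
10-30% in $\alpha$ (the saturation of the rising branch trails the
truncation onset), so a 50% mixture typically reads out as
$\alpha^{*} \approx 2.2$-$2.8$ rather than exactly 2.
Second, the estimator inherits a mild upward bias when integration sites
coincide with model atom positions, because truncation artefacts
reconstruct (negative) model density precisely there; integrating the
appearing features — the displaced atoms' *intermediate* positions —
avoids that term.

### Degenerate inputs and tie-breaks

`on == off` gives an identically zero difference map (rms 0 is kept and
sigma-scaling is skipped); extrapolation then returns `F_off` exactly for
every alpha. A fraction-1 noiseless mixture scanned against an exact
model gives a flat-then-declining curve whose tie-break lands on
$\alpha^{*} = 1$, i.e. occupancy 100%. Argmax ties are resolved with a
relative tolerance of 1e-9 toward smaller alpha so that floating-point
noise on an exactly flat curve cannot push the estimate upward.

## Design choices that were genuinely open

- **Bootstrap "shuffling"**: read as permutation of a random 25% subset
  of residual entries; resampling with replacement is exposed as an
  option but not the default.
- **Component matching across conditions**: by ascending-tau rank.
- **Convergence rule**: relative chi-square change below 1e-10 or 500
  iterations; the historical "chi-square below 1e-5" check is reported
  as a diagnostic only, since its normalisation is not defined.
- **q-weight formula**: binned shrinkage estimator (above), bin count
  10, floor 0.01.
- **Alpha grid**: default 1.0-6.0 in steps of 0.1; integration radius
  2.0 Angstrom; threshold 3 sigma. All configurable.
- **Delay-window averaging**: the spectrum at delay $t$ averages the 10
  nearest surrounding delay columns (5 each side, centre excluded);
  window joins hold no duplicate delays by construction.
- **Negative extrapolated amplitudes**: clamped at zero and counted
  (the alternative — keeping them — has no physical reading for an
  amplitude).

## Known limitations

- P1 only; no space-group symmetry, scaling, bulk solvent, or
  refinement. Occupancy estimation replaces difference refinement
  entirely.
- Form factors cover C, N, O, S.
- The alpha-scan's accuracy depends on the realism of the model-error
  background and is intrinsically limited by the broad maximum of its
  ratio curve; on these toys the spread of single-run estimates is a
  few tenths in alpha (see above), so recovering an occupancy to better
  than ~10% from a single synthetic run should not be expected.
- The spectroscopic generator's DAS shapes are conventional; only their
  qualitative band structure is meaningful.
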