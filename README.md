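# PumpProbeTools

Analysis toolkit for pump-probe studies of reversibly switchable
fluorescent proteins (RSFPs) and similar photoactive systems, covering the
two quantitative workhorses of such studies:

1. **Global lifetime analysis** of transient UV-visible absorption
   matrices ΔA(λ, t): a variable-projection multi-exponential fit with
   shared time constants and per-wavelength decay-associated spectra
   (DAS), curvature-matrix and residual-shuffling-bootstrap uncertainty
   estimates, residual diagnostics, and kinetic isotope-effect comparison
   (τ_D/τ_H = k_H/k_D) across H₂O/D₂O conditions. Model:

   ΔA(λ, t) = Σᵢ DASᵢ(λ) · exp(−t/τᵢ)

2. **Time-resolved crystallographic difference analysis** on toy P1
   models: kinematic structure factors, Bayesian q-weighted difference
   Fourier maps, extrapolated structure factors

   F_ext = α · (q/⟨q⟩) · (F_on − F_off) + F_off,

   peak integration around sites of interest, and the α-scan occupancy
   estimator (occupancy = 1/α\* at the maximum of the peak-integral ratio
   curve).

Synthetic-data generators with known ground truth (reference kinetic
schemes with published time constants; toy off/intermediate crystal pairs
with a refinement-accuracy phase model) make every stage testable end to
end without external data.

## Worked example

Simulate the H₂O-condition experiment, fit three exponentials globally,
and compare with the D₂O condition:

```r
library(PumpProbeTools)

grid <- defaultAcquisitionGrid(thin = 50)   # the three ns-ms delay windows
tsH <- simulateTransientSpectra(buildReferenceScheme("H2O"), grid,
                                sigma = 0.01, seed = 7)
fitH <- fitGlobal(tsH, 3)
fitH
#> GlobalFitResult: 3 components, converged in 10 iterations
#>   taus (us):   5.57, 36.7, 825
#>   stderr (us): 0.0343, 0.78, 4.94
#>   chi2: 1.06746
```

The three recovered time constants (≈5.6, 37, 825 µs) match the
generator's ground truth (5.57, 36.1, 824.8 µs) to within the noise;
their meaning in the photocycle is ground-state relaxation of the
trans-protonated chromophore toward the cis-anionic on-state, the slowest
step being the ms-scale deprotonation. Fitting the D₂O condition and
comparing,

```r
tsD <- simulateTransientSpectra(buildReferenceScheme("D2O"), grid,
                                sigma = 0.01, seed = 8)
isotopeRatios(fitH, fitGlobal(tsD, 3))
#> IsotopeComparison: tau_D/tau_H (= k_H/k_D) by ascending-tau rank
#>   ratios: 0.92, 2.37, 2.48
```

ratios well above 2 for the two slower components flag them as
proton-transfer steps (ground truth 2.45 and 2.47, recovered here to
within the fit noise), while the first component (ratio ≈ 0.92) is
isotope-insensitive.

On the crystallographic side, estimate the occupancy of a photoactivated
intermediate from simulated laser_off/laser_on amplitudes:

```r
pair <- buildToyPair(seed = 1)                    # off/intermediate/refined
obs <- simulateObservedPair(pair$off, pair$intermediate, fraction = 0.5,
                            dmin = 1.5, noiseFrac = 0.02, seed = 2)
sites <- rbind(as.matrix(atoms(pair$off)[pair$displaced, c("x","y","z")]),
               as.matrix(atoms(pair$intermediate)[pair$displaced, c("x","y","z")]))
alphaScan(obs$laser_on, obs$laser_off, pair$refined, sites)
#> AlphaScanResult: alpha* = 2.7, occupancy = 37.0%
```

A single synthetic run recovers the generating fraction (50%, i.e.
α = 2) only to within the broad maximum of the ratio curve; medians over
ten replicate syntheses land at α\* ≈ 2.2–2.8 depending on the seed
family (see the methods vignette for the estimator's bias and scatter).

Both workflows are wrapped by `runTAPipeline()` / `runXtalPipeline()`
(YAML-configurable, deterministic under a seed, JSON + text reports) and
by a thin command-line wrapper, `inst/cli/pumpprobe.R`, with subcommands
`simulate-ta`, `fit-ta`, `bootstrap`, `compare-isotope`, `simulate-xtal`,
`maps`, `alpha-scan`, `run-all`.

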