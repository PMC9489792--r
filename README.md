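# photokin

Photophysics and voltage-sensing analyses for fluorescent
microbial-rhodopsin voltage indicators (archaerhodopsin-3 derivatives of
the QuasAr/Archon family), written for spectroscopists and simulators who
need the full computational chain behind such a study in one tested
package:

* **Global kinetic analysis of transient absorption.** A wavelength ×
  delay surface ΔA(λ, t) is fitted as C(t)·S(λ) with IRF-convolved
  sequential (or branched) compartment kinetics sharing one set of time
  constants across all wavelengths — variable projection with
  Levenberg–Marquardt on log τ, exact linear solve for the
  evolution-associated difference spectra (EADS) at every trial. A
  branched scheme with branch fraction φ feeds a photointermediate chain,
  and the photoisomerization yield is recovered from the
  terminal-to-initial ground-state-bleach amplitude ratio.
* **Fluorescence-decay analysis.** Iterative reconvolution of
  multiexponential decays with the measured IRF histogram (Poisson
  weights, fitted time-origin shift), fractional amplitudes
  βᵢ = αᵢτᵢ/Σαⱼτⱼ, the population-weighted mean lifetime
  τ̄_pop = Σβᵢτᵢ, the amplitude-weighted mean τ_avg = Στᵢαᵢ/Σαᵢ, and a
  Hill-model fit of depolarization time courses.
* **Steady-state photophysics.** Nernst membrane-voltage calibration
  V = (RT/zF)·ln([K]out/[K]in), relative fluorescence quantum yield
  against a dye standard with refractive-index correction, two-state
  Henderson–Hasselbalch pKa fitting of Schiff-base titrations, HPLC
  retinal-isomer fractions by baseline-corrected peak integration, and
  Stern–Volmer quenching.
* **MD trajectory post-processing.** Hydrogen-bond probabilities
  (donor–acceptor ≤ 3 Å, donor–H–acceptor ≥ 150°, carboxylate oxygens of
  one residue deduplicated), inward/outward side-chain orientation by
  minimal distances, distance–angle distributions, pocket-water counts,
  and last-window equilibrated-frame selection, on multi-MODEL PDB
  trajectories.
* **Synthetic-data generators** for every input type, with ground truth
  attached, fixed seeds, and bit-reproducible output, so every stage of
  the pipeline is verifiable without external data.

## Worked example

Simulate a five-compartment transient-absorption surface with the
QuasAr2-like constants (0.183, 4, 40, 288 ps and a non-decaying terminal
state), 1% noise, and fit it globally:

```r
library(photokin)

sch <- kinetic_scheme(c(0.183, 4, 40, 288, Inf), "sequential",
                      irf_center = 0, irf_sigma = 0.034)
wl  <- seq(360, 720, length.out = 150)
spec <- tas_sim_spec(sch, tas_default_bands(5), wl,
                     tas_delay_grid(t_max = 2e4),
                     noise_sd = 0.0094, seed = 42)
dat <- simulate_tas(spec)
fit <- fit_global(dat, n_components = 5, fit_irf = TRUE)
fit
#> Global sequential fit, 5 compartments, rms residual 0.00931
#>   tau_0 = 0.1837 (se 0.00604)
#>   tau_1 = 4.165 (se 0.119)
#>   tau_2 = 39.99 (se 0.127)
#>   tau_3 = 285.5 (se 9.17)
#>   tau_4 = Inf
#>   converged: TRUE after 30 iterations
```

All four finite constants come back within ~4% of the generator truth;
`fit$component_spectra` holds the EADS and
`fit$concentrations %*% fit$component_spectra + fit$residual_matrix`
reconstructs the data exactly.

The population-weighted mean lifetime from the four printed
fluorescence-decay components at resting membrane voltage:

```r
mean_lifetime_population(c(0.895, 0.04, 0.01, 0.055), c(90, 300, 790, 2850))
#> [1] 257.2    # ps, the published ~260 ps
```

The `analysis/` directory holds the narrative drivers
(`01_photocycle_tas.R` … `04_md_hbond_networks.R`); each simulates its
inputs at the study conditions, runs the corresponding analysis, prints
what it found, and writes tables under `results/`.

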