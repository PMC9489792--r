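---
title: "Models and methods in photokin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in photokin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photokin)
```

photokin implements the computational side of a photophysics study of
fluorescent microbial-rhodopsin voltage indicators (archaerhodopsin-3
derivatives of the QuasAr/Archon family): global kinetic analysis of
transient absorption surfaces, fluorescence-decay deconvolution,
steady-state photophysics arithmetic, and geometric post-processing of
molecular-dynamics trajectories. Every analysis has a matching synthetic
generator with stored ground truth, so the whole pipeline is verifiable
at desk scale. This vignette records the models, the defaults, and the
numerical choices.

## Global analysis of transient absorption

A pump–probe experiment measures the difference absorbance
$\Delta A(\lambda, t)$ on a wavelength × delay grid. The kinetic model is
a compartment cascade: compartment populations $c_k(t)$ share one set of
time constants across all wavelengths, and the surface factorizes as
$\Delta A = C(t)\,S(\lambda)$ with one spectrum per compartment —
evolution-associated difference spectra (EADS) for a sequential scheme,
decay-associated spectra (DAS) for a parallel one.

The elementary response is an exponential convolved with a Gaussian
instrument response function (IRF):

$$c(t) = \tfrac12\, e^{-(t-\mu)^2/2\sigma^2}\,
  \operatorname{erfcx}\!\Big(\frac{\mu + k\sigma^2 - t}{\sigma\sqrt2}\Big),
  \qquad k = 1/\tau .$$

`exp_conv_irf()` evaluates this through the scaled complementary error
function, switching to the plain `erfc` form where its exponent is
nonpositive and to an asymptotic series for very large scaled arguments,
so the value stays finite for $|t-\mu|$ up to $\pm 50\sigma$ and
$\tau/\sigma$ from $10^{-3}$ to $10^9$ (verified against adaptive
quadrature to $10^{-8}$). An infinite time constant is implemented as
rate zero — the Gaussian cumulative — and models a compartment that does
not decay on the experimental window.

Multi-compartment populations come from the closed-form first-order
cascade (Bateman) solution, each term IRF-convolved. Near-degenerate
rates (relative gap below $10^{-6}$) are perturbed by $10^{-6}$ with a
warning to avoid the cascade singularity; the fit reports constants
sorted ascending, so the ordering of initial guesses is irrelevant.

`fit_global()` is a variable projection: the outer Levenberg–Marquardt
iteration moves only $\log\tau_k$ (and optionally the IRF position and
log-width), and at every trial the spectra are the exact linear
least-squares solution. Fitting $\log\tau$ enforces positivity and
conditions the femtosecond-to-microsecond range. When no initial scheme
is given, finite constants start log-spaced across the decades spanned
by the positive delays, with an infinite terminal constant. The
reconstruction identity `concentrations %*% component_spectra +
residual_matrix == data` holds exactly by construction of the linear
solve. Standard errors for the constants come from the curvature of the
reduced objective.

### Branched schemes and the photoproduct yield

Only a small fraction $\varphi$ of excited chromophores photoisomerizes;
the rest recover the initial ground state. The branched topology models
this as an excited compartment feeding a photointermediate chain with
fraction $\varphi$ and a spectrally silent recovered-ground sink with
$1-\varphi$. Because the branched populations are exact scalar multiples
of the corresponding sequential basis, a sequential fit represents
branched data exactly, and the branch fraction survives in the spectra:
the terminal EADS carries a ground-state-bleach amplitude $\varphi$
times that of the excited compartment.

`estimate_photoproduct_yield()` therefore returns
$|S_{\text{last}}(\lambda_{\text{GSB}})| /
|S_{\text{first}}(\lambda_{\text{GSB}})|$, with "first" meaning the
earliest *post-IRF* component — constants below $3\sigma_{\text{IRF}}$
are coherent-spike artifacts, not populations, and are skipped. The
generator's branched band set places the photointermediate bands at
640/620 nm ($\sigma$ = 12 nm) against a 590 nm bleach ($\sigma$ = 15 nm),
so band overlap at the bleach center is under 1% and the estimator is
unbiased by construction. This amplitude-ratio definition is this
package's own; it is validated on synthetic branched data where the true
$\varphi$ is known.

### Synthetic surfaces

`simulate_tas()` builds $C(t)S(\lambda)$ plus additive Gaussian noise.
Spectral bands are Gaussians in wavelength — a deliberate simplification
of the spectroscopic convention of bands in wavenumber. Delay grids
follow pump–probe practice: 50 linear points through the IRF region,
then 150 log-spaced points to the final delay. The default noise level
used throughout the study conditions is 1% of the maximum absolute
signal; the surfaces the instruments produce do not come with a stated
noise figure, so this is an exposed parameter. What these simulations do
*not* contain: wavelength-dependent IRF dispersion (chirp), coherent
artifacts around time zero, correlated detector noise, and scattered
pump light. Recovery results on them demonstrate estimator correctness,
not robustness to those instrument effects.

Study-condition recoveries (150 wavelengths × 200 delays, 1% noise,
fixed seeds — the sizes keep a single fit under a second): the
five-constant sequential surface (0.183, 4, 40, 288 ps, ∞; IRF σ =
34 fs) returns all finite constants within a few percent; a branch
fraction of 0.04 is recovered within ±0.01; the two-component
excited-state pair (14, 75 ps) within a few percent.

## Fluorescence decay analysis

Decay histograms are fitted by iterative reconvolution:
$I(t)=\sum_i \alpha_i e^{-t/\tau_i}$ convolved with the *measured* IRF
histogram on the channel grid (defaults mirror time-correlated
single-photon counting: 1024 channels × 19.5 ps), weighted least squares
with Poisson weights $1/\max(y,1)$, amplitudes solved linearly per trial
(variable projection again), plus one scalar time-origin shift between
IRF and decay — a standard nuisance parameter. Channels before the rise
are included; reconvolution handles them.

Numerical choices worth recording:

* The channel-grid convolution is carried out on an 8× oversampled
  spline of the IRF. Plain channel-rate convolution biases a lifetime of
  ~5 channels by about 1%; oversampling reduces that systematic to
  ~0.25%, below the few-percent tolerances of interest but *not* below
  the statistical error at very high counts. The standard-error coverage
  property is therefore tested with the generator's `"discrete"` forward
  model (same discretization as the fitter), which isolates statistical
  calibration from this known discretization systematic.
* Standard errors use the unscaled curvature of the weighted objective:
  Poisson weights already carry the per-channel variance, and a
  $\chi^2$ rescale would be deflated by the many empty tail channels.
* Components with fitted lifetime under half the IRF full width at half
  maximum are flagged `below_resolution`: a 14 ps component under a
  50 ps-resolution instrument is reported but not resolved — resolving
  it takes the 3.5 ps streak-camera response.
* The component count `n` is user-specified (four for the FLIM-style
  fits, one for streak traces); adjacent-`n` comparison is by reduced
  $\chi^2$, with no automatic model selection.

Two mean lifetimes summarize a multiexponential fit. With fractional
(intensity) amplitudes $\beta_i = \alpha_i\tau_i / \sum_j \alpha_j\tau_j$,
the population-weighted mean is $\bar\tau_{\mathrm{pop}} = \sum_i
\beta_i\tau_i$; the amplitude-weighted mean is $\tau_{\mathrm{avg}} =
\sum_i \tau_i A_i / \sum_i A_i$. Both lie inside $[\min\tau, \max\tau]$
and $\tau_{\mathrm{avg}} \le \bar\tau_{\mathrm{pop}}$ always. The
printed per-component percentages of the published FLIM fits are read as
the fractional amplitudes $\beta_i$: that reading reproduces the printed
~260 ps (resting) and ~220 ps (depolarized) means —

```{r}
mean_lifetime_population(c(0.895, 0.04, 0.01, 0.055), c(90, 300, 790, 2850))
mean_lifetime_population(c(0.945, 0.02, 0.02, 0.015), c(100, 460, 2000, 5200))
```

— whereas reading them as raw amplitudes $\alpha_i$ would give means
near 1.8 ns, far from the printed values.

The depolarization time course (fluorescence rise after an ionophore
collapses the membrane voltage) is fitted with a Hill model
$F(t) = F_0 + (F_{\max}-F_0)\,t^n/(t^n + t_{1/2}^n)$; $t_{1/2}$ is the
reported time constant. The Hill exponent is fitted by default (the
published curve does not state whether it was fixed); a constant trace
is flagged unidentifiable rather than fitted.

## Steady-state photophysics

* **Nernst calibration.** $V = (RT/zF)\ln([K]_{out}/[K]_{in})$ in mV.
  The default temperature is 293.15 K: room temperature, and the value
  that reproduces the standard proteoliposome calibration points (−75,
  0, +68 mV for 0.5/10, 10/10, 150/10 mM gradients) within a millivolt.
  The exact temperature behind those printed numbers is not stated;
  temperature is an argument.
* **Relative quantum yield.** $\Phi_s = \Phi_{ref}\,(f_{ref}/f_s)\,
  (F_s/F_{ref})\,(n_s/n_{ref})^2$ with $f = 1 - 10^{-A}$, the decadic
  absorbance convention ("1 − transmittance" with the log base
  unstated; decadic is standard for optical density). Absorbances above
  0.05 warn — the dilution rule that keeps reabsorption negligible.
  Defaults assume an aqueous sample against a dye standard in ethanol.
* **pKa titration.** Two-state Henderson–Hasselbalch,
  $A(\mathrm{pH}) = A_{deprot} + (A_{prot}-A_{deprot})/(1 +
  10^{\,n(\mathrm{pH}-\mathrm{p}K_a)})$, Hill coefficient fitted with
  start 1 (a single protonatable site, the retinal Schiff base). The fit
  is invariant under affine transforms of the absorbance axis and under
  monitoring the protonated versus the deprotonated band. Series with
  fewer than 5 points or under 2 pH units of span are flagged untrusted.
* **HPLC isomer fractions.** Trapezoid integration per labelled
  retention window after subtracting a linear baseline anchored on
  short averaged edge regions (5% of the window at each end; averaging
  keeps single-sample noise from tilting the baseline across the whole
  window — whether the original integration subtracted a baseline is
  not described, so the choice is recorded here). Negative corrected
  areas clip to zero with a warning; fractions normalize to 1 exactly.
* **Stern–Volmer quenching.** Ordinary least squares of $F_0/F$ against
  quencher concentration; the slope is $K_{SV}$ and the intercept should
  be ≈1.

## Trajectory post-processing

The geometry module consumes multi-MODEL PDB trajectories with explicit
hydrogens (the all-atom simulations it mirrors have them; no
hydrogen-placement heuristic is applied). Analyses:

* **Hydrogen bonds:** donor–acceptor distance ≤ 3 Å *and*
  donor–hydrogen–acceptor interior angle ≥ 150° (180° = linear); both
  cutoffs inclusive so printed thresholds are attainable. When both
  carboxyl oxygens of one Asp/Glu pass with the same donor, the pair
  counts once (the closer oxygen is kept). Per-pair probabilities are
  bonded-frame fractions computed by brute force over every frame.
* **Side-chain orientation:** per frame, the probe atom (e.g. the
  arginine Cζ at position 92) classifies inward when its minimal
  distance to the inward reference set (the Schiff-base counterions) is
  strictly smaller than to the outward set (the extracellular
  glutamates); exact ties classify outward — a deterministic rule at a
  measure-zero boundary, chosen for reproducibility.
* **Distance–angle distributions** of the protonated-Schiff-base–
  counterion geometry, binned 2-D with mass equal to the frame count.
* **Pocket waters:** water oxygens (HOH/WAT/SOL) within a radius of a
  center that is either fixed or the per-frame midpoint of named atoms.
  The published counting region lives in supplementary material not
  reproduced here; the declared default (midpoint of the counterion
  reference atoms, 5 Å) is a stated convention, not an inference.
* **Equilibrated window:** the last 100 ns of each trajectory (closed
  interval `t >= t_end - window`), the standard discard-equilibration
  rule; a zero window keeps the final frame.

All geometric operations are invariant under rigid rotation+translation
of every frame (tested with random rigid transforms), and the detector
is tested against an exhaustive double-loop oracle. There is no
periodic-boundary minimum-image handling: trajectories must be
pre-wrapped whole molecules, which the fixtures are — a flagged
limitation for raw MD output.

The trajectory generator scripts its truth exactly: `round(fraction *
n_frames)` frames satisfy each condition, selected by a seeded
permutation, so scripted occupancies are recovered without statistical
slack. It makes no attempt at force-field realism — no solvent
structure, no thermal ensembles — so passing tests demonstrate the
correctness of the geometric counting rules, not anything about real
protein dynamics. Replicate-level statistics (mean ± SD across
independent runs) are computed per-trajectory first, then aggregated.

## What is deliberately out of reach

The published hydrogen-bond probabilities from microsecond-scale MD,
measured voltage sensitivities (ΔF/F), and absolute quantum yields
(0.49–0.79%) require wet-lab data or long simulations and are not
desk-scale reproducible; they are covered only by estimator-recovery and
property tests on synthetic inputs. Spectral decomposition of
overlapping photoproduct absorption bands, anisotropy, Raman analysis,
and pixel-level lifetime-image clustering are out of scope.
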