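---
title: "Virtual homonuclear decoupling of echo-modulated spectra: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual homonuclear decoupling of echo-modulated spectra: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pureshiftnn)
```

## The problem

Proton NMR spectra of small molecules are congested because every proton
resonance is split into a multiplet by scalar (J) couplings to its neighbours.
A *pure shift* spectrum removes that structure — one singlet per chemically
distinct proton — at a large cost in sensitivity when done experimentally by
broadband homonuclear decoupling. `pureshiftnn` implements a *virtual*
alternative: a spin-echo experiment is recorded (or simulated) at five echo
durations $T$; the echo refocuses chemical-shift evolution but not homonuclear
J evolution, so each multiplet component at offset $\delta$ from its chemical
shift acquires a phase $e^{i 2\pi \delta T}$ and each spin an attenuation
$e^{-T/T_2}$. Across the five delays this imprints a $J$-specific modulation
pattern — effectively a sparse, exponentially weighted sampling of the
indirect dimension of a J-resolved experiment. A convolutional network maps
the five modulated spectra onto the coupling-free spectrum of the same system
and predicts, per point, an uncertainty for that reconstruction.

## The simulator

A spin system is specified by chemical shifts (ppm), a symmetric coupling
matrix $J$ (Hz), per-spin intensities, and per-spin $T_2$ (s). Multiplets are
built in the weak-coupling (first-order) approximation: the lines of spin $i$
sit at $\sum_k m_k J_{ik}$, $m_k = \pm\tfrac12$, with binomial intensities.
Couplings below 0.2 Hz are dropped to bound the line tree, and lines
degenerate within $10^{-9}$ Hz are merged.

**Semiweak correction.** First-order intensities are then tilted by the AB
"roof effect": for each partner $j$ at shift difference $\Delta\nu_{ij}$ (Hz),
with $D_{ij} = \sqrt{\Delta\nu_{ij}^2 + J_{ij}^2}$, the line displaced toward
the partner gains the factor $1 + |J_{ij}|/D_{ij}$ and the outer line
$1 - |J_{ij}|/D_{ij}$. This reproduces the exact two-spin (AB) intensities at
any coupling strength while keeping first-order line *positions*; the residual
position error, $(D - \Delta\nu)/2$, is what "strong coupling" means here, and
it is quantified in the test suite against an exact $4\times 4$ Hamiltonian
diagonalization. Degenerate but magnetically inequivalent pairs
($\Delta\nu = 0$, $J \neq 0$) cannot be handled this way; the correction is
skipped with a warning. Full density-matrix simulation of strongly coupled
many-spin systems is deliberately out of scope — the training data share this
limitation, and so does the trained transform.

**Lineshape.** Signals are synthesized as complex Lorentzians in the time
domain (dwell $1/\mathrm{SW}$, first point halved) and Fourier transformed;
the $T = 0$ spectrum is absorptive by construction and equals the conventional
1D spectrum. For $T > 0$ the echo phase factors deliberately leave dispersive
character in the real part: that mixed-phase lineshape *is* the physical
J-modulated input the decoupler consumes. As in standard NMR processing, an
exponential apodization (default 3 Hz, matched to the default digital
resolution of $\approx 3.1$ Hz/point) damps every FID: the desk-scale
acquisition window is only $N/\mathrm{SW} \approx 0.3$ s while $T_2$ runs to
2 s, and without a window function such truncated FIDs ring phase-coherently
across the spectrum — the windowed mass of a narrow singlet then varies by
almost a factor of two with the sub-grid line position, which would make
regional quantification ill-conditioned no matter how the spectra are
processed afterwards. Apodization adds to every linewidth but provably leaves
total integrals and the echo-modulation law untouched (the first FID point is
unchanged), which is how the analytic $\cos(\pi J T)\,e^{-T/T_2}$ oracles are
still checked to machine precision; `apodization = 0` restores the raw
truncated lineshape. *Regional* oracles in the tests additionally use short
$T_2$ so the FID decays fully within the acquisition window.

**Axis conventions.** The default grid is 2048 points over 4 ppm at 800 MHz
(1024 points for the scaled-down trained model); internal arrays are indexed
by increasing frequency, and `axis_ppm()`/`axis_hz()` expose the grid for
display (ppm conventionally decreasing left to right).

**The synthetic distribution.** `random_spin_system()` draws 1–12 spins,
shifts uniform over 1.3–4.7 ppm (0.3 ppm margins keep all multiplet lines of
even the most heavily coupled spin inside the window), each pair coupled with
probability 0.3 with $|J|$ uniform in 1–18 Hz and random sign, $T_2$
log-uniform over 0.1–2 s, and intensities uniform over 0.5–1.5. These ranges
emulate small-molecule ^1^H spectra (vicinal/geminal couplings, sub-Hz to
few-Hz linewidths). What they do *not* emulate: solvent signals, ^13^C
satellites, baseline distortions, chemical exchange, strong-coupling
frequency shifts, and $B_0$ inhomogeneity lineshapes — so passing tests
demonstrate correctness of the method under its stated approximation, not
performance on arbitrary experimental data. Noise is white Gaussian, defined
by SNR = (tallest noiseless $T=0$ peak) / (noise s.d.); a per-multiplet SNR
definition was rejected for reproducibility.

## The decoupler network

The five real spectra enter channels-first into a stack of gated, dilated 1D
convolutions (kernel 3, dilations 1–32, 48 filters) with residual and skip
connections; a $1\times 1$ head on the accumulated skip features emits the
predicted intensity $\mu$, and a small two-layer probe emits a log-variance
per point. The probe reads the trunk features through a stop-gradient: the
trunk is shaped purely by the intensity objective, so the uncertainty model
can never destabilize the reconstruction it describes (in pilots, letting the
unweighted variance gradient reach the trunk halved the center-recovery
rate). The default receptive
field spans $\pm 63$ points ($\approx \pm 200$ Hz at the 1024-point training
grid), comfortably wider than any multiplet the generator produces
($\pm 99$ Hz worst case). A learned per-delay linear combination of the input
spectra feeds the intensity head directly: to first order the pure-shift
trace is a matched-filter projection of the five J-modulated spectra, so this
skip makes singlet passthrough trivial and lets the convolution stack spend
its capacity on moving multiplet intensity to the chemical shift. Inputs are
scaled so the tallest $|T=0|$ intensity is 1 and outputs (both $\mu$ and
$\sigma$) are rescaled back, making the transform exactly scale-equivariant.

At roughly $10^5$ parameters the default scaled-down model trains in minutes
on one CPU core; the architecture is deliberately sized for that budget
(spectra of 1024 points), not for production-scale 64k-point spectra.

## Training

Training streams freshly simulated systems (no stored corpus): each example
is a random system, its echo series with white noise at an SNR drawn
log-uniformly over 20:1–$10^5$:1, paired with the same system's spectrum
computed with all couplings set to zero. The loss is the heteroscedastic
Gaussian negative log-likelihood per point,
$\tfrac12[\log\sigma^2 + (y-\mu)^2/\sigma^2]$, which makes $\sigma$ a proper
predictive uncertainty. For *optimization* the mean-head gradient of each
point is weighted by the detached $\sigma^{2\beta}$ with $\beta = 1$ (the
"$\beta$-NLL" weighting): with the plain NLL the variance head quickly learns
to explain away the residuals of tall narrow singlet targets, starving the
mean head of gradient exactly where quantitative accuracy matters — in pilots
the median multiplet integral error plateaued near 35% under plain NLL and
fell several-fold under $\beta$-NLL at an equal step budget. The variance
head keeps the *plain* NLL gradient: weighting it too would de-emphasize
low-$\sigma$ baseline points, leaving their predicted uncertainty loose and
the 1$\sigma$ coverage inflated. Neither choice moves any per-point
stationary point ($\sigma^2 =$ squared residual), so the uncertainty
semantics and the downstream calibration are unaffected; reported
training/validation losses are always the plain NLL (nats/point). A variance
floor of $10^{-6}$ (normalized units) guards against runaway shrinking of
$\sigma$ on exactly-fit baseline.

Training ends with a *probe refinement* phase (`probe_corpus` fresh examples,
default 96, refitted for `probe_epochs` passes, default 50): the variance
probe is re-initialized and fitted against the frozen trunk, because during
joint training it chases the shrinking residuals of an improving mean and
would otherwise finish biased high exactly at the peaks — the classic reason
heteroscedastic variance models are fitted in a second stage on the
residuals of the converged mean. Trunk features for the corpus are cached,
so the refit costs a fraction of a joint-training step per pass. The probe
also uses a $3\times$ learning-rate multiplier throughout: its per-point NLL
gradient is bounded while the informative peak points are sparse.

The optimizer is Adam at a fixed learning rate ($10^{-3}$ default, no
schedule). Runs are fully seeded — system draws, noise draws, and weight
initialization all derive from the configured seeds, so training is exactly
reproducible in a single-threaded session. Divergence (non-finite loss)
aborts with a diagnostic rather than continuing silently.

**Problem sizes used by the test suite.** The acceptance-level model is
trained for 1200 steps of batch 4 on the 1024-point axis and evaluated on 200
held-out systems; smoke tests use 256-point axes and 8–16 filters. These
sizes are the package's desk-scale defaults; larger models and longer runs
only improve the reported recovery rates.

## Uncertainty calibration

Networks trained across a wide noise range mis-scale their predicted
uncertainties (typically underpredicting). The calibration curve is built by
simulating fresh systems at each of 8 log-spaced SNRs across the validity
span 20:1–$10^5$:1 and recording the multiplicative factor
$\mathrm{RMS}(\text{residual})/\overline{\sigma}$; queries interpolate
linearly in $\log$ SNR and clamp (with a warning) outside the span.
Calibration is *multiplicative and SNR-indexed only* — per-point or
per-intensity calibration was rejected as unidentifiable from the available
signal. A result may be calibrated exactly once; the intensity trace is never
touched. The `coverage_check()` diagnostic verifies the result: for
well-calibrated Gaussian errors, about 68.3% of points lie within
$1\sigma$.

When no recorded noise level accompanies a series, `estimate_snr()` measures
the noise floor from the high-frequency content of the $T=0$ spectrum,
$1.4826\,\mathrm{MAD}(\Delta^2\text{values})/\sqrt{6}$ (the second difference
of i.i.d. noise has variance $6\sigma^2$): exact for white noise, insensitive
to the sparse sharp peaks, and — unlike floors estimated from raw
low-intensity points — blind to smooth Lorentzian tails and baseline roll,
which are locally linear and vanish from the curvature. Near-noiseless data
are capped at SNR $10^9$.

## Quantification statistics

Peak integrals are trapezoidal over user-defined ppm regions with
independent-point error propagation,
$\sigma_I = \sqrt{\sum_p \sigma_p^2}\,\Delta\mathrm{ppm}$ (correlated-error
propagation is noted as future work). Linearity against concentration is
summarized by the Pearson coefficient and by the time-normalized RMSD
$\tilde\rho = \sqrt{t_\mathrm{acq}/t_\mathrm{acq,conv}}\;
\mathrm{RMSD}/\mathrm{slope}$, where the slope comes from an ordinary
least-squares fit of integral on concentration. The square-root time
convention reflects sensitivity-per-$\sqrt{\text{time}}$ (recording the
five-delay series costs five conventional acquisitions); a linear convention
is selectable by flag since the normalization convention is genuinely
ambiguous.

Sensitivity under noise is evaluated by titration: noise is added at
descending SNR levels, each series decoupled and calibrated, and a region's
peak counted as *retained* when its maximum intensity is at least $3\times$
the local (median in-region) calibrated $\sigma$ — a conventional
detection-limit criterion adopted because "retained" needs an operational
definition. Finally, `flag_uncertainty_spikes()` marks points whose $\sigma$
exceeds 5$\times$ a 51-point rolling median: a sudden localized uncertainty
spike is the signature of a reconstruction artifact rather than a real
resonance.

## Numerical choices and degenerate inputs

* Coupling cutoff 0.2 Hz; degenerate-line merge tolerance $10^{-9}$ Hz.
* Axis lengths are powers of two ($\geq 64$); multiplet lines falling outside
  the spectral window raise an aliasing error instead of wrapping.
* All-zero input to `decouple()` returns a zero trace with a finite floor
  uncertainty rather than NaN.
* Variance floor $10^{-6}$ (normalized); calibration factors are clamped at
  the grid edges; double calibration is an error.
* Every random draw (systems, noise, weights, SNRs) is derived from explicit
  integer seeds; `with_seed()` isolates the package from the caller's RNG
  state.

## Known limitations

* Strong coupling: line positions are first-order; the roof tilt corrects
  intensities only. Expect artifacts near degenerate, coupled spins — the
  same regime flagged by uncertainty spikes.
* At desk scale the trained network reconstructs *below* the input noise
  floor, so held-out residuals are dominated by smooth, heavy-tailed model
  error rather than propagated noise. Two consequences, both visible in the
  test suite: the calibrated 1$\sigma$ coverage sits above the nominal
  Gaussian band (typical points are over-covered after energy-matched
  calibration), and peaks far outside the generator's intensity range (e.g. a
  1% satellite next to a full-intensity resonance) are attenuated and carry
  honestly large $\sigma$, so they never reach 3$\sigma$ detection. Both
  effects shrink as the model is scaled up; uncertainties should be read as
  energy-calibrated error envelopes, not exact pointwise Gaussian widths.
* The uncertainty-spike flagger assumes a locally flat $\sigma$ background;
  with the strongly peak-structured $\sigma$ fields of this model it also
  marks genuine resonances, so treat its output as candidates for inspection
  rather than verdicts.
* The trained transform is only valid on the grid/schedule it was trained
  for; the model file records both and `decouple()` enforces them.
* Calibration validity is 20:1 to $10^5$:1; outside that span factors are
  clamped and a warning raised.
* The 2D path processes indirect-dimension slices independently; correlations
  along the indirect dimension are not exploited.
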