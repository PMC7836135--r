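---
title: "Modeling SSVEP brain-behavior moderation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling SSVEP brain-behavior moderation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssvepmod)
```

# The scientific problem

Steady-state visual evoked potentials (SSVEPs) index cortical excitation:
a pattern-reversal stimulus flickering at 25 Hz drives an oscillatory
response at exactly 25 Hz, strongest over primary visual cortex (electrode
Oz). When the same stimulus is shown at five brightness intensities and
participants rate its unpleasantness on the Gracely Box Scale (GBS,
0--20), three questions arise: does brightness drive cortical excitation;
does excitation drive unpleasantness; and do participant-level
characteristics -- menstrual pain, somatic symptoms, experimentally evoked
bladder pain -- *moderate* those within-participant relationships? The
moderation question is central to multisensory hypersensitivity (MSH):
if participants with high visceral pain report more unpleasantness at
*equal* cortical excitation, amplification happens downstream of primary
sensory cortex.

`ssvepmod` implements the full pipeline for this design -- synthetic data
generation, EEG preprocessing, a spherical-spline surface Laplacian,
spectral estimation, and the two-stage multilevel moderation models --
so that every stage is testable end to end without access to any
participant data.

# The two-stage multilevel model

## Level 1 (within participant)

For participant $i$ and electrode $e$, with mean-centered brightness codes
$x_j \in \{-2,-1,0,1,2\}$ over the five blocks $j$:

* **Analysis 1** regresses 25 Hz power (dB) on brightness:
  $\mathrm{PSD}_{ij} = b_{0i} + b_{1i} x_j + \varepsilon_{ij}$.
* **Analysis 2** regresses unpleasantness on brightness and power:
  $U_{ij} = b_{0i} + b_{1i} x_j + b_{2i} \mathrm{PSD}^{c}_{ij} +
  \varepsilon_{ij}$.

Both fits are ordinary least squares on five points (closed form for
Analysis 1: $b_1 = \sum x y / 10$, $b_0 = \bar y$). The PSD predictor is
centered *within participant* by default, so $b_{0i}$ is participant
$i$'s mean unpleasantness collapsed across brightness -- the reading that
makes the second-level intercept interpretable as "average unpleasantness
at average moderator levels". Grand-mean centering is available via
`center_psd = "none"` after centering externally; only the intercept
terms change, slopes are unaffected.

## Level 2 (between participants)

Each first-level coefficient becomes the response in a between-participant
regression on the grand-mean-centered moderators $M$ (menstrual pain,
somatic symptoms, bladder pain):
$$\hat b_{ki} = \gamma_{k0} + \gamma_{k1} M_{1i} + \gamma_{k2} M_{2i} +
  \gamma_{k3} M_{3i} + u_{ki}.$$
Analysis 1 uses intercept-only second levels. Inference per term uses a
model-comparison sum of squares -- $SS = SSE(\text{term deleted}) -
SSE(\text{full})$, equivalent to Type III for 1-df terms -- with the
full-model MSE, giving $F = SS/MSE$, two-tailed $p$, a $t$-based 95% CI,
and partial eta-squared $\eta_p^2 = SS/(SS + df \cdot MSE)$. These
identities are re-asserted on every emitted table
(`check_level2_identities`), so a reported row can always be reconstructed
from its own components.

Participants with a rank-deficient first-level fit (e.g. PSD collinear
with brightness), a missing block, or missing moderators are dropped
listwise, and the denominator df reflects the included N (N-1 for
Analysis 1, N-4 for Analysis 2).

## Multiple comparisons

Oz is the a-priori channel and is reported unadjusted. The remaining 31
electrodes form the exploratory family; Benjamini--Hochberg step-up
adjustment is applied separately within each (model, term) cell,
mirroring per-model exploratory reporting. `fdr_adjust()` returns `NA`
for the a-priori channel to make the family structure explicit.

## Bootstrapped correlations

The moderator correlation table uses Pearson r with a seeded percentile
bootstrap (default B = 2000; neither the bootstrap flavour nor B is
canonical in this literature, so both are exposed) and a two-tailed p
from the t transform of r.

# Signal processing

The preprocessing order is fixed and logged: mastoid re-reference,
high-pass, resample, notch, epoch, reject, surface Laplacian, PSD.

* **Re-reference**: average of the two mastoid channels subtracted from
  every scalp channel; mastoids are then dropped, leaving the 32-channel
  scalp montage.
* **High-pass** (1 Hz, 2 Hz transition): Hamming windowed-sinc FIR built
  by spectral inversion of a unit-DC-gain low-pass, applied with zero
  phase by compensating the integer group delay of the linear-phase
  kernel. The -6 dB half-amplitude point sits at the cutoff (measured
  -6.07 dB at 1 Hz); DC is removed exactly (the kernel sums to zero by
  construction); passband ripple above 5 Hz is below 0.01 dB. The filter
  order follows the Hamming transition-width rule $N = 3.3 f_s/\Delta f$.
* **Resampling** (500 to 256 Hz): Fourier-domain resampling, which is
  exact for band-limited content -- a 25 Hz tone passes with error at the
  1e-12 level. Content above 90% of the new Nyquist frequency is removed
  as a brick-wall anti-alias guard band; nothing the analysis uses lives
  above 115 Hz. Marker indices are remapped to the nearest new sample.
* **Notch** (60 Hz): second-order Butterworth band-stop (+/-2 Hz),
  forward-backward for zero phase; measured attenuation at 60 Hz exceeds
  100 dB while 25 Hz changes by under 0.01 dB. A multitaper regression
  approach would preserve more of the 58--62 Hz band, but nothing in the
  analysis uses that band, so the IIR notch is sufficient and simpler.
* **Epochs**: 2-s windows sliding in 1-s steps from each block onset;
  the final partial window is discarded, so a 20-s block yields exactly
  19 epochs and a session 95. Rejection marks any epoch whose absolute
  voltage exceeds 100 uV on any channel at any sample, *before* the
  Laplacian (the threshold is defined on voltage, and the Laplacian's
  units are arbitrary); kept + rejected always equals generated.

## Surface Laplacian (current source density)

The spherical-spline surface Laplacian sharpens topography by removing
the spatially smooth component that volume conduction spreads across the
scalp. From the inter-electrode cosine matrix the package builds
$$g(x) = \frac{1}{4\pi}\sum_{n=1}^{N}\frac{2n+1}{(n(n+1))^m}P_n(x),
\qquad
h(x) = \frac{1}{4\pi}\sum_{n=1}^{N}\frac{2n+1}{(n(n+1))^{m-1}}P_n(x),$$
with Legendre polynomials by the three-term recurrence. The smoothed
spline solve is the KKT system $[G+\lambda I, \mathbf 1; \mathbf 1', 0]$
(flat-spline constraint: coefficients sum to zero), projected through
$H$ and scaled by the squared head radius. The whole transform is
precomputed as one matrix, so batch and sample-wise application coincide
and a constant map yields exactly zero.

Parameters $m = 4$, 50 Legendre terms, $\lambda = 10^{-5}$, head radius
10 cm are the published defaults of the reference CSD implementation for
this electrode count; all are exposed. At $m=4$ the $g$ series terms
decay as $n^{-7}$ ($h$ as $n^{-5}$), so 50 terms leave a tail below
1e-6. The global scale of CSD units cancels in every dB *difference*
downstream (slopes, moderation terms); only intercepts depend on it,
which is why the package reports the unit label but makes no claims
about absolute CSD magnitudes.

The montage itself is an idealized unit-sphere 10-20/10-10 layout built
geometrically (midline and circumferential arcs in 10%/20% steps,
intermediate rows by spherical interpolation) -- digitized positions vary
across labs and the analysis only needs a consistent, symmetric geometry.

## Spectral estimation

Per epoch and channel, a Hamming-tapered FFT periodogram with density
(power/Hz) normalization; 2-s epochs at 256 Hz give 0.5 Hz bins, so
25 Hz falls exactly on a bin and no zero-padding is needed. Per block,
the *linear* power at the 25 Hz bin is averaged across kept epochs and
then converted to dB (`10*log10`); averaging before the log is the
standard reduction for averaged periodograms, and a `db_first` flag
provides the alternative order. The density normalization constant
cancels in all slopes but not intercepts -- same caveat as the CSD
scale.

# The synthetic-data generator

The generator is first-class, tested code: it defines the statistical
population every downstream property is tested against.

## Covariates

A Gaussian copula: latent trivariate normal with the planted correlation
matrix (0.28 menstrual-bladder, 0.28 bladder-somatic, 0.16
somatic-menstrual), mapped affinely to the planted means/SDs
(menstrual 62.5/26.1, somatic 2.37/2.4, bladder 12.2/16) and clipped at
the scale bounds. Clipping is deliberate: bladder pain in such cohorts
has a large point mass at zero, and clamping the latent normal at 0
reproduces exactly that. The cost is documented bias: the realized
bladder mean rises to 14.25 and the menstrual-bladder correlation
attenuates to about 0.26. Both effects are covered by tolerance tests,
and `censored_covariate_means()` gives the realized means in closed
form. The somatic-sum upper bound is an exposed parameter (instrument
versions differ in item count); at the default mean/SD it never binds.

Because the planted level-2 model must be centered where the *realized*
population mean is (that is what grand-mean centering estimates in the
analysis), `planted_model()` centers its gammas at the clipped-normal
means by default. Centering at the latent means instead would bias every
recovered intercept by $\gamma^\top (\mu_{\text{censored}} -
\mu_{\text{latent}})$ -- about +0.12 GBS on the mean-unpleasantness
intercept.

## EEG sessions

Each session is 32 scalp channels plus two mastoids at 500 Hz: a 2-s
lead-in, five 20-s stimulation blocks (randomized order) separated by
2-s gaps, and a 1-s tail. The SSVEP is a 25 Hz sinusoid whose amplitude
falls off as $\exp(-1.2\,\theta)$ with angular distance $\theta$ from Oz
-- occipitally peaked but measurable scalp-wide, as this paradigm shows.
Pink (1/f) noise is synthesized by spectral shaping; optional 60 Hz line
noise and half-cosine blink transients (frontally weighted, ~0.3 s) can
be enabled. The artifact-light default stands in for component-based
artifact cleaning, which is out of scope.

The SSVEP is planted **on the dB scale**: the generator promises that
the full analysis chain recovers `base + slope * brightness + subject
deviation` dB at Oz. Two calibrations make that exact:

1. **Gain calibration**: the chain's dB output for a unit-amplitude tone
   with the planted topography is measured once (every stage is linear,
   so amplitudes for any target follow as $10^{(target-gain)/20}$).
2. **Noise-floor compensation**: background noise contributes power at
   the stimulation bin, so with noise on, the planted amplitude is
   reduced until *expected total* bin power (signal + measured floor)
   hits the target. The floor is measured by pushing noise-only sessions
   through the chain (averaged over four realizations, ~380 epochs) and
   scales with the squared noise RMS. Targets below the floor clamp to
   zero signal: the floor is a physical lower bound, and planted lines
   that dip below it cannot be realized -- a property real recordings
   share.

The default noise scale (pink RMS = 1.5x the planted tone amplitude)
keeps broadband noise dominant in the raw trace while leaving roughly
7 dB of bin-level margin below the dimmest block, consistent with the
clearly visible 25 Hz spectral peak this paradigm produces. Because both
the tone amplitude and the default noise RMS scale with the subject's
deviation, that margin is subject-invariant.

Default dB parameters: intercept -23.76 dB, slope 2.05 dB per brightness
step, between-subject SDs 5.58 (intercept) and 0.91 (slope), level-1 dB
noise 2.0. The variance defaults come from partitioning the second-level
mean squares typical of this paradigm (about 31.9 for intercepts, 1.22
for slopes at n = 147) into a level-1 sampling part
($\sigma^2/5$ and $\sigma^2/10$ for a five-point design) and a
between-subject part; the level-1 SD of 2.0 dB itself is a realism
choice, not an identified quantity.

## Ratings

Per participant, $b_0, b_1, b_2$ are drawn from the planted level-2
model plus independent Gaussian random effects (independence is a
modeling choice -- the coefficients' covariance is not identified by
anything this package targets), and ratings are the level-1 linear
predictor plus residual noise, clipped to the 0-20 GBS range. Ratings
stay continuous by default (the analysis treats them as continuous);
integer rounding sits behind a flag. Random-effect SDs (3.84, 0.75,
0.39) and the residual SD (1.0 GBS) follow the same variance-partition
logic as the dB parameters, here against second-level mean squares of
about 14.9, 0.66 and 0.17.

With all moderator gammas zero the generator produces an exact null for
the moderation tests; with all SDs zero it is fully deterministic, which
is what makes round-trip recovery exact.

## What the generator does *not* emulate

Real EEG has spatially correlated, non-stationary noise, genuine ocular
and myogenic artifact topographies, electrode drift and impedance
changes, and behavioral idiosyncrasies (anchoring, integer-only ratings,
sequence effects). Passing the recovery suites therefore shows that the
*estimator and signal chain* are correct under the stated statistical
model -- it does not validate artifact handling against real recordings,
and the +/-100 uV rejection here stands in for the heavier cleaning a
real study would apply.

# Verification design and problem sizes

The test suite follows a dual-route principle: every nontrivial
computation is checked against an independent oracle -- direct DFT sums
for the periodogram, a dense KKT solve for the Laplacian, literal
normal-equation solves for the regressions, textbook step-up for the
FDR, and printed-table identities for the reporting statistics.

Monte Carlo suites run on the statistical fast path
(`simulate_psd_table()` draws the dB model directly, bypassing EEG
synthesis), which makes hundreds of full two-stage analyses at n = 147
cheap; the EEG path is separately verified to realize the same dB model.
Sizes used: 200 replicates for parameter recovery (each planted
coefficient within 3 Monte Carlo SEs), 300 replicates for type-I-error
calibration. Recovery and calibration run with clipping disabled: they
test estimator unbiasedness, which is a property of the uncensored
model; censoring attenuation is small (about 1% on the mean-unpleasantness
intercept at the defaults) and is documented and tested separately. The
null calibration pools the nine moderator cells (weakly dependent within
a replicate) for its exact binomial check and bounds each individual
cell by a wide binomial region; full-chain calibration uses five
noise-free sessions with fixed zero-sum subject deviations, so the
planted mean slope is exactly 2.05 dB/step while the second level keeps
positive error variance.

# Known limitations

* The Laplacian's and periodogram's global scale conventions make
  absolute intercepts implementation-specific; only differences and
  slopes are comparable across implementations.
* The generator's noise is spatially independent pink noise; spatial
  correlation would mainly lower the effective noise floor after the
  Laplacian, making the defaults conservative.
* Planted dB lines far below the noise floor are clamped (see above);
  recovery properties are stated for the default regime where no
  clamping occurs.
* First-level fits use five points; with `psd_noise_sd = 0` the PSD
  predictor is exactly collinear with brightness and Analysis-2 fits are
  (correctly) flagged rank-deficient -- the moderation design requires
  within-participant PSD variability beyond brightness.
* BrainVision support covers the multiplexed IEEE-float subset the
  package writes, not vendor extensions.
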