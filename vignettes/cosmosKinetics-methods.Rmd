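---
title: "Models and methods behind cosmosKinetics"
author: "cosmosKinetics authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cosmosKinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cosmosKinetics)
```

# The measurement

Colocalization single-molecule spectroscopy (CoSMoS) detects binding of a
labeled protein to individual surface-tethered RNA molecules as transient
spatial coincidence of two spectrally separated fluorophores. The package
models the assay used to characterize Lsm2–8 heteroheptamer binding to the
3' end of yeast U6 snRNA: Cy5-labeled RNAs immobilized on a passivated
slide, DY549-labeled Lsm2–8 in solution, and two excitation lasers
alternated frame by frame. With 1 s exposures and about 0.5 s of lag per
channel, the binding channel is sampled once every **3 s**; movies last
about **1800 s**. Every analysis stage in the package — spot detection,
trace idealization, dwell-time statistics, kinetic-scheme fitting — can be
run on synthetic data generated with known ground truth, so each stage is
testable by parameter recovery.

# The kinetic model

A tethered molecule is described by a continuous-time Markov chain
(`KineticScheme`). Off-diagonal generator entries are rate constants;
edges flagged concentration-dependent carry second-order constants
(M^-1^ s^-1^) multiplied by the ligand concentration. Several states may
share one *observable class* — `dark`, `bound` or `bound2` (two ligands at
once) — making the chain an **aggregated Markov model**: the data identify
the class sequence, not the hidden state.

The default ground truth is the four-state linear chain

```
U* <-> U <-> UL <-> UL*
```

with a single-step association `U -> UL` at kon = 1.94e7 M^-1^ s^-1^ and
dissociation at koff = 0.045 s^-1^, plus two rare excursions: `U*`, a dark
state from which the complex cannot form, and `UL*`, a bound state from
which the ligand cannot dissociate. This scheme has six free rate
parameters. The four rare-state rates are not constrained by a published
value; the package uses **0.002 s^-1^ in each direction as a documented
assumption** (`fourStateScheme()` exposes all six).

```{r}
fourStateScheme()
```

# Synthetic data generation

`simulateTrajectory()` draws exact Gillespie paths. By default a path
starts in the scheme's declared initial state; `start = "dark"` draws the
start from the stationary distribution conditioned on the dark class,
which is the physically sensible choice for a movie that begins shortly
after ligand addition (the unbound states have equilibrated among
themselves, binding has not started from steady state).

`discretizePath()` converts a path to one observable class per frame by
**majority occupancy** within each frame window, mimicking camera
integration. The rule makes missed-event behavior explicit: an excursion
occupying less than half of every frame it touches disappears. Ties are
broken toward the lower class, deterministically.

`renderIntensity()` draws one Gaussian intensity per frame around its
class mean. The default emission model uses means 100/300/500 (arbitrary
units) and sd 25, i.e. one binding step of 200 at SNR (step/sd) = 8, with
double occupancy exactly one step brighter than single occupancy —
realistic for well-behaved CoSMoS data. `renderMovie()` produces full
two-channel image stacks: spots are symmetric 2D Gaussians (sigma 1.1 px),
fiducial beads are bright in both channels, drift is applied cumulatively,
and camera noise is Poisson shot noise plus Gaussian read noise.

All randomness flows from one master seed through per-molecule sub-seeds
(`subSeeds`), so every generator output is bit-reproducible.

What the generator does **not** emulate: pixel-dependent sCMOS noise,
focus drift, spectral crosstalk, dye blinking, or surface heterogeneity.
Tests passing on synthetic data therefore validate the estimators under
the stated noise model, not robustness to every artifact of real
microscopy.

# Image front end

Coordinates are 0-based with pixel centers at integers; all fit and
integration windows are 5 x 5 px.

* **Channel mapping** (`estimateMapping`): least-squares nonreflective
  similarity between matched fiducial coordinates, solved in closed form
  by treating points as complex numbers (w = a z + b; |a| is the scale,
  Arg(a) the rotation). Reflections are excluded by construction.
* **Drift** (`estimateDrift`): subpixel cross-correlation (upsampled
  discrete Fourier transform, default upsampling 20) of 10-frame block
  averages against the first block; block averaging suppresses shot
  noise, per-frame displacements are interpolated linearly.
* **Detection** (`detectAOIs`): the detection image is the average of the
  first five frames. For each pixel a generalized likelihood ratio test
  compares a Gaussian-PSF spot against a flat background; with amplitude
  and background profiled out the statistic reduces to the matched-filter
  correlation with the mean-subtracted PSF template divided by the image
  noise sd, standard normal under the null. The default per-pixel false
  alarm probability is 1e-6 (about 0.26 expected false detections on a
  512^2^ image). Candidates are local maxima above the quantile
  threshold, then refined by `fitSpot` (Levenberg–Marquardt 2D Gaussian)
  and gated on fitted sigma, center shift (<= 1.5 px) and residual RMS
  (<= 3 noise sd).
* **Extraction** (`extractTraces`): per frame, the other channel's
  intensity is integrated over the 5 x 5 window centered on the mapped,
  drift-corrected AOI position; windows leaving the image mark the trace
  partial.

The 1.5 px gates are package defaults chosen at the PSF scale, not values
inferred from any published analysis.

# Trace idealization (DISC-style)

`idealizeDISC()` converts a noisy trace to a piecewise-constant level
sequence in three deterministic stages:

1. **Change-point segmentation.** The segment structure minimizes total
   within-segment SSE plus a per-change-point penalty, solved exactly by
   PELT dynamic programming. The penalty is a chi-squared(1) critical
   value, Bonferroni-corrected over candidate split points, scaled by the
   noise variance. Using the *noise* variance — estimated robustly from
   the MAD of first differences and refined once on within-segment
   residuals — rather than a segment's own variance is essential: a
   segment's empirical variance is inflated by unresolved structure,
   which silences greedy split tests on alternating signals. An exact
   search also finds short dwells flanked by the same level, which greedy
   binary splitting provably cannot isolate when no single cut improves
   the criterion.
2. **Agglomerative clustering** of length-weighted segment means; the
   number of intensity levels (up to `maxStates`) is chosen by BIC on the
   frame-wise Gaussian likelihood. Adjacent levels closer than 3 noise sd
   are merged so noise is never split into two levels.
3. **Viterbi refinement** with Gaussian emissions per level and
   transition probabilities estimated from the provisional assignment.

Level 0 (lowest mean) is dark; `toBinary()` maps level >= 1 to bound. The
minimum event length is one frame — no dead-time filter beyond the frame
clock, so missed-event behavior is attributable solely to discretization.

# Dwell-time statistics

Dwells are run lengths of the binary signal times the frame interval; the
first and last dwell of each trace are **censored** (their true duration
is only bounded below). Dwell distributions are modeled as exponential
mixtures with the normalized density

$$P(x) = \sum_{k=1}^{K} \frac{A_k}{\tau_k}\, e^{-x/\tau_k},
\qquad \sum_k A_k = 1 .$$

This is the only form in which the amplitudes are dimensionless and each
$\tau_k$ is a time constant; mixtures are reported with $\tau$ ascending
(the short-/long-lived convention).

`fitExpMixture()` maximizes the likelihood by EM. Censoring is handled
two ways: `"drop"` (default for mixture fits) excludes boundary dwells;
`"likelihood"` keeps them as survival terms $\sum_k A_k e^{-c/\tau_k}$
and, in the M-step, imputes a censored dwell's expected duration
$c + \tau_k$. The censored likelihood is essentially unbiased even when
$\tau$ exceeds the movie length — the photobleaching control (true
lifetime ~2682 s against 1800 s movies, half the spots never bleaching)
is recovered within a few percent, while dropping censored dwells caps
every duration at the horizon and underestimates grossly; this contrast
is exercised in the test suite. The photobleach control therefore always
uses censored likelihood, whose K = 1 MLE is simply total observed time
over the number of uncensored spots. Multi-start uses quantile-spread
initializations with fixed sub-seeds, plus a warm start from the
(K-1)-component fit and a degenerate equal-tau start that reproduces the
single-exponential optimum exactly, making logL provably nondecreasing
in K.

**Model selection** (`selectMixtureModel`) climbs a log-likelihood-ratio
ladder with 2 degrees of freedom per added component (one amplitude, one
time constant) at level 0.05, and compares the winner against a gamma fit
by BIC. The mixture LLR does not satisfy the regularity conditions of
Wilks' theorem — the null sits on the boundary of the parameter space —
so the chi-squared(2) calibration is *conservative*: the measured type-I
error is about 0.01–0.02 at nominal 0.05. The test still controls size,
and its errors go toward fewer components, never spurious ones; this is
a documented property, not a defect of the implementation.

Summaries: `occupancyFraction` (bound time over total time, per technical
replicate), `eventsPerMolecule` (bound dwell counts, optionally relative
to a reference condition), `rastergramData` (per-molecule binding
intervals sorted by first event) and `multiOccupancyFraction` (time at
occupancy >= 2, the double-binding readout).

# Global kinetic fitting

`schemeLogLik()` evaluates the discrete-time likelihood of idealized
class sequences under a scheme: the frame-to-frame transition matrix is
exp(Q dt), the emission is the deterministic class map, and the forward
algorithm marginalizes hidden states within each observable class. The
chain is taken stationary at the first frame. Sequences are run-length
encoded and the forward pass runs in C++ with per-class masked-matrix
powers, so one evaluation over ~5e5 frames costs milliseconds. Frames
whose class lies outside a scheme's alphabet (a spurious double-occupancy
level under a single-ligand scheme) are truncated to the nearest
representable class (`bound2 -> bound`) rather than declared impossible.

`fitGlobal()` maximizes this likelihood over all free rates jointly
across concentrations — second-order constants scale with concentration,
which is what identifies them — using bounded L-BFGS-B on log-rates
(bounds 1e-6..1e2 s^-1^ first order, 1e4..1e10 M^-1^ s^-1^ second order)
with seeded multi-start. Confidence intervals are Wald intervals from the
numerically estimated observed information on the log scale; this is much
cheaper than profile likelihood or bootstrap at these data sizes and is
accurate here because the log-rate likelihood is close to quadratic, but
it is a local approximation — rates with flat information are flagged and
reported with bound-to-bound intervals instead.

`bic()` implements k log N - 2 logL with **N = total frames across all
molecules and concentrations**, and `selectScheme()` ranks candidate
schemes by it, breaking ties toward fewer parameters and ranking
non-converged fits last.

No missed-event (dead-time) correction is applied beyond the frame clock.
Dwells shorter than about two frame intervals are under-observed, which
biases fast rates slightly toward slower values; at the default study
conditions (mean bound dwell ~7 frames) the bias on kon and koff stays
well inside 10%, as the recovery tests demonstrate.

# Binding curves

Fluorescence-polarization titrations are normalized per replicate to the
0 nM well (0%) and the maximum (100%), then averaged; the rescale is
affine, so the output is invariant to affine transforms of the raw data.
`fit4PL()` fits

$$\%\mathrm{Bound} = FP_{min} + \frac{FP_{max} - FP_{min}}
{1 + 10^{(\log K_D - \log[\mathrm{Protein}]) \cdot H}}$$

by nonlinear least squares on the log-concentration axis with multi-start
over log K~D~. H is constrained positive: the H < 0 mirror solution swaps
FP~min~/FP~max~ and is excluded as an identifiability convention. A K~D~
outside the assayed range is flagged extrapolated.

# Study conditions and test scale

The generator's defaults are the study conditions: 1800 s movies, 3 s
effective frames, concentrations 1/3/10 nM, the four-state scheme above,
SNR 8 emission, photobleaching lifetime 2682 s. The dwell-mixture catalog
(`dwellMixtureCatalog()`) records the fitted two-exponential parameters
per RNA construct; components without a reported value (the long unbound
and short bound time constants, and one unreported long bound value) are
package assumptions flagged `assumed` — 400 s for long unbound times,
15 s for short bound times, 250 s / 200 s for the unreported long bound
components, each inside the reported "~200 to 300 s" long-lived range.
The "86 to 32 s" unbound time constants are paired with the
dominant-amplitude (short) component.

Recovery tests run at 300 molecules x 600 frames per concentration
(about 5.4e5 frames per fit), 10 seeds for scheme selection, 1e4–2e4
dwells per mixture recovery, 500 spots for the photobleach control and
2000 null datasets for the type-I measurement — sizes chosen so sampling
error sits comfortably inside the assertion tolerances.

# Known limitations

* Majority-occupancy discretization plus the absence of a dead-time
  correction biases rate estimates when true dwells approach the frame
  interval (at 10 nM the mean unbound dwell is under two frames; the
  aggregated-likelihood fit absorbs most, not all, of this).
* The LLR ladder for mixture components is conservative (above).
* Wald confidence intervals can be optimistic for rare-state rates whose
  likelihood is asymmetric.
* The image model assumes a spatially uniform PSF and background; there
  is no autofocus or chromatic-aberration model beyond the similarity
  transform.
* Double occupancy is modeled as an intensity level, not as two resolved
  fluorophores; dye photophysics (blinking, partial bleaching steps) is
  not simulated.
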