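# cosmosKinetics

Kinetic analysis of colocalization single-molecule spectroscopy (CoSMoS)
experiments, built around the assembly of the yeast U6 snRNP: DY549-labeled
Lsm2–8 heteroheptamer binding and unbinding on individual Cy5-labeled,
surface-tethered U6 snRNAs, imaged in two alternating laser channels
(effective 3 s frames, ~1800 s movies). The package is for single-molecule
biophysicists who need to go from two-channel image stacks (or per-molecule
intensity traces) to rate constants, and to validate every analysis stage by
parameter recovery on synthetic data with known ground truth.

## What it computes

* **Synthetic data with ground truth** — exact Gillespie simulation of
  continuous-time Markov binding schemes (e.g. the four-state chain
  `U* <-> U <-> UL <-> UL*` with kon = 1.94×10⁷ M⁻¹s⁻¹, koff = 0.045 s⁻¹ and
  rare off-pathway states), majority-occupancy frame discretization, Gaussian
  emission traces, full two-channel movies with PSF spots, fiducials, drift
  and Poisson + read noise, dwell-time mixture samples, and 4PL
  fluorescence-polarization titrations.
* **Image front end** — fiducial-based nonreflective similarity mapping
  between channels, subpixel drift correction by upsampled cross-correlation,
  GLRT spot detection on the average of the first five frames, 2D Gaussian
  AOI fits in 5×5 px windows, and drift-corrected trace extraction.
* **Trace idealization (DISC-style)** — exact penalized change-point
  segmentation, BIC-guided clustering of intensity levels (including double
  occupancy), and Viterbi refinement; deterministic given the trace.
* **Dwell-time statistics** — right-censored exponential-mixture maximum
  likelihood, `P(x) = Σ (A_k/τ_k) exp(−x/τ_k)`, with log-likelihood-ratio
  component selection and a gamma alternative; occupancy fractions,
  events-per-molecule, rastergram tables, double-occupancy time fractions,
  and the censored single-exponential photobleaching control.
* **Global kinetic fitting** — aggregated-Markov forward likelihood of
  idealized trajectories with transition matrix `exp(QΔt)`, fitted jointly
  across ligand concentrations, with scheme ranking by
  `BIC = k·log(N) − 2·logL` (N = frames analyzed).
* **Binding curves** — four-parameter logistic fits of normalized
  fluorescence-polarization titrations on the log-concentration axis.

## Worked example

Simulate forty molecules at 1 nM from the one-step binding model, idealize
the traces, and summarize occupancy and dwell times:

```r
library(cosmosKinetics)

cfg <- simConfig(seed = 11, nMolecules = 40L, movieLength = 1800,
                 concentration = 1)
traces  <- simulateTraces(twoStateScheme(kon = 1.94e7, koff = 0.045), cfg)
ideals  <- lapply(split(traces$intensity, traces$molecule_id),
                  idealizeDISC, frameInterval = 3)
binaries <- lapply(ideals, toBinary)

occupancyFraction(binaries, replicate = rep(1:2, each = 20))$mean
#> [1] 0.313

dwells <- extractDwells(binaries, frameInterval = 3)
dwells
#> DwellSet: 1813 dwells (80 censored) from 40 molecules
#>   unbound  n=921, median 39 s
#>   bound    n=892, median 18 s

fitExpMixture(dwells, K = 1, state = "bound", seed = 11)
#> ExpMixtureFit K=1 (drop censoring, 881 dwells, 0 censored)
#>   A1 = 1.000  tau1 = 25.3 s
#>   logL = -3726.892
```

The occupancy at 1 nM (0.313) matches the stationary prediction
konC/(konC + koff) = 0.301 within sampling error, and the mean bound dwell
(25.3 s) sits near 1/koff = 22.2 s — slightly above it because dwells
shorter than half a frame are invisible to the 3 s camera clock.
`fitGlobal()` removes most of that bias by fitting the frame-sampled chain
directly; `selectScheme()` then ranks candidate schemes by BIC. The
photobleaching control recovers a ~2682 s dye lifetime from 1800 s movies by
censored maximum likelihood:

```r
photobleachControl(sampleDwells(1, 2682, 500, censorAt = 1800, seed = 6))$tau
#> [1] 2921.6
```

A YAML-driven orchestration (`runPipeline()`, with a shell wrapper in
`inst/scripts/run_pipeline.R`) chains the stages
simulate → idealize → dwells → fitmix → fitrates → fp and writes CSV/JSON
outputs plus a provenance record.

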