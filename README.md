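# fbmtrack

Gaussian-process inference of anomalous diffusion from single-particle
tracking data.

Live-imaging experiments — tracking fluorescently labeled chromatin loci,
membrane proteins, or any sub-resolution spot — produce short, noisy
trajectories with missing frames. The standard analysis fits a power law to
the mean squared displacement (MSD), which throws away the temporal
correlations inside each trajectory, handles localization noise awkwardly,
and cannot deal with occlusions. `fbmtrack` instead models the whole
trajectory as a Gaussian process with the fractional Brownian motion (FBM)
kernel

```
Σ(t, t') = D (|t|^α + |t'|^α − |t − t'|^α),        MSD = 2 n_dim D t^α
```

and works with the exact likelihood of all observed positions, with
per-point localization errors σᵢ on the covariance diagonal. Two parameters
summarize the motion: the apparent diffusion coefficient `D`
(length²/time^α) and the anomalous exponent `α ∈ (0, 2)` (α = 1 Brownian,
α < 1 sub-diffusive, α > 1 super-diffusive).

What the package does:

* **Parameter inference** — maximum a posteriori fits (`fitTrajectory()`)
  and Metropolis–Hastings posterior sampling with credible intervals
  (`samplePosterior()`), under flat priors on `(D, α, μ)`.
* **Substrate correction** — when ≥ 2 particles share a cell, the motion
  common to all of them (cell displacement, drift) is modeled as one extra
  FBM process and marginalized exactly; `fitEnsemble()` jointly estimates
  every particle and the substrate, and `inferSubstratePath()` reconstructs
  the substrate path with a credible band.
* **Interpolation** — `interpolateTrajectory()` returns the most probable
  position at any time with a 95% band, filling occlusions.
* **Simulation** — exact FBM sampling, noise/occlusion corruption, and
  ready-made benchmark datasets with ground truth (`simulateFBM()`,
  `corruptTrajectory()`, `simulateEnsemble()`, `benchmarkDataset()`).
* **Baselines** — reference MSD and displacement-distribution (DDB)
  estimators for benchmarking (`fitMSD()`, `fitDDB()`).
* **Diagnostics** — FBM velocity autocorrelation, displacement
  self-similarity/Gaussianity checks, and an inter- vs intra-cell variance
  decomposition by the law of total variance.
* **Imaging** — sub-pixel spot refinement by rotated 2D-Gaussian fitting
  with an MCMC localization-error estimate (`refineSpot()`), and two-channel
  affine alignment (`estimateAlignment()`).
* **I/O and CLI** — trajectory CSV and results JSON readers/writers
  (schemas in `inst/extdata/`), TIFF stacks, and a `runCLI()` front end with
  an `Rscript` wrapper in `inst/scripts/fbmtrack`.

## Worked example

```r
library(fbmtrack)

## a 250-point track (dt = 0.5 s), 0.1 px localization noise, 10% occlusion
clean <- simulateFBM(nPoints = 250, dt = 0.5, D = 0.5, alpha = 0.7, seed = 42)
obs   <- corruptTrajectory(clean, sigma = 0.1, occlusionRate = 0.1, seed = 42)
obs
#> Trajectory 'sim1' (group 'group1'): 225 points, 2D, t in [0, 124.5] s
#>   mean localization error: 0.1

fit <- fitTrajectory(obs)
fit
#> FbmFit (224 displacements): D = 0.4718, alpha = 0.6537, logPost = -523.063
```

The fit recovers the generating parameters (D = 0.5, α = 0.7) from a single
noisy, occluded track. Posterior sampling quantifies the uncertainty — the
true values sit inside the 95% credible intervals:

```r
chain <- samplePosterior(obs, nSamples = 2000, burnIn = 700, seed = 42,
                         mapFit = fit)
round(credibleIntervals(chain)[1:2, ], 3)
#>       lower median upper
#> D     0.419  0.477 0.548
#> alpha 0.551  0.657 0.777
```

GP conditioning interpolates through occluded stretches with a pointwise
95% band (`x` is the posterior-mean x-coordinate, `lo`/`hi` the band):

```r
path <- interpolateTrajectory(obs, fittedParams(fit), c(10, 10.5, 11))
#>  time      x     lo    hi
#>  10.0  1.433  1.240 1.626
#>  10.5  1.124  0.931 1.318
#>  11.0 -0.178 -0.372 0.015
```

When two particles share a cell, common substrate motion inflates naive
per-track estimates; the joint fit removes it. Here both particles ride a
substrate with D_R = 0.8 (true particle D: 0.3 and 0.6):

```r
sim  <- simulateEnsemble(c(0.3, 0.6), c(0.5, 0.8),
                         substrateD = 0.8, substrateAlpha = 1.2, seed = 7)
efit <- fitEnsemble(trajectories(sim$ensemble))
vapply(uncorrectedFits(efit), diffusionCoef, 0)   # ignoring the substrate
#> [1] 1.044 1.336
vapply(particleParams(efit), diffusionCoef, 0)    # substrate-corrected
#> [1] 0.314 0.590
substrateParams(efit)
#> DiffusionParams: D = 0.7252, alpha = 1.256, mu = (0, 0)
```

Uncorrected estimates are inflated 2–3×; the corrected ones land on the
truth, and the substrate's own parameters are recovered as a by-product.

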