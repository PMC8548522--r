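---
title: "Gaussian-process inference of anomalous diffusion: models and methods"
author: "fbmtrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gaussian-process inference of anomalous diffusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

A tracked particle (in our motivating case a fluorescently labeled chromatin
locus, but any sub-resolution spot tracked over time fits) produces a time
series of positions $r(t_i)$ with per-point localization errors
$\sigma_i$ and, frequently, missing frames. `fbmtrack` models the whole
trajectory as a Gaussian process with the fractional Brownian motion (FBM)
kernel

$$\Sigma_{D,\alpha}(t, t') = D\left(|t|^\alpha + |t'|^\alpha
  - |t - t'|^\alpha\right),$$

which follows from assuming stationary increments and a power-law variance.
Two parameters describe the motion: the apparent diffusion coefficient $D$
(units length$^2$/time$^\alpha$) and the anomalous exponent
$\alpha \in (0, 2)$; $\alpha = 1$ recovers ordinary Brownian motion
($\Sigma = 2D\min(t,t')$), $\alpha < 1$ is sub-diffusive (chromatin's usual
regime), $\alpha > 1$ super-diffusive. The implied mean squared displacement
is $\langle r^2 \rangle = 2 n_{\mathrm{dim}} D t^\alpha$.

The likelihood of an observed trajectory is the exact multivariate normal
density under this kernel with the localization-error variances
$\sigma_i^2$ added to the diagonal. Unlike estimators built from individual
displacements, this uses every temporal correlation in the data, weights
noisy points correctly, and is untroubled by missing frames.

**Anchoring.** Trajectories are re-referenced so their first observed point
is the origin: the likelihood acts on displacements $r(t_i) - r(t_0)$. This
avoids a singular covariance row at the process origin and makes estimates
exactly invariant to rigid translations. A constant per-dimension mean
$\mu$ is retained as a free parameter (it absorbs residual offsets, e.g.
the anchor's own localization error); spatial dimensions are independent
processes sharing $(D, \alpha)$.

**Priors and transforms.** Estimation uses flat priors on $(D, \alpha, \mu)$
in natural space, so the posterior mode is the likelihood optimum.
Optimization and sampling run in the unconstrained space
$\theta = (\log D,\ \log\frac{\alpha}{2-\alpha},\ \mu)$; the
Metropolis-Hastings target carries the change-of-variables Jacobian
$\log D + \log(\alpha(2-\alpha)/2)$ explicitly so the chain samples the
natural-space posterior. The transform enforces $D > 0$ and
$0 < \alpha < 2$ by construction.

## Substrate motion

When two or more particles share a cell, motion common to all of them
(cell displacement, stage drift, chromosome rearrangement) inflates every
apparent $D$ and $\alpha$. Writing each observed track as
$r_k(t) = a_k(t) + R(t)$ with independent FBM processes $a_k$ (particle) and
$R$ (substrate), marginalizing $R$ gives a joint Gaussian over the stacked
trajectories with covariance blocks

$$\begin{pmatrix} \Sigma_1 + \Sigma_R & \Sigma_R \\
  \Sigma_R & \Sigma_2 + \Sigma_R \end{pmatrix},$$

generalizing to $K$ particles (diagonal $\Sigma_k + \Sigma_R$, every
off-diagonal block $\Sigma_R$). `fitEnsemble()` maximizes this joint
likelihood over all particle parameters and the substrate $(D_R, \alpha_R)$;
because the blocks are built on each particle's own observation times, no
common grid is required (anchors may even differ — the implementation uses
the exact increment covariance
$\mathrm{Cov}[R(t)-R(a_k), R(t')-R(a_l)]$).

The conditional mean of the substrate path given the tracks is

$$\langle R \rangle = \Big(\Sigma_R^{-1} + \sum_k \Sigma_k^{-1}\Big)^{-1}
  \sum_k \Sigma_k^{-1}(r_k - \mu_k),$$

with covariance $(\Sigma_R^{-1} + \sum_k \Sigma_k^{-1})^{-1}$. The sign of
this expression was validated by a simulation oracle: across simulated
ensembles the implemented mean has strictly smaller mean squared error
against the true substrate path than its negation, and correlates
positively with it (see `test-inference.R`).

## Interpolation

Given fitted parameters, standard GP conditioning yields the most probable
(noise-free) position at any query time along with a pointwise credible
band (`interpolateTrajectory()`; 95% band = mean ± 1.96 sd). At a
noiselessly observed time the band collapses onto the observation; at the
anchor it collapses onto the anchor. On simulated tracks with 10% occlusion
the 95% band covers the hidden true positions at the nominal rate (the
acceptance suite measures this on 200 tracks).

## Baselines

Two displacement-based reference estimators ship for benchmarking:

* **MSD** (`msdCurve()` + `fitMSD()`): sliding-window mean squared
  displacement over the first 10% of step intervals (beyond that,
  single-trajectory correlations dominate), fitted to
  $2 n_{\mathrm{dim}} D t^\alpha + 2\sigma^2$ by ordinary least squares in
  log-log space after subtracting the noise floor. The paper-standard noise
  floor convention $+2\sigma^2$ is used as printed. "Linear regression" is
  interpreted as OLS on log-transformed values; the routine is isolated so a
  weighted variant can be swapped in.
* **DDB** (`fitDDB()`): the radial displacement density
  $\rho(r \mid t) = \frac{r}{2Dt^\alpha + \sigma^2}
  \exp(-\frac{r^2}{4Dt^\alpha + 2\sigma^2})$ fitted over frame lags 1-10.
  The default maximizes the unbinned per-displacement likelihood — the
  zero-bin-width limit of a histogram fit, avoiding two undocumented free
  choices (bin count and range); a Freedman-Diaconis binned multinomial
  mode is available for fidelity comparisons.

Both treat overlapping-window displacements as independent; that discarded
correlation is exactly the information the GP uses, and is why the GP
estimator dominates them across the benchmark ranges.

## The simulator and what the tests do (and do not) show

`simulateFBM()` draws exact FBM trajectories by Cholesky factorization of
the full kernel matrix — at a few hundred points this is trivially cheap and
exact, so no approximate scheme (circulant embedding, increments recursion)
is used. `corruptTrajectory()` adds i.i.d. Gaussian localization noise and
removes a uniformly random subset of non-anchor points
(`round(o (N-1))` of them); path, noise and occlusion use independent
sub-streams of the seed so each stage is separately reproducible.
`benchmarkDataset()` draws parameters uniformly from the standard benchmark
ranges $0.01 < D < 1.5$, $0.01 < \alpha < 1.9$, $0.1 < dt < 1$,
$0.001 < \sigma < 0.25$, occlusion $0$-$0.8$, redrawn per trajectory, with
250 points per track.

The generator emulates: power-law correlated Gaussian motion, frame-wise
localization noise, uniformly random missed detections, and additive
substrate motion shared within a cell. It does **not** emulate: regime
switching over long time scales (a crossover between diffusion regimes is
documented in the literature and this single-kernel model would have to be
extended for it), non-Gaussian diffusion (CTRW-like waiting times,
heterogeneous diffusivity), localization errors correlated across frames,
or detection dropouts correlated with position (e.g. defocus). Passing
tests therefore demonstrate correctness and calibration *under the FBM
model class*, not that any particular experimental system is FBM — that is
what the adequacy diagnostics are for.

## Diagnostics

* `theoreticalVACF()` / `empiricalVACF()`: the FBM velocity
  autocorrelation $\frac{(\tau+\epsilon)^\alpha - 2\tau^\alpha +
  |\tau-\epsilon|^\alpha}{2\epsilon^\alpha}$ versus its ensemble- and
  time-averaged empirical counterpart ($\epsilon$ defaults to one frame;
  occluded products are dropped, never imputed, keeping the diagnostic
  model-free). The anti-persistent dip at $\tau = \epsilon$ is the
  characteristic FBM signature for $\alpha < 1$.
* `selfSimilarityCheck()`: rescales lag-$n$ displacements by
  $(n\,dt)^{-\alpha/2}$ and reports per-lag normality summaries (KS
  distance, excess kurtosis) plus a cross-lag collapse statistic (maximum
  pairwise two-sample KS distance). No single test statistic is privileged;
  both are reported.
* `varianceDecomposition()`: law-of-total-variance split of per-track
  estimates into within-cell and between-cell components. Population
  variances and member-weighted group means make the identity
  intra + inter = total exact for arbitrary group sizes (the weighting
  convention is a documented choice); singleton groups are excluded with a
  warning.

## Imaging

`refineSpot()` fits the 7-parameter rotated 2D Gaussian spot model
(center, per-axis size, rotation/correlation parameter $\theta \in (-1,1)$,
signal, background) to an image patch by Nelder-Mead under an i.i.d.
Gaussian residual model with the noise variance profiled out, then runs a
short Metropolis-Hastings chain whose posterior standard deviation of the
center is reported as the localization error — the $\sigma_i$ consumed by
the GP likelihood. The residual model is a documented choice (the
alternative would be Poisson shot noise); the default patch is 11×11 pixels
around the tracker's detection. Note the spot $\theta$ is a bounded
correlation-type parameter, distinct from the alignment rotation angle
below.

`estimateAlignment()` corrects dual-camera/chromatic offsets between two
channels with the affine family scaling × translation × rotation about a
center $c$, maximizing $-\frac{WH}{2}\log\sum_{k,l}[I_2(k,l|\Omega) -
I_1(k,l)]^2$ over $(s_x, s_y, d_x, d_y, \theta)$ by Nelder-Mead. $c$ is
fixed at the image center because the likelihood is degenerate in $(c, d)$
jointly. Intensities are used raw by default with an optional per-frame
median normalization (exposure handling before the residual is otherwise
under-determined). Pixel convention: x = column, y = row, origin top-left,
centers on integer coordinates; `applyAlignment()` resamples bilinearly and
fills out-of-bounds pixels with a border-median background estimate.

## Numerical choices

* Cholesky factorizations throughout; explicit inverses appear only in the
  small-instance test oracles. A relative jitter of $10^{-10} \times
  \max(\mathrm{diag})$ precedes every factorization (the FBM kernel becomes
  severely ill-conditioned as $\alpha \to 2$); a factorization failure
  returns $-\infty$ and the optimizer simply avoids that region.
* Kernel assembly caches the unique values of $|t_i - t_j|$ once per
  dataset, so a likelihood evaluation needs only a few hundred `pow` calls;
  the assembly and the multivariate-normal density run in compiled code
  (RcppArmadillo).
* MAP fits use Nelder-Mead with a moment-based start (a quick MSD power-law
  fit) plus two deterministically perturbed restarts; perturbed restarts run
  a quarter-budget exploratory simplex and are polished only when they find
  a better basin. Ties break toward the lower $\alpha$. Defaults:
  `maxit = 500`, `reltol = 1e-7`.
* Ensemble fits initialize particles from their independent fits and the
  substrate from an empirical cross-correlation power-law fit; for stacked
  sizes above 320 points the simplex first runs on a 2× time-thinned
  ensemble and full resolution only polishes that optimum. These stage
  sizes are accuracy/cost choices validated by the substrate-correction
  study in the acceptance suite.
* MH defaults: 10,000 kept sweeps after 2,000 burn-in, per-coordinate
  Gaussian random walk with scales adapted every 50 burn-in sweeps toward
  ~30% acceptance and then frozen (adaptation during sampling would break
  detailed balance). The simulation studies in the test suite use shorter
  chains (2,000 kept / 700 burn-in) and 100-point tracks, sizes at which
  one calibration replicate costs ~1.5 s.
* Degenerate inputs: trajectories need at least `minPoints = 5` usable
  displacements (the minimum track length for experimental fits is exposed
  as this knob since no universal value exists); flat image patches and
  boundary-hugging spot fits are flagged rather than silently returned;
  MSD fits clamp out-of-range slopes into $(0, 2)$ with a flag; a
  vanishing total variance flags the decomposition's proportions as NA.

## Problem sizes in the validation suite

The simulation studies in `tests/testthat/test-acceptance.R` are scaled-down
but otherwise faithful reproductions of the package's claims: 200
trajectories for the estimator comparison (ranges above), 200
substrate-coupled pairs at $dt = 0.5$, $\sigma = 0.1$, 10% occlusion (plus
30 five-particle ensembles at 80 points for the more-particles-help trend),
200 tracks for interpolation coverage, 200 chains for posterior
calibration, 5,000 replicates for the exact-sampler covariance check, and
1,000 tracks per exponent for the velocity autocorrelation. The
`scripts/acceptance.R` report re-runs the same studies at 100 / 40 / 50 /
50 replicates. These sizes keep every Monte-Carlo margin a small multiple
of its standard error; enlarging them only tightens the same comparisons.

## Known limitations

* Only the FBM kernel ships. The likelihood machinery is kernel-agnostic
  (any positive-definite $\Sigma(t,t')$ on anchored increments would slot
  in), but confined/Ornstein-Uhlenbeck or crossover kernels are not
  implemented.
* Flat priors make single short, noisy tracks yield wide (conservative)
  posteriors; informative priors are a natural extension point but are not
  shipped.
* The substrate path is reconstructed on the times observed by every
  particle (the conditional-mean formula needs a common grid); with heavy,
  disjoint occlusion this grid can be sparse.
* The DDB baseline is 2D-only, as its radial density is.
* Spot refinement assumes Gaussian residuals and a single spot per patch;
  overlapping spots are not deconvolved.
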