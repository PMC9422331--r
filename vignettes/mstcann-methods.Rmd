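---
title: "Modelling multisensory integration and causal inference in MST-d"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling multisensory integration and causal inference in MST-d}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(mstcann)
```

## The scientific problem

Neurons in the dorsal medial superior temporal area (MST-d) of the macaque
respond to both visual optic flow and vestibular self-motion. When the two
cues disagree, the brain must decide whether they came from one cause (and
should be integrated) or two (and should be kept separate). `mstcann`
implements a complete modelling chain for this problem:

1. **Tuning analysis** — classify neurons as *balanced* or *imbalanced* by the
   ratio of their maximal visual and vestibular responses, and measure their
   unisensory and multisensory preferred-direction disparities.
2. **A hierarchical ring-attractor network** — two unisensory layers (MT,
   PIVC) feed a multisensory subnetwork; one settled bump encodes
   integration, two bumps encode separation, and the synaptic ratio of the
   forward weights controls which happens.
3. **Causal-inference observers** — a single-unit fixed-criterion rule and a
   population-level Bayesian observer, with parameter fitting.
4. **A population sampling decision** — a decision neuron compares pooled
   balanced and imbalanced responses drawn by Monte-Carlo sampling.

All stages run on synthetic data from the package's generator; no recorded
data ship with the package.

## The network model

Each of the three layers is a ring of $L = 180$ rate units, 2° of direction
per unit, with activity $y_k \in [0,1]$ evolving as

$$\tau \frac{dy_k}{dt} = -y_k + S\!\left(I_{k,\mathrm{lat}} + I_{k,\mathrm{ext}}
+ I_{k,\mathrm{noise}}\right), \qquad
S(I) = \frac{1}{1+e^{-g (I - \phi)}} .$$

Lateral coupling is a Mexican hat,
$w_{jk} = \beta\,[\,w_\mathrm{ex} e^{-d_{jk}^2/2\sigma_\mathrm{ex}^2} -
w_\mathrm{in} e^{-d_{jk}^2/2\sigma_\mathrm{in}^2}\,]$ with zero
self-coupling; the unisensory layers receive one broad Gaussian input each
(peak $w_\mathrm{ext} = 25$, range $\sigma_\mathrm{ext} = 160°$), and the
subnetwork receives topologically aligned Gaussian forward projections
(range $\sigma_\mathrm{fwd} = 5°$) from both layers. Intrinsic noise is an
independent $N(0, \sigma_\mathrm{noise}^2)$ draw per neuron and Euler step,
injected inside the activation; no dt-rescaling is applied, because the noise
scale is specified relative to the input amplitude (the best-fit level 6.5 is
about a quarter of the 25-unit input peak). The published kernel widths are
interpreted in degrees; the alternative neuron-index reading (all widths
doubled) was tested during development and rejected because its nearly
global inhibition removes the graded, distance-dependent competition the
bifurcation-boundary phenomenology requires.

### Calibrated parameters

The activation gain and offset, the time constant, and the absolute scale of
the forward weights are free parameters of this implementation (only the
*ratio* of the forward weights is specified by the science). They were
calibrated once, against three qualitative anchors plus the published
noise-free bifurcation boundaries, and then frozen:

* gain $g = 1$, offset $\phi = 24$ — a single broad external input produces
  exactly one bump, robustly for noise levels up to the best-fit value;
* $\tau = 20$ ms, $dt = \tau/10 = 2$ ms — trajectories settle well before the
  3000 ms trial end in the noise-free regime;
* forward-weight scale $g(r)$ — for synaptic ratio $r$ the dominant and
  subordinate weights are $g(r)\,r$ and $g(r)$, with $g(\cdot)$ linearly
  interpolated through the knots $(1, 5.32)$, $(1.28, 6.28)$, $(1.8, 6.15)$,
  $(2.2, 4.70)$, $(2.6, 4.20)$ and clamped outside. The knots were chosen so
  the noise-free one-to-two-bump boundary reproduces the published criterion
  curve: about 70° at $r = 1$, 90° at 1.8, 130° at 2.2 and 150° at 2.6
  (measured 71/91/130/151°). Between the knots the boundary is monotone to
  within a few degrees (the sweep resolution); the calibration interpolates,
  it does not extrapolate new science.

Everything downstream of the boundary curve — the 50 % crossing of the
disparity-averaged integration probability near ratio 1.8, the outcome
fractions of the balanced and imbalanced group experiments, and the
stochastic-resonance maximum of the balanced/imbalanced efficiency near
noise 6 — is emergent, not calibrated.

### Numerical choices

* Explicit Euler integration; activities stay in $(0,1)$ by construction.
* The classified "final state" is the mean activity over the last 100 ms,
  which suppresses noise flicker.
* Bump detection thresholds the state at 0.15; contiguous suprathreshold
  runs on the ring are regions. One region is integration; two regions are
  separation with disparity measured between activity-weighted circular
  centres of mass; zero, all-ring, or more than two regions are excluded.
  Excluded trials in sweeps are re-drawn with fresh noise up to a capped
  number of rounds.
* Grid argmax ties in the tuning analysis resolve toward the smallest
  disparity, then the smallest visual then vestibular direction. A ratio of
  exactly 1.7 classifies as balanced.
* Repeat averaging removes the single repeat most deviant from the median
  (ties: the first), then averages the rest; fewer than three repeats is an
  error, mirroring the recording-exclusion rule.
* The efficiency statistics clip probabilities into $[\delta, 1-\delta]$
  with $\delta = 10^{-6}$ and are computed exactly as printed,
  $\varepsilon = \sum p_\mathrm{bal}\log_2 p_\mathrm{imbal} -
  p_\mathrm{bal}\log_2 p_\mathrm{bal}$: for the model's nested curves
  (imbalanced above balanced) this is positive and grows as the curves
  separate, and it vanishes both for identical curves and in the
  noise-dominated regime. The negated value (the formal KL divergence) is
  attached as an attribute for audit.

## What the synthetic generator emulates — and what it does not

`generate_dataset()` plants, per neuron: a group (balanced/imbalanced at the
recorded 70:45 proportion by default), a response ratio drawn from a
truncated-exponential on the group's range with the recorded group means
(1.28, 2.35 — a uniform draw on [1.7, 4] would have mean 2.85, contradicting
the reported mean, which is why the density decays), unisensory preferred
directions with a planted disparity, and a multisensory preference pair
whose disparity follows the group's distribution (balanced: uniform;
imbalanced: mass decaying by half per 45° bin). Tuning curves are circular
Gaussians on the 45° grid; the multisensory grid is a separable product of
two shifted profiles re-centred on the planted pair; trial noise is
additive Gaussian clipped at zero.

This captures the statistical structure the analysis relies on (group
proportions, ratio ranges and means, disparity preferences, grid argmax),
so noise-free datasets are recovered *exactly* by `analyze_neurons()` — the
package's strongest self-test. It does **not** reproduce the recorded
dataset's histograms, response-template shapes (`f_bal`, `f_imbal`), tuning
asymmetries, or any temporal structure; passing tests demonstrate the
correctness of the analysis chain, not fidelity to the undeposited
recordings. The default decision-model templates (width 60°, baseline 0,
peak 60 spikes/s) are synthetic stand-ins chosen so the default decision
curve falls from about 0.7 at 0° toward 0 at 180°; only directional effects
of reliability scaling and sample size are quantitative claims.

## Known limitations and divergences

These are properties of the calibrated implementation that differ from the
published description; they are deliberate, documented outcomes rather than
bugs, and the relevant checks are left failing rather than weakened:

* **Congruent/opposite efficiency.** The congruent and opposite curves are
  pooled means of the two ratio groups' integration functions over the
  0–90° and 90–180° half-ranges. Wherever the two groups' boundaries
  disagree, pooling creates intermediate (≈0.5) values, so the statistic
  keeps measuring group disagreement and remains large at moderate noise:
  its maximum sits near noise 6 rather than 0.8, and the
  balanced/imbalanced-to-congruent/opposite efficiency ratio at the
  best-fit noise is far below the published ≈185 %. No reading of the
  printed formula we tried yields a low-noise peak without contradicting
  the formula itself.
* **Balanced-group outcome fraction.** In the 1000-trial balanced
  experiment (ratios with mean 1.28, the 8 × 8 stimulus-pairing disparity
  mix) about 55 % of trials end with two response regions, short of the
  published ≈66 %. The fraction follows directly from the σ = 6 integration
  functions once the boundary curve is calibrated; the imbalanced
  experiment's one-bump fraction does land on the published two thirds.
* **High noise.** Above noise ≈ 8 the time-averaged final state usually
  fails the 0.15 effective-response criterion and most trials are excluded;
  the published "all functions approach 50 %" description holds only for
  the surviving trials.
* **Weak lateral coupling.** Below $\beta \approx 0.8$ the subnetwork loses
  its effective response entirely at this operating point, so the published
  $\beta = 0$ and $0.5$ conditions are unreachable; the direction of the
  lateral-scaling effect is verified on $\beta \in [1, 2]$.
* **Late separation.** Under best-fit noise the one-to-two-bump transition
  can complete after the 500–1500 ms analysis window; window-mean
  disparities therefore include pre-separation epochs, and the 60–180° band
  is a property of the separated epochs.
* **Symmetry breaking.** For sub-boundary disparities the merged bump
  settles on one cue (deterministically in the noise-free case) rather than
  the midpoint; the mirror-symmetry invariant applies to the two-bump
  regime and to exchanging the cue labels.

## Problem sizes

The test suite and the acceptance script scale the simulations to what a
single CPU completes comfortably: integration sweeps use 100–200 trials per
(ratio, disparity) cell on the 45° disparity grid, the stochastic-resonance
sweep 50 trials per cell on a 22.5° grid over 14 noise levels, and the
group experiments 1000 classified trials, matching the published trial
count. Observer fits use $10^5$ Monte-Carlo repetitions as published. The
chosen sizes keep Monte-Carlo standard errors a factor of a few below every
stated tolerance.

## A worked example

```{r example}
library(mstcann)

# the physiological analysis on a synthetic population
ds <- generate_dataset(generator_config(seed = 7))
summaries <- analyze_neurons(ds)
empirical_integration_function(summaries)

# one network trial and the bifurcation boundary
trial <- run_trial(dtheta_uni = 120, ratio = 1.0, sigma_noise = 0)
autoplot(trial)
noise_free_boundary(1.0)   # ~71 deg
noise_free_boundary(2.6)   # ~151 deg

# integration functions and their 50% crossing at the best-fit noise
sweep <- integration_sweep(seq(1, 2.6, by = 0.4), sigma_noise = 6,
                           n_trials = 200, seed = 1)
pint_crossing(group_mean_pint(sweep))   # ~1.8

# observers
fc <- fit_kappa(sweep[sweep$ratio == 1.8, ], sigma_noise = 30)
tidy(fc)
curve <- decision_curve(decision_config(), seed = 1)
fit_bci(curve, sigma = 30, fit = "prior")
```
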