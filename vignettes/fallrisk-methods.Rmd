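---
title: "Methods: metastable gait, absorbing chains and fall-risk models"
author: "fallrisk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: metastable gait, absorbing chains and fall-risk models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fallrisk)
```

## The problem

A metastable walker survives small random perturbations for a long but
finite time. Its stability is naturally summarised by the mean first
passage time (MFPT): the expected number of steps before it enters the
absorbing "fallen" state. Because falls are rare, estimating the MFPT by
simulation alone is hopeless for stable gaits (it can exceed billions of
steps), while many popular mechanics-based stability metrics — margins of
the extrapolated centre of mass, foot rotation indices, Lyapunov
exponents, variability measures — are cheap to compute but only loosely
validated as predictors of actual fall risk. This package implements a
pipeline that (1) computes the MFPT exactly from an absorbing Markov
chain model of the gait, (2) computes 49 gait metrics both from simulated
step sequences and directly from the chain, (3) quantifies how metric
accuracy depends on the number of steps observed, and (4) fits and
evaluates regression models that predict ln(MFPT) from the metrics.

## Step-to-step dynamics as an absorbing Markov chain

One step maps a start-of-step state and a horizontal impulse perturbation
(m/s, applied once per step) to an end-of-step state or a fall. Meshing
the state space and the perturbation axis (201 grid values from −0.200 to
+0.200 m/s at 0.002 m/s) gives a deterministic transition catalogue; a
Gaussian perturbation distribution N(0, 0.013² m²/s²) converts it to a
stochastic chain with transient block $Q$ and failure column $R$. Two
MFPT estimates are computed:

- eigenvalue form: $\mathrm{MFPT} \approx -1/\log\lambda_2$ with
  $\lambda_2$ the largest-magnitude eigenvalue of $Q$ (the second-largest
  of the full transition matrix). This is the default "true MFPT"
  downstream;
- exact form: $\mathrm{MFPT} = \sum_i n_{1i}$, with
  $n_{1i} = [(I-Q)^{-1}]_{1i}$ the expected number of visits to state $i$
  starting from the nominal step.

The two agree to better than 1% once survival per step exceeds ~0.999;
both are always reported and the choice is switchable. Numerical choices:
$(I-Q)X = I$ is solved densely (no explicit inverse); Gaussian cell
masses are CDF differences over half-open grid cells with the tails
folded into the extreme cells, so each row of $[Q\,|\,R]$ sums to one
exactly with no renormalisation; complex eigenvalues contribute through
their modulus. Perturbation and state grids are symmetrised in floating
point so that mirror-symmetric dynamics give exactly mirror-symmetric
chains.

## The 49 metrics

Per condition the package computes: mean and SD of the per-step maxima of
the extrapolated centre of mass
$\mathrm{XCoM} = (x_7 - x_{st}) + \dot x_7 \sqrt{\ell/g}$ (hip position
relative to the stance contact plus a pendulum-scaled velocity term) and
of the foot rotation index
$\mathrm{FRI} = (\vec{OG}\times\vec{F_g} - \vec{OA}\times\vec{F_a} -
\tau_a)/F_n - x_{st}$ (the ground point where the reaction force would
have to act to keep the stance foot from rotating); mean and SD of speed,
step length and step duration; short- and long-term Lyapunov exponents of
the six joint angles and their velocities; and the average log
variability (per-time-point SD across steps, logged, averaged over the
100-sample step) of the 15 cyclical coordinates — the horizontal hip
position is excluded because the walker progresses. Sample SDs (n−1) are
used wherever a plain SD over steps is taken; the probability-weighted
chain statistics below use their population-weighted forms verbatim.

The FRI moment expression is typographically ambiguous in its usual
renderings (where the division by $F_n$ and the $-x_{st}$ sit); this
package implements the moment-balance form above, under which the
relative FRI is exactly the point solving the planar net-moment balance
about the contact. The XCoM velocity term is read as
$\dot x_7\sqrt{\ell/g}$, the standard pendulum time-constant scaling.

### Lyapunov exponents

Each coordinate's 100-sample steps are concatenated and delay-embedded
(delay 15 samples, dimension 5). Each embedded point's nearest neighbour
is sought outside a ±50-sample exclusion window (so neighbours come from
different steps; ties go to the smaller index, and the search crosses
step boundaries). The mean divergence curve
$y(i) = \langle \ln d_j(i)\rangle / \Delta t$ tracks the pair distances
$i$ samples ahead, floored at $10^{-7}$ (repeated identical steps
otherwise give $\ln 0$); the short- and long-term exponents are its
least-squares slopes over indices 1–200 (0–1 strides) and 801–2000 (4–10
strides). $\Delta t = 1/100$ in step-normalised time: steps are resampled
to 100 samples, so exponents are per unit of normalised step time and the
resampling deliberately removes step-duration variability from the
series. At least 50 steps are required for meaningful exponents; with
fewer the entries are flagged missing.

The delay is a signal-timescale parameter (0.15 steps). For validating
the estimator on a map — where one sample *is* one step of the dynamics —
the natural delay is one iterate; with delay 1 and everything else at
defaults the estimator recovers the logistic map's analytic exponent
$\ln 2$ to well within 10% over the initial linear region of the curve
(before nearest-neighbour distances saturate at the attractor size),
which is how the test suite checks it.

## Metrics directly from the chain

For every metric except the Lyapunov exponents, the chain replaces the
per-step sample statistics with weighted ones: for each transient state
$i$, the mean $\mu_i$ and SD $\sigma_i$ of the per-transition value
$\rho_{ij}$ over surviving transitions, weighted by the perturbation
masses (failed transitions are excluded from numerator and denominator —
the walker takes no complete step on them); then the overall
$\mu = \sum_i n_{1i}\mu_i / \sum_i n_{1i}$ and
$\sigma^2 = \sum_i n_{1i}(\sigma_i^2 + (\mu_i - \mu)^2)/\sum_i n_{1i}$,
the weighted law of total variance with the expected visit counts as
frequency weights. Joint variability goes through the same two-stage
statistics per time point and coordinate before the log and time average.
When several perturbations realise the same transition, the stored
trajectory is the one for their median perturbation — the chain's
within-cell quantisation, which the validation quantifies.

Chain-side Lyapunov exponents cannot use these formulas (they need step
*sequences*), so they are estimated from random trajectories through the
chain: from each of the 20 most-visited states (largest $n_{1i}$), 20
seeded 50-step trajectories are sampled (400 in total, re-drawing and
eventually dropping, with weight renormalisation, trajectories absorbed
early); each trajectory's exponents are pooled by a weighted mean with
weights $n_{1i}\cdot(1/20)$, normalised to sum to one. This is the
procedure at its full default scale; its cost is dominated by the 4800
divergence curves, so the test suite and the acceptance script exercise
it through the `n_states`, `n_vectors` and `coords` arguments at reduced
counts, leaving the defaults untouched.

## Validation and convergence

Chain metrics are compared to the distribution of brute-force metrics
over 200 disjoint 50-step segments: a metric matches when the chain value
lies within one SD of the brute-force mean, in normalized units (the
normalization record — per-metric mean and sample SD across the training
conditions — is fitted on the chain metrics and then reused unchanged on
all brute-force metrics; zero-variance metrics get scale 1 with a
warning). Lyapunov and variability coordinates are pooled by type when
aggregating. Short-term Lyapunov agreement is *not* expected: the state
discretization introduces small discontinuities between consecutive steps
that dominate short-range divergence, a known limitation of the chain
construction; long-range divergence (4–10 strides) is much less
sensitive to them.

Accuracy versus observation length is quantified by cutting 1000-step
simulations into disjoint segments of
$n \in \{10,20,\dots,100,200,300,500,1000\}$ steps, computing the
percentage of segments within 0.1 or 0.5 normalized units of the chain
value, and fitting $p = \alpha_1\ln n + \alpha_0$. The estimated number
of steps for 90% agreement is $\lceil e^{(90-\alpha_0)/\alpha_1}\rceil$,
floored at 10 (predictions under 10 steps are rounded up); non-positive
slopes report the target as unattainable, and extrapolations beyond ten
times the largest observed $n$ are flagged.

## Fall-risk models

The response is $y = \ln(\mathrm{MFPT})$: raw MFPTs span many orders of
magnitude and only the log is usable in a regression. Individual models
are quadratics $\hat y = \beta_0 + \beta_1\rho + \beta_2\rho^2$ per
metric. The combined model normalizes the chain metric matrix, takes the
first 15 principal-component scores (SVD, no rescaling — the metrics are
already unit variance; component signs fixed so the largest-magnitude
loading is positive), and selects among the 30 linear and squared score
terms (no interactions; higher polynomial orders amplify metric noise) by
consensus stepwise regression: ten bidirectional stepwise runs, each with
three whole conditions removed at random (about 10% of the data), pooling
the terms selected in at least three runs, and a final stepwise pass over
the pool. Two variants exist: one excluding all Lyapunov exponents (the
default) and one including the long-term ones; short-term exponents are
never used because they cannot be reliably computed either way. The
excluding variant is the one used for held-out evaluation in the
acceptance script: it is deterministic given the chain and more robust on
brute-force inputs, where the long-term exponents are the least
transferable metrics.

Two numerical-design points deserve flagging:

- *Entry threshold.* Bidirectional stepwise uses term F-tests with exit
  p = 0.10 and entry p = 0.05 Bonferroni-adjusted by the number of
  candidates screened at that forward step. The adjustment is essential:
  entering the best of ~30 candidates at a raw 0.05 threshold selects
  spurious terms in well over half of pure-noise datasets, and the
  consensus vote cannot rescue this because significance on the full data
  is highly correlated across the ten reduced fits.
- *PCA rank guard.* Principal directions whose singular value is below
  $10^{-7}$ of the leading one are dropped (with a warning) before the
  requested 15 scores are taken. Such directions are collinearity
  artefacts; their scores are machine noise, and coefficients fitted to
  them explode when the model is applied to data with real sampling
  noise.

Goodness of fit is summarised by RMSE, MAE, MAPE
($\frac{100}{n}\sum|\,(\hat y - y)/y\,|$, excluding zero-valued $y$ with
a count), RAAE ($\sum|\hat y - y| / (n\,\sigma_{\hat y})$, with the SD of
the *predictions* in the denominator — the printed reading of an
ambiguous convention), the maximum absolute error, the percentage of
predictions within a tolerance band on ln(MFPT) (default 3.3, ten percent
of a roughly 33-log-unit reference MFPT range; `mfpt_tolerance()`
recomputes it from any dataset), and the evaluation line $\hat y = \alpha_1 y +
\alpha_0$ with its adjusted $R^2$ (written $R_e^2$). Ideal values are
slope 1, intercept 0, $R_e^2 = 1$.

## The synthetic walker and the preset bank

All study data come from a synthetic walker: a contracting affine
step-to-step return map $x^+ = a\,x + b_{\mathrm{eff}}\,s$ with an
absorbing failure region $|x| > x_{\mathrm{fail}}$ (survivors saturate at
the boundary), and within-step trajectories synthesised from per-channel
100-sample templates deformed linearly by the start-state deviation and
the perturbation. The three perturbation timings (start of double
support, start of single support, halfway through single support) scale
the effective perturbation gain (1.0 / 0.9 / 0.6) and shift the onset of
the waveform deformation — later pushes couple less strongly into the
next step, which is why the same gait can be orders of magnitude more
stable under mid-stance perturbations.

The preset bank grades a fragility coordinate $t \in [0,1]$ through the
contraction (0.35–0.65), the failure boundary (0.030–0.072), nominal step
length and duration (speeds ~0.91–1.12 m/s), and the waveform and
spatiotemporal sensitivities, in two template families that differ in
amplitudes and perturbation gain. Three intentional design features:

- *Idiosyncratic jitter.* Each condition perturbs its parameters by a
  small deterministic jitter derived from its own seed (e.g. ±3% on the
  failure boundary, ±8% on sensitivities). Without it the chain metrics
  determine ln(MFPT) *exactly*, stepwise selection degenerates (p-values
  on numerically zero residuals), and the regression exercise is
  meaningless. Real gait families carry exactly this kind of
  off-manifold variation.
- *Resolvable convergence.* Per-step spatiotemporal noise is sized at
  roughly 2–4× the between-condition spread of the corresponding means
  (duration and length noise gains are opposite in sign so speed = L/T is
  genuinely noisy). This makes the accuracy-vs-steps percentages climb
  across the whole 10–1000-step grid instead of saturating immediately —
  the structure the convergence analysis assumes. The implied
  variability (step-time CV around 10%) is higher than healthy human
  walking; it is a resolution choice, not a physiological claim.
- *Span.* MFPTs across the bank run from below $10^2$ to beyond $10^8$
  steps (about eleven orders of magnitude), verified via the exact MFPT,
  while staying clear of the regime where $1 - \lambda_2$ underflows.

What the generator does *not* emulate: multi-dimensional fall modes
(supported dimension is 1–2 and the bank is 1-D), dynamically consistent
kinetics (the force/torque channels are template-based, so FRI-type
metrics are fixture properties rather than physics), continuous sensory
noise, and human-scale variability magnitudes. Passing tests therefore
show that the *pipeline* — chain construction, weighted statistics,
estimators, model fitting — is correct and self-consistent on data with
the assumed structure, not that the metrics predict human falls.

## Problem sizes

The test suite and the acceptance script run the pipeline at desk scale,
chosen to finish in minutes while leaving every estimator in its
operating regime: 41-state chains (201 perturbations each), 36 training
and 12 validation conditions, 200 × 50-step segments for chain-vs-brute
validation on six long-walking presets, five 1000-step trials per
condition for the convergence grid, three 300-step segments per
validation condition for held-out prediction, and reduced trajectory
counts (with unchanged defaults) for the chain-sampled Lyapunov
procedure. Serialization uses JSON at 17 significant digits (exact
round-trip for doubles) and CSV at 17 significant digits; YAML configs
are for human editing and round-trip to near machine precision.

## Known limitations

- Short-term Lyapunov exponents from the chain disagree with brute force
  by construction (discretization discontinuities); no attempt is made to
  refine the mesh to rescue them.
- The chain's stored median-perturbation trajectory quantises
  within-transition variation; with the default grids the resulting bias
  is small relative to brute-force sampling SD, but it grows if the state
  grid is coarsened.
- MFPTs far beyond ~$10^{12}$ steps push $1-\lambda_2$ toward the limit
  of double precision; the bank avoids that regime deliberately.
- Whether the per-state weighted sums should include the failure column
  is not derivable from first principles here; failed transitions are
  excluded (no completed step exists to measure), and that choice is
  applied consistently on both the chain and brute-force sides.
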